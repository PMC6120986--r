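norm_line_labels <- function(obj, line_labels) {
  meta_lines <- if (is.null(line_labels)) obj$meta$line else line_labels
  if (!all(meta_lines %in% c("High", "Low")))
    stop('line labels must be "High" or "Low"', call. = FALSE)
  meta_lines
}

#' Exact negative-binomial test for differential expression
#'
#' Two-group test of equal means on raw counts, conditioning on the per-gene
#' sum of counts in the two lines. Library sizes are equalized by scaling each
#' sample's counts to the geometric mean of the upper-quartile-effective
#' library sizes (rounded pseudo-counts). Per-gene dispersions are estimated
#' by method of moments within each line, pooled, and shrunk 50/50 toward the
#' 20\%-trimmed mean of all genewise dispersions. Under the null the High-line
#' sum is negative binomial conditional on the total; the two-sided p-value
#' doubles the smaller tail (capped at 1).
#'
#' This is an approximation of the tagwise empirical-Bayes scheme of the
#' standard count-based DE packages, kept in-package so its calibration can be
#' audited directly; bit-exact parity with those packages is not a goal.
#'
#' @param counts a filtered \code{\link{count_matrix}}.
#' @param line_labels optional override of \code{counts$meta$line}.
#' @return data.frame: gene, log2fc (High vs Low, normalized means with a 0.5
#'   prior), pvalue, dispersion.
#' @export
de_test <- function(counts, line_labels = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  line <- norm_line_labels(counts, line_labels)
  n_high <- sum(line == "High"); n_low <- sum(line == "Low")
  if (n_high < 2 || n_low < 2)
    stop("each line needs at least 2 samples", call. = FALSE)
  y <- counts$counts
  lib <- colSums(y)
  uq <- upper_quartile_normalize(counts)
  eff_lib <- lib * uq$norm_factors
  common <- geometric_mean(eff_lib)
  pseudo <- round(sweep(y, 2, common / eff_lib, `*`))

  hi <- line == "High"; lo <- line == "Low"
  disp_mom <- function(mat) {
    m <- rowMeans(mat)
    v <- row_vars(mat)
    phi <- (v - m) / m^2
    phi[!is.finite(phi)] <- 0
    pmax(phi, 0)
  }
  phi_g <- (disp_mom(pseudo[, hi, drop = FALSE]) * (n_high - 1) +
            disp_mom(pseudo[, lo, drop = FALSE]) * (n_low - 1)) /
           (n_high + n_low - 2)
  phi_bar <- mean(phi_g[phi_g > 0], trim = 0.2)
  if (!is.finite(phi_bar)) phi_bar <- 0
  phi <- pmax(0.5 * phi_g + 0.5 * phi_bar, 1e-8)

  s_high <- rowSums(pseudo[, hi, drop = FALSE])
  s_low <- rowSums(pseudo[, lo, drop = FALSE])
  pval <- nb_exact_pvalue(s_high, s_low, n_high, n_low, phi)
  log2fc <- log2((s_high / n_high + 0.5) / (s_low / n_low + 0.5))
  data.frame(gene = rownames(y), log2fc = log2fc, pvalue = pval,
             dispersion = phi, stringsAsFactors = FALSE, row.names = NULL)
}

# Two-sided exact NB test p-values, vectorized over genes.
# s_a ~ sum of n_a NB(mu, 1/phi) samples, tested conditional on s_a + s_b.
nb_exact_pvalue <- function(s_a, s_b, n_a, n_b, phi) {
  t_tot <- s_a + s_b
  p <- rep(1, length(t_tot))
  for (g in which(t_tot > 0)) {
    tt <- t_tot[g]
    mu <- tt / (n_a + n_b)
    size_a <- n_a / phi[g]; size_b <- n_b / phi[g]
    center <- tt * n_a / (n_a + n_b)
    halfwidth <- ceiling(20 * sqrt(n_a * (mu + phi[g] * mu^2)) + 10)
    lo_s <- max(0, floor(center - halfwidth))
    hi_s <- min(tt, ceiling(center + halfwidth))
    if (s_a[g] < lo_s || s_a[g] > hi_s) { lo_s <- 0; hi_s <- tt }
    supp <- lo_s:hi_s
    logf <- stats::dnbinom(supp, size = size_a, mu = n_a * mu, log = TRUE) +
      stats::dnbinom(tt - supp, size = size_b, mu = n_b * mu, log = TRUE)
    f <- exp(logf - max(logf))
    f <- f / sum(f)
    obs <- s_a[g] - lo_s + 1
    p_lower <- sum(f[seq_len(obs)])
    p_upper <- sum(f[obs:length(f)])
    p[g] <- min(1, 2 * min(p_lower, p_upper))
  }
  p
}

#' F test for differential variability
#'
#' Per-gene ratio of sample variances (High / Low) of log expression, with
#' the two-sided p-value from the F distribution on
#' \code{(n_high - 1, n_low - 1)} degrees of freedom, exactly as the classic
#' variance-ratio test computes it. Genes with zero variance in either line
#' get \code{NA} statistics and an exclusion flag.
#'
#' @param expr an \code{expr_matrix}.
#' @param line_labels optional override of \code{expr$meta$line}.
#' @return data.frame: gene, f_statistic, pvalue, direction (line with the
#'   larger variance, \code{"none"} on exact ties), excluded.
#' @export
dv_test <- function(expr, line_labels = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  line <- norm_line_labels(expr, line_labels)
  n_high <- sum(line == "High"); n_low <- sum(line == "Low")
  if (n_high < 3 || n_low < 3)
    stop("each line needs at least 3 samples", call. = FALSE)
  v_high <- row_vars(expr$values[, line == "High", drop = FALSE])
  v_low <- row_vars(expr$values[, line == "Low", drop = FALSE])
  excluded <- v_high == 0 | v_low == 0
  f <- ifelse(excluded, NA_real_, v_high / v_low)
  pf_lower <- stats::pf(f, n_high - 1, n_low - 1)
  p <- 2 * pmin(pf_lower, 1 - pf_lower)
  p[excluded] <- NA_real_
  direction <- ifelse(is.na(f), NA_character_,
                      ifelse(f > 1, "High", ifelse(f < 1, "Low", "none")))
  data.frame(gene = rownames(expr$values), f_statistic = f, pvalue = p,
             direction = direction, excluded = excluded,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Sequential goodness-of-fit (SGoF) multiple-testing adjustment
#'
#' Binomial SGoF: with \code{F} of the \code{n} p-values at or below
#' \code{gamma}, the metatest asks whether \code{F} exceeds what a
#' Binomial(n, gamma) null allows at level \code{alpha}. Discoveries are
#' granted sequentially: while \code{P(Bin(n - i, gamma) >= F - i) <= alpha},
#' one more of the smallest p-values is declared significant and both counts
#' are decremented, so a batch in which every p-value is tiny is rejected in
#' full. \code{R = 0} whenever the initial metatest is not significant.
#'
#' The discovery-count rule lives entirely in this function so an alternative
#' SGoF variant can be swapped in.
#'
#' @param pvalues numeric vector in [0, 1] (NAs never count as discoveries).
#' @param gamma p-value threshold of the metatest (default 0.05).
#' @param alpha significance level of the metatest (default 0.05).
#' @return list: \code{n_discoveries} and logical \code{significant} marking
#'   exactly the R smallest p-values (ties broken by position).
#' @export
sgof_adjust <- function(pvalues, gamma = 0.05, alpha = 0.05) {
  stop_if_not_scalar_prob(gamma, "gamma")
  stop_if_not_scalar_prob(alpha, "alpha")
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  n <- sum(ok)
  flags <- rep(FALSE, length(pvalues))
  if (n == 0) return(list(n_discoveries = 0L, significant = flags))
  f_count <- sum(pvalues[ok] <= gamma)
  r <- 0L
  # epsilon guards the boundary case P == alpha against round-off
  while (r < f_count &&
         stats::pbinom(f_count - r - 1, n - r, gamma, lower.tail = FALSE) <=
           alpha + 1e-12)
    r <- r + 1L
  if (r > 0) {
    ord <- order(pvalues, na.last = NA)
    flags[ord[seq_len(r)]] <- TRUE
  }
  list(n_discoveries = r, significant = flags)
}

#' Line-specific correlation changes for every gene pair
#'
#' Pearson correlations per line for all unordered pairs of the network
#' genes, the Fisher z test of the correlation difference
#' \code{z = (atanh r_high - atanh r_low) / sqrt(1/(n_high-3) + 1/(n_low-3))}
#' (two-sided), and the "changed edge" call: correlation difference larger
#' than \code{delta_min} in absolute value AND z-test p below \code{p_max}.
#'
#' @param expr_high,expr_low \code{expr_matrix} objects (one line each) over
#'   the same genes; at least 5 samples per line.
#' @param genes optional subset (the culled network gene list).
#' @param delta_min minimum |r_high - r_low| (default 0.5).
#' @param p_max maximum z-test p (default 0.01).
#' @return list of class \code{"edge_change_set"}: genes, matrices
#'   \code{r_low}, \code{r_high}, \code{pvalue}, \code{changed}, counts and
#'   thresholds.
#' @export
edge_changes <- function(expr_high, expr_low, genes = NULL,
                         delta_min = 0.5, p_max = 0.01) {
  vh <- if (inherits(expr_high, "expr_matrix")) expr_high$values else expr_high
  vl <- if (inherits(expr_low, "expr_matrix")) expr_low$values else expr_low
  if (!is.null(genes)) {
    vh <- vh[genes, , drop = FALSE]; vl <- vl[genes, , drop = FALSE]
  }
  if (!identical(rownames(vh), rownames(vl)))
    stop("the two lines must cover the same genes in the same order",
         call. = FALSE)
  n_high <- ncol(vh); n_low <- ncol(vl)
  if (n_high <= 3 || n_low <= 3)
    stop("Fisher z needs more than 3 samples per line", call. = FALSE)
  if (n_high < 5 || n_low < 5)
    stop("need at least 5 samples per line", call. = FALSE)
  r_high <- stats::cor(t(vh)); r_low <- stats::cor(t(vl))
  clamp <- function(r) pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  z <- (atanh(clamp(r_high)) - atanh(clamp(r_low))) /
    sqrt(1 / (n_high - 3) + 1 / (n_low - 3))
  pval <- 2 * stats::pnorm(-abs(z))
  changed <- abs(r_high - r_low) > delta_min & pval < p_max
  diag(changed) <- FALSE
  structure(list(genes = rownames(vh), r_low = r_low, r_high = r_high,
                 pvalue = pval, changed = changed, n_low = n_low,
                 n_high = n_high, delta_min = delta_min, p_max = p_max),
            class = "edge_change_set")
}

#' Edge list view of an edge-change set
#'
#' @param x an \code{\link{edge_changes}} result.
#' @param ... unused.
#' @return data.frame with one row per unordered gene pair: gene_a, gene_b,
#'   r_low, r_high, delta_r, z_pvalue, changed.
#' @export
as.data.frame.edge_change_set <- function(x, ...) {
  ut <- upper.tri(x$r_low)
  idx <- which(ut, arr.ind = TRUE)
  out <- data.frame(gene_a = x$genes[idx[, 1]], gene_b = x$genes[idx[, 2]],
                    r_low = x$r_low[ut], r_high = x$r_high[ut],
                    delta_r = x$r_high[ut] - x$r_low[ut],
                    z_pvalue = x$pvalue[ut], changed = x$changed[ut],
                    stringsAsFactors = FALSE)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Per-gene differential wiring binomial test
#'
#' The network-wide incidence of changing edges (total changed edges over all
#' \code{N(N-1)/2} pairs) is the binomial rate; each gene's trials are its
#' \code{N - 1} incident edges and its successes its changed edges; the
#' p-value is the upper-tail exact binomial probability
#' \code{P(X >= successes)}, so a gene with no changed edges gets p = 1.
#'
#' @param changes an \code{\link{edge_changes}} result over >= 3 genes.
#' @return data.frame: gene, changed_edges, trials, rate, pvalue.
#' @export
dw_test <- function(changes) {
  stopifnot(inherits(changes, "edge_change_set"))
  n <- length(changes$genes)
  if (n < 3) stop("need at least 3 network genes", call. = FALSE)
  total_edges <- n * (n - 1) / 2
  if (total_edges == 0) stop("no edges in the network", call. = FALSE)
  successes <- rowSums(changes$changed)
  total_changed <- sum(successes) / 2
  rate <- total_changed / total_edges
  trials <- n - 1
  pval <- stats::pbinom(successes - 1, trials, rate, lower.tail = FALSE)
  data.frame(gene = changes$genes, changed_edges = as.integer(successes),
             trials = as.integer(trials), rate = rate, pvalue = pval,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Venn decomposition of per-region gene sets
#'
#' @param sets_by_region named list (>= 2 regions) of character vectors.
#' @return list: \code{cells} (named list of disjoint Venn-cell member
#'   vectors, names like \code{"A&B"}), \code{counts}, \code{pairwise}
#'   (intersection sizes), \code{common} (full intersection).
#' @export
overlap_sets <- function(sets_by_region) {
  stopifnot(is.list(sets_by_region), length(sets_by_region) >= 2,
            !is.null(names(sets_by_region)))
  regions <- names(sets_by_region)
  universe <- unique(unlist(sets_by_region))
  if (length(universe) == 0) {
    pairwise <- integer(0)
    for (i in seq_len(length(regions) - 1)) for (j in (i + 1):length(regions))
      pairwise[paste(regions[i], regions[j], sep = "&")] <- 0L
    return(list(cells = list(), counts = integer(0), pairwise = pairwise,
                common = character(0)))
  }
  membership <- vapply(sets_by_region, function(s) universe %in% s,
                       logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(universe, regions))
  key <- apply(membership, 1, function(row)
    paste(regions[row], collapse = "&"))
  cells <- split(universe, key)
  cells <- cells[names(cells) != ""]
  pairwise <- list()
  for (i in seq_len(length(regions) - 1)) for (j in (i + 1):length(regions))
    pairwise[[paste(regions[i], regions[j], sep = "&")]] <-
      length(intersect(sets_by_region[[i]], sets_by_region[[j]]))
  list(cells = cells,
       counts = vapply(cells, length, integer(1)),
       pairwise = unlist(pairwise),
       common = Reduce(intersect, sets_by_region))
}
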