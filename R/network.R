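#' Soft-thresholded coexpression adjacency
#'
#' Pearson correlations of log2-normalized expression across samples, raised
#' to the soft power \code{beta} (default 6). Unsigned networks use
#' \code{|r|^beta}; the signed option uses \code{((1 + r)/2)^beta}. The
#' diagonal is set to zero so connectivity sums never include self-edges.
#' Genes with zero variance carry no correlation information and are dropped
#' with a warning.
#'
#' @param expr an \code{expr_matrix} (or a plain genes x samples matrix).
#' @param beta positive soft-thresholding power.
#' @param signed use the signed transform instead of \code{|r|^beta}.
#' @return A list of class \code{"adjacency"}: \code{weights} (symmetric
#'   matrix in [0,1], zero diagonal), \code{genes}, \code{beta}, \code{signed}.
#' @export
adjacency <- function(expr, beta = 6, signed = FALSE) {
  values <- if (inherits(expr, "expr_matrix")) expr$values else expr
  stopifnot(is.matrix(values))
  if (ncol(values) < 4) stop("need at least 4 samples", call. = FALSE)
  if (beta <= 0) stop("beta must be positive", call. = FALSE)
  v <- row_vars(values)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene(s) dropped from the network")
    values <- values[v > 0, , drop = FALSE]
  }
  r <- stats::cor(t(values))
  w <- if (signed) ((1 + r) / 2)^beta else abs(r)^beta
  diag(w) <- 0
  structure(list(weights = w, genes = rownames(values), beta = beta,
                 signed = signed), class = "adjacency")
}

#' @export
print.adjacency <- function(x, ...) {
  cat(sprintf("adjacency: %d genes, beta = %g, %s\n", length(x$genes),
              x$beta, if (x$signed) "signed" else "unsigned"))
  invisible(x)
}

scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < 3) return(list(fit = NA_real_, slope = NA_real_, bins = 0L))
  cuts <- cut(k, breaks = n_bins)
  freq <- tapply(k, cuts, length)
  kmean <- tapply(k, cuts, mean)
  keep <- !is.na(freq) & freq > 0
  freq <- freq[keep]; kmean <- kmean[keep]
  if (length(freq) < 3) return(list(fit = NA_real_, slope = NA_real_,
                                    bins = length(freq)))
  fit <- stats::lm(log10(freq / sum(freq)) ~ log10(kmean))
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2]
  list(fit = -sign(slope) * r2, slope = unname(slope), bins = length(freq))
}

#' Scan soft powers for approximate scale-free topology
#'
#' For each candidate power, builds the adjacency, bins the connectivity
#' distribution and reports the signed R^2 of the log-log regression of bin
#' frequency on mean bin connectivity (positive when the slope is negative,
#' i.e. when high-connectivity genes are rare). The chosen power is the
#' smallest one whose fit reaches \code{fit_target}, falling back to the
#' power with the maximal fit.
#'
#' @param expr an \code{expr_matrix}.
#' @param powers candidate soft powers (>= 2 values).
#' @param fit_target signed R^2 considered an adequate scale-free fit.
#' @param signed passed to \code{\link{adjacency}}.
#' @return list with \code{beta} (chosen power) and \code{table}
#'   (data.frame power / fit / slope).
#' @export
soft_power_scan <- function(expr, powers = c(1:10, 12, 14, 16, 18, 20),
                            fit_target = 0.8, signed = FALSE) {
  if (length(powers) < 2) stop("need at least 2 candidate powers", call. = FALSE)
  base <- adjacency(expr, beta = 1, signed = signed)
  rows <- lapply(powers, function(p) {
    sf <- scale_free_fit(rowSums(base$weights^p))
    if (sf$bins < 3 && is.na(sf$fit))
      stop("fewer than 3 connectivity bins at power ", p, call. = FALSE)
    data.frame(power = p, fit = sf$fit, slope = sf$slope)
  })
  tab <- do.call(rbind, rows)
  ok <- which(tab$fit >= fit_target)
  beta <- if (length(ok) > 0) tab$power[ok[1]] else tab$power[which.max(tab$fit)]
  list(beta = beta, table = tab)
}

#' Cull a network to its most connected genes
#'
#' Two readings of "top 80\% by connectivity" are supported.
#' \code{"cumulative"} (default) sorts genes by total connectivity
#' descending and keeps the smallest prefix whose summed connectivity reaches
#' \code{fraction} of the total, i.e. the genes that together contribute that
#' share of network connectivity; this is the mode that reproduces a
#' ~15,000 to ~6,500 gene reduction on realistic data. \code{"quantile"}
#' keeps the top \code{ceiling(fraction * N)} genes by connectivity. Ties are
#' broken by ascending gene id; kept genes stay in their original order.
#'
#' @param adj an \code{\link{adjacency}}.
#' @param mode \code{"cumulative"} or \code{"quantile"}.
#' @param fraction in (0, 1].
#' @return The re-sliced \code{\link{adjacency}} (weights unchanged).
#' @export
cull_network <- function(adj, mode = c("cumulative", "quantile"), fraction = 0.8) {
  stopifnot(inherits(adj, "adjacency"))
  mode <- match.arg(mode)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]", call. = FALSE)
  k <- rowSums(adj$weights)
  ord <- order(-k, adj$genes)
  if (mode == "cumulative") {
    csum <- cumsum(k[ord])
    target <- fraction * sum(k)
    m <- if (sum(k) == 0) length(k) else which(csum >= target - 1e-12)[1]
  } else {
    m <- ceiling(fraction * length(k))
  }
  if (is.na(m) || m < 1) stop("culling produced an empty network", call. = FALSE)
  keep <- sort(ord[seq_len(m)])
  structure(list(weights = adj$weights[keep, keep, drop = FALSE],
                 genes = adj$genes[keep], beta = adj$beta, signed = adj$signed),
            class = "adjacency")
}

module_colors <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                   "black", "pink", "magenta", "purple", "greenyellow", "tan",
                   "salmon", "cyan", "midnightblue", "lightcyan", "grey60",
                   "lightgreen", "lightyellow", "royalblue")

# Relative height-gap needed to declare a split, indexed by deep_split 0..4.
# deep_split = 4 is the most aggressive (smallest gap suffices).
deep_split_gaps <- c(0.30, 0.20, 0.10, 0.05, 0.02)

#' Detect modules by average linkage and a dynamic hybrid cut
#'
#' Clusters the adjacency on the dissimilarity \code{1 - weight} with
#' average-linkage hierarchical clustering, then cuts the dendrogram in three
#' stages: (i) a static cut at \code{cut_height}; (ii) recursive refinement
#' inside each branch, splitting a merge when its relative height gap
#' \code{(h - max(child heights)) / h} reaches the \code{deep_split}-indexed
#' sensitivity (see \code{deep_split_gaps} in the source) and at least one
#' child could form a viable cluster; (iii) clusters smaller than
#' \code{min_cluster_size} are dissolved into \code{"unassigned"}, followed by
#' one PAM-like rescue pass that reassigns an unassigned gene to the module
#' with the highest mean adjacency when that mean both exceeds the gene's mean
#' adjacency to the unassigned set and reaches half the module's internal
#' density. Modules are labelled by decreasing size from a fixed color list.
#'
#' @param adj a culled \code{\link{adjacency}}.
#' @param cut_height static cut height on the dissimilarity dendrogram.
#' @param min_cluster_size smallest allowed module.
#' @param deep_split integer 0-4; 4 splits most aggressively.
#' @return A list of class \code{"module_partition"}: \code{assignment}
#'   (named character vector, label \code{"unassigned"} reserved) and
#'   \code{parameters}.
#' @export
detect_modules <- function(adj, cut_height = 0.9995, min_cluster_size = 100,
                           deep_split = 4) {
  stopifnot(inherits(adj, "adjacency"))
  if (!deep_split %in% 0:4) stop("deep_split must be an integer in 0..4",
                                 call. = FALSE)
  genes <- adj$genes
  n <- length(genes)
  params <- list(cut_height = cut_height, min_cluster_size = min_cluster_size,
                 deep_split = deep_split)
  if (n < min_cluster_size) {
    warning("fewer genes than min_cluster_size; everything unassigned")
    return(structure(list(assignment = stats::setNames(rep("unassigned", n), genes),
                          parameters = params), class = "module_partition"))
  }
  d <- 1 - adj$weights
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  gap_thr <- deep_split_gaps[deep_split + 1]

  nm <- nrow(hc$merge)
  members <- vector("list", nm)
  sizes <- integer(nm)
  for (i in seq_len(nm)) {
    a <- hc$merge[i, 1]; b <- hc$merge[i, 2]
    members[[i]] <- c(if (a < 0) -a else members[[a]],
                      if (b < 0) -b else members[[b]])
    sizes[i] <- length(members[[i]])
  }
  child_height <- function(j) if (j < 0) 0 else hc$height[j]
  labels <- integer(n)
  next_lab <- 0L
  stack <- nm
  while (length(stack) > 0) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (nd < 0) { next_lab <- next_lab + 1L; labels[-nd] <- next_lab; next }
    h <- hc$height[nd]
    a <- hc$merge[nd, 1]; b <- hc$merge[nd, 2]
    sa <- if (a < 0) 1L else sizes[a]
    sb <- if (b < 0) 1L else sizes[b]
    do_split <- FALSE
    if (h > cut_height) {
      do_split <- TRUE
    } else if (h > 0) {
      gap <- (h - max(child_height(a), child_height(b))) / h
      if (gap >= gap_thr && max(sa, sb) >= min_cluster_size) do_split <- TRUE
    }
    if (do_split) {
      stack <- c(stack, a, b)
    } else {
      next_lab <- next_lab + 1L
      labels[members[[nd]]] <- next_lab
    }
  }

  # dissolve undersized clusters
  tab <- table(labels)
  small <- as.integer(names(tab)[tab < min_cluster_size])
  labels[labels %in% small] <- 0L

  # PAM-like rescue pass (computed against the pre-rescue assignment)
  mods <- sort(unique(labels[labels > 0]))
  if (length(mods) > 0 && any(labels == 0)) {
    un <- which(labels == 0)
    mod_idx <- lapply(mods, function(m) which(labels == m))
    density <- vapply(mod_idx, function(ix)
      mean(adj$weights[ix, ix][upper.tri(matrix(0, length(ix), length(ix)))]),
      numeric(1))
    mean_to_mod <- vapply(mod_idx, function(ix)
      rowMeans(adj$weights[un, ix, drop = FALSE]), numeric(length(un)))
    mean_to_mod <- matrix(mean_to_mod, nrow = length(un))
    mean_to_un <- if (length(un) > 1)
      (rowSums(adj$weights[un, un, drop = FALSE])) / (length(un) - 1)
    else rep(0, length(un))
    best <- max.col(mean_to_mod, ties.method = "first")
    best_val <- mean_to_mod[cbind(seq_along(un), best)]
    move <- best_val > mean_to_un & best_val >= 0.5 * density[best]
    labels[un[move]] <- mods[best[move]]
  }

  # size-ranked color labels, ties by smallest member gene id
  tab <- table(labels[labels > 0])
  if (length(tab) > 0) {
    first_gene <- vapply(as.integer(names(tab)), function(m)
      min(genes[labels == m]), character(1))
    ord <- order(-as.integer(tab), first_gene)
    ranked <- as.integer(names(tab))[ord]
    color <- c(module_colors, sprintf("module%03d", seq_len(max(0, length(ranked) -
                                                     length(module_colors)))))
    map <- stats::setNames(color[seq_along(ranked)], as.character(ranked))
    assignment <- ifelse(labels == 0, "unassigned", map[as.character(labels)])
  } else {
    assignment <- rep("unassigned", n)
  }
  structure(list(assignment = stats::setNames(assignment, genes),
                 parameters = params), class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  tab <- sort(table(x$assignment), decreasing = TRUE)
  cat("module_partition:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                                 collapse = ", "), "\n")
  invisible(x)
}

#' Total, intramodular and normalized intramodular connectivity
#'
#' \code{k_total} is a gene's summed adjacency to all network genes,
#' \code{k_within} its summed adjacency to genes of its own module (the
#' unassigned set counts as its own group for \code{k_within} but is excluded
#' from hub calls), and \code{k_norm} is \code{k_within} divided by the
#' maximum \code{k_within} of the gene's module, so every non-empty module
#' has a gene at exactly 1. Size-1 groups get \code{k_norm = 0}.
#'
#' @param adj an \code{\link{adjacency}}.
#' @param partition a \code{\link{detect_modules}} partition covering the
#'   network genes.
#' @return data.frame of class \code{"connectivity_profile"}: gene, module,
#'   k_total, k_within, k_norm.
#' @export
intramodular_connectivity <- function(adj, partition) {
  stopifnot(inherits(adj, "adjacency"), inherits(partition, "module_partition"))
  lab <- partition$assignment[adj$genes]
  if (anyNA(lab)) stop("partition does not cover all network genes", call. = FALSE)
  k_total <- rowSums(adj$weights)
  k_within <- numeric(length(adj$genes))
  k_norm <- numeric(length(adj$genes))
  for (m in unique(lab)) {
    ix <- which(lab == m)
    kw <- rowSums(adj$weights[ix, ix, drop = FALSE])
    k_within[ix] <- kw
    k_norm[ix] <- if (length(ix) > 1 && max(kw) > 0) kw / max(kw) else 0
  }
  out <- data.frame(gene = adj$genes, module = unname(lab),
                    k_total = unname(k_total), k_within = k_within,
                    k_norm = k_norm, stringsAsFactors = FALSE)
  class(out) <- c("connectivity_profile", "data.frame")
  out
}

#' Module hub genes
#'
#' Genes with normalized intramodular connectivity above \code{threshold}
#' (default 0.8), excluding the unassigned set.
#'
#' @param profile an \code{\link{intramodular_connectivity}} result.
#' @param threshold hub cutoff on \code{k_norm}.
#' @return Character vector of gene ids.
#' @export
hub_genes <- function(profile, threshold = 0.8) {
  stopifnot(inherits(profile, "connectivity_profile"))
  profile$gene[profile$k_norm > threshold & profile$module != "unassigned"]
}
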