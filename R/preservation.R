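fisher_2x2_tails <- function(overlap, group_size, set_size, background_size) {
  # hypergeometric tails of the 2x2 table (enrichment / depletion, one-sided)
  p_enrich <- stats::phyper(overlap - 1, set_size, background_size - set_size,
                            group_size, lower.tail = FALSE)
  p_deplete <- stats::phyper(overlap, set_size, background_size - set_size,
                             group_size, lower.tail = TRUE)
  c(enrich = p_enrich, deplete = p_deplete)
}

#' Module enrichment and depletion in a gene set
#'
#' One 2x2 Fisher exact test per module against the network background: is
#' the overlap between the module and the gene set (e.g. the DE / DV / DW
#' genes at unadjusted p < 0.01) larger or smaller than chance? Both
#' one-sided tails are reported — the depletion tail is what identifies
#' modules conserved under selection — with Bonferroni correction over the
#' number of modules. The unassigned set is not a module but stays in the
#' background.
#'
#' @param partition a \code{module_partition}.
#' @param gene_set character vector (trimmed to the background).
#' @param background character vector of network genes; defaults to all genes
#'   of the partition.
#' @return data.frame: module, module_size, set_size, overlap, expected,
#'   odds_ratio, p_enrich, p_deplete, bonferroni_enrich, bonferroni_deplete.
#' @export
module_gene_set_enrichment <- function(partition, gene_set, background = NULL) {
  stopifnot(inherits(partition, "module_partition"))
  if (is.null(background)) background <- names(partition$assignment)
  if (length(background) == 0) stop("empty background", call. = FALSE)
  gene_set <- intersect(unique(gene_set), background)
  lab <- partition$assignment[background]
  modules <- setdiff(sort(unique(lab)), "unassigned")
  n_bg <- length(background)
  n_set <- length(gene_set)
  rows <- lapply(modules, function(m) {
    members <- background[lab == m]
    a <- length(intersect(members, gene_set))
    b <- length(members) - a
    c_ <- n_set - a
    d <- n_bg - length(members) - c_
    tails <- fisher_2x2_tails(a, length(members), n_set, n_bg)
    odds <- (a * d) / (b * c_)
    data.frame(module = m, module_size = length(members), set_size = n_set,
               overlap = a, expected = length(members) * n_set / n_bg,
               odds_ratio = odds, p_enrich = tails["enrich"],
               p_deplete = tails["deplete"], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_mod <- length(modules)
  out$bonferroni_enrich <- pmin(1, out$p_enrich * n_mod)
  out$bonferroni_deplete <- pmin(1, out$p_deplete * n_mod)
  out
}

#' Tabulation-based module preservation between two partitions
#'
#' Cross-tabulates the modules of two partitions over their shared gene
#' universe and scores every module pair's overlap with a one-sided Fisher
#' exact (hypergeometric) test, reported as -log10(p). A module of one region
#' is preserved in this sense when it has one or a few strongly overlapping
#' counterparts in the other region's partition.
#'
#' @param partition_a,partition_b \code{module_partition} objects.
#' @return list of class \code{"tabulation_preservation"}: \code{overlap},
#'   \code{fisher_p} and \code{neg_log10_p} matrices (rows = modules of A,
#'   columns = modules of B), plus \code{n_shared}.
#' @export
tabulation_preservation <- function(partition_a, partition_b) {
  stopifnot(inherits(partition_a, "module_partition"),
            inherits(partition_b, "module_partition"))
  shared <- intersect(names(partition_a$assignment), names(partition_b$assignment))
  if (length(shared) == 0) stop("no shared genes between partitions", call. = FALSE)
  la <- partition_a$assignment[shared]
  lb <- partition_b$assignment[shared]
  mods_a <- setdiff(sort(unique(la)), "unassigned")
  mods_b <- setdiff(sort(unique(lb)), "unassigned")
  n <- length(shared)
  overlap <- matrix(0L, length(mods_a), length(mods_b),
                    dimnames = list(mods_a, mods_b))
  fisher_p <- matrix(1, length(mods_a), length(mods_b),
                     dimnames = list(mods_a, mods_b))
  for (i in seq_along(mods_a)) for (j in seq_along(mods_b)) {
    sa <- sum(la == mods_a[i]); sb <- sum(lb == mods_b[j])
    ov <- sum(la == mods_a[i] & lb == mods_b[j])
    overlap[i, j] <- ov
    fisher_p[i, j] <- stats::phyper(ov - 1, sb, n - sb, sa, lower.tail = FALSE)
  }
  structure(list(overlap = overlap, fisher_p = fisher_p,
                 neg_log10_p = -log10(pmax(fisher_p, .Machine$double.xmin)),
                 n_shared = n),
            class = "tabulation_preservation")
}

#' Permutation Zsummary module preservation
#'
#' For each module of network A, two statistics measure whether its genes
#' stay densely interconnected in network B: the density statistic (mean
#' within-module adjacency in B) and the connectivity statistic (correlation,
#' over module genes, of within-module connectivity in A and in B). Each is
#' standardized against a permutation null of random same-size gene sets
#' drawn from all shared network genes, and the composite
#' \code{z_summary} is the median of the two Z scores (one Z alone is used
#' when the other is undefined, e.g. identical networks give a degenerate
#' connectivity null). Interpretation follows the usual bars: below 2 not
#' preserved, 2-10 preserved, above 10 highly preserved.
#'
#' @param adj_a,adj_b \code{\link{adjacency}} objects sharing genes.
#' @param partition_a modules detected in network A.
#' @param n_permutations permutation count for the null (>= 2; default 200).
#' @param seed integer seed for the permutation stream.
#' @return data.frame of class \code{"zsummary_preservation"}: module, size,
#'   z_density, z_connectivity, z_summary, interpretation.
#' @export
zsummary_preservation <- function(adj_a, adj_b, partition_a,
                                  n_permutations = 200, seed = 1L) {
  stopifnot(inherits(adj_a, "adjacency"), inherits(adj_b, "adjacency"),
            inherits(partition_a, "module_partition"))
  if (n_permutations < 2)
    stop("need at least 2 permutations for a null", call. = FALSE)
  shared <- intersect(adj_a$genes, adj_b$genes)
  if (length(shared) < 3) stop("fewer than 3 shared genes", call. = FALSE)
  wa <- adj_a$weights[match(shared, adj_a$genes), match(shared, adj_a$genes)]
  wb <- adj_b$weights[match(shared, adj_b$genes), match(shared, adj_b$genes)]
  lab <- partition_a$assignment[shared]
  modules <- setdiff(sort(unique(lab)), "unassigned")
  set.seed(seed)

  mod_stats <- function(idx) {
    ka <- rowSums(wa[idx, idx, drop = FALSE])
    kb <- rowSums(wb[idx, idx, drop = FALSE])
    dens <- sum(kb) / (length(idx) * (length(idx) - 1))
    conn <- suppressWarnings(stats::cor(ka, kb))
    c(density = dens, connectivity = conn)
  }
  rows <- list()
  for (m in modules) {
    idx <- which(lab == m)
    if (length(idx) < 3) {
      warning("module ", m, " has fewer than 3 shared genes; skipped")
      next
    }
    obs <- mod_stats(idx)
    null_mat <- vapply(seq_len(n_permutations), function(i)
      mod_stats(sample(length(shared), length(idx))), numeric(2))
    zify <- function(o, nul) {
      nul <- nul[is.finite(nul)]
      if (length(nul) < 2) return(NA_real_)
      s <- stats::sd(nul)
      # a (numerically) constant null carries no information
      if (!is.finite(s) || s <= 1e-8 * max(1, abs(mean(nul)))) return(NA_real_)
      (o - mean(nul)) / s
    }
    z_den <- if (is.finite(obs["density"]))
      zify(obs["density"], null_mat["density", ]) else NA_real_
    z_con <- if (is.finite(obs["connectivity"]))
      zify(obs["connectivity"], null_mat["connectivity", ]) else NA_real_
    zs <- stats::median(c(z_den, z_con), na.rm = TRUE)
    rows[[m]] <- data.frame(module = m, size = length(idx),
                            z_density = z_den, z_connectivity = z_con,
                            z_summary = zs, stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(module = character(0), size = integer(0),
               z_density = numeric(0), z_connectivity = numeric(0),
               z_summary = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$interpretation <- cut(out$z_summary, c(-Inf, 2, 10, Inf),
                            labels = c("not_preserved", "preserved",
                                       "highly_preserved"))
  class(out) <- c("zsummary_preservation", "data.frame")
  out
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated format: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("malformed GMT line ", i, ": need name, description, >=1 gene",
           call. = FALSE)
    sets[[parts[1]]] <- unique(parts[-(1:2)])
  }
  sets
}

#' Gene-set (GMT) enrichment of a gene list
#'
#' One-sided Fisher exact (hypergeometric) enrichment of the list in each
#' gene set, sets trimmed to the background, Benjamini-Hochberg FDR across
#' sets. A generic stand-in for annotation-database enrichment tools.
#'
#' @param gene_list character vector (trimmed to the background).
#' @param gmt a GMT file path or a named list of gene sets.
#' @param background character vector of testable genes.
#' @return data.frame: set, set_size, overlap, expected, odds_ratio, pvalue,
#'   fdr; ordered by p-value.
#' @export
gmt_enrichment <- function(gene_list, gmt, background) {
  if (length(background) == 0) stop("empty background", call. = FALSE)
  sets <- if (is.character(gmt) && length(gmt) == 1) read_gmt(gmt) else gmt
  stopifnot(is.list(sets), !is.null(names(sets)))
  gene_list <- intersect(unique(gene_list), background)
  n_bg <- length(background)
  n_list <- length(gene_list)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], background)
    a <- length(intersect(s, gene_list))
    b <- n_list - a
    c_ <- length(s) - a
    d <- n_bg - n_list - c_
    data.frame(set = nm, set_size = length(s), overlap = a,
               expected = length(s) * n_list / n_bg,
               odds_ratio = (a * d) / (b * c_),
               pvalue = stats::phyper(a - 1, length(s), n_bg - length(s),
                                      n_list, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$pvalue, method = "BH")
  out <- out[order(out$pvalue, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
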