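#' Line-specific connectivity profiles under shared modules
#'
#' Recomputes the adjacency separately from each line's samples at the same
#' soft power and evaluates normalized intramodular connectivity under the
#' module assignment obtained from the combined-sample network, so hub status
#' can be compared between the High and Low lines gene by gene.
#'
#' @param expr_high,expr_low \code{expr_matrix} objects (>= 5 samples each)
#'   over the partition's genes.
#' @param partition the combined-network \code{module_partition}.
#' @param beta soft power (default 6).
#' @param signed passed to \code{\link{adjacency}}.
#' @return list with elements \code{high} and \code{low}, each a
#'   \code{connectivity_profile}.
#' @export
line_connectivity <- function(expr_high, expr_low, partition, beta = 6,
                              signed = FALSE) {
  vh <- if (inherits(expr_high, "expr_matrix")) expr_high$values else expr_high
  vl <- if (inherits(expr_low, "expr_matrix")) expr_low$values else expr_low
  if (ncol(vh) < 5 || ncol(vl) < 5)
    stop("need at least 5 samples per line", call. = FALSE)
  genes <- intersect(names(partition$assignment), rownames(vh))
  genes <- intersect(genes, rownames(vl))
  if (length(genes) == 0) stop("no genes shared with the partition", call. = FALSE)
  prof <- function(v) {
    adj <- adjacency(v[genes, , drop = FALSE], beta = beta, signed = signed)
    intramodular_connectivity(adj, partition)
  }
  list(high = prof(vh), low = prof(vl))
}

#' Paired test of an intramodular connectivity shift between lines
#'
#' Compares normalized intramodular connectivity of a gene set between the
#' two line-specific profiles with a paired two-sided Wilcoxon signed-rank
#' test (an exact sign-flip permutation test of the mean difference is used
#' below 5 genes). Genes are paired by id; identical profiles give p = 1.
#'
#' @param profile_high,profile_low \code{connectivity_profile} objects.
#' @param gene_set genes to compare (must appear in both profiles).
#' @return list: mean_high, mean_low, n, pvalue, method.
#' @export
connectivity_shift_test <- function(profile_high, profile_low, gene_set) {
  kh <- profile_high$k_norm[match(gene_set, profile_high$gene)]
  kl <- profile_low$k_norm[match(gene_set, profile_low$gene)]
  if (anyNA(kh) || anyNA(kl))
    stop("gene_set contains genes absent from a profile", call. = FALSE)
  d <- kh - kl
  n <- length(d)
  if (all(d == 0)) {
    return(list(mean_high = mean(kh), mean_low = mean(kl), n = n,
                pvalue = 1, method = "degenerate (no differences)"))
  }
  if (n < 5) {
    warning("fewer than 5 genes; using an exact sign-flip permutation test")
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null_means <- abs(signs %*% abs(d)) / n
    p <- mean(null_means >= abs(mean(d)) - 1e-12)
    method <- "exact permutation"
  } else {
    p <- stats::wilcox.test(kh, kl, paired = TRUE, exact = FALSE)$p.value
    method <- "wilcoxon signed-rank"
  }
  list(mean_high = mean(kh), mean_low = mean(kl), n = n, pvalue = p,
       method = method)
}

#' Hub-status transitions between lines
#'
#' Classifies genes whose normalized intramodular connectivity crosses the
#' hub threshold between lines: \code{gained_hub} when
#' \code{k_low <= threshold < k_high}, \code{lost_hub} symmetrically. Sorted
#' by the absolute connectivity change, largest first.
#'
#' @param profile_high,profile_low \code{connectivity_profile} objects
#'   sharing genes.
#' @param threshold hub cutoff on k_norm (default 0.8).
#' @return data.frame: gene, k_low, k_high, class.
#' @export
hub_transitions <- function(profile_high, profile_low, threshold = 0.8) {
  genes <- intersect(profile_high$gene, profile_low$gene)
  kh <- profile_high$k_norm[match(genes, profile_high$gene)]
  kl <- profile_low$k_norm[match(genes, profile_low$gene)]
  gained <- kl <= threshold & kh > threshold
  lost <- kh <= threshold & kl > threshold
  out <- data.frame(gene = genes, k_low = kl, k_high = kh,
                    class = ifelse(gained, "gained_hub",
                                   ifelse(lost, "lost_hub", NA_character_)),
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$class), , drop = FALSE]
  out <- out[order(-abs(out$k_high - out$k_low), out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Core grouping of counterpart affected modules across regions
#'
#' Takes one designated (affected) module per region and returns the genes of
#' the smallest designated module that are members of the designated modules
#' of every other region, together with per-region overlap fractions.
#'
#' @param partitions named list (region -> \code{module_partition}).
#' @param affected_module_per_region named list/vector (region -> module
#'   label); every region must be designated.
#' @return list: core_genes, reference_region (smallest designated module),
#'   fractions (per other region: share of the reference module found in that
#'   region's designated module), sizes.
#' @export
core_module_grouping <- function(partitions, affected_module_per_region) {
  regions <- names(partitions)
  missing_reg <- setdiff(regions, names(affected_module_per_region))
  if (length(missing_reg) > 0)
    stop("missing affected-module designation for region(s): ",
         paste(missing_reg, collapse = ", "), call. = FALSE)
  member_sets <- lapply(regions, function(r) {
    lab <- partitions[[r]]$assignment
    names(lab)[lab == affected_module_per_region[[r]]]
  })
  names(member_sets) <- regions
  sizes <- vapply(member_sets, length, integer(1))
  if (any(sizes == 0))
    stop("designated module empty in region(s): ",
         paste(regions[sizes == 0], collapse = ", "), call. = FALSE)
  ref <- regions[which.min(sizes)]
  core <- member_sets[[ref]]
  for (r in setdiff(regions, ref)) core <- intersect(core, member_sets[[r]])
  fractions <- vapply(setdiff(regions, ref), function(r)
    length(intersect(member_sets[[ref]], member_sets[[r]])) / sizes[ref],
    numeric(1))
  list(core_genes = sort(core), reference_region = ref,
       fractions = fractions, sizes = sizes)
}

#' Integrated priority gene screen across regions
#'
#' Reproduces the hub-based screening logic at the top of the pipeline:
#' (1) the genes called differentially variable (after SGoF adjustment) in
#' every region; (2) the genes that are module hubs (\code{k_norm} above the
#' hub threshold) in every region's combined-sample network; (3) the core
#' grouping of the per-region affected modules (each region's module most
#' enriched in DV genes unless designated explicitly). The priority genes are
#' the three-way intersection, ordered by their maximum normalized
#' connectivity across regions (then gene id).
#'
#' @param diff_tables named list (region -> data.frame with columns gene,
#'   dv_pvalue, dv_sig).
#' @param profiles named list (region -> \code{connectivity_profile} from the
#'   combined-sample network).
#' @param partitions named list (region -> \code{module_partition}).
#' @param hub_threshold k_norm cutoff for hub status (default 0.8).
#' @param affected_modules optional named designation (region -> module
#'   label); by default the module with the smallest Bonferroni-corrected
#'   DV-enrichment p-value (DV genes at unadjusted p < 0.01) in each region.
#' @param dv_enrich_p unadjusted DV p cutoff used to build the enrichment
#'   input sets (default 0.01).
#' @return list of class \code{"screen_result"}: common_dv,
#'   cross_region_hubs, core_module_genes, affected_modules, priority_genes,
#'   evidence (per-priority-gene statistics).
#' @export
priority_screen <- function(diff_tables, profiles, partitions,
                            hub_threshold = 0.8, affected_modules = NULL,
                            dv_enrich_p = 0.01) {
  regions <- names(diff_tables)
  for (nm in list(profiles, partitions))
    if (!setequal(names(nm), regions))
      stop("diff_tables, profiles and partitions must cover the same regions: ",
           paste(regions, collapse = ", "), call. = FALSE)
  regions <- sort(regions)

  dv_sets <- lapply(diff_tables, function(tb) tb$gene[tb$dv_sig %in% TRUE])
  common_dv <- sort(Reduce(intersect, dv_sets))

  hub_sets <- lapply(regions, function(r) {
    pr <- profiles[[r]]
    pr$gene[pr$k_norm > hub_threshold & pr$module != "unassigned"]
  })
  cross_hubs <- sort(Reduce(intersect, hub_sets))

  if (is.null(affected_modules)) {
    affected_modules <- lapply(regions, function(r) {
      tb <- diff_tables[[r]]
      dv_raw <- tb$gene[!is.na(tb$dv_pvalue) & tb$dv_pvalue < dv_enrich_p]
      enr <- module_gene_set_enrichment(partitions[[r]], dv_raw)
      enr$module[order(enr$bonferroni_enrich, enr$p_enrich)][1]
    })
    names(affected_modules) <- regions
  }
  core <- core_module_grouping(partitions, affected_modules)

  priority <- Reduce(intersect, list(common_dv, cross_hubs, core$core_genes))
  if (length(priority) > 0) {
    max_k <- vapply(priority, function(g)
      max(vapply(regions, function(r) {
        pr <- profiles[[r]]
        pr$k_norm[match(g, pr$gene)]
      }, numeric(1))), numeric(1))
    priority <- priority[order(-max_k, priority)]
    evidence <- do.call(rbind, lapply(priority, function(g) {
      data.frame(gene = g,
                 region = regions,
                 k_norm = vapply(regions, function(r)
                   profiles[[r]]$k_norm[match(g, profiles[[r]]$gene)], numeric(1)),
                 module = vapply(regions, function(r)
                   profiles[[r]]$module[match(g, profiles[[r]]$gene)], character(1)),
                 dv_pvalue = vapply(regions, function(r) {
                   tb <- diff_tables[[r]]
                   tb$dv_pvalue[match(g, tb$gene)]
                 }, numeric(1)),
                 stringsAsFactors = FALSE)
    }))
    rownames(evidence) <- NULL
  } else {
    evidence <- data.frame(gene = character(0), region = character(0),
                           k_norm = numeric(0), module = character(0),
                           dv_pvalue = numeric(0), stringsAsFactors = FALSE)
  }
  structure(list(common_dv = common_dv,
                 cross_region_hubs = cross_hubs,
                 core_module_genes = core$core_genes,
                 core_fractions = core$fractions,
                 affected_modules = affected_modules,
                 priority_genes = priority,
                 evidence = evidence),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(paste0("screen_result: %d common DV, %d cross-region hubs, ",
                     "%d core module genes -> %d priority gene(s)\n"),
              length(x$common_dv), length(x$cross_region_hubs),
              length(x$core_module_genes), length(x$priority_genes)))
  if (length(x$priority_genes) > 0)
    cat("priority:", paste(x$priority_genes, collapse = ", "), "\n")
  invisible(x)
}
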