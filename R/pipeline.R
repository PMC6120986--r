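#' Pipeline configuration
#'
#' Collects every stage parameter of the differential-coexpression pipeline
#' with its standard default, plus the per-region inputs. Regions are given
#' either as file paths (\code{list(counts = ..., metadata = ...)}) or as
#' in-memory \code{\link{count_matrix}} objects.
#'
#' @param regions named list, one entry per region.
#' @param out_dir output directory for the report bundle (NULL: nothing
#'   written).
#' @param min_cpm mean-CPM expression threshold (default 1).
#' @param beta soft power (default 6).
#' @param signed signed adjacency flag (default FALSE).
#' @param cull_mode,cull_fraction connectivity culling rule (default
#'   cumulative 0.8, see \code{\link{cull_network}}).
#' @param cut_height,min_cluster_size,deep_split dynamic hybrid cut
#'   parameters (defaults 0.9995, 100, 4).
#' @param hub_threshold normalized connectivity hub cutoff (default 0.8).
#' @param delta_min,edge_p changed-edge thresholds (defaults 0.5, 0.01).
#' @param sgof_gamma,sgof_alpha SGoF parameters (defaults 0.05, 0.05).
#' @param adjust_dw apply SGoF to the DW binomial p-values as well (default
#'   TRUE; set FALSE to flag on raw p < 0.05).
#' @param enrich_p unadjusted p cutoff for the module-enrichment input gene
#'   sets (default 0.01).
#' @param zsummary_permutations permutations for the Zsummary null (default
#'   200).
#' @param region_fold fold-difference threshold for the cross-region
#'   expression report (default 10).
#' @param seed root seed for all stochastic stages.
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(regions, out_dir = NULL, min_cpm = 1, beta = 6,
                            signed = FALSE, cull_mode = "cumulative",
                            cull_fraction = 0.8, cut_height = 0.9995,
                            min_cluster_size = 100, deep_split = 4,
                            hub_threshold = 0.8, delta_min = 0.5,
                            edge_p = 0.01, sgof_gamma = 0.05,
                            sgof_alpha = 0.05, adjust_dw = TRUE,
                            enrich_p = 0.01, zsummary_permutations = 200,
                            region_fold = 10, seed = 1L) {
  if (!is.list(regions) || length(regions) == 0 || is.null(names(regions)) ||
      any(!nzchar(names(regions))))
    stop("regions must be a non-empty named list", call. = FALSE)
  for (r in names(regions)) {
    reg <- regions[[r]]
    if (inherits(reg, "count_matrix")) next
    if (!is.list(reg) || !all(c("counts", "metadata") %in% names(reg)))
      stop("region '", r, "' must be a count_matrix or list(counts, metadata)",
           call. = FALSE)
    for (p in unlist(reg[c("counts", "metadata")]))
      if (!file.exists(p))
        stop("region '", r, "': file not found: ", p, call. = FALSE)
  }
  cfg <- list(regions = regions, out_dir = out_dir, min_cpm = min_cpm,
              beta = beta, signed = signed, cull_mode = cull_mode,
              cull_fraction = cull_fraction, cut_height = cut_height,
              min_cluster_size = min_cluster_size, deep_split = deep_split,
              hub_threshold = hub_threshold, delta_min = delta_min,
              edge_p = edge_p, sgof_gamma = sgof_gamma,
              sgof_alpha = sgof_alpha, adjust_dw = adjust_dw,
              enrich_p = enrich_p,
              zsummary_permutations = zsummary_permutations,
              region_fold = region_fold, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# One region: preprocess -> network -> DE/DV/DW -> SGoF flags -> enrichment.
analyze_region <- function(counts, cfg) {
  filtered <- filter_by_cpm(counts, cfg$min_cpm)
  expr <- upper_quartile_normalize(filtered)
  adj <- adjacency(expr, beta = cfg$beta, signed = cfg$signed)
  culled <- cull_network(adj, mode = cfg$cull_mode, fraction = cfg$cull_fraction)
  partition <- detect_modules(culled, cut_height = cfg$cut_height,
                              min_cluster_size = cfg$min_cluster_size,
                              deep_split = cfg$deep_split)
  profile <- intramodular_connectivity(culled, partition)

  line <- expr$meta$line
  de <- de_test(filtered)
  dv <- dv_test(expr)
  hi_samples <- expr$meta$sample_id[line == "High"]
  lo_samples <- expr$meta$sample_id[line == "Low"]
  changes <- edge_changes(subset_expr(expr, culled$genes, hi_samples),
                          subset_expr(expr, culled$genes, lo_samples),
                          delta_min = cfg$delta_min, p_max = cfg$edge_p)
  dw <- dw_test(changes)

  tab <- data.frame(gene = de$gene, de_log2fc = de$log2fc,
                    de_pvalue = de$pvalue, stringsAsFactors = FALSE)
  tab$dv_f_statistic <- dv$f_statistic[match(tab$gene, dv$gene)]
  tab$dv_pvalue <- dv$pvalue[match(tab$gene, dv$gene)]
  tab$dv_direction <- dv$direction[match(tab$gene, dv$gene)]
  tab$dw_changed_edges <- dw$changed_edges[match(tab$gene, dw$gene)]
  tab$dw_trials <- dw$trials[match(tab$gene, dw$gene)]
  tab$dw_pvalue <- dw$pvalue[match(tab$gene, dw$gene)]
  tab$de_sig <- sgof_adjust(tab$de_pvalue, cfg$sgof_gamma, cfg$sgof_alpha)$significant
  tab$dv_sig <- sgof_adjust(tab$dv_pvalue, cfg$sgof_gamma, cfg$sgof_alpha)$significant
  tab$dw_sig <- if (cfg$adjust_dw)
    sgof_adjust(tab$dw_pvalue, cfg$sgof_gamma, cfg$sgof_alpha)$significant
  else !is.na(tab$dw_pvalue) & tab$dw_pvalue < 0.05

  enrich_sets <- list(
    DE = tab$gene[!is.na(tab$de_pvalue) & tab$de_pvalue < cfg$enrich_p],
    DV = tab$gene[!is.na(tab$dv_pvalue) & tab$dv_pvalue < cfg$enrich_p],
    DW = tab$gene[!is.na(tab$dw_pvalue) & tab$dw_pvalue < cfg$enrich_p])
  enrichment <- do.call(rbind, lapply(names(enrich_sets), function(s) {
    e <- module_gene_set_enrichment(partition, enrich_sets[[s]],
                                    background = culled$genes)
    if (nrow(e) > 0) cbind(statistic = s, e) else NULL
  }))

  hub_profiles <- line_connectivity(
    subset_expr(expr, culled$genes, hi_samples),
    subset_expr(expr, culled$genes, lo_samples),
    partition, beta = cfg$beta, signed = cfg$signed)
  transitions <- hub_transitions(hub_profiles$high, hub_profiles$low,
                                 threshold = cfg$hub_threshold)

  list(filtered = filtered, expr = expr, adjacency = culled,
       adjacency_full = adj,
       partition = partition, profile = profile, diff = tab,
       changes = changes, enrichment = enrichment,
       line_profiles = hub_profiles, hub_transitions = transitions)
}

#' Run the full differential-coexpression pipeline
#'
#' Per region: CPM filtering, upper-quartile normalization, soft-thresholded
#' network with connectivity culling, dynamic hybrid module detection,
#' DE / DV / DW statistics with SGoF adjustment, module enrichment and
#' line-specific connectivity. Across regions: affected-gene overlaps,
#' tabulation and permutation-Zsummary module preservation, and the
#' integrated priority gene screen. When \code{out_dir} is set, all tables
#' plus a JSON/markdown report (with every parameter echoed) are written;
#' reruns with the same config and seed produce byte-identical files.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return Invisibly, the full result bundle (per-region results,
#'   cross-region overlaps, preservation, screen, report list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  regions <- names(config$regions)
  per_region <- lapply(regions, function(r) {
    reg <- config$regions[[r]]
    counts <- if (inherits(reg, "count_matrix")) reg else
      read_counts(reg$counts, reg$metadata)
    res <- tryCatch(analyze_region(counts, config), error = function(e)
      stop("stage failure in region '", r, "': ", conditionMessage(e),
           call. = FALSE))
    res
  })
  names(per_region) <- regions

  sig_sets <- function(col) lapply(per_region, function(x)
    x$diff$gene[x$diff[[col]] %in% TRUE])
  overlaps <- if (length(regions) >= 2)
    list(DE = overlap_sets(sig_sets("de_sig")),
         DV = overlap_sets(sig_sets("dv_sig")),
         DW = overlap_sets(sig_sets("dw_sig")))
  else NULL

  fold_diffs <- if (length(regions) >= 2)
    region_fold_differences(lapply(per_region, `[[`, "expr"),
                            fold = config$region_fold)
  else NULL

  preservation <- list()
  if (length(regions) >= 2) {
    pair_id <- 0L
    for (a in regions) for (b in setdiff(regions, a)) {
      pair_id <- pair_id + 1L
      preservation[[paste(a, b, sep = "_vs_")]] <- list(
        tabulation = tabulation_preservation(per_region[[a]]$partition,
                                             per_region[[b]]$partition),
        # preservation on the full (pre-cull) adjacency: the permutation
        # null needs the background genes the culled network strips away
        zsummary = zsummary_preservation(per_region[[a]]$adjacency_full,
                                         per_region[[b]]$adjacency_full,
                                         per_region[[a]]$partition,
                                         n_permutations = config$zsummary_permutations,
                                         seed = derive_seed(config$seed, pair_id)))
    }
  }

  screen <- if (length(regions) >= 2)
    priority_screen(lapply(per_region, `[[`, "diff"),
                    lapply(per_region, `[[`, "profile"),
                    lapply(per_region, `[[`, "partition"),
                    hub_threshold = config$hub_threshold,
                    dv_enrich_p = config$enrich_p)
  else NULL

  report <- list(
    parameters = config[setdiff(names(config), c("regions", "out_dir"))],
    regions = lapply(per_region, function(x) list(
      n_genes_expressed = nrow(x$filtered$counts),
      n_genes_network = length(x$adjacency$genes),
      n_samples = ncol(x$filtered$counts),
      modules = as.list(table(x$partition$assignment)),
      n_de = sum(x$diff$de_sig, na.rm = TRUE),
      n_dv = sum(x$diff$dv_sig, na.rm = TRUE),
      n_dw = sum(x$diff$dw_sig, na.rm = TRUE))),
    overlaps = if (!is.null(overlaps))
      lapply(overlaps, function(o) as.list(o$counts)) else NULL,
    priority_genes = if (!is.null(screen)) screen$priority_genes else NULL)

  bundle <- list(per_region = per_region, overlaps = overlaps,
                 fold_differences = fold_diffs, preservation = preservation,
                 screen = screen, report = report, config = config)
  if (!is.null(config$out_dir)) write_report_bundle(bundle, config$out_dir)
  invisible(bundle)
}

write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- bundle$config
  for (r in names(bundle$per_region)) {
    x <- bundle$per_region[[r]]
    write_tsv(x$diff, file.path(out_dir, paste0("diff_results_", r, ".tsv")))
    write_tsv(data.frame(gene = names(x$partition$assignment),
                         module = unname(x$partition$assignment),
                         stringsAsFactors = FALSE),
              file.path(out_dir, paste0("modules_", r, ".tsv")))
    write_tsv(x$profile, file.path(out_dir, paste0("connectivity_", r, ".tsv")))
    if (!is.null(x$enrichment))
      write_tsv(x$enrichment, file.path(out_dir, paste0("enrichment_", r, ".tsv")))
    con <- gzfile(file.path(out_dir, paste0("edge_changes_", r, ".tsv.gz")), "wb")
    utils::write.table(as.data.frame(x$changes), con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    close(con)
  }
  for (nm in names(bundle$preservation)) {
    pres <- bundle$preservation[[nm]]
    write_tsv(as.data.frame(pres$tabulation$neg_log10_p),
              file.path(out_dir, paste0("preservation_tabulation_", nm, ".tsv")))
    write_tsv(pres$zsummary,
              file.path(out_dir, paste0("preservation_z_", nm, ".tsv")))
  }
  if (!is.null(bundle$overlaps)) {
    jsonlite::write_json(lapply(bundle$overlaps, function(o)
      list(cells = o$cells, common = o$common)),
      file.path(out_dir, "venn.json"), auto_unbox = FALSE, digits = NA)
  }
  if (!is.null(bundle$fold_differences))
    write_tsv(bundle$fold_differences,
              file.path(out_dir, "region_fold_differences.tsv"))
  if (!is.null(bundle$screen)) {
    write_tsv(bundle$screen$evidence, file.path(out_dir, "priority_evidence.tsv"))
  }
  jsonlite::write_json(bundle$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  md <- c("# Differential coexpression pipeline report", "",
          "## Parameters", "",
          sprintf("- %s: %s", names(bundle$report$parameters),
                  vapply(bundle$report$parameters, function(p)
                    paste(format(p), collapse = ", "), character(1))),
          "", "## Regions", "")
  for (r in names(bundle$report$regions)) {
    reg <- bundle$report$regions[[r]]
    md <- c(md, sprintf(
      "- %s: %d expressed genes, %d network genes, %d samples; DE=%d DV=%d DW=%d",
      r, reg$n_genes_expressed, reg$n_genes_network, reg$n_samples,
      reg$n_de, reg$n_dv, reg$n_dw))
  }
  if (!is.null(bundle$report$priority_genes)) {
    md <- c(md, "", "## Priority genes", "",
            if (length(bundle$report$priority_genes) > 0)
              paste("-", bundle$report$priority_genes) else "(none)")
  }
  md <- c(md, "",
          paste("Note: the connectivity-shift p-values treat genes as",
                "independent observations, which coexpressed genes are not;",
                "interpret them as descriptive."))
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}
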