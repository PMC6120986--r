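#!/usr/bin/env Rscript

# Stage 4: module enrichment and cross-region module preservation.
#
# Per region: Fisher enrichment/depletion of each module in the DE/DV/DW
# gene sets at unadjusted p < 0.01 (the enrichment-input threshold), with
# Bonferroni correction over modules. Across regions: tabulation-based
# preservation (-log10 Fisher p of module overlaps) and the permutation
# Zsummary composite on the per-region adjacencies.

suppressPackageStartupMessages(library(coexdiff))

fix_dir <- "results/fixtures"
net_dir <- "results/network"
diff_dir <- "results/differential"
out_dir <- "results/preservation"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
regions <- list.dirs(fix_dir, recursive = FALSE, full.names = FALSE)

parts <- list(); adjs <- list()
for (r in regions) {
  mods <- read.delim(file.path(net_dir, paste0("modules_", r, ".tsv")))
  parts[[r]] <- structure(list(
    assignment = setNames(mods$module, mods$gene),
    parameters = list(cut_height = 0.9995, min_cluster_size = 30,
                      deep_split = 4)), class = "module_partition")
  ex <- read.delim(file.path(net_dir, paste0("expr_", r, ".tsv")),
                   check.names = FALSE)
  vals <- as.matrix(ex[, -1]); rownames(vals) <- ex$gene
  # full (pre-cull) adjacency: the Zsummary permutation null needs the
  # background genes the culled network strips away
  adjs[[r]] <- adjacency(vals, beta = 6)

  diff <- read.delim(file.path(diff_dir, paste0("diff_results_", r, ".tsv")))
  enr_all <- list()
  for (s in c("de", "dv", "dw")) {
    gene_set <- diff$gene[!is.na(diff[[paste0(s, "_pvalue")]]) &
                            diff[[paste0(s, "_pvalue")]] < 0.01]
    enr <- module_gene_set_enrichment(parts[[r]], gene_set,
                                      background = mods$gene)
    enr_all[[s]] <- cbind(statistic = toupper(s), enr)
    top <- enr[which.min(enr$bonferroni_enrich), ]
    cat(sprintf("%s %s: most-enriched module %s (overlap %d/%d, Bonferroni p %.2g)\n",
                r, toupper(s), top$module, top$overlap, top$module_size,
                top$bonferroni_enrich))
  }
  write.table(do.call(rbind, enr_all),
              file.path(out_dir, paste0("enrichment_", r, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

for (a in regions) for (b in setdiff(regions, a)) {
  tag <- paste(a, "vs", b, sep = "_")
  tp <- tabulation_preservation(parts[[a]], parts[[b]])
  zs <- zsummary_preservation(adjs[[a]], adjs[[b]], parts[[a]],
                              n_permutations = 200,
                              seed = 7L + match(a, regions) * 10L +
                                match(b, regions))
  write.table(as.data.frame(tp$neg_log10_p),
              file.path(out_dir, paste0("tabulation_", tag, ".tsv")),
              sep = "\t", quote = FALSE)
  write.table(zs, file.path(out_dir, paste0("zsummary_", tag, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: Zsummary %s\n", tag,
              paste(sprintf("%s=%.1f (%s)", zs$module, zs$z_summary,
                            zs$interpretation), collapse = ", ")))
}
cat("Preservation tables in", out_dir, "\n")
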