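#!/usr/bin/env Rscript

# Stage 1: simulate the three-region, two-line study with planted truth.
#
# One shared ground truth (module membership, DE/DV/DW gene and edge sets,
# six planted priority genes) and one count matrix per brain-region analog,
# written as plain-text fixtures under results/fixtures/. Every later stage
# starts from these files, so the whole analysis can be reproduced from here.

suppressPackageStartupMessages(library(coexdiff))

out_dir <- "results/fixtures"
seed <- 20180828L

cfg <- simulation_config(n_genes = 600, n_modules = 3, module_size = 100,
                         n_samples_per_line = 40, n_priority = 6, seed = seed)
truth <- generate_truth(cfg)
regions <- simulate_region_set(truth, regions = c("SHx", "CEAx", "PLx"))

for (r in names(regions))
  write_fixture(truth, regions[[r]], file.path(out_dir, r))

cat("Simulated", length(regions), "regions x", cfg$n_genes, "genes x",
    2 * cfg$n_samples_per_line, "samples (seed", seed, ")\n")
cat("Planted:", nrow(truth$de_genes), "DE genes,", nrow(truth$dv_genes),
    "DV genes,", length(truth$dw_genes), "rewired genes (",
    nrow(truth$dw_edges), "edges ),", length(truth$priority_genes),
    "priority genes:", paste(truth$priority_genes, collapse = ", "), "\n")
cat("Fixtures in", out_dir, "\n")
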