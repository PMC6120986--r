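# coexdiff

Differential coexpression-network analysis for two selectively bred lines
profiled by bulk RNA-seq across several brain regions.

Selection experiments (e.g., High vs Low ethanol-preference lines bred from
genetically diverse founders) often change the brain transcriptome in ways
that ordinary differential expression barely sees: mean shifts are small and
scattered, while the *variability* of genes and the *wiring* of the
coexpression network — which genes correlate with which — shift profoundly
and reproducibly. `coexdiff` implements that three-pronged analysis as a
tested, reusable pipeline, together with a synthetic-data generator that
plants all of the effects with a recorded ground truth so every stage can be
scored against what was actually simulated.

## What it computes

Per region, from a gene × sample count matrix with line labels:

* **Preprocessing** — mean-CPM > 1 expression filter; upper-quartile
  normalization to log2 CPM.
* **Network** — unsigned soft-thresholded adjacency `a_ij = |cor(x_i, x_j)|^β`
  with β = 6 (scale-free fit scan included); culling to the genes carrying
  80% of total connectivity; average-linkage clustering of `1 − a` with a
  dynamic hybrid tree cut (cutHeight 0.9995, minClusterSize 100, deepSplit 4);
  intramodular connectivity `k_within` and its normalized form
  `k_norm ∈ [0, 1]`, with hubs at `k_norm > 0.8`.
* **DE** — exact negative-binomial test conditional on the per-gene count
  total, with moment dispersions shrunk toward the genewise trimmed mean.
* **DV** — variance-ratio F test `F = s²_High / s²_Low` on log expression,
  two-sided.
* **DW** — per gene pair, line-specific Pearson correlations and the Fisher
  z test of their difference; an edge "changes" when `|Δr| > 0.5` and
  z-p < 0.01; per gene, the exact upper binomial tail
  `P(X ≥ changed edges)` with trials `N − 1` and the network-wide changing
  rate as the binomial rate.
* **Multiple testing** — binomial sequential goodness-of-fit (SGoF) at
  γ = α = 0.05 for all three statistics.
* **Module level** — Fisher enrichment/depletion of modules in affected-gene
  sets (Bonferroni over modules); cross-region module preservation by
  tabulation (−log10 Fisher p of partition overlaps) and by a permutation
  Zsummary (median of density and connectivity Z scores; preserved > 2,
  highly preserved > 10); generic GMT gene-set enrichment with BH FDR.
* **Screen** — line-specific connectivity under shared modules, paired
  Wilcoxon connectivity-shift test, hub transitions between lines, the core
  grouping of per-region affected modules, and the priority gene list:
  common-DV ∩ cross-region hubs ∩ core module genes.

The generator (`simulation_config()`, `generate_truth()`,
`simulate_expression()`, `simulate_region_set()`, `write_fixture()`)
produces negative-binomial counts from a Gaussian latent-factor model with
planted modules, mean shifts, variance inflation, correlation rewiring and
priority genes; see the methods vignette (`vignettes/methods.Rmd`) for the
model and every default.

## Worked example

```r
library(coexdiff)

cfg    <- simulation_config(n_priority = 6, seed = 1)  # 600 genes, 3 modules
truth  <- generate_truth(cfg)
counts <- simulate_expression(truth, region = "SH")
counts
#> count_matrix: 600 genes x 80 samples (High=40, Low=40)

expr    <- upper_quartile_normalize(filter_by_cpm(counts))
net     <- cull_network(adjacency(expr, beta = 6))
modules <- detect_modules(net, min_cluster_size = 30)
modules
#> module_partition: turquoise=68, blue=63, brown=58

adjusted_rand_index(modules$assignment, truth$module_assignment[net$genes])
#> [1] 1

dv     <- dv_test(expr)
called <- dv$gene[sgof_adjust(dv$pvalue)$significant]
length(called)                                    # 28 DV calls ...
length(intersect(called, truth$dv_genes$gene))    # ... all 28 are planted (of 44)

profile <- intramodular_connectivity(net, modules)
head(hub_genes(profile), 8)
#> [1] "g00001" "g00002" "g00003" "g00004" "g00005" "g00006" "g00062" "g00103"
```

The three modules are recovered exactly (adjusted Rand index 1); the 28
SGoF-significant DV genes are all planted ones; the six planted priority
genes (`g00001`–`g00006`, hub loading 0.95 with a strong variance response)
head the hub list.

## The full analysis

`analysis/` contains numbered drivers that run the whole study on a
simulated three-region fixture and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R               # 3 regions x 600 genes, planted truth
Rscript analysis/02_preprocess_network.R     # filter, normalize, network, modules
Rscript analysis/03_differential.R           # DE / DV / DW + SGoF + Venn overlaps
Rscript analysis/04_preservation_enrichment.R# module enrichment + preservation
Rscript analysis/05_screen.R                 # line connectivity + priority screen
```

On the default fixture the drivers report, among other things: module
recovery at ARI 1.000 in all three regions; planted rewired genes inside
the top DW-p-value decile in every region; the affected module's DV genes
raising their mean intramodular connectivity from ≈ 0.4 (Low) to ≈ 0.8
(High) with Wilcoxon p ≈ 1e-06; counterpart affected modules highly
preserved across regions (Zsummary ≈ 39–50); and the screen returning
exactly the six planted priority genes.

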