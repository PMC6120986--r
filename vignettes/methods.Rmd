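---
title: "Differential coexpression analysis of selected lines: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential coexpression analysis of selected lines: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`coexdiff` implements a differential coexpression-network workflow for
comparing two selectively bred lines (here called High and Low) across
several brain regions from bulk RNA-seq gene counts. The workflow asks three
questions per gene — did selection change its mean expression (DE), its
expression variability (DV), or its pattern of correlations with other genes
(DW, "differential wiring")? — and then integrates the answers at the level
of coexpression modules: which modules are enriched in affected genes, how
well is module structure preserved across regions, and which genes are
simultaneously strong module hubs and differentially variable in every
region. Because such studies' raw data are rarely available at desk scale,
the package ships a synthetic-data generator that plants all of these
effects with a recorded ground truth, and every statistical claim in the
test suite is made against that truth or against an independent oracle.

# Preprocessing

Counts enter as a genes-by-samples integer matrix with sample metadata
(line, region, sex). Three steps mirror standard practice:

* **Expression threshold.** Genes with mean CPM (counts per million) at or
  below 1 are removed; only strictly greater passes. The filter is applied
  per region, on raw CPM, before normalization.
* **Upper-quartile normalization.** Each sample's scaling factor is the 75th
  percentile (linear interpolation) of its library-size-scaled counts over
  genes with nonzero total, rescaled so the factors have geometric mean 1.
  The method only names the quantile; the estimator and the rescaling are
  our choices, pinned by two invariances the tests assert: factors are
  unchanged when the whole matrix is multiplied by a constant, and two
  samples that are exact scalar multiples normalize to identical columns.
  The latter also forces the log pseudocount (default 0.5) to be scaled by
  each sample's effective library size.
* **Log transform.** Correlations and variance tests run on
  `log2((count + pc) / (factor * libsize) * 1e6)`. Pearson correlation on
  raw counts would be dominated by abundance.

# Network construction

The adjacency between genes *i* and *j* is `|cor(x_i, x_j)|^beta` with
`beta = 6` (unsigned by default; a signed variant `((1+r)/2)^beta` is
available behind a flag). `soft_power_scan()` reports, per candidate power,
the signed R² of the log–log regression of binned connectivity frequency on
connectivity — the usual scale-free topology check.

The network is then **culled** to its most connected genes. Two readings of
"top 80% by connectivity" exist and both are implemented: the default
*cumulative* mode keeps the smallest prefix of genes (sorted by total
connectivity) that together carry 80% of total network connectivity — the
reading consistent with a roughly 15,000 → 6,500 gene reduction on real
data — while *quantile* mode keeps the top `ceiling(0.8 N)` genes. Ties
break by ascending gene id everywhere, for determinism.

**Module detection** clusters `1 - adjacency` with average linkage and cuts
the tree in a dynamic-hybrid style with the conventional parameters
(`cut_height = 0.9995`, `min_cluster_size = 100`, `deep_split = 4`):

1. a static cut at `cut_height`;
2. recursive refinement inside each branch: a merge is split when its
   relative height gap `(h - max(child heights)) / h` reaches a
   `deep_split`-indexed sensitivity (0.30, 0.20, 0.10, 0.05, 0.02 for
   levels 0–4) and at least one child is large enough to stand as a module;
3. clusters below `min_cluster_size` dissolve into `"unassigned"`, followed
   by one rescue pass that reassigns an unassigned gene to its
   best-matching module when its mean adjacency there both exceeds its mean
   adjacency to the unassigned set *and* reaches half that module's
   internal density. The second condition matters: for a background gene
   the first comparison is noise against noise, and without the density
   floor roughly half of the unstructured genes would be assigned to
   modules at random.

This re-implementation preserves the three published parameters and the
observable behavior (separable blocks are recovered exactly; an all-zero
adjacency yields only `"unassigned"`; planted modules are recovered with
median ARI 1.0 at loading 0.8); exact equivalence with the reference
hybrid-cut implementation is explicitly not a goal. Average-linkage chaining
can still assemble weak clusters out of background noise just under the cut
height; they are genuine clustering artifacts, they carry low internal
density, and downstream preservation statistics correctly score them as
unpreserved.

Intramodular connectivity `k_within` is a gene's summed adjacency to its
module mates (no self-edges); the normalized version `k_norm` divides by the
module maximum, and genes with `k_norm > 0.8` are *hubs*.

# Differential statistics

**DE.** A two-group exact negative-binomial test conditional on the
per-gene sum of counts. Library sizes are equalized by scaling counts to the
geometric mean of the upper-quartile effective library sizes (rounded
pseudo-counts). Per-gene dispersions are method-of-moments estimates pooled
across the two lines and shrunk 50/50 toward the 20%-trimmed mean of all
genewise dispersions; the two-sided p-value doubles the smaller conditional
tail. This is a deliberately transparent approximation of the tagwise
empirical-Bayes exact test of the standard count packages — close enough
that p-values correlate above 0.9 with that reference on simulated data
(a unit test), and calibrated: the empirical type-I error at α = 0.05 on an
all-null NB simulation of 10,000 genes is within a percentage point of
nominal. Bit-exact parity with the reference package is not a goal.

**DV.** The classic variance-ratio test: `F = var(High) / var(Low)` on log
expression, two-sided p from the F distribution; a unit test asserts exact
per-gene agreement with `stats::var.test`. Note the test assumes
near-Gaussian values; on counts the log transform satisfies this well for
moderately expressed genes, and the simulated fixtures keep expressed genes
at realistic depth for that reason.

**DW.** For every unordered pair of network genes, per-line Pearson
correlations and the Fisher z test of their difference
(`z = (atanh r_H - atanh r_L) / sqrt(1/(n_H-3) + 1/(n_L-3))`, two-sided; the
paper behind the procedure states only the thresholds, not the test, so
Fisher z is our documented choice). An edge *changes* when `|r_H - r_L| >
0.5` **and** z-p < 0.01 — a conjunction, so an overwhelming z with a small
correlation delta does not count. Per gene, the binomial test then asks
whether it carries a disproportionate share of changing edges: the rate is
the network-wide incidence of changing edges over all `N(N-1)/2` pairs
(the network is treated as a complete weighted graph; no edge-presence
cutoff exists), trials are the gene's `N - 1` incident edges, successes its
changing edges, and the p-value the exact upper binomial tail.

**SGoF adjustment.** All three p-value families are adjusted by binomial
sequential goodness-of-fit with `gamma = alpha = 0.05`. With `F` of `n`
p-values at or below `gamma`, discoveries are granted while
`P(Bin(n - i, gamma) >= F - i) <= alpha`, decrementing both counts, so a
batch of uniformly tiny p-values is rejected in full; `R = 0` whenever the
initial metatest fails, which bounds the weak familywise error by `alpha`.
Variants that subtract a fixed binomial quantile from `F` exist in the
literature; the rule is isolated in one function so it can be swapped.
Whether DW p-values receive the same adjustment as DE/DV is not fixed by
the source procedure; we adjust them identically by default
(`adjust_dw = FALSE` switches to raw p < 0.05). Headline gene lists use the
adjusted calls; module-enrichment input sets use unadjusted p < 0.01, the
dual-threshold convention of the original analysis.

# Module-level integration

**Enrichment.** Per module, a 2×2 Fisher exact test of overlap with a gene
set against the network background, with both one-sided tails reported —
the depletion tail is what identifies modules *conserved* under selection —
and Bonferroni correction over the number of modules. Gene-set (GMT)
enrichment for annotation collections uses the same hypergeometric machinery
with Benjamini–Hochberg FDR across sets.

**Tabulation preservation.** The module partitions of two regions are
cross-tabulated over shared genes and each cell scored by a one-sided
Fisher test, reported as −log10 p; a module is preserved in this sense when
it has one or few strong counterparts.

**Zsummary preservation.** For each module of network A, a density
statistic (mean within-module adjacency in B) and a connectivity statistic
(correlation of intramodular connectivity between A and B over module
genes), each standardized against a permutation null of random same-size
gene sets drawn from all shared network genes; the composite is the median
of the two Z scores, with the conventional interpretation bars at 2 and 10.
This is a deliberate simplification of the reference implementation's larger
statistic menu — agreement is directional (classification behavior), not
numeric. Two practical notes baked into the design: identical networks make
the connectivity null degenerate (every permuted set has correlation 1), so
a numerically constant null is treated as uninformative and the composite
falls back to the remaining statistic; and the permutation null needs
background genes to be meaningful, so preservation is computed on the full
pre-cull adjacency — a culled network contains little but module genes, and
random "null" sets then overlap the modules themselves.

**Line connectivity and the screen.** Line-specific adjacencies are
recomputed from each line's samples at the same β under the combined-sample
module assignment; shifts in `k_norm` over a gene set are tested with a
paired two-sided Wilcoxon signed-rank test (genes are not independent —
the report flags the p-values as descriptive; below 5 genes an exact
sign-flip permutation test is used). Hub transitions are genes crossing the
0.8 bar between lines. The priority screen intersects three gene sets:
common DV genes (SGoF-adjusted, all regions), cross-region hubs
(`k_norm > 0.8` in every region), and the core grouping of the per-region
affected modules — each region's module designated by the smallest
Bonferroni DV-enrichment p (overridable), intersected starting from the
smallest designated module. The result is ordered by maximal `k_norm`, then
gene id, and the intersection property is assertable on every run.

# The synthetic-data generator

The generator emulates the study design — two selected lines, several brain
regions, tens of samples per line, correlated gene modules on an
unstructured background — with a Gaussian latent-factor model on the log
scale feeding negative-binomial counts:

* gene *g*, sample *s*: latent deviation
  `x_gs = sigma_g (lambda_g f_m(s) + sqrt(1 - lambda_g^2) e_gs)`;
  module genes share the factor `f_m`, so within-module latent correlation
  is `lambda_i lambda_j` (default loading 0.8);
* expected counts `mu = a_g exp(x) L_s / L0` with lognormal abundances
  `a_g` and uniform library sizes; observed counts are NB with dispersion
  0.05 on top of the modeled biological variance (the NB dispersion here is
  the technical/residual component, which is why it sits below typical
  tagwise estimates that absorb all biological variance);
* **DE**: High-line mean multiplied by `2^±1` for 5% of genes, drawn from
  the background so they stay low-connectivity leaves (as DE genes were
  observed to be);
* **DV**: 7.4% of genes (the observed DV rate per networked genes in the
  motivating study, 479/6,500) get their High-line log-scale variance
  multiplied by 4. Module genes realize the inflation through a boosted
  factor loading — raising their High-line intramodular connectivity along
  with their variance, the empirical signature of the affected modules —
  while background DV genes scale their idiosyncratic signal. A
  compensating mean factor `exp(-(ratio-1) sigma^2 / 2)` keeps DV a pure
  variance effect on the count scale. 70% of DV genes sit in module 1, the
  "affected" module, mirroring the single-module concentration seen in
  data;
* **DW**: a small set of *rewired* genes per module load on an alternative
  module factor in the Low line and the true factor in the High line, so
  every rewired-by-unrewired pair moves from r ≈ 0 to r ≈ loading² — a
  detectable change of ≈ 0.6. The recorded edge set is exactly
  `round(dw_fraction × within-module pairs)`, split by largest remainders.
  A per-edge pair-factor scheme was considered and rejected: with module
  loading 0.8 a unit-variance pair factor on an intact module loading can
  shift r by at most 0.36, below the 0.5 detection threshold, and edges
  sharing genes make per-edge targets unattainable anyway;
* **priority genes**: `n_priority` genes of module 1 planted as the joint
  extreme the screen targets — hub loading 0.95 and variance ratio 6.
  The screen looks for genes at the intersection of strong hubness and
  strong variance response; planting them as exactly that is what makes
  "the screen recovers the planted priority genes" a meaningful test;
* **multi-region studies** reuse one truth with region-specific seeds
  derived deterministically from the root seed (one linear-congruential
  step per region), so planted sets are shared and expression noise is not.

Three desk-scale corrections deserve explanation because they are about
emulating *genome-scale* data with hundreds of genes, not about the model:

1. **Mass partition.** Module genes hold 20% of library mass
   (`module_mass_share`), the background the rest. In a 600-gene matrix an
   unconstrained split lets the module factors move the library total
   itself, imprinting spurious compositional correlations (r ≈ −0.2
   between modules) on CPM values; in real 15,000-gene libraries modules
   are a sliver of mass and this artifact is negligible.
2. **Quiet background.** Background genes use a lower biological log-sd
   (0.4 vs 0.8), as housekeeping-heavy high-abundance genes do; this also
   keeps the upper-quartile statistic — an order statistic over only a few
   hundred genes here — from tracking the module factors.
3. **Per-line factor standardization.** Factor vectors are standardized to
   zero mean and unit variance within each line, so the single factor draw
   of a finite simulation carries no random line-level variance offset.
   Without this, all ~100 genes of a module shift their F statistics
   together by luck of the draw — a module-level batch effect the
   variance-ratio test cannot distinguish from planted DV — and both the
   sensitivity and the false-discovery proportion of DV recovery become
   erratic. Real data do carry such shared fluctuations; passing recovery
   tests on the standardized generator therefore demonstrates correctness
   of the statistics, not robustness to correlated biological noise.

What the generator does **not** emulate: sex effects, batch effects,
region-specific expression baselines (regions differ only by noise
realization), gene-length effects, read-level noise, or annotation
structure. Recovery results on fixtures bound what the pipeline can do on
clean planted signal; they do not certify performance on real tissue.

# Problem sizes and numerical choices

Simulated fixtures use 600 genes (3 modules × 100) for network-level
checks and 2,000 genes for genome-scale DV recovery. The two DV-gated
recovery fixtures (DV sensitivity and the priority screen) use 60 samples
per line — SGoF's excess-counting discovery rule needs strong per-gene
power before sensitivity targets become attainable — while network and
wiring checks run at 40 per line; both sit inside the 54–71
samples-per-region range of the motivating study once split over two lines.
`min_cluster_size` is scaled to 30 on 100-gene-module fixtures (the
real-data default of 100 assumes 6,500-gene networks). Zsummary uses 200
permutations in analyses and 100 in tests. Determinism is enforced
throughout: one root seed per study, derived per-region streams,
tie-breaking by gene id, and byte-identical pipeline outputs under a fixed
configuration (a test asserts this with checksums). Truth objects round
their real-valued fields to 12 significant digits so the JSON fixture
serialization round-trips bit-exactly. Correlations are clamped away from
±1 before `atanh`; conditional NB tails are evaluated on a ±20-sd window
in log space; a numerically constant permutation null yields `NA` rather
than an unbounded Z.

# Known limitations

* The hybrid tree cut and the exact NB test are transparent
  re-implementations matched on behavior, not bit-for-bit ports of their
  reference implementations.
* The variance-ratio test inherits its Gaussian assumption; very
  low-count genes show mildly heavy-tailed F statistics on count data.
* The Wilcoxon connectivity-shift p-values treat genes as independent
  observations, which coexpressed genes are not.
* Zsummary here is a two-statistic composite; absolute values are not
  comparable with the reference implementation's composite, only the
  preserved / not-preserved classification is.
* Memory scales as the square of the network gene count (dense matrices);
  the intended scale is desk-size fixtures and networks up to a few
  thousand genes.
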