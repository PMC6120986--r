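test_that("line-specific connectivity reflects planted loading changes", {
  # identical line sample sets -> identical profiles
  set.seed(51)
  m <- matrix(rnorm(40 * 20), 40, 20,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:20)))
  part <- toy_partition(setNames(rep(c("blue", "brown"), each = 20),
                                 rownames(m)))
  lp <- line_connectivity(toy_expr(m), toy_expr(m), part)
  expect_equal(lp$high, lp$low)
  expect_error(line_connectivity(toy_expr(m[, 1:4]), toy_expr(m), part),
               "5 samples")

  # planted High-line loading increase (module DV genes) raises k_norm(High)
  wins <- vapply(1:10, function(s) {
    cfg <- simulation_config(n_genes = 300, n_modules = 1, module_size = 80,
                             dv_fraction = 0.1, dv_module_share = 1,
                             de_fraction = 0, dw_fraction = 0, seed = 60 + s)
    tr <- generate_truth(cfg)
    cm <- simulate_expression(tr, "R1")
    expr <- upper_quartile_normalize(filter_by_cpm(cm))
    net_genes <- intersect(names(tr$module_assignment)[
      tr$module_assignment == "M1"], rownames(expr$values))
    part1 <- toy_partition(setNames(rep("blue", length(net_genes)), net_genes))
    hi <- expr$meta$sample_id[expr$meta$line == "High"]
    lo <- expr$meta$sample_id[expr$meta$line == "Low"]
    lp1 <- line_connectivity(coexdiff:::subset_expr(expr, net_genes, hi),
                             coexdiff:::subset_expr(expr, net_genes, lo),
                             part1)
    dvg <- intersect(tr$dv_genes$gene, net_genes)
    mean(lp1$high$k_norm[match(dvg, lp1$high$gene)]) >
      mean(lp1$low$k_norm[match(dvg, lp1$low$gene)])
  }, logical(1))
  expect_gte(sum(wins), 9)
})

test_that("connectivity shift test behaves on degenerate and shifted inputs", {
  prof <- function(k) {
    out <- data.frame(gene = sprintf("g%02d", seq_along(k)), module = "blue",
                      k_total = k, k_within = k, k_norm = k,
                      stringsAsFactors = FALSE)
    class(out) <- c("connectivity_profile", "data.frame")
    out
  }
  set.seed(52)
  k <- runif(30, 0.2, 0.6)
  expect_equal(connectivity_shift_test(prof(k), prof(k), sprintf("g%02d", 1:30))$pvalue, 1)
  up <- connectivity_shift_test(prof(k + 0.3), prof(k), sprintf("g%02d", 1:30))
  expect_gt(up$mean_high, up$mean_low)
  expect_lt(up$pvalue, 1e-5)
  # below 5 genes: exact sign-flip permutation test
  expect_warning(
    small <- connectivity_shift_test(prof(k[1:4] + 0.2), prof(k[1:4]),
                                     sprintf("g%02d", 1:4)),
    "permutation")
  expect_equal(small$method, "exact permutation")
  expect_equal(small$pvalue, 2 / 16)  # all-positive shifts: both sign patterns
})

test_that("connectivity shift test keeps its nominal size on null profiles", {
  set.seed(53)
  rej <- vapply(1:500, function(i) {
    kh <- runif(30); kl <- kh + rnorm(30, 0, 0.1)
    kl <- pmin(pmax(kl, 0), 1)
    p <- suppressWarnings(stats::wilcox.test(kh, kl, paired = TRUE,
                                             exact = FALSE)$p.value)
    p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("hub transitions classify threshold crossings exactly", {
  mk <- function(genes, k) {
    out <- data.frame(gene = genes, module = "blue", k_total = k,
                      k_within = k, k_norm = k, stringsAsFactors = FALSE)
    class(out) <- c("connectivity_profile", "data.frame")
    out
  }
  genes <- c("Ntrk2", "steady_hub", "lost", "leaf")
  ph <- mk(genes, c(0.821, 0.95, 0.30, 0.10))
  pl <- mk(genes, c(0.197, 0.85, 0.88, 0.15))
  ht <- hub_transitions(ph, pl, 0.8)
  expect_equal(ht$class[ht$gene == "Ntrk2"], "gained_hub")
  expect_equal(ht$class[ht$gene == "lost"], "lost_hub")
  expect_false("steady_hub" %in% ht$gene)  # hub in both lines
  expect_false("leaf" %in% ht$gene)
  expect_equal(ht$gene[1], "Ntrk2")        # largest |change| first

  # brute-force rule oracle on random profiles
  set.seed(54)
  g <- sprintf("g%02d", 1:60)
  kh <- runif(60); kl <- runif(60)
  ht2 <- hub_transitions(mk(g, kh), mk(g, kl), 0.8)
  oracle_gain <- g[kl <= 0.8 & kh > 0.8]
  oracle_lost <- g[kh <= 0.8 & kl > 0.8]
  expect_setequal(ht2$gene[ht2$class == "gained_hub"], oracle_gain)
  expect_setequal(ht2$gene[ht2$class == "lost_hub"], oracle_lost)
})

test_that("core module grouping intersects designated modules across regions", {
  genes <- sprintf("g%03d", 1:120)
  pa <- toy_partition(setNames(rep(c("blue", "grey"), c(40, 80)), genes))
  # identical partitions -> the module itself
  core0 <- core_module_grouping(list(A = pa, B = pa),
                                list(A = "blue", B = "blue"))
  expect_setequal(core0$core_genes, genes[1:40])
  expect_equal(unname(core0$fractions), 1)

  # disjoint designated modules -> empty core
  pb <- toy_partition(setNames(rep(c("grey", "red"), c(40, 80)), genes))
  expect_length(core_module_grouping(list(A = pa, B = pb),
                                     list(A = "blue", B = "red"))$core_genes, 0)

  # ~80% membership sharing across three regions
  set.seed(55)
  shared <- genes[1:32]                    # 80% of the smallest module
  pa2 <- toy_partition(setNames(ifelse(genes %in% genes[1:40], "m", "grey"),
                                genes))
  mk <- function(extra) toy_partition(setNames(
    ifelse(genes %in% c(shared, extra), "m", "grey"), genes))
  pb2 <- mk(genes[61:88])
  pc2 <- mk(genes[81:110])
  core <- core_module_grouping(list(A = pa2, B = pb2, C = pc2),
                               list(A = "m", B = "m", C = "m"))
  expect_setequal(core$core_genes, shared)
  expect_lt(max(abs(core$fractions - 0.8)), 0.05)
  expect_error(core_module_grouping(list(A = pa2, B = pb2),
                                    list(A = "m")), "missing")
})

test_that("the priority screen returns exactly the planted cross-region DV hubs", {
  cfg <- simulation_config(n_priority = 6, n_samples_per_line = 60, seed = 1)
  tr <- generate_truth(cfg)
  cms <- simulate_region_set(tr)
  diffs <- list(); profs <- list(); parts <- list()
  for (r in names(cms)) {
    net <- network_from_counts(cms[[r]])
    dv <- dv_test(net$expr)
    sg <- sgof_adjust(dv$pvalue)
    diffs[[r]] <- data.frame(gene = dv$gene, dv_pvalue = dv$pvalue,
                             dv_sig = sg$significant, stringsAsFactors = FALSE)
    profs[[r]] <- intramodular_connectivity(net$adj, net$partition)
    parts[[r]] <- net$partition
  }
  sc <- priority_screen(diffs, profs, parts)
  expect_setequal(sc$priority_genes, tr$priority_genes)
  # the intersection property holds by construction
  expect_true(all(sc$priority_genes %in% sc$common_dv))
  expect_true(all(sc$priority_genes %in% sc$cross_region_hubs))
  expect_true(all(sc$priority_genes %in% sc$core_module_genes))
  # permuting the region order changes nothing
  sc2 <- priority_screen(diffs[c(3, 1, 2)], profs[c(3, 1, 2)], parts[c(3, 1, 2)])
  expect_identical(sc2$priority_genes, sc$priority_genes)

  # empty common-DV set -> empty priority list
  diffs0 <- diffs
  diffs0[[1]]$dv_sig <- FALSE
  sc0 <- priority_screen(diffs0, profs, parts)
  expect_length(sc0$priority_genes, 0)
  expect_error(priority_screen(diffs[1:2], profs, parts), "regions")
})

test_that("the pipeline runs end to end deterministically", {
  cfg <- simulation_config(n_genes = 300, n_modules = 2, module_size = 60,
                           n_samples_per_line = 20, n_priority = 2, seed = 71)
  tr <- generate_truth(cfg)
  cms <- simulate_region_set(tr, regions = c("R1", "R2"))
  out1 <- file.path(tempfile("run"), "a")
  out2 <- file.path(tempfile("run"), "b")
  pc1 <- pipeline_config(regions = cms, out_dir = out1, min_cluster_size = 20,
                         zsummary_permutations = 25, seed = 7)
  b1 <- run_pipeline(pc1)
  pc2 <- pipeline_config(regions = cms, out_dir = out2, min_cluster_size = 20,
                         zsummary_permutations = 25, seed = 7)
  b2 <- run_pipeline(pc2)

  expect_named(b1$report$regions, c("R1", "R2"))
  expect_true(all(c("n_de", "n_dv", "n_dw") %in%
                    names(b1$report$regions$R1)))
  expect_s3_class(b1$screen, "screen_result")
  expect_true(length(b1$preservation) == 2)
  # byte-identical reruns
  f1 <- list.files(out1, recursive = TRUE)
  f2 <- list.files(out2, recursive = TRUE)
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))),
                     info = f)
  # invalid config fails before any computation
  expect_error(pipeline_config(regions = list(R1 = list(counts = "nope.tsv",
                                                        metadata = "nope2.tsv"))),
               "not found")
  expect_error(pipeline_config(regions = list()), "named list")
})
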