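test_that("adjacency matches closed forms and a brute-force pairwise oracle", {
  # exact correlation -0.5 -> unsigned weight 0.5^6
  v <- vectors_with_exact_cor(-0.5, 20, seed = 2)
  m <- rbind(g1 = v$x, g2 = v$y)
  adj <- adjacency(toy_expr(m), beta = 6)
  expect_equal(adj$weights["g1", "g2"], 0.5^6, tolerance = 1e-12)
  # r = 1 (perfect copy) -> weight 1; r ~ 0 -> weight ~ 0
  u <- vectors_with_exact_cor(0, 20, seed = 3)
  m2 <- rbind(g1 = u$x, g2 = u$y, g3 = u$x)
  adj2 <- adjacency(toy_expr(m2), beta = 6)
  expect_equal(adj2$weights["g1", "g3"], 1, tolerance = 1e-12)
  expect_equal(adj2$weights["g1", "g2"], 0, tolerance = 1e-12)
  expect_equal(diag(adj2$weights), c(g1 = 0, g2 = 0, g3 = 0))

  # 5-gene brute force
  set.seed(5)
  m3 <- matrix(rnorm(50), 5, 10, dimnames = list(sprintf("g%d", 1:5), NULL))
  adj3 <- adjacency(toy_expr(m3), beta = 6)
  for (i in 1:5) for (j in 1:5) if (i != j)
    expect_equal(adj3$weights[i, j], abs(cor(m3[i, ], m3[j, ]))^6)
  expect_true(isSymmetric(adj3$weights))

  # constant gene dropped with a warning
  m4 <- rbind(m3, g6 = rep(1, 10))
  expect_warning(a4 <- adjacency(toy_expr(m4)), "zero-variance")
  expect_false("g6" %in% a4$genes)
})

test_that("scale-free fit is high for a power-law degree sequence", {
  set.seed(6)
  k <- rep(1:50, round(2000 * (1:50)^-2))
  fit <- coexdiff:::scale_free_fit(k)
  expect_gt(fit$fit, 0.9)
  expect_lt(fit$slope, 0)
  expect_error(coexdiff:::scale_free_fit(c(1, 2)), NA) # returns NA fit, no crash
  expect_true(is.na(coexdiff:::scale_free_fit(c(1, 2))$fit))
})

test_that("soft power scan returns a power from the grid and a full table", {
  set.seed(7)
  m <- matrix(rnorm(4000), 100, 40, dimnames = list(sprintf("g%03d", 1:100), NULL))
  sp <- soft_power_scan(toy_expr(m), powers = c(2, 4, 6, 8))
  expect_equal(sp$table$power, c(2, 4, 6, 8))
  expect_true(sp$beta %in% c(2, 4, 6, 8))
  expect_error(soft_power_scan(toy_expr(m), powers = 6), "at least 2")
})

test_that("chosen soft power is stable across simulated fixtures", {
  betas <- vapply(1:5, function(s) {
    cfg <- simulation_config(n_genes = 1000, seed = s)
    cm <- simulate_expression(generate_truth(cfg), "R1")
    expr <- upper_quartile_normalize(filter_by_cpm(cm))
    soft_power_scan(expr, powers = c(2, 4, 6, 8, 10, 12))$beta
  }, numeric(1))
  expect_gte(max(table(betas)), 4)
})

test_that("culling follows the cumulative and quantile rules exactly", {
  # k_total = (10, 5, 3, 1, 1) by construction
  w <- matrix(0, 5, 5, dimnames = list(sprintf("g%d", 1:5), sprintf("g%d", 1:5)))
  w["g1", "g2"] <- w["g2", "g1"] <- 5
  w["g1", "g3"] <- w["g3", "g1"] <- 3
  w["g1", "g4"] <- w["g4", "g1"] <- 1
  w["g1", "g5"] <- w["g5", "g1"] <- 1
  adj <- toy_adjacency(w)
  expect_equal(unname(rowSums(adj$weights)), c(10, 5, 3, 1, 1))
  kept <- cull_network(adj, "cumulative", 0.8)  # target 16 -> k 10, 5, 3
  expect_identical(kept$genes, c("g1", "g2", "g3"))
  # fraction 1 keeps everything in either mode
  expect_length(cull_network(adj, "cumulative", 1)$genes, 5)
  expect_length(cull_network(adj, "quantile", 1)$genes, 5)
  # uniform connectivity, quantile 0.8 -> ceiling(0.8 * 5) = 4 genes,
  # tie broken by ascending gene id (g5 dropped)
  wu <- matrix(0.5, 5, 5, dimnames = dimnames(w))
  adju <- toy_adjacency(wu)
  keptu <- cull_network(adju, "quantile", 0.8)
  expect_identical(keptu$genes, c("g1", "g2", "g3", "g4"))
  # weights are re-sliced, unchanged
  expect_equal(kept$weights, w[1:3, 1:3])
  expect_error(cull_network(adj, fraction = 0), "fraction")
})

test_that("culling never improves a gene's connectivity rank", {
  set.seed(9)
  m <- matrix(rnorm(600), 30, 20, dimnames = list(sprintf("g%02d", 1:30), NULL))
  adj <- adjacency(toy_expr(m))
  culled <- cull_network(adj, "cumulative", 0.6)
  k_all <- sort(rowSums(adj$weights), decreasing = TRUE)
  expect_true(all(culled$genes %in% names(k_all)[seq_along(culled$genes)]))
})

test_that("module detection separates perfect blocks and degenerate inputs", {
  n <- 12
  w <- matrix(0, 2 * n, 2 * n)
  w[1:n, 1:n] <- 1
  w[(n + 1):(2 * n), (n + 1):(2 * n)] <- 1
  rownames(w) <- colnames(w) <- sprintf("g%02d", 1:(2 * n))
  part <- detect_modules(toy_adjacency(w), min_cluster_size = 10)
  labs <- part$assignment
  expect_length(setdiff(unique(labs), "unassigned"), 2)
  expect_length(unique(labs[1:n]), 1)
  expect_length(unique(labs[(n + 1):(2 * n)]), 1)
  expect_false(labs[1] == labs[n + 1])

  # all-zero adjacency -> everything unassigned
  z <- toy_adjacency(matrix(0, 15, 15))
  expect_true(all(detect_modules(z, min_cluster_size = 5)$assignment ==
                    "unassigned"))
  # fewer genes than min size -> single unassigned partition, warning
  expect_warning(p0 <- detect_modules(toy_adjacency(matrix(0.5, 4, 4)),
                                      min_cluster_size = 100))
  expect_true(all(p0$assignment == "unassigned"))
})

test_that("planted modules are recovered on simulated fixtures", {
  aris <- vapply(1:10, function(s) {
    cfg <- simulation_config(seed = s)  # loading 0.8, 40 samples/line
    tr <- generate_truth(cfg)
    net <- network_from_counts(simulate_expression(tr, "R1"))
    adjusted_rand_index(net$partition$assignment,
                        tr$module_assignment[net$adj$genes])
  }, numeric(1))
  expect_gte(median(aris), 0.9)
})

test_that("module detection is invariant to gene input order", {
  cfg <- simulation_config(n_genes = 300, n_modules = 2, module_size = 60,
                           n_samples_per_line = 40, seed = 13)
  tr <- generate_truth(cfg)
  cm <- simulate_expression(tr, "R1")
  expr <- upper_quartile_normalize(filter_by_cpm(cm))
  adj1 <- cull_network(adjacency(expr))
  set.seed(1)
  perm <- sample(nrow(expr$values))
  expr2 <- expr
  expr2$values <- expr$values[perm, ]
  adj2 <- cull_network(adjacency(expr2))
  p1 <- detect_modules(adj1, min_cluster_size = 20)
  p2 <- detect_modules(adj2, min_cluster_size = 20)
  shared <- intersect(names(p1$assignment), names(p2$assignment))
  expect_equal(adjusted_rand_index(p1$assignment[shared],
                                   p2$assignment[shared]), 1)
})

test_that("intramodular connectivity matches hand-computed sums", {
  # 4-gene module with explicit weights
  w <- matrix(c(0, .5, .2, .1,
                .5, 0, .4, .3,
                .2, .4, 0, .6,
                .1, .3, .6, 0), 4, 4, byrow = TRUE,
              dimnames = list(sprintf("g%d", 1:4), sprintf("g%d", 1:4)))
  adj <- toy_adjacency(w)
  part <- toy_partition(setNames(rep("blue", 4), sprintf("g%d", 1:4)))
  prof <- intramodular_connectivity(adj, part)
  expect_equal(prof$k_within, c(.8, 1.2, 1.2, 1.0))
  expect_equal(prof$k_total, prof$k_within)
  expect_equal(prof$k_norm, c(.8, 1.2, 1.2, 1.0) / 1.2)

  # equal pairwise weights -> every k_norm 1
  we <- matrix(0.3, 5, 5)
  adje <- toy_adjacency(we)
  parte <- toy_partition(setNames(rep("m", 5), adje$genes))
  expect_true(all(intramodular_connectivity(adje, parte)$k_norm == 1))

  # isolated extra gene gets k_norm 0 and leaves the rest unchanged
  w2 <- rbind(cbind(w, g5 = 0), g5 = 0)
  rownames(w2)[5] <- "g5"
  adj2 <- toy_adjacency(w2)
  part2 <- toy_partition(setNames(rep("blue", 5), rownames(w2)))
  prof2 <- intramodular_connectivity(adj2, part2)
  expect_equal(prof2$k_norm[5], 0)
  expect_equal(prof2$k_norm[1:4], prof$k_norm)
})

test_that("exactly one gene per module reaches normalized connectivity 1", {
  set.seed(10)
  m <- matrix(rnorm(1200), 60, 20, dimnames = list(sprintf("g%02d", 1:60), NULL))
  adj <- adjacency(toy_expr(m))
  part <- toy_partition(setNames(rep(c("a", "b", "unassigned"), each = 20),
                                 adj$genes))
  prof <- intramodular_connectivity(adj, part)
  for (mod in c("a", "b"))
    expect_equal(sum(prof$k_norm[prof$module == mod] == 1), 1)
})

test_that("hub calls apply the threshold rule exactly", {
  prof <- data.frame(gene = c("Ntrk2_high", "Ntrk2_low", "top", "u"),
                     module = c("blue", "blue", "blue", "unassigned"),
                     k_total = 1, k_within = 1,
                     k_norm = c(0.821, 0.197, 1.0, 0.99),
                     stringsAsFactors = FALSE)
  class(prof) <- c("connectivity_profile", "data.frame")
  expect_setequal(hub_genes(prof, 0.8), c("Ntrk2_high", "top"))
  # k_norm > 1 is impossible, so threshold 1 gives the empty set
  expect_length(hub_genes(prof, 1), 0)
  # brute-force scan oracle on a random profile
  set.seed(11)
  rp <- data.frame(gene = sprintf("g%02d", 1:50),
                   module = sample(c("a", "b", "unassigned"), 50, TRUE),
                   k_total = 1, k_within = 1, k_norm = runif(50),
                   stringsAsFactors = FALSE)
  class(rp) <- c("connectivity_profile", "data.frame")
  oracle <- rp$gene[rp$k_norm > 0.6 & rp$module != "unassigned"]
  expect_identical(hub_genes(rp, 0.6), oracle)
})
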