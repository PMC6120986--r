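test_that("exact NB test is degenerate-safe and recovers planted fold changes", {
  # identical counts in all samples -> log2fc 0, p = 1
  counts <- matrix(rep(c(50L, 100L, 20L), 8), 3, 8,
                   dimnames = list(c("gA", "gB", "gC"), NULL))
  colnames(counts) <- sprintf("s%d", 1:8)
  cm <- toy_count_matrix(counts, line = rep(c("High", "Low"), each = 4))
  de <- de_test(cm)
  expect_equal(de$log2fc, rep(0, 3))
  expect_equal(de$pvalue, rep(1, 3))

  # planted log2fc = 1 genes: median estimate within +/- 0.2
  set.seed(11)
  ng <- 3000; npl <- 30
  mu <- exp(rnorm(ng, log(100), 1))
  lfc <- c(rep(1, 500), rep(0, ng - 500))
  big <- cbind(matrix(rnbinom(ng * npl, mu = mu * 2^lfc, size = 10), ng, npl),
               matrix(rnbinom(ng * npl, mu = mu, size = 10), ng, npl))
  rownames(big) <- sprintf("g%04d", seq_len(ng))
  colnames(big) <- sprintf("s%02d", seq_len(2 * npl))
  cmb <- toy_count_matrix(big, line = rep(c("High", "Low"), each = npl))
  deb <- de_test(cmb)
  expect_lt(abs(median(deb$log2fc[1:500]) - 1), 0.2)
  expect_lt(abs(median(deb$log2fc[501:ng])), 0.2)
  expect_error(de_test(toy_count_matrix(counts[, 1:3, drop = FALSE],
                                        line = c("High", "Low", "Low"))),
               "at least 2")
})

test_that("exact NB p-values track the reference count-based implementation", {
  skip_if_not_installed("edgeR")
  set.seed(12)
  ng <- 400; npl <- 15
  mu <- exp(rnorm(ng, log(80), 1))
  lfc <- sample(c(0, 0, 0, 1, -1), ng, replace = TRUE)
  counts <- cbind(matrix(rnbinom(ng * npl, mu = mu * 2^lfc, size = 8), ng, npl),
                  matrix(rnbinom(ng * npl, mu = mu, size = 8), ng, npl))
  rownames(counts) <- sprintf("g%03d", seq_len(ng))
  colnames(counts) <- sprintf("s%02d", seq_len(2 * npl))
  cm <- toy_count_matrix(counts, line = rep(c("High", "Low"), each = npl))
  de <- de_test(cm)
  y <- edgeR::DGEList(counts = counts, group = rep(c("High", "Low"), each = npl))
  y <- edgeR::calcNormFactors(y, method = "upperquartile")
  y <- edgeR::estimateDisp(y)
  et <- edgeR::exactTest(y, pair = c("Low", "High"))
  expect_gt(cor(de$log2fc, et$table$logFC), 0.99)
  expect_gt(cor(-log10(de$pvalue), -log10(et$table$PValue)), 0.9)
})

test_that("variance-ratio test matches var.test and its symmetries", {
  set.seed(13)
  m <- matrix(rnorm(20 * 24), 20, 24,
              dimnames = list(sprintf("g%02d", 1:20), NULL))
  line <- rep(c("High", "Low"), each = 12)
  ex <- toy_expr(m, line = line)
  dv <- dv_test(ex)
  for (g in 1:20) {
    vt <- var.test(m[g, line == "High"], m[g, line == "Low"])
    expect_equal(dv$f_statistic[g], unname(vt$statistic))
    expect_equal(dv$pvalue[g], vt$p.value)
  }
  # label swap inverts F and keeps the two-sided p
  ex_sw <- toy_expr(m, line = rep(c("Low", "High"), each = 12))
  dv_sw <- dv_test(ex_sw)
  expect_equal(dv_sw$f_statistic, 1 / dv$f_statistic)
  expect_equal(dv_sw$pvalue, dv$pvalue)
  # direction = line with larger variance
  expect_identical(dv$direction, ifelse(dv$f_statistic > 1, "High", "Low"))

  # the two lines are the same sample set -> F = 1, p = 1
  same <- toy_expr(cbind(m[, 1:12], m[, 1:12]), line = line)
  dv_same <- dv_test(same)
  expect_equal(dv_same$f_statistic, rep(1, 20))
  expect_equal(dv_same$pvalue, rep(1, 20))

  # zero variance -> excluded
  m2 <- m; m2[1, line == "High"] <- 5
  dvz <- dv_test(toy_expr(m2, line = line))
  expect_true(dvz$excluded[1])
  expect_true(is.na(dvz$pvalue[1]))
})

test_that("binomial SGoF follows its published sequential definition", {
  # independent literal implementation: repeatedly test the count of
  # below-threshold p-values against Binomial(n - i, gamma) at level alpha,
  # granting one discovery per significant step
  sgof_oracle <- function(p, gamma = 0.05, alpha = 0.05) {
    n <- length(p)
    f <- sum(p <= gamma)
    r <- 0
    while (r < f) {
      meta_p <- stats::binom.test(f - r, n - r, gamma,
                                  alternative = "greater")$p.value
      if (meta_p > alpha + 1e-12) break
      r <- r + 1
    }
    r
  }
  expect_equal(sgof_adjust(rep(1, 50))$n_discoveries, 0)
  all_tiny <- rep(1e-10, 100)
  expect_equal(sgof_adjust(all_tiny)$n_discoveries, 100)
  expect_equal(sgof_oracle(all_tiny), 100)

  set.seed(14)
  for (i in 1:50) {
    n <- sample(20:400, 1)
    p <- c(runif(n), rbeta(sample(0:30, 1), 0.05, 1))
    got <- sgof_adjust(p)
    expect_equal(got$n_discoveries, sgof_oracle(p))
    # flags mark exactly the R smallest p-values
    r <- got$n_discoveries
    if (r > 0) {
      expect_equal(sum(got$significant), r)
      expect_true(max(p[got$significant]) <= min(p[!got$significant]))
    }
  }
})

test_that("SGoF controls the weak familywise error under the global null", {
  set.seed(15)
  hits <- vapply(1:1000, function(i)
    sgof_adjust(runif(1000))$n_discoveries > 0, logical(1))
  expect_lte(mean(hits), 0.05 + 0.02)
})

test_that("SGoF discoveries shrink as alpha tightens", {
  set.seed(16)
  p <- c(rbeta(60, 0.05, 1), runif(400))
  r <- vapply(c(0.1, 0.05, 0.01, 0.001), function(a)
    sgof_adjust(p, alpha = a)$n_discoveries, integer(1))
  expect_true(all(diff(r) <= 0))
})

test_that("edge change calls require both the correlation delta and the z test", {
  # identical lines -> no changed edges
  set.seed(17)
  m <- matrix(rnorm(5 * 30), 5, 30, dimnames = list(sprintf("g%d", 1:5), NULL))
  ch0 <- edge_changes(m, m)
  expect_equal(sum(ch0$changed), 0)

  # delta 0.4 with an overwhelming z -> still not changed (conjunction)
  n <- 2000
  a <- vectors_with_exact_cor(0.0, n, seed = 18)
  b <- vectors_with_exact_cor(0.4, n, seed = 19)
  mh <- rbind(g1 = b$x, g2 = b$y)
  ml <- rbind(g1 = a$x, g2 = a$y)
  ch1 <- edge_changes(mh, ml)
  expect_lt(ch1$pvalue[1, 2], 1e-6)
  expect_false(ch1$changed[1, 2])

  # delta 0.8 -> changed
  c2 <- vectors_with_exact_cor(0.8, n, seed = 20)
  ch2 <- edge_changes(rbind(g1 = c2$x, g2 = c2$y), ml)
  expect_true(ch2$changed[1, 2])

  # z statistic matches its definition
  z_manual <- (atanh(ch2$r_high[1, 2]) - atanh(ch2$r_low[1, 2])) /
    sqrt(1 / (n - 3) + 1 / (n - 3))
  expect_equal(ch2$pvalue[1, 2], 2 * pnorm(-abs(z_manual)))

  expect_error(edge_changes(m[, 1:4], m[, 1:4]), "5 samples")
  expect_error(edge_changes(m[, 1:3], m[, 1:3]), "3 samples")
})

test_that("edge list view covers every unordered pair exactly once", {
  set.seed(21)
  m <- matrix(rnorm(6 * 40), 6, 40, dimnames = list(sprintf("g%d", 1:6), NULL))
  ch <- edge_changes(m + rnorm(length(m)), m)
  df <- as.data.frame(ch)
  expect_equal(nrow(df), choose(6, 2))
  expect_true(all(df$gene_a < df$gene_b))
  expect_equal(df$delta_r, df$r_high - df$r_low)
})

test_that("differential wiring binomial test matches exact tail summation", {
  # synthetic changed-edge pattern over 40 genes
  set.seed(22)
  n <- 40
  changed <- matrix(FALSE, n, n)
  idx <- which(upper.tri(changed))
  on <- sample(idx, 30)
  changed[on] <- TRUE
  changed <- changed | t(changed)
  genes <- sprintf("g%02d", 1:n)
  ch <- structure(list(genes = genes, r_low = diag(n), r_high = diag(n),
                       pvalue = matrix(1, n, n), changed = changed,
                       n_low = 10, n_high = 10, delta_min = 0.5, p_max = 0.01),
                  class = "edge_change_set")
  dw <- dw_test(ch)
  rate <- 30 / choose(n, 2)
  expect_equal(dw$rate, rep(rate, n))
  # direct summation oracle for the upper-tail binomial probability
  tail_oracle <- function(s, tr, pr)
    sum(vapply(s:tr, function(k) choose(tr, k) * pr^k * (1 - pr)^(tr - k),
               numeric(1)))
  for (g in seq_len(n)) {
    s <- dw$changed_edges[g]
    expect_equal(dw$trials[g], n - 1)
    expect_equal(dw$pvalue[g],
                 if (s == 0) 1 else tail_oracle(s, n - 1, rate),
                 tolerance = 1e-12)
  }
  # a gene with zero changed edges has p = 1 (upper tail includes 0)
  expect_true(all(dw$pvalue[dw$changed_edges == 0] == 1))
  # sum of per-gene successes double-counts each edge
  expect_equal(sum(dw$changed_edges), 2 * 30)
  # spec arithmetic case: rate .01, 100 trials, 5 successes
  expect_equal(pbinom(4, 100, 0.01, lower.tail = FALSE),
               tail_oracle(5, 100, 0.01), tolerance = 1e-12)
})

test_that("venn decomposition equals brute-force set algebra", {
  A <- c("a", "b", "c", "d")
  B <- c("c", "d", "e")
  C <- c("d", "e", "f")
  ov <- overlap_sets(list(A = A, B = B, C = C))
  expect_setequal(ov$cells[["A"]], c("a", "b"))
  expect_setequal(ov$cells[["A&B"]], "c")
  expect_setequal(ov$cells[["A&B&C"]], "d")
  expect_setequal(ov$cells[["B&C"]], "e")
  expect_setequal(ov$cells[["C"]], "f")
  expect_equal(unname(ov$pairwise["A&B"]), 2)
  expect_equal(ov$common, "d")

  # disjoint and identical sets
  expect_length(overlap_sets(list(x = c("a"), y = c("b")))$common, 0)
  expect_setequal(overlap_sets(list(x = A, y = A))$common, A)

  # random brute force
  set.seed(23)
  u <- sprintf("g%02d", 1:40)
  sets <- list(R1 = sample(u, 20), R2 = sample(u, 15), R3 = sample(u, 25))
  ov2 <- overlap_sets(sets)
  for (g in u) {
    memb <- names(sets)[vapply(sets, function(s) g %in% s, logical(1))]
    if (length(memb) == 0) next
    key <- paste(memb, collapse = "&")
    expect_true(g %in% ov2$cells[[key]])
  }
  expect_equal(sum(lengths(ov2$cells)), length(unique(unlist(sets))))
})
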