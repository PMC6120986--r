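# Shared builders for small in-code fixtures.

toy_count_matrix <- function(counts, line = NULL, region = "R1") {
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  if (is.null(line)) line <- rep(c("High", "Low"), length.out = ncol(counts))
  meta <- data.frame(sample_id = colnames(counts), line = line,
                     region = region,
                     sex = rep_len(c("F", "M"), ncol(counts)),
                     stringsAsFactors = FALSE)
  count_matrix(counts, meta)
}

toy_expr <- function(values, line = NULL) {
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(line)) line <- rep(c("High", "Low"), length.out = ncol(values))
  meta <- data.frame(sample_id = colnames(values), line = line,
                     region = "R1", sex = "F", stringsAsFactors = FALSE)
  structure(list(values = values, meta = meta,
                 norm_factors = rep(1, ncol(values))), class = "expr_matrix")
}

toy_adjacency <- function(weights, beta = 6) {
  if (is.null(rownames(weights))) {
    rownames(weights) <- colnames(weights) <-
      sprintf("g%03d", seq_len(nrow(weights)))
  }
  diag(weights) <- 0
  structure(list(weights = weights, genes = rownames(weights), beta = beta,
                 signed = FALSE), class = "adjacency")
}

toy_partition <- function(labels, cut_height = 0.9995, min_cluster_size = 2,
                          deep_split = 4) {
  structure(list(assignment = labels,
                 parameters = list(cut_height = cut_height,
                                   min_cluster_size = min_cluster_size,
                                   deep_split = deep_split)),
            class = "module_partition")
}

# Brute-force hypergeometric tail by direct summation over the table space.
hyper_tail_oracle <- function(overlap, module, set, background, upper = TRUE) {
  ks <- if (upper) overlap:min(module, set) else 0:overlap
  sum(vapply(ks, function(k)
    choose(set, k) * choose(background - set, module - k) /
      choose(background, module), numeric(1)))
}

# Two sample vectors with an exact given Pearson correlation.
vectors_with_exact_cor <- function(r, n, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  e <- rnorm(n)
  e <- residuals(lm(e ~ x))
  x <- (x - mean(x)) / sd(x)
  e <- e / sd(e)
  list(x = x, y = r * x + sqrt(1 - r^2) * e)
}

# Analysis steps shared by several recovery tests.
network_from_counts <- function(cm, min_cluster_size = 30, beta = 6,
                                cull = TRUE) {
  filt <- filter_by_cpm(cm)
  expr <- upper_quartile_normalize(filt)
  adj <- adjacency(expr, beta = beta)
  if (cull) adj <- cull_network(adj)
  part <- detect_modules(adj, min_cluster_size = min_cluster_size)
  list(filtered = filt, expr = expr, adj = adj, partition = part)
}
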