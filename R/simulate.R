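#' Simulation configuration for the two-line latent-factor count generator
#'
#' Bundles and validates every knob of the synthetic RNA-seq generator. The
#' generator emulates the design of a selection study: two lines (High / Low)
#' sampled from one brain region, a handful of correlated gene modules on a
#' background of unstructured genes, and planted line effects on means (DE),
#' variances (DV) and pairwise correlations (DW).
#'
#' Genes follow a Gaussian latent-factor model on the natural-log scale: the
#' biological deviation of gene g in sample s is
#' \code{sigma * (lambda_g * f_m(s) + sqrt(1 - lambda_g^2) * e_gs)} where
#' \code{f_m} is the factor of g's module and \code{e} idiosyncratic noise, so
#' two genes of the same module have latent correlation
#' \code{lambda_i * lambda_j}. Expected counts are the exponentiated deviations
#' scaled by a lognormal gene abundance and the sample library size, and
#' observed counts are negative binomial with per-gene dispersion.
#'
#' Planted effects:
#' \itemize{
#'   \item DE genes: High-line mean multiplied by \code{2^log2fc} (random sign,
#'     magnitude \code{de_effect}); drawn from the unstructured background so
#'     they stay low-connectivity "leaf" genes.
#'   \item DV genes: centered latent signal scaled by \code{sqrt(dv_ratio)} in
#'     the High line, which multiplies the log-scale variance by
#'     \code{dv_ratio} while leaving all correlations untouched.
#'   \item DW ("rewired") genes: load on an alternative module factor in the
#'     Low line and on the true module factor in the High line, so every
#'     rewired-by-unrewired pair inside the module moves from r ~ 0 (Low) to
#'     r = lambda_i*lambda_j (High) while module membership is kept.
#'   \item Priority genes: \code{n_priority} genes of module 1 planted as the
#'     joint extreme the gene screen targets: high loading
#'     (\code{hub_loading}, making them module hubs) plus a strong variance
#'     response (\code{priority_dv_ratio}); always members of the DV set.
#' }
#'
#' @param n_genes total number of genes.
#' @param n_modules number of planted coexpression modules.
#' @param module_size genes per module (\code{n_modules * module_size <= n_genes}).
#' @param n_samples_per_line samples per selected line (>= 4).
#' @param de_fraction,de_effect fraction of genes with a planted mean shift and
#'   its |log2 fold-change|.
#' @param dv_fraction,dv_ratio fraction of genes with a planted variance effect
#'   and the High/Low log-scale variance ratio (> 0).
#' @param dw_fraction fraction of within-module gene pairs planted as rewired
#'   edges.
#' @param latent_factor_loading module-factor loading in [0, 1) for ordinary
#'   module genes; within-module latent correlation is its square.
#' @param nb_dispersion negative-binomial dispersion, scalar or per gene.
#' @param library_size_range two positive integers; per-sample library sizes
#'   are drawn uniformly from this range.
#' @param baseline_log_sd natural-log standard deviation of the biological
#'   signal (total latent sd per gene) for module genes and planted
#'   DE / DV genes.
#' @param background_log_sd natural-log sd for the unstructured background
#'   (housekeeping-like genes vary less between animals than the signalling
#'   modules; this also keeps the upper-quartile normalization statistic
#'   stable at desk-scale gene counts).
#' @param dv_module_share share of non-priority DV genes placed inside module 1
#'   (the "affected" module); the rest come from the background.
#' @param low_expr_fraction share of background genes simulated far below the
#'   CPM threshold, so expression filtering has work to do.
#' @param module_mass_share share of the library's read mass held by the
#'   module genes (default 0.2). In real libraries the coexpression modules
#'   of interest hold a minority of total read mass (a few hundred networked
#'   genes against ~15,000 expressed, with the housekeeping end of the
#'   abundance range on top); at a desk-scale gene count an unconstrained
#'   split would let the module factors move the library total itself and
#'   imprint spurious compositional correlations on CPM values.
#' @param abundance_log_sd natural-log sd of the gene abundance distribution
#'   (default 0.9, about two orders of magnitude across an expressed-gene
#'   panel).
#' @param n_priority number of planted priority (cross-region DV hub) genes.
#' @param priority_dv_ratio,hub_loading variance ratio and loading used for
#'   priority genes.
#' @param seed root integer seed; all region streams derive from it.
#' @return A validated list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n_genes = 600,
                              n_modules = 3,
                              module_size = 100,
                              n_samples_per_line = 40,
                              de_fraction = 0.05,
                              de_effect = 1,
                              dv_fraction = 0.074,
                              dv_ratio = 4,
                              dw_fraction = 0.01,
                              latent_factor_loading = 0.8,
                              nb_dispersion = 0.05,
                              library_size_range = c(3e5, 5e5),
                              baseline_log_sd = 0.8,
                              background_log_sd = 0.4,
                              dv_module_share = 0.7,
                              low_expr_fraction = 0.05,
                              module_mass_share = 0.2,
                              abundance_log_sd = 0.9,
                              n_priority = 0,
                              priority_dv_ratio = 6,
                              hub_loading = 0.95,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              n_samples_per_line = as.integer(n_samples_per_line),
              de_fraction = de_fraction, de_effect = de_effect,
              dv_fraction = dv_fraction, dv_ratio = dv_ratio,
              dw_fraction = dw_fraction,
              latent_factor_loading = latent_factor_loading,
              nb_dispersion = nb_dispersion,
              library_size_range = as.numeric(library_size_range),
              baseline_log_sd = baseline_log_sd,
              background_log_sd = background_log_sd,
              dv_module_share = dv_module_share,
              low_expr_fraction = low_expr_fraction,
              module_mass_share = module_mass_share,
              abundance_log_sd = abundance_log_sd,
              n_priority = as.integer(n_priority),
              priority_dv_ratio = priority_dv_ratio,
              hub_loading = hub_loading,
              seed = as.integer(seed))
  for (f in c("de_fraction", "dv_fraction", "dw_fraction", "dv_module_share",
              "low_expr_fraction"))
    stop_if_not_scalar_prob(cfg[[f]], f)
  if (cfg$n_modules * cfg$module_size > cfg$n_genes)
    stop("module_size x n_modules exceeds n_genes", call. = FALSE)
  if (cfg$n_samples_per_line < 4)
    stop("n_samples_per_line must be >= 4", call. = FALSE)
  if (cfg$dv_ratio <= 0 || cfg$priority_dv_ratio <= 0)
    stop("variance ratios must be positive", call. = FALSE)
  if (cfg$latent_factor_loading < 0 || cfg$latent_factor_loading >= 1 ||
      cfg$hub_loading < 0 || cfg$hub_loading >= 1)
    stop("factor loadings must lie in [0, 1)", call. = FALSE)
  if (any(cfg$nb_dispersion <= 0)) stop("nb_dispersion must be positive", call. = FALSE)
  stop_if_not_scalar_prob(cfg$module_mass_share, "module_mass_share")
  if (cfg$abundance_log_sd <= 0)
    stop("abundance_log_sd must be positive", call. = FALSE)
  if (length(cfg$library_size_range) != 2 || any(cfg$library_size_range <= 0) ||
      diff(cfg$library_size_range) < 0)
    stop("library_size_range must be an increasing pair of positive numbers",
         call. = FALSE)
  if (cfg$n_priority > cfg$module_size)
    stop("n_priority cannot exceed module_size", call. = FALSE)
  class(cfg) <- "simulation_config"
  cfg
}

#' Draw the planted ground truth for one simulated study
#'
#' Fixes, deterministically from \code{config$seed}, everything that is shared
#' across regions of a study: module membership, per-gene loadings and
#' abundances, and the planted DE / DV / DW gene and edge sets. Expression
#' noise is drawn later, per region, by \code{\link{simulate_expression}}.
#'
#' DW edges are allocated so that their total count equals
#' \code{round(dw_fraction * total within-module pairs)}, split across modules
#' by largest remainders. Within a module the edges are all pairs between a
#' small set of "rewired" genes and the remaining module genes (truncated to
#' the quota); the rewired genes themselves are recorded in \code{dw_genes}.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return A list of class \code{"synthetic_truth"}; see the fields in the
#'   implementation and the fixture JSON schema in
#'   \code{\link{write_fixture}}.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("g%05d", seq_len(n))

  # Contiguous module blocks, background afterwards (gene ids are arbitrary;
  # downstream operations are order-invariant, which the tests check).
  module_of <- rep("background", n)
  for (m in seq_len(config$n_modules)) {
    idx <- ((m - 1) * config$module_size + 1):(m * config$module_size)
    module_of[idx] <- sprintf("M%d", m)
  }
  names(module_of) <- genes
  background <- genes[module_of == "background"]

  loading <- ifelse(module_of == "background", 0, config$latent_factor_loading)
  names(loading) <- genes

  # Priority genes: first genes of module 1, boosted loading.
  priority <- character(0)
  if (config$n_priority > 0) {
    priority <- genes[module_of == "M1"][seq_len(config$n_priority)]
    loading[priority] <- config$hub_loading
  }

  # Gene abundance: lognormal within each compartment, then scaled so module
  # genes hold module_mass_share of the expected library and the background
  # the rest; a slice of the background is pushed far below the CPM threshold.
  mean_lib <- mean(config$library_size_range)
  abundance <- exp(rnorm(n, mean = 0, sd = config$abundance_log_sd))
  names(abundance) <- genes
  in_module <- module_of != "background"
  if (any(in_module))
    abundance[in_module] <- abundance[in_module] /
      sum(abundance[in_module]) * config$module_mass_share * mean_lib
  if (any(!in_module))
    abundance[!in_module] <- abundance[!in_module] /
      sum(abundance[!in_module]) *
      (1 - if (any(in_module)) config$module_mass_share else 0) * mean_lib
  n_low <- round(config$low_expr_fraction * length(background))
  low_expr <- character(0)
  if (n_low > 0) {
    low_expr <- sample(background, n_low)
    abundance[low_expr] <- abundance[low_expr] * 1e-4
  }
  informative_bg <- setdiff(background, low_expr)

  # DE genes: background leaves, random sign.
  n_de <- round(config$de_fraction * n)
  de_pool <- informative_bg
  if (n_de > length(de_pool)) n_de <- length(de_pool)
  de_genes <- if (n_de > 0) sort(sample(de_pool, n_de)) else character(0)
  de <- data.frame(gene = de_genes,
                   log2fc = if (n_de > 0)
                     config$de_effect * sample(c(-1, 1), n_de, replace = TRUE)
                   else numeric(0),
                   stringsAsFactors = FALSE)

  # DW rewired genes and edge quota per module.
  mod_sizes <- rep(config$module_size, config$n_modules)
  pairs_per_mod <- mod_sizes * (mod_sizes - 1) / 2
  total_quota <- round(config$dw_fraction * sum(pairs_per_mod))
  quota <- floor(total_quota * pairs_per_mod / max(1, sum(pairs_per_mod)))
  remainder <- total_quota - sum(quota)
  if (remainder > 0 && config$n_modules > 0) {
    frac <- total_quota * pairs_per_mod / max(1, sum(pairs_per_mod)) - quota
    bump <- order(frac, decreasing = TRUE)[seq_len(remainder)]
    quota[bump] <- quota[bump] + 1
  }
  dw_genes <- character(0)
  dw_edges <- list()
  for (m in seq_len(config$n_modules)) {
    if (config$n_modules == 0 || quota[m] == 0) next
    members <- genes[module_of == sprintf("M%d", m)]
    eligible <- setdiff(members, priority)
    n_rw <- min(max(1L, ceiling(quota[m] / (length(members) - 1))),
                floor(length(members) / 4))
    rw <- sort(sample(eligible, n_rw))
    partners <- setdiff(members, rw)
    grid <- expand.grid(gene_a = rw, gene_b = partners,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[order(grid$gene_a, grid$gene_b), , drop = FALSE]
    grid <- grid[seq_len(min(quota[m], nrow(grid))), , drop = FALSE]
    grid$r_low <- 0
    grid$r_high <- loading[grid$gene_a] * loading[grid$gene_b]
    dw_genes <- c(dw_genes, rw)
    dw_edges[[m]] <- grid
  }
  dw_edges <- if (length(dw_edges) > 0) do.call(rbind, dw_edges) else
    data.frame(gene_a = character(0), gene_b = character(0),
               r_low = numeric(0), r_high = numeric(0),
               stringsAsFactors = FALSE)
  rownames(dw_edges) <- NULL

  # DV genes: priority genes first, then module-1 members, rest background.
  n_dv <- round(config$dv_fraction * n)
  dv_genes <- priority
  n_rest <- max(0, n_dv - length(priority))
  mod1_pool <- setdiff(genes[module_of == "M1"], c(priority, dw_genes))
  n_mod1 <- min(round(config$dv_module_share * n_rest), length(mod1_pool))
  if (n_mod1 > 0) dv_genes <- c(dv_genes, sample(mod1_pool, n_mod1))
  bg_pool <- setdiff(informative_bg, de_genes)
  n_bg <- min(n_rest - n_mod1, length(bg_pool))
  if (n_bg > 0) dv_genes <- c(dv_genes, sample(bg_pool, n_bg))
  dv <- data.frame(gene = dv_genes,
                   ratio = ifelse(dv_genes %in% priority,
                                  config$priority_dv_ratio, config$dv_ratio),
                   stringsAsFactors = FALSE)
  dv <- dv[order(dv$gene), , drop = FALSE]
  rownames(dv) <- NULL

  disp <- rep_len(config$nb_dispersion, n)
  names(disp) <- genes

  # Per-gene biological log-sd: quiet housekeeping background, responsive
  # module and planted-effect genes.
  log_sd <- ifelse(module_of == "background", config$background_log_sd,
                   config$baseline_log_sd)
  names(log_sd) <- genes
  log_sd[dv$gene] <- config$baseline_log_sd

  # real-valued fields are kept at 12 significant digits so that the decimal
  # JSON fixture serialization round-trips bit-exactly
  abundance <- signif(abundance, 12)
  loading <- signif(loading, 12)
  dw_edges$r_high <- signif(dw_edges$r_high, 12)
  dw_edges$r_low <- signif(dw_edges$r_low, 12)
  truth <- list(genes = genes,
                module_assignment = module_of,
                loading = loading,
                abundance = abundance,
                de_genes = de,
                dv_genes = dv,
                dw_genes = sort(dw_genes),
                dw_edges = dw_edges,
                priority_genes = priority,
                low_expr_genes = sort(low_expr),
                nb_dispersion = disp,
                log_sd = log_sd,
                library_size_range = config$library_size_range,
                n_samples_per_line = config$n_samples_per_line,
                baseline_log_sd = config$baseline_log_sd,
                seed = config$seed,
                config = unclass(config))
  class(truth) <- "synthetic_truth"
  truth
}

#' Simulate one region's count matrix from a planted truth
#'
#' Draws library sizes, module factors, alternative (rewiring) factors and
#' idiosyncratic noise for \code{2 * n_samples_per_line} samples, applies the
#' planted DE / DV / DW effects and samples negative-binomial counts.
#' Repeated calls with different seeds and the same truth produce the
#' region replicates of a multi-region study (shared module membership and
#' planted gene sets, independent expression noise).
#'
#' @param truth a \code{\link{generate_truth}} result.
#' @param region region label written into the sample metadata.
#' @param seed integer seed for this region's stream; defaults to a
#'   deterministic derivation from \code{truth$seed}.
#' @return A \code{\link{count_matrix}}: integer counts (genes x samples) plus
#'   sample metadata (line, region, sex).
#' @export
simulate_expression <- function(truth, region = "R1", seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (is.null(seed)) seed <- derive_seed(truth$seed, 1L)
  set.seed(seed)
  n <- length(truth$genes)
  npl <- truth$n_samples_per_line
  ns <- 2L * npl
  line <- rep(c("High", "Low"), each = npl)
  sample_id <- sprintf("%s_%s_%02d", region, line, c(seq_len(npl), seq_len(npl)))
  sex <- rep_len(c("F", "M"), ns)

  lib <- round(runif(ns, truth$library_size_range[1], truth$library_size_range[2]))
  n_mod <- truth$config$n_modules
  f_mod <- matrix(rnorm(n_mod * ns), n_mod, ns)   # module factors
  f_alt <- matrix(rnorm(n_mod * ns), n_mod, ns)   # Low-line rewiring factors
  eps <- matrix(rnorm(n * ns), n, ns)
  # Standardize each factor within each line (mean 0, unit sample variance):
  # realized module variance then carries no line-level random offset, so the
  # planted DE/DV/DW effects are the only systematic line differences.
  is_low <- line == "Low"
  standardize_rows <- function(m, cols) {
    s <- m[, cols, drop = FALSE]
    s <- s - rowMeans(s)
    sd_s <- sqrt(rowSums(s^2) / (ncol(s) - 1))
    m[, cols] <- s / sd_s
    m
  }
  if (n_mod > 0) for (cols in list(which(is_low), which(!is_low))) {
    f_mod <- standardize_rows(f_mod, cols)
    f_alt <- standardize_rows(f_alt, cols)
  }

  lam <- truth$loading
  mod_idx <- match(truth$module_assignment, sprintf("M%d", seq_len(max(1, n_mod))))
  signal <- sqrt(1 - lam^2) * eps
  in_mod <- !is.na(mod_idx)
  if (any(in_mod))
    signal[in_mod, ] <- signal[in_mod, ] + lam[in_mod] * f_mod[mod_idx[in_mod], , drop = FALSE]
  # rewired genes: swap the module factor for the alternative one in the Low line
  rw <- truth$genes %in% truth$dw_genes
  if (any(rw) && any(is_low)) {
    swap <- lam[rw] * (f_alt[mod_idx[rw], is_low, drop = FALSE] -
                       f_mod[mod_idx[rw], is_low, drop = FALSE])
    signal[rw, is_low] <- signal[rw, is_low] + swap
  }
  # DV: multiply the latent (log-scale) variance by `ratio` in the High line.
  # Module genes realize the inflation through a boosted factor loading, so
  # their High-line intramodular connectivity rises along with their variance
  # (the pattern the variance-responsive modules show in real selected lines);
  # background genes scale their idiosyncratic signal.
  is_high <- !is_low
  if (nrow(truth$dv_genes) > 0) {
    i <- match(truth$dv_genes$gene, truth$genes)
    rho <- truth$dv_genes$ratio
    lam_dv <- lam[i]
    boost <- lam_dv > 0 & rho >= 1
    if (any(boost)) {
      ib <- i[boost]
      rho_f <- (rho[boost] - (1 - lam_dv[boost]^2)) / lam_dv[boost]^2
      extra <- (sqrt(rho_f) - 1) * lam_dv[boost] *
        f_mod[mod_idx[ib], is_high, drop = FALSE]
      signal[ib, is_high] <- signal[ib, is_high] + extra
    }
    if (any(!boost)) {
      iw <- i[!boost]
      signal[iw, is_high] <- signal[iw, is_high] * sqrt(rho[!boost])
    }
  }
  x <- truth$log_sd * signal

  mu <- truth$abundance * exp(x)
  if (nrow(truth$dv_genes) > 0) {
    # keep DV a pure variance effect on the count scale: cancel the mean
    # inflation E[exp(x)] of the widened lognormal
    i <- match(truth$dv_genes$gene, truth$genes)
    shrink <- exp(-(truth$dv_genes$ratio - 1) * truth$log_sd[i]^2 / 2)
    mu[i, is_high] <- mu[i, is_high] * shrink
  }
  if (nrow(truth$de_genes) > 0) {
    i <- match(truth$de_genes$gene, truth$genes)
    mu[i, is_high] <- mu[i, is_high] * 2^truth$de_genes$log2fc
  }
  mu <- sweep(mu, 2, lib / mean(truth$library_size_range), `*`)

  counts <- matrix(rnbinom(n * ns, mu = mu, size = rep(1 / truth$nb_dispersion, ns)),
                   n, ns, dimnames = list(truth$genes, sample_id))
  storage.mode(counts) <- "integer"
  meta <- data.frame(sample_id = sample_id, line = line, region = region,
                     sex = sex, stringsAsFactors = FALSE)
  count_matrix(counts, meta)
}

#' Simulate a multi-region study
#'
#' One shared truth, one count matrix per region with region-specific derived
#' seeds; mirrors a design in which the same selected lines are profiled in
#' several brain regions.
#'
#' @inheritParams simulate_expression
#' @param regions character vector of region labels.
#' @return Named list of \code{\link{count_matrix}} objects.
#' @export
simulate_region_set <- function(truth, regions = c("R1", "R2", "R3")) {
  out <- lapply(seq_along(regions), function(i)
    simulate_expression(truth, region = regions[i],
                        seed = derive_seed(truth$seed, i)))
  names(out) <- regions
  out
}

#' Write a simulated fixture to disk
#'
#' Persists counts (TSV, gene_id first column), sample metadata (TSV) and the
#' ground truth (JSON, full double precision) so that reading the files back
#' reproduces the inputs exactly.
#'
#' @param truth a \code{synthetic_truth}.
#' @param counts a \code{\link{count_matrix}}.
#' @param directory output directory (created if missing).
#' @return Invisibly, the three file paths (counts, metadata, truth).
#' @export
write_fixture <- function(truth, counts, directory) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  paths <- c(counts = file.path(directory, "counts.tsv"),
             metadata = file.path(directory, "metadata.tsv"),
             truth = file.path(directory, "truth.json"))
  cdf <- data.frame(gene_id = rownames(counts$counts), counts$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(cdf, paths["counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(counts$meta, paths["metadata"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ser <- truth
  class(ser) <- NULL
  ser$module_assignment <- as.list(ser$module_assignment)
  ser$loading <- as.list(ser$loading)
  ser$abundance <- as.list(ser$abundance)
  ser$nb_dispersion <- as.list(ser$nb_dispersion)
  ser$log_sd <- as.list(ser$log_sd)
  jsonlite::write_json(ser, paths["truth"], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}

#' Read a fixture written by \code{\link{write_fixture}}
#'
#' @param directory the fixture directory.
#' @return A list with elements \code{truth} (a \code{synthetic_truth}) and
#'   \code{counts} (a \code{\link{count_matrix}}).
#' @export
read_fixture <- function(directory) {
  counts <- read_counts(file.path(directory, "counts.tsv"),
                        file.path(directory, "metadata.tsv"))
  raw <- jsonlite::read_json(file.path(directory, "truth.json"),
                             simplifyVector = TRUE)
  empty_df <- function(x, cols, types) {
    if (is.data.frame(x) && nrow(x) > 0) return(x)
    out <- lapply(types, function(t) vector(t, 0))
    names(out) <- cols
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  truth <- list(
    genes = as.character(raw$genes),
    module_assignment = unlist(raw$module_assignment),
    loading = unlist(raw$loading),
    abundance = unlist(raw$abundance),
    de_genes = empty_df(raw$de_genes, c("gene", "log2fc"),
                        c("character", "numeric")),
    dv_genes = empty_df(raw$dv_genes, c("gene", "ratio"),
                        c("character", "numeric")),
    dw_genes = as.character(unlist(raw$dw_genes)),
    dw_edges = empty_df(raw$dw_edges, c("gene_a", "gene_b", "r_low", "r_high"),
                        c("character", "character", "numeric", "numeric")),
    priority_genes = as.character(unlist(raw$priority_genes)),
    low_expr_genes = as.character(unlist(raw$low_expr_genes)),
    nb_dispersion = unlist(raw$nb_dispersion),
    log_sd = unlist(raw$log_sd),
    library_size_range = as.numeric(raw$library_size_range),
    n_samples_per_line = as.integer(raw$n_samples_per_line),
    baseline_log_sd = raw$baseline_log_sd,
    seed = as.integer(raw$seed),
    config = raw$config)
  truth$config$library_size_range <- as.numeric(truth$config$library_size_range)
  for (f in c("n_genes", "n_modules", "module_size", "n_samples_per_line",
              "n_priority", "seed"))
    truth$config[[f]] <- as.integer(truth$config[[f]])
  class(truth) <- "synthetic_truth"
  list(truth = truth, counts = counts)
}
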