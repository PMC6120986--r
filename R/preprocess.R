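#' Construct a validated count matrix with sample metadata
#'
#' @param counts integer matrix, genes x samples, with dimnames.
#' @param meta data.frame with columns \code{sample_id}, \code{line}
#'   (\code{"High"}/\code{"Low"}), \code{region}, \code{sex}, one row per
#'   sample of \code{counts}.
#' @return A list of class \code{"count_matrix"} with elements \code{counts}
#'   and \code{meta} (metadata reordered to the column order of the counts).
#' @export
count_matrix <- function(counts, meta) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must be a matrix with gene and sample names", call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "),
         call. = FALSE)
  needed <- c("sample_id", "line", "region", "sex")
  missing_cols <- setdiff(needed, names(meta))
  if (length(missing_cols) > 0)
    stop("metadata lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  absent <- setdiff(colnames(counts), meta$sample_id)
  if (length(absent) > 0)
    stop("samples without metadata: ", paste(absent, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative", call. = FALSE)
  if (any(counts != round(counts))) {
    bad <- rownames(counts)[which(rowSums(counts != round(counts)) > 0)[1]]
    stop("non-integer counts (first offending gene: ", bad, ")", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  meta <- meta[match(colnames(counts), meta$sample_id), needed, drop = FALSE]
  rownames(meta) <- NULL
  structure(list(counts = counts, meta = meta), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(table(x$meta$line)),
                            as.integer(table(x$meta$line))), collapse = ", ")))
  invisible(x)
}

#' Read a count matrix and its sample metadata from TSV files
#'
#' The counts file has a \code{gene_id} first column and one column per
#' sample; the metadata file has columns \code{sample_id}, \code{line},
#' \code{region}, \code{sex}. Sample order of the counts file is preserved.
#'
#' @param path_counts,path_metadata file paths.
#' @return A \code{\link{count_matrix}}.
#' @export
read_counts <- function(path_counts, path_metadata) {
  for (p in c(path_counts, path_metadata))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  raw <- utils::read.delim(path_counts, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("counts file needs gene_id plus >=1 sample column",
                          call. = FALSE)
  mat <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric count cells in ", path_counts,
                             call. = FALSE)
  rownames(mat) <- as.character(raw[[1]])
  meta <- utils::read.delim(path_metadata, stringsAsFactors = FALSE)
  count_matrix(mat, meta)
}

#' Counts per million
#'
#' \code{cpm[g, s] = counts[g, s] / library_size[s] * 1e6}; every column of
#' the result sums to 1e6.
#'
#' @param counts a \code{\link{count_matrix}}.
#' @return Numeric matrix of the same dimensions.
#' @export
cpm <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  lib <- colSums(counts$counts)
  if (any(lib == 0))
    stop("zero library size for sample(s): ",
         paste(colnames(counts$counts)[lib == 0], collapse = ", "),
         call. = FALSE)
  sweep(counts$counts, 2, lib, `/`) * 1e6
}

#' Filter genes by mean CPM
#'
#' Keeps exactly the genes whose mean CPM across all samples is strictly
#' greater than \code{threshold} (default 1, the usual read-density bar for
#' inclusion in network analyses). Gene order is preserved; idempotent.
#'
#' @param counts a \code{\link{count_matrix}}.
#' @param threshold non-negative mean-CPM cutoff.
#' @return The filtered \code{\link{count_matrix}}.
#' @export
filter_by_cpm <- function(counts, threshold = 1) {
  stopifnot(inherits(counts, "count_matrix"))
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0)
    stop("threshold must be a single non-negative number", call. = FALSE)
  keep <- rowMeans(cpm(counts)) > threshold
  count_matrix(counts$counts[keep, , drop = FALSE], counts$meta)
}

#' Upper-quartile normalization to log2 CPM
#'
#' Per-sample scaling factors are the 75th percentiles (linear interpolation)
#' of the library-size-scaled counts, taken over genes with nonzero total
#' count, rescaled to geometric mean 1. Normalized values are
#' \code{log2((count + pc_s) / (factor * library_size) * 1e6)} where
#' \code{pc_s} is the pseudocount scaled by the sample's effective library
#' size relative to the mean, so two samples that are exact scalar multiples
#' of each other normalize to identical columns.
#'
#' @param counts a filtered \code{\link{count_matrix}}.
#' @param pseudocount added before the log (default 0.5).
#' @return A list of class \code{"expr_matrix"}: \code{values} (log2 CPM
#'   matrix), \code{meta}, \code{norm_factors}.
#' @export
upper_quartile_normalize <- function(counts, pseudocount = 0.5) {
  stopifnot(inherits(counts, "count_matrix"))
  lib <- colSums(counts$counts)
  if (any(lib == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts$counts)[lib == 0], collapse = ", "),
         call. = FALSE)
  nz <- rowSums(counts$counts) > 0
  if (!any(nz)) stop("no genes with nonzero counts", call. = FALSE)
  q75 <- apply(counts$counts[nz, , drop = FALSE], 2,
               stats::quantile, probs = 0.75, type = 7) / lib
  factors <- q75 / geometric_mean(q75)
  eff <- factors * lib
  pc <- pseudocount * eff / mean(eff)
  values <- log2(sweep(sweep(counts$counts, 2, pc, `+`), 2, eff, `/`) * 1e6)
  structure(list(values = values, meta = counts$meta, norm_factors = factors),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (log2 CPM, UQ-normalized)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

subset_expr <- function(expr, genes = NULL, samples = NULL) {
  v <- expr$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  meta <- expr$meta
  if (!is.null(samples)) {
    v <- v[, samples, drop = FALSE]
    meta <- meta[match(samples, meta$sample_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  structure(list(values = v, meta = meta, norm_factors = expr$norm_factors),
            class = "expr_matrix")
}

#' Genes with large expression differences between regions
#'
#' Flags genes whose ratio of mean linear-scale expression between any two
#' regions reaches \code{fold}, reporting the direction (region with the
#' higher mean).
#'
#' @param expr_by_region named list (region -> \code{expr_matrix}) sharing a
#'   gene universe (the intersection is used).
#' @param fold minimum ratio (default 10).
#' @return data.frame with columns \code{gene}, \code{region_a},
#'   \code{region_b}, \code{ratio} (>= fold), \code{higher}.
#' @export
region_fold_differences <- function(expr_by_region, fold = 10) {
  stopifnot(is.list(expr_by_region), length(expr_by_region) >= 2)
  genes <- Reduce(intersect, lapply(expr_by_region, function(e) rownames(e$values)))
  if (length(genes) == 0) stop("no genes shared across regions", call. = FALSE)
  means <- vapply(expr_by_region, function(e)
    rowMeans(2^e$values[genes, , drop = FALSE]), numeric(length(genes)))
  means <- matrix(means, nrow = length(genes),
                  dimnames = list(genes, names(expr_by_region)))
  regions <- names(expr_by_region)
  out <- list()
  for (i in seq_len(length(regions) - 1)) for (j in (i + 1):length(regions)) {
    ratio <- means[, i] / means[, j]
    hit <- ratio >= fold | ratio <= 1 / fold
    if (!any(hit)) next
    r <- ratio[hit]
    out[[length(out) + 1]] <- data.frame(
      gene = genes[hit], region_a = regions[i], region_b = regions[j],
      ratio = pmax(r, 1 / r),
      higher = ifelse(r >= 1, regions[i], regions[j]),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(gene = character(0), region_a = character(0),
                      region_b = character(0), ratio = numeric(0),
                      higher = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
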