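#' Filter lowly expressed genes
#'
#' Two stages: (1) drop genes with zero counts in every sample; (2) after
#' library-size normalization (count scaled by mean library size over sample
#' library size, library size being the column sum after stage 1), keep genes
#' with normalized count strictly greater than `min_count` in at least
#' `min_samples` samples.
#'
#' @param counts Non-negative count matrix, genes x samples.
#' @param min_count Normalized-count threshold (strict inequality).
#' @param min_samples Minimum number of samples above threshold.
#' @return Filtered count matrix, gene order preserved, with attributes
#'   `n_zero_removed` and `n_low_removed`.
#' @export
filter_genes <- function(counts, min_count = 5, min_samples = 2) {
  if (any(counts < 0)) stop("counts must be non-negative")
  nonzero <- rowSums(counts) > 0
  n_zero <- sum(!nonzero)
  counts1 <- counts[nonzero, , drop = FALSE]
  lib <- colSums(counts1)
  norm <- sweep(counts1, 2, mean(lib) / lib, `*`)
  keep <- rowSums(norm > min_count) >= min_samples
  n_low <- sum(!keep)
  if (!any(keep)) {
    stop(sprintf("no genes survive filtering (> %g normalized counts in >= %d samples)",
                 min_count, min_samples))
  }
  out <- counts1[keep, , drop = FALSE]
  attr(out, "n_zero_removed") <- n_zero
  attr(out, "n_low_removed") <- n_low
  out
}

#' Library-size normalization and log2 transform
#'
#' Computes `log2(count * (mean library size / sample library size) + 1)`.
#' The +1 pseudocount keeps values finite and stabilizes the variance at the
#' low-expression end.
#'
#' @param counts Non-negative count matrix.
#' @param library_sizes Per-sample library sizes; defaults to column sums.
#' @return Matrix of log2 normalized values (class-less, same dimnames), with
#'   attribute `library_sizes`.
#' @export
normalize_log2 <- function(counts, library_sizes = colSums(counts)) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(library_sizes <= 0)) stop("library sizes must be > 0")
  out <- log2(sweep(counts, 2, mean(library_sizes) / library_sizes, `*`) + 1)
  attr(out, "library_sizes") <- library_sizes
  out
}

#' Trimmed mean of M-values scale factors
#'
#' Robinson-Oshlack TMM normalization: for each sample against the reference,
#' gene-wise log ratios of relative proportions (M values) and average log
#' abundances (A values) are doubly trimmed (30% on M, 5% on A, each side),
#' and the factor is two to the precision-weighted mean of the retained M
#' values, with weights from the inverse asymptotic (delta-method) variance.
#' Factors are rescaled to have geometric mean one.
#'
#' @param counts Count matrix with at least two samples.
#' @param ref_sample Reference column name or index; default picks the sample
#'   whose upper-quartile proportion is closest to the mean of those
#'   quartiles.
#' @param trim_m,trim_a Two-sided trim fractions for M and A values.
#' @return Numeric vector of positive factors, one per sample, with attribute
#'   `ref_sample`.
#' @export
tmm_factors <- function(counts, ref_sample = NULL, trim_m = 0.3, trim_a = 0.05) {
  if (ncol(counts) < 2) stop("TMM needs at least two samples")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("sample(s) with all-zero counts: ",
         toString(colnames(counts)[lib == 0]))
  }
  if (is.null(ref_sample)) {
    uq <- apply(counts, 2, function(x) stats::quantile(x / sum(x), 0.75))
    ref_sample <- which.min(abs(uq - mean(uq)))
  }
  if (is.character(ref_sample)) ref_sample <- match(ref_sample, colnames(counts))
  xr <- counts[, ref_sample]
  nr <- lib[ref_sample]
  factors <- vapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    n <- lib[j]
    ok <- x > 0 & xr > 0
    if (!any(ok)) return(1)
    m <- log2((x[ok] / n) / (xr[ok] / nr))
    a <- 0.5 * log2((x[ok] / n) * (xr[ok] / nr))
    w <- 1 / ((n - x[ok]) / (n * x[ok]) + (nr - xr[ok]) / (nr * xr[ok]))
    keep_m <- m >= stats::quantile(m, trim_m, type = 7) &
      m <= stats::quantile(m, 1 - trim_m, type = 7)
    keep_a <- a >= stats::quantile(a, trim_a, type = 7) &
      a <= stats::quantile(a, 1 - trim_a, type = 7)
    keep <- keep_m & keep_a
    if (!any(keep)) return(1)
    2^(sum(w[keep] * m[keep]) / sum(w[keep]))
  }, numeric(1))
  factors <- factors / exp(mean(log(factors)))
  names(factors) <- colnames(counts)
  attr(factors, "ref_sample") <- ref_sample
  factors
}

#' PCA on the top-variance genes
#'
#' Selects the `n_top` genes with highest row variance of the (log-scale)
#' normalized matrix, centers each gene, and computes sample-space principal
#' components.
#'
#' @param norm Log2 normalized matrix, genes x samples.
#' @param n_top Number of top-variance genes to use.
#' @return List with `coords` (samples x PCs), `var_frac` (variance fraction
#'   per PC, non-increasing, summing to 1), and `genes` (the selected genes).
#' @export
pca_top_variance <- function(norm, n_top = 500) {
  if (ncol(norm) < 3) stop("PCA needs at least three samples")
  if (n_top > nrow(norm)) stop("`n_top` exceeds the number of genes")
  rv <- rowVars(norm)
  top <- order(rv, decreasing = TRUE)[seq_len(n_top)]
  x <- t(norm[top, , drop = FALSE])
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  list(coords = pc$x, var_frac = var_frac, genes = rownames(norm)[top])
}

rowVars <- function(x) {
  m <- rowMeans(x)
  rowSums((x - m)^2) / (ncol(x) - 1)
}

#' Preprocess a count matrix end to end
#'
#' Convenience wrapper: filter, compute TMM factors, and log2-normalize on
#' TMM-effective library sizes (library size times TMM factor), so that
#' compositional shifts — e.g. a handful of strongly induced genes inflating
#' a sample's total — do not masquerade as global down-regulation.
#'
#' @param counts Raw count matrix.
#' @param min_count,min_samples Passed to [filter_genes()].
#' @return List with `counts` (filtered), `norm` (log2 normalized),
#'   `tmm` (scale factors), `library_sizes`.
#' @export
preprocess_counts <- function(counts, min_count = 5, min_samples = 2) {
  filtered <- filter_genes(counts, min_count, min_samples)
  lib <- colSums(filtered)
  tmm <- tmm_factors(filtered)
  norm <- normalize_log2(filtered, lib * tmm)
  list(counts = filtered, norm = norm, tmm = tmm, library_sizes = lib,
       n_zero_removed = attr(filtered, "n_zero_removed"),
       n_low_removed = attr(filtered, "n_low_removed"))
}
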