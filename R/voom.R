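#' Precision weights from the mean-variance trend of log counts
#'
#' Re-implementation of the voom idea: log2-CPM values (0.5 offset, TMM
#' effective library sizes) are fitted gene-wise by least squares on the
#' design; a lowess trend of the square-root residual standard deviation
#' against average log2 count is interpolated at each fitted log2 count; the
#' precision weight of an observation is the inverse fourth power of the
#' trend value (i.e. the inverse of the predicted variance).
#'
#' @param counts Filtered count matrix, genes x samples.
#' @param design Design matrix (samples x columns), full column rank, with an
#'   intercept.
#' @param scale_factors Optional TMM factors from [tmm_factors()].
#' @param lib_sizes Library sizes; defaults to column sums.
#' @param span Lowess span for the trend.
#' @return List with `logcpm` (log2-CPM matrix), `weights` (same shape, all
#'   positive), `trend` (list `x`, `y` of the lowess curve), and
#'   `fitted_logcount` (matrix at which the trend was evaluated).
#' @export
voom_weights <- function(counts, design, scale_factors = NULL,
                         lib_sizes = colSums(counts), span = 0.5) {
  n <- ncol(counts)
  if (nrow(design) != n) stop("design rows must match samples")
  if (qr(design)$rank < ncol(design)) stop("design matrix is rank deficient")
  eff_lib <- if (is.null(scale_factors)) lib_sizes else
    lib_sizes * scale_factors
  y <- t(log2(t(counts + 0.5) / (eff_lib + 1) * 1e6))
  fit <- stats::lm.fit(design, t(y))
  df_resid <- n - ncol(design)
  s <- sqrt(colSums(as.matrix(fit$residuals)^2) / df_resid)
  sx <- rowMeans(y) + mean(log2(eff_lib + 1)) - log2(1e6)
  sy <- sqrt(s)
  if (diff(range(sx)) < 1e-8 || all(sy == 0)) {
    warning("degenerate mean-variance trend; using uniform weights")
    w <- matrix(1, nrow(counts), n, dimnames = dimnames(counts))
    return(list(logcpm = y, weights = w,
                trend = list(x = range(sx), y = c(1, 1)),
                fitted_logcount = y))
  }
  lo <- stats::lowess(sx, sy, f = span)
  trend_fun <- stats::approxfun(lo$x, lo$y, rule = 2, ties = mean)
  fitted_cpm <- t(design %*% fit$coefficients)
  fitted_logcount <- t(t(fitted_cpm) + log2(eff_lib + 1) - log2(1e6))
  dimnames(fitted_logcount) <- dimnames(counts)
  w <- trend_fun(fitted_logcount)^-4
  w <- matrix(w, nrow(counts), n, dimnames = dimnames(counts))
  if (any(!is.finite(w)) || any(w <= 0)) {
    warning("non-finite precision weights; using uniform weights")
    w[] <- 1
  }
  list(logcpm = y, weights = w, trend = list(x = lo$x, y = lo$y),
       fitted_logcount = fitted_logcount)
}

#' Evaluate a stored mean-variance trend
#'
#' Recomputes precision weights from a `trend` and fitted log2 counts as
#' returned by [voom_weights()] (internal-consistency contract).
#'
#' @param trend List with `x`, `y` from [voom_weights()].
#' @param fitted_logcount Matrix of fitted log2 counts.
#' @return Weight matrix.
#' @export
trend_weights <- function(trend, fitted_logcount) {
  f <- stats::approxfun(trend$x, trend$y, rule = 2, ties = mean)
  w <- f(fitted_logcount)^-4
  matrix(w, nrow(fitted_logcount), ncol(fitted_logcount),
         dimnames = dimnames(fitted_logcount))
}
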