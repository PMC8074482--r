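#' Natural cubic spline design for a time vector
#'
#' Intercept plus a natural cubic spline basis with `df` degrees of freedom;
#' interior knots at quantiles of the (restricted) sample times, boundary
#' knots at the extremes.
#'
#' @param time_h Sample times (replicates included as repeated values).
#' @param df Spline degrees of freedom.
#' @return Design matrix with an intercept column named `(Intercept)`.
#' @export
spline_design <- function(time_h, df = 3) {
  if (length(unique(time_h)) < df + 2) {
    stop("need at least df + 2 distinct times for a spline fit")
  }
  basis <- splines::ns(time_h, df = df)
  X <- cbind(`(Intercept)` = 1, basis)
  colnames(X)[-1] <- paste0("spline", seq_len(df))
  X
}

## Gene-wise weighted least squares with a shared design and per-gene
## weights. Returns coefficients, residual sums of squares of the full and
## intercept-only fits, and the residual df.
wls_by_gene <- function(y, X, weights) {
  n <- ncol(y)
  k <- ncol(X)
  G <- nrow(y)
  coefs <- matrix(NA_real_, G, k, dimnames = list(rownames(y), colnames(X)))
  rss1 <- rss0 <- numeric(G)
  for (g in seq_len(G)) {
    w <- weights[g, ]
    sw <- sqrt(w)
    fit <- stats::lm.fit(X * sw, y[g, ] * sw)
    if (fit$rank < k) stop("rank-deficient weighted design")
    coefs[g, ] <- fit$coefficients
    rss1[g] <- sum(fit$residuals^2)
    mu0 <- sum(w * y[g, ]) / sum(w)
    rss0[g] <- sum(w * (y[g, ] - mu0)^2)
  }
  list(coefficients = coefs, rss1 = rss1, rss0 = rss0, df_resid = n - k)
}

#' Spline time-dependence test with empirical-Bayes moderation
#'
#' Fits a natural cubic spline (default 3 df) of expression on time by
#' weighted least squares per gene, restricted to times at or below
#' `horizon_h`, squeezes residual variances across genes
#' ([squeeze_var()]), and tests the spline coefficients (not the intercept)
#' with a moderated F statistic. Replicates enter as independent samples
#' sharing the time covariate.
#'
#' @param y Matrix of expression values on the log2 scale (e.g. `logcpm` from
#'   [voom_weights()]), genes x samples.
#' @param samples Sample sheet (`sample_id`, `time_h`, `replicate`).
#' @param horizon_h Use samples with `time_h <= horizon_h` (8 or 48 in the
#'   reference design).
#' @param df Spline degrees of freedom.
#' @param weights Optional precision-weight matrix (same shape as `y`);
#'   uniform if `NULL`.
#' @return A `DETable` data.frame: `gene`, spline coefficients, `sigma2`
#'   (residual variance), `F`, `p`, `q` (BH across genes), with attributes
#'   `horizon_h`, `df_resid`, `df_prior`, `var_prior`, `method`.
#' @export
spline_fit_test <- function(y, samples, horizon_h = 48, df = 3,
                            weights = NULL) {
  sel <- samples$time_h <= horizon_h
  if (!any(sel)) stop("no samples at or below horizon ", horizon_h, " h")
  ys <- y[, sel, drop = FALSE]
  tt <- samples$time_h[sel]
  X <- tryCatch(spline_design(tt, df),
                error = function(e) stop("horizon ", horizon_h, " h: ",
                                         conditionMessage(e)))
  if (is.null(weights)) weights <- matrix(1, nrow(ys), ncol(ys))
  else weights <- weights[, sel, drop = FALSE]
  fit <- wls_by_gene(ys, X, weights)
  s2 <- fit$rss1 / fit$df_resid
  sq <- squeeze_var(s2, fit$df_resid)
  Fstat <- ((fit$rss0 - fit$rss1) / df) / sq$var_post
  df2 <- fit$df_resid + min(sq$df_prior, 1e6)
  p <- stats::pf(Fstat, df, df2, lower.tail = FALSE)
  out <- data.frame(gene = rownames(ys), fit$coefficients, sigma2 = s2,
                    F = Fstat, p = p, q = bh_adjust(p),
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  attr(out, "horizon_h") <- horizon_h
  attr(out, "df_resid") <- fit$df_resid
  attr(out, "df_prior") <- sq$df_prior
  attr(out, "var_prior") <- sq$var_prior
  attr(out, "method") <- "spline-ebayes-F"
  out
}

#' Cubic polynomial time-dependence test with a goodness-of-fit filter
#'
#' Per-gene ordinary least squares on `1, t, t^2, t^3` over the first
#' `horizon_h` hours, an overall regression F-test, BH correction, and a
#' selection flag requiring both `q < fdr` and `R^2 >= r2_min`.
#'
#' @param y Log2 expression matrix.
#' @param samples Sample sheet.
#' @param degree Polynomial degree.
#' @param r2_min Minimum coefficient of determination for selection.
#' @param horizon_h Time horizon in hours.
#' @param fdr BH threshold used for the `selected` flag.
#' @return `DETable` data.frame with `gene`, coefficients, `r2`, `F`, `p`,
#'   `q`, `selected`.
#' @export
polynomial_fit_test <- function(y, samples, degree = 3, r2_min = 0.6,
                                horizon_h = 48, fdr = 0.05) {
  sel <- samples$time_h <= horizon_h
  tt <- samples$time_h[sel]
  if (length(unique(tt)) < degree + 2) {
    stop("need at least degree + 2 distinct times")
  }
  ys <- y[, sel, drop = FALSE]
  X <- stats::poly(tt, degree = degree, raw = TRUE)
  X <- cbind(`(Intercept)` = 1, X)
  colnames(X)[-1] <- paste0("t", seq_len(degree))
  fit <- stats::lm.fit(X, t(ys))
  rss1 <- colSums(as.matrix(fit$residuals)^2)
  tss <- rowSums((ys - rowMeans(ys))^2)
  df_resid <- length(tt) - degree - 1
  r2 <- 1 - rss1 / tss
  Fstat <- ((tss - rss1) / degree) / (rss1 / df_resid)
  p <- stats::pf(Fstat, degree, df_resid, lower.tail = FALSE)
  q <- bh_adjust(p)
  out <- data.frame(gene = rownames(ys), t(fit$coefficients), r2 = r2,
                    F = Fstat, p = p, q = q,
                    selected = q < fdr & r2 >= r2_min,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  attr(out, "method") <- "polynomial-F"
  out
}

#' Partition genes by which spline horizon detects them
#'
#' @param short,long `DETable`s from [spline_fit_test()] at the short and
#'   long horizon, over the same gene universe.
#' @param fdr Significance threshold on `q`.
#' @return List of gene-id vectors: `short_only`, `long_only`, `both`,
#'   `union`.
#' @export
select_time_dependent <- function(short, long, fdr = 0.05) {
  if (!setequal(short$gene, long$gene)) {
    stop("short and long tables cover different gene universes")
  }
  s <- short$gene[short$q < fdr]
  l <- long$gene[long$q < fdr]
  list(short_only = setdiff(s, l), long_only = setdiff(l, s),
       both = intersect(s, l), union = union(s, l))
}
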