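#' Empirical-Bayes variance moderation
#'
#' Shrinks gene-wise residual variances toward a prior estimated across genes,
#' assuming a scaled inverse chi-square prior. The prior degrees of freedom
#' and scale are estimated by moment matching on the log variances: under the
#' hierarchical model, `log(s^2)` follows a scaled log-F distribution whose
#' mean and variance involve digamma/trigamma functions; the trigamma
#' equation is inverted by Newton iteration.
#'
#' @param s2 Gene-wise residual variances (zeros are clamped at 1e-12).
#' @param df Residual degrees of freedom (scalar, shared across genes).
#' @return List with `var_post` (moderated variances), `var_prior` (`s0^2`),
#'   and `df_prior` (possibly `Inf`).
#' @export
squeeze_var <- function(s2, df) {
  if (df <= 0) stop("residual df must be > 0")
  s2 <- pmax(s2, 1e-12)
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  e_mean <- mean(e)
  e_var <- sum((e - e_mean)^2) / (length(e) - 1) - trigamma(df / 2)
  if (is.na(e_var) || e_var <= 0) {
    df_prior <- Inf
    var_prior <- exp(e_mean)
  } else {
    df_prior <- 2 * trigamma_inverse(e_var)
    var_prior <- exp(e_mean + digamma(df_prior / 2) - log(df_prior / 2))
  }
  var_post <- if (is.infinite(df_prior)) rep(var_prior, length(s2)) else
    (df_prior * var_prior + df * s2) / (df_prior + df)
  list(var_post = var_post, var_prior = var_prior, df_prior = df_prior)
}

## Newton inversion of trigamma(y) = x for y > 0 (monotone decreasing).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over `p.adjust(method = "BH")`, kept as the package's single
#' FDR entry point.
#'
#' @param p Vector of p-values.
#' @return BH-adjusted q-values.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
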