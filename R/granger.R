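#' Sliding windows over a time grid
#'
#' Windows cover `width` consecutive grid positions regardless of wall-clock
#' spacing, overlap by `width - 1`, and are indexed from 1 at the earliest
#' start.
#'
#' @param grid A [time_grid()].
#' @param width Number of consecutive time points per window.
#' @return data.frame: `index`, `start` (grid position), `first_h`, `last_h`.
#' @export
make_windows <- function(grid, width = 6) {
  stopifnot_grid(grid)
  nt <- length(grid$times)
  if (nt < width) stop("need at least ", width, " time points")
  n_win <- nt - width + 1
  data.frame(index = seq_len(n_win), start = seq_len(n_win),
             first_h = grid$times[seq_len(n_win)],
             last_h = grid$times[seq_len(n_win) + width - 1])
}

## Extract per-window lag-1 transition matrices. Each gene's 6 values are
## centered and unit-scaled within window x replicate, then within-replicate
## transitions are stacked (no cross-replicate transitions): with width 6 and
## two replicates this yields n = 10 realized transitions.
## Returns X (rows = transitions, cols = genes, values at step t), Y (values
## at step t + 1), and `degenerate` (genes with zero variance in the window).
window_transitions <- function(norm, samples, grid, window_start, width = 6) {
  idx <- window_start:(window_start + width - 1)
  times <- grid$times[idx]
  reps <- sort(unique(samples$replicate))
  Xs <- list(); Ys <- list()
  degenerate <- rep(FALSE, nrow(norm))
  for (r in reps) {
    cols <- vapply(times, function(tp) {
      which(samples$time_h == tp & samples$replicate == r)
    }, integer(1))
    block <- norm[, cols, drop = FALSE]
    mu <- rowMeans(block)
    sd_ <- apply(block, 1, stats::sd)
    degenerate <- degenerate | sd_ < 1e-10
    z <- (block - mu) / ifelse(sd_ < 1e-10, 1, sd_)
    z[sd_ < 1e-10, ] <- 0
    Xs[[length(Xs) + 1L]] <- t(z[, seq_len(width - 1), drop = FALSE])
    Ys[[length(Ys) + 1L]] <- t(z[, 2:width, drop = FALSE])
  }
  X <- do.call(rbind, Xs)
  Y <- do.call(rbind, Ys)
  colnames(X) <- colnames(Y) <- rownames(norm)
  list(X = X, Y = Y, degenerate = degenerate, times = times)
}

#' Bivariate Granger-causality tests within one window
#'
#' For every ordered gene pair (x -> y), fits the lag-1 regression
#' `y_{t+1} = a + alpha y_t + beta x_t + e` by ordinary least squares on the
#' stacked within-replicate transitions (the intercept matches `lm()`'s
#' default formula and absorbs the response's nonzero window mean) and
#' reports the two-sided t-test of `beta = 0`. Pairs involving a
#' zero-variance (within window) gene are flagged degenerate with
#' `beta = 0`, `p = 1`.
#'
#' @param norm Log2 normalized matrix restricted to the genes of interest.
#' @param samples Sample sheet.
#' @param grid The [time_grid()].
#' @param window_start Grid position at which the window starts.
#' @param width Window width (time points).
#' @return data.frame: `source`, `target`, `beta`, `t`, `p`, `degenerate`.
#' @export
bivariate_gc_window <- function(norm, samples, grid, window_start, width = 6) {
  tr <- window_transitions(norm, samples, grid, window_start, width)
  X <- tr$X; Y <- tr$Y
  n <- nrow(X); p <- ncol(X)
  genes <- colnames(X)
  df_resid <- n - 3
  out <- vector("list", p)
  for (j in seq_len(p)) {          # target gene y
    y1 <- Y[, j]
    base <- cbind(1, X[, j])
    qr_b <- qr(base)
    ry <- qr.resid(qr_b, y1)
    RX <- qr.resid(qr_b, X)
    sxx <- colSums(RX^2)
    sxy <- colSums(RX * ry)
    ok <- sxx > 1e-12 & !tr$degenerate & !tr$degenerate[j]
    beta <- ifelse(ok, sxy / sxx, 0)
    rss <- pmax(sum(ry^2) - beta^2 * sxx, 0)
    se <- sqrt(rss / df_resid / sxx)
    tstat <- ifelse(ok & se > 0, beta / se, 0)
    pval <- ifelse(ok & se > 0,
                   2 * stats::pt(abs(tstat), df_resid, lower.tail = FALSE), 1)
    res <- data.frame(source = genes, target = genes[j], beta = beta,
                      t = tstat, p = pval, degenerate = !ok,
                      stringsAsFactors = FALSE)
    out[[j]] <- res[-j, ]
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

## ---- LASSO and de-biasing machinery ---------------------------------------

## lasso with glmnet at a single penalty; lambda uses the 1/(2n) RSS
## parameterization. lambda = 0 with p < n falls back to exact OLS.
lasso_fit <- function(X, y, lambda) {
  p <- ncol(X)
  if (lambda == 0 && p < nrow(X)) {
    return(qr.solve(X, y))
  }
  fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = 1,
                        lambda = lambda, standardize = FALSE,
                        intercept = FALSE, thresh = 1e-10)
  as.numeric(fit$beta)
}

## scaled-lasso noise level: alternate lasso at lambda = 1.1 * sigma * lam0
## and sigma^2 = RSS / n until sigma stabilizes
scaled_lasso_sigma <- function(X, y, lam0, max_iter = 20) {
  n <- nrow(X)
  sigma <- stats::sd(y)
  if (sigma < 1e-12) return(list(sigma = 0, beta = numeric(ncol(X))))
  beta <- numeric(ncol(X))
  for (i in seq_len(max_iter)) {
    beta <- lasso_fit(X, y, 1.1 * sigma * lam0)
    res <- y - X %*% beta
    sigma_new <- sqrt(sum(res^2) / n)
    if (sigma_new < 1e-12) { sigma <- sigma_new; break }
    if (abs(sigma_new - sigma) < 1e-6 * sigma) { sigma <- sigma_new; break }
    sigma <- sigma_new
  }
  list(sigma = sigma, beta = beta)
}

## node-wise-lasso relaxed inverse (van de Geer et al. style): row j comes
## from the lasso regression of X_j on the remaining columns
debias_M_nodewise <- function(X, lam0) {
  n <- nrow(X); p <- ncol(X)
  M <- matrix(0, p, p)
  for (j in seq_len(p)) {
    xj <- X[, j]
    Xmj <- X[, -j, drop = FALSE]
    sl <- scaled_lasso_sigma(Xmj, xj, lam0)
    gamma <- sl$beta
    tau2 <- sum(xj * (xj - Xmj %*% gamma)) / n
    if (tau2 < 1e-10) tau2 <- 1e-10
    M[j, j] <- 1 / tau2
    M[j, -j] <- -gamma / tau2
  }
  M
}

## convex-program approximate inverse (Javanmard-Montanari style): row j
## minimizes m' Sigma m - 2 m_j + 2 mu |m|_1 by coordinate descent, whose
## stationarity conditions enforce |Sigma m - e_j|_inf <= mu
debias_M_jm <- function(X, mu, max_iter = 200) {
  n <- nrow(X); p <- ncol(X)
  Sigma <- crossprod(X) / n
  M <- matrix(0, p, p)
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  for (j in seq_len(p)) {
    mu_j <- mu
    repeat {
      m <- numeric(p)
      m[j] <- 1 / Sigma[j, j]
      converged <- FALSE
      for (it in seq_len(max_iter)) {
        m_old <- m
        for (k in seq_len(p)) {
          ej <- as.numeric(k == j)
          r <- ej - sum(Sigma[k, ] * m) + Sigma[k, k] * m[k]
          m[k] <- soft(r, mu_j) / Sigma[k, k]
        }
        if (max(abs(m - m_old)) < 1e-8) { converged <- TRUE; break }
      }
      if (converged || mu_j > 1) break
      mu_j <- mu_j * 1.5
    }
    M[j, ] <- m
  }
  M
}

#' Multivariate (network) Granger causality within one window
#'
#' Regresses each target gene's next-step value on the current values of all
#' `p` genes jointly: a LASSO fit at the universal penalty
#' `lambda = 1.1 * sigma_hat * sqrt(2 log(p) / n)` (noise level via scaled
#' lasso, with a degrees-of-freedom correction `RSS/(n - s - 1)` over the
#' selected support size `s` for the reported standard errors, which the
#' plain `RSS/n` estimate understates at these window sample sizes), then a
#' de-biased estimate `beta_d = beta + M X'(y - X beta)/n`
#' with `M` from either the node-wise-lasso relaxed inverse
#' (`variant = "nodewise"`) or the convex-program approximate inverse
#' (`variant = "jm"`), and a two-sided normal-approximation p-value per
#' coefficient. With `lambda = 0` and `p < n` both variants reduce exactly to
#' ordinary least squares.
#'
#' @param norm Log2 normalized matrix restricted to the gene set.
#' @param samples Sample sheet.
#' @param grid The [time_grid()].
#' @param window_start Grid position of the window start.
#' @param width Window width.
#' @param variant `"nodewise"` or `"jm"`.
#' @param lambda Optional fixed penalty overriding the universal choice
#'   (`0` forces the OLS limit; requires `p < n`).
#' @return data.frame: `source`, `target`, `beta` (de-biased), `se`, `p`,
#'   `alpha` (the target's own autoregressive de-biased coefficient).
#' @export
multivariate_gc_window <- function(norm, samples, grid, window_start,
                                   width = 6,
                                   variant = c("nodewise", "jm"),
                                   lambda = NULL) {
  variant <- match.arg(variant)
  tr <- window_transitions(norm, samples, grid, window_start, width)
  X <- tr$X; Y <- tr$Y
  n <- nrow(X); p <- ncol(X)
  if (n < 3) stop("window ", window_start, ": fewer than 3 transitions")
  genes <- colnames(X)
  lam0 <- sqrt(2 * log(p) / n)
  Sigma <- crossprod(X) / n
  M <- if (!is.null(lambda) && lambda == 0 && p < n) {
    n * solve(crossprod(X))
  } else if (variant == "nodewise") {
    debias_M_nodewise(X, lam0)
  } else {
    debias_M_jm(X, mu = lam0 / 1.5)
  }
  MSM <- M %*% Sigma %*% t(M)
  var_scale <- diag(MSM) / n
  out <- vector("list", p)
  for (j in seq_len(p)) {
    y1 <- Y[, j]
    if (tr$degenerate[j]) {
      out[[j]] <- data.frame(source = genes[-j], target = genes[j], beta = 0,
                             se = NA_real_, p = 1, alpha = 0,
                             stringsAsFactors = FALSE)
      next
    }
    beta <- if (is.null(lambda)) scaled_lasso_sigma(X, y1, lam0)$beta else
      lasso_fit(X, y1, lambda)
    resid <- y1 - X %*% beta
    ## degrees-of-freedom-corrected noise level: the plain scaled-lasso
    ## sigma (RSS/n) is biased down at these sample sizes
    n_sel <- sum(beta != 0)
    sigma <- sqrt(sum(resid^2) / max(n - n_sel - 1, 1))
    beta_d <- as.numeric(beta + M %*% crossprod(X, resid) / n)
    se <- sigma * sqrt(var_scale)
    z <- ifelse(se > 0, beta_d / se, 0)
    pval <- ifelse(se > 0, 2 * stats::pnorm(abs(z), lower.tail = FALSE), 1)
    pval[tr$degenerate] <- 1
    res <- data.frame(source = genes, target = genes[j], beta = beta_d,
                      se = se, p = pval, alpha = beta_d[j],
                      stringsAsFactors = FALSE)
    out[[j]] <- res[-j, ]
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Sliding-window Granger-causality scan
#'
#' Runs [bivariate_gc_window()] or [multivariate_gc_window()] over all (or
#' selected) windows and stacks the per-window regressions.
#'
#' @param norm Log2 normalized matrix restricted to the gene set.
#' @param samples Sample sheet.
#' @param grid The [time_grid()].
#' @param mode `"bivariate"` or `"multivariate"`.
#' @param variant De-biasing variant for multivariate mode.
#' @param width Window width.
#' @param windows Optional integer vector of window indices (default all).
#' @return Long data.frame with a `window` column plus the per-window
#'   regression columns.
#' @export
granger_scan <- function(norm, samples, grid,
                         mode = c("bivariate", "multivariate"),
                         variant = "nodewise", width = 6, windows = NULL) {
  mode <- match.arg(mode)
  win <- make_windows(grid, width)
  if (!is.null(windows)) win <- win[win$index %in% windows, , drop = FALSE]
  res <- lapply(seq_len(nrow(win)), function(i) {
    w <- win$start[i]
    tab <- if (mode == "bivariate") {
      bivariate_gc_window(norm, samples, grid, w, width)
    } else {
      multivariate_gc_window(norm, samples, grid, w, width, variant)
    }
    tab$window <- win$index[i]
    tab
  })
  out <- do.call(rbind, res)
  attr(out, "windows") <- win
  attr(out, "mode") <- mode
  out
}

## longest run of consecutive window indices with consistent sign;
## returns length and the sign of that run
max_sign_run <- function(win_idx, signs) {
  if (length(win_idx) == 0) return(list(len = 0L, sign = NA_real_))
  o <- order(win_idx)
  w <- win_idx[o]; s <- signs[o]
  best_len <- 1L; best_sign <- s[1]
  cur_len <- 1L
  if (length(w) > 1) {
    for (i in 2:length(w)) {
      if (w[i] == w[i - 1] + 1 && s[i] == s[i - 1]) {
        cur_len <- cur_len + 1L
      } else {
        cur_len <- 1L
      }
      if (cur_len > best_len) {
        best_len <- cur_len
        best_sign <- s[i]
      }
    }
  }
  list(len = best_len, sign = best_sign)
}

#' Aggregate per-window regressions into candidate edges
#'
#' BH correction is applied within each window across all tested
#' coefficients; for every ordered gene pair the maximal run of consecutive
#' significant windows with consistent coefficient sign is computed. The
#' overall sign is defined only when all significant windows agree.
#'
#' @param scan Long table from [granger_scan()].
#' @param fdr BH threshold for per-window significance.
#' @return `GCEdge` data.frame: `source`, `target`, `n_sig`, `run_len`,
#'   `run_sign`, `overall_sign` (NA when signs disagree), and list-columns
#'   `sig_windows`, `sig_signs`.
#' @export
aggregate_edges <- function(scan, fdr = 0.05) {
  scan$q <- stats::ave(scan$p, scan$window,
                       FUN = function(p) stats::p.adjust(p, "BH"))
  sig <- scan[scan$q < fdr, , drop = FALSE]
  if (nrow(sig) == 0) {
    return(data.frame(source = character(), target = character(),
                      n_sig = integer(), run_len = integer(),
                      run_sign = numeric(), overall_sign = numeric()))
  }
  key <- paste(sig$source, sig$target, sep = "\r")
  parts <- split(sig, key)
  rows <- lapply(parts, function(d) {
    run <- max_sign_run(d$window, sign(d$beta))
    all_sign <- unique(sign(d$beta))
    data.frame(source = d$source[1], target = d$target[1],
               n_sig = nrow(d), run_len = run$len, run_sign = run$sign,
               overall_sign = if (length(all_sign) == 1) all_sign else NA_real_,
               sig_windows = I(list(d$window)), sig_signs = I(list(sign(d$beta))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter candidate edges into a high-confidence lead-lag network
#'
#' Keeps edges whose qualifying run — at least `min_consecutive` consecutive
#' significant windows, all with the `keep_sign` coefficient sign, every
#' window's last time point at or below `horizon_h` — exists, and whose two
#' endpoints are not cyclic genes. Connected components are computed ignoring
#' edge direction and sorted by size.
#'
#' @param edges `GCEdge` table from [aggregate_edges()] (needs the
#'   list-columns).
#' @param cyclic_genes Character vector of cyclic gene ids (may be empty).
#' @param windows Window table from [make_windows()].
#' @param min_consecutive Minimum qualifying run length.
#' @param horizon_h Qualifying windows must end at or before this hour.
#' @param keep_sign `"negative"` or `"positive"`.
#' @return `GCNetwork` list: `nodes`, `edges` (data.frame), `components`
#'   (named membership vector), `n_components`.
#' @export
filter_network <- function(edges, cyclic_genes, windows, min_consecutive = 3,
                           horizon_h = 24, keep_sign = c("negative", "positive")) {
  keep_sign <- match.arg(keep_sign)
  want <- if (keep_sign == "negative") -1 else 1
  eligible <- windows$index[windows$last_h <= horizon_h]
  keep <- logical(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    if (edges$source[i] %in% cyclic_genes ||
        edges$target[i] %in% cyclic_genes) next
    w <- edges$sig_windows[[i]]
    s <- edges$sig_signs[[i]]
    ok <- w %in% eligible & s == want
    run <- max_sign_run(w[ok], s[ok])
    keep[i] <- run$len >= min_consecutive
  }
  kept <- edges[keep, c("source", "target", "n_sig", "run_len"), drop = FALSE]
  rownames(kept) <- NULL
  if (nrow(kept) == 0) {
    return(list(nodes = character(), edges = kept,
                components = integer(), n_components = 0L))
  }
  g <- igraph::graph_from_data_frame(kept[, 1:2], directed = FALSE)
  comp <- igraph::components(g)
  ord <- order(-comp$csize)
  relabel <- match(seq_along(comp$csize), ord)
  membership <- relabel[comp$membership]
  names(membership) <- names(comp$membership)
  list(nodes = names(membership), edges = kept, components = membership,
       n_components = comp$no)
}
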