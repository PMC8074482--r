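#' Resample a dense time course onto the regular 6 h rhythm grid
#'
#' Subsets the nine regularly spaced hours 0, 6, 12, 18, 24, 30, 36, 42, 48
#' from each replicate; the 18 h value, which the dense design does not
#' sample, is the mean of the 16 h and 20 h normalized values. Replicates are
#' kept separate.
#'
#' @param norm Log2 normalized matrix.
#' @param samples Sample sheet.
#' @return List with `values` (genes x 9*replicates matrix, columns
#'   `H<hour>_R<rep>` ordered hour-major), `hours` (the 9 grid hours), and
#'   `replicates`.
#' @export
resample_regular_grid <- function(norm, samples) {
  hours <- c(0, 6, 12, 18, 24, 30, 36, 42, 48)
  need <- c(0, 6, 12, 16, 20, 24, 30, 36, 42, 48)
  missing <- setdiff(need, samples$time_h)
  if (length(missing)) {
    stop("missing required time point(s): ", toString(missing), " h")
  }
  reps <- sort(unique(samples$replicate))
  cols <- list()
  for (h in hours) {
    for (r in reps) {
      v <- if (h == 18) {
        (norm[, samples$time_h == 16 & samples$replicate == r] +
           norm[, samples$time_h == 20 & samples$replicate == r]) / 2
      } else {
        norm[, samples$time_h == h & samples$replicate == r]
      }
      cols[[paste0("H", h, "_R", r)]] <- v
    }
  }
  values <- do.call(cbind, cols)
  rownames(values) <- rownames(norm)
  list(values = values, hours = hours, replicates = length(reps))
}

## --- exact Kendall null ----------------------------------------------------
## With a tie-free data vector and a tied cosine rank template, the Kendall S
## statistic is a linear function of a Jonckheere-Terpstra count J over the
## template's tie groups, and under permutation J is the independent sum of
## Mann-Whitney U counts U(n_1 + ... + n_{j-1}, n_j). The exact pmf follows
## by convolution of exact U pmfs.

## counts of Mann-Whitney U(m, n) arrangements, u = 0..m*n
mwu_counts <- function(m, n, cache = new.env(parent = emptyenv())) {
  key <- paste(m, n)
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- if (m == 0 || n == 0) 1 else {
    a <- mwu_counts(m - 1, n, cache)  # largest item from first group: adds n
    b <- mwu_counts(m, n - 1, cache)  # largest item from second group: adds 0
    out <- numeric(m * n + 1)
    out[n + seq_along(a)] <- a
    out[seq_along(b)] <- out[seq_along(b)] + b
    out
  }
  cache[[key]] <- res
  res
}

#' Exact null distribution of the Jonckheere-Terpstra count for tie groups
#'
#' @param group_sizes Sizes of the template's tie groups (order irrelevant).
#' @return Numeric vector of probabilities over `J = 0..max`, where max is
#'   the number of cross-group pairs.
#' @export
jt_null_pmf <- function(group_sizes) {
  cache <- new.env(parent = emptyenv())
  pmf <- 1
  cum <- 0
  ## sort so templates with the same tie-group multiset (e.g. a phase and
  ## its anti-phase) get bit-identical pmfs, keeping exact ties exact
  group_sizes <- sort(group_sizes)
  for (n_j in group_sizes) {
    if (cum > 0) {
      u <- mwu_counts(cum, n_j, cache)
      u <- u / sum(u)
      ## exact polynomial convolution (FFT round-off would break the exact
      ## symmetry of the null and hence deterministic tie-breaking)
      out <- numeric(length(pmf) + length(u) - 1)
      for (i in seq_along(u)) {
        idx <- i:(i + length(pmf) - 1)
        out[idx] <- out[idx] + u[i] * pmf
      }
      pmf <- out
    }
    cum <- cum + n_j
  }
  pmf <- (pmf + rev(pmf)) / 2   # enforce the exact symmetry of the null
  pmf / sum(pmf)
}

## Kendall S between data x and template y (sum over pairs of sign products)
kendall_s <- function(x, y) {
  sx <- sign(outer(x, x, `-`))
  sy <- sign(outer(y, y, `-`))
  ut <- upper.tri(sx)
  sum(sx[ut] * sy[ut])
}

## exact two-sided p for observed S given template tie-group sizes;
## J = (S + T)/2 with T the number of cross-group pairs
jtk_exact_p <- function(s_obs, group_sizes, pmf = jt_null_pmf(group_sizes)) {
  n_cross <- (sum(group_sizes)^2 - sum(group_sizes^2)) / 2
  j_obs <- (s_obs + n_cross) / 2
  idx <- round(j_obs) + 1
  p_le <- sum(pmf[seq_len(min(idx, length(pmf)))])
  p_ge <- sum(pmf[idx:length(pmf)])
  min(1, 2 * min(p_le, p_ge))
}

## build the cosine rank templates for the scanned lattice
jtk_templates <- function(hours, replicates, periods_h, step_h = 6) {
  templates <- list()
  for (P in periods_h) {
    for (phi in seq(0, P - step_h, by = step_h)) {
      ## round so exactly tied template values are seen as ties by the sign
      ## comparisons as well as by the tie-group bookkeeping
      tmpl <- round(cos(2 * pi * (hours - phi) / P), 9)
      tmpl_rep <- rep(tmpl, each = replicates)
      templates[[length(templates) + 1L]] <- list(
        period_h = P, phase_h = phi, values = tmpl_rep,
        group_sizes = as.integer(table(tmpl_rep))
      )
    }
  }
  templates
}

#' Rhythm test for one gene (rank-based cosine template scan)
#'
#' Scans a lattice of cosine reference templates (periods in `periods_h`,
#' phases stepped by the 6 h sampling interval), computing Kendall's S
#' between the gene's values and each template (replicates enter as
#' duplicated template ranks), with the exact two-sided permutation p-value
#' from the convolution null. The minimum p over the lattice is
#' Bonferroni-adjusted by the number of templates. The amplitude is half the
#' peak-to-trough of the least-squares cosine at the best (period, phase).
#'
#' @param values Numeric vector ordered hour-major as produced by
#'   [resample_regular_grid()] (length 9 * replicates).
#' @param hours The 9 grid hours.
#' @param replicates Number of replicates.
#' @param periods_h Scanned periods in hours.
#' @param templates Optional precomputed template list (with null pmfs) from
#'   the internal scan machinery.
#' @return One-row data.frame: `period_h`, `phase_h`, `tau`, `p`
#'   (Bonferroni-adjusted within gene), `amplitude`.
#' @export
jtk_test_gene <- function(values, hours, replicates, periods_h = c(18, 24, 30),
                          templates = NULL) {
  if (is.null(templates)) {
    templates <- jtk_templates(hours, replicates, periods_h)
    for (i in seq_along(templates)) {
      templates[[i]]$pmf <- jt_null_pmf(templates[[i]]$group_sizes)
    }
  }
  n <- length(values)
  if (diff(range(values)) < 1e-12) {
    return(data.frame(period_h = periods_h[1], phase_h = 0, tau = 0, p = 1,
                      amplitude = 0))
  }
  sx <- sign(outer(values, values, `-`))
  ut <- upper.tri(sx)
  sxu <- sx[ut]
  best <- NULL
  for (tm in templates) {
    sy <- sign(outer(tm$values, tm$values, `-`))
    s_obs <- sum(sxu * sy[ut])
    p <- jtk_exact_p(s_obs, tm$group_sizes, tm$pmf)
    n_pairs <- n * (n - 1) / 2
    tie_y <- sum(vapply(tm$group_sizes, function(g) g * (g - 1) / 2, 1))
    tau <- s_obs / sqrt(n_pairs * (n_pairs - tie_y))
    ## strictly smaller p wins; on exact ties (an anti-phase template gives
    ## the same two-sided p) prefer the positively correlated template
    if (is.null(best) || p < best$p ||
        (p == best$p && tau > best$tau)) {
      best <- list(period_h = tm$period_h, phase_h = tm$phase_h, tau = tau,
                   p = p)
    }
  }
  p_adj <- min(1, best$p * length(templates))
  hh <- rep(hours, each = replicates)
  co <- cos(2 * pi * (hh - best$phase_h) / best$period_h)
  fit <- stats::lm.fit(cbind(1, co), values)
  data.frame(period_h = best$period_h, phase_h = best$phase_h, tau = best$tau,
             p = p_adj, amplitude = abs(fit$coefficients[2]))
}

#' Scan all genes for circadian-scale rhythms
#'
#' Applies [jtk_test_gene()] to every gene on the regular 6 h grid and adds
#' BH correction across genes on the within-gene-adjusted p-values.
#'
#' @param norm Log2 normalized matrix.
#' @param samples Sample sheet.
#' @param periods_h Scanned periods (hours).
#' @return `CycleCall` data.frame: `gene`, `period_h`, `phase_h`, `tau`, `p`,
#'   `q`, `amplitude`.
#' @export
jtk_scan <- function(norm, samples, periods_h = c(18, 24, 30)) {
  reg <- resample_regular_grid(norm, samples)
  templates <- jtk_templates(reg$hours, reg$replicates, periods_h)
  for (i in seq_along(templates)) {
    templates[[i]]$pmf <- jt_null_pmf(templates[[i]]$group_sizes)
  }
  rows <- lapply(seq_len(nrow(reg$values)), function(g) {
    jtk_test_gene(reg$values[g, ], reg$hours, reg$replicates, periods_h,
                  templates)
  })
  out <- do.call(rbind, rows)
  out <- cbind(gene = rownames(norm), out, stringsAsFactors = FALSE)
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Select cyclic genes
#'
#' Keeps genes with BH Q-value below `q_max` and amplitude strictly greater
#' than `amp_min` (in log2 units).
#'
#' @param calls `CycleCall` table from [jtk_scan()].
#' @param q_max BH Q-value cutoff.
#' @param amp_min Amplitude cutoff (strict).
#' @return Character vector of gene ids.
#' @export
select_cyclic <- function(calls, q_max = 0.05, amp_min = 0.5) {
  calls$gene[calls$q < q_max & calls$amplitude > amp_min]
}
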