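## shared helpers for the test suite: small fixtures and literal brute-force
## oracles kept deliberately naive and independent of the package internals

flat_class_table <- function(n, prefix = "g") {
  data.frame(gene_id = sprintf("%s%03d", prefix, seq_len(n)), class = "FLAT",
             stringsAsFactors = FALSE)
}

all_flat_fixture <- function(n_genes, seed) {
  cfg <- fixture_config(n_genes = n_genes)
  cfg$n_class <- c(FLAT = n_genes, METABOLIC_DIP = 0, IMMEDIATE_SUSTAINED = 0,
                   TRANSIENT = 0, DIP_THEN_PEAK = 0, CYCLIC = 0)
  simulate_experiment(cfg, seed = seed, couplings = list())
}

mixed_fixture <- function(n_genes, seed) {
  simulate_experiment(fixture_config(n_genes = n_genes), seed = seed)
}

## adjusted Rand index computed from a contingency table
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

## literal BH step-up: largest k with p_(k) <= k*alpha/m rejected; q-values by
## the standard cumulative-minimum definition written out longhand
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, p[o[k]] * m / k)
    q[o[k]] <- val
    prev <- val
  }
  q
}

## literal trimmed-mean-of-M TMM factor of sample j against reference r
tmm_bruteforce <- function(counts, j, r, trim_m = 0.3, trim_a = 0.05) {
  n_j <- sum(counts[, j]); n_r <- sum(counts[, r])
  ms <- c(); as_ <- c(); ws <- c()
  for (g in seq_len(nrow(counts))) {
    x <- counts[g, j]; xr <- counts[g, r]
    if (x > 0 && xr > 0) {
      ms <- c(ms, log2((x / n_j) / (xr / n_r)))
      as_ <- c(as_, 0.5 * log2((x / n_j) * (xr / n_r)))
      ws <- c(ws, 1 / ((n_j - x) / (n_j * x) + (n_r - xr) / (n_r * xr)))
    }
  }
  lo_m <- quantile(ms, trim_m); hi_m <- quantile(ms, 1 - trim_m)
  lo_a <- quantile(as_, trim_a); hi_a <- quantile(as_, 1 - trim_a)
  keep <- ms >= lo_m & ms <= hi_m & as_ >= lo_a & as_ <= hi_a
  2^(sum(ws[keep] * ms[keep]) / sum(ws[keep]))
}

## literal maxmean statistic of a member subset of a named stat vector
maxmean_literal <- function(stats_vec, members) {
  s <- stats_vec[members[members %in% names(stats_vec)]]
  pos <- s[s > 0]; neg <- s[s < 0]
  s_plus <- sum(pos) / length(s)
  s_minus <- sum(-neg) / length(s)
  if (s_plus >= s_minus) s_plus else -s_minus
}

## all permutations of a vector (for exact-null enumeration at tiny n)
all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

## Kendall S between two vectors, written out pair by pair
kendall_s_literal <- function(x, y) {
  s <- 0
  n <- length(x)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- s + sign(x[j] - x[i]) * sign(y[j] - y[i])
    }
  }
  s
}
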