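#' Read a GMT gene-set file
#'
#' Tab-separated: set name, description, then member gene ids.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1))
  sets
}

#' Paired two-class gene statistics for one time point vs baseline
#'
#' The paired design matches each replicate's time-point sample to the same
#' replicate's baseline sample (class vector (-1, 1, -2, 2) in the
#' two-replicate case). The per-gene statistic is the mean within-replicate
#' difference divided by the standard deviation of those differences plus an
#' exchangeability constant `s0` (the median of the per-gene difference
#' standard deviations).
#'
#' @param norm Log2 normalized matrix.
#' @param samples Sample sheet.
#' @param time_h The post-baseline time point to contrast.
#' @return Named vector of per-gene statistics, with attribute `s0`.
#' @export
paired_gene_stats <- function(norm, samples, time_h) {
  reps <- sort(unique(samples$replicate))
  diffs <- vapply(reps, function(r) {
    it <- which(samples$time_h == time_h & samples$replicate == r)
    ib <- which(samples$time_h == 0 & samples$replicate == r)
    if (length(it) != 1 || length(ib) != 1) {
      stop("missing paired sample for replicate ", r, " at ", time_h, " h")
    }
    norm[, it] - norm[, ib]
  }, numeric(nrow(norm)))
  d_mean <- rowMeans(diffs)
  d_sd <- apply(diffs, 1, stats::sd)
  s0 <- stats::median(d_sd)
  denom <- d_sd + s0
  stat <- ifelse(denom > 0, d_mean / denom, 0)
  names(stat) <- rownames(norm)
  attr(stat, "s0") <- s0
  stat
}

#' Raw maxmean score of a gene set
#'
#' The mean of the positive parts and the mean of the negative parts of the
#' member statistics are compared; the larger wins and gives the score its
#' sign (ties break toward positive).
#'
#' @param stats_vec Named per-gene statistics.
#' @param members Member gene ids (those absent from `stats_vec` are
#'   ignored).
#' @return Signed raw maxmean score.
#' @export
maxmean_raw <- function(stats_vec, members) {
  s <- stats_vec[intersect(members, names(stats_vec))]
  if (length(s) == 0) stop("gene set has no members in the data")
  s_pos <- mean(pmax(s, 0))
  s_neg <- mean(pmax(-s, 0))
  if (s_pos >= s_neg) s_pos else -s_neg
}

#' Restandardized maxmean score
#'
#' The raw maxmean is centered and scaled by the mean and standard deviation
#' of the same functional over random gene sets of equal size drawn from all
#' genes (row randomization).
#'
#' @param stats_vec Named per-gene statistics.
#' @param members Member gene ids.
#' @param n_random Number of random sets for the restandardization moments.
#' @param random_scores Optional precomputed vector of raw maxmean scores of
#'   random same-size sets (overrides `n_random`).
#' @return Restandardized score with attributes `raw`, `null_mean`,
#'   `null_sd`.
#' @export
maxmean_score <- function(stats_vec, members, n_random = 1000,
                          random_scores = NULL) {
  raw <- maxmean_raw(stats_vec, members)
  m <- length(intersect(members, names(stats_vec)))
  if (is.null(random_scores)) {
    random_scores <- vapply(seq_len(n_random), function(i) {
      maxmean_raw(stats_vec, sample(names(stats_vec), m))
    }, numeric(1))
  }
  mu <- mean(random_scores)
  sd0 <- stats::sd(random_scores)
  if (sd0 < 1e-12) sd0 <- 1
  out <- (raw - mu) / sd0
  attr(out, "raw") <- raw
  attr(out, "null_mean") <- mu
  attr(out, "null_sd") <- sd0
  out
}

## raw maxmean for many sets at once given an index list (rows of `idx` are
## sampled member indices) -- used for the permutation null
maxmean_raw_idx <- function(stats_vec, idx) {
  s <- stats_vec[idx]
  s_pos <- mean(pmax(s, 0))
  s_neg <- mean(pmax(-s, 0))
  if (s_pos >= s_neg) s_pos else -s_neg
}

#' Permutation-calibrated gene-set scores per time point
#'
#' For each gene set (size >= `min_size` after intersecting with the data)
#' and each requested time point, computes the restandardized maxmean score
#' and a two-sided permutation p-value. Because the paired two-replicate
#' design admits only four distinct sample-label sign flips, the null
#' augments label flips with row (gene) randomization: each permutation draws
#' a random same-size gene set under a random label flip.
#'
#' @param sets Named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param norm Log2 normalized matrix.
#' @param samples Sample sheet.
#' @param time_points Time points to score (default: all positive times
#'   <= 48 h present).
#' @param n_perm Number of permutations (>= 100).
#' @param min_size Minimum member genes present in the data.
#' @param score_min,p_max Selection rule: a set is flagged if
#'   `|score| > score_min` and `p < p_max` at one or more time points.
#' @return data.frame: `set`, `time_h`, `size`, `score`, `p`, `direction`,
#'   `selected`.
#' @export
gsa_permutation <- function(sets, norm, samples, time_points = NULL,
                            n_perm = 1000, min_size = 5, score_min = 2.5,
                            p_max = 0.05) {
  if (n_perm < 100) stop("`n_perm` must be at least 100")
  if (is.null(time_points)) {
    time_points <- sort(unique(samples$time_h[samples$time_h > 0 &
                                                samples$time_h <= 48]))
  }
  genes <- rownames(norm)
  sets <- lapply(sets, intersect, genes)
  sizes <- lengths(sets)
  drop <- sizes < min_size
  if (any(drop)) {
    message("dropping ", sum(drop), " set(s) with < ", min_size,
            " genes in the data")
    sets <- sets[!drop]
  }
  if (length(sets) == 0) stop("no gene sets left after the size filter")
  reps <- sort(unique(samples$replicate))
  ## the distinct paired label flips: each replicate's pair may swap
  flips <- as.matrix(expand.grid(rep(list(c(1, -1)), length(reps))))
  rows <- list()
  for (tp in time_points) {
    stat_obs <- paired_gene_stats(norm, samples, tp)
    ## per-replicate differences for flip-based nulls
    diffs <- vapply(reps, function(r) {
      norm[, samples$time_h == tp & samples$replicate == r] -
        norm[, samples$time_h == 0 & samples$replicate == r]
    }, numeric(nrow(norm)))
    stat_flip <- function(fl) {
      d <- sweep(diffs, 2, fl, `*`)
      dm <- rowMeans(d)
      ds <- apply(d, 1, stats::sd)
      dm / (ds + stats::median(ds))
    }
    flip_stats <- lapply(seq_len(nrow(flips)), function(i) stat_flip(flips[i, ]))
    for (sn in names(sets)) {
      m <- length(sets[[sn]])
      ## restandardization moments from random sets on the observed stats
      rnd <- vapply(seq_len(500), function(i) {
        maxmean_raw_idx(stat_obs, sample.int(length(stat_obs), m))
      }, numeric(1))
      mu <- mean(rnd); sd0 <- max(stats::sd(rnd), 1e-12)
      obs <- (maxmean_raw(stat_obs, sets[[sn]]) - mu) / sd0
      null_scores <- vapply(seq_len(n_perm), function(i) {
        st <- flip_stats[[(i - 1L) %% length(flip_stats) + 1L]]
        (maxmean_raw_idx(st, sample.int(length(st), m)) - mu) / sd0
      }, numeric(1))
      p <- (1 + sum(abs(null_scores) >= abs(obs))) / (1 + n_perm)
      rows[[length(rows) + 1L]] <- data.frame(
        set = sn, time_h = tp, size = m, score = obs, p = p,
        direction = if (obs >= 0) "up" else "down",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  hit <- tapply(abs(out$score) > score_min & out$p < p_max, out$set, any)
  out$selected <- as.logical(hit[out$set])
  rownames(out) <- NULL
  out
}
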