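#' @name synthetic-data
#' @title Synthetic count-matrix generator with planted temporal structure
#'
#' @description
#' The generator emulates a dense immune-stimulation time course: a baseline at
#' 0 h, 20 post-stimulation times out to 120 h, two replicates, and
#' negative-binomial counts over thousands of genes. Each gene belongs to one
#' of six temporal profile classes, and directed lag couplings can be planted
#' between genes so that downstream lead-lag inference has a known answer key.
NULL

PROFILE_CLASSES <- c("IMMEDIATE_SUSTAINED", "TRANSIENT", "DIP_THEN_PEAK",
                     "METABOLIC_DIP", "CYCLIC", "FLAT")

## Unit-height smooth bump peaking at t = peak_h; shape exponent k controls
## how fast it rises and resolves.
gamma_bump <- function(t, peak_h, k) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- (t[pos] / peak_h)^k * exp(k * (1 - t[pos] / peak_h))
  out
}

#' Default shape parameters for a profile class
#'
#' Values are log2-fold-change deviations from each gene's baseline. The
#' immediate-sustained class peaks within 2 h and stays above half its peak
#' through day 5; the transient class peaks at 5-8 h and resolves; the
#' dip-then-peak class goes below baseline at 1-2 h before peaking at 8-12 h;
#' the metabolic-dip class bottoms out at 5-8 h and recovers by 24 h; the
#' cyclic class follows a cosine.
#'
#' @param class One of `r toString(PROFILE_CLASSES)`.
#' @return Named list of shape parameters.
#' @export
default_class_params <- function(class) {
  switch(class,
    IMMEDIATE_SUSTAINED = list(peak_h = 1.5, peak_lfc = 5, sustain_lfc = 3.5,
                               decay_tau_h = 48),
    TRANSIENT = list(peak_h = 6, peak_lfc = 3, shape_k = 2),
    DIP_THEN_PEAK = list(dip_h = 1.5, dip_lfc = 1.2, peak_h = 10,
                         peak_lfc = 2.5),
    METABOLIC_DIP = list(dip_h = 6, dip_lfc = 2),
    CYCLIC = list(period_h = 24, phase_h = 0, amplitude = 1),
    FLAT = list(),
    stop("unknown profile class: ", class)
  )
}

#' Evaluate a profile class deviation at given times
#'
#' Returns the planted log2-fold-change deviation from baseline for one gene.
#'
#' @param class Profile class name.
#' @param t Numeric vector of times (hours).
#' @param params Optional named list overriding [default_class_params()].
#' @return Numeric vector of log2 deviations, one per time.
#' @export
profile_deviation <- function(class, t, params = list()) {
  if (!class %in% PROFILE_CLASSES) stop("unknown profile class: ", class)
  p <- utils::modifyList(default_class_params(class), params)
  bad <- vapply(p, function(v) !is.numeric(v) || !all(is.finite(v)), TRUE)
  if (any(bad)) stop("non-finite shape parameter(s): ", toString(names(p)[bad]))
  switch(class,
    FLAT = numeric(length(t)),
    CYCLIC = p$amplitude * cos(2 * pi * (t - p$phase_h) / p$period_h),
    IMMEDIATE_SUSTAINED = {
      out <- numeric(length(t))
      rise <- t < p$peak_h
      out[rise] <- p$peak_lfc * t[rise] / p$peak_h
      out[!rise] <- p$sustain_lfc + (p$peak_lfc - p$sustain_lfc) *
        exp(-(t[!rise] - p$peak_h) / p$decay_tau_h)
      out
    },
    TRANSIENT = p$peak_lfc * gamma_bump(t, p$peak_h, p$shape_k),
    DIP_THEN_PEAK = -p$dip_lfc * gamma_bump(t, p$dip_h, 2) +
      p$peak_lfc * gamma_bump(t, p$peak_h, 3),
    METABOLIC_DIP = -p$dip_lfc * gamma_bump(t, p$dip_h, 2)
  )
}

#' Build latent log2 expression trajectories for a table of genes
#'
#' @param grid A [time_grid()].
#' @param class_table data.frame with columns `gene_id`, `class`, and
#'   optionally a list-column `params` of per-gene shape overrides.
#' @param baseline_log2 Numeric vector (recycled) of baseline log2 expression
#'   per gene.
#' @return Matrix of latent log2 expression, genes x samples
#'   (columns ordered as `grid$samples`). Deterministic: both replicates share
#'   the same latent trajectory.
#' @export
build_latent_profiles <- function(grid, class_table, baseline_log2 = 8) {
  stopifnot_grid(grid)
  if (nrow(class_table) == 0) stop("`class_table` is empty")
  if (!all(class_table$class %in% PROFILE_CLASSES)) {
    stop("unknown profile class: ",
         toString(setdiff(class_table$class, PROFILE_CLASSES)))
  }
  baseline_log2 <- rep_len(baseline_log2, nrow(class_table))
  has_params <- !is.null(class_table$params)
  dev <- t(vapply(seq_len(nrow(class_table)), function(i) {
    profile_deviation(class_table$class[i], grid$times,
                      if (has_params) class_table$params[[i]] else list())
  }, numeric(length(grid$times))))
  latent_t <- dev + baseline_log2
  ## expand times -> samples (replicates share the latent trajectory)
  latent <- latent_t[, rep(seq_along(grid$times), each = grid$replicates),
                     drop = FALSE]
  dimnames(latent) <- list(class_table$gene_id, grid$samples$sample_id)
  latent
}

#' Construct a planted coupling
#'
#' A `direct` coupling adds `coefficient` times the source gene's log2
#' deviation at grid step `t` to the target gene at step `t + lag`. A
#' `confounded-pair` coupling instead routes a hidden driver into both genes
#' with lags differing by one step (source earlier), with no direct
#' source-to-target term: the pair shows a lead-lag correlation with no causal
#' link, the classic confounding trap for bivariate lead-lag tests.
#'
#' @param source,target Gene identifiers (must differ).
#' @param lag Positive integer lag in grid steps (index positions, not hours).
#' @param coefficient Signed, non-zero multiplier on the propagated deviation.
#' @param kind `"direct"` or `"confounded-pair"`.
#' @param driver For `confounded-pair`: function of time (hours) giving the
#'   hidden driver's log2 deviation. Default is a smooth transient impulse.
#' @return A `chronoseq_coupling` list.
#' @export
coupling <- function(source, target, lag = 1L, coefficient = 1,
                     kind = c("direct", "confounded-pair"), driver = NULL) {
  kind <- match.arg(kind)
  lag <- as.integer(lag)
  if (is.na(lag) || lag < 1) stop("`lag` must be a positive integer")
  if (!is.finite(coefficient) || coefficient == 0) {
    stop("`coefficient` must be finite and non-zero")
  }
  if (identical(source, target)) stop("`source` and `target` must differ")
  if (kind == "confounded-pair" && is.null(driver)) {
    driver <- function(t) profile_deviation("TRANSIENT", t)
  }
  structure(list(source = source, target = target, lag = lag,
                 coefficient = coefficient, kind = kind, driver = driver),
            class = "chronoseq_coupling")
}

#' Propagate planted couplings through latent trajectories
#'
#' Couplings act on log2 deviations from each gene's baseline (the value at
#' 0 h), with unit-step lags on the index grid, independently within each
#' replicate. Steps are processed in time order using current (already
#' updated) deviations, so chains of couplings propagate.
#'
#' @param latent Latent log2 matrix from [build_latent_profiles()].
#' @param couplings List of [coupling()] objects.
#' @param grid The [time_grid()] used to build `latent`.
#' @return Latent matrix with coupling contributions added.
#' @export
apply_couplings <- function(latent, couplings, grid) {
  stopifnot_grid(grid)
  if (length(couplings) == 0) return(latent)
  genes <- rownames(latent)
  for (cp in couplings) {
    missing <- setdiff(c(cp$source, cp$target), genes)
    if (length(missing)) {
      stop("coupling references unknown gene(s): ", toString(missing))
    }
  }
  nt <- length(grid$times)
  baseline <- latent[, grid$samples$time_h == 0, drop = FALSE]
  for (r in seq_len(grid$replicates)) {
    cols <- which(grid$samples$replicate == r)  # ordered by time
    base_r <- latent[, cols[1]]
    dev <- latent[, cols, drop = FALSE] - base_r
    for (s in seq_len(nt - 1)) {
      for (cp in couplings) {
        if (cp$kind == "direct") {
          tgt_step <- s + cp$lag
          if (tgt_step <= nt) {
            dev[cp$target, tgt_step] <- dev[cp$target, tgt_step] +
              cp$coefficient * dev[cp$source, s]
          }
        }
      }
    }
    ## hidden drivers: source receives driver at lag, target at lag + 1
    for (cp in couplings) {
      if (cp$kind == "confounded-pair") {
        d <- cp$driver(grid$times)
        for (s in seq_len(nt)) {
          if (s + cp$lag <= nt) {
            dev[cp$source, s + cp$lag] <- dev[cp$source, s + cp$lag] +
              cp$coefficient * d[s]
          }
          if (s + cp$lag + 1 <= nt) {
            dev[cp$target, s + cp$lag + 1] <- dev[cp$target, s + cp$lag + 1] +
              cp$coefficient * d[s]
          }
        }
      }
    }
    latent[, cols] <- dev + base_r
  }
  latent
}

#' Draw negative-binomial counts from a synthetic truth
#'
#' Counts for gene g in sample j are drawn with mean
#' `s_j * 2^latent[g, j]`, where `s_j` is the sample's library-size factor
#' (library size divided by the geometric-mean library size), and shared
#' dispersion `dispersion` (variance `mu + dispersion * mu^2`). At
#' `dispersion = 0` the Poisson limit is used.
#'
#' @param truth A `chronoseq_truth` from [simulate_experiment()], or any list
#'   with elements `latent`, `dispersion`, `lib_sizes`, `seed`.
#' @return Integer-valued matrix of counts, genes x samples.
#' @export
sample_counts <- function(truth) {
  latent <- truth$latent
  disp <- truth$dispersion
  lib <- truth$lib_sizes
  if (disp < 0) stop("`dispersion` must be >= 0")
  if (any(lib <= 0)) stop("library sizes must be > 0")
  s <- lib / exp(mean(log(lib)))
  mu <- sweep(2^latent, 2, s, `*`)
  if (any(mu > 2^40)) stop("overflow-scale negative-binomial means (> 2^40)")
  set.seed(truth$seed)
  n <- length(mu)
  counts <- if (disp == 0) stats::rpois(n, mu) else
    stats::rnbinom(n, size = 1 / disp, mu = mu)
  counts <- matrix(counts, nrow = nrow(latent), dimnames = dimnames(latent))
  storage.mode(counts) <- "double"
  counts
}

#' Default fixture configuration
#'
#' 2,000 genes (1,700 flat housekeeping, 100 metabolic-dip, 60
#' immediate-sustained, 60 transient, 40 dip-then-peak, 40 cyclic), 20 planted
#' couplings (5 negative among non-cyclic genes, 3 negative among cyclic
#' genes, 10 positive, 2 hidden-driver confounded pairs), log-normal library
#' sizes around 2e7, and gene-shared dispersion 0.05.
#'
#' @param n_genes Total gene count; class proportions are kept fixed.
#' @param dispersion Negative-binomial dispersion shared across genes.
#' @param replicate_sd Log2 replicate-level offset standard deviation
#'   (batch-like effect); 0 disables it.
#' @return A list understood by [simulate_experiment()].
#' @export
fixture_config <- function(n_genes = 2000, dispersion = 0.05,
                           replicate_sd = 0) {
  frac <- c(FLAT = 0.85, METABOLIC_DIP = 0.05, IMMEDIATE_SUSTAINED = 0.03,
            TRANSIENT = 0.03, DIP_THEN_PEAK = 0.02, CYCLIC = 0.02)
  n_class <- round(frac * n_genes)
  n_class["FLAT"] <- n_genes - sum(n_class[-1])
  list(n_class = n_class, dispersion = dispersion, replicate_sd = replicate_sd,
       lib_meanlog = log(2e7), lib_sdlog = 0.15,
       baseline_meanlog2 = 8, baseline_sdlog2 = 1.8)
}

default_couplings <- function(class_table) {
  ids <- function(cl) class_table$gene_id[class_table$class == cl]
  tr <- ids("TRANSIENT"); fl <- ids("FLAT"); cy <- ids("CYCLIC")
  is_ <- ids("IMMEDIATE_SUSTAINED")
  if (length(tr) < 10 || length(cy) < 6 || length(is_) < 5 ||
      length(fl) < 19) {
    stop("default couplings need >= 10 transient, 6 cyclic, 5 ",
         "immediate-sustained and 19 flat genes; pass `couplings` ",
         "explicitly for smaller fixtures")
  }
  cps <- list()
  ## 5 persistent negative couplings among non-cyclic genes: transient sources
  ## drive flat targets with an inverted lag-1 copy
  for (i in 1:5) {
    cps <- c(cps, list(coupling(tr[i], fl[i], lag = 1, coefficient = -1.5)))
  }
  ## 3 negative couplings with cyclic endpoints
  for (i in 1:3) {
    cps <- c(cps, list(coupling(cy[i], cy[i + 3], lag = 1, coefficient = -1)))
  }
  ## 10 positive couplings (filtered out downstream by the negative-edge rule)
  for (i in 1:5) {
    cps <- c(cps, list(coupling(tr[i + 5], fl[i + 5], lag = 1, coefficient = 1.5)))
  }
  for (i in 1:5) {
    cps <- c(cps, list(coupling(is_[i], fl[i + 10], lag = 1, coefficient = 1.5)))
  }
  ## 2 hidden-driver confounded pairs among otherwise flat genes
  cps <- c(cps, list(
    coupling(fl[16], fl[17], lag = 1, coefficient = 1, kind = "confounded-pair"),
    coupling(fl[18], fl[19], lag = 1, coefficient = -1, kind = "confounded-pair")
  ))
  cps
}

#' Simulate a full synthetic experiment
#'
#' Builds the class table, latent trajectories, planted couplings, library
#' sizes and counts for the reference design, together with the ground truth
#' needed for recovery testing. A functional-annotation table is returned for
#' the planted-signal and coupling-target genes (the analogue of "genes with
#' available functional annotation").
#'
#' @param config A list from [fixture_config()].
#' @param seed Integer seed; recorded in the truth object.
#' @param grid A [time_grid()].
#' @param couplings List of [coupling()]s, or `NULL` for the default set
#'   (requires the default class mix).
#' @return List with `counts` (matrix), `samples` (sample sheet), `truth`
#'   (class `chronoseq_truth`: `class_table`, `latent`, `couplings`,
#'   `dispersion`, `lib_sizes`, `seed`), and `annotation` (data.frame
#'   `gene_id`, `label`, `immune`).
#' @export
simulate_experiment <- function(config = fixture_config(), seed = 1,
                                grid = time_grid(), couplings = NULL) {
  stopifnot_grid(grid)
  set.seed(seed)
  n_class <- config$n_class
  classes <- rep(names(n_class), n_class)
  n <- length(classes)
  ## interleave classes through the gene ordering so class is not confounded
  ## with gene index
  ord <- sample.int(n)
  classes <- classes[ord]
  class_table <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n)),
    class = classes,
    stringsAsFactors = FALSE
  )
  ## modest per-gene variation of the headline shape parameter
  class_table$params <- lapply(seq_len(n), function(i) {
    cl <- classes[i]
    switch(cl,
      IMMEDIATE_SUSTAINED = {
        pk <- stats::runif(1, 4, 6)
        list(peak_lfc = pk, sustain_lfc = stats::runif(1, 0.55, 0.75) * pk)
      },
      TRANSIENT = list(peak_lfc = stats::runif(1, 2.5, 3.5),
                       peak_h = stats::runif(1, 5, 7)),
      DIP_THEN_PEAK = list(peak_lfc = stats::runif(1, 2, 3)),
      METABOLIC_DIP = list(dip_lfc = stats::runif(1, 1.5, 2.5)),
      CYCLIC = list(amplitude = 1, phase_h = sample(c(0, 6, 12, 18), 1)),
      list()
    )
  })
  baseline <- stats::rnorm(n, config$baseline_meanlog2, config$baseline_sdlog2)
  latent <- build_latent_profiles(grid, class_table, baseline)
  if (is.null(couplings)) couplings <- default_couplings(class_table)
  latent <- apply_couplings(latent, couplings, grid)
  if (config$replicate_sd > 0) {
    off <- stats::rnorm(grid$replicates, 0, config$replicate_sd)
    latent <- sweep(latent, 2, off[grid$samples$replicate], `+`)
  }
  lib_sizes <- stats::rlnorm(n_samples(grid), config$lib_meanlog,
                             config$lib_sdlog)
  truth <- structure(list(class_table = class_table, latent = latent,
                          couplings = couplings,
                          dispersion = config$dispersion,
                          lib_sizes = lib_sizes, seed = seed + 10^6L),
                     class = "chronoseq_truth")
  counts <- sample_counts(truth)
  coupled <- unique(unlist(lapply(couplings, function(cp) c(cp$source, cp$target))))
  annotated <- class_table$gene_id[class_table$class != "FLAT"]
  annotated <- union(annotated, coupled)
  annotation <- data.frame(
    gene_id = annotated,
    label = class_table$class[match(annotated, class_table$gene_id)],
    immune = class_table$class[match(annotated, class_table$gene_id)] %in%
      c("IMMEDIATE_SUSTAINED", "TRANSIENT"),
    stringsAsFactors = FALSE
  )
  list(counts = counts, samples = grid$samples, truth = truth,
       annotation = annotation, grid = grid)
}

#' Write a simulated fixture to disk
#'
#' Counts and the sample sheet are written as TSV; the ground truth (classes,
#' couplings, dispersion, library sizes, seed) as JSON.
#'
#' @param sim Result of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts_path <- file.path(dir, "counts.tsv")
  write_counts_tsv(sim$counts, counts_path)
  samples_path <- file.path(dir, "samples.tsv")
  utils::write.table(sim$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_path <- file.path(dir, "truth.json")
  tr <- sim$truth
  truth_json <- list(
    classes = stats::setNames(tr$class_table$class, tr$class_table$gene_id),
    couplings = lapply(tr$couplings, function(cp) {
      cp[c("source", "target", "lag", "coefficient", "kind")]
    }),
    dispersion = tr$dispersion,
    lib_sizes = tr$lib_sizes,
    seed = tr$seed
  )
  jsonlite::write_json(truth_json, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(counts = counts_path, samples = samples_path, truth = truth_path))
}

#' Simulate a normalized-scale gene system for lead-lag studies
#'
#' Generates log2 expression series directly on the normalized scale: each
#' gene is a baseline plus a deterministic class deviation, couplings are
#' propagated on the index grid, and independent Gaussian measurement noise
#' (default sd 0.15 log2 units, typical replicate scatter for moderately
#' expressed genes) is added per sample. This is the working material for
#' Granger-causality calibration and recovery studies, where the count layer
#' would only add an extra, irrelevant noise transform.
#'
#' @param class_table data.frame as for [build_latent_profiles()]; genes not
#'   listed are flat.
#' @param couplings List of [coupling()]s.
#' @param noise_sd Gaussian noise sd on the log2 scale.
#' @param seed Integer seed.
#' @param grid A [time_grid()].
#' @return List with `norm` (matrix genes x samples), `samples`, `grid`,
#'   `class_table`, `couplings`.
#' @export
simulate_gc_system <- function(class_table, couplings = list(),
                               noise_sd = 0.15, seed = 1, grid = time_grid()) {
  stopifnot_grid(grid)
  set.seed(seed)
  latent <- build_latent_profiles(grid, class_table, baseline_log2 = 8)
  latent <- apply_couplings(latent, couplings, grid)
  norm <- latent + matrix(stats::rnorm(length(latent), 0, noise_sd),
                          nrow(latent))
  dimnames(norm) <- dimnames(latent)
  list(norm = norm, samples = grid$samples, grid = grid,
       class_table = class_table, couplings = couplings)
}

#' Class table for a confounded-triplet system
#'
#' An early-impulse driver gene C (transient, peaking at 4 h with a sharp
#' rise and fall, the shape of immediate-early immune genes) feeds gene A at
#' lag 1 and gene B at lag 2 (so A leads B by one step with no direct A-to-B
#' link), embedded in `n_null` flat noise genes. The classic trap: bivariate lead-lag testing
#' sees a strong A-to-B edge, while multivariate testing conditioned on the
#' whole system should not.
#'
#' @param n_null Number of flat background genes.
#' @return List with `class_table` and `couplings` ready for
#'   [simulate_gc_system()].
#' @export
confounded_triplet_system <- function(n_null = 27) {
  ct <- data.frame(
    gene_id = c("C", "A", "B", sprintf("n%02d", seq_len(n_null))),
    class = c("TRANSIENT", "FLAT", "FLAT", rep("FLAT", n_null)),
    stringsAsFactors = FALSE
  )
  ct$params <- c(list(list(peak_h = 4, peak_lfc = 3, shape_k = 3)),
                 rep(list(list()), n_null + 2))
  cps <- list(coupling("C", "A", lag = 1, coefficient = 1),
              coupling("C", "B", lag = 2, coefficient = 1))
  list(class_table = ct, couplings = cps)
}

#' Gene system with planted persistent negative couplings
#'
#' A master-set-scale system for lead-lag edge recovery: five transient
#' driver genes (sharp impulses with peaks staggered over 4-12 h, so each pair is identifiable)
#' each feed a dedicated target with a negative lag-1 coupling; three cyclic
#' (24 h cosine) genes feed cyclic targets negatively; four transient drivers
#' feed targets positively; the rest are flat nulls. The answer key for the
#' negative-edge network filter is the five transient-driven negative
#' couplings — cyclic-endpoint edges must be excluded and positive edges
#' dropped.
#'
#' @param n_null Number of flat background genes.
#' @return List with `class_table`, `couplings`, and `negative_truth`
#'   (data.frame `source`, `target` of the expected recovered edges).
#' @export
gc_recovery_system <- function(n_null = 20) {
  tr_src <- sprintf("trS%d", 1:9)
  tr_tgt <- sprintf("trT%d", 1:9)
  cy_src <- sprintf("cyS%d", 1:3)
  cy_tgt <- sprintf("cyT%d", 1:3)
  nul <- sprintf("nul%02d", seq_len(n_null))
  ct <- data.frame(
    gene_id = c(tr_src, tr_tgt, cy_src, cy_tgt, nul),
    class = c(rep("TRANSIENT", 9), rep("FLAT", 9), rep("CYCLIC", 3),
              rep("FLAT", 3), rep("FLAT", n_null)),
    stringsAsFactors = FALSE
  )
  ## sharp, well-separated impulse peaks so each driver-target pair is
  ## identifiable against the other drivers
  peaks <- c(4, 6, 8, 10, 12, 5, 7, 9, 11)
  lfcs <- c(rep(5, 5), rep(3, 4))
  ct$params <- c(mapply(function(p, l) list(peak_h = p, peak_lfc = l,
                                            shape_k = 3),
                        peaks, lfcs, SIMPLIFY = FALSE),
                 rep(list(list()), 9),
                 lapply(c(0, 6, 12), function(ph) list(phase_h = ph)),
                 rep(list(list()), 3 + n_null))
  cps <- c(
    lapply(1:5, function(i) coupling(tr_src[i], tr_tgt[i], 1, -1)),
    lapply(1:3, function(i) coupling(cy_src[i], cy_tgt[i], 1, -1)),
    lapply(6:9, function(i) coupling(tr_src[i], tr_tgt[i], 1, 1))
  )
  list(class_table = ct, couplings = cps,
       negative_truth = data.frame(source = tr_src[1:5], target = tr_tgt[1:5],
                                   stringsAsFactors = FALSE))
}
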