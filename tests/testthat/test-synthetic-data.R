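grid <- time_grid()

test_that("time grid validates its invariants", {
  expect_error(time_grid(c(1, 2, 3)), "baseline")
  expect_error(time_grid(c(0, 2, 2)), "increasing")
  expect_error(time_grid(study_times(), 0), ">= 1")
  g <- time_grid()
  expect_length(g$times, 21)
  expect_equal(nrow(g$samples), 42)
})

test_that("profile shapes honor their class contracts", {
  t <- grid$times
  ## flat gene: identically the baseline
  expect_equal(profile_deviation("FLAT", t), rep(0, 21))
  ## cosine symmetry: peak-to-trough of a 24 h, amplitude-1 cosine is 2
  cyc <- profile_deviation("CYCLIC", c(0, 12),
                           list(period_h = 24, phase_h = 0, amplitude = 1))
  expect_equal(cyc[1] - cyc[2], 2)
  ## immediate-sustained closed form: peak log2FC 6 at 2 h, sustain 4
  p <- list(peak_h = 2, peak_lfc = 6, sustain_lfc = 4, decay_tau_h = 48)
  f <- profile_deviation("IMMEDIATE_SUSTAINED", c(0, 2, 120), p)
  expect_equal(f[2] - f[1], 6)
  expect_equal(f[3] - f[1], 4 + 2 * exp(-118 / 48))
  expect_gte(f[3] - f[1], 3)
  ## sustained >= 50% of peak through the last time (default parameters)
  f_def <- profile_deviation("IMMEDIATE_SUSTAINED", t)
  expect_gte(min(f_def[t >= 2]), 0.5 * max(f_def))
  ## transient: peaks at 5-8 h, within 0.25 of baseline by 72 h
  ftr <- profile_deviation("TRANSIENT", t)
  expect_true(t[which.max(ftr)] >= 5 && t[which.max(ftr)] <= 8)
  expect_lt(max(abs(ftr[t >= 72])), 0.25)
  ## dip-then-peak: below baseline at 1-2 h, peak 8-12 h, back by 48-72 h
  fdp <- profile_deviation("DIP_THEN_PEAK", t)
  expect_lt(max(fdp[t >= 1 & t <= 2]), 0)
  expect_true(t[which.max(fdp)] >= 8 && t[which.max(fdp)] <= 12)
  expect_lt(max(abs(fdp[t >= 72])), 0.25)
  ## metabolic dip: minimum at 5-8 h, recovered by 24 h
  fmd <- profile_deviation("METABOLIC_DIP", t)
  expect_true(t[which.min(fmd)] >= 5 && t[which.min(fmd)] <= 8)
  expect_lt(max(abs(fmd[t >= 24])), 0.25)
})

test_that("invalid profile classes and parameters are rejected", {
  expect_error(profile_deviation("SPIKY", 1:3), "unknown profile class")
  expect_error(profile_deviation("CYCLIC", 1:3, list(amplitude = NaN)),
               "non-finite")
  ct <- data.frame(gene_id = "g1", class = "NOPE", stringsAsFactors = FALSE)
  expect_error(build_latent_profiles(grid, ct), "unknown profile class")
  expect_error(build_latent_profiles(grid, ct[0, ]), "empty")
})

test_that("couplings propagate lagged deviations (hand-propagated case)", {
  ct <- data.frame(gene_id = c("A", "B"), class = c("TRANSIENT", "FLAT"),
                   stringsAsFactors = FALSE)
  lat0 <- build_latent_profiles(grid, ct, baseline_log2 = 8)
  ## empty coupling list: identity
  expect_identical(apply_couplings(lat0, list(), grid), lat0)
  lat1 <- apply_couplings(lat0, list(coupling("A", "B", 1, -1)), grid)
  devA <- lat0["A", ] - 8
  for (r in 1:2) {
    cols <- which(grid$samples$replicate == r)
    expect_equal(unname(lat1["B", cols][-1] - 8),
                 unname(-devA[cols][-length(cols)]))
  }
  ## unknown gene rejected
  expect_error(apply_couplings(lat0, list(coupling("A", "Z")), grid),
               "unknown gene")
})

test_that("hidden-driver pairs are correlated but conditionally independent", {
  long_grid <- time_grid(0:100, 2)
  ct <- flat_class_table(2)
  cp <- coupling(ct$gene_id[1], ct$gene_id[2], lag = 1, coefficient = 1,
                 kind = "confounded-pair",
                 driver = function(t) sin(t / 5) * 2)
  sys <- simulate_gc_system(ct, list(cp), noise_sd = 0.3, seed = 4,
                            grid = long_grid)
  drv <- sin(long_grid$times / 5) * 2
  pc <- sapply(1:2, function(r) {
    cols <- which(sys$samples$replicate == r)
    a <- sys$norm[1, cols]; b <- sys$norm[2, cols]
    nt <- length(cols)
    ## A_t carries driver(t-1), B_{t+1} carries driver(t-1) as well
    a_t <- a[3:(nt - 1)]; b_t1 <- b[4:nt]; d_t1 <- drv[2:(nt - 2)]
    raw <- cor(a_t, b_t1)
    ra <- resid(lm(a_t ~ d_t1)); rb <- resid(lm(b_t1 ~ d_t1))
    c(raw = raw, partial = cor(ra, rb))
  })
  expect_gt(min(pc["raw", ]), 0.8)          # confounded marginal correlation
  expect_lt(max(abs(pc["partial", ])), 0.25) # vanishes given the driver
})

test_that("count sampling matches its stated moments and is reproducible", {
  ## Poisson branch: dispersion 0, mean 100
  ct <- flat_class_table(1)
  lat <- matrix(log2(100), 1, 10000,
                dimnames = list("g001", paste0("s", 1:10000)))
  truth <- list(latent = lat, dispersion = 0, lib_sizes = rep(1, 10000),
                seed = 7)
  cts <- sample_counts(truth)
  expect_lt(abs(mean(cts) - 100), 3 * sqrt(100 / 10000))
  expect_true(all(cts >= 0) && all(cts == floor(cts)))
  ## negative binomial moments: var = mu + disp * mu^2 within MC error
  truth$dispersion <- 0.1
  cts2 <- sample_counts(truth)
  v_expect <- 100 + 0.1 * 100^2
  expect_lt(abs(var(as.numeric(cts2)) - v_expect), 5 * v_expect / sqrt(5000))
  ## determinism under a fixed seed
  expect_identical(sample_counts(truth), sample_counts(truth))
  ## overflow-scale means rejected
  truth$latent[] <- 60
  expect_error(sample_counts(truth), "overflow")
})

test_that("simulated experiments are deterministic and class-separable", {
  sim1 <- mixed_fixture(400, seed = 5)
  sim2 <- mixed_fixture(400, seed = 5)
  expect_identical(sim1$counts, sim2$counts)
  ## z-scored class mean trajectories pairwise correlated < 0.8
  cls <- c("IMMEDIATE_SUSTAINED", "TRANSIENT", "DIP_THEN_PEAK",
           "METABOLIC_DIP", "CYCLIC")
  prof <- sapply(cls, function(cl) {
    d <- profile_deviation(cl, grid$times)
    (d - mean(d)) / sd(d)
  })
  ## signed correlation below 0.8: classes are either dissimilar or
  ## anticorrelated (maximally distant under the Pearson metric)
  cors <- cor(prof)
  expect_lt(max(cors[upper.tri(cors)]), 0.8)
})

test_that("fixtures round-trip through the TSV/JSON writers", {
  sim <- mixed_fixture(400, seed = 9)
  dir <- withr::local_tempdir()
  paths <- write_fixture(sim, dir)
  back <- read_counts_tsv(paths["counts"])
  expect_equal(back, sim$counts)
  truth <- jsonlite::read_json(paths["truth"])
  expect_equal(length(truth$couplings), length(sim$truth$couplings))
  expect_equal(truth$seed, sim$truth$seed)
})
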