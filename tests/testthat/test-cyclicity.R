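grid <- time_grid()

test_that("regular-grid resampling subsets and interpolates 18 h", {
  sim <- all_flat_fixture(20, seed = 16)
  pre <- preprocess_counts(sim$counts)
  norm <- pre$norm
  norm[1, sim$samples$time_h == 16 & sim$samples$replicate == 1] <- 3
  norm[1, sim$samples$time_h == 20 & sim$samples$replicate == 1] <- 5
  reg <- resample_regular_grid(norm, sim$samples)
  expect_equal(unname(reg$values[1, "H18_R1"]), 4)
  expect_equal(reg$hours, c(0, 6, 12, 18, 24, 30, 36, 42, 48))
  ## exact subsetting at sampled hours
  expect_equal(unname(reg$values[2, "H24_R2"]),
               unname(norm[2, sim$samples$time_h == 24 & sim$samples$replicate == 2]))
  ## flat gene stays constant
  flat <- matrix(7, 2, nrow(sim$samples),
                 dimnames = list(c("f1", "f2"), sim$samples$sample_id))
  regf <- resample_regular_grid(flat, sim$samples)
  expect_true(all(regf$values == 7))
  ## cosine resampling: 18 h average bounded by the curvature at 18 h
  co <- cos(2 * pi * sim$samples$time_h / 24)
  m <- rbind(cosgene = 8 + co)
  colnames(m) <- sim$samples$sample_id
  regc <- resample_regular_grid(m, sim$samples)
  exact <- 8 + cos(2 * pi * regc$hours / 24)
  err <- abs(regc$values[1, ] - rep(exact, each = 2))
  interp_err <- abs((cos(2 * pi * 16 / 24) + cos(2 * pi * 20 / 24)) / 2 -
                      cos(2 * pi * 18 / 24))
  expect_lte(max(err), interp_err + 1e-12)
  ## missing a required time point is a named error
  bad <- sim$samples[sim$samples$time_h != 16, ]
  expect_error(resample_regular_grid(norm[, bad$sample_id], bad), "16")
})

test_that("the convolution null equals full permutation enumeration", {
  ## 6 observations, template with tie groups 2/2/2 and 3/3
  for (tmpl in list(c(1, 0, -1, 0, 1, 0), c(1, 1, 1, -1, -1, -1))) {
    gs <- as.integer(table(tmpl))
    pmf <- jt_null_pmf(gs)
    vals <- c(2.3, -1.1, 0.5, 1.7, -0.4, 0.9)
    svals <- vapply(all_perms(vals), kendall_s_literal, numeric(1), y = tmpl)
    nc <- (sum(gs)^2 - sum(gs^2)) / 2
    emp <- tabulate((svals + nc) / 2 + 1, nbins = nc + 1) / length(svals)
    expect_equal(pmf, emp, tolerance = 1e-12)
    ## tail p matches enumeration for every achievable S
    for (s_obs in unique(svals)) {
      p_pkg <- chronoseq:::jtk_exact_p(s_obs, gs, pmf)
      p_enum <- min(1, 2 * min(mean(svals <= s_obs), mean(svals >= s_obs)))
      expect_equal(p_pkg, p_enum, tolerance = 1e-12)
    }
  }
})

test_that("rhythm detection finds noise-free cosines at the right period", {
  hours <- c(0, 6, 12, 18, 24, 30, 36, 42, 48)
  vals <- rep(cos(2 * pi * hours / 24), each = 2)
  vals <- vals + seq_along(vals) * 1e-9  # break exact ties deterministically
  call <- jtk_test_gene(vals, hours, 2)
  expect_equal(call$period_h, 24)
  expect_equal(call$phase_h, 0)
  expect_equal(call$amplitude, 1, tolerance = 1e-6)
  ## p equals the minimal achievable tail times the Bonferroni factor
  tmpl <- round(cos(2 * pi * (hours - 0) / 24), 9)
  gs <- as.integer(table(rep(tmpl, each = 2)))
  pmf <- jt_null_pmf(gs)
  expect_equal(call$p, min(1, 12 * 2 * pmf[length(pmf)]), tolerance = 1e-9)
  ## reversed phase: same |tau|, phase shifted by half a period
  call_rev <- jtk_test_gene(-vals, hours, 2)
  expect_equal(abs(call_rev$tau), abs(call$tau), tolerance = 1e-9)
  expect_equal(call_rev$period_h, 24)
  expect_equal(call_rev$phase_h %% 24, (call$phase_h + 12) %% 24)
  ## all-tied series
  flat_call <- jtk_test_gene(rep(1, 18), hours, 2)
  expect_equal(flat_call$p, 1)
  expect_equal(flat_call$amplitude, 0)
})

test_that("rank statistics are invariant to monotone transformation and shift", {
  set.seed(17)
  hours <- c(0, 6, 12, 18, 24, 30, 36, 42, 48)
  vals <- rep(cos(2 * pi * hours / 24), each = 2) + rnorm(18, 0, 0.3)
  a <- jtk_test_gene(vals, hours, 2)
  b <- jtk_test_gene(exp(vals), hours, 2)      # monotone transform
  d <- jtk_test_gene(vals + 5, hours, 2)       # constant shift
  expect_equal(a$p, b$p)
  expect_equal(a$tau, b$tau)
  expect_equal(a$p, d$p)
  expect_equal(a$amplitude, d$amplitude, tolerance = 1e-9)
})

test_that("white-noise genes rarely pass the within-gene adjusted test", {
  set.seed(18)
  hours <- c(0, 6, 12, 18, 24, 30, 36, 42, 48)
  n_genes <- 400
  m <- matrix(rnorm(n_genes * 18), n_genes)
  hits <- 0
  tmpl <- chronoseq:::jtk_templates(hours, 2, c(18, 24, 30))
  for (i in seq_along(tmpl)) tmpl[[i]]$pmf <- jt_null_pmf(tmpl[[i]]$group_sizes)
  for (g in seq_len(n_genes)) {
    hits <- hits + (jtk_test_gene(m[g, ], hours, 2, templates = tmpl)$p < 0.05)
  }
  expect_lte(hits / n_genes, 0.05)  # Bonferroni within gene is conservative
})

test_that("cyclic-gene selection applies both cutoffs strictly", {
  calls <- data.frame(gene = c("a", "b", "c"),
                      period_h = 24, phase_h = 0, tau = 0.8,
                      p = c(0.001, 0.001, 0.5),
                      q = c(0.04, 0.04, 0.9),
                      amplitude = c(0.5, 0.8, 2))
  expect_identical(select_cyclic(calls), "b")    # 0.5 fails the strict >
  expect_length(select_cyclic(calls[calls$q > 0.5, ]), 0)
})
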