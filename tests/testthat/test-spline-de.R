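test_that("variance squeezing sits between gene and prior variances", {
  set.seed(4)
  s2 <- rchisq(500, df = 10) / 10 * exp(rnorm(500, 0, 0.5))
  sq <- squeeze_var(s2, df = 10)
  expect_true(all(
    (sq$var_post >= pmin(s2, sq$var_prior) - 1e-12) &
      (sq$var_post <= pmax(s2, sq$var_prior) + 1e-12)
  ))
  ## equal variances: infinite prior df, full pooling
  sq2 <- squeeze_var(rep(2, 100), df = 10)
  expect_true(is.infinite(sq2$df_prior))
  ## full pooling; the log-scale moment correction exp(log(d/2)-digamma(d/2))
  ## applies even to degenerate constant input
  expect_equal(unique(sq2$var_post), 2 * exp(log(5) - digamma(5)),
               tolerance = 1e-6)
  ## heavy spread: prior df small, posterior close to gene variances
  s2w <- exp(rnorm(2000, 0, 3))
  sqw <- squeeze_var(s2w, df = 50)
  expect_lt(sqw$df_prior, 5)
  expect_gt(cor(log(sqw$var_post), log(s2w)), 0.95)
})

test_that("trigamma inversion solves trigamma(y) = x", {
  for (x in c(1e-5, 0.01, 0.5, 2, 50, 1e8)) {
    y <- chronoseq:::trigamma_inverse(x)
    expect_equal(trigamma(y), x, tolerance = 1e-6)
  }
})

test_that("BH adjustment matches a literal step-up on short vectors", {
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(3:20, 1))
    expect_equal(bh_adjust(p), bh_bruteforce(p), tolerance = 1e-12)
  }
})

test_that("voom-style weights track the mean-variance trend", {
  sim <- all_flat_fixture(400, seed = 6)
  design <- spline_design(sim$samples$time_h, 3)
  pre <- preprocess_counts(sim$counts)
  vw <- voom_weights(pre$counts, design, pre$tmm, pre$library_sizes)
  expect_true(all(vw$weights > 0))
  ## counts overdispersed: weight (precision) increases with expression,
  ## i.e. the sqrt-sd trend is non-increasing over the central mean range
  ord <- order(vw$trend$x)
  xs <- vw$trend$x[ord]; ys <- vw$trend$y[ord]
  central <- xs >= quantile(xs, 0.05) & xs <= quantile(xs, 0.95)
  yc <- ys[central]
  expect_true(all(diff(yc) <= 0.005))       # non-increasing up to lowess wiggle
  expect_lt(yc[length(yc)], yc[1] - 0.05)   # and clearly decreasing overall
  ## internal consistency: weights recomputable from the stored trend
  expect_equal(trend_weights(vw$trend, vw$fitted_logcount), vw$weights,
               tolerance = 1e-12)
  ## homoscedastic Gaussian data in place of counts: near-flat trend
  flat <- matrix(2^rnorm(length(pre$counts), 10, 0.05),
                 nrow = nrow(pre$counts), ncol = ncol(pre$counts),
                 dimnames = dimnames(pre$counts))
  vw2 <- voom_weights(flat, design)
  ratio <- max(vw2$weights) / min(vw2$weights)
  expect_lt(ratio, 1.5)
})

test_that("weighted spline fits reduce to textbook least squares", {
  sim <- all_flat_fixture(50, seed = 7)
  pre <- preprocess_counts(sim$counts)
  tab <- spline_fit_test(pre$norm, sim$samples, horizon_h = 48, df = 3)
  sel <- sim$samples$time_h <= 48
  X <- spline_design(sim$samples$time_h[sel], 3)
  for (g in c(1, 25, 50)) {
    beta <- solve(crossprod(X), crossprod(X, pre$norm[g, sel]))
    expect_equal(unname(unlist(tab[g, 2:5])), unname(beta[, 1]),
                 tolerance = 1e-10)
  }
})

test_that("spline tests detect the planted slow dip-recover class", {
  cfg <- fixture_config(n_genes = 500)
  cfg$n_class <- c(FLAT = 450, METABOLIC_DIP = 50, IMMEDIATE_SUSTAINED = 0,
                   TRANSIENT = 0, DIP_THEN_PEAK = 0, CYCLIC = 0)
  hits <- 0; total <- 0
  for (s in 1:3) {
    sim <- simulate_experiment(cfg, seed = s, couplings = list())
    pre <- preprocess_counts(sim$counts)
    design <- spline_design(sim$samples$time_h, 3)
    vw <- voom_weights(pre$counts, design, pre$tmm, pre$library_sizes)
    tab <- spline_fit_test(vw$logcpm, sim$samples, 48, weights = vw$weights)
    md <- sim$truth$class_table$gene_id[
      sim$truth$class_table$class == "METABOLIC_DIP"]
    hits <- hits + sum(tab$q < 0.05 & tab$gene %in% md)
    total <- total + length(md)
  }
  expect_gte(hits / total, 0.9)
})

test_that("polynomial fits apply both the FDR and goodness-of-fit gates", {
  grid <- time_grid()
  samples <- grid$samples
  sel <- samples$time_h <= 48
  tt <- samples$time_h[sel]
  set.seed(8)
  ## exact cubic, flat noise, and a borderline gene with real signal but
  ## R^2 capped at ~0.5 by added noise
  cubic <- 5 + 0.01 * tt - 0.002 * tt^2 + 3e-5 * tt^3
  flat <- rep(5, length(tt))
  sig <- scale(cubic)[, 1]
  borderline <- sig + rnorm(length(tt), 0, 1.05)
  y <- rbind(cubic = cubic, flat = flat + rnorm(length(tt), 0, 0.1),
             borderline = borderline)
  full <- matrix(5, 3, nrow(samples), dimnames = list(rownames(y), samples$sample_id))
  full[, sel] <- y
  tab <- polynomial_fit_test(full, samples)
  expect_equal(tab$r2[tab$gene == "cubic"], 1, tolerance = 1e-9)
  expect_true(tab$selected[tab$gene == "cubic"])
  expect_lt(tab$r2[tab$gene == "flat"], 0.2)
  expect_false(tab$selected[tab$gene == "flat"])
  b <- tab[tab$gene == "borderline", ]
  expect_lt(b$q, 0.05)        # clearly time-dependent ...
  expect_lt(b$r2, 0.6)        # ... but fails the fit-quality gate
  expect_false(b$selected)
})

test_that("horizon partitions are disjoint and exhaustive", {
  sim <- mixed_fixture(400, seed = 9)
  pre <- preprocess_counts(sim$counts)
  design <- spline_design(sim$samples$time_h, 3)
  vw <- voom_weights(pre$counts, design, pre$tmm, pre$library_sizes)
  t8 <- spline_fit_test(vw$logcpm, sim$samples, 8, weights = vw$weights)
  t48 <- spline_fit_test(vw$logcpm, sim$samples, 48, weights = vw$weights)
  sets <- select_time_dependent(t8, t48)
  expect_equal(length(sets$short_only) + length(sets$long_only) +
                 length(sets$both), length(sets$union))
  expect_length(intersect(sets$short_only, sets$long_only), 0)
  ## identical tables: everything lands in `both`
  same <- select_time_dependent(t48, t48)
  expect_identical(sort(same$both), sort(same$union))
  expect_length(same$short_only, 0)
  ## mismatched universes rejected
  expect_error(select_time_dependent(t8[-1, ], t48), "universe")
})
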