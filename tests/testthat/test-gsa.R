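make_paired_fixture <- function(n_genes, seed, shift_genes = NULL, shift = 0,
                                time_h = 8) {
  sim <- all_flat_fixture(n_genes, seed = seed)
  pre <- preprocess_counts(sim$counts)
  norm <- pre$norm
  if (!is.null(shift_genes)) {
    norm[shift_genes, sim$samples$time_h == time_h] <-
      norm[shift_genes, sim$samples$time_h == time_h] + shift
  }
  list(norm = norm, samples = sim$samples)
}

test_that("paired statistics follow their closed form", {
  fx <- make_paired_fixture(100, seed = 30)
  ## identical t and baseline: statistic exactly zero
  norm0 <- fx$norm
  for (r in 1:2) {
    norm0[, fx$samples$time_h == 8 & fx$samples$replicate == r] <-
      norm0[, fx$samples$time_h == 0 & fx$samples$replicate == r]
  }
  st0 <- paired_gene_stats(norm0, fx$samples, 8)
  expect_equal(as.numeric(st0), rep(0, 100))
  ## both replicate differences exactly +2: statistic = 2 / s0
  norm2 <- fx$norm
  for (r in 1:2) {
    norm2[1, fx$samples$time_h == 8 & fx$samples$replicate == r] <-
      norm2[1, fx$samples$time_h == 0 & fx$samples$replicate == r] + 2
  }
  st2 <- paired_gene_stats(norm2, fx$samples, 8)
  expect_equal(unname(st2[1]), 2 / attr(st2, "s0"))
  ## swapping the class labels negates every statistic
  swapped <- transform(fx$samples,
                       time_h = ifelse(time_h == 0, 8,
                                       ifelse(time_h == 8, 0, time_h)))
  st_f <- paired_gene_stats(fx$norm, fx$samples, 8)
  st_r <- paired_gene_stats(fx$norm, swapped, 8)
  expect_equal(unname(st_f), -unname(st_r))
  ## missing pair is an error
  broken <- fx$samples[-(1:2), ]
  expect_error(paired_gene_stats(fx$norm[, broken$sample_id], broken, 8),
               "missing paired sample")
})

test_that("the maxmean score matches its literal definition", {
  set.seed(31)
  stats_vec <- setNames(rnorm(200), paste0("g", 1:200))
  ## all member statistics +1
  ones <- setNames(rep(1, 10), paste0("g", 1:10))
  expect_equal(maxmean_raw(ones, names(ones)), 1)
  ## {+2, -2}: positive and negative parts tie; tie breaks positive
  two <- setNames(c(2, -2), c("a", "b"))
  expect_equal(maxmean_raw(two, c("a", "b")), 1)
  ## random sets against the independent literal implementation
  for (i in 1:25) {
    members <- sample(names(stats_vec), sample(5:30, 1))
    expect_equal(maxmean_raw(stats_vec, members),
                 maxmean_literal(stats_vec, members))
    ## invariant to member order
    expect_equal(maxmean_raw(stats_vec, rev(members)),
                 maxmean_raw(stats_vec, members))
  }
  expect_error(maxmean_raw(stats_vec, "absent"), "no members")
})

test_that("restandardized scores of random sets are standard-normal-ish", {
  set.seed(32)
  stats_vec <- setNames(rnorm(1000), paste0("g", 1:1000))
  scores <- vapply(1:300, function(i) {
    members <- sample(names(stats_vec), 20)
    as.numeric(maxmean_score(stats_vec, members, n_random = 400))
  }, numeric(1))
  expect_lt(abs(mean(scores)), 0.15)
  expect_lt(abs(sd(scores) - 1), 0.2)
})

test_that("permutation p-values are calibrated on flat sets and find signal", {
  ## null: a set of flat genes, p roughly uniform over repeated fixtures
  ps <- vapply(1:40, function(s) {
    fx <- make_paired_fixture(300, seed = 100 + s)
    sets <- list(nullset = rownames(fx$norm)[sample(300, 15)])
    out <- gsa_permutation(sets, fx$norm, fx$samples, time_points = 8,
                           n_perm = 400)
    out$p
  }, numeric(1))
  ## permutation p-values are discrete (multiples of 1/401), so ks.test
  ## warns about ties; the uniformity check itself is unaffected
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_true(all(ps > 0))   # add-one convention: never exactly zero
  ## signal: a set shifted up at 8 h scores "up" with small p
  hits <- 0
  for (s in 1:10) {
    fx <- make_paired_fixture(300, seed = 200 + s,
                              shift_genes = paste0("g", sprintf("%04d", 1:15)),
                              shift = 2)
    sets <- list(upset = rownames(fx$norm)[1:15])
    out <- gsa_permutation(sets, fx$norm, fx$samples, time_points = 8,
                           n_perm = 400)
    hits <- hits + (out$direction == "up" && out$p < 0.05)
  }
  expect_gte(hits, 9)
  ## sets below the size floor are dropped with a log message
  fx <- make_paired_fixture(300, seed = 300)
  sets <- list(tiny = rownames(fx$norm)[1:3],
               ok = rownames(fx$norm)[1:20])
  expect_message(out <- gsa_permutation(sets, fx$norm, fx$samples,
                                        time_points = 8, n_perm = 150),
                 "dropping")
  expect_identical(unique(out$set), "ok")
  expect_error(gsa_permutation(sets, fx$norm, fx$samples, n_perm = 10),
               "at least 100")
})

test_that("GMT round trip preserves set membership", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4\tg5"), path)
  sets <- read_gmt(path)
  expect_identical(sets$setA, c("g1", "g2", "g3"))
  expect_identical(sets$setB, c("g4", "g5"))
})
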