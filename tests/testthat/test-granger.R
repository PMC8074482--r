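grid <- time_grid()

test_that("window construction follows the index grid", {
  w <- make_windows(grid)
  expect_equal(nrow(w), 16)                 # 21 - 6 + 1
  expect_equal(w$first_h[1], 0)
  expect_equal(w$last_h[1], 5)              # window 1: hours 0..5
  expect_equal(w$index, 1:16)
  ## a window ends within the first day iff its index is at most 9
  expect_equal(w$index[w$last_h <= 24], 1:9)
  ## degenerate width
  g6 <- time_grid(c(0, 1, 2, 3, 4, 5))
  expect_equal(nrow(make_windows(g6)), 1)
  expect_error(make_windows(time_grid(c(0, 1, 2))), "at least 6")
})

test_that("bivariate tests find planted lead-lag pairs and flag degeneracy", {
  set.seed(33)
  hits <- 0
  for (s in 1:20) {
    ## y_{t+1} = 0.9 x_t + small noise on a 6-point grid, x white
    g6 <- time_grid(c(0, 1, 2, 3, 4, 5))
    x <- matrix(rnorm(12), 2, 6, byrow = FALSE)
    y <- matrix(0, 2, 6)
    for (r in 1:2) for (t in 2:6) y[r, t] <- 0.9 * x[r, t - 1] + rnorm(1, 0, 0.15)
    norm <- rbind(x = as.vector(rbind(x[1, ], x[2, ])),
                  y = as.vector(rbind(y[1, ], y[2, ])))
    colnames(norm) <- g6$samples$sample_id
    tab <- bivariate_gc_window(norm, g6$samples, g6, 1)
    row <- tab[tab$source == "x" & tab$target == "y", ]
    hits <- hits + (row$beta > 0 && row$p < 0.01)
  }
  expect_gte(hits / 20, 0.95)
  ## perfect collinearity with the autoregressive term: flagged degenerate
  ct <- flat_class_table(3)
  sys <- simulate_gc_system(ct, seed = 34)
  norm2 <- sys$norm
  norm2[2, ] <- norm2[1, ]   # x identical to y
  tab2 <- bivariate_gc_window(norm2, sys$samples, grid, 4)
  row2 <- tab2[tab2$source == ct$gene_id[1] & tab2$target == ct$gene_id[2], ]
  expect_true(row2$degenerate)
  expect_equal(row2$p, 1)
})

test_that("gene relabeling and rescaling leave the tests unchanged", {
  ct <- flat_class_table(5)
  sys <- simulate_gc_system(ct, seed = 35)
  tab <- bivariate_gc_window(sys$norm, sys$samples, grid, 3)
  ## permuting gene rows permutes results consistently
  perm <- c(3, 5, 1, 2, 4)
  tab_p <- bivariate_gc_window(sys$norm[perm, ], sys$samples, grid, 3)
  key <- function(d) {
    d <- d[order(d$source, d$target), c("beta", "p")]
    rownames(d) <- NULL
    d
  }
  expect_equal(key(tab), key(tab_p), tolerance = 1e-12)
  ## multiplying one gene's series by a positive constant changes nothing
  scaled <- sys$norm
  scaled[2, ] <- scaled[2, ] * 7.3
  tab_s <- bivariate_gc_window(scaled, sys$samples, grid, 3)
  expect_equal(key(tab), key(tab_s), tolerance = 1e-10)
  mv <- multivariate_gc_window(sys$norm, sys$samples, grid, 3)
  mv_s <- multivariate_gc_window(scaled, sys$samples, grid, 3)
  expect_equal(key(mv), key(mv_s), tolerance = 1e-8)
})

test_that("de-biased estimates collapse to least squares in low dimension", {
  ct <- flat_class_table(3)
  sys <- simulate_gc_system(ct, seed = 36)
  tr <- chronoseq:::window_transitions(sys$norm, sys$samples, grid, 5)
  ols <- qr.solve(tr$X, tr$Y)
  for (variant in c("nodewise", "jm")) {
    mv <- multivariate_gc_window(sys$norm, sys$samples, grid, 5,
                                 variant = variant, lambda = 0)
    for (j in 1:3) {
      got <- mv$beta[mv$target == ct$gene_id[j]]
      want <- ols[-j, j]
      expect_equal(got, unname(want), tolerance = 1e-8)
    }
  }
})

test_that("the two de-biasing variants agree on well-conditioned systems", {
  ct <- flat_class_table(8)
  sys <- simulate_gc_system(ct, seed = 37)
  a <- multivariate_gc_window(sys$norm, sys$samples, grid, 6, variant = "nodewise")
  b <- multivariate_gc_window(sys$norm, sys$samples, grid, 6, variant = "jm")
  joint_se <- sqrt(a$se^2 + b$se^2)
  expect_true(all(abs(a$beta - b$beta) <= 2 * joint_se))
})

test_that("all-null multivariate systems keep the BH edge yield at bay", {
  ct <- flat_class_table(30)
  yields <- c()
  for (s in 1:3) {
    sys <- simulate_gc_system(ct, seed = 40 + s)
    mv <- multivariate_gc_window(sys$norm, sys$samples, grid, 2 + 4 * s)
    q <- p.adjust(mv$p, "BH")
    yields <- c(yields, mean(q < 0.05))
  }
  se <- sqrt(0.05 * 0.95 / (30 * 29))
  expect_true(all(yields <= 0.05 + 2 * se))
})

test_that("edge aggregation computes sign-consistent runs", {
  scan <- data.frame(
    source = "a", target = "b",
    window = 1:8,
    beta = c(-1, -1, -1, -1, 1, -1, -1, -1),
    p = c(0.5, 1e-6, 1e-6, 1e-6, 1e-6, 0.5, 1e-6, 0.9))
  ## pad with null rows so BH keeps only the tiny p-values
  pad <- data.frame(source = "c", target = "d", window = rep(1:8, 10),
                    beta = 0.1, p = runif(80, 0.5, 1))
  edges <- aggregate_edges(rbind(scan, pad), fdr = 0.05)
  e <- edges[edges$source == "a", ]
  ## significant windows 2,3,4,5,7; sign flips at 5: longest run is 2..4
  expect_equal(e$run_len, 3)
  expect_equal(e$run_sign, -1)
  expect_true(is.na(e$overall_sign))  # signs disagree across windows
  ## windows {2,3,4,7} with one sign: run of 3
  scan2 <- scan
  scan2$beta <- -1
  scan2$p <- c(0.5, 1e-6, 1e-6, 1e-6, 0.5, 0.5, 1e-6, 0.9)
  e2 <- aggregate_edges(rbind(scan2, pad), fdr = 0.05)
  e2 <- e2[e2$source == "a", ]
  expect_equal(e2$run_len, 3)
  expect_equal(e2$overall_sign, -1)
})

test_that("network filtering enforces sign, persistence, horizon and cyclicity", {
  win <- make_windows(grid)
  mk_edge <- function(source, target, windows, signs) {
    data.frame(source = source, target = target, n_sig = length(windows),
               run_len = NA, run_sign = NA, overall_sign = NA,
               sig_windows = I(list(windows)), sig_signs = I(list(signs)),
               stringsAsFactors = FALSE)
  }
  edges <- rbind(
    mk_edge("a", "b", 2:5, rep(-1, 4)),      # qualifies
    mk_edge("c", "d", 2:5, rep(1, 4)),       # positive: dropped
    mk_edge("e", "f", c(2, 4, 6), rep(-1, 3)),  # not consecutive
    mk_edge("g", "h", 8:11, rep(-1, 4)),     # run exceeds the 24 h horizon
    mk_edge("k", "cyc", 2:5, rep(-1, 4))     # cyclic endpoint
  )
  net <- filter_network(edges, cyclic_genes = "cyc", windows = win)
  expect_equal(nrow(net$edges), 1)
  expect_identical(net$edges$source, "a")
  expect_equal(net$n_components, 1)
  expect_setequal(net$nodes, c("a", "b"))
  ## all edges positive: empty network
  net0 <- filter_network(edges[2, ], character(), win)
  expect_equal(length(net0$nodes), 0)
  expect_equal(net0$n_components, 0)
  ## window 8 starts at hour 10 and ends at hour 20: a run of 3 fully
  ## inside the first 24 h qualifies even at late indices
  e_ok <- mk_edge("p", "q", 7:9, rep(-1, 3))
  expect_equal(nrow(filter_network(e_ok, character(), win)$edges), 1)
})
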