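test_that("VAR coefficients are recovered from simulated data", {
  a1 <- matrix(c(0.5, 0.0, 0.3, 0.4), 2, 2, byrow = TRUE)
  a2 <- matrix(c(-0.2, 0.0, 0.0, 0.1), 2, 2, byrow = TRUE)
  x <- sim_var2(list(a1, a2), diag(2), n = 10000, seed = 1)
  m <- fit_var(x, max_order = 6)
  expect_equal(m$order, 2)
  expect_lt(max(abs(m$A[, , 1] - a1)), 0.05)
  expect_lt(max(abs(m$A[, , 2] - a2)), 0.05)
  expect_true(m$stable)
  expect_gt(m$whiteness_p, 0.01)
})

test_that("white noise fits to near-zero coefficients; constants rejected", {
  set.seed(2)
  wn <- matrix(rnorm(4000), 2000, 2)
  m <- fit_var(wn, order = 2)
  expect_lt(max(abs(m$A)), 0.06)
  expect_error(fit_var(cbind(rep(1, 500), rnorm(500))), "singular|constant")
})

test_that("spectral causality matches the nested-regression oracle", {
  # y driven by x with a 1-sample lag; x autonomous
  a1 <- matrix(c(0.5, 0.0, 0.4, 0.3), 2, 2, byrow = TRUE)
  x <- sim_var2(list(a1), diag(c(1, 1)), n = 20000, seed = 3)
  m <- fit_var(x, order = 1)
  freqs <- seq(0.5, 499.5, by = 0.5)
  g <- spectral_gc(m, freqs, fs = 1000)
  # no reverse coupling: y -> x flat near zero
  expect_lt(mean(g$gc[, "y_to_x"]), 0.01)
  # Geweke consistency: spectral mean ~ time-domain value
  td <- nested_gc(x[, 2], x[, 1], p = 2)   # causality x -> y
  expect_gt(td, 0.05)
  expect_lt(abs(mean(g$gc[, "x_to_y"]) - td) / td, 0.05)
  expect_true(all(g$gc >= 0))
})

test_that("independent channels show no causality either way", {
  set.seed(4)
  x <- cbind(stats::filter(rnorm(5000), 0.6, "recursive"),
             stats::filter(rnorm(5000), 0.6, "recursive"))
  x <- x[101:5000, ]
  m <- fit_var(x, order = 2)
  g <- spectral_gc(m, seq(1, 499, 2), fs = 1000)
  expect_lt(mean(g$gc), 0.005)
})

test_that("pairwise causality is invariant under channel scaling", {
  a1 <- matrix(c(0.5, 0.0, 0.4, 0.3), 2, 2, byrow = TRUE)
  x <- sim_var2(list(a1), diag(2), n = 8000, seed = 5)
  freqs <- seq(1, 499, 2)
  g1 <- spectral_gc(fit_var(x, order = 1), freqs)
  xs <- x %*% diag(c(100, 0.01))
  g2 <- spectral_gc(fit_var(xs, order = 1), freqs)
  expect_equal(g1$gc, g2$gc, tolerance = 1e-8)
})

test_that("conditioning removes a common driver and spares real coupling", {
  set.seed(6)
  n <- 6000
  z <- stats::filter(rnorm(n + 2), c(0.9, -0.3), "recursive")[3:(n + 2)]
  x <- 0.8 * z + rnorm(n, 0, 0.5)
  y <- 0.8 * c(0, z[-n]) + rnorm(n, 0, 0.5)   # z drives y at a lag
  freqs <- seq(1, 499, 4)
  un <- spectral_gc(fit_var(cbind(x, y), order = 4), freqs)
  cd <- conditional_spectral_gc(x, y, z, freqs, order = 4)
  expect_gt(mean(un$gc[, "x_to_y"]), 0.05)    # spurious without conditioning
  expect_lt(mean(cd$gc[, "x_to_y"]),
            0.2 * mean(un$gc[, "x_to_y"]))    # suppressed >= 80%
  # with z independent of both, conditional ~ unconditional
  a1 <- matrix(c(0.5, 0.0, 0.4, 0.3), 2, 2, byrow = TRUE)
  v <- sim_var2(list(a1), diag(2), n = 8000, seed = 7)
  z2 <- stats::filter(rnorm(8000), 0.5, "recursive")
  un2 <- spectral_gc(fit_var(v, order = 2), freqs)
  cd2 <- conditional_spectral_gc(v[, 1], v[, 2], z2, freqs, order = 2)
  expect_equal(mean(cd2$gc[, "x_to_y"]), mean(un2$gc[, "x_to_y"]),
               tolerance = 0.05)
  expect_error(conditional_spectral_gc(x, x, x, freqs), "collinear")
})

test_that("sliding windows track a mid-series direction switch", {
  a_fwd <- matrix(c(0.5, 0.0, 0.45, 0.3), 2, 2, byrow = TRUE)
  a_rev <- matrix(c(0.3, 0.45, 0.0, 0.5), 2, 2, byrow = TRUE)
  seg1 <- sim_var2(list(a_fwd), diag(2), n = 3000, seed = 8)
  seg2 <- sim_var2(list(a_rev), diag(2), n = 3000, seed = 9)
  x <- c(seg1[, 1], seg2[, 1]); y <- c(seg1[, 2], seg2[, 2])
  sl <- sliding_gc(x, y, window = 600, step = 300, band = c(1, 499),
                   order = 2)
  early <- sl$dominant[sl$t_mid < 2500]
  late <- sl$dominant[sl$t_mid > 3500]
  expect_true(all(early == "x->y"))
  expect_true(all(late == "y->x"))
  # stationary unidirectional series never flips
  sl1 <- sliding_gc(seg1[, 1], seg1[, 2], window = 600, step = 300,
                    band = c(1, 499), order = 2)
  expect_true(all(sl1$dominant == "x->y"))
  expect_error(sliding_gc(x[1:100], y[1:100], window = 600), "longer")
})

test_that("the VAR fixture's analytic ground truth matches estimation", {
  a1 <- matrix(c(0.4, 0.3, 0.0, 0.5), 2, 2, byrow = TRUE)
  # channel 1 = y (driven), channel 2 = x (autonomous)
  fx <- gen_var_process(a1, diag(2), n = 10000, trials = 1, seed = 10)
  truth <- fx$true_gc[1, 2]
  expect_gt(truth, 0)
  est <- nested_gc(fx$trials[[1]][, 1], fx$trials[[1]][, 2], p = 2)
  expect_lt(abs(est - truth) / truth, 0.1)
  # zero coupling: truth exactly zero
  a0 <- matrix(c(0.4, 0, 0, 0.5), 2, 2, byrow = TRUE)
  f0 <- gen_var_process(a0, diag(2), n = 100, trials = 1, seed = 11)
  expect_lt(f0$true_gc[1, 2], 0.01)
  expect_error(gen_var_process(diag(2) * 1.1, diag(2), 100), "unstable")
})
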