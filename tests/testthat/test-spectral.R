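test_that("Slepian tapers are orthonormal and match the reference values", {
  h <- dpss_tapers(32, nw = 3, k = 5)
  expect_equal(crossprod(h), diag(5), tolerance = 1e-10)
  # reference values computed independently with scipy.signal.windows.dpss
  ref0 <- c(0.0008685216, 0.0028992355, 0.0069621987, 0.0140001733,
            0.0249883443, 0.0407827077, 0.0619444784, 0.0885686738)
  ref3 <- c(0.0736679018, 0.1312061877, 0.1917693190, 0.2438154189,
            0.2753174651, 0.2765922960, 0.2429346666, 0.1763570243)
  expect_equal(h[1:8, 1], ref0, tolerance = 1e-7)
  expect_equal(abs(h[1:8, 4]), abs(ref3), tolerance = 1e-7)
})

test_that("PSD recovers a sinusoid peak and satisfies Parseval", {
  tt <- (0:999) / 1000
  x <- sin(2 * pi * 40 * tt)
  psd <- multitaper_psd(x, nw = 5)
  expect_equal(psd$freq[which.max(psd$value)], 40, tolerance = 2.5)
  set.seed(1)
  wn <- matrix(rnorm(2000 * 10), 2000, 10)
  p <- multitaper_psd(wn, nw = 5)
  df <- p$freq[2] - p$freq[1]
  expect_equal(sum(p$value) * df, 1, tolerance = 0.02)
  expect_true(all(multitaper_psd(rep(0, 500))$value == 0))
})

test_that("coherence is 1 for identical signals and bias-level for noise", {
  set.seed(2)
  x <- matrix(rnorm(1000 * 8), 1000, 8)
  self <- multitaper_coherence(x, x)
  expect_true(all(abs(self$value - 1) < 1e-8, na.rm = TRUE))
  y <- matrix(rnorm(1000 * 8), 1000, 8)
  co <- multitaper_coherence(x, y)
  bias <- shuffle_bias(x, y, n_shuffles = 10, seed = 1)
  expect_lt(abs(mean(co$value) - mean(bias$value)), 0.02)
  expect_true(all(co$value >= 0 & co$value <= 1, na.rm = TRUE))
})

test_that("a shared lagged oscillation is coherent only at its frequency", {
  set.seed(3)
  tt <- (0:1499) / 1000
  mk <- function(lag) sapply(1:10, function(m)
    cos(2 * pi * 40 * (tt - lag) + m) + rnorm(1500, 0, 0.5))
  x <- sapply(1:10, function(m) cos(2 * pi * 40 * tt + m) +
                rnorm(1500, 0, 0.5))
  set.seed(3)
  phases <- runif(10, 0, 2 * pi)
  x <- sapply(1:10, function(m) cos(2 * pi * 40 * tt + phases[m]) +
                rnorm(1500, 0, 0.5))
  y <- sapply(1:10, function(m) cos(2 * pi * 40 * (tt - 0.005) +
                                      phases[m]) + rnorm(1500, 0, 0.5))
  co <- multitaper_coherence(x, y)
  at40 <- co$value[which.min(abs(co$freq - 40))]
  away <- mean(co$value[co$freq > 60 & co$freq < 200])
  expect_gt(at40, 0.8)
  expect_lt(away, 0.2)
})

test_that("coherence is symmetric and scale-invariant", {
  set.seed(4)
  fx <- gen_phase_locked_oscillation(30, jitter_sd = 0.4, amp_sd = 0.3,
                                     n = 800, trials = 12, seed = 4,
                                     noise_sd = 0.3)
  a <- multitaper_coherence(fx$x, fx$y)
  b <- multitaper_coherence(fx$y, fx$x)
  expect_equal(a$value, b$value, tolerance = 1e-10)
  c2 <- multitaper_coherence(fx$x * 7, fx$y * 0.01)
  expect_equal(a$value, c2$value, tolerance = 1e-8)
})

test_that("amplitude and phase components separate their fixtures", {
  # identical amplitudes, random relative phase: amplitude high, phase low
  set.seed(5)
  tt <- (0:999) / 1000
  x <- sapply(1:12, function(m) cos(2 * pi * 40 * tt + runif(1, 0, 2 * pi)))
  y <- sapply(1:12, function(m) cos(2 * pi * 40 * tt + runif(1, 0, 2 * pi)))
  cc <- coherence_components(x, y)
  i40 <- which.min(abs(cc$freq - 40))
  expect_gt(cc$amplitude[i40], 0.9)
  expect_lt(cc$phase[i40], 0.3)
  # constant relative phase, random amplitudes: phase ~1, amplitude low
  # (per-trial frequency jitter keeps the tone off exact DFT bins)
  amp_x <- exp(rnorm(12)); amp_y <- exp(rnorm(12))
  fm <- 40 + runif(12, -0.4, 0.4)
  x2 <- sapply(1:12, function(m) amp_x[m] * cos(2 * pi * fm[m] * tt + m))
  y2 <- sapply(1:12, function(m)
    amp_y[m] * cos(2 * pi * fm[m] * tt + m + 1))
  c2 <- coherence_components(x2, y2)
  expect_gt(c2$phase[i40], 0.95)
  expect_lt(c2$amplitude[i40], c2$phase[i40])
  # y = x: both components 1
  c3 <- coherence_components(x2, x2)
  expect_gt(c3$phase[i40], 0.999)
  expect_gt(c3$amplitude[i40], 0.999)
})

test_that("the shuffle estimator validates its preconditions", {
  set.seed(6)
  x <- matrix(rnorm(200 * 4), 200, 4)
  expect_error(shuffle_bias(x, x, n_shuffles = 0), "n_shuffles")
  expect_error(shuffle_bias(x[, 1:2], x[, 1:2]), "at least 3")
})

test_that("Morlet phase advances at the carrier frequency", {
  tt <- (0:999) / 1000
  x <- cos(2 * pi * 40 * tt)
  tf <- morlet_transform(x, c(20, 40, 60))
  pw <- wavelet_power(tf)
  mid <- 300:700
  expect_true(all(colMeans(pw[mid, ])[2] > colMeans(pw[mid, ])[c(1, 3)]))
  ph <- wavelet_phase(tf)[mid, 2]
  dph <- diff(ph)
  dph <- dph - 2 * pi * round(dph / (2 * pi))
  expect_equal(mean(dph) * 1000 / (2 * pi), 40, tolerance = 0.5)
  # unit cosine gives |coef| ~ 1 under the chosen normalisation
  expect_equal(mean(abs(tf$coef[mid, 2])), 1, tolerance = 0.02)
  expect_true(all(wavelet_power(morlet_transform(rep(0, 400), 30)) == 0))
  expect_error(morlet_transform(x, 600), "Nyquist|fs/2")
})

test_that("40 Hz power trace recovers an amplitude modulation envelope", {
  tt <- (0:1999) / 1000
  env <- 1 + 0.8 * sin(2 * pi * 3 * tt)
  x <- env * cos(2 * pi * 40 * tt)
  tf <- morlet_transform(x, 40)
  amp <- abs(tf$coef[, 1])
  mid <- 200:1800
  expect_gt(stats::cor(amp[mid], env[mid]), 0.99)
})

test_that("band metrics locate constructed peaks", {
  est <- structure(list(freq = seq(0, 100, 0.5),
                        value = rep(1, 201)), class = "spectral_estimate")
  est$value[est$freq == 42] <- 50
  bm <- band_metrics(est, search = c(20, 80))
  expect_equal(bm$peak_freq, 42)
  expect_equal(bm$band_power, mean(est$value[est$freq >= 32 &
                                               est$freq <= 52]))
  flat <- structure(list(freq = seq(0, 100, 0.5), value = rep(3, 201)),
                    class = "spectral_estimate")
  expect_equal(band_metrics(flat, c(20, 80))$band_power, 3)
  expect_error(band_metrics(flat, c(200, 300)), "outside")
})

test_that("phase binning of gamma power finds the injected preference", {
  ph <- seq(-pi, pi, length.out = 5000)
  pw <- 1 + cos(ph)
  cc <- alpha_gamma_coupling(ph, pw, n_bins = 18)
  # the two bins flanking zero share the maximum
  expect_lt(abs(cc$phase_deg[which.max(cc$power)]), 11)
  flat <- alpha_gamma_coupling(ph, rep(2, 5000), n_bins = 18)
  expect_true(all(abs(flat$power - 2) < 1e-12))
})
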