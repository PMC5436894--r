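# Parametric signal generators with known spectral / causal / phase-locking
# ground truth, used as oracles for the analysis modules. Their RNG use is
# self-contained (explicit seeds) so oracle tests never couple to the
# simulator's streams.

#' Simulate a VAR process with analytic Granger-causality ground truth
#'
#' Draws `trials` realisations of the VAR defined by `coeffs` and `Sigma`.
#' The time-domain causality for each ordered channel pair is computed
#' analytically from the model itself: the full-model residual variance is
#' read off `Sigma`, and the reduced-model innovation variance of the target
#' channel is obtained from the model's marginal spectrum via the
#' Kolmogorov formula sigma^2 = exp( (1/2 pi) int log S(lambda) dlambda ),
#' so the ground truth never depends on any estimator under test.
#'
#' @param coeffs nch x nch x p coefficient array.
#' @param Sigma Residual covariance.
#' @param n Samples per trial.
#' @param trials Number of trials.
#' @param seed Integer seed.
#' @param burn Burn-in samples discarded per trial.
#' @return List of class `var_fixture`: `trials` (list of n x nch
#'   matrices), `true_gc` (nch x nch matrix, `[i, j]` = causality j -> i),
#'   `coeffs`, `Sigma`.
#' @export
gen_var_process <- function(coeffs, Sigma, n, trials = 1, seed = 1,
                            burn = 200) {
  a <- if (length(dim(coeffs)) == 3) coeffs
       else array(coeffs, c(nrow(coeffs), ncol(coeffs), 1))
  nch <- dim(a)[1]; p <- dim(a)[3]
  comp <- matrix(0, nch * p, nch * p)
  for (k in seq_len(p))
    comp[1:nch, ((k - 1) * nch + 1):(k * nch)] <- a[, , k]
  if (p > 1)
    comp[(nch + 1):(nch * p), 1:(nch * (p - 1))] <- diag(nch * (p - 1))
  if (max(Mod(eigen(comp, only.values = TRUE)$values)) >= 1)
    stop("unstable VAR coefficients", call. = FALSE)
  ch <- chol(Sigma)
  set.seed(seed)
  sims <- lapply(seq_len(trials), function(tr) {
    tt <- n + burn
    e <- matrix(stats::rnorm(tt * nch), tt, nch) %*% ch
    x <- matrix(0, tt, nch)
    for (i in (p + 1):tt) {
      acc <- e[i, ]
      for (k in seq_len(p)) acc <- acc + a[, , k] %*% x[i - k, ]
      x[i, ] <- acc
    }
    x[(burn + 1):tt, , drop = FALSE]
  })
  # analytic marginal spectrum of channel i on a fine grid
  grid <- seq(0, pi, length.out = 2049)[-1]
  model <- list(A = a, order = p)
  smat <- vapply(grid, function(lam) {
    h <- var_transfer(model, lam)
    Re(diag(h %*% Sigma %*% Conj(t(h))))
  }, numeric(nch))
  # Kolmogorov innovation variance of each channel's own-past-only model;
  # log(red/full) is the exact bivariate GC (others -> i) for nch == 2 and
  # the joint causality of all other channels onto i otherwise.
  true_gc <- matrix(0, nch, nch)
  for (i in seq_len(nch)) {
    red_var <- exp(mean(log(smat[i, ])))
    for (j in seq_len(nch)) {
      if (i != j) true_gc[i, j] <- max(0, log(red_var / Sigma[i, i]))
    }
  }
  structure(list(trials = sims, true_gc = true_gc, coeffs = a,
                 Sigma = Sigma),
            class = "var_fixture")
}

#' Paired oscillations with controlled phase jitter and amplitude variability
#'
#' Each trial holds two sinusoids at `f0` whose relative phase is jittered
#' across trials by a wrapped normal of sd `jitter_sd` and whose amplitudes
#' vary log-normally with sd `amp_sd`. The expected phase-locking value is
#' the wrapped-normal characteristic function exp(-jitter_sd^2 / 2),
#' recorded as ground truth.
#'
#' @param f0 Oscillation frequency, Hz.
#' @param jitter_sd Across-trial relative-phase sd, radians.
#' @param amp_sd Log-amplitude sd.
#' @param freq_jitter Half-width of a per-trial uniform frequency jitter,
#'   Hz (shared by the pair within a trial; keeps the tone off exact DFT
#'   bins, as for any physical oscillation of finite line width).
#' @param n Samples per trial.
#' @param trials Number of trials.
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed.
#' @param noise_sd Additive white noise sd.
#' @return List of class `oscillation_fixture`: `x`, `y` (n x trials
#'   matrices), `expected_locking`, `f0`.
#' @export
gen_phase_locked_oscillation <- function(f0, jitter_sd = 0, amp_sd = 0,
                                         n = 1000, trials = 20, fs = 1000,
                                         seed = 1, noise_sd = 0,
                                         freq_jitter = 0.3) {
  stopifnot(f0 < fs / 2)
  set.seed(seed)
  tt <- (seq_len(n) - 1) / fs
  x <- matrix(0, n, trials); y <- matrix(0, n, trials)
  for (m in seq_len(trials)) {
    th <- stats::runif(1, 0, 2 * pi)
    dlt <- stats::rnorm(1, 0, jitter_sd)
    fm <- f0 + stats::runif(1, -freq_jitter, freq_jitter)
    ax <- exp(stats::rnorm(1, 0, amp_sd))
    ay <- exp(stats::rnorm(1, 0, amp_sd))
    x[, m] <- ax * cos(2 * pi * fm * tt + th) +
      stats::rnorm(n, 0, noise_sd)
    y[, m] <- ay * cos(2 * pi * fm * tt + th + dlt) +
      stats::rnorm(n, 0, noise_sd)
  }
  structure(list(x = x, y = y,
                 expected_locking = exp(-jitter_sd^2 / 2), f0 = f0),
            class = "oscillation_fixture")
}

#' Spike train with von Mises phase modulation of known concentration
#'
#' Inhomogeneous Poisson process whose rate is modulated by the phase trace:
#' rate(t) = base_rate * exp(kappa cos(phase(t) - preferred)) / I0(kappa),
#' normalised so the mean rate stays near `base_rate`. Ground truth
#' (kappa, preferred phase) is recorded.
#'
#' @param base_rate Mean rate, Hz.
#' @param phase Phase trace, radians.
#' @param phase_times Times of the phase samples, ms.
#' @param kappa Von Mises concentration (>= 0).
#' @param preferred Preferred phase, radians.
#' @param seed Integer seed.
#' @return List of class `spike_fixture`: `spike_times` (ms), `kappa`,
#'   `preferred`.
#' @export
gen_modulated_spikes <- function(base_rate, phase, phase_times, kappa = 0,
                                 preferred = 0, seed = 1) {
  stopifnot(kappa >= 0, base_rate >= 0)
  set.seed(seed)
  dt <- stats::median(diff(phase_times))
  rate <- base_rate * exp(kappa * cos(phase - preferred)) /
    besselI(kappa, 0)
  p <- pmin(1, rate * dt / 1000)
  fired <- stats::runif(length(p)) < p
  structure(list(spike_times = phase_times[fired], kappa = kappa,
                 preferred = preferred),
            class = "spike_fixture")
}
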