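.taper_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-half-bandwidth
#' product `nw`, via the classical symmetric tridiagonal eigenproblem
#' (diagonal ((n-1-2t)/2)^2 cos(2 pi W), off-diagonal t(n-t)/2). Tapers are
#' unit-norm; symmetric tapers have positive mean, antisymmetric ones start
#' with a positive lobe. Results are cached per (n, nw, k): the n = 2000
#' eigendecomposition is computed once per session.
#'
#' @param n Taper length, samples.
#' @param nw Time-half-bandwidth product (default 5).
#' @param k Number of tapers (default `2 nw - 1`).
#' @return n x k matrix of tapers.
#' @export
dpss_tapers <- function(n, nw = 5, k = 2 * nw - 1) {
  stopifnot(n > 2 * k, nw > 0, k >= 1)
  key <- paste(n, nw, k, sep = "_")
  hit <- .taper_cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- nw / n
  tt <- 0:(n - 1)
  dg <- ((n - 1 - 2 * tt) / 2)^2 * cos(2 * pi * w)
  od <- tt[-1] * (n - tt[-1]) / 2
  m <- matrix(0, n, n)
  diag(m) <- dg
  m[cbind(1:(n - 1), 2:n)] <- od
  m[cbind(2:n, 1:(n - 1))] <- od
  ev <- eigen(m, symmetric = TRUE)
  h <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    s <- sum(h[, j])
    if (abs(s) > 1e-8) {
      if (s < 0) h[, j] <- -h[, j]
    } else if (sum(h[seq_len(n %/% 2), j]) < 0) {
      h[, j] <- -h[, j]
    }
  }
  .taper_cache[[key]] <- h
  h
}

# coerce trial input (vector, matrix time x trials, or list) to a matrix
as_trial_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    len <- vapply(x, length, integer(1))
    if (length(unique(len)) != 1)
      stop("trials of unequal length", call. = FALSE)
    x <- do.call(cbind, x)
  }
  if (!is.matrix(x)) x <- matrix(as.numeric(x), ncol = 1)
  storage.mode(x) <- "double"
  x
}

# one-sided frequency grid and tapered FFTs: array nf x K x M (complex)
taper_ffts <- function(x, nw, fs) {
  x <- as_trial_matrix(x)
  nt <- nrow(x); m <- ncol(x)
  h <- dpss_tapers(nt, nw)
  k <- ncol(h)
  x <- sweep(x, 2, colMeans(x))
  nf <- nt %/% 2 + 1
  out <- array(0i, c(nf, k, m))
  for (j in seq_len(k)) {
    xf <- stats::mvfft(x * h[, j])
    out[, j, ] <- xf[seq_len(nf), , drop = FALSE]
  }
  list(ffts = out, freq = (seq_len(nf) - 1) * fs / nt, n = nt, k = k, m = m)
}

#' Multitaper power spectral density
#'
#' Trial- and taper-averaged one-sided PSD of equal-length trials sampled at
#' `fs`, with `2 nw - 1` Slepian tapers (spectral half-bandwidth
#' W = nw / T). Satisfies Parseval: the PSD integrates to the signal
#' variance (up to taper bias).
#'
#' @param x Trials: numeric vector, time-by-trial matrix, or list of
#'   equal-length vectors.
#' @param nw Time-half-bandwidth product.
#' @param fs Sampling rate, Hz (1 kHz for 1 ms spike-time histograms).
#' @return List of class `spectral_estimate` with `freq` (Hz), `value`
#'   (power density, x^2/Hz), `n_tapers`, `bandwidth_hz`, `n_trials`.
#' @export
multitaper_psd <- function(x, nw = 5, fs = 1000) {
  tf <- taper_ffts(x, nw, fs)
  p <- apply(abs(tf$ffts)^2, 1, mean) / fs
  # fold to one-sided density
  nf <- length(tf$freq)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (tf$n %% 2 == 0) dbl[nf] <- 1
  structure(list(freq = tf$freq, value = p * dbl, n_tapers = tf$k,
                 bandwidth_hz = nw * fs / tf$n, n_trials = tf$m),
            class = "spectral_estimate")
}

#' Multitaper coherence between two sets of trials
#'
#' C(f) = |Sxy|^2 / (Sxx Syy), with cross- and auto-spectra averaged over
#' tapers and trials; values in \[0, 1\]. Frequencies where either signal has
#' (numerically) zero power are returned as NA rather than propagated.
#'
#' @param x,y Matched trials (same shapes accepted as [multitaper_psd()]).
#' @param nw Time-half-bandwidth product.
#' @param fs Sampling rate, Hz.
#' @return `spectral_estimate` with coherence in `value`.
#' @export
multitaper_coherence <- function(x, y, nw = 5, fs = 1000) {
  tx <- taper_ffts(x, nw, fs); ty <- taper_ffts(y, nw, fs)
  if (tx$n != ty$n || tx$m != ty$m)
    stop("x and y trials must match in length and count", call. = FALSE)
  sxy <- apply(tx$ffts * Conj(ty$ffts), 1, mean)
  sxx <- apply(abs(tx$ffts)^2, 1, mean)
  syy <- apply(abs(ty$ffts)^2, 1, mean)
  denom <- sxx * syy
  c2 <- ifelse(denom > .Machine$double.eps * max(denom),
               Mod(sxy)^2 / denom, NA_real_)
  structure(list(freq = tx$freq, value = pmin(c2, 1), n_tapers = tx$k,
                 bandwidth_hz = nw * fs / tx$n, n_trials = tx$m),
            class = "spectral_estimate")
}

#' Amplitude and phase components of the coherence
#'
#' Decomposes trial-to-trial coherence into a phase-consistency component
#' (coherence of unit-magnitude per-taper/per-trial cross-spectral terms, so
#' amplitude information is removed) and an amplitude-covariation component
#' (Pearson correlation of per-taper/per-trial spectral amplitudes across
#' the two signals, floored at 0). Both lie in \[0, 1\].
#'
#' @inheritParams multitaper_coherence
#' @return List of class `coherence_decomposition` with `freq`, `total`,
#'   `amplitude`, `phase`.
#' @export
coherence_components <- function(x, y, nw = 5, fs = 1000) {
  tx <- taper_ffts(x, nw, fs); ty <- taper_ffts(y, nw, fs)
  if (tx$m < 2) stop("need at least 2 trials", call. = FALSE)
  z <- tx$ffts * Conj(ty$ffts)
  az <- Mod(z)
  unit <- ifelse(az > 0, z / az, 0i)
  phase <- Mod(apply(unit, 1, mean))^2
  ax <- abs(tx$ffts); ay <- abs(ty$ffts)
  nf <- dim(ax)[1]
  amp <- vapply(seq_len(nf), function(i) {
    a <- as.vector(ax[i, , ]); b <- as.vector(ay[i, , ])
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    max(0, stats::cor(a, b))
  }, numeric(1))
  tot <- multitaper_coherence(x, y, nw, fs)
  structure(list(freq = tx$freq, total = tot$value, amplitude = amp,
                 phase = pmin(phase, 1)),
            class = "coherence_decomposition")
}

#' Trial-shuffle bias of the coherence (and its components)
#'
#' Estimates the coherence bias floor by re-pairing the trials of `y` with a
#' random derangement (no trial is ever paired with itself) and averaging
#' the resulting coherence over `n_shuffles` shuffles.
#'
#' @inheritParams multitaper_coherence
#' @param n_shuffles Number of shuffles (>= 1).
#' @param seed Integer seed for the shuffle draws.
#' @param components Also average the amplitude/phase components.
#' @return `spectral_estimate` (bias in `value`); if `components`, extra
#'   fields `amplitude` and `phase`.
#' @export
shuffle_bias <- function(x, y, n_shuffles = 20, seed = 1,
                         components = FALSE, nw = 5, fs = 1000) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1", call. = FALSE)
  x <- as_trial_matrix(x); y <- as_trial_matrix(y)
  m <- ncol(y)
  if (m < 3) stop("need at least 3 trials to shuffle", call. = FALSE)
  set.seed(seed)
  derange <- function() {
    repeat {
      p <- sample.int(m)
      if (all(p != seq_len(m))) return(p)
    }
  }
  acc <- NULL; acc_a <- NULL; acc_p <- NULL; freq <- NULL
  for (s in seq_len(n_shuffles)) {
    ys <- y[, derange(), drop = FALSE]
    if (components) {
      cc <- coherence_components(x, ys, nw, fs)
      acc <- if (is.null(acc)) cc$total else acc + cc$total
      acc_a <- if (is.null(acc_a)) cc$amplitude else acc_a + cc$amplitude
      acc_p <- if (is.null(acc_p)) cc$phase else acc_p + cc$phase
      freq <- cc$freq
    } else {
      cc <- multitaper_coherence(x, ys, nw, fs)
      acc <- if (is.null(acc)) cc$value else acc + cc$value
      freq <- cc$freq
    }
  }
  out <- structure(list(freq = freq, value = acc / n_shuffles,
                        n_tapers = 2 * nw - 1, bandwidth_hz = NA,
                        n_trials = m),
                   class = "spectral_estimate")
  if (components) {
    out$amplitude <- acc_a / n_shuffles
    out$phase <- acc_p / n_shuffles
  }
  out
}

#' Complex Morlet wavelet transform
#'
#' Convolves the signal with complex Morlet wavelets whose Gaussian envelope
#' width scales as sigma_t = 1/f0 (one period of the centre frequency).
#' Coefficients are normalised so that a unit-amplitude sinusoid at f0 gives
#' |coefficient| = 1; phase 0 corresponds to the signal peak. Samples within
#' 2 sigma_t of either edge are flagged invalid.
#'
#' @param x Numeric signal sampled at `fs`.
#' @param freqs Centre frequencies, Hz (all below Nyquist).
#' @param fs Sampling rate, Hz.
#' @return List of class `timefreq`: `time` (ms), `freq`, complex `coef`
#'   (time x freq), logical `valid` (time x freq edge mask).
#' @export
morlet_transform <- function(x, freqs, fs = 1000) {
  stopifnot(is.numeric(x), length(freqs) >= 1)
  if (any(freqs <= 0) || any(freqs >= fs / 2))
    stop("frequencies must lie in (0, fs/2)", call. = FALSE)
  nt <- length(x)
  coef <- matrix(0i, nt, length(freqs))
  valid <- matrix(TRUE, nt, length(freqs))
  for (j in seq_along(freqs)) {
    f0 <- freqs[j]
    s <- fs / f0                       # sigma_t in samples
    half <- ceiling(4 * s)
    tt <- (-half):half
    env <- exp(-tt^2 / (2 * s^2))
    wav <- env * exp(2i * pi * f0 * tt / fs)
    wav <- wav / (sum(env) / 2)
    nl <- nt + length(wav) - 1
    nfft <- stats::nextn(nl, c(2, 3, 5))
    xf <- stats::fft(c(x, rep(0, nfft - nt)))
    wf <- stats::fft(c(wav, rep(0, nfft - length(wav))))
    conv <- stats::fft(xf * wf, inverse = TRUE) / nfft
    coef[, j] <- conv[half + seq_len(nt)]
    edge <- ceiling(2 * s)
    if (edge >= 1) {
      valid[seq_len(min(edge, nt)), j] <- FALSE
      valid[seq.int(max(1, nt - edge + 1), nt), j] <- FALSE
    }
  }
  structure(list(time = seq_len(nt) / fs * 1000, freq = freqs, coef = coef,
                 valid = valid, fs = fs),
            class = "timefreq")
}

#' Power of a `timefreq` object
#' @param tf A `timefreq`.
#' @return time x freq matrix of |coef|^2.
#' @export
wavelet_power <- function(tf) Mod(tf$coef)^2

#' Phase of a `timefreq` object
#' @param tf A `timefreq`.
#' @return time x freq matrix of phases in (-pi, pi].
#' @export
wavelet_phase <- function(tf) Arg(tf$coef)

#' Band-averaged wavelet power trace
#'
#' Mean power over all centre frequencies inside `band`, per time point.
#'
#' @param tf A `timefreq`.
#' @param band Length-2 frequency band, Hz.
#' @return Numeric power trace (NA where any contributing frequency is
#'   edge-flagged).
#' @export
wavelet_band_power <- function(tf, band = c(20, 50)) {
  sel <- tf$freq >= band[1] & tf$freq <= band[2]
  if (!any(sel)) stop("band outside the frequency grid", call. = FALSE)
  p <- Mod(tf$coef[, sel, drop = FALSE])^2
  p[!tf$valid[, sel, drop = FALSE]] <- NA
  rowMeans(p)
}

#' Spectral peak and band power
#'
#' Locates the spectral peak inside a search band and averages power over a
#' symmetric band of `2 * halfwidth` Hz centred on it.
#'
#' @param est A `spectral_estimate`.
#' @param search Peak search band, Hz.
#' @param halfwidth Half-width of the averaging band, Hz.
#' @return List with `peak_freq` (Hz) and `band_power`.
#' @export
band_metrics <- function(est, search = c(20, 80), halfwidth = 10) {
  sel <- est$freq >= search[1] & est$freq <= search[2]
  if (!any(sel)) stop("search band outside the spectrum", call. = FALSE)
  fsub <- est$freq[sel]; vsub <- est$value[sel]
  pk <- fsub[which.max(vsub)]
  bsel <- est$freq >= pk - halfwidth & est$freq <= pk + halfwidth
  list(peak_freq = pk, band_power = mean(est$value[bsel], na.rm = TRUE))
}

#' Gamma power as a function of alpha phase
#'
#' Averages a gamma-band power trace within bins of the simultaneous alpha
#' phase; bins tile \[-180, 180) degrees. NA power samples (wavelet edges)
#' are dropped.
#'
#' @param alpha_phase Alpha phase per time point, radians.
#' @param gamma_power Gamma power trace, same length.
#' @param n_bins Number of phase bins.
#' @return Data frame with `phase_deg` (bin centres) and `power`.
#' @export
alpha_gamma_coupling <- function(alpha_phase, gamma_power, n_bins = 18) {
  stopifnot(length(alpha_phase) == length(gamma_power))
  ph <- ((alpha_phase + pi) %% (2 * pi)) - pi
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  idx <- pmin(n_bins, pmax(1L, findInterval(ph, edges)))
  ok <- !is.na(gamma_power)
  pw <- vapply(seq_len(n_bins), function(b) {
    v <- gamma_power[ok & idx == b]
    if (!length(v)) NA_real_ else mean(v)
  }, numeric(1))
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  data.frame(phase_deg = centers * 180 / pi, power = pw)
}
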