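#' Gamma phase of a spike-time histogram
#'
#' Extracts the instantaneous gamma phase of an STH via a complex Morlet
#' wavelet at the STH's own gamma peak frequency (or a given frequency).
#' Phases use the sine-referenced convention: the rhythm's peak sits at
#' +90 degrees (as for sin(wt) at its maximum), so a population whose
#' spikes ride the crest of its own rhythm has a spike-phase histogram
#' peaking near 90 degrees. Edge-flagged samples are NA.
#'
#' @param sth Spike-time histogram (1 ms bins).
#' @param freq Centre frequency, Hz; NULL picks the STH's spectral peak
#'   inside `search`.
#' @param search Peak search band, Hz.
#' @return List with `phase` (radians, NA at edges), `freq`, `times` (ms).
#' @export
sth_gamma_phase <- function(sth, freq = NULL, search = c(25, 60)) {
  if (is.null(freq))
    freq <- band_metrics(multitaper_psd(sth), search)$peak_freq
  tf <- morlet_transform(sth, freq)
  ph <- Arg(tf$coef[, 1]) + pi / 2
  ph <- ((ph + pi) %% (2 * pi)) - pi
  ph[!tf$valid[, 1]] <- NA
  list(phase = ph, freq = freq, times = tf$time)
}

# unwrap a wrapped phase series (inverse of %% (2*pi))
unwrap_phase <- function(theta) {
  d <- diff(theta)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(theta[1], d))
}

# instantaneous phase at arbitrary spike times by linear interpolation of
# the unwrapped phase trace; NA outside the trace or in NA-masked samples
phase_at_times <- function(spike_times, phase, phase_times) {
  ok <- !is.na(phase)
  if (sum(ok) < 2) return(rep(NA_real_, length(spike_times)))
  up <- unwrap_phase(phase[ok])
  out <- stats::approx(phase_times[ok], up, xout = spike_times,
                       rule = 1)$y
  ((out + pi) %% (2 * pi)) - pi
}

#' Spike-phase histogram
#'
#' Assigns each spike the instantaneous phase of an oscillation (e.g. the
#' gamma phase of an STH extracted by [morlet_transform()]) at its time and
#' returns the normalised per-bin spike probability, together with the
#' circular resultant, preferred phase and a von Mises concentration
#' estimate.
#'
#' @param spike_times Spike times, ms.
#' @param phase Phase trace, radians (may contain NA for edge-masked
#'   samples).
#' @param phase_times Times of the phase samples, ms.
#' @param n_bins Number of phase bins tiling (-180, 180\].
#' @return List of class `phase_histogram`: `bins` data frame
#'   (`phase_deg`, `prob`, `count`), `n_spikes`, `n_dropped`,
#'   `preferred_deg`, `resultant`, `kappa`.
#' @export
spike_phase_histogram <- function(spike_times, phase, phase_times,
                                  n_bins = 16) {
  ph <- phase_at_times(spike_times, phase, phase_times)
  dropped <- sum(is.na(ph))
  ph <- ph[!is.na(ph)]
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  idx <- pmin(n_bins, pmax(1L, findInterval(ph, edges)))
  cnt <- tabulate(idx, nbins = n_bins)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  r <- if (length(ph)) Mod(mean(exp(1i * ph))) else NA_real_
  pref <- if (length(ph)) Arg(mean(exp(1i * ph))) else NA_real_
  structure(list(
    bins = data.frame(phase_deg = centers * 180 / pi,
                      prob = if (sum(cnt)) cnt / sum(cnt) else cnt,
                      count = cnt),
    n_spikes = length(ph), n_dropped = dropped,
    preferred_deg = pref * 180 / pi, resultant = r,
    kappa = vm_kappa(r)),
    class = "phase_histogram")
}

#' Von Mises concentration from a mean resultant length
#'
#' Standard approximate inversion of A(kappa) = I1(kappa)/I0(kappa) = R.
#'
#' @param r Mean resultant length in \[0, 1\].
#' @return Estimated concentration kappa.
#' @export
vm_kappa <- function(r) {
  if (is.na(r)) return(NA_real_)
  if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
}

#' Gamma-phase-resolved spike transmission probability
#'
#' For every spike of an area-1 RS neuron, the binary outcome is whether any
#' of its feedforward targets in area 2 fires within (t+1, t+4\] ms (the
#' window matching the synaptic activation delay; there are no axonal
#' delays). Sender spikes are binned by a gamma phase trace, bins are
#' equalised by randomly removing spikes until each bin holds the same
#' number (so a higher probability is not a by-product of more spikes in a
#' bin), and the per-bin transmission probability is returned.
#'
#' @param result A `sim_result` from a connected two-area run.
#' @param phase Gamma phase trace, radians (NA allowed at edges).
#' @param phase_times Times of the phase samples, ms.
#' @param direction Integer pair, sender then receiver area (default 1, 2).
#' @param window Transmission window (open, closed\] offsets in ms.
#' @param n_bins Number of phase bins.
#' @param seed Seed for the equalising subsample.
#' @param pairs `"connected"` (each sender against its own targets) or
#'   `"all"` (against every area-2 neuron).
#' @return List of class `transmission_probability`: `bins` data frame
#'   (`phase_deg`, `prob`, `n_spikes`), `equalised_count`.
#' @export
transmission_probability <- function(result, phase, phase_times,
                                     direction = c(1, 2), window = c(1, 4),
                                     n_bins = 16, seed = 1,
                                     pairs = c("connected", "all")) {
  pairs <- match.arg(pairs)
  sp <- result$spikes
  snd <- sp[sp$area == direction[1] & sp$type == "RS", ]
  rcv <- sp[sp$area == direction[2], ]
  key <- paste0(direction[1], "->", direction[2])
  if (pairs == "connected" && is.null(result$ff[[key]]))
    stop("no feedforward connectivity stored for this direction",
         call. = FALSE)
  # pooled sorted target spike times per sender neuron
  rcv_split <- split(rcv$time, rcv$neuron)
  senders <- sort(unique(snd$neuron))
  pool <- lapply(senders, function(i) {
    tg <- if (pairs == "connected")
      result$ff[[key]][[as.character(i)]]
    else unique(rcv$neuron)
    sort(unlist(rcv_split[as.character(tg)], use.names = FALSE))
  })
  names(pool) <- senders
  ph <- phase_at_times(snd$time, phase, phase_times)
  keep <- !is.na(ph)
  snd <- snd[keep, ]; ph <- ph[keep]
  if (!nrow(snd)) stop("no sender spikes with defined phase", call. = FALSE)
  outcome <- logical(nrow(snd))
  for (i in seq_len(nrow(snd))) {
    v <- pool[[as.character(snd$neuron[i])]]
    if (!length(v)) next
    t0 <- snd$time[i]
    outcome[i] <- findInterval(t0 + window[2], v) >
      findInterval(t0 + window[1], v)
  }
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  idx <- pmin(n_bins, pmax(1L, findInterval(ph, edges)))
  cnt <- tabulate(idx, nbins = n_bins)
  if (all(cnt == 0)) stop("all phase bins empty", call. = FALSE)
  target <- min(cnt[cnt > 0])
  set.seed(seed)
  prob <- rep(NA_real_, n_bins)
  for (b in seq_len(n_bins)) {
    ii <- which(idx == b)
    if (!length(ii)) next
    if (length(ii) > target) ii <- sample(ii, target)
    prob[b] <- mean(outcome[ii])
  }
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  structure(list(bins = data.frame(phase_deg = centers * 180 / pi,
                                   prob = prob, n_spikes = cnt),
                 equalised_count = target),
            class = "transmission_probability")
}
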