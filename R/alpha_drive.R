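#' Configuration of the alpha (10 Hz) modulatory drive
#'
#' The pulvinar is represented only by its output: a noisy ~10 Hz phase
#' trajectory per area, converted to a modulation current delivered to the
#' inhibitory cells. Two areas receive phases coupled by a Kuramoto term so
#' that their difference stays near a target offset.
#'
#' @param amplitude Modulation amplitude A, pA. Default 23.
#' @param freq Mean alpha frequency, Hz. Default 10.
#' @param coupling Kuramoto coupling J, 1/ms. Default 0.2.
#' @param offset_deg Target relative alpha phase, degrees, normalised to
#'   [-180, 180); negative values mean area 1 leads in time (see
#'   [generate_coupled_phases()] for the sign convention).
#' @param phase_noise_sd Phase-noise standard deviation, rad/sqrt(ms).
#' @param waveform `"sin2"` (non-negative, sin^2(phi/2), effective frequency
#'   `freq`) or `"sin"` (zero-mean control).
#' @return List of class `alpha_config`.
#' @export
alpha_config <- function(amplitude = 23, freq = 10, coupling = 0.2,
                         offset_deg = 0, phase_noise_sd = 0.1,
                         waveform = c("sin2", "sin")) {
  waveform <- match.arg(waveform)
  stopifnot(amplitude >= 0, freq > 0, coupling >= 0, phase_noise_sd >= 0)
  offset_deg <- ((offset_deg + 180) %% 360) - 180
  structure(list(amplitude = amplitude, freq = freq, coupling = coupling,
                 offset_deg = offset_deg, phase_noise_sd = phase_noise_sd,
                 waveform = waveform),
            class = "alpha_config")
}

#' Generate two coupled noisy alpha-phase trajectories
#'
#' Euler-integrates the coupled phase equations
#' \deqn{\dot\phi_1 = \omega_0 + \eta_1 + J \sin((\phi_2 - \Delta\phi) - \phi_1)}
#' \deqn{\dot\phi_2 = \omega_0 + \eta_2 + J \sin((\phi_1 + \Delta\phi) - \phi_2)}
#' in rad/ms, with white phase noise of sd `phase_noise_sd` per sqrt(ms).
#' The coupling acts on the deviation from the target offset, so the
#' realised circular mean of the offset tracks `offset_deg` for any target.
#'
#' Sign convention: the relative alpha phase is realised as
#' phi2 - phi1 = Delta-phi, so a negative `offset_deg` means area 1 runs
#' ahead in time (its modulation peaks earlier); at -90 degrees area 1
#' leads area 2 by a quarter of an alpha cycle (25 ms at 10 Hz).
#'
#' @param config An `alpha_config`.
#' @param duration Trace length, ms.
#' @param dt Integration step, ms.
#' @param seed Optional integer seed.
#' @param init_phase Initial phase of area 1 in radians, or `"random"`.
#' @param init_offset Initial realised offset phi2 - phi1 in radians
#'   (default: the target offset, so the trace starts converged).
#' @return List of class `phase_trace` with `phi1`, `phi2` (unwrapped, rad),
#'   `time` (ms) and `dt`.
#' @export
generate_coupled_phases <- function(config, duration, dt = 0.5, seed = NULL,
                                    init_phase = "random",
                                    init_offset = NULL) {
  stopifnot(duration > 0, dt > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- ceiling(duration / dt)
  w0 <- 2 * pi * config$freq / 1000        # rad per ms
  J <- config$coupling
  dphi <- config$offset_deg * pi / 180
  sd_step <- config$phase_noise_sd * sqrt(dt)
  p1 <- numeric(n); p2 <- numeric(n)
  phi1 <- if (identical(init_phase, "random")) runif(1, 0, 2 * pi)
          else as.numeric(init_phase)
  phi2 <- phi1 + if (is.null(init_offset)) dphi else init_offset
  e1 <- rnorm(n, 0, sd_step); e2 <- rnorm(n, 0, sd_step)
  for (t in seq_len(n)) {
    d1 <- w0 + J * sin((phi2 - dphi) - phi1)
    d2 <- w0 + J * sin((phi1 + dphi) - phi2)
    phi1 <- phi1 + dt * d1 + e1[t]
    phi2 <- phi2 + dt * d2 + e2[t]
    p1[t] <- phi1; p2[t] <- phi2
  }
  structure(list(phi1 = p1, phi2 = p2, time = seq_len(n) * dt, dt = dt,
                 config = config),
            class = "phase_trace")
}

#' Convert a phase trajectory to a modulation current
#'
#' `sin2`: I(t) = A sin^2(phi/2), range \[0, A\], fundamental at the phase's
#' own frequency (the half-angle halves the frequency of sin^2, keeping an
#' effective 10 Hz rhythm with non-zero mean). `sin`: I(t) = A sin(phi),
#' zero-mean control.
#'
#' @param phases Numeric vector of phases, rad (unwrapped or wrapped).
#' @param amplitude A, pA.
#' @param waveform `"sin2"` or `"sin"`.
#' @return Numeric current vector, same length as `phases`.
#' @export
modulation_current <- function(phases, amplitude = 23,
                               waveform = c("sin2", "sin")) {
  waveform <- match.arg(waveform)
  if (waveform == "sin2") amplitude * sin(phases / 2)^2
  else amplitude * sin(phases)
}

#' Conversion between physiological picoamperes and model current units
#'
#' The Izhikevich equations carry current in dimensionless model units; the
#' configuration interfaces quote physiological pA. The conversion is fixed
#' by matching the reported operating points of the alpha drive (a 23 pA
#' modulation produces strong but not silencing gamma-power modulation,
#' roughly twice that amplitude nearly silences the troughs): 23 pA
#' corresponds to 10 model units.
#'
#' @return Model current units per pA.
#' @export
current_scale <- function() 10 / 23

#' Circular mean of an angle vector
#'
#' @param theta Angles in radians.
#' @return Circular mean in (-pi, pi].
#' @export
circular_mean <- function(theta) {
  Arg(mean(exp(1i * theta)))
}
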