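#' Izhikevich parameters for a cortical cell type
#'
#' Returns the dimensionless Izhikevich parameters (a, b, c, d; c in mV) for
#' one of the three cell types used in the network: regular spiking (RS)
#' excitatory pyramidal cells, fast spiking (FS) interneurons and low
#' threshold spiking (LTS) interneurons.
#'
#' @param cell_type One of `"RS"`, `"FS"`, `"LTS"`.
#' @return A list of class `neuron_params` with fields `cell_type`, `a`, `b`,
#'   `c`, `d` and `excitatory` (logical).
#' @export
#' @examples
#' neuron_params("RS")
neuron_params <- function(cell_type) {
  tab <- list(
    RS  = list(a = 0.02, b = 0.20, c = -65, d = 8, excitatory = TRUE),
    FS  = list(a = 0.10, b = 0.20, c = -65, d = 2, excitatory = FALSE),
    LTS = list(a = 0.02, b = 0.25, c = -65, d = 2, excitatory = FALSE)
  )
  if (length(cell_type) != 1L || !cell_type %in% names(tab))
    stop("unknown cell_type: must be one of 'RS', 'FS', 'LTS'",
         call. = FALSE)
  structure(c(list(cell_type = cell_type), tab[[cell_type]]),
            class = "neuron_params")
}

#' Analytic resting state of an Izhikevich neuron
#'
#' Solves 0.04 v^2 + (5 - b) v + 140 + I = 0 for the stable (more negative)
#' fixed point and returns `v` together with `u = b v`, at which both
#' derivatives vanish.
#'
#' @param params A `neuron_params` object.
#' @param I Constant input current (default 0).
#' @return List with `v` (mV) and `u`.
#' @export
resting_state <- function(params, I = 0) {
  disc <- (5 - params$b)^2 - 4 * 0.04 * (140 + I)
  if (disc < 0)
    stop("no fixed point at this current (above rheobase)", call. = FALSE)
  v <- (-(5 - params$b) - sqrt(disc)) / (2 * 0.04)
  list(v = v, u = params$b * v)
}

#' Rheobase current of an Izhikevich neuron
#'
#' Current at which the two quadratic nullcline roots merge (discriminant of
#' 0.04 v^2 + (5 - b) v + 140 + I = 0 equals zero); above it no resting state
#' exists and the neuron fires tonically.
#'
#' @param params A `neuron_params` object.
#' @return Rheobase current (model units).
#' @export
rheobase <- function(params) {
  (5 - params$b)^2 / (4 * 0.04) - 140
}

#' Advance an Izhikevich neuron by one forward-Euler step
#'
#' Integrates dv/dt = 0.04 v^2 + 5 v + 140 - u + I and du/dt = a (b v - u)
#' for one step of length `dt`. If v reaches 30 mV the spike flag is set and
#' the reset v <- c, u <- u + d is applied; the returned `v_peak` is the
#' pre-reset value (the spike time is the time of the peak).
#'
#' Vectorised over neurons: `state$v`, `state$u`, `I` and the parameter
#' fields may all be vectors of equal length.
#'
#' @param state List with numeric `v` (mV) and `u`.
#' @param params A `neuron_params` object, or a list of vectors `a,b,c,d`.
#' @param I Input current(s).
#' @param dt Step size, ms.
#' @return List with updated `state`, logical `spiked`, and `v_peak`.
#' @export
izhikevich_step <- function(state, params, I, dt) {
  stopifnot(dt > 0)
  if (any(!is.finite(I))) stop("non-finite input current", call. = FALSE)
  v <- state$v; u <- state$u
  v_new <- v + dt * (0.04 * v^2 + 5 * v + 140 - u + I)
  u_new <- u + dt * params$a * (params$b * v - u)
  if (any(!is.finite(v_new)) || any(!is.finite(u_new)))
    stop("non-finite state after step: simulation aborted", call. = FALSE)
  spiked <- v_new >= 30
  v_peak <- v_new
  if (any(spiked)) {
    cvec <- rep_len(params$c, length(v_new))
    dvec <- rep_len(params$d, length(u_new))
    v_new[spiked] <- cvec[spiked]
    u_new[spiked] <- u_new[spiked] + dvec[spiked]
  }
  list(state = list(v = v_new, u = u_new), spiked = spiked, v_peak = v_peak)
}

#' Firing rate versus input current (FI) curve
#'
#' Integrates a single neuron at each constant current and returns the firing
#' rate in Hz. Used to relate the model's native current units to pA by
#' comparison with physiological FI curves.
#'
#' @param params A `neuron_params` object.
#' @param currents Numeric vector of constant input currents.
#' @param duration Integration time per current, ms (>= 1000).
#' @param dt Euler step, ms.
#' @return Data frame with columns `current` and `rate_hz`.
#' @export
fi_curve <- function(params, currents, duration = 2000, dt = 0.5) {
  if (length(currents) == 0) stop("empty current grid", call. = FALSE)
  stopifnot(duration >= 1000)
  rates <- vapply(currents, function(I) {
    st <- resting_state(params, I = min(I, rheobase(params) - 1e-6))
    state <- list(v = st$v, u = st$u)
    nstep <- ceiling(duration / dt)
    nsp <- 0L
    for (i in seq_len(nstep)) {
      out <- izhikevich_step(state, params, I, dt)
      state <- out$state
      nsp <- nsp + as.integer(out$spiked)
    }
    1000 * nsp / duration
  }, numeric(1))
  data.frame(current = currents, rate_hz = rates)
}

#' Connection-strength bounds between cell types
#'
#' Signed per-spike PSC bounds; entry `[post, pre]` is the endpoint of the
#' uniform distribution (starting at 0) from which the weight of a
#' pre -> post connection is drawn. Excitatory rows of the presynaptic side
#' are positive, inhibitory negative; LTS -> LTS connections are absent.
#'
#' @return 3x3 numeric matrix with dimnames `post` x `pre`.
#' @export
connectivity_bounds <- function() {
  m <- matrix(c(
    #  pre: RS      FS      LTS
    0.0375, -0.25, -0.30,   # post RS
    0.1250, -0.15, -0.10,   # post FS
    0.1250, -0.10,  0.00),  # post LTS
    nrow = 3, byrow = TRUE,
    dimnames = list(post = c("RS", "FS", "LTS"), pre = c("RS", "FS", "LTS")))
  m
}

#' Build an all-to-all within-population connectivity matrix
#'
#' Each ordered pair of distinct neurons is connected; the weight is drawn
#' uniformly between 0 and the signed bound for the (pre, post) type pair.
#' The matrix is stored target-major: `W[j, i]` is the PSC amplitude evoked
#' in neuron j by a spike of neuron i.
#'
#' @param sizes Named integer vector of per-type counts, e.g.
#'   `c(RS = 400, FS = 75, LTS = 25)`.
#' @param bounds Bounds matrix as from [connectivity_bounds()].
#' @param seed Optional integer seed (uses the current RNG stream if NULL).
#' @return List of class `connectivity` with `weights` (N x N, `[target,
#'   source]`), `types` (character per neuron) and `bounds`.
#' @export
build_connectivity <- function(sizes = c(RS = 400, FS = 75, LTS = 25),
                               bounds = connectivity_bounds(), seed = NULL) {
  stopifnot(all(sizes > 0), all(names(sizes) %in% rownames(bounds)))
  if (!is.null(seed)) set.seed(seed)
  types <- rep(names(sizes), sizes)
  n <- length(types)
  w <- matrix(runif(n * n), n, n)
  # scale column i (source) / row j (target) by the signed bound
  b <- bounds[types, types, drop = FALSE]  # [target, source]
  w <- w * b
  diag(w) <- 0
  structure(list(weights = w, types = types, bounds = bounds),
            class = "connectivity")
}

#' Decay synaptic current accumulators and add incoming spikes
#'
#' One discrete step of the PSC dynamics: both accumulators decay by
#' exp(-dt/tau) with tau_e = 2.5 ms (currents evoked by excitatory cells) and
#' tau_i = 6 ms (inhibitory), then each spiking source adds its weight row to
#' its targets instantaneously.
#'
#' @param syn List with numeric vectors `psc_e`, `psc_i` (one entry per
#'   target neuron).
#' @param spikes Logical vector, one flag per source neuron.
#' @param conn A `connectivity` object (weights `[target, source]`).
#' @param dt Step, ms.
#' @param tau_e,tau_i Decay constants, ms.
#' @return Updated `syn` list.
#' @export
update_synaptic_currents <- function(syn, spikes, conn, dt,
                                     tau_e = 2.5, tau_i = 6) {
  stopifnot(dt > 0)
  psc_e <- syn$psc_e * exp(-dt / tau_e)
  psc_i <- syn$psc_i * exp(-dt / tau_i)
  if (any(spikes)) {
    exc <- conn$types == "RS"
    se <- which(spikes & exc)
    si <- which(spikes & !exc)
    if (length(se))
      psc_e <- psc_e + rowSums(conn$weights[, se, drop = FALSE])
    if (length(si))
      psc_i <- psc_i + rowSums(conn$weights[, si, drop = FALSE])
  }
  list(psc_e = psc_e, psc_i = psc_i)
}
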