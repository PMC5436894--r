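#' Specification of one cortical area
#'
#' An area is a local, all-to-all connected population of 400 RS excitatory,
#' 75 FS and 25 LTS inhibitory Izhikevich neurons. Each neuron receives
#' independent Gaussian noise current per integration substep, with per-type
#' mean/sd, and optionally the alpha modulation on its inhibitory (default)
#' or excitatory cells.
#'
#' @param n_rs,n_fs,n_lts Neuron counts.
#' @param noise 3x2 matrix (rows RS/FS/LTS, cols mu/sd) of noise parameters.
#' @param alpha_target Which cells receive the alpha current:
#'   `"inhibitory"` (FS and LTS), `"fs"` (FS only), `"excitatory"` (RS) or
#'   `"none"`.
#' @param n_subpops Number of equal labelled subpopulations the RS cells are
#'   split into (for selective stimulation/wiring experiments).
#' @return List of class `area_spec`.
#' @export
area_spec <- function(n_rs = 400, n_fs = 75, n_lts = 25,
                      noise = default_noise(),
                      alpha_target = c("inhibitory", "fs", "excitatory", "none"),
                      n_subpops = 1) {
  alpha_target <- match.arg(alpha_target)
  stopifnot(n_rs > 0, n_fs > 0, n_lts > 0, n_subpops >= 1,
            n_rs %% n_subpops == 0)
  structure(list(n_rs = n_rs, n_fs = n_fs, n_lts = n_lts, noise = noise,
                 alpha_target = alpha_target, n_subpops = n_subpops),
            class = "area_spec")
}

#' Default per-type noise parameters
#'
#' Mean and standard deviation of the Gaussian noise current drawn
#' independently per neuron and integration substep.
#'
#' @return 3x2 matrix, rows RS/FS/LTS, columns mu/sd.
#' @export
default_noise <- function() {
  matrix(c(4, 6,
           5, 4,
           4, 4), nrow = 3, byrow = TRUE,
         dimnames = list(c("RS", "FS", "LTS"), c("mu", "sd")))
}

#' Specification of a one- or two-area network
#'
#' Inter-areal projections originate from RS cells only and contact RS and FS
#' cells of the other area with sparse random connectivity. The projection
#' parameters are not constrained by physiology here and are the main free
#' choice of the model; they are exposed so users can probe their effect.
#' With `subpop_wiring = TRUE`, RS -> RS feedforward connections are
#' restricted to matching subpopulation labels (no overlap between channels).
#'
#' @param areas List of `area_spec` (length 1 or 2).
#' @param directionality `"none"`, `"forward"` (area 1 -> area 2) or
#'   `"bidirectional"`.
#' @param ff_prob Connection probability of an inter-areal pair.
#' @param ff_scale Multiplier on the within-area RS->RS / RS->FS uniform
#'   weight bounds used for the inter-areal draw; either a single number or
#'   a named vector with entries `RS` and `FS` (the projection onto the
#'   target interneurons carries the gamma entrainment, the one onto the
#'   target pyramidal cells the stimulus-rate transfer).
#' @param ff_targets Cell types contacted in the target area.
#' @param subpop_wiring Restrict RS->RS projections to matching subpops.
#' @return List of class `network_spec`.
#' @export
network_spec <- function(areas = list(area_spec(), area_spec()),
                         directionality = c("forward", "none",
                                            "bidirectional"),
                         ff_prob = 0.25, ff_scale = c(RS = 2.5, FS = 1.5),
                         ff_targets = c("RS", "FS"),
                         subpop_wiring = FALSE) {
  directionality <- match.arg(directionality)
  stopifnot(length(areas) %in% 1:2, ff_prob >= 0, ff_prob <= 1,
            all(ff_scale >= 0), all(ff_targets %in% c("RS", "FS")))
  if (length(ff_scale) == 1) ff_scale <- c(RS = unname(ff_scale),
                                           FS = unname(ff_scale))
  if (length(areas) == 1) directionality <- "none"
  structure(list(areas = areas, directionality = directionality,
                 ff_prob = ff_prob, ff_scale = ff_scale,
                 ff_targets = ff_targets, subpop_wiring = subpop_wiring),
            class = "network_spec")
}

#' Stimulus specification
#'
#' A step increase in excitatory input current to (a subpopulation of) the
#' RS cells of one area.
#'
#' @param area Target area index.
#' @param onset Onset time, ms.
#' @param duration Stimulus duration, ms.
#' @param amplitude Current step, pA.
#' @param subpop RS subpopulation label to target, or NULL for all RS cells.
#' @return List of class `stimulus_spec`.
#' @export
stimulus_spec <- function(area = 1, onset = 500, duration = 100,
                          amplitude = 24, subpop = NULL) {
  stopifnot(onset >= 0, duration > 0)
  structure(list(area = area, onset = onset, duration = duration,
                 amplitude = amplitude, subpop = subpop),
            class = "stimulus_spec")
}

#' Assemble the global weight matrix and neuron tables for a network
#'
#' Draws all within-area (all-to-all, uniform per type pair) and inter-areal
#' (sparse random) weights. Reproducible from the RNG state; call
#' `set.seed()` first or pass `seed`.
#'
#' @param spec A `network_spec`.
#' @param seed Optional integer seed.
#' @return List of class `network` with the global target-major weight
#'   matrix `wt`, per-neuron tables (`type`, `area`, `subpop`, Izhikevich
#'   parameters, noise), and `ff` adjacency (list per direction: integer
#'   target vectors per source neuron).
#' @export
build_network <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nar <- length(spec$areas)
  bounds <- connectivity_bounds()
  per_area <- lapply(spec$areas, function(a) {
    conn <- build_connectivity(c(RS = a$n_rs, FS = a$n_fs, LTS = a$n_lts),
                               bounds)
    sub <- c(rep(seq_len(a$n_subpops), each = a$n_rs / a$n_subpops),
             rep(0L, a$n_fs + a$n_lts))
    list(conn = conn, subpop = sub)
  })
  sizes <- vapply(per_area, function(p) length(p$conn$types), integer(1))
  offs <- cumsum(c(0L, sizes))[seq_len(nar)]
  n <- sum(sizes)
  type <- unlist(lapply(per_area, function(p) p$conn$types))
  area <- rep(seq_len(nar), sizes)
  subpop <- unlist(lapply(per_area, function(p) p$subpop))
  wt <- matrix(0, n, n)
  for (k in seq_len(nar)) {
    idx <- offs[k] + seq_len(sizes[k])
    wt[idx, idx] <- per_area[[k]]$conn$weights
  }
  dirs <- switch(spec$directionality,
                 none = list(),
                 forward = list(c(1L, 2L)),
                 bidirectional = list(c(1L, 2L), c(2L, 1L)))
  ff <- list()
  for (d in dirs) {
    src_area <- d[1]; tgt_area <- d[2]
    src <- which(area == src_area & type == "RS")
    tgt <- which(area == tgt_area & type %in% spec$ff_targets)
    mask <- matrix(runif(length(tgt) * length(src)) < spec$ff_prob,
                   length(tgt), length(src))
    if (spec$subpop_wiring) {
      # RS->RS only between matching subpopulation labels
      rs_tgt <- type[tgt] == "RS"
      same <- outer(subpop[tgt], subpop[src], "==")
      mask[rs_tgt, ] <- mask[rs_tgt, , drop = FALSE] &
        same[rs_tgt, , drop = FALSE]
    }
    b <- bounds[type[tgt], "RS"] * spec$ff_scale[type[tgt]]
    w <- matrix(runif(length(tgt) * length(src)), length(tgt), length(src))
    w <- w * b * mask
    wt[tgt, src] <- w
    ff[[paste0(src_area, "->", tgt_area)]] <-
      lapply(seq_along(src), function(i) tgt[mask[, i]])
    names(ff[[paste0(src_area, "->", tgt_area)]]) <- src
  }
  pars <- lapply(c("a", "b", "c", "d"), function(f)
    vapply(type, function(tp) neuron_params(tp)[[f]], numeric(1),
           USE.NAMES = FALSE))
  names(pars) <- c("a", "b", "c", "d")
  noise_mu <- numeric(n); noise_sd <- numeric(n)
  for (k in seq_len(nar)) {
    idx <- offs[k] + seq_len(sizes[k])
    nz <- spec$areas[[k]]$noise
    noise_mu[idx] <- nz[type[idx], "mu"]
    noise_sd[idx] <- nz[type[idx], "sd"]
  }
  structure(list(spec = spec, wt = wt, n = n, type = type, area = area,
                 subpop = subpop, params = pars, noise_mu = noise_mu,
                 noise_sd = noise_sd, is_exc = type == "RS", ff = ff),
            class = "network")
}

#' Run one network simulation
#'
#' Integrates the full network with 0.5 ms forward-Euler substeps (two per
#' 1 ms simulation step). Per substep each neuron receives its within- and
#' inter-areal PSCs, fresh Gaussian noise, the alpha current (on its area's
#' target cells) and the stimulus current when active. Deterministic given
#' `seed` (network wiring included when `network` is NULL).
#'
#' @param spec A `network_spec`.
#' @param alpha An `alpha_config`, or NULL for no modulation.
#' @param stimulus A `stimulus_spec`, or NULL.
#' @param duration Simulated time, ms (>= 100).
#' @param seed Integer seed for noise, initial jitter and alpha phases.
#' @param network Optional prebuilt `network` (reused across trials so that
#'   trials share wiring but not noise).
#' @param dt Substep, ms.
#' @param stim_onset Overrides `stimulus$onset` (e.g. onset chosen from the
#'   realised alpha phase), ms.
#' @param noise_hold Number of consecutive substeps over which one noise
#'   draw is held; 2 redraws the noise once per 1 ms simulation
#'   step, 1 (default) redraws it every substep.
#' @return List of class `sim_result`: `spikes` data frame (`time`,
#'   `neuron`, `area`, `type`, `subpop`), `duration`, `dt`, `alpha`
#'   (phases/currents at substep resolution), `network` echo, `seed`.
#' @export
run_simulation <- function(spec, alpha = NULL, stimulus = NULL,
                           duration = 2000, seed = 1, network = NULL,
                           dt = 0.5, stim_onset = NULL, noise_hold = 1) {
  stopifnot(duration >= 100)
  if (is.null(network)) {
    set.seed(seed)
    network <- build_network(spec)
  }
  set.seed(seed + 1L)
  n <- network$n
  nsub <- ceiling(duration / dt)
  nar <- length(spec$areas)

  # external current channels: one alpha channel per area, one stimulus
  ext <- matrix(0, nsub, nar + 1L)
  gain <- matrix(0, n, nar + 1L)
  phases <- NULL
  if (!is.null(alpha) && alpha$amplitude > 0) {
    phases <- generate_coupled_phases(alpha, duration, dt)
    phi <- list(phases$phi1, phases$phi2)
    for (k in seq_len(nar)) {
      ext[, k] <- modulation_current(phi[[k]],
                                     alpha$amplitude * current_scale(),
                                     alpha$waveform)
      tgt <- switch(spec$areas[[k]]$alpha_target,
                    inhibitory = network$type %in% c("FS", "LTS"),
                    fs = network$type == "FS",
                    excitatory = network$type == "RS",
                    none = rep(FALSE, n))
      gain[network$area == k & tgt, k] <- 1
    }
  }
  if (!is.null(stimulus)) {
    onset <- if (is.null(stim_onset)) stimulus$onset else stim_onset
    if (onset + stimulus$duration > duration)
      stop("stimulus extends past the end of the simulation", call. = FALSE)
    i0 <- floor(onset / dt) + 1L
    i1 <- min(nsub, ceiling((onset + stimulus$duration) / dt))
    ext[i0:i1, nar + 1L] <- stimulus$amplitude * current_scale()
    sel <- network$area == stimulus$area & network$type == "RS"
    if (!is.null(stimulus$subpop))
      sel <- sel & network$subpop == stimulus$subpop
    gain[sel, nar + 1L] <- 1
    stimulus <- c(stimulus, list(onset_used = onset))
  }

  # start every neuron at its type's analytic resting state; the
  # independent per-neuron noise currents break symmetry from the first
  # substep
  v0 <- numeric(n); u0 <- numeric(n)
  for (tp in c("RS", "FS", "LTS")) {
    idx <- network$type == tp
    rs <- resting_state(neuron_params(tp))
    v0[idx] <- rs$v
    u0[idx] <- rs$u
  }

  out <- sim_core_cpp(network$wt, network$is_exc,
                      network$params$a, network$params$b,
                      network$params$c, network$params$d,
                      network$noise_mu, network$noise_sd,
                      ext, gain, v0, u0, dt, 2.5, 6, as.integer(noise_hold))
  id <- out$neuron
  spikes <- data.frame(time = out$time, neuron = id,
                       area = network$area[id],
                       type = network$type[id],
                       subpop = network$subpop[id])
  structure(list(spikes = spikes, duration = duration, dt = dt,
                 alpha = list(config = alpha, phases = phases,
                              current = if (is.null(phases)) NULL
                                        else ext[, seq_len(nar), drop = FALSE]),
                 stimulus = stimulus,
                 counts = table(area = network$area, type = network$type),
                 ff = network$ff, seed = seed),
            class = "sim_result")
}

#' Run repeated trials over a shared network
#'
#' Builds the wiring once from `seed`, then runs `n_trials` simulations with
#' independent noise/alpha realisations (per-trial seeds drawn from the
#' seeded stream, kept below 2^31).
#'
#' @inheritParams run_simulation
#' @param n_trials Number of trials.
#' @return List of `sim_result`.
#' @export
run_trials <- function(spec, alpha = NULL, stimulus = NULL, duration = 2000,
                       n_trials = 10, seed = 1, network = NULL) {
  set.seed(seed)
  if (is.null(network)) network <- build_network(spec)
  trial_seeds <- sample.int(2^30, n_trials)
  lapply(trial_seeds, function(s)
    run_simulation(spec, alpha = alpha, stimulus = stimulus,
                   duration = duration, seed = s, network = network))
}

#' Spike-time histogram of a population
#'
#' Counts spikes of the selected (area, types, subpop) in bins of `bin` ms;
#' bin t covers the interval (t-1, t] for the default 1 ms bin. The bin sums
#' equal the total spike count of the selection.
#'
#' @param result A `sim_result`.
#' @param area Area index.
#' @param types Character vector of cell types to pool.
#' @param bin Bin width, ms.
#' @param subpop Optional subpopulation label.
#' @return Numeric vector of counts, length `duration / bin`.
#' @export
compute_sth <- function(result, area = 1, types = "RS", bin = 1,
                        subpop = NULL) {
  stopifnot(bin > 0)
  nb <- ceiling(result$duration / bin)
  sp <- result$spikes
  sel <- sp$area == area & sp$type %in% types
  if (!is.null(subpop)) sel <- sel & sp$subpop == subpop
  tt <- sp$time[sel]
  if (!length(tt)) return(numeric(nb))
  idx <- pmin(nb, pmax(1L, ceiling(tt / bin)))
  tabulate(idx, nbins = nb)
}

#' Mean firing rates per area and cell type
#'
#' r = sum_i n_i / (N T), in Hz.
#'
#' @param result A `sim_result`.
#' @return Data frame with `area`, `type`, `n_neurons`, `rate_hz`.
#' @export
mean_firing_rates <- function(result) {
  cnt <- result$counts
  out <- expand.grid(area = as.integer(rownames(cnt)),
                     type = colnames(cnt), stringsAsFactors = FALSE)
  out$n_neurons <- mapply(function(a, tp) cnt[as.character(a), tp],
                          out$area, out$type)
  nsp <- mapply(function(a, tp)
    sum(result$spikes$area == a & result$spikes$type == tp),
    out$area, out$type)
  out$rate_hz <- 1000 * nsp / (out$n_neurons * result$duration)
  out[out$n_neurons > 0, ]
}

#' Stimulus-evoked rate increase
#'
#' Mean firing rate of the selected population in the `window` ms after
#' stimulus onset, minus the rate of the same population in the same window
#' of a matched no-stimulus baseline run (same seed, hence same alpha
#' phases).
#'
#' @param result A `sim_result` containing a stimulus.
#' @param baseline A matched `sim_result` without the stimulus.
#' @param area Area whose response is measured.
#' @param window Response window, ms.
#' @param subpop Optional RS subpopulation restriction.
#' @return Rate increase, Hz.
#' @export
stimulus_response <- function(result, baseline, area = 1, window = 30,
                              subpop = NULL) {
  if (is.null(result$stimulus)) stop("no stimulus in result", call. = FALSE)
  onset <- result$stimulus$onset_used
  if (onset + window > result$duration)
    stop("response window extends past the simulation end", call. = FALSE)
  count_in <- function(res) {
    sp <- res$spikes
    sel <- sp$area == area & sp$type == "RS"
    if (!is.null(subpop)) sel <- sel & sp$subpop == subpop
    tt <- sp$time[sel]
    sum(tt > onset & tt <= onset + window)
  }
  n_rs <- result$counts[as.character(area), "RS"]
  if (!is.null(subpop)) {
    # subpops are equal splits of the RS population
    nsub <- max(1L, max(result$spikes$subpop))
    n_rs <- n_rs / nsub
  }
  r1 <- 1000 * count_in(result) / (n_rs * window)
  r0 <- 1000 * count_in(baseline) / (n_rs * window)
  r1 - r0
}

#' Find the time at which the area-1 alpha phase crosses a target value
#'
#' Scans the realised (noisy) phase trajectory for the first crossing of
#' `target_deg` (mod 360) after `after` ms. Used to time stimulus onsets at
#' controlled alpha phases.
#'
#' @param phases A `phase_trace` (from a previous run's `result$alpha$phases`
#'   or [generate_coupled_phases()]).
#' @param target_deg Target phase, degrees.
#' @param after Earliest admissible time, ms.
#' @return Crossing time, ms (NA if none).
#' @export
phase_crossing_time <- function(phases, target_deg, after = 200) {
  tgt <- target_deg * pi / 180
  # unwrapped phi1 minus target: find upward crossing of a multiple of 2*pi
  x <- (phases$phi1 - tgt) / (2 * pi)
  k <- floor(x)
  cross <- which(diff(k) >= 1) + 1L
  tt <- phases$time[cross]
  tt <- tt[tt >= after]
  if (!length(tt)) return(NA_real_)
  tt[1]
}
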