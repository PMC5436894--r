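# Named, config-driven scenario drivers. Each reruns one network experiment
# end to end from (config, seed) and returns plain data frames; pass
# `out_dir` to also write them as CSV next to a JSON echo of the resolved
# configuration.

default_scenario_config <- function(scenario) {
  base <- list(
    n_trials = 10, duration = 2000, amplitude = 23,
    dphi_grid = seq(-180, 150, by = 30),
    net_seed = 5,
    ff_prob = 0.25, ff_scale = c(RS = 2.5, FS = 1.5)
  )
  extra <- switch(scenario,
    single_area = list(drive_grid = c(-4, 0, 4), n_trials_grid = 3),
    phase_sweep = list(n_trials = 5, amp_grid = c(0, 11.5, 23, 34.5, 45),
                       n_shuffles = 10),
    spike_coupling = list(n_trials = 5, dphi_plus = 0, dphi_minus = 180,
                          n_bins = 16),
    stimulus = list(onset_grid = seq(0, 315, by = 45), n_presentations = 20,
                    stim_amplitude = 24, stim_duration = 100,
                    warmup = 400, trial_length = 800, n_folds = 5,
                    subset_sizes = c(200, 100, 50, 20)),
    bidirectional = list(n_trials = 5, gc_dphis = c(-90, 0, 90),
                         gc_order = 12, window = 500, step = 100),
    list())
  utils::modifyList(base, extra)
}

resolve_config <- function(scenario, config) {
  cfg <- utils::modifyList(default_scenario_config(scenario),
                           as.list(config))
  cfg$scenario <- scenario
  cfg
}

write_outputs <- function(tables, cfg, out_dir) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  echo <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  writeLines(echo, file.path(out_dir, "config.json"))
  hash <- sum(utf8ToInt(as.character(echo))) %% 1e9
  for (nm in names(tables)) {
    if (is.data.frame(tables[[nm]])) {
      df <- tables[[nm]]
      df$config_hash <- hash
      utils::write.csv(df, file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(NULL)
}

gamma_band_coherence <- function(x, y, band = c(30, 50), nw = 5) {
  co <- multitaper_coherence(x, y, nw = nw)
  mean(co$value[co$freq >= band[1] & co$freq <= band[2]], na.rm = TRUE)
}

#' Single-area scenario: gamma genesis and alpha-gamma coupling
#'
#' Reruns the one-area experiments: (i) a grid of extra drive currents to
#' the E and I populations mapping gamma band power and peak frequency
#' (PING signature: E drive raises power, I drive lowers it, frequency
#' rises with both); (ii) an alpha-modulated run measuring the STH spectra,
#' the alpha-phase/gamma-power coupling curve, and the E-I alpha phase
#' offset.
#'
#' @param config Named list of overrides (see
#'   `default_scenario_config("single_area")`): `drive_grid` (native
#'   current offsets), `n_trials`, `amplitude` (pA), `duration`.
#' @param seed Integer seed.
#' @param out_dir Optional output directory for CSV tables.
#' @return List with `drive_surface`, `rates`, `coupling`, `spectrum`,
#'   `ei_offset_deg`.
#' @export
scenario_single_area <- function(config = list(), seed = 1,
                                 out_dir = NULL) {
  cfg <- resolve_config("single_area", config)
  grid <- expand.grid(d_e = cfg$drive_grid, d_i = cfg$drive_grid)
  surf <- lapply(seq_len(nrow(grid)), function(i) {
    nz <- default_noise()
    nz["RS", "mu"] <- nz["RS", "mu"] + grid$d_e[i]
    nz[c("FS", "LTS"), "mu"] <- nz[c("FS", "LTS"), "mu"] + grid$d_i[i]
    spec <- network_spec(areas = list(area_spec(noise = nz)),
                         directionality = "none")
    res <- run_trials(spec, NULL, duration = cfg$duration,
                      n_trials = cfg$n_trials_grid,
                      seed = seed + 17 * i)
    sth <- sapply(res, compute_sth, area = 1, types = "RS")
    psd <- multitaper_psd(sth)
    bm <- band_metrics(psd, search = c(20, 80))
    data.frame(d_e = grid$d_e[i], d_i = grid$d_i[i],
               gamma_power = bm$band_power, gamma_freq = bm$peak_freq)
  })
  surf <- do.call(rbind, surf)

  spec <- network_spec(areas = list(area_spec()), directionality = "none")
  alpha <- alpha_config(amplitude = cfg$amplitude)
  res <- run_trials(spec, alpha, duration = cfg$duration,
                    n_trials = cfg$n_trials, seed = seed)
  rates <- do.call(rbind, lapply(res, mean_firing_rates))
  rates <- stats::aggregate(rate_hz ~ area + type, rates, mean)
  sth_e <- sapply(res, compute_sth, area = 1, types = "RS")
  sth_i <- sapply(res, compute_sth, area = 1, types = c("FS", "LTS"))
  psd <- multitaper_psd(sth_e)
  cpl <- NULL; offs <- numeric(length(res))
  for (i in seq_along(res)) {
    te <- morlet_transform(sth_e[, i], 10)
    ti <- morlet_transform(sth_i[, i], 10)
    ok <- te$valid[, 1]
    offs[i] <- circular_mean(Arg(te$coef[ok, 1] * Conj(ti$coef[ok, 1])))
    tg <- morlet_transform(sth_e[, i], seq(20, 50, 5))
    gp <- wavelet_band_power(tg, c(20, 50))
    cc <- alpha_gamma_coupling(Arg(te$coef[, 1]), gp, 18)
    cpl <- if (is.null(cpl)) cc else
      within(cpl, power <- power + cc$power)
  }
  cpl$power <- cpl$power / length(res)
  out <- list(drive_surface = surf, rates = rates, coupling = cpl,
              spectrum = data.frame(freq = psd$freq, power = psd$value),
              ei_offset_deg = circular_mean(offs) * 180 / pi)
  write_outputs(out, cfg, out_dir)
  out
}

#' Phase-sweep scenario: gamma coherence versus relative alpha phase
#'
#' Sweeps the alpha phase offset between the two areas of the forward
#' network and measures inter-areal gamma-band coherence of the E-population
#' STHs, its amplitude/phase decomposition with trial-shuffle bias, and the
#' per-population firing rates. Optionally repeats the extreme offsets over
#' an amplitude grid (modulation depth versus alpha amplitude).
#'
#' @param config Overrides: `dphi_grid`, `n_trials`, `duration`,
#'   `amplitude`, `amp_grid` (set NULL to skip), `n_shuffles`.
#' @param seed Integer seed.
#' @param out_dir Optional CSV directory.
#' @return List with `coherence` (per dphi: gamma coherence, components,
#'   bias, rates), `spectra` (coherence spectra at the extremes),
#'   `amplitude_sweep`.
#' @export
scenario_phase_sweep <- function(config = list(), seed = 1,
                                 out_dir = NULL) {
  cfg <- resolve_config("phase_sweep", config)
  spec <- network_spec(ff_prob = cfg$ff_prob, ff_scale = cfg$ff_scale)
  set.seed(seed)
  trial_seeds <- sample.int(2^30, cfg$n_trials)
  net <- build_network(spec, seed = cfg$net_seed)

  run_dphi <- function(dphi, amplitude) {
    al <- alpha_config(amplitude = amplitude, offset_deg = dphi)
    x <- NULL; y <- NULL; rr <- NULL
    for (s in trial_seeds) {
      r <- run_simulation(spec, al, duration = cfg$duration, seed = s,
                          network = net)
      x <- cbind(x, compute_sth(r, 1, "RS"))
      y <- cbind(y, compute_sth(r, 2, "RS"))
      rr <- rbind(rr, mean_firing_rates(r))
    }
    list(x = x, y = y, rates = rr)
  }
  rows <- list(); spectra <- list()
  for (dphi in cfg$dphi_grid) {
    d <- run_dphi(dphi, cfg$amplitude)
    cc <- coherence_components(d$x, d$y)
    gsel <- cc$freq >= 30 & cc$freq <= 50
    bias <- shuffle_bias(d$x, d$y, n_shuffles = cfg$n_shuffles,
                         seed = seed + dphi + 360, components = TRUE)
    rt <- stats::aggregate(rate_hz ~ area + type, d$rates, mean)
    rows[[length(rows) + 1]] <- data.frame(
      dphi = dphi,
      gamma_coherence = mean(cc$total[gsel], na.rm = TRUE),
      gamma_phase_comp = mean(cc$phase[gsel], na.rm = TRUE),
      gamma_amp_comp = mean(cc$amplitude[gsel], na.rm = TRUE),
      bias_total = mean(bias$value[gsel], na.rm = TRUE),
      bias_phase = mean(bias$phase[gsel], na.rm = TRUE),
      bias_amp = mean(bias$amplitude[gsel], na.rm = TRUE),
      rate_e1 = rt$rate_hz[rt$area == 1 & rt$type == "RS"],
      rate_e2 = rt$rate_hz[rt$area == 2 & rt$type == "RS"],
      rate_i1 = mean(rt$rate_hz[rt$area == 1 & rt$type != "RS"]),
      rate_i2 = mean(rt$rate_hz[rt$area == 2 & rt$type != "RS"]))
    spectra[[as.character(dphi)]] <- cc
  }
  coh <- do.call(rbind, rows)
  best <- coh$dphi[which.max(coh$gamma_coherence)]
  worst <- coh$dphi[which.min(coh$gamma_coherence)]
  spec_tab <- rbind(
    data.frame(dphi = best, freq = spectra[[as.character(best)]]$freq,
               coherence = spectra[[as.character(best)]]$total),
    data.frame(dphi = worst, freq = spectra[[as.character(worst)]]$freq,
               coherence = spectra[[as.character(worst)]]$total))

  amp_tab <- NULL
  if (!is.null(cfg$amp_grid)) {
    amp_tab <- do.call(rbind, lapply(cfg$amp_grid, function(a) {
      if (a == 0) {
        d <- run_dphi(best, 0)
        cb <- gamma_band_coherence(d$x, d$y)
        return(data.frame(amplitude = 0, coh_best = cb, coh_worst = cb))
      }
      db <- run_dphi(best, a); dw <- run_dphi(worst, a)
      data.frame(amplitude = a,
                 coh_best = gamma_band_coherence(db$x, db$y),
                 coh_worst = gamma_band_coherence(dw$x, dw$y))
    }))
  }
  out <- list(coherence = coh, spectra = spec_tab,
              amplitude_sweep = amp_tab,
              best_dphi = best, worst_dphi = worst)
  write_outputs(out, cfg, out_dir)
  out
}

# pooled spike-phase histogram across trials against a per-trial phase trace
pool_phase_hist <- function(trials_spikes, trials_phase, times, n_bins) {
  counts <- numeric(n_bins); tot <- 0
  for (i in seq_along(trials_spikes)) {
    h <- spike_phase_histogram(trials_spikes[[i]], trials_phase[[i]],
                               times, n_bins)
    counts <- counts + h$bins$count
    tot <- tot + h$n_spikes
  }
  data.frame(phase_deg = h$bins$phase_deg,
             prob = if (tot > 0) counts / tot else counts,
             count = counts)
}

#' Spike-coupling scenario: locking to local and non-local gamma
#'
#' Compares the best and worst alpha phase offsets: spike-phase histograms
#' of each area against its own and the other area's gamma rhythm (phases
#' from a Morlet transform of the E-STH at its gamma peak frequency), and
#' the rate-equalised 1-4 ms spike-transmission probability binned by gamma
#' phase.
#'
#' @param config Overrides: `dphi_plus`, `dphi_minus`, `n_trials`,
#'   `duration`, `amplitude`, `n_bins`.
#' @param seed Integer seed.
#' @param out_dir Optional CSV directory.
#' @return List with `histograms` (long data frame over conditions) and
#'   `transmission`.
#' @export
scenario_spike_coupling <- function(config = list(), seed = 1,
                                    out_dir = NULL) {
  cfg <- resolve_config("spike_coupling", config)
  spec <- network_spec(ff_prob = cfg$ff_prob, ff_scale = cfg$ff_scale)
  set.seed(seed)
  trial_seeds <- sample.int(2^30, cfg$n_trials)
  net <- build_network(spec, seed = cfg$net_seed)
  conds <- c(plus = cfg$dphi_plus, minus = cfg$dphi_minus)
  hists <- list(); trans <- list()
  for (cn in names(conds)) {
    al <- alpha_config(amplitude = cfg$amplitude, offset_deg = conds[[cn]])
    sp1 <- list(); sp2 <- list(); ph1 <- list(); ph2 <- list()
    tp1 <- NULL; tp2 <- NULL
    for (i in seq_along(trial_seeds)) {
      r <- run_simulation(spec, al, duration = cfg$duration,
                          seed = trial_seeds[i], network = net)
      e1 <- compute_sth(r, 1, "RS"); e2 <- compute_sth(r, 2, "RS")
      g1 <- sth_gamma_phase(e1)$phase
      g2 <- sth_gamma_phase(e2)$phase
      s1 <- r$spikes$time[r$spikes$area == 1 & r$spikes$type == "RS"]
      s2 <- r$spikes$time[r$spikes$area == 2 & r$spikes$type == "RS"]
      sp1[[i]] <- s1; sp2[[i]] <- s2
      ph1[[i]] <- g1; ph2[[i]] <- g2
      tm <- seq_along(e1)
      tr1 <- transmission_probability(r, g1, tm, n_bins = cfg$n_bins,
                                      seed = seed + i)
      tr2 <- transmission_probability(r, g2, tm, n_bins = cfg$n_bins,
                                      seed = seed + i)
      tp1 <- if (is.null(tp1)) tr1$bins$prob / cfg$n_trials
             else tp1 + tr1$bins$prob / cfg$n_trials
      tp2 <- if (is.null(tp2)) tr2$bins$prob / cfg$n_trials
             else tp2 + tr2$bins$prob / cfg$n_trials
    }
    tm <- seq_len(cfg$duration)
    hs <- rbind(
      cbind(pool_phase_hist(sp1, ph1, tm, cfg$n_bins),
            spikes = "area1", rhythm = "area1"),
      cbind(pool_phase_hist(sp2, ph2, tm, cfg$n_bins),
            spikes = "area2", rhythm = "area2"),
      cbind(pool_phase_hist(sp1, ph2, tm, cfg$n_bins),
            spikes = "area1", rhythm = "area2"))
    hs$condition <- cn
    hists[[cn]] <- hs
    trans[[cn]] <- data.frame(
      phase_deg = tr1$bins$phase_deg,
      prob_vs_area1 = tp1, prob_vs_area2 = tp2, condition = cn)
  }
  out <- list(histograms = do.call(rbind, hists),
              transmission = do.call(rbind, trans))
  write_outputs(out, cfg, out_dir)
  out
}

# replicate the phase stream a given run_simulation seed will draw, and
# return the onset time at which area 1 crosses the target alpha phase
onset_for_phase <- function(alpha, duration, seed, target_deg, after) {
  set.seed(seed + 1L)
  ph <- generate_coupled_phases(alpha, duration, 0.5)
  phase_crossing_time(ph, target_deg, after = after)
}

#' Stimulus scenario: phase-gated responses, decoding and information
#'
#' (i) Sweeps the area-1 alpha phase at stimulus onset and measures the
#' 30 ms rate response over matched no-stimulus baselines (same seed, hence
#' identical alpha and noise streams); (ii) sweeps the alpha phase offset at
#' the optimal onset phase and measures the area-2 response; (iii) presents
#' two stimuli to disjoint area-1 subpopulations wired to matching area-2
#' subpopulations and decodes stimulus identity from area-2 spike counts
#' (cross-validated linear max-margin decoder), reporting accuracy and
#' mutual information per offset and versus decoder population size.
#'
#' @param config Overrides: `onset_grid` (degrees), `n_presentations`,
#'   `stim_amplitude`/`stim_duration` (pA / ms), `trial_length`, `warmup`,
#'   `dphi_grid`, `n_folds`, `subset_sizes`.
#' @param seed Integer seed.
#' @param out_dir Optional CSV directory.
#' @return List with `onset_response`, `optimal_onset`, `transfer`,
#'   `decoding`, `decoding_curve`.
#' @export
scenario_stimulus <- function(config = list(), seed = 1, out_dir = NULL) {
  cfg <- resolve_config("stimulus", config)
  spec <- network_spec(ff_prob = cfg$ff_prob, ff_scale = cfg$ff_scale)
  net <- build_network(spec, seed = cfg$net_seed)
  dur <- cfg$trial_length

  present <- function(al, onset_deg, s, subpop = NULL, spec_ = spec,
                      net_ = net) {
    onset <- onset_for_phase(al, dur, s, onset_deg, cfg$warmup)
    if (is.na(onset) || onset + 40 > dur) return(NULL)
    st <- stimulus_spec(area = 1, onset = onset,
                        duration = cfg$stim_duration,
                        amplitude = cfg$stim_amplitude, subpop = subpop)
    r1 <- run_simulation(spec_, al, st, duration = dur, seed = s,
                         network = net_)
    r0 <- run_simulation(spec_, al, NULL, duration = dur, seed = s,
                         network = net_)
    list(stim = r1, base = r0)
  }

  al0 <- alpha_config(amplitude = cfg$amplitude, offset_deg = 0)
  onset_tab <- do.call(rbind, lapply(cfg$onset_grid, function(pdeg) {
    rs <- vapply(seq_len(cfg$n_presentations), function(k) {
      p <- present(al0, pdeg, seed + 1000 + 37 * k + pdeg)
      if (is.null(p)) return(NA_real_)
      stimulus_response(p$stim, p$base, area = 1)
    }, numeric(1))
    data.frame(onset_deg = pdeg, response_hz = mean(rs, na.rm = TRUE))
  }))
  optimal_onset <- onset_tab$onset_deg[which.max(onset_tab$response_hz)]

  transfer <- do.call(rbind, lapply(cfg$dphi_grid, function(dp) {
    al <- alpha_config(amplitude = cfg$amplitude, offset_deg = dp)
    rs <- t(vapply(seq_len(cfg$n_presentations), function(k) {
      p <- present(al, optimal_onset, seed + 2000 + 53 * k + dp)
      if (is.null(p)) return(c(NA_real_, NA_real_))
      c(stimulus_response(p$stim, p$base, area = 1),
        stimulus_response(p$stim, p$base, area = 2))
    }, numeric(2)))
    data.frame(dphi = dp, response_a1 = mean(rs[, 1], na.rm = TRUE),
               response_a2 = mean(rs[, 2], na.rm = TRUE))
  }))

  # discrimination: two stimuli to disjoint subpopulations
  spec2 <- network_spec(
    areas = list(area_spec(n_subpops = 2), area_spec(n_subpops = 2)),
    ff_prob = cfg$ff_prob, ff_scale = cfg$ff_scale, subpop_wiring = TRUE)
  net2 <- build_network(spec2, seed = cfg$net_seed)
  a2_rs <- which(net2$area == 2 & net2$type == "RS")
  sub_of <- net2$subpop[a2_rs]
  count_features <- function(res, onset) {
    sp <- res$spikes
    sel <- sp$area == 2 & sp$type == "RS" &
      sp$time > onset & sp$time <= onset + 30
    tabulate(match(sp$neuron[sel], a2_rs), nbins = length(a2_rs))
  }
  dec <- list(); dec_curve <- NULL
  for (dp in cfg$dphi_grid) {
    al <- alpha_config(amplitude = cfg$amplitude, offset_deg = dp)
    feats <- list(); labs <- c()
    for (k in seq_len(cfg$n_presentations)) {
      for (stim_id in 1:2) {
        s <- seed + 3000 + 101 * k + 7 * stim_id + dp
        onset <- onset_for_phase(al, dur, s, optimal_onset, cfg$warmup)
        if (is.na(onset) || onset + 40 > dur) next
        st <- stimulus_spec(area = 1, onset = onset,
                            duration = cfg$stim_duration,
                            amplitude = cfg$stim_amplitude,
                            subpop = stim_id)
        r <- run_simulation(spec2, al, st, duration = dur, seed = s,
                            network = net2)
        feats[[length(feats) + 1]] <- count_features(r, onset)
        labs <- c(labs, stim_id)
      }
    }
    x <- do.call(rbind, feats)
    # decoder features: per-subpopulation mean counts (per-neuron counts
    # feed the population-size curve below)
    xm <- cbind(rowMeans(x[, sub_of == 1, drop = FALSE]),
                rowMeans(x[, sub_of == 2, drop = FALSE]))
    jd <- decode_and_tabulate(xm, labs, folds = cfg$n_folds,
                              seed = seed + dp)
    dec[[length(dec) + 1]] <- data.frame(
      dphi = dp, accuracy = jd$accuracy,
      mi_bits = mutual_information(jd), n_trials = length(labs))
    if (!is.null(cfg$subset_sizes)) {
      dcv <- decoding_curve(x, labs, cfg$subset_sizes, n_repeats = 3,
                            folds = cfg$n_folds, seed = seed + dp)
      dcv$dphi <- dp
      dec_curve <- rbind(dec_curve, dcv)
    }
  }
  out <- list(onset_response = onset_tab, optimal_onset = optimal_onset,
              transfer = transfer, decoding = do.call(rbind, dec),
              decoding_curve = dec_curve)
  write_outputs(out, cfg, out_dir)
  out
}

#' Bidirectional scenario: alpha phase sets the direction of communication
#'
#' Runs the reciprocally connected two-area network over the phase-offset
#' grid (gamma coherence curve), computes conditional spectral Granger
#' causality between the E-population STHs at selected offsets
#' (conditioning on the common alpha drive), and the sliding-window
#' directionality at zero offset.
#'
#' @param config Overrides: `dphi_grid`, `gc_dphis`, `gc_order`,
#'   `n_trials`, `duration`, `amplitude`, `window`, `step`.
#' @param seed Integer seed.
#' @param out_dir Optional CSV directory.
#' @return List with `coherence`, `gc` (per dphi spectra, both directions),
#'   `sliding` (direction time course at zero offset).
#' @export
scenario_bidirectional <- function(config = list(), seed = 1,
                                   out_dir = NULL) {
  cfg <- resolve_config("bidirectional", config)
  spec <- network_spec(directionality = "bidirectional",
                       ff_prob = cfg$ff_prob, ff_scale = cfg$ff_scale)
  set.seed(seed)
  trial_seeds <- sample.int(2^30, cfg$n_trials)
  net <- build_network(spec, seed = cfg$net_seed)
  freqs <- seq(2, 100, by = 2)

  run_dphi <- function(dphi) {
    al <- alpha_config(amplitude = cfg$amplitude, offset_deg = dphi)
    x <- NULL; y <- NULL; z <- NULL
    for (s in trial_seeds) {
      r <- run_simulation(spec, al, duration = cfg$duration, seed = s,
                          network = net)
      x <- cbind(x, compute_sth(r, 1, "RS"))
      y <- cbind(y, compute_sth(r, 2, "RS"))
      # common alpha drive at 1 ms resolution (mean of the two currents)
      cur <- rowMeans(r$alpha$current)
      z <- cbind(z, colMeans(matrix(cur, nrow = 2)))
    }
    list(x = x, y = y, z = z)
  }
  coh <- do.call(rbind, lapply(cfg$dphi_grid, function(dp) {
    d <- run_dphi(dp)
    data.frame(dphi = dp, gamma_coherence = gamma_band_coherence(d$x, d$y))
  }))
  gc_tab <- do.call(rbind, lapply(cfg$gc_dphis, function(dp) {
    d <- run_dphi(dp)
    g <- conditional_spectral_gc(d$x, d$y, d$z, freqs,
                                 order = cfg$gc_order)
    data.frame(dphi = dp, freq = g$freq,
               gc_1to2 = g$gc[, "x_to_y"], gc_2to1 = g$gc[, "y_to_x"])
  }))
  d0 <- run_dphi(0)
  sl <- sliding_gc(as.vector(d0$x[, 1]), as.vector(d0$y[, 1]),
                   window = cfg$window, step = cfg$step,
                   order = cfg$gc_order)
  out <- list(coherence = coh, gc = gc_tab, sliding = sl)
  write_outputs(out, cfg, out_dir)
  out
}

#' Run a named scenario
#'
#' Dispatcher used by the command-line wrapper: loads a YAML or JSON config
#' (if given), merges it over the scenario defaults and runs the scenario.
#'
#' @param scenario One of `"single_area"`, `"phase_sweep"`,
#'   `"spike_coupling"`, `"stimulus"`, `"bidirectional"`.
#' @param config_file Optional YAML/JSON file of overrides.
#' @param seed Integer seed.
#' @param out_dir Optional output directory.
#' @return The scenario's result list.
#' @export
run_scenario <- function(scenario = c("single_area", "phase_sweep",
                                      "spike_coupling", "stimulus",
                                      "bidirectional"),
                         config_file = NULL, seed = 1, out_dir = NULL) {
  scenario <- match.arg(scenario)
  cfg <- list()
  if (!is.null(config_file)) {
    cfg <- if (grepl("\\.ya?ml$", config_file))
      yaml::read_yaml(config_file)
    else jsonlite::fromJSON(config_file, simplifyVector = TRUE)
  }
  fn <- switch(scenario,
               single_area = scenario_single_area,
               phase_sweep = scenario_phase_sweep,
               spike_coupling = scenario_spike_coupling,
               stimulus = scenario_stimulus,
               bidirectional = scenario_bidirectional)
  fn(config = cfg, seed = seed, out_dir = out_dir)
}
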