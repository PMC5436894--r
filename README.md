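# alphagate

Two cortical areas talk to each other best when their fast (gamma, 30–50 Hz)
rhythms are coherent. `alphagate` is an R package for studying how a slow
(alpha, 10 Hz) modulation — the kind the pulvinar broadcasts to visual
cortex — can open and close that gamma channel by shifting the *relative
alpha phase* Δφ between the two areas. It is aimed at computational
neuroscientists who want a seeded, configurable spiking-network testbed for
communication-through-coherence questions, plus a self-contained
oscillatory-analysis toolkit usable on its own.

The package contains:

* **The network model** — one or two areas of Izhikevich neurons
  (400 regular-spiking pyramidal cells, 75 fast-spiking and 25
  low-threshold-spiking interneurons per area; all-to-all within an area,
  sparse excitatory projections between areas), with exponentially decaying
  synaptic currents (τ_E = 2.5 ms, τ_I = 6 ms), per-substep Gaussian noise
  drive and an alpha-band current A·sin²(φ/2) on the inhibitory cells whose
  phases follow coupled noisy Kuramoto oscillators with a controllable
  offset Δφ (negative Δφ = area 1 leads). Gamma arises from the
  pyramidal–interneuron (PING) loop, and its power is locked to the alpha
  phase.
* **The measurement stack** — multitaper power and coherence
  (NW = 5 Slepian tapers) with an amplitude/phase decomposition and
  trial-shuffle bias; complex Morlet wavelets (σ_t = 1/f₀) for
  time-resolved phase and power; multi-trial VAR fitting with Geweke
  spectral and conditional Granger causality f_{Y→X}(λ) =
  ln |S_xx| / |S_xx − H_xy Σ_yy H_xy*| (conditioning removes the common
  alpha drive); gamma-phase spike histograms and the rate-equalised 1–4 ms
  spike-transmission probability; linear max-margin decoding with mutual
  information I(r, s) = H(r) − H(r|s) in bits.
* **Scenario drivers** — five named, config-driven experiments
  (`single_area`, `phase_sweep`, `spike_coupling`, `stimulus`,
  `bidirectional`) that rerun each in-model study end to end from a seed,
  returning plain data frames and optionally writing CSV. A thin CLI lives
  at `inst/cli/alphagate.R`
  (`Rscript alphagate.R run phase_sweep --seed 1 --out out/`).

## Worked example

```r
library(alphagate)

## one quiescent area, 2 s: rates and the emergent gamma peak
spec <- network_spec(areas = list(area_spec()), directionality = "none")
res  <- run_simulation(spec, alpha = NULL, duration = 2000, seed = 1)
mean_firing_rates(res)
#>   area type n_neurons rate_hz
#> 1    1   FS        75  35.320
#> 2    1  LTS        25  33.920
#> 3    1   RS       400   7.255

sth <- compute_sth(res, area = 1, types = "RS")
band_metrics(multitaper_psd(sth), search = c(20, 80))
#> $peak_freq
#> [1] 45.5
#> $band_power
#> [1] 0.04417079
```

Excitatory cells fire at ~7 Hz and interneurons at ~35 Hz — the
physiological operating point — and the E-population spike-time histogram
oscillates at 45.5 Hz without any imposed pacemaker: the PING loop sets the
rhythm.

```r
## two areas, alpha on the interneurons: gamma coherence versus offset
sweep <- scenario_phase_sweep(config = list(n_trials = 3, amp_grid = NULL,
                                            n_shuffles = 5), seed = 42)
sweep$coherence[, c("dphi", "gamma_coherence", "gamma_phase_comp")]
#>    dphi gamma_coherence gamma_phase_comp
#> 1  -180      0.0392           0.0312
#> 2  -150      0.0693           0.0485
#> ...
#> 6   -30      0.3965           0.2885
#> 7     0      0.5288           0.4102
#> 8    30      0.2170           0.1648
#> ...
#> 10   90      0.0551           0.0450
```

The same wiring, the same rates (they vary by ~2% across the sweep) — yet
gamma coherence between the two areas swings more than ten-fold with the
alpha phase offset, peaking when the areas are near-aligned-to-slightly
sender-led and collapsing to the bias floor on the opposite phase: the
alpha offset acts as a gate on the gamma channel.

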