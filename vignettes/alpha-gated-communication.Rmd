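---
title: "Alpha-phase gating of gamma-band communication: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alpha-phase gating of gamma-band communication: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

Visual cortical areas communicate selectively: the same anatomical pathway
transmits well under some cognitive states and poorly under others. One
candidate mechanism puts a higher-order thalamic nucleus (the pulvinar) in
the role of a conductor: it broadcasts an ~10 Hz (alpha) modulation to the
inhibitory populations of connected cortical areas, and by shifting the
*relative phase* of that modulation between two areas it opens or closes a
gamma-band communication channel between them. `alphagate` implements a
two-area spiking-network model of this idea together with the measurement
stack needed to quantify it: multitaper coherence with an amplitude/phase
decomposition and shuffle bias, wavelet phase-power coupling, parametric
conditional spectral Granger causality, spike-transmission statistics and
linear decoding with mutual information.

# The network model

Each cortical area is a local, all-to-all connected population of 400
regular-spiking (RS) pyramidal cells, 75 fast-spiking (FS) and 25
low-threshold-spiking (LTS) interneurons, all integrated as Izhikevich
neurons

$$\dot v = 0.04v^2 + 5v + 140 - u + I,\qquad \dot u = a(bv - u),$$

with the reset $v \leftarrow c,\; u \leftarrow u + d$ when $v$ reaches
30 mV. The $(a, b, c, d)$ sets are the classic RS/FS/LTS values
(`neuron_params()`). Spike-evoked postsynaptic currents jump by the
connection weight and decay exponentially with $\tau_E = 2.5$ ms (AMPA-like)
and $\tau_I = 6$ ms (GABA-like). Within-area weights are drawn uniformly
between 0 and a signed per-type-pair bound (`connectivity_bounds()`);
LTS→LTS connections are absent. Each neuron receives independent Gaussian
noise current per 0.5 ms integration substep, with per-type means and
standard deviations (`default_noise()`) that put the quiescent network into
an asynchronous regime with E rates of 5–10 Hz and I rates of 25–35 Hz.
Gamma oscillations (30–50 Hz spectral peak of the E-population spike-time
histogram) emerge from the pyramidal–interneuron (PING) loop; no pacemaker
is built in.

Integration uses forward Euler at 0.5 ms (two substeps per 1 ms simulation
step, the resolution of all spike-time histograms), with spike detection
after every substep and the spike time recorded at the voltage peak before
reset. Initial conditions are the per-type analytic resting states; the
independent noise breaks symmetry from the first substep, so no initial
jitter is applied. A cross-check against a 0.01 ms reference integrator
bounds the spike-count error of a tonically firing RS cell at moderate
drive below 2%.

## The alpha drive

The pulvinar is represented only by its output: one noisy phase trajectory
per area, integrated from coupled Kuramoto equations in rad/ms with mean
frequency 10 Hz, coupling $J = 0.2\,\mathrm{ms^{-1}}$ applied to the
deviation from a target offset $\Delta\varphi$, and white phase noise
(default 0.1 rad/√ms — unconstrained by data; chosen once so the alpha line
acquires a visible width while the realised offset stays within ~10° of its
target). The printed coupling form pulls the two phases together; to hold
an arbitrary offset we couple each phase to the *target-shifted* partner
phase, the only form consistent with a maintained nonzero offset.

**Sign convention.** The package realises
$\varphi_2 - \varphi_1 = \Delta\varphi$: negative offsets mean area 1 runs
ahead in time (at $-90^\circ$ its modulation peaks 25 ms — a quarter alpha
cycle — before area 2's). This convention was chosen so that "negative
offset = sender leads", matching the directionality of the reported optimum.

The phase is converted to a current $I(t) = A\sin^2(\varphi/2)$ (effective
frequency 10 Hz, non-negative, mean $A/2$ — the biologically plausible
choice, since stronger pulvinar drive means more incoming spikes), or
$A\sin(\varphi)$ as a zero-mean control. By default the current is injected
into the inhibitory cells (FS and LTS) of each area; the alpha rhythm
reaches the E cells only through the strong I→E projection, which places the
E-population alpha component approximately in antiphase to the I population
(the realised offset is ~150°, the E burst lagging the inhibition trough by
7–8 ms of integration time).

**Current units.** The Izhikevich equations carry current in dimensionless
model units. The configuration interfaces quote pA and convert with a fixed
factor `current_scale()` = 10/23 model units per pA, pinned by two
amplitude landmarks of the modulated network: at the reference 23 pA the
gamma rhythm survives (strongly modulated) at all alpha phases, while at
about twice that amplitude the troughs are nearly silenced. Noise
parameters and FI-curve currents remain in native units; `fi_curve()` is
provided so users can re-derive or replace the mapping.

## The inter-areal projection

Nothing in the underlying physiology pins the area-1 → area-2 projection;
it is the model's single largest free choice and deliberately prominent in
the configuration (`network_spec()`). Defaults: every RS cell of the source
area contacts each RS and FS cell of the target area with probability 0.25;
weights are uniform draws scaled from the within-area RS-row bounds by 2.5
(RS targets) and 1.5 (FS targets). This excitation-dominant mix was
calibrated — jointly, once — so that (i) target-area rates stay inside the
physiological bands and vary by only ~2% across the full offset sweep
(the excitatory and inhibitory entrainment effects on the target rate
nearly cancel), (ii) a stimulus in area 1 produces a positive transferred
rate response in area 2, and (iii) the gamma coherence between the two
E-population histograms is strongly gated by the alpha offset (range
~0.03–0.5 at the default amplitude). An FS-heavy mix shifts the coherence
optimum toward larger sender leads but breaks (i) and (ii); the trade-off
is exposed through `ff_scale` rather than hidden.

With the default mix the coherence optimum sits at an offset of about 0 to
−60° (sender leading by 0–17 ms) and the minimum near the opposite phase;
the reference behaviour this model family aims at places the optimum at a
full −90°. Across a wide exploration (projection targets, scales,
probability, alpha amplitude and phase noise) the optimum never moved past
a ~60° sender lead while respecting (i) and (ii); we report what the model
does rather than force the landmark.

## Stimuli, decoding and information

A stimulus is a step current (default 24 pA for 100 ms) to the RS cells —
optionally one labelled half (subpopulation) — of area 1. Responses are
measured as the rate increase over a matched no-stimulus baseline in the
30 ms after onset; matching reruns the identical seed without the stimulus,
so alpha phases and noise streams agree sample for sample. Onsets are
placed at controlled alpha phases by scanning the realised phase trajectory
(`phase_crossing_time()`). For discrimination experiments the RS population
of each area splits into two 200-cell subpopulations with channel-private
RS→RS feedforward wiring; a linear max-margin decoder (soft margin at large
cost; `e1071` backend) reads the area-2 response — by default the two
subpopulation mean counts, following the description of the decoding
features; per-neuron counts are available — under stratified k-fold
cross-validation, and the pooled held-out confusion table yields the mutual
information in bits.

# The measurement stack

* **Multitaper spectra and coherence** (`multitaper_psd()`,
  `multitaper_coherence()`): Slepian tapers computed from the tridiagonal
  eigenproblem (NW = 5 over 2000 ms windows, 9 tapers, half-bandwidth
  2.5 Hz), trial- and taper-averaged, 1 kHz sampling throughout. The
  `n = 2000` eigendecomposition is cached per session.
* **Coherence decomposition** (`coherence_components()`): the source
  description of the decomposition is verbal, so the implementation is an
  interpretation and documented as such: the *phase component* is the
  squared resultant of unit-normalised per-taper/per-trial cross-spectra
  (amplitude information removed); the *amplitude component* is the Pearson
  correlation of per-taper/per-trial spectral amplitudes, floored at zero.
  The *shuffle bias* re-pairs trials by random derangements.
* **Wavelets** (`morlet_transform()`): complex Morlet with
  $\sigma_t = 1/f_0$ (envelope one period wide), normalised so a unit
  cosine at $f_0$ gives unit coefficient magnitude; samples within
  $2\sigma_t$ of an edge are flagged and excluded from coupling curves.
  Spike-phase work uses the sine-referenced convention (rhythm peak at
  +90°, `sth_gamma_phase()`), under which a population locked to its own
  rhythm peaks near 90° — the convention that makes the local and
  non-local locking claims mutually consistent.
* **Granger causality** (`fit_var()`, `spectral_gc()`,
  `conditional_spectral_gc()`, `sliding_gc()`): multi-trial least-squares
  VAR with AIC order selection (default cap 20 at 1 kHz; portmanteau
  whiteness reported), Geweke's spectral measure after residual rotation,
  and the dual-model (full vs reduced) conditional construction used to
  discount the common alpha drive. Fixtures with closed-form ground truth
  (Kolmogorov innovation variance from the model spectrum) validate both
  paths; on simulated data the conditioning is what exposes the gamma-band
  directionality, since the shared alpha otherwise dominates.
* **Spike coupling** (`spike_phase_histogram()`,
  `transmission_probability()`): transmission is the probability that a
  sender spike is followed by a spike of one of its actual postsynaptic
  targets within the half-open window (t+1, t+4] ms — the synaptic
  activation delay; there are no axonal delays — with per-phase-bin spike
  counts equalised by seeded subsampling before the probability is taken
  (16 bins per cycle by default).

# Scenario drivers and reproducibility

`run_scenario()` (or the thin `inst/cli/alphagate.R` wrapper) exposes five
named experiments: `single_area` (gamma genesis surfaces and alpha-gamma
coupling), `phase_sweep` (coherence and its decomposition versus offset,
plus the amplitude sweep), `spike_coupling`, `stimulus` (phase-gated
responses, decoding, information) and `bidirectional` (conditional Granger
directionality and its sliding-window alternation). Every scenario resolves
its configuration over documented defaults, derives all randomness from one
seed, and can write CSV tables plus a JSON configuration echo; identical
(config, seed) pairs reproduce bit-identically.

Default problem sizes are desk-scale choices: 2000 ms trials, 10 trials for
single-area statistics, 5 trials per offset for the 12-point sweep, 20
stimulus presentations per condition, 40 per stimulus class for decoding.
The package's own test suite uses smaller counts (3–10 trials, 8
presentations) chosen to exercise every claim while keeping a full run in
the tens of minutes on one core.

# What the synthetic fixtures do and do not show

The oracle fixtures (`gen_var_process()`,
`gen_phase_locked_oscillation()`, `gen_modulated_spikes()`) generate
signals whose spectral, causal and phase-locking structure is known in
closed form, and every analysis operation is validated against them. They
emulate controlled line spectra, finite-order VAR dynamics and von Mises
phase modulation — not the nonstationary, history-dependent statistics of
real spiking data. Passing fixture tests therefore certifies the
*estimators*, not the biological fidelity of the network; conversely the
network experiments certify the *mechanism* within this model family, not
in cortex. Pure sinusoidal fixtures carry a per-trial frequency jitter
(default 0.3 Hz) because a zero-linewidth tone exactly on a DFT bin
interacts pathologically with antisymmetric Slepian tapers.

# Known limitations

* The coherence optimum sits at a smaller sender lead (0–60°) than the
  −90° landmark, and the transfer gate closes fully at unfavourable
  offsets, so decoding accuracy falls to chance there instead of remaining
  at ceiling; both are properties of this calibration, documented rather
  than tuned away.
* The E–I alpha antiphase is realised at ~150°, not a full 180°: the E
  window lags the inhibition trough by the E cells' integration time.
* The amplitude component of coherence is modulated by the offset almost
  as strongly as the phase component (the reference behaviour has the
  phase component clearly dominant).
* No axonal delays, no synaptic plasticity, no laminar structure, at most
  two areas, and the pulvinar itself is not a spiking model — only its
  modulatory output is represented.
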