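---
title: "Models and methods behind the pfcmicro microcircuit simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the pfcmicro microcircuit simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pfcmicro` simulates a 20-neuron prefrontal-cortex microcircuit — 16
pyramidal cells plus two fast-spiking (FS), one regular-spiking (RS) and one
irregular-spiking (IS) interneuron — and the persistent-activity induction
experiment performed on it: a 120-synapse glutamatergic volley train on the
pyramidal proximal apical dendrites, delivered ten times at 20 Hz, after
which the network either falls silent or settles into self-sustained firing.
This vignette is the package's own account of the modelling choices: the cell
and synapse models, the parameters that matter and why they have the defaults
they do, the numerics, and what the simulations can and cannot say.

## Cell models

All four cell types are branched cylinder-compartment conductance-based
models integrated with the cable equation. The pyramidal model has a soma,
a basal, a proximal and a distal apical compartment; FS and RS models have a
soma, a dendrite and an axon; the IS model has a soma, two dendrites and an
axon, mimicking a bipolar cell. Passive properties of the interneurons are
the published table values (membrane capacitance 1.2 µF/cm², axial
resistivity 150 Ω·cm, membrane resistivity 10/40/20 kΩ·cm² for FS/RS/IS), as
are their channel densities per compartment.

Two classes of parameters are *not* published and are treated as
calibration parameters, pinned against the cell-level validation surfaces
and shipped frozen in `default_params()`:

* **Compartment dimensions.** Only the input resistances are printed, so
  cylinder dimensions were chosen such that the assembled cells reproduce
  them: pyramidal 91.3 MΩ, FS 250 MΩ, RS 483 MΩ, IS 519 MΩ, preserving the
  published ordering PYR < FS < RS < IS.
* **Gating kinetics.** Each mechanism (fast Na⁺, delayed-rectifier K⁺,
  A-type K⁺, slow K⁺, D-type K⁺, N- and T-type Ca²⁺, H, fast
  Ca²⁺-activated K⁺) uses a Boltzmann steady state
  $x_\infty(v) = 1/(1+e^{-(v-v_h)/k})$ and a bell-shaped voltage-dependent
  time constant. The constants are per-cell-type calibration values chosen
  so that each cell hits its printed electrophysiological anchors: the FS
  model fires 6 spikes to a 0.05 nA / 500 ms somatic step and 100 Hz at
  0.2 nA; the RS model 15 spikes and 60 Hz; the IS model an initial cluster
  of 2–6 spikes (growing with drive) followed by irregular firing; the
  pyramidal model regular adapting spiking at 0.17 nA.

Three design choices deserve explanation:

* **RS rate flattening.** The printed RS firing pair (30 Hz at 0.05 nA,
  60 Hz at 0.2 nA) is strongly sublinear — a quadrupling of drive only
  doubles the rate. A conventional delayed-rectifier/A-current split cannot
  produce this with the published densities, so the RS model assigns the
  fast repolarizing role to its large A-type conductance and turns the
  delayed rectifier into a sharp low-threshold brake whose deactivation is
  slow selectively near the afterhyperpolarization trough. The slow
  trough-side deactivation accumulates at short intervals only, capping the
  high-drive rate without touching the near-rheobase ISI.
* **No plateau attractors.** During network calibration three cells turned
  out to possess unintended stable attractors reachable by synaptic drive
  but not by somatic steps: a sodium-window plateau in the FS dendrite and
  axon, and a T-type rebound limit cycle in the RS cell. These are
  pathological for a recurrent network (a cell that never stops firing
  locks the circuit), so the FS dendritic A-current keeps a depolarized
  availability window, the FS axonal Na⁺ inactivation is sharp and fast,
  and the RS T-type deinactivation midpoint sits at −88 mV. All cell-level
  validation numbers were re-established after these changes.
* **Pyramidal ceiling.** The pyramidal delayed rectifier deactivates slowly
  below −55 mV, which saturates the maximal sustained firing rate well
  below the nominal cable limit. This is what turns the network's active
  state into a finite-rate attractor rather than a runaway.

The intracellular calcium pool is a single first-order buffered pool per
somatic compartment, $d[Ca]/dt = -\phi I_{Ca} - ([Ca]-[Ca]_{rest})/\tau$,
feeding the saturating calcium factor of the fAHP conductance.

## Synapses

AMPA, NMDA, GABA-A and GABA-B conductances are bi-exponential
(rise/decay 0.5/3, 5/100, 0.5/7 and 50/150 ms), normalized so a unitary
event peaks at its weight. The NMDA conductance is multiplied by the
standard sigmoidal magnesium unblock at 1 mM Mg²⁺ (half unblock near
−20.5 mV). GABA-B is a reduced model of the metabotropic cascade: a slow
delayed bi-exponential driving a K⁺-reversal conductance.

Two operational conventions had to be fixed because the source constrains
ratios, not conductances:

* **NMDA-to-AMPA ratios** (1.25 pyramidal, 0.5 FS, 0.8 RS; IS set to the
  smallest candidate at which the IS model fires during the stimulus, see
  `calibrate_is_nmda_ratio()`) are peak-conductance ratios. Under the
  simulated paired-recording protocol (`clamp_current_ratio()`, holding at
  −70 mV for AMPA and +60 mV for NMDA with the synaptic compartment
  clamped and a no-synapse control subtracted) the measured normalized
  peak-current ratios come out at 0.49/0.77/1.23 for FS/RS/PYR targets.
* **The GABA-B-to-GABA-A ratio** (control 0.2) is applied as a ratio of
  unitary conductance-charge transfers rather than peak conductances. The
  slow GABA-B kinetics integrate roughly 26× more charge per unit peak than
  GABA-A; a peak-based reading makes any somatic GABA-A strength that paces
  the network collapse persistent activity outright. The charge reading
  preserves the intended fast/slow balance; the normalization constant of
  the slow component (`gabab_norm`) is a network-level calibration value.
* **NMDA saturation.** Each connection's NMDA conductance saturates at a
  multiple (`nmda_cap_mult`) of its summed contact weight, implemented as
  event increments scaled by the remaining headroom. Unitary events are
  unaffected (the EPSP and clamp calibrations are exactly preserved), but
  sustained high-rate drive compresses: this is what gives the network a
  stable low-rate persistent state instead of a binary silent/saturated
  pair. Receptor desensitization and release stochasticity remain out of
  scope.

The unitary pyramidal AMPA conductance is found by deterministic bisection
so that one basal-dendrite synapse depolarizes the soma by 0.1 mV
(`calibrate_unitary_ampa()`); the frozen value is 7.23e-5 µS.

## Network

The control circuit wires the published connection table: pyramidal cells
fully recurrently connected at the basal dendrites (24 contacts/pair, 8
autaptic), FS→pyramidal somatic (15/pair) plus one somatic FS autapse,
RS→distal (12/pair), IS→distal (10/pair) and IS→RS (2), and pyramidal
drive onto the interneuron dendrites (12/14/7 contacts to FS/RS/IS).
Latencies are truncated-Gaussian (mean 1.7 ms, sd 0.9 ms, floored at
0.1 ms for causality, drawn by rejection). Inhibitory contacts onto a
pyramidal cell are 10.7% of its excitatory count, below the 13% anatomical
bound. The RS→pyramidal GABA-A pair current is 1/10 of the FS→pyramidal
pair current, and IS→pyramidal 1/10 of RS→pyramidal.

Manipulations (`manipulation_spec()`) rebuild the circuit: interneuron
knock-outs remove the population with all its synapses; `fs_scale` retains
`round(f·15)` FS contacts per pair, sampled reproducibly; `fs_retarget`
moves the FS projection to the basal (D0), proximal (D1) or distal (D2)
compartment; the reverse networks give two RS (or IS) models the somatic
role with its 15 contacts/pair while one FS model takes the displaced
distal projection with 12 contacts/pair, each interneuron keeping its own
unitary strength.

**Background noise.** The source describes somatic Poisson noise with
"mean rate 0.02" (0.035 for IS). Read as events per second this produces
one event per minute — functionally no noise — so the package exposes the
unit and defaults the network protocols to the events-per-millisecond
reading (20 and 35 events/s), which produces membrane fluctuations of the
kind the noise is stated to emulate and desynchronizes the otherwise
perfectly symmetric circuit. Event amplitude (0.2 nA, 2 ms decay) is a
calibration value.

## Induction protocol and classification

A trial delivers the volley train, simulates past the classification
window, and classifies: induced if at least 75% of the pyramidal cells fire
at ≥ 2 Hz during the window from 1 to 4 s after stimulus end. The source
shows persistent activity but never defines "induced" operationally; these
defaults classify the documented phenotype (pyramidal firing at 8–17 Hz
outlasting the stimulus by seconds) as induced and a silent network as not,
and the boolean is insensitive to moderate (±50%) changes of the rate
threshold. Ratio grids default to a small grid bracketing the control point
(NMDA/AMPA 1.25, GABA-B/GABA-A 0.2); the source's exact grid extents are
not printed, so trends rather than per-cell map values are the meaningful
output. Trial seeds drive both the wiring latencies and the noise, so
induction probabilities reflect genuine trial-to-trial variability.

## Analysis stack

* `binned_isi_cv()`: per-neuron interspike intervals and coefficients of
  variation in 500 ms bins; an interval belongs to the bin containing its
  terminating spike (a deterministic convention; alternatives only shift
  bin edges). Bins with fewer than two intervals are reported missing.
* `spike_distance_index()`: the time-averaged SPIKE-distance over all
  pairs. The pairwise profile is piecewise linear between event
  breakpoints, so the package integrates it exactly by trapezoid over the
  breakpoints; the multivariate index equals the mean of the pairwise time
  averages, and pairwise values are available via `pairwise = TRUE`. Zero
  for identical trains, larger for asynchronous firing.
* `discrete_time_rate()`: population spike counts in 1 ms bins.
* `synaptic_current_spectrum()`: per trial, the summed pyramidal AMPA +
  NMDA + GABA-A currents over a 1 s window (standard use: starting 3 s
  after stimulus end) are mean-subtracted, decimated to 1 kHz with FIR
  anti-aliasing (the decimation target retains all sub-100 Hz structure of
  interest), and a plain untapered periodogram is computed and averaged
  over trials. The scaling satisfies Parseval: one-sided power sums to the
  windowed variance.

Epoch conventions: "stimulus" runs from stimulus onset to end;
"persistent" from 500 ms after stimulus end (excluding the offset
transient) to the end of the trial.

## Numerics

The integrator (Rcpp) advances gating variables, calcium pools and
synaptic states with their exact exponential updates at the previous
voltage, then solves the voltage system implicitly on each cell's
compartment tree (Hines-ordered elimination), which is unconditionally
stable at the default step of 0.025 ms; halving the step changes
subthreshold somatic traces by far less than 0.5 mV RMS. Gating rates are
tabulated on a 0.05 mV grid with linear interpolation. Spikes are upward
0 mV crossings with a 2 ms lockout, linearly interpolated in time;
synaptic events are quantized to the step grid for determinism. The
voltage clamp is a stiff series-resistance clamp sharing the same
integrator path. Every random draw is attributable to (seed, stream):
network wiring uses the network seed, noise a derived trial seed, and
identically-seeded runs are bit-identical.

## Desk-scale problem sizes

The shipped defaults favour tractable desk-scale runs: induction trials of
~4.7 s simulated time, probability grids of a few points at around ten
trials per point, and ten-trial spectra. The full-scale figures (100-trial
probability maps, wide ratio grids) are reproducible with the same
functions by raising `n_trials` and the grid vectors.

## Limitations

The pyramidal channel roster and all gating kinetics stand in for
unavailable supplemental material; they reproduce the printed validation
anchors but are not the original mechanisms, so quantities outside those
anchors (exact AP shapes, subthreshold resonance) should not be
over-interpreted. The network-level calibration reproduces the qualitative
regime structure — a noise-desynchronized low-rate persistent state under
control conditions, faster and more regular firing as FS input is removed,
and a beta-band population rhythm — but the 20-neuron circuit with
identical cells is strongly synchronization-prone, and network-level
quantities are sensitive to the inhibition working point in a way the
single-cell anchors are not. Synaptic plasticity, receptor desensitization,
stochastic gating and temperature corrections are out of scope.
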