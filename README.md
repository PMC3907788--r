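# pfcmicro

`pfcmicro` is an R package that simulates a small prefrontal-cortex (PFC)
microcircuit — 16 conductance-based pyramidal neuron models plus the three
main interneuron classes (2 fast-spiking, 1 regular-spiking, 1
irregular-spiking) — and the *persistent activity* experiment performed on
it: a brief glutamatergic stimulus to the pyramidal apical dendrites after
which the network either falls silent or keeps firing on its own. Persistent
firing of PFC neurons past the end of a stimulus is the cellular correlate
of working memory, and the balance between NMDA-receptor-mediated
excitation and GABAergic inhibition decides whether it is induced and how
it looks. The package is written for computational neuroscientists who want
a self-contained, deterministic, testable implementation of this circuit and
its manipulation experiments (interneuron knock-outs, graded removal of
fast-spiking inputs, projection retargeting, interneuron role reversal).

## The models

Each cell is a branched set of cylindrical compartments obeying the cable
equation

$$C_m \frac{dV_i}{dt} = -\sum_c \bar g_c \, m_c^{p}h_c \,(V_i - E_c)
  + \sum_{j} g_{ij}(V_j - V_i) + I_{\mathrm{syn}} + I_{\mathrm{inj}},$$

with Hodgkin–Huxley-style gating ($\dot x = (x_\infty(V)-x)/\tau_x(V)$),
a first-order somatic calcium pool, and channel complements per the
published per-compartment density tables (fast Na⁺, delayed-rectifier,
A-type, slow and D-type K⁺, N- and T-type Ca²⁺, H, and fast
Ca²⁺-activated K⁺ where present). Synapses are event-driven
bi-exponential AMPA, NMDA (with sigmoidal Mg²⁺ unblock and per-connection
saturation), GABA-A and GABA-B conductances; connection counts, targets and
truncated-Gaussian latencies follow the published wiring table. Ratio
parameters — NMDA-to-AMPA per target class and GABA-B-to-GABA-A — are the
experiment's independent variables. Everything is integrated by a compiled
implicit (unconditionally stable) staggered scheme at dt = 0.025 ms;
identically-seeded runs are bit-identical.

The validated single-cell anchors: input resistances 91.3 MΩ (pyramidal),
250 MΩ (FS), 483 MΩ (RS), 519 MΩ (IS); the FS model answers a
0.05 nA / 500 ms somatic step with 6 spikes and 0.2 nA with 100 Hz; the RS
model with 15 spikes and 60 Hz; the IS model fires an initial cluster of
2–6 spikes then continues irregularly; a single calibrated AMPA synapse
depolarizes the pyramidal soma by 0.1 mV.

## Worked example

```r
library(pfcmicro)

# single-cell validation
fs <- build_cell("FS")
measure_input_resistance(fs)        # 250.2 MOhm
current_step_response(fs, 0.05)$n_spikes   # 6
f_i_point(fs, 0.2)                  # 100 Hz

# one induction trial of the control network
trial <- run_induction_trial(network_spec(), seed = 1, record_syn = TRUE)
trial$induced                       # TRUE: persistent activity was induced
ep <- analysis_epochs(stimulus_spec(), trial$duration)
population_mean_isi(trial$spikes, ep$persistent, neurons = 1:16)
# mean pyramidal interspike interval (ms) during persistent activity

# synchrony and spectrum of the same trial
spike_distance_index(trial$spikes, ep$persistent)
sp <- synaptic_current_spectrum(list(trial$syn),
                                window = trial$stim_end + c(3000, 4000))
peak_frequency(sp)                  # dominant rhythm of the summed currents

# a knocked-out variant
ko <- network_spec(manipulation = manipulation_spec("fs_ko"))
run_induction_trial(ko, seed = 1)$induced   # TRUE: induction never fails
```

`measure_input_resistance(fs)` returns 250.2; the FS step responses return
6 spikes and 100 Hz, matching the validation targets above. Trial-level
outputs (ISIs, synchrony, spectra) are stochastic over seeds; the induction
probability over a ratio grid is computed by
`induction_probability_grid()`, and `autoplot()` methods draw rasters,
probability maps, ISI profiles and spectra.

A thin command-line front end ships in `inst/cli/pfcmicro.R`
(`validate-cells`, `validate-synapses`, `run`, `sweep`, `analyze`) over
serializable experiment manifests (`experiment_manifest()`,
`run_manifest()`), whose bundles are reproducible byte-for-byte and
resumable per trial.

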