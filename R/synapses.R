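# Synaptic receptor models (AMPA, NMDA with magnesium block, GABA-A, GABA-B),
# ratio-based scaling, and the voltage-clamp validation protocols.

#' Synaptic receptor kinetics
#'
#' Bi-exponential conductance time course with a rise and decay time
#' constant, normalized so that a unitary event reaches `gmax` at its peak.
#' The NMDA conductance is additionally multiplied by the voltage-dependent
#' magnesium unblock factor [mg_block_factor()]; GABA-B is modelled as a
#' slow delayed bi-exponential conductance with a potassium reversal, a
#' reduced form of the metabotropic activation cascade.
#'
#' @param receptor `"AMPA"`, `"NMDA"`, `"GABAA"` or `"GABAB"`.
#' @param rise_tau,decay_tau Rise/decay time constants (ms);
#'   `decay_tau > rise_tau > 0`.
#' @param reversal Reversal potential (mV).
#' @param gmax Peak conductance of a unitary event (uS).
#' @export
synapse_kinetics <- function(receptor = c("AMPA", "NMDA", "GABAA", "GABAB"),
                             rise_tau = NULL, decay_tau = NULL,
                             reversal = NULL, gmax = 1e-3) {
  receptor <- match.arg(receptor)
  def <- switch(receptor,
    AMPA  = list(rise = 0.5, decay = 3,   rev = 0),
    NMDA  = list(rise = 5,   decay = 100, rev = 0),
    GABAA = list(rise = 0.5, decay = 7,   rev = -80),
    GABAB = list(rise = 50,  decay = 150, rev = -90))
  rise_tau <- rise_tau %||% def$rise
  decay_tau <- decay_tau %||% def$decay
  reversal <- reversal %||% def$rev
  if (!(decay_tau > rise_tau && rise_tau > 0))
    abort("`decay_tau` must exceed `rise_tau`, both positive")
  if (gmax < 0) abort("`gmax` must be non-negative")
  structure(list(receptor = receptor, rise_tau = rise_tau,
                 decay_tau = decay_tau, reversal = reversal, gmax = gmax),
            class = "synapse_kinetics")
}

#' Voltage-dependent magnesium unblock of the NMDA receptor
#'
#' Sigmoidal unblock \eqn{B(v) = 1/(1 + e^{-0.062 v} [Mg]/3.57)} at 1 mM
#' extracellular magnesium; monotonically increasing in voltage, half
#' unblocked at \eqn{v = \ln(1/3.57)/0.062 \approx -20.5} mV.
#'
#' @param v Membrane voltage (mV), finite.
#' @return Unblocked fraction in (0, 1).
#' @export
mg_block_factor <- function(v) {
  if (!all(is.finite(v))) abort("`v` must be finite (mV)")
  1 / (1 + exp(-0.062 * v) / 3.57)
}

#' Synaptic ratio configuration
#'
#' Peak-conductance ratios between slow and fast receptor components per
#' connection class, plus the relative inhibitory strengths of the
#' non-fast-spiking somatic/dendritic inputs.
#'
#' @param nmda_ampa_pyr NMDA-to-AMPA ratio on pyramidal targets (control
#'   1.25).
#' @param nmda_ampa_fs,nmda_ampa_rs NMDA-to-AMPA ratio on FS (0.5) and RS
#'   (0.8) targets.
#' @param nmda_ampa_is NMDA-to-AMPA ratio on the IS target, set to the
#'   smallest tested value at which the IS model fires during the standard
#'   stimulus.
#' @param gabab_gabaa GABA-B-to-GABA-A ratio (control 0.2).
#' @param rs_pyr_gabaa_scale RS-to-pyramidal GABA-A pair current relative to
#'   the FS-to-pyramidal pair (0.1).
#' @param is_pyr_gabaa_scale IS-to-pyramidal GABA-A pair current relative to
#'   the RS-to-pyramidal pair (0.1).
#' @export
ratio_config <- function(nmda_ampa_pyr = 1.25, nmda_ampa_fs = 0.5,
                         nmda_ampa_rs = 0.8, nmda_ampa_is = 1.5,
                         gabab_gabaa = 0.2, rs_pyr_gabaa_scale = 0.1,
                         is_pyr_gabaa_scale = 0.1) {
  vals <- c(nmda_ampa_pyr, nmda_ampa_fs, nmda_ampa_rs, nmda_ampa_is,
            gabab_gabaa, rs_pyr_gabaa_scale, is_pyr_gabaa_scale)
  if (any(vals < 0)) abort("all ratios must be non-negative")
  structure(list(nmda_ampa_pyr = nmda_ampa_pyr, nmda_ampa_fs = nmda_ampa_fs,
                 nmda_ampa_rs = nmda_ampa_rs, nmda_ampa_is = nmda_ampa_is,
                 gabab_gabaa = gabab_gabaa,
                 rs_pyr_gabaa_scale = rs_pyr_gabaa_scale,
                 is_pyr_gabaa_scale = is_pyr_gabaa_scale),
            class = "ratio_config")
}

#' A single synaptic contact
#'
#' @param pre Presynaptic neuron index (or `NA` for an externally driven
#'   synapse).
#' @param post Postsynaptic neuron index.
#' @param post_compartment Target compartment label.
#' @param receptors List of [synapse_kinetics()] whose `gmax` fields carry
#'   the weights; excitatory contacts mix AMPA+NMDA, inhibitory
#'   GABAA+GABAB.
#' @param latency Conduction plus synaptic delay (ms), positive.
#' @param is_autapse Logical.
#' @export
synapse_instance <- function(pre, post, post_compartment, receptors,
                             latency = 1.7, is_autapse = FALSE) {
  if (latency <= 0) abort("`latency` must be positive")
  recs <- vapply(receptors, function(r) r$receptor, character(1))
  exc <- all(recs %in% c("AMPA", "NMDA"))
  inh <- all(recs %in% c("GABAA", "GABAB"))
  if (!exc && !inh)
    abort("receptor mix must be excitatory (AMPA/NMDA) or inhibitory (GABAA/GABAB)")
  structure(list(pre = pre, post = post,
                 post_compartment = post_compartment, receptors = receptors,
                 latency = latency, is_autapse = isTRUE(is_autapse)),
            class = "synapse_instance")
}

# bi-exponential conductance of one receptor for activation times `act`
biexp_g <- function(kin, t, act) {
  tp <- kin$rise_tau * kin$decay_tau / (kin$decay_tau - kin$rise_tau) *
    log(kin$decay_tau / kin$rise_tau)
  norm <- 1 / (exp(-tp / kin$decay_tau) - exp(-tp / kin$rise_tau))
  g <- numeric(length(t))
  for (a in act) {
    d <- t - a
    on <- d > 0
    g[on] <- g[on] + kin$gmax * norm *
      (exp(-d[on] / kin$decay_tau) - exp(-d[on] / kin$rise_tau))
  }
  g
}

#' Closed-form synaptic current of one contact
#'
#' Evaluates the summed bi-exponential receptor conductances of a contact at
#' given times (superposition over presynaptic activation events) and
#' returns the current at a fixed postsynaptic voltage. This is the analytic
#' reference form; network simulations integrate the same kinetics as ODE
#' state variables.
#'
#' @param instance A [synapse_instance()].
#' @param spike_times Presynaptic spike times (ms); each activates the
#'   contact at `spike time + latency`.
#' @param v_post Postsynaptic voltage (mV).
#' @param t Evaluation times (ms).
#' @return Current (nA) at each `t`; positive = outward.
#' @export
synaptic_current <- function(instance, spike_times, v_post, t) {
  act <- spike_times + instance$latency
  i <- numeric(length(t))
  for (kin in instance$receptors) {
    g <- biexp_g(kin, t, act)
    if (kin$receptor == "NMDA") g <- g * mg_block_factor(v_post)
    i <- i + g * (v_post - kin$reversal)
  }
  i
}

# default synaptic weight table (uS, peak conductance of one contact).
# The pyramidal unitary AMPA weight reproduces a 0.1 mV somatic EPSP
# (see calibrate_unitary_ampa); interneuron excitatory weights and the
# GABA-A weights are network-level calibration constants.
default_syn_weights <- function() {
  list(
    ampa_pyr = 7.23e-5,     # unitary AMPA onto pyramidal basal dendrite
    ampa_fs = 1.23e-4,      # Pyr -> FS dendrite
    ampa_rs = 6.0e-4,       # Pyr -> RS dendrite
    ampa_is = 6.0e-4,       # Pyr -> IS dendrite
    gabaa_fs_pyr = 2.46e-4, # FS -> Pyr soma, per contact
    gabaa_fs_aut = 3.0e-3,  # FS somatic autapse
    gabaa_is_rs = 1.5e-3,   # IS -> RS dendrite
    stim_ampa = 3.67e-4,    # stimulus synapse onto proximal dendrite
    nmda_cap_mult = 6,      # NMDA saturation cap per connection, x total weight
    gabab_norm = 1.75       # normalization of the slow GABA-B component
  )
}

#' Calibrate the unitary pyramidal AMPA conductance
#'
#' Finds, by deterministic bisection, the peak conductance of a single AMPA
#' synapse on the basal dendrite that depolarizes the soma by the target
#' amplitude from rest.
#'
#' @param pyr A pyramidal `cell_model`.
#' @param target Peak somatic EPSP amplitude (mV).
#' @param tol Relative tolerance on the amplitude.
#' @param bounds Search bounds on the conductance (uS).
#' @return The calibrated conductance (uS).
#' @export
calibrate_unitary_ampa <- function(pyr, target = 0.1, tol = 0.02,
                                   bounds = c(1e-6, 1e-2)) {
  peak <- function(w) unitary_epsp_peak(pyr, w)
  lo <- bounds[1]; hi <- bounds[2]
  if (peak(hi) < target || peak(lo) > target)
    abort("bisection bounds do not bracket the target amplitude")
  for (i in 1:40) {
    mid <- sqrt(lo * hi)
    p <- peak(mid)
    if (abs(p - target) <= tol * target) return(mid)
    if (p < target) lo <- mid else hi <- mid
  }
  mid
}

#' Peak somatic EPSP of a single basal AMPA synapse
#'
#' @param pyr A pyramidal `cell_model`.
#' @param gmax Synaptic peak conductance (uS).
#' @return Peak somatic depolarization from rest (mV).
#' @export
unitary_epsp_peak <- function(pyr, gmax) {
  if (gmax == 0) return(0)
  sim <- new_sim(list(pyr))
  kin <- synapse_kinetics("AMPA")
  sim <- add_event_rows(sim, tibble(
    post = 1L, comp = "basal", receptor = "AMPA",
    tau_rise = kin$rise_tau, tau_decay = kin$decay_tau,
    erev = kin$reversal, weight = gmax, group = -1L, time = 500))
  res <- run_sim(sim, sim_config(duration = 600))
  v <- res$v[, 1]
  base <- v[max(which(res$time <= 500))]
  max(v[res$time > 500]) - base
}

#' Simulated voltage-clamp of a connected pair
#'
#' Clamps the postsynaptic soma, fires the presynaptic model once with a
#' brief strong current pulse, and records the clamp current. The standard
#' protocol uses holding potentials of -70 mV (AMPA-dominated inward
#' current) and +60 mV (NMDA-dominated outward current).
#'
#' @param pre_type,post_type Cell types of the connected pair.
#' @param hold Holding potential (mV).
#' @param ratios A [ratio_config()].
#' @param receptors Receptors present (disable one to isolate the other).
#' @param n_contacts Number of synaptic contacts (defaults to the
#'   connection-table count for the pair).
#' @param subtract_control Subtract an identical run with the synapse
#'   disabled, removing the holding current and any slow intrinsic drift at
#'   depolarized holds.
#' @return A tibble with `time` (ms, 0 = presynaptic spike) and `i` (nA).
#' @export
voltage_clamp_pair <- function(pre_type, post_type, hold,
                               ratios = ratio_config(),
                               receptors = c("AMPA", "NMDA"),
                               n_contacts = NULL,
                               subtract_control = TRUE) {
  wts <- default_syn_weights()
  pairs <- list(
    "PYR.PYR" = list(w = wts$ampa_pyr, ratio = ratios$nmda_ampa_pyr,
                     comp = "basal", n = 24),
    "PYR.FS" = list(w = wts$ampa_fs, ratio = ratios$nmda_ampa_fs,
                    comp = "dendrite", n = 12),
    "PYR.RS" = list(w = wts$ampa_rs, ratio = ratios$nmda_ampa_rs,
                    comp = "dendrite", n = 14),
    "PYR.IS" = list(w = wts$ampa_is, ratio = ratios$nmda_ampa_is,
                    comp = "dendrite", n = 7)
  )
  key <- paste(pre_type, post_type, sep = ".")
  if (!key %in% names(pairs)) abort(sprintf("unknown pair %s", key))
  pp <- pairs[[key]]
  n <- n_contacts %||% pp$n

  run_once <- function(wscale) {
    pre <- build_cell(pre_type)
    post <- build_cell(post_type)
    sim <- new_sim(list(pre, post))
    # one presynaptic spike via a brief strong pulse
    sim <- add_injection(sim, 1, "soma", 200, 203, 2)
    rows <- list()
    for (rec in receptors) {
      kin <- synapse_kinetics(rec)
      w <- if (rec == "AMPA") pp$w else pp$w * pp$ratio
      rows[[rec]] <- tibble(pre = 1L, post = 2L, comp = pp$comp,
                            receptor = rec, tau_rise = kin$rise_tau,
                            tau_decay = kin$decay_tau, erev = kin$reversal,
                            weight = w * n * wscale, latency = 1.7,
                            group = -1L)
    }
    sim <- add_synapse_rows(sim, dplyr::bind_rows(rows))
    # clamp the soma and the synaptic compartment so active dendritic
    # conductances cannot contaminate the measured synaptic current
    sim <- add_clamp(sim, 2, "soma", 0, 700, hold, g = 50)
    if (pp$comp != "soma") sim <- add_clamp(sim, 2, pp$comp, 0, 700, hold,
                                            g = 50)
    run_sim(sim, sim_config(duration = 700))
  }
  res <- run_once(1)
  pre_spike <- res$spikes$time[res$spikes$neuron == 1][1]
  if (is.na(pre_spike)) abort("presynaptic cell failed to fire")
  i <- res$clamp_i
  if (subtract_control) i <- i - run_once(0)$clamp_i
  tibble(time = seq(0, length.out = length(i), by = res$dt) - pre_spike,
         i = i)
}

#' NMDA-to-AMPA ratio across the standard clamp holds
#'
#' Runs the pair voltage clamp with only NMDA at +60 mV and only AMPA at
#' -70 mV, as in the standard recording protocol, and returns the ratio of
#' peak current amplitudes normalized by driving force (the quantity the
#' experimental standardization refers to), together with the ratio of
#' charge transfers of the same traces.
#'
#' @inheritParams voltage_clamp_pair
#' @param window Measurement window after the presynaptic spike (ms).
#' @return A list with `ratio` (normalized peak currents), `charge_ratio`,
#'   and the underlying peak currents `i_nmda`, `i_ampa` (nA).
#' @export
clamp_current_ratio <- function(pre_type, post_type,
                                ratios = ratio_config(), window = 400) {
  tr_n <- voltage_clamp_pair(pre_type, post_type, 60, ratios,
                             receptors = "NMDA")
  tr_a <- voltage_clamp_pair(pre_type, post_type, -70, ratios,
                             receptors = "AMPA")
  meas <- function(tr, drive) {
    keep <- tr$time > 0 & tr$time <= window
    base <- mean(tr$i[tr$time < 0 & tr$time > -50])
    dev <- tr$i[keep] - base
    dt <- tr$time[2] - tr$time[1]
    c(peak = max(abs(dev)) / abs(drive),
      charge = sum(abs(dev)) * dt / abs(drive))
  }
  n <- meas(tr_n, 60)
  a <- meas(tr_a, -70)
  list(ratio = n[["peak"]] / a[["peak"]],
       charge_ratio = n[["charge"]] / a[["charge"]],
       i_nmda = n[["peak"]] * 60, i_ampa = a[["peak"]] * 70)
}

#' Construct the FS somatic inhibitory autapse
#'
#' Each fast-spiking interneuron carries exactly one somatic GABA-A autapse
#' whose weight is a configuration constant. The source reports its evoked
#' transient as "0.35 mA", a dimensionally implausible value for a unitary
#' synapse (plausibly nA); the default weight is therefore a calibrated
#' conductance producing a large fast somatic IPSC rather than a literal
#' reading of that number.
#'
#' @param fs An FS `cell_model`.
#' @param neuron Index of the neuron in its network.
#' @param weight GABA-A peak conductance (uS).
#' @param gabab_gabaa GABA-B-to-GABA-A ratio (autapse uses GABA-A only when
#'   0).
#' @return A [synapse_instance()] with `is_autapse = TRUE`.
#' @export
fs_autapse <- function(fs, neuron = 1L,
                       weight = default_syn_weights()$gabaa_fs_aut,
                       gabab_gabaa = 0) {
  stopifnot(inherits(fs, "cell_model"))
  if (fs$cell_type != "FS") abort("autapse construction requires an FS cell")
  recs <- list(synapse_kinetics("GABAA", gmax = weight))
  if (gabab_gabaa > 0)
    recs <- c(recs, list(synapse_kinetics("GABAB",
                                          gmax = weight * gabab_gabaa)))
  synapse_instance(pre = neuron, post = neuron, post_compartment = "soma",
                   receptors = recs, latency = 1, is_autapse = TRUE)
}
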