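# Persistent-activity induction protocol: stimulus delivery, trial
# classification, probability maps over synaptic-ratio grids, and the
# NMDA-to-AMPA modulation experiments.

#' Stimulation protocol
#'
#' The standard induction stimulus: 120 excitatory synapses (AMPA + NMDA)
#' on the proximal apical dendrite of every pyramidal model, activated as a
#' fixed number of volleys at a fixed rate. The identical stimulus is
#' delivered to all pyramidal cells.
#'
#' @param n_synapses Number of stimulus synapses per pyramidal cell.
#' @param target Target compartment.
#' @param pulses Number of volleys.
#' @param rate Volley rate (Hz); 20 by default, 40 in the high-frequency
#'   variant.
#' @param onset Stimulus onset (ms).
#' @param weight Per-synapse AMPA peak conductance (uS); `NULL` uses the
#'   calibrated default.
#' @export
stimulus_spec <- function(n_synapses = 120L, target = "proximal",
                          pulses = 10L, rate = 20, onset = 200,
                          weight = NULL) {
  stopifnot(n_synapses >= 0, pulses >= 1, rate > 0, onset >= 0)
  structure(list(n_synapses = as.integer(n_synapses), target = target,
                 pulses = as.integer(pulses), rate = rate, onset = onset,
                 weight = weight),
            class = "stimulus_spec")
}

stimulus_end <- function(stim) {
  stim$onset + (stim$pulses - 1) * 1000 / stim$rate + 50
}

#' Persistent-activity classification criterion
#'
#' A trial counts as induced when at least `min_fraction` of the pyramidal
#' population fires at `min_rate` or more during the window
#' `[stimulus end + window_start, + window_start + window_length]`.
#'
#' @param window_start Start of the classification window after stimulus
#'   end (ms).
#' @param window_length Window length (ms).
#' @param min_rate Minimum firing rate (Hz).
#' @param min_fraction Minimum fraction of pyramidal cells at or above
#'   `min_rate`.
#' @export
induction_criterion <- function(window_start = 1000, window_length = 3000,
                                min_rate = 2, min_fraction = 0.75) {
  stopifnot(window_start > 0, window_length > 0, min_rate > 0,
            min_fraction > 0, min_fraction <= 1)
  structure(list(window_start = window_start,
                 window_length = window_length,
                 min_rate = min_rate, min_fraction = min_fraction),
            class = "induction_criterion")
}

#' Run one induction trial
#'
#' Builds (or takes) a network, delivers the standard stimulus plus
#' background noise, simulates, and classifies the pyramidal response.
#'
#' @param net A `pfc_network` or a [network_spec()]; a spec is built with
#'   `seed`, so that wiring latencies vary across trials.
#' @param stim A [stimulus_spec()].
#' @param crit An [induction_criterion()].
#' @param seed Trial seed (drives wiring and noise).
#' @param duration Total simulated time (ms); default runs to the end of
#'   the classification window.
#' @param record_syn Record summed pyramidal synaptic currents.
#' @return List with `induced`, `spikes` (a [spike_train_set()]),
#'   `stim_end`, `duration`, `syn` (currents tibble or `NULL`), and
#'   `pyr_rates`.
#' @export
run_induction_trial <- function(net, stim = stimulus_spec(),
                                crit = induction_criterion(), seed = 1L,
                                duration = NULL, record_syn = FALSE) {
  if (inherits(net, "network_spec")) {
    spec <- net
    spec$seed <- as.integer(seed)
    net <- build_network(spec)
  }
  stopifnot(inherits(net, "pfc_network"))
  stim_end <- stimulus_end(stim)
  duration <- duration %||%
    (stim_end + crit$window_start + crit$window_length)
  if (duration < stim_end + crit$window_start + crit$window_length)
    abort("`duration` must cover the classification window")

  sim <- new_sim(net$cells)
  sim <- add_synapse_rows(sim, net$synapses)

  # stimulus events: identical volley times on every pyramidal cell
  w <- stim$weight %||% net$spec$weights$stim_ampa
  if (stim$n_synapses > 0 && w > 0) {
    kinA <- synapse_kinetics("AMPA")
    kinN <- synapse_kinetics("NMDA")
    times <- stim$onset + (seq_len(stim$pulses) - 1) * 1000 / stim$rate
    pyr <- net$populations$neuron[net$populations$cell_type == "PYR"]
    ev <- tidyr::expand_grid(post = pyr, time = times)
    rows <- dplyr::bind_rows(
      dplyr::mutate(ev, comp = stim$target, receptor = "AMPA",
                    tau_rise = kinA$rise_tau, tau_decay = kinA$decay_tau,
                    erev = kinA$reversal, weight = w * stim$n_synapses,
                    group = 0L, cap_mult = 0),
      dplyr::mutate(ev, comp = stim$target, receptor = "NMDA",
                    tau_rise = kinN$rise_tau, tau_decay = kinN$decay_tau,
                    erev = kinN$reversal,
                    weight = w * net$spec$ratios$nmda_ampa_pyr *
                      stim$n_synapses,
                    group = 1L,
                    cap_mult = net$spec$weights$nmda_cap_mult %||% 0))
    sim <- add_event_rows(sim, rows)
  }

  nz <- background_noise_sources(net, seed = seed + 500013L,
                                 duration = duration)
  if (nrow(nz)) sim <- add_noise_rows(sim, nz)
  sim$noise_tau <- net$spec$noise$tau

  res <- run_sim(sim, sim_config(duration = duration,
                                 record_syn = record_syn))

  pyr <- net$populations$neuron[net$populations$cell_type == "PYR"]
  w0 <- stim_end + crit$window_start
  w1 <- w0 + crit$window_length
  counts <- vapply(pyr, function(n)
    sum(res$spikes$neuron == n & res$spikes$time >= w0 &
          res$spikes$time <= w1), numeric(1))
  rates <- counts / (crit$window_length / 1000)
  induced <- mean(rates >= crit$min_rate) >= crit$min_fraction

  spikes <- spike_train_set(res$spikes, neurons = net$populations,
                            duration = duration, seed = seed,
                            condition = net$spec$manipulation$mode)
  list(induced = induced, spikes = spikes, stim_end = stim_end,
       duration = duration, syn = res$syn, pyr_rates = rates,
       result = res)
}

#' Stimulus and persistent-activity analysis epochs
#'
#' The stimulus epoch runs from stimulus onset to stimulus end; the
#' persistent epoch from 500 ms after stimulus end (excluding the offset
#' transient) to the end of the trial.
#'
#' @param stim A [stimulus_spec()].
#' @param duration Trial duration (ms).
#' @return List with `stimulus` and `persistent` windows.
#' @export
analysis_epochs <- function(stim, duration) {
  se <- stimulus_end(stim)
  list(stimulus = c(stim$onset, se),
       persistent = c(se + 500, duration))
}

#' Induction probability over a synaptic-ratio grid
#'
#' Runs independently seeded trials at every point of an
#' (NMDA-to-AMPA x GABA-B-to-GABA-A) grid and returns the per-point
#' induction probability with Clopper-Pearson binomial intervals.
#'
#' @param spec A [network_spec()] template (its ratios are overwritten per
#'   grid point).
#' @param nmda_ampa,gabab_gabaa Grid values for the pyramidal
#'   NMDA-to-AMPA and the GABA-B-to-GABA-A ratio.
#' @param n_trials Trials per grid point.
#' @param base_seed Base seed; trial seeds are derived deterministically.
#' @param stim,crit Protocol settings.
#' @return An `induction_result`: tibble `grid` (`nmda_ampa`,
#'   `gabab_gabaa`, `probability`, `n_trials`, `ci_lo`, `ci_hi`) plus the
#'   per-trial outcomes in `trials`.
#' @export
induction_probability_grid <- function(spec,
                                       nmda_ampa = c(0.5, 1.25, 2),
                                       gabab_gabaa = c(0, 0.2, 0.4),
                                       n_trials = 10L, base_seed = 1L,
                                       stim = stimulus_spec(),
                                       crit = induction_criterion()) {
  stopifnot(length(nmda_ampa) >= 1, length(gabab_gabaa) >= 1, n_trials >= 1)
  grid <- tidyr::expand_grid(nmda_ampa = nmda_ampa,
                             gabab_gabaa = gabab_gabaa)
  trials <- list()
  for (gi in seq_len(nrow(grid))) {
    sp <- spec
    sp$ratios$nmda_ampa_pyr <- grid$nmda_ampa[gi]
    sp$ratios$gabab_gabaa <- grid$gabab_gabaa[gi]
    for (tr in seq_len(n_trials)) {
      seed <- base_seed + 1009L * gi + tr
      out <- run_induction_trial(sp, stim, crit, seed = seed)
      trials[[length(trials) + 1]] <- tibble(
        nmda_ampa = grid$nmda_ampa[gi], gabab_gabaa = grid$gabab_gabaa[gi],
        trial = tr, seed = seed, induced = out$induced,
        mean_rate = mean(out$pyr_rates))
    }
  }
  trials <- dplyr::bind_rows(trials)
  res <- trials |>
    dplyr::group_by(.data$nmda_ampa, .data$gabab_gabaa) |>
    dplyr::summarise(probability = mean(.data$induced),
                     n_trials = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(
      ci_lo = stats::qbeta(0.025, .data$probability * .data$n_trials,
                           .data$n_trials - .data$probability * .data$n_trials + 1),
      ci_hi = stats::qbeta(0.975, .data$probability * .data$n_trials + 1,
                           .data$n_trials - .data$probability * .data$n_trials))
  structure(list(grid = res, trials = trials,
                 manipulation = spec$manipulation$mode),
            class = "induction_result")
}

#' @export
print.induction_result <- function(x, ...) {
  cat(sprintf("<induction_result> %s network, %d grid points x %d trials; mean p = %.2f\n",
              x$manipulation, nrow(x$grid), x$grid$n_trials[1],
              mean(x$grid$probability)))
  invisible(x)
}

#' NMDA-to-AMPA modulation experiment
#'
#' Varies the NMDA-to-AMPA ratio on either the pyramidal or the FS targets
#' and reports, per ratio, the induction probability and the pyramidal
#' persistent-activity interspike intervals.
#'
#' @param spec A [network_spec()] template.
#' @param target_pop `"PYR"` or `"FS"`.
#' @param ratios Ratio values to test.
#' @param n_trials Trials per ratio.
#' @param base_seed Base seed.
#' @param stim,crit Protocol settings.
#' @return A tibble: `ratio`, `probability`, `mean_isi` (population mean
#'   pyramidal ISI in the persistent epoch, averaged over induced trials).
#' @export
nmda_modulation_experiment <- function(spec, target_pop = c("PYR", "FS"),
                                       ratios = c(0.5, 1.25, 2),
                                       n_trials = 5L, base_seed = 1L,
                                       stim = stimulus_spec(),
                                       crit = induction_criterion()) {
  target_pop <- match.arg(target_pop)
  if (any(ratios < 0)) abort("ratios must be non-negative")
  out <- list()
  for (ri in seq_along(ratios)) {
    sp <- spec
    if (target_pop == "PYR") sp$ratios$nmda_ampa_pyr <- ratios[ri]
    else sp$ratios$nmda_ampa_fs <- ratios[ri]
    induced <- logical(n_trials)
    isis <- rep(NA_real_, n_trials)
    for (tr in seq_len(n_trials)) {
      seed <- base_seed + 2003L * ri + tr
      res <- run_induction_trial(sp, stim, crit, seed = seed)
      induced[tr] <- res$induced
      ep <- analysis_epochs(stim, res$duration)$persistent
      pyr <- res$spikes$neurons$neuron[res$spikes$neurons$cell_type == "PYR"]
      if (res$induced)
        isis[tr] <- population_mean_isi(res$spikes, ep, neurons = pyr)
    }
    out[[ri]] <- tibble(target = target_pop, ratio = ratios[ri],
                        probability = mean(induced),
                        mean_isi = mean(isis, na.rm = TRUE),
                        n_trials = n_trials)
  }
  dplyr::bind_rows(out)
}

#' Calibrate the IS NMDA-to-AMPA ratio
#'
#' The irregular-spiking interneuron has no recorded NMDA-to-AMPA ratio;
#' following the construction procedure, the ratio is set to the smallest
#' candidate at which the IS model fires action potentials during the
#' standard stimulus.
#'
#' @param spec A [network_spec()].
#' @param candidates Ratio values tested in increasing order.
#' @param stim A [stimulus_spec()].
#' @param seed Trial seed.
#' @return The selected ratio (smallest candidate that makes the IS model
#'   fire during the stimulus), or `NA` if none does.
#' @export
calibrate_is_nmda_ratio <- function(spec, candidates = seq(0.5, 3, by = 0.5),
                                    stim = stimulus_spec(), seed = 1L) {
  candidates <- sort(candidates)
  se <- stimulus_end(stim)
  for (r in candidates) {
    sp <- spec
    sp$ratios$nmda_ampa_is <- r
    sp$seed <- as.integer(seed)
    net <- build_network(sp)
    is_id <- net$populations$neuron[net$populations$cell_type == "IS"]
    if (!length(is_id)) abort("network has no IS model")
    sim <- new_sim(net$cells)
    sim <- add_synapse_rows(sim, net$synapses)
    w <- stim$weight %||% sp$weights$stim_ampa
    kinA <- synapse_kinetics("AMPA"); kinN <- synapse_kinetics("NMDA")
    times <- stim$onset + (seq_len(stim$pulses) - 1) * 1000 / stim$rate
    pyr <- net$populations$neuron[net$populations$cell_type == "PYR"]
    ev <- tidyr::expand_grid(post = pyr, time = times)
    rows <- dplyr::bind_rows(
      dplyr::mutate(ev, comp = stim$target, receptor = "AMPA",
                    tau_rise = kinA$rise_tau, tau_decay = kinA$decay_tau,
                    erev = 0, weight = w * stim$n_synapses, group = -1L,
                    cap_mult = 0),
      dplyr::mutate(ev, comp = stim$target, receptor = "NMDA",
                    tau_rise = kinN$rise_tau, tau_decay = kinN$decay_tau,
                    erev = 0,
                    weight = w * sp$ratios$nmda_ampa_pyr * stim$n_synapses,
                    group = -1L,
                    cap_mult = sp$weights$nmda_cap_mult %||% 0))
    sim <- add_event_rows(sim, rows)
    res <- run_sim(sim, sim_config(duration = se + 100))
    n_is <- sum(res$spikes$neuron == is_id &
                  res$spikes$time >= stim$onset & res$spikes$time <= se)
    if (n_is > 0) return(r)
  }
  NA_real_
}
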