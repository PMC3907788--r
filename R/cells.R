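# Construction of the four validated cell types and their single-cell
# validation protocols (input resistance, current steps, f-I points,
# irregular-spiking discharge classification).

channel_reversal <- function(kind, rev) {
  switch(kind,
    Na = rev$na,
    Kdr = , KA = , Kslow = , KD = , fAHP = rev$k,
    CaN = , CaT = rev$ca,
    H = rev$h,
    abort(sprintf("unknown channel kind '%s'", kind))
  )
}

# build the gate list of a channel for one cell type, applying per-type
# kinetic overrides
make_gates <- function(kind, kin_over) {
  base <- base_kinetics()[[kind]]
  over <- kin_over[[kind]]
  gates <- vector("list", length(base))
  for (i in seq_along(base)) {
    par <- base[[i]]
    if (!is.null(over) && length(over) >= i && !is.null(over[[i]]))
      par <- modifyList(par, over[[i]])
    gates[[i]] <- gating_scheme(role = par$role, vh = par$vh, k = par$k,
                                exponent = par$exponent,
                                tau_min = par$tau_min, tau_amp = par$tau_amp,
                                vt = par$vt, ks1 = par$ks1, ks2 = par$ks2)
  }
  gates
}

#' Build one of the four validated cell models
#'
#' Assembles a branched compartmental model with passive properties, the
#' published per-compartment channel densities, the calibrated default
#' geometry and gating kinetics, and a somatic calcium pool.
#'
#' @param cell_type `"PYR"`, `"FS"`, `"RS"` or `"IS"`.
#' @param overrides Named list of parameter overrides merged strictly into
#'   the defaults of [default_params()] for this cell type (unknown names
#'   are an error). Example:
#'   `list(passive = list(rm = 12))`.
#' @return A `cell_model` object.
#' @export
build_cell <- function(cell_type = c("PYR", "FS", "RS", "IS"),
                       overrides = list()) {
  cell_type <- match.arg(cell_type)
  all_par <- default_params()
  kin_over <- overrides$kinetics
  overrides$kinetics <- NULL
  kbc_over <- overrides$kinetics_by_comp
  overrides$kinetics_by_comp <- NULL
  par <- merge_strict(all_par[[cell_type]], overrides,
                      paste0(cell_type, "$"))
  # kinetic overrides are positional per gate and may introduce new kinds
  if (!is.null(kin_over)) {
    if (!all(names(kin_over) %in% names(base_kinetics())))
      abort("kinetics override names an unknown mechanism")
    for (kind in names(kin_over)) {
      cur <- par$kinetics[[kind]] %||% list()
      for (i in seq_along(kin_over[[kind]])) {
        if (is.null(kin_over[[kind]][[i]])) next
        prev <- if (length(cur) >= i && !is.null(cur[[i]])) cur[[i]] else list()
        cur[[i]] <- modifyList(prev, kin_over[[kind]][[i]])
      }
      par$kinetics[[kind]] <- cur
    }
  }
  if (!is.null(kbc_over)) {
    if (!all(names(kbc_over) %in% names(par$geometry)))
      abort("kinetics_by_comp names an unknown compartment")
    for (cn in names(kbc_over)) {
      cur <- par$kinetics_by_comp[[cn]] %||% list()
      for (kd in names(kbc_over[[cn]])) cur[[kd]] <- kbc_over[[cn]][[kd]]
      par$kinetics_by_comp[[cn]] <- cur
    }
  }
  rev <- all_par$reversals

  geom <- par$geometry
  compartments <- data.frame(
    name = names(geom),
    length = vapply(geom, function(g) g$length, numeric(1)),
    diameter = vapply(geom, function(g) g$diameter, numeric(1)),
    parent = vapply(geom, function(g)
      if (is.null(g$parent) || is.na(g$parent)) NA_character_
      else g$parent, character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )

  channels <- list()
  for (cn in names(par$densities)) {
    kinds <- par$densities[[cn]]
    kinds <- kinds[vapply(kinds, function(g) g > 0, logical(1))]
    # compartment-specific kinetic overrides stack on the cell-type ones
    kin <- par$kinetics
    extra <- par$kinetics_by_comp[[cn]]
    if (!is.null(extra)) {
      for (kd in names(extra)) {
        cur <- kin[[kd]] %||% list()
        for (i in seq_along(extra[[kd]])) {
          if (is.null(extra[[kd]][[i]])) next
          prev <- if (length(cur) >= i && !is.null(cur[[i]])) cur[[i]]
                  else list()
          cur[[i]] <- modifyList(prev, extra[[kd]][[i]])
        }
        kin[[kd]] <- cur
      }
    }
    channels[[cn]] <- lapply(names(kinds), function(kind)
      channel_spec(kind = kind, gbar = kinds[[kind]],
                   reversal = channel_reversal(kind, rev),
                   gates = make_gates(kind, kin)))
  }
  calcium <- setNames(
    lapply(par$calcium_comps, function(cn)
      calcium_pool(concentration = par$calcium$rest,
                   rest_concentration = par$calcium$rest,
                   decay_tau = par$calcium$tau,
                   influx_factor = par$calcium$influx)),
    par$calcium_comps
  )
  structure(list(
    cell_type = cell_type,
    compartments = compartments,
    passive = par$passive,
    channels = channels,
    calcium = calcium,
    v_rest_target = par$v_rest_target,
    v_init = par$v_rest_target
  ), class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  nch <- sum(lengths(x$channels))
  cat(sprintf("<cell_model> %s: %d compartments, %d conductances, rest target %g mV\n",
              x$cell_type, nrow(x$compartments), nch, x$v_rest_target))
  invisible(x)
}

#' Total membrane area of a cell model
#' @param cell A `cell_model`.
#' @return Area in cm2.
#' @export
cell_area <- function(cell) {
  sum(comp_area_cm2(cell$compartments$length, cell$compartments$diameter))
}

# let the model settle to its resting state; returns rest voltage (soma)
settle_cell <- function(cell, duration = 1000, dt = 0.025) {
  sim <- new_sim(list(cell))
  res <- run_sim(sim, sim_config(dt = dt, duration = duration,
                                 record_stride = 40L))
  v <- res$v[, 1]
  list(v_rest = v[length(v)], trace = res)
}

#' Measure input resistance with a small somatic current step
#'
#' Applies a small (hyperpolarizing by default) somatic current step from
#' rest and returns the steady-state voltage deflection divided by the
#' current.
#'
#' @param cell A `cell_model`.
#' @param i_step Step amplitude (nA); must remain subthreshold.
#' @return Input resistance (MOhm).
#' @export
measure_input_resistance <- function(cell, i_step = -0.01) {
  stopifnot(i_step != 0)
  settle <- 1500
  step_dur <- 1500
  sim <- new_sim(list(cell))
  sim <- add_injection(sim, 1, "soma", settle, settle + step_dur, i_step)
  res <- run_sim(sim, sim_config(duration = settle + step_dur,
                                 record_stride = 20L))
  v <- res$v[, 1]
  t <- res$time
  if (nrow(res$spikes) > 0)
    abort("current step elicited a spike; use a smaller `i_step`")
  v_pre <- v[max(which(t <= settle))]
  v_end <- v[length(v)]
  (v_end - v_pre) / i_step  # mV / nA = MOhm
}

#' Somatic current-step response
#'
#' Injects a current step at the soma from rest and returns detected spike
#' times and the somatic voltage trace.
#'
#' @param cell A `cell_model`.
#' @param amplitude Step amplitude (nA).
#' @param duration Step duration (ms).
#' @param settle Pre-step settling time (ms).
#' @return List with `spike_times` (ms, relative to step onset), `trace`
#'   (tibble `time`, `v`, time relative to step onset), `threshold` (voltage
#'   at the peak-acceleration foot of the first spike, mV, or `NA`).
#' @export
current_step_response <- function(cell, amplitude, duration = 500,
                                  settle = 1000) {
  stopifnot(duration > 0)
  sim <- new_sim(list(cell))
  sim <- add_injection(sim, 1, "soma", settle, settle + duration, amplitude)
  res <- run_sim(sim, sim_config(duration = settle + duration + 100))
  v <- res$v[, 1]
  t <- res$time - settle
  sp <- res$spikes$time - settle
  sp <- sp[sp >= 0 & sp <= duration]
  thr <- NA_real_
  if (length(sp)) {
    # voltage at which dV/dt first exceeds 10 mV/ms before the first spike
    idx <- which(t > 0 & t <= sp[1] + 1)
    dv <- diff(v[idx]) / diff(t[idx])
    hit <- which(dv > 10)
    if (length(hit)) thr <- v[idx[hit[1]]]
  }
  list(spike_times = sp,
       trace = tibble(time = t, v = v),
       threshold = thr,
       n_spikes = length(sp))
}

#' Firing rate at one current amplitude
#'
#' Spike count over a 500 ms somatic step divided by the step duration.
#'
#' @param cell A `cell_model`.
#' @param amplitude Step amplitude (nA), non-negative.
#' @param duration Step duration (ms).
#' @return Firing rate (Hz).
#' @export
f_i_point <- function(cell, amplitude, duration = 500) {
  stopifnot(amplitude >= 0)
  resp <- current_step_response(cell, amplitude, duration)
  resp$n_spikes / (duration / 1000)
}

#' Classify the irregular-spiking discharge signature
#'
#' The IS phenotype is an initial cluster of action potentials followed by
#' irregular firing. The cluster is counted as the spikes preceding the
#' first interspike interval longer than twice the first interval; the
#' irregularity flag is the coefficient of variation of the post-cluster
#' intervals exceeding 0.2.
#'
#' @param cell A `cell_model` (IS), or `NULL` when `spike_times` is given.
#' @param amplitude Step amplitude (nA).
#' @param spike_times Optional explicit spike-time vector, bypassing the
#'   simulation (used to classify synthetic trains).
#' @return List with `cluster_size`, `irregular` (logical flag) and
#'   `conclusive`.
#' @export
is_discharge_signature <- function(cell = NULL, amplitude = 0.05,
                                   spike_times = NULL) {
  if (is.null(spike_times)) {
    stopifnot(inherits(cell, "cell_model"))
    if (cell$cell_type != "IS")
      abort("the discharge classifier applies to the IS cell type")
    spike_times <- current_step_response(cell, amplitude,
                                         duration = 1000)$spike_times
  }
  if (length(spike_times) < 4)
    return(list(cluster_size = length(spike_times), irregular = NA,
                conclusive = FALSE))
  isi <- diff(spike_times)
  brk <- which(isi > 2 * isi[1])
  cluster <- if (length(brk)) brk[1] else length(spike_times)
  # without a cluster break the whole train is judged for regularity
  post <- if (length(brk)) isi[seq_along(isi) >= cluster] else isi
  if (length(post) < 3)
    return(list(cluster_size = cluster, irregular = NA, conclusive = FALSE))
  cv <- sd(post) / mean(post)
  list(cluster_size = cluster, irregular = cv > 0.2, conclusive = TRUE,
       post_cluster_cv = cv)
}
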