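# Simulation assembly and execution: converts cell models, synapse tables and
# stimulation programs into the flat arrays consumed by the compiled
# integrator, and wraps its output in tidy result containers.

#' Simulation configuration
#'
#' @param dt Integration step (ms). The integrator is an unconditionally
#'   stable staggered implicit scheme; 0.025 ms is the standard resolution.
#' @param duration Total simulated time (ms).
#' @param record_stride Store every n-th sample of the recorded traces.
#' @param spike_threshold Somatic threshold-crossing voltage (mV) for spike
#'   detection.
#' @param spike_lockout Refractory lockout between detected spikes (ms).
#' @param record_syn Record the per-receptor summed synaptic currents of the
#'   pyramidal population.
#' @export
sim_config <- function(dt = 0.025, duration = 1000, record_stride = 1L,
                       spike_threshold = 0, spike_lockout = 2,
                       record_syn = FALSE) {
  stopifnot(dt > 0, duration > 0, record_stride >= 1)
  structure(list(dt = dt, duration = duration,
                 record_stride = as.integer(record_stride),
                 spike_threshold = spike_threshold,
                 spike_lockout = spike_lockout,
                 record_syn = isTRUE(record_syn)),
            class = "sim_config")
}

# internal: a simulation problem under assembly
new_sim <- function(cells) {
  stopifnot(length(cells) >= 1,
            all(vapply(cells, inherits, logical(1), "cell_model")))
  structure(list(
    cells = cells,
    synapses = tibble(pre = integer(), post = integer(), comp = character(),
                      receptor = character(), tau_rise = numeric(),
                      tau_decay = numeric(), erev = numeric(),
                      weight = numeric(), latency = numeric(),
                      group = integer(), cap_mult = numeric()),
    events = tibble(post = integer(), comp = character(),
                    receptor = character(), tau_rise = numeric(),
                    tau_decay = numeric(), erev = numeric(),
                    weight = numeric(), group = integer(), time = numeric(),
                    cap_mult = numeric()),
    noise = tibble(cell = integer(), comp = character(), time = numeric(),
                   amp = numeric()),
    noise_tau = 2,
    injections = tibble(cell = integer(), comp = character(), t0 = numeric(),
                        t1 = numeric(), amp = numeric()),
    clamps = tibble(cell = integer(), comp = character(), t0 = numeric(),
                    t1 = numeric(), v = numeric(), g = numeric())
  ), class = "sim_problem")
}

add_injection <- function(sim, cell, comp, t0, t1, amp) {
  sim$injections <- dplyr::bind_rows(
    sim$injections, tibble(cell = as.integer(cell), comp = comp,
                           t0 = t0, t1 = t1, amp = amp))
  sim
}

add_clamp <- function(sim, cell, comp, t0, t1, v, g = 10) {
  sim$clamps <- dplyr::bind_rows(
    sim$clamps, tibble(cell = as.integer(cell), comp = comp, t0 = t0,
                       t1 = t1, v = v, g = g))
  sim
}

# synapses: `rows` with pre (0 = external/none), post, comp, receptor,
# tau_rise, tau_decay, erev, weight, latency, group
add_synapse_rows <- function(sim, rows) {
  sim$synapses <- dplyr::bind_rows(sim$synapses, rows)
  sim
}

add_event_rows <- function(sim, rows) {
  sim$events <- dplyr::bind_rows(sim$events, rows)
  sim
}

add_noise_rows <- function(sim, rows) {
  sim$noise <- dplyr::bind_rows(sim$noise, rows)
  sim
}

# geometry helpers -----------------------------------------------------------

comp_area_cm2 <- function(length_um, diameter_um) {
  pi * length_um * diameter_um * 1e-8
}

# flatten one cell's compartments; returns per-comp tibble
cell_comp_table <- function(cell) {
  g <- cell$compartments
  area <- comp_area_cm2(g$length, g$diameter)
  tibble(name = g$name, length = g$length, diameter = g$diameter,
         parent = g$parent, area = area)
}

# compile a list of cells (+ assembly tables) to engine arrays
compile_sim <- function(sim, cfg) {
  cells <- sim$cells
  ncell <- length(cells)

  comp_tabs <- lapply(cells, cell_comp_table)
  ncomps <- vapply(comp_tabs, nrow, integer(1))
  offset <- cumsum(c(0L, ncomps))[seq_len(ncell)]

  parent <- integer(0); cellid <- integer(0)
  c_nf <- numeric(0); g_leak <- numeric(0); e_leak <- numeric(0)
  g_par <- numeric(0); v0 <- numeric(0)
  comp_key <- character(0)

  for (i in seq_len(ncell)) {
    cell <- cells[[i]]
    ct <- comp_tabs[[i]]
    p <- cell$passive
    idx_of <- setNames(seq_len(nrow(ct)), ct$name)
    par_loc <- ifelse(is.na(ct$parent), -1L, idx_of[ct$parent] - 1L)
    if (any(!is.na(ct$parent) & par_loc >= seq_len(nrow(ct)) - 1L))
      abort("compartments must be ordered parents-first")
    parent <- c(parent, ifelse(par_loc < 0, -1L, par_loc + offset[i]))
    cellid <- c(cellid, rep(i - 1L, nrow(ct)))
    c_nf <- c(c_nf, p$cm * ct$area * 1e3)
    g_leak <- c(g_leak, 1000 * ct$area / p$rm)
    e_leak <- c(e_leak, rep(p$e_leak, nrow(ct)))
    v0 <- c(v0, rep(cell$v_init %||% p$e_leak, nrow(ct)))
    # axial conductance child->parent
    half_r <- function(j) {
      p$ra * (ct$length[j] / 2 * 1e-4) / (pi * (ct$diameter[j] / 2 * 1e-4)^2)
    }
    gp <- vapply(seq_len(nrow(ct)), function(j) {
      if (is.na(ct$parent[j])) return(0)
      1e6 / (half_r(j) + half_r(idx_of[[ct$parent[j]]]))
    }, numeric(1))
    g_par <- c(g_par, gp)
    comp_key <- c(comp_key, paste0(i, ".", ct$name))
  }
  comp_index <- setNames(seq_along(comp_key) - 1L, comp_key)

  # channels + gates + schemes
  sch_sig <- character(0); sch_list <- list()
  gate_scheme <- integer(0); gate_comp <- integer(0); gate_exp <- integer(0)
  ch_comp <- integer(0); ch_g <- numeric(0); ch_erev <- numeric(0)
  ch_cadep <- integer(0); ch_cakd <- numeric(0); ch_isca <- integer(0)
  ch_gbeg <- integer(0); ch_gcnt <- integer(0)

  scheme_id <- function(par) {
    sig <- paste(unlist(par[c("vh", "k", "tau_min", "tau_amp", "vt",
                              "ks1", "ks2")]), collapse = "|")
    hit <- match(sig, sch_sig)
    if (!is.na(hit)) return(hit - 1L)
    sch_sig <<- c(sch_sig, sig)
    sch_list[[length(sch_list) + 1L]] <<- par[c("vh", "k", "tau_min",
                                                "tau_amp", "vt", "ks1", "ks2")]
    length(sch_list) - 1L
  }

  ca_comp <- integer(0); ca_rest <- numeric(0); ca_tau <- numeric(0)
  ca_influx <- numeric(0); ca_area <- numeric(0)

  for (i in seq_len(ncell)) {
    cell <- cells[[i]]
    ct <- comp_tabs[[i]]
    for (cn in names(cell$channels)) {
      gidx <- comp_index[[paste0(i, ".", cn)]]
      area <- ct$area[match(cn, ct$name)]
      for (sp in cell$channels[[cn]]) {
        ch_comp <- c(ch_comp, gidx)
        ch_g <- c(ch_g, sp$gbar * area * 1e6)
        ch_erev <- c(ch_erev, sp$reversal)
        ch_cadep <- c(ch_cadep, as.integer(sp$calcium_dependent))
        ch_cakd <- c(ch_cakd, sp$ca_kd)
        ch_isca <- c(ch_isca, as.integer(sp$kind %in% c("CaN", "CaT")))
        ch_gbeg <- c(ch_gbeg, length(gate_scheme))
        ch_gcnt <- c(ch_gcnt, length(sp$gates))
        for (gt in sp$gates) {
          gate_scheme <- c(gate_scheme, scheme_id(gt$params))
          gate_comp <- c(gate_comp, gidx)
          gate_exp <- c(gate_exp, gt$exponent)
        }
      }
    }
    for (cn in names(cell$calcium)) {
      pool <- cell$calcium[[cn]]
      ca_comp <- c(ca_comp, comp_index[[paste0(i, ".", cn)]])
      ca_rest <- c(ca_rest, pool$rest_concentration)
      ca_tau <- c(ca_tau, pool$decay_tau)
      ca_influx <- c(ca_influx, pool$influx_factor)
      ca_area <- c(ca_area, ct$area[match(cn, ct$name)])
    }
  }

  dt <- cfg$dt
  nsteps <- as.integer(round(cfg$duration / dt))

  # synapse banks: deduplicate by (comp, kinetics, group)
  syn <- sim$synapses
  ev <- sim$events
  all_syn <- dplyr::bind_rows(
    dplyr::mutate(syn, .src = "syn", time = NA_real_),
    dplyr::mutate(ev, pre = 0L, latency = NA_real_, .src = "ev")
  )
  if (nrow(all_syn)) {
    if (is.null(all_syn$cap_mult)) all_syn$cap_mult <- 0
    all_syn$cap_mult[is.na(all_syn$cap_mult)] <- 0
    gcomp <- comp_index[paste0(all_syn$post, ".", all_syn$comp)]
    if (anyNA(gcomp)) abort("synapse targets a nonexistent compartment")
    # saturating receptors get per-source banks so the cap is per connection
    srckey <- ifelse(all_syn$cap_mult > 0,
                     paste0(all_syn$pre, "/", all_syn$.src), "")
    key <- paste(gcomp, all_syn$receptor, all_syn$tau_rise,
                 all_syn$tau_decay, all_syn$erev, all_syn$group, srckey,
                 sep = "|")
    bank_of <- match(key, unique(key)) - 1L
    first <- !duplicated(key)
    bank_comp <- gcomp[first]
    bank_tr <- all_syn$tau_rise[first]
    bank_td <- all_syn$tau_decay[first]
    bank_erev <- all_syn$erev[first]
    bank_nmda <- as.integer(all_syn$receptor[first] == "NMDA")
    bank_group <- as.integer(all_syn$group[first])
    # cap: synapse banks saturate at cap_mult * total member weight;
    # event banks at cap_mult * one volley's compound weight
    fb <- factor(bank_of, levels = 0:max(bank_of))
    wsum <- as.numeric(tapply(ifelse(all_syn$.src == "syn",
                                     all_syn$weight, 0), fb, sum,
                              default = 0))
    wmax <- as.numeric(tapply(ifelse(all_syn$.src == "ev",
                                     all_syn$weight, 0), fb, max,
                              default = 0))
    bank_cap <- all_syn$cap_mult[first] * pmax(wsum, wmax, na.rm = TRUE)
    bank_cap[is.na(bank_cap)] <- 0
  } else {
    bank_of <- integer(0)
    bank_comp <- integer(0); bank_tr <- numeric(0); bank_td <- numeric(0)
    bank_erev <- numeric(0); bank_nmda <- integer(0); bank_group <- integer(0)
    bank_cap <- numeric(0)
  }

  is_syn <- if (nrow(all_syn)) all_syn$.src == "syn" else logical(0)
  conn <- all_syn[is_syn & all_syn$pre > 0L, , drop = FALSE]
  conn_bank <- bank_of[is_syn & all_syn$pre > 0L]
  out_delay <- pmax(1L, as.integer(round(conn$latency / dt)))

  evs <- all_syn[!is_syn, , drop = FALSE]
  ev_bank <- bank_of[!is_syn]
  ev_step <- as.integer(floor(evs$time / dt))
  ord <- order(ev_step)

  ckey <- function(cell, comp) {
    if (!length(cell)) return(integer(0))
    idx <- comp_index[paste0(cell, ".", comp)]
    if (anyNA(idx)) abort("reference to a nonexistent compartment")
    as.integer(idx)
  }

  nz <- sim$noise
  noise_step <- as.integer(floor(nz$time / dt))
  nord <- order(noise_step)
  noise_comp <- ckey(nz$cell, nz$comp)

  inj <- sim$injections
  cl <- sim$clamps

  soma_comp <- vapply(seq_len(ncell), function(i)
    comp_index[[paste0(i, ".soma")]], integer(1))

  list(
    net = list(
      parent = as.integer(parent), cell = as.integer(cellid),
      c_nf = c_nf, g_leak = g_leak, e_leak = e_leak, g_par = g_par, v0 = v0,
      schemes = sch_list,
      gate_scheme = as.integer(gate_scheme),
      gate_comp = as.integer(gate_comp),
      gate_exp = as.integer(gate_exp),
      ch_comp = as.integer(ch_comp), ch_g = ch_g, ch_erev = ch_erev,
      ch_cadep = as.integer(ch_cadep), ch_cakd = ch_cakd,
      ch_isca = as.integer(ch_isca),
      ch_gbeg = as.integer(ch_gbeg), ch_gcnt = as.integer(ch_gcnt),
      ca_comp = as.integer(ca_comp), ca_rest = ca_rest, ca_tau = ca_tau,
      ca_influx = ca_influx, ca_area = ca_area,
      bank_comp = as.integer(bank_comp), bank_tau_rise = bank_tr,
      bank_tau_decay = bank_td, bank_erev = bank_erev,
      bank_nmda = as.integer(bank_nmda), bank_group = as.integer(bank_group),
      bank_cap = bank_cap,
      out_src = as.integer(conn$pre - 1L), out_bank = as.integer(conn_bank),
      out_delay = out_delay, out_w = conn$weight,
      ev_step = as.integer(ev_step[ord]),
      ev_bank = as.integer(ev_bank[ord]), ev_w = evs$weight[ord],
      noise_step = as.integer(noise_step[nord]),
      noise_comp = as.integer(noise_comp[nord]),
      noise_amp = nz$amp[nord], noise_tau = sim$noise_tau,
      inj_comp = ckey(inj$cell, inj$comp),
      inj_t0 = inj$t0, inj_t1 = inj$t1, inj_amp = inj$amp,
      clamp_comp = ckey(cl$cell, cl$comp),
      clamp_t0 = cl$t0, clamp_t1 = cl$t1, clamp_v = cl$v, clamp_g = cl$g
    ),
    comp_key = comp_key,
    soma_comp = soma_comp,
    nsteps = nsteps
  )
}

#' Run a compiled simulation problem
#'
#' Low-level entry point used by the single-cell protocols and the network
#' protocols; most users call [current_step_response()],
#' [run_induction_trial()] and friends instead.
#'
#' @param sim A simulation problem (internal).
#' @param cfg A [sim_config()].
#' @param record Character vector of compartment keys (`"<cell>.<comp>"`) to
#'   record, or `"somas"` (default) for every somatic compartment.
#' @return A `sim_result` with elements `trace` (wide voltage matrix plus
#'   `time`), `spikes` (tibble of `neuron`, `time`), `syn` (per-receptor
#'   summed synaptic currents, nA) and `clamp_i`.
#' @keywords internal
run_sim <- function(sim, cfg, record = "somas") {
  comp <- compile_sim(sim, cfg)
  rec <- if (identical(record, "somas")) comp$soma_comp
         else if (identical(record, "all")) seq_along(comp$comp_key) - 1L
         else {
           idx <- match(record, comp$comp_key) - 1L
           if (anyNA(idx)) abort("unknown compartment in `record`")
           idx
         }
  rec_names <- comp$comp_key[rec + 1L]
  ecfg <- list(dt = cfg$dt, nsteps = comp$nsteps,
               record_comp = as.integer(rec),
               record_stride = cfg$record_stride,
               spike_threshold = cfg$spike_threshold,
               spike_lockout = cfg$spike_lockout,
               spike_comp = as.integer(comp$soma_comp),
               record_syn = cfg$record_syn)
  out <- .engine_run(comp$net, ecfg)
  v <- out$v
  colnames(v) <- rec_names
  spikes <- tibble(neuron = out$spike_neuron + 1L, time = out$spike_time)
  spikes <- spikes[order(spikes$neuron, spikes$time), ]
  syn <- NULL
  if (cfg$record_syn) {
    syn <- tibble(time = out$time,
                  ampa = out$syn[, 1], nmda = out$syn[, 2],
                  gabaa = out$syn[, 3], gabab = out$syn[, 4])
  }
  structure(list(time = out$time, v = v, spikes = spikes, syn = syn,
                 clamp_i = out$clamp_i, dt = cfg$dt,
                 duration = cfg$duration, cfg = cfg),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %g ms at dt = %g ms; %d spikes across %d neurons\n",
              x$duration, x$dt, nrow(x$spikes),
              length(unique(x$spikes$neuron))))
  invisible(x)
}

#' Detect spikes in a voltage trace
#'
#' Upward threshold crossings separated by at least the lockout, with the
#' crossing time linearly interpolated between samples.
#'
#' @param v Voltage samples (mV) on a uniform time base.
#' @param time Sample times (ms), same length as `v`.
#' @param threshold Crossing voltage (mV).
#' @param lockout Minimum separation between detected spikes (ms).
#' @return Numeric vector of spike times (ms).
#' @export
detect_spikes <- function(v, time, threshold = 0, lockout = 2) {
  stopifnot(length(v) == length(time), length(v) >= 2)
  up <- which(v[-length(v)] < threshold & v[-1] >= threshold)
  if (!length(up)) return(numeric(0))
  frac <- (threshold - v[up]) / (v[up + 1] - v[up])
  tcross <- time[up] + frac * (time[up + 1] - time[up])
  keep <- numeric(0)
  last <- -Inf
  for (tc in tcross) {
    if (tc - last >= lockout) {
      keep <- c(keep, tc)
      last <- tc
    }
  }
  keep
}

`%||%` <- function(a, b) if (is.null(a)) b else a
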