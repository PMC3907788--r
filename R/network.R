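# Microcircuit assembly: the 20-neuron control network (16 pyramidal, 2 FS,
# 1 RS, 1 IS) wired from the published connection table, plus the manipulated
# variants used in the knock-out, input-scaling, retargeting and
# role-reversal experiments.

#' Connection rules of the control microcircuit
#'
#' One row per connection class: source and target population, target
#' compartment, synaptic contacts per connected pair, and receptor class.
#' Latencies are drawn per contact from a Gaussian with mean 1.7 ms and
#' standard deviation 0.9 ms, truncated below at 0.1 ms.
#'
#' @return A tibble of connection rules.
#' @export
connection_rules <- function() {
  tibble(
    source = c("PYR", "PYR", "PYR", "PYR", "PYR", "FS", "FS", "RS", "IS", "IS"),
    target = c("PYR", "PYR", "FS", "RS", "IS", "PYR", "FS", "PYR", "PYR", "RS"),
    autapse = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
                FALSE),
    compartment = c("basal", "basal", "dendrite", "dendrite", "dendrite",
                    "soma", "soma", "distal", "distal", "dendrite"),
    n_synapses = c(24L, 8L, 12L, 14L, 7L, 15L, 1L, 12L, 10L, 2L),
    class = c("exc", "exc", "exc", "exc", "exc", "inh", "inh", "inh", "inh",
              "inh")
  )
}

#' Network manipulation specification
#'
#' @param mode One of `"control"`, `"fs_ko"`, `"rs_ko"`, `"is_ko"`
#'   (population removed with all its synapses), `"fs_scale"` (a fraction of
#'   FS-to-pyramidal contacts retained), `"fs_retarget"` (FS projection moved
#'   to a dendritic compartment), `"reverse_rs"`, `"reverse_is"` (two RS or
#'   IS models take over the somatic projection and its contact count while
#'   one FS model projects distally).
#' @param fs_fraction Fraction of FS-to-pyramidal contacts retained
#'   (`fs_scale` only), in \[0, 1\].
#' @param retarget_site `"basal"` (D0), `"proximal"` (D1) or `"distal"`
#'   (D2) (`fs_retarget` only).
#' @export
manipulation_spec <- function(mode = c("control", "fs_ko", "rs_ko", "is_ko",
                                       "fs_scale", "fs_retarget",
                                       "reverse_rs", "reverse_is"),
                              fs_fraction = NULL, retarget_site = NULL) {
  mode <- match.arg(mode)
  if (mode == "fs_scale") {
    if (is.null(fs_fraction) || fs_fraction < 0 || fs_fraction > 1)
      abort("`fs_fraction` in [0, 1] is required for fs_scale")
  } else if (!is.null(fs_fraction)) {
    abort("`fs_fraction` applies to fs_scale only")
  }
  if (mode == "fs_retarget") {
    retarget_site <- match.arg(retarget_site, c("basal", "proximal", "distal"))
  } else if (!is.null(retarget_site)) {
    abort("`retarget_site` applies to fs_retarget only")
  }
  structure(list(mode = mode, fs_fraction = fs_fraction,
                 retarget_site = retarget_site),
            class = "manipulation_spec")
}

#' Network specification
#'
#' @param ratios A [ratio_config()].
#' @param manipulation A [manipulation_spec()].
#' @param seed Integer seed governing latency draws and contact subsampling.
#' @param weights Synaptic weight table (see `default_syn_weights`).
#' @param noise Background-noise settings: Poisson event rate (`rate`,
#'   `rate_is`), rate unit (`"hz"` for events per second, the printed
#'   convention, or `"per_ms"`), event current amplitude (nA) and decay time
#'   constant (ms).
#' @param n_pyr,n_fs,n_rs,n_is Population sizes of the control circuit.
#' @param cell_overrides Named list of per-cell-type parameter overrides
#'   passed to [build_cell()] (e.g. `list(PYR = list(...))`).
#' @export
network_spec <- function(ratios = ratio_config(),
                         manipulation = manipulation_spec("control"),
                         seed = 1L,
                         weights = default_syn_weights(),
                         noise = list(rate = 0.02, rate_is = 0.035,
                                      unit = "per_ms", amp = 0.38, tau = 2),
                         n_pyr = 16L, n_fs = 2L, n_rs = 1L, n_is = 1L,
                         cell_overrides = list()) {
  stopifnot(inherits(ratios, "ratio_config"),
            inherits(manipulation, "manipulation_spec"))
  structure(list(ratios = ratios, manipulation = manipulation,
                 seed = as.integer(seed), weights = weights, noise = noise,
                 n_pyr = n_pyr, n_fs = n_fs, n_rs = n_rs, n_is = n_is,
                 cell_overrides = cell_overrides),
            class = "network_spec")
}

#' Draw synaptic latencies
#'
#' Independent Gaussian latencies (mean 1.7 ms, sd 0.9 ms) truncated below
#' at 0.1 ms by rejection, reproducible by seed.
#'
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @param mean,sd Gaussian parameters (ms).
#' @param min Truncation bound (ms).
#' @return Numeric vector of `n` latencies, all `> min`.
#' @export
draw_latencies <- function(n, seed = NULL, mean = 1.7, sd = 0.9, min = 0.1) {
  stopifnot(n >= 1)
  draw <- function() {
    x <- rnorm(n, mean, sd)
    bad <- which(x <= min)
    while (length(bad)) {
      x[bad] <- rnorm(length(bad), mean, sd)
      bad <- which(x <= min)
    }
    x
  }
  if (is.null(seed)) draw()
  else { old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
         set.seed(seed); draw() }
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# conductance-charge (integral of the unit-peak bi-exponential) of a receptor
unit_charge <- function(kin) {
  tp <- kin$rise_tau * kin$decay_tau / (kin$decay_tau - kin$rise_tau) *
    log(kin$decay_tau / kin$rise_tau)
  norm <- 1 / (exp(-tp / kin$decay_tau) - exp(-tp / kin$rise_tau))
  norm * (kin$decay_tau - kin$rise_tau)
}

# peak-conductance scale giving GABA-B the requested fraction of the GABA-A
# unitary charge transfer; `mult` is the calibrated normalization of the
# slow metabotropic component relative to that reference
gabab_charge_scale <- function(mult = 1) {
  mult * unit_charge(synapse_kinetics("GABAA")) /
    unit_charge(synapse_kinetics("GABAB"))
}

# per-connection-class receptor weight lookup (uS per contact)
class_weights <- function(spec) {
  w <- spec$weights
  r <- spec$ratios
  bscale <- r$gabab_gabaa * gabab_charge_scale(spec$weights$gabab_norm %||% 1)
  fs_pair <- 15 * w$gabaa_fs_pyr
  w_rs <- r$rs_pyr_gabaa_scale * fs_pair / 12
  w_is <- r$is_pyr_gabaa_scale * (12 * w_rs) / 10
  list(
    "PYR.PYR" = list(AMPA = w$ampa_pyr, NMDA = w$ampa_pyr * r$nmda_ampa_pyr),
    "PYR.FS" = list(AMPA = w$ampa_fs, NMDA = w$ampa_fs * r$nmda_ampa_fs),
    "PYR.RS" = list(AMPA = w$ampa_rs, NMDA = w$ampa_rs * r$nmda_ampa_rs),
    "PYR.IS" = list(AMPA = w$ampa_is, NMDA = w$ampa_is * r$nmda_ampa_is),
    "FS.PYR" = list(GABAA = w$gabaa_fs_pyr,
                    GABAB = w$gabaa_fs_pyr * bscale),
    "FS.FS" = list(GABAA = w$gabaa_fs_aut),
    "RS.PYR" = list(GABAA = w_rs, GABAB = w_rs * bscale),
    "IS.PYR" = list(GABAA = w_is, GABAB = w_is * bscale),
    "IS.RS" = list(GABAA = w$gabaa_is_rs,
                   GABAB = w$gabaa_is_rs * bscale)
  )
}

rec_group <- function(receptor, target_is_pyr) {
  if (!target_is_pyr) return(-1L)
  match(receptor, c("AMPA", "NMDA", "GABAA", "GABAB")) - 1L
}

#' Build the microcircuit
#'
#' Instantiates the populations demanded by the specification (with its
#' manipulation applied), wires every connection class of
#' [connection_rules()] with per-contact truncated-Gaussian latencies, and
#' returns a `pfc_network` ready for simulation. Construction is
#' deterministic given `spec$seed`.
#'
#' @param spec A [network_spec()].
#' @return A `pfc_network`: populations table, cell models, synapse table,
#'   and the originating spec.
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  m <- spec$manipulation

  pops <- tibble(cell_type = c(rep("PYR", spec$n_pyr),
                               rep("FS", spec$n_fs),
                               rep("RS", spec$n_rs),
                               rep("IS", spec$n_is)))
  rules <- connection_rules()

  if (m$mode %in% c("fs_ko", "rs_ko", "is_ko")) {
    drop <- toupper(sub("_ko", "", m$mode))
    pops <- pops[pops$cell_type != drop, , drop = FALSE]
    rules <- rules[rules$source != drop & rules$target != drop, , drop = FALSE]
  } else if (m$mode == "fs_retarget") {
    rules$compartment[rules$source == "FS" & rules$target == "PYR"] <-
      m$retarget_site
  } else if (m$mode %in% c("reverse_rs", "reverse_is")) {
    other <- toupper(sub("reverse_", "", m$mode))
    # the somatic role (15 contacts on the soma) passes to two models of the
    # other type; one FS model takes the displaced distal projection with
    # the displaced contact count
    n_other <- if (other == "RS") spec$n_rs else spec$n_is
    pops <- tibble(cell_type = c(rep("PYR", spec$n_pyr), "FS",
                                 rep("RS", if (other == "RS") 2 else spec$n_rs),
                                 rep("IS", if (other == "IS") 2 else spec$n_is)))
    displaced <- rules[rules$source == other & rules$target == "PYR", ]
    rules$compartment[rules$source == "FS" & rules$target == "PYR"] <-
      displaced$compartment[1]
    rules$n_synapses[rules$source == "FS" & rules$target == "PYR"] <-
      displaced$n_synapses[1]
    rules$compartment[rules$source == other & rules$target == "PYR"] <- "soma"
    rules$n_synapses[rules$source == other & rules$target == "PYR"] <- 15L
  }

  pops$neuron <- seq_len(nrow(pops))
  cells <- lapply(pops$cell_type, function(ct)
    build_cell(ct, spec$cell_overrides[[ct]] %||% list()))

  cw <- class_weights(spec)
  kin <- list(AMPA = synapse_kinetics("AMPA"),
              NMDA = synapse_kinetics("NMDA"),
              GABAA = synapse_kinetics("GABAA"),
              GABAB = synapse_kinetics("GABAB"))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  rows <- list()
  for (ri in seq_len(nrow(rules))) {
    rule <- rules[ri, ]
    src <- pops$neuron[pops$cell_type == rule$source]
    tgt <- pops$neuron[pops$cell_type == rule$target]
    for (s in src) for (p in tgt) {
      if (rule$autapse && s != p) next
      if (!rule$autapse && s == p) next
      n_syn <- rule$n_synapses
      if (m$mode == "fs_scale" && rule$source == "FS" &&
          rule$target == "PYR" && !rule$autapse)
        n_syn <- as.integer(round(m$fs_fraction * n_syn))
      if (n_syn == 0L) next
      lat <- draw_latencies(n_syn)
      wts <- cw[[paste(rule$source, rule$target, sep = ".")]]
      for (rec in names(wts)) {
        if (wts[[rec]] <= 0) next
        rows[[length(rows) + 1]] <- tibble(
          pre = s, post = p, comp = rule$compartment, receptor = rec,
          tau_rise = kin[[rec]]$rise_tau, tau_decay = kin[[rec]]$decay_tau,
          erev = kin[[rec]]$reversal, weight = wts[[rec]],
          latency = lat,
          group = rec_group(rec, rule$target == "PYR"),
          cap_mult = if (rec == "NMDA") spec$weights$nmda_cap_mult %||% 0
                     else 0,
          class = paste(rule$source, rule$target,
                        if (rule$autapse) "aut" else "", sep = "."))
      }
    }
  }
  synapses <- dplyr::bind_rows(rows)

  structure(list(spec = spec, populations = pops, cells = cells,
                 synapses = synapses),
            class = "pfc_network")
}

#' @export
print.pfc_network <- function(x, ...) {
  comp <- paste(sprintf("%d %s", table(x$populations$cell_type)[unique(x$populations$cell_type)],
                        unique(x$populations$cell_type)), collapse = ", ")
  cat(sprintf("<pfc_network> %s; %d synaptic contacts; manipulation: %s\n",
              comp, nrow(x$synapses), x$spec$manipulation$mode))
  invisible(x)
}

#' Apply a manipulation to a control network
#'
#' Pure: rebuilds the network from its specification with the manipulation
#' installed; the input object is not modified.
#'
#' @param net A control `pfc_network`.
#' @param m A [manipulation_spec()].
#' @return A new `pfc_network`.
#' @export
apply_manipulation <- function(net, m) {
  stopifnot(inherits(net, "pfc_network"), inherits(m, "manipulation_spec"))
  if (net$spec$manipulation$mode != "control")
    abort("manipulations apply to a control network only")
  spec <- net$spec
  spec$manipulation <- m
  build_network(spec)
}

#' Background noise event generators
#'
#' Independent homogeneous Poisson trains of brief somatic current
#' transients for every neuron, reproducible by seed. The IS model uses a
#' larger rate parameter. The printed rate convention (events per second)
#' is the default; an events-per-ms reading is selectable via the network
#' spec's noise `unit`.
#'
#' @param net A `pfc_network`.
#' @param seed Integer seed.
#' @param duration Horizon over which to generate events (ms).
#' @return A tibble of events: `cell`, `comp`, `time` (ms), `amp` (nA).
#' @export
background_noise_sources <- function(net, seed, duration) {
  nz <- net$spec$noise
  per_ms <- switch(nz$unit,
                   hz = c(nz$rate, nz$rate_is) / 1000,
                   per_ms = c(nz$rate, nz$rate_is),
                   abort("unknown noise rate unit"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- lapply(net$populations$neuron, function(n) {
    rate <- if (net$populations$cell_type[n] == "IS") per_ms[2] else per_ms[1]
    times <- poisson_times(rate, duration)
    if (!length(times)) return(NULL)
    tibble(cell = n, comp = "soma", time = times, amp = nz$amp)
  })
  dplyr::bind_rows(rows)
}

# homogeneous Poisson event times on [0, duration) at `rate` events/ms
poisson_times <- function(rate, duration) {
  if (rate <= 0) return(numeric(0))
  n <- rpois(1, rate * duration)
  sort(runif(n, 0, duration))
}

#' Network manifest
#'
#' Aggregated edge list for auditing and diffing manipulated variants.
#'
#' @param net A `pfc_network`.
#' @return A tibble with one row per (pre, post, compartment, receptor):
#'   contact count, total weight and mean latency.
#' @export
network_manifest <- function(net) {
  net$synapses |>
    dplyr::group_by(.data$pre, .data$post, .data$comp, .data$receptor) |>
    dplyr::summarise(n = dplyr::n(), weight = sum(.data$weight),
                     mean_latency = mean(.data$latency), .groups = "drop")
}
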