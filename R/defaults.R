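# Default biophysical parameter set for the four cell types.
#
# Passive values and channel densities for the FS, RS and IS interneurons are
# the published table values. Compartment dimensions, gating kinetics and the
# pyramidal channel complement are calibration parameters: they were pinned
# numerically against the cell-level validation surfaces (input resistance,
# resting potential, spike counts and rates at the standard current steps)
# and are shipped frozen here. The slow K+ conductance of the FS and IS
# somata is present in the mechanism roster but has no published density; it
# is likewise a calibrated value.

default_reversals <- function() {
  list(na = 55, k = -90, ca = 120, h = -30)
}

# gate parameter shorthand
.g <- function(role, vh, k, exponent = 1L, tau_min = 1, tau_amp = 0,
               vt = vh, ks1 = 15, ks2 = 15) {
  list(role = role, vh = vh, k = k, exponent = as.integer(exponent),
       tau_min = tau_min, tau_amp = tau_amp, vt = vt, ks1 = ks1, ks2 = ks2)
}

# Baseline gating kinetics for each mechanism in the library. Values follow
# conventional Hodgkin-Huxley-style formulations for each current family;
# per-cell-type entries in `default_params()` override individual constants.
base_kinetics <- function() {
  list(
    Na = list(
      .g("activation", vh = -35, k = 6, exponent = 3L,
         tau_min = 0.05, tau_amp = 0.15, vt = -35, ks1 = 10, ks2 = 10),
      .g("inactivation", vh = -62, k = -6.5,
         tau_min = 0.4, tau_amp = 6, vt = -55, ks1 = 15, ks2 = 15)
    ),
    Kdr = list(
      .g("activation", vh = -28, k = 9, exponent = 2L,
         tau_min = 0.8, tau_amp = 4, vt = -30, ks1 = 20, ks2 = 20)
    ),
    KA = list(
      .g("activation", vh = -45, k = 9, exponent = 3L, tau_min = 0.3),
      .g("inactivation", vh = -70, k = -8, tau_min = 15)
    ),
    Kslow = list(
      .g("activation", vh = -35, k = 6, tau_min = 150)
    ),
    KD = list(
      .g("activation", vh = -50, k = 9, tau_min = 2),
      .g("inactivation", vh = -70, k = -9, tau_min = 600)
    ),
    CaN = list(
      .g("activation", vh = -18, k = 7, exponent = 2L, tau_min = 1.5),
      .g("inactivation", vh = -45, k = -13, tau_min = 90)
    ),
    CaT = list(
      .g("activation", vh = -52, k = 5.5, exponent = 2L,
         tau_min = 2, tau_amp = 6, vt = -52),
      .g("inactivation", vh = -78, k = -5.5,
         tau_min = 15, tau_amp = 60, vt = -78)
    ),
    H = list(
      # opens with hyperpolarization: negative slope, inactivation-type gate
      .g("inactivation", vh = -84, k = -8,
         tau_min = 60, tau_amp = 300, vt = -84)
    ),
    fAHP = list(
      .g("activation", vh = -20, k = 12, tau_min = 2)
    )
  )
}


#' Default biophysical parameters of the four cell types
#'
#' Returns the full nested parameter list used by [build_cell()]: compartment
#' geometry, passive properties, channel densities per compartment, gating
#' kinetics overrides, calcium-pool settings and the resting-potential
#' target. Interneuron passive values and densities are the published table
#' values; geometry, kinetics and the pyramidal complement are calibrated
#' defaults (see the package vignette).
#'
#' @return A named list with one entry per cell type (`PYR`, `FS`, `RS`,
#'   `IS`) plus `reversals`.
#' @export
default_params <- function() {
  rev <- default_reversals()
  list(
    reversals = rev,
    PYR = list(
      geometry = list(
        soma = list(length = 23.6, diameter = 25, parent = NA),
        basal = list(length = 284, diameter = 6, parent = "soma"),
        proximal = list(length = 189, diameter = 4, parent = "soma"),
        distal = list(length = 236.5, diameter = 3.466, parent = "proximal")
      ),
      passive = list(cm = 1.2, ra = 150, rm = 12, e_leak = -70.45),
      v_rest_target = -70,
      densities = list(
        soma = list(Na = 0.1, Kdr = 0.012, KA = 0.004, Kslow = 0.0015,
                    CaN = 0.0005, fAHP = 0.00012, H = 0.000005),
        basal = list(Na = 0.012, Kdr = 0.003, KA = 0.01),
        proximal = list(Na = 0.012, Kdr = 0.003, KA = 0.01),
        distal = list(Na = 0.012, Kdr = 0.003, KA = 0.012, H = 0.00002)
      ),
      kinetics = list(
        Na = list(list(vh = -43), list(vh = -60)),
        Kslow = list(list(tau_min = 200)),
        # slow subthreshold deactivation caps the maximal sustained rate,
        # bounding the network's active state at a finite firing rate
        Kdr = list(list(tau_min = 0.8, tau_amp = 36, vt = -55,
                        ks1 = 10, ks2 = 10))
      ),
      calcium_comps = "soma",
      calcium = list(rest = 5e-5, tau = 60, influx = 5e-3)
    ),
    FS = list(
      geometry = list(
        soma = list(length = 18.97, diameter = 20, parent = NA),
        dendrite = list(length = 237.2, diameter = 3, parent = "soma"),
        axon = list(length = 142.3, diameter = 1, parent = "soma")
      ),
      passive = list(cm = 1.2, ra = 150, rm = 10, e_leak = -73),
      v_rest_target = -73,
      densities = list(
        soma = list(Na = 0.135, Kdr = 0.036, CaN = 0.0003, KD = 0.0000725,
                    H = 0.00001, KA = 0.0032, fAHP = 0.0001, Kslow = 0.0012),
        axon = list(Na = 1.35, Kdr = 0.018),
        dendrite = list(Na = 0.09, Kdr = 0.0075, KA = 0.032)
      ),
      kinetics = list(
        Na = list(list(vh = -41.7), list(vh = -63.7)),
        Kdr = list(list(vh = -15, tau_min = 0.5, tau_amp = 5.1, vt = -40,
                        ks1 = 15, ks2 = 15))
      ),
      # dendritic A-type stays available at depolarized potentials so the
      # sodium-rich dendrite cannot latch into a plateau under synaptic drive
      # axonal Na inactivates sharply and fast: the high-density axon fires
      # during action potentials but cannot hold a window-current plateau
      kinetics_by_comp = list(
        dendrite = list(KA = list(list(vh = -38, k = 7),
                                  list(vh = -45, k = -6, tau_min = 15))),
        axon = list(Na = list(NULL, list(vh = -70, k = -3.5,
                                         tau_min = 0.3, tau_amp = 1.5,
                                         vt = -60, ks1 = 10, ks2 = 10)))
      ),
      calcium_comps = "soma",
      calcium = list(rest = 5e-5, tau = 40, influx = 5e-3)
    ),
    RS = list(
      geometry = list(
        soma = list(length = 12.8, diameter = 20, parent = NA),
        dendrite = list(length = 256, diameter = 5, parent = "soma"),
        axon = list(length = 96, diameter = 1.5, parent = "soma")
      ),
      passive = list(cm = 1.2, ra = 150, rm = 40, e_leak = -60.4),
      v_rest_target = -64,
      densities = list(
        soma = list(Na = 0.075, Kdr = 0.018, CaT = 0.003, H = 0.000002,
                    KA = 0.035),
        axon = list(Na = 0.75, Kdr = 0.009),
        dendrite = list(Na = 0.018, Kdr = 0.009, KA = 0.00875)
      ),
      kinetics = list(
        Na = list(list(vh = -41), list(vh = -61)),
        KA = list(list(vh = -36, k = 7, tau_min = 0.3),
                  list(vh = -70, k = -6, tau_min = 30)),
        # deep T-type deinactivation midpoint: no rebound limit cycle at rest
        CaT = list(NULL, list(vh = -88)),
        Kdr = list(list(vh = -28, k = 5, exponent = 1L, tau_min = 0.9,
                        tau_amp = 64, vt = -65, ks1 = 4, ks2 = 4))
      ),
      calcium_comps = "soma",
      calcium = list(rest = 5e-5, tau = 60, influx = 5e-3)
    ),
    IS = list(
      geometry = list(
        soma = list(length = 13.8, diameter = 16, parent = NA),
        dendrite = list(length = 216, diameter = 1, parent = "soma"),
        dendrite2 = list(length = 151, diameter = 1, parent = "soma"),
        axon = list(length = 130, diameter = 1, parent = "soma")
      ),
      passive = list(cm = 1.2, ra = 150, rm = 20, e_leak = -63.5),
      v_rest_target = -70,
      densities = list(
        soma = list(Na = 0.015, Kdr = 0.018, KD = 0.000725, CaN = 0.001,
                    fAHP = 0.00003, Kslow = 0.005),
        axon = list(Na = 0.15, Kdr = 0.009),
        dendrite = list(Na = 0.075, Kdr = 0.009),
        dendrite2 = list(Na = 0.075, Kdr = 0.009)
      ),
      kinetics = list(
        Na = list(list(vh = -43), list(vh = -64)),
        Kslow = list(list(vh = -38, tau_min = 80))
      ),
      calcium_comps = "soma",
      calcium = list(rest = 5e-5, tau = 80, influx = 5e-3)
    )
  )
}

# Merge user overrides into the defaults, refusing unknown names at any level.
merge_strict <- function(base, over, path = "") {
  if (is.null(over) || (is.list(over) && length(over) == 0)) return(base)
  if (!is.list(over) || !is.list(base)) return(over)
  nm <- names(over)
  if (is.null(nm) || any(nm == ""))
    abort(sprintf("overrides at '%s' must be a fully named list", path))
  for (n in nm) {
    if (is.data.frame(base) || !n %in% names(base))
      abort(sprintf("unknown parameter '%s%s'", path, n))
    base[[n]] <- merge_strict(base[[n]], over[[n]], paste0(path, n, "$"))
  }
  base
}
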