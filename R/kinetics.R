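#' Voltage-gated channel gating scheme
#'
#' A gating variable of a Hodgkin-Huxley-style conductance. The steady state
#' is a Boltzmann sigmoid \eqn{x_\infty(v) = 1/(1+\exp(-(v-v_h)/k))} and the
#' voltage-dependent time constant a bell-shaped function
#' \eqn{\tau(v) = \tau_{min} + \tau_{amp} / (e^{(v-v_t)/k_1} + e^{-(v-v_t)/k_2})}
#' (constant \eqn{\tau_{min}} when `tau_amp = 0`). Activation gates use
#' `k > 0`, inactivation gates `k < 0`.
#'
#' @param role `"activation"` or `"inactivation"`.
#' @param vh Half-activation voltage (mV).
#' @param k Slope factor (mV); negative for inactivation gates.
#' @param exponent Small positive integer power the gate enters the
#'   conductance with.
#' @param tau_min Minimum (or constant) time constant (ms).
#' @param tau_amp Amplitude of the bell-shaped voltage-dependent component
#'   (ms); 0 gives a voltage-independent time constant.
#' @param vt Voltage of the bell peak (mV).
#' @param ks1,ks2 Slopes of the rising/falling flanks of the bell (mV).
#' @return A `gating_scheme` object with closures `steady_state_fn` and
#'   `time_constant_fn`.
#' @export
gating_scheme <- function(role = c("activation", "inactivation"),
                          vh, k, exponent = 1L,
                          tau_min = 1, tau_amp = 0, vt = vh,
                          ks1 = 15, ks2 = 15) {
  role <- match.arg(role)
  stopifnot(is.finite(vh), is.finite(k), k != 0, exponent >= 1,
            tau_min > 0, tau_amp >= 0, ks1 > 0, ks2 > 0)
  if (role == "activation" && k < 0)
    abort("activation gates require a positive slope factor `k`")
  if (role == "inactivation" && k > 0)
    abort("inactivation gates require a negative slope factor `k`")
  params <- list(vh = vh, k = k, tau_min = tau_min, tau_amp = tau_amp,
                 vt = vt, ks1 = ks1, ks2 = ks2)
  structure(
    list(
      role = role,
      exponent = as.integer(exponent),
      params = params,
      steady_state_fn = function(v) 1 / (1 + exp(-(v - vh) / k)),
      time_constant_fn = function(v) {
        if (tau_amp <= 0) rep_len(tau_min, length(v))
        else tau_min + tau_amp / (exp((v - vt) / ks1) + exp(-(v - vt) / ks2))
      }
    ),
    class = "gating_scheme"
  )
}

#' @export
print.gating_scheme <- function(x, ...) {
  p <- x$params
  cat(sprintf("<gating_scheme> %s^%d, vh = %g mV, k = %g mV, tau in [%g, ~%g] ms\n",
              x$role, x$exponent, p$vh, p$k, p$tau_min,
              p$tau_min + if (p$tau_amp > 0) p$tau_amp / 2 else 0))
  invisible(x)
}

#' Evaluate a gating variable's steady state
#'
#' @param scheme A [gating_scheme()].
#' @param v Membrane voltage (mV); must be finite.
#' @return Steady-state open fraction, clamped to \[0, 1\].
#' @export
evaluate_steady_state <- function(scheme, v) {
  stopifnot(inherits(scheme, "gating_scheme"))
  if (!all(is.finite(v))) abort("`v` must be finite (mV)")
  pmin(1, pmax(0, scheme$steady_state_fn(v)))
}

#' Advance a gating variable with the exact exponential update
#'
#' Integrates \eqn{dx/dt = (x_\infty(v) - x)/\tau(v)} over a step of fixed
#' voltage: \eqn{x(t+dt) = x_\infty + (x - x_\infty) e^{-dt/\tau}}.
#'
#' @param scheme A [gating_scheme()].
#' @param x Current open fraction in \[0, 1\].
#' @param v Membrane voltage (mV), held constant over the step.
#' @param dt Step (ms), non-negative.
#' @return Updated open fraction.
#' @export
advance_gate <- function(scheme, x, v, dt) {
  stopifnot(inherits(scheme, "gating_scheme"))
  if (!all(is.finite(v))) abort("`v` must be finite (mV)")
  if (any(dt < 0)) abort("`dt` must be non-negative")
  if (any(x < 0 | x > 1)) abort("`x` must lie in [0, 1]")
  xinf <- evaluate_steady_state(scheme, v)
  tau <- scheme$time_constant_fn(v)
  xinf + (x - xinf) * exp(-dt / tau)
}

#' Ionic channel specification
#'
#' One conductance placed on one compartment: a maximal density, a reversal
#' potential, and the gating variables that multiply the open probability.
#' The fast calcium-activated potassium current (`"fAHP"`) additionally
#' carries a saturating calcium-dependent factor
#' \eqn{[Ca]/([Ca] + K_d)} read from the compartment's calcium pool.
#'
#' @param kind One of `"Na"`, `"Kdr"`, `"KA"`, `"Kslow"`, `"KD"`, `"CaN"`,
#'   `"CaT"`, `"H"`, `"fAHP"`.
#' @param gbar Maximal conductance density (S/cm2), non-negative.
#' @param reversal Reversal potential (mV).
#' @param gates List of [gating_scheme()] objects (possibly empty).
#' @param calcium_dependent Logical; `TRUE` only for `"fAHP"`.
#' @param ca_kd Half-saturation calcium concentration of the
#'   calcium-dependent factor (mM).
#' @export
channel_spec <- function(kind, gbar, reversal, gates = list(),
                         calcium_dependent = identical(kind, "fAHP"),
                         ca_kd = 5e-4) {
  kind <- match.arg(kind, c("Na", "Kdr", "KA", "Kslow", "KD", "CaN", "CaT",
                            "H", "fAHP"))
  stopifnot(is.numeric(gbar), gbar >= 0, is.finite(reversal), ca_kd > 0)
  if (calcium_dependent && kind != "fAHP")
    abort("only the fAHP conductance is calcium dependent")
  if (!all(vapply(gates, inherits, logical(1), "gating_scheme")))
    abort("`gates` must be a list of gating_scheme objects")
  structure(
    list(kind = kind, gbar = gbar, reversal = reversal, gates = gates,
         calcium_dependent = isTRUE(calcium_dependent), ca_kd = ca_kd),
    class = "channel_spec"
  )
}

#' Instantaneous channel current density
#'
#' Ohmic form \eqn{I = \bar g \prod_i x_i^{p_i} (v - E)} (positive =
#' outward), with the calcium-dependent multiplier applied for the fAHP
#' conductance.
#'
#' @param spec A [channel_spec()].
#' @param gate_values Open fractions, one per gate of `spec`, each in
#'   \[0, 1\].
#' @param v Membrane voltage (mV).
#' @param ca Calcium concentration (mM); used only when the channel is
#'   calcium dependent.
#' @return Current density (mA/cm2).
#' @export
channel_current <- function(spec, gate_values, v, ca = 0) {
  stopifnot(inherits(spec, "channel_spec"))
  if (length(gate_values) != length(spec$gates))
    abort(sprintf("expected %d gate values, got %d",
                  length(spec$gates), length(gate_values)))
  if (length(gate_values) && any(gate_values < 0 | gate_values > 1))
    abort("gate values must lie in [0, 1]")
  open <- 1
  for (i in seq_along(spec$gates))
    open <- open * gate_values[[i]]^spec$gates[[i]]$exponent
  if (spec$calcium_dependent) open <- open * ca / (ca + spec$ca_kd)
  spec$gbar * open * (v - spec$reversal)
}

#' Intracellular calcium pool
#'
#' A single first-order buffered pool: calcium current drives influx and the
#' concentration relaxes back to rest,
#' \eqn{d[Ca]/dt = -\phi \, I_{Ca} - ([Ca] - [Ca]_{rest})/\tau}.
#'
#' @param concentration Current concentration (mM).
#' @param rest_concentration Resting concentration (mM).
#' @param decay_tau Relaxation time constant (ms).
#' @param influx_factor \eqn{\phi}: concentration change per ms per unit
#'   inward calcium current density (mM cm2 / mA / ms).
#' @export
calcium_pool <- function(concentration = 5e-5, rest_concentration = 5e-5,
                         decay_tau = 50, influx_factor = 5e-3) {
  stopifnot(concentration >= 0, rest_concentration >= 0, decay_tau > 0,
            influx_factor >= 0)
  structure(
    list(concentration = concentration,
         rest_concentration = rest_concentration,
         decay_tau = decay_tau, influx_factor = influx_factor),
    class = "calcium_pool"
  )
}

#' Advance a calcium pool
#'
#' Analytic update over a step during which the calcium current density is
#' held constant; the concentration relaxes exponentially toward the fixed
#' point \eqn{[Ca]_{rest} - \phi I_{Ca} \tau} and is floored at zero.
#'
#' @param pool A [calcium_pool()].
#' @param i_ca Calcium current density (mA/cm2), negative = inward.
#' @param dt Step (ms), non-negative.
#' @return Updated [calcium_pool()].
#' @export
advance_calcium <- function(pool, i_ca, dt) {
  stopifnot(inherits(pool, "calcium_pool"))
  if (dt < 0) abort("`dt` must be non-negative")
  ca_inf <- pool$rest_concentration -
    pool$influx_factor * i_ca * pool$decay_tau
  newca <- ca_inf + (pool$concentration - ca_inf) * exp(-dt / pool$decay_tau)
  pool$concentration <- max(0, newca)
  pool
}
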