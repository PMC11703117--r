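# Single-neuron and single-synapse equations.
#
# The network consists of steady-state firing-rate neurons: the membrane
# equilibrates much faster than the synapses (tau_s >> tau_m), so rates are
# algebraic functions of the synaptic state and only channel-open and
# release probabilities carry dynamics.

#' Logistic firing-rate function
#'
#' Maps the steady-state membrane potential to a firing rate through a
#' logistic sigmoid, `r = r_max / (1 + exp(-slope * (U - half_point)))`.
#'
#' @param U_inf steady-state membrane potential(s), mV above rest.
#' @param constants a [model_constants()] object.
#' @return firing rate(s) in Hz, in the open interval (0, r_max).
#' @export
firing_rate <- function(U_inf, constants = model_constants()) {
  if (!is.numeric(U_inf) || any(!is.finite(U_inf)))
    cx_stop("U_inf must be finite numeric", "cx_invalid_argument")
  constants$r_max / (1 + exp(-constants$slope * (U_inf - constants$half_point)))
}

#' Total relative synaptic conductance under neuromodulation
#'
#' The effective conductance of a synapse is its unmodulated weight plus the
#' modulatory weights of each angular-velocity input scaled by that input's
#' current transmitter release probability:
#' `g_tot = g_s + sum_j P_rel[j] * g_mod[j]`.
#'
#' @param g_s unmodulated (signed) synaptic weight.
#' @param g_mod vector of modulatory weights, one per modulatory input.
#' @param P_rel vector of release probabilities, same length as `g_mod`.
#' @return the effective synaptic weight.
#' @export
total_conductance <- function(g_s, g_mod = numeric(0), P_rel = numeric(0)) {
  if (length(g_mod) != length(P_rel))
    cx_stop("g_mod and P_rel must have equal length", "cx_invalid_argument")
  if (length(P_rel) && (any(P_rel < 0) || any(P_rel > 1)))
    cx_stop("P_rel entries must lie in [0, 1]", "cx_invalid_argument")
  g_s + sum(P_rel * g_mod)
}

#' Steady-state membrane potential
#'
#' Conductance-based steady state of a passive membrane driven by synapses
#' with open probabilities `P_s` and reversal potentials `E_s`:
#' `U = sum(g * P * E) / (1 + sum(g * P))`. The shunting denominator keeps
#' the potential inside the convex hull of rest and the active reversal
#' potentials for non-negative conductances.
#'
#' @param g_tot effective weights, one per input synapse.
#' @param P_s channel open probabilities, one per input synapse.
#' @param E_s reversal potentials in mV, one per input synapse.
#' @param constants a [model_constants()] object (supplies the denominator
#'   guard `eps_denom`).
#' @return membrane potential in mV.
#' @export
steady_state_potential <- function(g_tot, P_s, E_s,
                                   constants = model_constants()) {
  if (length(g_tot) != length(P_s) || length(P_s) != length(E_s))
    cx_stop("g_tot, P_s and E_s must have equal length", "cx_invalid_argument")
  den <- 1 + sum(g_tot * P_s)
  if (den <= constants$eps_denom)
    cx_stop(sprintf("degenerate membrane denominator %.3g", den),
            "cx_numerical_degeneracy")
  if (!length(g_tot)) return(0)
  sum(g_tot * P_s * E_s) / den
}

#' Time derivative of the synaptic open probability
#'
#' Poisson presynaptic spiking convolved with a single-exponential channel
#' kernel gives `dP/dt = P_s_max * r - (r + 1/tau_s) * P`, with the rate in
#' 1/ms. Its fixed point for constant rate is `r / (r + 1/tau_s)`.
#'
#' @param P_s open probability.
#' @param r_pre presynaptic rate, Hz.
#' @param constants a [model_constants()] object.
#' @return dP/dt in 1/ms.
#' @export
synapse_derivative <- function(P_s, r_pre, constants = model_constants()) {
  if (any(r_pre < 0) || any(!is.finite(r_pre)))
    cx_stop("r_pre must be non-negative and finite", "cx_invalid_argument")
  r <- r_pre / 1000  # Hz -> 1/ms
  constants$P_s_max * r - (r + 1 / constants$tau_s) * P_s
}

#' Fixed point of the synaptic open probability
#' @inheritParams synapse_derivative
#' @return the stationary open probability for a constant presynaptic rate.
#' @export
synapse_fixed_point <- function(r_pre, constants = model_constants()) {
  r <- r_pre / 1000
  constants$P_s_max * r / (r + 1 / constants$tau_s)
}

#' Time derivative of the modulatory release probability
#'
#' Modulatory (angular-velocity) inputs change the transmitter release
#' probability of the synapses they modulate in proportion to their own rate:
#' `P_rel` relaxes towards `r_mod / r_av_max` with time constant `tau_s_mod`,
#' which is proportional to the rate at the fixed point and confines `P_rel`
#' to [0, 1].
#'
#' @param P_rel release probability.
#' @param r_mod modulatory input rate, Hz, in `[0, r_av_max]`.
#' @param constants a [model_constants()] object.
#' @return dP_rel/dt in 1/ms.
#' @export
release_derivative <- function(P_rel, r_mod, constants = model_constants()) {
  if (any(r_mod < 0) || any(r_mod > constants$r_av_max + 1e-12))
    cx_stop("r_mod must lie in [0, r_av_max]", "cx_invalid_argument")
  (r_mod / constants$r_av_max - P_rel) / constants$tau_s_mod
}
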