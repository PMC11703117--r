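# Model constants and classed error conditions.
#
# Internal unit conventions: time in ms, rates in kHz (Hz at all user-facing
# interfaces), membrane potentials in mV relative to rest, angles in degrees
# wrapped to [0, 360).

cx_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "cx_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Physiological model constants
#'
#' Returns the fixed parameters of the neuron and synapse model. Values not
#' constrained by data are exposed as arguments so they can be overridden from
#' a configuration file.
#'
#' @param tau_m membrane time constant, ms. Absorbed by the steady-state
#'   assumption; kept for documentation and for validating `tau_s >> tau_m`.
#' @param tau_s synaptic time constant, ms. The default (25 ms, >> tau_m) is
#'   chosen so that, together with `tau_s_mod`, all synaptic transients
#'   settle well inside the 200 ms optimisation window; see the methods
#'   vignette.
#' @param tau_s_mod time constant of modulatory release-probability dynamics,
#'   ms; must exceed `tau_s` (neuromodulation involves signalling cascades).
#'   The default keeps the release transient ~96% complete within the 160 ms
#'   shift phase of training, which pins the steady-state shift gain.
#' @param r_max maximum firing rate of the logistic rate function, Hz.
#' @param slope slope of the logistic rate function, 1/mV.
#' @param half_point membrane potential of half-maximal rate, mV.
#' @param P_s_max maximum synaptic channel open probability.
#' @param E_ex excitatory synaptic reversal potential, mV above rest. Under
#'   the signed-conductance convention this is the single reversal potential;
#'   inhibition is a negative conductance.
#' @param E_in inhibitory reversal potential, mV; retained for configuration
#'   completeness, unused under the signed-conductance convention.
#' @param r_bias constant firing rate of the bias neuron, Hz.
#' @param r_av_max maximum firing rate of angular-velocity neurons, Hz.
#' @param v_max maximum angular velocity, degrees/s.
#' @param bump_amplitude rate amplitude of the compass bump, Hz.
#' @param bump_baseline operating point (baseline rate) of the bump, Hz.
#' @param dt default integration time step, ms.
#' @param eps_denom guard for the denominator of the steady-state potential.
#' @return An object of class `cx_constants` (a validated named list).
#' @export
model_constants <- function(tau_m = 1.5, tau_s = 25, tau_s_mod = 50,
                            r_max = 99.6, slope = 0.19, half_point = 17.8,
                            P_s_max = 1, E_ex = 60, E_in = -60,
                            r_bias = 100, r_av_max = 30, v_max = 150,
                            bump_amplitude = 5, bump_baseline = 25,
                            dt = 1, eps_denom = 1e-3) {
  cst <- list(tau_m = tau_m, tau_s = tau_s, tau_s_mod = tau_s_mod,
              r_max = r_max, slope = slope, half_point = half_point,
              P_s_max = P_s_max, E_ex = E_ex, E_in = E_in,
              r_bias = r_bias, r_av_max = r_av_max, v_max = v_max,
              bump_amplitude = bump_amplitude, bump_baseline = bump_baseline,
              dt = dt, eps_denom = eps_denom)
  validate_constants(cst)
  class(cst) <- "cx_constants"
  cst
}

validate_constants <- function(cst) {
  num <- vapply(cst, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num))
    cx_stop("all model constants must be finite scalars", "cx_invalid_argument")
  if (cst$tau_s < 10 * cst$tau_m)
    cx_stop("slow-synapse assumption violated: need tau_s >= 10 * tau_m",
            "cx_invalid_argument")
  if (cst$tau_s_mod <= cst$tau_s)
    cx_stop("need tau_s_mod > tau_s", "cx_invalid_argument")
  if (cst$P_s_max != 1)
    cx_stop("P_s_max must equal 1", "cx_invalid_argument")
  if (cst$r_max <= 0 || cst$slope <= 0)
    cx_stop("r_max and slope must be positive", "cx_invalid_argument")
  if (cst$v_max <= 0 || cst$r_av_max <= 0)
    cx_stop("v_max and r_av_max must be positive", "cx_invalid_argument")
  invisible(cst)
}

#' Read or write model constants as a flat YAML file
#'
#' @param path file path.
#' @param constants a `cx_constants` object.
#' @return `read_constants` returns a `cx_constants` object.
#' @export
read_constants <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(model_constants))
  extra <- setdiff(names(vals), known)
  if (length(extra))
    cx_stop(paste("unknown constant(s) in config:", paste(extra, collapse = ", ")),
            "cx_format_error")
  do.call(model_constants, vals)
}

#' @rdname read_constants
#' @export
write_constants <- function(constants, path) {
  stopifnot(inherits(constants, "cx_constants"))
  yaml::write_yaml(unclass(constants), path)
  invisible(path)
}

#' @export
print.cx_constants <- function(x, ...) {
  cat("Heading-circuit model constants:\n")
  for (nm in names(x)) cat(sprintf("  %-14s %g\n", nm, x[[nm]]))
  invisible(x)
}

# Angle helpers ---------------------------------------------------------

#' Wrap angles to [0, 360)
#' @param x angles in degrees.
#' @return wrapped angles.
#' @export
wrap_angle <- function(x) x %% 360

#' Signed circular difference a - b in (-180, 180]
#' @param a,b angles in degrees.
#' @return signed difference in degrees.
#' @export
angle_diff <- function(a, b) {
  d <- (a - b + 180) %% 360 - 180
  ifelse(d == -180, 180, d)
}
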