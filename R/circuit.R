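# Circuit construction: neuron indexing, anatomical connectivity masks,
# angular-velocity input tuning, compass-bump initialisation and decoding.
#
# The network has 34 units: 16 CL1a and 16 CL2 columnar neurons (one per
# protocerebral-bridge column, indexed 0..15 = L8..R8 from left to right),
# one bias neuron firing at a constant rate, and two angular-velocity (AV)
# neurons (clockwise / counterclockwise) that act purely as neuromodulators.
# Conventional (feed-forward) synapses run among the 32 columnar neurons plus
# the bias input; AV neurons scale those synapses multiplicatively.

N_COL <- 16L   # PB columns
N_CN  <- 32L   # columnar neurons (CL1a + CL2)
N_PRE <- 33L   # presynaptic sources: columnar neurons + bias

#' PB column labels and neuron names
#' @return character vectors of neuron names in circuit order.
#' @export
pb_columns <- function() c(paste0("L", 8:1), paste0("R", 1:8))

#' @rdname pb_columns
#' @export
neuron_names <- function() {
  c(paste0("CL1a_", pb_columns()), paste0("CL2_", pb_columns()), "BIAS")
}

#' Preferred heading directions of the 16 CL1a neurons (degrees)
#' @export
phi_pref <- function() (0:15) * 22.5

# CBL (lower central body) column occupied by each neuron's output arbor.
# Columnar neurons of each PB hemisphere project to alternating CBL columns
# across the full CBL width; the CL2 scheme is shifted by one column relative
# to CL1a, mirror-symmetrically in the two hemispheres. 0-based.
cbl_col_cl1a <- function(k) ifelse(k < 8, 2L * k, 2L * (k - 8L) + 1L)
cbl_col_cl2  <- function(k) ifelse(k < 8, cbl_col_cl1a(k) + 1L, cbl_col_cl1a(k) - 1L)

#' Build the biologically constrained connectivity mask
#'
#' Encodes which synapses may exist, without specifying sign or strength.
#' Rows are postsynaptic (16 CL1a then 16 CL2), columns presynaptic
#' (16 CL1a, 16 CL2, bias). The rules, derived from projection anatomy:
#'
#' 1. Each CL1a neuron may drive the CL2 neuron of the same PB column.
#' 2. Each CL2 neuron may drive CL1a neurons whose CBL input arbors overlap
#'    its (one-column-shifted) CBL output column: the same-column
#'    contralateral CL1a plus ipsi- and contralateral flanking CL1a neurons.
#' 3. CL1a neurons may drive CL1a neurons whose CBL arbors overlap theirs
#'    (central column plus up to two flanking columns, both hemispheres,
#'    including self-connections).
#' 4. CL2 neurons arborising in the same lower nodulus (i.e. originating
#'    from the same PB hemisphere) are all-to-all connected, including self.
#' 5. The bias neuron may drive every CL1a and CL2 neuron.
#'
#' CBL columns are treated as a linear (crescent-shaped, non-wrapping) array;
#' arbor overlap means the source output column lies within two columns of
#' the target CL1a central column.
#'
#' @param modulated which postsynaptic populations the angular-velocity
#'   neurons may modulate: both (default), or restricted to synapses onto
#'   CL1a or onto CL2 neurons only (used for the re-optimised variants).
#' @return An object of class `cx_mask`: list with logical matrices `ff`
#'   (32 x 33 feed-forward mask) and `mod` (32 x 32 modulatory mask, equal
#'   for both AV neurons), plus bookkeeping indices.
#' @export
build_columnar_mask <- function(modulated = c("CL1a", "CL2")) {
  modulated <- match.arg(modulated, c("CL1a", "CL2"), several.ok = TRUE)
  k <- 0:15
  ff <- matrix(FALSE, N_CN, N_PRE,
               dimnames = list(neuron_names()[1:32], neuron_names()))
  c1 <- cbl_col_cl1a(k)  # CL1a central CBL columns
  c2 <- cbl_col_cl2(k)   # CL2 output CBL columns
  # (3) CL1a -> CL1a: CBL arbor overlap, distance <= 2 (linear, no wrap)
  ff[1:16, 1:16] <- abs(outer(c1, c1, "-")) <= 2
  # (2) CL2 -> CL1a: CL2 output column within the CL1a input arbor
  ff[1:16, 17:32] <- abs(outer(c1, c2, "-")) <= 2
  # (1) CL1a -> CL2: same PB column
  ff[cbind(17:32, 1:16)] <- TRUE
  # (4) CL2 <-> CL2: same NOL group = same PB hemisphere of origin
  hemi <- rep(c(0L, 1L), each = 8)
  ff[17:32, 17:32] <- outer(hemi, hemi, "==")
  # (5) bias -> all columnar neurons
  ff[, 33] <- TRUE

  mod <- ff[, 1:32]
  if (!"CL1a" %in% modulated) mod[1:16, ] <- FALSE
  if (!"CL2" %in% modulated) mod[17:32, ] <- FALSE

  structure(list(ff = ff, mod = mod, modulated = modulated,
                 cbl_cl1a = c1, cbl_cl2 = c2),
            class = "cx_mask")
}

#' @export
print.cx_mask <- function(x, ...) {
  cat(sprintf("Connectivity mask: %d feed-forward, %d modulatory positions (x2 AV neurons); modulated: %s\n",
              sum(x$ff), sum(x$mod), paste(x$modulated, collapse = "+")))
  invisible(x)
}

#' Angular-velocity neuron firing rates
#'
#' One AV neuron is tuned to clockwise (`v > 0`), one to counterclockwise
#' rotation; each fires proportionally to `|v|`, reaching `r_av_max` at
#' `v_max`.
#'
#' @param v angular velocity, degrees/s (vectorised).
#' @param constants a [model_constants()] object.
#' @param clip if `TRUE`, velocities beyond `v_max` are clipped; otherwise
#'   out-of-range input is an error.
#' @return a matrix with columns `cw` and `ccw` of rates in Hz.
#' @export
av_rates <- function(v, constants = model_constants(), clip = TRUE) {
  if (any(abs(v) > constants$v_max)) {
    if (!clip)
      cx_stop("|v| exceeds v_max and clipping is disabled", "cx_invalid_argument")
    v <- pmin(pmax(v, -constants$v_max), constants$v_max)
  }
  s <- constants$r_av_max * abs(v) / constants$v_max
  cbind(cw = ifelse(v > 0, s, 0), ccw = ifelse(v < 0, s, 0))
}

#' Sinusoidal compass-bump rate profile
#'
#' The population rate profile encoding heading `phi`:
#' `r_k = a * cos(phi_pref_k - phi) + b`.
#'
#' @param phi heading, degrees.
#' @param constants a [model_constants()] object (supplies amplitude `a` and
#'   operating point `b`).
#' @return a 16-vector of rates in Hz.
#' @export
cosine_bump <- function(phi, constants = model_constants()) {
  constants$bump_amplitude * cos((phi_pref() - phi) * pi / 180) +
    constants$bump_baseline
}

#' Initial circuit state for a given heading
#'
#' CL1a and CL2 rates are set to identical cosine bumps encoding `phi0`; AV
#' neurons encode zero angular velocity; all synaptic open probabilities
#' start at their fixed points for those rates (the stationary state reached
#' after prolonged zero-velocity input) and all release probabilities at 0.
#'
#' @param phi0 initial heading, degrees (wrapped to `[0, 360)`).
#' @param constants a [model_constants()] object.
#' @return An object of class `cx_state`: rates (Hz, named, 34 units),
#'   `P_s` (33 open probabilities: columnar + bias), `P_rel` (2), `phi_true`,
#'   and time `t` in ms.
#' @export
init_state <- function(phi0, constants = model_constants()) {
  if (!is.finite(phi0)) cx_stop("phi0 must be finite", "cx_invalid_argument")
  phi0 <- wrap_angle(phi0)
  bump <- cosine_bump(phi0, constants)
  rates <- c(bump, bump, constants$r_bias, 0, 0)
  names(rates) <- c(neuron_names(), "AV_cw", "AV_ccw")
  P_s <- synapse_fixed_point(rates[1:33], constants)
  structure(list(rates = rates, P_s = P_s, P_rel = c(cw = 0, ccw = 0),
                 phi_true = phi0, t = 0),
            class = "cx_state")
}

#' Decode the heading from CL1a population activity
#'
#' Least-squares fit of `r ~ alpha * cos(phi_pref) + beta * sin(phi_pref) +
#' gamma`; the decoded heading is the phase `atan2(beta, alpha)`. With
#' equally spaced preferred directions the regression has a closed form.
#'
#' @param r_cl1a 16 CL1a rates in Hz.
#' @param eps_amplitude fitted amplitudes below this raise an
#'   undefined-phase error.
#' @return a list with `phi` (degrees in `[0, 360)`), `amplitude`,
#'   `baseline`, and the fitted `profile`.
#' @export
decode_heading <- function(r_cl1a, eps_amplitude = 1e-9) {
  if (length(r_cl1a) != 16 || any(!is.finite(r_cl1a)))
    cx_stop("r_cl1a must be 16 finite rates", "cx_invalid_argument")
  ang <- phi_pref() * pi / 180
  alpha <- sum(r_cl1a * cos(ang)) / 8
  beta  <- sum(r_cl1a * sin(ang)) / 8
  amp <- sqrt(alpha^2 + beta^2)
  if (amp < eps_amplitude)
    cx_stop("fitted cosine amplitude ~ 0: heading undefined", "cx_undefined_phase")
  phi <- wrap_angle(atan2(beta, alpha) * 180 / pi)
  list(phi = phi, amplitude = amp, baseline = mean(r_cl1a),
       profile = alpha * cos(ang) + beta * sin(ang) + mean(r_cl1a))
}

# Vectorised decoding of a 16 x B rate matrix; returns phases and amplitudes
# without error signalling (NA phase where the amplitude is degenerate).
decode_phase_mat <- function(R, eps_amplitude = 1e-9) {
  ang <- phi_pref() * pi / 180
  alpha <- drop(crossprod(R, cos(ang))) / 8
  beta  <- drop(crossprod(R, sin(ang))) / 8
  amp <- sqrt(alpha^2 + beta^2)
  phi <- wrap_angle(atan2(beta, alpha) * 180 / pi)
  phi[amp < eps_amplitude] <- NA_real_
  list(phi = phi, amplitude = amp)
}

# Relative mean-squared deviation between a 16-vector rate profile and its
# best-fitting cosine, normalised by the profile's variance around its mean.
relative_cosine_mse <- function(r) {
  ang <- phi_pref() * pi / 180
  alpha <- sum(r * cos(ang)) / 8
  beta  <- sum(r * sin(ang)) / 8
  fit <- alpha * cos(ang) + beta * sin(ang) + mean(r)
  denom <- mean((r - mean(r))^2)
  if (denom == 0) return(0)
  mean((r - fit)^2) / denom
}

#' Effective (modulated) connectivity matrix
#'
#' Combines the unmodulated weights with the modulatory weights scaled by
#' the AV neurons' current release probabilities:
#' `effective = g_s + P_rel_cw * g_mod_cw + P_rel_ccw * g_mod_ccw`.
#'
#' @param weights a `cx_weights` object.
#' @param P_rel_cw,P_rel_ccw release probabilities in `[0, 1]`.
#' @return the 32 x 33 effective weight matrix.
#' @export
effective_matrix <- function(weights, P_rel_cw = 0, P_rel_ccw = 0) {
  g <- weights$gs
  g[, 1:32] <- g[, 1:32] + P_rel_cw * weights$gcw + P_rel_ccw * weights$gccw
  g
}
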