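# Forward simulation: fixed-step 4th-order Runge-Kutta integration of the
# synaptic state variables, batched over trials.
#
# Integrated state per trial: 33 channel-open probabilities P_s (32 columnar
# neurons + bias) and 2 release probabilities P_rel (one per AV neuron).
# Rates are algebraic functions of the synaptic state (steady-state rate
# assumption), recomputed from the membrane equation and the logistic rate
# function at every stage. Internally rates are in kHz (1/ms).

# Rates (kHz) of the 32 columnar neurons given the full P_s matrix (33 x B)
# and per-trial release probabilities. Optionally adds frozen membrane noise
# (mV, 32 x B) before the rate nonlinearity. Returns r and the quantities
# needed for adjoint computations.
rates_stage <- function(P, pc, pcc, gs, gcw, gccw, cst, noise_U = NULL) {
  S <- gs %*% P
  if (!is.null(gcw)) {
    X32 <- P[1:32, , drop = FALSE]
    S <- S + (gcw %*% X32) * rep(pc, each = 32) +
      (gccw %*% X32) * rep(pcc, each = 32)
  }
  den <- 1 + S
  if (any(den <= cst$eps_denom))
    cx_stop("membrane denominator fell below eps: pathological weights",
            "cx_numerical_degeneracy")
  U <- cst$E_ex * S / den
  if (!is.null(noise_U)) U <- U + noise_U
  r <- (cst$r_max / 1000) / (1 + exp(-cst$slope * (U - cst$half_point)))
  list(r = r, S = S, U = U, den = den)
}

# Derivative of the integrated state. P is 33 x B; pc, pcc length B.
state_deriv <- function(P, pc, pcc, tcw, tccw, gs, gcw, gccw, cst,
                        noise_U = NULL) {
  rs <- rates_stage(P, pc, pcc, gs, gcw, gccw, cst, noise_U)
  X32 <- P[1:32, , drop = FALSE]
  inv_ts <- 1 / cst$tau_s
  dP <- P  # reuse shape; P_s_max = 1 enforced by the constants
  dP[1:32, ] <- rs$r - X32 * (rs$r + inv_ts)
  rb <- cst$r_bias / 1000
  dP[33, ] <- rb - P[33, ] * (rb + inv_ts)
  list(dP = dP,
       dpc = (tcw - pc) / cst$tau_s_mod,
       dpcc = (tccw - pcc) / cst$tau_s_mod,
       r = rs$r)
}

# One RK4 step of the joint state. v (deg/s, length B) is held constant
# (zero-order hold) during the step. Probabilities are clamped to [0, 1]
# afterwards; for healthy states the clamp is inactive since [0,1] is
# forward-invariant for the exact flow.
rk4_step_batch <- function(P, pc, pcc, v, dt, gs, gcw, gccw, cst,
                           noise_U = NULL) {
  av <- pmin(abs(v), cst$v_max) / cst$v_max
  tcw <- ifelse(v > 0, av, 0)
  tccw <- ifelse(v < 0, av, 0)
  h2 <- dt / 2
  k1 <- state_deriv(P, pc, pcc, tcw, tccw, gs, gcw, gccw, cst, noise_U)
  k2 <- state_deriv(P + h2 * k1$dP, pc + h2 * k1$dpc, pcc + h2 * k1$dpcc,
                    tcw, tccw, gs, gcw, gccw, cst, noise_U)
  k3 <- state_deriv(P + h2 * k2$dP, pc + h2 * k2$dpc, pcc + h2 * k2$dpcc,
                    tcw, tccw, gs, gcw, gccw, cst, noise_U)
  k4 <- state_deriv(P + dt * k3$dP, pc + dt * k3$dpc, pcc + dt * k3$dpcc,
                    tcw, tccw, gs, gcw, gccw, cst, noise_U)
  P2 <- P + (dt / 6) * (k1$dP + 2 * k2$dP + 2 * k3$dP + k4$dP)
  list(P = pmin(pmax(P2, 0), 1),
       pc = pmin(pmax(pc + (dt / 6) * (k1$dpc + 2 * k2$dpc + 2 * k3$dpc + k4$dpc), 0), 1),
       pcc = pmin(pmax(pcc + (dt / 6) * (k1$dpcc + 2 * k2$dpcc + 2 * k3$dpcc + k4$dpcc), 0), 1))
}

#' One RK4 integration step of a circuit state
#'
#' Advances all synaptic state variables of a [init_state()] object by one
#' time step and recomputes the algebraic firing rates.
#'
#' @param state a `cx_state` object.
#' @param weights a `cx_weights` object.
#' @param v angular velocity during the step, degrees/s.
#' @param dt time step in ms; the integrator is accurate for steps of 1-8 ms.
#' @param constants a [model_constants()] object.
#' @return the advanced `cx_state`.
#' @export
rk4_step <- function(state, weights, v = 0, dt = 1,
                     constants = model_constants()) {
  if (!is.numeric(dt) || dt <= 0)
    cx_stop("dt must be positive", "cx_invalid_argument")
  P <- matrix(state$P_s, ncol = 1)
  st <- rk4_step_batch(P, state$P_rel[1], state$P_rel[2], v, dt,
                       weights$gs, weights$gcw, weights$gccw, constants)
  rs <- rates_stage(st$P, st$pc, st$pcc, weights$gs, weights$gcw,
                    weights$gccw, constants)
  state$P_s <- drop(st$P)
  state$P_rel <- c(cw = st$pc, ccw = st$pcc)
  rav <- av_rates(v, constants)
  state$rates[1:32] <- rs$r * 1000
  state$rates[33] <- constants$r_bias
  state$rates[34:35] <- rav[1, ]
  state$phi_true <- wrap_angle(state$phi_true + v * dt / 1000)
  state$t <- state$t + dt
  state
}

# Core batched simulation. P0: 33 x B, prel0: 2 x B, V: n_steps x B matrix of
# angular velocities (deg/s, zero-order hold per step). noise: list with
# sigma_U (mV) and beta_pseudocount (Inf = off); per-millisecond noise
# requires dt = 1. record: "final" (final rates only) or "cl1a"
# (CL1a rate trajectory, (n_steps+1) x 16 x B) or "rates" (all 32).
sim_engine <- function(weights, P0, prel0, V, dt, cst,
                       sigma_U = 0, beta_pseudocount = Inf,
                       record = "final") {
  gs <- weights$gs; gcw <- weights$gcw; gccw <- weights$gccw
  if (all(gcw == 0) && all(gccw == 0)) { gcw <- NULL; gccw <- NULL }
  n_steps <- nrow(V); B <- ncol(P0)
  noisy <- sigma_U > 0 || is.finite(beta_pseudocount)
  if (noisy && dt != 1)
    cx_stop("per-millisecond noise requires dt = 1 ms", "cx_invalid_argument")
  P <- P0; pc <- prel0[1, ]; pcc <- prel0[2, ]
  traj <- NULL
  rec_rates <- record %in% c("cl1a", "rates")
  if (rec_rates) {
    nrec <- if (record == "cl1a") 16L else 32L
    traj <- array(NA_real_, c(n_steps + 1L, nrec, B))
    r0 <- rates_stage(P, pc, pcc, gs, gcw, gccw, cst)$r
    traj[1, , ] <- r0[seq_len(nrec), ] * 1000
  }
  for (n in seq_len(n_steps)) {
    nU <- if (sigma_U > 0) {
      matrix(stats::rnorm(32L * B, 0, sigma_U), 32L, B)
    } else NULL
    st <- rk4_step_batch(P, pc, pcc, V[n, ], dt, gs, gcw, gccw, cst, nU)
    P <- st$P; pc <- st$pc; pcc <- st$pcc
    if (is.finite(beta_pseudocount)) {
      mu <- pmin(pmax(P, 1e-6), 1 - 1e-6)
      P <- matrix(stats::rbeta(length(P), beta_pseudocount * mu,
                               beta_pseudocount * (1 - mu)), 33L, B)
    }
    if (rec_rates) {
      rn <- rates_stage(P, pc, pcc, gs, gcw, gccw, cst,
                        if (sigma_U > 0) nU else NULL)$r
      traj[n + 1L, , ] <- rn[seq_len(nrec), ] * 1000
    }
  }
  rfin <- rates_stage(P, pc, pcc, gs, gcw, gccw, cst)$r * 1000
  list(P = P, pc = pc, pcc = pcc, rates = rfin, traj = traj)
}

#' Simulate the heading circuit
#'
#' Forward-simulates the circuit from an initial heading under a supplied
#' angular-velocity time series (zero-order hold between samples), while
#' co-integrating the ground-truth heading.
#'
#' @param weights a `cx_weights` object.
#' @param av angular-velocity series in degrees/s, one value per integration
#'   step (recycled if shorter than `n_steps`).
#' @param phi0 initial heading, degrees.
#' @param dt integration step, ms (1-8 ms recommended).
#' @param constants a [model_constants()] object.
#' @param sigma_U membrane-noise SD in mV, applied every millisecond
#'   (requires `dt = 1`); 0 disables.
#' @param beta_pseudocount pseudocount of per-millisecond Beta resampling of
#'   the channel-open probabilities; `Inf` disables.
#' @param record `"cl1a"` records the CL1a rate trajectory, `"rates"` all 32
#'   columnar rates, `"final"` only the final state.
#' @return An object of class `cx_simulation`: `t` (ms), `phi_true` (degrees,
#'   per recorded time point), `phi_decoded` (if rates recorded), `rates`
#'   (final rates, Hz), `traj` (rate array, if recorded), final `state`
#'   pieces.
#' @export
simulate_circuit <- function(weights, av, phi0, dt = 1,
                             constants = model_constants(),
                             sigma_U = 0, beta_pseudocount = Inf,
                             record = c("cl1a", "rates", "final")) {
  record <- match.arg(record)
  if (dt <= 0) cx_stop("dt must be positive", "cx_invalid_argument")
  n_steps <- length(av)
  s0 <- init_state(phi0, constants)
  out <- sim_engine(weights, matrix(s0$P_s, ncol = 1),
                    matrix(s0$P_rel, ncol = 1), matrix(av, ncol = 1),
                    dt, constants, sigma_U, beta_pseudocount, record)
  tt <- seq(0, n_steps) * dt
  phi_true <- wrap_angle(true_heading(av, phi0 = phi0, dt = dt))
  res <- list(t = tt, phi_true = phi_true, rates = drop(out$rates),
              P_s = drop(out$P), P_rel = c(cw = out$pc, ccw = out$pcc),
              dt = dt)
  if (!is.null(out$traj)) {
    R <- out$traj[, , 1]
    res$traj <- R
    res$phi_decoded <- decode_phase_mat(t(R[, 1:16]))$phi
  }
  class(res) <- "cx_simulation"
  res
}

#' @export
print.cx_simulation <- function(x, ...) {
  cat(sprintf("Circuit simulation: %d steps of %g ms\n", length(x$t) - 1, x$dt))
  if (!is.null(x$phi_decoded)) {
    n <- length(x$phi_decoded)
    cat(sprintf("  final true heading %.1f deg, decoded %.1f deg (error %.2f deg)\n",
                x$phi_true[n], x$phi_decoded[n],
                abs(angle_diff(x$phi_true[n], x$phi_decoded[n]))))
  }
  invisible(x)
}

#' Convert a recorded simulation to a long-format data frame
#' @param x a `cx_simulation` with a recorded trajectory.
#' @param ... unused.
#' @return a data frame with columns `t_ms`, `neuron`, `rate_hz`.
#' @export
as.data.frame.cx_simulation <- function(x, ...) {
  if (is.null(x$traj)) cx_stop("simulation recorded no trajectory", "cx_invalid_argument")
  nn <- neuron_names()[seq_len(ncol(x$traj))]
  data.frame(t_ms = rep(x$t, times = ncol(x$traj)),
             neuron = rep(nn, each = nrow(x$traj)),
             rate_hz = as.vector(x$traj))
}
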