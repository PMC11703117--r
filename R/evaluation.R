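# Quantitative evaluation protocols: angular-error metric, the
# walking-locust angular-velocity fixture generator, the noise-robustness
# integration suite, and the attractor-stability suite.

#' Absolute angular error between two headings
#'
#' `|((phi - phi_est + 180) mod 360) - 180|`, bounded in `[0, 180]` degrees
#' and symmetric in its arguments.
#'
#' @param phi,phi_est headings in degrees (vectorised).
#' @return absolute angular errors in degrees.
#' @export
angular_error <- function(phi, phi_est) abs(angle_diff(phi, phi_est))

#' Noise configuration for the evaluation suites
#'
#' @param sigma_U membrane-noise SD, mV (applied every millisecond).
#' @param release_pseudocount pseudocount of the Beta resampling of the
#'   channel-open probabilities (`Inf` disables; must be >= 2 so both Beta
#'   shape parameters stay positive).
#' @param weight_noise_range half-range of the once-per-trial multiplicative
#'   weight noise.
#' @param presyn_rate_sigma_rel SD of the initial presynaptic-rate
#'   perturbation, relative to the bump amplitude (attractor suite).
#' @param seed integer seed for the suite.
#' @return a `cx_noise` list.
#' @export
noise_config <- function(sigma_U = 0, release_pseudocount = Inf,
                         weight_noise_range = 0, presyn_rate_sigma_rel = 0,
                         seed = 1L) {
  if (sigma_U < 0 || weight_noise_range < 0 || presyn_rate_sigma_rel < 0)
    cx_stop("noise levels must be non-negative", "cx_invalid_argument")
  if (release_pseudocount < 2)
    cx_stop("release pseudocount must be >= 2", "cx_invalid_argument")
  structure(list(sigma_U = sigma_U,
                 release_pseudocount = release_pseudocount,
                 weight_noise_range = weight_noise_range,
                 presyn_rate_sigma_rel = presyn_rate_sigma_rel,
                 seed = as.integer(seed)),
            class = "cx_noise")
}

#' Generate a walking-locust angular-velocity trajectory
#'
#' First-order low-pass-filtered Gaussian noise: a stationary AR(1) process
#' with autocorrelation time `tau_ms` and stationary SD `sd_dps`, sampled at
#' `dt` and clipped to `[-v_max, v_max]`. Mimics the meandering rotational
#' trajectories of walking locusts: zero-mean, temporally correlated,
#' bounded.
#'
#' @param duration_ms trajectory length, ms.
#' @param dt sample interval, ms.
#' @param seed integer seed (`NULL` uses the current RNG state).
#' @param tau_ms filter time constant, ms.
#' @param sd_dps stationary standard deviation before clipping, degrees/s.
#' @param v_max clipping bound, degrees/s.
#' @return a numeric vector of angular velocities, degrees/s, one per step.
#' @export
generate_av_trajectory <- function(duration_ms, dt = 1, seed = NULL,
                                   tau_ms = 500, sd_dps = 50, v_max = 150) {
  if (duration_ms <= 0) cx_stop("duration must be positive", "cx_invalid_argument")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_ms / dt)
  rho <- exp(-dt / tau_ms)
  innov_sd <- sd_dps * sqrt(1 - rho^2)
  v <- numeric(n)
  v[1] <- stats::rnorm(1, 0, sd_dps)
  eps <- stats::rnorm(n - 1, 0, innov_sd)
  for (i in seq_len(n - 1)) v[i + 1] <- rho * v[i] + eps[i]
  pmin(pmax(v, -v_max), v_max)
}

# Batched AV trajectories as an n_steps x B matrix (column-wise AR(1)).
generate_av_matrix <- function(n_steps, B, dt, tau_ms, sd_dps, v_max) {
  rho <- exp(-dt / tau_ms)
  innov_sd <- sd_dps * sqrt(1 - rho^2)
  V <- matrix(0, n_steps, B)
  V[1, ] <- stats::rnorm(B, 0, sd_dps)
  for (i in seq_len(n_steps - 1))
    V[i + 1, ] <- rho * V[i, ] + stats::rnorm(B, 0, innov_sd)
  pmin(pmax(V, -v_max), v_max)
}

init_batch_states <- function(phi0, constants) {
  P0 <- vapply(phi0, function(p) init_state(p, constants)$P_s, numeric(33))
  list(P0 = P0, prel0 = matrix(0, 2, length(phi0)))
}

#' Noise robustness of heading and angular-velocity integration
#'
#' Runs `n_trials` integration trials of `duration_ms` each: random initial
#' heading, low-pass-filtered Gaussian angular-velocity input, optional
#' membrane noise (each millisecond), Beta resampling of channel-open
#' probabilities (each millisecond), and multiplicative weight noise (once
#' per trial). Reports the absolute angular error between the decoded and
#' true heading at each trial's endpoint.
#'
#' @param weights a trained `cx_weights` object.
#' @param noise a [noise_config()].
#' @param n_trials number of trials.
#' @param duration_ms trial length, ms.
#' @param dt integration step, ms (noise requires 1 ms).
#' @param constants a [model_constants()] object.
#' @param av_tau_ms,av_sd_dps parameters of the angular-velocity generator.
#' @return An object of class `cx_integration_result` with per-trial
#'   `errors` (degrees), their `mean` and `sem`, and the settings used.
#' @export
run_integration_suite <- function(weights, noise = noise_config(),
                                  n_trials = 2000, duration_ms = 4000,
                                  dt = 1, constants = model_constants(),
                                  av_tau_ms = 500, av_sd_dps = 50) {
  set.seed(derive_seed(noise$seed, "integration"))
  n_steps <- round(duration_ms / dt)
  phi0 <- stats::runif(n_trials, 0, 360)
  V <- generate_av_matrix(n_steps, n_trials, dt, av_tau_ms, av_sd_dps,
                          constants$v_max)
  phi_end <- vapply(seq_len(n_trials), function(b)
    true_heading(V[, b], phi0[b], dt)[n_steps + 1], numeric(1))
  st <- init_batch_states(phi0, constants)
  if (noise$weight_noise_range > 0) {
    rates <- matrix(NA_real_, 16, n_trials)
    for (b in seq_len(n_trials)) {
      wb <- perturb_weights(weights, noise$weight_noise_range)
      out <- sim_engine(wb, st$P0[, b, drop = FALSE],
                        st$prel0[, b, drop = FALSE], V[, b, drop = FALSE],
                        dt, constants, noise$sigma_U,
                        noise$release_pseudocount, record = "final")
      rates[, b] <- out$rates[1:16, 1]
    }
  } else {
    out <- sim_engine(weights, st$P0, st$prel0, V, dt, constants,
                      noise$sigma_U, noise$release_pseudocount,
                      record = "final")
    rates <- out$rates[1:16, , drop = FALSE]
  }
  dec <- decode_phase_mat(rates)
  errors <- angular_error(phi_end, dec$phi)
  structure(list(errors = errors, mean = mean(errors),
                 sem = stats::sd(errors) / sqrt(n_trials),
                 n = n_trials, duration_ms = duration_ms, noise = noise),
            class = "cx_integration_result")
}

#' @export
print.cx_integration_result <- function(x, ...) {
  cat(sprintf("Integration suite: mean absolute heading error %.2f deg +/- %.2f (SEM), n = %d trials of %g s\n",
              x$mean, x$sem, x$n, x$duration_ms / 1000))
  invisible(x)
}

#' @export
as.data.frame.cx_integration_result <- function(x, ...) {
  data.frame(trial = seq_len(x$n), final_error_deg = x$errors,
             sigma_U = x$noise$sigma_U,
             release_pseudocount = x$noise$release_pseudocount,
             weight_noise_range = x$noise$weight_noise_range)
}

#' Attractor stability of the compass states
#'
#' Perturbs the initial presynaptic rate vector (Gaussian noise with SD
#' relative to the bump amplitude) before seeding the synaptic fixed points,
#' optionally applies once-per-trial weight noise, integrates for
#' `duration_ms` under low-pass-filtered angular-velocity input, and reports
#' the relative mean-squared deviation between the final CL1a activity and
#' its best-fitting cosine.
#'
#' @inheritParams run_integration_suite
#' @return An object of class `cx_attractor_result` with per-trial
#'   `rmse_initial` and `rmse_final`.
#' @export
run_attractor_suite <- function(weights, noise = noise_config(),
                                n_trials = 1000, duration_ms = 100,
                                dt = 1, constants = model_constants(),
                                av_tau_ms = 500, av_sd_dps = 50) {
  set.seed(derive_seed(noise$seed, "attractor"))
  n_steps <- round(duration_ms / dt)
  phi0 <- stats::runif(n_trials, 0, 360)
  V <- generate_av_matrix(n_steps, n_trials, dt, av_tau_ms, av_sd_dps,
                          constants$v_max)
  sdn <- noise$presyn_rate_sigma_rel * constants$bump_amplitude
  bumps <- make_targets(phi0, constants)               # 16 x B
  r0 <- rbind(bumps, bumps) + matrix(stats::rnorm(32 * n_trials, 0, sdn),
                                     32, n_trials)
  r0 <- pmax(r0, 0)
  rmse_initial <- apply(r0[1:16, , drop = FALSE], 2, relative_cosine_mse)
  P0 <- rbind(synapse_fixed_point(r0, constants),
              synapse_fixed_point(rep(constants$r_bias, n_trials), constants))
  prel0 <- matrix(0, 2, n_trials)
  if (noise$weight_noise_range > 0) {
    rates <- matrix(NA_real_, 16, n_trials)
    for (b in seq_len(n_trials)) {
      wb <- perturb_weights(weights, noise$weight_noise_range)
      out <- sim_engine(wb, P0[, b, drop = FALSE], prel0[, b, drop = FALSE],
                        V[, b, drop = FALSE], dt, constants,
                        noise$sigma_U, noise$release_pseudocount, "final")
      rates[, b] <- out$rates[1:16, 1]
    }
  } else {
    out <- sim_engine(weights, P0, prel0, V, dt, constants, noise$sigma_U,
                      noise$release_pseudocount, "final")
    rates <- out$rates[1:16, , drop = FALSE]
  }
  rmse_final <- apply(rates, 2, relative_cosine_mse)
  structure(list(rmse_initial = rmse_initial, rmse_final = rmse_final,
                 final_rates = rates, n = n_trials,
                 duration_ms = duration_ms, noise = noise),
            class = "cx_attractor_result")
}

#' @export
print.cx_attractor_result <- function(x, ...) {
  cat(sprintf("Attractor suite: relative cosine MSE %.4f (initial) -> %.4f (final), n = %d trials of %g ms\n",
              mean(x$rmse_initial), mean(x$rmse_final), x$n, x$duration_ms))
  invisible(x)
}

#' @export
as.data.frame.cx_attractor_result <- function(x, ...) {
  data.frame(trial = seq_len(x$n), rmse_initial = x$rmse_initial,
             rmse_final = x$rmse_final,
             presyn_rate_sigma_rel = x$noise$presyn_rate_sigma_rel,
             weight_noise_range = x$noise$weight_noise_range)
}
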