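# Closed-loop walking agent: the heading circuit's CL1a output drives an
# adapted goal-directed steering circuit (TB1 heading layer, hard-coded CPU4
# goal encoding, CPU1-style left/right comparison), whose turn commands move
# the agent and feed realised angular velocity back into the circuit.

TB1_PREF <- (0:7) * 45  # preferred directions of the 8 TB1 units, degrees

#' Wind perturbation configuration
#'
#' Gusts either translate the agent one step-length sideways per agent step
#' or rotate it; translation and rotation are mutually exclusive. Each gust
#' lasts a random duration between `gust_min_ms` and `gust_max_ms`.
#'
#' @param p_translation,p_rotation per-step probabilities of a new gust.
#' @param gust_min_ms,gust_max_ms gust duration bounds, ms.
#' @param rot_magnitude_max total rotation magnitude bound of a rotation
#'   gust, degrees (drawn uniformly in `[-max, max]`, applied smoothly over
#'   the gust).
#' @return a `cx_wind` list.
#' @export
wind_config <- function(p_translation = 0, p_rotation = 0,
                        gust_min_ms = 500, gust_max_ms = 1500,
                        rot_magnitude_max = 90) {
  if (p_translation < 0 || p_rotation < 0 || p_translation + p_rotation > 1)
    cx_stop("need p_translation, p_rotation >= 0 and their sum <= 1",
            "cx_invalid_argument")
  structure(list(p_translation = p_translation, p_rotation = p_rotation,
                 gust_min_ms = gust_min_ms, gust_max_ms = gust_max_ms,
                 rot_magnitude_max = rot_magnitude_max),
            class = "cx_wind")
}

# Rounded-square-wave activity profile over a set of preferred directions.
rounded_square_wave <- function(theta, prefs, slope = 3) {
  stats::plogis(slope * cos((theta - prefs) * pi / 180))
}

#' Fit the CL1a-to-TB1 interface of the steering circuit
#'
#' Maps the 16-unit single-bump CL1a heading representation (squashed
#' through a logistic sigmoid into a rounded square wave) onto 8 TB1 units
#' carrying the same representation, with a small phase shift compensating
#' the discretisation bias of the steering stage. The weights are
#' constrained non-negative, restricted to anatomically permissible
#' positions (each TB1 subtype has two input domains in the PB, half a turn
#' apart, interpreted permissively as one PB column plus a flanking column
#' on either side), and regularised by quadratic weight decay so that
#' unnecessary connections are pruned towards zero.
#'
#' @param seed integer seed for the random training phases.
#' @param phase_shift target phase offset of the TB1 bump relative to the
#'   CL1a bump, degrees. This constant compensates implementation-specific
#'   biases between the continuous heading representation and the
#'   discretised steering stage (it moves the closed-loop equilibrium to
#'   `goal - phase_shift`); the default is calibrated so closed-loop
#'   deviations are symmetric about zero for this implementation.
#' @param n_phases number of random heading phases used for the fit.
#' @param ridge quadratic weight-decay strength.
#' @param squash_slope,squash_mid logistic squash applied to CL1a rates
#'   (1/Hz and Hz).
#' @param rsw_slope slope of the rounded-square-wave profile.
#' @param gain steering gain, degrees/s per comparator unit.
#' @param goal_length amplitude of the hard-coded goal encoding.
#' @param constants a [model_constants()] object.
#' @return an object of class `cx_steering`.
#' @export
optimize_cl1a_tb1_map <- function(seed = 1L, phase_shift = 0,
                                  n_phases = 240, ridge = 1e-2,
                                  squash_slope = 0.5, squash_mid = 25,
                                  rsw_slope = 3, gain = 90, goal_length = 1,
                                  constants = model_constants()) {
  set.seed(seed)
  theta <- stats::runif(n_phases, 0, 360)
  U <- vapply(theta, function(th)
    stats::plogis(squash_slope * (cosine_bump(th, constants) - squash_mid)),
    numeric(16))                                      # 16 x P
  Y <- vapply(theta, function(th)
    rounded_square_wave(th + phase_shift, TB1_PREF, rsw_slope),
    numeric(8))                                       # 8 x P
  # permissible synapses: CL1a PB column within +/-1 of either input domain
  k <- 0:15
  msk <- t(vapply(0:7, function(m) {
    d1 <- pmin(abs(k - 2 * m) %% 16, (-(k - 2 * m)) %% 16)
    d2 <- pmin(abs(k - 2 * m - 8) %% 16, (-(k - 2 * m - 8)) %% 16)
    pmin(d1, d2) <= 1
  }, logical(16)))                                    # 8 x 16
  W <- matrix(0, 8, 16)
  UUt <- tcrossprod(U) / n_phases
  for (m in 1:8) {
    free <- which(msk[m, ])
    A <- UUt[free, free] + ridge * diag(length(free))
    b <- drop(U[free, , drop = FALSE] %*% Y[m, ]) / n_phases
    fit <- stats::optim(rep(0.1, length(free)),
                        fn = function(w) drop(t(w) %*% A %*% w) - 2 * sum(b * w),
                        gr = function(w) 2 * drop(A %*% w) - 2 * b,
                        method = "L-BFGS-B", lower = 0,
                        control = list(maxit = 200, factr = 1e5))
    W[m, free] <- fit$par
  }
  dimnames(W) <- list(paste0("TB1_", 1:8), neuron_names()[1:16])
  structure(list(W = W, mask = msk, phase_shift = phase_shift,
                 squash_slope = squash_slope, squash_mid = squash_mid,
                 rsw_slope = rsw_slope, gain = gain,
                 goal_length = goal_length),
            class = "cx_steering")
}

#' @export
print.cx_steering <- function(x, ...) {
  cat(sprintf("CL1a->TB1 steering interface: %d/%d permissible weights > 1%% of max; phase shift %g deg\n",
              sum(x$W > 0.01 * max(x$W)), sum(x$mask), x$phase_shift))
  invisible(x)
}

#' TB1 activity from CL1a rates
#' @param interface a `cx_steering` object.
#' @param r_cl1a 16 CL1a rates in Hz (vector or 16 x B matrix).
#' @return TB1 activities (8-vector or 8 x B matrix).
#' @export
tb1_activity <- function(interface, r_cl1a) {
  u <- stats::plogis(interface$squash_slope *
                       (r_cl1a - interface$squash_mid))
  interface$W %*% (if (is.matrix(u)) u else matrix(u, ncol = 1))
}

#' Hard-coded goal-direction encoding (CPU4 layer)
#' @param theta_goal goal direction(s), degrees.
#' @param length goal-vector length (scales the steering drive).
#' @return an 8 x length(theta_goal) matrix.
#' @export
goal_encoding <- function(theta_goal, length = 1) {
  vapply(theta_goal, function(th)
    length * (0.5 + 0.5 * cos((th - TB1_PREF) * pi / 180)), numeric(8))
}

#' Steering command from TB1 heading and goal encodings
#'
#' CPU1-style left/right comparison: the goal encoding is compared against
#' the TB1 representation shifted one column in each direction; the
#' difference of the two summed products is an odd function of the heading
#' error and vanishes when heading and goal align.
#'
#' @param tb1 8 x B TB1 activities (or 8-vector).
#' @param goal 8 x B goal encodings (or 8-vector).
#' @param gain turn gain, degrees/s per comparator unit.
#' @return turn command(s) in degrees/s (positive = clockwise, i.e. towards
#'   increasing heading angle).
#' @export
steering_step <- function(tb1, goal, gain = 90) {
  if (!is.matrix(tb1)) tb1 <- matrix(tb1, ncol = 1)
  if (!is.matrix(goal)) goal <- matrix(goal, ncol = 1)
  if (nrow(tb1) != 8 || !all(dim(tb1) == dim(goal)))
    cx_stop("tb1 and goal must be 8 x B", "cx_invalid_argument")
  rot <- function(x, s) x[(seq_len(8) - 1 + s) %% 8 + 1, , drop = FALSE]
  drop(gain * colSums(goal * (rot(tb1, -1) - rot(tb1, 1))))
}

#' Closed-loop agent simulation
#'
#' Simulates `n_trials` walking agents for `n_steps` agent steps of
#' `step_ms` each. Per step: the heading circuit's CL1a rates are mapped to
#' TB1, compared against the fixed goal encoding, and the resulting turn
#' (plus any wind-gust rotation, jointly clipped to the angular-velocity
#' range) is applied to the agent's heading and fed back into the heading
#' circuit as realised angular velocity. The agent always advances one
#' step-length per step (it can neither rotate on the spot nor move
#' sideways); translation gusts displace it laterally without touching its
#' heading.
#'
#' @param weights a trained `cx_weights` object.
#' @param interface a [optimize_cl1a_tb1_map()] steering interface.
#' @param wind a [wind_config()].
#' @param n_trials number of agents.
#' @param seed integer seed (initial headings, goals, gusts).
#' @param n_steps agent steps per trial.
#' @param step_ms agent step duration, ms (the circuit is integrated in
#'   `circuit_dt` increments within each step).
#' @param circuit_dt heading-circuit integration step, ms.
#' @param speed step-lengths per agent step.
#' @param constants a [model_constants()] object.
#' @param record_trajectory number of trials for which to record the full
#'   (x, y, heading) trajectory.
#' @return An object of class `cx_agent_result`: signed final deviations
#'   (degrees, agent heading minus goal), absolute deviations, signed
#'   deviations at 5-s checkpoints, and optional trajectories.
#' @export
run_agent_trials <- function(weights, interface, wind = wind_config(),
                             n_trials = 200, seed = 1L, n_steps = 200,
                             step_ms = 100, circuit_dt = 1, speed = 1,
                             constants = model_constants(),
                             record_trajectory = 0) {
  set.seed(derive_seed(seed, "agent"))
  B <- n_trials
  heading <- stats::runif(B, 0, 360)
  goal_dir <- stats::runif(B, 0, 360)
  goal <- goal_encoding(goal_dir, interface$goal_length)
  st <- init_batch_states(heading, constants)
  P <- st$P0; prel <- st$prel0
  rates <- {
    rs <- rates_stage(P, prel[1, ], prel[2, ], weights$gs,
                      if (any(weights$gcw != 0)) weights$gcw else NULL,
                      if (any(weights$gccw != 0)) weights$gccw else NULL,
                      constants)
    rs$r * 1000
  }
  x <- numeric(B); y <- numeric(B)
  gust_left <- integer(B); gust_rot <- numeric(B); gust_side <- integer(B)
  gust_type <- integer(B)  # 0 none, 1 translation, 2 rotation
  sub_steps <- round(step_ms / circuit_dt)
  ck_steps <- seq(0, n_steps, by = n_steps / 4)
  checkpoints <- matrix(NA_real_, length(ck_steps), B)
  checkpoints[1, ] <- angle_diff(heading, goal_dir)
  ntraj <- min(record_trajectory, B)
  traj <- if (ntraj > 0)
    array(NA_real_, c(n_steps + 1, 3, ntraj),
          dimnames = list(NULL, c("x", "y", "heading_deg"), NULL)) else NULL
  if (ntraj > 0) traj[1, , ] <- rbind(x[1:ntraj], y[1:ntraj], heading[1:ntraj])
  for (n in seq_len(n_steps)) {
    # wind-gust bookkeeping
    idle <- gust_left == 0L
    if (any(idle) && (wind$p_translation > 0 || wind$p_rotation > 0)) {
      u <- stats::runif(B)
      new_t <- idle & u < wind$p_translation
      new_r <- idle & !new_t & u < wind$p_translation + wind$p_rotation
      newg <- new_t | new_r
      if (any(newg)) {
        dur <- pmax(1L, as.integer(round(
          stats::runif(sum(newg), wind$gust_min_ms, wind$gust_max_ms) / step_ms)))
        gust_left[newg] <- dur
        gust_type[newg] <- ifelse(new_t[newg], 1L, 2L)
        gust_side[newg] <- sample(c(-1L, 1L), sum(newg), replace = TRUE)
        tot_rot <- stats::runif(sum(newg), -wind$rot_magnitude_max,
                                wind$rot_magnitude_max)
        gust_rot[newg] <- ifelse(new_r[newg], tot_rot / dur, 0)
      }
    }
    rot_active <- gust_left > 0L & gust_type == 2L
    trans_active <- gust_left > 0L & gust_type == 1L
    # steering from the circuit's current heading representation
    tb1 <- tb1_activity(interface, rates[1:16, , drop = FALSE])
    turn_cmd <- steering_step(tb1, goal, interface$gain)   # deg/s
    dphi <- turn_cmd * step_ms / 1000 + ifelse(rot_active, gust_rot, 0)
    max_turn <- constants$v_max * step_ms / 1000
    dphi <- pmin(pmax(dphi, -max_turn), max_turn)
    v_real <- dphi / (step_ms / 1000)                       # deg/s
    # heading circuit sees the realised angular velocity
    V <- matrix(rep(v_real, each = sub_steps), sub_steps, B)
    out <- sim_engine(weights, P, prel, V, circuit_dt, constants,
                      record = "final")
    P <- out$P; prel <- rbind(out$pc, out$pcc); rates <- out$rates
    # move the agent
    heading <- wrap_angle(heading + dphi)
    hrad <- heading * pi / 180
    x <- x + speed * cos(hrad)
    y <- y + speed * sin(hrad)
    if (any(trans_active)) {
      lrad <- (heading + 90 * gust_side) * pi / 180
      x <- x + ifelse(trans_active, speed * cos(lrad), 0)
      y <- y + ifelse(trans_active, speed * sin(lrad), 0)
    }
    gust_left <- pmax(gust_left - 1L, 0L)
    if (ntraj > 0) traj[n + 1, , ] <- rbind(x[1:ntraj], y[1:ntraj],
                                            heading[1:ntraj])
    ci <- match(n, ck_steps)
    if (!is.na(ci)) checkpoints[ci, ] <- angle_diff(heading, goal_dir)
  }
  dev <- angle_diff(heading, goal_dir)
  structure(list(deviation_signed = dev, deviation_abs = abs(dev),
                 checkpoints = checkpoints,
                 checkpoint_steps = ck_steps, step_ms = step_ms,
                 goal_dir = goal_dir, wind = wind, n = B,
                 trajectory = traj),
            class = "cx_agent_result")
}

#' @export
print.cx_agent_result <- function(x, ...) {
  cat(sprintf("Agent suite: n = %d trials of %d steps; median |final deviation| %.1f deg (mean %.1f)\n",
              x$n, max(x$checkpoint_steps),
              stats::median(x$deviation_abs), mean(x$deviation_abs)))
  invisible(x)
}

#' @export
as.data.frame.cx_agent_result <- function(x, ...) {
  data.frame(trial = seq_len(x$n), final_deviation_deg = x$deviation_signed,
             goal_deg = x$goal_dir,
             p_translation = x$wind$p_translation,
             p_rotation = x$wind$p_rotation)
}
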