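# Single-neuron/synapse equations and the RK4 integrator.

cst <- model_constants()

test_that("logistic rate function hits its midpoint, asymptotes and a direct evaluation", {
  expect_equal(firing_rate(17.8, cst), 99.6 / 2)
  expect_lt(firing_rate(-1e3, cst), 1e-12)          # lower asymptote
  expect_equal(firing_rate(0, cst), 99.6 / (1 + exp(0.19 * 17.8)))
  expect_error(firing_rate(NaN, cst), class = "cx_invalid_argument")
})

test_that("rate function is strictly increasing and bounded in (0, r_max)", {
  u <- sort(runif(200, -50, 100))   # outside this range r saturates to
                                    # numerically indistinguishable values
  r <- firing_rate(u, cst)
  expect_true(all(diff(r) > 0))
  expect_true(all(r > 0 & r < cst$r_max))
})

test_that("total conductance reduces to the unmodulated weight and combines linearly", {
  expect_equal(total_conductance(1.2), 1.2)
  expect_equal(total_conductance(1.2, c(0.4, -0.3), c(0, 0)), 1.2)
  expect_equal(total_conductance(1.2, c(0, 0), c(0.7, 0.2)), 1.2)
  expect_equal(total_conductance(1, c(0.5, -0.5), c(1, 0)), 1.5)
  expect_error(total_conductance(1, c(0.5), c(1, 0)), class = "cx_invalid_argument")
  expect_error(total_conductance(1, c(0.5), c(1.5)), class = "cx_invalid_argument")
})

test_that("steady-state potential: empty input, shunting saturation, direct value, degeneracy guard", {
  expect_equal(steady_state_potential(numeric(0), numeric(0), numeric(0), cst), 0)
  expect_equal(steady_state_potential(1, 0.5, 60, cst), 20)
  expect_equal(steady_state_potential(1e9, 1, 60, cst), 60, tolerance = 1e-6)
  expect_error(steady_state_potential(-1, 1, 60, cst),
               class = "cx_numerical_degeneracy")
})

test_that("potential stays in the convex hull of rest and reversal potentials for g >= 0", {
  for (i in 1:50) {
    g <- runif(5, 0, 3); P <- runif(5); E <- runif(5, -80, 80)
    u <- steady_state_potential(g, P, E, cst)
    expect_gte(u, min(0, E) - 1e-12)
    expect_lte(u, max(0, E) + 1e-12)
  }
})

test_that("synaptic open-probability dynamics: decay, drive, and root-found fixed point", {
  expect_equal(synapse_derivative(0.4, 0, cst), -0.4 / cst$tau_s)
  expect_equal(synapse_derivative(0, 50, cst), 50 / 1000)
  expect_error(synapse_derivative(0.5, -1, cst), class = "cx_invalid_argument")
  # independent oracle: root of the derivative located numerically
  for (r in c(5, 25, 80)) {
    root <- uniroot(function(p) synapse_derivative(p, r, cst), c(0, 1),
                    tol = 1e-12)$root
    expect_equal(root, synapse_fixed_point(r, cst), tolerance = 1e-9)
    expect_equal(synapse_derivative(synapse_fixed_point(r, cst), r, cst), 0,
                 tolerance = 1e-15)
  }
})

test_that("release probability relaxes to the normalised rate with the modulatory time constant", {
  expect_lt(release_derivative(0.3, 0, cst), 0)          # decays to 0
  expect_gt(release_derivative(0.3, cst$r_av_max, cst), 0) # rises to 1
  expect_equal(release_derivative(1, cst$r_av_max, cst), 0)
  expect_error(release_derivative(0.5, -2, cst), class = "cx_invalid_argument")
  expect_error(release_derivative(0.5, 31, cst), class = "cx_invalid_argument")
  # step response matches the closed-form solution of the first-order law
  p <- 0; dt <- 1
  for (i in 1:400) p <- p + dt * release_derivative(p, cst$r_av_max, cst)
  expect_equal(p, 1 - exp(-400 / cst$tau_s_mod), tolerance = 1e-3)
})

test_that("P_s converges to its fixed point within 1% after 5 tau_s at constant rate", {
  r <- 40
  p <- 0.9; dt <- 2
  for (i in seq_len(5 * cst$tau_s / dt))
    p <- p + dt * synapse_derivative(p, r, cst)
  fp <- synapse_fixed_point(r, cst)
  expect_lt(abs(p - fp) / fp, 0.01)
})

test_that("an RK4 step rejects bad dt and leaves a zero-weight state on its slow decay", {
  mask <- build_columnar_mask()
  w0 <- vector_to_weights(rep(0, n_free_params(mask)), mask)
  s <- init_state(0, cst)
  expect_error(rk4_step(s, w0, v = 0, dt = 0), class = "cx_invalid_argument")
  s2 <- rk4_step(s, w0, v = 0, dt = 4)
  # with zero weights all columnar rates are the zero-input rate
  expect_equal(unname(s2$rates[1:32]), rep(firing_rate(0, cst), 32))
  # P_s moves towards the fixed point of that rate
  fp <- synapse_fixed_point(firing_rate(0, cst), cst)
  expect_true(all(abs(s2$P_s[1:32] - fp) <= abs(s$P_s[1:32] - fp)))
})

test_that("RK4 matches the analytic exponential with 4th-order global accuracy", {
  # with zero weights each P_s follows a linear ODE with known solution
  mask <- build_columnar_mask()
  w0 <- vector_to_weights(rep(0, n_free_params(mask)), mask)
  r_k <- firing_rate(0, cst) / 1000
  lam <- r_k + 1 / cst$tau_s
  p_inf <- r_k / lam
  T_end <- 200
  global_err <- function(dt) {
    s <- init_state(90, cst)
    p0 <- s$P_s[1]
    for (i in seq_len(T_end / dt)) s <- rk4_step(s, w0, 0, dt)
    exact <- p_inf + (p0 - p_inf) * exp(-lam * T_end)
    abs(s$P_s[1] - exact)
  }
  e4 <- global_err(4); e8 <- global_err(8)
  expect_lt(e8 / e4, 40)    # ~2^4 = 16, allow slack
  expect_gt(e8 / e4, 6)
  expect_lt(e4, 1e-8)
})

test_that("probabilities stay in [0,1] along random trajectories", {
  mask <- build_columnar_mask()
  set.seed(5)
  for (rep in 1:5) {
    w <- vector_to_weights(runif(n_free_params(mask), -0.3, 0.3), mask)
    av <- generate_av_trajectory(500, dt = 1, seed = rep)
    sim <- simulate_circuit(w, av, phi0 = runif(1, 0, 360), dt = 1,
                            record = "final")
    expect_true(all(sim$P_s >= 0 & sim$P_s <= 1))
    expect_true(all(sim$P_rel >= 0 & sim$P_rel <= 1))
    expect_true(all(sim$rates[1:32] >= 0 & sim$rates[1:32] <= cst$r_max))
  }
})

test_that("model constants validate their physiological invariants", {
  expect_error(model_constants(tau_s = 10), class = "cx_invalid_argument")
  expect_error(model_constants(tau_s_mod = 20), class = "cx_invalid_argument")
  expect_error(model_constants(P_s_max = 0.5), class = "cx_invalid_argument")
  expect_error(model_constants(slope = -1), class = "cx_invalid_argument")
  cfg <- file.path(tempdir(), "constants.yaml")
  write_constants(cst, cfg)
  expect_equal(read_constants(cfg), cst)
})
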