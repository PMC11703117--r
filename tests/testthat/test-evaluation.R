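# Error metric, the angular-velocity fixture generator, and the noise
# machinery of the evaluation suites.

cst <- model_constants()

test_that("angular error wraps, is symmetric and bounded in [0, 180]", {
  expect_equal(angular_error(10, 350), 20)
  expect_equal(angular_error(350, 10), 20)
  expect_equal(angular_error(123, 123), 0)
  expect_equal(angular_error(0, 180), 180)
  set.seed(1)
  a <- runif(200, -720, 720); b <- runif(200, -720, 720)
  e <- angular_error(a, b)
  expect_true(all(e >= 0 & e <= 180))
  expect_equal(e, angular_error(b, a))
})

test_that("noise configuration validates its domains", {
  expect_error(noise_config(sigma_U = -1), class = "cx_invalid_argument")
  expect_error(noise_config(release_pseudocount = 1),
               class = "cx_invalid_argument")
  expect_error(noise_config(weight_noise_range = -0.1),
               class = "cx_invalid_argument")
  ok <- noise_config(sigma_U = 0.5, release_pseudocount = 100)
  expect_s3_class(ok, "cx_noise")
})

test_that("angular-velocity generator is zero-mean, bounded, correlated and reproducible", {
  v <- generate_av_trajectory(2e5, dt = 1, seed = 10)
  expect_true(all(abs(v) <= 150))
  # zero-mean within sampling error: SD of the mean is ~3.5 deg/s here
  expect_lt(abs(mean(v)), 9)
  expect_equal(sd(v), 50, tolerance = 0.1)
  # autocorrelation at one filter time constant is ~ 1/e
  n <- length(v)
  ac <- cor(v[1:(n - 500)], v[501:n])
  expect_equal(ac, exp(-1), tolerance = 0.05)
  expect_identical(generate_av_trajectory(1000, seed = 7),
                   generate_av_trajectory(1000, seed = 7))
  expect_error(generate_av_trajectory(0), class = "cx_invalid_argument")
})

test_that("per-millisecond noise requires 1 ms steps and keeps probabilities valid", {
  mask <- build_columnar_mask()
  set.seed(2)
  w <- vector_to_weights(runif(n_free_params(mask), -0.2, 0.2), mask)
  expect_error(
    simulate_circuit(w, rep(0, 10), 0, dt = 2, sigma_U = 0.5),
    class = "cx_invalid_argument")
  sim <- simulate_circuit(w, rep(20, 200), 0, dt = 1, sigma_U = 1,
                          beta_pseudocount = 10, record = "final")
  expect_true(all(sim$P_s >= 0 & sim$P_s <= 1))
  expect_true(all(is.finite(sim$rates)))
})

test_that("integration suite returns per-trial errors with matching summary", {
  w <- trained_weights("joint")
  res <- run_integration_suite(w, noise_config(seed = 3), n_trials = 20,
                               duration_ms = 500)
  expect_length(res$errors, 20)
  expect_true(all(res$errors >= 0 & res$errors <= 180))
  expect_equal(res$mean, mean(res$errors))
  expect_equal(res$sem, sd(res$errors) / sqrt(20))
  df <- as.data.frame(res)
  expect_equal(nrow(df), 20)
  # identical seeds reproduce identical errors
  res2 <- run_integration_suite(w, noise_config(seed = 3), n_trials = 20,
                                duration_ms = 500)
  expect_identical(res$errors, res2$errors)
})

test_that("synaptic release noise and weight noise degrade integration accuracy", {
  w <- trained_weights("joint")
  base <- run_integration_suite(w, noise_config(seed = 61), n_trials = 40,
                                duration_ms = 2000)
  beta <- run_integration_suite(w, noise_config(release_pseudocount = 10,
                                                seed = 61),
                                n_trials = 40, duration_ms = 2000)
  expect_gte(beta$mean, base$mean - 2 * (base$sem + beta$sem))
  wn <- run_integration_suite(w, noise_config(weight_noise_range = 0.05,
                                              seed = 61),
                              n_trials = 20, duration_ms = 2000)
  base20 <- run_integration_suite(w, noise_config(seed = 61), n_trials = 20,
                                  duration_ms = 2000)
  # even small weight noise shifts the error distribution clearly upwards
  expect_gt(wn$mean, base20$mean)
})

test_that("attractor suite reports initial and final cosine deviations", {
  w <- trained_weights("joint")
  res <- run_attractor_suite(w, noise_config(presyn_rate_sigma_rel = 0.5,
                                             seed = 5),
                             n_trials = 30, duration_ms = 100)
  expect_length(res$rmse_final, 30)
  expect_true(all(res$rmse_initial >= 0))
  expect_gt(mean(res$rmse_initial), 0.01)   # the perturbation is visible
  # unperturbed trials start on an exact cosine
  res0 <- run_attractor_suite(w, noise_config(seed = 5), n_trials = 5,
                              duration_ms = 50)
  expect_lt(max(res0$rmse_initial), 1e-20)
})
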