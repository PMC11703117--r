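# Training objective, analytic gradient, and optimisation plumbing.

cst <- model_constants()
mask <- build_columnar_mask()

test_that("true heading integrates, holds, and wraps", {
  expect_equal(tail(true_heading(rep(90, 2000), phi0 = 0, dt = 1), 1), 180)
  expect_equal(unique(true_heading(rep(0, 100), phi0 = 33, dt = 1)), 33)
  expect_equal(tail(true_heading(rep(150, 2400), phi0 = 0, dt = 1), 1), 0)
})

test_that("activity targets are cosine bumps summing to 16 times the baseline", {
  expect_equal(make_targets(50, cst)[, 1], cosine_bump(50, cst))
  for (phi in c(0, 17, 123.4, 280)) {
    expect_equal(sum(make_targets(phi, cst)), 16 * cst$bump_baseline)
    expect_equal(make_targets(phi, cst), make_targets(phi + 360, cst))
  }
  # antipodal heading flips the bump around the baseline
  expect_equal(make_targets(10, cst) + make_targets(190, cst),
               matrix(2 * cst$bump_baseline, 16, 1))
})

test_that("training batch follows the study conditions", {
  b <- make_training_batch(seed = 4, constants = cst)
  expect_equal(length(b$phi0), 128)
  expect_equal(sum(b$is_shift), 64)
  expect_true(all(abs(b$v) <= 150))
  expect_true(all(b$v[!b$is_shift] == 0))
  expect_equal(b$n_steps, 49)                     # trajectory rows 0..49
  expect_equal(b$maint_rows, c(0, 10, 20, 30, 40))
  expect_equal(b$shift_rows, 40:49)
  # velocity is applied for the first 4/5 of the horizon only
  expect_true(all(b$V[41:49, ] == 0))
  expect_true(all(b$V[1:40, b$is_shift] != 0 | b$v[b$is_shift] == 0))
})

test_that("at zero weights the loss matches its closed form and is rotation invariant", {
  b <- make_training_batch(n_shift = 6, n_maintenance = 6, seed = 2,
                           constants = cst)
  w0 <- rep(0, n_free_params(mask))
  tl <- training_loss(w0, mask, b, cst)
  # constant output rate c against cosine targets: MSE = (c-b)^2 + a^2/2
  cc <- firing_rate(0, cst)
  expect_equal(tl$data_term,
               4 * ((cc - cst$bump_baseline)^2 + cst$bump_amplitude^2 / 2),
               tolerance = 1e-12)
  expect_equal(tl$reg_term, 0)
  expect_equal(tl$value, tl$data_term + 0.1 * tl$reg_term)
  # rotating every trial heading leaves the objective unchanged
  b2 <- b
  b2$phi0 <- b$phi0 + 77
  b2$maint_targets <- make_targets(b$phi0[!b$is_shift] + 77, cst)
  b2$shift_targets <- make_targets(
    b$phi0[b$is_shift] + 77 + b$v[b$is_shift] * 40 * b$dt / 1000, cst)
  expect_equal(training_loss(w0, mask, b2, cst)$value, tl$value,
               tolerance = 1e-12)
})

test_that("weights constant along each masked quadrant diagonal zero the regulariser", {
  ids <- locustcompass:::reg_group_ids(mask)
  w <- as.numeric(ids) * 0.01                # value depends only on the group
  b <- make_training_batch(n_shift = 2, n_maintenance = 2, seed = 3,
                           constants = cst)
  expect_equal(training_loss(w, mask, b, cst)$reg_term, 0)
  # breaking one diagonal raises it
  w[1] <- w[1] + 1
  expect_gt(training_loss(w, mask, b, cst)$reg_term, 0)
})

test_that("analytic gradient matches central finite differences to 1e-4", {
  b <- make_training_batch(n_shift = 3, n_maintenance = 2, seed = 7,
                           constants = cst)
  set.seed(42)
  w <- runif(n_free_params(mask), -0.05, 0.05)
  g <- training_loss(w, mask, b, cst, grad = TRUE)$grad
  # per-coordinate checks on the largest components ...
  idx <- order(abs(g), decreasing = TRUE)[1:12]
  h <- 1e-6
  fd <- vapply(idx, function(i) {
    wp <- w; wm <- w
    wp[i] <- wp[i] + h; wm[i] <- wm[i] - h
    (training_loss(wp, mask, b, cst)$value -
       training_loss(wm, mask, b, cst)$value) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(fd - g[idx]) / pmax(abs(fd), 1e-6)), 1e-4)
  # ... and well-scaled directional derivatives over the full vector
  set.seed(8)
  h <- 1e-5
  for (k in 1:4) {
    u <- rnorm(length(w)); u <- u / sqrt(sum(u^2))
    fd_u <- (training_loss(w + h * u, mask, b, cst)$value -
               training_loss(w - h * u, mask, b, cst)$value) / (2 * h)
    expect_lt(abs(fd_u - sum(g * u)) / max(abs(fd_u), 1e-6), 1e-4)
  }
})

test_that("gradient check also holds for the restricted modulation variants", {
  for (variant in list("CL1a", "CL2")) {
    mv <- build_columnar_mask(modulated = variant)
    b <- make_training_batch(n_shift = 2, n_maintenance = 2, seed = 5,
                             constants = cst)
    set.seed(6)
    w <- runif(n_free_params(mv), -0.05, 0.05)
    g <- training_loss(w, mv, b, cst, grad = TRUE)$grad
    idx <- order(abs(g), decreasing = TRUE)[c(1, 5, 20)]
    h <- 1e-6
    fd <- vapply(idx, function(i) {
      wp <- w; wm <- w
      wp[i] <- wp[i] + h; wm[i] <- wm[i] - h
      (training_loss(wp, mv, b, cst)$value -
         training_loss(wm, mv, b, cst)$value) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(fd - g[idx]) / pmax(abs(fd), 1e-6)), 1e-4)
  }
})

test_that("optimisation is reproducible for a fixed seed and logs its progress", {
  f1 <- suppressWarnings(optimize_weights(mask, seed = 9, n_shift = 4,
                                          n_maintenance = 4, maxit = 5))
  f2 <- suppressWarnings(optimize_weights(mask, seed = 9, n_shift = 4,
                                          n_maintenance = 4, maxit = 5))
  expect_identical(weights_to_vector(f1$weights), weights_to_vector(f2$weights))
  expect_true(all(c("evaluation", "loss", "data_term", "reg_term") %in%
                    names(f1$log)))
  expect_lt(min(f1$log$loss), f1$log$loss[1])     # it made progress
})

test_that("training reduces the objective on the standard problem (cached fit)", {
  fit <- trained_fit("joint")
  expect_lt(fit$loss, 5)                          # far below the w=0 loss (~62)
  expect_equal(fit$log$loss[which.min(fit$log$loss)], fit$loss,
               tolerance = 1e-6)
})
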