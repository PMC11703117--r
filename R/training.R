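# Weight optimisation: activity-target generation, the training objective
# (mean-squared rate errors plus a diagonal-variance regulariser), its
# analytic gradient via a reverse-mode adjoint through the RK4 integrator,
# and the L-BFGS driver.

#' Ground-truth heading from an angular-velocity series
#'
#' Integrates the angular velocity with the trapezoidal rule on the sampling
#' grid and wraps the result, `phi(t_n) = phi0 + int v dt`.
#'
#' @param av angular velocities in degrees/s, one per integration step.
#' @param phi0 initial heading, degrees.
#' @param dt step length, ms.
#' @return headings in degrees, length `length(av) + 1` (including `phi0`).
#' @export
true_heading <- function(av, phi0 = 0, dt = 1) {
  n <- length(av)
  if (n == 0) return(wrap_angle(phi0))
  vn <- c(av, av[n])                       # hold the final sample
  incr <- (vn[-(n + 1)] + vn[-1]) / 2 * dt / 1000
  wrap_angle(phi0 + c(0, cumsum(incr)))
}

#' Activity targets encoding a heading
#'
#' The target rate profile is the cosine bump of [cosine_bump()]; CL1a and
#' CL2 targets are identical.
#'
#' @param phi heading(s), degrees.
#' @param constants a [model_constants()] object.
#' @return a 16 x length(phi) matrix of target rates, Hz.
#' @export
make_targets <- function(phi, constants = model_constants()) {
  vapply(phi, cosine_bump, numeric(16), constants = constants)
}

#' Assemble a training batch
#'
#' Maintenance trials hold zero angular velocity throughout and are penalised
#' against their initial bump at every 10th integration step; shift trials
#' apply a random constant velocity for the first 4/5 of the horizon and zero
#' for the final 1/5, and are penalised against the bump of the true final
#' heading over the final 10 steps.
#'
#' @param n_shift,n_maintenance numbers of trials.
#' @param horizon integration interval, ms.
#' @param dt integration step, ms.
#' @param seed integer RNG seed.
#' @param constants a [model_constants()] object.
#' @return an object of class `cx_batch`.
#' @export
make_training_batch <- function(n_shift = 64, n_maintenance = 64,
                                horizon = 200, dt = 4, seed = 1L,
                                constants = model_constants()) {
  set.seed(seed)
  B <- n_maintenance + n_shift
  n_rows <- round(horizon / dt)           # trajectory rows 0 .. n_rows-1
  n_steps <- n_rows - 1L
  n_shift_steps <- round(4 / 5 * horizon / dt)  # = 40 for 200 ms / 4 ms
  phi0 <- stats::runif(B, 0, 360)
  v <- c(rep(0, n_maintenance),
         stats::runif(n_shift, -constants$v_max, constants$v_max))
  is_shift <- c(rep(FALSE, n_maintenance), rep(TRUE, n_shift))
  V <- matrix(0, n_steps, B)
  V[seq_len(n_shift_steps), is_shift] <- rep(v[is_shift], each = n_shift_steps)
  phi_end <- phi0 + v * n_shift_steps * dt / 1000
  structure(list(
    phi0 = phi0, v = v, is_shift = is_shift, V = V,
    dt = dt, n_rows = n_rows, n_steps = n_steps,
    maint_rows = seq(0, n_steps, by = 10),
    shift_rows = seq(n_steps - 9, n_steps),
    maint_targets = make_targets(phi0[!is_shift], constants),
    shift_targets = make_targets(phi_end[is_shift], constants),
    P0 = vapply(phi0, function(p) init_state(p, constants)$P_s, numeric(33))),
    class = "cx_batch")
}

# --- Regulariser -------------------------------------------------------

# Group labels for the diagonal-variance regulariser, aligned with the
# parameter vector of weights_to_vector(). Within each 16x16 quadrant of the
# columnar connectivity, masked weights sharing the same wrapped diagonal
# offset (pre - post mod 16) form a group; the bias column forms one group
# per postsynaptic population. Applied identically to g_s, g_mod_cw and
# g_mod_ccw (with distinct group ids per matrix).
reg_group_ids <- function(mask) {
  block_offset_ids <- function(mat_mask) {
    idx <- which(mat_mask)
    i <- (idx - 1) %% 32 + 1          # post row
    j <- (idx - 1) %/% 32 + 1         # pre col
    ids <- integer(length(idx))
    colb <- j <= 32
    bi <- (i - 1) %% 16               # 0-based within-block indices
    bj <- (j - 1) %% 16
    block <- 2 * ((i - 1) %/% 16) + ifelse(j <= 16, 0, 1)  # 0..3
    ids[colb] <- (block[colb] * 16 + ((bj[colb] - bi[colb]) %% 16)) + 1
    if (any(!colb))                    # bias column: one group per population
      ids[!colb] <- 64 + 1 + (i[!colb] - 1) %/% 16
    ids
  }
  gs_ids <- block_offset_ids(mask$ff)
  mod_ids <- block_offset_ids(mask$mod)
  base <- max(gs_ids)
  nmod <- if (length(mod_ids)) max(mod_ids) else 0L
  c(gs_ids, base + mod_ids, base + nmod + mod_ids)
}

# Sum of population variances within regulariser groups; optionally its
# gradient with respect to the packed parameter vector.
reg_penalty <- function(w, groups, grad = FALSE) {
  f <- match(groups, sort(unique(groups)))   # contiguous group index
  n_g <- tabulate(f)
  mean_g <- rowsum(w, f)[, 1] / n_g
  dev <- w - mean_g[f]
  var_g <- rowsum(dev^2, f)[, 1] / n_g
  out <- list(value = sum(var_g))
  if (grad) out$grad <- 2 * dev / n_g[f]
  out
}

# --- Forward / backward passes ----------------------------------------

# Forward simulation of a batch at training resolution, storing the RK4
# stage states needed for the adjoint sweep. No clamping (the training
# trajectories stay inside [0,1]; see vignette).
training_forward <- function(gs, gcw, gccw, batch, cst, keep_stages = TRUE) {
  B <- length(batch$phi0)
  dt <- batch$dt; h2 <- dt / 2
  P <- if (!is.null(batch$P0)) batch$P0 else
    vapply(batch$phi0, function(p) init_state(p, cst)$P_s, numeric(33))
  pc <- rep(0, B); pcc <- rep(0, B)
  av <- pmin(abs(batch$v), cst$v_max) / cst$v_max
  tcw_all <- ifelse(batch$v > 0, av, 0)
  tccw_all <- ifelse(batch$v < 0, av, 0)
  rows_needed <- sort(unique(c(batch$maint_rows, batch$shift_rows)))
  row_state <- vector("list", batch$n_steps + 1L)
  if (0 %in% rows_needed) row_state[[1]] <- list(P = P, pc = pc, pcc = pcc)
  stages <- if (keep_stages) vector("list", batch$n_steps) else NULL
  for (n in seq_len(batch$n_steps)) {
    on <- batch$V[n, ] != 0
    tcw <- ifelse(on, tcw_all, 0); tccw <- ifelse(on, tccw_all, 0)
    k1 <- state_deriv(P, pc, pcc, tcw, tccw, gs, gcw, gccw, cst)
    y2 <- P + h2 * k1$dP; c2 <- pc + h2 * k1$dpc; cc2 <- pcc + h2 * k1$dpcc
    k2 <- state_deriv(y2, c2, cc2, tcw, tccw, gs, gcw, gccw, cst)
    y3 <- P + h2 * k2$dP; c3 <- pc + h2 * k2$dpc; cc3 <- pcc + h2 * k2$dpcc
    k3 <- state_deriv(y3, c3, cc3, tcw, tccw, gs, gcw, gccw, cst)
    y4 <- P + dt * k3$dP; c4 <- pc + dt * k3$dpc; cc4 <- pcc + dt * k3$dpcc
    k4 <- state_deriv(y4, c4, cc4, tcw, tccw, gs, gcw, gccw, cst)
    if (keep_stages)
      stages[[n]] <- list(y1 = P, y2 = y2, y3 = y3, y4 = y4,
                          pc = cbind(pc, c2, c3, c4),
                          pcc = cbind(pcc, cc2, cc3, cc4))
    P <- P + (dt / 6) * (k1$dP + 2 * k2$dP + 2 * k3$dP + k4$dP)
    pc <- pc + (dt / 6) * (k1$dpc + 2 * k2$dpc + 2 * k3$dpc + k4$dpc)
    pcc <- pcc + (dt / 6) * (k1$dpcc + 2 * k2$dpcc + 2 * k3$dpcc + k4$dpcc)
    if (n %in% rows_needed) row_state[[n + 1L]] <- list(P = P, pc = pc, pcc = pcc)
  }
  list(row_state = row_state, stages = stages)
}

# Rates (Hz, 32 x B) at a stored row state.
row_rates_hz <- function(st, gs, gcw, gccw, cst) {
  rates_stage(st$P, st$pc, st$pcc, gs, gcw, gccw, cst)$r * 1000
}

# Adjoint chain through the algebraic rate computation. Given the rate
# adjoint w_r (kHz-scale, 32 x B) at a state (P, pc, pcc), returns the
# induced state adjoint (33 x B) and accumulates weight gradients in env.
rate_chain_vjp <- function(w_r, P, pc, pcc, gs, gcw, gccw, cst, acc) {
  rs <- rates_stage(P, pc, pcc, gs, gcw, gccw, cst)
  rmax_k <- cst$r_max / 1000
  w_S <- w_r * (cst$slope * rs$r * (1 - rs$r / rmax_k)) *
    (cst$E_ex / (rs$den * rs$den))
  acc$dGs <- acc$dGs + tcrossprod(w_S, P)
  lam <- crossprod(gs, w_S)
  if (!is.null(gcw)) {
    X32 <- P[1:32, , drop = FALSE]
    wc <- w_S * rep(pc, each = 32)
    wcc <- w_S * rep(pcc, each = 32)
    acc$dGcw <- acc$dGcw + tcrossprod(wc, X32)
    acc$dGccw <- acc$dGccw + tcrossprod(wcc, X32)
    lam[1:32, ] <- lam[1:32, ] + crossprod(gcw, wc) + crossprod(gccw, wcc)
  }
  list(lam = lam, r = rs$r)
}

# VJP of the state derivative F at a stage. c is the adjoint of F (33 x B);
# returns the adjoint of the stage state.
deriv_vjp <- function(cc, P, pc, pcc, gs, gcw, gccw, cst, acc) {
  X32 <- P[1:32, , drop = FALSE]
  c32 <- cc[1:32, , drop = FALSE]
  w_r <- (cst$P_s_max - X32) * c32
  ch <- rate_chain_vjp(w_r, P, pc, pcc, gs, gcw, gccw, cst, acc)
  g <- ch$lam
  g[1:32, ] <- g[1:32, ] - (ch$r + 1 / cst$tau_s) * c32
  g[33, ] <- g[33, ] - (cst$r_bias / 1000 + 1 / cst$tau_s) * cc[33, ]
  g
}

#' Training objective (and gradient) for a weight set
#'
#' Mean-squared error between simulated CL1a/CL2 rates and the maintenance
#' and shift activity targets of a batch, plus `reg_weight` times the
#' diagonal-variance regulariser. The gradient is computed by a reverse-mode
#' adjoint sweep through the RK4 integration.
#'
#' @param w packed parameter vector (see [weights_to_vector()]) or a
#'   `cx_weights` object.
#' @param mask the connectivity mask (ignored if `w` is a `cx_weights`).
#' @param batch a [make_training_batch()] object.
#' @param constants a [model_constants()] object.
#' @param reg_weight relative weight of the regulariser.
#' @param grad if `TRUE`, also return the analytic gradient.
#' @return a list with `value`, `data_term`, `reg_term`, and optionally
#'   `grad`.
#' @export
training_loss <- function(w, mask = NULL, batch, constants = model_constants(),
                          reg_weight = 0.1, grad = FALSE) {
  if (inherits(w, "cx_weights")) {
    mask <- w$mask
    wvec <- weights_to_vector(w)
  } else wvec <- w
  wts <- vector_to_weights(wvec, mask)
  gs <- wts$gs
  has_mod <- sum(mask$mod) > 0
  gcw <- if (has_mod) wts$gcw else NULL
  gccw <- if (has_mod) wts$gccw else NULL
  cst <- constants
  B <- length(batch$phi0)
  im <- which(!batch$is_shift); is <- which(batch$is_shift)
  fw <- training_forward(gs, gcw, gccw, batch, cst, keep_stages = grad)

  # per-term denominators (each term is a mean over trials x rows x 16)
  den_m <- length(im) * length(batch$maint_rows) * 16
  den_s <- length(is) * length(batch$shift_rows) * 16
  terms <- c(m1 = 0, m2 = 0, s1 = 0, s2 = 0)
  err_at <- function(row, cols, targets) {
    st <- fw$row_state[[row + 1L]]
    R <- row_rates_hz(list(P = st$P[, cols, drop = FALSE],
                           pc = st$pc[cols], pcc = st$pcc[cols]),
                      gs, gcw, gccw, cst)
    R - rbind(targets, targets)
  }
  for (row in batch$maint_rows) {
    e <- err_at(row, im, batch$maint_targets)
    terms["m1"] <- terms["m1"] + sum(e[1:16, ]^2) / den_m
    terms["m2"] <- terms["m2"] + sum(e[17:32, ]^2) / den_m
  }
  for (row in batch$shift_rows) {
    e <- err_at(row, is, batch$shift_targets)
    terms["s1"] <- terms["s1"] + sum(e[1:16, ]^2) / den_s
    terms["s2"] <- terms["s2"] + sum(e[17:32, ]^2) / den_s
  }
  groups <- reg_group_ids(mask)
  rp <- reg_penalty(wvec, groups, grad = grad)
  out <- list(value = sum(terms) + reg_weight * rp$value,
              data_term = sum(terms), reg_term = rp$value, terms = terms)
  if (!grad) return(out)

  # ---- adjoint sweep -------------------------------------------------
  acc <- new.env(parent = emptyenv())
  acc$dGs <- matrix(0, 32, 33)
  acc$dGcw <- matrix(0, 32, 32); acc$dGccw <- matrix(0, 32, 32)
  inject <- function(lam, row) {
    # gradient of the readout loss at this row; returns updated lambda
    st <- fw$row_state[[row + 1L]]
    add <- function(cols, targets, den) {
      sub <- list(P = st$P[, cols, drop = FALSE], pc = st$pc[cols],
                  pcc = st$pcc[cols])
      R <- row_rates_hz(sub, gs, gcw, gccw, cst)
      w_r <- 2 * (R - rbind(targets, targets)) / den * 1000  # kHz adjoint
      ch <- rate_chain_vjp(w_r, sub$P, sub$pc, sub$pcc, gs, gcw, gccw, cst, acc)
      lam[, cols] <<- lam[, cols] + ch$lam
    }
    if (row %in% batch$maint_rows) add(im, batch$maint_targets, den_m)
    if (row %in% batch$shift_rows) add(is, batch$shift_targets, den_s)
    lam
  }
  dt <- batch$dt
  lam <- matrix(0, 33, B)
  lam <- inject(lam, batch$n_steps)
  for (n in rev(seq_len(batch$n_steps))) {
    sg <- fw$stages[[n]]
    vj <- function(c_adj, k) deriv_vjp(c_adj, sg[[k]], sg$pc[, k], sg$pcc[, k],
                                       gs, gcw, gccw, cst, acc)
    g4 <- vj((dt / 6) * lam, 4L)
    g3 <- vj((dt / 3) * lam + dt * g4, 3L)
    g2 <- vj((dt / 3) * lam + (dt / 2) * g3, 2L)
    g1 <- vj((dt / 6) * lam + (dt / 2) * g2, 1L)
    lam <- lam + g1 + g2 + g3 + g4
    lam <- inject(lam, n - 1L)
  }
  gvec <- c(acc$dGs[mask$ff], acc$dGcw[mask$mod], acc$dGccw[mask$mod])
  out$grad <- gvec + reg_weight * rp$grad
  out
}

#' Fit all free synaptic weights by L-BFGS
#'
#' Minimises [training_loss()] over the masked weights with
#' `stats::optim(method = "L-BFGS-B")` and the analytic adjoint gradient.
#' Reproducible given `seed` (which is expanded into independent seeds for
#' batch generation and weight initialisation).
#'
#' @param mask a [build_columnar_mask()] object (use `modulated =` for the
#'   CL1a-only / CL2-only variants).
#' @param seed integer master seed.
#' @param constants a [model_constants()] object.
#' @param n_shift,n_maintenance,horizon,dt training-batch settings, passed to
#'   [make_training_batch()].
#' @param reg_weight relative regulariser weight.
#' @param maxit,lmm,pgtol,factr L-BFGS settings (history size `lmm`).
#' @param init_scale half-width of the uniform weight initialisation.
#' @param init optional `cx_weights` object (or packed vector) to warm-start
#'   from instead of the random initialisation.
#' @param verbose print optimiser progress.
#' @return an object of class `cx_fit`: `weights`, final `loss`, the
#'   optimiser `convergence` code and `message`, and a `log` data frame
#'   (evaluation, loss, data term, regulariser term).
#' @export
optimize_weights <- function(mask, seed = 1L, constants = model_constants(),
                             n_shift = 64, n_maintenance = 64,
                             horizon = 200, dt = 4, reg_weight = 0.1,
                             maxit = 500, lmm = 50, pgtol = 1e-7, factr = 1e7,
                             init_scale = 0.01, init = NULL, verbose = FALSE) {
  batch <- make_training_batch(n_shift, n_maintenance, horizon, dt,
                               seed = derive_seed(seed, "batch"),
                               constants = constants)
  w0 <- if (is.null(init)) {
    weights_to_vector(init_weights(mask, seed = derive_seed(seed, "init"),
                                   scale = init_scale))
  } else if (inherits(init, "cx_weights")) weights_to_vector(init) else init
  log_env <- new.env(parent = emptyenv())
  log_env$rows <- list()
  cache <- new.env(parent = emptyenv())
  evaluate <- function(w) {
    if (!is.null(cache$w) && identical(w, cache$w)) return(cache$res)
    res <- tryCatch(
      training_loss(w, mask, batch, constants, reg_weight, grad = TRUE),
      cx_numerical_degeneracy = function(e) {
        list(value = 1e8, data_term = 1e8, reg_term = 0,
             grad = rep(0, length(w)))
      })
    cache$w <- w; cache$res <- res
    log_env$rows[[length(log_env$rows) + 1L]] <-
      c(res$value, res$data_term, res$reg_term)
    if (verbose && length(log_env$rows) %% 25 == 0)
      message(sprintf("eval %d: loss %.4f (data %.4f, reg %.4f)",
                      length(log_env$rows), res$value, res$data_term,
                      res$reg_term))
    res
  }
  opt <- stats::optim(w0, fn = function(w) evaluate(w)$value,
                      gr = function(w) evaluate(w)$grad,
                      method = "L-BFGS-B",
                      control = list(maxit = maxit, lmm = lmm,
                                     pgtol = pgtol, factr = factr))
  if (opt$convergence != 0)
    warning(sprintf("L-BFGS did not fully converge (code %d, final loss %.4f): %s",
                    opt$convergence, opt$value, opt$message))
  logm <- do.call(rbind, log_env$rows)
  structure(list(
    weights = vector_to_weights(opt$par, mask),
    loss = opt$value, convergence = opt$convergence, message = opt$message,
    log = data.frame(evaluation = seq_len(nrow(logm)), loss = logm[, 1],
                     data_term = logm[, 2], reg_term = logm[, 3]),
    seed = seed, maxit = maxit),
    class = "cx_fit")
}

#' @export
print.cx_fit <- function(x, ...) {
  cat(sprintf("Fitted heading-circuit weights: final loss %.4f after %d evaluations (seed %d)\n",
              x$loss, nrow(x$log), x$seed))
  invisible(x)
}
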