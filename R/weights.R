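# The free parameters: unmodulated weights plus per-AV-neuron modulatory
# weights, all living on the connectivity mask.

#' Construct a weight set on a connectivity mask
#'
#' @param mask a [build_columnar_mask()] object.
#' @param gs 32 x 33 matrix of unmodulated (signed) weights; must be zero
#'   off-mask.
#' @param gcw,gccw 32 x 32 matrices of modulatory weights of the clockwise /
#'   counterclockwise AV neuron; zero off the modulatory mask.
#' @return an object of class `cx_weights`.
#' @export
new_weights <- function(mask, gs, gcw, gccw) {
  stopifnot(inherits(mask, "cx_mask"),
            all(dim(gs) == c(32, 33)), all(dim(gcw) == c(32, 32)),
            all(dim(gccw) == c(32, 32)))
  if (any(gs[!mask$ff] != 0) || any(gcw[!mask$mod] != 0) ||
      any(gccw[!mask$mod] != 0))
    cx_stop("weights must be zero off-mask", "cx_invalid_argument")
  dimnames(gs) <- dimnames(mask$ff)
  dimnames(gcw) <- dimnames(gccw) <- dimnames(mask$ff)[c(1, 1)]
  colnames(gcw) <- colnames(gccw) <- rownames(mask$ff)
  structure(list(gs = gs, gcw = gcw, gccw = gccw, mask = mask),
            class = "cx_weights")
}

#' Random small initial weights
#'
#' Zero-mean uniform initialisation on the masked positions.
#'
#' @param mask a `cx_mask`.
#' @param seed integer RNG seed.
#' @param scale half-width of the uniform distribution.
#' @return a `cx_weights` object.
#' @export
init_weights <- function(mask, seed = 1L, scale = 0.01) {
  set.seed(seed)
  w <- stats::runif(n_free_params(mask), -scale, scale)
  vector_to_weights(w, mask)
}

#' Number of free parameters on a mask
#' @param mask a `cx_mask`.
#' @export
n_free_params <- function(mask) sum(mask$ff) + 2 * sum(mask$mod)

#' Pack masked weights into a parameter vector and back
#'
#' The vector layout is `[gs on ff-mask, gcw on mod-mask, gccw on mod-mask]`
#' in column-major mask order.
#'
#' @param weights a `cx_weights` object.
#' @param w numeric parameter vector of length [n_free_params()].
#' @param mask a `cx_mask`.
#' @export
weights_to_vector <- function(weights) {
  m <- weights$mask
  c(weights$gs[m$ff], weights$gcw[m$mod], weights$gccw[m$mod])
}

#' @rdname weights_to_vector
#' @export
vector_to_weights <- function(w, mask) {
  nf <- sum(mask$ff); nm <- sum(mask$mod)
  if (length(w) != nf + 2 * nm)
    cx_stop("parameter vector length does not match mask", "cx_invalid_argument")
  gs <- matrix(0, 32, 33); gs[mask$ff] <- w[seq_len(nf)]
  gcw <- matrix(0, 32, 32); gcw[mask$mod] <- w[nf + seq_len(nm)]
  gccw <- matrix(0, 32, 32); gccw[mask$mod] <- w[nf + nm + seq_len(nm)]
  new_weights(mask, gs, gcw, gccw)
}

#' Apply multiplicative weight noise
#'
#' Each weight (feed-forward and modulatory) is multiplied by an independent
#' factor uniform in `[1 - range, 1 + range]`, as done once at the start of a
#' perturbed trial.
#'
#' @param weights a `cx_weights` object.
#' @param range noise half-range (0 disables).
#' @return a perturbed `cx_weights` object.
#' @export
perturb_weights <- function(weights, range) {
  if (range < 0) cx_stop("noise range must be >= 0", "cx_invalid_argument")
  if (range == 0) return(weights)
  m <- weights$mask
  w <- weights_to_vector(weights)
  w <- w * stats::runif(length(w), 1 - range, 1 + range)
  vector_to_weights(w, m)
}

#' @export
print.cx_weights <- function(x, ...) {
  cat(sprintf("Heading-circuit weight set: %d free parameters (%d feed-forward, 2 x %d modulatory)\n",
              n_free_params(x$mask), sum(x$mask$ff), sum(x$mask$mod)))
  cat(sprintf("  |g_s| range: [%.3g, %.3g]; modulated populations: %s\n",
              min(abs(x$gs[x$mask$ff])), max(abs(x$gs)),
              paste(x$mask$modulated, collapse = "+")))
  invisible(x)
}
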