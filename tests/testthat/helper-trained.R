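# Shared fixtures: trained weight sets are expensive, so they are fitted
# once per test run and memoised. Training uses the standard study
# conditions (64 shift + 64 maintenance trials, 200 ms horizon, 4 ms steps,
# regulariser weight 0.1); the optimiser iteration cap is the test-scale
# problem size documented in the methods vignette.

.fit_cache <- new.env(parent = emptyenv())

trained_fit <- function(variant = c("joint", "cl1a", "cl2")) {
  variant <- match.arg(variant)
  if (!is.null(.fit_cache[[variant]])) return(.fit_cache[[variant]])
  mask <- switch(variant,
                 joint = build_columnar_mask(),
                 cl1a = build_columnar_mask(modulated = "CL1a"),
                 cl2 = build_columnar_mask(modulated = "CL2"))
  fit <- suppressWarnings(
    optimize_weights(mask, seed = 20L, maxit = 1200, verbose = FALSE))
  .fit_cache[[variant]] <- fit
  fit
}

trained_weights <- function(variant = "joint") trained_fit(variant)$weights

cached_integration <- function(variant = "joint", n_trials = 200, seed = 101L) {
  key <- paste0("int_", variant, "_", n_trials, "_", seed)
  if (is.null(.fit_cache[[key]]))
    .fit_cache[[key]] <- run_integration_suite(
      trained_weights(variant), noise_config(seed = seed),
      n_trials = n_trials, duration_ms = 4000)
  .fit_cache[[key]]
}
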