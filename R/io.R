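# Serialisation and reproducibility plumbing: weight files, trajectory
# export, deterministic per-stage seed derivation, and run manifests.

WEIGHTS_FORMAT_VERSION <- 1L

#' Deterministic per-stage seeds from one master seed
#'
#' Expands a master seed and a stage label into an independent seed, so that
#' partial re-runs of a pipeline stay reproducible. Results are in
#' `[1, 2^31 - 2]`.
#'
#' @param seed integer master seed.
#' @param stage character stage label (e.g. `"batch"`, `"trial_17"`).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  m <- 2147483647
  h <- as.double(seed %% m)
  for (code in utf8ToInt(as.character(stage)))
    h <- (h * 48271 + code) %% m
  as.integer(h %% (m - 1)) + 1L
}

#' Save and load a weight set
#'
#' Weights are written as a long-format CSV (`matrix`, `post`, `pre`,
#' `value`) with full double precision and a versioned header comment, so
#' that a save/load round trip is bit-exact. Loading rebuilds the
#' connectivity mask from the recorded modulated-population variant and
#' verifies that the stored positions match it.
#'
#' @param weights a `cx_weights` object.
#' @param path file path.
#' @return `load_weights` returns a `cx_weights` object.
#' @export
save_weights <- function(weights, path) {
  stopifnot(inherits(weights, "cx_weights"))
  m <- weights$mask
  nn <- neuron_names()
  block <- function(mat, msk, label, ncolmax) {
    idx <- which(msk)
    i <- (idx - 1) %% 32 + 1
    j <- (idx - 1) %/% 32 + 1
    data.frame(matrix = label, post = nn[i], pre = nn[j],
               value = sprintf("%.17g", mat[idx]))
  }
  df <- rbind(block(weights$gs, m$ff, "g_s"),
              block(weights$gcw, m$mod, "g_mod_cw"),
              block(weights$gccw, m$mod, "g_mod_ccw"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# locustcompass weights v%d", WEIGHTS_FORMAT_VERSION),
               sprintf("# modulated: %s", paste(m$modulated, collapse = "+"))),
             con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path) {
  head2 <- readLines(path, n = 2)
  if (!grepl("^# locustcompass weights v", head2[1]))
    cx_stop("not a locustcompass weights file", "cx_format_error")
  ver <- as.integer(sub("^# locustcompass weights v", "", head2[1]))
  if (!identical(ver, WEIGHTS_FORMAT_VERSION))
    cx_stop(sprintf("unsupported weights format version %s", ver),
            "cx_format_error")
  modulated <- strsplit(sub("^# modulated: ", "", head2[2]), "\\+")[[1]]
  if (!all(modulated %in% c("CL1a", "CL2")))
    cx_stop("corrupt modulated-population header", "cx_format_error")
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c("character", "character", "character",
                                       "numeric"))
  mask <- build_columnar_mask(modulated = modulated)
  nn <- neuron_names()
  fill <- function(label, msk, ncols) {
    sub <- df[df$matrix == label, ]
    if (label != "g_s" && nrow(sub) == 0 && sum(msk) > 0)
      cx_stop(sprintf("weights file is missing the %s block", label),
              "cx_format_error")
    i <- match(sub$post, nn); j <- match(sub$pre, nn)
    if (any(is.na(i)) || any(is.na(j)) || any(j > ncols))
      cx_stop("unknown neuron name in weights file", "cx_format_error")
    mat <- matrix(0, 32, ncols)
    pos <- cbind(i, j)
    expected <- which(msk)
    got <- sort(as.integer((j - 1) * 32 + i))
    if (!identical(got, expected))
      cx_stop(sprintf("stored %s positions do not match the connectivity mask",
                      label), "cx_format_error")
    mat[pos] <- sub$value
    mat
  }
  new_weights(mask,
              fill("g_s", mask$ff, 33),
              fill("g_mod_cw", mask$mod, 32),
              fill("g_mod_ccw", mask$mod, 32))
}

#' Export a connectivity mask as named CSV matrices
#'
#' Writes the feed-forward and modulatory masks as 0/1 matrices with neuron
#' names as header row and row names.
#'
#' @param mask a `cx_mask`.
#' @param ff_path,mod_path output paths (`NULL` skips a matrix).
#' @export
write_mask <- function(mask, ff_path = NULL, mod_path = NULL) {
  if (!is.null(ff_path))
    utils::write.csv(1L * mask$ff, ff_path)
  if (!is.null(mod_path))
    utils::write.csv(1L * mask$mod, mod_path)
  invisible(NULL)
}

#' Write a rate trajectory as long-format CSV
#'
#' @param sim a `cx_simulation` with a recorded trajectory.
#' @param path output path.
#' @export
write_rate_trajectory <- function(sim, path) {
  utils::write.csv(as.data.frame(sim), path, row.names = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records what produced a set of outputs: subcommand, configuration values,
#' seeds, package version, and the MD5 of any input files.
#'
#' @param path output path.
#' @param command character label of the pipeline stage.
#' @param config a named list of settings.
#' @param seed master seed.
#' @param inputs character vector of input file paths (hashed if they exist).
#' @export
write_manifest <- function(path, command, config = list(), seed = NA_integer_,
                           inputs = character(0)) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else NULL
  manifest <- list(
    command = command,
    package = "locustcompass",
    version = as.character(utils::packageVersion("locustcompass")),
    seed = seed,
    config = config,
    input_md5 = hashes,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
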