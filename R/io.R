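#' Experiment directory layout
#'
#' An experiment is stored as a directory of plain-text files:
#' \describe{
#'   \item{`traces.csv`}{N x T trace matrix (original polarity, one row per
#'     trial, full floating-point precision).}
#'   \item{`meta.json`}{sampling rate, polarity, units, stimulus timing,
#'     per-trial powers and target lists, target locations, and the full
#'     generating configuration and seed when simulated.}
#'   \item{`truth.json` / `truth_events.csv`}{optional simulator ground
#'     truth.}
#' }
#' Results directories hold `artifact.csv`, `demixed.csv`, `batches.json`
#' (per-batch factors and diagnostics) and `config.json`.
#'
#' @name experiment-io
NULL

.write_matrix <- function(x, path) {
  readr::write_csv(as.data.frame(x), path, col_names = FALSE, progress = FALSE)
}

.read_matrix <- function(path) {
  m <- as.matrix(data.table::fread(path, header = FALSE))
  dimnames(m) <- NULL
  m
}

.require_field <- function(meta, ...) {
  keys <- c(...)
  node <- meta
  for (k in keys) {
    if (is.null(node[[k]]))
      pd_stop("experiment metadata missing required field \"%s\"",
              paste(keys, collapse = "/"))
    node <- node[[k]]
  }
  node
}

#' Write an experiment to a directory
#'
#' @param experiment list as returned by [simulate_mapping_experiment()]
#'   (fields `raw`, `metadata`, `window`, optionally `truth`, `config`).
#' @param path directory to create/populate.
#' @param polarity sign convention of `experiment$raw`.
#' @param units units of the stored traces.
#' @return `path`, invisibly.
#' @export
write_experiment <- function(experiment, path, polarity = "inward_negative",
                             units = "pA") {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  .write_matrix(experiment$raw, file.path(path, "traces.csv"))
  md <- experiment$metadata
  w <- experiment$window
  meta <- list(
    sampling_rate_hz = w$sampling_rate_hz,
    polarity = polarity,
    units = units,
    stim = list(onset_sample = w$t1,
                duration_samples = w$stim_duration_samples,
                power_mW = md$powers_mW,
                max_power_mW = md$max_power_mW,
                targets = md$targets,
                target_locations_um = md$target_locations_um,
                trial_times_s = md$trial_times_s),
    config = experiment$config)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(experiment$truth)) {
    tr <- experiment$truth
    jsonlite::write_json(
      list(connected = tr$connected, weights = tr$weights,
           q_flags = tr$q_flags, mu = tr$mu, A = tr$A,
           kinetics = unclass(tr$kinetics)),
      file.path(path, "truth.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(tr$psc_events))
      readr::write_csv(tr$psc_events, file.path(path, "truth_events.csv"),
                       progress = FALSE)
  }
  invisible(path)
}

#' Read an experiment directory
#'
#' Validates the layout (errors name the missing field), normalizes units
#' to pA, and returns typed objects.
#'
#' @param path experiment directory.
#' @return list with `raw` (original polarity, pA), `Y` (a rectified
#'   [trace_matrix()]), `metadata`, `window`, `polarity`, and `truth`
#'   (`NULL` when absent).
#' @export
read_experiment <- function(path) {
  tf <- file.path(path, "traces.csv")
  if (!file.exists(tf)) pd_stop("experiment at %s missing traces.csv", path)
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) pd_stop("experiment at %s missing meta.json", path)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  fs <- .require_field(meta, "sampling_rate_hz")
  polarity <- .require_field(meta, "polarity")
  onset <- .require_field(meta, "stim", "onset_sample")
  dur <- .require_field(meta, "stim", "duration_samples")
  powers <- .require_field(meta, "stim", "power_mW")
  max_p <- .require_field(meta, "stim", "max_power_mW")
  targets <- .require_field(meta, "stim", "targets")
  raw <- to_pA(.read_matrix(tf), meta$units %||% "pA")
  if (length(powers) != nrow(raw))
    pd_stop("shape mismatch: %d trials in traces.csv vs %d powers",
            nrow(raw), length(powers))
  if (!is.list(targets)) targets <- as.list(targets)
  locs <- meta$stim$target_locations_um
  if (!is.null(locs)) locs <- matrix(unlist(locs), ncol = 3, byrow = FALSE)
  metadata <- stimulus_metadata(powers, max_p, targets,
                                target_locations_um = locs,
                                trial_times_s = meta$stim$trial_times_s)
  window <- window_spec(onset, dur, fs, n_samples = ncol(raw))
  Y <- rectify_traces(raw, polarity, fs, onset, dur)
  truth <- NULL
  tj <- file.path(path, "truth.json")
  if (file.exists(tj)) {
    truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
    te <- file.path(path, "truth_events.csv")
    if (file.exists(te))
      truth$psc_events <- as.data.frame(data.table::fread(te))
  }
  list(raw = raw, Y = Y, metadata = metadata, window = window,
       polarity = polarity, truth = truth, config = meta$config)
}

#' Write demixing results to a directory
#'
#' @param fit a `demix_fit` from [remove_photocurrents()].
#' @param path directory to create/populate.
#' @return `path`, invisibly.
#' @export
write_results <- function(fit, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  .write_matrix(fit$artifact, file.path(path, "artifact.csv"))
  .write_matrix(fit$demixed, file.path(path, "demixed.csv"))
  batches <- lapply(fit$batches, function(b) list(
    U_base = as.vector(b$U_base), V_base = b$V_base,
    U_stim = b$U_stim, V_stim = b$V_stim, beta = b$beta))
  jsonlite::write_json(
    list(assignment = fit$partition$assignment,
         order = fit$partition$order,
         sizes = fit$partition$sizes,
         batches = batches,
         diagnostics = fit$diagnostics),
    file.path(path, "batches.json"), auto_unbox = TRUE, digits = NA)
  cfg <- fit$config
  cfg$admm <- unclass(cfg$admm)
  jsonlite::write_json(unclass(cfg), file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a results directory
#'
#' @param path results directory written by [write_results()].
#' @return list with `artifact`, `demixed`, `assignment`, `batches`,
#'   `diagnostics`, `config`.
#' @export
read_results <- function(path) {
  bj <- jsonlite::read_json(file.path(path, "batches.json"),
                            simplifyVector = TRUE)
  list(artifact = .read_matrix(file.path(path, "artifact.csv")),
       demixed = .read_matrix(file.path(path, "demixed.csv")),
       assignment = bj$assignment, batches = bj$batches,
       diagnostics = bj$diagnostics,
       config = jsonlite::read_json(file.path(path, "config.json"),
                                    simplifyVector = TRUE))
}
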