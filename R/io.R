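# On-disk layout: a directory of plain CSV tables.
#   neurons.csv  neuron_id, condition, anesthetic, duration_s
#   spikes.csv   neuron_id, spike_time_s           (long, one row per spike)
#   trials.csv   neuron_id, onset_s, stim_duration_s        (optional)
#   motion.csv   session_id, sample_rate_hz, energy         (optional)
#   labels.csv   neuron_id, type, ...                       (optional)
# Times are seconds everywhere.

#' Write a dataset to a directory of CSV files
#'
#' @param dataset List with `neurons` (required) and optional `trials`,
#'   `motion`, `labels` as produced by the simulators.
#' @param path Directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_spike_dataset <- function(dataset, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  n <- dataset$neurons
  validate_spike_trains(n)
  readr::write_csv(
    tibble::tibble(neuron_id = n$neuron_id, condition = n$condition,
                   anesthetic = n$anesthetic, duration_s = n$duration),
    file.path(path, "neurons.csv"))
  readr::write_csv(
    tidyr::unnest(tibble::tibble(neuron_id = n$neuron_id,
                                 spike_time_s = n$spikes),
                  "spike_time_s"),
    file.path(path, "spikes.csv"))
  if (!is.null(dataset$trials)) {
    tr <- dataset$trials
    readr::write_csv(
      tidyr::unnest(tibble::tibble(neuron_id = tr$neuron_id,
                                   stim_duration_s = tr$stim_duration,
                                   onset_s = tr$onsets), "onset_s"),
      file.path(path, "trials.csv"))
  }
  if (!is.null(dataset$motion)) {
    m <- dataset$motion
    readr::write_csv(
      tibble::tibble(session_id = m$session_id,
                     sample_rate_hz = attr(m, "sample_rate"),
                     energy = m$energy),
      file.path(path, "motion.csv"))
  }
  if (!is.null(dataset$labels))
    readr::write_csv(dataset$labels, file.path(path, "labels.csv"))
  invisible(path)
}

#' Read a dataset from a directory of CSV files
#'
#' Validates every record; malformed rows fail with an error naming the
#' neuron and the violated invariant.
#'
#' @param path Directory written by [write_spike_dataset()] (or following
#'   the same layout).
#' @return List with `neurons` and, when present on disk, `trials`,
#'   `motion`, `labels`.
#' @export
read_spike_dataset <- function(path) {
  f_neurons <- file.path(path, "neurons.csv")
  if (!file.exists(f_neurons)) abort(paste0("no neurons.csv in ", path))
  meta <- readr::read_csv(f_neurons, show_col_types = FALSE)
  need <- c("neuron_id", "condition", "anesthetic", "duration_s")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    abort(paste0("neurons.csv: missing column(s) ", paste(miss, collapse = ", ")))
  if (any(is.na(meta$duration_s)))
    abort(sprintf("neurons.csv row %d: missing duration",
                  which(is.na(meta$duration_s))[1]))
  spk <- readr::read_csv(file.path(path, "spikes.csv"), show_col_types = FALSE)
  unknown <- setdiff(unique(spk$neuron_id), meta$neuron_id)
  if (length(unknown))
    abort(paste0("spikes.csv: neuron absent from neurons.csv: ", unknown[1]))
  spikes <- lapply(meta$neuron_id, function(id)
    spk$spike_time_s[spk$neuron_id == id])
  neurons <- spike_trains(meta$neuron_id, spikes, meta$duration_s,
                          meta$condition, meta$anesthetic)
  out <- list(neurons = neurons)
  f_tr <- file.path(path, "trials.csv")
  if (file.exists(f_tr)) {
    tr <- readr::read_csv(f_tr, show_col_types = FALSE)
    ids <- unique(tr$neuron_id)
    out$trials <- trial_sets(
      ids, lapply(ids, function(id) sort(tr$onset_s[tr$neuron_id == id])),
      stim_duration = tr$stim_duration_s[1])
  }
  f_m <- file.path(path, "motion.csv")
  if (file.exists(f_m)) {
    m <- readr::read_csv(f_m, show_col_types = FALSE)
    sid <- unique(m$session_id)
    traces <- lapply(sid, function(id) {
      rows <- m[m$session_id == id, ]
      motion_trace(id, rows$energy, rows$sample_rate_hz[1])
    })
    mo <- dplyr::bind_rows(traces)
    attr(mo, "sample_rate") <- m$sample_rate_hz[1]
    out$motion <- mo
  }
  f_l <- file.path(path, "labels.csv")
  if (file.exists(f_l))
    out$labels <- readr::read_csv(f_l, show_col_types = FALSE)
  out
}

#' Write analysis results
#'
#' Tabular results (feature tables, modulation records, tidy label or
#' assignment tables) go to CSV; a fitted mixture goes to JSON with its
#' means, covariances, weights, labels and BIC curve so it can be reloaded.
#'
#' @param x A tibble, `hab_features`, `hab_gmm` or `hab_match`.
#' @param path Output file path (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  if (inherits(x, "hab_gmm")) {
    obj <- list(
      k = x$k, covariance = x$covariance, weights = x$weights,
      means = x$means, covariances = x$covariances,
      loglik = x$loglik, bic = x$bic, labels = x$labels,
      neuron_id = x$neuron_id, feature_names = x$feature_names,
      bic_table = x$bic_table, k_grid = x$k_grid
    )
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                         pretty = TRUE)
  } else if (inherits(x, "hab_match")) {
    obj <- list(similarity = x$similarity, assignment = x$assignment,
                accepted = x$accepted, threshold = x$threshold)
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                         pretty = TRUE)
  } else if (is.data.frame(x)) {
    drop <- vapply(x, is.list, logical(1))
    readr::write_csv(x[, !drop, drop = FALSE], path)
  } else {
    abort("unsupported result type")
  }
  invisible(path)
}

#' Re-read a mixture model written by [write_results()]
#'
#' Restores the numeric content (means, covariances, weights, labels, BIC
#' table); the attached feature table is not serialized.
#'
#' @param path JSON file path.
#' @return A list mirroring the serialized `hab_gmm` fields.
#' @export
read_cluster_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$means <- as.matrix(obj$means)
  if (is.array(obj$covariances) && length(dim(obj$covariances)) == 3) {
    obj$covariances <- lapply(seq_len(dim(obj$covariances)[1]),
                              function(i) obj$covariances[i, , ])
  }
  obj
}
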