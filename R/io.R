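#' Write a recording to CSV
#'
#' Layout: columns `time_s`, the six motion channels, `pad1`, `pad2`.
#'
#' @param recording A `raw_recording`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_recording_csv <- function(recording, path) {
  stopifnot(inherits(recording, "raw_recording"))
  df <- data.frame(time_s = recording$time, recording$motion, recording$pads)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a recording from CSV
#'
#' Expects the layout written by [write_recording_csv()]. The sampling rate
#' is recovered from the time column and checked for uniformity.
#'
#' @param path Input file path.
#' @param metadata Named list attached to the recording.
#' @return A `raw_recording`.
#' @export
read_recording_csv <- function(path, metadata = list()) {
  df <- utils::read.csv(path)
  needed <- c("time_s", promp_channels, "pad1", "pad2")
  if (!all(needed %in% names(df))) {
    stop("recording CSV must have columns: ", paste(needed, collapse = ", "))
  }
  dt <- diff(df$time_s)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * stats::median(dt)) {
    stop("time column must be strictly increasing and uniformly sampled")
  }
  new_raw_recording(1 / stats::median(dt),
                    as.matrix(df[, promp_channels]),
                    as.matrix(df[, c("pad1", "pad2")]),
                    metadata = metadata)
}

#' Write a study manifest to CSV
#'
#' @param study A `promp_study`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_manifest_csv <- function(study, path) {
  stopifnot(inherits(study, "promp_study"))
  utils::write.csv(study$manifest, path, row.names = FALSE)
  invisible(path)
}

#' Write a stroke set to CSV
#'
#' Long layout: `stroke_id`, `phase_index`, then the six channels; one row
#' per (stroke, phase point).
#'
#' @param set A [stroke_set()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_stroke_set_csv <- function(set, path) {
  stopifnot(inherits(set, "stroke_set"))
  d <- dim(set$data)
  df <- data.frame(stroke_id = rep(seq_len(d[1]), each = d[2]),
                   phase_index = rep(seq_len(d[2]), d[1]))
  mat <- matrix(aperm(set$data, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
  colnames(mat) <- dimnames(set$data)[[3]]
  utils::write.csv(cbind(df, mat), path, row.names = FALSE)
  invisible(path)
}

#' Serialize a fitted ProMP to JSON
#'
#' Stores the basis configuration, weight mean and covariance, observation
#' noise and fit settings; [read_promp_json()] reconstructs the model
#' (recomputing the basis matrix from its configuration).
#'
#' @param model A `promp_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_promp_json <- function(model, path) {
  stopifnot(inherits(model, "promp_model"))
  payload <- list(M = model$basis$M, T = model$basis$grid$T, D = model$D,
                  lambda = model$lambda, jitter = model$jitter, n = model$n,
                  channels = model$channels, direction = model$direction,
                  sigma_y = unname(model$sigma_y),
                  weight_mean = unname(model$mean),
                  weight_cov = unname(model$cov))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a fitted ProMP from JSON
#'
#' @param path File written by [write_promp_json()].
#' @return A `promp_model`.
#' @export
read_promp_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  basis <- make_basis(p$M, phase_grid(p$T))
  structure(list(basis = basis, mean = as.numeric(p$weight_mean),
                 cov = matrix(unlist(p$weight_cov), p$M * p$D, p$M * p$D,
                              byrow = TRUE),
                 sigma_y = stats::setNames(as.numeric(p$sigma_y), p$channels),
                 lambda = p$lambda, jitter = p$jitter, n = p$n, D = p$D,
                 channels = p$channels, direction = p$direction,
                 metadata = list()),
            class = "promp_model")
}

#' Write a divergence table to CSV
#'
#' @param table Divergence table from [compare_phases()] or
#'   [detect_outliers()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_divergence_csv <- function(table, path) {
  stopifnot(is.data.frame(table))
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Write a sliding-window profile to CSV
#'
#' Columns `phase_center`, `value`.
#'
#' @param profile A `window_profile` from [sliding_window_kls()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_window_csv <- function(profile, path) {
  stopifnot(inherits(profile, "window_profile"))
  utils::write.csv(data.frame(phase_center = profile$centers,
                              value = profile$values),
                   path, row.names = FALSE)
  invisible(path)
}
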