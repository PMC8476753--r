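#' Uniform movement-phase grid
#'
#' The common phase axis all strokes are resampled onto. Phase rescales time
#' to `[0, 1]` per stroke, decoupling trajectory shape from duration.
#'
#' @param n_points Number of grid points `T`.
#' @return An object of class `phase_grid` with fields `T` and `z`
#'   (strictly increasing, `z[1] = 0`, `z[T] = 1`).
#' @export
phase_grid <- function(n_points = 100) {
  stopifnot(is.numeric(n_points), length(n_points) == 1, n_points >= 2)
  structure(list(T = as.integer(n_points),
                 z = seq(0, 1, length.out = as.integer(n_points))),
            class = "phase_grid")
}

#' Default pad-transition to movement-direction map
#'
#' Maps the ordered pad pair of a segmented stroke to a movement direction.
#' The anatomical definition (inward: the elbow angle decreases) is not
#' computable from the signals alone, so the map is explicit configuration;
#' the default matches the synthetic generator, where inward strokes travel
#' from pad 1 to pad 2.
#'
#' @param inward_from Pad the inward stroke starts from (1 or 2).
#' @return Named list mapping `"1->2"` and `"2->1"` to direction labels.
#' @export
default_direction_convention <- function(inward_from = 1) {
  stopifnot(inward_from %in% c(1, 2))
  if (inward_from == 1) {
    list("1->2" = "inward", "2->1" = "outward")
  } else {
    list("2->1" = "inward", "1->2" = "outward")
  }
}

#' Detect pad contacts in a recording
#'
#' A tap is the first sample at which the absolute pad signal crosses a
#' threshold expressed as a fraction of that channel's maximum; re-crossings
#' within the refractory window are suppressed. Events from both pads are
#' merged and returned in time order.
#'
#' @param recording A `raw_recording`.
#' @param threshold Fraction of the per-channel maximum absolute amplitude,
#'   in (0, 1). Default 0.5.
#' @param refractory Minimum time between events on the same pad, seconds.
#' @return A `data.frame` with columns `sample_index`, `pad_id` and `time`,
#'   strictly ordered in time.
#' @export
detect_taps <- function(recording, threshold = 0.5, refractory = 0.1) {
  stopifnot(inherits(recording, "raw_recording"))
  stopifnot(threshold > 0, threshold < 1, refractory > 0)
  fs <- recording$sampling_rate
  refr_n <- refractory * fs
  events <- list()
  for (pad in 1:2) {
    x <- abs(recording$pads[, pad])
    m <- max(x)
    if (m == 0) {
      stop(sprintf("no taps detected: pad channel %d is flat", pad))
    }
    above <- x >= threshold * m
    onsets <- which(above & !c(FALSE, above[-length(above)]))
    keep <- integer(0)
    last <- -Inf
    for (s in onsets) {
      if (s - last > refr_n) {
        keep <- c(keep, s)
        last <- s
      }
    }
    events[[pad]] <- data.frame(sample_index = keep, pad_id = pad)
  }
  ev <- rbind(events[[1]], events[[2]])
  ev <- ev[order(ev$sample_index, ev$pad_id), ]
  rownames(ev) <- NULL
  ev$time <- (ev$sample_index - 1) / fs
  ev
}

#' Segment a recording into directed strokes
#'
#' Each pair of consecutive tap events delimits one stroke, so `K + 1`
#' events yield `K` strokes with alternating directions. The direction is
#' assigned from the ordered pad pair via `convention`. Runs of events on
#' the same pad (double contacts) are reduced to their first event with a
#' warning.
#'
#' @param recording A `raw_recording`.
#' @param events Tap events from [detect_taps()].
#' @param convention Pad-transition map, see [default_direction_convention()].
#' @return A list with components `inward` and `outward`, each a list of
#'   `stroke` objects (fields `samples`, `direction`, `interval`).
#' @export
segment_strokes <- function(recording, events,
                            convention = default_direction_convention()) {
  stopifnot(inherits(recording, "raw_recording"), is.data.frame(events))
  runs <- rle(events$pad_id)
  if (any(runs$lengths > 1)) {
    warning(sprintf("%d repeated same-pad event(s) discarded (keeping first of each run)",
                    sum(runs$lengths) - length(runs$lengths)))
    first_of_run <- cumsum(c(1, runs$lengths[-length(runs$lengths)]))
    events <- events[first_of_run, ]
  }
  n_ev <- nrow(events)
  if (n_ev < 2) stop("need at least 2 tap events to segment strokes")
  strokes <- list(inward = list(), outward = list())
  for (i in seq_len(n_ev - 1)) {
    key <- paste0(events$pad_id[i], "->", events$pad_id[i + 1])
    dir <- convention[[key]]
    if (is.null(dir)) stop("no direction defined for pad transition ", key)
    s0 <- events$sample_index[i]
    s1 <- events$sample_index[i + 1]
    stroke <- structure(list(samples = recording$motion[s0:(s1 - 1), , drop = FALSE],
                             direction = dir, interval = c(s0, s1)),
                        class = "stroke")
    strokes[[dir]] <- c(strokes[[dir]], list(stroke))
  }
  strokes
}

#' Select the fitting strokes from a sequence
#'
#' Takes `n_select` strokes counting back from the end while excluding the
#' final stroke (which in a metronome task is contaminated by the reaction
#' to the stop signal): of `K` strokes, positions `K - n_select` through
#' `K - 1` (1-based) are returned.
#'
#' @param strokes List of `stroke` objects (one direction).
#' @param n_select Number of strokes to keep. Default 20.
#' @return A list of `n_select` strokes.
#' @export
select_strokes <- function(strokes, n_select = 20) {
  K <- length(strokes)
  if (K < n_select + 1) {
    stop(sprintf("need at least %d strokes to select %d (final stroke excluded), got %d",
                 n_select + 1, n_select, K))
  }
  strokes[(K - n_select):(K - 1)]
}

#' Resample a stroke onto a phase grid
#'
#' Rescales the stroke's own sample times to `[0, 1]` and linearly
#' interpolates each channel onto the grid phases. Endpoints are preserved
#' exactly, and a stroke already sampled at the grid phases is returned
#' unchanged.
#'
#' @param stroke A `stroke` object or a plain `L x 6` sample matrix.
#' @param grid A [phase_grid()].
#' @return A `T x 6` matrix on the grid.
#' @export
normalize_time <- function(stroke, grid = phase_grid(100)) {
  stopifnot(inherits(grid, "phase_grid"))
  samples <- if (inherits(stroke, "stroke")) stroke$samples else stroke
  L <- nrow(samples)
  if (is.null(L) || L < 2) stop("a stroke needs at least 2 samples")
  if (!all(is.finite(samples))) stop("non-finite samples in stroke")
  x <- seq(0, 1, length.out = L)
  out <- apply(samples, 2, function(y) stats::approx(x, y, xout = grid$z)$y)
  colnames(out) <- colnames(samples)
  out
}

#' Assemble phase-normalized strokes into a stroke set
#'
#' @param strokes List of `stroke` objects sharing one direction.
#' @param grid A [phase_grid()].
#' @param metadata Named list (participant, stimulation, phase, experiment).
#' @return An object of class `stroke_set`: an `n x T x 6` array on the
#'   shared grid plus direction and metadata. At least two strokes are
#'   required (the weight covariance is undefined otherwise).
#' @export
stroke_set <- function(strokes, grid = phase_grid(100), metadata = list()) {
  n <- length(strokes)
  if (n < 2) stop("a stroke_set needs at least 2 strokes")
  dirs <- unique(vapply(strokes, function(s) s$direction, character(1)))
  if (length(dirs) != 1) stop("all strokes in a set must share one direction")
  data <- array(NA_real_, dim = c(n, grid$T, 6),
                dimnames = list(NULL, NULL, promp_channels))
  for (j in seq_len(n)) {
    data[j, , ] <- normalize_time(strokes[[j]], grid)
  }
  if (anyNA(data)) stop("missing values after normalization")
  structure(list(data = data, direction = dirs, grid = grid,
                 metadata = metadata),
            class = "stroke_set")
}

#' Preprocess a recording into aligned stroke sets
#'
#' Runs the full preprocessing chain: tap detection, segmentation into
#' directed strokes, selection of the fitting strokes, and phase-grid
#' normalization — yielding one `stroke_set` per movement direction.
#'
#' @param recording A `raw_recording`.
#' @param grid A [phase_grid()].
#' @param threshold,refractory Passed to [detect_taps()].
#' @param n_select Passed to [select_strokes()].
#' @param convention Passed to [segment_strokes()].
#' @return A list with components `inward` and `outward`, each a
#'   `stroke_set` carrying the recording's metadata.
#' @export
preprocess_recording <- function(recording, grid = phase_grid(100),
                                 threshold = 0.5, refractory = 0.1,
                                 n_select = 20,
                                 convention = default_direction_convention()) {
  events <- detect_taps(recording, threshold = threshold, refractory = refractory)
  segs <- segment_strokes(recording, events, convention = convention)
  lapply(segs, function(strokes) {
    stroke_set(select_strokes(strokes, n_select = n_select), grid = grid,
               metadata = recording$metadata)
  })
}

#' Zero-phase low-pass filter of the motion channels
#'
#' Optional preprocessing stage (off by default in the pipeline: ProMPs with
#' a limited number of smooth basis functions already act as a low-pass
#' filter on the fitted means). Applies a 4th-order Butterworth filter
#' forwards and backwards ([signal::filtfilt()]) to the motion channels;
#' pad channels are untouched.
#'
#' @param recording A `raw_recording`.
#' @param cutoff Cutoff frequency in Hz, within `(0, sampling_rate / 2)`.
#' @return The filtered `raw_recording`.
#' @export
lowpass_filter <- function(recording, cutoff = 20) {
  stopifnot(inherits(recording, "raw_recording"))
  fs <- recording$sampling_rate
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0 || cutoff >= fs / 2) {
    stop("'cutoff' must lie in (0, sampling_rate / 2)")
  }
  bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
  recording$motion <- apply(recording$motion, 2,
                            function(x) signal::filtfilt(bf, x))
  colnames(recording$motion) <- promp_channels
  recording
}

#' @export
print.stroke_set <- function(x, ...) {
  cat(sprintf("stroke_set: %d %s strokes on a %d-point phase grid, 6 channels\n",
              dim(x$data)[1], x$direction, dim(x$data)[2]))
  invisible(x)
}
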