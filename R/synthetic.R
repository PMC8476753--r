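#' Configuration for synthetic tapping recordings
#'
#' Bundles the acquisition and movement parameters used by
#' [generate_recording()] and [generate_study()]. The defaults emulate a
#' rhythmic tapping run: a metronome rate of 1.5 taps per second, 30 tap
#' cycles, and accelerometers sampled at 2000 Hz. One tap cycle consists of
#' an inward stroke to the far pad and an outward stroke back, so a recording
#' holds `2 * n_cycles` strokes and the same number of pad contacts.
#'
#' Each stroke follows a minimum-jerk acceleration template (biphasic,
#' antisymmetric about mid-phase) scaled per channel by `stroke_amplitude`.
#' Stroke-to-stroke variability enters through a per-channel Gaussian
#' amplitude multiplier (`amplitude_cv`) and a log-normal duration jitter
#' (`duration_jitter`); additive Gaussian sensor noise (`noise_std`) is
#' applied to all motion channels, including the dwell intervals where the
#' finger rests on a pad.
#'
#' @param sampling_rate Samples per second for all channels. Default 2000 Hz.
#' @param n_cycles Number of tap cycles (inward + outward stroke pairs).
#' @param tempo Tap rate in taps per second; the inter-tap interval is
#'   `1 / tempo` and must exceed `dwell`.
#' @param stroke_amplitude Peak acceleration per channel (arbitrary units);
#'   scalar or length-6 vector in the order of [promp_channels].
#' @param duration_jitter Log-normal standard deviation (on the log scale) of
#'   the stroke duration around its nominal value.
#' @param amplitude_cv Coefficient of variation of the per-stroke, per-channel
#'   amplitude multiplier.
#' @param shape_cv Relative magnitude of the smooth per-stroke shape
#'   perturbation: each stroke and channel receives an independent
#'   low-frequency deviation from the template built from 8 Gaussian bumps
#'   whose coefficients have standard deviation `shape_cv` times the channel
#'   amplitude. Human stroke-to-stroke variability is high-dimensional in
#'   shape, not just in scale; without this term all phase-normalized
#'   variability collapses onto the 6 amplitude multipliers and the null
#'   distribution of downstream divergences becomes unrealistically
#'   heavy-tailed.
#' @param noise_std Gaussian sensor-noise standard deviation per motion
#'   channel; scalar or length 6.
#' @param dwell Rest time on the pad between a landing and the next stroke
#'   onset, in seconds.
#' @param pad_pulse Duration of the rectangular pad-contact pulse in seconds.
#' @param effect Optional [stimulation_effect()] applied to strokes of
#'   recordings whose phase matches the effect's `applies_to`.
#' @return An object of class `synthetic_config`.
#' @seealso [generate_recording()], [generate_study()], [stimulation_effect()]
#' @export
synthetic_config <- function(sampling_rate = 2000, n_cycles = 30, tempo = 1.5,
                             stroke_amplitude = c(hand_x = 1, hand_y = 0.6,
                                                  hand_z = 0.8, wrist_x = 0.7,
                                                  wrist_y = 0.45, wrist_z = 0.55),
                             duration_jitter = 0.05, amplitude_cv = 0.1,
                             shape_cv = 0.1, noise_std = 0.05, dwell = 0.1,
                             pad_pulse = 0.02, effect = NULL) {
  stopifnot(is.numeric(sampling_rate), length(sampling_rate) == 1, sampling_rate > 0)
  stopifnot(is.numeric(n_cycles), length(n_cycles) == 1, n_cycles >= 1)
  stopifnot(is.numeric(tempo), length(tempo) == 1, tempo > 0)
  stopifnot(is.numeric(duration_jitter), duration_jitter >= 0)
  stopifnot(is.numeric(amplitude_cv), amplitude_cv >= 0)
  stopifnot(is.numeric(shape_cv), shape_cv >= 0)
  stopifnot(is.numeric(dwell), dwell >= 0, is.numeric(pad_pulse), pad_pulse > 0)
  if (any(noise_std < 0)) stop("'noise_std' must be non-negative")
  if (!length(stroke_amplitude) %in% c(1L, 6L)) {
    stop("'stroke_amplitude' must have length 1 or 6")
  }
  if (!length(noise_std) %in% c(1L, 6L)) stop("'noise_std' must have length 1 or 6")
  stroke_duration <- 1 / tempo - dwell
  if (stroke_duration <= 0) {
    stop("non-positive stroke duration: 1/tempo must exceed 'dwell'")
  }
  if (!is.null(effect) && !inherits(effect, "stimulation_effect")) {
    stop("'effect' must be created by stimulation_effect()")
  }
  cfg <- list(
    sampling_rate = sampling_rate,
    n_cycles = as.integer(n_cycles),
    tempo = tempo,
    stroke_amplitude = stats::setNames(rep_len(stroke_amplitude, 6L), promp_channels),
    duration_jitter = duration_jitter,
    amplitude_cv = amplitude_cv,
    shape_cv = shape_cv,
    noise_std = rep_len(noise_std, 6L),
    dwell = dwell,
    pad_pulse = pad_pulse,
    stroke_duration = stroke_duration,
    effect = effect
  )
  class(cfg) <- "synthetic_config"
  cfg
}

#' Distributional shift emulating a stimulation effect
#'
#' A synthetic stand-in for a true stimulation effect: an additive mean shift
#' and/or a multiplicative amplitude change applied to the noiseless stroke
#' template. The shift can be confined to a sub-interval of the movement
#' phase, which makes time-localized differences detectable by
#' [sliding_window_kls()].
#'
#' @param mean_shift Additive shift of the stroke template, scalar or length-6
#'   vector (acceleration units).
#' @param amplitude_scale Multiplicative factor on the template, scalar or
#'   length 6.
#' @param phase_support Interval of the stroke phase `[0, 1]` on which the
#'   mean shift applies. Default whole stroke.
#' @param applies_to Recording phases the effect applies to; `NULL` means all.
#' @return An object of class `stimulation_effect`. The identity effect
#'   (shift 0, scale 1) leaves generation unchanged.
#' @export
stimulation_effect <- function(mean_shift = 0, amplitude_scale = 1,
                               phase_support = c(0, 1),
                               applies_to = c("Post1", "Post2", "Post3")) {
  stopifnot(is.numeric(mean_shift), length(mean_shift) %in% c(1L, 6L))
  stopifnot(is.numeric(amplitude_scale), length(amplitude_scale) %in% c(1L, 6L))
  stopifnot(is.numeric(phase_support), length(phase_support) == 2)
  if (phase_support[1] < 0 || phase_support[2] > 1 ||
      phase_support[1] > phase_support[2]) {
    stop("'phase_support' must be an ordered sub-interval of [0, 1]")
  }
  structure(list(mean_shift = mean_shift, amplitude_scale = amplitude_scale,
                 phase_support = phase_support, applies_to = applies_to),
            class = "stimulation_effect")
}

#' Study design for a multi-participant stimulation protocol
#'
#' Enumerates the factorial design of a tapping study: participants,
#' stimulation conditions, recording phases and tapping patterns (unit
#' experiments). The defaults reproduce a 10 x 4 x 5 x 8 protocol: ten
#' participants, four stimulation conditions (Sham, tACS, tDCS, tRNS), five
#' recording phases (a familiarization run `Erst`, the pre-stimulation
#' baseline `Prae` and three post-stimulation recordings `Post1`-`Post3`)
#' and eight tapping patterns, i.e. 1600 recordings in total.
#'
#' @param n_participants Number of participants.
#' @param stimulations Character vector of stimulation condition labels.
#' @param phases Character vector of recording phase labels.
#' @param n_experiments Number of tapping patterns (unit experiments).
#' @param anomalies List of [anomaly_spec()] objects describing sensor
#'   misplacements to inject into specific recordings.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_participants = 10,
                         stimulations = c("Sham", "tACS", "tDCS", "tRNS"),
                         phases = c("Erst", "Prae", "Post1", "Post2", "Post3"),
                         n_experiments = 8, anomalies = list()) {
  stopifnot(n_participants >= 1, n_experiments >= 1)
  stopifnot(is.character(stimulations), length(stimulations) >= 1)
  stopifnot(is.character(phases), length(phases) >= 1)
  if (anyDuplicated(stimulations) || anyDuplicated(phases)) {
    stop("stimulation and phase labels must be unique")
  }
  if (!all(vapply(anomalies, inherits, logical(1), "anomaly_spec"))) {
    stop("'anomalies' must be a list of anomaly_spec objects")
  }
  structure(list(n_participants = as.integer(n_participants),
                 stimulations = stimulations, phases = phases,
                 n_experiments = as.integer(n_experiments),
                 anomalies = anomalies),
            class = "study_design")
}

#' Sensor-misplacement anomaly
#'
#' Describes an axis swap or axis flip affecting one recording of a study,
#' emulating a misplaced or misoriented inertial sensor.
#'
#' @param participant,stimulation,phase,experiment The target recording.
#' @param kind `"axis_flip"` negates the named channels; `"axis_swap"`
#'   exchanges consecutive channel pairs.
#' @param channels Affected motion channel names. For `"axis_swap"` the
#'   vector is interpreted as pairs `(1,2), (3,4), ...` and must have even
#'   length.
#' @return An object of class `anomaly_spec`.
#' @export
anomaly_spec <- function(participant, stimulation, phase, experiment,
                         kind = c("axis_flip", "axis_swap"),
                         channels = c("hand_x", "hand_y", "wrist_x", "wrist_y")) {
  kind <- match.arg(kind)
  stopifnot(is.character(channels), length(channels) >= 1)
  if (kind == "axis_swap" && length(channels) %% 2 != 0) {
    stop("'axis_swap' needs an even number of channels (swapped in pairs)")
  }
  structure(list(participant = as.integer(participant),
                 stimulation = as.character(stimulation),
                 phase = as.character(phase),
                 experiment = as.integer(experiment),
                 kind = kind, channels = channels),
            class = "anomaly_spec")
}

# Deterministic per-cell seed: a small multiplicative hash of the root seed
# and the (participant, stimulation, phase, experiment) indices, kept below
# 2^31 so it is a valid set.seed() argument. Exact in double arithmetic
# (all intermediates < 2^53).
cell_seed <- function(seed, qi, si, oi, pi) {
  h <- as.numeric(seed) %% 2147483647
  for (k in c(qi, si, oi, pi)) {
    h <- (h * 69069 + k * 30011 + 1) %% 2147483647
  }
  as.integer(h)
}

new_raw_recording <- function(sampling_rate, motion, pads, metadata = list(),
                              truth = NULL) {
  n <- nrow(motion)
  stopifnot(nrow(pads) == n, ncol(motion) == 6, ncol(pads) == 2)
  colnames(motion) <- promp_channels
  colnames(pads) <- c("pad1", "pad2")
  structure(list(sampling_rate = sampling_rate,
                 time = (seq_len(n) - 1) / sampling_rate,
                 motion = motion, pads = pads,
                 metadata = metadata, truth = truth),
            class = "raw_recording")
}

#' Generate one synthetic stroke
#'
#' Draws a single point-to-point stroke from the generative model in
#' `config`: a minimum-jerk acceleration template scaled per channel, with a
#' per-stroke Gaussian amplitude multiplier, a log-normal duration, an
#' optional stimulation effect, and additive Gaussian sensor noise. Outward
#' strokes are the time-reversed, sign-negated counterpart of inward strokes,
#' so inward and outward statistics mirror each other.
#'
#' Uses the current R random-number state; seed it with [set.seed()] for
#' reproducibility.
#'
#' @param config A [synthetic_config()].
#' @param direction `"inward"` or `"outward"`.
#' @param apply_effect Whether to apply `config$effect`. Defaults to `TRUE`
#'   when an effect is configured.
#' @return An `L x 6` matrix of acceleration samples (variable `L`) with the
#'   stroke duration in seconds as attribute `"duration"`.
#' @export
generate_stroke_profile <- function(config, direction = c("inward", "outward"),
                                    apply_effect = !is.null(config$effect)) {
  stopifnot(inherits(config, "synthetic_config"))
  direction <- match.arg(direction)
  dur <- if (config$duration_jitter > 0) {
    stats::rlnorm(1, meanlog = log(config$stroke_duration),
                  sdlog = config$duration_jitter)
  } else {
    config$stroke_duration
  }
  L <- round(dur * config$sampling_rate)
  if (L < 2) stop("stroke duration too short for the sampling rate")
  z <- seq(0, 1, length.out = L)
  amp <- config$stroke_amplitude
  if (config$amplitude_cv > 0) {
    amp <- amp * (1 + stats::rnorm(6, 0, config$amplitude_cv))
  }
  prof <- outer(min_jerk_accel(z), amp)
  if (config$shape_cv > 0) {
    # smooth per-stroke deviation from the template: 8 Gaussian bumps per
    # channel with independent Gaussian coefficients
    K <- 8L
    centers <- seq(0, 1, length.out = K)
    bumps <- exp(-outer(z, centers, `-`)^2 / (2 * 0.2 * (1 / (K - 1))^2))
    coef <- matrix(stats::rnorm(K * 6, 0,
                                rep(config$shape_cv * abs(config$stroke_amplitude),
                                    each = K)), K, 6)
    prof <- prof + bumps %*% coef
  }
  if (direction == "outward") {
    prof <- -prof[L:1, , drop = FALSE]
  }
  if (apply_effect && !is.null(config$effect)) {
    ef <- config$effect
    prof <- sweep(prof, 2, rep_len(ef$amplitude_scale, 6), `*`)
    in_support <- z >= ef$phase_support[1] & z <= ef$phase_support[2]
    if (any(in_support)) {
      prof[in_support, ] <- sweep(prof[in_support, , drop = FALSE], 2,
                                  rep_len(ef$mean_shift, 6), `+`)
    }
  }
  if (any(config$noise_std > 0)) {
    prof <- prof + matrix(stats::rnorm(L * 6, 0, rep(config$noise_std, each = L)),
                          L, 6)
  }
  colnames(prof) <- promp_channels
  attr(prof, "duration") <- L / config$sampling_rate
  prof
}

#' Generate one synthetic tapping recording
#'
#' Assembles a continuous multi-channel recording: the finger starts at rest
#' on pad 1, then `2 * n_cycles` alternating inward/outward strokes are
#' concatenated, each followed by a dwell interval on the landing pad. Every
#' landing produces a rectangular pulse on the corresponding pad channel
#' (pad 2 for inward landings, pad 1 for outward), so the recording carries
#' `2 * n_cycles` pad pulses. Sensor noise is added to the motion channels
#' throughout, including the dwell intervals.
#'
#' The returned object carries the generating ground truth (per-stroke start
#' and landing sample indices and direction labels) in its `truth` field,
#' which round-trip tests of the preprocessing stage can compare against.
#'
#' @param config A [synthetic_config()].
#' @param metadata Named list attached to the recording (participant,
#'   stimulation, phase, experiment). When `config$effect` restricts itself
#'   to certain phases via `applies_to`, the effect is only applied if
#'   `metadata$phase` matches.
#' @return A `raw_recording`: sampling rate, time vector, `N x 6` motion
#'   matrix, `N x 2` pad matrix, metadata and generator ground truth.
#' @export
generate_recording <- function(config, metadata = list()) {
  stopifnot(inherits(config, "synthetic_config"))
  fs <- config$sampling_rate
  apply_effect <- !is.null(config$effect) &&
    (is.null(config$effect$applies_to) || is.null(metadata$phase) ||
       metadata$phase %in% config$effect$applies_to)
  dwell_n <- round(config$dwell * fs)
  pulse_n <- max(1L, round(config$pad_pulse * fs))
  n_strokes <- 2L * config$n_cycles
  noisy_dwell <- function(m) {
    if (m == 0) return(NULL)
    dw <- matrix(0, m, 6)
    if (any(config$noise_std > 0)) {
      dw <- dw + matrix(stats::rnorm(m * 6, 0, rep(config$noise_std, each = m)), m, 6)
    }
    dw
  }
  segs <- vector("list", 2L * n_strokes + 1L)
  segs[[1]] <- noisy_dwell(dwell_n)
  pos <- dwell_n
  start <- integer(n_strokes)
  land <- integer(n_strokes)
  dirs <- character(n_strokes)
  for (k in seq_len(n_strokes)) {
    dirs[k] <- if (k %% 2 == 1) "inward" else "outward"
    prof <- generate_stroke_profile(config, dirs[k], apply_effect)
    start[k] <- pos + 1L
    pos <- pos + nrow(prof)
    land[k] <- pos + 1L
    segs[[2L * k]] <- prof
    # dwell after the landing; the final dwell must host the last pad pulse
    m <- if (k == n_strokes) max(dwell_n, pulse_n) else dwell_n
    segs[[2L * k + 1L]] <- noisy_dwell(m)
    pos <- pos + m
  }
  motion <- do.call(rbind, segs[!vapply(segs, is.null, logical(1))])
  N <- nrow(motion)
  pads <- matrix(0, N, 2)
  for (k in seq_len(n_strokes)) {
    pad <- if (dirs[k] == "inward") 2L else 1L
    idx <- land[k]:min(N, land[k] + pulse_n - 1L)
    pads[idx, pad] <- 1
  }
  truth <- data.frame(stroke = seq_len(n_strokes), direction = dirs,
                      start = start, land = land)
  new_raw_recording(fs, motion, pads, metadata = metadata, truth = truth)
}

#' Generate a full synthetic study
#'
#' Lays out one recording per design cell (participant x stimulation x phase
#' x experiment) with a manifest row per recording. Recordings are generated
#' lazily by [study_recording()]; each cell owns a deterministic random
#' substream derived by hashing the root seed with the cell indices, so a
#' cell's recording is reproducible independently of generation order.
#'
#' @param design A [study_design()].
#' @param config A [synthetic_config()] shared by all cells.
#' @param seed Integer root seed.
#' @return An object of class `promp_study` holding the design, config, seed
#'   and a manifest `data.frame` with columns `participant`, `stimulation`,
#'   `phase`, `experiment` and `cell_seed`.
#' @export
generate_study <- function(design = study_design(), config = synthetic_config(),
                           seed = 1) {
  stopifnot(inherits(design, "study_design"), inherits(config, "synthetic_config"))
  stopifnot(is.numeric(seed), length(seed) == 1)
  manifest <- expand.grid(experiment = seq_len(design$n_experiments),
                          phase = design$phases,
                          stimulation = design$stimulations,
                          participant = seq_len(design$n_participants),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  manifest <- manifest[, c("participant", "stimulation", "phase", "experiment")]
  rownames(manifest) <- NULL
  manifest$cell_seed <- mapply(
    cell_seed, seed,
    manifest$participant,
    match(manifest$stimulation, design$stimulations),
    match(manifest$phase, design$phases),
    manifest$experiment
  )
  if (length(design$anomalies) > 0) {
    targets <- vapply(design$anomalies, function(a) {
      paste(a$participant, a$stimulation, a$phase, a$experiment, sep = "|")
    }, character(1))
    if (anyDuplicated(targets)) stop("duplicate anomaly targets")
    cells <- paste(manifest$participant, manifest$stimulation, manifest$phase,
                   manifest$experiment, sep = "|")
    if (!all(targets %in% cells)) {
      stop("anomaly target does not resolve to a recording in the design: ",
           paste(setdiff(targets, cells), collapse = ", "))
    }
  }
  structure(list(design = design, config = config, seed = seed,
                 manifest = manifest),
            class = "promp_study")
}

#' Materialize one recording of a synthetic study
#'
#' @param study A `promp_study` from [generate_study()].
#' @param i Row index into `study$manifest`.
#' @return A `raw_recording` for that cell, with any matching anomalies from
#'   the design applied.
#' @export
study_recording <- function(study, i) {
  stopifnot(inherits(study, "promp_study"))
  row <- study$manifest[i, ]
  set.seed(row$cell_seed)
  meta <- list(participant = row$participant, stimulation = row$stimulation,
               phase = row$phase, experiment = row$experiment)
  rec <- generate_recording(study$config, metadata = meta)
  for (a in study$design$anomalies) {
    if (a$participant == row$participant && a$stimulation == row$stimulation &&
        a$phase == row$phase && a$experiment == row$experiment) {
      rec <- inject_anomaly(rec, a)
    }
  }
  rec
}

#' Inject a sensor-misplacement anomaly into a recording
#'
#' `axis_flip` negates the named motion channels; `axis_swap` exchanges
#' consecutive channel pairs. Both operations are involutions: applying the
#' same anomaly twice restores the original recording.
#'
#' @param recording A `raw_recording`.
#' @param spec An [anomaly_spec()] (its target fields are ignored here; only
#'   `kind` and `channels` are used).
#' @return The modified `raw_recording`.
#' @export
inject_anomaly <- function(recording, spec) {
  stopifnot(inherits(recording, "raw_recording"), inherits(spec, "anomaly_spec"))
  unknown <- setdiff(spec$channels, colnames(recording$motion))
  if (length(unknown) > 0) {
    stop("unknown channel name: ", paste(unknown, collapse = ", "))
  }
  if (spec$kind == "axis_flip") {
    recording$motion[, spec$channels] <- -recording$motion[, spec$channels]
  } else {
    for (j in seq(1, length(spec$channels), by = 2)) {
      a <- spec$channels[j]
      b <- spec$channels[j + 1]
      tmp <- recording$motion[, a]
      recording$motion[, a] <- recording$motion[, b]
      recording$motion[, b] <- tmp
    }
  }
  recording
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("raw_recording: %d samples at %g Hz (%.1f s), 6 motion + 2 pad channels\n",
              nrow(x$motion), x$sampling_rate, nrow(x$motion) / x$sampling_rate))
  if (length(x$metadata)) {
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.promp_study <- function(x, ...) {
  d <- x$design
  cat(sprintf("promp_study: %d participants x %d stimulations x %d phases x %d experiments = %d recordings\n",
              d$n_participants, length(d$stimulations), length(d$phases),
              d$n_experiments, nrow(x$manifest)))
  invisible(x)
}
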