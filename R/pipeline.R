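#' Fit ProMPs to every cell of a study
#'
#' Iterates over the study manifest, preprocesses each recording into the
#' two directed stroke sets and fits one ProMP per (cell, direction),
#' storing the marginal trajectory distributions. Cells whose recordings
#' cannot be preprocessed (e.g. too few strokes to select from) are logged
#' as missing and skipped; the pipeline continues.
#'
#' Familiarization (`Erst`) cells are fitted like any other but are excluded
#' from all downstream statistics by [compare_phases()].
#'
#' @param study A `promp_study` from [generate_study()], or a list of
#'   `raw_recording` objects with complete metadata.
#' @param grid A [phase_grid()].
#' @param M,lambda ProMP hyperparameters, see [fit_promp()].
#' @param n_select,threshold,refractory,convention Preprocessing settings,
#'   see [preprocess_recording()].
#' @param keep_empirical Also store the empirical distributions (needed for
#'   reconstruction-loss reporting). Default `FALSE`.
#' @return An object of class `promp_fits`: a `cells` data.frame, a named
#'   list `distributions` keyed by
#'   `participant|stimulation|phase|experiment|direction`, optional
#'   `empirical` list, and a `missing` log.
#' @export
run_experiment_fit <- function(study, grid = phase_grid(100), M = 20,
                               lambda = 1e-6, n_select = 20, threshold = 0.5,
                               refractory = 0.1,
                               convention = default_direction_convention(),
                               keep_empirical = FALSE) {
  if (inherits(study, "promp_study")) {
    n_rec <- nrow(study$manifest)
    get_rec <- function(i) study_recording(study, i)
    meta_of <- function(i) study$manifest[i, c("participant", "stimulation",
                                               "phase", "experiment")]
  } else if (is.list(study)) {
    n_rec <- length(study)
    get_rec <- function(i) study[[i]]
    meta_of <- function(i) as.data.frame(study[[i]]$metadata)
  } else {
    stop("'study' must be a promp_study or a list of raw_recording objects")
  }
  basis <- make_basis(M, grid)
  distributions <- list()
  empirical <- list()
  missing <- list()
  cells <- list()
  for (i in seq_len(n_rec)) {
    meta <- meta_of(i)
    rec <- get_rec(i)
    sets <- tryCatch(
      preprocess_recording(rec, grid = grid, threshold = threshold,
                           refractory = refractory, n_select = n_select,
                           convention = convention),
      error = function(e) e
    )
    if (inherits(sets, "error")) {
      missing[[length(missing) + 1L]] <-
        data.frame(meta, reason = conditionMessage(sets))
      next
    }
    for (dir in names(sets)) {
      key <- paste(meta$participant, meta$stimulation, meta$phase,
                   meta$experiment, dir, sep = "|")
      model <- fit_promp(sets[[dir]], M = M, lambda = lambda, basis = basis)
      distributions[[key]] <- marginal_distribution(model)
      if (keep_empirical) empirical[[key]] <- empirical_distribution(sets[[dir]])
      cells[[length(cells) + 1L]] <- data.frame(meta, direction = dir, key = key)
    }
  }
  structure(list(cells = do.call(rbind, cells),
                 distributions = distributions,
                 empirical = if (keep_empirical) empirical else NULL,
                 missing = if (length(missing)) do.call(rbind, missing) else NULL,
                 grid = grid, M = M, lambda = lambda),
            class = "promp_fits")
}

#' Baseline-versus-post divergences for every study cell
#'
#' For every (participant, stimulation, experiment, direction) with a fitted
#' pre-stimulation baseline (`Prae`), computes the symmetric KL divergence
#' between the ProMP-reconstructed trajectory distributions of `Prae` and
#' each available post-stimulation phase (`Post1`-`Post3`). Familiarization
#' (`Erst`) cells never enter the comparison; keys without a `Prae` fit are
#' skipped and recorded in the `"skipped"` attribute.
#'
#' @param fits A `promp_fits` from [run_experiment_fit()].
#' @return A `data.frame` with columns `participant`, `stimulation`,
#'   `experiment`, `direction`, `comparison` (e.g. `"Prae-Post1"`) and
#'   `value`.
#' @export
compare_phases <- function(fits) {
  stopifnot(inherits(fits, "promp_fits"))
  cells <- fits$cells
  if (is.null(cells) || nrow(cells) == 0) stop("no fitted cells")
  units <- unique(cells[, c("participant", "stimulation", "experiment",
                            "direction")])
  post_phases <- c("Post1", "Post2", "Post3")
  rows <- list()
  skipped <- list()
  for (u in seq_len(nrow(units))) {
    key_of <- function(phase) {
      paste(units$participant[u], units$stimulation[u], phase,
            units$experiment[u], units$direction[u], sep = "|")
    }
    prae <- fits$distributions[[key_of("Prae")]]
    if (is.null(prae)) {
      skipped[[length(skipped) + 1L]] <- units[u, ]
      next
    }
    for (post in post_phases) {
      dist_post <- fits$distributions[[key_of(post)]]
      if (is.null(dist_post)) next
      rows[[length(rows) + 1L]] <- data.frame(
        units[u, , drop = FALSE],
        comparison = paste0("Prae-", post),
        value = trajectory_kls(prae, dist_post)$value
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(participant = integer(0), stimulation = character(0),
               experiment = integer(0), direction = character(0),
               comparison = character(0), value = numeric(0))
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  out
}

#' Three-sigma outlier exclusion
#'
#' Flags a comparison unit (participant, stimulation, experiment,
#' comparison) when its divergence exceeds `mu_D + 3 sigma_D` in *either*
#' movement direction. `mu_D` and `sigma_D` describe the non-corrupted
#' experiments, so for each unit they are computed from the pooled values
#' (both directions, all comparisons) of all *other* units — a corrupted
#' unit must not inflate the very statistics used to detect it, which
#' matters in small studies where one sensor mishap can dominate the pooled
#' variance. Only the high side is excluded: unusually small divergences
#' are valid. With zero variance among the reference rows nothing is
#' flagged.
#'
#' @param table Divergence table from [compare_phases()].
#' @return A list with `table` (the input plus a logical `outlier` column;
#'   both direction rows of a flagged unit are marked) and `report`
#'   (the pooled `mu_d` and `sigma_d` over all rows for reference, the
#'   flagged unit keys, and the count).
#' @export
detect_outliers <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) >= 2)
  unit_key <- paste(table$participant, table$stimulation, table$experiment,
                    table$comparison, sep = "|")
  units <- unique(unit_key)
  flagged_units <- character(0)
  for (u in units) {
    own <- unit_key == u
    ref <- table$value[!own]
    if (length(ref) < 2) next
    # strict inequality: with zero reference variance, values equal to the
    # common level are not flagged
    if (any(table$value[own] > mean(ref) + 3 * stats::sd(ref))) {
      flagged_units <- c(flagged_units, u)
    }
  }
  table$outlier <- unit_key %in% flagged_units
  flagged <- unique(table[table$outlier,
                          c("participant", "stimulation", "experiment",
                            "comparison")])
  rownames(flagged) <- NULL
  list(table = table,
       report = list(mu_d = mean(table$value),
                     sigma_d = stats::sd(table$value),
                     n_flagged_units = length(flagged_units),
                     flagged = flagged))
}

#' Aggregate divergences over participants and experiments
#'
#' Rows flagged as outliers are dropped, then divergences are averaged per
#' (stimulation, comparison, direction) group and overall per direction —
#' the per-direction overall pair summarizes the inward/outward consistency
#' of the measure.
#'
#' @param table Divergence table, optionally with an `outlier` column from
#'   [detect_outliers()].
#' @return A list with `by_group` (mean, sd and n per stimulation x
#'   comparison x direction) and `overall` (mean, sd and n per direction).
#'   Groups with no remaining rows are absent, not reported as zero.
#' @export
aggregate_results <- function(table) {
  stopifnot(is.data.frame(table))
  if (!is.null(table$outlier)) table <- table[!table$outlier, ]
  if (nrow(table) == 0) stop("no rows left to aggregate")
  agg <- function(by) {
    m <- stats::aggregate(value ~ ., data = table[, c(by, "value")], FUN = mean)
    s <- stats::aggregate(value ~ ., data = table[, c(by, "value")],
                          FUN = stats::sd)
    n <- stats::aggregate(value ~ ., data = table[, c(by, "value")], FUN = length)
    names(m)[names(m) == "value"] <- "mean"
    m$sd <- s$value
    m$n <- n$value
    m
  }
  list(by_group = agg(c("stimulation", "comparison", "direction")),
       overall = agg("direction"))
}

#' Run the complete study analysis
#'
#' End-to-end orchestration on a synthetic study: generation, preprocessing
#' and per-cell ProMP fitting, baseline-versus-post divergences, three-sigma
#' outlier exclusion, and aggregation. The whole run is a pure function of
#' (design, config, seed, settings): identical inputs give identical result
#' bundles.
#'
#' @param design A [study_design()].
#' @param config A [synthetic_config()].
#' @param seed Root seed for the synthetic study.
#' @param grid,M,lambda,n_select,threshold,refractory,convention Passed to
#'   [run_experiment_fit()].
#' @param include_erst Must be `FALSE`: the familiarization phase is fitted
#'   but never enters the statistics, because participants explore during
#'   it. Requesting otherwise is refused.
#' @param out_dir Optional directory; when given, the divergence table,
#'   outlier report and summary are written there as CSV/JSON.
#' @return A list (class `promp_result`) with `study`, `fits`,
#'   `divergences`, `outliers` and `summary`.
#' @export
run_pipeline <- function(design = study_design(), config = synthetic_config(),
                         seed = 1, grid = phase_grid(100), M = 20,
                         lambda = 1e-6, n_select = 20, threshold = 0.5,
                         refractory = 0.1,
                         convention = default_direction_convention(),
                         include_erst = FALSE, out_dir = NULL) {
  if (isTRUE(include_erst)) {
    stop("the familiarization phase 'Erst' is excluded from statistics by design: ",
         "participants explore during it, so its divergences do not reflect ",
         "stimulation effects; 'include_erst = TRUE' is not supported")
  }
  study <- generate_study(design, config, seed)
  fits <- run_experiment_fit(study, grid = grid, M = M, lambda = lambda,
                             n_select = n_select, threshold = threshold,
                             refractory = refractory, convention = convention)
  divergences <- compare_phases(fits)
  out <- detect_outliers(divergences)
  summary <- aggregate_results(out$table)
  result <- structure(list(study = study, fits = fits,
                           divergences = out$table,
                           outliers = out$report, summary = summary),
                      class = "promp_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_divergence_csv(out$table, file.path(out_dir, "divergences.csv"))
    jsonlite::write_json(out$report, file.path(out_dir, "outliers.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    utils::write.csv(summary$by_group, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  }
  result
}

#' @export
print.promp_result <- function(x, ...) {
  cat(sprintf("promp_result: %d divergence rows, %d unit(s) flagged as outliers\n",
              nrow(x$divergences), x$outliers$n_flagged_units))
  print(x$summary$overall)
  invisible(x)
}
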