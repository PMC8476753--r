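#' Kullback-Leibler divergence between two univariate Gaussians
#'
#' Closed form of `KL(N(mu1, sd1^2) || N(mu2, sd2^2))`:
#' `log(sd2/sd1) + (sd1^2 + (mu1 - mu2)^2) / (2 sd2^2) - 1/2`.
#' Vectorized over all four arguments.
#'
#' @param mu1,sd1 Mean and standard deviation of the first Gaussian.
#' @param mu2,sd2 Mean and standard deviation of the second Gaussian.
#' @return Non-negative divergence value(s); zero iff the parameters match.
#' @export
kl_gaussian <- function(mu1, sd1, mu2, sd2) {
  if (any(sd1 <= 0) || any(sd2 <= 0)) {
    stop("standard deviations must be strictly positive")
  }
  log(sd2 / sd1) + (sd1^2 + (mu1 - mu2)^2) / (2 * sd2^2) - 0.5
}

#' Symmetric Kullback-Leibler divergence between two univariate Gaussians
#'
#' The average of the two directed divergences, which for Gaussians
#' collapses to the closed form
#' `(1/4) * (sd1^2/sd2^2 + sd2^2/sd1^2 + (mu1-mu2)^2 (1/sd1^2 + 1/sd2^2) - 2)`.
#' Symmetric in its arguments, non-negative, zero iff the parameters match,
#' and strictly increasing in `|mu1 - mu2|` at fixed standard deviations.
#' Vectorized.
#'
#' @inheritParams kl_gaussian
#' @return Non-negative divergence value(s).
#' @export
kls_gaussian <- function(mu1, sd1, mu2, sd2) {
  if (any(sd1 <= 0) || any(sd2 <= 0)) {
    stop("standard deviations must be strictly positive")
  }
  v1 <- sd1^2
  v2 <- sd2^2
  # every term is symmetric at the floating-point level, so swapping the
  # arguments returns bit-identical values
  0.25 * (v1 / v2 + v2 / v1 + (mu1 - mu2)^2 * (1 / v1 + 1 / v2) - 2)
}

#' Symmetric KL divergence between two trajectory distributions
#'
#' Applies [kls_gaussian()] to the per-phase-point, per-channel marginals of
#' the two distributions and averages over all phase points and channels.
#' Per-point standard deviations are floored at `1e-8` times the channel's
#' root-mean-square level to keep degenerate variances from blowing up the
#' ratio terms.
#'
#' @param a,b `trajectory_distribution` objects on the same grid with the
#'   same channels.
#' @return An object of class `divergence_result` with fields `value` (the
#'   grand mean, non-negative), `per_point` (`T x D` matrix), `z`,
#'   `channels` and `direction`.
#' @export
trajectory_kls <- function(a, b) {
  stopifnot(inherits(a, "trajectory_distribution"),
            inherits(b, "trajectory_distribution"))
  if (!all(dim(a$mean) == dim(b$mean)) ||
      !isTRUE(all.equal(a$z, b$z, tolerance = 1e-10))) {
    stop("trajectory distributions must share grid and channel set")
  }
  floor_std <- function(x) {
    lo <- 1e-8 * pmax(sqrt(colMeans(x^2)), .Machine$double.eps)
    pmax(x, rep(lo, each = nrow(x)))
  }
  sa <- floor_std(a$std)
  sb <- floor_std(b$std)
  pp <- kls_gaussian(a$mean, sa, b$mean, sb)
  colnames(pp) <- a$channels
  structure(list(value = mean(pp), per_point = pp, z = a$z,
                 channels = a$channels,
                 direction = a$direction %||% b$direction),
            class = "divergence_result")
}

#' Sliding-window divergence profile
#'
#' Localizes a trajectory difference in phase: a window of fixed fractional
#' width slides across `[0, 1]`, and the per-point symmetric KL values of
#' all channels whose phase falls inside the window are averaged (not
#' summed, so values are comparable across window sizes).
#'
#' @param a,b `trajectory_distribution` objects on the same grid.
#' @param window_fraction Window width as a fraction of the phase, in
#'   `(0, 1]`. Default `1/10`.
#' @param stride_fraction Step between window starts; defaults to one grid
#'   spacing. Must not exceed the window width.
#' @return An object of class `window_profile` with window `centers` (the
#'   window midpoints) and non-negative `values`. With
#'   `window_fraction = 1` the single value equals the [trajectory_kls()]
#'   value.
#' @export
sliding_window_kls <- function(a, b, window_fraction = 0.1,
                               stride_fraction = NULL) {
  if (window_fraction <= 0 || window_fraction > 1) {
    stop("'window_fraction' must lie in (0, 1]")
  }
  res <- trajectory_kls(a, b)
  z <- res$z
  if (is.null(stride_fraction)) stride_fraction <- z[2] - z[1]
  if (stride_fraction <= 0 || stride_fraction > window_fraction) {
    stop("'stride_fraction' must lie in (0, window_fraction]")
  }
  starts <- seq(0, 1 - window_fraction, by = stride_fraction)
  if (starts[length(starts)] < 1 - window_fraction - 1e-12) {
    starts <- c(starts, 1 - window_fraction)
  }
  eps <- 1e-9
  values <- vapply(starts, function(s) {
    sel <- z >= s - eps & z <= s + window_fraction + eps
    if (!any(sel)) stop("window contains no phase points; refine the grid")
    mean(res$per_point[sel, , drop = FALSE])
  }, numeric(1))
  structure(list(window_fraction = window_fraction,
                 centers = starts + window_fraction / 2,
                 values = values),
            class = "window_profile")
}

#' Mean reconstruction loss over a collection of stroke sets
#'
#' For every stroke set, the symmetric KL divergence between its empirical
#' per-phase distribution and the marginal distribution of the matching
#' fitted model; the loss is the mean over sets. Used to choose the number
#' of basis functions: too few basis functions cannot track the per-phase
#' mean and variance and the loss is large.
#'
#' @param sets List of [stroke_set()] objects.
#' @param models List of `promp_model` objects, one per set.
#' @return The scalar mean loss, with the per-set losses in attribute
#'   `"per_cell"`.
#' @export
reconstruction_loss <- function(sets, models) {
  if (length(sets) != length(models)) {
    stop("need exactly one model per stroke set")
  }
  if (length(sets) == 0) stop("empty collection")
  per_cell <- mapply(function(set, model) {
    trajectory_kls(empirical_distribution(set), marginal_distribution(model))$value
  }, sets, models)
  structure(mean(per_cell), per_cell = unname(per_cell))
}

#' Reconstruction loss across candidate basis sizes
#'
#' Convenience wrapper refitting every stroke set for each candidate `M` and
#' reporting the mean reconstruction loss per `M`.
#'
#' @param sets List of [stroke_set()] objects.
#' @param M_values Candidate numbers of basis functions.
#' @param lambda Ridge regularizer passed to [fit_promp()].
#' @return A `data.frame` with columns `M` and `loss`.
#' @export
select_basis_size <- function(sets, M_values = c(5, 10, 15, 20), lambda = 1e-6) {
  stopifnot(length(sets) >= 1)
  grid <- sets[[1]]$grid
  loss <- vapply(M_values, function(M) {
    basis <- make_basis(M, grid)
    models <- lapply(sets, fit_promp, M = M, lambda = lambda, basis = basis)
    as.numeric(reconstruction_loss(sets, models))
  }, numeric(1))
  data.frame(M = M_values, loss = loss)
}

#' @export
print.divergence_result <- function(x, ...) {
  cat(sprintf("divergence_result: D_KLS = %.4g (mean over %d phase points x %d channels)\n",
              x$value, nrow(x$per_point), ncol(x$per_point)))
  invisible(x)
}

#' @export
print.window_profile <- function(x, ...) {
  cat(sprintf("window_profile: window = %g of phase, %d positions, max %.4g at phase %.2f\n",
              x$window_fraction, length(x$values), max(x$values),
              x$centers[which.max(x$values)]))
  invisible(x)
}
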