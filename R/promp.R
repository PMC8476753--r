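#' Normalized Gaussian radial basis on a phase grid
#'
#' Constructs `M` Gaussian bumps with centers uniformly spaced on `[0, 1]`
#' and a common bandwidth `h = 0.2 * (delta c)^2`, where `delta c` is the
#' center spacing — wide enough that neighboring bumps overlap. Basis values
#' are normalized per phase point so that every row of the basis matrix sums
#' to one.
#'
#' @param M Number of basis functions, at least 2 (the bandwidth is defined
#'   from the center spacing).
#' @param grid A [phase_grid()].
#' @return An object of class `promp_basis` with fields `M`, `centers`,
#'   `bandwidth`, `grid`, and the `T x M` normalized basis matrix `Phi`
#'   (entries non-negative — bumps far from a phase point underflow to zero
#'   in double precision for large `M` — with every row summing to 1).
#' @export
make_basis <- function(M, grid = phase_grid(100)) {
  stopifnot(inherits(grid, "phase_grid"))
  if (!is.numeric(M) || length(M) != 1 || M < 2) {
    stop("'M' must be at least 2 (bandwidth is undefined for M < 2)")
  }
  M <- as.integer(M)
  centers <- seq(0, 1, length.out = M)
  h <- 0.2 * (centers[2] - centers[1])^2
  raw <- exp(-outer(grid$z, centers, `-`)^2 / (2 * h))
  Phi <- raw / rowSums(raw)
  structure(list(M = M, centers = centers, bandwidth = h, grid = grid,
                 Phi = Phi),
            class = "promp_basis")
}

#' Block-diagonal multi-channel feature matrix
#'
#' Repeats the basis matrix once per channel along the diagonal, matching a
#' channel-major vectorization of a multi-channel stroke (all `T` phase
#' points of channel 1, then channel 2, ...).
#'
#' @param Phi A `T x M` basis matrix or a `promp_basis`.
#' @param D Number of channels.
#' @return The `(T*D) x (M*D)` block-diagonal feature matrix.
#' @export
build_block_feature <- function(Phi, D) {
  if (inherits(Phi, "promp_basis")) Phi <- Phi$Phi
  stopifnot(is.matrix(Phi), is.numeric(D), length(D) == 1, D >= 1)
  kronecker(diag(as.integer(D)), Phi)
}

# Channel-major vectorization of a stroke set: column j holds all T phase
# points of channel 1 of stroke j, then channel 2, etc.
stroke_set_targets <- function(set) {
  d <- dim(set$data)
  matrix(aperm(set$data, c(2, 3, 1)), nrow = d[2] * d[3], ncol = d[1])
}

#' Ridge-regression stroke weights
#'
#' Solves the damped least-squares problem
#' `W = (A'A + lambda I)^-1 A' tau` for every stroke in the set, where `A`
#' is the block-diagonal feature matrix and each column of `tau` is one
#' stroke vectorized channel-major. The ridge term guards against the
#' singularities that arise from small or poorly varied demonstration sets.
#'
#' @param set A [stroke_set()].
#' @param basis A `promp_basis` from [make_basis()].
#' @param lambda Ridge regularizer, non-negative. Default `1e-6`.
#' @return An `(M*D) x n` weight matrix, one column per stroke, with the
#'   fit configuration in attributes `M`, `D` and `lambda`.
#' @export
fit_weights <- function(set, basis, lambda = 1e-6) {
  stopifnot(inherits(set, "stroke_set"), inherits(basis, "promp_basis"))
  stopifnot(is.numeric(lambda), length(lambda) == 1, lambda >= 0)
  if (dim(set$data)[2] != basis$grid$T) {
    stop("stroke set and basis are on different phase grids")
  }
  D <- dim(set$data)[3]
  tau <- stroke_set_targets(set)
  A <- build_block_feature(basis, D)
  G <- crossprod(A) + lambda * diag(ncol(A))
  W <- tryCatch(
    solve(G, crossprod(A, tau)),
    error = function(e) {
      if (lambda == 0) {
        stop("normal equations are singular with lambda = 0; ",
             "use lambda > 0 to regularize the fit", call. = FALSE)
      }
      stop(e)
    }
  )
  structure(W, M = basis$M, D = D, lambda = lambda)
}

#' Gaussian distribution over stroke weights
#'
#' Collapses the per-stroke weight columns into a weight mean and an
#' unbiased sample covariance, with a diagonal jitter for numerical positive
#' semi-definiteness. With `n` strokes and `M*D` weights the sample
#' covariance is typically rank-deficient; this is benign because only
#' per-channel marginal variances are consumed downstream.
#'
#' @param W Weight matrix from [fit_weights()].
#' @param jitter Diagonal jitter added to the covariance. Default
#'   `1e-9 * trace / (M*D)`.
#' @return List with `mean` (length `M*D`), `cov` (`(M*D) x (M*D)`), and
#'   the `jitter` used.
#' @export
fit_weight_distribution <- function(W, jitter = NULL) {
  stopifnot(is.matrix(W))
  n <- ncol(W)
  if (n < 2) stop("need at least 2 strokes to estimate a weight covariance")
  mu <- rowMeans(W)
  S <- stats::cov(t(W))
  if (is.null(jitter)) jitter <- 1e-9 * sum(diag(S)) / nrow(S)
  S <- S + jitter * diag(nrow(S))
  list(mean = mu, cov = S, jitter = jitter)
}

#' Per-channel observation-noise estimate
#'
#' The residual root-mean-square of the ridge reconstruction, per channel,
#' across all strokes and phase points, floored at a small epsilon so that
#' downstream divergences never divide by zero.
#'
#' @param set The fitted [stroke_set()].
#' @param W Weights from [fit_weights()].
#' @param basis The `promp_basis` used for the fit.
#' @param floor Lower bound on the estimate. Default `1e-6`.
#' @return Named numeric vector of per-channel noise standard deviations.
#' @export
estimate_noise <- function(set, W, basis, floor = 1e-6) {
  stopifnot(inherits(set, "stroke_set"), inherits(basis, "promp_basis"))
  D <- dim(set$data)[3]
  M <- basis$M
  sigma <- numeric(D)
  for (d in seq_len(D)) {
    idx <- ((d - 1) * M + 1):(d * M)
    pred <- basis$Phi %*% W[idx, , drop = FALSE]     # T x n
    obs <- t(set$data[, , d])                        # T x n
    sigma[d] <- sqrt(mean((obs - pred)^2))
  }
  stats::setNames(pmax(sigma, floor), dimnames(set$data)[[3]])
}

#' Fit a Probabilistic Movement Primitive to a stroke set
#'
#' The complete fit: basis construction, per-stroke ridge weights, weight
#' mean and covariance, and per-channel observation noise. The resulting
#' model induces a Gaussian distribution over trajectories whose per-phase
#' marginals are exposed by [marginal_distribution()].
#'
#' @param set A [stroke_set()].
#' @param M Number of basis functions. Default 20.
#' @param lambda Ridge regularizer. Default `1e-6`.
#' @param basis Optional precomputed `promp_basis` (must match `M` and the
#'   set's grid); avoids rebuilding the basis across many fits.
#' @param jitter Covariance jitter, see [fit_weight_distribution()].
#' @param noise_floor Floor for the noise estimate, see [estimate_noise()].
#' @param sigma_y Optional fixed per-channel noise standard deviation
#'   overriding the residual estimate; scalar or length `D`.
#' @return An object of class `promp_model`.
#' @export
fit_promp <- function(set, M = 20, lambda = 1e-6, basis = NULL, jitter = NULL,
                      noise_floor = 1e-6, sigma_y = NULL) {
  stopifnot(inherits(set, "stroke_set"))
  if (is.null(basis)) {
    basis <- make_basis(M, set$grid)
  } else {
    stopifnot(inherits(basis, "promp_basis"))
    if (basis$M != M) stop("precomputed basis does not match 'M'")
  }
  D <- dim(set$data)[3]
  W <- fit_weights(set, basis, lambda = lambda)
  wd <- fit_weight_distribution(W, jitter = jitter)
  sy <- if (is.null(sigma_y)) {
    estimate_noise(set, W, basis, floor = noise_floor)
  } else {
    stats::setNames(pmax(rep_len(sigma_y, D), noise_floor),
                    dimnames(set$data)[[3]])
  }
  structure(list(basis = basis, mean = wd$mean, cov = wd$cov,
                 sigma_y = sy, lambda = lambda, jitter = wd$jitter,
                 n = ncol(W), D = D,
                 channels = dimnames(set$data)[[3]],
                 direction = set$direction, metadata = set$metadata),
            class = "promp_model")
}

new_trajectory_distribution <- function(mean, std, z, channels,
                                        direction = NULL) {
  stopifnot(all(dim(mean) == dim(std)), all(std > 0))
  colnames(mean) <- channels
  colnames(std) <- channels
  structure(list(mean = mean, std = std, z = z, channels = channels,
                 direction = direction),
            class = "trajectory_distribution")
}

#' Marginal trajectory distribution of a ProMP
#'
#' Integrates out the weights: per channel `d` and phase point `t` the
#' marginal is Gaussian with mean `phi_t' mu_w(d)` and variance
#' `phi_t' Sigma_w(d,d) phi_t + sigma_y(d)^2`, where `(d)` selects the
#' channel's weight block. The observation noise guarantees strictly
#' positive variance everywhere.
#'
#' @param model A `promp_model` from [fit_promp()].
#' @return A `trajectory_distribution`: `T x D` matrices `mean` and `std`
#'   plus the phase vector.
#' @export
marginal_distribution <- function(model) {
  stopifnot(inherits(model, "promp_model"))
  Phi <- model$basis$Phi
  M <- model$basis$M
  Tn <- nrow(Phi)
  D <- model$D
  mean <- matrix(NA_real_, Tn, D)
  var <- matrix(NA_real_, Tn, D)
  for (d in seq_len(D)) {
    idx <- ((d - 1) * M + 1):(d * M)
    mean[, d] <- Phi %*% model$mean[idx]
    v <- rowSums((Phi %*% model$cov[idx, idx]) * Phi)
    if (any(v < -1e-8 * max(abs(v), 1))) {
      stop("weight covariance is not positive semi-definite after jitter")
    }
    var[, d] <- pmax(v, 0) + model$sigma_y[d]^2
  }
  new_trajectory_distribution(mean, sqrt(var), model$basis$grid$z,
                              model$channels, model$direction)
}

#' Empirical per-phase trajectory distribution
#'
#' The sample mean and unbiased sample standard deviation across strokes at
#' every phase point and channel — the model-free counterpart of
#' [marginal_distribution()] used as the reference in the reconstruction
#' loss.
#'
#' @param set A [stroke_set()] with at least 2 strokes.
#' @param floor Lower bound on the standard deviation (degenerate variance
#'   occurs for duplicated strokes).
#' @return A `trajectory_distribution`.
#' @export
empirical_distribution <- function(set, floor = 1e-6) {
  stopifnot(inherits(set, "stroke_set"))
  if (dim(set$data)[1] < 2) stop("need at least 2 strokes")
  mean <- apply(set$data, c(2, 3), mean)
  std <- pmax(apply(set$data, c(2, 3), stats::sd), floor)
  new_trajectory_distribution(mean, std, set$grid$z, dimnames(set$data)[[3]],
                              set$direction)
}

#' @export
print.promp_model <- function(x, ...) {
  cat(sprintf("promp_model: M = %d basis functions, D = %d channels, n = %d strokes, lambda = %g\n",
              x$basis$M, x$D, x$n, x$lambda))
  cat(sprintf("  sigma_y: %s\n",
              paste(sprintf("%.4g", x$sigma_y), collapse = " ")))
  invisible(x)
}

#' @export
print.trajectory_distribution <- function(x, ...) {
  cat(sprintf("trajectory_distribution: %d phase points x %d channels\n",
              nrow(x$mean), ncol(x$mean)))
  invisible(x)
}

#' Plot a trajectory distribution as mean and 2-sigma band
#'
#' @param x A `trajectory_distribution`.
#' @param channels Channels to draw. Default all.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.trajectory_distribution <- function(x, channels = x$channels, ...) {
  old <- graphics::par(mfrow = c(length(channels), 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  for (ch in channels) {
    m <- x$mean[, ch]
    s <- x$std[, ch]
    graphics::plot(x$z, m, type = "n", ylim = range(m - 2 * s, m + 2 * s),
                   xlab = "phase", ylab = ch, ...)
    graphics::polygon(c(x$z, rev(x$z)), c(m - 2 * s, rev(m + 2 * s)),
                      col = "grey85", border = NA)
    graphics::lines(x$z, m, lwd = 2)
  }
  invisible(x)
}
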