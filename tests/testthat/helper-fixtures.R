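# Shared fixture builders. All randomness is seeded by the caller.

# Config with all stochastic elements switched off (pure template strokes).
clean_config <- function(...) {
  synthetic_config(duration_jitter = 0, amplitude_cv = 0, shape_cv = 0,
                   noise_std = 0, ...)
}

# Wrap plain sample matrices as stroke objects.
as_strokes <- function(mats, direction = "inward") {
  lapply(mats, function(m) {
    structure(list(samples = m, direction = direction,
                   interval = c(1L, nrow(m) + 1L)),
              class = "stroke")
  })
}

# Generate a stroke set directly from the stroke generator, bypassing the
# tap-detection stage (used where only the fitted statistics matter).
gen_direct_set <- function(config, n = 20, direction = "inward",
                           grid = phase_grid(100)) {
  mats <- lapply(seq_len(n), function(i) generate_stroke_profile(config, direction))
  stroke_set(as_strokes(mats, direction), grid = grid)
}

# Build a stroke_set straight from an n x T x D array already on the grid.
array_stroke_set <- function(arr, grid, direction = "inward") {
  dimnames(arr) <- list(NULL, NULL, prompkl::promp_channels[seq_len(dim(arr)[3])])
  structure(list(data = arr, direction = direction, grid = grid,
                 metadata = list()),
            class = "stroke_set")
}

# Minimal trajectory_distribution for closed-form divergence tests.
make_dist <- function(mean, std, z = seq(0, 1, length.out = nrow(mean))) {
  ch <- prompkl::promp_channels[seq_len(ncol(mean))]
  colnames(mean) <- ch
  colnames(std) <- ch
  structure(list(mean = mean, std = std, z = z, channels = ch,
                 direction = NULL),
            class = "trajectory_distribution")
}

# A ProMP with known parameters: template-shaped weight mean, diagonal
# weight covariance, fixed observation noise. Returned as a promp_model so
# marginal_distribution() applies.
known_promp <- function(M = 10, sigma_y = 0.05, grid = phase_grid(100),
                        weight_sd = 0.08) {
  set.seed(981)
  model <- fit_promp(gen_direct_set(clean_config(sampling_rate = 500),
                                    n = 2, grid = grid), M = M)
  p <- length(model$mean)
  model$cov <- diag(rep(weight_sd^2, p))
  model$sigma_y[] <- sigma_y
  model$jitter <- 0
  model
}

# Draw n trajectories from a known ProMP with diagonal weight covariance.
sample_promp_set <- function(model, n) {
  M <- model$basis$M
  D <- model$D
  Phi <- model$basis$Phi
  Tn <- nrow(Phi)
  sds <- sqrt(diag(model$cov))
  arr <- array(NA_real_, c(n, Tn, D))
  for (j in seq_len(n)) {
    w <- model$mean + stats::rnorm(M * D, 0, sds)
    for (d in seq_len(D)) {
      idx <- ((d - 1) * M + 1):(d * M)
      arr[j, , d] <- Phi %*% w[idx] + stats::rnorm(Tn, 0, model$sigma_y[d])
    }
  }
  array_stroke_set(arr, model$basis$grid)
}

# Numerical-integration oracle for the directed Gaussian KL divergence.
kl_numeric <- function(mu1, sd1, mu2, sd2) {
  stats::integrate(function(x) {
    stats::dnorm(x, mu1, sd1) *
      (stats::dnorm(x, mu1, sd1, log = TRUE) - stats::dnorm(x, mu2, sd2, log = TRUE))
  }, lower = mu1 - 14 * sd1, upper = mu1 + 14 * sd1,
  rel.tol = 1e-10, subdivisions = 400L)$value
}

kls_numeric <- function(mu1, sd1, mu2, sd2) {
  0.5 * (kl_numeric(mu1, sd1, mu2, sd2) + kl_numeric(mu2, sd2, mu1, sd1))
}

# Hand-rolled divergence table for outlier-rule tests.
fake_table <- function(values, direction = "inward") {
  n <- length(values)
  data.frame(participant = seq_len(n), stimulation = "Sham",
             experiment = 1L, direction = direction,
             comparison = "Prae-Post1", value = values)
}
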