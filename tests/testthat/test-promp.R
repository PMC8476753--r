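test_that("basis bandwidth follows the squared center spacing", {
  b <- make_basis(20, phase_grid(100))
  expect_equal(b$bandwidth, 0.2 * (20 - 1)^-2)
  expect_equal(b$centers[1], 0)
  expect_equal(b$centers[20], 1)
  expect_equal(diff(b$centers), rep(1 / 19, 19))
})

test_that("basis rows are normalized and strictly positive", {
  for (M in c(2, 5, 20)) {
    for (Tn in c(10, 100)) {
      Phi <- make_basis(M, phase_grid(Tn))$Phi
      expect_lt(max(abs(rowSums(Phi) - 1)), 1e-12)
      expect_true(all(Phi >= 0))
      expect_true(all(apply(Phi, 1, max) > 0))
    }
  }
  expect_error(make_basis(1, phase_grid(10)), "at least 2")
})

test_that("basis values match direct evaluation of the Gaussian bumps", {
  # M = 3 on a grid containing z = 0.25; recompute from scratch
  grid <- phase_grid(5)           # z = 0, 0.25, 0.5, 0.75, 1
  b <- make_basis(3, grid)
  h <- 0.2 * 0.5^2
  raw <- exp(-(0.25 - c(0, 0.5, 1))^2 / (2 * h))
  expect_equal(unname(b$Phi[2, ]), raw / sum(raw), tolerance = 1e-14)
  # the two near bumps dominate equally at z = 0.25
  expect_equal(b$Phi[2, 1], b$Phi[2, 2], tolerance = 1e-14)
})

test_that("block feature stacks the basis once per channel", {
  Phi <- make_basis(4, phase_grid(9))$Phi
  expect_equal(build_block_feature(Phi, 1), Phi)
  A <- build_block_feature(Phi, 6)
  expect_equal(dim(A), c(9 * 6, 4 * 6))
  expect_equal(sum(A != 0), 6 * 9 * 4)
  # A %*% w equals the per-channel products, by loop construction
  set.seed(31)
  w <- rnorm(24)
  expected <- unlist(lapply(1:6, function(d) Phi %*% w[((d - 1) * 4 + 1):(d * 4)]))
  expect_equal(as.numeric(A %*% w), expected, tolerance = 1e-14)
})

test_that("ridge weights match a brute-force normal-equation solve", {
  set.seed(33)
  for (rep in 1:20) {
    Tn <- sample(5:20, 1)
    M <- sample(2:5, 1)
    D <- sample(1:2, 1)
    n <- sample(2:6, 1)
    lambda <- 10^runif(1, -8, -2)
    grid <- phase_grid(Tn)
    arr <- array(rnorm(n * Tn * D), c(n, Tn, D))
    set <- array_stroke_set(arr, grid)
    basis <- make_basis(M, grid)
    W <- fit_weights(set, basis, lambda)
    # oracle: element-by-element block matrix, explicit normal equations
    A <- matrix(0, Tn * D, M * D)
    for (d in seq_len(D)) {
      for (t in seq_len(Tn)) for (m in seq_len(M)) {
        A[(d - 1) * Tn + t, (d - 1) * M + m] <- basis$Phi[t, m]
      }
    }
    tau <- sapply(seq_len(n), function(j) as.numeric(arr[j, , ]))
    W_oracle <- qr.solve(t(A) %*% A + lambda * diag(M * D), t(A) %*% tau)
    expect_lt(max(abs(W - W_oracle)), 1e-8)
  }
})

test_that("ridge fit handles degenerate and exactly representable targets", {
  grid <- phase_grid(30)
  basis <- make_basis(5, grid)
  zero_set <- array_stroke_set(array(0, c(3, 30, 2)), grid)
  expect_equal(max(abs(fit_weights(zero_set, basis, 1e-6))), 0)
  expect_equal(max(abs(fit_weights(zero_set, basis, 0))), 0)
  # defaults mirror the operating point used for the analyses
  expect_equal(eval(formals(fit_weights)$lambda), 1e-6)

  # noiseless in-span strokes are recovered exactly
  set.seed(35)
  A <- build_block_feature(basis, 2)
  w_true <- matrix(rnorm(10 * 4), 10, 4)
  arr <- array(NA_real_, c(4, 30, 2))
  for (j in 1:4) arr[j, , ] <- matrix(A %*% w_true[, j], 30, 2)
  W <- fit_weights(array_stroke_set(arr, grid), basis, lambda = 1e-12)
  expect_lt(max(abs(W - w_true)), 1e-6)

  # lambda = 0 with an underdetermined basis is refused with advice
  grid_small <- phase_grid(3)
  basis_big <- make_basis(10, grid_small)
  small_set <- array_stroke_set(array(rnorm(12), c(2, 3, 2)), grid_small)
  expect_error(fit_weights(small_set, basis_big, lambda = 0), "lambda > 0")
})

test_that("weight distribution collapses stroke columns to mean and covariance", {
  W <- matrix(c(1, 2, 3), 3, 5)   # five identical strokes
  wd <- fit_weight_distribution(W, jitter = 1e-4)
  expect_equal(wd$mean, c(1, 2, 3))
  expect_equal(wd$cov, 1e-4 * diag(3))
  expect_error(fit_weight_distribution(W[, 1, drop = FALSE]), "at least 2")

  set.seed(37)
  W2 <- matrix(rnorm(4 * 50), 4, 50)
  expect_equal(fit_weight_distribution(W2)$mean, rowMeans(W2))
})

test_that("weight moments are recovered from many demonstrations", {
  set.seed(39)
  mu_true <- c(1, -2, 0.5, 3)
  sd_true <- c(0.5, 1, 0.2, 2)
  W <- mu_true + matrix(rnorm(4 * 500), 4, 500) * sd_true
  wd <- fit_weight_distribution(W)
  se <- sd_true / sqrt(500)
  expect_true(all(abs(wd$mean - mu_true) < 3 * se))
  expect_true(all(abs(diag(wd$cov) - sd_true^2) / sd_true^2 < 0.2))
})

test_that("noise estimate recovers the injected observation noise", {
  grid <- phase_grid(80)
  basis <- make_basis(8, grid)
  A <- build_block_feature(basis, 2)
  set.seed(41)
  w <- rnorm(16)
  clean <- matrix(A %*% w, 80, 2)
  n <- 60
  arr_clean <- array(NA_real_, c(n, 80, 2))
  arr_noisy <- arr_clean
  for (j in 1:n) {
    arr_clean[j, , ] <- clean
    arr_noisy[j, , ] <- clean + matrix(rnorm(160, 0, 0.1), 80, 2)
  }
  set_c <- array_stroke_set(arr_clean, grid)
  set_n <- array_stroke_set(arr_noisy, grid)
  sig_c <- estimate_noise(set_c, fit_weights(set_c, basis, 1e-10), basis)
  expect_equal(unname(sig_c), rep(1e-6, 2))   # zero residual hits the floor
  sig_n <- estimate_noise(set_n, fit_weights(set_n, basis, 1e-6), basis)
  expect_true(all(abs(sig_n - 0.1) / 0.1 < 0.1))
})

test_that("marginal distribution matches its defining degenerate case", {
  grid <- phase_grid(40)
  set.seed(43)
  arr <- array(rep(rnorm(40 * 2), each = 3), c(3, 40, 2))  # identical strokes
  set <- array_stroke_set(arr, grid)
  model <- fit_promp(set, M = 6, jitter = 0, sigma_y = 1e-6)
  dist <- marginal_distribution(model)
  expect_equal(unname(dist$std), matrix(1e-6, 40, 2))
  expect_equal(unname(dist$mean[, 1]),
               as.numeric(model$basis$Phi %*% model$mean[1:6]))
})

test_that("analytic marginal moments match Monte-Carlo sampling", {
  model <- known_promp(M = 5, sigma_y = 0.05, grid = phase_grid(30),
                       weight_sd = 0.1)
  dist <- marginal_distribution(model)
  set.seed(45)
  big <- sample_promp_set(model, 1e4)
  emp <- empirical_distribution(big)
  expect_lt(max(abs(emp$std / dist$std - 1)), 0.03)
  expect_lt(max(abs(emp$mean - dist$mean)), 4 * max(dist$std) / sqrt(1e4) * 4)
  # marginal variance never drops below the observation noise
  expect_true(all(dist$std >= model$sigma_y[1]))
})

test_that("a ProMP refit on its own samples reproduces the distribution", {
  model <- known_promp(M = 10, sigma_y = 0.05)
  set.seed(47)
  refit <- fit_promp(sample_promp_set(model, 200), M = 10)
  d <- trajectory_kls(marginal_distribution(model),
                      marginal_distribution(refit))$value
  expect_lt(d, 0.1)
})

test_that("empirical distribution equals the loop-computed sample moments", {
  grid <- phase_grid(15)
  set.seed(49)
  arr <- array(rnorm(8 * 15 * 3), c(8, 15, 3))
  emp <- empirical_distribution(array_stroke_set(arr, grid))
  for (t in c(1, 7, 15)) for (d in 1:3) {
    expect_equal(unname(emp$mean[t, d]), mean(arr[, t, d]))
    expect_equal(unname(emp$std[t, d]), sd(arr[, t, d]))
  }
  # duplicated strokes floor the standard deviation
  dup <- array(rep(rnorm(15 * 3), each = 2), c(2, 15, 3))
  expect_equal(unname(empirical_distribution(array_stroke_set(dup, grid))$std),
               matrix(1e-6, 15, 3))
  # large-n standard deviations approach the generating values
  big <- array(rnorm(4000 * 15 * 1, sd = 0.7), c(4000, 15, 1))
  emp_big <- empirical_distribution(array_stroke_set(big, grid))
  expect_true(all(abs(emp_big$std - 0.7) / 0.7 < 0.05))
})
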