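test_that("stroke generation is deterministic given the RNG state", {
  cfg <- synthetic_config(sampling_rate = 500)
  set.seed(11)
  a <- generate_stroke_profile(cfg, "inward")
  set.seed(11)
  b <- generate_stroke_profile(cfg, "inward")
  expect_identical(a, b)

  set.seed(11)
  r1 <- generate_recording(cfg)
  set.seed(11)
  r2 <- generate_recording(cfg)
  expect_identical(r1, r2)
})

test_that("noiseless stroke follows the minimum-jerk acceleration polynomial", {
  cfg <- clean_config(sampling_rate = 500)
  set.seed(1)
  prof <- generate_stroke_profile(cfg, "inward")
  L <- nrow(prof)
  # direct polynomial evaluation at 11 interior sample phases (the template
  # is proportional to 60z - 180z^2 + 120z^3 per channel)
  # avoid the template's mid-phase root at z = 0.5
  k <- round(seq(0.05, 0.93, length.out = 11) * (L - 1)) + 1
  z <- (k - 1) / (L - 1)
  poly <- 60 * z - 180 * z^2 + 120 * z^3
  for (d in 1:6) {
    ratio <- prof[k, d] / poly
    expect_lt(max(abs(ratio - mean(ratio))), 1e-10)
  }
  # endpoints of the template are zero
  expect_equal(unname(prof[1, ]), rep(0, 6))
  expect_equal(unname(prof[L, ]), rep(0, 6))
})

test_that("outward strokes are the time-reversed, sign-negated inward strokes", {
  cfg <- clean_config(sampling_rate = 500)
  set.seed(3)
  inward <- generate_stroke_profile(cfg, "inward")
  set.seed(3)
  outward <- generate_stroke_profile(cfg, "outward")
  expect_equal(outward, -inward[nrow(inward):1, ],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("stimulation effect scales and shifts the noiseless stroke", {
  base_cfg <- clean_config(sampling_rate = 500)
  set.seed(5)
  base <- generate_stroke_profile(base_cfg, "inward")

  doubled_cfg <- clean_config(sampling_rate = 500,
                              effect = stimulation_effect(amplitude_scale = 2,
                                                          applies_to = NULL))
  set.seed(5)
  doubled <- generate_stroke_profile(doubled_cfg, "inward")
  expect_equal(doubled, 2 * base, ignore_attr = TRUE, tolerance = 1e-12)

  identity_cfg <- clean_config(sampling_rate = 500,
                               effect = stimulation_effect(applies_to = NULL))
  set.seed(5)
  same <- generate_stroke_profile(identity_cfg, "inward")
  expect_equal(same, base, tolerance = 1e-12)

  # a shift confined to a sub-phase leaves the rest untouched
  shifted_cfg <- clean_config(sampling_rate = 500,
                              effect = stimulation_effect(mean_shift = 0.5,
                                                          phase_support = c(0.8, 1),
                                                          applies_to = NULL))
  set.seed(5)
  shifted <- generate_stroke_profile(shifted_cfg, "inward")
  z <- seq(0, 1, length.out = nrow(base))
  expect_equal(shifted[z < 0.8, ], base[z < 0.8, ], tolerance = 1e-12)
  expect_equal(shifted[z >= 0.8, ], base[z >= 0.8, ] + 0.5,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("a recording carries one pad pulse per contact", {
  cfg <- synthetic_config(sampling_rate = 500, n_cycles = 30)
  set.seed(7)
  rec <- generate_recording(cfg)
  rises <- sum(diff(rec$pads[, 1] > 0.5) == 1) + (rec$pads[1, 1] > 0.5) +
    sum(diff(rec$pads[, 2] > 0.5) == 1) + (rec$pads[1, 2] > 0.5)
  expect_equal(unname(rises), 2 * 30)
  expect_equal(nrow(rec$truth), 2 * 30)
})

test_that("zero-amplitude template leaves pure Gaussian sensor noise", {
  cfg <- synthetic_config(sampling_rate = 2000, stroke_amplitude = 0,
                          noise_std = 0.1, amplitude_cv = 0)
  set.seed(9)
  rec <- generate_recording(cfg)
  expect_gt(length(rec$motion), 1e5)
  expect_lt(abs(sd(rec$motion) - 0.1) / 0.1, 0.05)
  expect_lt(abs(mean(rec$motion)), 0.005)
})

test_that("study manifests enumerate the factorial design", {
  study <- generate_study(study_design(), synthetic_config(), seed = 1)
  expect_equal(nrow(study$manifest), 10 * 4 * 5 * 8)
  expect_equal(nrow(unique(study$manifest[, 1:4])), 1600)

  small <- study_design(n_participants = 2, stimulations = c("Sham", "tACS"),
                        phases = c("Prae", "Post1"), n_experiments = 2)
  expect_equal(nrow(generate_study(small, synthetic_config(), 1)$manifest), 16)
})

test_that("study cells are reproducible independently of generation order", {
  study <- generate_study(study_design(n_participants = 2,
                                       stimulations = c("Sham", "tACS"),
                                       phases = c("Prae", "Post1"),
                                       n_experiments = 2),
                          synthetic_config(sampling_rate = 300), seed = 4)
  r5 <- study_recording(study, 5)
  study_recording(study, 2)   # disturb the RNG state
  expect_identical(study_recording(study, 5), r5)
  expect_identical(r5$metadata,
                   as.list(study$manifest[5, c("participant", "stimulation",
                                               "phase", "experiment")]))
})

test_that("anomaly targets are validated", {
  a <- anomaly_spec(1, "Sham", "Post1", 1, kind = "axis_flip",
                    channels = "hand_x")
  design_dup <- study_design(n_participants = 2,
                             stimulations = c("Sham", "tACS"),
                             phases = c("Prae", "Post1"), n_experiments = 2,
                             anomalies = list(a, a))
  expect_error(generate_study(design_dup, synthetic_config(), 1),
               "duplicate anomaly targets")
  bad <- anomaly_spec(9, "Sham", "Post1", 1)
  design_bad <- study_design(n_participants = 2,
                             stimulations = c("Sham", "tACS"),
                             phases = c("Prae", "Post1"), n_experiments = 2,
                             anomalies = list(bad))
  expect_error(generate_study(design_bad, synthetic_config(), 1),
               "does not resolve")
})

test_that("axis flips and swaps are involutions on the named channels only", {
  set.seed(13)
  rec <- generate_recording(synthetic_config(sampling_rate = 300, n_cycles = 5))

  flip <- anomaly_spec(1, "Sham", "Post1", 1, kind = "axis_flip",
                       channels = "hand_x")
  flipped <- inject_anomaly(rec, flip)
  expect_equal(flipped$motion[, "hand_x"], -rec$motion[, "hand_x"])
  expect_equal(flipped$motion[, -1], rec$motion[, -1])
  expect_identical(inject_anomaly(flipped, flip)$motion, rec$motion)

  swap <- anomaly_spec(1, "Sham", "Post1", 1, kind = "axis_swap",
                       channels = c("hand_x", "wrist_x"))
  swapped <- inject_anomaly(rec, swap)
  expect_equal(swapped$motion[, "hand_x"], rec$motion[, "wrist_x"])
  expect_equal(swapped$motion[, "wrist_x"], rec$motion[, "hand_x"])
  expect_identical(inject_anomaly(swapped, swap)$motion, rec$motion)

  expect_error(inject_anomaly(rec, anomaly_spec(1, "Sham", "Post1", 1,
                                                channels = "hand_q")),
               "unknown channel")
})

test_that("inward and outward stroke sets mirror each other without noise", {
  # dwell = 0 so that pad-to-pad segments coincide with the pure strokes
  cfg <- clean_config(sampling_rate = 1000, n_cycles = 25, dwell = 0)
  set.seed(15)
  rec <- generate_recording(cfg)
  sets <- preprocess_recording(rec)
  m_in <- apply(sets$inward$data, c(2, 3), mean)
  m_out <- apply(sets$outward$data, c(2, 3), mean)
  # outward mean = negated, time-reversed inward mean
  expect_equal(m_out, -m_in[nrow(m_in):1, ], tolerance = 1e-6)
})

test_that("downstream divergence is non-decreasing in the injected mean shift", {
  deltas <- c(0, 0.5, 1, 2)   # multiples of the unit template peak
  grid <- phase_grid(60)
  mean_kls <- sapply(deltas, function(delta) {
    vals <- sapply(1:20, function(s) {
      cfg0 <- synthetic_config(sampling_rate = 300)
      cfg1 <- synthetic_config(sampling_rate = 300,
                               effect = stimulation_effect(mean_shift = delta,
                                                           applies_to = NULL))
      set.seed(1000 + s)
      a <- fit_promp(gen_direct_set(cfg0, 20, grid = grid), M = 10)
      set.seed(5000 + s)
      b <- fit_promp(gen_direct_set(cfg1, 20, grid = grid), M = 10)
      trajectory_kls(marginal_distribution(a), marginal_distribution(b))$value
    })
    mean(vals)
  })
  expect_true(all(diff(mean_kls) >= 0))
})
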