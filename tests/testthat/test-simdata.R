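test_that("geometry derives spacing and carrier frequency correctly", {
  geom <- acquisition_geometry()
  expect_equal(geom$axial_spacing_mm, 1540e3 / (2 * 96e6))
  expect_equal(geom$carrier_cycles_per_mm, 2 * 24e6 / 1540e3)
  expect_equal(geom$axial_extent_mm, geom$axial_spacing_mm * geom$n_axial)
  expect_equal(geom$lateral_extent_mm, geom$line_pitch_mm * geom$n_lines)
  expect_error(acquisition_geometry(axial_sample_freq_hz = 50e6), "4x")
  expect_error(acquisition_geometry(transmit_freq_hz = -1), "positive")
})

test_that("ground-truth spec validates its inputs", {
  expect_error(ground_truth_spec(respiration_amplitude_mm = -1), ">= 0")
  expect_error(ground_truth_spec(clutter_power_db = Inf), "finite")
  expect_error(ground_truth_spec(scatterer_density_per_mm2 = 0), "positive")
  expect_error(ground_truth_spec(perfusion_curve = function(t) t + 1),
               "0 dB")
  expect_silent(ground_truth_spec(blood_power_db = -Inf))
})

test_that("rendered speckle power matches the analytic calibration", {
  # E[power per sample] = rho A^2 (sqrt(pi) sig_z / 2)(sqrt(pi) sig_x);
  # scatterer_amplitude inverts this, so a blood-only noiseless field
  # should carry close to unit mean power (0 dB).
  geom <- acquisition_geometry()
  spec <- ground_truth_spec(clutter_power_db = -Inf, noise_power_db = -Inf,
                            blood_speed_mm_per_s = 0, seed = 10)
  pows <- vapply(1:8, function(s) {
    spec$seed <- 100 + s
    ens <- simulate_ensemble(spec, geom, n_frames = 2)
    mean(ens$frames^2)
  }, numeric(1))
  expect_lt(abs(10 * log10(mean(pows))), 0.6)
})

test_that("simulated ensembles have the advertised shape and determinism", {
  geom <- acquisition_geometry()
  spec <- ground_truth_spec(seed = 4)
  ens <- simulate_ensemble(spec, geom)
  expect_s3_class(ens, "ensemble_stack")
  expect_equal(dim(ens$frames), c(geom$n_axial, geom$n_lines, 16))
  expect_equal(ens$slow_time_rate_hz, 8)
  expect_equal(nrow(ens$true_displacement), 16)
  # frame 1 is the displacement reference
  expect_equal(ens$true_displacement$axial_mm[1], 0)
  expect_equal(ens$true_displacement$lateral_mm[1], 0)
  expect_equal(max(abs(ens$true_displacement$lateral_mm)),
               spec$respiration_amplitude_mm)
  ens2 <- simulate_ensemble(spec, geom)
  expect_identical(ens$frames, ens2$frames)
  expect_error(simulate_ensemble(spec, geom, t = -1), "pre")
})

test_that("default power ledger yields about 15 dB echo SNR", {
  geom <- acquisition_geometry()
  echo <- simulate_ensemble(ground_truth_spec(noise_power_db = -Inf,
                                              seed = 21), geom, n_frames = 2)
  noise <- simulate_ensemble(ground_truth_spec(clutter_power_db = -Inf,
                                               blood_power_db = -Inf,
                                               seed = 22), geom, n_frames = 2)
  snr_db <- 10 * log10(mean(echo$frames^2) / mean(noise$frames^2))
  expect_lt(abs(snr_db - 15), 1)
})

test_that("ischemic perfusion curve hits its defining parameters", {
  p_max <- 3; p_min <- -6; t_rec <- 9
  curve <- ischemic_perfusion_curve(p_max, p_min, t_rec)
  expect_equal(curve(0), 0)
  expect_equal(curve(2), p_min)                       # minimum at day 2
  expect_equal(curve(t_rec), 0, tolerance = 1e-9)     # recovery crossing
  # 20-min spike sits p_max above the local early trend
  u <- log10(c(10, 30, 60))
  trend <- predict(lm(db ~ u + I(u^2),
                      data = data.frame(u = u, db = curve(c(10, 30, 60) / 1440))),
                   data.frame(u = log10(20)))
  expect_equal(curve(20 / 1440) - unname(trend), p_max, tolerance = 1e-9)
  expect_lte(curve(28), 1)                            # late cap
  expect_error(ischemic_perfusion_curve(3, 1, 9), "negative")
  expect_error(ischemic_perfusion_curve(3, -6, 2), "\\(2, 28\\]")
})

test_that("noiseless mouse profiles follow the curve on the schedule", {
  prof <- simulate_mouse_profile(3, -6, 9, noise_sd_db = 0)
  expect_equal(nrow(prof), 12)
  expect_equal(prof$pdus_db[prof$time_label == "pre"], 0)
  expect_equal(prof$pdus_db[prof$time_label == "2 d"], -6)
  p1 <- simulate_mouse_profile(3, -6, 9, seed = 5)
  p2 <- simulate_mouse_profile(3, -6, 9, seed = 5)
  expect_identical(p1$pdus_db, p2$pdus_db)
})

test_that("cohort simulation produces the requested design", {
  cs <- cohort_spec(groups = c("HS", "DS"), sexes = "M", n_per_group = 3,
                    seed = 2)
  co <- simulate_cohort(cs)
  expect_equal(nrow(co$mice), 6)
  expect_equal(nrow(co$profiles), 6 * 12)
  expect_setequal(unique(co$profiles$group), c("HS", "DS"))
  expect_true(all(co$mice$t_true > 2 & co$mice$t_true <= 28))
  expect_true(all(co$mice$p_min_true < 0))
  # diabetic covariate shift is present in expectation
  expect_gt(mean(co$mice$weight_g[co$mice$group == "DS"]),
            mean(co$mice$weight_g[co$mice$group == "HS"]))
  co2 <- simulate_cohort(cs)
  expect_identical(co$profiles, co2$profiles)
  expect_error(cohort_spec(groups = "XX"), "HS")
  expect_error(cohort_spec(param_means = list(HS = c(3, -6, 2)),
                           groups = "HS"), "\\(2, 28\\]")
})
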