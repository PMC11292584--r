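test_that("the PSD grid spans the slow-time Nyquist band in 0.5 Hz steps", {
  M <- matrix(rnorm(20 * 16), 20, 16)
  psd <- doppler_psd(M, rate_hz = 8)
  expect_equal(psd$freq_hz, seq(-3.5, 4, by = 0.5))
  expect_s3_class(psd, "doppler_spectrum")
})

test_that("the PSD satisfies Parseval's relation", {
  set.seed(14)
  M <- matrix(rnorm(50 * 16), 50, 16)
  psd <- doppler_psd(M, rate_hz = 8)
  expect_equal(sum(psd$psd), mean(M^2), tolerance = 1e-12)
  # and picks up the rate from the matrix attributes
  attr(M, "rate_hz") <- 8
  expect_equal(doppler_psd(M)$freq_hz, psd$freq_hz)
  attr(M, "rate_hz") <- NULL
  expect_error(doppler_psd(M), "rate_hz")
})

test_that("a pure slow-time tone lands in its frequency bin", {
  t <- (0:15) / 8
  M <- matrix(rep(cos(2 * pi * 2 * t), 5), 5, 16, byrow = TRUE)
  psd <- doppler_psd(M, rate_hz = 8)
  top <- psd$freq_hz[order(psd$psd, decreasing = TRUE)[1:2]]
  expect_setequal(top, c(-2, 2))
})

test_that("axial tissue motion of one velocity bin shifts the Doppler peak", {
  # v = f c / (2 f0): 0.5 Hz at 24 MHz corresponds to about 0.016 mm/s
  geom <- acquisition_geometry()
  v <- 0.5 * 1540e3 / (2 * 24e6)
  expect_equal(v, 0.016, tolerance = 5e-3)
  spec <- ground_truth_spec(blood_power_db = -Inf, noise_power_db = -Inf,
                            respiration_amplitude_mm = 0,
                            axial_drift_mm_per_s = v, seed = 71)
  ens <- simulate_ensemble(spec, geom)
  psd <- doppler_psd(casorati(ens, roi_center(geom)), stage = "original")
  top <- psd$freq_hz[order(psd$psd, decreasing = TRUE)[1:2]]
  expect_setequal(abs(top), 0.5)
})

test_that("mean power matches its definition and the PSD integral", {
  M <- matrix(c(1, -1, 2, 0), 2, 2)
  expect_equal(pdus_power(M), mean(M^2))
  expect_error(pdus_power(matrix(numeric(0))), "Empty")
})

test_that("baseline normalization puts the pre point at 0 dB", {
  df <- tibble::tibble(time_label = c("pre", "1 d", "2 d"),
                       power = c(2, 1, 0.5))
  out <- normalize_profile(df)
  expect_equal(out$pdus_db, c(0, 10 * log10(0.5), 10 * log10(0.25)))
  expect_error(normalize_profile(df[-1, ]), "baseline")
  expect_error(normalize_profile(dplyr::mutate(df, power = c(0, 1, 1))),
               "positive")
})

test_that("group averaging reports mean, se and n per time point", {
  prof <- tidyr::expand_grid(mouse_id = c("a", "b", "c"),
                             time_label = c("pre", "1 d"))
  prof$group <- "HS"
  prof$pdus_db <- c(0, -4, 0, -6, 0, -5)
  avg <- cohort_average(prof)
  d1 <- avg[avg$time_label == "1 d", ]
  expect_equal(d1$mean_db, -5)
  expect_equal(d1$se_db, sd(c(-4, -6, -5)) / sqrt(3))
  expect_equal(d1$n, 3L)
  one <- cohort_average(prof[prof$mouse_id == "a", ])
  expect_true(all(is.na(one$se_db)))
  expect_error(cohort_average(prof[0, ]), "Empty")
})

test_that("process_recording runs the ensemble chain end to end", {
  geom <- acquisition_geometry()
  spec <- ground_truth_spec(seed = 72)
  frames <- lapply(1:32, function(i) {
    spec$seed <- 720 + i
    simulate_ensemble(spec, geom, n_frames = 1)$frames[, , 1]
  })
  rec <- doppler_recording(frames, geom, roi_set = list(roi_center(geom)))
  res <- process_recording(rec, register = FALSE)
  expect_equal(nrow(res$detail), 2)  # 32 frames -> 2 ensembles, 1 ROI
  expect_true(res$power > 0)
  expect_true(all(res$detail$gap_db > 0))
  expect_equal(res$power, mean(res$detail$power))
})
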