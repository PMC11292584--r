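test_that("injected sub-sample shifts are recovered to sub-micron error", {
  geom <- acquisition_geometry()
  ens <- simulate_ensemble(ground_truth_spec(seed = 31), geom, n_frames = 2)
  f1 <- ens$frames[, , 1]
  shifts <- rbind(c(0.013, -0.022), c(-0.007, 0.004), c(0.0, 0.018))
  for (i in seq_len(nrow(shifts))) {
    f2 <- pdus:::fourier_shift(f1,
                               shifts[i, 1] / geom$axial_spacing_mm,
                               shifts[i, 2] / geom$line_pitch_mm)
    e2 <- pdus:::new_ensemble_stack(array(c(f1, f2), c(dim(f1), 2)), geom)
    d <- estimate_displacements(e2)
    expect_lt(abs(d$axial_mm[2] - shifts[i, 1]), 1e-3)
    expect_lt(abs(d$lateral_mm[2] - shifts[i, 2]), 1e-3)
  }
})

test_that("respiration motion of 0.010 mm is recovered within 0.001 mm", {
  geom <- acquisition_geometry()
  for (s in 1:3) {
    ens <- simulate_ensemble(ground_truth_spec(seed = 40 + s), geom)
    d <- estimate_displacements(ens)
    expect_lt(abs(max(abs(d$lateral_mm)) - 0.010), 0.001)
    expect_lt(max(abs(d$lateral_mm - ens$true_displacement$lateral_mm)),
              1.5e-3)
  }
})

test_that("registration shifts frames back onto the reference", {
  geom <- acquisition_geometry()
  ens <- simulate_ensemble(ground_truth_spec(seed = 51), geom)
  d <- estimate_displacements(ens)
  reg <- apply_registration(ens, d)
  roi <- roi_center(geom)
  expect_gt(interframe_correlation(reg, roi),
            interframe_correlation(ens, roi))
  expect_true(reg$provenance$registered)
  # frame 1 is untouched
  expect_identical(reg$frames[, , 1], ens$frames[, , 1])
})

test_that("registration rejects implausible displacement traces", {
  geom <- acquisition_geometry()
  ens <- simulate_ensemble(ground_truth_spec(seed = 52), geom, n_frames = 2)
  bad <- tibble::tibble(axial_mm = c(0, geom$axial_extent_mm / 2),
                        lateral_mm = c(0, 0))
  expect_error(apply_registration(ens, bad), "10%")
  expect_error(apply_registration(ens, bad[1, ]), "match")
})

test_that("degenerate inputs fail loudly", {
  geom <- acquisition_geometry(n_axial = 16, n_lines = 8)
  const <- pdus:::new_ensemble_stack(array(1, c(16, 8, 3)), geom)
  expect_error(estimate_displacements(const), "constant")
  one <- pdus:::new_ensemble_stack(array(rnorm(16 * 8), c(16, 8, 1)), geom)
  expect_error(estimate_displacements(one), "at least 2 frames")
  expect_error(interframe_correlation(const), "undefined")
})

test_that("the Tukey taper is flat in the center and zero at the edges", {
  w <- pdus:::tukey_window(101, 0.25)
  expect_equal(w[1], 0)
  expect_equal(w[101], 0)
  expect_true(all(w[40:60] == 1))
  expect_true(all(diff(w[1:13]) > 0))
  expect_equal(pdus:::tukey_window(7, 0), rep(1, 7))
})

test_that("the Fourier shift is exact for circular translations", {
  set.seed(9)
  m <- matrix(rnorm(32 * 16), 32, 16)
  s <- pdus:::fourier_shift(m, 3, -5)  # integer shift = circular roll
  expect_equal(s, m[((seq_len(32) - 1 - 3) %% 32) + 1,
                    ((seq_len(16) - 1 + 5) %% 16) + 1],
               tolerance = 1e-12)
  # shifting forth and back is the identity for signals without energy at
  # the Nyquist bins (which the shift symmetrizes to stay real-valued)
  F <- fft(m)
  F[17, ] <- 0
  F[, 9] <- 0
  mb <- Re(fft(F, inverse = TRUE)) / length(F)
  back <- pdus:::fourier_shift(pdus:::fourier_shift(mb, 0.37, -1.22),
                               -0.37, 1.22)
  expect_equal(back, mb, tolerance = 1e-12)
})
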