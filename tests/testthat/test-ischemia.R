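make_profile <- function(db) {
  sched <- pdus_schedule()
  tibble::tibble(time_label = sched$time_label, pdus_db = db)
}

test_that("a profile lying on one parabola has zero spike height", {
  sched <- pdus_schedule()
  u <- log10(sched$time_min)
  prof <- make_profile(0.5 * u^2 - 1.2 * u + 0.3)
  expect_equal(estimate_pmax(prof)$p_max_db, 0, tolerance = 1e-9)
})

test_that("a constructed 3 dB spike is recovered exactly", {
  sched <- pdus_schedule()
  u <- log10(sched$time_min)
  db <- -0.8 * u^2 + 0.1 * u
  db[sched$time_label == "20 m"] <- db[sched$time_label == "20 m"] + 3
  est <- estimate_pmax(make_profile(db), replicates_20m = c(2.8, 3.1, 3.0))
  expect_equal(est$p_max_db, 3, tolerance = 1e-9)
  expect_equal(est$sd_db, sd(c(2.8, 3.1, 3.0)))
  expect_error(estimate_pmax(make_profile(db)[-3, ]), "20 m")
})

test_that("a recovery parabola crossing 0 dB at day 9 gives T = 9", {
  sched <- pdus_schedule()
  u <- log10(sched$time_days)
  a <- 6 / (log10(9) - log10(2))^2
  db <- a * (u - log10(2))^2 - 6
  est <- estimate_recovery_time(make_profile(db))
  expect_equal(est$t_days, 9, tolerance = 1e-6)
  expect_false(est$censored)
})

test_that("profiles that never recover are censored", {
  sched <- pdus_schedule()
  u <- log10(sched$time_days)
  db <- 0.05 * (u - log10(2))^2 - 6  # shallow parabola, stays far below 0
  est <- estimate_recovery_time(make_profile(db))
  expect_true(est$censored)
  expect_true(is.na(est$t_days))
})

test_that("an all-baseline profile reports the day-1 boundary", {
  expect_warning(est <- estimate_recovery_time(make_profile(rep(0, 12))),
                 "Degenerate")
  expect_equal(est$t_days, 1)
})

test_that("P_min is the measured minimum, excluding the baseline", {
  db <- c(0, -1, 2, -3, -6.2, -4, -2, -1, 0, 1, 0.5, 0)
  expect_equal(estimate_pmin(make_profile(db)), -6.2)
  # a negative pre value is not eligible
  db2 <- c(-9, 1, 2, 3, 1, 1, 1, 1, 1, 1, 1, 1)
  expect_equal(estimate_pmin(make_profile(db2)), 1)
})

test_that("offset invariance: P_max fixed, P_min shifted", {
  prof <- simulate_mouse_profile(3, -6, 9, noise_sd_db = 0.4, seed = 80)
  base <- estimate_ischemic_params(prof)
  shifted <- prof
  shifted$pdus_db <- shifted$pdus_db + 2.5
  sh <- estimate_ischemic_params(shifted)
  expect_equal(sh$p_max_db, base$p_max_db, tolerance = 1e-9)
  expect_equal(sh$p_min_db, base$p_min_db + 2.5, tolerance = 1e-9)
})

test_that("the fitted object exposes tidy and glance views", {
  fit <- estimate_ischemic_params(simulate_mouse_profile(3, -6, 9, 0))
  td <- generics::tidy(fit)
  expect_setequal(unique(td$fit), c("spike", "recovery"))
  expect_equal(nrow(td), 6)  # two quadratics, three coefficients each
  gl <- generics::glance(fit)
  expect_named(gl, c("p_max_db", "p_max_sd_db", "p_min_db", "t_days",
                     "censored"))
  expect_output(print(fit), "ischemic_fit")
})

test_that("cohort parameter extraction keeps mouse identity and group", {
  co <- simulate_cohort(cohort_spec(groups = c("HS", "DS"), sexes = "M",
                                    n_per_group = 2, seed = 6))
  pars <- cohort_ischemic_params(co$profiles)
  expect_equal(nrow(pars), 4)
  expect_setequal(pars$mouse_id, unique(co$profiles$mouse_id))
  expect_true(all(c("p_max_db", "p_min_db", "t_days", "censored")
                  %in% names(pars)))
})
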