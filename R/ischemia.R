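#' Estimate the 20-min perfusion spike height
#'
#' Fits the baseline (`pre`, placed at 1 min on the log-time axis) and the
#' 10-, 30-, and 60-min points to a second-order polynomial in
#' `log10(minutes)` and reports the difference (dB) between the measured
#' 20-min value and the fitted trend at 20 min. The fit excludes the 20-min
#' point itself. When replicate 20-min measurements (across ensembles/ROIs)
#' are supplied, their standard deviation is reported as the uncertainty.
#'
#' @param profile Tibble with `time_label` and `pdus_db` containing at
#'   least the `pre`, `10 m`, `20 m`, `30 m`, `60 m` points.
#' @param replicates_20m Optional numeric vector of replicate 20-min dB
#'   values.
#' @return A list: `p_max_db`, `sd_db` (`NA` without replicates), `fit`
#'   (the `lm` object).
#' @export
#' @examples
#' prof <- simulate_mouse_profile(3, -6, 9, noise_sd_db = 0)
#' estimate_pmax(prof)$p_max_db
estimate_pmax <- function(profile, replicates_20m = NULL) {
  need <- c("pre", "10 m", "20 m", "30 m", "60 m")
  labs <- as.character(profile$time_label)
  if (!all(need %in% labs)) {
    abort("Profile must contain pre, 10 m, 20 m, 30 m, 60 m points.")
  }
  sched <- pdus_schedule()
  tmin <- setNames(sched$time_min, as.character(sched$time_label))
  fit_labs <- c("pre", "10 m", "30 m", "60 m")
  d <- tibble(
    u = log10(tmin[fit_labs]),
    db = profile$pdus_db[match(fit_labs, labs)]
  )
  fit <- lm(db ~ u + I(u^2), data = d)
  u20 <- log10(tmin[["20 m"]])
  trend <- unname(predict(fit, tibble(u = u20)))
  measured <- profile$pdus_db[match("20 m", labs)]
  list(p_max_db = measured - trend,
       sd_db = if (is.null(replicates_20m)) NA_real_ else sd(replicates_20m),
       fit = fit)
}

#' Estimate the minimum perfusion
#'
#' The minimum measured (not fitted) baseline-normalized value over the
#' post-ligation points of the 28-day experiment.
#'
#' @param profile Tibble with `time_label` and `pdus_db`.
#' @return Minimum dB value.
#' @export
estimate_pmin <- function(profile) {
  post <- profile$pdus_db[as.character(profile$time_label) != "pre"]
  if (length(post) == 0) abort("No post-ligation points.")
  min(post)
}

#' Estimate the perfusion recovery time
#'
#' Fits the day 1, 2, 3, 7, and 14 points to a second-order polynomial in
#' `log10(days)` and reports the time at which the fit crosses the 0-dB
#' (baseline) axis from below -- the upward crossing with positive slope
#' within (1, 28] days, ties broken toward the earlier crossing. If the fit
#' never reaches baseline within 28 days the estimate is censored. A
#' degenerate all-baseline profile reports the day-1 boundary with a
#' warning.
#'
#' @param profile Tibble with `time_label` and `pdus_db` containing the
#'   `1 d`, `2 d`, `3 d`, `1 w`, `2 w` points.
#' @return A list: `t_days`, `censored` (logical), `fit`.
#' @export
#' @examples
#' prof <- simulate_mouse_profile(3, -6, 9, noise_sd_db = 0)
#' estimate_recovery_time(prof)$t_days
estimate_recovery_time <- function(profile) {
  need <- c("1 d", "2 d", "3 d", "1 w", "2 w")
  labs <- as.character(profile$time_label)
  if (sum(need %in% labs) < 3) {
    abort("Need at least 3 recovery-phase points for a quadratic fit.")
  }
  sched <- pdus_schedule()
  tday <- setNames(sched$time_days, as.character(sched$time_label))
  use <- need[need %in% labs]
  d <- tibble(u = log10(tday[use]), db = profile$pdus_db[match(use, labs)])
  fit <- lm(db ~ u + I(u^2), data = d)
  cf <- coef(fit)  # db = c0 + b u + a u^2
  a <- unname(cf["I(u^2)"])
  b <- unname(cf["u"])
  c0 <- unname(cf["(Intercept)"])
  if (all(abs(c(a, b, c0)) < 1e-10)) {
    warn("Degenerate recovery fit (profile at baseline); reporting day-1 boundary.")
    return(list(t_days = 1, censored = FALSE, fit = fit))
  }
  roots <- if (abs(a) < 1e-12) {
    if (abs(b) < 1e-12) numeric(0) else -c0 / b
  } else {
    disc <- b^2 - 4 * a * c0
    if (disc < 0) numeric(0) else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  upward <- roots[2 * a * roots + b > 0]
  t_candidates <- sort(10^upward)
  t_candidates <- t_candidates[t_candidates > 1 & t_candidates <= 28]
  if (length(t_candidates) == 0) {
    list(t_days = NA_real_, censored = TRUE, fit = fit)
  } else {
    list(t_days = t_candidates[1], censored = FALSE, fit = fit)
  }
}

#' Full ischemic-response characterization of one profile
#'
#' Bundles [estimate_pmax()], [estimate_pmin()] and
#' [estimate_recovery_time()] into a fitted object with [tidy()] and
#' [glance()] methods.
#'
#' @inheritParams estimate_pmax
#' @return An `ischemic_fit` object.
#' @export
#' @examples
#' fit <- estimate_ischemic_params(simulate_mouse_profile(3, -6, 9, 0))
#' glance(fit)
estimate_ischemic_params <- function(profile, replicates_20m = NULL) {
  pmax_est <- estimate_pmax(profile, replicates_20m)
  trec <- estimate_recovery_time(profile)
  structure(
    list(p_max_db = pmax_est$p_max_db,
         p_max_sd_db = pmax_est$sd_db,
         p_min_db = estimate_pmin(profile),
         t_days = trec$t_days,
         censored = trec$censored,
         spike_fit = pmax_est$fit,
         recovery_fit = trec$fit,
         profile = profile),
    class = "ischemic_fit"
  )
}

#' @export
print.ischemic_fit <- function(x, ...) {
  cat(sprintf(
    "<ischemic_fit> P_max = %.2f dB, P_min = %.2f dB, T = %s days%s\n",
    x$p_max_db, x$p_min_db,
    if (is.na(x$t_days)) "NA" else sprintf("%.2f", x$t_days),
    if (x$censored) " (censored)" else ""))
  invisible(x)
}

#' @rdname estimate_ischemic_params
#' @param x An `ischemic_fit`.
#' @param ... Unused.
#' @export
tidy.ischemic_fit <- function(x, ...) {
  bind_rows(
    tibble(fit = "spike",
           term = names(coef(x$spike_fit)),
           estimate = unname(coef(x$spike_fit))),
    tibble(fit = "recovery",
           term = names(coef(x$recovery_fit)),
           estimate = unname(coef(x$recovery_fit)))
  )
}

#' @rdname estimate_ischemic_params
#' @export
glance.ischemic_fit <- function(x, ...) {
  tibble(p_max_db = x$p_max_db, p_max_sd_db = x$p_max_sd_db,
         p_min_db = x$p_min_db, t_days = x$t_days, censored = x$censored)
}

#' Ischemic parameters for every mouse in a cohort
#'
#' @param profiles Tibble of per-mouse profiles (`mouse_id`, `group`,
#'   `time_label`, `pdus_db`, optionally `sex`).
#' @return Tibble with one row per mouse: identifiers plus `p_max_db`,
#'   `p_min_db`, `t_days`, `censored`.
#' @export
cohort_ischemic_params <- function(profiles) {
  ids <- unique(profiles$mouse_id)
  purrr::map_dfr(ids, function(id) {
    prof <- profiles %>% filter(.data$mouse_id == id)
    g <- glance(estimate_ischemic_params(prof))
    meta <- prof[1, intersect(c("mouse_id", "group", "sex"), names(prof))]
    dplyr::bind_cols(meta, g %>% select(-"p_max_sd_db"))
  })
}
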