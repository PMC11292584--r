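#' Plot a displacement trace
#'
#' Axial and lateral tissue displacement versus slow time for one
#' ensemble, the standard registration diagnostic.
#'
#' @param object A `displacement_trace` from [estimate_displacements()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.displacement_trace <- function(object, ...) {
  d <- tidyr::pivot_longer(object, c("axial_mm", "lateral_mm"),
                           names_to = "axis", values_to = "displacement_mm")
  ggplot(d, aes(x = .data$time_s, y = .data$displacement_mm,
                colour = .data$axis)) +
    geom_line() +
    geom_point(size = 1) +
    scale_colour_manual(values = c(axial_mm = "blue", lateral_mm = "red"),
                        labels = c("axial", "lateral"), name = NULL) +
    labs(x = "time (s)", y = "displacement (mm)")
}

#' Plot a singular spectrum
#'
#' @param object A `singular_spectrum` from [svd_filter()], or several
#'   bound together with a `stage` column.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.singular_spectrum <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$rank, y = 20 * log10(.data$value)))
  if ("stage" %in% names(object)) {
    p <- p + geom_line(aes(colour = .data$stage)) +
      geom_point(aes(colour = .data$stage), size = 1)
  } else {
    p <- p + geom_line() + geom_point(size = 1)
  }
  p + labs(x = "singular value rank", y = "singular value (dB)")
}

#' Plot a Doppler spectrum
#'
#' @param object A `doppler_spectrum` from [doppler_psd()]; spectra from
#'   several processing stages can be row-bound and are distinguished by
#'   their `stage` column.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.doppler_spectrum <- function(object, ...) {
  ggplot(object, aes(x = .data$freq_hz,
                     y = 10 * log10(pmax(.data$psd, .Machine$double.xmin)),
                     colour = .data$stage)) +
    geom_line() +
    labs(x = "Doppler frequency (Hz)", y = "PSD (dB)", colour = NULL)
}

#' Plot group-averaged perfusion curves
#'
#' Mean baseline-normalized perfusion per group with +/- 1 se error bars on
#' a logarithmic time axis.
#'
#' @param curves Output of [cohort_average()].
#' @param group Name of the grouping column.
#' @return A ggplot object.
#' @export
plot_perfusion_curves <- function(curves, group = "group") {
  sched <- pdus_schedule()
  d <- curves %>%
    left_join(sched, by = "time_label")
  ggplot(d, aes(x = .data$time_min, y = .data$mean_db,
                colour = .data[[group]])) +
    geom_line() +
    geom_point(size = 1) +
    geom_errorbar(aes(ymin = .data$mean_db - .data$se_db,
                      ymax = .data$mean_db + .data$se_db), width = 0.05) +
    scale_x_log10(breaks = sched$time_min,
                  labels = as.character(sched$time_label)) +
    labs(x = "time post-ligation", y = "PD-US (dB re baseline)",
         colour = NULL)
}

#' Plot the polynomial fits behind an ischemic parameter estimate
#'
#' @param object An `ischemic_fit`.
#' @param ... Unused.
#' @return A ggplot object showing the measured points, the early-time
#'   trend fit (whose 20-min excess is the spike height), and the recovery
#'   fit whose 0-dB crossing defines the recovery time.
#' @export
autoplot.ischemic_fit <- function(object, ...) {
  sched <- pdus_schedule()
  prof <- object$profile %>%
    left_join(sched %>% select("time_label", "time_min"),
              by = "time_label", suffix = c("", ".sched"))
  if (!"time_min" %in% names(prof)) prof$time_min <- prof$time_min.sched
  spike_u <- seq(0, log10(60), length.out = 50)
  spike <- tibble(time_min = 10^spike_u,
                  db = predict(object$spike_fit, tibble(u = spike_u)))
  rec_u <- seq(0, log10(14), length.out = 50)
  recov <- tibble(time_min = 1440 * 10^rec_u,
                  db = predict(object$recovery_fit, tibble(u = rec_u)))
  ggplot(prof, aes(x = .data$time_min, y = .data$pdus_db)) +
    geom_point() +
    geom_line(data = spike, aes(y = .data$db), colour = "steelblue") +
    geom_line(data = recov, aes(y = .data$db), colour = "firebrick") +
    geom_hline(yintercept = 0, linetype = 2) +
    scale_x_log10(breaks = sched$time_min,
                  labels = as.character(sched$time_label)) +
    labs(x = "time post-ligation", y = "PD-US (dB re baseline)")
}
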