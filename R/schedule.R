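#' Measurement schedule for the hindlimb-ischemia study
#'
#' Perfusion is measured before femoral ligation (`"pre"`), at 10-60 min
#' post-ligation, then daily and weekly through four weeks. This helper
#' returns the canonical schedule with each point's time in minutes and days.
#' The `"pre"` point is assigned 1 min so that it occupies a finite position
#' on the logarithmic time axis used by the trend fits; all estimators treat
#' it as the 0-dB baseline regardless of that placement.
#'
#' @return A tibble with columns `time_label` (ordered factor), `time_min`,
#'   and `time_days`.
#' @export
#' @examples
#' pdus_schedule()
pdus_schedule <- function() {
  labels <- c("pre", "10 m", "20 m", "30 m", "60 m",
              "1 d", "2 d", "3 d", "1 w", "2 w", "3 w", "4 w")
  mins <- c(1, 10, 20, 30, 60,
            1440, 2880, 4320, 7 * 1440, 14 * 1440, 21 * 1440, 28 * 1440)
  tibble(
    time_label = factor(labels, levels = labels, ordered = TRUE),
    time_min = mins,
    time_days = mins / 1440
  )
}

schedule_labels <- function() as.character(pdus_schedule()$time_label)

#' Convert a baseline-relative dB value to percent of baseline
#'
#' Perfusion profiles are expressed in dB relative to the pre-ligation
#' baseline; `db_to_percent(-5)` returns about 32 (i.e. 32% of baseline)
#' and `db_to_percent(-7)` about 20.
#'
#' @param db Numeric vector of dB values (power ratio, 10 log10).
#' @return Percent of baseline, `100 * 10^(db/10)`.
#' @export
#' @examples
#' db_to_percent(c(-5, -7))
db_to_percent <- function(db) 100 * 10^(db / 10)

#' @rdname db_to_percent
#' @param percent Percent of baseline.
#' @export
percent_to_db <- function(percent) 10 * log10(percent / 100)

#' Analytic relations implied by the acquisition settings
#'
#' Derives, from an [acquisition_geometry()], the quantities that fix the
#' Doppler measurement scale: slow-time Doppler-frequency resolution
#' (Hz; the reciprocal of the ensemble duration), the slow-time Nyquist
#' band (+/- half the Doppler frame rate), the velocity resolution
#' corresponding to one frequency bin via `v = f c / (2 f0)`, the number of
#' complete 16-frame ensembles per recording, and the round-trip attenuation
#' for a target at `depth_cm` given `attenuation_db_cm_mhz`.
#'
#' @param geom An [acquisition_geometry()].
#' @param ensemble_length Frames per slow-time ensemble (default 16).
#' @param depth_cm Target depth in cm for the attenuation estimate.
#' @param attenuation_db_cm_mhz Attenuation coefficient in dB/(cm MHz).
#' @return A one-row tibble with columns `freq_resolution_hz`,
#'   `nyquist_hz`, `velocity_resolution_mm_s`, `n_ensembles`,
#'   `round_trip_attenuation_db`.
#' @export
#' @examples
#' acquisition_relations(acquisition_geometry())
acquisition_relations <- function(geom = acquisition_geometry(),
                                  ensemble_length = 16,
                                  depth_cm = 0.2,
                                  attenuation_db_cm_mhz = 0.5) {
  stopifnot(inherits(geom, "acquisition_geometry"))
  ensemble_duration_s <- ensemble_length / geom$doppler_frame_rate_hz
  df <- 1 / ensemble_duration_s
  c_mm_s <- geom$sound_speed_m_per_s * 1e3
  tibble(
    freq_resolution_hz = df,
    nyquist_hz = geom$doppler_frame_rate_hz / 2,
    velocity_resolution_mm_s = df * c_mm_s / (2 * geom$transmit_freq_hz),
    n_ensembles = floor(geom$n_doppler_frames / ensemble_length),
    round_trip_attenuation_db =
      attenuation_db_cm_mhz * 2 * depth_cm * geom$transmit_freq_hz / 1e6
  )
}
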