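#' Flow-mediated dilation from a vessel-diameter series
#'
#' FMD is the fractional increase of the femoral-artery diameter after a
#' 5-min pressure-cuff occlusion: `(Da - Db) / Db`, where `Db` is the mean
#' pre-cuff baseline diameter and `Da` the largest diameter measured during
#' the hyperemic response (by default within 5 min of cuff release, where
#' the peak occurs about 1 min after release). The index is dimensionless
#' and invariant to the diameter unit.
#'
#' @param df Tibble with columns `time_min` (cuff release at 0; baseline
#'   points at `time_min <= 0`) and `diameter_mm` (> 0).
#' @param window_min Post-release search window for the peak, minutes.
#' @return FMD as a dimensionless fraction.
#' @export
#' @examples
#' compute_fmd(tibble::tibble(time_min = c(-1, 1, 2),
#'                            diameter_mm = c(0.300, 0.339, 0.320)))
compute_fmd <- function(df, window_min = 5) {
  if (!all(c("time_min", "diameter_mm") %in% names(df))) {
    abort("`df` needs columns `time_min` and `diameter_mm`.")
  }
  if (any(df$diameter_mm <= 0)) abort("Diameters must be positive.")
  db <- df$diameter_mm[df$time_min <= 0]
  da <- df$diameter_mm[df$time_min > 0 & df$time_min <= window_min]
  if (length(db) == 0) abort("No pre-cuff baseline diameter.")
  if (length(da) == 0) abort("No post-release diameter in the window.")
  (max(da) - mean(db)) / mean(db)
}

#' Reactive hyperemia index from a PD-US power series
#'
#' RH is the dB ratio of the peak post-occlusion PD-US power to the
#' pre-cuff baseline power: `10 log10(PDUSa / PDUSb)`, with the baseline
#' taken as the average of the pre-cuff estimates and the peak searched in
#' the post-release window. Unit-invariant and monotone in the peak power.
#'
#' @param df Tibble with columns `time_min` (release at 0) and `power`
#'   (linear PD-US power, > 0).
#' @param window_min Post-release search window, minutes.
#' @return RH in dB.
#' @export
#' @examples
#' compute_rh(tibble::tibble(time_min = c(-1, 1), power = c(1, 2)))
compute_rh <- function(df, window_min = 5) {
  if (!all(c("time_min", "power") %in% names(df))) {
    abort("`df` needs columns `time_min` and `power`.")
  }
  if (any(df$power <= 0)) abort("Powers must be positive.")
  pb <- df$power[df$time_min <= 0]
  pa <- df$power[df$time_min > 0 & df$time_min <= window_min]
  if (length(pb) == 0) abort("No pre-cuff baseline power.")
  if (length(pa) == 0) abort("No post-release power in the window.")
  10 * log10(max(pa) / mean(pb))
}

#' Classify endothelial indices against normal ranges
#'
#' Normal murine FMD lies between 0.13 and 0.14, and normal RH between 3.9
#' and 5.2 dB; values below the lower edge indicate reduced endothelial
#' function in conduit (FMD) or resistance (RH) vessels. Classification is
#' inclusive at the lower edge, and the thresholds are configurable.
#'
#' @param fmd FMD fraction(s).
#' @param rh_db RH value(s), dB.
#' @param fmd_normal_min Lower edge of the normal FMD range.
#' @param rh_normal_min_db Lower edge of the normal RH range, dB.
#' @return Tibble with `fmd`, `rh_db`, `conduit`, `resistance`
#'   (each `"normal"` or `"reduced"`).
#' @export
#' @examples
#' classify_endothelial(fmd = c(0.135, 0.065), rh_db = c(4.5, 3.9))
classify_endothelial <- function(fmd, rh_db, fmd_normal_min = 0.13,
                                 rh_normal_min_db = 3.9) {
  tibble(
    fmd = fmd,
    rh_db = rh_db,
    conduit = ifelse(fmd >= fmd_normal_min, "normal", "reduced"),
    resistance = ifelse(rh_db >= rh_normal_min_db, "normal", "reduced")
  )
}

#' Coefficient of variation
#'
#' `100 * sd / |mean|` using the sample (n - 1) standard deviation; the
#' repeatability metric used for repeated RH measurements.
#'
#' @param values Numeric vector (length >= 2, non-zero mean).
#' @return CV in percent.
#' @export
#' @examples
#' coefficient_of_variation(c(9, 11))
coefficient_of_variation <- function(values) {
  if (length(values) < 2) abort("Need at least 2 values.")
  m <- mean(values)
  if (m == 0) abort("Mean is zero; CV undefined.")
  100 * sd(values) / abs(m)
}
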