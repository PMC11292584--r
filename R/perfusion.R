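#' Slow-time Doppler power spectral density
#'
#' Spatially averaged periodogram of the slow-time signal in each spatial
#' sample of a (filtered) Casorati matrix. A 16-frame ensemble at 8 Hz gives
#' 0.5 Hz frequency resolution over the +/- 4 Hz slow-time Nyquist band. No
#' taper is applied and the mean is not removed: the 0 Hz bin is part of
#' the filtered spectrum. The PSD satisfies Parseval's relation: its sum
#' equals the mean signal power of the matrix.
#'
#' @param M Space x time matrix (e.g. from [svd_filter()]).
#' @param rate_hz Slow-time sampling rate; taken from the matrix attribute
#'   if present.
#' @param stage Label describing the processing stage (e.g. `"original"`,
#'   `"registered"`, `"filtered"`, `"registered & filtered"`).
#' @return A `doppler_spectrum` tibble: `freq_hz` (from -rate/2 in
#'   rate/ncol steps), `psd`, `stage`.
#' @export
#' @examples
#' M <- matrix(rnorm(320), 20, 16)
#' psd <- doppler_psd(M, rate_hz = 8)
#' sum(psd$psd) - mean(M^2)  # Parseval
doppler_psd <- function(M, rate_hz = NULL, stage = "filtered") {
  if (is.null(rate_hz)) rate_hz <- attr(M, "rate_hz")
  if (is.null(rate_hz)) abort("`rate_hz` is required.")
  n <- ncol(M)
  if (is.null(n) || n < 2) abort("Need at least 2 time samples.")
  X <- t(apply(M, 1, fft))
  psd <- colMeans(Mod(X)^2) / n^2
  half <- floor(n / 2)
  ord <- c((half + 2):n, 1:(half + 1))  # fftshift for even/odd n
  freqs <- (seq_len(n) - 1) * rate_hz / n
  freqs[freqs > rate_hz / 2] <- freqs[freqs > rate_hz / 2] - rate_hz
  structure(
    tibble(freq_hz = freqs[ord], psd = psd[ord], stage = stage),
    class = c("doppler_spectrum", "tbl_df", "tbl", "data.frame")
  )
}

#' Mean signal power of a space-time matrix
#'
#' The power-Doppler estimate for one ensemble/ROI: the mean squared sample
#' value over space and slow time (equal to the integral of the Doppler PSD
#' by Parseval's relation).
#'
#' @param M Space x time matrix.
#' @return Mean linear power (a scalar, >= 0).
#' @export
pdus_power <- function(M) {
  if (length(M) == 0) abort("Empty matrix.")
  mean(M^2)
}

#' Process one recording into a PD-US power estimate
#'
#' The full ensemble-level chain: partition the recording into slow-time
#' ensembles, optionally register each to its first frame, restrict to each
#' ROI (Casorati form), apply the SVD clutter filter, and estimate signal
#' power. Per-ensemble/ROI powers are averaged on the linear scale into a
#' single 12-s estimate.
#'
#' @param rec A [doppler_recording()] (its `roi_set` is used unless `rois`
#'   is given).
#' @param rois Optional list of [roi_rect()] regions.
#' @param register Apply rigid registration before filtering?
#' @param n_removed Singular components removed by the clutter filter.
#' @param frame_indices Echo-frame selections to average over (see
#'   [assemble_ensembles()]); default uses only the first echo frame.
#' @return A list with `power` (mean linear power), `se` (standard error of
#'   the per-ensemble/ROI powers), and `detail` (tibble: `ensemble`, `roi`,
#'   `frame_index`, `power`, `gap_db`).
#' @export
process_recording <- function(rec, rois = NULL, register = TRUE,
                              n_removed = 1, frame_indices = 1) {
  stopifnot(inherits(rec, "doppler_recording"))
  rois <- rois %||% rec$roi_set
  if (length(rois) == 0) rois <- list(roi_center(rec$geom))
  rows <- list()
  for (fi in frame_indices) {
    ens_list <- assemble_ensembles(rec, frame_index = fi)
    for (k in seq_along(ens_list)) {
      ens <- ens_list[[k]]
      if (register) {
        ens <- apply_registration(ens, estimate_displacements(ens))
      }
      for (r in seq_along(rois)) {
        flt <- svd_filter(casorati(ens, rois[[r]]), n_removed = n_removed)
        rows[[length(rows) + 1]] <- tibble(
          ensemble = k, roi = r, frame_index = fi,
          power = pdus_power(flt$filtered),
          gap_db = subspace_gap(flt$spectrum)
        )
      }
    }
  }
  detail <- bind_rows(rows)
  list(power = mean(detail$power),
       se = sd(detail$power) / sqrt(nrow(detail)),
       detail = detail)
}

#' Normalize raw powers to the pre-ligation baseline
#'
#' Converts per-time-point linear powers into a baseline-normalized profile
#' in dB: `10 log10(power / power_pre)`. The baseline point is 0 dB by
#' construction, so any constant processing offset (for instance a PSD
#' floor change introduced by registration) cancels.
#'
#' @param df Tibble with columns `time_label` and `power` (linear, already
#'   averaged within the mouse).
#' @param baseline_label Label of the baseline row (default `"pre"`).
#' @return The input tibble with an added `pdus_db` column.
#' @export
#' @examples
#' normalize_profile(tibble::tibble(
#'   time_label = c("pre", "1 d"), power = c(2, 1)))
normalize_profile <- function(df, baseline_label = "pre") {
  if (!all(c("time_label", "power") %in% names(df))) {
    abort("`df` needs columns `time_label` and `power`.")
  }
  base <- df$power[as.character(df$time_label) == baseline_label]
  if (length(base) != 1) abort("Exactly one baseline row is required.")
  if (!is.finite(base) || base <= 0) {
    abort("Baseline power must be positive.")
  }
  df %>% mutate(pdus_db = 10 * log10(.data$power / base))
}

#' Group-average perfusion curves across mice
#'
#' Within-mouse averaging happens on linear power before dB conversion;
#' across mice, statistics are computed on the dB values (the scale on
#' which group curves are reported). Sample size may vary by time point.
#'
#' @param profiles Tibble with columns `mouse_id`, `time_label`, `pdus_db`
#'   and a grouping column.
#' @param group Name of the grouping column (default `"group"`).
#' @return Tibble with `time_label`, group, `mean_db`, `se_db` (`NA` for
#'   n = 1), `n`.
#' @export
cohort_average <- function(profiles, group = "group") {
  if (nrow(profiles) == 0) abort("Empty profile table.")
  if (!group %in% names(profiles)) {
    abort(sprintf("Column `%s` not found.", group))
  }
  profiles %>%
    group_by(.data[[group]], .data$time_label) %>%
    summarise(mean_db = mean(.data$pdus_db),
              se_db = if (dplyr::n() > 1) {
                sd(.data$pdus_db) / sqrt(dplyr::n())
              } else {
                NA_real_
              },
              n = dplyr::n(), .groups = "drop")
}

#' Per-pixel power-Doppler image
#'
#' Filters the full-frame Casorati matrix and maps each pixel's slow-time
#' mean power to dB with a configurable dynamic range; a display aid, not
#' part of the quantitative pipeline.
#'
#' @param ens An `ensemble_stack`.
#' @param n_removed Singular components removed.
#' @param dynamic_range_db Values below `max - dynamic_range_db` are
#'   clipped.
#' @return Matrix of dB values with the frame's spatial dimensions.
#' @export
pdus_image <- function(ens, n_removed = 1, dynamic_range_db = 40) {
  M <- casorati(ens)
  flt <- svd_filter(M, n_removed = n_removed)$filtered
  pw <- rowMeans(flt^2)
  img_db <- 10 * log10(pmax(pw, .Machine$double.xmin))
  img_db <- pmax(img_db, max(img_db) - dynamic_range_db)
  matrix(img_db, attr(M, "roi_dim")[1], attr(M, "roi_dim")[2])
}
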