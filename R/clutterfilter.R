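#' Casorati (space x slow-time) matrix of an ensemble
#'
#' Column t holds the vectorized ROI samples of frame t. The mapping is
#' lossless: `uncasorati()` restores the ROI sample block exactly.
#'
#' @param ens An `ensemble_stack` with at least 2 frames.
#' @param roi Optional [roi_rect()]; default uses the whole frame.
#' @return A numeric matrix (space x time) with attributes `roi_dim`
#'   (ROI rows/columns) and `rate_hz` (slow-time rate).
#' @export
#' @examples
#' ens <- simulate_ensemble(ground_truth_spec(seed = 5), n_frames = 4)
#' M <- casorati(ens, roi_center(ens$geom))
#' dim(M)
casorati <- function(ens, roi = NULL) {
  stopifnot(inherits(ens, "ensemble_stack"))
  if (ens$n_frames < 2) abort("Need at least 2 frames.")
  idx <- if (is.null(roi)) {
    list(axial = seq_len(dim(ens$frames)[1]),
         lateral = seq_len(dim(ens$frames)[2]))
  } else {
    roi_indices(roi, ens$geom)
  }
  block <- ens$frames[idx$axial, idx$lateral, , drop = FALSE]
  M <- matrix(block, length(idx$axial) * length(idx$lateral), ens$n_frames)
  attr(M, "roi_dim") <- c(length(idx$axial), length(idx$lateral))
  attr(M, "rate_hz") <- ens$slow_time_rate_hz
  M
}

#' @rdname casorati
#' @param M A Casorati matrix from [casorati()].
#' @export
uncasorati <- function(M) {
  rd <- attr(M, "roi_dim")
  if (is.null(rd)) abort("Matrix does not carry ROI dimensions.")
  array(M, c(rd[1], rd[2], ncol(M)))
}

#' SVD clutter filter
#'
#' Removes the leading `n_removed` singular components of the space-time
#' matrix -- the subspace dominated by strong, slowly-moving tissue echoes
#' -- leaving the blood-echo and noise subspaces. With motionless tissue,
#' removing only the first singular component minimizes the clutter power,
#' so `n_removed = 1` is the default and is held fixed across time points.
#'
#' @param M Space x time matrix (finite entries).
#' @param n_removed Number of leading singular components removed;
#'   `0 <= n_removed < min(dim(M))`.
#' @return A list with `filtered` (matrix, same attributes as `M`) and
#'   `spectrum` (a `singular_spectrum` tibble: `rank`, `value`,
#'   `normalized`, the energy fraction `value^2 / sum(value^2)`).
#' @export
#' @examples
#' M <- matrix(rnorm(80), 20, 4)
#' f <- svd_filter(M)
#' f$spectrum
svd_filter <- function(M, n_removed = 1) {
  if (length(M) == 0) abort("Empty matrix.")
  if (!all(is.finite(M))) abort("Matrix entries must be finite.")
  k <- min(dim(M))
  if (n_removed < 0 || n_removed >= k) {
    abort(sprintf("`n_removed` must be in [0, %d).", k))
  }
  s <- svd(M)
  filtered <- M
  if (n_removed > 0) {
    lead <- s$u[, seq_len(n_removed), drop = FALSE] %*%
      (s$d[seq_len(n_removed)] *
         t(s$v[, seq_len(n_removed), drop = FALSE]))
    filtered <- M - lead
  }
  attr(filtered, "roi_dim") <- attr(M, "roi_dim")
  attr(filtered, "rate_hz") <- attr(M, "rate_hz")
  spectrum <- structure(
    tibble(rank = seq_along(s$d), value = s$d,
           normalized = s$d^2 / sum(s$d^2)),
    class = c("singular_spectrum", "tbl_df", "tbl", "data.frame")
  )
  list(filtered = filtered, spectrum = spectrum)
}

#' Gap between the first two singular values
#'
#' `20 log10(s1 / s2)` in dB. A larger gap means less overlap between the
#' clutter and blood subspaces, hence more reliable clutter filtering;
#' spatial registration typically widens it.
#'
#' @param ss A `singular_spectrum` from [svd_filter()], or a numeric vector
#'   of singular values.
#' @return Gap in dB (`Inf` if the second singular value is 0).
#' @export
subspace_gap <- function(ss) {
  vals <- if (is.data.frame(ss)) ss$value else ss
  if (length(vals) < 2) abort("Need at least 2 singular values.")
  if (vals[2] == 0) return(Inf)
  20 * log10(vals[1] / vals[2])
}
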