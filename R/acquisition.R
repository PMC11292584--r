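#' Convert a baseband IQ frame to an RF frame
#'
#' Reconstructs real-valued RF from complex in-phase/quadrature samples:
#' each line is spectrally zero-padded (FFT resampling) from the IQ sample
#' rate to the RF axial sampling rate, remodulated by the demodulation
#' carrier, and the real part is taken. The target rate must be at least 4x
#' the carrier so the RF oscillation is represented; the conversion is exact
#' for signals band-limited within the IQ Nyquist band (`rf_to_iq()`
#' inverts it to numerical precision for such signals).
#'
#' @param iq Complex matrix, IQ samples x lines.
#' @param geom An [acquisition_geometry()]; `axial_sample_freq_hz` is the
#'   target RF rate.
#' @param demod_freq_hz Demodulation (carrier) frequency, Hz. Required; no
#'   default is assumed.
#' @param iq_sample_freq_hz IQ axial sampling rate, Hz. The RF rate must be
#'   an integer multiple of it.
#' @return Real matrix with `L = rf_rate / iq_rate` times as many rows.
#' @export
#' @examples
#' geom <- acquisition_geometry(n_axial = 64)
#' iq <- matrix(complex(real = 1, imaginary = 0), 16, 2)
#' rf <- iq_to_rf(iq, geom, demod_freq_hz = 24e6, iq_sample_freq_hz = 24e6)
iq_to_rf <- function(iq, geom, demod_freq_hz, iq_sample_freq_hz) {
  if (missing(demod_freq_hz) || is.null(demod_freq_hz)) {
    abort("`demod_freq_hz` is required; refusing to assume a carrier.")
  }
  if (missing(iq_sample_freq_hz) || is.null(iq_sample_freq_hz)) {
    abort("`iq_sample_freq_hz` is required.")
  }
  fs_rf <- geom$axial_sample_freq_hz
  if (fs_rf < 4 * demod_freq_hz) {
    abort("RF sampling rate must be >= 4x the demodulation frequency.")
  }
  L <- fs_rf / iq_sample_freq_hz
  if (abs(L - round(L)) > 1e-9 || L < 1) {
    abort("RF rate must be an integer multiple of the IQ rate.")
  }
  L <- round(L)
  n <- nrow(iq)
  up <- apply(iq, 2, fft_upsample, L = L)
  up <- matrix(up, n * L, ncol(iq))
  tt <- (seq_len(n * L) - 1) / fs_rf
  carrier <- exp(2i * pi * demod_freq_hz * tt)
  Re(up * carrier)
}

#' @rdname iq_to_rf
#' @param rf Real RF matrix at the geometry's axial sampling rate.
#' @export
rf_to_iq <- function(rf, geom, demod_freq_hz, iq_sample_freq_hz) {
  if (missing(demod_freq_hz) || is.null(demod_freq_hz)) {
    abort("`demod_freq_hz` is required.")
  }
  fs_rf <- geom$axial_sample_freq_hz
  L <- round(fs_rf / iq_sample_freq_hz)
  n <- nrow(rf)
  tt <- (seq_len(n) - 1) / fs_rf
  carrier <- exp(-2i * pi * demod_freq_hz * tt)
  w <- rf * 2 * carrier
  out <- apply(w, 2, fft_downsample, L = L)
  matrix(out, n / L, ncol(rf))
}

# FFT zero-pad upsampling of a (complex) vector by integer factor L.
fft_upsample <- function(x, L) {
  n <- length(x)
  if (L == 1) return(x)
  X <- fft(x)
  half <- floor(n / 2)
  Y <- complex(n * L)
  Y[seq_len(half)] <- X[seq_len(half)]
  Y[(n * L - (n - half) + 1):(n * L)] <- X[(half + 1):n]
  L * fft(Y, inverse = TRUE) / (n * L)
}

# Inverse: brick-wall lowpass to the target band, then spectral truncation.
fft_downsample <- function(x, L) {
  n <- length(x)
  if (L == 1) return(x)
  m <- n / L
  X <- fft(x)
  half <- floor(m / 2)
  Y <- complex(m)
  Y[seq_len(half)] <- X[seq_len(half)]
  Y[(half + 1):m] <- X[(n - (m - half) + 1):n]
  fft(Y, inverse = TRUE) / n
}

#' Doppler recording container
#'
#' Holds the Doppler frames of one 12-s acquisition together with the
#' geometry and ROI set. Each Doppler frame is a list of echo frames (RF or
#' IQ matrices); recordings built from simulated data typically carry one
#' echo frame per Doppler frame (the first of the color-flow group).
#'
#' @param doppler_frames List of Doppler frames; each element is a matrix
#'   (single echo frame) or a list of matrices.
#' @param geom An [acquisition_geometry()].
#' @param is_rf `TRUE` if frames are real RF; `FALSE` for complex IQ (in
#'   which case `demod_freq_hz` and `iq_sample_freq_hz` must be given).
#' @param demod_freq_hz,iq_sample_freq_hz IQ metadata; see [iq_to_rf()].
#' @param roi_set List of [roi_rect()] regions (up to 3 of ~1 mm^2 each).
#' @param id Recording identifier carried into provenance.
#' @return An object of class `doppler_recording`.
#' @export
doppler_recording <- function(doppler_frames, geom = acquisition_geometry(),
                              is_rf = TRUE, demod_freq_hz = NULL,
                              iq_sample_freq_hz = NULL, roi_set = list(),
                              id = "rec") {
  if (length(doppler_frames) == 0) abort("No Doppler frames supplied.")
  doppler_frames <- lapply(doppler_frames, function(f) {
    if (is.matrix(f)) list(f) else f
  })
  if (!is_rf && (is.null(demod_freq_hz) || is.null(iq_sample_freq_hz))) {
    abort("IQ recordings require `demod_freq_hz` and `iq_sample_freq_hz`.")
  }
  for (r in roi_set) roi_indices(r, geom)  # validates placement
  structure(
    list(doppler_frames = doppler_frames, geom = geom, is_rf = is_rf,
         demod_freq_hz = demod_freq_hz,
         iq_sample_freq_hz = iq_sample_freq_hz,
         roi_set = roi_set, id = id),
    class = "doppler_recording"
  )
}

#' Partition a Doppler recording into slow-time ensembles
#'
#' Selects one echo frame from each Doppler frame (the first, by default)
#' and partitions the resulting slow-time sequence into consecutive groups
#' of `ensemble_length` frames: a full 96-frame recording yields 6 ensembles
#' of 16 frames spanning 2 s each. IQ frames are converted to RF first.
#' Short recordings yield as many complete ensembles as possible (with a
#' warning); a recording too short for a single ensemble is an error.
#'
#' @param rec A [doppler_recording()].
#' @param ensemble_length Frames per ensemble (default 16).
#' @param frame_index Which echo frame within each Doppler frame to select.
#'   Power-estimate precision can be improved downstream by averaging
#'   estimates over several `frame_index` selections.
#' @return A list of `ensemble_stack` objects.
#' @export
#' @examples
#' geom <- acquisition_geometry(n_axial = 32, n_lines = 8)
#' frames <- replicate(16, matrix(rnorm(32 * 8), 32, 8), simplify = FALSE)
#' ens <- assemble_ensembles(doppler_recording(frames, geom))
#' length(ens)
assemble_ensembles <- function(rec, ensemble_length = 16, frame_index = 1) {
  stopifnot(inherits(rec, "doppler_recording"))
  sel <- lapply(rec$doppler_frames, function(df) {
    if (frame_index > length(df)) {
      abort("`frame_index` exceeds the echo frames per Doppler frame.")
    }
    df[[frame_index]]
  })
  if (!rec$is_rf) {
    sel <- lapply(sel, iq_to_rf, geom = rec$geom,
                  demod_freq_hz = rec$demod_freq_hz,
                  iq_sample_freq_hz = rec$iq_sample_freq_hz)
  }
  n <- length(sel)
  n_complete <- floor(n / ensemble_length)
  if (n_complete == 0) {
    abort(sprintf("Recording has %d Doppler frames; need >= %d for one ensemble.",
                  n, ensemble_length))
  }
  if (n %% ensemble_length != 0) {
    warn(sprintf("Recording length %d is not a multiple of %d; using %d ensemble(s), dropping %d frame(s).",
                 n, ensemble_length, n_complete, n %% ensemble_length))
  }
  lapply(seq_len(n_complete), function(k) {
    idx <- ((k - 1) * ensemble_length + 1):(k * ensemble_length)
    frames <- simplify2array(sel[idx])
    new_ensemble_stack(frames, rec$geom,
                       provenance = list(recording_id = rec$id,
                                         ensemble_index = k,
                                         frame_index = frame_index))
  })
}

#' Serialize and restore Doppler recordings
#'
#' Recordings and ensembles are stored as single-file R serializations
#' (`saveRDS`). Tabular results (profiles, spectra, traces) are ordinary
#' tibbles and are written as CSV with `write.csv`/`readr`.
#'
#' @param rec A [doppler_recording()] or `ensemble_stack`.
#' @param path Destination file.
#' @return `read_recording()` returns the restored object.
#' @export
write_recording <- function(rec, path) {
  saveRDS(rec, path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) readRDS(path)
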