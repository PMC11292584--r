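#' Rectangular region of interest in physical coordinates
#'
#' ROIs are specified by their center (axial depth, lateral position, in mm
#' from the top-left frame corner) and size. The default is the ~1 mm^2
#' analysis region used for spatially averaged power estimates.
#'
#' @param axial_mm,lateral_mm Center of the region, mm.
#' @param height_mm,width_mm Axial and lateral extent, mm.
#' @return An object of class `pdus_roi`.
#' @export
#' @examples
#' roi_rect(1.0, 1.2)
roi_rect <- function(axial_mm, lateral_mm, height_mm = 1, width_mm = 1) {
  if (height_mm <= 0 || width_mm <= 0) abort("ROI size must be positive.")
  structure(list(axial_mm = axial_mm, lateral_mm = lateral_mm,
                 height_mm = height_mm, width_mm = width_mm),
            class = "pdus_roi")
}

#' Centered default ROI for a geometry
#'
#' @param geom An [acquisition_geometry()].
#' @param height_mm,width_mm Region size, mm.
#' @return A [roi_rect()] centered in the imaged field.
#' @export
roi_center <- function(geom, height_mm = 1, width_mm = 1) {
  roi_rect(geom$axial_extent_mm / 2, geom$lateral_extent_mm / 2,
           height_mm, width_mm)
}

# Sample/line index sets covered by an ROI; errors if outside the field.
roi_indices <- function(roi, geom) {
  stopifnot(inherits(roi, "pdus_roi"))
  z0 <- roi$axial_mm - roi$height_mm / 2
  z1 <- roi$axial_mm + roi$height_mm / 2
  x0 <- roi$lateral_mm - roi$width_mm / 2
  x1 <- roi$lateral_mm + roi$width_mm / 2
  if (z0 < 0 || x0 < 0 || z1 > geom$axial_extent_mm ||
      x1 > geom$lateral_extent_mm) {
    abort("ROI extends outside the imaged field.")
  }
  ax <- which((seq_len(geom$n_axial) - 1) * geom$axial_spacing_mm >= z0 &
                (seq_len(geom$n_axial) - 1) * geom$axial_spacing_mm <= z1)
  lat <- which((seq_len(geom$n_lines) - 1) * geom$line_pitch_mm >= x0 &
                 (seq_len(geom$n_lines) - 1) * geom$line_pitch_mm <= x1)
  if (length(ax) == 0 || length(lat) == 0) abort("ROI contains no samples.")
  list(axial = ax, lateral = lat)
}

#' Read a set of ROIs from a YAML configuration
#'
#' The file holds a list of regions, each with fields `axial_mm`,
#' `lateral_mm`, `height_mm`, `width_mm`.
#'
#' @param path Path to a YAML file.
#' @return A list of [roi_rect()] objects.
#' @export
read_roi_yaml <- function(path) {
  spec <- yaml::read_yaml(path)
  regions <- if (!is.null(spec$regions)) spec$regions else spec
  lapply(regions, function(r) {
    roi_rect(r$axial_mm, r$lateral_mm,
             r$height_mm %||% 1, r$width_mm %||% 1)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
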