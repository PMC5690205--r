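#' Lever-arm geometry of the frame-mounted device
#'
#' The device couples an abdominal central piece (longitudinal coordinate
#' `Z0`) to bars that pivot at their contact point with the frame sidewall
#' pieces (`Zp`). A vertical displacement `A0` of the central piece produces
#' a proportionally smaller vertical displacement of the bar wires at any
#' axial slice plane `Z` between the pivot and the central piece:
#' \deqn{A_z = A_0 (Z - Z_p)/(Z_0 - Z_p)}
#' and inversely \eqn{A_0 = A_z (Z_0 - Z_p)/(Z - Z_p)}.
#'
#' Rod rotation about the pivot is treated as pure vertical translation at
#' each slice (small-angle approximation): for displacements up to 10 mm over
#' lever arms of hundreds of mm the angular correction is well below 0.1 mm.
#'
#' All longitudinal coordinates must be in one consistent system (DICOM or
#' stereotactic); the device is aligned so the two differ only by origin.
#'
#' @param z0_mm longitudinal coordinate of the central piece, mm.
#' @param zp_mm longitudinal coordinate of the bar/sidewall pivot point, mm.
#' @param bar_length_mm physical bar length, mm (default 470).
#' @return an object of class `frame_geometry`.
#' @examples
#' g <- frame_geometry(z0_mm = 580, zp_mm = 180)
#' project_amplitude_to_slice(10, 380, g)   # lever ratio 0.5 -> 5 mm
#' scale_amplitude_to_central(5, 380, g)    # back to 10 mm
#' @export
frame_geometry <- function(z0_mm = 580, zp_mm = 180, bar_length_mm = 470) {
  stopifnot(is.numeric(z0_mm), is.numeric(zp_mm), is.numeric(bar_length_mm),
            is.finite(z0_mm), is.finite(zp_mm), is.finite(bar_length_mm))
  if (z0_mm == zp_mm) stop("Z0 must differ from Zp")
  if (abs(z0_mm - zp_mm) > bar_length_mm) {
    stop("|Z0 - Zp| exceeds the bar length")
  }
  structure(list(z0 = z0_mm, zp = zp_mm, bar_length = bar_length_mm),
            class = "frame_geometry")
}

#' @export
print.frame_geometry <- function(x, ...) {
  cat(sprintf("<frame_geometry> Z0=%.1f mm Zp=%.1f mm bar=%.0f mm (lever span %.1f mm)\n",
              x$z0, x$zp, x$bar_length, x$z0 - x$zp))
  invisible(x)
}

check_slice_z <- function(z, g) {
  lo <- min(g$zp, g$z0); hi <- max(g$zp, g$z0)
  # slice must lie strictly beyond the pivot and not beyond the central piece
  if (any(z == g$zp)) {
    stop("slice Z coincides with the pivot Zp: wires do not move there")
  }
  if (any(z <= lo) || any(z > hi)) {
    stop("slice Z must lie in (Zp, Z0]: no extrapolation beyond the central piece")
  }
  invisible(TRUE)
}

#' Lever ratio at a slice plane
#'
#' `(Z - Zp)/(Z0 - Zp)`, the fraction of the central-piece displacement seen
#' by the wires at slice `Z`.
#'
#' @param z slice longitudinal coordinate, mm.
#' @param g a [frame_geometry()].
#' @return numeric in (0, 1].
#' @export
lever_ratio <- function(z, g) {
  stopifnot(inherits(g, "frame_geometry"))
  check_slice_z(z, g)
  (z - g$zp) / (g$z0 - g$zp)
}

#' Project a central-piece amplitude to a slice plane
#'
#' Forward direction of the lever-arm relation (used by the simulator):
#' `Az = A0 (Z - Zp)/(Z0 - Zp)`.
#'
#' @param a0 central-piece displacement or amplitude, mm (>= 0 for an
#'   amplitude; any sign for a pointwise displacement).
#' @param z slice longitudinal coordinate, mm; must lie in `(Zp, Z0]`.
#' @param g a [frame_geometry()].
#' @return wire displacement at the slice, mm.
#' @export
project_amplitude_to_slice <- function(a0, z, g) {
  a0 * lever_ratio(z, g)
}

#' Scale a wire amplitude at a slice up to the central piece
#'
#' Inverse direction of the lever-arm relation (used on measurements):
#' `A0 = Az (Z0 - Zp)/(Z - Zp)`. Exact inverse of
#' [project_amplitude_to_slice()].
#'
#' By linearity the relation applies equally to a single fitted amplitude or
#' pointwise to a whole displacement trace; this package scales the pointwise
#' trace and fits afterwards (the results are identical either way).
#'
#' @inheritParams project_amplitude_to_slice
#' @param az wire displacement measured at the slice, mm.
#' @return central-piece displacement, mm.
#' @export
scale_amplitude_to_central <- function(az, z, g) {
  az / lever_ratio(z, g)
}
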