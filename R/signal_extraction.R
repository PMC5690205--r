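# From wire tracks to the central-piece respiratory trace.
#
# Per frame, the wire amplitude at the slice is the mean of each wire's
# distance below its own exhale extreme (the frame where it sits closest to
# the table, i.e. maximal image Y):
#     Az(t) = ((y1max - y1(t)) + (y2max - y2(t))) / 2
# in pixels, converted to mm by the pixel spacing. Averaging the two wires
# is the robust amplitude indicator for the slice. The central-piece
# displacement then follows from the lever-arm relation
#     A0(t) = Az(t) (Z0 - Zp)/(Z - Zp),
# applied pointwise (the relation is linear, so scaling before or after
# sine fitting is equivalent).

#' Per-frame wire amplitude series at a slice
#'
#' Each wire is referenced to its own exhale extreme over the observed cine
#' sequence (maximum image Y = closest to the table). The series is >= 0 and
#' reaches 0 at the frame(s) defining the maxima. With a 16 s cine covering
#' at least two full 6 s cycles the observed maximum captures true exhale;
#' shorter captures are flagged with a warning.
#'
#' @param track a `wire_track` from [track_wires()] with >= 2 valid entries.
#' @param pixel_spacing mm per pixel; defaults to the track's recorded
#'   spacing.
#' @param min_cycles_warn warn when the capture is shorter than this many
#'   nominal breathing cycles (default 2, assuming ~6 s cycles).
#' @return data.frame (class `az_series`) with `time_s`, `az_mm`, one row
#'   per valid track entry.
#' @export
compute_az_series <- function(track, pixel_spacing = NULL,
                              min_cycles_warn = 2) {
  stopifnot(inherits(track, "wire_track"))
  if (is.null(pixel_spacing)) pixel_spacing <- attr(track, "pixel_spacing")
  stopifnot(is.numeric(pixel_spacing), pixel_spacing > 0)
  v <- track[track$valid, , drop = FALSE]
  if (nrow(v) < 2L) stop("track has fewer than 2 valid entries")
  span <- diff(range(v$time_s))
  if (span < min_cycles_warn * 6) {
    warning("capture spans fewer than ", min_cycles_warn,
            " nominal breathing cycles; exhale reference may be unreliable")
  }
  y1max <- max(v$y_left_px)
  y2max <- max(v$y_right_px)
  az_px <- ((y1max - v$y_left_px) + (y2max - v$y_right_px)) / 2
  out <- data.frame(time_s = v$time_s, az_mm = az_px * pixel_spacing)
  attr(out, "pixel_spacing") <- pixel_spacing
  attr(out, "slice_id") <- attr(track, "slice_id")
  class(out) <- c("az_series", "data.frame")
  out
}

#' Scale a wire amplitude series to the central piece
#'
#' Applies the lever-arm relation pointwise, yielding the respiratory trace:
#' the vertical displacement of the abdominal central piece above its exhale
#' baseline, in mm, at each acquisition time.
#'
#' @param az an `az_series` from [compute_az_series()].
#' @param z slice longitudinal coordinate, mm; must lie in `(Zp, Z0]`.
#' @param g a [frame_geometry()].
#' @return data.frame (class `respiratory_trace`) with `time_s`,
#'   `displacement_mm`; attributes `slice_z`, `provenance`.
#' @export
build_respiratory_trace <- function(az, z, g) {
  stopifnot(inherits(az, "az_series"), inherits(g, "frame_geometry"))
  disp <- scale_amplitude_to_central(az$az_mm, z, g)
  out <- data.frame(time_s = az$time_s, displacement_mm = disp)
  attr(out, "slice_z") <- z
  attr(out, "provenance") <- list(
    pixel_spacing = attr(az, "pixel_spacing"),
    geometry = unclass(g),
    source_slices = attr(az, "slice_id")
  )
  class(out) <- c("respiratory_trace", "data.frame")
  out
}

#' Average respiratory traces from multiple slices
#'
#' Pointwise mean of traces sharing one time base (slices of the same slab
#' are acquired simultaneously). Averaging independent slices reduces the
#' detection-noise variance of the trace.
#'
#' @param traces list of `respiratory_trace` objects.
#' @param time_tol maximum allowed timestamp difference between traces, s.
#' @return a `respiratory_trace`; provenance lists all contributing slices.
#' @export
average_traces <- function(traces, time_tol = 1e-6) {
  stopifnot(length(traces) >= 1L,
            all(vapply(traces, inherits, logical(1), "respiratory_trace")))
  t0 <- traces[[1]]$time_s
  for (tr in traces[-1]) {
    if (nrow(tr) != length(t0) || any(abs(tr$time_s - t0) > time_tol)) {
      stop("traces do not share a time base")
    }
  }
  disp <- rowMeans(vapply(traces, function(tr) tr$displacement_mm,
                          numeric(length(t0))))
  out <- data.frame(time_s = t0, displacement_mm = disp)
  attr(out, "slice_z") <- attr(traces[[1]], "slice_z")
  attr(out, "provenance") <- list(
    pixel_spacing = attr(traces[[1]], "provenance")$pixel_spacing,
    geometry = attr(traces[[1]], "provenance")$geometry,
    source_slices = unlist(lapply(traces, function(tr)
      attr(tr, "provenance")$source_slices))
  )
  class(out) <- c("respiratory_trace", "data.frame")
  out
}

#' Write a respiratory trace to CSV (with a JSON provenance block)
#'
#' @param trace a `respiratory_trace`.
#' @param path CSV output file; provenance goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(time_s = trace$time_s,
                   displacement_mm = trace$displacement_mm,
                   slice_z_mm = attr(trace, "slice_z") %||% NA)
  utils::write.csv(df, path, row.names = FALSE)
  prov <- attr(trace, "provenance")
  if (!is.null(prov)) {
    jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
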