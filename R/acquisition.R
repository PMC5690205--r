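#' Cine acquisition configuration
#'
#' Parameters of a cine-mode axial acquisition on a multi-slice scanner:
#' slabs of simultaneously acquired slices, each slab imaged repeatedly
#' (without table motion) for `cine_duration_s` at one frame every
#' `frame_interval_s`. Defaults emulate a 10-slice scanner protocol with
#' 8 x 3 mm cine slabs, 0.5 s exposure, 0.8 s inter-frame interval, 16 s
#' cine duration, 500 mm FOV and a 768 x 768 matrix (0.651 mm pixels).
#'
#' Each frame is an instantaneous sample of the motion at its nominal
#' timestamp; the finite exposure's motion blur can be enabled with
#' `blur_subsamples > 1`, which averages that many evenly spaced sub-samples
#' across the exposure window. Optional uniform timing jitter of half-width
#' `jitter_s` emulates an irregular inter-frame interval.
#'
#' @param n_slabs number of contiguous cine slabs acquired sequentially.
#' @param slices_per_slab simultaneous slices per slab.
#' @param slice_thickness_mm slice thickness, mm.
#' @param frame_interval_s nominal time between frames of one slab, s.
#' @param exposure_time_s tube-on time per frame, s.
#' @param cine_duration_s cine duration per slab, s.
#' @param fov_mm reconstruction field of view, mm.
#' @param matrix_px image matrix size (square), pixels.
#' @param noise_sd_hu standard deviation of additive Gaussian image noise, HU.
#' @param seed integer seed making a simulated study reproducible; `NULL`
#'   uses the current RNG state.
#' @param wire_x_mm lateral positions of the left and right wire
#'   cross-sections in image coordinates, mm from the left image edge.
#'   Default: 20% and 80% of the FOV.
#' @param wire_baseline_y_mm vertical wire position at zero displacement, mm
#'   from the top image edge (image Y increases toward the table).
#' @param wire_diameter_mm copper wire diameter, mm.
#' @param wire_hu wire intensity, HU. Copper saturates clinical HU scales;
#'   a fixed 3000 HU is used for reproducibility.
#' @param body render a soft-tissue body cross-section (40 HU, with
#'   -700 HU lung regions) on the -1000 HU background.
#' @param jitter_s half-width of uniform timing jitter per frame, s (0 = off).
#' @param blur_subsamples number of motion sub-samples averaged across the
#'   exposure window (1 = instantaneous sampling).
#' @param slab_gap_s idle time between consecutive slabs, s.
#' @return an object of class `acquisition_config`.
#' @examples
#' cfg <- acquisition_config()
#' cfg$pixel_spacing   # 500/768 ~ 0.651 mm
#' cfg$frames_per_slice
#' @export
acquisition_config <- function(n_slabs = 4,
                               slices_per_slab = 8,
                               slice_thickness_mm = 3,
                               frame_interval_s = 0.8,
                               exposure_time_s = 0.5,
                               cine_duration_s = 16,
                               fov_mm = 500,
                               matrix_px = 768,
                               noise_sd_hu = 20,
                               seed = NULL,
                               wire_x_mm = NULL,
                               wire_baseline_y_mm = NULL,
                               wire_diameter_mm = 2,
                               wire_hu = 3000,
                               body = TRUE,
                               jitter_s = 0,
                               blur_subsamples = 1,
                               slab_gap_s = 0) {
  stopifnot(n_slabs >= 1, slices_per_slab >= 1, slice_thickness_mm > 0,
            frame_interval_s > 0, cine_duration_s > 0,
            fov_mm > 0, matrix_px >= 16, noise_sd_hu >= 0,
            exposure_time_s >= 0, jitter_s >= 0, blur_subsamples >= 1,
            slab_gap_s >= 0)
  if (is.null(wire_x_mm)) wire_x_mm <- c(0.2, 0.8) * fov_mm
  if (is.null(wire_baseline_y_mm)) wire_baseline_y_mm <- 0.35 * fov_mm
  stopifnot(length(wire_x_mm) == 2L, wire_x_mm[1] < wire_x_mm[2])
  cfg <- list(
    n_slabs = as.integer(n_slabs),
    slices_per_slab = as.integer(slices_per_slab),
    slice_thickness = slice_thickness_mm,
    frame_interval = frame_interval_s,
    exposure_time = exposure_time_s,
    cine_duration = cine_duration_s,
    fov = fov_mm,
    matrix = as.integer(matrix_px),
    noise_sd = noise_sd_hu,
    seed = if (is.null(seed)) NULL else as.integer(seed),
    wire_x_mm = wire_x_mm,
    wire_baseline_y_mm = wire_baseline_y_mm,
    wire_diameter_mm = wire_diameter_mm,
    wire_hu = wire_hu,
    body = isTRUE(body),
    jitter_s = jitter_s,
    blur_subsamples = as.integer(blur_subsamples),
    slab_gap_s = slab_gap_s
  )
  cfg$pixel_spacing <- fov_mm / cfg$matrix
  # tiny epsilon so an exact multiple (16 s / 0.8 s) is not lost to
  # floating-point rounding
  cfg$frames_per_slice <- as.integer(floor(cine_duration_s / frame_interval_s + 1e-9))
  stopifnot(cfg$frames_per_slice >= 1)
  class(cfg) <- "acquisition_config"
  cfg
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf(
    "<acquisition_config> %d slab(s) x %d slices x %d frames; %.3g mm px; noise %.3g HU\n",
    x$n_slabs, x$slices_per_slab, x$frames_per_slice, x$pixel_spacing, x$noise_sd))
  invisible(x)
}

# Evaluate code with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
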