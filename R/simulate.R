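#' Simulate a cine-CT study of the moving-wire device
#'
#' Renders a full cine study with known ground truth. For each slice plane
#' `Z` and frame time `t`, the wire vertical displacement is the waveform
#' displacement projected to the slice through the lever-arm geometry
#' ([project_amplitude_to_slice()]), converted to image coordinates where Y
#' increases toward the table — so exhale (minimum anterior displacement)
#' corresponds to maximal image Y.
#'
#' Slabs are acquired sequentially, each for `cfg$cine_duration` (plus
#' `cfg$slab_gap_s` between slabs); the phantom keeps moving continuously, so
#' timestamps carry across slabs. Consecutive groups of
#' `cfg$slices_per_slab` entries of `slice_zs` form one slab and share
#' timestamps.
#'
#' @param waveform ground-truth [motion_waveform()] of the central piece.
#' @param g a [frame_geometry()].
#' @param cfg an [acquisition_config()]; if `cfg$seed` is set the study is
#'   bit-reproducible.
#' @param slice_zs longitudinal coordinates of the slices to simulate, mm;
#'   all must lie in `(Zp, Z0]`.
#' @param target optional target description:
#'   `list(x_mm, y_mm, z_mm, radius_mm, hu, waveform_y, waveform_z)` — a
#'   sphere centred at `(x_mm, y_mm, z_mm)` whose in-plane cross-section is
#'   rendered per frame; `waveform_y` (anterior-posterior) and `waveform_z`
#'   (longitudinal) are independent [motion_waveform()]s. The target is a
#'   demonstration payload for phase sorting; the signal pipeline never
#'   uses it.
#' @return an object of class `cine_study`: list with `frames` (each frame a
#'   list of `slab`, `slice`, `z`, `time`, `spacing`, `pixels`, plus the
#'   true sub-pixel wire centres under `truth`), `geometry`, `config`,
#'   `ground_truth`.
#' @examples
#' cfg <- acquisition_config(matrix_px = 160, fov_mm = 104, n_slabs = 1,
#'                           slices_per_slab = 1, noise_sd_hu = 0, seed = 1)
#' g <- frame_geometry()
#' w <- motion_waveform("sine", A = 10, T = 6)
#' st <- simulate_cine_study(w, g, cfg, slice_zs = 380)
#' length(st$frames)
#' @export
simulate_cine_study <- function(waveform, g, cfg, slice_zs, target = NULL) {
  stopifnot(inherits(waveform, "motion_waveform"),
            inherits(g, "frame_geometry"),
            inherits(cfg, "acquisition_config"))
  if (length(slice_zs) == 0L) stop("slice_zs must be non-empty")
  check_slice_z(slice_zs, g)

  with_local_seed(cfg$seed, {
    base <- make_base_image(cfg)
    nf <- cfg$frames_per_slice
    slab_of <- (seq_along(slice_zs) - 1L) %/% cfg$slices_per_slab + 1L
    frames <- vector("list", length(slice_zs) * nf)
    k <- 0L
    for (si in seq_along(slice_zs)) {
      z <- slice_zs[si]
      ratio <- lever_ratio(z, g)
      slab <- slab_of[si]
      slab_start <- (slab - 1L) * (cfg$cine_duration + cfg$slab_gap_s)
      t_nom <- slab_start + (seq_len(nf) - 1L) * cfg$frame_interval
      if (cfg$jitter_s > 0) {
        t_nom <- t_nom + stats::runif(nf, -cfg$jitter_s, cfg$jitter_s)
        t_nom <- sort(t_nom)
      }
      for (fi in seq_len(nf)) {
        t <- t_nom[fi]
        d <- if (cfg$blur_subsamples > 1L) {
          # average the displacement over the exposure window
          ts <- t + (seq_len(cfg$blur_subsamples) - 0.5) /
            cfg$blur_subsamples * cfg$exposure_time
          mean(evaluate_waveform(waveform, ts))
        } else {
          evaluate_waveform(waveform, t)
        }
        y_mm <- cfg$wire_baseline_y_mm - d * ratio      # anterior = up
        wy <- c(y_mm, y_mm)
        tgt <- target_cross_section(target, z, t)
        px <- render_frame(cfg, wy, noise = TRUE, base = base, target = tgt)
        k <- k + 1L
        frames[[k]] <- list(
          slab = slab, slice = si, z = z, time = t,
          spacing = cfg$pixel_spacing, pixels = px,
          truth = list(
            x_px = mm_to_px(cfg$wire_x_mm, cfg$pixel_spacing),
            y_px = mm_to_px(wy, cfg$pixel_spacing),
            displacement_mm = d
          )
        )
      }
    }
    structure(list(frames = frames, geometry = g, config = cfg,
                   ground_truth = waveform, target = target),
              class = "cine_study")
  })
}

# In-plane cross-section of a moving sphere at slice z and time t.
target_cross_section <- function(target, z, t) {
  if (is.null(target)) return(NULL)
  zc <- target$z_mm
  if (!is.null(target$waveform_z)) {
    zc <- zc + evaluate_waveform(target$waveform_z, t)
  }
  dz <- z - zc
  if (abs(dz) >= target$radius_mm) return(NULL)
  y <- target$y_mm
  if (!is.null(target$waveform_y)) {
    y <- y - evaluate_waveform(target$waveform_y, t)   # anterior = up
  }
  list(x_mm = target$x_mm, y_mm = y,
       radius_mm = sqrt(target$radius_mm^2 - dz^2),
       hu = target$hu %||% 50)
}

#' @export
print.cine_study <- function(x, ...) {
  zs <- unique(vapply(x$frames, `[[`, numeric(1), "z"))
  cat(sprintf("<cine_study> %d frames, %d slice(s), matrix %dx%d, %.3g mm px\n",
              length(x$frames), length(zs), x$config$matrix, x$config$matrix,
              x$config$pixel_spacing))
  invisible(x)
}

#' Extract the frames of one slice from a study
#'
#' Cine frames of a single slice position, ordered by acquisition time —
#' the unit the tracking and signal-extraction steps operate on.
#'
#' @param study a `cine_study`.
#' @param slice slice index (position in the `slice_zs` used at simulation,
#'   or as read from file metadata).
#' @return list of frames ordered by time.
#' @export
slice_frames <- function(study, slice) {
  fr <- Filter(function(f) f$slice == slice, study$frames)
  if (length(fr) == 0L) stop("no frames for slice ", slice)
  fr[order(vapply(fr, `[[`, numeric(1), "time"))]
}
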