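#' Dynamic-phantom study presets
#'
#' The motion matrix of the reference phantom experiments: surrogate
#' (central-piece) waveform, internal target motion and target diameter for
#' each study. Cycle time is 6 s throughout. Studies acquired helically
#' (no cine) carry `acquisition = "helicoidal"` and cannot be simulated as
#' cine studies.
#'
#' @return data.frame with columns `id`, `acquisition`, `motion`,
#'   `surrogate_A_mm`, `target_long_A_mm`, `target_ap_A_mm`,
#'   `target_ll_A_mm`, `target_diameter_cm`, `n_slabs`.
#' @export
cirs_presets <- function() {
  data.frame(
    id = sprintf("CIRS%02d", 1:12),
    acquisition = c("helicoidal", "helicoidal", "cine", "cine", "cine",
                    "helicoidal", "helicoidal", "cine", "cine", "cine",
                    "cine", "cine"),
    motion = c("none", "sine", "sine", "sine", "sharkfin", "none", "sine",
               "sine", "sharkfin", "sine", "sine", "sine"),
    surrogate_A_mm = c(0, 10, 10, 6, 10, 0, 10, 10, 10, 2, 1, 3),
    target_long_A_mm = c(0, 10, 10, 10, 10, 0, 10, 10, 10, 10, 10, 10),
    target_ap_A_mm = c(0, 5, 5, 5, 5, 0, 5, 5, 5, 5, 5, 5),
    target_ll_A_mm = c(0, 5, 5, 5, 5, 0, 5, 5, 5, 5, 5, 5),
    target_diameter_cm = c(3, 3, 3, 3, 3, 1, 1, 1, 1, 3, 3, 3),
    n_slabs = c(NA, NA, 4, 4, 4, NA, NA, 7, 4, 4, 4, 4)
  )
}

#' Build a simulation scenario from a study preset
#'
#' Returns the surrogate waveform, lever-arm geometry, acquisition
#' configuration and slice positions for one cine preset of
#' [cirs_presets()], plus an optional moving target sphere in the lung
#' region for end-to-end sorting demonstrations (the target never enters
#' the signal pipeline).
#'
#' @param id preset id, e.g. `"CIRS03"`.
#' @param seed simulation seed.
#' @param n_slices_per_slab,matrix_px,fov_mm acquisition overrides (the
#'   full 768 matrix and all 8 slices per slab are costly; demos may scale
#'   down).
#' @param with_target render the target sphere.
#' @param T_s cycle time, s.
#' @return list `(waveform, geometry, config, slice_zs, target)` ready for
#'   [simulate_cine_study()].
#' @export
cirs_scenario <- function(id, seed = 1, n_slices_per_slab = 8,
                          matrix_px = 768, fov_mm = 500,
                          with_target = FALSE, T_s = 6) {
  p <- cirs_presets()
  row <- p[p$id == id, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown preset id: ", id)
  if (row$acquisition != "cine") {
    stop(id, " is a helicoidal study; only cine presets can be simulated")
  }
  g <- frame_geometry()
  cfg <- acquisition_config(n_slabs = row$n_slabs,
                            slices_per_slab = n_slices_per_slab,
                            matrix_px = matrix_px, fov_mm = fov_mm,
                            seed = seed)
  w <- motion_waveform(row$motion, A = row$surrogate_A_mm, T = T_s)
  # slices of the most distal slab start 200 mm from the central piece and
  # step toward it by the slice thickness
  n_slices <- row$n_slabs * n_slices_per_slab
  slice_zs <- g$z0 - 200 + (seq_len(n_slices) - 1L) * cfg$slice_thickness
  slice_zs <- slice_zs[slice_zs <= g$z0]
  target <- NULL
  if (with_target) {
    target <- list(
      x_mm = 0.38 * fov_mm, y_mm = 0.60 * fov_mm,
      z_mm = mean(range(slice_zs)),
      radius_mm = row$target_diameter_cm * 10 / 2, hu = 50,
      waveform_y = motion_waveform(row$motion, A = row$target_ap_A_mm,
                                   T = T_s),
      waveform_z = motion_waveform(row$motion, A = row$target_long_A_mm,
                                   T = T_s)
    )
  }
  list(waveform = w, geometry = g, config = cfg, slice_zs = slice_zs,
       target = target)
}
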