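# Shared fixtures: compact acquisition configurations keeping the standard
# 0.651 mm pixel pitch (500/768) on a small matrix, so rendering stays fast
# while sub-pixel geometry matches the full-scale protocol.

compact_config <- function(matrix_px = 184, noise_sd_hu = 20, seed = NULL,
                           ...) {
  acquisition_config(matrix_px = matrix_px,
                     fov_mm = matrix_px * 500 / 768,
                     n_slabs = 1, slices_per_slab = 1,
                     noise_sd_hu = noise_sd_hu, seed = seed, ...)
}

# One-slice study at the standard evaluation plane (200 mm from the central
# piece, lever ratio 0.5 with the default geometry).
quick_study <- function(A = 10, kind = "sine", T = 6, seed = 1,
                        noise_sd_hu = 20, cfg = NULL, ...) {
  if (is.null(cfg)) cfg <- compact_config(noise_sd_hu = noise_sd_hu,
                                          seed = seed, ...)
  g <- frame_geometry()
  w <- motion_waveform(kind, A = A, T = T)
  simulate_cine_study(w, g, cfg, slice_zs = g$z0 - 200)
}

# Independent brute-force intensity-weighted centroid of a bright blob over
# a known uniform background: the oracle the renderer and detector are
# checked against.
brute_centroid <- function(img, background = -1000) {
  w <- img - background
  w[w < 0] <- 0
  ii <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
  jj <- matrix(seq_len(ncol(img)), nrow(img), ncol(img), byrow = TRUE)
  c(x = sum(w * jj) / sum(w), y = sum(w * ii) / sum(w))
}

# Manually built wire track (for arithmetic-level checks of the amplitude
# equation).
make_track <- function(time_s, y_left, y_right, x_left = 10, x_right = 30,
                       spacing = 1) {
  df <- data.frame(frame_idx = seq_along(time_s), time_s = time_s,
                   x_left_px = x_left, y_left_px = y_left,
                   x_right_px = x_right, y_right_px = y_right,
                   valid = TRUE)
  attr(df, "slice_id") <- 1L
  attr(df, "pixel_spacing") <- spacing
  attr(df, "valid_fraction") <- 1
  class(df) <- c("wire_track", "data.frame")
  df
}

# Exact respiratory trace sampled from a waveform (bypasses imaging).
trace_from_waveform <- function(w, times) {
  out <- data.frame(time_s = times,
                    displacement_mm = evaluate_waveform(w, times))
  class(out) <- c("respiratory_trace", "data.frame")
  out
}
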