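# End-to-end conveniences: study -> track -> amplitude series -> trace ->
# sinusoid fit, and the simulation sweep used to benchmark the whole chain.

#' Extract the respiratory trace from a cine study
#'
#' Runs wire tracking, the per-frame amplitude (exhale-referenced mean of
#' the two wires) and the lever-arm scaling for one or more slices,
#' optionally averaging the per-slice traces of a common time base.
#'
#' @param study a `cine_study`.
#' @param slices slice indices to process; default all slices in the study.
#' @param average average the per-slice traces (requires one slab / common
#'   time base); if `FALSE` a list of traces is returned.
#' @param ... detection parameters passed to [track_wires()].
#' @return a `respiratory_trace`, or a list of them when `average = FALSE`
#'   and several slices are requested.
#' @export
extract_respiratory_signal <- function(study, slices = NULL, average = TRUE,
                                       ...) {
  stopifnot(inherits(study, "cine_study"))
  if (is.null(slices)) {
    slices <- sort(unique(vapply(study$frames, `[[`, numeric(1), "slice")))
  }
  traces <- lapply(slices, function(s) {
    fr <- slice_frames(study, s)
    track <- track_wires(fr, ...)
    az <- compute_az_series(track)
    build_respiratory_trace(az, fr[[1]]$z, study$geometry)
  })
  if (length(traces) == 1L) return(traces[[1]])
  if (average) average_traces(traces) else traces
}

#' Run the full signal pipeline on one slice and fit the sinusoid
#'
#' @param study a `cine_study`.
#' @param slice slice index (default 1).
#' @param ... passed to [track_wires()].
#' @return list with `track`, `az`, `trace`, `fit`, and — when the study
#'   carries ground truth — `comparison` from [compare_to_preset()].
#' @export
process_slice <- function(study, slice = 1, ...) {
  fr <- slice_frames(study, slice)
  track <- track_wires(fr, ...)
  az <- compute_az_series(track)
  trace <- build_respiratory_trace(az, fr[[1]]$z, study$geometry)
  fit <- fit_sine(trace)
  out <- list(track = track, az = az, trace = trace, fit = fit)
  if (!is.null(study$ground_truth) && isTRUE(fit$converged)) {
    out$comparison <- compare_to_preset(fit, study$ground_truth)
  }
  out
}

#' Sort a cine study into respiratory bins
#'
#' Extracts the respiratory trace of a reference slice, fits the sinusoid,
#' assigns phases to every frame time and bins the frames.
#'
#' @param study a `cine_study`.
#' @param n_bins number of bins.
#' @param mode binning mode, see [bin_frames()].
#' @param reference_slice slice used for the respiratory signal.
#' @param ... passed to [track_wires()].
#' @return list with `binned` (a `phase_binned_study`), `fit`, `trace`,
#'   `assignments`.
#' @export
sort_study <- function(study, n_bins = 10,
                       mode = c("phase", "amplitude", "amplitude+velocity"),
                       reference_slice = 1, ...) {
  mode <- match.arg(mode)
  res <- process_slice(study, reference_slice, ...)
  slabs <- vapply(study$frames, `[[`, numeric(1), "slab")
  ref_slab <- study$frames[[which(
    vapply(study$frames, `[[`, numeric(1), "slice") == reference_slice)[1]
  ]]$slab
  asg <- assign_phases(res$trace, res$fit)
  if (length(unique(slabs)) > 1L) {
    # other slabs: phases from the fitted periodic model at their frame
    # times; amplitude from the model (the reference trace does not span
    # those times)
    other_t <- sort(unique(vapply(
      study$frames[slabs != ref_slab], `[[`, numeric(1), "time")))
    model <- res$fit$y0 +
      res$fit$A * sin(2 * pi * (other_t - res$fit$tc) / res$fit$T)
    extra <- data.frame(
      time_s = other_t,
      phase = ((other_t - res$fit$tc) / res$fit$T) %% 1,
      amplitude_mm = model,
      velocity = ifelse(cos(2 * pi * (other_t - res$fit$tc) / res$fit$T) >= 0,
                        "inhale", "exhale"))
    asg <- rbind(asg, extra)
  }
  binned <- bin_frames(study, asg, n_bins = n_bins, mode = mode)
  list(binned = binned, fit = res$fit, trace = res$trace, assignments = asg)
}

#' Simulated accuracy sweep of the full pipeline
#'
#' Simulates seeded sinusoidal cine studies over a set of preset amplitudes,
#' runs detection, amplitude extraction, lever-arm scaling and sine fitting
#' on each, and tabulates fitted-versus-preset discrepancies. This is the
#' package's standard benchmark of end-to-end accuracy: one evaluation
#' slice 200 mm from the central piece (lever ratio 0.5 with the default
#' geometry), 20 frames at 0.8 s, 0.651 mm pixels, 20 HU noise.
#'
#' @param amplitudes preset amplitudes, mm.
#' @param n_seeds simulated studies per amplitude.
#' @param base_seed integer; per-run seeds are derived from it
#'   deterministically.
#' @param T_s preset cycle time, s.
#' @param noise_sd_hu image noise, HU.
#' @param matrix_px,fov_mm image matrix and field of view (defaults keep
#'   the standard 0.651 mm pixel pitch).
#' @param slice_offset_mm distance of the evaluation slice from the central
#'   piece, mm.
#' @return data.frame with one row per run: `A_preset_mm`, `seed`,
#'   `A_mm`, `T_s`, `delta_A_mm`, `delta_T_s`, `sd_A_mm`, `sd_T_s`,
#'   `adjusted_r2`, `max_abs_residual_mm`.
#' @export
benchmark_sine_sweep <- function(amplitudes = c(1, 2, 3, 6, 10),
                                 n_seeds = 10, base_seed = 1, T_s = 6,
                                 noise_sd_hu = 20, matrix_px = 768,
                                 fov_mm = 500, slice_offset_mm = 200) {
  g <- frame_geometry()
  z <- g$z0 - slice_offset_mm
  rows <- list()
  run <- 0L
  for (ai in seq_along(amplitudes)) {
    for (si in seq_len(n_seeds)) {
      run <- run + 1L
      seed <- as.integer((as.numeric(base_seed) * 7919 + run * 104729) %%
                           2147483647)
      cfg <- acquisition_config(n_slabs = 1, slices_per_slab = 1,
                                matrix_px = matrix_px, fov_mm = fov_mm,
                                noise_sd_hu = noise_sd_hu, seed = seed)
      w <- motion_waveform("sine", A = amplitudes[ai], T = T_s)
      study <- simulate_cine_study(w, g, cfg, slice_zs = z)
      res <- process_slice(study)
      cmp <- res$comparison
      rows[[run]] <- data.frame(
        A_preset_mm = amplitudes[ai], seed = seed,
        A_mm = cmp$measured_A_mm, T_s = cmp$measured_T_s,
        delta_A_mm = cmp$delta_A_mm, delta_T_s = cmp$delta_T_s,
        sd_A_mm = cmp$sd_A_mm, sd_T_s = cmp$sd_T_s,
        adjusted_r2 = cmp$adjusted_r2,
        max_abs_residual_mm = cmp$max_abs_residual_mm)
    }
  }
  do.call(rbind, rows)
}
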