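# Study persistence: multi-page 16-bit TIFF for pixels plus a JSON sidecar
# for metadata. Pixel arrays are integer HU; they are stored as
# uint16 = HU + 1024 (the usual CT rescale intercept), which round-trips
# bit-exactly for HU in [-1024, 64511].

HU_OFFSET <- 1024

#' Write a cine study to disk
#'
#' Writes `frames.tif` (one page per frame, 16-bit, acquisition order) and
#' `study.json` (per-frame slab/slice/Z/time/pixel-spacing, the geometry,
#' the acquisition parameters, and the ground-truth waveform when present)
#' into directory `path`. [read_study()] round-trips metadata and pixels
#' exactly.
#'
#' @param study a `cine_study`.
#' @param path output directory (created if absent).
#' @param format storage format; only `"tiff"` (TIFF + JSON sidecar) is
#'   supported.
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path, format = c("tiff", "dicom")) {
  format <- match.arg(format)
  if (format == "dicom") {
    stop("DICOM output is not supported; use format = \"tiff\"")
  }
  stopifnot(inherits(study, "cine_study"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  pages <- lapply(study$frames, function(f) {
    v <- f$pixels + HU_OFFSET
    if (any(v < 0 | v > 65535)) stop("pixel values outside the uint16 range")
    v / 65535
  })
  tiff::writeTIFF(pages, file.path(path, "frames.tif"),
                  bits.per.sample = 16L, compression = "none")
  meta <- list(
    frames = lapply(study$frames, function(f) {
      f[c("slab", "slice", "z", "time", "spacing")]
    }),
    geometry = unclass(study$geometry),
    config = unclass(study$config)[c("fov", "matrix", "frame_interval",
                                     "cine_duration", "noise_sd",
                                     "slices_per_slab", "n_slabs")],
    ground_truth = if (!is.null(study$ground_truth)) {
      unclass(study$ground_truth)
    }
  )
  jsonlite::write_json(meta, file.path(path, "study.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a cine study written by [write_study()]
#'
#' @param path directory containing `frames.tif` and `study.json`.
#' @return a `cine_study`. Ground truth is restored when the sidecar has it.
#' @export
read_study <- function(path) {
  jf <- file.path(path, "study.json")
  tf <- file.path(path, "frames.tif")
  if (!file.exists(jf) || !file.exists(tf)) {
    stop("not a study directory (missing frames.tif or study.json): ", path)
  }
  meta <- jsonlite::read_json(jf, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  pages <- tiff::readTIFF(tf, all = TRUE)
  if (length(pages) != length(meta$frames)) {
    stop("frame count mismatch between TIFF and sidecar")
  }
  frames <- Map(function(m, p) {
    list(slab = m$slab, slice = m$slice, z = m$z, time = m$time,
         spacing = m$spacing, pixels = round(p * 65535) - HU_OFFSET)
  }, meta$frames, pages)
  gt <- NULL
  if (!is.null(meta$ground_truth)) {
    gt <- motion_waveform(meta$ground_truth$kind, A = meta$ground_truth$A,
                          T = meta$ground_truth$T, tc = meta$ground_truth$tc,
                          y0 = meta$ground_truth$y0,
                          sharkfin_exponent =
                            meta$ground_truth$sharkfin_exponent %||% 4)
  }
  g <- frame_geometry(meta$geometry$z0, meta$geometry$zp,
                      meta$geometry$bar_length)
  structure(list(frames = frames, geometry = g, config = meta$config,
                 ground_truth = gt),
            class = "cine_study")
}

#' Read a pipeline configuration from YAML
#'
#' Reads the scenario configuration with blocks
#' `waveform: {kind, amplitude_mm, period_s, tc_s, baseline_mm}`,
#' `geometry: {z0_mm, zp_mm, bar_length_mm}` and optional `acquisition:`
#' overrides of [acquisition_config()] arguments.
#'
#' @param path YAML file path.
#' @return list with elements `waveform`, `geometry`, `config`, `slice_zs`.
#' @export
read_scenario_config <- function(path) {
  y <- yaml::read_yaml(path)
  geom <- y$geometry %||% list()
  g <- frame_geometry(z0_mm = geom$z0_mm %||% 580,
                      zp_mm = geom$zp_mm %||% 180,
                      bar_length_mm = geom$bar_length_mm %||% 470)
  acq <- y$acquisition %||% list()
  cfg <- do.call(acquisition_config, acq)
  list(
    waveform = if (!is.null(y$waveform)) waveform_from_config(y$waveform),
    geometry = g,
    config = cfg,
    slice_zs = unlist(y$slice_zs %||% NULL)
  )
}
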