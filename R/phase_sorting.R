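# Retrospective 4D sorting: each cine frame receives a respiratory phase
# (fraction of the fitted cycle) and/or amplitude, and frames are binned
# into per-phase 3D sets with one representative frame per (bin, slice).

#' Assign respiratory phases to the samples of a trace
#'
#' Phase is the fraction of the fitted cycle,
#' `phase(t) = ((t - tc)/T) mod 1`, with phase 0 at the fitted upward
#' zero-crossing (`t = tc`); `origin = "peak_inhale"` re-references phase 0
#' to peak inhale for the clinical convention. Amplitude is the measured
#' trace displacement (not the fitted model), so irregular breathing
#' degrades gracefully. The velocity sign comes from the fitted model
#' derivative: inhale while the model rises, exhale while it falls.
#'
#' @param trace a `respiratory_trace`.
#' @param fit a converged `sine_fit` for the same signal.
#' @param origin phase-zero convention, `"zero_crossing"` (default) or
#'   `"peak_inhale"`.
#' @return data.frame (class `phase_assignment`) with `time_s`, `phase` in
#'   `[0, 1)`, `amplitude_mm`, `velocity` (`"inhale"`/`"exhale"`).
#' @export
assign_phases <- function(trace, fit,
                          origin = c("zero_crossing", "peak_inhale")) {
  origin <- match.arg(origin)
  stopifnot(inherits(fit, "sine_fit"))
  if (!isTRUE(fit$converged)) {
    stop("fit did not converge; phase assignment requires a converged fit ",
         "(amplitude-only binning remains available)")
  }
  t <- trace$time_s
  ph <- ((t - fit$tc) / fit$T) %% 1
  if (origin == "peak_inhale") ph <- (ph - 0.25) %% 1
  vel <- ifelse(cos(2 * pi * (t - fit$tc) / fit$T) >= 0, "inhale", "exhale")
  out <- data.frame(time_s = t, phase = ph,
                    amplitude_mm = trace$displacement_mm,
                    velocity = vel)
  class(out) <- c("phase_assignment", "data.frame")
  out
}

# circular distance between phases in [0,1)
phase_dist <- function(p, c) pmin(abs(p - c), 1 - abs(p - c))

#' Bin cine frames into respiratory bins
#'
#' Every frame of the study is matched to its assignment by acquisition
#' time and placed in exactly one bin:
#' * `mode = "phase"`: bin `k` covers phase `[(k-1)/n, k/n)`.
#' * `mode = "amplitude"`: `n_bins` equal-width bins over
#'   `[0, max amplitude]`.
#' * `mode = "amplitude+velocity"`: amplitude bins split by velocity sign,
#'   giving up to `2 n_bins` bins labelled `"<k>-inhale"` / `"<k>-exhale"`.
#'
#' The representative frame per (bin, slice) is the frame whose phase (or
#' amplitude) is closest to the bin centre, ties broken by earliest time.
#' Empty (bin, slice) cells are reported, never interpolated: the cine
#' protocol cannot guarantee full coverage, and fabricating slices would be
#' silent data invention.
#'
#' @param study a `cine_study`.
#' @param assignments a `phase_assignment` covering every distinct frame
#'   time of the study (frames of one slab share timestamps with its trace).
#' @param n_bins number of bins (>= 1).
#' @param mode binning mode.
#' @param time_tol matching tolerance between frame and assignment times, s.
#' @return object of class `phase_binned_study`: `frames` (data.frame
#'   `frame_id`, `slab`, `slice`, `z`, `time_s`, `bin`, plus the binning
#'   value), `representatives` (`bin`, `slice`, `z`, `frame_id`),
#'   `coverage` (bins x slices count table), `empty_cells`, `n_bins`,
#'   `mode`, `bin_labels`.
#' @export
bin_frames <- function(study, assignments, n_bins = 10,
                       mode = c("phase", "amplitude", "amplitude+velocity"),
                       time_tol = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(inherits(study, "cine_study"), n_bins >= 1)
  n_bins <- as.integer(n_bins)
  fi <- data.frame(
    frame_id = seq_along(study$frames),
    slab = vapply(study$frames, `[[`, numeric(1), "slab"),
    slice = vapply(study$frames, `[[`, numeric(1), "slice"),
    z = vapply(study$frames, `[[`, numeric(1), "z"),
    time_s = vapply(study$frames, `[[`, numeric(1), "time")
  )
  m <- vapply(fi$time_s, function(tt) {
    d <- abs(assignments$time_s - tt)
    i <- which.min(d)
    if (d[i] > time_tol) NA_integer_ else i
  }, integer(1))
  if (anyNA(m)) stop("every frame needs an assignment within time_tol")
  ph <- assignments$phase[m]
  am <- assignments$amplitude_mm[m]
  vl <- assignments$velocity[m]

  if (mode == "phase") {
    k <- pmin(floor(ph * n_bins) + 1L, n_bins)
    labels <- as.character(seq_len(n_bins))
    centers <- (seq_len(n_bins) - 0.5) / n_bins
    bin <- labels[k]
    dist <- phase_dist(ph, centers[k])
    value <- ph
  } else {
    amax <- max(am)
    width <- if (amax > 0) amax / n_bins else 1
    k <- pmin(floor(am / width) + 1L, n_bins)
    centers <- (seq_len(n_bins) - 0.5) * width
    dist <- abs(am - centers[k])
    value <- am
    if (mode == "amplitude") {
      labels <- as.character(seq_len(n_bins))
      bin <- labels[k]
    } else {
      labels <- as.vector(outer(seq_len(n_bins), c("inhale", "exhale"),
                                paste, sep = "-"))
      bin <- paste(k, vl, sep = "-")
    }
  }
  fi$bin <- bin
  fi$value <- value
  fi$dist_to_center <- dist

  slices <- sort(unique(fi$slice))
  used_labels <- labels[labels %in% unique(bin)]
  reps <- do.call(rbind, lapply(used_labels, function(b) {
    sub <- fi[fi$bin == b, , drop = FALSE]
    do.call(rbind, lapply(sort(unique(sub$slice)), function(s) {
      ss <- sub[sub$slice == s, , drop = FALSE]
      ss <- ss[order(ss$dist_to_center, ss$time_s), , drop = FALSE]
      ss[1, c("bin", "slice", "z", "frame_id"), drop = FALSE]
    }))
  }))
  rownames(reps) <- NULL
  cov <- table(factor(fi$bin, levels = labels),
               factor(fi$slice, levels = slices))
  empty <- which(cov == 0, arr.ind = TRUE)
  empty_cells <- if (nrow(empty)) {
    data.frame(bin = rownames(cov)[empty[, 1]],
               slice = as.integer(colnames(cov)[empty[, 2]]))
  } else {
    data.frame(bin = character(0), slice = integer(0))
  }
  structure(list(frames = fi, representatives = reps, coverage = cov,
                 empty_cells = empty_cells, n_bins = n_bins, mode = mode,
                 bin_labels = labels),
            class = "phase_binned_study")
}

#' @export
print.phase_binned_study <- function(x, ...) {
  cat(sprintf("<phase_binned_study> mode=%s, %d bin(s), %d frames, %d empty (bin, slice) cells\n",
              x$mode, length(x$bin_labels), nrow(x$frames), nrow(x$empty_cells)))
  invisible(x)
}

#' Export per-bin volumes
#'
#' For each non-empty bin, writes the stack of representative slices
#' (ordered by Z) as a multi-page 16-bit TIFF `bin_<label>.tif`, plus a
#' `manifest.json` listing every (bin, slice, frame id) triple and the
#' empty cells; bins with no representative are skipped and recorded in the
#' manifest.
#'
#' @param study the `cine_study` the binning came from.
#' @param binned a `phase_binned_study`.
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
export_phase_volumes <- function(study, binned, path) {
  stopifnot(inherits(binned, "phase_binned_study"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(mode = binned$mode, n_bins = binned$n_bins,
                   volumes = list(), skipped_bins = character(0),
                   empty_cells = binned$empty_cells)
  for (b in binned$bin_labels) {
    reps <- binned$representatives[binned$representatives$bin == b, ,
                                   drop = FALSE]
    if (nrow(reps) == 0L) {
      manifest$skipped_bins <- c(manifest$skipped_bins, b)
      next
    }
    reps <- reps[order(reps$z), , drop = FALSE]
    pages <- lapply(reps$frame_id, function(i) {
      (study$frames[[i]]$pixels + HU_OFFSET) / 65535
    })
    fn <- sprintf("bin_%s.tif", gsub("[^0-9A-Za-z-]", "_", b))
    tiff::writeTIFF(pages, file.path(path, fn), bits.per.sample = 16L,
                    compression = "none")
    manifest$volumes[[length(manifest$volumes) + 1L]] <- list(
      bin = b, file = fn,
      slices = reps[, c("slice", "z", "frame_id")]
    )
  }
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
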