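# Native re-implementation of the interactive windowing / binary-filter /
# particle-tracking chain used on the original workstation: fixed HU
# threshold, 8-connected component labelling, area filtering, sub-pixel
# intensity-weighted centroids, and x-ordered identity linking.

# Label a sparse set of pixels (rows, cols) into 8-connected components.
# Above-threshold sets here are tens of pixels, so a BFS over the sparse
# set is cheap and keeps the connectivity rule explicit.
label_components8 <- function(rows, cols, nrow_img) {
  n <- length(rows)
  if (n == 0L) return(integer(0))
  key <- (cols - 1L) * nrow_img + rows
  idx_of <- match(key, key)          # identity, used with match() below
  labels <- integer(n)
  comp <- 0L
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (i in seq_len(n)) {
    if (labels[i] > 0L) next
    comp <- comp + 1L
    queue <- i
    labels[i] <- comp
    while (length(queue) > 0L) {
      p <- queue[[1L]]; queue <- queue[-1L]
      nb_key <- (cols[p] + offs$dc - 1L) * nrow_img + (rows[p] + offs$dr)
      hit <- match(nb_key, key)
      hit <- hit[!is.na(hit)]
      new <- hit[labels[hit] == 0L]
      labels[new] <- comp
      queue <- c(queue, new)
    }
  }
  labels
}

# Sub-pixel centroid of one component: background-subtracted
# intensity-weighted mean over a small window around the component. The
# local background is the median of the window border, so the weights are
# proportional to the wire's partial-pixel coverage and the centroid
# recovers the true disc centre rather than the quantised pixel grid.
component_centroid <- function(img, rows, cols, pad = 3L) {
  i0 <- max(1L, min(rows) - pad); i1 <- min(nrow(img), max(rows) + pad)
  j0 <- max(1L, min(cols) - pad); j1 <- min(ncol(img), max(cols) + pad)
  win <- img[i0:i1, j0:j1, drop = FALSE]
  border <- c(win[1, ], win[nrow(win), ], win[, 1], win[, ncol(win)])
  w <- win - stats::median(border)
  wy <- matrix(i0:i1, nrow(win), ncol(win))
  wx <- matrix(j0:j1, nrow(win), ncol(win), byrow = TRUE)
  sw <- sum(w)
  c(x = sum(w * wx) / sw, y = sum(w * wy) / sw)
}

#' Detect the two wire cross-sections in one frame
#'
#' Pixels above `threshold` are labelled into 8-connected components;
#' components outside `[min_area, max_area]` pixels are discarded; the two
#' largest survivors are returned as sub-pixel intensity-weighted centroids,
#' ordered left then right by image X. Image coordinates have their origin
#' at the upper-left corner; Y increases toward the table.
#'
#' @param image numeric HU matrix, finite.
#' @param threshold segmentation threshold, HU. Default 1500 sits midway
#'   between soft tissue and the 3000 HU wire.
#' @param min_area,max_area component area bounds, pixels.
#' @param roi optional `c(xmin, xmax)` column range restricting detection to
#'   lateral bands where the wires are expected.
#' @return list with `left` and `right`, each `c(x, y)` in pixels, and
#'   `areas` (component areas, left then right).
#'
#' Fewer than two surviving components raises a condition of class
#' `resp4d_wires_not_found`; more than two components of similar size (third
#' within 10% of the second's area) raises `resp4d_wire_ambiguity` carrying
#' the component list — ambiguous frames are flagged rather than guessed.
#' @export
detect_wires <- function(image, threshold = 1500, min_area = 3,
                         max_area = 200, roi = NULL) {
  if (!all(is.finite(image))) stop("image must be finite")
  sel <- which(image > threshold)
  nr <- nrow(image)
  rows <- ((sel - 1L) %% nr) + 1L
  cols <- ((sel - 1L) %/% nr) + 1L
  if (!is.null(roi)) {
    keep <- cols >= roi[1] & cols <= roi[2]
    rows <- rows[keep]; cols <- cols[keep]
  }
  labels <- label_components8(rows, cols, nr)
  if (length(labels) == 0L) {
    stop(wires_not_found("no pixels above threshold"))
  }
  areas <- tabulate(labels)
  ok <- which(areas >= min_area & areas <= max_area)
  if (length(ok) < 2L) {
    stop(wires_not_found(sprintf(
      "%d component(s) within area bounds; two wires expected", length(ok))))
  }
  ord <- ok[order(areas[ok], decreasing = TRUE)]
  if (length(ord) >= 3L && areas[ord[3]] >= 0.9 * areas[ord[2]]) {
    stop(structure(
      class = c("resp4d_wire_ambiguity", "error", "condition"),
      list(message = "more than two wire-like components of similar size",
           call = sys.call(-1),
           components = data.frame(label = ord, area = areas[ord]))))
  }
  picks <- ord[1:2]
  cents <- lapply(picks, function(l) {
    component_centroid(image, rows[labels == l], cols[labels == l])
  })
  if (cents[[1]]["x"] > cents[[2]]["x"]) {
    cents <- rev(cents); picks <- rev(picks)
  }
  list(left = cents[[1]], right = cents[[2]], areas = areas[picks])
}

wires_not_found <- function(msg) {
  structure(class = c("resp4d_wires_not_found", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Track the wires across the cine frames of one slice
#'
#' Runs [detect_wires()] on every frame and links detections into left and
#' right identities by image X and nearest-neighbour continuity with the
#' previous valid frame. Frames where detection fails (or where a detection
#' jumps implausibly far from the previous valid frame) are flagged invalid
#' and excluded from downstream statistics rather than aborting the track.
#'
#' @param frames list of cine frames of one slice (see [slice_frames()]),
#'   ordered by time; at least 2.
#' @param threshold,min_area,max_area,roi passed to [detect_wires()].
#' @param max_jump_px largest credible frame-to-frame centroid move, px.
#' @param min_valid_fraction minimum fraction of valid frames below which
#'   the track is rejected as unusable.
#' @return a `wire_track`: data.frame with columns `frame_idx`, `time_s`,
#'   `x_left_px`, `y_left_px`, `x_right_px`, `y_right_px`, `valid`;
#'   attributes `slice_id`, `pixel_spacing`, `valid_fraction`.
#' @export
track_wires <- function(frames, threshold = 1500, min_area = 3,
                        max_area = 200, roi = NULL, max_jump_px = 40,
                        min_valid_fraction = 0.5) {
  stopifnot(length(frames) >= 2L)
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (any(diff(times) <= 0)) stop("frame times must strictly increase")
  n <- length(frames)
  out <- data.frame(frame_idx = seq_len(n), time_s = times,
                    x_left_px = NA_real_, y_left_px = NA_real_,
                    x_right_px = NA_real_, y_right_px = NA_real_,
                    valid = FALSE)
  prev <- NULL
  for (i in seq_len(n)) {
    det <- tryCatch(
      detect_wires(frames[[i]]$pixels, threshold, min_area, max_area, roi),
      resp4d_wires_not_found = function(e) NULL,
      resp4d_wire_ambiguity = function(e) NULL
    )
    if (is.null(det)) next
    if (!is.null(prev)) {
      jump <- max(abs(det$left - prev$left), abs(det$right - prev$right))
      if (jump > max_jump_px) next
    }
    out$x_left_px[i] <- det$left["x"]; out$y_left_px[i] <- det$left["y"]
    out$x_right_px[i] <- det$right["x"]; out$y_right_px[i] <- det$right["y"]
    out$valid[i] <- TRUE
    prev <- det
  }
  vf <- mean(out$valid)
  if (vf < min_valid_fraction) {
    stop(sprintf("track unusable: only %.0f%% of frames valid", 100 * vf))
  }
  attr(out, "slice_id") <- frames[[1]]$slice
  attr(out, "pixel_spacing") <- frames[[1]]$spacing
  attr(out, "valid_fraction") <- vf
  class(out) <- c("wire_track", "data.frame")
  out
}

#' Write a wire track to CSV
#'
#' @param track a `wire_track`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(track, path) {
  df <- as.data.frame(track)
  df <- cbind(slice_id = attr(track, "slice_id") %||% NA, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
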