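# Synthetic frame rendering.
#
# Image convention (matches the processing chain downstream): the matrix is
# indexed [row, col]; the origin is the upper-left corner, column index is
# image X (patient left-right), row index is image Y increasing downward,
# i.e. toward the patient table. A physical position y mm from the top edge
# falls at continuous pixel coordinate y/spacing + 0.5 (pixel centres sit at
# half-integer physical offsets).

mm_to_px <- function(mm, spacing) mm / spacing + 0.5

px_to_mm <- function(px, spacing) (px - 0.5) * spacing

# Noiseless anatomical background: -1000 HU air, a 40 HU soft-tissue ellipse
# with two -700 HU lung fields. Proportions scale with the FOV so compact
# test configurations keep the same layout.
make_base_image <- function(cfg) {
  n <- cfg$matrix
  s <- cfg$pixel_spacing
  img <- matrix(-1000, n, n)
  if (!cfg$body) return(img)
  xc <- px_to_mm(matrix(rep(seq_len(n), each = n), n, n), s)   # col coord, mm
  yc <- px_to_mm(matrix(rep(seq_len(n), times = n), n, n), s)  # row coord, mm
  f <- cfg$fov
  in_ell <- function(cx, cy, ax, ay) ((xc - cx) / ax)^2 + ((yc - cy) / ay)^2 <= 1
  body <- in_ell(0.5 * f, 0.62 * f, 0.30 * f, 0.18 * f)
  img[body] <- 40
  lungL <- in_ell(0.38 * f, 0.60 * f, 0.095 * f, 0.115 * f)
  lungR <- in_ell(0.62 * f, 0.60 * f, 0.095 * f, 0.115 * f)
  img[lungL | lungR] <- -700
  img
}

# Composite an anti-aliased disc onto `img`. Coverage of each pixel is
# computed by area-weighted supersampling (16 x 16 sub-pixels), giving a
# coverage quantisation of 1/256 and a centroid fidelity far below 0.1 px.
# The disc value replaces the underlying value in proportion to coverage.
composite_disc <- function(img, cx_px, cy_px, r_px, value, supersample = 16L) {
  n_r <- nrow(img); n_c <- ncol(img)
  j0 <- floor(cx_px - r_px); j1 <- ceiling(cx_px + r_px)
  i0 <- floor(cy_px - r_px); i1 <- ceiling(cy_px + r_px)
  if (j0 < 1 || i0 < 1 || j1 > n_c || i1 > n_r) {
    stop("disc overlaps the image border")
  }
  jj <- j0:j1; ii <- i0:i1
  k <- supersample
  off <- (seq_len(k) - 0.5) / k - 0.5
  # sub-pixel sample coordinates for the bounding box
  sx <- rep(jj, each = k) + rep(off, times = length(jj))
  sy <- rep(ii, each = k) + rep(off, times = length(ii))
  inside <- outer((sy - cy_px)^2, (sx - cx_px)^2, `+`) <= r_px^2
  # collapse k x k sub-samples per pixel
  cov <- matrix(0, length(ii), length(jj))
  for (a in seq_along(ii)) {
    rows <- (a - 1L) * k + seq_len(k)
    block <- inside[rows, , drop = FALSE]
    cov[a, ] <- colSums(matrix(colSums(block), k, length(jj))) / (k * k)
  }
  sub <- img[ii, jj, drop = FALSE]
  img[ii, jj] <- sub + cov * (value - sub)
  img
}

#' Render one synthetic cine frame
#'
#' Draws the two wire cross-sections (anti-aliased discs of the configured
#' wire diameter at 3000 HU) at sub-pixel positions over the anatomical
#' background, optionally adds a target disc, then adds Gaussian noise of
#' `cfg$noise_sd` HU and quantises to integer HU (as CT pixel data is
#' integer-valued under its rescale).
#'
#' On the noiseless image the intensity-weighted centroid of each disc is
#' within 0.1 px of the requested centre.
#'
#' @param cfg an [acquisition_config()].
#' @param wire_y_mm length-2 vector: vertical positions (mm from the top
#'   edge) of the left and right wire centres.
#' @param wire_x_mm length-2 vector of lateral positions, mm; defaults to
#'   `cfg$wire_x_mm`.
#' @param noise add Gaussian noise of sd `cfg$noise_sd` (uses the current
#'   RNG state).
#' @param base pre-computed noiseless background from an earlier call
#'   (performance cache); `NULL` renders it.
#' @param target optional list `list(x_mm, y_mm, radius_mm, hu)` for a
#'   target disc (e.g. a sphere cross-section).
#' @return integer-valued HU matrix `cfg$matrix` x `cfg$matrix`.
#' @export
render_frame <- function(cfg, wire_y_mm, wire_x_mm = NULL, noise = TRUE,
                         base = NULL, target = NULL) {
  stopifnot(inherits(cfg, "acquisition_config"), length(wire_y_mm) == 2L,
            all(is.finite(wire_y_mm)))
  if (is.null(wire_x_mm)) wire_x_mm <- cfg$wire_x_mm
  s <- cfg$pixel_spacing
  img <- if (is.null(base)) make_base_image(cfg) else base
  r_px <- (cfg$wire_diameter_mm / 2) / s
  for (w in 1:2) {
    img <- composite_disc(img, mm_to_px(wire_x_mm[w], s),
                          mm_to_px(wire_y_mm[w], s), r_px, cfg$wire_hu)
  }
  if (!is.null(target) && isTRUE(target$radius_mm > 0)) {
    img <- composite_disc(img, mm_to_px(target$x_mm, s),
                          mm_to_px(target$y_mm, s),
                          target$radius_mm / s, target$hu %||% 50)
  }
  if (noise && cfg$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(length(img), 0, cfg$noise_sd),
                        nrow(img), ncol(img))
  }
  # integer HU with the scanner's air floor
  pmax(round(img), -1024)
}
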