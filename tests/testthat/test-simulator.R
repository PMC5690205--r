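test_that("acquisition defaults reproduce the cine protocol", {
  cfg <- acquisition_config()
  expect_equal(cfg$pixel_spacing, 500 / 768)
  expect_equal(cfg$frames_per_slice, 20L)
  expect_equal(cfg$n_slabs, 4L)
  expect_equal(cfg$slices_per_slab, 8L)
})

test_that("a pixel-centre-aligned wire renders its peak at that pixel", {
  cfg <- compact_config(matrix_px = 64, noise_sd_hu = 0, body = FALSE)
  s <- cfg$pixel_spacing
  # centre of pixel (row 20, col 16): x = 15.5 s, y = 19.5 s
  img <- render_frame(cfg, wire_y_mm = c(19.5 * s, 19.5 * s),
                      wire_x_mm = c(15.5 * s, 47.5 * s), noise = FALSE)
  peak <- which(img == max(img), arr.ind = TRUE)
  expect_true(any(peak[, 1] == 20 & peak[, 2] == 16))
})

test_that("noiseless rendered discs have sub-0.1 px centroid error", {
  cfg <- compact_config(matrix_px = 64, noise_sd_hu = 0, body = FALSE)
  s <- cfg$pixel_spacing
  set.seed(301)
  worst <- 0
  for (k in 1:100) {
    cx <- runif(1, 10, 36); cy <- runif(1, 10, 54)   # px, sub-pixel
    img <- render_frame(cfg, wire_y_mm = rep((cy - 0.5) * s, 2),
                        wire_x_mm = c((cx - 0.5) * s, 58 * s), noise = FALSE)
    win <- img[, 1:40, drop = FALSE]                 # isolate left disc
    cen <- brute_centroid(win)
    worst <- max(worst, abs(cen["x"] - cx), abs(cen["y"] - cy))
  }
  expect_lt(worst, 0.1)
})

test_that("mirrored wire positions render a left-right symmetric image", {
  cfg <- compact_config(matrix_px = 64, noise_sd_hu = 0, body = FALSE)
  f <- cfg$fov
  img <- render_frame(cfg, wire_y_mm = c(20, 20),
                      wire_x_mm = c(f / 2 - 12, f / 2 + 12), noise = FALSE)
  expect_equal(img, img[, ncol(img):1])
})

test_that("wire discs touching the image border are rejected", {
  cfg <- compact_config(matrix_px = 64, noise_sd_hu = 0, body = FALSE)
  expect_error(render_frame(cfg, wire_y_mm = c(0.3, 20), noise = FALSE),
               "border")
})

test_that("study layout follows the acquisition configuration", {
  cfg <- acquisition_config(matrix_px = 32, fov_mm = 32 * 500 / 768,
                            n_slabs = 4, slices_per_slab = 8,
                            noise_sd_hu = 0, body = FALSE, seed = 5)
  g <- frame_geometry()
  w <- motion_waveform("constant", y0 = 0)
  zs <- seq(380, by = 3, length.out = 32)
  st <- simulate_cine_study(w, g, cfg, slice_zs = zs)
  expect_length(st$frames, 4 * 8 * 20)
  # times strictly increase within a slice; slabs follow sequentially
  for (s in c(1, 9, 32)) {
    fr <- slice_frames(st, s)
    tt <- vapply(fr, `[[`, numeric(1), "time")
    expect_true(all(diff(tt) > 0))
    expect_equal(tt[1], (fr[[1]]$slab - 1) * cfg$cine_duration)
    expect_equal(diff(tt), rep(cfg$frame_interval, 19))
  }
  # constant waveform, zero noise: all frames of a slice identical
  fr <- slice_frames(st, 3)
  expect_identical(fr[[1]]$pixels, fr[[20]]$pixels)
})

test_that("identical seeds give bit-identical studies", {
  st1 <- quick_study(A = 6, seed = 99, matrix_px = 96)
  st2 <- quick_study(A = 6, seed = 99, matrix_px = 96)
  expect_identical(lapply(st1$frames, `[[`, "pixels"),
                   lapply(st2$frames, `[[`, "pixels"))
  st3 <- quick_study(A = 6, seed = 100, matrix_px = 96)
  expect_false(identical(st1$frames[[1]]$pixels, st3$frames[[1]]$pixels))
})

test_that("simulated wire travel matches the lever-projected amplitude", {
  st <- quick_study(A = 10, noise_sd_hu = 0, seed = 1)   # lever ratio 0.5
  ys <- vapply(st$frames, function(f) f$truth$y_px[1], numeric(1))
  travel_mm <- (max(ys) - min(ys)) * st$config$pixel_spacing
  # 20 samples of a 6 s cycle at 0.8 s: grid maximum within cos(pi*0.4/6)
  expect_equal(travel_mm, 10, tolerance = 0.05)
})

test_that("studies round-trip through tiff+json exactly", {
  st <- quick_study(A = 3, seed = 21, matrix_px = 64)
  st$frames <- st$frames[1:2]
  dir <- withr::local_tempdir()
  write_study(st, dir)
  back <- read_study(dir)
  expect_identical(back$frames[[1]]$pixels, st$frames[[1]]$pixels)
  expect_identical(back$frames[[2]]$pixels, st$frames[[2]]$pixels)
  expect_equal(vapply(back$frames, `[[`, numeric(1), "time"),
               vapply(st$frames, `[[`, numeric(1), "time"))
  expect_equal(back$frames[[1]]$z, st$frames[[1]]$z)
  expect_equal(back$frames[[1]]$spacing, st$frames[[1]]$spacing)
  # ground truth restored
  expect_equal(back$ground_truth$A, 3)
  expect_equal(back$ground_truth$kind, "sine")
  # and absent when the study has none
  st$ground_truth <- NULL
  write_study(st, dir)
  expect_null(read_study(dir)$ground_truth)
})

test_that("DICOM output is reported as unsupported", {
  st <- quick_study(A = 1, seed = 2, matrix_px = 64)
  expect_error(write_study(st, tempfile(), format = "dicom"), "not supported")
})

test_that("scenario YAML configures waveform, geometry and acquisition", {
  path <- system.file("extdata", "example_scenario.yaml", package = "resp4d")
  sc <- read_scenario_config(path)
  expect_s3_class(sc$waveform, "motion_waveform")
  expect_equal(sc$waveform$A, 10)
  expect_equal(sc$geometry$z0 - sc$geometry$zp, 400)
  expect_equal(sc$slice_zs, 380)
  expect_equal(sc$config$noise_sd, 20)
})
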