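# a converged fit + exact trace on the standard cine grid
fixture_fit <- function(tc = 0.7, T = 6, A = 10) {
  w <- motion_waveform("sine", A = A, T = T, tc = tc, y0 = A)
  tr <- trace_from_waveform(w, seq(0, 15.2, by = 0.8))
  list(trace = tr, fit = fit_sine(tr))
}

test_that("phase is the cycle fraction anchored at the upward zero-crossing", {
  fx <- fixture_fit(tc = 0.7)
  tr <- fx$trace; fit <- fx$fit
  tr$time_s <- c(fit$tc, fit$tc + fit$T / 2, tr$time_s[-(1:2)])
  tr$displacement_mm <- fit$y0 + fit$A * sin(2 * pi * (tr$time_s - fit$tc) / fit$T)
  asg <- assign_phases(tr, fit)
  expect_equal(asg$phase[1], 0, tolerance = 1e-9)
  expect_equal(asg$phase[2], 0.5, tolerance = 1e-9)
  expect_true(all(asg$phase >= 0 & asg$phase < 1))
  # peak-inhale convention shifts phase zero by a quarter cycle
  asg2 <- assign_phases(tr, fit, origin = "peak_inhale")
  expect_equal(asg2$phase, (asg$phase - 0.25) %% 1, tolerance = 1e-9)
})

test_that("20 frames over 16 s at T=6 wrap 2 2/3 cycles with near-even deciles", {
  fx <- fixture_fit(tc = 0)
  asg <- assign_phases(fx$trace, fx$fit)
  # direct enumeration of the sampling grid: phases are multiples of
  # 0.8/6 mod 1; decile occupancy differs by at most 2
  counts <- table(floor(asg$phase * 10))
  expect_lte(max(counts) - min(counts), 2)
  unwrapped <- (fx$trace$time_s - fx$fit$tc) / fx$fit$T
  expect_gt(max(unwrapped) - min(unwrapped), 2.5)
})

test_that("an unconverged fit is rejected for phase assignment", {
  tr <- trace_from_waveform(motion_waveform("constant", y0 = 0),
                            seq(0, 15.2, 0.8))
  fit <- fit_sine(tr)
  expect_error(assign_phases(tr, fit), "converge")
})

test_that("binning partitions every frame exactly once", {
  st <- quick_study(A = 10, seed = 81, matrix_px = 96)
  res <- sort_study(st, n_bins = 10, mode = "phase")
  binned <- res$binned
  expect_equal(nrow(binned$frames), length(st$frames))
  expect_equal(sum(binned$coverage), length(st$frames))
  expect_true(all(table(binned$frames$frame_id) == 1))
  # representatives: at most one per (bin, slice)
  expect_false(any(duplicated(binned$representatives[c("bin", "slice")])))
})

test_that("a single bin holds everything and covers every slice", {
  st <- quick_study(A = 10, seed = 82, matrix_px = 96)
  res <- sort_study(st, n_bins = 1, mode = "phase")
  expect_true(all(res$binned$frames$bin == "1"))
  expect_equal(nrow(res$binned$empty_cells), 0)
  expect_error(bin_frames(st, res$assignments, n_bins = 0), "n_bins")
})

test_that("the default cine grid fills at least 9 of 10 phase bins per slice", {
  st <- quick_study(A = 10, seed = 83, matrix_px = 96)
  res <- sort_study(st, n_bins = 10, mode = "phase")
  per_slice_filled <- colSums(res$binned$coverage > 0)
  expect_true(all(per_slice_filled >= 9))
})

test_that("amplitude+velocity splits equal-amplitude frames by breathing direction", {
  st <- quick_study(A = 10, seed = 84, matrix_px = 96)
  res <- sort_study(st, n_bins = 5, mode = "amplitude+velocity")
  fr <- res$binned$frames
  lab <- strsplit(fr$bin, "-")
  fr$k <- vapply(lab, `[[`, character(1), 1)
  fr$dir <- vapply(lab, `[[`, character(1), 2)
  both <- split(fr$dir, fr$k)
  expect_true(any(vapply(both, function(d) all(c("inhale", "exhale") %in% d),
                         logical(1))))
  # within one amplitude bin, representatives of the two velocity bins exist
  reps <- res$binned$representatives
  expect_true(all(grepl("-(inhale|exhale)$", reps$bin)))
})

test_that("phase assignment is equivariant under time translation of the study", {
  fx <- fixture_fit(tc = 0.4)
  asg0 <- assign_phases(fx$trace, fx$fit)
  delta <- 5.1
  tr2 <- fx$trace; tr2$time_s <- tr2$time_s + delta
  fit2 <- fx$fit; fit2$tc <- fit2$tc + delta
  asg1 <- assign_phases(tr2, fit2)
  expect_equal(asg1$phase, asg0$phase, tolerance = 1e-9)
})

test_that("exported per-bin volumes round-trip and the manifest is complete", {
  st <- quick_study(A = 10, seed = 85, matrix_px = 96)
  res <- sort_study(st, n_bins = 4, mode = "phase")
  dir <- withr::local_tempdir()
  export_phase_volumes(st, res$binned, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  triples <- do.call(rbind, lapply(seq_len(nrow(man$volumes)), function(i) {
    cbind(bin = man$volumes$bin[i], man$volumes$slices[[i]])
  }))
  expect_false(any(duplicated(triples[, c("bin", "slice")])))
  expect_equal(nrow(triples), nrow(res$binned$representatives))
  # pixel round-trip of the first volume
  v1 <- tiff::readTIFF(file.path(dir, man$volumes$file[1]), all = TRUE)
  fid <- man$volumes$slices[[1]]$frame_id[1]
  expect_identical(round(v1[[1]] * 65535) - 1024, st$frames[[fid]]$pixels)
})

test_that("sorting recovers the full excursion of a moving target sphere", {
  cfg <- compact_config(matrix_px = 184, noise_sd_hu = 20, seed = 86,
                        body = FALSE)
  g <- frame_geometry()
  w <- motion_waveform("sine", A = 10, T = 6)
  f <- cfg$fov
  target <- list(x_mm = 0.5 * f, y_mm = 0.62 * f, z_mm = 380,
                 radius_mm = 5, hu = 50,
                 waveform_y = motion_waveform("sine", A = 5, T = 6))
  st <- simulate_cine_study(w, g, cfg, slice_zs = 380, target = target)
  res <- sort_study(st, n_bins = 10, mode = "phase")
  reps <- res$binned$representatives
  cy <- vapply(reps$frame_id, function(i) {
    img <- st$frames[[i]]$pixels
    rows <- round(nrow(img) * 0.45):nrow(img)       # target region only
    # clamp at -500 HU so noisy background pixels carry zero weight
    brute_centroid(img[rows, , drop = FALSE], background = -500)["y"]
  }, numeric(1))
  extent_mm <- diff(range(cy)) * cfg$pixel_spacing
  expect_gte(extent_mm, 0.9 * 2 * 5)
})
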