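grid_times <- seq(0, 15.2, by = 0.8)   # 20 cine samples

test_that("the period guess lands within 10% on the cine sampling grid", {
  w <- motion_waveform("sine", A = 10, T = 6, y0 = 10)
  tr <- trace_from_waveform(w, grid_times)
  g <- initial_guess(tr)
  expect_lt(abs(g$T - 6) / 6, 0.10)
  expect_equal(g$y0, mean(tr$displacement_mm))
  expect_equal(g$A, diff(range(tr$displacement_mm)) / 2)
})

test_that("a flat trace raises a no-oscillation error", {
  tr <- trace_from_waveform(motion_waveform("constant", y0 = 5), grid_times)
  expect_error(initial_guess(tr), class = "resp4d_no_oscillation")
})

test_that("the guess shifts tc by exactly the time-origin shift", {
  w <- motion_waveform("sine", A = 10, T = 6, tc = 1.1, y0 = 10)
  tr <- trace_from_waveform(w, grid_times)
  g0 <- initial_guess(tr)
  delta <- 2.3
  tr2 <- tr; tr2$time_s <- tr$time_s + delta
  g1 <- initial_guess(tr2)
  expect_equal(g1$T, g0$T, tolerance = 1e-9)
  expect_equal((g1$tc - g0$tc) %% g0$T, delta %% g0$T, tolerance = 1e-6)
})

test_that("noiseless sine samples are recovered exactly", {
  w <- motion_waveform("sine", A = 10, T = 6, tc = 0.7, y0 = 10)
  tr <- trace_from_waveform(w, grid_times)
  fit <- fit_sine(tr)
  expect_true(fit$converged)
  expect_equal(fit$A, 10, tolerance = 1e-6)
  expect_equal(fit$T, 6, tolerance = 1e-6)
  expect_equal(fit$tc, 0.7, tolerance = 1e-5)
  expect_equal(fit$y0, 10, tolerance = 1e-6)
  expect_equal(fit$adjusted_r2, 1, tolerance = 1e-9)
  expect_lt(fit$max_abs_residual, 1e-6)
  expect_length(fit$residuals, length(grid_times))
})

test_that("a zero trace yields the degenerate zero-amplitude fit", {
  tr <- trace_from_waveform(motion_waveform("constant", y0 = 0), grid_times)
  fit <- fit_sine(tr)
  expect_lt(fit$A, 1e-9)
  expect_false(fit$converged)
})

test_that("fitting never degrades the initial guess (monotone improvement)", {
  set.seed(501)
  for (k in 1:5) {
    w <- motion_waveform("sine", A = runif(1, 2, 12), T = runif(1, 4, 8),
                         tc = runif(1, 0, 6), y0 = runif(1, 0, 10))
    tr <- trace_from_waveform(w, grid_times)
    tr$displacement_mm <- tr$displacement_mm + rnorm(length(grid_times), 0, 0.5)
    g <- initial_guess(tr)
    sse_guess <- sum((tr$displacement_mm -
      (g$y0 + g$A * sin(2 * pi * (tr$time_s - g$tc) / g$T)))^2)
    fit <- fit_sine(tr, guess = g)
    expect_lte(fit$sse, sse_guess + 1e-9)
  }
})

test_that("the fit is invariant under time-origin translation", {
  set.seed(502)
  w <- motion_waveform("sine", A = 8, T = 6, tc = 0.9, y0 = 8)
  tr <- trace_from_waveform(w, grid_times)
  tr$displacement_mm <- tr$displacement_mm + rnorm(length(grid_times), 0, 0.3)
  f0 <- fit_sine(tr)
  delta <- 3.7
  tr2 <- tr; tr2$time_s <- tr$time_s + delta
  f1 <- fit_sine(tr2)
  expect_equal(f1$A, f0$A, tolerance = 1e-6)
  expect_equal(f1$T, f0$T, tolerance = 1e-6)
  expect_equal(f1$adjusted_r2, f0$adjusted_r2, tolerance = 1e-9)
  expect_equal((f1$tc - f0$tc) %% f0$T, delta %% f0$T, tolerance = 1e-4)
})

test_that("amplitude bias through the imaging chain stays below a third of a pixel", {
  est <- vapply(1:100, function(s) {
    process_slice(quick_study(A = 6, seed = 600 + s, matrix_px = 96))$fit$A
  }, numeric(1))
  expect_lt(abs(mean(est) - 6), 0.33)
})

test_that("a shark-fin trace fits a sinusoid worse than a sine trace", {
  r2 <- vapply(c("sine", "sharkfin"), function(kind) {
    st <- quick_study(A = 10, kind = kind, seed = 71)
    process_slice(st)$fit$adjusted_r2
  }, numeric(1))
  expect_lt(r2[["sharkfin"]], r2[["sine"]])
})

test_that("the discrepancy report carries the preset-vs-fitted columns", {
  mk_fit <- function(A, T) {
    structure(list(y0 = A, A = A, tc = 0, T = T,
                   residuals = numeric(4), fitted = numeric(4),
                   times = 1:4, data = numeric(4),
                   sd_y0 = 0.1, sd_A = 0.16, sd_tc = 0.01, sd_T = 0.017,
                   residual_sd = 0.3, max_abs_residual = 0.817,
                   r2 = 0.996, adjusted_r2 = 0.9954, sse = 0.1, n = 4,
                   converged = TRUE), class = "sine_fit")
  }
  cmp <- compare_to_preset(mk_fit(10.24, 5.983),
                           motion_waveform("sine", A = 10, T = 6))
  expect_equal(cmp$delta_A_mm, 0.24, tolerance = 1e-12)
  expect_equal(cmp$delta_T_s, -0.017, tolerance = 1e-12)
  expect_equal(cmp$adjusted_r2, 0.9954)
  # fit identical to the preset: all-zero discrepancies
  cmp0 <- compare_to_preset(mk_fit(10, 6), motion_waveform("sine", A = 10, T = 6))
  expect_equal(cmp0$delta_A_mm, 0)
  expect_equal(cmp0$delta_T_s, 0)
  # unconverged fits are refused
  bad <- mk_fit(10, 6); bad$converged <- FALSE
  expect_error(compare_to_preset(bad, motion_waveform("sine", A = 10, T = 6)),
               "converge")
})
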