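#' Parametric breathing waveform
#'
#' Constructs a periodic displacement-versus-time function used both to
#' drive the phantom simulator and as the model fitted to measured
#' respiratory traces. Three kinds are supported:
#'
#' * `"sine"`: \eqn{y(t) = y_0 + A \sin(2\pi (t - t_c)/T)}. `tc` is the time
#'   of the upward zero-crossing.
#' * `"sharkfin"`: an asymmetric surrogate breathing pattern with prolonged
#'   exhale dwell and sharp inhale peaks,
#'   \eqn{y(t) = y_0 + A (2 u(t) - 1)} with
#'   \eqn{u(t) = |\sin(\pi (t - t_c)/T)|^p}. The exponent `p` (default 4)
#'   controls the sharpness of the inhale peak. Commercial motion phantoms
#'   ship a similar pattern; the exact factory curve is proprietary, so this
#'   is a configurable stand-in with the same qualitative shape.
#' * `"constant"`: \eqn{y(t) = y_0}, for static (no-motion) studies.
#'
#' Positive displacement is anterior motion (inhale, away from the table).
#'
#' @param kind one of `"sine"`, `"sharkfin"`, `"constant"`.
#' @param A amplitude in mm (half the peak-to-peak excursion); must be >= 0.
#' @param T cycle time in seconds; must be > 0.
#' @param tc time offset in seconds (upward zero-crossing for the sine).
#' @param y0 baseline offset in mm.
#' @param sharkfin_exponent sharpness exponent `p` for the shark-fin form.
#' @return an object of class `motion_waveform`.
#' @examples
#' w <- motion_waveform("sine", A = 10, T = 6)
#' evaluate_waveform(w, c(0, 1.5, 3, 4.5))
#' @export
motion_waveform <- function(kind = c("sine", "sharkfin", "constant"),
                            A = 0, T = 6, tc = 0, y0 = 0,
                            sharkfin_exponent = 4) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(A), length(A) == 1L, is.finite(A),
            is.numeric(T), length(T) == 1L, is.finite(T),
            is.numeric(tc), length(tc) == 1L, is.finite(tc),
            is.numeric(y0), length(y0) == 1L, is.finite(y0))
  if (A < 0) stop("amplitude A must be >= 0")
  if (T <= 0) stop("cycle time T must be > 0")
  if (sharkfin_exponent <= 0) stop("sharkfin_exponent must be > 0")
  structure(
    list(kind = kind, A = A, T = T, tc = tc, y0 = y0,
         sharkfin_exponent = sharkfin_exponent),
    class = "motion_waveform"
  )
}

#' Evaluate a motion waveform at given times
#'
#' @param w a [motion_waveform()].
#' @param t numeric vector of times in seconds; must be finite.
#' @return displacement in mm, one value per element of `t`.
#' @export
evaluate_waveform <- function(w, t) {
  stopifnot(inherits(w, "motion_waveform"))
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop("times must be finite numeric values")
  }
  switch(w$kind,
    sine = w$y0 + w$A * sin(2 * pi * (t - w$tc) / w$T),
    sharkfin = {
      u <- abs(sin(pi * (t - w$tc) / w$T))^w$sharkfin_exponent
      w$y0 + w$A * (2 * u - 1)
    },
    constant = rep(w$y0, length(t))
  )
}

#' Sample a motion waveform on a time grid
#'
#' Elementwise [evaluate_waveform()]; order and length of `times` are
#' preserved.
#'
#' @param w a [motion_waveform()].
#' @param times non-empty numeric vector of times in seconds.
#' @return numeric vector of displacements in mm.
#' @export
sample_waveform <- function(w, times) {
  if (length(times) == 0L) stop("times must be non-empty")
  evaluate_waveform(w, times)
}

#' @export
print.motion_waveform <- function(x, ...) {
  cat(sprintf("<motion_waveform> kind=%s A=%.3g mm T=%.3g s tc=%.3g s y0=%.3g mm\n",
              x$kind, x$A, x$T, x$tc, x$y0))
  invisible(x)
}

#' Build a motion waveform from a configuration list
#'
#' Accepts the YAML waveform block
#' `{kind, amplitude_mm, period_s, tc_s, baseline_mm}`.
#'
#' @param cfg a named list as read from YAML.
#' @return a [motion_waveform()].
#' @export
waveform_from_config <- function(cfg) {
  stopifnot(is.list(cfg), !is.null(cfg$kind))
  motion_waveform(
    kind = cfg$kind,
    A = cfg$amplitude_mm %||% 0,
    T = cfg$period_s %||% 6,
    tc = cfg$tc_s %||% 0,
    y0 = cfg$baseline_mm %||% 0,
    sharkfin_exponent = cfg$sharkfin_exponent %||% 4
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
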