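#' One-phase exponential decay parameters
#'
#' The enzymatic phase of an amperometric measurement is modeled as
#' \deqn{I(t) = A e^{-B t} + C}
#' where `A` is the span amplitude (proportional to the analyte amount, in
#' current units), `B` the decay rate of the reaction (1/s), and `C` the
#' asymptotic current I-infinity — the value the trace stabilizes at and the
#' quantity the endpoint predictor reports. Model time `t` runs from the
#' detected onset of the decay (`t = 0` at onset), so `A` is directly the span
#' above the asymptote at onset.
#'
#' @param A Span amplitude, current units.
#' @param B Decay rate, 1/s. Must be finite; accepted fits require `B >= 0`.
#' @param C Asymptotic current, current units.
#' @return A named numeric vector of class `"decay_params"`.
#' @examples
#' p <- decay_params(10, 0.2, 2)
#' model_current(5, p)   # 10 * exp(-1) + 2
#' @export
decay_params <- function(A, B, C) {
  p <- c(A = as.numeric(A), B = as.numeric(B), C = as.numeric(C))
  if (!all(is.finite(p))) stop("decay parameters must be finite", call. = FALSE)
  structure(p, class = "decay_params")
}

#' @export
print.decay_params <- function(x, ...) {
  cat(sprintf("<decay params> A = %.6g, B = %.6g /s, C = %.6g\n",
              x[["A"]], x[["B"]], x[["C"]]))
  invisible(x)
}

as_decay_params <- function(p) {
  if (inherits(p, "decay_params")) return(p)
  p <- as.numeric(p)
  if (length(p) != 3L) stop("expected 3 decay parameters (A, B, C)", call. = FALSE)
  decay_params(p[1], p[2], p[3])
}

#' Evaluate the decay model
#'
#' @param t Time(s) in seconds since onset; vectorized.
#' @param params A [decay_params()] (or numeric `c(A, B, C)`).
#' @return `A * exp(-B * t) + C`, same length as `t`.
#' @export
model_current <- function(t, params) {
  params <- as_decay_params(params)
  if (!all(is.finite(t))) stop("`t` must be finite", call. = FALSE)
  params[["A"]] * exp(-params[["B"]] * t) + params[["C"]]
}

#' Jacobian of the decay model with respect to (A, B, C)
#'
#' Rows are \eqn{(\partial I/\partial A, \partial I/\partial B,
#' \partial I/\partial C) = (e^{-Bt}, -A t e^{-Bt}, 1)}; the building block of
#' the Levenberg-Marquardt normal equations.
#'
#' @inheritParams model_current
#' @return A `length(t) x 3` matrix with columns `A`, `B`, `C`.
#' @export
model_jacobian <- function(t, params) {
  params <- as_decay_params(params)
  if (!all(is.finite(t))) stop("`t` must be finite", call. = FALSE)
  e <- exp(-params[["B"]] * t)
  cbind(A = e, B = -params[["A"]] * t * e, C = rep(1, length(t)))
}

#' Post-onset fit window
#'
#' The buffer of samples the decay model is fitted to, with time re-based so
#' that `t[1] == 0` at the detected onset.
#'
#' @param t Times in seconds relative to onset, strictly increasing, `t[1] == 0`.
#' @param y Currents over the buffer.
#' @return A list of class `"fit_window"` with elements `t`, `y`, `length`.
#' @export
fit_window <- function(t, y) {
  t <- as.numeric(t)
  y <- as.numeric(y)
  if (length(t) != length(y)) stop("`t` and `y` lengths differ", call. = FALSE)
  if (length(t) < 1L || t[1] != 0) stop("`t` must start at 0 (onset)", call. = FALSE)
  if (length(t) > 1L && any(diff(t) <= 0)) {
    stop("`t` must be strictly increasing", call. = FALSE)
  }
  if (!all(is.finite(t)) || !all(is.finite(y))) {
    stop("fit window must be finite", call. = FALSE)
  }
  structure(list(t = t, y = y, length = length(t)), class = "fit_window")
}
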