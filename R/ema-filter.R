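#' Exponential moving average low-pass filter
#'
#' Smooths an amperogram with the recursive filter
#' \deqn{A_n = \alpha M_n + (1 - \alpha) A_{n-1}}
#' where `M_n` is the raw measurement and `A_n` the filtered value. Smaller
#' `alpha` smooths more but delays the signal; the trade-off is between
#' removing injection noise and preserving the true onset of the decay.
#'
#' The recurrence is seeded with a virtual `A_0`: by default the first raw
#' sample, so a constant signal passes through unchanged and `alpha = 1`
#' reproduces the input exactly.
#'
#' @param trace An [amperogram()] (finite values; clean first).
#' @param alpha Filter constant in `(0, 1]`. `alpha = 0` would freeze the
#'   output at the seed forever and is rejected as degenerate.
#' @param init Seed `A_0` for the recurrence; `NULL` (default) uses the first
#'   raw sample.
#' @return A filtered [amperogram()] on the same time grid; `meta$alpha`
#'   records the constant used.
#' @examples
#' tr <- amperogram(0:2, c(0, 1, 1))
#' ema_filter(tr, 0.5, init = 0)$currents   # 0, 0.5, 0.75
#' @seealso [alpha_from_p()] for the sweep schedule over filter periods.
#' @export
ema_filter <- function(trace, alpha, init = NULL) {
  stopifnot(inherits(trace, "amperogram"))
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha > 1) {
    stop("`alpha` must be a single value in (0, 1]", call. = FALSE)
  }
  y <- trace$currents
  a0 <- if (is.null(init)) y[1] else as.numeric(init)
  if (!is.finite(a0)) stop("filter seed must be finite", call. = FALSE)
  out <- as.numeric(stats::filter(alpha * y, 1 - alpha,
                                  method = "recursive", init = a0))
  meta <- trace$meta
  meta$alpha <- alpha
  amperogram(trace$times, out, dt = trace$dt, meta = meta)
}

#' Filter constant from the averaging period
#'
#' The filter sweep is parameterized by an averaging period `p` through the
#' standard exponential-moving-average relation \eqn{\alpha = 2 / (p + 1)};
#' sweeping `p` over even values 2..20 yields the ten-point alpha grid used to
#' pick the operating constant (0.22 at `p = 8`).
#'
#' @param p Averaging period, numeric `>= 1`; vectorized.
#' @param digits Optional rounding for reporting (number of decimals as
#'   printed in a summary table); `NULL` returns full precision.
#' @return `2 / (p + 1)`, optionally rounded.
#' @examples
#' alpha_from_p(8)            # 0.2222...
#' alpha_from_p(8, digits = 2)  # 0.22
#' @export
alpha_from_p <- function(p, digits = NULL) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 1)) {
    stop("`p` must be numeric >= 1", call. = FALSE)
  }
  a <- 2 / (p + 1)
  if (!is.null(digits)) a <- round(a, digits)
  a
}
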