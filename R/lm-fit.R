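#' Levenberg-Marquardt solver configuration
#'
#' @param lambda0 Initial damping, in `(0, 1]` (default 0.1).
#' @param lambda_factor Damping adjustment multiplier, `> 1` (default 10):
#'   divides lambda after an accepted step, multiplies it after a rejection.
#' @param max_iter Iteration cap (default 200).
#' @param sse_rel_tol Stop once the relative SSE decrease over an accepted
#'   step falls below this (default 1e-8) — the operational reading of
#'   "the error does not decrease anymore".
#' @param xtol Relative step-size tolerance (default 1e-10): a proposed step
#'   this small means the parameters cannot move further at machine
#'   precision, which also counts as the error no longer decreasing.
#' @param lambda_max Divergence guard on the damping (default 1e10).
#' @param damping `"identity"` adds `lambda * I` to the approximate Hessian
#'   `J'J` (the default); `"hessian_diag"` scales its diagonal instead
#'   (`lambda * diag(J'J)`, the classic Marquardt variant).
#' @return A list of class `"lm_config"`.
#' @export
lm_config <- function(lambda0 = 0.1, lambda_factor = 10, max_iter = 200L,
                      sse_rel_tol = 1e-8, xtol = 1e-10, lambda_max = 1e10,
                      damping = c("identity", "hessian_diag")) {
  damping <- match.arg(damping)
  if (!is.finite(lambda0) || lambda0 <= 0 || lambda0 > 1) {
    stop("`lambda0` must be in (0, 1]", call. = FALSE)
  }
  if (!is.finite(lambda_factor) || lambda_factor <= 1) {
    stop("`lambda_factor` must be > 1", call. = FALSE)
  }
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L) stop("`max_iter` must be >= 1", call. = FALSE)
  structure(list(lambda0 = lambda0, lambda_factor = lambda_factor,
                 max_iter = max_iter, sse_rel_tol = sse_rel_tol,
                 xtol = xtol, lambda_max = lambda_max, damping = damping),
            class = "lm_config")
}

window_sse <- function(window, params) {
  r <- window$y - model_current(window$t, params)
  sum(r * r)
}

#' Initial guess by linearization
#'
#' Seeds the nonlinear fit by transforming the decay model to a linear one:
#' given an asymptote estimate `C0`, `log(y - C0)` is linear in `t` with
#' intercept `log(A)` and slope `-B`, and ordinary least squares on the
#' transformed window gives the starting `(A, B, C)`.
#'
#' `C0` comes from the three-point property of equally spaced samples of an
#' exponential: for window values `y0, ym, y2m` at times `0, m, 2m`,
#' \deqn{C = (y_0 y_{2m} - y_m^2) / (y_0 + y_{2m} - 2 y_m)}
#' exactly. When that estimate is unusable (noise can push it to or above the
#' window minimum, or make the denominator vanish on near-linear windows),
#' `C0` falls back to `min(y) - eps * span`, which keeps the log defined at
#' the cost of a low-biased asymptote. `B` is floored at `b_floor` so the
#' seed is a decay.
#'
#' @param window A [fit_window()] of length >= 3.
#' @param eps Fraction of the span subtracted from `min(y)` in the fallback
#'   asymptote (default 0.01).
#' @param b_floor Lower bound on the seeded decay rate, 1/s (default 1e-6).
#' @return A [decay_params()].
#' @examples
#' w <- fit_window(0:14, 10 * exp(-0.2 * (0:14)) + 2)
#' initial_guess(w)
#' @export
initial_guess <- function(window, eps = 0.01, b_floor = 1e-6) {
  stopifnot(inherits(window, "fit_window"))
  if (window$length < 3L) stop("need at least 3 samples to seed a fit", call. = FALSE)
  y <- window$y
  n <- window$length
  span <- max(y) - min(y)
  if (span <= .Machine$double.eps * max(1, abs(max(y)))) {
    stop("degenerate window: constant signal, nothing to fit", call. = FALSE)
  }
  # three equally spaced anchors (1, m, 2m - 1 in sample index)
  m <- (n + 1L) %/% 2L
  y0 <- y[1]; y1 <- y[m]; y2 <- y[2L * m - 1L]
  denom <- y0 + y2 - 2 * y1
  c0 <- NA_real_
  if (abs(denom) > .Machine$double.eps * (abs(y0) + abs(y2) + 2 * abs(y1))) {
    c3 <- (y0 * y2 - y1 * y1) / denom
    if (is.finite(c3) && c3 < min(y) - 1e-3 * span && min(y) - c3 < 10 * span) {
      c0 <- c3
    }
  }
  if (!is.finite(c0)) c0 <- min(y) - eps * span
  z <- y - c0
  if (any(z <= 0)) stop("log transform undefined: window values at or below the shifted asymptote", call. = FALSE)
  coefs <- stats::lm.fit(cbind(1, window$t), log(z))$coefficients
  decay_params(A = exp(coefs[1]), B = max(-coefs[2], b_floor), C = c0)
}

#' One damped Gauss-Newton step
#'
#' Builds the Jacobian `J` of the decay model over the window, the residual
#' `E = y - f(beta)`, and solves the damped normal equations
#' \deqn{(J'J + \lambda I)\,\delta = J'E}
#' (or with `lambda * diag(J'J)` under the `"hessian_diag"` damping). The
#' candidate `beta + delta` is accepted if it does not increase the sum of
#' squared errors, in which case lambda shrinks by `lambda_factor`; otherwise
#' the candidate is discarded and lambda grows by the same factor, steering
#' the next step toward gradient descent.
#'
#' @param params Current [decay_params()].
#' @param lambda Current damping value.
#' @param window A [fit_window()].
#' @param config An [lm_config()].
#' @return A list: `params` (new or unchanged), `lambda` (updated),
#'   `accepted`, `sse` (of the returned params), `delta`, `gradient`.
#' @export
lm_step <- function(params, lambda, window, config = lm_config()) {
  stopifnot(inherits(window, "fit_window"), inherits(config, "lm_config"))
  params <- as_decay_params(params)
  J <- model_jacobian(window$t, params)
  E <- window$y - model_current(window$t, params)
  H <- crossprod(J)
  g <- crossprod(J, E)
  damp <- switch(config$damping,
                 identity = diag(3),
                 hessian_diag = diag(diag(H), 3))
  delta <- tryCatch(drop(solve(H + lambda * damp, g)),
                    error = function(e) {
                      stop("damped normal equations are singular: ",
                           conditionMessage(e), call. = FALSE)
                    })
  sse_old <- sum(E * E)
  candidate <- unclass(params) + delta
  sse_new <- if (all(is.finite(candidate))) window_sse(window, candidate) else Inf
  if (is.finite(sse_new) && sse_new <= sse_old) {
    list(params = decay_params(candidate[1], candidate[2], candidate[3]),
         lambda = lambda / config$lambda_factor, accepted = TRUE,
         sse = sse_new, delta = delta, gradient = drop(g))
  } else {
    list(params = params, lambda = lambda * config$lambda_factor,
         accepted = FALSE, sse = sse_old, delta = delta, gradient = drop(g))
  }
}

#' Fit the decay model to a window
#'
#' Iterates [lm_step()] from the linearization seed (or a supplied start)
#' until the relative SSE decrease over an accepted step drops below
#' `sse_rel_tol`, the gradient reaches machine scale, the iteration cap is
#' hit, or the damping diverges past `lambda_max`. The best parameters ever
#' seen are returned. A final decay rate `B < 0` contradicts the decay model
#' and is flagged as non-converged.
#'
#' @inheritParams lm_step
#' @param init Starting [decay_params()], or `NULL` to use [initial_guess()].
#' @return A list of class `"decay_fit"`: `params`, `sse`, `n_iter`,
#'   `converged`, `lambda_final`, and `history` (a data frame with one row per
#'   iteration: `sse`, `lambda`, `accepted`).
#' @examples
#' w <- fit_window(0:14, 10 * exp(-0.2 * (0:14)) + 2)
#' fit <- lm_fit(w)
#' fit$params
#' @export
lm_fit <- function(window, config = lm_config(), init = NULL) {
  stopifnot(inherits(window, "fit_window"), inherits(config, "lm_config"))
  if (window$length < 3L) stop("need at least 3 samples to fit", call. = FALSE)
  params <- if (is.null(init)) initial_guess(window) else as_decay_params(init)
  lambda <- config$lambda0
  sse <- window_sse(window, params)
  best_params <- params
  best_sse <- sse

  gtol <- .Machine$double.eps^(2 / 3)
  grad_small <- function(g, s) max(abs(g)) <= gtol * (1 + s)

  hist_sse <- numeric(0)
  hist_lambda <- numeric(0)
  hist_accepted <- logical(0)
  converged <- FALSE
  n_iter <- 0L

  g0 <- crossprod(model_jacobian(window$t, params),
                  window$y - model_current(window$t, params))
  if (grad_small(g0, sse)) converged <- TRUE

  while (!converged && n_iter < config$max_iter) {
    step <- lm_step(params, lambda, window, config)
    n_iter <- n_iter + 1L
    hist_sse <- c(hist_sse, step$sse)
    hist_lambda <- c(hist_lambda, step$lambda)
    hist_accepted <- c(hist_accepted, step$accepted)
    if (step$accepted) {
      rel_dec <- (sse - step$sse) / max(sse, .Machine$double.xmin)
      params <- step$params
      sse <- step$sse
      if (sse < best_sse) {
        best_sse <- sse
        best_params <- params
      }
      if (rel_dec < config$sse_rel_tol || sse == 0) converged <- TRUE
    } else {
      if (max(abs(step$delta)) <= config$xtol * (1 + max(abs(unclass(params))))) {
        # the step has collapsed to machine zero: nothing left to gain
        converged <- TRUE
        lambda <- step$lambda
        break
      }
      if (step$lambda > config$lambda_max) {
        # the error no longer decreases even under near-gradient-descent steps
        converged <- grad_small(step$gradient, sse)
        break
      }
    }
    lambda <- step$lambda
  }

  if (best_params[["B"]] < 0) converged <- FALSE
  structure(
    list(params = best_params, sse = best_sse, n_iter = n_iter,
         converged = converged, lambda_final = lambda,
         history = data.frame(sse = hist_sse, lambda = hist_lambda,
                              accepted = hist_accepted)),
    class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay fit> A = %.6g, B = %.6g /s, C = %.6g | SSE = %.4g, %d iteration(s), %s\n",
    x$params[["A"]], x$params[["B"]], x$params[["C"]], x$sse, x$n_iter,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
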