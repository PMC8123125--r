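#' Read an amperogram from CSV
#'
#' Expects a header `time_s,current` and numeric rows; the parsed series is
#' screened with [clean_trace()] and a rejection is raised as an error naming
#' the reason (and offending data lines where known).
#'
#' @param path CSV file path.
#' @param dt Expected sampling interval, s (default 1).
#' @param ... Passed to [clean_trace()] (e.g. `gap_max`, `min_len`).
#' @return An [amperogram()].
#' @export
read_trace <- function(path, dt = 1, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "current") %in% names(df))) {
    stop("`", path, "`: expected columns time_s,current; found: ",
         paste(names(df), collapse = ","), call. = FALSE)
  }
  for (col in c("time_s", "current")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !is.na(v))
      if (length(bad)) {
        stop("`", path, "`: non-numeric ", col, " at data line(s) ",
             paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
      }
      df[[col]] <- parsed
    }
  }
  res <- clean_trace(df$time_s, df$current, dt = dt, ...,
                     meta = list(source = path))
  if (is_rejected(res)) {
    detail <- if (!is.null(res$detail) && length(res$detail)) {
      paste0(" (data line(s) ", paste(utils::head(res$detail, 5), collapse = ", "), ")")
    } else ""
    stop("`", path, "`: trace rejected: ", res$reason, detail, call. = FALSE)
  }
  res
}

#' Write an amperogram to CSV
#'
#' @param trace An [amperogram()].
#' @param path Output path; columns `time_s,current`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "amperogram"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

outcome_to_list <- function(o) {
  l <- list(
    status = o$status,
    reason = if (is.na(o$reason)) NULL else o$reason,
    onset_time = o$onset_time,
    trace_duration = o$trace_duration,
    window_size = o$window_size,
    I_estimated = o$I_estimated,
    I_real = o$I_real,
    pe = o$pe,
    saved_time = o$saved_time,
    params = if (!is.null(o$fit)) as.list(unclass(o$fit$params)) else NULL
  )
  l[!vapply(l, is.null, logical(1))]
}

#' Write pipeline outcomes as JSON lines
#'
#' One JSON object per trace, stable field order; round-trips through
#' [read_outcomes()].
#'
#' @param outcomes List of `"stream_outcome"`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_outcomes <- function(outcomes, path) {
  lines <- vapply(outcomes, function(o) {
    as.character(jsonlite::toJSON(outcome_to_list(o), auto_unbox = TRUE,
                                  na = "null", digits = NA))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read pipeline outcomes from a JSON-lines file
#'
#' @param path File written by [write_outcomes()].
#' @return A list of `"stream_outcome"`s (without the full onset/fit
#'   objects; fitted parameters are restored when present).
#' @export
read_outcomes <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
    fit <- NULL
    if (!is.null(x$params)) {
      fit <- structure(list(params = decay_params(x$params$A, x$params$B,
                                                  x$params$C),
                            sse = NA_real_, n_iter = NA_integer_,
                            converged = TRUE, lambda_final = NA_real_,
                            history = NULL),
                       class = "decay_fit")
    }
    stream_outcome(
      status = x$status,
      reason = if (is.null(x$reason)) NA_character_ else x$reason,
      fit = fit,
      I_estimated = num(x$I_estimated), I_real = num(x$I_real),
      pe = num(x$pe), saved_time = num(x$saved_time),
      onset_time = num(x$onset_time), trace_duration = num(x$trace_duration),
      window_size = if (is.null(x$window_size)) NA_integer_ else as.integer(x$window_size))
  })
}

#' Default run configuration
#'
#' The method's operating point: filter constant alpha = 0.22 (period p = 8),
#' a 15-sample fit buffer, LM damping starting at 0.1 with adjustment
#' factor 10.
#'
#' @return A nested named list with sections `filter`, `onset`, `lm`,
#'   `estimator`.
#' @export
default_config <- function() {
  list(
    filter = list(alpha = 0.22, p = NULL),
    onset = list(confirm_k = 3L, rise_eps = 0, min_drop = 0),
    lm = list(lambda0 = 0.1, factor = 10, max_iter = 200L, tol = 1e-8,
              lambda_max = 1e10, damping = "identity"),
    estimator = list(window_size = 15L, endpoint_mode = "asymptote",
                     drop_guard_k = 6, baseline_n = 10L)
  )
}

overlay_config <- function(base, user, prefix = "") {
  for (nm in names(user)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (!nm %in% names(base)) {
      stop("unknown config key: `", key, "`", call. = FALSE)
    }
    if (is.list(base[[nm]]) && !is.null(user[[nm]])) {
      if (!is.list(user[[nm]])) {
        stop("config key `", key, "` must be a section", call. = FALSE)
      }
      base[[nm]] <- overlay_config(base[[nm]], user[[nm]], key)
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Load a run configuration
#'
#' Reads a YAML (or JSON — YAML is a superset) file and overlays it on
#' [default_config()]. Unknown keys fail closed, naming the key; invariant
#' violations name the offending value. Giving `filter.p` computes
#' `filter.alpha` via [alpha_from_p()].
#'
#' @param path Config file path, or `NULL` for pure defaults.
#' @return A validated config list as in [default_config()].
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    cfg <- overlay_config(cfg, user)
  }
  if (!is.null(cfg$filter$p)) cfg$filter$alpha <- alpha_from_p(cfg$filter$p)
  a <- cfg$filter$alpha
  if (!is.numeric(a) || a <= 0 || a > 1) {
    stop("config error: filter.alpha must be in (0, 1], got ", a, call. = FALSE)
  }
  l0 <- cfg$lm$lambda0
  if (!is.numeric(l0) || l0 <= 0 || l0 > 1) {
    stop("config error: lm.lambda0 must be in (0, 1], got ", l0, call. = FALSE)
  }
  if (cfg$lm$factor <= 1) {
    stop("config error: lm.factor must be > 1", call. = FALSE)
  }
  if (cfg$estimator$window_size < 3) {
    stop("config error: estimator.window_size must be >= 3", call. = FALSE)
  }
  if (cfg$onset$confirm_k < 1) {
    stop("config error: onset.confirm_k must be >= 1", call. = FALSE)
  }
  cfg
}

#' Build an estimator config from a run configuration
#'
#' @param cfg A list from [load_config()] / [default_config()].
#' @return An [estimator_config()].
#' @export
as_estimator_config <- function(cfg) {
  estimator_config(
    window_size = cfg$estimator$window_size,
    alpha = cfg$filter$alpha,
    onset = onset_config(cfg$onset$confirm_k, cfg$onset$rise_eps,
                         cfg$onset$min_drop),
    lm = lm_config(lambda0 = cfg$lm$lambda0, lambda_factor = cfg$lm$factor,
                   max_iter = cfg$lm$max_iter, sse_rel_tol = cfg$lm$tol,
                   lambda_max = cfg$lm$lambda_max, damping = cfg$lm$damping),
    endpoint_mode = cfg$estimator$endpoint_mode,
    drop_guard_k = cfg$estimator$drop_guard_k,
    baseline_n = cfg$estimator$baseline_n
  )
}
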