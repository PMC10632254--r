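# Core waveform container and resampling.

ws_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "wavesep_error", "error", "condition")))
}

#' Single-beat waveform
#'
#' Container for a sampled single-beat signal: aortic flow, velocity,
#' pressure, or cross-sectional area (the latter usable as an uncalibrated
#' pressure surrogate).
#'
#' @param t Time samples in ms, strictly increasing.
#' @param v Signal values; arbitrary units for uncalibrated flow/area,
#'   mmHg for calibrated pressure, cm/s for velocity.
#' @param kind One of `"flow"`, `"velocity"`, `"pressure"`, `"area"`.
#' @param cycle_length Cardiac cycle length in ms; defaults to the sampled
#'   span `t[length(t)] - t[1]`. Must be at least the sampled span.
#'
#' @return An object of class `"waveform"`: a list with elements `t`, `v`,
#'   `kind`, `cycle_length`.
#' @examples
#' tt <- seq(0, 800, length.out = 128)
#' w <- waveform(tt, pmax(sin(pi * tt / 300), 0), "flow")
#' @export
waveform <- function(t, v, kind = c("flow", "velocity", "pressure", "area"),
                     cycle_length = NULL) {
  kind <- match.arg(kind)
  t <- as.numeric(t)
  v <- as.numeric(v)
  if (length(t) != length(v)) {
    ws_stop("time and value vectors must have equal length", "ws_invalid_input")
  }
  if (length(t) < 16) {
    ws_stop("a waveform needs at least 16 samples", "ws_invalid_input")
  }
  if (!all(is.finite(t)) || !all(is.finite(v))) {
    ws_stop("waveform samples must all be finite", "ws_invalid_input")
  }
  if (any(diff(t) <= 0)) {
    ws_stop("time vector must be strictly increasing", "ws_invalid_input")
  }
  span <- t[length(t)] - t[1]
  if (is.null(cycle_length)) cycle_length <- span
  if (!is.finite(cycle_length) || cycle_length < span - 1e-9) {
    ws_stop("cycle_length must be >= the sampled time span", "ws_invalid_input")
  }
  structure(list(t = t, v = v, kind = kind, cycle_length = cycle_length),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %s, %d samples, %.1f-%.1f ms, cycle %.1f ms>\n",
              x$kind, length(x$t), x$t[1], x$t[length(x$t)], x$cycle_length))
  invisible(x)
}

is_waveform <- function(x) inherits(x, "waveform")

stopifnot_waveform <- function(x, arg = "w") {
  if (!is_waveform(x)) {
    ws_stop(sprintf("`%s` must be a waveform object", arg), "ws_invalid_input")
  }
  invisible(x)
}

# Interpolate waveform values at arbitrary times. `method` "spline" is the
# classical C2 cubic spline (exact on cubic polynomials); "pchip" is the
# shape-preserving Hermite alternative (no overshoot at the dicrotic notch);
# "linear" for strictly local behaviour.
interp_values <- function(t, v, t_out, method = c("spline", "pchip", "linear")) {
  method <- match.arg(method)
  switch(method,
    spline = stats::spline(t, v, xout = t_out, method = "fmm")$y,
    pchip  = pracma::pchip(t, v, t_out),
    linear = stats::approx(t, v, xout = t_out, rule = 2)$y
  )
}

#' Resample a waveform on a uniform time grid
#'
#' Piecewise-cubic interpolation of the beat onto `n_points` uniformly
#' spaced samples spanning the original time range. Endpoints are
#' reproduced exactly.
#'
#' @param w A [waveform()].
#' @param n_points Number of output samples (at least 16).
#' @param method Interpolation scheme: `"spline"` (default, classical cubic
#'   spline, exact on polynomials up to degree 3) or `"pchip"`
#'   (shape-preserving piecewise cubic Hermite).
#'
#' @return A [waveform()] on the uniform grid.
#' @export
resample_uniform <- function(w, n_points, method = c("spline", "pchip")) {
  stopifnot_waveform(w)
  method <- match.arg(method)
  if (!is.numeric(n_points) || length(n_points) != 1 || n_points < 16) {
    ws_stop("n_points must be a single number >= 16", "ws_invalid_input")
  }
  n_points <- as.integer(n_points)
  t_out <- seq(w$t[1], w$t[length(w$t)], length.out = n_points)
  v_out <- interp_values(w$t, w$v, t_out, method)
  # endpoints exactly
  v_out[1] <- w$v[1]
  v_out[n_points] <- w$v[length(w$v)]
  waveform(t_out, v_out, w$kind, w$cycle_length)
}

# trapezoidal integral of sampled signal
trapz_int <- function(t, v) {
  sum(diff(t) * (v[-length(v)] + v[-1]) / 2)
}

#' Read a waveform from CSV or JSON
#'
#' CSV files carry two named columns `time_ms,value`; JSON files carry
#' fields `t`, `v`, `kind` and `cycle_length_ms`.
#'
#' @param path File path; format chosen by extension (`.json` vs anything
#'   else treated as CSV).
#' @param kind Signal kind used for CSV input (JSON carries its own).
#' @return A [waveform()].
#' @export
read_waveform <- function(path, kind = "flow") {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path)
    for (f in c("t", "v")) {
      if (is.null(obj[[f]])) {
        ws_stop(sprintf("waveform JSON is missing field '%s'", f), "ws_format_error")
      }
    }
    return(waveform(obj$t, obj$v,
                    kind = if (!is.null(obj$kind)) obj$kind else kind,
                    cycle_length = obj$cycle_length_ms))
  }
  d <- utils::read.csv(path)
  if (!all(c("time_ms", "value") %in% names(d))) {
    ws_stop("waveform CSV must have columns 'time_ms' and 'value'", "ws_format_error")
  }
  waveform(d$time_ms, d$value, kind)
}

#' Write a waveform to CSV or JSON
#'
#' @param w A [waveform()].
#' @param path Output path; `.json` selects the JSON representation,
#'   anything else the two-column `time_ms,value` CSV.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(w, path) {
  stopifnot_waveform(w)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(t = w$t, v = w$v, kind = w$kind, cycle_length_ms = w$cycle_length),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("time_ms,value", con)
    writeLines(sprintf("%.17g,%.17g", w$t, w$v), con)
  }
  invisible(path)
}
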