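# Virtual Doppler ultrasound: sample-volume placement, envelope/mean/peak
# velocity traces from a cross-sectional velocity field, and trace
# post-processing.

#' Cross-sectional velocity field
#'
#' Time series of through-plane velocities on a 2-D pixel grid with a
#' lumen mask, as produced by phase-contrast imaging segmentation or by
#' [simulate_velocity_field()].
#'
#' @param t Frame times (ms).
#' @param x,y Pixel-centre coordinates (mm), uniformly spaced.
#' @param u Velocity array (cm/s), dim `c(length(x), length(y), length(t))`.
#' @param mask Logical lumen-membership array, either per-frame with the
#'   same dim as `u` or a static `length(x) x length(y)` matrix.
#' @return Object of class `"velocity_field"`; `pixel_area` (mm^2) is
#'   derived from the grid spacing.
#' @export
velocity_field <- function(t, x, y, u, mask) {
  if (!is.array(u) || length(dim(u)) != 3 ||
      !all(dim(u) == c(length(x), length(y), length(t)))) {
    ws_stop("u must be an array of dim (length(x), length(y), length(t))",
            "ws_invalid_input")
  }
  if (is.matrix(mask)) {
    mask <- array(mask, dim = dim(u))
  }
  if (!all(dim(mask) == dim(u))) {
    ws_stop("mask must match the velocity array dimensions", "ws_invalid_input")
  }
  if (!all(is.finite(u))) {
    ws_stop("velocities must all be finite", "ws_invalid_input")
  }
  for (k in seq_along(t)) {
    if (!any(mask[, , k])) {
      ws_stop(sprintf("frame %d has an empty lumen mask", k), "ws_invalid_input")
    }
  }
  pixel_area <- mean(diff(x)) * mean(diff(y))
  structure(list(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
                 u = u, mask = mask > 0, pixel_area = pixel_area),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity field: %dx%d px (%.2f mm2/px), %d frames>\n",
              length(x$x), length(x$y), x$pixel_area, length(x$t)))
  invisible(x)
}

#' Place the virtual Doppler sample volume
#'
#' A square sample volume whose side covers `coverage` of the minimum
#' effective lumen diameter over the beat, centred at the time-averaged
#' lumen centroid. The effective diameter of a frame is `2*sqrt(A/pi)`
#' with `A` the lumen area (mask pixel count times pixel area).
#'
#' @param vf A [velocity_field()].
#' @param coverage Fraction of the minimum effective diameter (default 0.5).
#' @return List with `center` (x, y in mm), `side` (mm), and the
#'   per-frame `diameter` series.
#' @export
place_sample_volume <- function(vf, coverage = 0.5) {
  if (!inherits(vf, "velocity_field")) {
    ws_stop("vf must be a velocity_field", "ws_invalid_input")
  }
  nt <- length(vf$t)
  diam <- numeric(nt)
  cx <- numeric(nt); cy <- numeric(nt)
  for (k in seq_len(nt)) {
    mk <- vf$mask[, , k]
    area <- sum(mk) * vf$pixel_area
    diam[k] <- 2 * sqrt(area / pi)
    idx <- which(mk, arr.ind = TRUE)
    cx[k] <- mean(vf$x[idx[, 1]])
    cy[k] <- mean(vf$y[idx[, 2]])
  }
  list(center = c(x = mean(cx), y = mean(cy)),
       side = coverage * min(diam), diameter = diam)
}

# percentile with linear interpolation between order statistics
pctl <- function(x, p) stats::quantile(x, probs = p, names = FALSE, type = 7)

#' Extract virtual Doppler traces
#'
#' Per frame: `dop_env` is the 95th percentile of velocity over the pixels
#' whose centres fall inside the sample volume (intersected with the
#' lumen), emulating a Doppler envelope trace; `dop_mean` is the mean over
#' the same pixels; `peak_u` is the 95th percentile over the whole lumen
#' (an ideal sample volume covering the entire lumen); `true_mean` is the
#' lumen mean (the velocity equivalent of volumetric flow). Percentiles
#' interpolate linearly between order statistics.
#'
#' @param vf A [velocity_field()].
#' @param sv A [place_sample_volume()] result.
#' @return Object of class `"doppler_traces"`: list of four velocity
#'   [waveform()]s (`dop_env`, `dop_mean`, `peak_u`, `true_mean`) sharing
#'   the frame time base, plus `sample_volume`.
#' @export
extract_traces <- function(vf, sv) {
  if (!inherits(vf, "velocity_field")) {
    ws_stop("vf must be a velocity_field", "ws_invalid_input")
  }
  nt <- length(vf$t)
  in_sq_x <- abs(vf$x - sv$center["x"]) <= sv$side / 2
  in_sq_y <- abs(vf$y - sv$center["y"]) <= sv$side / 2
  sq <- outer(in_sq_x, in_sq_y, "&")
  env <- mn <- pk <- tm <- numeric(nt)
  for (k in seq_len(nt)) {
    mk <- vf$mask[, , k]
    uin <- vf$u[, , k][sq & mk]
    if (!length(uin)) {
      ws_stop(sprintf("sample volume misses the lumen in frame %d", k),
              "ws_coverage_error")
    }
    ulum <- vf$u[, , k][mk]
    env[k] <- pctl(uin, 0.95)
    mn[k] <- mean(uin)
    pk[k] <- pctl(ulum, 0.95)
    tm[k] <- mean(ulum)
  }
  mk_w <- function(v) waveform(vf$t, v, "velocity")
  structure(list(dop_env = mk_w(env), dop_mean = mk_w(mn),
                 peak_u = mk_w(pk), true_mean = mk_w(tm),
                 sample_volume = sv),
            class = "doppler_traces")
}

#' Post-process a Doppler-derived velocity trace
#'
#' Doppler envelope traces tend to sit above zero during diastole. The
#' trace is offset so that its end-diastolic level at beat onset (the
#' floor of the trace up to the upstroke foot) is zero, then zeroed from
#' its post-systolic zero return through the beat end; a trace that never
#' returns to zero is left uncut. Any flow-reversal lobe after the zero
#' return is dropped with the diastole, mirroring the envelope's
#' inability to capture reversal. Idempotent on traces that are already
#' zero in diastole.
#'
#' @param w Velocity [waveform()] (a trace).
#' @param lm Optional landmarks; detected from the trace itself when
#'   `NULL`.
#' @return The cleaned velocity [waveform()].
#' @export
postprocess_trace <- function(w, lm = NULL) {
  stopifnot_waveform(w)
  if (is.null(lm)) lm <- detect_landmarks(w)
  # end-diastolic level: the floor of the trace up to the upstroke foot
  v0 <- min(w$v[w$t <= lm$t_onset], w$v[1])
  v <- w$v - v0
  # diastolic cut: zero from the offset trace's first non-positive sample
  # after the systolic peak (its zero return). Grid-level and idempotent;
  # also drops any residual flow-reversal lobe, which Doppler envelope
  # traces cannot capture anyway.
  n <- length(v)
  ipk <- which.max(v)
  icut <- which(v <= 0 & seq_len(n) > ipk)
  if (length(icut)) v[icut[1]:n] <- 0
  waveform(w$t, v, w$kind, w$cycle_length)
}

#' Read / write a velocity field (JSON bundle)
#'
#' Plain-text JSON with grid coordinates, frame times, and flattened
#' velocity and mask arrays (column-major).
#'
#' @param vf A [velocity_field()].
#' @param path JSON file path.
#' @return `path` invisibly (write); a [velocity_field()] (read).
#' @export
write_velocity_field <- function(vf, path) {
  jsonlite::write_json(list(
    t = vf$t, x = vf$x, y = vf$y,
    u = as.numeric(vf$u), mask = as.integer(vf$mask)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_velocity_field
#' @export
read_velocity_field <- function(path) {
  obj <- jsonlite::fromJSON(path)
  for (f in c("t", "x", "y", "u", "mask")) {
    if (is.null(obj[[f]])) {
      ws_stop(sprintf("velocity field JSON is missing field '%s'", f),
              "ws_format_error")
    }
  }
  d <- c(length(obj$x), length(obj$y), length(obj$t))
  velocity_field(obj$t, obj$x, obj$y, array(obj$u, d),
                 array(obj$mask > 0, d))
}
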