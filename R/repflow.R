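# Representative flow waveform: two-anchor time normalization, cohort
# averaging with Savitzky-Golay smoothing and a late-diastolic ramp, and
# de-normalization back onto an individual beat.

#' Common normalized-time grid
#'
#' Normalized time tau places the 50%-upstroke crossing at 0 and
#' end-systole at 1. The default grid of 1000 points spans tau in
#' [-0.3, 2.5], covering pre-foot through late diastole at all
#' physiological heart rates.
#'
#' @param n Number of grid points.
#' @param range Two-element tau range.
#' @return Numeric vector of tau values.
#' @export
tau_grid <- function(n = 1000, range = c(-0.3, 2.5)) {
  seq(range[1], range[2], length.out = n)
}

#' Normalize a beat in amplitude and time
#'
#' Divides by the peak value (peak becomes 1.0; the 50%-upstroke anchor is
#' 0.5 by construction) and maps time affinely so that the 50%-upstroke
#' crossing sits at tau = 0 and end-systole at tau = 1, then resamples onto
#' a common tau grid. Outside the beat's own tau range, values are extended
#' with the beat's boundary values (diastolic flow is near zero).
#'
#' @param w Flow or velocity [waveform()].
#' @param lm Optional [detect_landmarks()] result; detected from `w` when
#'   `NULL`.
#' @param grid Common tau grid from [tau_grid()].
#' @param method Interpolation scheme, see [resample_uniform()].
#' @return Object of class `"normalized_waveform"`: list with `tau`, `v`,
#'   `anchors` (times mapped to 0 and 1), and `peak_value` (the original
#'   amplitude divided out).
#' @export
normalize_beat <- function(w, lm = NULL, grid = tau_grid(),
                           method = c("spline", "pchip")) {
  stopifnot_waveform(w)
  method <- match.arg(method)
  if (is.null(lm)) lm <- detect_landmarks(w)
  if (lm$t_es - lm$t_50up <= .Machine$double.eps * max(1, abs(lm$t_es))) {
    ws_stop("degenerate beat: end-systole coincides with the 50%-upstroke time",
            "ws_degenerate_beat")
  }
  vmax <- max(w$v)
  tau_in <- (w$t - lm$t_50up) / (lm$t_es - lm$t_50up)
  vn <- w$v / vmax
  v_out <- rep(NA_real_, length(grid))
  inside <- grid >= tau_in[1] & grid <= tau_in[length(tau_in)]
  v_out[inside] <- interp_values(tau_in, vn, grid[inside], method)
  v_out[grid < tau_in[1]] <- vn[1]
  v_out[grid > tau_in[length(tau_in)]] <- vn[length(vn)]
  structure(list(tau = grid, v = v_out,
                 anchors = c(t_50up = lm$t_50up, t_es = lm$t_es),
                 peak_value = vmax),
            class = "normalized_waveform")
}

# Savitzky-Golay smoothing with window expressed in tau units; polynomial
# order 3, window forced to the nearest odd sample count (minimum 5).
sg_smooth <- function(v, dtau, span, order = 3) {
  n_win <- round(span / dtau)
  if (n_win %% 2 == 0) n_win <- n_win + 1
  n_win <- max(n_win, order + 2 + (order %% 2 == 0))
  if (n_win %% 2 == 0) n_win <- n_win + 1
  if (n_win >= length(v)) {
    ws_stop("smoothing window exceeds the signal length", "ws_invalid_input")
  }
  as.numeric(signal::sgolayfilt(v, p = order, n = n_win))
}

# First return to zero of the mean waveform after its end-systolic
# minimum, as a tau value; falls back to the last grid point.
zero_return_tau <- function(tau, v) {
  ipk <- which.max(v)
  n <- length(v)
  ies <- NA_integer_
  if (ipk + 1 <= n - 1) {
    for (i in seq(ipk + 1, n - 1)) {
      if (v[i] < v[i - 1] && v[i] <= v[i + 1]) { ies <- i; break }
    }
  }
  if (is.na(ies)) ies <- ipk + which.min(v[seq(ipk + 1, n)])
  tol <- 1e-3 * max(abs(v))
  if (v[ies] < 0) {
    for (i in seq(ies, n - 1)) {
      if (v[i] <= 0 && v[i + 1] >= 0) return(tau[i + 1])
    }
  } else {
    for (i in seq(ies, n)) {
      if (v[i] <= tol) return(tau[i])
    }
  }
  tau[n]
}

#' Build the representative flow waveform from a cohort
#'
#' Averages amplitude- and time-normalized flow waveforms pointwise,
#' smooths the average with a Savitzky-Golay filter (polynomial order 3)
#' spanning `smooth_span` normalized time units, and enforces zero flow in
#' late diastole by multiplying with a three-segment weighting function:
#' 1.0 until the mean waveform first returns to zero after its
#' end-systolic minimum, then a linear ramp from 1.0 to 0.0 over
#' `ramp_len` tau units, then 0.0. The 5th/95th percentile envelopes are
#' computed from the unsmoothed, unramped inputs.
#'
#' @param ws List of [normalize_beat()] results on one common grid
#'   (at least 2).
#' @param smooth_span Savitzky-Golay window in tau units (default 0.125).
#' @param ramp_len Ramp duration in tau units (default 0.6).
#' @return Object of class `"representative_waveform"`: list with `tau`,
#'   `v`, `n_contributors`, `ci_lo`, `ci_hi`, `ensemble_mean` (unsmoothed,
#'   unramped), `ramp_start` (tau of zero return) and `ramp_len`.
#' @export
build_representative <- function(ws, smooth_span = 0.125, ramp_len = 0.6) {
  if (!is.list(ws) || length(ws) < 2 ||
      !all(vapply(ws, inherits, TRUE, "normalized_waveform"))) {
    ws_stop("need a list of at least 2 normalized waveforms", "ws_invalid_input")
  }
  tau <- ws[[1]]$tau
  for (w in ws[-1]) {
    if (length(w$tau) != length(tau) || max(abs(w$tau - tau)) > 1e-12) {
      ws_stop("all normalized waveforms must share one tau grid", "ws_invalid_input")
    }
  }
  m <- vapply(ws, function(w) w$v, numeric(length(tau)))
  mean_v <- rowMeans(m)
  ci <- apply(m, 1, stats::quantile, probs = c(0.05, 0.95), names = FALSE,
              type = 7)
  dtau <- tau[2] - tau[1]
  sm <- sg_smooth(mean_v, dtau, smooth_span)
  tau0 <- zero_return_tau(tau, sm)
  wgt <- rep(1, length(tau))
  ramp_zone <- tau > tau0 & tau < tau0 + ramp_len
  wgt[ramp_zone] <- 1 - (tau[ramp_zone] - tau0) / ramp_len
  wgt[tau >= tau0 + ramp_len] <- 0
  structure(list(tau = tau, v = sm * wgt, n_contributors = length(ws),
                 ci_lo = ci[1, ], ci_hi = ci[2, ], ensemble_mean = mean_v,
                 ramp_start = tau0, ramp_len = ramp_len),
            class = "representative_waveform")
}

#' @export
print.representative_waveform <- function(x, ...) {
  cat(sprintf("<representative waveform: %d contributors, %d tau points, ramp %.2f-%.2f>\n",
              x$n_contributors, length(x$tau), x$ramp_start,
              x$ramp_start + x$ramp_len))
  invisible(x)
}

#' De-normalize a representative waveform onto an individual beat
#'
#' Inverse of the two-anchor time normalization: aligns tau = 0 with the
#' individual's 50%-upstroke time and tau = 1 with its end-systolic time
#' (landmarks typically detected from the subject's measured flow, or from
#' a pressure/area waveform in a pressure-only deployment), then resamples
#' onto the requested time grid. The amplitude stays at the normalized
#' scale: wave separation indices depend only on the flow waveform's
#' shape. Outside the representative waveform's tau support the output is
#' zero.
#'
#' @param rep A [build_representative()] result (or anything with `tau`
#'   and `v` fields, e.g. a loaded external normalized waveform).
#' @param lm [detect_landmarks()] result for the target beat.
#' @param grid Numeric vector of output times (ms).
#' @param method Interpolation scheme.
#' @return A flow [waveform()] on `grid`.
#' @export
denormalize_representative <- function(rep, lm, grid,
                                       method = c("spline", "pchip")) {
  method <- match.arg(method)
  if (is.null(rep$tau) || is.null(rep$v)) {
    ws_stop("rep must carry tau and v fields", "ws_invalid_input")
  }
  scale <- lm$t_es - lm$t_50up
  if (!is.finite(scale) || scale <= 0) {
    ws_stop("landmarks must satisfy t_es > t_50up", "ws_invalid_input")
  }
  tau_target <- (grid - lm$t_50up) / scale
  v <- rep(0, length(grid))
  inside <- tau_target >= rep$tau[1] & tau_target <= rep$tau[length(rep$tau)]
  if (any(inside)) {
    v[inside] <- interp_values(rep$tau, rep$v, tau_target[inside], method)
  }
  waveform(grid, v, "flow")
}

#' Write / read a representative waveform as two-column CSV
#'
#' The on-disk form is a `tau,value` table (full double precision), the
#' same shape as an externally supplied normalized waveform.
#'
#' @param rep A [build_representative()] result.
#' @param path Output CSV path.
#' @return `path` invisibly (write); a minimal representative-waveform
#'   object with `tau` and `v` (read).
#' @export
write_representative <- function(rep, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("tau,value", con)
  writeLines(sprintf("%.17g,%.17g", rep$tau, rep$v), con)
  invisible(path)
}

#' @rdname write_representative
#' @export
read_representative <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("tau", "value") %in% names(d))) {
    ws_stop("representative waveform CSV must have columns 'tau' and 'value'",
            "ws_format_error")
  }
  structure(list(tau = d$tau, v = d$value, n_contributors = NA_integer_),
            class = "representative_waveform")
}

#' Landmarks from a pressure or area waveform
#'
#' For pressure-only deployments with no measured flow: subtracts the
#' waveform minimum and applies the flow landmark logic, so end-systole is
#' the first post-peak local minimum (the dicrotic notch) of the pressure
#' or area signal.
#'
#' @param p Pressure or area [waveform()].
#' @inheritParams detect_landmarks
#' @return A `"beat_landmarks"` object.
#' @export
pressure_landmarks <- function(p, onset_frac = 0.05, es_window_frac = 0.6) {
  stopifnot_waveform(p, "p")
  detect_landmarks(waveform(p$t, p$v - min(p$v), "flow", p$cycle_length),
                   onset_frac = onset_frac, es_window_frac = es_window_frac)
}

#' Leave-one-out cross-validation of the representative waveform
#'
#' For each subject, builds a representative waveform from all other
#' subjects' flows, de-normalizes it onto that subject's beat, runs wave
#' separation with both the measured flow (reference) and the
#' representative flow (estimate), and tabulates the errors via
#' [compare_separations()]. The left-out subject's flow never contributes
#' to its own representative.
#'
#' @param flows List of measured flow [waveform()]s (>= 3).
#' @param pressures List of paired pressure/area [waveform()]s, same
#'   length and time grids.
#' @param grid Common tau grid.
#' @param smooth_span,ramp_len Passed to [build_representative()].
#' @param landmarks_from `"flow"` (default) to anchor the de-normalization
#'   with the measured-flow landmarks, `"pressure"` to emulate a
#'   pressure-only deployment via [pressure_landmarks()].
#' @return data.frame with one row per subject: reference and estimated
#'   RM and Tr, signed and absolute percent errors, component RMSEs, and
#'   the number of contributors to each representative.
#' @export
loo_cross_validate <- function(flows, pressures, grid = tau_grid(),
                               smooth_span = 0.125, ramp_len = 0.6,
                               landmarks_from = c("flow", "pressure")) {
  landmarks_from <- match.arg(landmarks_from)
  n <- length(flows)
  if (n < 3 || length(pressures) != n) {
    ws_stop("need at least 3 paired flow/pressure waveforms", "ws_invalid_input")
  }
  lms <- lapply(flows, detect_landmarks)
  norms <- mapply(function(w, lm) normalize_beat(w, lm, grid), flows, lms,
                  SIMPLIFY = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rep_i <- build_representative(norms[-i], smooth_span = smooth_span,
                                  ramp_len = ramp_len)
    lm_i <- if (landmarks_from == "flow") lms[[i]] else
      pressure_landmarks(pressures[[i]])
    q_hat <- denormalize_representative(rep_i, lm_i, flows[[i]]$t)
    ref <- separate_waves(pressures[[i]], flows[[i]])
    est <- separate_waves(pressures[[i]], q_hat)
    row <- compare_separations(ref, est)
    row$subject <- i
    row$n_contributors <- rep_i$n_contributors
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  out[, c("subject", setdiff(names(out), "subject"))]
}
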