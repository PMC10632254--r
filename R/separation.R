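# Characteristic impedance, forward/backward decomposition, reflection
# magnitude and centroid-method return time.

same_grid <- function(a, b) {
  length(a$t) == length(b$t) && max(abs(a$t - b$t)) <= 1e-9
}

#' Estimate characteristic impedance from the early-systolic P-Q relation
#'
#' Fits a least-squares line to pressure (or its area surrogate) against
#' flow over the early systolic upstroke, the segment least contaminated by
#' reflected waves. The window runs from the flow onset until the flow
#' first reaches `upstroke_fraction` of its peak. Any intercept (diastolic
#' baseline, uncalibrated offsets) is absorbed by the fit; the slope is the
#' characteristic impedance Zc, in arbitrary units when the inputs are
#' uncalibrated.
#'
#' @param p Pressure (or area) [waveform()].
#' @param q Flow (or velocity) [waveform()] on the same time grid.
#' @param upstroke_fraction Upper end of the fitting window as a fraction
#'   of peak flow (default 0.95).
#' @param onset_frac Passed to [detect_landmarks()] for the flow onset.
#' @return The slope Zc (> 0).
#' @export
estimate_zc <- function(p, q, upstroke_fraction = 0.95, onset_frac = 0.05) {
  stopifnot_waveform(p, "p"); stopifnot_waveform(q, "q")
  if (!same_grid(p, q)) {
    ws_stop("p and q must be sampled on the same time grid", "ws_invalid_input")
  }
  lm_q <- detect_landmarks(q, onset_frac = onset_frac)
  qmax <- max(q$v)
  i_hi <- which(q$v >= upstroke_fraction * qmax)
  i_end <- if (length(i_hi)) min(i_hi) else which.max(q$v)
  idx <- which(q$t >= lm_q$t_onset & seq_along(q$t) <= i_end)
  if (length(idx) < 4) {
    ws_stop("fewer than 4 samples in the early-systolic fitting window",
            "ws_insufficient_data")
  }
  fit <- stats::lm.fit(cbind(1, q$v[idx]), p$v[idx])
  zc <- unname(fit$coefficients[2])
  if (!is.finite(zc) || zc <= 0) {
    ws_stop("degenerate P-Q loop: non-positive early-systolic slope",
            "ws_degenerate_loop")
  }
  zc
}

#' Separate pressure into forward and backward components
#'
#' Linear wave separation: with characteristic impedance Zc and undisturbed
#' pressure Pud,
#' \deqn{P_f = (P - P_{ud} + Z_c Q)/2, \quad P_b = (P - P_{ud} - Z_c Q)/2,}
#' so that \eqn{P_f + P_b = P - P_{ud}} pointwise. Also forms the input
#' pressure \eqn{P_{f,in} = Z_c Q} (the pressure that would exist without
#' any reflection), the component amplitudes (max minus min over the beat)
#' and the derived reflection magnitude and centroid return time.
#'
#' @param p Pressure (or calibrated/uncalibrated area) [waveform()].
#' @param q Flow [waveform()] on the same grid.
#' @param zc Characteristic impedance; estimated via [estimate_zc()] when
#'   `NULL`.
#' @param p_ud Undisturbed pressure, default 0.
#' @return An object of class `"separation_result"`: list with `zc`, `pf`,
#'   `pb`, `pf_in` (waveforms), `dpf`, `dpb`, `rm`, `tr`, `p_ud`, and the
#'   input `p` and `q`.
#' @export
separate_waves <- function(p, q, zc = NULL, p_ud = 0) {
  stopifnot_waveform(p, "p"); stopifnot_waveform(q, "q")
  if (!same_grid(p, q)) {
    ws_stop("p and q must share one time grid", "ws_invalid_input")
  }
  if (is.null(zc)) zc <- estimate_zc(p, q)
  if (!is.finite(zc) || zc <= 0) {
    ws_stop("zc must be a positive finite slope", "ws_invalid_input")
  }
  pf_v <- 0.5 * (p$v - p_ud + zc * q$v)
  pb_v <- 0.5 * (p$v - p_ud - zc * q$v)
  res <- structure(list(
    zc = zc,
    pf = waveform(p$t, pf_v, "pressure", p$cycle_length),
    pb = waveform(p$t, pb_v, "pressure", p$cycle_length),
    pf_in = waveform(p$t, zc * q$v, "pressure", p$cycle_length),
    dpf = max(pf_v) - min(pf_v),
    dpb = max(pb_v) - min(pb_v),
    p_ud = p_ud, p = p, q = q,
    rm = NA_real_, tr = NA_real_), class = "separation_result")
  res$rm <- reflection_magnitude(res)
  # reflection-free beats have no backward wave to time: Tr is NA there
  res$tr <- tryCatch(return_time_centroid(res),
                     wavesep_error = function(e) NA_real_)
  res
}

#' @export
print.separation_result <- function(x, ...) {
  cat(sprintf("<wave separation: Zc=%.4g, dPf=%.4g, dPb=%.4g, RM=%.3f, Tr=%.1f ms>\n",
              x$zc, x$dpf, x$dpb, x$rm, x$tr))
  invisible(x)
}

#' Reflection magnitude
#'
#' Ratio of backward to forward pressure-component amplitudes,
#' \eqn{RM = \Delta P_b / \Delta P_f}, an index of total arterial wave
#' reflection; dimensionless and invariant to amplitude scaling of the flow
#' and to affine recalibration of the pressure.
#'
#' @param res A [separate_waves()] result.
#' @return RM (>= 0).
#' @export
reflection_magnitude <- function(res) {
  if (!inherits(res, "separation_result")) {
    ws_stop("res must be a separation_result", "ws_invalid_input")
  }
  if (res$dpf <= 0) {
    ws_stop("zero forward amplitude: reflection magnitude undefined",
            "ws_degenerate_input")
  }
  res$dpb / res$dpf
}

#' Reflected-wave return time by the centroid method
#'
#' Return time Tr is the delay between the time-axis centroids of the
#' backward pressure component and the input pressure waveform
#' \eqn{P_{f,in} = Z_c Q}. Following the originating convention, the
#' backward component is offset to a minimum value of zero before the
#' centroid integral; the input pressure waveform is used as-is. Centroids
#' are \eqn{\int t\,s(t)\,dt / \int s(t)\,dt} by trapezoidal quadrature
#' over the full beat.
#'
#' @param res A [separate_waves()] result.
#' @return Tr in ms.
#' @export
return_time_centroid <- function(res) {
  if (!inherits(res, "separation_result")) {
    ws_stop("res must be a separation_result", "ws_invalid_input")
  }
  t <- res$pb$t
  pb_off <- res$pb$v - min(res$pb$v)
  i_pb <- trapz_int(t, pb_off)
  i_pf <- trapz_int(t, res$pf_in$v)
  if (abs(i_pb) <= .Machine$double.eps * length(t) * max(1, max(abs(pb_off)))) {
    ws_stop("offset backward component integrates to zero: centroid undefined",
            "ws_degenerate_input")
  }
  if (abs(i_pf) <= .Machine$double.eps * length(t) * max(1, max(abs(res$pf_in$v)))) {
    ws_stop("input pressure waveform integrates to zero: centroid undefined",
            "ws_degenerate_input")
  }
  c_pb <- trapz_int(t, t * pb_off) / i_pb
  c_pf <- trapz_int(t, t * res$pf_in$v) / i_pf
  c_pb - c_pf
}

#' Calibrate an area waveform to brachial pressures
#'
#' Maps an aortic cross-sectional area waveform linearly onto pressure so
#' that its mean equals the measured mean arterial pressure and its minimum
#' equals the diastolic pressure: `v -> alpha*v + beta` with
#' `mean(out) == map_mmHg` and `min(out) == dbp_mmHg`. The mean is the
#' arithmetic mean of the samples.
#'
#' @param a Area [waveform()].
#' @param map_mmHg Mean arterial pressure (mmHg), must exceed `dbp_mmHg`.
#' @param dbp_mmHg Diastolic pressure (mmHg).
#' @return A pressure [waveform()] in mmHg.
#' @export
calibrate_area_to_pressure <- function(a, map_mmHg, dbp_mmHg) {
  stopifnot_waveform(a, "a")
  if (map_mmHg <= dbp_mmHg) {
    ws_stop("mean pressure must exceed diastolic pressure", "ws_invalid_input")
  }
  m <- mean(a$v); mn <- min(a$v)
  if (m - mn <= .Machine$double.eps * max(1, abs(m))) {
    ws_stop("flat area waveform cannot be calibrated", "ws_degenerate_input")
  }
  alpha <- (map_mmHg - dbp_mmHg) / (m - mn)
  beta <- map_mmHg - alpha * m
  waveform(a$t, alpha * a$v + beta, "pressure", a$cycle_length)
}
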