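# Beat landmark detection on flow/velocity waveforms.

#' Detect beat landmarks on a flow or velocity waveform
#'
#' Locates the fiducial points that anchor all downstream processing:
#' the systolic peak, the 50%-of-peak upstroke crossing, the foot of the
#' upstroke, end-systole (the local minimum following the peak, i.e. the
#' valve-closure notch) and, when present, the first post-systolic return
#' to zero. All crossing times are returned as sub-sample (linearly
#' interpolated) times; the peak time is the grid argmax.
#'
#' @param w A [waveform()] with a single dominant positive systolic lobe.
#' @param onset_frac Upstroke-foot threshold as a fraction of the peak
#'   value (default 0.05). The onset is the last time before the 50%
#'   crossing at which the signal is at or below this threshold.
#' @param es_window_frac End-systole search window after the peak, as a
#'   fraction of the cycle length (default 0.6; systole occupies less than
#'   60% of the cycle at physiological heart rates).
#'
#' @return An object of class `"beat_landmarks"`: list with `t_onset`,
#'   `t_50up`, `t_peak`, `t_es`, `t_zero` (NA when the signal stays
#'   positive to beat end), and `ejection_time` (`t_es - t_onset`), all ms.
#' @export
detect_landmarks <- function(w, onset_frac = 0.05, es_window_frac = 0.6) {
  stopifnot_waveform(w)
  if (!w$kind %in% c("flow", "velocity")) {
    ws_stop("landmark detection expects a flow or velocity waveform",
            "ws_invalid_input")
  }
  t <- w$t; v <- w$v; n <- length(t)
  vmax <- max(v)
  if (vmax <= 0) {
    ws_stop("no positive systolic peak found", "ws_landmark_error")
  }
  ipk <- which.max(v)
  t_peak <- t[ipk]

  # 50% upstroke crossing: last upward crossing of 0.5*vmax before the peak
  half <- 0.5 * vmax
  i50 <- NA_integer_
  if (ipk > 1) {
    for (i in seq(ipk - 1, 1)) {
      if (v[i] <= half && v[i + 1] > half) { i50 <- i; break }
    }
  }
  if (is.na(i50)) {
    # beat may start above half-peak
    t_50up <- t[1]
  } else if (v[i50] == half) {
    t_50up <- t[i50]
  } else {
    t_50up <- t[i50] + (half - v[i50]) / (v[i50 + 1] - v[i50]) * (t[i50 + 1] - t[i50])
  }

  # onset: last time before t_50up at which v <= onset_frac * vmax
  thr <- onset_frac * vmax
  ion <- NA_integer_
  last_before <- max(which(t <= t_50up))
  for (i in seq(last_before, 1)) {
    if (v[i] <= thr) { ion <- i; break }
  }
  if (is.na(ion)) {
    t_onset <- t[1]
  } else if (ion < n && v[ion + 1] > thr && v[ion] < thr) {
    t_onset <- t[ion] + (thr - v[ion]) / (v[ion + 1] - v[ion]) * (t[ion + 1] - t[ion])
  } else {
    t_onset <- t[ion]
  }
  t_onset <- min(t_onset, t_50up)

  # end-systole: first local minimum after the peak within the search window
  t_lim <- t_peak + es_window_frac * w$cycle_length
  t_es <- NA_real_
  if (ipk + 1 <= n - 1) {
    for (i in seq(ipk + 1, n - 1)) {
      if (t[i] > t_lim) break
      if (v[i] < v[i - 1] && v[i] <= v[i + 1]) {
        if (v[i] < v[i + 1]) {
          # strict minimum: parabolic sub-sample refinement
          dt <- t[i + 1] - t[i]
          denom <- v[i - 1] - 2 * v[i] + v[i + 1]
          delta <- if (denom > 0) 0.5 * (v[i - 1] - v[i + 1]) / denom else 0
          delta <- max(min(delta, 0.5), -0.5)
          t_es <- t[i] + delta * dt
        } else {
          # tie with the right neighbour: earliest time
          t_es <- t[i]
        }
        break
      }
    }
  }
  if (is.na(t_es)) {
    ws_stop("no end-systolic local minimum found after the peak within the search window",
            "ws_landmark_error")
  }

  # first return to zero at or after end-systole
  ies <- max(which(t <= t_es + 1e-9))
  t_zero <- NA_real_
  if (v[ies] <= 0) {
    t_zero <- t_es
  } else if (ies < n) {
    for (i in seq(ies, n - 1)) {
      if (v[i] > 0 && v[i + 1] <= 0) {
        t_zero <- t[i] + (0 - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
        break
      }
    }
  }

  lm <- structure(list(t_onset = t_onset, t_50up = t_50up, t_peak = t_peak,
                       t_es = t_es, t_zero = t_zero,
                       ejection_time = t_es - t_onset),
                  class = "beat_landmarks")
  if (lm$ejection_time <= 0) {
    ws_stop("degenerate beat: non-positive ejection time", "ws_landmark_error")
  }
  lm
}

#' @export
print.beat_landmarks <- function(x, ...) {
  cat(sprintf(paste0("<beat landmarks: onset %.1f, 50%%-up %.1f, peak %.1f, ",
                     "end-systole %.1f, zero %s ms; ejection %.1f ms>\n"),
              x$t_onset, x$t_50up, x$t_peak, x$t_es,
              if (is.na(x$t_zero)) "absent" else sprintf("%.1f", x$t_zero),
              x$ejection_time))
  invisible(x)
}
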