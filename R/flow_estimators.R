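# Non-representative flow surrogates: triangular waveform synthesis and
# externally supplied normalized waveforms.

#' Synthesize a triangular flow waveform
#'
#' Piecewise-linear flow surrogate: zero before the upstroke onset, a
#' linear rise to a unit-amplitude apex, a linear fall to zero at
#' end-systole, and zero thereafter. The triangle base spans from the
#' onset of the flow upstroke to the end-systolic minimum; the apex sits
#' at `apex_fraction` of ejection time after onset (0.25 for the Tri25
#' variant, 0.30 for Tri30) or, with `apex_fraction = "peak"`, at the
#' individually measured time of peak flow (`t_peak_true`).
#'
#' @param lm [detect_landmarks()] result for the target beat.
#' @param grid Numeric vector of output times (ms).
#' @param apex_fraction Fraction of ejection time in (0, 1), or `"peak"`.
#' @param t_peak_true Measured peak-flow time (ms), required with
#'   `apex_fraction = "peak"`.
#' @return A flow [waveform()] with unit peak.
#' @export
triangular_flow <- function(lm, grid, apex_fraction = 0.25,
                            t_peak_true = NULL) {
  if (identical(apex_fraction, "peak")) {
    if (is.null(t_peak_true)) {
      ws_stop("apex_fraction = \"peak\" requires t_peak_true", "ws_invalid_parameter")
    }
    t_apex <- t_peak_true
  } else {
    if (!is.numeric(apex_fraction) || length(apex_fraction) != 1 ||
        apex_fraction <= 0 || apex_fraction >= 1) {
      ws_stop("apex_fraction must lie in (0, 1) or be \"peak\"",
              "ws_invalid_parameter")
    }
    t_apex <- lm$t_onset + apex_fraction * lm$ejection_time
  }
  if (t_apex <= lm$t_onset || t_apex >= lm$t_es) {
    ws_stop("triangle apex must lie strictly between onset and end-systole",
            "ws_invalid_parameter")
  }
  v <- numeric(length(grid))
  up <- grid > lm$t_onset & grid <= t_apex
  dn <- grid > t_apex & grid < lm$t_es
  v[up] <- (grid[up] - lm$t_onset) / (t_apex - lm$t_onset)
  v[dn] <- (lm$t_es - grid[dn]) / (lm$t_es - t_apex)
  waveform(grid, v, "flow")
}

#' Load an externally supplied normalized flow waveform
#'
#' Reads a two-column `tau,value` file holding a flow waveform normalized
#' with the same anchor convention as the representative waveform (tau = 0
#' at the 50% upstroke crossing, tau = 1 at end-systole) and de-normalizes
#' it onto an individual beat exactly as
#' [denormalize_representative()] does. The anchor convention of the file
#' is the caller's assertion; it cannot be verified from the data alone.
#'
#' @param path CSV path with columns `tau` and `value`.
#' @param lm [detect_landmarks()] result for the target beat.
#' @param grid Numeric vector of output times (ms).
#' @param method Interpolation scheme.
#' @return A flow [waveform()]; its `provenance` attribute records the
#'   source path.
#' @export
load_external_normalized <- function(path, lm, grid,
                                     method = c("spline", "pchip")) {
  rep <- read_representative(path)
  w <- denormalize_representative(rep, lm, grid, method = method)
  attr(w, "provenance") <- path
  w
}
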