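# Tube-load synthetic hemodynamics with known ground-truth reflection.
#
# Minimal single-reflection transmission-line picture: a compact forward
# pressure wave F(t) plus a scaled, delayed reflected copy. Pressure adds
# the two, flow carries their difference scaled by the characteristic
# impedance, and area is a linear map of pressure. No re-reflection, so
# the ground truth for the reflection coefficient and round-trip delay is
# unambiguous and closed-form.

# evaluate code with a locally seeded RNG, restoring the caller's state
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Ground truth for a simulated beat
#'
#' Parameter bundle for the tube-load generator. The forward wave is a
#' skewed half-sine of `ejection_ms` duration peaking at `rise_frac` of
#' ejection, with amplitude `amplitude_mmHg` on top of a
#' `baseline_mmHg` diastolic pressure. The reflected wave is
#' `gamma` times the forward wave delayed by `delay_ms` (round trip).
#' Area is the linear surrogate `area_baseline + area_slope*(p - baseline)`.
#'
#' @param gamma Reflection coefficient, in `[0, 0.8]`.
#' @param delay_ms Round-trip reflection delay (ms), less than the cycle.
#' @param zc Characteristic impedance (mmHg·s/mL as mmHg per mL/s).
#' @param hr_bpm Heart rate (beats per minute).
#' @param ejection_ms Ejection (forward-wave) duration (ms).
#' @param rise_frac Fraction of ejection at which the forward wave peaks.
#' @param amplitude_mmHg Forward-wave amplitude (mmHg).
#' @param baseline_mmHg Diastolic pressure baseline (mmHg).
#' @param noise_sd Additive Gaussian noise, as a fraction of each
#'   signal's pulse amplitude (0 = noiseless).
#' @param skew Velocity-profile displacement at peak flow, as a fraction
#'   of the lumen radius, in `[0, 1)`.
#' @param profile_exponent Velocity-profile bluntness exponent (>= 2;
#'   2 = parabolic, `Inf` = flat).
#' @return Object of class `"sim_truth"`.
#' @export
sim_truth <- function(gamma = 0.4, delay_ms = 120, zc = 0.1, hr_bpm = 70,
                      ejection_ms = 300, rise_frac = 0.25,
                      amplitude_mmHg = 40, baseline_mmHg = 70,
                      noise_sd = 0, skew = 0, profile_exponent = 2) {
  cycle <- 60000 / hr_bpm
  if (gamma < 0 || gamma > 0.8) {
    ws_stop("gamma must lie in [0, 0.8]", "ws_invalid_parameter")
  }
  if (delay_ms < 0 || delay_ms >= cycle) {
    ws_stop("delay_ms must be non-negative and below the cycle length",
            "ws_invalid_parameter")
  }
  if (zc <= 0) ws_stop("zc must be positive", "ws_invalid_parameter")
  if (rise_frac <= 0 || rise_frac >= 1) {
    ws_stop("rise_frac must lie in (0, 1)", "ws_invalid_parameter")
  }
  if (skew < 0 || skew >= 1) {
    ws_stop("skew must lie in [0, 1)", "ws_invalid_parameter")
  }
  if (!(is.infinite(profile_exponent) || profile_exponent >= 2)) {
    ws_stop("profile_exponent must be >= 2 (or Inf for a flat profile)",
            "ws_invalid_parameter")
  }
  if (ejection_ms >= cycle) {
    ws_stop("ejection must be shorter than the cycle", "ws_invalid_parameter")
  }
  structure(list(gamma = gamma, delay_ms = delay_ms, zc = zc,
                 hr_bpm = hr_bpm, cycle_ms = cycle,
                 ejection_ms = ejection_ms, rise_frac = rise_frac,
                 amplitude_mmHg = amplitude_mmHg,
                 baseline_mmHg = baseline_mmHg, noise_sd = noise_sd,
                 skew = skew, profile_exponent = profile_exponent),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim truth: gamma=%.2f, delay=%.0f ms, Zc=%.3g, HR=%.0f bpm, ET=%.0f ms>\n",
              x$gamma, x$delay_ms, x$zc, x$hr_bpm, x$ejection_ms))
  invisible(x)
}

# skewed half-sine forcing with unit peak: sine rise to the peak at
# rise_frac*ejection, cosine fall back to zero at ejection; zero outside
forward_wave <- function(t, ejection_ms, rise_frac) {
  tp <- rise_frac * ejection_ms
  v <- numeric(length(t))
  up <- t >= 0 & t < tp
  dn <- t >= tp & t <= ejection_ms
  v[up] <- sin(pi / 2 * t[up] / tp)
  v[dn] <- cos(pi / 2 * (t[dn] - tp) / (ejection_ms - tp))
  v
}

#' Simulate one ground-truthed beat
#'
#' Constructs the tube-load beat on a uniform grid of `n_samples` over one
#' cycle (default 128, emulating the temporal resolution of segmented
#' phase-contrast imaging): with forward wave `Pf = A*F(t)` and backward
#' wave `Pb = gamma*A*F(t - delay)`,
#' `p = Pf + Pb + baseline`, `q = (Pf - Pb)/zc`, and
#' `a = area_baseline + area_slope*(p - baseline)`. Optional seeded
#' Gaussian noise is added to all three signals.
#'
#' @param gt A [sim_truth()].
#' @param n_samples Samples per cycle (default 128).
#' @param seed Optional integer seed for the noise; the caller's RNG
#'   state is preserved.
#' @param area_slope,area_baseline Linear pressure-area map (mm^2/mmHg,
#'   mm^2).
#' @return List with `p`, `q`, `a` ([waveform()]s) and `truth` (the input
#'   `gt`).
#' @export
simulate_beat <- function(gt, n_samples = 128, seed = NULL,
                          area_slope = 2, area_baseline = 450) {
  if (!inherits(gt, "sim_truth")) {
    ws_stop("gt must be a sim_truth object", "ws_invalid_parameter")
  }
  if (gt$delay_ms >= gt$cycle_ms) {
    ws_stop("delay must be below the cycle length", "ws_invalid_parameter")
  }
  t <- seq(0, gt$cycle_ms, length.out = n_samples)
  f <- gt$amplitude_mmHg * forward_wave(t, gt$ejection_ms, gt$rise_frac)
  fb <- gt$gamma * gt$amplitude_mmHg *
    forward_wave(t - gt$delay_ms, gt$ejection_ms, gt$rise_frac)
  p_v <- f + fb + gt$baseline_mmHg
  q_v <- (f - fb) / gt$zc
  a_v <- area_baseline + area_slope * (p_v - gt$baseline_mmHg)
  if (gt$noise_sd > 0) {
    with_local_seed(seed, {
      p_v <- p_v + stats::rnorm(n_samples, 0, gt$noise_sd * gt$amplitude_mmHg)
      q_v <- q_v + stats::rnorm(n_samples, 0,
                                gt$noise_sd * gt$amplitude_mmHg / gt$zc)
      a_v <- a_v + stats::rnorm(n_samples, 0,
                                gt$noise_sd * gt$amplitude_mmHg * area_slope)
    })
  }
  list(p = waveform(t, p_v, "pressure", gt$cycle_ms),
       q = waveform(t, q_v, "flow", gt$cycle_ms),
       a = waveform(t, a_v, "area", gt$cycle_ms),
       truth = gt)
}

#' Simulate a cohort of beats with jittered parameters
#'
#' Draws per-subject parameters uniformly from the stated ranges and
#' simulates one beat per subject. All randomness flows through one
#' seeded generator, so identical seeds give identical cohorts.
#'
#' @param base A [sim_truth()] providing every non-jittered parameter.
#' @param n Number of subjects (>= 3).
#' @param jitter Named list of two-element ranges for any of `gamma`,
#'   `delay_ms`, `hr_bpm`, `ejection_ms`, `rise_frac`. Defaults follow
#'   the study conditions for a reflection cohort: gamma 0.3-0.6,
#'   delay 80-160 ms, heart rate 55-90 bpm, ejection 270-330 ms, rise
#'   fraction 0.22-0.28. Collapsed ranges (equal endpoints) give a
#'   jitter-free cohort.
#' @param n_samples Samples per beat.
#' @param seed Integer seed.
#' @return Object of class `"sim_cohort"`: list with `subjects` (each a
#'   [simulate_beat()] result) and `truths` (data.frame of drawn
#'   parameters).
#' @export
simulate_cohort <- function(base = sim_truth(), n = 20,
                            jitter = list(gamma = c(0.3, 0.6),
                                          delay_ms = c(80, 160),
                                          hr_bpm = c(55, 90),
                                          ejection_ms = c(270, 330),
                                          rise_frac = c(0.22, 0.28)),
                            n_samples = 128, seed = NULL) {
  if (n < 3) ws_stop("a cohort needs at least 3 subjects", "ws_invalid_input")
  allowed <- c("gamma", "delay_ms", "hr_bpm", "ejection_ms", "rise_frac")
  if (length(jitter)) {
    if (is.null(names(jitter)) || !all(names(jitter) %in% allowed)) {
      ws_stop(paste("jitter names must be among:", paste(allowed, collapse = ", ")),
              "ws_invalid_parameter")
    }
    for (rg in jitter) {
      if (length(rg) != 2 || !all(is.finite(rg)) || rg[2] < rg[1]) {
        ws_stop("each jitter entry must be a finite range c(lo, hi)",
                "ws_invalid_parameter")
      }
    }
  }
  with_local_seed(seed, {
    subjects <- vector("list", n)
    truths <- vector("list", n)
    for (i in seq_len(n)) {
      pars <- list(gamma = base$gamma, delay_ms = base$delay_ms,
                   zc = base$zc, hr_bpm = base$hr_bpm,
                   ejection_ms = base$ejection_ms, rise_frac = base$rise_frac,
                   amplitude_mmHg = base$amplitude_mmHg,
                   baseline_mmHg = base$baseline_mmHg,
                   noise_sd = base$noise_sd, skew = base$skew,
                   profile_exponent = base$profile_exponent)
      for (nm in names(jitter)) {
        pars[[nm]] <- stats::runif(1, jitter[[nm]][1], jitter[[nm]][2])
      }
      gt_i <- do.call(sim_truth, pars)
      subjects[[i]] <- simulate_beat(gt_i, n_samples = n_samples)
      truths[[i]] <- data.frame(subject = i, gamma = gt_i$gamma,
                                delay_ms = gt_i$delay_ms, zc = gt_i$zc,
                                hr_bpm = gt_i$hr_bpm,
                                ejection_ms = gt_i$ejection_ms,
                                rise_frac = gt_i$rise_frac)
    }
    structure(list(subjects = subjects, truths = do.call(rbind, truths)),
              class = "sim_cohort")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<simulated cohort: %d subjects>\n", length(x$subjects)))
  invisible(x)
}

#' Simulate a cross-sectional velocity field for a beat
#'
#' Builds a power-law velocity profile on a circular lumen of radius
#' `radius_mm`: `u(r') = s(t) * (1 - (r'/R)^n)+` with bluntness exponent
#' `n = profile_exponent` (flat for `Inf`), where `r'` is measured from a
#' profile centre displaced along x by `skew * R * q(t)/max(q)` —
#' secondary-flow displacement grows with instantaneous velocity, which is
#' what makes envelope- and sample-volume-based traces misrepresent mean
#' flow. Each frame is renormalized so the lumen-mean velocity equals
#' `q(t)/A` exactly (with the 100x factor converting mL/s over mm^2 to
#' cm/s).
#'
#' @param gt A [sim_truth()] (supplies `skew` and `profile_exponent`).
#' @param q Flow [waveform()] (mL/s).
#' @param radius_mm Lumen radius (mm).
#' @param n_pixels Pixels per axis of the square grid spanning the lumen.
#' @return A [velocity_field()] (velocities in cm/s).
#' @export
simulate_velocity_field <- function(gt, q, radius_mm = 10, n_pixels = 41) {
  if (!inherits(gt, "sim_truth")) {
    ws_stop("gt must be a sim_truth object", "ws_invalid_parameter")
  }
  stopifnot_waveform(q, "q")
  R <- radius_mm
  x <- seq(-R, R, length.out = n_pixels)
  y <- x
  px_area <- (x[2] - x[1])^2
  r2 <- outer(x^2, y^2, "+")
  mask <- r2 <= R^2
  area <- sum(mask) * px_area
  nt <- length(q$t)
  u <- array(0, dim = c(n_pixels, n_pixels, nt))
  nexp <- gt$profile_exponent
  qmax <- max(q$v)
  target <- 100 * q$v / area  # cm/s
  for (k in seq_len(nt)) {
    if (is.infinite(nexp)) {
      raw <- matrix(1, n_pixels, n_pixels)
    } else {
      dx <- gt$skew * R * q$v[k] / qmax
      rp2 <- outer((x - dx)^2, y^2, "+")
      raw <- pmax(1 - (sqrt(rp2) / R)^nexp, 0) * (nexp + 2) / nexp
    }
    m_raw <- mean(raw[mask])
    u[, , k] <- raw * (target[k] / m_raw)
  }
  velocity_field(q$t, x, y, u, mask)
}
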