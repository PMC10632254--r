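test_that("normalization anchors the beat at 0.5/tau=0 and peak 1", {
  w <- half_sine_beat()
  nb <- normalize_beat(w)
  expect_equal(stats::approx(nb$tau, nb$v, 0)$y, 0.5, tolerance = 1e-5)
  expect_equal(max(nb$v), 1, tolerance = 1e-6)
  # half-sine: peak at tau = (150 - 50)/(300 - 50) = 0.4
  dtau <- nb$tau[2] - nb$tau[1]
  expect_lt(abs(nb$tau[which.max(nb$v)] - 0.4), 2 * dtau)
})

test_that("normalization removes affine time and amplitude scale", {
  w1 <- smooth_beat(sys_ms = 300, beat_ms = 800, n = 256)
  # same shape, stretched 1.3x in time and scaled 85x in amplitude
  w2 <- waveform(w1$t * 1.3, 85 * w1$v, "flow")
  n1 <- normalize_beat(w1)
  n2 <- normalize_beat(w2)
  expect_lt(max(abs(n1$v - n2$v)), 1e-6)
})

test_that("degenerate landmarks are rejected at normalization", {
  w <- half_sine_beat()
  lm <- detect_landmarks(w)
  lm$t_es <- lm$t_50up
  expect_error(normalize_beat(w, lm), class = "ws_degenerate_beat")
})

test_that("a cohort of identical smooth beats reproduces the input shape", {
  nb <- normalize_beat(smooth_beat())
  rep <- build_representative(list(nb, nb, nb, nb))
  keep <- rep$tau <= rep$ramp_start
  expect_lt(max(abs(rep$v[keep] - nb$v[keep])), 1e-3)
  expect_equal(stats::approx(rep$tau, rep$v, 0)$y, 0.5, tolerance = 0.01)
  expect_true(all(rep$v[rep$tau >= rep$ramp_start + rep$ramp_len] == 0))
  # envelopes collapse onto the mean for identical inputs
  expect_equal(rep$ci_lo, rep$ensemble_mean)
  expect_equal(rep$ci_hi, rep$ensemble_mean)
})

test_that("the representative waveform ignores cohort order and duplication", {
  co <- simulate_cohort(n = 6, seed = 3)
  norms <- lapply(co$subjects, function(s) normalize_beat(s$q))
  r1 <- build_representative(norms)
  r2 <- build_representative(rev(norms))
  r3 <- build_representative(c(norms, norms))
  expect_equal(r1$v, r2$v)
  expect_equal(r1$v, r3$v)
  expect_equal(r1$ramp_start, r3$ramp_start)
})

test_that("the Savitzky-Golay stage reproduces cubic polynomials exactly", {
  tau <- tau_grid()
  v <- 0.3 + 0.2 * tau - 0.5 * tau^2 + 0.1 * tau^3
  sm <- wavesep:::sg_smooth(v, tau[2] - tau[1], 0.125)
  expect_lt(max(abs(sm - v)), 1e-9)
})

test_that("de-normalization inverts normalization on the shared support", {
  co <- simulate_cohort(n = 5, seed = 9)
  norms <- lapply(co$subjects, function(s) normalize_beat(s$q))
  rep <- build_representative(norms)
  w <- co$subjects[[3]]$q
  lm <- detect_landmarks(w)
  # fine target grid keeps the round trip free of resampling loss
  fine <- seq(w$t[1], w$t[length(w$t)], length.out = 1500)
  den <- denormalize_representative(rep, lm, fine)
  # the de-normalized waveform crosses half-peak at the subject's anchor
  lm_den <- detect_landmarks(den)
  dt <- w$t[2] - w$t[1]
  expect_lt(abs(lm_den$t_50up - lm$t_50up), dt)
  # round trip back to tau reproduces the representative shape
  back <- normalize_beat(den, lm)
  tau_lo <- (fine[1] - lm$t_50up) / (lm$t_es - lm$t_50up)
  tau_hi <- (fine[length(fine)] - lm$t_50up) / (lm$t_es - lm$t_50up)
  keep <- rep$tau > tau_lo + 0.05 & rep$tau < tau_hi - 0.05
  scale <- max(den$v)  # normalization re-divides by the peak
  expect_lt(max(abs(back$v[keep] * scale - rep$v[keep])), 1e-4)
})

test_that("leave-one-out on an identical cohort gives (near) zero errors", {
  w <- smooth_beat()
  v <- w$v
  p <- waveform(w$t, 70 + 40 * v + 12 * c(rep(0, 30), v[1:(length(v) - 30)]),
                "pressure")
  loo <- loo_cross_validate(rep(list(w), 5), rep(list(p), 5))
  expect_lt(max(loo$abs_rm_error_pct), 0.1)
  expect_lt(max(loo$abs_tr_error_pct), 1)
  expect_lt(max(loo$rmse_pf), 0.1)
  # every representative excludes exactly the held-out subject
  expect_true(all(loo$n_contributors == 4))
  expect_error(loo_cross_validate(rep(list(w), 2), rep(list(p), 2)),
               class = "ws_invalid_input")
})

test_that("upstroke variability is smaller than downstroke variability", {
  co <- simulate_cohort(seed = 21)
  norms <- lapply(co$subjects, function(s) normalize_beat(s$q))
  m <- vapply(norms, `[[`, numeric(1000), "v")
  tau <- norms[[1]]$tau
  sd_tau <- apply(m, 1, stats::sd)
  up <- tau > 0 & tau < 0.25
  down <- tau > 0.4 & tau < 1
  expect_lt(mean(sd_tau[up]), mean(sd_tau[down]))
})

test_that("pressure-derived landmarks support a pressure-only deployment", {
  co <- simulate_cohort(n = 8, seed = 5)
  flows <- lapply(co$subjects, `[[`, "q")
  ps <- lapply(co$subjects, `[[`, "p")
  loo_p <- loo_cross_validate(flows, ps, landmarks_from = "pressure")
  loo_f <- loo_cross_validate(flows, ps, landmarks_from = "flow")
  expect_true(all(is.finite(loo_p$rm_est)))
  # anchoring on the pressure waveform costs accuracy relative to
  # flow-derived anchors (its first post-peak minimum sits at the
  # reflected-wave arrival on these synthetic beats)
  expect_gt(mean(loo_p$abs_rm_error_pct), mean(loo_f$abs_rm_error_pct))
})

test_that("representative waveforms survive the CSV round trip", {
  co <- simulate_cohort(n = 4, seed = 13)
  rep <- build_representative(lapply(co$subjects, function(s) normalize_beat(s$q)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_representative(rep, path)
  rep2 <- read_representative(path)
  expect_equal(rep2$tau, rep$tau, tolerance = 1e-15)
  expect_equal(rep2$v, rep$v, tolerance = 1e-15)
})
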