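test_that("early-systolic slope recovers exact linear and affine P-Q relations", {
  q <- half_sine_beat()
  p2 <- waveform(q$t, 2 * q$v, "pressure", q$cycle_length)
  p3 <- waveform(q$t, 3 * q$v + 5, "pressure", q$cycle_length)
  expect_equal(estimate_zc(p2, q), 2, tolerance = 1e-12)
  expect_equal(estimate_zc(p3, q), 3, tolerance = 1e-12)
})

test_that("impedance estimation fails informatively on degenerate input", {
  q <- half_sine_beat()
  p_neg <- waveform(q$t, -2 * q$v + 10, "pressure", q$cycle_length)
  expect_error(estimate_zc(p_neg, q), class = "ws_degenerate_loop")
  # upstroke reaching 95% of peak within fewer than 4 samples
  tt <- seq(0, 600, by = 12)
  v <- ifelse(tt <= 24, tt / 24, ifelse(tt <= 300, (300 - tt) / 276, 0))
  q_steep <- waveform(tt, v, "flow")
  p <- waveform(tt, 2 * v + 70, "pressure")
  expect_error(estimate_zc(p, q_steep), class = "ws_insufficient_data")
  # grid mismatch
  q2 <- resample_uniform(q, 128)
  expect_error(estimate_zc(waveform(q$t, 2 * q$v, "pressure"), q2),
               class = "ws_invalid_input")
})

test_that("impedance is recovered within 3% on tube-load beats", {
  for (g in c(0.1, 0.4, 0.7)) {
    b <- simulate_beat(sim_truth(gamma = g, delay_ms = 120))
    expect_lt(abs(estimate_zc(b$p, b$q) - 0.1) / 0.1, 0.03)
  }
})

test_that("separation limits: pure forward flow and closed-valve", {
  q <- half_sine_beat()
  p <- waveform(q$t, 2.5 * q$v, "pressure", q$cycle_length)
  res <- separate_waves(p, q, zc = 2.5)
  expect_lt(max(abs(res$pb$v)), 1e-12)
  expect_equal(res$rm, 0, tolerance = 1e-12)

  # q identically zero: both components are half the pressure
  q0 <- waveform(q$t, rep(0, length(q$t)), "flow", q$cycle_length)
  p_any <- waveform(q$t, 80 + 20 * sin(pi * q$t / 300), "pressure", q$cycle_length)
  res0 <- separate_waves(p_any, q0, zc = 1)
  expect_equal(res0$pf$v, p_any$v / 2, tolerance = 1e-12)
  expect_equal(res0$pb$v, p_any$v / 2, tolerance = 1e-12)
})

test_that("tube-load backward wave is recovered exactly with the true impedance", {
  gt <- sim_truth(gamma = 0.4, delay_ms = 120)
  b <- simulate_beat(gt)
  res <- separate_waves(b$p, b$q, zc = gt$zc, p_ud = gt$baseline_mmHg)
  pb_true <- gt$gamma * gt$amplitude_mmHg *
    wavesep:::forward_wave(b$p$t - gt$delay_ms, gt$ejection_ms, gt$rise_frac)
  expect_lt(max(abs(res$pb$v - pb_true)), 1e-10)
})

test_that("forward plus backward reconstructs pressure to machine precision", {
  set.seed(11)
  for (i in 1:25) {
    g <- runif(1, 0, 0.8); d <- runif(1, 40, 300); pud <- sample(c(0, 70), 1)
    b <- simulate_beat(sim_truth(gamma = g, delay_ms = d, noise_sd = 0.02),
                       seed = i)
    res <- separate_waves(b$p, b$q, p_ud = pud)
    err <- max(abs(res$pf$v + res$pb$v - (b$p$v - pud)))
    expect_lt(err / max(abs(b$p$v)), 1e-12)
  }
})

test_that("reflection magnitude is the backward-to-forward amplitude ratio", {
  gt <- sim_truth(gamma = 0.5, delay_ms = 150)
  b <- simulate_beat(gt)
  res <- separate_waves(b$p, b$q, zc = gt$zc)
  expect_equal(res$rm, res$dpb / res$dpf)
  expect_equal(reflection_magnitude(res), res$rm)
  # flat pressure with zero flow: zero forward amplitude is degenerate
  tt <- seq(0, 600, length.out = 64)
  pc <- waveform(tt, rep(80, 64), "pressure")
  q0 <- waveform(tt, rep(0, 64), "flow")
  expect_error(separate_waves(pc, q0, zc = 1), class = "ws_degenerate_input")
})

test_that("centroid return time equals the shift between identical pulses", {
  tt <- seq(0, 857, length.out = 512)
  zc <- 2
  # craft a beat whose input pressure is a pulse at 100 ms and whose
  # backward component is the identical pulse at 300 ms
  q <- waveform(tt, pulse_at(tt, 100) / zc, "flow")
  p <- waveform(tt, zc * q$v + 2 * pulse_at(tt, 300), "pressure")
  res <- separate_waves(p, q, zc = zc)
  expect_equal(res$tr, 200, tolerance = 1e-6)

  # backward component proportional to the input pressure: zero delay
  p0 <- waveform(tt, zc * q$v + 2 * 0.35 * zc * q$v, "pressure")
  res0 <- separate_waves(p0, q, zc = zc)
  expect_equal(res0$tr, 0, tolerance = 1e-9)
})

test_that("tube-load centroid return time follows the delay/(1-gamma) law", {
  # with flow distorted by the reflected wave, the centroid of Zc*Q sits
  # early by gamma*delay/(1-gamma), so Tr = delay/(1-gamma) exactly
  for (g in c(0.2, 0.5, 0.7)) for (d in c(60, 130, 200)) {
    b <- simulate_beat(sim_truth(gamma = g, delay_ms = d))
    dt <- b$p$t[2] - b$p$t[1]
    res <- separate_waves(b$p, b$q, zc = 0.1)
    expect_lt(abs(res$tr - d / (1 - g)), dt)
  }
})

test_that("area calibration solves the two-point linear map", {
  tt <- seq(0, 750, by = 50)
  a <- waveform(tt, rep(c(450, 550), 8), "area")
  out <- calibrate_area_to_pressure(a, map_mmHg = 90, dbp_mmHg = 60)
  expect_equal(mean(out$v), 90, tolerance = 1e-12)
  expect_equal(min(out$v), 60, tolerance = 1e-12)
  expect_equal(out$v, 0.6 * a$v - 210, tolerance = 1e-12)
  # recalibrating a pressure waveform to its own mean/min is the identity
  p <- simulate_beat(sim_truth())$p
  p_area <- waveform(p$t, p$v, "area", p$cycle_length)
  back <- calibrate_area_to_pressure(p_area, mean(p$v), min(p$v))
  expect_equal(back$v, p$v, tolerance = 1e-12)
  expect_error(calibrate_area_to_pressure(
    waveform(tt, rep(500, length(tt)), "area"), 90, 60),
    class = "ws_degenerate_input")
  expect_error(calibrate_area_to_pressure(a, 60, 90), class = "ws_invalid_input")
})

test_that("reflection indices are invariant to flow scale and pressure calibration", {
  gt <- sim_truth(gamma = 0.45, delay_ms = 140)
  b <- simulate_beat(gt)
  ref <- separate_waves(b$p, b$q)

  # amplitude scaling of Q: the estimated impedance compensates
  q_scaled <- waveform(b$q$t, 7 * b$q$v, "flow", b$q$cycle_length)
  s1 <- separate_waves(b$p, q_scaled)
  expect_lt(abs(s1$rm - ref$rm) / ref$rm, 1e-10)
  expect_lt(abs(s1$tr - ref$tr) / abs(ref$tr), 1e-10)

  # affine recalibration of P (area surrogate -> mmHg)
  a_cal <- calibrate_area_to_pressure(b$a, 95, 65)
  ref_a <- separate_waves(b$a, b$q)
  s2 <- separate_waves(a_cal, b$q)
  expect_lt(abs(s2$rm - ref_a$rm) / ref_a$rm, 1e-10)
  expect_lt(abs(s2$tr - ref_a$tr) / abs(ref_a$tr), 1e-10)
})
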