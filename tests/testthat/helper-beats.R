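# Fixtures built in code: analytic beats with known landmark geometry.

# half-sine systole (0..sys_ms) followed by zero diastole
half_sine_beat <- function(sys_ms = 300, beat_ms = 600, n = 601) {
  tt <- seq(0, beat_ms, length.out = n)
  waveform(tt, ifelse(tt <= sys_ms, sin(pi * tt / sys_ms), 0), "flow")
}

# triangle: onset 0, unit apex at apex_ms, zero at base_ms and after
triangle_beat <- function(apex_ms = 75, base_ms = 300, beat_ms = 600, dt = 2.5) {
  tt <- seq(0, beat_ms, by = dt)
  v <- ifelse(tt <= apex_ms, tt / apex_ms,
              ifelse(tt <= base_ms, (base_ms - tt) / (base_ms - apex_ms), 0))
  waveform(tt, v, "flow")
}

# C3-smooth skewed ejection pulse: negligible Savitzky-Golay residual
smooth_beat <- function(sys_ms = 300, beat_ms = 800, n = 256) {
  tt <- seq(0, beat_ms, length.out = n)
  x <- pmin(pmax(tt / sys_ms, 0), 1)
  v <- sin(pi * x)^4 * exp(-1.5 * x)
  v[tt > sys_ms] <- 0
  waveform(tt, v / max(v), "flow")
}

# compactly supported unit pulse centred at c_ms (raised cosine, width w_ms)
pulse_at <- function(tt, c_ms, w_ms = 80) {
  u <- (tt - c_ms) / (w_ms / 2)
  ifelse(abs(u) <= 1, 0.5 * (1 + cos(pi * u)), 0)
}
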