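test_that("end-tidal extraction finds sinusoid crests at the analytic extrema", {
  t <- seq(0, 60, by = 0.05)
  v <- 38 + 5 * sin(2 * pi * t / 4)   # period 4 s, crests at value 43
  tr <- detect_end_tidal_peaks(t, v)
  expect_equal(tr$source, "end_tidal_extracted")
  expect_true(all(abs(tr$values_mmHg - 43) < 1e-6))
  expect_true(all(abs(diff(tr$times_s) - 4) < 0.11))
})

test_that("square-wave breaths yield one peak per plateau (brute-force oracle)", {
  # 0.25 s plateaus at 40 mmHg every 3 s, baseline 5 mmHg, 20 Hz sampling
  t <- seq(0, 30, by = 0.05)
  v <- rep(5, length(t))
  plateau_starts <- seq(1, 28, by = 3)
  for (s in plateau_starts) v[t >= s & t < s + 0.25] <- 40
  tr <- detect_end_tidal_peaks(t, v)
  # oracle: per cycle, the argmax of the waveform
  expect_length(tr$times_s, length(plateau_starts))
  oracle_vals <- vapply(plateau_starts, function(s) max(v[t >= s & t < s + 3]),
                        numeric(1))
  expect_equal(tr$values_mmHg, oracle_vals)
  # each peak sits inside its plateau
  expect_true(all(vapply(seq_along(plateau_starts), function(i) {
    tr$times_s[i] >= plateau_starts[i] - 1e-9 &&
      tr$times_s[i] < plateau_starts[i] + 0.25
  }, logical(1))))
})

test_that("constant input has no extrema and raises an empty-trace error", {
  t <- seq(0, 20, by = 0.1)
  expect_error(detect_end_tidal_peaks(t, rep(40, length(t))),
               class = "cvrsvd_empty_trace")
})

test_that("peak detection recovers simulated end-tidal levels through a raw waveform", {
  p <- study_paradigm()
  cfg <- sim_config(breath_jitter_sd_s = 0, seed = 2)
  et <- simulate_etco2(p, cfg)
  # raw capnogram: end-tidal level reached at each breath time, with an
  # inspiratory dip between breaths
  t <- seq(0, max(et$times_s), by = 0.1)
  level <- approx(et$times_s, et$values_mmHg, xout = t, rule = 2)$y
  phase <- (t %% cfg$breath_interval_s) / cfg$breath_interval_s
  raw <- level - 30 * (1 - cos(2 * pi * phase)) / 2
  tr <- detect_end_tidal_peaks(t, raw)
  recovered <- approx(tr$times_s, tr$values_mmHg, xout = et$times_s,
                      rule = 2)$y
  expect_true(max(abs(recovered - et$values_mmHg)) < 0.25)
})

test_that("resampling is the identity for a trace already on the volume grid", {
  n <- 40; tr_s <- 2
  tk <- volume_times(n, tr_s)
  trace <- etco2_trace(tk, 38 + sin(tk / 10), source = "simulated")
  reg <- resample_to_volumes(trace, n, tr_s)
  expect_equal(reg$values_mmHg, trace$values_mmHg)
  expect_equal(reg$applied_delay_s, 0)
})

test_that("linear interpolation and edge hold match hand values", {
  trace <- etco2_trace(c(0, 10), c(38, 48), source = "simulated")
  reg <- resample_to_volumes(trace, 10, 1)   # mid-TR stamps 0.5..9.5
  expect_equal(reg$values_mmHg[5], 42.5)     # t = 4.5 s
  # queries past the last sample hold the final value
  reg2 <- resample_to_volumes(trace, 16, 1)
  expect_equal(reg2$values_mmHg[12:16], rep(48, 5))
})

test_that("insufficient trace coverage raises an error", {
  trace <- etco2_trace(c(0, 5), c(38, 40), source = "simulated")
  expect_error(resample_to_volumes(trace, 100, 1),
               class = "cvrsvd_insufficient_trace")
})

test_that("zero delay is the identity shift", {
  s <- short_setup(seed = 4)
  reg <- resample_to_volumes(s$trace, 80, 1.5)
  expect_equal(shift_regressor(reg, 0)$values_mmHg, reg$values_mmHg)
})

test_that("a one-TR delay on a grid-sampled trace shifts indices and duplicates the first value", {
  n <- 30; tr_s <- 2
  tk <- volume_times(n, tr_s)
  vals <- 38 + seq_len(n) / 5
  trace <- etco2_trace(tk, vals, source = "simulated")
  reg <- resample_to_volumes(trace, n, tr_s)
  shifted <- shift_regressor(reg, tr_s)
  expect_equal(shifted$values_mmHg, c(vals[1], vals[-n]))
  expect_equal(shifted$applied_delay_s, tr_s)
})

test_that("shift then unshift restores interior values", {
  s <- short_setup(seed = 6)
  reg <- resample_to_volumes(s$trace, 80, 1.5)
  back <- shift_regressor(shift_regressor(reg, 7), -7)
  interior <- 10:70
  expect_equal(back$values_mmHg[interior], reg$values_mmHg[interior],
               tolerance = 1e-12)
  expect_equal(back$applied_delay_s, 0)
})

test_that("monotone traces stay monotone and bounds are never exceeded after shifting", {
  for (seed in 1:5) {
    set.seed(seed)
    times <- cumsum(runif(50, 1, 3))
    vals <- 35 + cumsum(runif(50, 0, 0.3))       # increasing
    trace <- etco2_trace(times, vals, source = "simulated")
    n <- floor(max(times) / 1.5)
    reg <- resample_to_volumes(trace, n, 1.5)
    expect_true(all(diff(reg$values_mmHg) >= -1e-12))
    for (d in c(-10, 5, 20)) {
      sh <- shift_regressor(reg, d)$values_mmHg
      expect_true(min(sh) >= min(vals) - 1e-12)
      expect_true(max(sh) <= max(vals) + 1e-12)
    }
  }
})

test_that("a delay at or beyond the scan duration is rejected", {
  s <- short_setup(seed = 4)
  reg <- resample_to_volumes(s$trace, 80, 1.5)
  expect_error(shift_regressor(reg, 80 * 1.5),
               class = "cvrsvd_invalid_argument")
})
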