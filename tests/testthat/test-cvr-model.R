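test_that("percent normalization matches hand arithmetic and is scale invariant", {
  expect_equal(normalize_percent(rep(5, 10)), rep(0, 10))
  expect_equal(normalize_percent(c(90, 110)), c(-10, 10))
  s <- 1000 + sin(1:50)
  expect_equal(normalize_percent(s), normalize_percent(3.7 * s))
  expect_equal(mean(normalize_percent(s)), 0)
  expect_error(normalize_percent(c(-2, -1, 0)), class = "cvrsvd_signal_error")
})

test_that("an exact linear relation is fitted with zero residual", {
  s <- short_setup(seed = 10)
  reg <- resample_to_volumes(s$trace, 80, 1.5)
  x <- reg$values_mmHg
  y <- 0.05 * (x - mean(x))
  f <- fit_at_delay(y, reg, 0)
  expect_equal(f$beta_co2, 0.05, tolerance = 1e-12)
  expect_lt(f$ssr, 1e-20)
})

test_that("a pure ramp is absorbed by the drift term, not the CO2 coefficient", {
  s <- short_setup(seed = 12)
  reg <- resample_to_volumes(s$trace, 80, 1.5)
  y <- 0.01 * (0:79)
  f <- fit_at_delay(y, reg, 0)
  expect_equal(f$beta_co2, 0, tolerance = 1e-10)
  expect_equal(f$beta_drift, 0.01, tolerance = 1e-10)
})

test_that("coefficients equal the normal-equations solution", {
  s <- short_setup(seed = 13)
  reg <- resample_to_volumes(s$trace, 80, 1.5)
  set.seed(13)
  y <- rnorm(80)
  f <- fit_at_delay(y, reg, 3)
  x <- shift_regressor(reg, 3)$values_mmHg
  X <- cbind(1, x, 0:79)
  beta <- normal_equations(X, y)
  expect_equal(c(f$intercept, f$beta_co2, f$beta_drift), beta,
               tolerance = 1e-9)
  expect_equal(f$ssr, sum((y - X %*% beta)^2), tolerance = 1e-9)
})

test_that("a constant regressor is a degenerate design", {
  trace <- etco2_trace(c(0, 50, 100), rep(40, 3), source = "simulated")
  reg <- resample_to_volumes(trace, 60, 1.5)
  expect_error(fit_at_delay(rnorm(60), reg, 0),
               class = "cvrsvd_degenerate_design")
})

test_that("a single-candidate grid reduces to fit_at_delay at that delay", {
  s <- short_setup(seed = 14, noise_sd_pct = 0.3)
  b <- simulate_bold_roi(s$trace, s$config)
  pct <- normalize_percent(b)
  res <- optimize_delay(pct, s$trace, delay_grid(0, 0, 1), tr_s = 1.5)
  reg <- resample_to_volumes(s$trace, 80, 1.5)
  f0 <- fit_at_delay(pct, reg, 0)
  expect_equal(res$delay_s, 0)
  expect_equal(res$cvr_pct_per_mmHg, f0$beta_co2)
  expect_equal(res$ssr, f0$ssr)
})

test_that("the selected delay attains the grid-wide SSR minimum (exhaustive check)", {
  grid <- delay_grid(-5, 20, 1)
  for (seed in 1:8) {
    set.seed(seed)
    s <- short_setup(seed = seed, noise_sd_pct = 0.4,
                     true_delay_s = sample(0:15, 1))
    pct <- normalize_percent(simulate_bold_roi(s$trace, s$config))
    res <- optimize_delay(pct, s$trace, grid, tr_s = 1.5)
    reg <- resample_to_volumes(s$trace, 80, 1.5)
    ssr_all <- vapply(grid$values,
                      function(d) fit_at_delay(pct, reg, d)$ssr, numeric(1))
    expect_equal(res$ssr, min(ssr_all), tolerance = 1e-12)
    expect_true(res$delay_s %in% grid$values)
  }
})

test_that("CVR, delay and R2 are invariant to rescaling the raw signal", {
  s <- short_setup(seed = 21, noise_sd_pct = 0.3)
  b <- simulate_bold_roi(s$trace, s$config)
  grid <- delay_grid(-5, 20, 1)
  r1 <- optimize_delay(normalize_percent(b$values), s$trace, grid, tr_s = 1.5)
  r2 <- optimize_delay(normalize_percent(b$values * 17.3), s$trace, grid,
                       tr_s = 1.5)
  expect_equal(r1$cvr_pct_per_mmHg, r2$cvr_pct_per_mmHg, tolerance = 1e-10)
  expect_equal(r1$delay_s, r2$delay_s)
  expect_equal(r1$r_squared, r2$r_squared, tolerance = 1e-10)
})

test_that("adding a zero-mean linear trend changes only the drift coefficient", {
  s <- short_setup(seed = 22)
  cfg <- s$config; cfg$noise_sd_pct <- 0
  b <- simulate_bold_roi(s$trace, cfg)
  grid <- delay_grid(-5, 20, 1)
  k <- 0:79
  trend <- 2 * (k - mean(k))            # raw signal units
  r1 <- optimize_delay(normalize_percent(b$values), s$trace, grid, tr_s = 1.5)
  r2 <- optimize_delay(normalize_percent(b$values + trend), s$trace, grid,
                       tr_s = 1.5)
  expect_equal(r2$cvr_pct_per_mmHg, r1$cvr_pct_per_mmHg, tolerance = 1e-8)
  expect_equal(r2$delay_s, r1$delay_s)
  expect_false(isTRUE(all.equal(r1$drift_pct_per_scan, r2$drift_pct_per_scan)))
})

test_that("CVR is recovered accurately at ROI-mean noise levels", {
  # noise SD 0.2% of baseline, the scale typical of ROI-mean series
  grid <- delay_grid(-5, 30, 1)
  p <- make_gas_paradigm(1, 1, 6)
  errs <- vapply(1:100, function(seed) {
    cfg <- sim_config(n_volumes = 232, true_delay_s = 8, noise_sd_pct = 0.2,
                      seed = seed)
    tr <- simulate_etco2(p, cfg)
    res <- optimize_delay(normalize_percent(simulate_bold_roi(tr, cfg)),
                          tr, grid, tr_s = cfg$tr_s)
    abs(res$cvr_pct_per_mmHg - cfg$true_cvr_pct_per_mmHg)
  }, numeric(1))
  expect_lt(median(errs), 0.005)
})

test_that("run_subject estimates every tissue and omits empty ROIs with a reason", {
  ms <- simulate_phantom_masks(c(24, 24, 24), c(2.5, 2.5, 2.5), seed = 1)
  p <- make_gas_paradigm(1, 1, 4)
  n_vol <- floor(p$total_duration_s / 1.55)
  cfg <- sim_config(n_volumes = n_vol, true_delay_s = 6,
                    drift_pct_per_scan = 0, noise_sd_pct = 0, seed = 3)
  trace <- simulate_etco2(p, cfg)
  true_cvr <- c(sgm = 0.171, nawm = 0.042, wmh = 0.040)

  dims <- c(24, 24, 24)
  bold <- array(cfg$baseline_signal, c(dims, n_vol))
  flat <- matrix(bold, prod(dims), n_vol)
  for (lab in names(true_cvr)) {
    cfg_lab <- cfg; cfg_lab$true_cvr_pct_per_mmHg <- true_cvr[[lab]]
    series <- simulate_bold_roi(trace, cfg_lab)$values
    vox <- which(ms$masks[[lab]])
    flat[vox, ] <- matrix(series, length(vox), n_vol, byrow = TRUE)
  }
  bold <- array(flat, c(dims, n_vol))

  res <- run_subject(bold, ms, trace, 1.55, grid = delay_grid(-5, 20, 1))
  expect_setequal(res$roi, c("sgm", "nawm", "wmh"))
  for (lab in names(true_cvr)) {
    expect_equal(res$cvr_pct_per_mmHg[res$roi == lab], true_cvr[[lab]],
                 tolerance = 1e-6, info = lab)
    expect_equal(res$delay_s[res$roi == lab], 6)
  }
  # determinism: a second identical run gives identical results
  res2 <- run_subject(bold, ms, trace, 1.55, grid = delay_grid(-5, 20, 1))
  expect_identical(res, res2)

  # empty WMH mask: omitted with a reason, other ROIs unaffected
  ms_empty <- ms
  ms_empty$masks$wmh <- array(FALSE, dims)
  res3 <- run_subject(bold, ms_empty, trace, 1.55,
                      grid = delay_grid(-5, 20, 1))
  expect_setequal(res3$roi, c("sgm", "nawm"))
  skipped <- attr(res3, "skipped")
  expect_equal(skipped$roi, "wmh")
  expect_match(skipped$reason, "empty")
})

test_that("an all-air paradigm yields a degenerate design for every ROI", {
  ms <- simulate_phantom_masks(c(24, 24, 24), c(2.5, 2.5, 2.5), seed = 2)
  p <- make_gas_paradigm(2, 3, 2)          # air only
  n_vol <- floor(p$total_duration_s / 1.55)
  cfg <- sim_config(n_volumes = n_vol, breath_jitter_sd_s = 0,
                    noise_sd_pct = 0, seed = 1)
  trace <- simulate_etco2(p, cfg)
  bold <- array(cfg$baseline_signal + rnorm(24^3 * n_vol, 0, 0.1),
                c(24, 24, 24, n_vol))
  res <- run_subject(bold, ms, trace, 1.55, grid = delay_grid(-5, 20, 1))
  expect_equal(nrow(res), 0)
  expect_equal(nrow(attr(res, "skipped")), 3)
})
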