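test_that("WMH volume transform is log10 with the expected anchors", {
  expect_equal(transform_wmh(1.0), 0)
  expect_equal(transform_wmh(0.51), log10(0.51))
  # a ten-fold volume increase adds exactly 1 to the predictor
  x <- c(0.3, 3)
  expect_equal(diff(transform_wmh(x)), 1)
  expect_warning(out <- transform_wmh(c(0.5, 0, -1)), "non-positive")
  expect_equal(is.na(out), c(FALSE, TRUE, TRUE))
})

test_that("univariable fit equals the normal-equations solution", {
  d <- tiny_cohort(n = 12, seed = 99)
  r <- fit_model(d, "nawm", "x", adjusted = FALSE)
  X <- cbind(1, d$x)
  beta <- normal_equations(X, d$cvr_nawm)
  expect_equal(r$B, beta[2], tolerance = 1e-10)
  expect_equal(r$model, "univariable")
  expect_equal(r$n_used, 12L)
  # t-based 95% CI with n - 2 residual df
  se <- sqrt(sum(lm(cvr_nawm ~ x, d)$residuals^2) / 10 /
               sum((d$x - mean(d$x))^2))
  expect_equal(r$ci95_high - r$B, qt(0.975, 10) * se, tolerance = 1e-10)
})

test_that("a null effect is estimated near zero with nominal CI coverage", {
  covered <- logical(120)
  for (i in seq_along(covered)) {
    d <- simulate_cohort(cohort_sim_config(n_subjects = 120, seed = 300 + i))
    r <- fit_model(d, "nawm", "svd_score", adjusted = TRUE)
    covered[i] <- r$ci95_low <= 0 && 0 <= r$ci95_high
  }
  expect_gt(mean(covered), 0.88)
})

test_that("missing data are excluded per model (complete-case)", {
  d <- simulate_cohort(cohort_sim_config(n_subjects = 182, seed = 50))
  d$moca[1:3] <- NA
  r <- fit_model(d, "nawm", "moca", adjusted = TRUE)
  expect_equal(r$n_used, 179L)
  # other models keep the full cohort
  expect_equal(fit_model(d, "nawm", "svd_score")$n_used, 182L)
  # too few complete cases is an explicit error
  d$svd_score[-(1:5)] <- NA
  expect_error(fit_model(d, "nawm", "svd_score"),
               class = "cvrsvd_insufficient_data")
})

test_that("near-duplicate covariates trigger the collinearity warning", {
  d <- simulate_cohort(cohort_sim_config(n_subjects = 182, seed = 51))
  d$map_mmHg <- 2 * d$age_years + rnorm(182, 0, 1e-4)
  expect_warning(fit_model(d, "nawm", "svd_score", adjusted = TRUE),
                 "collinearity")
})

test_that("standardized coefficients follow the z-score convention", {
  set.seed(7)
  d <- data.frame(x = rnorm(40, 10, 4), cvr_nawm = rnorm(40, 0.04, 0.02))
  r <- fit_model(d, "nawm", "x", adjusted = FALSE)
  rs <- standardize_coefficients(r, d)
  expect_equal(rs$standardized_B, r$B * sd(d$x) / sd(d$cvr_nawm))

  # pre-z-scored variables: standardized equals raw
  dz <- data.frame(x = scale(d$x)[, 1], cvr_nawm = scale(d$cvr_nawm)[, 1])
  rz <- fit_model(dz, "nawm", "x", adjusted = FALSE)
  rzs <- standardize_coefficients(rz, dz)
  expect_equal(rzs$standardized_B, rz$B, tolerance = 1e-10)

  # doubling the predictor units halves B but not standardized B
  d2 <- d; d2$x <- d$x / 2
  r2 <- standardize_coefficients(fit_model(d2, "nawm", "x", adjusted = FALSE), d2)
  expect_equal(r2$B, 2 * r$B, tolerance = 1e-10)
  expect_equal(r2$standardized_B, rs$standardized_B, tolerance = 1e-10)

  # predictor-only convention
  rp <- standardize_coefficients(r, d, convention = "predictor_only")
  expect_equal(rp$standardized_B, r$B * sd(d$x))

  # zero variance flagged as undefined
  d0 <- d; d0$x <- 5
  r0 <- r
  expect_warning(rs0 <- standardize_coefficients(r0, d0), "zero variance")
  expect_true(is.na(rs0$standardized_B))
})

test_that("paired region differences match hand calculation and handle edge cases", {
  d <- data.frame(cvr_sgm = c(0.20, 0.15, 0.19),
                  cvr_nawm = c(0.05, 0.04, 0.06))
  pd <- paired_region_difference(d, "sgm", "nawm")
  diffs <- d$cvr_sgm - d$cvr_nawm
  expect_equal(pd$mean_difference, mean(diffs))
  hw <- qt(0.975, 2) * sd(diffs) / sqrt(3)
  expect_equal(pd$ci95_low, mean(diffs) - hw, tolerance = 1e-10)
  expect_equal(pd$ci95_high, mean(diffs) + hw, tolerance = 1e-10)
  expect_equal(pd$n_pairs, 3L)

  # identical columns: zero difference with a degenerate [0,0] interval
  d2 <- data.frame(cvr_sgm = c(0.1, 0.2, 0.3), cvr_nawm = c(0.1, 0.2, 0.3))
  pd2 <- paired_region_difference(d2, "sgm", "nawm")
  expect_equal(pd2$mean_difference, 0)
  expect_equal(pd2$ci95_low, 0)
  expect_equal(pd2$ci95_high, 0)

  # pairwise-complete cases only; fewer than 3 pairs errors
  d3 <- data.frame(cvr_sgm = c(0.2, NA, 0.3), cvr_nawm = c(0.1, 0.1, NA))
  expect_error(paired_region_difference(d3, "sgm", "nawm"),
               class = "cvrsvd_insufficient_data")
})

test_that("assumption checks calibrate on clean data and detect heteroscedasticity", {
  pass_both <- logical(40)
  for (i in seq_along(pass_both)) {
    d <- simulate_cohort(cohort_sim_config(n_subjects = 182, seed = 600 + i))
    chk <- check_assumptions(fit_model(d, "nawm", "svd_score"))
    pass_both[i] <- chk$available && !chk$normality_flagged &&
      !chk$heteroscedasticity_flagged
  }
  expect_gt(mean(pass_both), 0.8)

  flagged <- logical(40)
  for (i in seq_along(flagged)) {
    set.seed(700 + i)
    x <- runif(182, 0, 4)
    mu <- 1 + 0.5 * x
    d <- data.frame(x = x, cvr_nawm = mu + rnorm(182, 0, 0.4 * mu))
    chk <- check_assumptions(fit_model(d, "nawm", "x", adjusted = FALSE))
    flagged[i] <- isTRUE(chk$heteroscedasticity_flagged)
  }
  expect_gt(mean(flagged), 0.8)

  # constant residuals (an exact fit): report unavailable
  d <- data.frame(x = 1:12, cvr_nawm = 2 * (1:12))
  chk <- suppressWarnings(
    check_assumptions(fit_model(d, "nawm", "x", adjusted = FALSE)))
  expect_false(chk$available)
})

test_that("the adjusted-analysis table has one model per predictor and ROI", {
  d <- simulate_cohort(cohort_sim_config(n_subjects = 182, seed = 60))
  t2 <- build_table2(d)
  expect_equal(nrow(t2), 20 * 3)
  expect_true(all(t2$model == "multivariable"))
  expect_true(all(t2$ci95_low <= t2$B & t2$B <= t2$ci95_high))
  expect_true(all(is.finite(t2$standardized_B)))
  expect_equal(t2$units_text[t2$predictor == "log10_wmh_pct_icv"][1],
               "%BOLD/mmHg per log_10(%ICV)")
  expect_equal(t2$units_text[t2$predictor == "n_lacunes"][1],
               "%BOLD/mmHg per lacune")

  # missing MoCA propagates into that model's n only
  d$moca[1:3] <- NA
  t2b <- build_table2(d)
  expect_equal(unique(t2b$n_used[t2b$predictor == "moca"]), 179L)
  expect_equal(unique(t2b$n_used[t2b$predictor == "svd_score"]), 182L)

  # an empty cohort returns an empty table without failing
  t2e <- build_table2(d[0, ])
  expect_equal(nrow(t2e), 0)
  expect_equal(nrow(attr(t2e, "errors")), 60)
})

test_that("univariable and multivariable estimates coincide under orthogonal covariates", {
  true_b <- -0.005
  cfg <- cohort_sim_config(
    n_subjects = 5000,
    coefficient_map = list(nawm = c(svd_score = true_b)),
    seed = 77
  )
  d <- simulate_cohort(cfg)
  bu <- fit_model(d, "nawm", "svd_score", adjusted = FALSE)$B
  bm <- fit_model(d, "nawm", "svd_score", adjusted = TRUE)$B
  expect_equal(bu, bm, tolerance = 0.05)
  expect_equal(bu, true_b, tolerance = 0.05)
})
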