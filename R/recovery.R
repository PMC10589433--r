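#' Coefficient-recovery simulation study
#'
#' Repeatedly simulates cohorts in which one SVD predictor has a known
#' true effect on CVR in one ROI, with the residual SD back-solved per
#' replicate so the fitted coefficient's standard error matches a printed
#' 95% CI ([calibrate_residual_sd()]), then refits the covariate-adjusted
#' model and records the estimate and whether its 95% CI covers the
#' truth. This is the package's parameter-recovery check: an unbiased
#' estimator with a correct interval should average to the generating
#' value with ~95% coverage.
#'
#' @param predictor Cohort predictor column (e.g. `"n_lacunes"`,
#'   `"log10_wmh_pct_icv"`).
#' @param true_b Generating coefficient (outcome units per predictor
#'   unit).
#' @param ci_low,ci_high Printed 95% CI bounds whose width calibrates the
#'   residual SD.
#' @param outcome_roi ROI whose CVR is the outcome.
#' @param intercept Outcome intercept, %/mmHg.
#' @param n_subjects Cohort size per replicate.
#' @param n_replicates Number of replicates.
#' @param seed Base seed; replicate seeds are derived from it.
#'
#' @return List with `mean_B`, `coverage`, `se_target`, `B` (per
#'   replicate), `n_replicates`, `n_subjects`.
#' @export
coefficient_recovery_study <- function(predictor, true_b, ci_low, ci_high,
                                       outcome_roi = "nawm",
                                       intercept = 0.042,
                                       n_subjects = 182,
                                       n_replicates = 200,
                                       seed = 1) {
  df <- n_subjects - 10   # intercept + predictor + 8 adjustment terms
  se_target <- ci_halfwidth_to_se(ci_low, ci_high, df)
  outcome <- paste0("cvr_", outcome_roi)
  B <- numeric(n_replicates)
  covered <- logical(n_replicates)
  for (i in seq_len(n_replicates)) {
    d <- simulate_cohort(cohort_sim_config(n_subjects = n_subjects,
                                           seed = seed + 2L * i))
    sigma <- calibrate_residual_sd(d, predictor, se_target)
    d[[outcome]] <- with_seed(seed + 2L * i + 1L,
      intercept + true_b * d[[predictor]] +
        stats::rnorm(n_subjects, 0, sigma))
    r <- fit_model(d, outcome_roi, predictor, adjusted = TRUE)
    B[i] <- r$B
    covered[i] <- r$ci95_low <= true_b && true_b <= r$ci95_high
  }
  list(mean_B = mean(B), coverage = mean(covered), se_target = se_target,
       B = B, n_replicates = n_replicates, n_subjects = n_subjects)
}

#' Paired inter-region contrast recovery study
#'
#' Simulates cohorts with a known true within-subject CVR difference
#' between two regions, the difference SD calibrated so the paired 95% CI
#' width matches a printed interval, and averages the paired estimator
#' ([paired_region_difference()]) over replicates.
#'
#' @param true_diff Generating mean within-subject difference, %/mmHg.
#' @param ci_low,ci_high Printed 95% CI of the mean difference.
#' @param base_mean,base_sd Marginal distribution of the reference
#'   region's CVR.
#' @param n_subjects Subjects per replicate.
#' @param n_replicates Number of replicates.
#' @param seed Base seed.
#'
#' @return List with `mean_difference` (average over replicates),
#'   `estimates`, `sd_diff`, `n_replicates`.
#' @export
paired_contrast_study <- function(true_diff, ci_low, ci_high,
                                  base_mean = 0.042, base_sd = 0.0156,
                                  n_subjects = 182, n_replicates = 200,
                                  seed = 1) {
  # printed CI half-width -> SE of the mean difference -> SD of
  # within-subject differences
  sd_diff <- ci_halfwidth_to_se(ci_low, ci_high, n_subjects - 1) *
    sqrt(n_subjects)
  est <- numeric(n_replicates)
  for (i in seq_len(n_replicates)) {
    d <- with_seed(seed + i, {
      ref <- stats::rnorm(n_subjects, base_mean, base_sd)
      data.frame(cvr_nawm = ref,
                 cvr_sgm = ref + stats::rnorm(n_subjects, true_diff, sd_diff))
    })
    est[i] <- paired_region_difference(d, "sgm", "nawm")$mean_difference
  }
  list(mean_difference = mean(est), estimates = est, sd_diff = sd_diff,
       n_replicates = n_replicates)
}
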