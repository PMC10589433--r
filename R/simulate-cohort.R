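#' Configuration for synthetic SVD cohort generation
#'
#' Defines the generative model for a cohort of small-vessel-disease
#' patients: covariates and SVD features drawn from distributions chosen
#' to approximate the study population's printed medians and IQRs, and
#' per-ROI CVR built as
#' `intercept_roi + sum_j B_j x_j + eps`, `eps ~ N(0, residual_sd_roi)`.
#'
#' @param n_subjects Cohort size; must exceed the number of model terms
#'   plus 2.
#' @param coefficient_map Named list, one element per ROI (`sgm`, `nawm`,
#'   `wmh`), each a named numeric vector of true coefficients per
#'   predictor unit (predictor names are cohort columns;
#'   `"log10_wmh_pct_icv"` refers to the log10 of WMH volume in %ICV).
#'   Omitted ROIs/predictors have zero effect.
#' @param residual_sd Named numeric: residual SD of CVR per ROI, %/mmHg.
#'   Defaults approximate the marginal spread of CVR in the study cohort
#'   (IQR/1.349 of the printed per-ROI distributions).
#' @param roi_intercepts Named numeric: CVR intercepts per ROI, %/mmHg;
#'   defaults are the printed cohort medians.
#' @param seed RNG seed recorded in the cohort.
#'
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_subjects = 182,
                              coefficient_map = list(),
                              residual_sd = c(sgm = 0.053, nawm = 0.0156,
                                              wmh = 0.029),
                              roi_intercepts = c(sgm = 0.171, nawm = 0.042,
                                                 wmh = 0.040),
                              seed = NULL) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 12) {
    stop_invalid("`n_subjects` must be at least 12 (model terms + 2)")
  }
  if (any(residual_sd <= 0)) stop_invalid("`residual_sd` must be > 0")
  rois <- c("sgm", "nawm", "wmh")
  if (!all(names(coefficient_map) %in% rois)) {
    stop_invalid("`coefficient_map` names must be among ", paste(rois, collapse = ", "))
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 coefficient_map = coefficient_map,
                 residual_sd = residual_sd,
                 roi_intercepts = roi_intercepts,
                 seed = seed),
            class = "cohort_sim_config")
}

# Predictors the generative model knows how to resolve to design columns.
.supported_predictors <- function() {
  c("log10_wmh_pct_icv", "wmh_pct_icv", "fazekas_pv", "fazekas_deep",
    "fazekas_total", "n_lacunes", "n_microbleeds", "atrophy_deep",
    "atrophy_superficial", "atrophy_total", "brain_pct_icv",
    "pvs_bg_score", "pvs_cso_score", "pvs_total_score",
    "pvs_bg_pct_roiv", "pvs_cso_pct_roiv", "pvs_total_pct_roiv",
    "svd_score", "nihss", "mrs", "moca",
    "age_years", "map_mmHg")
}

# Draw covariates and SVD features for n subjects. Families and parameters
# approximate the study's printed medians/IQRs: normals for age/MAP/brain
# volume, log-normals for WMH and PVS volumes, categorical scores, an
# overdispersed count for lacunes and a zero-inflated count for
# microbleeds.
.draw_covariates <- function(n) {
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    age_years = pmin(pmax(stats::rnorm(n, 66, 13), 30), 95),
    sex = factor(sample(c("male", "female"), n, TRUE, prob = c(0.68, 0.32)),
                 levels = c("female", "male")),
    map_mmHg = stats::rnorm(n, 106, 12),
    smoking = factor(sample(c("never", "ex_gt1y", "current_recent"), n, TRUE,
                            prob = c(0.46, 0.39, 0.15)),
                     levels = c("never", "ex_gt1y", "current_recent")),
    hypertension = stats::rbinom(n, 1, 0.70),
    diabetes = stats::rbinom(n, 1, 0.20),
    hypercholesterolaemia = stats::rbinom(n, 1, 0.74),
    wmh_pct_icv = 10^stats::rnorm(n, -0.29, 0.50),
    fazekas_pv = sample(0:3, n, TRUE, prob = c(0.15, 0.45, 0.25, 0.15)),
    fazekas_deep = sample(0:3, n, TRUE, prob = c(0.15, 0.45, 0.25, 0.15)),
    n_lacunes = stats::rnbinom(n, size = 0.9, mu = 1.8),
    n_microbleeds = stats::rbinom(n, 1, 0.22) *
      (1 + stats::rnbinom(n, size = 0.6, mu = 2)),
    atrophy_deep = pmin(pmax(round(stats::rnorm(n, 3, 1.2)), 0), 6),
    atrophy_superficial = pmin(pmax(round(stats::rnorm(n, 3, 1.2)), 0), 6),
    brain_pct_icv = stats::rnorm(n, 67.5, 4.7),
    pvs_bg_score = sample(0:4, n, TRUE, prob = c(0.10, 0.30, 0.30, 0.20, 0.10)),
    pvs_cso_score = sample(0:4, n, TRUE, prob = c(0.05, 0.15, 0.50, 0.20, 0.10)),
    pvs_bg_pct_roiv = stats::rlnorm(n, log(4.9), 0.49),
    pvs_cso_pct_roiv = stats::rlnorm(n, log(3.3), 0.76),
    svd_score = sample(0:4, n, TRUE, prob = c(0.30, 0.30, 0.20, 0.13, 0.07)),
    nihss = stats::rpois(n, 1.3),
    mrs = sample(0:2, n, TRUE, prob = c(0.20, 0.60, 0.20)),
    moca = pmin(pmax(round(stats::rnorm(n, 24.5, 3.3)), 0), 30)
  )
}

.finish_covariates <- function(d) {
  d$fazekas_total <- d$fazekas_pv + d$fazekas_deep
  d$atrophy_total <- d$atrophy_deep + d$atrophy_superficial
  d$pvs_total_score <- pmin(d$pvs_bg_score + d$pvs_cso_score, 8)
  d$pvs_total_pct_roiv <- d$pvs_bg_pct_roiv + d$pvs_cso_pct_roiv
  d$log10_wmh_pct_icv <- log10(d$wmh_pct_icv)
  d
}

#' Simulate a cohort of SVD subjects with known CVR effects
#'
#' Draws covariates and SVD features per subject, then builds per-ROI CVR
#' as a linear model with the configured true coefficients plus Gaussian
#' residual noise. WMH volume is drawn log-normal so that
#' `log10(wmh_pct_icv)` is the linear predictor, matching how WMH volume
#' enters the cohort regressions. If a drawn design is singular (a
#' constant covariate, possible at small `n_subjects`), the cohort is
#' regenerated with the next seed, with a warning.
#'
#' @param config A [cohort_sim_config()].
#'
#' @return A data.frame of one row per subject (see the column dictionary
#'   in the package vignette) including `cvr_sgm`, `cvr_nawm`, `cvr_wmh`,
#'   with attributes `seed` and `true_coefficients`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  bad <- setdiff(unlist(lapply(config$coefficient_map, names)),
                 .supported_predictors())
  if (length(bad)) {
    stop_invalid("unsupported predictors in coefficient_map: ",
                 paste(bad, collapse = ", "))
  }

  seed <- config$seed
  for (attempt in 1:5) {
    d <- with_seed(seed, {
      d <- .finish_covariates(.draw_covariates(config$n_subjects))
      for (roi in c("sgm", "nawm", "wmh")) {
        mu <- rep(config$roi_intercepts[[roi]], nrow(d))
        betas <- config$coefficient_map[[roi]]
        if (!is.null(betas)) {
          for (p in names(betas)) mu <- mu + betas[[p]] * d[[p]]
        }
        d[[paste0("cvr_", roi)]] <-
          mu + stats::rnorm(nrow(d), 0, config$residual_sd[[roi]])
      }
      d
    })
    num <- vapply(d[setdiff(names(d), "subject_id")],
                  function(col) stats::var(as.numeric(col)), numeric(1))
    if (all(num > 0)) {
      attr(d, "seed") <- seed
      attr(d, "true_coefficients") <- config$coefficient_map
      return(d)
    }
    warning("singular design (constant covariate); regenerating with a new seed")
    seed <- if (is.null(seed)) NULL else seed + 1L
  }
  stop_invalid("could not draw a non-singular cohort in 5 attempts")
}

#' Back-solve the residual SD that reproduces a printed standard error
#'
#' For an OLS coefficient, `Var(B_j) = sigma^2 / RSS(x_j | other terms)`,
#' where the denominator is the residual sum of squares of the predictor
#' regressed on all other model terms. Given a target SE (e.g. derived
#' from a printed 95% CI) and a realised design, the residual SD that
#' yields that SE is `sigma = SE * sqrt(RSS(x_j | others))`. This makes
#' coefficient-recovery simulations match the precision of the reported
#' estimates.
#'
#' @param cohort A cohort data.frame (e.g. from [simulate_cohort()]).
#' @param predictor Predictor column name.
#' @param se_target Target standard error of the predictor's coefficient.
#' @param covariates Other model terms; defaults to the standard
#'   adjustment set ([cvr_adjustment_covariates()]).
#'
#' @return The calibrated residual SD (same units as the outcome).
#' @export
calibrate_residual_sd <- function(cohort, predictor, se_target,
                                  covariates = cvr_adjustment_covariates()) {
  assert_scalar_pos(se_target, "se_target")
  if (!predictor %in% names(cohort)) {
    stop_invalid("predictor '", predictor, "' not in cohort")
  }
  f <- stats::reformulate(covariates, response = predictor)
  rss <- sum(stats::residuals(stats::lm(f, data = cohort))^2)
  se_target * sqrt(rss)
}

#' Convert a printed 95% confidence interval to a standard error
#'
#' @param ci_low,ci_high Printed interval bounds.
#' @param df Residual degrees of freedom of the reported model (t-based
#'   CI).
#' @return The implied standard error `(ci_high - ci_low) / 2 / t_{0.975,df}`.
#' @export
ci_halfwidth_to_se <- function(ci_low, ci_high, df) {
  if (ci_high < ci_low) stop_invalid("`ci_high` must be >= `ci_low`")
  assert_scalar_pos(df, "df")
  (ci_high - ci_low) / 2 / stats::qt(0.975, df)
}
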