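#' Standard adjustment covariates for the cohort regressions
#'
#' The multivariable CVR models adjust for age, sex, mean arterial
#' pressure, smoking history (current/recent vs ex-smoker >1 year vs
#' never; never is the reference level) and diagnoses of hypertension,
#' diabetes and hypercholesterolaemia.
#'
#' @return Character vector of cohort column names.
#' @export
cvr_adjustment_covariates <- function() {
  c("age_years", "sex", "map_mmHg", "smoking",
    "hypertension", "diabetes", "hypercholesterolaemia")
}

#' Log10-transform WMH volume
#'
#' WMH volumes (in %ICV) are strongly right-skewed; regressions use
#' `log10` so residuals are closer to normal. A downstream coefficient is
#' then in %/mmHg per ten-fold increase in WMH volume. Non-positive
#' volumes cannot be transformed and return `NA` (those subjects drop out
#' of the affected models as missing data); their count is reported via a
#' warning.
#'
#' @param wmh_pct_icv Numeric WMH volumes, %ICV.
#' @return `log10(wmh_pct_icv)`, with `NA` where the input is not
#'   positive.
#' @export
transform_wmh <- function(wmh_pct_icv) {
  x <- as.numeric(wmh_pct_icv)
  bad <- !is.na(x) & x <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive WMH volume(s) set to NA before log10")
    x[bad] <- NA_real_
  }
  log10(x)
}

.units_text <- function(predictor) {
  units <- c(
    log10_wmh_pct_icv = "%BOLD/mmHg per log_10(%ICV)",
    n_lacunes = "%BOLD/mmHg per lacune",
    n_microbleeds = "%BOLD/mmHg per microbleed",
    brain_pct_icv = "%BOLD/mmHg per %ICV",
    pvs_bg_pct_roiv = "%BOLD/mmHg per %ROIV",
    pvs_cso_pct_roiv = "%BOLD/mmHg per %ROIV",
    pvs_total_pct_roiv = "%BOLD/mmHg per %ROIV"
  )
  if (predictor %in% names(units)) units[[predictor]]
  else "%BOLD/mmHg per score unit"
}

#' Fit one cohort regression of CVR on a predictor
#'
#' Ordinary least squares with CVR in one ROI as outcome and a single SVD
#' or clinical predictor of interest, either univariable or adjusted for
#' the standard covariate set ([cvr_adjustment_covariates()]). One model
#' per (ROI, predictor) pair. Missing data are excluded per model
#' (complete-case); at least 10 complete cases are required. The scaled
#' design's condition number is checked and a collinearity warning issued
#' above the threshold. The 95% CI uses the t distribution with residual
#' degrees of freedom.
#'
#' @param cohort Cohort data.frame with a `cvr_<roi>` outcome column.
#' @param outcome_roi One of `"sgm"`, `"nawm"`, `"wmh"`.
#' @param predictor Predictor column name.
#' @param adjusted Adjust for the standard covariates? (default `TRUE`).
#' @param condition_threshold Condition-number threshold for the
#'   collinearity warning.
#'
#' @return A one-row data.frame (`regression_result`): `outcome_roi`,
#'   `predictor`, `model`, `B`, `ci95_low`, `ci95_high`, `p_value`,
#'   `n_used`, `units_text`, `standardized_B` (NA until
#'   [standardize_coefficients()]). The `lm` fit is attached as attribute
#'   `fit`.
#' @export
fit_model <- function(cohort, outcome_roi, predictor, adjusted = TRUE,
                      condition_threshold = 30) {
  outcome <- paste0("cvr_", outcome_roi)
  if (!outcome %in% names(cohort)) stop_invalid("no column ", outcome)
  if (!predictor %in% names(cohort)) stop_invalid("no column ", predictor)
  covars <- if (adjusted) cvr_adjustment_covariates() else character()
  covars <- setdiff(covars, predictor)
  vars <- c(outcome, predictor, covars)
  cc <- stats::complete.cases(cohort[vars])
  d <- cohort[cc, vars, drop = FALSE]
  if (nrow(d) < 10L) {
    stop(errorCondition(
      sprintf("only %d complete cases for %s ~ %s (need >= 10)",
              nrow(d), outcome, predictor),
      class = c("cvrsvd_insufficient_data", "error")))
  }

  f <- stats::reformulate(c(predictor, covars), response = outcome)
  fit <- stats::lm(f, data = d)

  X <- stats::model.matrix(fit)[, -1, drop = FALSE]
  Xs <- scale(X)
  if (!anyNA(Xs) && ncol(Xs) > 1) {
    kap <- kappa(Xs, exact = TRUE)
    if (is.finite(kap) && kap > condition_threshold) {
      warning(sprintf("collinearity: design condition number %.1f > %g",
                      kap, condition_threshold))
    }
  }

  sm <- summary(fit)$coefficients
  # a factor predictor would contribute several terms; predictors of
  # interest here are numeric, so there is exactly one matching row
  row <- grep(paste0("^", predictor), rownames(sm))[1]
  ci <- stats::confint(fit, level = 0.95)[row, ]
  out <- data.frame(outcome_roi = outcome_roi,
                    predictor = predictor,
                    model = if (adjusted) "multivariable" else "univariable",
                    B = sm[row, "Estimate"],
                    ci95_low = ci[[1]],
                    ci95_high = ci[[2]],
                    p_value = sm[row, "Pr(>|t|)"],
                    n_used = nrow(d),
                    units_text = .units_text(predictor),
                    standardized_B = NA_real_,
                    row.names = NULL)
  class(out) <- c("regression_result", "data.frame")
  attr(out, "fit") <- fit
  out
}

#' Standardize a regression coefficient
#'
#' Converts a raw coefficient to standardized form for forest-plot
#' comparison across predictors with different units. The default
#' (`"both"`) is the z-score convention `B * sd(x) / sd(y)` on the
#' complete cases used for that model; `"predictor_only"` gives
#' `B * sd(x)` (outcome units per SD of predictor).
#'
#' @param result A `regression_result` from [fit_model()].
#' @param cohort The cohort the model was fitted on.
#' @param convention `"both"` or `"predictor_only"`.
#'
#' @return The `regression_result` with `standardized_B` filled in.
#' @export
standardize_coefficients <- function(result, cohort,
                                     convention = c("both", "predictor_only")) {
  convention <- match.arg(convention)
  stopifnot(inherits(result, "regression_result"))
  outcome <- paste0("cvr_", result$outcome_roi)
  cc <- stats::complete.cases(cohort[c(outcome, result$predictor)])
  x <- as.numeric(cohort[[result$predictor]][cc])
  y <- cohort[[outcome]][cc]
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (!is.finite(sx) || sx == 0 || (convention == "both" && (!is.finite(sy) || sy == 0))) {
    warning("zero variance: standardized coefficient undefined")
    result$standardized_B <- NA_real_
    return(result)
  }
  result$standardized_B <- if (convention == "both") result$B * sx / sy
                           else result$B * sx
  result
}

#' Paired within-subject CVR contrast between two regions
#'
#' Mean of the within-subject CVR differences (`roi_a - roi_b`) over
#' pairwise-complete subjects, with a t-based 95% CI. Used for the
#' SGM-NAWM and WMH-NAWM contrasts.
#'
#' @param cohort Cohort data.frame with `cvr_<roi>` columns.
#' @param roi_a,roi_b Region labels.
#'
#' @return List with `mean_difference`, `ci95_low`, `ci95_high`,
#'   `p_value`, `n_pairs`.
#' @export
paired_region_difference <- function(cohort, roi_a, roi_b) {
  a <- cohort[[paste0("cvr_", roi_a)]]
  b <- cohort[[paste0("cvr_", roi_b)]]
  if (is.null(a) || is.null(b)) stop_invalid("missing cvr columns")
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3L) {
    stop(errorCondition("fewer than 3 complete pairs",
                        class = c("cvrsvd_insufficient_data", "error")))
  }
  diffs <- a[ok] - b[ok]
  if (stats::sd(diffs) == 0) {
    m <- mean(diffs)
    return(list(mean_difference = m, ci95_low = m, ci95_high = m,
                p_value = NA_real_, n_pairs = length(diffs)))
  }
  tt <- stats::t.test(a[ok], b[ok], paired = TRUE)
  list(mean_difference = unname(tt$estimate),
       ci95_low = tt$conf.int[1], ci95_high = tt$conf.int[2],
       p_value = tt$p.value, n_pairs = length(diffs))
}

#' Residual diagnostics for a cohort regression
#'
#' Advisory checks of the OLS assumptions: Shapiro-Wilk for normality of
#' residuals and Breusch-Pagan for heteroscedasticity, flagged at
#' alpha = 0.05. No refitting is performed; the flags inform e.g. whether
#' a predictor should be transformed.
#'
#' @param fit An `lm` fit, or a `regression_result` carrying one.
#' @param alpha Flagging level.
#'
#' @return List with `available`, `shapiro_p`, `breusch_pagan_p`,
#'   `normality_flagged`, `heteroscedasticity_flagged`.
#' @export
check_assumptions <- function(fit, alpha = 0.05) {
  if (inherits(fit, "regression_result")) fit <- attr(fit, "fit")
  if (!inherits(fit, "lm")) stop_invalid("`fit` must be an lm or regression_result")
  res <- stats::residuals(fit)
  if (length(res) < 3L || length(res) > 5000L ||
      stats::sd(res) < sqrt(.Machine$double.eps)) {
    return(list(available = FALSE, shapiro_p = NA_real_,
                breusch_pagan_p = NA_real_,
                normality_flagged = NA, heteroscedasticity_flagged = NA))
  }
  sw <- stats::shapiro.test(res)
  bp <- lmtest::bptest(fit)
  list(available = TRUE,
       shapiro_p = sw$p.value,
       breusch_pagan_p = unname(bp$p.value),
       normality_flagged = sw$p.value < alpha,
       heteroscedasticity_flagged = unname(bp$p.value) < alpha)
}

# Predictor rows of the adjusted-analysis table, in presentation order.
.table2_predictors <- function() {
  c("log10_wmh_pct_icv", "fazekas_pv", "fazekas_deep", "fazekas_total",
    "n_lacunes", "n_microbleeds", "atrophy_deep", "atrophy_superficial",
    "atrophy_total", "brain_pct_icv", "pvs_bg_score", "pvs_cso_score",
    "pvs_total_score", "pvs_bg_pct_roiv", "pvs_cso_pct_roiv",
    "pvs_total_pct_roiv", "svd_score", "nihss", "mrs", "moca")
}

#' Build the full adjusted-analysis table
#'
#' Fits one covariate-adjusted model per SVD/clinical predictor and ROI
#' (20 predictors x 3 ROIs when all columns are present): CVR as outcome,
#' adjusted for age, sex and vascular risk factors. WMH volume enters as
#' `log10(%ICV)` (computed here via [transform_wmh()] if not already a
#' column). Models that cannot be fitted (missing column, too few
#' complete cases) are collected in the `errors` attribute rather than
#' aborting the table.
#'
#' @param cohort Cohort data.frame.
#' @param rois ROIs to model.
#' @param standardize Also fill `standardized_B` (z-score convention)?
#'
#' @return A data.frame of stacked [fit_model()] rows with attribute
#'   `errors` (data.frame of skipped models and reasons).
#' @export
build_table2 <- function(cohort, rois = c("sgm", "nawm", "wmh"),
                         standardize = TRUE) {
  if (nrow(cohort) > 0 && !"log10_wmh_pct_icv" %in% names(cohort) &&
      "wmh_pct_icv" %in% names(cohort)) {
    cohort$log10_wmh_pct_icv <- transform_wmh(cohort$wmh_pct_icv)
  }
  rows <- list()
  errors <- data.frame(outcome_roi = character(), predictor = character(),
                       reason = character())
  for (pred in .table2_predictors()) {
    for (roi in rois) {
      r <- tryCatch({
        res <- fit_model(cohort, roi, pred, adjusted = TRUE)
        if (standardize) res <- standardize_coefficients(res, cohort)
        attr(res, "fit") <- NULL
        res
      }, error = function(e) e)
      if (inherits(r, "error")) {
        errors <- rbind(errors, data.frame(outcome_roi = roi, predictor = pred,
                                           reason = conditionMessage(r)))
      } else {
        rows[[paste(pred, roi)]] <- r
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
         else {
           data.frame(outcome_roi = character(), predictor = character(),
                      model = character(), B = numeric(),
                      ci95_low = numeric(), ci95_high = numeric(),
                      p_value = numeric(), n_used = integer(),
                      units_text = character(), standardized_B = numeric())
         }
  attr(out, "errors") <- errors
  out
}
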