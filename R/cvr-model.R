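#' Candidate delay grid for the SSR search
#'
#' @param min_s,max_s Grid bounds, seconds; must bracket 0.
#' @param step_s Grid step, seconds; 0 must lie on the grid. The default
#'   -5 to +60 s in 1 s steps covers the hemodynamic lags seen in
#'   small-vessel disease, where white-matter responses can trail the
#'   stimulus by tens of seconds.
#'
#' @return A `delay_grid` object with a `values` vector.
#' @export
delay_grid <- function(min_s = -5, max_s = 60, step_s = 1) {
  if (!is.numeric(min_s) || !is.numeric(max_s) || min_s > max_s) {
    stop_invalid("`min_s` must be <= `max_s`")
  }
  assert_scalar_pos(step_s, "step_s")
  values <- seq(min_s, max_s, by = step_s)
  if (!any(abs(values) < 1e-9)) {
    stop_invalid("the delay grid must contain 0")
  }
  structure(list(min_s = min_s, max_s = max_s, step_s = step_s,
                 values = values),
            class = "delay_grid")
}

#' Percent-normalize a BOLD series
#'
#' Expresses the signal as percent change about its own temporal mean:
#' `100 * (S - mean(S)) / mean(S)`. The output has zero mean and is
#' invariant to rescaling the raw signal, which is what makes CVR
#' comparable across subjects and scanners.
#'
#' @param series Numeric vector, or an `roi_series` / `bold_series`.
#' @return Numeric vector of percent signal change, zero mean.
#' @export
normalize_percent <- function(series) {
  s <- if (inherits(series, "roi_series")) series$mean_signal
       else if (inherits(series, "bold_series")) series$values
       else as.numeric(series)
  if (anyNA(s) || any(!is.finite(s))) {
    stop(errorCondition("series contains non-finite values",
                        class = c("cvrsvd_signal_error", "error")))
  }
  m <- mean(s)
  if (m <= 0) {
    stop(errorCondition("series temporal mean must be positive",
                        class = c("cvrsvd_signal_error", "error")))
  }
  100 * (s - m) / m
}

#' Fit the CVR regression at one candidate delay
#'
#' Ordinary least squares of the percent-normalized ROI signal on the
#' delay-shifted EtCO2 regressor (mmHg) and the volume index 0..n-1 (the
#' linear drift term), plus an intercept. The EtCO2 coefficient is the CVR
#' (%/mmHg) at this delay.
#'
#' @param percent_series Percent signal change, from [normalize_percent()].
#' @param regressor A `volume_regressor` (any applied delay).
#' @param delay_s Candidate delay, seconds; the regressor is (re)shifted to
#'   this total delay before fitting.
#'
#' @return List with `beta_co2` (%/mmHg), `beta_drift` (% per volume),
#'   `intercept`, `ssr`, `r_squared`, `delay_s`.
#' @export
fit_at_delay <- function(percent_series, regressor, delay_s) {
  stopifnot(inherits(regressor, "volume_regressor"))
  y <- as.numeric(percent_series)
  n <- length(y)
  if (length(regressor$values_mmHg) != n) {
    stop_invalid("regressor length does not match the series")
  }
  x <- shift_regressor(regressor, delay_s - regressor$applied_delay_s)$values_mmHg
  if (stats::sd(x) < 1e-10) {
    stop(errorCondition(
      "EtCO2 regressor is (numerically) constant: degenerate design",
      class = c("cvrsvd_degenerate_design", "error")))
  }
  k <- seq_len(n) - 1
  X <- cbind(intercept = 1, etco2 = x, drift = k)
  fit <- stats::lm.fit(X, y)
  if (fit$rank < 3L) {
    stop(errorCondition("rank-deficient design in CVR regression",
                        class = c("cvrsvd_degenerate_design", "error")))
  }
  res <- fit$residuals
  ssr <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) max(0, min(1, 1 - ssr / tss)) else NA_real_
  list(beta_co2 = unname(fit$coefficients["etco2"]),
       beta_drift = unname(fit$coefficients["drift"]),
       intercept = unname(fit$coefficients["intercept"]),
       ssr = ssr, r_squared = r2, delay_s = delay_s)
}

#' Estimate CVR and hemodynamic delay by SSR grid search
#'
#' Fits the CVR regression of [fit_at_delay()] at every delay on the grid
#' and returns the fit with the lowest sum of squared residuals. Ties (to
#' within relative 1e-9) are broken towards the smallest `|delay|`, then
#' the smaller delay.
#'
#' @param percent_series Percent signal change, from [normalize_percent()].
#' @param trace An [etco2_trace()] covering the scan.
#' @param grid A [delay_grid()].
#' @param tr_s Repetition time, seconds.
#' @param label ROI label recorded in the result.
#' @param n_voxels Optionally recorded voxel count.
#' @param convention Volume timestamp convention, see [volume_times()].
#'
#' @return A `cvr_result` object: list with `label`,
#'   `cvr_pct_per_mmHg`, `delay_s`, `drift_pct_per_scan`
#'   (`beta_drift * n_volumes`), `intercept`, `ssr`, `r_squared`,
#'   `n_volumes`, `n_voxels`.
#' @export
optimize_delay <- function(percent_series, trace, grid = delay_grid(),
                           tr_s, label = "roi", n_voxels = NA_integer_,
                           convention = c("mid", "start")) {
  stopifnot(inherits(grid, "delay_grid"))
  convention <- match.arg(convention)
  y <- as.numeric(percent_series)
  n <- length(y)
  reg <- resample_to_volumes(trace, n, tr_s, convention)

  fits <- vector("list", length(grid$values))
  for (i in seq_along(grid$values)) {
    fits[[i]] <- tryCatch(fit_at_delay(y, reg, grid$values[i]),
                          cvrsvd_degenerate_design = function(e) NULL)
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    stop(errorCondition("all candidate delays gave degenerate designs",
                        class = c("cvrsvd_estimation_error", "error")))
  }
  ssr <- vapply(fits, function(f) if (is.null(f)) Inf else f$ssr, numeric(1))
  tie <- which(ssr <= min(ssr) * (1 + 1e-9) + 1e-300)
  tie <- tie[order(abs(grid$values[tie]), grid$values[tie])]
  best <- fits[[tie[1]]]

  structure(
    list(label = label,
         cvr_pct_per_mmHg = best$beta_co2,
         delay_s = best$delay_s,
         drift_pct_per_scan = best$beta_drift * n,
         intercept = best$intercept,
         ssr = best$ssr,
         r_squared = best$r_squared,
         n_volumes = n,
         n_voxels = n_voxels),
    class = "cvr_result"
  )
}

#' @export
print.cvr_result <- function(x, ...) {
  cat(sprintf("CVR [%s]: %.5f %%/mmHg at delay %g s (R2 %.3f, %d volumes%s)\n",
              x$label, x$cvr_pct_per_mmHg, x$delay_s, x$r_squared, x$n_volumes,
              if (is.na(x$n_voxels)) "" else sprintf(", %d voxels", x$n_voxels)))
  invisible(x)
}

#' Run the per-subject CVR pipeline over all tissue ROIs
#'
#' Conditions the tissue masks ([prepare_roi_masks()]), extracts the mean
#' BOLD series per ROI, percent-normalizes it and estimates CVR and delay
#' by the SSR grid search, independently per ROI. ROIs whose mask is empty
#' after conditioning (typically small WMH masks) are omitted with a
#' logged reason rather than failing the subject.
#'
#' @param bold_4d 4D numeric array of motion-realigned BOLD data.
#' @param mask_set An [roi_mask_set()] in BOLD-registered space.
#' @param trace An [etco2_trace()].
#' @param tr_s Repetition time, seconds.
#' @param grid A [delay_grid()].
#' @param prepare If `TRUE` (default) run [prepare_roi_masks()] first.
#' @param rois ROI labels to analyse.
#' @param ... Passed to [prepare_roi_masks()].
#'
#' @return A data.frame with one row per estimated ROI (columns `roi`,
#'   `cvr_pct_per_mmHg`, `delay_s`, `drift_pct_per_scan`, `r_squared`,
#'   `ssr`, `n_volumes`, `n_voxels`), with an attribute `skipped`: a
#'   data.frame of omitted ROIs and reasons.
#' @export
run_subject <- function(bold_4d, mask_set, trace, tr_s,
                        grid = delay_grid(), prepare = TRUE,
                        rois = c("sgm", "nawm", "wmh"), ...) {
  stopifnot(inherits(mask_set, "roi_mask_set"))
  ms <- if (prepare) prepare_roi_masks(mask_set, ...) else mask_set

  rows <- list()
  skipped <- data.frame(roi = character(), reason = character())
  for (lab in rois) {
    res <- tryCatch({
      series <- extract_roi_mean_series(bold_4d, ms$masks[[lab]], lab)
      pct <- normalize_percent(series)
      optimize_delay(pct, trace, grid, tr_s, label = lab,
                     n_voxels = series$n_voxels)
    },
    cvrsvd_empty_roi = function(e) e,
    cvrsvd_signal_error = function(e) e,
    cvrsvd_estimation_error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- rbind(skipped,
                       data.frame(roi = lab, reason = conditionMessage(res)))
    } else {
      rows[[lab]] <- data.frame(roi = lab,
                                cvr_pct_per_mmHg = res$cvr_pct_per_mmHg,
                                delay_s = res$delay_s,
                                drift_pct_per_scan = res$drift_pct_per_scan,
                                r_squared = res$r_squared,
                                ssr = res$ssr,
                                n_volumes = res$n_volumes,
                                n_voxels = res$n_voxels)
    }
  }
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
         else data.frame()
  attr(out, "skipped") <- skipped
  attr(out, "provenance") <- ms$provenance
  out
}
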