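#' Simulate an ROI-mean BOLD time series with known CVR and delay
#'
#' Generates the mean BOLD signal of a tissue region responding to an
#' end-tidal CO2 trace with a known reactivity, hemodynamic delay, linear
#' drift and Gaussian noise:
#'
#' \deqn{S_k = S_0 \left(1 + \frac{CVR}{100}(x_k - \bar x)
#'   + \frac{d}{100}\frac{k - \bar k}{n}\right) + \epsilon_k}
#'
#' where \eqn{x_k} is the EtCO2 trace evaluated at the volume timestamp
#' minus the true delay, \eqn{d} the drift amplitude (percent per scan) and
#' \eqn{\epsilon_k \sim N(0, (\sigma/100) S_0)}. The CO2 and drift
#' components are mean-centred, so `baseline_signal` is exactly the
#' temporal mean of the noiseless series and `true_cvr_pct_per_mmHg` is
#' exactly the percent-of-mean signal change per mmHg: the generative
#' inverse of the [optimize_delay()] estimator, which recovers CVR and
#' delay exactly from noiseless data when the delay lies on the search
#' grid.
#'
#' @param trace An [etco2_trace()] spanning the scan duration.
#' @param config A [sim_config()]; uses `tr_s`, `n_volumes`,
#'   `true_cvr_pct_per_mmHg`, `true_delay_s`, `drift_pct_per_scan`,
#'   `noise_sd_pct`, `baseline_signal`, `seed`.
#'
#' @return A `bold_series` object: list with `values` (length
#'   `n_volumes`), `tr_s`, and the generating `config`.
#' @export
simulate_bold_roi <- function(trace, config) {
  stopifnot(inherits(trace, "etco2_trace"), inherits(config, "cvr_sim_config"))
  n <- config$n_volumes
  tr <- config$tr_s
  scan_dur <- n * tr
  if (abs(config$true_delay_s) >= scan_dur) {
    stop_invalid("`true_delay_s` must be smaller in magnitude than the scan duration")
  }

  reg <- resample_to_volumes(trace, n, tr)
  x <- shift_regressor(reg, config$true_delay_s)$values_mmHg
  xc <- x - mean(x)
  k <- seq_len(n) - 1L
  kc <- (k - mean(k)) / n

  noise <- with_seed(config$seed,
                     stats::rnorm(n, 0, config$noise_sd_pct / 100 *
                                    config$baseline_signal))
  values <- config$baseline_signal *
    (1 + config$true_cvr_pct_per_mmHg / 100 * xc +
       config$drift_pct_per_scan / 100 * kc) + noise

  structure(list(values = values, tr_s = tr, config = config),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("BOLD series: %d volumes, TR %.3g s, mean %.4g\n",
              length(x$values), x$tr_s, mean(x$values)))
  invisible(x)
}
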