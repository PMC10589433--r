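#' Configuration for single-subject BOLD-CVR simulation
#'
#' Bundles the generating parameters for the end-tidal CO2 and mean-BOLD
#' simulators. Defaults reflect a 12-minute gas-challenge acquisition
#' (TR 1.55 s) in normal-appearing white matter of a small-vessel-disease
#' cohort: a ~38 mmHg resting EtCO2 rising by ~8 mmHg under 6% CO2, a CVR
#' of 0.042 %/mmHg (the cohort NAWM median) and a hemodynamic delay of
#' 10 s.
#'
#' @param tr_s Repetition time between BOLD volumes, seconds.
#' @param n_volumes Number of BOLD volumes. Default covers 12 minutes at
#'   TR 1.55 s.
#' @param etco2_baseline_mmHg Resting end-tidal CO2, mmHg.
#' @param etco2_delta_mmHg EtCO2 increase reached asymptotically during CO2
#'   blocks, mmHg.
#' @param transition_tau_s Time constant of the first-order exponential
#'   EtCO2 response to a block transition, seconds.
#' @param breath_interval_s Mean inter-breath interval, seconds.
#' @param breath_jitter_sd_s SD of Gaussian jitter on inter-breath
#'   intervals, seconds. 0 gives regularly spaced breaths.
#' @param true_cvr_pct_per_mmHg Generating CVR: percent BOLD signal change
#'   (relative to the series temporal mean) per mmHg EtCO2.
#' @param true_delay_s Generating hemodynamic delay: the BOLD series
#'   responds to the EtCO2 value `true_delay_s` seconds earlier.
#' @param drift_pct_per_scan Linear drift amplitude: total percent signal
#'   excursion across the scan (mean-centred).
#' @param noise_sd_pct Gaussian noise SD as percent of `baseline_signal`.
#' @param baseline_signal Temporal mean of the noiseless BOLD series,
#'   arbitrary scanner units.
#' @param seed RNG seed recorded in all outputs; `NULL` uses the current
#'   RNG state.
#'
#' @return A `cvr_sim_config` list.
#' @export
sim_config <- function(tr_s = 1.55,
                       n_volumes = 464,
                       etco2_baseline_mmHg = 38,
                       etco2_delta_mmHg = 8,
                       transition_tau_s = 15,
                       breath_interval_s = 4,
                       breath_jitter_sd_s = 0.4,
                       true_cvr_pct_per_mmHg = 0.042,
                       true_delay_s = 10,
                       drift_pct_per_scan = 0.5,
                       noise_sd_pct = 0.2,
                       baseline_signal = 1000,
                       seed = NULL) {
  assert_scalar_pos(tr_s, "tr_s")
  if (!is.numeric(n_volumes) || length(n_volumes) != 1L || n_volumes < 2) {
    stop_invalid("`n_volumes` must be >= 2")
  }
  assert_scalar_pos(noise_sd_pct, "noise_sd_pct", strict = FALSE)
  assert_scalar_pos(breath_interval_s, "breath_interval_s")
  assert_scalar_pos(breath_jitter_sd_s, "breath_jitter_sd_s", strict = FALSE)
  assert_scalar_pos(baseline_signal, "baseline_signal")
  structure(
    list(tr_s = tr_s, n_volumes = as.integer(n_volumes),
         etco2_baseline_mmHg = etco2_baseline_mmHg,
         etco2_delta_mmHg = etco2_delta_mmHg,
         transition_tau_s = transition_tau_s,
         breath_interval_s = breath_interval_s,
         breath_jitter_sd_s = breath_jitter_sd_s,
         true_cvr_pct_per_mmHg = true_cvr_pct_per_mmHg,
         true_delay_s = true_delay_s,
         drift_pct_per_scan = drift_pct_per_scan,
         noise_sd_pct = noise_sd_pct,
         baseline_signal = baseline_signal,
         seed = seed),
    class = "cvr_sim_config"
  )
}

# Underlying EtCO2 level at arbitrary times: baseline + delta * indicator,
# smoothed by a first-order exponential with time constant tau. Solved
# block-by-block in closed form (level relaxes towards each block's target).
etco2_level <- function(paradigm, times_s, baseline_mmHg, delta_mmHg, tau_s) {
  stopifnot(inherits(paradigm, "gas_paradigm"))
  if (!is.numeric(tau_s) || length(tau_s) != 1L || tau_s <= 0) {
    stop_invalid("`transition_tau_s` must be > 0")
  }
  b <- paradigm$block_sequence
  starts <- cumsum(c(0, b$duration_s))[seq_len(nrow(b))]
  targets <- baseline_mmHg + delta_mmHg * (b$gas_state == "co2")

  # level at the start of each block, propagated recursively
  level0 <- numeric(nrow(b))
  level0[1] <- baseline_mmHg
  if (nrow(b) > 1) {
    for (i in seq_len(nrow(b) - 1)) {
      level0[i + 1] <- targets[i] +
        (level0[i] - targets[i]) * exp(-b$duration_s[i] / tau_s)
    }
  }

  idx <- findInterval(times_s, starts)
  idx[idx < 1L] <- 1L
  out <- targets[idx] +
    (level0[idx] - targets[idx]) * exp(-(times_s - starts[idx]) / tau_s)
  # times beyond the paradigm keep relaxing towards the final target
  out
}

#' Simulate a breath-resolved end-tidal CO2 trace
#'
#' Generates end-tidal CO2 samples at (jittered) breath times over a gas
#' paradigm. The underlying EtCO2 level follows
#' `baseline + delta * block_indicator` smoothed by a first-order
#' exponential with time constant `transition_tau_s`, the simplest
#' physiologically plausible block response.
#'
#' @param paradigm A [make_gas_paradigm()] object.
#' @param config A [sim_config()] object; fields used:
#'   `etco2_baseline_mmHg`, `etco2_delta_mmHg`, `transition_tau_s`,
#'   `breath_interval_s`, `breath_jitter_sd_s`, `seed`.
#'
#' @return An [etco2_trace()] with `source = "simulated"`. The generating
#'   seed is recorded in the `seed` attribute.
#' @export
simulate_etco2 <- function(paradigm, config) {
  stopifnot(inherits(paradigm, "gas_paradigm"), inherits(config, "cvr_sim_config"))
  if (config$transition_tau_s <= 0) stop_invalid("`transition_tau_s` must be > 0")
  total <- paradigm$total_duration_s

  times <- with_seed(config$seed, {
    # draw generously, then truncate to the paradigm window
    n_max <- ceiling(total / config$breath_interval_s) + 10L
    gaps <- config$breath_interval_s +
      stats::rnorm(n_max, 0, config$breath_jitter_sd_s)
    gaps <- pmax(gaps, 0.2 * config$breath_interval_s)  # keep times increasing
    cumsum(c(0, gaps))
  })
  times <- times[times <= total]
  values <- etco2_level(paradigm, times,
                        config$etco2_baseline_mmHg,
                        config$etco2_delta_mmHg,
                        config$transition_tau_s)
  tr <- etco2_trace(times, values, source = "simulated")
  attr(tr, "seed") <- config$seed
  tr
}
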