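#' End-tidal CO2 trace
#'
#' Container for a breath-resolved end-tidal CO2 time series, the source of
#' the vasodilatory regressor.
#'
#' @param times_s Strictly increasing sample times, seconds (>= 0).
#' @param values_mmHg End-tidal CO2 values, mmHg; must lie in (0, 150).
#' @param source One of `"measured"`, `"end_tidal_extracted"`,
#'   `"simulated"`.
#'
#' @return An `etco2_trace` object (list with `times_s`, `values_mmHg`,
#'   `source`).
#' @export
etco2_trace <- function(times_s, values_mmHg,
                        source = c("measured", "end_tidal_extracted", "simulated")) {
  source <- match.arg(source)
  times_s <- as.numeric(times_s)
  values_mmHg <- as.numeric(values_mmHg)
  if (length(times_s) != length(values_mmHg)) {
    stop_invalid("times and values must have equal length")
  }
  if (length(times_s) < 2L) {
    stop(errorCondition("an EtCO2 trace needs at least 2 samples",
                        class = c("cvrsvd_empty_trace", "error")))
  }
  if (anyNA(times_s) || anyNA(values_mmHg)) stop_invalid("trace contains NA")
  if (any(times_s < 0) || any(diff(times_s) <= 0)) {
    stop_invalid("trace times must be non-negative and strictly increasing")
  }
  if (any(values_mmHg <= 0 | values_mmHg >= 150)) {
    stop_invalid("EtCO2 values must lie in (0, 150) mmHg")
  }
  structure(list(times_s = times_s, values_mmHg = values_mmHg, source = source),
            class = "etco2_trace")
}

#' @export
print.etco2_trace <- function(x, ...) {
  cat(sprintf("EtCO2 trace (%s): %d samples over %.1f s, %.1f-%.1f mmHg\n",
              x$source, length(x$times_s), diff(range(x$times_s)),
              min(x$values_mmHg), max(x$values_mmHg)))
  invisible(x)
}

# Topographic prominence of a local maximum at index `i`: height above the
# higher of the two lowest points separating it from higher terrain (or the
# record edge on sides with no higher terrain).
.peak_prominence <- function(v, i) {
  h <- v[i]
  left <- v[seq_len(i - 1)]
  right <- if (i < length(v)) v[(i + 1):length(v)] else numeric()
  lh <- which(left >= h)
  lmin <- if (length(lh)) min(left[(max(lh) + 1):length(left)]) else min(left)
  rh <- which(right >= h)
  rmin <- if (length(rh)) min(right[seq_len(min(rh) - 1)]) else min(right)
  h - max(lmin, rmin)
}

#' Extract end-tidal values from a raw CO2 recording
#'
#' Identifies one end-tidal sample per breath as the local maximum of the
#' expiratory CO2 waveform, subject to a minimum breath separation and a
#' minimum topographic prominence (to reject cardiogenic ripple and
#' noise). Plateau maxima contribute a single peak at the plateau centre.
#'
#' @param raw_times Sample times of the raw recording, seconds.
#' @param raw_co2 Raw CO2 waveform, mmHg.
#' @param min_breath_interval_s Minimum separation between retained peaks,
#'   seconds.
#' @param min_prominence_mmHg Minimum peak prominence, mmHg.
#'
#' @return An [etco2_trace()] with `source = "end_tidal_extracted"`.
#' @export
detect_end_tidal_peaks <- function(raw_times, raw_co2,
                                   min_breath_interval_s = 1.5,
                                   min_prominence_mmHg = 1) {
  raw_times <- as.numeric(raw_times)
  raw_co2 <- as.numeric(raw_co2)
  if (length(raw_times) != length(raw_co2) || length(raw_times) < 3L) {
    stop_invalid("raw recording must have >= 3 samples of equal length vectors")
  }
  if (any(diff(raw_times) <= 0)) stop_invalid("raw times must be strictly increasing")

  # plateau-safe local maxima via run-length compression; prominence is
  # computed on the compressed series, where a local maximum always has
  # strictly lower neighbours
  r <- rle(raw_co2)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  cand_runs <- integer()
  if (k >= 3L) {
    for (j in 2:(k - 1)) {
      if (r$values[j] > r$values[j - 1] && r$values[j] > r$values[j + 1]) {
        cand_runs <- c(cand_runs, j)
      }
    }
  }
  if (!length(cand_runs)) {
    stop(errorCondition("no end-tidal peaks found in recording",
                        class = c("cvrsvd_empty_trace", "error")))
  }

  prom <- vapply(cand_runs, function(j) .peak_prominence(r$values, j),
                 numeric(1))
  cand_runs <- cand_runs[prom >= min_prominence_mmHg]
  cand <- as.integer(floor((starts[cand_runs] + ends[cand_runs]) / 2))
  if (!length(cand)) {
    stop(errorCondition("no peaks exceed the prominence threshold",
                        class = c("cvrsvd_empty_trace", "error")))
  }

  # enforce minimum separation, keeping the taller peak
  ord <- cand[order(raw_co2[cand], decreasing = TRUE)]
  kept <- integer()
  for (i in ord) {
    if (!length(kept) ||
        all(abs(raw_times[i] - raw_times[kept]) >= min_breath_interval_s)) {
      kept <- c(kept, i)
    }
  }
  kept <- sort(kept)
  if (length(kept) < 2L) {
    stop(errorCondition("fewer than 2 breaths detected",
                        class = c("cvrsvd_empty_trace", "error")))
  }
  etco2_trace(raw_times[kept], raw_co2[kept], source = "end_tidal_extracted")
}

#' Mid-acquisition timestamps of BOLD volumes
#'
#' @param n_volumes Number of volumes.
#' @param tr_s Repetition time, seconds.
#' @param convention `"mid"` (default, volume k stamped at `k*tr + tr/2`,
#'   k from 0) or `"start"` (`k*tr`).
#' @return Numeric vector of length `n_volumes`.
#' @export
volume_times <- function(n_volumes, tr_s, convention = c("mid", "start")) {
  convention <- match.arg(convention)
  t0 <- if (convention == "mid") tr_s / 2 else 0
  (seq_len(n_volumes) - 1L) * tr_s + t0
}

#' Resample an EtCO2 trace onto the BOLD volume grid
#'
#' Linear interpolation of the trace at volume timestamps, with constant
#' extrapolation beyond the trace endpoints so that every volume remains
#' usable at every candidate delay.
#'
#' @param trace An [etco2_trace()].
#' @param n_volumes,tr_s BOLD grid geometry.
#' @param convention Volume timestamp convention, see [volume_times()].
#'
#' @return A `volume_regressor` object: list with `values_mmHg` (length
#'   `n_volumes`), `tr_s`, `applied_delay_s = 0`, `convention` and the
#'   source `trace` (kept so later delay shifts re-interpolate the original
#'   samples rather than the resampled ones).
#' @export
resample_to_volumes <- function(trace, n_volumes, tr_s,
                                convention = c("mid", "start")) {
  stopifnot(inherits(trace, "etco2_trace"))
  convention <- match.arg(convention)
  assert_scalar_pos(tr_s, "tr_s")
  n_volumes <- as.integer(n_volumes)
  if (n_volumes < 2L) stop_invalid("`n_volumes` must be >= 2")

  scan_dur <- n_volumes * tr_s
  covered <- min(max(trace$times_s), scan_dur) - max(min(trace$times_s), 0)
  if (covered < 0.5 * scan_dur) {
    stop(errorCondition(
      sprintf("EtCO2 trace covers %.0f%% of the scan window (need >= 50%%)",
              100 * max(covered, 0) / scan_dur),
      class = c("cvrsvd_insufficient_trace", "error")))
  }

  tk <- volume_times(n_volumes, tr_s, convention)
  vals <- stats::approx(trace$times_s, trace$values_mmHg, xout = tk,
                        rule = 2)$y
  structure(
    list(values_mmHg = vals, tr_s = tr_s, applied_delay_s = 0,
         convention = convention, trace = trace),
    class = "volume_regressor"
  )
}

#' Time-shift a volume regressor
#'
#' Re-evaluates the regressor at `t - delay_s`: a positive delay moves the
#' EtCO2 profile later in time, matching the hemodynamic lag of the BOLD
#' response behind the stimulus. Edges are extended with the boundary value
#' so the regressor length (and hence the residual count in the delay
#' search) is the same at every candidate delay.
#'
#' @param regressor A `volume_regressor` from [resample_to_volumes()].
#' @param delay_s Additional delay to apply, seconds; the total applied
#'   delay must stay below the scan duration in magnitude.
#'
#' @return A `volume_regressor` with updated `values_mmHg` and
#'   `applied_delay_s`.
#' @export
shift_regressor <- function(regressor, delay_s) {
  stopifnot(inherits(regressor, "volume_regressor"))
  if (!is.numeric(delay_s) || length(delay_s) != 1L || !is.finite(delay_s)) {
    stop_invalid("`delay_s` must be a single finite number")
  }
  n <- length(regressor$values_mmHg)
  scan_dur <- n * regressor$tr_s
  total_delay <- regressor$applied_delay_s + delay_s
  if (abs(total_delay) >= scan_dur) {
    stop_invalid("total delay (", total_delay, " s) must be smaller in ",
                 "magnitude than the scan duration (", scan_dur, " s)")
  }
  tk <- volume_times(n, regressor$tr_s, regressor$convention)
  out <- regressor
  if (!is.null(regressor$trace)) {
    out$values_mmHg <- stats::approx(regressor$trace$times_s,
                                     regressor$trace$values_mmHg,
                                     xout = tk - total_delay, rule = 2)$y
  } else {
    out$values_mmHg <- stats::approx(tk, regressor$values_mmHg,
                                     xout = tk - delay_s, rule = 2)$y
  }
  out$applied_delay_s <- total_delay
  out
}
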