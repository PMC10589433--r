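#' Build an alternating air / CO2 gas paradigm
#'
#' Constructs the block design of a hypercapnia CVR acquisition: blocks of
#' medical air alternating with CO2-enriched air, always starting with air.
#' The final block is truncated so that the blocks sum exactly to
#' `total_min`.
#'
#' @param air_min Duration of each air block, minutes.
#' @param co2_min Duration of each CO2 block, minutes.
#' @param total_min Total paradigm duration, minutes. Must accommodate at
#'   least one full air block.
#' @param co2_fraction Inspired CO2 fraction during CO2 blocks
#'   (dimensionless; 0.06 for a 6% CO2 gas mixture).
#'
#' @return A `gas_paradigm` object: a list with `block_sequence` (data.frame
#'   with columns `gas_state` in `{"air","co2"}` and `duration_s`),
#'   `total_duration_s`, and `co2_fraction`.
#'
#' @examples
#' p <- make_gas_paradigm(2, 3, 12)
#' p$block_sequence
#' @export
make_gas_paradigm <- function(air_min = 2, co2_min = 3, total_min = 12,
                              co2_fraction = 0.06) {
  assert_scalar_pos(air_min, "air_min")
  assert_scalar_pos(co2_min, "co2_min")
  assert_scalar_pos(total_min, "total_min")
  assert_scalar_pos(co2_fraction, "co2_fraction")
  if (total_min < air_min) {
    stop_invalid("`total_min` must accommodate at least one full air block")
  }

  states <- character()
  durs <- numeric()
  remaining <- total_min
  state <- "air"
  while (remaining > 1e-12) {
    d <- min(if (state == "air") air_min else co2_min, remaining)
    states <- c(states, state)
    durs <- c(durs, d)
    remaining <- remaining - d
    state <- if (state == "air") "co2" else "air"
  }

  structure(
    list(
      block_sequence = data.frame(gas_state = states, duration_s = durs * 60),
      total_duration_s = total_min * 60,
      co2_fraction = co2_fraction
    ),
    class = "gas_paradigm"
  )
}

#' @export
print.gas_paradigm <- function(x, ...) {
  b <- x$block_sequence
  cat(sprintf("Gas paradigm: %d blocks, %.1f min total, FiCO2 %.0f%% in CO2 blocks\n",
              nrow(b), x$total_duration_s / 60, 100 * x$co2_fraction))
  cat(paste(sprintf("%s %.1f min", b$gas_state, b$duration_s / 60),
            collapse = " | "), "\n")
  invisible(x)
}

# CO2 block indicator (0/1) at arbitrary times (seconds from paradigm start).
# Times beyond the paradigm keep the last block's state.
block_indicator <- function(paradigm, times_s) {
  stopifnot(inherits(paradigm, "gas_paradigm"))
  b <- paradigm$block_sequence
  ends <- cumsum(b$duration_s)
  idx <- findInterval(times_s, c(0, ends), rightmost.closed = FALSE,
                      left.open = TRUE)
  idx[times_s <= 0] <- 1L
  idx[idx > nrow(b)] <- nrow(b)
  as.numeric(b$gas_state[idx] == "co2")
}
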