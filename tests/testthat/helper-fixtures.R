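# Shared fixtures: all synthetic, built in code at test time.

# Standard 12-min study paradigm (2 min air / 3 min CO2).
study_paradigm <- function() make_gas_paradigm(2, 3, 12)

# Noiseless, drift-free configuration with a grid-aligned delay: the
# setting in which the estimator must invert the generator exactly.
noiseless_config <- function(true_cvr = 0.042, true_delay = 10, seed = 42,
                             ...) {
  sim_config(true_cvr_pct_per_mmHg = true_cvr, true_delay_s = true_delay,
             drift_pct_per_scan = 0, noise_sd_pct = 0, seed = seed, ...)
}

# Short paradigm + series for cheap fitting tests.
short_setup <- function(seed = 1, n_volumes = 80, tr_s = 1.5, ...) {
  paradigm <- make_gas_paradigm(1, 1, n_volumes * tr_s / 60)
  config <- sim_config(tr_s = tr_s, n_volumes = n_volumes, seed = seed, ...)
  trace <- simulate_etco2(paradigm, config)
  list(paradigm = paradigm, config = config, trace = trace)
}

# Independent least-squares oracle: normal equations solved directly.
normal_equations <- function(X, y) as.vector(solve(t(X) %*% X, t(X) %*% y))

# Minimal cohort with exactly known structure for hand-checked model fits.
tiny_cohort <- function(n = 12, seed = 99) {
  set.seed(seed)
  data.frame(
    x = seq_len(n),
    z = rnorm(n),
    cvr_nawm = rnorm(n)
  )
}

# Box mask helper: TRUE inside [lo, hi] (inclusive, voxel indices) per axis.
box_mask <- function(dims, lo, hi) {
  m <- array(FALSE, dims)
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  m
}
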