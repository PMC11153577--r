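# Shared fixtures for the suite. Everything is generated in code; the
# only stored file is carbonate-reference.csv (frozen outputs of an
# independent root-finding solver used as the cross-validation oracle).

default_spec <- function(...) respirometer_spec(volume_l = 3.9, ...)

# A quick noiseless fish trace at reduced sampling for unit tests.
quick_trace <- function(true_smr = 60, mass_g = 159.4, noise_sd = 0,
                        occupancy_h = 2, sampling_hz = 0.5, seed = 1,
                        ...) {
  sp <- respirometer_spec(volume_l = 3.9, sampling_hz = sampling_hz)
  list(spec = sp,
       trace = generate_o2_trace(
         list(true_smr = true_smr, mass_g = mass_g, alive = TRUE), sp,
         noise_sd = noise_sd, occupancy_h = occupancy_h, seed = seed,
         ...))
}

# Independent brute-force least squares via the normal equations.
brute_ols_slope <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  beta[2, 1]
}

# Equal-halves sample whose empty interval around the median is
# `gap_sem` standard errors wide (self-consistent by fixed-point
# iteration); used for split-rule power checks.
make_gap_sample <- function(n = 16, gap_sem = 6) {
  lower <- rnorm(n / 2)
  upper <- rnorm(n / 2)
  upper <- upper - min(upper) + max(lower) # edges touching
  g <- 1.5 * sd(c(lower, upper))
  for (i in 1:6) {
    x <- c(lower, upper + g)
    g <- gap_sem * sd(x) / sqrt(n)
  }
  c(lower, upper + g)
}
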