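# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so generators are deterministic without clobbering
# the session stream. A NULL seed uses (and advances) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("codstress_config_error",
                                             "error", "condition")))
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_config(name, " must be a single positive finite number")
  }
}

# Ordinary least squares on (x, y) returning slope, intercept, r2, and the
# standard error of the slope. Kept tiny and dependency-free because it is
# the workhorse for trace windows and plate kinetics.
ols_fit <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 2L)
  mx <- mean(x)
  my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) stop("degenerate regression: no spread in x")
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  resid <- y - intercept - slope * x
  sse <- sum(resid^2)
  sst <- sum((y - my)^2)
  r2 <- if (sst <= .Machine$double.eps * n * max(1, my^2)) {
    # flat response: a perfect fit of a constant; define r2 = 1 when the
    # residuals are numerically zero, NA otherwise
    if (sse <= 1e-20) 1 else NA_real_
  } else {
    1 - sse / sst
  }
  se <- if (n > 2) sqrt(sse / (n - 2) / sxx) else NA_real_
  list(slope = slope, intercept = intercept, r2 = r2, slope_se = se, n = n)
}
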