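# Intermittent-flow respirometry: raw O2-saturation traces -> per-cycle
# mass-specific MO2 -> lowest-decile standard metabolic rate.

#' Respirometer specification
#'
#' Geometry, flush/measure schedule and optode calibration for one
#' intermittent-flow respirometer. The experiment used cylindrical 3 or
#' 3.9 L chambers on a 20-min cycle: 15-min flush followed by a 5-min
#' sealed measurement phase.
#'
#' @param volume_l Total respirometer volume V_r, litres.
#' @param flush_s Flush-phase duration, seconds.
#' @param measure_s Sealed measurement-phase duration, seconds.
#' @param sampling_hz Optode sampling rate, Hz (the instrument's rate is
#'   not critical; 1 Hz default).
#' @param cal Two-point calibration anchors: raw signal at 0% and at 100%
#'   air saturation, as `c(zero = , full = )`.
#' @return An object of class `respirometer_spec`.
#' @examples
#' respirometer_spec(volume_l = 3.9)
#' @export
respirometer_spec <- function(volume_l = 3.9, flush_s = 900, measure_s = 300,
                              sampling_hz = 1,
                              cal = c(zero = 0, full = 100)) {
  stopifnot_scalar_pos(volume_l, "volume_l")
  stopifnot_scalar_pos(flush_s, "flush_s")
  stopifnot_scalar_pos(measure_s, "measure_s")
  stopifnot_scalar_pos(sampling_hz, "sampling_hz")
  if (length(cal) != 2L || !is.numeric(cal)) {
    stop_config("cal must be two numeric anchors (raw at 0% and 100%)")
  }
  if (cal[[1]] == cal[[2]]) {
    stop_config("calibration anchors must be distinct")
  }
  structure(
    list(volume_l = volume_l, flush_s = flush_s, measure_s = measure_s,
         cycle_s = flush_s + measure_s, sampling_hz = sampling_hz,
         cal = c(zero = unname(cal[[1]]), full = unname(cal[[2]]))),
    class = "respirometer_spec"
  )
}

#' @export
print.respirometer_spec <- function(x, ...) {
  cat(sprintf(
    "Respirometer: %.2f L, cycle %ds (%ds flush + %ds measure), %g Hz\n",
    x$volume_l, x$cycle_s, x$flush_s, x$measure_s, x$sampling_hz))
  invisible(x)
}

#' Construct an oxygen trace object
#'
#' A classed data frame holding one respirometry session: time (s), oxygen
#' (% air saturation) and the phase label of each sample, with water
#' temperature and salinity carried as attributes (needed later to convert
#' saturation to concentration).
#'
#' @param time_s Sample times, seconds, strictly increasing.
#' @param o2 Oxygen, % air saturation. Values outside [-2, 110] error;
#'   small excursions from noise are tolerated inside that band.
#' @param phase Character vector of phase labels per sample, from
#'   `c("pre_background", "flush", "measure", "post_background")`.
#' @param temperature,salinity Water temperature (degC) and salinity.
#' @return An `o2_trace` data frame.
#' @export
o2_trace <- function(time_s, o2, phase, temperature, salinity) {
  stopifnot(length(time_s) == length(o2), length(o2) == length(phase))
  if (any(diff(time_s) <= 0)) stop("time_s must be strictly increasing")
  if (any(!is.finite(o2))) stop("o2 contains non-finite values")
  if (any(o2 < -2 | o2 > 110)) {
    stop("o2 outside the plausible band [-2, 110] %sat")
  }
  ok <- c("pre_background", "flush", "measure", "post_background")
  if (!all(phase %in% ok)) {
    stop("unknown phase label(s): ", paste(setdiff(unique(phase), ok),
                                           collapse = ", "))
  }
  structure(
    data.frame(time_s = time_s, o2 = o2, phase = phase,
               stringsAsFactors = FALSE),
    temperature = temperature, salinity = salinity,
    class = c("o2_trace", "data.frame")
  )
}

#' Two-point calibration of a raw optode signal
#'
#' Maps raw optode readings to % air saturation through the linear
#' two-point calibration (0% from sodium-sulfite water, 100% from
#' vigorously bubbled water). Readings beyond the anchors extrapolate and
#' are flagged, not clipped.
#'
#' @param raw_signal Raw optode readings.
#' @param spec A [respirometer_spec()] carrying the `cal` anchors.
#' @return Numeric vector of % air saturation with attribute
#'   `extrapolated` (logical vector, TRUE where the reading fell outside
#'   the anchor interval).
#' @examples
#' sp <- respirometer_spec(cal = c(zero = 0.2, full = 1.8))
#' calibrate_trace(1.0, sp) # 50
#' @export
calibrate_trace <- function(raw_signal, spec) {
  stopifnot(inherits(spec, "respirometer_spec"))
  a0 <- spec$cal[["zero"]]
  a100 <- spec$cal[["full"]]
  sat <- (raw_signal - a0) / (a100 - a0) * 100
  lo <- min(0, 100); hi <- max(0, 100)
  structure(sat, extrapolated = sat < lo | sat > hi)
}

#' Segment a trace into measurement windows and background hours
#'
#' Splits an [o2_trace()] into its 5-min sealed measurement windows (the
#' only phases analysed) plus the fish-free pre- and post-session
#' background hours. Phase labels drive the segmentation; each maximal run
#' of `"measure"` samples is one window, indexed in time order.
#'
#' @param trace An [o2_trace()].
#' @param spec A [respirometer_spec()]; used to check the windows are
#'   schedule-consistent (each complete window spans `measure_s` seconds).
#' @param require_complete Drop trailing windows shorter than
#'   `measure_s` (default TRUE).
#' @return List with `windows` (list of data frames, one per measurement
#'   window), `pre` and `post` (data frames of the background hours,
#'   possibly empty), and `n_windows`.
#' @export
segment_cycles <- function(trace, spec, require_complete = TRUE) {
  stopifnot(inherits(trace, "o2_trace"), inherits(spec, "respirometer_spec"))
  r <- rle(trace$phase)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  win_idx <- which(r$values == "measure")
  if (length(win_idx) == 0L) {
    stop("segmentation error: trace contains no measurement phase; ",
         "check the flush/measure schedule against the trace extent")
  }
  windows <- lapply(win_idx, function(i) {
    trace[starts[i]:ends[i], , drop = FALSE]
  })
  if (require_complete) {
    dt <- 1 / spec$sampling_hz
    spans <- vapply(windows, function(w) {
      max(w$time_s) - min(w$time_s) + dt
    }, numeric(1))
    windows <- windows[spans >= spec$measure_s - dt / 2]
  }
  if (length(windows) == 0L) {
    stop("segmentation error: no complete measurement window in trace")
  }
  pre <- trace[trace$phase == "pre_background", , drop = FALSE]
  post <- trace[trace$phase == "post_background", , drop = FALSE]
  list(windows = windows, pre = pre, post = post,
       n_windows = length(windows))
}

#' Least-squares oxygen slope over one measurement window
#'
#' Ordinary least-squares slope of % saturation against time after
#' discarding the first `trim_s` seconds of the window (chamber mixing
#' transient). Declining oxygen gives a negative slope.
#'
#' @param window Data frame with `time_s` and `o2` columns (one element of
#'   `segment_cycles()$windows`), or an [o2_trace()] subset.
#' @param trim_s Seconds discarded from the start of the window.
#' @param min_points Minimum samples required after trimming.
#' @return List with `slope` (% sat s^-1), `r2`, `slope_se`, `n`.
#' @export
estimate_slope <- function(window, trim_s = 30, min_points = 10) {
  stopifnot(is.data.frame(window), all(c("time_s", "o2") %in% names(window)))
  t0 <- min(window$time_s)
  keep <- window$time_s >= t0 + trim_s
  if (sum(keep) < min_points) {
    stop("window rejected: ", sum(keep), " samples after trimming (need ",
         min_points, ")")
  }
  fit <- ols_fit(window$time_s[keep], window$o2[keep])
  list(slope = fit$slope, r2 = fit$r2, slope_se = fit$slope_se, n = fit$n)
}

#' Background respiration model
#'
#' Microbial (background) oxygen consumption is measured for one hour
#' before the fish enters the chamber and one hour after it leaves. The
#' background slope during occupancy is linearly interpolated in time
#' between the two; with only one background available it is held
#' constant (with a warning), and with neither it falls back to zero.
#'
#' @param pre_slope,post_slope Background slopes (% sat s^-1) from the
#'   pre/post hours; `NA` if unavailable.
#' @param t_start,t_end Occupancy span (s) over which to interpolate:
#'   `t_start` is the time the pre background ended, `t_end` the time the
#'   post background started.
#' @return A function of time returning the background slope (% sat s^-1).
#' @examples
#' bg <- background_model(0, -0.002, 0, 100)
#' bg(50) # -0.001
#' @export
background_model <- function(pre_slope, post_slope, t_start, t_end) {
  has_pre <- !is.null(pre_slope) && length(pre_slope) == 1 &&
    is.finite(pre_slope)
  has_post <- !is.null(post_slope) && length(post_slope) == 1 &&
    is.finite(post_slope)
  if (!has_pre && !has_post) {
    warning("no background measurement available; assuming zero ",
            "background respiration")
    return(function(t) rep(0, length(t)))
  }
  if (has_pre && !has_post) {
    warning("post background missing; using constant pre-session slope")
    force(pre_slope)
    return(function(t) rep(pre_slope, length(t)))
  }
  if (!has_pre && has_post) {
    warning("pre background missing; using constant post-session slope")
    force(post_slope)
    return(function(t) rep(post_slope, length(t)))
  }
  stopifnot(t_end > t_start)
  function(t) {
    f <- (t - t_start) / (t_end - t_start)
    f <- pmin(pmax(f, 0), 1)
    pre_slope + f * (post_slope - pre_slope)
  }
}

#' Mass-specific oxygen consumption for one measurement window
#'
#' Converts the fish-phase and background saturation slopes into
#' mass-specific MO2 (mg O2 kg^-1 h^-1):
#' \deqn{MO_2 = \frac{(V_r - V_f)\, r_{fish} - V_r\, r_{bg}}{m}}
#' where the fish term uses the water volume actually respired in
#' (chamber minus fish, fish volume from body mass at tissue density
#' 1 g mL^-1), the background term uses the full chamber volume, and each
#' r is the saturation slope converted to a concentration rate
#' (mg O2 L^-1 h^-1) through [o2_solubility()] at the session temperature
#' and salinity. Slopes follow the instrument convention: oxygen declines
#' give negative slopes; consumption is reported positive.
#'
#' @param slope_fish Saturation slope during fish occupancy, % sat s^-1.
#' @param slope_bg Background saturation slope, % sat s^-1.
#' @param spec A [respirometer_spec()] (for V_r).
#' @param mass_g Fish body mass, g.
#' @param temperature,salinity Session water conditions.
#' @return MO2, mg O2 kg^-1 h^-1. Vectorised over slopes.
#' @export
compute_mo2 <- function(slope_fish, slope_bg, spec, mass_g,
                        temperature, salinity) {
  stopifnot(inherits(spec, "respirometer_spec"))
  stopifnot_scalar_pos(mass_g, "mass_g")
  v_r <- spec$volume_l
  v_f <- mass_g / 1000 # density 1 g/mL
  if (v_f >= v_r) {
    stop("geometry error: fish volume (", v_f, " L) >= respirometer volume (",
         v_r, " L)")
  }
  if (any(!is.finite(slope_fish)) || any(!is.finite(slope_bg))) {
    stop("non-finite slope")
  }
  solub <- o2_solubility(temperature, salinity) # mg/L at 100% sat
  # %sat/s -> mg O2 / L / h of *consumption* (declines are negative slopes)
  r_fish <- -slope_fish * 3600 / 100 * solub
  r_bg <- -slope_bg * 3600 / 100 * solub
  ((v_r - v_f) * r_fish - v_r * r_bg) / (mass_g / 1000)
}

#' Standard metabolic rate from a series of MO2 values
#'
#' SMR is the mean of the lowest 10% of the per-cycle MO2 values from the
#' 20-h session, after removing outliers more than 2 standard deviations
#' below that decile's mean (spuriously low cycles, e.g. leaks). The
#' decile size uses the ceiling rule (`ceiling(decile * n)`), so the
#' canonical 60-value session keeps 6; the SD is the sample (n-1) SD; the
#' outliers are identified once from the initial decile statistics (single
#' filtering pass, no re-iteration).
#'
#' @param mo2 Numeric vector of per-cycle MO2 values (>= 10 required).
#' @param decile Fraction of lowest values retained (default 0.10).
#' @param outlier_sd Outlier cutoff in SDs below the decile mean.
#' @return An object of class `smr_estimate`: list with `smr`, `n_used`,
#'   `n_outliers_removed`, `decile_values`, `decile_mean`, `decile_sd`.
#' @examples
#' estimate_smr(c(20, 50, 51, 52, 53, 54, rep(60, 54)))$smr # 52
#' @export
estimate_smr <- function(mo2, decile = 0.10, outlier_sd = 2) {
  mo2 <- mo2[is.finite(mo2)]
  n <- length(mo2)
  if (n < 10) stop("need at least 10 MO2 values to estimate SMR (got ",
                   n, ")")
  k <- ceiling(decile * n)
  dec <- sort(mo2)[seq_len(k)]
  m <- mean(dec)
  s <- stats::sd(dec)
  cutoff <- m - outlier_sd * s
  keep <- if (is.na(s) || s == 0) rep(TRUE, k) else dec >= cutoff
  if (!any(keep)) {
    stop("estimation error: all lowest-decile values removed as outliers; ",
         "pathological trace")
  }
  structure(
    list(smr = mean(dec[keep]), n_used = sum(keep),
         n_outliers_removed = sum(!keep), decile_values = dec,
         decile_mean = m, decile_sd = s, cutoff = cutoff,
         n_cycles = n),
    class = "smr_estimate"
  )
}

#' @export
print.smr_estimate <- function(x, ...) {
  cat(sprintf(
    "SMR %.2f mg O2/kg/h (lowest %d of %d cycles, %d outlier%s removed)\n",
    x$smr, length(x$decile_values), x$n_cycles, x$n_outliers_removed,
    if (x$n_outliers_removed == 1) "" else "s"))
  invisible(x)
}

#' Process one respirometry trace to MO2 series and SMR
#'
#' Full per-fish chain: segment the trace, fit the background slopes from
#' the pre/post hours, fit each measurement window's slope (optionally
#' gated on r^2), interpolate the background at each window midpoint,
#' convert to mass-specific MO2, and estimate SMR.
#'
#' @param trace An [o2_trace()] (phases labelled, temperature/salinity
#'   attributes set).
#' @param spec A [respirometer_spec()].
#' @param mass_g Fish body mass, g.
#' @param fish_id Identifier carried into the outputs.
#' @param trim_s Mixing-transient trim per window, seconds.
#' @param min_r2 Minimum window r^2; windows below it are dropped.
#'   Default `NULL` (no gate; whether the original analysis used one is
#'   unstated).
#' @param decile,outlier_sd Passed to [estimate_smr()].
#' @return List with `series` (data frame: fish_id, cycle, slope_fish,
#'   slope_bg, r2, mo2) and `smr` (an `smr_estimate`).
#' @export
process_trace <- function(trace, spec, mass_g, fish_id = NA_character_,
                          trim_s = 30, min_r2 = NULL,
                          decile = 0.10, outlier_sd = 2) {
  seg <- segment_cycles(trace, spec)
  temperature <- attr(trace, "temperature")
  salinity <- attr(trace, "salinity")
  bg_fit <- function(df) {
    if (nrow(df) < 10) return(NA_real_)
    ols_fit(df$time_s, df$o2)$slope
  }
  pre_slope <- bg_fit(seg$pre)
  post_slope <- bg_fit(seg$post)
  t_start <- if (nrow(seg$pre)) max(seg$pre$time_s) else
    min(seg$windows[[1]]$time_s)
  t_end <- if (nrow(seg$post)) min(seg$post$time_s) else
    max(seg$windows[[seg$n_windows]]$time_s)
  bg <- background_model(pre_slope, post_slope, t_start, t_end)

  rows <- lapply(seq_along(seg$windows), function(i) {
    w <- seg$windows[[i]]
    fit <- tryCatch(estimate_slope(w, trim_s = trim_s),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    if (!is.null(min_r2) && !is.na(fit$r2) && fit$r2 < min_r2) return(NULL)
    mid <- (min(w$time_s) + max(w$time_s)) / 2
    sb <- bg(mid)
    data.frame(fish_id = fish_id, cycle = i, slope_fish = fit$slope,
               slope_bg = sb, r2 = fit$r2,
               mo2 = compute_mo2(fit$slope, sb, spec, mass_g,
                                 temperature, salinity),
               stringsAsFactors = FALSE)
  })
  series <- do.call(rbind, rows)
  if (is.null(series) || nrow(series) < 10) {
    stop("too few usable measurement windows for fish ", fish_id)
  }
  series$mass_g <- mass_g
  series$fish_volume_l <- mass_g / 1000
  class(series) <- c("mo2_series", "data.frame")
  smr <- estimate_smr(series$mo2, decile = decile, outlier_sd = outlier_sd)
  smr$fish_id <- fish_id
  list(series = series, smr = smr)
}
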