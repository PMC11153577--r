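# Seawater carbonate system from total-scale pH and total alkalinity,
# plus the TRIS electrode calibration and the water-quality comparison
# statistics used on the weekly monitoring data.

# Equilibrium constants at (T degC, S), surface pressure, total pH scale
# (mol/kg-SW). Default set: K1/K2 from the Lueker et al. (2000) total-scale
# refit of Mehrbach's constants; K0 Weiss (1974); KB Dickson (1990); KW
# Millero (1995, total scale); KS Dickson (1990a, free scale); KF Perez &
# Fraga (1987); boron/sulfate/fluoride/calcium totals from salinity
# (Uppstrom boron); calcite/aragonite solubility products Mucci (1983).
carb_constants <- function(temperature, salinity) {
  tk <- temperature + 273.15
  s <- salinity
  ln_k0 <- -60.2409 + 93.4517 * (100 / tk) + 23.3585 * log(tk / 100) +
    s * (0.023517 - 0.023656 * (tk / 100) + 0.0047036 * (tk / 100)^2)
  pk1 <- 3633.86 / tk - 61.2172 + 9.6777 * log(tk) -
    0.011555 * s + 0.0001152 * s^2
  pk2 <- 471.78 / tk + 25.929 - 3.16967 * log(tk) -
    0.01781 * s + 0.0001122 * s^2
  ln_kb <- (-8966.90 - 2890.53 * sqrt(s) - 77.942 * s +
              1.728 * s^1.5 - 0.0996 * s^2) / tk +
    148.0248 + 137.1942 * sqrt(s) + 1.62142 * s +
    (-24.4344 - 25.085 * sqrt(s) - 0.2474 * s) * log(tk) +
    0.053105 * sqrt(s) * tk
  ln_kw <- 148.9652 - 13847.26 / tk - 23.6521 * log(tk) +
    (118.67 / tk - 5.977 + 1.0495 * log(tk)) * sqrt(s) - 0.01615 * s
  ion <- 19.924 * s / (1000 - 1.005 * s)
  ln_ks <- -4276.1 / tk + 141.328 - 23.093 * log(tk) +
    (-13856 / tk + 324.57 - 47.986 * log(tk)) * sqrt(ion) +
    (35474 / tk - 771.54 + 114.723 * log(tk)) * ion -
    2698 / tk * ion^1.5 + 1776 / tk * ion^2 + log(1 - 0.001005 * s)
  ln_kf <- 874 / tk - 9.68 + 0.111 * sqrt(s)
  l10_kspc <- -171.9065 - 0.077993 * tk + 2839.319 / tk +
    71.595 * log10(tk) +
    (-0.77712 + 0.0028426 * tk + 178.34 / tk) * sqrt(s) -
    0.07711 * s + 0.0041249 * s^1.5
  l10_kspa <- -171.945 - 0.077993 * tk + 2903.293 / tk +
    71.595 * log10(tk) +
    (-0.068393 + 0.0017276 * tk + 88.135 / tk) * sqrt(s) -
    0.10018 * s + 0.0059415 * s^1.5
  list(
    k0 = exp(ln_k0), k1 = 10^(-pk1), k2 = 10^(-pk2),
    kb = exp(ln_kb), kw = exp(ln_kw), ks = exp(ln_ks), kf = exp(ln_kf),
    ksp_calcite = 10^l10_kspc, ksp_aragonite = 10^l10_kspa,
    bt = 0.000232 / 10.811 * s / 1.80655,
    st = 0.14 / 96.062 * s / 1.80655,
    ft = 0.000067 / 18.998 * s / 1.80655,
    ca = 0.02128 / 40.087 * s / 1.80655
  )
}

# Non-carbonate alkalinity terms (mol/kg) at total-scale [H+] h.
# Positive contributors: borate, hydroxide; negative: free proton,
# bisulfate, HF.
.ta_noncarb <- function(h, k) {
  h_free <- h / (1 + k$st / k$ks)
  k$bt * k$kb / (k$kb + h) + k$kw / h -
    h_free - k$st * h_free / (k$ks + h_free) - k$ft * h / (k$kf + h)
}

#' Solve the seawater carbonate system from pH and total alkalinity
#'
#' With [H+] fixed by the total-scale pH, the alkalinity balance
#' (carbonate + borate + water +/- bisulfate, HF and the free proton) is
#' solved analytically for DIC; carbonate speciation, pCO2 (= [CO2*]/K0)
#' and the calcite/aragonite saturation states follow. All equilibrium
#' constants are evaluated at the sample temperature and salinity on the
#' total scale at surface pressure; nutrient alkalinity is taken as zero
#' (phosphate/silicate were not reported for these waters).
#'
#' @param ph_ts Total-scale pH (must lie in (6, 9)).
#' @param ta Total alkalinity, umol kg^-1 (> 0).
#' @param temperature Temperature, degC.
#' @param salinity Practical salinity.
#' @param constants_set Name of the constants set; only
#'   `"lueker_mehrbach"` (the Mehrbach refit, CO2SYS-style default) is
#'   provided.
#' @return A data frame of class `carb_result` with one row per input:
#'   `pco2` (uatm), `dic`, `co2`, `hco3`, `co3` (umol kg^-1),
#'   `omega_calcite`, `omega_aragonite`, `constants_set`.
#' @examples
#' solve_carbonate(8.06, 2308, 12.95, 32.62)$pco2 # ~392 uatm
#' @export
solve_carbonate <- function(ph_ts, ta, temperature, salinity,
                            constants_set = "lueker_mehrbach") {
  constants_set <- match.arg(constants_set)
  n <- max(length(ph_ts), length(ta), length(temperature), length(salinity))
  ph_ts <- rep_len(ph_ts, n); ta <- rep_len(ta, n)
  temperature <- rep_len(temperature, n); salinity <- rep_len(salinity, n)
  if (any(!is.finite(ph_ts)) || any(ph_ts <= 6 | ph_ts >= 9)) {
    stop("ph_ts must lie in (6, 9)")
  }
  if (any(!is.finite(ta)) || any(ta <= 0)) stop("ta must be positive")
  out <- lapply(seq_len(n), function(i) {
    k <- carb_constants(temperature[i], salinity[i])
    h <- 10^(-ph_ts[i])
    ta_mol <- ta[i] * 1e-6
    ta_carb <- ta_mol - .ta_noncarb(h, k)
    denom <- h^2 + k$k1 * h + k$k1 * k$k2
    carb_factor <- (k$k1 * h + 2 * k$k1 * k$k2) / denom
    if (ta_carb <= 0) {
      stop("chemistry error: non-carbonate alkalinity exceeds TA at pH ",
           ph_ts[i], ", TA ", ta[i], " umol/kg")
    }
    dic <- ta_carb / carb_factor
    co2 <- dic * h^2 / denom
    hco3 <- dic * k$k1 * h / denom
    co3 <- dic * k$k1 * k$k2 / denom
    data.frame(
      ph_ts = ph_ts[i], ta = ta[i], temperature = temperature[i],
      salinity = salinity[i],
      pco2 = co2 / k$k0 * 1e6,
      dic = dic * 1e6, co2 = co2 * 1e6, hco3 = hco3 * 1e6, co3 = co3 * 1e6,
      omega_calcite = k$ca * co3 / k$ksp_calcite,
      omega_aragonite = k$ca * co3 / k$ksp_aragonite,
      constants_set = constants_set, stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  class(res) <- c("carb_result", "data.frame")
  res
}

#' Recompute total-scale pH from DIC and total alkalinity
#'
#' Root-finds the total-scale [H+] whose alkalinity balance matches the
#' given TA at the given DIC — the inverse of [solve_carbonate()]'s
#' (pH, TA) -> DIC direction; used for round-trip verification and when
#' DIC rather than pH is the measured quantity.
#'
#' @param dic Dissolved inorganic carbon, umol kg^-1.
#' @param ta Total alkalinity, umol kg^-1.
#' @param temperature,salinity Sample conditions.
#' @return Total-scale pH. Vectorised.
#' @export
ph_from_dic_ta <- function(dic, ta, temperature, salinity) {
  n <- max(length(dic), length(ta), length(temperature), length(salinity))
  dic <- rep_len(dic, n); ta <- rep_len(ta, n)
  temperature <- rep_len(temperature, n); salinity <- rep_len(salinity, n)
  vapply(seq_len(n), function(i) {
    k <- carb_constants(temperature[i], salinity[i])
    dic_mol <- dic[i] * 1e-6
    ta_mol <- ta[i] * 1e-6
    resid <- function(ph) {
      h <- 10^(-ph)
      denom <- h^2 + k$k1 * h + k$k1 * k$k2
      dic_mol * (k$k1 * h + 2 * k$k1 * k$k2) / denom +
        .ta_noncarb(h, k) - ta_mol
    }
    stats::uniroot(resid, c(3, 11), tol = 1e-12)$root
  }, numeric(1))
}

#' Fit the TRIS/AMP electrode calibration line
#'
#' Least-squares line mapping raw electrode response to certified
#' total-scale pH of TRIS/AMP buffer solutions (S = 32), used to place the
#' weekly water samples on the total pH scale.
#'
#' @param reading Raw electrode readings for the buffer measurements.
#' @param ph_cert Certified total-scale pH of each buffer.
#' @return List of class `tris_calibration`: `slope`, `intercept`, `r2`,
#'   `n`, and `predict(reading)`.
#' @export
fit_tris_calibration <- function(reading, ph_cert) {
  if (length(reading) < 2 || length(reading) != length(ph_cert)) {
    stop("calibration error: need >= 2 paired buffer readings")
  }
  fit <- ols_fit(reading, ph_cert)
  structure(
    list(slope = fit$slope, intercept = fit$intercept, r2 = fit$r2,
         n = fit$n,
         predict = function(x) fit$intercept + fit$slope * x),
    class = "tris_calibration"
  )
}

#' @export
print.tris_calibration <- function(x, ...) {
  cat(sprintf("TRIS/AMP pH calibration: pH_TS = %.5f + %.5f * reading ",
              x$intercept, x$slope))
  cat(sprintf("(n = %d, r2 = %.4f)\n", x$n, x$r2))
  invisible(x)
}

#' Two-sided variance-ratio (F) test from summary statistics
#'
#' F is the larger variance over the smaller (so F >= 1), with degrees of
#' freedom ordered accordingly, and a two-sided p-value from the F
#' distribution — the test behind the monitoring table's "F-ratio var."
#' column comparing ambient and manipulated water conditions.
#'
#' @param sd1,sd2 Group standard deviations (> 0).
#' @param n1,n2 Group sizes (>= 2).
#' @return List: `f`, `df1`, `df2`, `p_value`.
#' @examples
#' variance_ratio_test(1.92, 60, 1.64, 40)$f # 1.37 -> prints as 1.4
#' @export
variance_ratio_test <- function(sd1, n1, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  if (!is.finite(sd1) || !is.finite(sd2) || sd1 <= 0 || sd2 <= 0) {
    stop("degenerate error: standard deviations must be positive")
  }
  v1 <- sd1^2; v2 <- sd2^2
  if (v1 >= v2) {
    f <- v1 / v2; df1 <- n1 - 1; df2 <- n2 - 1
  } else {
    f <- v2 / v1; df1 <- n2 - 1; df2 <- n1 - 1
  }
  p <- min(1, 2 * stats::pf(f, df1, df2, lower.tail = FALSE))
  list(f = f, df1 = df1, df2 = df2, p_value = p)
}

#' Pooled-variance two-sample t test from summary statistics
#'
#' Classical equal-variance t test computed from group means, SDs and
#' sizes (df = n1 + n2 - 2); used to compare the ambient- and low-pH
#' groups' weekly pH readings, for which only summaries are retained.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return List: `t`, `df`, `p_value`.
#' @examples
#' pooled_t_test(8.06, 0.08, 60, 7.67, 0.30, 40)$t # ~9.6
#' @export
pooled_t_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 + n2 <= 2) stop("need n1 + n2 > 2")
  if (sd1 < 0 || sd2 < 0 || (sd1 == 0 && sd2 == 0)) {
    stop("domain error: SDs must be non-negative and not both zero")
  }
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(t = t, df = df, p_value = p)
}
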