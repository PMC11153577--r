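# Seeded synthetic-data generators reproducing the experiment's design:
# 5 treatments x 4 tanks x 5 fish, 20-h respirometry sessions of 20-min
# cycles, ecotype-linked bimodal SMR in the freshening and multi-stressor
# treatments, weekly water chemistry matching the monitoring summaries,
# and mortality as printed.

#' Cohort configuration for the synthetic generator
#'
#' Defaults encode the experiment as run: five treatments (control,
#' freshening, warming, acidification, all three combined), four tanks of
#' five fish each; start biometrics drawn from the cohort summary
#' (24.3 +/- 3.5 cm, 159.4 +/- 72.6 g); expected deaths 0/4/2/2/2 per
#' treatment of 20; ecotype recorded only for the genotyped treatments
#' (control, low salinity, multi-stressor), with offshore fractions
#' matching the genotyping tallies; and an ecotype-linked bimodal SMR
#' response in the low-salinity and multi-stressor treatments (offshore
#' -> heightened, coastal -> reduced, with configurable concordance).
#'
#' @param n_treatments,tanks_per_treatment,fish_per_tank Design sizes.
#' @param treatment_names Unique treatment labels.
#' @param ecotype_fractions Per-treatment probability that a fish carries
#'   the offshore ecotype. Applies to non-bimodal treatments; in bimodal
#'   treatments the latent ecotype is drawn conditional on the (balanced)
#'   response class via `concordance`, implying an offshore fraction near
#'   0.5 there.
#' @param genotyped_treatments Treatments whose fish have their ecotype
#'   recorded; elsewhere ecotype is `"unknown"` (the latent ecotype still
#'   drives the response class).
#' @param smr_baseline Baseline SMR, mg O2 kg^-1 h^-1.
#' @param smr_effects Per-treatment additive SMR shifts.
#' @param bimodal_treatments Named list: treatment -> c(heightened = ,
#'   reduced = ) additive SMR offsets for the two response classes.
#' @param smr_sd Between-fish SD of true SMR within a class.
#' @param concordance P(response class matches ecotype) in bimodal
#'   treatments (offshore-heightened / coastal-reduced).
#' @param mass_mean,mass_sd,length_mean,length_sd Start biometrics (g, cm).
#' @param growth_mean Per-treatment mean relative weight gain over the
#'   4-week exposure (endpoint biometrics are generated directly; the
#'   study reports only endpoints).
#' @param growth_sd SD of relative weight gain.
#' @param class_growth_adj Additive growth adjustment by response class
#'   (heightened-SMR fish grew less).
#' @param mortality_probs Per-treatment death probability during
#'   exposure.
#' @param seed Integer seed; every generator output is deterministic
#'   given it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(
    n_treatments = 5, tanks_per_treatment = 4, fish_per_tank = 5,
    treatment_names = c("control", "low_salinity", "high_temp",
                        "low_pH", "multi_stressor"),
    ecotype_fractions = c(control = 0.31, low_salinity = 0.53,
                          high_temp = 0.42, low_pH = 0.42,
                          multi_stressor = 0.41),
    genotyped_treatments = c("control", "low_salinity", "multi_stressor"),
    smr_baseline = 80,
    smr_effects = c(control = 0, low_salinity = -4, high_temp = 6,
                    low_pH = 2, multi_stressor = 8),
    bimodal_treatments = list(
      low_salinity = c(heightened = 22, reduced = -18),
      multi_stressor = c(heightened = 22, reduced = -18)),
    smr_sd = 6,
    concordance = 0.8,
    mass_mean = 159.4, mass_sd = 72.6,
    length_mean = 24.3, length_sd = 3.5,
    growth_mean = c(control = 0.10, low_salinity = 0.14, high_temp = 0.02,
                    low_pH = 0.10, multi_stressor = 0.08),
    growth_sd = 0.03,
    class_growth_adj = c(heightened = -0.05, reduced = 0.05),
    mortality_probs = c(control = 0, low_salinity = 0.2, high_temp = 0.1,
                        low_pH = 0.1, multi_stressor = 0.1),
    seed = 1) {
  for (nm in c("n_treatments", "tanks_per_treatment", "fish_per_tank")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v)) {
      stop_config(nm, " must be a positive integer")
    }
  }
  if (length(treatment_names) != n_treatments ||
      anyDuplicated(treatment_names)) {
    stop_config("treatment_names must be ", n_treatments, " unique labels")
  }
  ecotype_fractions <- rep_len(ecotype_fractions, n_treatments)
  names(ecotype_fractions) <- treatment_names
  mortality_probs <- rep_len(mortality_probs, n_treatments)
  names(mortality_probs) <- treatment_names
  smr_effects <- rep_len(smr_effects, n_treatments)
  names(smr_effects) <- treatment_names
  growth_mean <- rep_len(growth_mean, n_treatments)
  names(growth_mean) <- treatment_names
  probs <- c(ecotype_fractions, mortality_probs, concordance)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop_config("probabilities must lie in [0, 1]")
  }
  stopifnot_scalar_pos(smr_baseline, "smr_baseline")
  stopifnot_scalar_pos(smr_sd, "smr_sd")
  stopifnot_scalar_pos(mass_mean, "mass_mean")
  stopifnot_scalar_pos(length_mean, "length_mean")
  if (mass_sd < 0 || length_sd < 0 || growth_sd < 0) {
    stop_config("SDs must be non-negative")
  }
  if (!all(names(bimodal_treatments) %in% treatment_names)) {
    stop_config("bimodal_treatments must name known treatments")
  }
  class_means <- smr_baseline + smr_effects
  for (tr in names(bimodal_treatments)) {
    off <- bimodal_treatments[[tr]]
    if (!all(c("heightened", "reduced") %in% names(off))) {
      stop_config("bimodal offsets need 'heightened' and 'reduced'")
    }
    class_means <- c(class_means, smr_baseline + smr_effects[tr] + off)
  }
  if (any(class_means <= 0)) {
    stop_config("configured SMR class means must be positive")
  }
  structure(
    list(n_treatments = n_treatments,
         tanks_per_treatment = tanks_per_treatment,
         fish_per_tank = fish_per_tank,
         treatment_names = treatment_names,
         ecotype_fractions = ecotype_fractions,
         genotyped_treatments = genotyped_treatments,
         smr_baseline = smr_baseline, smr_effects = smr_effects,
         bimodal_treatments = bimodal_treatments, smr_sd = smr_sd,
         concordance = concordance,
         mass_mean = mass_mean, mass_sd = mass_sd,
         length_mean = length_mean, length_sd = length_sd,
         growth_mean = growth_mean,
         growth_sd = growth_sd, class_growth_adj = class_growth_adj,
         mortality_probs = mortality_probs, seed = seed),
    class = "cohort_config"
  )
}

# Normal draws truncated below at `lo` by resampling.
rnorm_trunc <- function(n, mean, sd, lo) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lo)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x <= lo)
  }
  x
}

#' Generate a synthetic fish cohort
#'
#' Draws one complete cohort under the configured design: treatments,
#' tanks, start/end biometrics, latent and observed ecotype, response
#' class, true SMR, and survival. In bimodal treatments the heightened
#' and reduced classes are balanced within treatment (the study observed
#' near-equal halves around the median) and the latent ecotype is
#' concordant with the class (offshore-heightened / coastal-reduced)
#' with probability `concordance`. Fish that die during exposure carry
#' no endpoint data (`NA` endpoint biometrics, `true_smr` and
#' `response_class`).
#'
#' @param config A [cohort_config()].
#' @return Data frame of class `fish_cohort`, one row per fish:
#'   `fish_id`, `treatment`, `tank`, `ecotype` (observed), `mass_g`,
#'   `length_cm` (endpoint), `mass_start_g`, `length_start_cm`, `alive`,
#'   `true_smr`, `response_class`.
#' @examples
#' nrow(generate_cohort(cohort_config(seed = 1))) # 100
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n_per_tr <- config$tanks_per_treatment * config$fish_per_tank
    n <- config$n_treatments * n_per_tr
    treatment <- rep(config$treatment_names, each = n_per_tr)
    tank_idx <- rep(rep(seq_len(config$tanks_per_treatment),
                        each = config$fish_per_tank),
                    times = config$n_treatments)
    tank <- sprintf("%s_T%d", treatment, tank_idx)
    fish_id <- sprintf("F%03d", seq_len(n))

    mass_start <- rnorm_trunc(n, config$mass_mean, config$mass_sd, lo = 20)
    length_start <- rnorm_trunc(n, config$length_mean, config$length_sd,
                                lo = 8)

    alive <- stats::runif(n) >= config$mortality_probs[treatment]

    # The response class is an endpoint observable: the bimodal treatments
    # divided their *survivors* into near-equal halves around the median,
    # so classes are balanced among surviving fish within treatment and
    # the latent ecotype is drawn conditional on class (offshore <->
    # heightened with the configured concordance). Elsewhere (and for
    # fish that died) ecotype follows the per-treatment offshore
    # fraction and the class is "none".
    is_bimodal <- treatment %in% names(config$bimodal_treatments)
    response_class <- rep("none", n)
    for (tr in names(config$bimodal_treatments)) {
      idx <- which(treatment == tr & alive)
      k <- length(idx)
      cls <- rep(c("heightened", "reduced"), length.out = k)
      response_class[sample(idx, k)] <- cls
    }
    concordant <- stats::runif(n) < config$concordance
    latent_eco <- ifelse(
      stats::runif(n) < config$ecotype_fractions[treatment],
      "offshore", "coastal")
    classed <- is_bimodal & alive
    latent_eco[classed] <- ifelse(
      (response_class[classed] == "heightened") == concordant[classed],
      "offshore", "coastal")
    ecotype <- ifelse(treatment %in% config$genotyped_treatments,
                      latent_eco, "unknown")

    offset <- numeric(n)
    for (tr in names(config$bimodal_treatments)) {
      sel <- treatment == tr
      offset[sel] <- config$bimodal_treatments[[tr]][
        ifelse(response_class[sel] == "heightened", "heightened", "reduced")]
    }
    true_smr <- config$smr_baseline + config$smr_effects[treatment] +
      offset + stats::rnorm(n, 0, config$smr_sd)
    true_smr <- pmax(true_smr, 1)

    growth <- stats::rnorm(n, config$growth_mean[treatment],
                           config$growth_sd)
    adj <- ifelse(response_class == "heightened",
                  config$class_growth_adj[["heightened"]],
                  ifelse(response_class == "reduced",
                         config$class_growth_adj[["reduced"]], 0))
    growth <- growth + adj
    mass_end <- mass_start * (1 + growth)
    length_end <- length_start * (1 + growth / 3)

    dead <- !alive
    mass_end[dead] <- NA_real_
    length_end[dead] <- NA_real_
    true_smr[dead] <- NA_real_
    response_class[dead] <- NA_character_

    out <- data.frame(
      fish_id = fish_id, treatment = treatment, tank = tank,
      ecotype = ecotype, mass_g = mass_end, length_cm = length_end,
      mass_start_g = mass_start, length_start_cm = length_start,
      alive = alive, true_smr = unname(true_smr),
      response_class = response_class, stringsAsFactors = FALSE)
    class(out) <- c("fish_cohort", "data.frame")
    out
  })
}

#' Simulate one respirometry oxygen trace
#'
#' Forward model of a 20-h intermittent-flow session bracketed by
#' fish-free background hours. During sealed measurement phases the
#' saturation declines at the rate implied by inverting the MO2 equation
#' for the fish's true SMR plus the (linearly drifting) background;
#' flush phases relax exponentially back to 100% saturation (60-s time
#' constant; cosmetic, since only measurement phases are analysed);
#' background hours decline at the background rate alone. Gaussian
#' optode noise is added throughout.
#'
#' @param fish A one-row data frame or list with `true_smr`
#'   (mg O2 kg^-1 h^-1), `mass_g`, and optionally `alive`.
#' @param spec A [respirometer_spec()].
#' @param background_rate Background saturation drift at the session
#'   start, % sat h^-1 (negative = microbial consumption).
#' @param background_rate_end Background rate at the session end
#'   (defaults to `background_rate`: constant background; set lower to
#'   emulate biofilm growth).
#' @param noise_sd Optode noise SD, % sat.
#' @param occupancy_h Hours the fish spends in the chamber.
#' @param background_h Duration of each background measurement, h.
#' @param temperature,salinity Session water conditions.
#' @param seed Integer seed (deterministic output).
#' @return An [o2_trace()].
#' @export
generate_o2_trace <- function(fish, spec, background_rate = -0.5,
                              background_rate_end = background_rate,
                              noise_sd = 0.2, occupancy_h = 20,
                              background_h = 1, temperature = 13,
                              salinity = 33, seed = NULL) {
  stopifnot(inherits(spec, "respirometer_spec"))
  fish <- as.list(fish)
  if (!is.null(fish$alive) && !isTRUE(as.logical(fish$alive))) {
    stop("cannot simulate a respirometry trace for a dead fish")
  }
  true_smr <- fish$true_smr
  mass_g <- fish$mass_g
  stopifnot(is.finite(true_smr), true_smr >= 0)
  stopifnot_scalar_pos(mass_g, "mass_g")
  v_r <- spec$volume_l
  v_f <- mass_g / 1000
  if (v_f >= v_r) {
    stop("geometry error: fish volume >= respirometer volume")
  }
  solub <- o2_solubility(temperature, salinity)
  dt <- 1 / spec$sampling_hz
  bg_s <- round(background_h * 3600)
  occ_s <- round(occupancy_h * 3600)
  n_cycles <- floor(occ_s / spec$cycle_s)
  occ_start <- bg_s
  occ_end <- bg_s + occ_s

  # background %sat/h at time t (linear drift across the occupancy span,
  # matching the analysis-side interpolation)
  bg_rate <- function(t) {
    f <- pmin(pmax((t - occ_start) / (occ_end - occ_start), 0), 1)
    background_rate + f * (background_rate_end - background_rate)
  }
  # saturation slope (%sat/s) during a sealed phase at time t: invert the
  # MO2 equation for total in-chamber decline = fish + background
  occ_slope <- function(t) {
    c_bg <- -bg_rate(t) / 100 * solub                 # mg O2/L/h consumed
    r_fish <- (true_smr * (mass_g / 1000) + v_r * c_bg) / (v_r - v_f)
    -r_fish / solub * 100 / 3600
  }

  with_seed(seed, {
    t_pre <- seq(0, bg_s - dt, by = dt)
    o_pre <- 100 + background_rate * t_pre / 3600
    segs <- list(data.frame(time_s = t_pre, o2 = o_pre,
                            phase = "pre_background"))
    level <- o_pre[length(o_pre)] + background_rate * dt / 3600
    for (k in seq_len(n_cycles)) {
      t0 <- occ_start + (k - 1) * spec$cycle_s
      t_fl <- seq(t0, t0 + spec$flush_s - dt, by = dt)
      o_fl <- 100 + (level - 100) * exp(-(t_fl - t0) / 60)
      level <- 100 + (o_fl[length(o_fl)] - 100) * exp(-dt / 60)
      t_me <- seq(t0 + spec$flush_s, t0 + spec$cycle_s - dt, by = dt)
      sl <- occ_slope((t_me[1] + t_me[length(t_me)]) / 2)
      o_me <- level + sl * (t_me - t_me[1])
      level <- o_me[length(o_me)] + sl * dt
      segs[[length(segs) + 1L]] <-
        data.frame(time_s = t_fl, o2 = o_fl, phase = "flush")
      segs[[length(segs) + 1L]] <-
        data.frame(time_s = t_me, o2 = o_me, phase = "measure")
    }
    t_post <- seq(occ_end, occ_end + bg_s - dt, by = dt)
    o_post <- 100 + background_rate_end * (t_post - occ_end) / 3600
    segs[[length(segs) + 1L]] <-
      data.frame(time_s = t_post, o2 = o_post, phase = "post_background")
    df <- do.call(rbind, segs)
    df$o2 <- df$o2 + stats::rnorm(nrow(df), 0, noise_sd)
    o2_trace(df$time_s, df$o2, df$phase, temperature = temperature,
             salinity = salinity)
  })
}

water_presets <- list(
  ph_ambient = c(mean = 8.06, sd = 0.08),
  ph_low = c(mean = 7.67, sd = 0.30),
  ta_ambient = c(mean = 2308, sd = 184),
  ta_low = c(mean = 2235, sd = 217),
  temp_control = c(mean = 12.95, sd = 0.35),
  temp_high = c(mean = 16.90, sd = 0.77),
  sal_ambient = c(mean = 32.62, sd = 1.92),
  sal_low = c(mean = 26.39, sd = 1.64)
)

#' Per-treatment water-chemistry distribution preset
#'
#' Mean/SD of pH_TS, total alkalinity, temperature and salinity for each
#' treatment, taken from the weekly monitoring summaries (ambient pH
#' 8.06 +/- 0.08, TA 2308 +/- 184, control temperature 12.95 +/- 0.35,
#' ambient salinity 32.62 +/- 1.92; manipulated values 7.67 +/- 0.30,
#' 2235 +/- 217, 16.90 +/- 0.77, 26.39 +/- 1.64).
#'
#' @param treatment Treatment label (or `"ambient"`, an alias for
#'   control).
#' @return Named list of `c(mean, sd)` for `ph_ts`, `ta`, `temperature`,
#'   `salinity`.
#' @export
water_preset <- function(treatment) {
  p <- water_presets
  switch(treatment,
         ambient = ,
         control = list(ph_ts = p$ph_ambient, ta = p$ta_ambient,
                        temperature = p$temp_control,
                        salinity = p$sal_ambient),
         low_salinity = list(ph_ts = p$ph_ambient, ta = p$ta_ambient,
                             temperature = p$temp_control,
                             salinity = p$sal_low),
         high_temp = list(ph_ts = p$ph_ambient, ta = p$ta_ambient,
                          temperature = p$temp_high,
                          salinity = p$sal_ambient),
         low_pH = list(ph_ts = p$ph_low, ta = p$ta_low,
                       temperature = p$temp_control,
                       salinity = p$sal_ambient),
         multi_stressor = list(ph_ts = p$ph_low, ta = p$ta_low,
                               temperature = p$temp_high,
                               salinity = p$sal_low),
         stop_config("unknown treatment preset: ", treatment))
}

#' Generate synthetic water-chemistry samples
#'
#' Independent normal draws of (pH_TS, TA, temperature, salinity) for one
#' treatment's weekly monitoring samples.
#'
#' @param treatment Treatment label (selects the [water_preset()] unless
#'   `params` is given).
#' @param n Number of samples (> 0).
#' @param params Named list of `c(mean, sd)` for `ph_ts`, `ta`,
#'   `temperature`, `salinity`; defaults to `water_preset(treatment)`.
#' @param seed Integer seed.
#' @return Data frame: `treatment`, `ph_ts`, `ta`, `temperature`,
#'   `salinity`.
#' @export
generate_water_samples <- function(treatment, n, params = NULL,
                                   seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop_config("n must be a positive count")
  }
  params <- params %||% water_preset(treatment)
  need <- c("ph_ts", "ta", "temperature", "salinity")
  if (!all(need %in% names(params))) {
    stop_config("params must provide ", paste(need, collapse = ", "))
  }
  sds <- vapply(params[need], function(p) p[["sd"]], numeric(1))
  if (any(sds < 0)) stop_config("negative SD in water params")
  with_seed(seed, {
    draw <- function(p) stats::rnorm(n, p[["mean"]], p[["sd"]])
    data.frame(treatment = treatment,
               ph_ts = draw(params$ph_ts), ta = draw(params$ta),
               temperature = draw(params$temperature),
               salinity = draw(params$salinity),
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic kinetic microplate
#'
#' Forward model for the plate reader: each well's absorbance is
#' A0 + slope * t + noise. For extinction-based assays (GST, GR) the
#' slope follows Beer-Lambert from the well's true rate
#' (`slope = rate_uM_min * epsilon * path * 1e-6` AU min^-1, negated for
#' decreasing assays); for standard-curve assays (tGSH, GSSG) sample
#' rates are `standard_gain * concentration`, and the same gain generates
#' the standard wells, so curve inversion recovers the configured
#' concentrations exactly at zero noise.
#'
#' @param true_activities Named vector: per-sample-well true rate, uM
#'   min^-1 for extinction-based assays, or extract concentration (uM,
#'   pre-dilution in the well) for standard-curve assays.
#' @param spec An [assay_spec()].
#' @param noise_sd Absorbance noise SD, AU.
#' @param times Reading times, s.
#' @param a0 Initial absorbance, AU.
#' @param standard_concs GSH standard concentrations (uM) for
#'   standard-curve assays; ignored otherwise.
#' @param standard_gain Recycling-assay gain, AU min^-1 per uM.
#' @param seed Integer seed.
#' @return Long data frame of class `plate_kinetics`: `well`, `role`
#'   (sample/standard/blank), `standard_conc`, `time_s`, `absorbance`.
#' @export
generate_kinetic_plate <- function(true_activities, spec, noise_sd = 0,
                                   times = seq(0, 300, by = 30),
                                   a0 = 0.05,
                                   standard_concs = c(0, 5, 10, 25, 50,
                                                      100),
                                   standard_gain = 0.002, seed = NULL) {
  stopifnot(inherits(spec, "assay_spec"))
  if (any(!is.finite(true_activities))) {
    stop_config("true_activities must be finite")
  }
  if (is.null(names(true_activities))) {
    names(true_activities) <- paste0("S", seq_along(true_activities))
  }
  uses_curve <- is.na(spec$extinction)
  sgn <- if (spec$direction == "increase") 1 else -1
  slope_au_min <- if (uses_curve) {
    standard_gain * true_activities
  } else {
    true_activities * spec$extinction * spec$path_cm * 1e-6
  }
  wells <- data.frame(well = names(true_activities), role = "sample",
                      standard_conc = NA_real_,
                      slope = sgn * slope_au_min, stringsAsFactors = FALSE)
  if (uses_curve) {
    std <- data.frame(well = sprintf("STD%02d",
                                     seq_along(standard_concs)),
                      role = "standard", standard_conc = standard_concs,
                      slope = sgn * standard_gain * standard_concs,
                      stringsAsFactors = FALSE)
    wells <- rbind(wells, std)
  }
  wells <- rbind(wells, data.frame(well = "BLANK", role = "blank",
                                   standard_conc = NA_real_, slope = 0,
                                   stringsAsFactors = FALSE))
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(wells)), function(i) {
      data.frame(well = wells$well[i], role = wells$role[i],
                 standard_conc = wells$standard_conc[i], time_s = times,
                 absorbance = a0 + wells$slope[i] * times / 60 +
                   stats::rnorm(length(times), 0, noise_sd),
                 stringsAsFactors = FALSE)
    }))
    class(out) <- c("plate_kinetics", "data.frame")
    out
  })
}
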