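# The seeded generators: cohort design, traces, water samples, plates.

test_that("default cohort reproduces the experimental design", {
  co <- generate_cohort(cohort_config(seed = 1))
  expect_equal(nrow(co), 100)
  expect_equal(unname(table(co$treatment)[c(
    "control", "low_salinity", "high_temp", "low_pH",
    "multi_stressor")]), rep(20L, 5), ignore_attr = TRUE)
  expect_equal(length(unique(co$tank)), 20)
  expect_true(all(table(co$tank) == 5))
  # start biometrics positive; endpoint data absent for dead fish
  expect_true(all(co$mass_start_g > 0 & co$length_start_cm > 0))
  dead <- !co$alive
  expect_true(all(is.na(co$true_smr[dead])))
  expect_true(all(is.na(co$mass_g[dead])))
  # ungenotyped treatments have unknown ecotype
  expect_true(all(co$ecotype[co$treatment %in%
                               c("high_temp", "low_pH")] == "unknown"))
  expect_true(all(co$ecotype[co$treatment == "control"] %in%
                    c("offshore", "coastal")))
})

test_that("zero mortality keeps every fish and invalid configs error", {
  co <- generate_cohort(cohort_config(seed = 3,
                                      mortality_probs = rep(0, 5)))
  expect_true(all(co$alive))
  expect_error(cohort_config(mortality_probs = rep(1.2, 5)), "0, 1")
  expect_error(cohort_config(fish_per_tank = 0), "positive integer")
  expect_error(cohort_config(smr_baseline = -5), "positive")
  expect_error(cohort_config(treatment_names = rep("a", 5)), "unique")
})

test_that("generators are byte-identical under the same seed", {
  c1 <- generate_cohort(cohort_config(seed = 7))
  c2 <- generate_cohort(cohort_config(seed = 7))
  expect_identical(c1, c2)
  sp <- respirometer_spec(sampling_hz = 0.2)
  f <- list(true_smr = 70, mass_g = 120, alive = TRUE)
  t1 <- generate_o2_trace(f, sp, occupancy_h = 1, seed = 5)
  t2 <- generate_o2_trace(f, sp, occupancy_h = 1, seed = 5)
  expect_identical(t1, t2)
  w1 <- generate_water_samples("control", 20, seed = 9)
  w2 <- generate_water_samples("control", 20, seed = 9)
  expect_identical(w1, w2)
  p1 <- generate_kinetic_plate(c(a = 1), assay_spec("GST"),
                               noise_sd = 0.01, seed = 4)
  p2 <- generate_kinetic_plate(c(a = 1), assay_spec("GST"),
                               noise_sd = 0.01, seed = 4)
  expect_identical(p1, p2)
})

test_that("offshore fraction follows the configured binomial rate", {
  # 10^4 fish in a single non-bimodal treatment at fraction 0.42
  cfg <- cohort_config(
    n_treatments = 1, tanks_per_treatment = 4, fish_per_tank = 2500,
    treatment_names = "control", ecotype_fractions = 0.42,
    genotyped_treatments = "control", bimodal_treatments = list(),
    smr_effects = 0, growth_mean = 0.1, mortality_probs = 0, seed = 11)
  co <- generate_cohort(cfg)
  p_hat <- mean(co$ecotype == "offshore")
  se <- sqrt(0.42 * 0.58 / nrow(co))
  expect_lt(abs(p_hat - 0.42), 3 * se)
})

test_that("ecotype/response concordance matches the configured
          probability", {
  cfg <- cohort_config(
    n_treatments = 1, tanks_per_treatment = 4, fish_per_tank = 250,
    treatment_names = "low_salinity", ecotype_fractions = 0.5,
    genotyped_treatments = "low_salinity",
    bimodal_treatments = list(low_salinity = c(heightened = 22,
                                               reduced = -18)),
    smr_effects = 0, growth_mean = 0.1, mortality_probs = 0,
    concordance = 0.8, seed = 13)
  co <- generate_cohort(cfg)
  conc_hat <- mean((co$ecotype == "offshore") ==
                     (co$response_class == "heightened"))
  n <- nrow(co)
  expect_lt(abs(conc_hat - 0.8), 1.96 * sqrt(0.8 * 0.2 / n))
  # classes balanced among survivors
  expect_equal(abs(diff(as.numeric(table(co$response_class)))), 0)
})

test_that("trace generator follows the flush/measure schedule and the
          zero-metabolism limit", {
  sp <- respirometer_spec(sampling_hz = 0.2)
  f0 <- list(true_smr = 0, mass_g = 100, alive = TRUE)
  tr <- generate_o2_trace(f0, sp, background_rate = 0, noise_sd = 0.05,
                          occupancy_h = 1, seed = 17)
  seg <- segment_cycles(tr, sp)
  expect_equal(seg$n_windows, 3)
  for (w in seg$windows) {
    fit <- estimate_slope(w)
    expect_lt(abs(fit$slope), 4 * fit$slope_se + 1e-9)
  }
  expect_error(
    generate_o2_trace(list(true_smr = 50, mass_g = 100, alive = FALSE),
                      sp), "dead")
  expect_error(
    generate_o2_trace(list(true_smr = 50, mass_g = 5000, alive = TRUE),
                      sp), "geometry")
})

test_that("water samples match the treatment presets", {
  n <- 800
  w <- generate_water_samples("ambient", n, seed = 19)
  se3 <- function(sd) 3 * sd / sqrt(n)
  expect_lt(abs(mean(w$ph_ts) - 8.06), se3(0.08))
  expect_lt(abs(mean(w$ta) - 2308), se3(184))
  expect_lt(abs(mean(w$temperature) - 12.95), se3(0.35))
  expect_lt(abs(mean(w$salinity) - 32.62), se3(1.92))
  # SD = 0: all samples identical to the mean
  p0 <- water_preset("control")
  for (nm in names(p0)) p0[[nm]]["sd"] <- 0
  w0 <- generate_water_samples("control", 5, params = p0, seed = 1)
  expect_true(all(w0$ph_ts == 8.06) && all(w0$ta == 2308))
  # large-n low-pH preset: sample SD of pH within 5% of 0.30
  wl <- generate_water_samples("low_pH", 1e4, seed = 23)
  expect_lt(abs(sd(wl$ph_ts) / 0.30 - 1), 0.05)
  bad <- water_preset("low_pH")
  bad$ph_ts["sd"] <- -1
  expect_error(generate_water_samples("low_pH", 5, params = bad),
               "negative SD")
  expect_error(generate_water_samples("control", 0), "positive")
})

test_that("kinetic plate forward model obeys Beer-Lambert and perfect
          standard curves", {
  sp <- assay_spec("GST")
  # zero rate -> flat well
  p0 <- generate_kinetic_plate(c(x = 0), sp, noise_sd = 0)
  w <- p0[p0$role == "sample", ]
  expect_equal(kinetic_rate(w$time_s, w$absorbance)$rate, 0,
               tolerance = 1e-12)
  # 1 uM/min, eps 9600, path 1 cm -> 0.0096 AU/min
  p1 <- generate_kinetic_plate(c(x = 1), sp, noise_sd = 0)
  w1 <- p1[p1$role == "sample", ]
  expect_equal(kinetic_rate(w1$time_s, w1$absorbance)$rate, 0.0096,
               tolerance = 1e-12)
  # six GSH standards on a perfect line: r2 = 1 for the rate-conc curve
  tg <- assay_spec("tGSH")
  p2 <- generate_kinetic_plate(c(x = 10), tg, noise_sd = 0,
                               standard_concs = c(0, 5, 10, 25, 50, 100))
  std <- p2[p2$role == "standard", ]
  rates <- vapply(split(std, std$standard_conc), function(w) {
    kinetic_rate(w$time_s, w$absorbance)$rate
  }, numeric(1))
  concs <- as.numeric(names(rates))
  expect_equal(cor(rates, concs)^2, 1, tolerance = 1e-10)
})
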