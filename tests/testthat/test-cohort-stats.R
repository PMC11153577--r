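# Condition factor, the median-gap split rule, treatment tests, tank
# checks, mortality and ecotype association.

test_that("Fulton's K matches direct evaluation and scales correctly", {
  expect_equal(fulton_k(10, 10), 1)
  expect_equal(fulton_k(159.4, 24.3), 1.11089, tolerance = 1e-5)
  expect_equal(fulton_k(2 * 159.4, 24.3), 2 * fulton_k(159.4, 24.3))
  expect_equal(fulton_k(159.4, 2 * 24.3), fulton_k(159.4, 24.3) / 8)
  expect_error(fulton_k(-1, 10), "positive")
  # the biometric-record invariant round-trips exactly
  w <- c(120.5, 210.2); l <- c(22.1, 27.9)
  k <- fulton_k(w, l)
  expect_equal(k, 100 * w / l^3, tolerance = 1e-12)
})

test_that("split rule fires on the hand-computed gap example and not on
          a uniform ladder", {
  v1 <- setNames(c(1, 2, 3, 10, 11, 12), paste0("f", 1:6))
  s1 <- split_within_treatment(v1)
  expect_true(s1$is_split)
  expect_equal(s1$median, 6.5)
  expect_equal(s1$sem, 2.0453, tolerance = 1e-4)
  expect_equal(s1$gap_low, 3.5)
  expect_equal(s1$gap_high, 3.5)
  expect_equal(unname(s1$assignments[c("f1", "f2", "f3")]),
               rep("A", 3))
  expect_equal(unname(s1$assignments[c("f4", "f5", "f6")]),
               rep("B", 3))
  # {1..6}: nearest points 0.5 from the median < SEM 0.76 -> no split
  s2 <- split_within_treatment(setNames(1:6, paste0("f", 1:6)))
  expect_false(s2$is_split)
  expect_equal(s2$sem, 0.7638, tolerance = 1e-4)
  # constant vector: no split, no assignments
  s3 <- split_within_treatment(setNames(rep(5, 6), paste0("f", 1:6)))
  expect_false(s3$is_split)
  expect_error(split_within_treatment(c(1, 2, 3)), ">= 4")
})

test_that("odd-n median ties and the strict variant behave as
          documented", {
  # odd n: the middle observation lies on the median -> cannot split
  s <- split_within_treatment(setNames(c(1, 2, 3, 50, 97, 98, 99),
                                       paste0("f", 1:7)))
  expect_false(s$is_split)
  expect_match(s$note, "tie")
  # the strict (two-points-per-side) reading coincides with the default
  # for even n: the second-nearest point is at least as far as the
  # nearest, so its distance condition is implied
  set.seed(97)
  for (i in 1:20) {
    v <- setNames(rnorm(16, 50, 8) + rep(c(0, sample(c(0, 25), 1)),
                                         each = 8),
                  paste0("f", 1:16))
    lax <- split_within_treatment(v)
    hard <- split_within_treatment(v, strict = TRUE)
    expect_identical(lax$is_split, hard$is_split)
  }
})

test_that("split rule is affine-equivariant", {
  set.seed(61)
  for (i in 1:40) {
    v <- setNames(rnorm(16, 50, 8), paste0("f", 1:16))
    if (i %% 3 == 0) v <- v + rep(c(0, 30), each = 8) # some bimodal
    a <- runif(1, 0.1, 20); b <- runif(1, -100, 100)
    s0 <- split_within_treatment(v)
    s1 <- split_within_treatment(a * v + b)
    expect_identical(s0$is_split, s1$is_split)
    expect_identical(s0$assignments, s1$assignments)
    # negative scale preserves the decision (labels mirror)
    s2 <- split_within_treatment(-a * v + b)
    expect_identical(s0$is_split, s2$is_split)
  }
})

test_that("treatment tests choose ANOVA on clean data and detect large
          shifts", {
  set.seed(67)
  g <- rep(c("a", "b", "c"), each = 20)
  v <- rnorm(60, 10, 1) + 5 * (g == "b") # 5-SD shift
  r <- treatment_tests(v, g)
  expect_equal(r$method, "anova")
  expect_lt(r$p_value, 1e-3)
  expect_true(!is.null(r$posthoc))
  ab <- r$posthoc[(r$posthoc$group1 == "a" & r$posthoc$group2 == "b") |
                    (r$posthoc$group1 == "b" & r$posthoc$group2 == "a"), ]
  expect_true(ab$significant)
  # identical groups: degenerate omnibus, no post-hoc flags
  r0 <- treatment_tests(rep(4, 30), rep(c("a", "b", "c"), 10))
  expect_equal(r0$p_value, 1)
  expect_null(r0$posthoc)
})

test_that("heteroscedastic data fall through the transform ladder to
          Kruskal-Wallis with the hand-ranked H", {
  # grossly unequal spread that no ladder transform fixes
  set.seed(71)
  g <- rep(c("a", "b", "c"), each = 8)
  v <- c(rnorm(8, 0, 0.01), rnorm(8, 0.5, 10), rexp(8, 0.05) - 10)
  r <- treatment_tests(v, g)
  expect_equal(r$method, "kruskal")
  # hand-ranked oracle for H (no ties)
  n <- length(v)
  rk <- rank(v)
  rs <- tapply(rk, g, sum)
  ns <- tapply(rk, g, length)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
  expect_equal(r$statistic, h, tolerance = 1e-10)
})

test_that("nested tank check has ~alpha false-positive rate and detects
          real tank effects", {
  set.seed(73)
  flags <- replicate(200, {
    d <- expand.grid(tank = 1:4, treatment = c("x", "y"), fish = 1:5)
    d$tank_id <- paste(d$treatment, d$tank)
    v <- rnorm(nrow(d))
    nested_tank_check(v, d$tank_id, d$treatment)$flagged
  })
  expect_lt(mean(flags), 0.12)
  expect_gt(mean(flags), 0.005)
  # a large tank effect is flagged
  d <- expand.grid(tank = 1:4, treatment = c("x", "y"), fish = 1:5)
  d$tank_id <- paste(d$treatment, d$tank)
  v <- rnorm(nrow(d)) + 3 * as.numeric(d$tank)
  expect_true(nested_tank_check(v, d$tank_id, d$treatment)$flagged)
  # single tank per treatment is an error
  expect_error(
    nested_tank_check(rnorm(10), rep("t1", 10), rep("x", 10)),
    ">= 2 tanks")
})

test_that("Yates chi-square matches hand computation and the independent
          implementation", {
  even <- yates_chi_square(matrix(5, 2, 2))
  expect_equal(even$chi2, 0)
  expect_equal(even$p_value, 1)
  # E = 7.5 in all cells: 4 * (2.5 - 0.5)^2 / 7.5 = 2.1333
  r <- yates_chi_square(matrix(c(10, 5, 5, 10), 2))
  expect_equal(r$chi2, 2.1333, tolerance = 1e-4)
  expect_equal(r$df, 1L)
  expect_equal(r$n, 30)
  expect_error(yates_chi_square(matrix(c(0, 0, 3, 4), 2)), "marginal")
  expect_error(yates_chi_square(matrix(1, 3, 3)), "2x2")
  # equivalence with stats::chisq.test(correct = TRUE) on random tables,
  # and corrected <= uncorrected always
  set.seed(79)
  for (i in 1:100) {
    tab <- matrix(rpois(4, 8) + 1, 2, 2)
    mine <- yates_chi_square(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = TRUE))
    expect_equal(mine$chi2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    raw <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_lte(mine$chi2, unname(raw$statistic) + 1e-12)
  }
})

test_that("mortality summary reproduces the survivor bookkeeping and
          flags extreme contrasts", {
  cfg <- cohort_config(seed = 1)
  co <- generate_cohort(cfg)
  # impose the printed death pattern deterministically: 0/4/2/2/2
  co$alive <- TRUE
  deaths <- c(control = 0, low_salinity = 4, high_temp = 2, low_pH = 2,
              multi_stressor = 2)
  for (tr in names(deaths)) {
    idx <- which(co$treatment == tr)
    if (deaths[[tr]] > 0) co$alive[idx[seq_len(deaths[[tr]])]] <- FALSE
  }
  m <- mortality_summary(co)
  cnt <- m$counts[match(names(deaths), m$counts$treatment), ]
  expect_equal(cnt$alive, c(20, 16, 18, 18, 18))
  expect_equal(cnt$dead, unname(deaths))
  # all alive -> degenerate, reported as no-variation
  co2 <- co; co2$alive <- TRUE
  expect_equal(mortality_summary(co2)$test$method, "degenerate")
  # 100% vs 0% mortality across 4 tanks each -> that pair flagged
  d <- data.frame(
    treatment = rep(c("hot", "ok"), each = 20),
    tank = rep(rep(paste0("t", 1:4), each = 5), 2),
    alive = rep(c(FALSE, TRUE), each = 20))
  d$tank <- paste(d$treatment, d$tank)
  m2 <- mortality_summary(d)
  expect_lt(m2$test$p_value, 0.05)
  expect_true(any(m2$posthoc$significant))
})

test_that("ecotype association rejects under perfect concordance and
          errors on degenerate inputs", {
  co <- generate_cohort(cohort_config(seed = 2, concordance = 1,
                                      mortality_probs = rep(0, 5)))
  spl <- lapply(c("low_salinity", "multi_stressor"), function(tr) {
    d <- co[co$treatment == tr, ]
    split_within_treatment(setNames(d$true_smr, d$fish_id),
                           treatment = tr, variable = "SMR")
  })
  expect_true(any(vapply(spl, `[[`, logical(1), "is_split")))
  a <- ecotype_association(spl, setNames(co$ecotype, co$fish_id), "SMR")
  expect_lt(a$p_value, 0.01)
  expect_s3_class(a, "association_result")
  # all one ecotype -> error
  eco1 <- setNames(rep("coastal", nrow(co)), co$fish_id)
  expect_error(ecotype_association(spl, eco1), "one ecotype")
  # too many unknowns -> error
  eco2 <- setNames(rep("unknown", nrow(co)), co$fish_id)
  expect_error(ecotype_association(spl, eco2), "known")
})
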