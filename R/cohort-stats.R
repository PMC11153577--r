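# Cohort-level statistics: condition factor, the within-treatment
# median-gap split rule, treatment tests with post-hoc comparisons, tank
# checks, mortality summaries and the ecotype-association chi-square.

#' Fulton's condition factor
#'
#' K = 100 W / L^3 with weight in g and length in cm — the standard
#' weight-for-length body-condition index for fish.
#'
#' @param weight_g Body weight, g (> 0).
#' @param length_cm Body length, cm (> 0).
#' @return K. Vectorised.
#' @examples
#' fulton_k(159.4, 24.3) # ~1.11
#' @export
fulton_k <- function(weight_g, length_cm) {
  if (any(!is.finite(weight_g)) || any(!is.finite(length_cm)) ||
      any(weight_g <= 0) || any(length_cm <= 0)) {
    stop("weight_g and length_cm must be positive")
  }
  100 * weight_g / length_cm^3
}

#' Within-treatment bimodality split rule
#'
#' A treatment's values are declared two distinct groups when the nearest
#' observation above the median and the nearest below it each lie one or
#' more standard errors (SEM = sample SD / sqrt(n), computed from all the
#' treatment's values) from the median. When the rule fires, fish below
#' the median form group A (reduced response) and fish above it group B
#' (heightened response); with even n the median falls between the
#' central pair, giving equal halves. A `strict` variant requires the two
#' nearest points on each side (four points total) to clear the gap.
#'
#' @param values Named numeric vector (names = fish ids), >= 4 values.
#' @param treatment,variable Optional labels carried into the result.
#' @param strict Use the two-points-per-side reading of the rule.
#' @return An object of class `split_result`: `is_split`, `assignments`
#'   (named character vector "A"/"B", empty when no split), `median`,
#'   `sem`, `gap_low`, `gap_high`, `note`.
#' @examples
#' split_within_treatment(setNames(c(1, 2, 3, 10, 11, 12), letters[1:6]))
#' @export
split_within_treatment <- function(values, treatment = NA_character_,
                                   variable = NA_character_,
                                   strict = FALSE) {
  if (length(values) < 4) stop("need >= 4 values to apply the split rule")
  if (any(!is.finite(values))) stop("values must be finite")
  if (is.null(names(values))) {
    names(values) <- paste0("fish", seq_along(values))
  }
  med <- stats::median(values)
  sem <- stats::sd(values) / sqrt(length(values))
  above <- sort(values[values > med])
  below <- sort(values[values < med], decreasing = TRUE)
  note <- NA_character_
  k <- if (strict) 2L else 1L
  res <- list(treatment = treatment, variable = variable,
              median = med, sem = sem, n = length(values))
  ties <- sum(values == med)
  if (length(above) < k || length(below) < k || sem == 0) {
    res$is_split <- FALSE
    res$gap_low <- NA_real_
    res$gap_high <- NA_real_
    res$assignments <- character(0)
    res$note <- if (sem == 0) "no variation" else
      "too few points on one side of the median"
  } else if (ties > 0) {
    # odd n: some observation sits exactly on the median and belongs to
    # neither side; the rule cannot allocate it
    res$is_split <- FALSE
    res$gap_low <- med - below[1]
    res$gap_high <- above[1] - med
    res$assignments <- character(0)
    res$note <- "tie at the median; no split"
  } else {
    gap_high <- above[seq_len(k)] - med
    gap_low <- med - below[seq_len(k)]
    res$gap_low <- unname(gap_low[1])
    res$gap_high <- unname(gap_high[1])
    res$is_split <- all(gap_high >= sem) && all(gap_low >= sem)
    res$assignments <- if (res$is_split) {
      stats::setNames(ifelse(values < med, "A", "B"), names(values))
    } else character(0)
    res$note <- note
  }
  class(res) <- "split_result"
  res
}

#' @export
print.split_result <- function(x, ...) {
  lab <- if (!is.na(x$treatment)) paste0(" [", x$treatment,
                                         if (!is.na(x$variable))
                                           paste0(": ", x$variable), "]")
  else ""
  if (x$is_split) {
    cat(sprintf(
      "Split%s: A (n=%d) < median %.4g < B (n=%d); gaps %.3g/%.3g >= SEM %.3g\n",
      lab, sum(x$assignments == "A"), x$median, sum(x$assignments == "B"),
      x$gap_low, x$gap_high, x$sem))
  } else {
    cat(sprintf("No split%s (median %.4g, SEM %.3g%s)\n", lab, x$median,
                x$sem,
                if (!is.na(x$note)) paste0("; ", x$note) else ""))
  }
  invisible(x)
}

# Brown-Forsythe (median-centred Levene) homogeneity test.
levene_bf <- function(values, group) {
  group <- factor(group)
  z <- abs(values - stats::ave(values, group, FUN = stats::median))
  fit <- stats::oneway.test(z ~ group, var.equal = TRUE)
  list(statistic = unname(fit$statistic), p_value = fit$p.value)
}

# Shapiro-Wilk on the groupwise-centred residuals.
shapiro_gate <- function(values, group) {
  resid <- values - stats::ave(values, group)
  if (length(resid) < 3 || stats::sd(resid) == 0) return(NA_real_)
  stats::shapiro.test(resid)$p.value
}

apply_transform <- function(values, transform) {
  switch(transform,
         identity = values,
         sqrt = if (any(values < 0)) NULL else sqrt(values),
         log = if (any(values <= 0)) NULL else log(values),
         log10_p1 = if (any(values < -1 + 1e-12)) NULL else
           log10(values + 1),
         stop("unknown transform ", transform))
}

# Pairwise comparisons after a significant omnibus test.
posthoc_table <- function(values, group, method, alpha) {
  group <- factor(group)
  lev <- levels(group)
  if (method == "hsd") {
    fit <- stats::aov(values ~ group)
    tk <- stats::TukeyHSD(fit)$group
    cmp <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
    out <- data.frame(group1 = cmp[, 2], group2 = cmp[, 1],
                      estimate = tk[, "diff"], p_value = tk[, "p adj"],
                      stringsAsFactors = FALSE, row.names = NULL)
    out$adjusted <- TRUE
  } else if (method == "lsd") {
    fit <- stats::aov(values ~ group)
    mse <- sum(stats::residuals(fit)^2) / fit$df.residual
    ns <- table(group)
    ms <- tapply(values, group, mean)
    pairs <- utils::combn(lev, 2)
    out <- data.frame(
      group1 = pairs[1, ], group2 = pairs[2, ],
      estimate = ms[pairs[2, ]] - ms[pairs[1, ]],
      stringsAsFactors = FALSE, row.names = NULL
    )
    se <- sqrt(mse * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]]))
    tstat <- out$estimate / se
    out$p_value <- 2 * stats::pt(abs(tstat), fit$df.residual,
                                 lower.tail = FALSE)
    out$adjusted <- FALSE
  } else { # dunn: nonparametric multiple comparisons on ranks
    n <- length(values)
    rk <- rank(values)
    rbar <- tapply(rk, group, mean)
    ns <- table(group)
    ties <- table(values)
    tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
    v <- n * (n + 1) / 12 - tie_corr
    pairs <- utils::combn(lev, 2)
    z <- (rbar[pairs[2, ]] - rbar[pairs[1, ]]) /
      sqrt(v * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]]))
    p <- pmin(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE) *
                ncol(pairs)) # Bonferroni across the pairs
    out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                      estimate = unname(rbar[pairs[2, ]] -
                                          rbar[pairs[1, ]]),
                      p_value = unname(p), adjusted = TRUE,
                      stringsAsFactors = FALSE, row.names = NULL)
  }
  out$significant <- out$p_value < alpha
  out
}

#' Treatment-level omnibus test with assumption gates and post-hoc table
#'
#' One-way comparison of a response across treatments following the
#' decision path used on the experimental endpoints: Shapiro-Wilk
#' normality and Brown-Forsythe homogeneity gates; a fixed transform
#' ladder (sqrt, log, log10(x+1)) tried in order until both gates pass;
#' one-way ANOVA on the first passing scale, otherwise Kruskal-Wallis.
#' Significant omnibus results are followed by the configured post-hoc
#' method: Tukey "unequal N" HSD (Tukey-Kramer; default, robust to
#' unequal group sizes), Fisher LSD (unadjusted), or Dunn-type rank
#' comparisons (used automatically after Kruskal-Wallis).
#'
#' @param values Numeric response.
#' @param group Treatment labels, same length.
#' @param posthoc `"hsd"`, `"lsd"` or `"dunn"`.
#' @param alpha Significance level for gates and post-hoc flags.
#' @param gate_alpha Alpha for the normality/homogeneity gates.
#' @return List of class `treatment_tests`: `method` ("anova" or
#'   "kruskal"), `transform`, `statistic`, `df`, `p_value`, `gates`
#'   (per-transform gate p-values), `posthoc` (data frame or NULL),
#'   `excluded` (groups dropped for having < 2 observations).
#' @export
treatment_tests <- function(values, group,
                            posthoc = c("hsd", "lsd", "dunn"),
                            alpha = 0.05, gate_alpha = 0.05) {
  posthoc <- match.arg(posthoc)
  stopifnot(length(values) == length(group))
  ok <- is.finite(values) & !is.na(group)
  values <- values[ok]
  group <- as.character(group)[ok]
  sizes <- table(group)
  excluded <- names(sizes)[sizes < 2]
  if (length(excluded)) {
    warning("excluding group(s) with < 2 observations: ",
            paste(excluded, collapse = ", "))
    keep <- !group %in% excluded
    values <- values[keep]; group <- group[keep]
  }
  if (length(unique(group)) < 2) stop("need >= 2 groups")
  if (stats::sd(values) == 0) {
    res <- list(method = "degenerate", transform = "identity",
                statistic = 0, df = NA_real_, p_value = 1,
                gates = list(), excluded = excluded, posthoc = NULL,
                posthoc_method = NA_character_)
    class(res) <- "treatment_tests"
    return(res)
  }
  ladder <- c("identity", "sqrt", "log", "log10_p1")
  gates <- list()
  chosen <- NULL
  for (tr in ladder) {
    v <- apply_transform(values, tr)
    if (is.null(v)) next
    sw <- shapiro_gate(v, group)
    lv <- levene_bf(v, group)$p_value
    gates[[tr]] <- c(shapiro_p = sw, levene_p = lv)
    if (!is.na(sw) && sw >= gate_alpha && lv >= gate_alpha) {
      chosen <- tr
      break
    }
  }
  g <- factor(group)
  if (!is.null(chosen)) {
    v <- apply_transform(values, chosen)
    fit <- stats::oneway.test(v ~ g, var.equal = TRUE)
    res <- list(method = "anova", transform = chosen,
                statistic = unname(fit$statistic),
                df = unname(fit$parameter), p_value = fit$p.value)
    ph_method <- posthoc
    ph_values <- v
  } else {
    kw <- stats::kruskal.test(values, g)
    res <- list(method = "kruskal", transform = "identity",
                statistic = unname(kw$statistic),
                df = unname(kw$parameter), p_value = kw$p.value)
    ph_method <- "dunn"
    ph_values <- values
  }
  res$gates <- gates
  res$excluded <- excluded
  res$posthoc <- if (!is.na(res$p_value) && res$p_value < alpha) {
    posthoc_table(ph_values, group, ph_method, alpha)
  } else NULL
  res$posthoc_method <- if (!is.null(res$posthoc)) ph_method else NA_character_
  class(res) <- "treatment_tests"
  res
}

#' @export
print.treatment_tests <- function(x, ...) {
  lbl <- switch(x$method, anova = "One-way ANOVA",
                kruskal = "Kruskal-Wallis", "Degenerate (no variation)")
  cat(sprintf("%s (%s scale): statistic = %.3f, p = %.4g\n",
              lbl, x$transform, x$statistic, x$p_value))
  if (!is.null(x$posthoc)) {
    cat("Post-hoc (", x$posthoc_method, "):\n", sep = "")
    print(x$posthoc, digits = 3)
  }
  invisible(x)
}

#' Nested ANOVA check for tank effects
#'
#' Tests the tank-within-treatment variance component by nesting tank
#' inside treatment in a two-stage ANOVA; a significant tank term means
#' tanks within the same treatment differ beyond residual noise and the
#' treatment comparison should be run on tank means.
#'
#' @param values Numeric response.
#' @param tank,treatment Tank and treatment labels per observation.
#' @param alpha Flag threshold for the tank term.
#' @return List: `f_tank`, `df1`, `df2`, `p_tank`, `flagged`,
#'   `excluded_tanks` (singleton tanks dropped).
#' @export
nested_tank_check <- function(values, tank, treatment, alpha = 0.05) {
  stopifnot(length(values) == length(tank),
            length(tank) == length(treatment))
  tank <- as.character(tank); treatment <- as.character(treatment)
  sizes <- table(tank)
  singletons <- names(sizes)[sizes < 2]
  if (length(singletons)) {
    keep <- !tank %in% singletons
    values <- values[keep]; tank <- tank[keep]
    treatment <- treatment[keep]
  }
  tanks_per <- tapply(tank, treatment, function(x) length(unique(x)))
  if (any(tanks_per < 2)) {
    stop("need >= 2 tanks per treatment (after dropping singletons); ",
         "offending treatment(s): ",
         paste(names(tanks_per)[tanks_per < 2], collapse = ", "))
  }
  g_tr <- factor(treatment)
  g_tk <- factor(tank)
  fit <- stats::aov(values ~ g_tr / g_tk)
  an <- stats::anova(fit)
  i <- grep("g_tr:g_tk", rownames(an))
  f <- an[i, "F value"]
  p <- an[i, "Pr(>F)"]
  list(f_tank = f, df1 = an[i, "Df"],
       df2 = an["Residuals", "Df"], p_tank = p,
       flagged = is.finite(p) && p < alpha,
       excluded_tanks = singletons)
}

#' Yates-corrected chi-square test for a 2x2 table
#'
#' Continuity-corrected chi-square
#' \deqn{\chi^2 = \sum (|O - E| - 0.5)^2 / E} with the correction clamped
#' so it never exceeds |O - E|, df = 1.
#'
#' @param table A 2x2 matrix of non-negative integer counts.
#' @return An object of class `association_result`: `table`, `chi2`,
#'   `df`, `p_value`, `n`, `expected`.
#' @examples
#' yates_chi_square(matrix(c(10, 5, 5, 10), 2))$chi2 # 2.133
#' @export
yates_chi_square <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table))) {
    stop("cell counts must be non-negative integers")
  }
  n <- sum(table)
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) {
    stop("undefined: zero marginal total")
  }
  expected <- outer(rs, cs) / n
  dev <- pmax(abs(table - expected) - 0.5, 0)
  chi2 <- sum(dev^2 / expected)
  structure(
    list(table = table, chi2 = chi2, df = 1L,
         p_value = stats::pchisq(chi2, 1, lower.tail = FALSE),
         n = n, expected = expected),
    class = "association_result"
  )
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("Corrected chi-square: X2(%d, N = %d) = %.3f, p = %.4g\n",
              x$df, x$n, x$chi2, x$p_value))
  print(x$table)
  invisible(x)
}

#' Mortality summary and tank-level rank test
#'
#' Per-treatment dead/alive counts plus a Kruskal-Wallis test on the
#' per-tank mortality proportions (tanks are the replicates), with
#' Dunn-type pairwise comparisons when the omnibus test is significant.
#' With no variation in mortality anywhere, the test is reported as
#' degenerate rather than run.
#'
#' @param cohort Data frame with columns `treatment`, `tank`, `alive`
#'   (logical).
#' @param alpha Significance level for the post-hoc flags.
#' @return List: `counts` (data frame: treatment, n, dead, alive,
#'   mortality), `tank_proportions`, `test` (Kruskal-Wallis or a
#'   degenerate marker), `posthoc`.
#' @export
mortality_summary <- function(cohort, alpha = 0.05) {
  stopifnot(all(c("treatment", "tank", "alive") %in% names(cohort)))
  if (any(is.na(cohort$alive))) stop("alive flags contain NA")
  counts <- do.call(rbind, lapply(split(cohort, cohort$treatment),
                                  function(d) {
    data.frame(treatment = d$treatment[1], n = nrow(d),
               dead = sum(!d$alive), alive = sum(d$alive),
               mortality = mean(!d$alive), stringsAsFactors = FALSE)
  }))
  rownames(counts) <- NULL
  tanks <- do.call(rbind, lapply(
    split(cohort, list(cohort$treatment, cohort$tank), drop = TRUE),
    function(d) data.frame(treatment = d$treatment[1], tank = d$tank[1],
                           prop_dead = mean(!d$alive),
                           stringsAsFactors = FALSE)))
  rownames(tanks) <- NULL
  if (stats::sd(tanks$prop_dead) == 0) {
    test <- list(method = "degenerate", statistic = NA_real_,
                 df = NA_integer_, p_value = NA_real_,
                 note = "no variation in tank mortality")
    ph <- NULL
  } else {
    kw <- stats::kruskal.test(tanks$prop_dead, factor(tanks$treatment))
    test <- list(method = "kruskal", statistic = unname(kw$statistic),
                 df = unname(kw$parameter), p_value = kw$p.value,
                 note = NA_character_)
    ph <- if (kw$p.value < alpha) {
      posthoc_table(tanks$prop_dead, tanks$treatment, "dunn", alpha)
    } else NULL
  }
  list(counts = counts, tank_proportions = tanks, test = test,
       posthoc = ph)
}

#' Ecotype association with the within-treatment response classes
#'
#' Pools the reduced (A) and heightened (B) groups from the
#' within-treatment splits across the designated treatments, tabulates
#' them against ecotype (coastal/offshore; fish of unknown ecotype are
#' excluded, and at least `min_known` of the split fish must be typed)
#' and applies the Yates-corrected chi-square.
#'
#' @param split_results A single `split_result` or list of them (only
#'   those with `is_split = TRUE` contribute).
#' @param ecotypes Named character vector fish_id -> ecotype
#'   ("offshore"/"coastal"/"unknown"; missing ids count as unknown).
#' @param endpoint Label for the endpoint tested ("SMR" or "OSR"),
#'   informational.
#' @param min_known Minimum fraction of split fish with known ecotype.
#' @return An `association_result` with extra fields `endpoint` and
#'   `n_excluded_unknown`.
#' @export
ecotype_association <- function(split_results, ecotypes,
                                endpoint = c("SMR", "OSR"),
                                min_known = 0.8) {
  endpoint <- match.arg(endpoint)
  if (inherits(split_results, "split_result")) {
    split_results <- list(split_results)
  }
  assignments <- unlist(lapply(split_results, function(s) {
    if (isTRUE(s$is_split)) s$assignments else character(0)
  }))
  if (length(assignments) == 0) {
    stop("no split fish: every split_result has is_split = FALSE")
  }
  eco <- ecotypes[names(assignments)]
  eco[is.na(eco)] <- "unknown"
  known <- eco %in% c("offshore", "coastal")
  if (mean(known) < min_known) {
    stop("ecotype known for only ", round(100 * mean(known)),
         "% of split fish (need >= ", round(100 * min_known), "%)")
  }
  cls <- assignments[known]
  eco <- eco[known]
  if (length(unique(cls)) < 2) stop("empty pooled response class")
  if (length(unique(eco)) < 2) {
    stop("all typed fish share one ecotype; association undefined")
  }
  tab <- table(ecotype = factor(eco, c("coastal", "offshore")),
               response = factor(cls, c("A", "B")))
  res <- yates_chi_square(unclass(tab))
  res$endpoint <- endpoint
  res$n_excluded_unknown <- sum(!known)
  res
}
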