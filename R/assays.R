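# Liver antioxidant assays: microplate kinetics -> protein-normalised
# enzyme activities (GST, GR) and glutathione levels (tGSH, GSSG, %GSSG).

#' Assay specification
#'
#' Optical and volumetric parameters for one microplate assay. Defaults
#' follow the liver protocols: GST via CDNB conjugation at 340 nm
#' (glutathione-DNB adduct, epsilon = 9600 M^-1 cm^-1), GR via DTNB
#' reduction at 405 nm (TNB, epsilon = 14151 M^-1 cm^-1), total
#' glutathione (sample diluted 80x in 1.3% SSA) and GSSG (undiluted,
#' after vinyl-pyridine blocking of GSH) by the DTNB recycling assay at
#' 415 nm read against a GSH standard curve, and Lowry protein with a BSA
#' standard curve. The microplate optical path depends on well fill
#' volume and is not fixed by the protocol; the 1-cm default should be
#' replaced by the plate-calibrated value when known, since activities
#' scale as 1/path.
#'
#' @param assay One of `"GST"`, `"GR"`, `"tGSH"`, `"GSSG"`, `"protein"`.
#' @param wavelength_nm Detection wavelength (informational).
#' @param extinction Molar extinction coefficient, M^-1 cm^-1 (`NA` for
#'   standard-curve assays).
#' @param path_cm Optical path length, cm.
#' @param reaction_ul,sample_ul Reaction and sample volumes, uL.
#' @param dilution Sample dilution factor applied before the assay.
#' @param direction `"increase"` or `"decrease"`: sign of the absorbance
#'   change as the reaction proceeds.
#' @return An object of class `assay_spec`.
#' @examples
#' assay_spec("GST")
#' assay_spec("tGSH") # dilution 80
#' @export
assay_spec <- function(assay = c("GST", "GR", "tGSH", "GSSG", "protein"),
                       wavelength_nm = NULL, extinction = NULL,
                       path_cm = 1.0, reaction_ul = 200, sample_ul = 20,
                       dilution = NULL, direction = NULL) {
  assay <- match.arg(assay)
  defaults <- list(
    GST     = list(wavelength_nm = 340, extinction = 9600,
                   dilution = 1, direction = "increase"),
    GR      = list(wavelength_nm = 405, extinction = 14151,
                   dilution = 1, direction = "increase"),
    tGSH    = list(wavelength_nm = 415, extinction = NA_real_,
                   dilution = 80, direction = "increase"),
    GSSG    = list(wavelength_nm = 415, extinction = NA_real_,
                   dilution = 1, direction = "increase"),
    protein = list(wavelength_nm = 750, extinction = NA_real_,
                   dilution = 1, direction = "increase")
  )[[assay]]
  wavelength_nm <- wavelength_nm %||% defaults$wavelength_nm
  extinction <- extinction %||% defaults$extinction
  dilution <- dilution %||% defaults$dilution
  direction <- direction %||% defaults$direction
  if (!direction %in% c("increase", "decrease")) {
    stop_config("direction must be 'increase' or 'decrease'")
  }
  if (!is.na(extinction) && extinction <= 0) {
    stop_config("extinction must be positive where used")
  }
  stopifnot_scalar_pos(path_cm, "path_cm")
  stopifnot_scalar_pos(reaction_ul, "reaction_ul")
  stopifnot_scalar_pos(sample_ul, "sample_ul")
  if (dilution < 1) stop_config("dilution must be >= 1")
  structure(
    list(assay = assay, wavelength_nm = wavelength_nm,
         extinction = extinction, path_cm = path_cm,
         reaction_ul = reaction_ul, sample_ul = sample_ul,
         dilution = dilution, direction = direction),
    class = "assay_spec"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Kinetic rate of one plate well
#'
#' OLS slope of absorbance against time over the configured linear window
#' (default: the first 3 min), blank-corrected, with the sign folded by
#' the assay direction so that a proceeding reaction always yields a
#' positive rate. Wells whose fit falls below the linearity gate are
#' flagged — not silently used.
#'
#' @param time_s Time of each reading, s.
#' @param absorbance Absorbance, AU (>= 3 readings).
#' @param blank_rate Blank rate to subtract, AU min^-1 (same sign
#'   convention as the output).
#' @param direction `"increase"` (default) or `"decrease"`.
#' @param window_s Linear window fitted from the first reading, s.
#' @param min_r2 Linearity gate on the window r^2.
#' @return List: `rate` (AU min^-1, blank-corrected), `r2`, `flagged`
#'   (TRUE when r2 < min_r2), `n`.
#' @export
kinetic_rate <- function(time_s, absorbance, blank_rate = 0,
                         direction = c("increase", "decrease"),
                         window_s = 180, min_r2 = 0.98) {
  direction <- match.arg(direction)
  stopifnot(length(time_s) == length(absorbance))
  if (length(time_s) < 3) stop("need >= 3 kinetic readings")
  if (any(!is.finite(absorbance))) stop("non-finite absorbance")
  keep <- time_s <= min(time_s) + window_s
  if (sum(keep) < 3) keep <- rep(TRUE, length(time_s))
  fit <- ols_fit(time_s[keep], absorbance[keep])
  sgn <- if (direction == "increase") 1 else -1
  rate <- sgn * fit$slope * 60 - blank_rate
  flagged <- !is.na(fit$r2) && fit$r2 < min_r2
  list(rate = rate, r2 = fit$r2, flagged = flagged, n = fit$n)
}

#' Specific enzyme activity from a kinetic rate
#'
#' Beer-Lambert inversion and volume/protein normalisation:
#' rate (AU min^-1) / (epsilon * path) gives the product formation rate in
#' the well (M min^-1 = 1e3 nmol mL^-1 min^-1); multiplying by the
#' reaction/sample volume ratio refers it to the sample, and dividing by
#' the protein concentration yields the specific activity.
#'
#' @param rate Blank-corrected rate, AU min^-1.
#' @param spec An [assay_spec()] with a molar extinction coefficient.
#' @param protein Protein concentration of the sample, mg mL^-1.
#' @return Specific activity, nmol min^-1 mg-protein^-1. Vectorised over
#'   `rate` and `protein`.
#' @examples
#' enzyme_activity(0.0096, assay_spec("GST", reaction_ul = 200,
#'                                    sample_ul = 20), protein = 1) # 10
#' @export
enzyme_activity <- function(rate, spec, protein) {
  stopifnot(inherits(spec, "assay_spec"))
  if (is.na(spec$extinction) || spec$extinction <= 0 || spec$path_cm <= 0) {
    stop_config("enzyme_activity needs a positive extinction coefficient ",
                "and path length")
  }
  if (any(protein <= 0)) stop("protein must be positive")
  well_um_min <- rate / (spec$extinction * spec$path_cm) * 1e6 # uM/min
  # uM/min == nmol/mL/min; refer to sample volume, then per mg protein
  well_um_min * (spec$reaction_ul / spec$sample_ul) / protein
}

#' Protein concentration by the Lowry standard curve
#'
#' Linear BSA standard-curve inversion of sample absorbances, with the
#' sample dilution applied. Samples outside the standard range are
#' extrapolated and flagged.
#'
#' @param sample_abs Sample absorbances.
#' @param standard_abs,standard_conc Standard-curve absorbances and
#'   concentrations (mg mL^-1), >= 3 points, monotone in concentration.
#' @param dilution Dilution factor applied to samples before the assay.
#' @return Protein, mg mL^-1, with attribute `extrapolated` (logical).
#' @export
lowry_protein <- function(sample_abs, standard_abs, standard_conc,
                          dilution = 1) {
  if (length(standard_abs) < 3 ||
      length(standard_abs) != length(standard_conc)) {
    stop("need >= 3 paired standards")
  }
  o <- order(standard_conc)
  if (any(diff(standard_abs[o]) <= 0)) {
    stop("curve error: standard absorbances not monotone increasing ",
         "with concentration")
  }
  fit <- ols_fit(standard_abs, standard_conc)
  conc <- (fit$intercept + fit$slope * sample_abs) * dilution
  structure(conc,
            extrapolated = sample_abs < min(standard_abs) |
              sample_abs > max(standard_abs))
}

#' Glutathione concentration from the DTNB recycling assay
#'
#' Inverts the GSH standard curve (recycling rate against standard
#' concentration) for sample rates, then applies the assay dilution
#' factor (80x for total glutathione, 1x for GSSG). Rates outside the
#' standard range are extrapolated and flagged.
#'
#' @param rate_sample Blank-corrected sample rates, AU min^-1.
#' @param standard_rate,standard_conc Standard rates (AU min^-1) and GSH
#'   concentrations (uM); the curve must be monotone increasing.
#' @param spec An [assay_spec()] (`"tGSH"` or `"GSSG"`) supplying the
#'   dilution factor.
#' @return Extract concentration, uM, with attribute `extrapolated`.
#' @export
glutathione_level <- function(rate_sample, standard_rate, standard_conc,
                              spec) {
  stopifnot(inherits(spec, "assay_spec"))
  if (length(standard_rate) < 2 ||
      length(standard_rate) != length(standard_conc)) {
    stop("need >= 2 paired standards")
  }
  o <- order(standard_conc)
  if (any(diff(standard_rate[o]) <= 0)) {
    stop("standard curve not monotone increasing")
  }
  fit <- ols_fit(standard_rate, standard_conc)
  conc <- (fit$intercept + fit$slope * rate_sample) * spec$dilution
  structure(conc,
            extrapolated = rate_sample < min(standard_rate) |
              rate_sample > max(standard_rate))
}

#' Percent oxidised glutathione
#'
#' The oxidative-stress index %GSSG = GSSG/GSH x 100, both in the same
#' units (the ratio is invariant to any common dilution or
#' tissue-normalisation factor).
#'
#' @param gssg,gsh Oxidised and reduced glutathione levels.
#' @param gsh_equivalents If TRUE, treat `gsh` as total glutathione
#'   assayed in GSH equivalents and use GSH = tGSH - 2 GSSG in the
#'   denominator. Default FALSE: the two assays are read independently,
#'   as in the original protocol.
#' @return %GSSG.
#' @examples
#' pct_gssg(5, 100) # 5
#' @export
pct_gssg <- function(gssg, gsh, gsh_equivalents = FALSE) {
  if (any(gssg < 0) || any(gsh <= 0)) {
    stop("gssg must be >= 0 and gsh > 0")
  }
  denom <- if (gsh_equivalents) gsh - 2 * gssg else gsh
  if (any(denom <= 0)) {
    stop("GSH equivalents non-positive after subtracting 2*GSSG")
  }
  gssg / denom * 100
}
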