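---
title: "Methods: from oxygen traces and water chemistry to ecotype-linked stress responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from oxygen traces and water chemistry to ecotype-linked stress responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codstress)
```

codstress implements the complete analysis chain of a multi-stressor
(freshening, warming, acidification) exposure experiment on juvenile
Atlantic cod: respirometry processing to standard metabolic rate (SMR),
seawater carbonate chemistry, liver antioxidant assay quantification,
within-treatment bimodality detection, and ecotype-association
statistics. This vignette documents the models, their assumptions, the
parameters that matter, and the design decisions taken where the
underlying protocols left choices open.

## Respirometry model

Intermittent-flow respirometry alternates a flush phase (chamber
renewed with saturated water) with a sealed measurement phase in which
the fish draws down oxygen. The default schedule is the experiment's:
20-min cycles of 15-min flush + 5-min measurement, 20-h occupancy
(60 usable cycles; 21 h gives 63), bracketed by one fish-free hour
before and after for background (microbial) respiration.

Each measurement window's saturation slope is fitted by ordinary least
squares after discarding the first `trim_s = 30` s (chamber mixing
transient; the protocol does not state a trim, 30 s is conventional and
configurable). Mass-specific oxygen consumption is

$$\mathrm{MO_2} = \frac{(V_r - V_f)\,r_{fish} - V_r\,r_{bg}}{m},$$

with $V_r$ the chamber volume (3 or 3.9 L), $V_f$ the fish volume from
body mass at tissue density 1 g mL$^{-1}$, and each $r$ a saturation
slope converted to mg O$_2$ L$^{-1}$ h$^{-1}$ via air-saturation
solubility. As printed, the source equation is notationally ambiguous
(the same $\Delta C_{wO2}$ symbol appears in both terms and the
$\Delta t$ placement is unclear); we read it as the subtraction of two
concentration *rates* — the fish-phase rate referenced to the effective
water volume $(V_r - V_f)$ minus the background rate referenced to the
full chamber — which is both the stated purpose of the background
measurements and standard respirometry practice. Declining oxygen gives
negative slopes; consumption is reported positive. The background slope
during occupancy is linearly interpolated in time between the pre- and
post-session fits; with one background missing it is held constant
(with a warning), with both missing it falls back to zero.

Oxygen solubility uses the Garcia–Gordon polynomial (Benson–Krause
refit) at 1 atm; barometric pressure was not reported. Two
independently typed coefficient sets (the mL L$^{-1}$ fit, and the
µmol kg$^{-1}$ fit combined with seawater density) agree to 4 decimals,
giving 8.577 mg L$^{-1}$ at 13 °C and salinity 33.

**SMR** is the mean of the lowest 10% of a fish's MO$_2$ values
(`ceiling(0.1 n)`, so 6 of 60), after removing values more than 2
sample SDs *below* that decile's mean — a single filtering pass using
the initial decile statistics, no re-iteration. Two order-theoretic
caveats are worth knowing: with the outlier filter active, the estimate
is not strictly monotone in the data (removing a newly lowered value
can raise the decile mean) and can in contrived series exceed the
overall mean; both properties hold exactly for the pure decile mean,
which is what the property tests assert.

## Synthetic data: what it emulates and what it does not

The original physiological raw data were not deposited, so the
generators reproduce the experiment's *statistical structure*, not its
biology:

* **Design** — 5 treatments × 4 tanks × 5 fish; start biometrics from
  the cohort summary (mass 159.4 ± 72.6 g, length 24.3 ± 3.5 cm,
  truncated at physical floors); per-treatment death probabilities
  defaulting to the printed expected mortality (0/4/2/2/2 of 20).
* **Traces** — 1 Hz optode sampling (rate not stated; configurable)
  with Gaussian noise of SD 0.2 %sat, a typical optode figure; sealed
  phases decline at the rate implied by inverting the MO$_2$ equation
  for the fish's true SMR plus background, so the noiseless chain
  round-trips exactly; flush phases relax exponentially to 100% with a
  60-s time constant (cosmetic — only sealed phases are analysed).
  Background drift defaults to a constant −0.5 %sat h$^{-1}$, with an
  optional end-of-session value to exercise the interpolation.
* **SMR structure** — baseline 80 mg O$_2$ kg$^{-1}$ h$^{-1}$ (a
  realistic juvenile-cod resting rate at 13 °C) with small treatment
  shifts and, in the freshening and multi-stressor treatments, a
  bimodal split: heightened +22 / reduced −18 around the treatment
  mean, between-fish SD 6. These magnitudes were fixed once to give the
  clear two-group separation the study describes.
* **Response classes and ecotype** — the study found its bimodal
  treatments divided into near-equal halves around the median, so the
  generator balances heightened/reduced classes among each bimodal
  treatment's survivors and draws the latent ecotype conditional on
  class (offshore↔heightened with probability `concordance`, default
  0.8 — strong but imperfect, matching the marginally significant
  association reported). Conditioning class on a Bernoulli ecotype
  instead would only rarely reproduce the observed equal halves. Only
  the genotyped treatments (control, freshening, multi-stressor) expose
  the ecotype; elsewhere it is `unknown`.
* **Water chemistry** — independent normal draws per parameter from the
  monitoring table's printed means and SDs, per treatment.
* **Plates** — absorbance = A$_0$ + slope·t + noise with Beer–Lambert
  slopes for extinction-based assays and a common gain for the
  glutathione standard curve, so noiseless plates invert exactly.

Not emulated: circadian or activity-driven MO$_2$ variation (the
lowest-decile SMR is robust to it), within-session temperature drift,
correlated water-parameter fluctuations, tank effects (generated null,
so the nested ANOVA check has its nominal size), plate-position
effects, and any mechanistic temperature–mortality dose response. A
green test therefore establishes that the *computational chain* is
correct and well-calibrated under the stated noise model — not that the
biological effect sizes are right.

## Carbonate system

With [H$^+$] fixed by total-scale pH, the alkalinity balance
(carbonate + borate + water − free proton − bisulfate − HF; nutrient
alkalinity assumed zero, surface pressure) is linear in DIC and solved
analytically; pCO$_2$ = [CO$_2^*$]/K$_0$ (no fugacity correction,
≈0.4%), and saturation states use Mucci solubility products with
calcium from salinity. The constants set was not named by the source
protocol; we default to the Lueker et al. (2000) total-scale refit of
Mehrbach's K$_1$/K$_2$ — the standard coastal default — with Weiss
K$_0$, Dickson K$_B$ and K$_S$, Millero K$_W$ and Perez & Fraga K$_F$.
Every constant reproduces its published check value at S = 35, 25 °C to
10$^{-4}$ in pK, and the solver agrees with an independently written
root-finding implementation to well under 0.5% in pCO$_2$ over
pH 7.4–8.2, TA 2000–2400, 5–20 °C, S 20–35.

At the ambient group's mean conditions (pH$_{TS}$ 8.06, TA 2308,
12.95 °C, S 32.62) the solver gives pCO$_2$ = 392 µatm against the
printed 404 ± 92 — a 3% difference comfortably inside the spread from
constants-set choice and from computing at mean inputs rather than
averaging per-sample results (Jensen gap). That gap matters more for
the low-pH group (pH SD 0.30): pCO$_2$ at the mean pH is ~1030 µatm
while the per-sample mean is ~1340 (printed: 1439 ± 1692), so the
low-pH pCO$_2$ is deliberately not used as a point target. Similarly,
aragonite at the low-pH group's *mean* pH is marginally undersaturated
($\Omega_{ar}$ = 0.97–1.00, confirmed by the independent
implementation) while the per-sample mean is ~1.15; the reported
"supersaturated in all treatments" is thus a statement about per-sample
values, and the tests check calcite strictly, ambient aragonite
strictly, and low-pH aragonite via the per-sample mean.

The monitoring table's variance column equals
(larger SD / smaller SD)$^2$ for every printed row — e.g.
(1.92/1.64)$^2$ = 1.37 → 1.4, (1692/92)$^2$ = 338 → its printed 339
from unrounded SDs — so it is implemented as a two-sided
variance-ratio F test with the larger variance in the numerator. The
pH comparison t(98) = 10 is a pooled-variance t from summary
statistics; rounded inputs give 9.59.

## Assays

Rates are OLS slopes over the first 3 min (configurable window), blank
corrected, sign-folded by assay direction, and gated at r$^2 \ge$ 0.98
(flagged, not dropped silently). Specific activity is
rate/(ε·path) × (reaction volume / sample volume) / protein. The
microplate optical path depends on fill volume and was not stated; it
defaults to 1 cm and *activities scale inversely with it*, so absolute
values should be read against a plate-calibrated path. Reaction/sample
volumes default to 200/20 µL (only partially stated). Total
glutathione uses the 80× dilution, GSSG is undiluted;
%GSSG = GSSG/GSH × 100 is invariant to any common dilution. Whether the
reported GSH is the assayed total or tGSH − 2·GSSG is ambiguous in the
protocol; both are available (`gsh_equivalents`), defaulting to
as-assayed since the assays were run independently.

## The split rule and association tests

A treatment is declared bimodal when the nearest observation above and
the nearest below the treatment median each lie ≥ 1 SEM
(sample SD/√n of *all* the treatment's values — the rule runs before
any subgroups exist) from the median; fish below the median form the
reduced group A, above it the heightened group B. Two readings of the
source phrasing ("the next closest two data points above and below the
median") exist; they coincide for even n — the second-nearest point is
never closer than the nearest — and with odd n the middle observation
ties the median, so the rule as stated cannot fire at all. Both
bimodal treatments in the study had even survivor counts. The rule is
exactly affine-equivariant, detects a 6-SEM empty interval essentially
always at n = 16, and false-fires on unimodal normal samples in under
10% of cases.

Treatment tests follow the protocol's decision path: Shapiro–Wilk on
centred residuals and Brown–Forsythe homogeneity gates (α = 0.05), a
fixed transform ladder (√x, log x, log$_{10}$(x+1)) tried in order,
one-way ANOVA on the first passing scale, otherwise Kruskal–Wallis
with Dunn-type rank post-hocs (Bonferroni-adjusted; the source's exact
non-parametric post-hoc variant is unnamed, so equality with it is not
asserted). The parametric default post-hoc is Tukey–Kramer ("unequal N
HSD"); Fisher LSD is available unadjusted. The ecotype association
pools A and B across the designated treatments, excludes unknown
ecotypes (requiring ≥ 80% typed), and applies the Yates-corrected
χ² with the correction clamped at |O − E|; SMR analyses can be run on
tank means (as the original analysis did) while the split rule always
uses per-fish values.

## Determinism and numerics

Every generator takes a seed and restores the caller's RNG state;
pipeline stage seeds derive from the master seed, and a rerun with the
same configuration is byte-identical (the report carries the seed and a
configuration hash). OLS is computed from centred sums (no matrix
inversion); flat windows with numerically zero residuals report
r$^2$ = 1. The carbonate solver is analytic given pH; the inverse
(pH from DIC + TA) brackets the root in pH 3–11 and round-trips to
10$^{-6}$. Degenerate inputs (constant responses, zero marginals,
single tanks, dead fish) error or report explicitly rather than
propagating NaN.

## Limitations

Absolute assay activities depend on the unstated optical path and
volumes; carbonate results carry the constants-set uncertainty (a few
percent in pCO$_2$); the biological effect sizes in the generator are
plausible settings, not estimates; and mortality is drawn from
configured probabilities, not a mechanistic dose–response. The split
rule, as specified, cannot declare groups in odd-sized treatments.
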