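# codstress

Analysis toolkit for a multi-stressor exposure experiment on juvenile
Atlantic cod (*Gadus morhua*), in which fish were held for four weeks
under control conditions, freshening (salinity 26), warming (18 °C),
ocean acidification (pH 7.5), or all three combined, in a 5 treatments ×
4 tanks × 5 fish design. The package is written for ecophysiologists who
need to take such an experiment from raw instrument output to the
reported statistics — and, because the original physiological raw data
were never deposited, it ships a seeded synthetic-data generator that
reproduces the experiment's statistical structure so every stage is
testable end to end.

## What it computes

**Respirometry → standard metabolic rate.** Intermittent-flow
respirometry alternates a 15-min flush with a 5-min sealed measurement
(20-min cycles; a 20-h session yields 60 MO₂ values per fish). Each
sealed window's oxygen-saturation slope is converted to mass-specific
oxygen consumption with background (microbial) correction:

    MO2 = [ (V_r − V_f) · r_fish − V_r · r_bg ] / m

where `V_r` is chamber volume (L), `V_f` fish volume (mass at
1 g mL⁻¹), and each `r` is a saturation slope converted to
mg O₂ L⁻¹ h⁻¹ through Garcia–Gordon air-saturation solubility at the
session temperature and salinity. The background slope is interpolated
between fish-free hours measured before and after the session. SMR is
the mean of the lowest 10% of a fish's MO₂ values after removing
outliers more than 2 SD below that decile's mean.

**Seawater carbonate system.** From total-scale pH and total alkalinity
(with T, S), the solver closes the alkalinity balance (carbonate,
borate, water, bisulfate, HF) analytically for DIC and reports pCO₂,
speciation and calcite/aragonite saturation states, using the Lueker et
al. total-scale refit of Mehrbach's constants (Weiss K₀, Dickson K_B and
K_S, Mucci solubility products). TRIS/AMP electrode calibration,
variance-ratio (F) tests and pooled t tests for the monitoring-table
comparisons are included.

**Liver antioxidant assays.** Microplate kinetics → blank-corrected
rates → Beer–Lambert inversion (GST via CDNB, ε = 9600 M⁻¹ cm⁻¹; GR via
TNB, ε = 14151 M⁻¹ cm⁻¹) normalised to Lowry protein, and
standard-curve quantification of total and oxidised glutathione
(%GSSG = GSSG/GSH × 100).

**Cohort statistics.** Fulton's condition factor K = 100·W/L³; the
within-treatment bimodality rule (two groups are declared when the
nearest observations above and below the treatment median each lie ≥ 1
SEM from it); assumption-gated one-way ANOVA / Kruskal–Wallis with
Tukey unequal-N HSD, Fisher LSD or Dunn post-hocs; nested-ANOVA tank
checks; mortality summaries; and Yates-corrected χ² tests of the
association between cod ecotype (coastal/offshore) and the
heightened/reduced response classes.

## Worked example

```r
library(codstress)

# Carbonate system at the ambient group's mean water conditions
solve_carbonate(ph_ts = 8.06, ta = 2308, temperature = 12.95,
                salinity = 32.62)[, c("pco2", "dic", "omega_calcite",
                                      "omega_aragonite")]
#    pco2     dic omega_calcite omega_aragonite
#   392.1 2111.31          3.51            2.24
```

pCO₂ ≈ 392 µatm and both minerals supersaturated — ambient coastal
seawater.

```r
# One fish through the respirometry chain
sp    <- respirometer_spec(volume_l = 3.9)
fish  <- list(true_smr = 72, mass_g = 180, alive = TRUE)
trace <- generate_o2_trace(fish, sp, noise_sd = 0.2, occupancy_h = 20,
                           seed = 42)
process_trace(trace, sp, mass_g = 180, fish_id = "F001")$smr
# SMR 70.62 mg O2/kg/h (lowest 6 of 60 cycles, 0 outliers removed)
```

The lowest-decile estimate recovers the simulated fish's true SMR of
72 mg O₂ kg⁻¹ h⁻¹ to within 2% at realistic optode noise.

```r
# Bimodal response detection and ecotype association on a full cohort
cohort <- generate_cohort(cohort_config(seed = 5))
splits <- lapply(c("low_salinity", "multi_stressor"), function(tr) {
  d <- cohort[cohort$alive & cohort$treatment == tr, ]
  split_within_treatment(setNames(d$true_smr, d$fish_id),
                         treatment = tr, variable = "SMR")
})
for (s in splits) print(s)
# Split [low_salinity: SMR]: A (n=9) < median 78.79 < B (n=9); gaps 7.32/7.32 >= SEM 5.03
# Split [multi_stressor: SMR]: A (n=9) < median 89.85 < B (n=9); gaps 11.7/11.7 >= SEM 5.77

ecotype_association(splits, setNames(cohort$ecotype, cohort$fish_id),
                    "SMR")
# Corrected chi-square: X2(1, N = 36) = 13.613, p = 0.0002247
#           response
# ecotype     A  B
#   coastal  16  4
#   offshore  2 14
```

Both stressed treatments divide into a reduced (A) and heightened (B)
SMR group around the median, and the heightened group is dominated by
the offshore ecotype — the pattern the analysis is designed to detect.

`run_pipeline(pipeline_config(seed = 1), out_dir = "run1")` chains all
stages (simulate → respirometry → carbonate chemistry → assays →
statistics) and writes the CSV/markdown report bundle; reruns with the
same configuration are byte-identical.

## Acceptance script

`scripts/acceptance.R` recomputes the desk-checkable quantity from the
study's water-chemistry table — the ambient-group pCO₂ implied by its
printed mean pH/TA/T/S — from scratch with the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
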