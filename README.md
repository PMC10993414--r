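# mitotox

Data evaluation for a multiplexed in vitro mitochondrial toxicity
screen, for toxicologists and effect-based water-quality assessors who
read three endpoints off the same 384-well plates: mitochondrial
membrane potential (MMP, red/green ratio of a potentiometric dye),
cytotoxicity (cell counts) and oxidative stress (Nrf2/ARE-driven
luciferase). The package takes per-well instrument tables to fitted
effect concentrations, specificity classifications and mixture (BEQ)
accounting, and ships a synthetic plate generator with known ground
truth so the whole pipeline is testable end to end.

## What it computes

Per-well effects are normalised against each plate's solvent controls
(effect% = (1 − x/x̄_ctrl)·100 for the MMP ratio and cell counts;
induction ratio IR = L/L̄_ctrl for luminescence). Each
treatment × endpoint is then fitted with a constrained four-parameter
log-logistic curve,

    effect(c) = bottom + (top − bottom) / (1 + (ec50/c)^hill),  bottom ≡ 0,

inverted in closed form for the effect concentrations IC10
(cytotoxicity), EC10 (MMP) and — from a forced-intercept linear fit of
the induction ratio on doses below IC10 — EC_IR1.5 (oxidative stress).
Two masking rules remove effects that are secondary to cell death: ARE
doses above IC10 are excluded before the linear fit, and an MMP EC10
more than 10 × IC10 is suppressed entirely.

Specificity is judged through unitless ratios against measured and
QSAR-predicted baseline cytotoxicity:

    TR          = IC10,baseline / IC10
    SR_cyto     = IC10 / EC10,MMP
    SR_baseline = IC10,baseline / EC10,MMP  ( = TR × SR_cyto )

with a strict threshold of 10 separating baseline-like from specific
behaviour. Water extracts, dosed as relative enrichment factors (REF),
are converted to bioanalytical equivalents: BEQ_bio = EC10_ref /
EC10_sample from the bioassay, BEQ_chem = Σ REP_i·C_i from detected
concentrations under concentration addition, and their ratio is the
percent of the measured mixture effect explained ("iceberg" accounting).

## Worked example

The `analysis/` scripts run the whole workflow on synthetic data
(`Rscript analysis/01_simulate_screen.R`, then `02`, `03`, `04`).
Condensed, the chemical screen is:

```r
library(mitotox)

chems <- example_chemicals()                 # six generative profiles
wells <- simulate_plate(chems, plate_design(), noise_model(), seed = 1)
write_well_table(wells, "wells.csv")
write_chemical_table(chemical_table(chems), "chems.csv")

res <- run_chemical_screen(list(
  well_table = "wells.csv", chemical_table = "chems.csv",
  baseline_slope = 0.8, baseline_intercept = 1.2,   # QSAR coefficients
  out_dir = "out"))
res$specificity
```

which prints (values in M; NA = not reached in the tested range):

```
           chem_id  mie_class     ic10 ec10_mmp      tr sr_cyto sr_baseline classification
1     baseline_tox   baseline 2.53e-04 2.41e-04   0.993    1.05        1.04  baseline_like
2        cI_potent   complexI       NA 9.34e-09      NA      NA    67544.72   specific_mmp
3 cI_rotenone_like   complexI 1.95e-07 2.49e-09 204.027   78.26    15966.77  specific_both
4    cIII_moderate complexIII 2.89e-06 5.71e-08  60.127   50.65     3045.66  specific_both
5   unc_24dnp_like  uncoupler 1.89e-05 6.46e-06 121.159    2.93      354.74  specific_both
6       unc_potent  uncoupler 6.08e-07 2.42e-07 496.349    2.51     1246.92  specific_both
```

The baseline toxicant — generated with its cytotoxicity on its own QSAR
prediction — comes back with TR and both SRs near 1 and is classified
`baseline_like`; the potent complex-I profile disrupts MMP at ~9 nM
without measurable cytotoxicity, so only its SR_baseline (≈ 6.8 × 10⁴)
is defined and it is classified `specific_mmp`. Fitted EC10s recover the
generative truth to within ~0.03 log10 units at the design's 5% noise.

The water screen (`analysis/03_water_screen.R`) fits a fully
characterised synthetic extract and closes the iceberg:

```
  sample_id  beq_bio beq_chem pct_explained n_uncovered
1      SW01 5.08e-06 4.33e-06          85.2           0
```

i.e. the two detected uncouplers explain ~85% of the measured mixture
effect at design noise (exactly 100% in the noise-free limit).

## Layout

- `R/` — package code: table I/O and validation, per-well
  quantification, concentration–response fitting and masking,
  specificity ratios and classification, BEQ/iceberg accounting, the
  synthetic generator, screen orchestration, validation studies.
- `analysis/01–04` — narrative workflow scripts writing under `results/`.
- `vignettes/mitotox-methods.Rmd` — models, assumptions, parameter
  choices and limitations.
- `tests/testthat/` — unit, property and end-to-end acceptance tests.
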