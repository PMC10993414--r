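---
title: "Methods: concentration-response evaluation of a multiplexed mitochondrial toxicity screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: concentration-response evaluation of a multiplexed mitochondrial toxicity screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitotox)
```

## The assay and its readouts

mitotox evaluates a multiplexed in vitro screen in which three endpoints
are read from the same 384-well plates of an ARE-reporter cell line:

* **Mitochondrial membrane potential (MMP)** — a potentiometric dye
  forms red-fluorescent aggregates in polarised mitochondria and stays a
  green-fluorescent monomer in the cytosol. The red/green intensity
  ratio per well drops as the membrane potential collapses.
* **Cytotoxicity** — cell counts per well after 24 h exposure.
* **Oxidative stress** — luciferase luminescence driven by the
  Nrf2/ARE response.

Treatments are dosed as 11-point geometric serial dilutions with two
technical replicate wells, repeated in three independent runs. Doses are
molar concentrations for single chemicals and relative enrichment
factors (REF, L water per L bioassay) for enriched water extracts; a
`dose_unit` column keeps the two scales apart and mixing them within one
treatment is rejected at read time.

## Per-well quantification

All normalisation is **plate-internal** against that plate's solvent
controls (at least 3 required; 16 are laid out by default). This absorbs
plate-to-plate gain differences, and all three measures are invariant
under any uniform positive rescaling of the raw signals on a plate:

* MMP effect% $= (1 - r/\bar r_{ctrl})\times 100$ with
  $r = \text{red}/\text{green}$; 0 at control level, 100 at complete
  loss of the aggregate signal.
* Cytotoxicity effect% $= (1 - N/\bar N_{ctrl})\times 100$ from cell
  counts.
* Induction ratio $IR = L/\bar L_{ctrl}$; control wells average to
  exactly 1.

The exact algebraic form of the published red/green normalisation is not
restated here; the ratio-of-ratios percent-effect convention above is
the standard one for this dye class and is what the package implements.
Quantification is at the well level (no per-cell normalisation before
plate averaging), technical replicates are kept as separate observations
so that curve fitting sees the true replicate variance, and negative
effects (stimulation/hormesis, or noise around control) are retained
rather than clipped. No background subtraction and no plate-position
(edge-well) corrections are applied.

## Concentration-response models

### Log-logistic fits for MMP and cytotoxicity

Pooled over runs and replicates, each treatment/endpoint is fitted with
a constrained four-parameter log-logistic curve

$$\text{effect}(c) = \text{bottom} +
  \frac{\text{top} - \text{bottom}}{1 + (ec_{50}/c)^{h}}$$

with **bottom fixed at 0** — effects are defined relative to the
plate controls, so the zero-dose asymptote is 0 by construction —
$\text{top} \in (0, 100]$ and $h > 0$. Fitting is least squares on the
log10-dose axis, via bounded quasi-Newton (L-BFGS-B) started from a
deterministic grid of 5 ec50 values spanning the tested range; among
cleanly converged starts the lowest sum of squares wins, so the fit is
reproducible with no randomness. Effect concentrations invert the fitted
curve in closed form:

$$c_x = ec_{50}\left(\frac{x - \text{bottom}}
  {\text{top} - x}\right)^{1/h},$$

giving IC10 (10% loss of viability) and EC10 (10% loss of MMP).

A treatment is called **active** when the fit converged, the fitted top
reaches the effect level (10% by default), and the effect concentration
lies between one tenth of the lowest tested dose and the highest tested
dose — a guard against far extrapolation. These operationalise an
activity call that the source workflows leave implicit; they are
deliberately conservative and configurable only at the effect-level
parameter.

### Masking rules

Apparent effects at already-cytotoxic doses are not specific:

* **Oxidative stress.** Doses above the cytotoxicity IC10 are excluded
  before fitting, because the cytotoxicity burst inflates reporter
  signals. On the retained low-effect region a line $IR = 1 + s\,c$ is
  fitted with the intercept forced to 1 (a solvent control has IR 1 by
  definition), and $EC_{IR1.5} = 0.5/s$. Fewer than 3 retained doses
  ("over-masked"), a non-positive slope, or an $EC_{IR1.5}$ beyond the
  highest retained dose all yield an inactive call. The excluded doses
  always form the upper tail of the ladder and masking is idempotent.
* **MMP.** The cutoff is relaxed tenfold: when the fitted EC10 for MMP
  lies more than 10 x IC10, the MMP loss is treated as secondary to cell
  death and no EC10 is reported. The boundary is inclusive — exactly
  10 x IC10 is retained. The multiplier is configurable
  (`mmp_cutoff_multiplier`).

## Specificity analysis

Baseline toxicity — the minimal, hydrophobicity-driven toxicity of any
chemical — is predicted from the liposome-water distribution ratio at
pH 7.4 by $\log_{10}(1/IC_{10,\text{baseline}}\,[\mathrm{M}]) =
a\,\log_{10} D_{lip/w} + b$. The coefficients $(a, b)$ are **required
configuration**, not constants: they are cell-line-specific published
QSAR values that the user must supply; every example in this package
uses stated placeholder coefficients.

Three unitless ratios summarise specificity, computed on the molar scale
only (REF-scale water extracts never enter this module):

* toxic ratio $TR = IC_{10,\text{baseline}} / IC_{10}$ — excess
  cytotoxicity over the QSAR prediction;
* $SR_{\text{cyto}} = IC_{10} / EC_{10,\text{MMP}}$ — specificity of MMP
  disruption versus measured cytotoxicity;
* $SR_{\text{baseline}} = IC_{10,\text{baseline}} / EC_{10,\text{MMP}}$,
  which satisfies $SR_{\text{baseline}} = TR \times SR_{\text{cyto}}$
  identically.

Classification uses a **strict** threshold (default 10): TR above it
flags specific cytotoxicity, either SR above it flags specific MMP
disruption, both flag both, all present ratios at or below it give
`baseline_like`, and nothing derivable gives `inactive`. Values exactly
at the threshold are therefore non-specific; strictness at the boundary
is a documented choice, as is the inclusive boundary of the 10 x IC10
rule above.

## Iceberg (BEQ) mixture accounting

A water extract's measured MMP effect is expressed as the concentration
of a reference chemical — by default an uncoupler playing the role
2,4-dinitrophenol plays in effect-based water screening — that would
cause the same effect:

$$BEQ_{bio} = \frac{EC_{10,\text{ref}}\ [\mathrm{M}]}
 {EC_{10,\text{sample}}\ [\mathrm{REF}]}
 \quad [\text{mol ref-equivalents / L water}].$$

From chemical analysis, each detected chemical $i$ at concentration
$C_i$ (mol per L of original water, REF = 1 basis; any extraction
enrichment is undone upstream) contributes through its relative effect
potency $REP_i = EC_{10,\text{ref}}/EC_{10,i}$:

$$BEQ_{chem} = \sum_i REP_i\, C_i, \qquad
 \%\ \text{explained} = 100\, BEQ_{chem}/BEQ_{bio}.$$

Detected chemicals without toxicity data, or inactive on MMP, contribute
zero and are reported in an `uncovered` list instead of being silently
dropped; no recovery correction for extraction losses is applied (
per-chemical recovery factors can be supplied as configuration).
The accounting assumes strict concentration addition — same-mode
constituents' toxic units $\rho\,C_i/ec_{50,i}$ sum — which is exact
when constituents share top and hill. Under that assumption
$\%\ \text{explained}$ closes to 100 for a fully characterised mixture,
which is the package's key end-to-end consistency check. Inactive
samples yield no $BEQ_{bio}$ rather than an interpolated equivalent.

## The synthetic-data generator

Because the raw instrument data behind such screens are not deposited,
the generator is a first-class module producing plates with known
ground truth. Its defaults are the study conditions: 11 concentrations,
1:2 dilution, duplicate wells, 3 runs, 16 solvent controls per 384-well
plate, 10,000 cells seeded per well, 5% CV noise. Expected signals per
well are

* green $= G_0$, red $= G_0\,r_0\,(1 - f_{\text{MMP}}(c)/100)$ with
  control ratio $r_0 = 2$,
* cells $= 10{,}000\,(1 - f_{\text{cyto}}(c)/100)$,
* luminescence $= L_0\,(1 + s\,c)$,

with multiplicative lognormal noise (mean-one factors,
`signal_cv = 0.05`) on fluorescence and luminescence and
negative-binomial counts (`count_dispersion = 0.0025`, about 5% CV at
seeding density) for cells — strictly positive signals with a realistic
CV structure; dispersion and CV of 0 give exactly noise-free plates.
Per-chemical top concentrations default to 100-fold the most potent
active ec50, so the 3-decade ladder brackets the potency by two orders
of magnitude. Mixture samples are generated under the same
concentration-addition model the iceberg module assumes, with an option
to withhold constituents from the emitted detection table to mimic
unidentified chemicals, and an `approximate` flag (toxic-unit-weighted
curve parameters) for constituents that do not share a curve shape.

What the generator does **not** emulate: plate positional (edge)
effects, autofluorescence and background, per-cell heterogeneity,
solubility ceilings, run-to-run systematic drift beyond what plate-wise
normalisation removes, and deviations from concentration addition.
Passing the simulation studies therefore demonstrates the correctness
and statistical behaviour of the evaluation pipeline under its own
stated assumptions — not the biological validity of those assumptions
for any particular real screen.

## Validation studies and problem sizes

Three packaged studies (also run by `scripts/acceptance.R` and
`analysis/04_validation_studies.R`) exercise the full path
generator → quantification → fitting → ratios/BEQ:

* `ec10_recovery_study()` — 100 chemicals with MMP ec50 spanning
  1 nM–1 mM, fitted at the full design under 5% CV noise; the median
  absolute log10 EC10 error is the headline statistic (observed ≈ 0.03,
  well under the 0.1 working bound).
* `mixture_closure_study()` — three same-shape uncoupler-like
  constituents, single-chemical screens for REPs, one fully
  characterised mixture; percent explained is ≈ 100 ± fit noise, exactly
  100 as noise → 0, and withholding a constituent removes exactly its
  BEQ share in the noise-free limit.
* `classification_recovery_study()` — 200 replicate noisy screens of a
  pure baseline toxicant (IC10 placed on its own QSAR prediction) and a
  complex-I-like profile; each must land in its expected class in at
  least 95% of replicates (observed 100%).

These sizes (100 chemicals, 200 replicates, 1000-draw identity and
inversion checks) were chosen as the smallest that pin down the
statistics stably; all complete in well under a minute each on one core.

## Numerical and degenerate-input choices

* Optimisation bounds: top ∈ [10⁻⁶, 100], hill ∈ [0.05, 15], log10 ec50
  within the tested range ± 3 decades; starts that fail or do not
  converge are dropped, and a fit with no usable start is reported
  inactive with a reason rather than erroring.
* Flat (e.g. all-zero) response data fit to a top below the effect level
  and are reported inactive ("fitted top below 10% effect").
* Wells with zero green fluorescence cannot form an MMP ratio and are
  excluded with a warning; a zero mean control count or luminescence is
  an error.
* Fewer than 5 distinct doses is an error for the log-logistic fit;
  fewer than 3 retained doses after ARE masking gives an inactive
  "over-masked" result.
* All delimited output is written with 17 significant digits so
  write→read round trips are lossless; reader output ordering is
  canonical (plate, well row, well column, run) and independent of file
  row order.
* Reruns of either screen with identical configuration and inputs are
  byte-identical; the provenance manifest deliberately records no
  timestamps.

## Known limitations

* Single-model fitting: no model selection, no hormesis-specific or
  biphasic models, and no bootstrap/Bayesian confidence intervals on
  effect concentrations.
* The QSAR is consumed, not fitted; ionisation/speciation chemistry for
  computing the distribution ratio itself is out of scope.
* Strict concentration addition only — no independent action or
  generalised concentration addition.
* Solubility capping of dose ladders is available as configuration but
  off by default.
* REF is treated as a unitless enrichment dose; converting detected
  concentrations to the REF = 1 basis (extraction enrichment, recovery)
  happens upstream of this package.
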