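---
title: "Modelling secondary cancer risk from DVHs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling secondary cancer risk from DVHs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dvhrisk)
```

This vignette is the package's own account of the science it implements:
the dose–response models, the conventions and tunable parameters, what the
synthetic cohort generator does and does not emulate, and the design choices
made where the methodology left room.

## Setting

Stage IIA/B seminoma is treated with modest radiation doses (30 GyRBE in 15
fractions for IIA, 36 GyRBE in 18 fractions for IIB, delivered as an initial
para-aortic/pelvic field plus a boost to involved nodes) to a young, highly
curable population. The dominant late concern is radiation-induced secondary
malignancy, so the question of interest is how much the choice of modality —
opposed-field 3D photons, VMAT, or proton pencil-beam scanning at a constant
RBE of 1.1 — changes the modelled risk. The substrate of every computation
is the per-organ dose–volume histogram (DVH).

## DVH conventions

A DVH is stored in differential form: strictly increasing bin edges starting
at 0 GyRBE and an absolute volume (cc) per bin. The representative dose of a
bin is its midpoint; fractional volumes are derived on demand. Absolute
storage was chosen because the clinically interesting V10 surrogate is
reported in cc; relative (percent) inputs are accepted and canonicalised on
read. Cumulative↔differential conversion is exact, with one caveat: a
cumulative file whose last volume is nonzero has an open final bin, which is
closed using the preceding edge spacing, so non-uniform grids round-trip in
volume but may re-infer the final edge. The synthetic generator uses a
uniform 0.1 GyRBE grid, fine enough that discretisation error in EUD/OED is
far below model uncertainty (halving the width changes cohort OEDs by well
under 0.1%).

`volume_at_dose()` interpolates the cumulative curve linearly inside the
containing bin, and `dose_at_volume()` is its exact inverse (taking the
smallest dose across flat segments).

## gEUD

The generalized equivalent uniform dose is the power mean
$EUD_a = (\sum_i v_i D_i^a)^{1/a}$. Exponents for the 13 contoured organs
are packaged in `inst/extdata/eud_a_values.yaml` (bladder 2 … spinal cord
20). All packaged exponents are positive, so zero-dose bins simply
contribute nothing; the negative-`a` path (target-type EUD) clamps zero
doses to a configurable floor purely for API completeness. gEUD is computed
on physical bin dose — whether a 2-Gy-equivalent conversion should precede
it is not settled in the clinical methodology, and physical dose is the
assumption made here (it is used as a morbidity comparator, separate from
the risk models, which carry their own fractionation correction).

## OED, EAR, LAR

Carcinogenesis is modelled through the organ equivalent dose
$OED = \sum_i v_i\,RED(D_i, d_i)$, with the risk-equivalent dose `RED` one
of four dose–response shapes (linear, bell, plateau, full mechanistic with
repopulation/repair parameter $R$), all using
$\alpha' = \alpha(1 + d/(\alpha/\beta))$, $\alpha/\beta = 3$ Gy. Each bin's
dose is assumed delivered over the plan's full fraction count,
$d_i = D_i/n$: the clinical two-phase regimen (initial field plus boost) is
folded into the combined prescription and fraction count because per-bin
phase attribution is not recoverable from a DVH. The mechanistic model is
dispatched to the bell/plateau closed forms when $R$ is exactly 0 or 1; the
near-endpoint formula is numerically stable to well below the $10^{-6}$
level checked in the tests.

EAR multiplies the OED by an initial slope $\beta_{EAR}$ and an age
modifier $\exp(\gamma_e(age_x - 30))(age_a/70)^{\gamma_a}$. LAR accumulates
the yearly EAR from the end of a latency period (default 5 years,
configurable including 0) to the projection age (default 70), with no
competing-mortality survival weighting — the clinical methodology states
only the projection window, and adding a survival model would import
assumptions the comparison does not need. Because a single EAR per organ is
conventionally reported over that window, the headline value here is the
window-averaged yearly EAR (`ear_window_mean()`); per-age values remain
available. These two reporting conventions (averaging; no survival
weighting) are assumptions, recorded here because the source methodology
does not pin them down.

### Risk parameters

The organ-specific dose–response parameters in the literature registry this
methodology builds on are not printed in the clinical report, so the package
deliberately ships a **demonstration** registry
(`inst/extdata/risk_params_demo.yaml`: every organ mechanistic,
$\alpha = 0.1$/Gy, $R = 0.5$, $\beta_{EAR} = 1$, $\gamma_e = \gamma_a = 0$)
rather than presenting invented numbers as literature values. Under it,
absolute EAR/LAR values are illustrative; between-modality orderings and
percent reductions — the scientifically meaningful comparisons — are
preserved because every modality is scored by the same monotone
dose–response. A transcribed literature registry can be supplied via
`default_risk_params(path = ...)`; kidneys and pancreas are cloned from the
small-bowel block at load time (their carcinoma-induction coefficients are
taken to match), and the nine risk-modelled organs are the soft-tissue set —
bone structures appear in dosimetry only, with leukemia represented by the
pelvic-ilium V10 surrogate rather than an unvalidated marrow model.

### Totals and reductions

Per-modality totals are plain sums over the nine organs. Percent reductions
are computed from totals rounded by the reporting convention (`report_round`:
one decimal at or above 2, two decimals below), because that is the
arithmetic under which the published totals (29.1 / 26.7 / 12.3 EAR;
3.4 / 3.2 / 1.52 % LAR) yield the published reductions (8 / 58 % EAR,
6 / 55 % LAR); unrounded reductions differ by up to a point (e.g. 4.7% vs
6% for the VMAT LAR).

## Cohort statistics

Paired modality comparisons use the two-sided Wilcoxon signed-rank test with
zeros dropped (classic signed-rank convention rather than Pratt), mid-ranks
for ties, the exact distribution whenever the nonzero differences are untied
and few, and otherwise a normal approximation with tie and continuity
correction. Confidence intervals are t-based (the normal-vs-t choice is not
stated in the clinical report; t is the conservative default at n = 10). No
multiple-testing correction is applied across organs, matching the published
analysis style. Significance flags use 0.05 two-sided.

## The synthetic cohort generator

Patient DVHs from the clinical cohort are not available, so the generator
emulates *cohort-level dosimetric statistics only* — it makes no anatomical
claim. Each structure's DVH is a three-part mixture: a near-prescription
normal component (fraction `f_rx`, spread `sigma_rx` = 1.5 GyRBE), an
exponential low-dose bath (fraction `f_bath`, modality-specific scale), and
the remaining volume at zero dose, truncated at 1.1 × prescription (a
clinically acceptable hotspot cap) and discretised at 0.1 GyRBE.

Calibration, frozen in `inst/extdata/organ_geometry.yaml`:

- **Body**: `f_rx`, `f_bath` and the bath scale per modality were solved in
  closed form against the published cohort anchors — body mean dose
  4.2 / 4.3 / 1.8 GyRBE for 3D / VMAT / PBS and body V20 ratios 0.36
  (VMAT:3D) and 0.33 (PBS:3D) — at the cohort-average prescription of
  33 GyRBE, then frozen. The structure is interpretable: 3D has a large
  prescription-level component (opposed fields treat through the body),
  VMAT trades it for a much larger low-dose bath, PBS shrinks both.
- **Organs**: each organ's target mean dose per modality is the published
  cohort mean; a modality profile (`phi`, the share of the mean supplied by
  the near-prescription component; a bath-volume cap; the bath scale)
  converts the target into mixture fractions. This reproduces, in
  expectation, the published rank order of 3D organ mean doses (vertebral
  bodies and spinal cord highest, femurs and liver lowest) and the per-organ
  PBS < 3D ordering. Matching the published per-organ EUD table cell-by-cell
  is explicitly not attempted — means do not determine distribution shape.
- **Variability**: a per-patient lognormal multiplier (mean 1, log-sd 0.25)
  on `f_rx` and `f_bath` is shared across modalities — it represents
  anatomy (e.g. boost-node proximity), so it preserves the pairing the
  Wilcoxon test relies on — plus a small per-modality lognormal jitter
  (log-sd 0.05) so paired differences are not degenerate. Structure volumes
  get an independent lognormal multiplier (log-sd 0.15) around fixed
  realistic volumes; the pelvic-ilium volume (600 cc) was chosen so V10
  magnitudes are on the clinical scale. When a drawn `f_rx + f_bath`
  exceeds 1 (high-dose organs with a large multiplier) both are scaled back
  proportionally, which biases the hottest organs' cohort means slightly
  low; orderings are unaffected.
- **Cohort design**: stages alternate IIA/IIB (n = 10 gives five of each),
  ages are uniform on the integers 32–54 (the published range; the
  published mean of 40 is matched in expectation), and per-patient child
  seeds derive from the master seed by a counter so a cohort can be
  extended without reshuffling existing patients. Generation is
  deterministic per seed and restores the caller's RNG state.

What passing the calibration tests shows: the generator reproduces the
published body-dose and conformality *statistics* and the qualitative
organ-sparing structure. What it does not show: realistic intra-organ dose
topology, boost-volume geometry, inter-organ dose correlations beyond the
shared patient multiplier, or out-of-field dose — conclusions about real
patients still require real DVHs, which the package accepts through the
same CSV interface.

## Problem sizes and numerics

The default analysis uses the 10-patient cohort on a 0.1 GyRBE grid
(~330–400 bins per structure, 14 structures, 3 modalities); stochastic
calibration checks average 20 independent master seeds, which holds the
cohort-mean body doses to within a few hundredths of a GyRBE of their
expectations. gEUD evaluation rescales by the maximum bin dose so exponents
up to 20 lose no precision; the mechanistic RED clamps sub-epsilon negative
values arising from cancellation near the R endpoints; exact Wilcoxon
enumeration is delegated to the signed-rank distribution for n up to 49
untied pairs.

## Known limitations

- Demonstration risk parameters: absolute EAR/LAR values are illustrative
  until a literature registry is supplied.
- No out-of-field scatter or neutron dose; constant proton RBE 1.1 is
  assumed baked into the input doses; no variable-RBE modelling.
- No plan generation or DICOM parsing: the package starts from exported
  tabular DVHs.
- LAR omits survival weighting and uses discrete yearly summation; both are
  stated conventions, not validated choices.
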