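---
title: "Methods: hair EtG quantification, validation and interpretation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hair EtG quantification, validation and interpretation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hairEtG)
```

## The measurement problem

Ethyl glucuronide (EtG) is a minor, non-oxidative ethanol metabolite that
accumulates in the keratin matrix of hair, where it records average alcohol
consumption over months. Quantification is performed by isotope-dilution
SRM: the EtG-TMS derivative is monitored on the quantifier transition
m/z 405→359, the penta-deuterated internal standard EtG-D5 on 410→359, and
identity is confirmed on the qualifiers 405→331 and 405→287 (all at 10 V
collision energy). The measured quantity is the response ratio
(analyte peak area / internal-standard peak area), converted to pg EtG per
mg hair through an external calibration built on spiked blank hair.

This package implements the computational chain around that measurement:
signal processing, calibration diagnostics, detection capability,
pretreatment optimization by design of experiments, validation statistics,
and interpretation of possibly censored subject results against the
Society of Hair Testing cut-off of 30 pg/mg for chronic excessive
drinking.

## Signal model and peak integration

Simulated SRM traces are a constant baseline plus Gaussian peaks with
i.i.d. Gaussian intensity noise. A Gaussian shape (no tailing) is the
minimal model sufficient for area and S/N arithmetic; tailing would change
none of the downstream statistics and is deliberately not modelled. Noise
is i.i.d. on intensity because the downstream S/N definition is an RMS
noise ratio; with that pairing, S/N scales as 1/noise SD, which the test
suite verifies by Monte Carlo.

`integratePeak()` works on an explicit, caller-supplied retention window —
no hidden peak-picking heuristic. The default baseline is a straight line
between the medians of the first and last three window samples, so height
and area are invariant under constant baseline offsets. When a window edge
sits on the peak itself (e.g. integrating half of a symmetric peak) the
edge median no longer estimates the baseline; for such windows the known
baseline level must be passed explicitly via the `baseline` argument. This
is the one place where the default estimator and the geometry of the
window can disagree, and we chose to keep the default simple and explicit
rather than add edge-detection logic.

`estimateNoiseRms()` removes a linear trend from a declared peak-free
region and returns the RMS of the residuals. Vendor "auto-RMS" noise
algorithms are proprietary; a detrended RMS is the reproducible member of
the same family, and it returns exactly zero on constant or linearly
drifting baselines.

Ion-ratio compliance uses a relative tolerance of ±20% around reference
ratios, the conventional identification-criteria window; the tolerance is
configurable because regulatory guidance varies. Reference ratios are
learned as the mean qualifier/quantifier area ratio across calibration
standards, since no canonical values exist for this derivative. A
co-eluting interference on a single qualifier (observed on 405→331 for
pulverized hair) inflates only that qualifier's ratio: quantitation on
405→359 remains valid provided one qualifier (405→287) still complies,
which is why the interference check reports qualifier problems as warnings
rather than failures.

## Calibration and linearity

Calibration uses unweighted ordinary least squares of response ratio on
concentration. Weighted fitting is deliberately excluded: the workflow
first runs the Fisher variance-ratio test on the extreme levels (default
alpha 0.01; the test is stated for this workflow without a level, and 0.01
is the conventional choice for a variance screen), and only a
homoscedastic design justifies the unweighted model that everything
downstream assumes.

Linearity is tested two ways at alpha 0.05:

* **Lack of fit** splits the residual SS of the line into pure error
  (within-level replicate scatter, n − k df) and lack of fit (k − 2 df).
* **Mandel** compares the linear and quadratic fits,
  F = (SSE₁ − SSE₂)/(SSE₂/(n − 3)).

Degenerate inputs are handled explicitly: with both SS terms numerically
zero the F statistic is defined as 0 (pass); an exactly quadratic response
gives SSE₂ = 0 and F = ∞ (fail). Type-I error of both tests is verified by
simulation (1000 null calibrations; the empirical rejection rate must fall
in the binomial band around 0.05).

Back-calculation inverts the line and scales by extract dilution and by
sample mass relative to the 50 mg of washed hair used for the calibrators.
Negative back-calculated concentrations are preserved — the censoring
layer reports them as "<LOD"; clamping them silently would bias any later
summary. Estimates above the 6–60 pg/mg working range route to the
extended 60–300 pg/mg curve, and above that to a dilution-required flag.
The extended curve is assumed to share the replicate structure and
internal-standard amount of the low curve, as nothing in the assay design
suggests otherwise.

## Detection capability

Two LOD routes are provided. The S/N route takes the lowest *measured*
level with S/N strictly above 3; it never interpolates, because detection
capability should be claimed only at concentrations actually measured.

The Hubaux–Vos route works from the calibration fit alone. The decision
limit x_C is where the expected response crosses the upper one-sided
(1 − α) prediction bound of a blank; the detection limit x_D is the
smallest concentration whose lower (1 − β) prediction bound clears that
same response level. Both bounds are one-sided — detection is a one-sided
decision. Because the band half-width depends on (x − x̄)²/Sxx, x_D has no
closed form and is found by root bisection to 1e-6 pg/mg. Defaults are
α = β = 0.05; in the flat-band limit this gives x_D ≈ 2·x_C. x_C is
exactly linear in s_y/x; x_D is linear to first order only (the band is
re-evaluated at the shifted concentration), which the tests acknowledge
with a 2% tolerance.

The LOQ rule is operational: the lowest level whose intra-assay CV and
absolute bias are both ≤ 20%. In this assay that is the lowest calibration
level, 6 pg/mg — which also means a declared abstinence (requiring
LOQ ≤ 5 pg/mg) is never assessable with this method, and
`classifyVsCutoff(purpose = "abstinence")` says so unconditionally.

## Pretreatment optimization (2³ factorial DoE)

The pretreatment experiment varies washing (a), incubation/extraction (b)
and shredding (c) at two levels each, in standard Yates run order
(0, a, b, ab, c, ac, bc, abc). An effect is the Montgomery contrast,
mean(high) − mean(low) = contrast/2^(k−1); replicate blocks (donors) are
averaged run-wise first. Effects equal exactly twice the OLS coefficients
of the coded regression, which the tests exploit as an independent oracle
on random designs.

Significance flagging defaults to a fixed threshold of 19.71 pg/mg — the
decision value published with the experiment. The t-test from which that
threshold derives cannot be reconstructed from the single printed block
(the "n = 6" replicate structure is not given), so the package treats
19.71 as a given constant and additionally offers two derivable modes:
a replicate-t test across blocks, and Lenth's pseudo-standard-error margin
for unreplicated designs.

Two arithmetic notes on the published table, which the package computes
from the data rather than copying: the cut+overnight vs pulverize+sonicate
deficits (b vs c, ab vs ac) give 28% and 8%; the cut+sonicate vs
cut+overnight comparison averaged over washing gives ≈48%, although the
accompanying text quotes 40%. `yieldDeficit()` reports the computed
values.

## Validation statistics

Precision is the sample RSD (n − 1 denominator) and trueness the signed
relative bias of the mean. Intra-day estimates use one day's ≥3
replicates; inter-day estimates pool all nine measurements (3 levels × 3
days) as a single sample — matching the "n = 9" convention of the
published summaries — rather than decomposing day-to-day variance. Values
are stored unrounded; only the serialization layer rounds, half-up, to the
printed precision (integer RSD, one-decimal bias magnitude). Recomputing
RSD and bias from the published means and SDs reproduces the printed
columns within that rounding; one printed intra-day bias (3.2% at
30 pg/mg, where the printed mean 31.8 implies 6%) is inconsistent with its
own row, and the package sides with the arithmetic.

QC acceptance limits default to 15% RSD and 20% bias. The blank
interference check back-calculates the apparent concentration in the
quantifier window of teetotaler hair and requires it below the LOD.

## Cohort interpretation

Results below the LOD or LOQ are reported as censored, and censored values
are never imputed (no LOD/2 substitution): class summaries give order
statistics of quantified values only, with censored records counted in n.
Classes are ordered Teetotal < Light < Social < Moderate < Heavy by
declared weekly units. Subjects declaring Moderate-or-higher consumption
but measuring censored are listed as anomalies for review — a reporting
convention, not a numeric adjustment, since no quantitative rule exists
for such discordances. The cosmetic-treatment flag is carried through
reports without numeric correction.

## Synthetic-data generators and what the tests show

Generator defaults are fixed once to the study conditions: calibration at
6/10/20/30/60 pg/mg in triplicate with constant-SD noise of 0.01 response
units (≈1 pg/mg at the default slope of 0.01 per pg/mg — chosen so the
simulated assay reproduces the method's reported detection capability,
LOD ≈ 4 pg/mg); the factorial generator defaults to the published effect
sizes, grand mean 147.3 pg/mg, three donor blocks and 8 pg/mg run noise; the
cohort generator to class sizes 6/6/4/6/6 with log-normal medians
0.5/2/15/25/120 pg/mg and geometric SDs 2/2/1.4/2.5/1.6, log-normality
being the natural strictly-positive right-skewed model for biomarker
concentrations.

The generators emulate the statistical structure the analysis assumes —
Gaussian peaks, linear response, orthogonal designs, log-normal cohorts.
They do not emulate chromatographic tailing, retention drift, carryover,
matrix effects, extraction-chemistry yields, or self-report error in
drinking class. Passing tests therefore demonstrate that the arithmetic
and decision logic are correct under the assumed models, not that the
models capture every feature of real hair extracts.

Problem sizes used in the test suite are chosen for tight Monte-Carlo
bounds at interactive runtimes: 1000 replicates for type-I error checks,
500 random designs for the estimator/OLS equivalence, 1500–2000 subjects
for cohort medians, and ~100 replicates for S/N scaling.

## Known limitations

* No weighted or nonlinear (4PL) calibration; the workflow is valid only
  after the homoscedasticity screen passes.
* No automatic peak picking or retention alignment; windows are explicit.
* No blank-population LOD (mean + 3·SD of blanks).
* No measurement-uncertainty budget, recovery or matrix-effect modules.
* No pharmacokinetic dose–concentration modelling and no segmental hair
  analysis; interpretation is strictly cut-off-based.
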