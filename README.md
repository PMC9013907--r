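# hairEtG

Quantification, validation and interpretation toolkit for hair ethyl
glucuronide (EtG) assays by GC-EI-MS/MS.

EtG is a minor, non-oxidative ethanol metabolite incorporated into hair and
is the consensus long-term biomarker of alcohol consumption: the Society of
Hair Testing (SoHT) interprets hair EtG at or above the 30 pg/mg cut-off as
evidence of chronic excessive drinking. Forensic and clinical laboratories
quantifying hair EtG by selected reaction monitoring (SRM) need, beyond the
instrument, a reproducible computational layer: peak integration and
signal-to-noise estimation, calibration with defensible linearity
diagnostics, detection and quantification limits, optimization of the
sample-pretreatment protocol, precision/trueness validation, and
censoring-aware reporting of subject results. `hairEtG` implements that
layer, for assay developers and for toxicologists interpreting cohort
results.

## What it computes

* **SRM signal processing** — baseline-subtracted peak height/area over
  explicit retention windows, detrended RMS baseline noise, S/N, and
  qualifier ion-ratio identity checks (quantifier m/z 405→359, EtG-D5
  internal standard 410→359, qualifiers 405→331 and 405→287).
* **Calibration** — unweighted OLS of the response ratio *y = a + b·x*
  with the Fisher homoscedasticity F test on the extreme levels, the
  replicate-based lack-of-fit test, and the Mandel test
  *F = (SSE₁ − SSE₂)/(SSE₂/(n−3))* comparing linear and quadratic fits;
  back-calculation with dilution/mass scaling and a dual working range
  (6–60 and 60–300 pg/mg).
* **Detection limits** — S/N > 3 rule on measured levels, and the
  Hubaux–Vos algorithm on the calibration prediction bands:
  *y_C = a + t₁₋α,ₙ₋₂ · s_y/x · √(1 + 1/n + x̄²/Sxx)*, decision limit
  *x_C = (y_C − a)/b*, detection limit *x_D* solved from the lower
  (1 − β) band.
* **2³ factorial design of experiments** — effect(S) = contrast/2^(k−1)
  over the coded ±1 design (washing, incubation, shredding), significance
  flagging (fixed threshold, replicate-t, or Lenth), and pairwise
  extraction-yield deficits.
* **Validation report** — intra-/inter-day RSD% and bias%, LOQ rule
  (CV and |bias| ≤ 20%), blank interference check, JSON report.
* **Cohort interpretation** — LOD/LOQ censoring without imputation,
  per-class summaries of quantified values, SoHT cut-off classification,
  and declared-vs-measured anomaly listing.

Synthetic-data generators (`simulateTraces`, `simulateCalibration`,
`simulateFactorial`, `simulateCohort`) emulate each input with known truth,
so every stage is testable end to end.

## Worked example

```r
library(hairEtG)

tab <- loadFixture("doe_table3")          # eight-run pretreatment DoE
eff <- estimateEffects(tab, maxOrder = 2)
flagSignificance(eff, threshold = attr(tab, "significanceThreshold"))
#>   label  value significant threshold
#> 1     a   3.55       FALSE     19.71
#> 2     b  34.95        TRUE     19.71
#> 3     c  66.95        TRUE     19.71
#> 4    ab   6.50       FALSE     19.71
#> 5    ac -11.70       FALSE     19.71
#> 6    bc -36.00        TRUE     19.71
```

Shredding (c, ball-mill pulverization vs scissor cutting) is by far the
largest effect (+66.95 pg/mg recovered EtG), incubation (b) matters, washing
(a) does not, and the negative b:c interaction says overnight incubation
adds nothing once the hair is pulverized.

```r
fit <- fitCalibration(simulateCalibration(CalibrationSimSpec()))
lodHubauxVos(fit)
#> LodResult (Hubaux-Vos): LOD 4.002 pg/mg, decision limit 2.015 pg/mg (alpha 0.05, beta 0.05)

summarizeByClass(loadFixture("cohort_table5"), cutoff = 30)
#>      class n n_quantified  min median   max n_above_cutoff
#> 1 Teetotal 6            0   NA     NA    NA              0
#> 2    Light 6            0   NA     NA    NA              0
#> 3   Social 4            3 13.3   14.9  19.3              0
#> 4 Moderate 6            4 23.4   65.6  93.2              3
#> 5    Heavy 3            3 58.3  127.9 199.8              3
```

All three heavy drinkers exceed the 30 pg/mg cut-off; every teetotaler and
light drinker is censored below the LOD/LOQ.

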