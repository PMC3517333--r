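---
title: "Validating self-report physical activity instruments against doubly labeled water"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating self-report physical activity instruments against doubly labeled water}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paeeval)
```

## The measurement problem

Free-living energy expenditure is expensive to measure well. The
criterion method, doubly labeled water (DLW), tracks the differential
elimination of two stable isotopes from body water and costs hundreds of
dollars per participant; indirect calorimetry pins down the basal
metabolic rate (BMR) but says nothing about activity. Epidemiology
therefore leans on self-report instruments, which are cheap but must be
validated against DLW before their numbers can be trusted.

`paeeval` implements both sides of that validation chain for two
instrument designs:

* a **24-hour activity record**: the day is cut into 96 slots of 15
  minutes, each slot holding one behavior from a compendium of coded
  activities (work, commute, leisure, sports), each code carrying a MET
  intensity (multiples of resting metabolic rate);
* a **7-day recall**: each day the respondent reports sleep hours and,
  for morning / afternoon / evening, hours spent in broad intensity
  classes (light 1.5–2.9 METs up to very high ≥ 8 METs).

## Scoring model

Both instruments reduce a day to its 24-hour average MET. For the diary
this is the plain mean of the 96 slot intensities. For the recall,

$$\bar{M} = \frac{0.9\,h_{sleep} + \sum_c M_c h_c + 1.3\,(24 - h_{sleep} - \sum_c h_c)}{24},$$

where the classes score at fixed METs (sleep 0.9, light 2.2, moderate
3.5, moderate-to-high 4.5, high 7.0, very high 10.0) and all unaccounted
time is scored *very light* (1.3 METs) — the instrument deliberately
offers no "reading / watching television" option, so that time surfaces
as the remainder of the 24 hours.

The conversion to total energy expenditure is

$$\mathrm{TEE\ (MJ/d)} = \mathrm{BMR\ (kcal/d)} \times \bar{M} \times \frac{1.1}{0.9} \times 4.184\times10^{-3},$$

with three constants worth spelling out: **1.1** lifts the supine
fasting BMR to the *sitting* resting rate that defines 1 MET; dividing
by **0.9** adds diet-induced thermogenesis of roughly 10% of intake; and
4.184 × 10⁻³ converts kilocalories to megajoules. Activity energy
expenditure strips both back out, $\mathrm{AEE} = 0.9\,\mathrm{TEE} -
\mathrm{BMR}$, and the physical activity level is
$\mathrm{PAL} = \mathrm{TEE}/\mathrm{BMR}$. The engine takes BMR in
kcal/day — that is the unit in which the printed constant is
dimensionally coherent — and reports MJ/day. Nothing is rounded during
computation; rounding (MJ to 2 decimals, percentages to 1, correlations
to 3) happens only in report output.

A design note on the recall conversion: the source systems state both
instruments were converted to energy expenditure but print the equation
only once. `score_recall_day()` applies the same equation, including the
1.1 sitting factor, so the two instruments remain comparable in a joint
analysis. If a cohort prefers a different convention, every constant is
an `ee_constants()` override.

Weekly summaries are arithmetic means of daily TEE/AEE/average-MET, with
PAL recomputed from the mean TEE; because the AEE identity is affine,
it carries over to weekly means exactly.

## The DLW reference

The calculator follows the standard two-point / intercept framework.
After a loading dose of ²H₂O (99.8 atom%, 0.12 g per kg predicted body
water) and H₂¹⁸O (10.0 atom%, 2.5 g/kg), urine enrichments are measured
at baseline and in duplicate on the mornings of days 1, 8 and 15.
All arithmetic is done in **mole-fraction space**: a δ‰ value versus
VSMOW is converted through the absolute ratios (²H/¹H = 155.76 ppm,
¹⁸O/¹⁶O = 2005.20 ppm) to an isotope mole fraction, and "excess" means
excess above the participant's own pre-dose baseline. Subtracting δ
values directly is only approximate, which is why the conversion comes
first.

* **Elimination**: ordinary least squares of log excess on time; the
  rate `k` is minus the slope, and back-extrapolation to dose time (the
  intercept method) gives the time-zero excess.
* **Dilution spaces**: dose excess tracer moles divided by the time-zero
  excess per atom of the element pool — for deuterium the dose spreads
  over two hydrogen sites per water molecule, so $N_d = \mathrm{mol}\,
  ^2\mathrm{H}/(2E_0)$. Total body water is the mean of $N_d/1.041$ and
  $N_O/1.007$; the ratio $N_d/N_O$ is a quality control statistic with a
  plausibility band (default 1.000–1.070) that flags, but does not
  discard, a result.
* **CO₂ production**: $r\mathrm{CO_2} = 0.4554\,\mathrm{TBW}\,(1.007k_O
  - 1.041k_D)$ mol/day; the constants embody breath-water fractionation
  with the revised dilution-space proportions.
* **TEE**: CO₂ moles × 22.414 L/mol, VO₂ from an assumed respiratory
  quotient of 0.85, and the protein-free abbreviated Weir equation
  $EE = 3.941\,V_{O_2} + 1.106\,V_{CO_2}$ kcal/day. The same Weir form,
  on measured gas exchange, provides the calorimetric BMR, accepted only
  when VO₂ varies by less than 25 mL/min over the averaging window.

For a two-week protocol, `dlw_week()` computes dilution spaces from the
full-period fit (all post-dose points, duplicates as separate
observations) and weekly elimination rates as two-point log slopes
between that week's endpoint days (1→8 or 8→15), with same-morning
duplicates averaged. The source protocol states only "the intercept
method"; this windowing is the package's choice and is exposed in the
result object.

## Method-comparison statistics

`pearson()` and `partial_pearson()` (residual-on-residual with degrees
of freedom reduced by the covariate count) quantify association;
`bland_altman()` quantifies agreement: mean difference, SD of
differences, limits of agreement at ±1.96 SD, and a trend test — the OLS
regression of difference on pair mean, whose slope t-test and
correlation t-test coincide. `compliance()` does the participant-day
accounting, and `flag_outliers()` implements the one-sided 3-SD screen
used for sensitivity reanalysis (over-reporting, not under-reporting, is
the characteristic self-report failure). The significance threshold
defaults to 0.01 and is reported, never used to censor output. Group
mean comparisons, where needed, are paired t-tests — an assumption,
since validation reports often omit the test name.

## What the simulator emulates — and what it does not

`simulate_study()` is truth-first: it draws physiology, builds a true
96-slot activity grid per day, and only then derives every measured
quantity from that truth, so recovery is well-defined at each stage.

* **Physiology** is sex-stratified from truncated normals matching a
  20-person mixed cohort archetype (e.g. male BMR ~ N(6.50, 0.89) MJ/d
  truncated to 4.77–8.00; female 4.87 ± 0.57 on 4.40–6.24; PAL 1.90 ±
  0.12 and 1.76 ± 0.22). The dilution-space ratio is drawn per
  participant from N(1.027, 0.007) truncated to [1.011, 1.043].
  Body water is 60%/50% of weight (men/women) with 3% lognormal noise;
  the deuterium elimination rate ~ N(0.10, 0.01)/day reflects normal
  water turnover (≈ 4 L/day at 40 L TBW).
* **Schedules** place a 23:00–07:00 sleep block and an
  occupation-dependent work/commute structure, then steer the remaining
  slots over a palette of common activities until the implied PAL
  (average MET × 1.1/0.9) is within 1% of the participant's true PAL; a
  sedentary template replaces the default when a low target leaves no
  MET budget. Slot placement is randomized, so seeds differ while the
  implied PAL does not.
* **Reporting error**: the diary misclassifies each slot with
  probability 0.05 (uniform wrong code — deliberately crude, and upward
  biased because the compendium mean exceeds a typical day's mean); the
  recall perturbs entry hours with a lognormal CV of 0.2; with
  probability 0.05 a participant is a *gross over-estimator* whose
  waking time is reported wholesale in the moderate-to-high class,
  mimicking the constant-elevated-entry failure mode. An optional
  sex-linked positive bias is off by default. These magnitudes are free
  parameters chosen once as plausible; they were **not** fitted to
  reproduce any published correlation — that would make the validation
  circular.
* **Isotopes**: each week's true TEE is inverted through the Weir/RQ
  chain to that week's k_O; enrichment decays piecewise-exponentially
  and is sampled at the protocol's time points with Gaussian analytic
  noise of 0.7‰ (²H) and 0.05‰ (¹⁸O), the routine precision of isotope
  ratio mass spectrometry.

The simulator does *not* emulate behavioral realism beyond
occupation-typed days, learning effects over the week, seasonal or
day-of-week activity structure, isotope plateau kinetics on day 0, or
non-Gaussian analytic error. A green test suite therefore shows the
pipeline is internally correct and calibrated to its configured truth,
not that any instrument achieves a particular validity in real humans.

## Numerical choices and degenerate inputs

* Intensity-class boundaries: the printed class ranges leave narrow gaps
  (2.9–3.0 etc.); classification extends each range half-open to the
  next lower bound, so 2.95 is light and 3.0 is moderate — a
  deterministic, total mapping. Sub-1.5-MET values are "sub-light",
  resolved to sleep or very-light by a context flag.
* Diary days must have exactly 96 resolvable slots; days crossing a
  daylight-saving change are rejected as malformed rather than scored
  with 92/100 slots. A day with missing slots is counted non-compliant,
  never silently dropped.
* Recall over-allocation (sleep + entries > 24 h) is an error, not a
  clip.
* The CO₂ molar volume defaults to the ideal 22.414 L/mol; the real-gas
  22.26 is selectable (sensitivity ≈ 0.7% on TEE).
* `rco2()` treats a bracket within 1e-12 of zero as the null-production
  boundary; a genuinely negative bracket (k ordering violated) is an
  error pointing at swapped isotopes or a failed fit.
* When week-1 and week-2 kinetics differ, the three sampling days are
  not collinear in log space and the full-period intercept (hence TBW)
  picks up a small bias — about 1.7% in N for an 8% difference in k_O.
  Round-trip guarantees of < 0.1% hold under constant kinetics; weekly
  TEE contrasts under strongly different weeks inherit the intercept
  bias. This mirrors the practice of using one dilution space for both
  weeks.
* Steady-window selection in calorimetry takes the *last* acceptable
  window of the requested length (rest deepens over the collection); the
  original averaging duration is not published, so the default is the
  whole series.

## Problem sizes in the test suite

The shipped tests run the full chain at deliberately small scale: unit
fixtures of single days, simulated studies of 4–10 participants,
calibration cohorts of 2000, a 200-participant noise-recovery study and
a 10,000-pair limits-of-agreement coverage check. The whole suite
completes in well under a minute on a single core; the same properties
hold at larger n but add nothing beyond tighter Monte-Carlo error.

## A worked mini-study

```{r, eval = FALSE}
dir <- tempfile()
simulate_study(n = 20, seed = 42, outdir = dir)
report <- run_study(list(
  diary = file.path(dir, "diary.csv"),
  recall = file.path(dir, "recall.csv"),
  iso = file.path(dir, "iso.csv"),
  dose = file.path(dir, "dose.csv"),
  gas = file.path(dir, "gas.csv"),
  assignment = file.path(dir, "assignment.csv")))
report$instruments$par24$aee$r
report$instruments$recall7$aee$bland_altman
```

Under default noise the diary tracks the DLW criterion closely
(AEE r above 0.9) while the recall shows the classic pattern of a
coarser instrument: moderate correlation, wider limits of agreement, and
an occasional gross over-estimator that the 3-SD screen catches — the
qualitative fingerprint one expects when a slot-level diary and a
class-level recall are validated against the same criterion.
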