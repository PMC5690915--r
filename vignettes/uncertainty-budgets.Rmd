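---
title: "Setup-uncertainty decomposition and budgets for frameless 6D IGRT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Setup-uncertainty decomposition and budgets for frameless 6D IGRT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(setupbudget)
```

## The problem

Frameless stereotactic radiotherapy (SRS/SRT) of cranial lesions replaces the
invasive head ring with a thermoplastic mask plus image guidance. A typical 6D
workflow positions the patient with infrared (IR) optical tracking, acquires a
stereoscopic kV image pair (the *X-ray correction*, XC), registers it to
reference DRRs by bone anatomy to obtain a 6D shift — three translations
(lateral, longitudinal, vertical, mm) and three rotations (pitch, roll, yaw,
degrees) — and, whenever that shift exceeds the action tolerance (0.7 mm /
1°), moves the robotic couch and verifies with a second pair (the *X-ray
verification*, XV).

Every hardware and software element of this chain leaves a fingerprint in the
recorded shifts. `setupbudget` turns the per-fraction shift records, the
monthly Winston–Lutz QA log and a couch-sag phantom table into a named
uncertainty budget and combines it into cumulative uncertainties before and
after the X-ray correction.

## The statistical model

Shift distributions are treated as normal; a **systematic** uncertainty
$\Sigma$ is the mean of a distribution (a reproducible bias attributable to
one component) and a **random** uncertainty $\sigma$ is its standard
deviation (session-to-session scatter). The estimator mapping is:

| component | type | estimator |
|---|---|---|
| mask $\Sigma_M$ | systematic, per treatment | mean of that course's XC shifts |
| setup $\sigma_S$ | random, per treatment | sample SD of that course's XC shifts |
| IR frame $\Sigma_F$ | systematic | mean of *all* XC shifts |
| localizer $\Sigma_L$ | systematic | mean of *all* XV shifts |
| X-ray registration $\sigma_{XR}$ | random | SD of all XV shifts |
| couch sag $\Sigma_C$ | systematic | phantom study over loads and angles |
| MV / kV / IR isocentricity $\Sigma_{ISO}$ | systematic | Winston–Lutz QA log |

The logic: before the correction the XC shift contains the patient's
placement error inside the mask (bias $m_t$ per course plus per-fraction
scatter) *and* the frame bias; averaging one course's XC shifts estimates
$m_t + \Sigma_F$ (the frame term is deliberately not subtracted — the
per-course "mask" estimate is the bias an uncorrected treatment would
actually suffer), and averaging over the whole cohort leaves $\Sigma_F$
because mask biases average out across patients. After the couch move the XV
residuals no longer contain any patient-specific term: their mean is the
localization chain's bias and their spread is the registration noise.

The MV-machine isocentricity composes the three mobile elements per axis,

$$\Sigma_{ISO}^{MV} = \Sigma_{Gantry} + \Sigma_{Coll} + \Sigma_{Couch},$$

with unmeasurable entries (vertical offset for collimator and couch-rotation
tests) contributing zero but kept visibly absent (`n/a`) in reports.

Each component is reduced to a single millimetre magnitude, canonically its
**radial** summary $r = \sqrt{x^2+y^2+z^2}$. For distribution-level
components the radial is the *mean of per-record radials*, not the radial of
the per-axis means: the two differ whenever shifts change sign (a cohort with
per-axis means near zero can still have a 2.5 mm mean displacement), and the
former is what the budget should carry.

Two combination rules are computed side by side:

* **model**: systematics add linearly, randoms in quadrature,
  $CU = \sum_i |\Sigma_i| + \big(\sum_j \sigma_j^2\big)^{1/2}$;
* **GUM**: everything in quadrature,
  $CU_{GUM} = \big(\sum_i \Sigma_i^2 + \sum_j \sigma_j^2\big)^{1/2}$,
  with expanded uncertainty $k \cdot CU_{GUM}$, $k = 2$ by default.

Since $\|v\|_1 \ge \|v\|_2$, the model value never falls below the GUM value
for the same budget; the package asserts this as a property. The *before-XC*
budget of a course holds its own mask and setup terms plus all shared
components; the *after-XC* budget keeps only what the correction cannot
remove (frame, localizer, couch sag, the three isocentricities and
$\sigma_{XR}$ — membership is a config option), contains nothing
patient-specific, and is therefore one number for the whole cohort. The
recommended PTV margin is the after-XC model CU rounded to 0.1 mm.

## The synthetic cohort

No clinical shift data are distributed with the package; a seeded generator
(`cohort_truth()` + `generate_cohort()`) produces cohorts with known ground
truth so every estimator is testable by parameter recovery. The generative
model per fraction of course $t$:

$$XC = m_t + \Sigma_F + \varepsilon_{setup} + \varepsilon_{XR}, \qquad
  XV = \Sigma_L + \varepsilon'_{XR},$$

with $m_t \sim N(0, \Sigma_{mask}^2)$ static per course and the noise terms
per-axis normal. An XV record is emitted exactly when the XC shift fails the
tolerance gate (a `force_xv` flag overrides this for estimator unit tests).
Registration noise enters XC and XV with the same spread — one $\sigma_{XR}$.

Defaults are the study conditions the package models: 49 treatment courses
over 35 patients in 1/3/5 fractions (4, 13 and 32 courses — 203 XC setups),
frame systematic (0.18, 0.25, −1.27) mm / (−0.32, 0.18, 0.47)°, localizer
systematic (−0.03, −0.01, 0.03) mm / (−0.03, 0.00, −0.01)°, setup scatter
(0.42, 0.46, 0.20) mm / (0.30, 0.33, 0.32)°, registration scatter
(0.25, 0.26, 0.21) mm / (0.25, 0.24, 0.24)°, Winston–Lutz axis offsets at
the magnitudes above, and a fixed 14-row couch-sag grid (loads 0–70 kg,
angles 0–315°) whose worst case is 1.09 mm radial at 70 kg / 315°. The mask
spread is not directly observable in published summaries, so it is set once
by variance subtraction from the pooled XC spread,
$\Sigma_{mask}^2 = \sigma_{XC,pooled}^2 - \sigma_S^2 - \sigma_{XR}^2$,
giving (0.73, 2.05, 1.37) mm and (0.51, 0.72, 0.87)° — by construction the
generated cohorts reproduce the pooled per-axis XC spread.

What the generator does *not* emulate: intra-fraction motion, time trends
(mask loosening appears only as an optional heavy-tailed bias via
`mask_tail_df`, not as drift), correlations between axes, and non-normal
registration error. Passing recovery tests therefore demonstrates that the
estimators are correct *under the stated model*, not that clinical shift
data obey it.

## Numerical and design choices

* **Sample SD with denominator $n-1$** everywhere; a single-fraction course
  contributes SD exactly 0 (the lone shift is its own mean) rather than `NA`,
  so one-fraction SRS courses stay in the budget.
* **Tolerance boundaries inclusive**: a setup exactly at 0.7 mm / 1° is
  treated without correction, matching clinical practice at-tolerance.
* **Signed means keep their sign** in component tables (a bias direction is
  informative) but enter linear sums as magnitudes: signed cancellation
  between independent devices would be physically unjustified.
* **`n/a` is an explicit absent marker**, parsed from and written back to
  files; arithmetic treats absent as contributing zero to sums and
  quadratures, never silently imputing it.
* **$\sigma_{XR}$** is canonically the pooled SD of all XV shifts;
  `sd_method = "of_means"` (SD of per-course XV means) is retained because
  both readings of the estimator table exist, and the pooled one is the one
  consistent with the per-axis values the estimators should reproduce.
* **Combination basis**: the canonical budget combines radial magnitudes
  (`basis = "radial"`). A per-axis alternative (combine each translational
  axis, then take the radial of the three cumulative values) is implemented
  because a single-number budget can be read either way; both are reported
  and they agree exactly on single-axis budgets (a test asserts this). The
  exact convention behind any particular published cumulative value is
  generally not recoverable, which is why the package exposes the choice
  instead of hard-coding one reconstruction.
* **Couch-sag worst case**: the budget entry is the phantom row with maximal
  radial sag, ties broken toward larger load then larger angle — the
  conservative choice, since sag at couch angles of 90°/270° cannot be
  imaged away (the stereoscopic view is blocked).
* **Degenerate t-tests are flagged**: with zero sample SD the t statistic is
  undefined; the summary reports p = 0 for a nonzero mean, p absent for an
  all-zero sample, and sets a `degenerate` flag instead of failing.
* **Grouping** is by treatment course (`treatment_id`; a patient may have
  several isocenters and hence several masks/courses); `group = "patient_id"`
  is available.

## Problem sizes used in the test suite

Unit tests run on 4–6-course cohorts; moment-consistency checks use 2,400
single-course units (12,000 fractions); estimator-recovery checks run 20
study-scale cohorts (49 courses, 203 XC setups each) with 3-standard-error
bands, where the grand-mean band accounts for mask biases being shared
within a course (clustered variance term $\Sigma_{mask}^2 \sum_t n_t^2 /
N^2$). The sign-flip resampling oracle for t-test p-values uses $10^5$
resamples at $n = 50$. These sizes make the full suite run in about a
minute while leaving Monte-Carlo slack well inside the asserted bands.

## Known limitations

The model assumes independent, normally distributed component errors and a
strictly sequential workflow; components whose uncertainties propagate into
several stages (CT slice thickness affects both localization and DRR
quality) are not separable by this decomposition. Rotational components are
carried through every estimator but the cumulative budget is translational
(mm); rotations matter clinically through the lever arm to off-axis targets,
which is out of scope here. The couch-sag entry is a static worst case, not
an angle-resolved correction model.
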