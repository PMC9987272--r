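---
title: "Methods: ultrasound + blood-gas triage of acute respiratory failure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ultrasound + blood-gas triage of acute respiratory failure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arftriage)
```

## The clinical problem

Dyspnoea in a newly admitted ICU patient has five broad
pathophysiological explanations: pneumonia (alveolar-lung defect),
cardiogenic pulmonary oedema (alveolar-cardiac defect), acute
exacerbation of COPD (ventilation-plus-alveolar defect), pulmonary
embolism (perfusion defect), and metabolic disorders in which acidosis
drives respiratory effort with structurally normal lungs. Lung
ultrasound alone separates the first two well but cannot see metabolic
disease and struggles to split COPD from embolism, because both can show
A-lines with right-heart strain. The algorithms implemented here resolve
this by adding two cheap bedside signals: the blood gas (CO2 separates
COPD from embolism; absence of hypoxemia flags metabolic disease) in the
ultrasound arm, and pulse-oximetry hypoxia in the radiograph arm.

## The two rule engines

Both engines are *total deterministic classifiers* over coded findings:
they always return exactly one label, and a record matching no branch
returns `UNCLASSIFIED` with a reason code rather than being coerced into
a category. Inputs are pre-coded interpretations (profiles, flags,
enumerations), never images: coding findings is the sonographer's or
radiologist's job, and thresholds the source definitions do not state
(ejection fraction for "LV dysfunction", IVC diameter for
"collapsed/distended") are deliberately not invented here — those fields
are consumed as enumerations.

**CCUS + ABG.** Hypoxemia is PaO2 < 60 mmHg (strict) and hypercarbia
PaCO2 > 45 mmHg (strict); boundary values are negative. Hypoxemia is
defined on room air; because nearly the entire target population is on
oxygen or ventilatory support, the same threshold is applied off room
air and the result carries an `off_room_air` warning annotation instead
of refusing to classify. The branches:

| category | findings |
|---|---|
| `ALVEOLAR_CARDIAC` | bilateral B-lines, LV dysfunction, IVC distended, hypoxemia |
| `VENT_ALVEOLAR` | focal B-lines or C-profile, RV dilated, IVC distended, hypoxemia **and** hypercarbia |
| `ALVEOLAR_LUNG` | any BLUE-protocol pneumonia pattern (C-profile + shred sign; focal interstitial syndrome; B0-profile; A-profile + PLAPS), normal LV, hypoxemia |
| `PERFUSION` | A-profile, DVT scan positive, RV dilated, hypoxemia |
| `METABOLIC` | A-profile, normal LV, DVT negative, **no** hypoxemia |

**Chest X-ray.** Air bronchogram/opacity + hypoxia → alveolar-lung;
bat-wing/cardiomegaly/hilar prominence + hypoxia → alveolar-cardiac;
hyperinflation/tubular heart/flat diaphragm + hypoxia →
ventilation-plus-alveolar; normal film + hypoxia → perfusion; normal
film without hypoxia → metabolic. A normal film is mutually exclusive
with the abnormality flags by construction. The SpO2 hypoxia flag is
accepted pre-coded; `spo2_is_hypoxic()` offers an optional SpO2 < 90%
derivation but no cut-off is baked into the rule.

**Branch priority.** The source definitions do not say what happens when
a record satisfies several branches (clinically real: combined cardiac
and pneumonic disease). We resolve overlap by a fixed, configurable
priority — cardiac, then COPD, then pneumonia, then perfusion, then
metabolic — chosen so that the branches with the most specific finding
sets are tested first; `triage_config(priority = ...)` reorders it for
sensitivity analyses. The perfusion branch does not require hypocarbia
(low CO2 supports embolism physiologically but is not part of the branch
definition); `require_hypocarbia_for_perfusion = TRUE` adds it, with a
PaCO2 < 35 mmHg default threshold.

## Accuracy and agreement statistics

Validation against a composite reference diagnosis reduces the K×K
cross-tabulation one-vs-rest per category (`dichotomize()`): the
diagonal cell is TP, the rest of the reference column FN, the rest of
the index row FP.

*Proportions.* Sensitivity, specificity, PPV, NPV each carry a **Wilson
score interval** (no continuity correction). The Wilson interval was
chosen because it is the score-test inversion, behaves at the 0/1
boundaries that occur in these tables (two categories have empty FP
cells), and reproduces the published interval for the headline
sensitivity (54/63 → 75.03–92.30%), which identifies it as the method
behind the printed tables. Likelihood ratios are reported as `Inf` when
specificity is 1; a Haldane–Anscombe +0.5 correction is available by
option. Zero denominators yield `NA` fields, never errors, so degenerate
tables still produce report rows.

*Kappa.* Cohen's kappa `(po − pe)/(1 − pe)` is computed per category on
the 2×2 reduction and overall on the full table ("percent agreement
beyond chance"). Two standard errors are implemented: the
Fleiss–Cohen–Everitt large-sample variance (default) and the simpler
agreement-variance formula `sqrt(po(1−po)/(n(1−pe)²))`. Neither
reproduces the kappa intervals printed in the source tables — the CI
method used there is not identifiable — so kappa intervals here are the
package's own (FCE) and only kappa *point estimates* are treated as
reference values. Interval endpoints are stored untruncated; an upper
bound above 1 simply reflects strong agreement on a small sample.

*Known misprints in the reference tables.* Recomputing every statistic
from the printed counts exposes a handful of typographic inconsistencies,
which the golden tests assert against the recomputed values: the
ventilation row of the accuracy table is garbled (its narrative values
83.33/97.44/98.06 and kappa 0.7883 are used); the chest-X-ray perfusion
kappa prints 0.1553 where the cells give 0.1533; the metabolic
sensitivity prints 62.65% where the cells give 20/32 = 62.5%; the
head-to-head perfusion and metabolic kappas print 0.10 and 0.28 where
the cells give 0.1077 and 0.2617.

*McNemar.* Paired correctness of the two algorithms is compared through
the discordant counts b and c: chi-square `(|b−c|−1)²/(b+c)` with
continuity correction by default, and an exact two-sided binomial
p-value used automatically when b + c < 25. The head-to-head comparison
needs patient-level pairing, so it is available for record-level data
(including synthetic cohorts) but not from the marginal count fixtures
alone.

## Kappa sample size

For a dichotomous trait rated by two raters with a common marginal
prevalence p, the kappa estimate has asymptotic variance Q/N, with Q
obtained by evaluating the Fleiss–Cohen–Everitt variance at the 2×2 cell
probabilities implied by (kappa, p):
p11 = p² + κp(1−p), p12 = p21 = (1−κ)p(1−p), p22 = (1−p)² + κp(1−p).
At κ = 0, Q = 1 exactly, for any p. The sample size to detect agreement
κ1 against a null κ0 at two-sided level α and power 1−β is

N = ((z_α √Q0 + z_β √QA) / (κ1 − κ0))²,

rounded up. `design = "two_sample"` doubles both variance terms for
comparing two independently estimated kappas. The one-sample design is
the default because it is the per-diagnosis calculation the package
targets: at κ0 = 0.5, κ1 = 0.8, p = 0.35 it gives N = 60, squarely in
the 50–60 range quoted for such studies, whereas the two-sample version
gives 119. Prevalence has no default on purpose: Q depends on it
strongly, and a sample-size calculation with a silently assumed
prevalence is worse than an error.

`simulate_kappa_power()` validates N by simulation: tables are drawn
multinomially at κ1, and each replicate performs a Wald test whose
standard error is evaluated *under the null* (Q at κ0 with the pooled
empirical prevalence). That choice mirrors the formula's own
construction — the α term uses Q0, the β term QA; using the SE at the
estimate instead inflates empirical power (≈87% vs the nominal 80% at
N = 60) because QA < Q0 here.

## The synthetic cohort generator

`calibrate_confusion()` turns an observed cross-tabulation into a
generative model: reference-category prevalence (column totals / n) and
the column-conditional distribution of the index label. `sample_cohort()`
then draws true categories (i.i.d. multinomial, or exact largest-remainder
margins with `sampling_mode = "fixed_margins"`), draws a CCUS label and a
CxR label *independently given the true category* — the published data
identify the two margins and the pairwise CCUS–CxR table but never the
three-way distribution, so the conditionally-independent model is the
assumption-light choice — and finally realizes a findings record for each
patient via `findings_for_labels()`.

`findings_for_labels()` inverts the rule engines: each label has finding
templates constructed to satisfy *exactly one* rule branch (verified in
the tests by classifying under rotated priority orders), continuous
blood-gas values are jittered uniformly within the label's constraint
region (PaO2 35–59.5 mmHg for hypoxemic labels, 60–95 otherwise; PaCO2
46–80 for the hypercarbic label, 25–45 otherwise — uniform because no
source distributions exist and it keeps the generator assumption-light),
and the round trip through both classifiers is asserted before the
record is returned. The ultrasound and radiograph arms touch disjoint
fields, so all 25 label pairs are realizable. Demographics (age roughly
normal around the cohort median of 53 years; 61.5% male; SOFA log-normal
with median 6 and sdlog 0.66 matched to the 4–9.8 IQR) are passengers:
no classifier reads them.

What the generator does *not* emulate: correlated CCUS/CxR errors within
patient (beyond what the true category induces), mixed-pathology
patients with two defensible true labels, missing or uninterpretable
scans, and any dependence of misclassification on severity. Passing the
fidelity tests therefore shows that the pipeline is statistically
faithful to its calibration — not that the algorithms would achieve
these accuracies on new patients.

## Numerical and testing choices

Fixture counts were cross-checked against all published margins before
freezing (rows against the per-algorithm distribution, columns against
the composite-diagnosis distribution; every total matches, n = 174).
Golden tests assert proportions to ±0.01 percentage points and kappas to
±0.001 (±0.005 where the source prints two decimals), with the misprints
listed above asserted against recomputed values. Property tests run on
1000 randomized instances each: kappa and percent agreement against a
brute-force recount from expanded item lists, the Bayes identity
PPV = sens·prev / (sens·prev + (1−spec)(1−prev)) to 1e−12,
dichotomization count conservation, and Wilson containment of the point
estimate; the Wilson closed form is additionally checked against a grid
inversion of the score test, multiclass kappa against an independent
implementation, and McNemar against the stats-package test and the exact
binomial tail. Simulation-based checks use fixed seeds and sizes chosen
for stable statistics: 10⁴ replicates for the Q-factor variance check
(tolerance 5%), 2000 replicates for power (±5 percentage points),
50,000 patients for generator fidelity (within 3 binomial standard
errors of calibration), and 1000 draws per label pair for the
round-trip guarantee (zero failures tolerated).
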