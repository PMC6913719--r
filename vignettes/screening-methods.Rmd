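---
title: "Screening methods: risk models, decision rules and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening methods: risk models, decision rules and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commscreen)
```

`commscreen` turns one participant's station-by-station screening
measurements into a mutually exclusive cardiovascular (CVD) risk category, a
diabetes risk category, a chronic kidney disease (CKD) risk composite,
albuminuria and lifestyle flags, then aggregates a cohort of such profiles
into the event report a screening program circulates to its providers. This
vignette is the package's own account of the models and the choices behind
them.

## The CVD risk model

Five-year absolute CVD risk for participants aged 30 and over uses the
Framingham (Anderson 1991) general cardiovascular equation in Weibull
accelerated-failure-time form, as adopted by the Australian (NVDPA)
absolute-risk guideline. The linear predictor on the log failure-time scale
combines sex, log age, log systolic blood pressure, current smoking, the log
total-cholesterol/HDL ratio, diabetes and left-ventricular hypertrophy; the
Weibull scale is itself a linear function of that predictor
(`sigma = exp(s0 + s1 * mu)`), and

$$\mathrm{risk}(t) = 1 - \exp\!\big(-\exp((\ln t - \mu)/\sigma)\big), \qquad t = 5\ \text{years}.$$

Assumptions worth keeping in view:

* **Smoking enters as *current* smoking.** Recent quitters score as
  non-smokers in the equation (they still carry the recent-quitter
  distinction elsewhere in the record).
* **LVH is fixed to "no".** Screening stations do not collect ECGs; the term
  is retained so a configured coefficient set remains complete, but it never
  fires by default.
* **Coefficients are configuration, not code.** The engine loads them from a
  provenance-commented YAML file and refuses to run if any term is missing
  or if a reference profile does not produce a probability in (0, 1). The
  test suite checks the evaluator against a second, independently written
  implementation of the same published equation to 1e-10.

## Category hierarchies

Screening cohorts are reported as mutually exclusive categories that sum to
the cohort size, so the classifiers are precedence chains, not independent
flags.

**CVD** (first match wins): established CVD (any self-reported coronary,
cerebrovascular or peripheral vascular diagnosis) → clinically high risk
(diabetes and age > 60; diabetes and albuminuria; SBP > 180 mmHg;
DBP > 110 mmHg; total cholesterol > 7.5 mmol/L) → under 30 → calculated
bands. Two deliberate resolutions:

* The medium band is *inclusive*, `[10%, 15%]`, with high risk strictly
  above 15% ("exceeding" the threshold). Thresholds are config
  (`threshold_config()`), so an exclusive reading is one edit away.
* Established CVD outranks the clinically-high conditions. For the binary
  "high risk" composite the order is irrelevant (it is an *any of*
  definition); mutually exclusive reporting rows force an order, and putting
  the established-disease row first matches how screening reports
  conventionally separate secondary from primary prevention.
* A rule fires only on an affirmatively met condition. A record reaching the
  calculated-risk stage with missing inputs is `indeterminate` — the
  "missing data" row of a cohort report. Unknown history with a computable
  low risk classifies as low: the deciding inputs for the calculated bands
  are the risk-equation inputs.

**Diabetes**: established (self-reported) diabetes → possible new diabetes
(HbA1c ≥ 6.5%, i.e. 48 mmol/mol, without a known diagnosis) → impaired
glycaemia (random capillary glucose in `[5.5, 11.1)` mmol/L) → AUSDRISK
bands high ≥ 12 / medium 6–11 / low ≤ 5. The band boundaries follow the
published instrument; printed report tables sometimes blur the 5/6 boundary,
and the instrument's standard banding resolves it. The glucose band is
half-open: a random glucose at or above 11.1 mmol/L is *not* treated as a
diagnosis — without a diabetic-range HbA1c the participant falls through to
their AUSDRISK band and is flagged `urgent_glucose_review`, because a single
random capillary reading is grounds for urgent confirmation, not labelling.

**AUSDRISK** is scored from a configured point table (range 0–38). The
instrument's country-of-birth item is retained in the table but screening
records do not collect it, so it contributes 0 points; the achievable
maximum from a screening record is therefore 36. Waist bands use the
instrument's sex- and descent-specific cut-offs. Any unanswered item makes
the whole score — and, absent a glycaemic rule, the category —
indeterminate.

**CKD risk** is `TRUE` if any of: BMI > 30 kg/m², current smoker, presence
of CVD, family history of CKD, presence of diabetes (established or
HbA1c-detected). "Presence of CVD" is read from the self-reported history
(equivalently, the established-CVD category); an HbA1c-detected diabetic
counts as diabetes here because the criterion is the disease, not the
awareness of it. The flag is `NA` only when *every* criterion is unknowable.

**HbA1c units.** Thresholds are stated in NGSP percent and stored that way;
IFCC mmol/mol is derived via the master equation
`mmol/mol = 10.929 × (% − 2.15)`, reproducing the conventional printed pairs
6.5% → 48, 7% → 53, 8% → 64.

## Care-gap policy

"Meeting guideline-recommended management goals" is not a single published
rule, so it is an explicit policy object (`care_policy()`) printed in every
report header. Defaults: established CVD should be on blood-pressure-
lowering, lipid-lowering *and* antiplatelet therapy; other high-CVD-risk
participants on the first two; BP at target means ≤ 140/90 mmHg; the
diabetes goal is HbA1c ≤ 7% (a lenient 8% variant is computed alongside).
Medication answers are self-reported tri-states and unknowns propagate:
`yes AND unknown` is unknown, `no AND unknown` is no.

## Validation and missingness

Missing is an explicit marker, never zero. `validate_screening()` returns
findings instead of throwing: implausible values (outside documented
point-of-care analyser-style ranges — assumptions, since instruments differ),
inverted blood pressure, and unknown categorical levels are `error` findings
whose values are blanked before classification, so a transcription error
becomes an indeterminate domain rather than a wrong category. Sex is
restricted to male/female because every threshold and report row in this
setting is binary by sex; other values are rejected at ingest with a clear
message — a documented limitation, not an oversight.

## The synthetic cohort generator

No participant data ship with the package, so `cohort_spec()` +
`generate_cohort()` emulate the screening population the engine targets. The
defaults are the published conditions of a nine-site community screening
program: per-site attendance (132, 114, 107, 118, 77, 119, 123, 127, 129 —
1046 in all), 61.19% female, 91.49% Aboriginal and/or Torres Strait
Islander, mean age 40.3 on 15–79, sex-specific lifestyle prevalences
(e.g. current smoking 38.8% female / 34.7% male, obesity 53.8%/44.8%,
elevated waist 76.1%/49.0%, BP > 140/90 31.3%/45.6%, dyslipidaemia
72.5%/75.9%), 16.54% known diabetes, 13.10% self-reported CVD, 17.30%
albuminuria, 4.30% undiagnosed diabetic-range HbA1c and 28.87% impaired
glycaemia.

Design of the draw:

* **Flags first, values second.** Each flag is Bernoulli at its specified
  prevalence; the continuous measurement is then drawn from the mixture
  component on the matching side of its threshold, so realized crossings
  equal the flags exactly and recovery is a clean binomial question.
* **Elevated components decay away from the threshold** (exponential tails
  for SBP and total cholesterol), keeping the clinically-high-risk
  conditions (SBP > 180, TC > 7.5) appropriately rare instead of uniform
  over the elevated range.
* **Glycaemic state is hierarchical**: known diabetes, then diabetic-range
  HbA1c, then impaired glucose, with conditional probabilities back-computed
  from the cohort proportions. Diabetic HbA1c is a truncated normal on
  [5, 14] with location/scale (6.34, 2.65) solved so that 42.2% sit at or
  below the 7% target and 61.9% at or below 8% — the attainment pattern
  reported for this kind of cohort.
* **Ages** are a truncated normal on [15, 79] whose location is solved
  numerically so the *truncated* mean equals the specified 40.3; the sd
  (default 16) is a free parameter, as no dispersion is published. A
  truncated normal under-represents the under-30 fifth-to-third of real
  community events — a documented shape limitation.
* **Independence.** Flags are drawn independently because only marginals are
  published. Real risk factors cluster; the generator therefore understates
  multimorbidity, and composite rates (high CKD risk ~81–83%, high CVD risk
  ~20–24%) *emerge* from the composition of marginals rather than being
  dialled in. That they land near published composite rates is a check of
  the rule logic, not a calibration.
* **Free parameters** the publication does not state were chosen once as
  field-plausible values and documented: family history of CKD 20%, parental
  diabetes 30%, prior high glucose 15%, per-domain missingness
  (anthropometry 1%, BP 2%, lipids 8%, HbA1c 3%, glucose 3%, ACR 5% —
  sized so the indeterminate-CVD fraction sits near the ~5% "missing data"
  row such programs report), medication uptake via a shared "well-managed"
  latent (40% of those with an indication on the guideline combination,
  echoing the ~40% guideline-treatment rates reported in Australian primary
  care).

What passing tests on this cohort do and do not show: they verify the
engine's arithmetic, rule logic, partition invariants and parameter recovery
under known marginals; they cannot validate behaviour under correlated risk
factors, informative missingness, or instrument error patterns of real
events.

## Follow-up prioritisation

The portal sort is deterministic and total: not-yet-followed-up before
followed-up, then a severity lattice (established/clinically-high/high-
calculated CVD > possible new diabetes or established diabetes with
HbA1c > 8% > albuminuria > high AUSDRISK > rest), then participant id. The
lattice is a package choice — published descriptions say only that the sort
prioritises by disease risk and follow-up status — and `prioritize_followup()`
accepts any replacement tier function. "Established diabetes with
HbA1c > 8%" is read as poorly controlled disease needing recall; possible
new diabetes ranks with it because an undiagnosed diabetic-range result is
the single most actionable screening finding.

## Numerical conventions

* Report percentages are `100 × count / denominator`, rounded **half-up**
  via one function (`percentage()`); half-to-even would disagree with
  hand-tallied report arithmetic at exact halves (e.g. 5/8 → 63%, not 62%).
  Cohort proportions print at 2 decimals, care-gap and per-sex rates at 1.
* A zero denominator yields an explicit `NA`, never a silent 0.
* BMI is reported at 1 decimal; the obesity comparison uses the rounded
  value, matching how report tables are tallied from printed BMIs.
* Ties in the sort cannot occur (participant id is a total tie-break);
  repeated runs are byte-identical, and all randomness lives in the
  generator behind explicit seeds.

## Problem sizes used by the test suite

The suite exercises the classifier/oracle equivalence on 10,000 random
in-range records, parameter recovery on a 10,000-person cohort at the
cohort specification's own fixed seed (3-binomial-sd bands), sort equivalence against a
brute-force comparator on 200 profiles, and file round-trips on the default
1046-person cohort — sizes at which binomial bands are tight enough to be
meaningful while the whole suite stays fast.

## Known limitations

* Single CVD equation; no recalibrated or 2023-generation Australian
  equations (pluggable coefficients are the extension point).
* Self-reported medication and history; no dose, adherence or dispensing
  model.
* Binary sex handling, as discussed above.
* The generator reproduces marginals, not joint structure; site-to-site
  heterogeneity beyond attendance counts is not modelled.
* Analyzer plausibility ranges are documented assumptions, not published
  instrument specifications.
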