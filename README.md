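# commscreen

A chronic-disease screening engine for community health events, built for the
kind of program where consenting participants move station by station through
demographics, self-reported history, anthropometry, blood pressure,
point-of-care lipids/HbA1c/glucose and urine albumin-creatinine testing, and
each participant leaves with a risk summary while nominated care providers
receive a prioritised follow-up list. The package implements the clinical
decision logic, the aggregate event reporting, and a seeded synthetic-cohort
generator so the entire pipeline is testable without any participant data.

It is aimed at population-health analysts and screening-program developers
working with Australian guideline rules: absolute cardiovascular (CVD) risk,
AUSDRISK diabetes risk, chronic kidney disease (CKD) risk composites, and
guideline care-gap metrics.

## The decision logic

**Absolute CVD risk.** For participants aged 30+, 5-year risk comes from the
Framingham (Anderson 1991) general cardiovascular equation in its Weibull
accelerated-failure-time form, the equation behind the Australian (NVDPA)
absolute-risk guideline. With indicator-coded sex, smoking, diabetes and LVH:

    mu    = b0 + b1*female + b2*ln(age) + b3*female*ln(age) + b4*ln(SBP)
            + b5*smoker + b6*ln(TC/HDL) + b7*diabetes + b8*female*diabetes
            + b9*LVH
    sigma = exp(s0 + s1*mu)
    risk(t) = 1 - exp(-exp((ln t - mu) / sigma)),  t = 5 years

Coefficients live in a provenance-commented config file
(`inst/extdata/framingham_cvd_1991.yaml`), never in code.

**CVD category** (mutually exclusive, first match wins): established CVD
(any self-reported coronary, cerebrovascular or peripheral vascular
diagnosis) → clinically high risk (diabetes and age > 60; diabetes and
albuminuria; SBP > 180 mmHg; DBP > 110 mmHg; TC > 7.5 mmol/L) → under 30 →
calculated bands (high > 15%, medium 10-15%, low < 10%) → indeterminate when
the deciding inputs are missing.

**Diabetes category**: established (known) diabetes → possible new diabetes
(HbA1c ≥ 6.5% / 48 mmol/mol, no known diagnosis) → impaired glycaemia
(random capillary glucose in [5.5, 11.1) mmol/L) → AUSDRISK bands
(high ≥ 12, medium 6-11, low ≤ 5). The AUSDRISK point table is config
(`inst/extdata/ausdrisk_points.yaml`), scored 0-38.

**CKD risk** is a composite: BMI > 30, current smoking, presence of CVD,
family history of CKD, or presence of diabetes. **Albuminuria**: urine ACR
≥ 2.5 mg/mmol (male) / ≥ 3.5 (female). Eight lifestyle/biomedical flags
(smoking, obesity, waist, activity, fruit, vegetables, BP > 140/90,
dyslipidaemia) use the thresholds in `inst/extdata/thresholds.yaml`.

Missingness is first-class: every flag is tri-state (yes/no/unknown), every
classifier returns `indeterminate` rather than guessing, and category counts
always partition the cohort.

## Worked example

```r
library(commscreen)

cohort    <- generate_cohort(cohort_spec(), seed = 1)   # 9 sites, 1046 people
profiles  <- screen_cohort(cohort)
caregaps  <- assess_care_gaps(cohort, profiles)
followups <- generate_followups(cohort, profiles, seed = 2)
report    <- event_report(cohort, profiles, caregaps, followups)
print(report)
```

```
==== Screening event report ====
Screened: 1046 participants at 9 site(s) (mean 116.2 per site)
Mean age 40.1 y; 646 (61.76%) female; 957 (91.49%) Aboriginal and/or Torres Strait Islander

-- CVD risk categories --
        category   n   pct
             low 492 47.04
          medium  41  3.92
 high_calculated  27  2.58
 clinically_high  80  7.65
 established_cvd 139 13.29
        under_30 210 20.08
   indeterminate  57  5.45

-- Diabetes risk categories --
              category   n   pct
          low_ausdrisk  26  2.49
       medium_ausdrisk 154 14.72
         high_ausdrisk 356 34.03
     impaired_glycemia 286 27.34
 possible_new_diabetes  42  4.02
  established_diabetes 179 17.11
         indeterminate   3  0.29

High CKD risk: 851 (81.36%); albuminuria: 178 (17.02%); urgent glucose review: 0

-- Care gaps --
Policy: CVD goal: BP-lowering + lipid-lowering (+ antiplatelet if established CVD) for established_cvd/clinically_high/high_calculated; BP target <=140/90 mmHg; diabetes goal: HbA1c <=7%
CVD (n=246): 99 (40.2%) on recommended medications; 133 (54.1%) BP at target
Diabetes (n=179): 143 (79.9%) oral agents; 57 (31.8%) insulin; 78 (43.6%) HbA1c<=7%; 111 (62%) HbA1c<=8%

Follow-up: 534 (51.05%) overall; high-risk subgroup (n=863): 57.01%
```

Reading the report: 246 participants (23.5%) have, or are at high risk of,
CVD; only 99 of them (40.2%) report taking the guideline medication
combination — that distance between recommended and received care is the
care gap the event exists to surface. The provider-portal sort puts
unfollowed, highest-severity participants first:

```r
head(prioritize_followup(profiles, followups), 3)
#>    participant_id followed_up tier    cvd_category    diabetes_category
#> 6         PT00006       FALSE    5 high_calculated established_diabetes
#> 21        PT00021       FALSE    5 established_cvd        high_ausdrisk
#> 34        PT00034       FALSE    5 established_cvd        high_ausdrisk
```

A thin CLI over the same functions lives at `inst/cli/commscreen.R`
(subcommands `validate`, `screen`, `report`, `followup`, `simulate`).

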