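# esbi — electronic alcohol screening and brief intervention engine

`esbi` is an R implementation of a hospital-outpatient **e-SBI** program: a
self-administered survey that screens patients for unhealthy alcohol use and
returns computer-generated personalized feedback on their drinking, together
with the feasibility metrics used to summarize a recruitment episode. It is
aimed at researchers piloting or trialling screening and brief intervention
in clinical waiting rooms, and at anyone who needs validated AUDIT / AUDIT-C
/ LDQ scoring and feedback logic as reusable, configurable components.

## What it computes

**Screening.** The AUDIT (10 items, total 0–40) and its consumption subscale
AUDIT-C (items 1–3, total 0–12) are scored from item-level responses. The
four-way risk classification uses AUDIT-C only:

| category | rule |
|---|---|
| `nondrinker_12m` | no alcohol in the past 12 months (gate question) |
| `negative` | AUDIT-C < 5 |
| `hazardous_harmful` | 5 ≤ AUDIT-C ≤ 9 (trial-eligible band) |
| `possible_dependence` | AUDIT-C ≥ 10 |

**Personalized feedback** (six components): the AUDIT score with a WHO risk
zone; estimated peak blood alcohol concentration for the heaviest recent
occasion via the Widmark model,

```
BAC (g/100 mL) = (drinks × g/drink) / (weight_kg × r × 10) − β × hours,  floor 0
```

with r = 0.68 (male) / 0.55 (female) and β = 0.015 g/100 mL/h by default;
estimated monthly spending on alcohol; single-occasion and weekly
consumption compared with guideline limits (4 and 2 × 7 standard drinks)
and same-age/gender norms — with the normative bars **suppressed whenever
own consumption is below the guideline**, so no one is encouraged to "drink
up" to the norm; and the LDQ dependence score (0–30) with a severity band.
All limits, norms, midpoints, prices and message texts live in an editable
YAML configuration.

**Survey flow.** A fixed page automaton
(`intro → demographics → gate12m → audit → episode → ldq → trauma →
feedback → thanks`) with a 12-month drinking gate that sends nondrinkers
straight to the thanks page, plus interruption/resume keyed by an opaque
linkage identifier and a pluggable (in-memory or JSON-file) session store.

**Feasibility.** Counts and percentages along the participant-flow tree
(approached → consented → eligible → completed → followed-up), the
screening-outcome mix, completion with a noncompletion-reason breakdown,
retention by subgroup, acceptability crosstabs and medians with quartiles.
Percentages are rounded half-up (one decimal for flow percentages, whole
numbers for acceptability/retention); zero-denominator ratios are reported
as undefined.

**Synthetic cohorts.** A seeded generator produces item-level respondents
with a requested screening-category mixture (AUDIT items 1–3 are sampled
from the exact solution sets of the target AUDIT-C range) and matching
flow-event records, so the whole pipeline is testable without patient data.

## Worked example

```r
library(esbi)

rec <- response_record("demo-01", gender = "male", age_years = 40,
  postcode = "2300", drank_past_12m = TRUE,
  audit_items  = c(3, 2, 2, 1, 0, 0, 1, 0, 0, 0),
  episode      = list(max_drinks = 10, duration_hours = 4, weight_kg = 80),
  ldq_items    = c(1, 0, 0, 0, 0, 0, 1, 0, 1, 0),
  trauma_items = c(0, 0, 1, 0, 0))

score_record(rec)
#> $audit_total : int 9
#> $audit_c     : int 7
#> $ldq_total   : int 3
#> $trauma_total: int 1

classify(TRUE, 7)$category        # "hazardous_harmful" (trial eligible)

bundle <- build_feedback(rec, score_record(rec))
cat(render_feedback(bundle, "text"))
#> Your AUDIT score
#> ----------------
#> Score: 9 (hazardous)
#> ...
#> Peak BAC for your heaviest recent occasion: 0.124 g/100 mL (marked)
#> ...
#> About AUD 302.50 per month.
#> ...
#> Your weekly consumption is below the recommended limit of 14 standard
#> drinks/week. ...
```

The AUDIT total of 9 falls in the hazardous zone; AUDIT-C of 7 places this
respondent in the trial-eligible 5–9 band. The peak BAC of 0.124 g/100 mL
is the Widmark estimate 10×10/(80×0.68×10) − 0.015×4. The weekly normative
bar is suppressed (consumption below the 14-drink weekly guideline) while
the single-occasion comparison is shown (5.5 ≥ 4).

A feasibility summary of the built-in deterministic pilot flow:

```r
recruitment_summary(pilot_flow_fixture())
#> Recruitment
#>   approached             172
#>   consented              108 (62.8%)
#>   refused                62 (36%)
#>   ...
#>   hazardous_harmful      33 (31.1%)
#>   unhealthy_use          41 (38.7%)
```

There is also a command line (`inst/cli/esbi`) with subcommands
`score`, `screen`, `feedback`, `run-flow` (interactive walk-through),
`simulate` and `summarize`.

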