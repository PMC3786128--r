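---
title: "Methods: screening, feedback and feasibility computations in esbi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, feedback and feasibility computations in esbi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esbi)
```

## The screening model

`esbi` implements electronic screening and brief intervention (e-SBI) for
unhealthy alcohol use in adult outpatients. Screening rests on two
instruments. The AUDIT is ten items; items 1–8 are scored 0–4 and items
9–10 take three options scored 0/2/4, giving a total of 0–40 summarised
into WHO risk zones (0–7 low risk, 8–15 hazardous, 16–19 harmful, 20–40
possible dependence). Risk **classification**, however, deliberately uses
only the AUDIT-C consumption subscale (items 1–3, range 0–12): asking the
full AUDIT and then classifying on it risks assessment reactivity, whereas
AUDIT-C retains similar sensitivity and specificity. The category rules are
fixed: below 5 screens negative; 5–9 is the hazardous/harmful band — the
band a brief intervention trial would recruit from, because above 9 the
probability of dependence is high enough that brief intervention alone is
probably insufficient; 10–12 flags possible dependence. A 12-month gate
question precedes everything; nondrinkers skip all instruments.

Scoring is strict: all items of an instrument must be answered with
in-range option indices, and missing items are errors rather than being
imputed or prorated. The program is self-administered to completion, so a
partial instrument indicates an interrupted session (to be resumed), not a
skipped item.

The Leeds Dependence Questionnaire (10 items, 0–3 each, total 0–30) feeds
only the feedback message, as does the five-item trauma history screen. The
trauma screen's published wording and scoring are not reproduced here: the
shipped items are an explicitly flagged placeholder (`placeholder: true` in
`instruments.yaml`) scored as the count of affirmative answers.

## Feedback computations and their parameters

Every completing drinker receives six components. The tunable parameters
all live in `feedback_config.yaml`:

* **Guidelines** — 4 standard drinks per single occasion and 2 per day
  (2009 Australian adult guidelines), with one standard drink = 10 g
  ethanol. The weekly comparison bar uses 7 × the daily limit
  (14 drinks/week); the guidelines themselves phrase the limit per day, so
  the weekly multiple is an engine choice made for comparability with
  weekly consumption estimates.
* **Widmark BAC** — peak BAC (g/100 mL) is
  `drinks × g_drink / (weight_kg × r × 10) − β × hours`, clamped at zero.
  Defaults are the standard forensic conventions r = 0.68 (male) / 0.55
  (female) and β = 0.015 g/100 mL per hour. The model assumes complete
  absorption, instantaneous distribution into total body water and linear
  elimination over the reported episode duration — adequate for educational
  feedback, not for forensic inference.
* **Monthly spend** — the product of configured numeric midpoints for the
  AUDIT item 1 (drinking days/month: 0, 1, 3, 11, 22) and item 2 (typical
  drinks: 1.5, 3.5, 5.5, 8, 11) response bands and a price per standard
  drink (default AUD 5). The bands are ordinal, so midpoints are a modelling
  convenience; they are documented in the config precisely because they are
  a choice, not a measurement.
* **Normative comparisons** — own consumption vs guideline vs the
  same-gender, same-age-group population value. The age groups are 18–34,
  35–54 and 55+. Suppression is the component's defining rule: if own
  consumption is *strictly below* the guideline, the norm bars are withheld
  entirely, so that light drinkers are never shown a population average
  they might drink up to. Equality with the guideline shows the bars (the
  rule is "lower than", not "not above"). Episodic and weekly comparisons
  are suppressed independently.
* **Norm table and prose** — the shipped norm values, band messages, BAC
  sequelae tiers and information pages are synthetic placeholders written
  for this engine and labelled as such; a deployment must substitute its
  national survey norms and clinically reviewed text.

Rendering is deterministic: one bundle always produces byte-identical text
or HTML, so an emailed copy is a faithful copy.

## Survey flow semantics

The flow is a fixed-order automaton with a single branch at the 12-month
gate. Sessions are keyed by caller-supplied opaque linkage identifiers
(a URL-safe random generator is provided); persistence is pluggable, with
in-memory and single-JSON-file stores shipped. Resume returns the session
at exactly the interrupted page with prior answers intact; visited pages
cannot be re-answered — allowing revision of, say, demographics on resume
would make the stored record's provenance ambiguous, so the engine forbids
it. Email addresses are syntax-checked at entry because hand-written
addresses are a known source of lost follow-up contact.

## Feasibility statistics

All summaries are frequencies with percentages, and medians with 25th/75th
percentiles, matching descriptive feasibility reporting practice.
Percentages are `100 × count / denominator` rounded **half-up** — base R's
`round()` rounds half to even, which does not reproduce conventionally
printed feasibility percentages — at one decimal for participant-flow
percentages and whole numbers for acceptability and retention tables.
Quartiles use linear interpolation between order statistics
(`stats::quantile` type 7); the convention is configurable because small
samples make the choice visible. Zero-denominator ratios are `NA`
(undefined), never 0% or 100%. Acceptability percentages use the category
size as denominator, so unanswered questions still count against it — the
convention under which a column of counts plus its missing answers
reconstructs the category total.

The package ships a deterministic pilot participant-flow fixture
(`pilot_flow_fixture()`): 172 approached, 108 consented, 106 eligible, 7
noncompleters (3 technical / 4 called away), completers splitting
15/43/33/8 across categories, 69 invited to follow-up with 52 completing
(30 and 22 in the hazardous/harmful subgroup). The acceptance script and
tests recompute every headline percentage from this fixture through the
same summary functions used for any cohort. One acceptability answer in
the hazardous/harmful column is deliberately missing, because the printed
column counts (6/11/10/5) sum to 32 of a category of 33.

## The synthetic-cohort generator

`generate_cohort()` draws, from a single seeded stream, one flow record per
approached participant and full item-level responses for completers. Its
defaults are frozen to the pilot recruitment episode's observed rates:
consent 108/172, ineligibility 2/172 at approach and 2/108 after consent,
completion 99/106 with a 3:4 reason split, category mixture 15/43/33/8,
category-conditional gender and age mixtures, follow-up invitation rates
32/43, 30/33 and 7/8 and follow-up completion 26/32, 22/30 and 4/7.

The category guarantee is exact by construction: a drinker's AUDIT items
1–3 are sampled uniformly from the enumerated set of score triples (out of
all 5³ = 125) whose sum lies in the intended category's AUDIT-C range, so
scoring followed by classification always returns the intended category.
AUDIT items 4–10, LDQ, trauma and episode sizes are drawn from
category-conditioned severity profiles that couple severity monotonically
across instruments. These profiles are synthetic modelling choices — they
emulate plausible marginal severity, not the empirical covariance of real
instruments. Passing tests on generated cohorts therefore demonstrates the
correctness of scoring, classification, flow accounting and suppression
logic; it does not validate distributional realism of item responses.

## Numerical and degenerate-input choices

* Half-up rounding uses a `1e-9` nudge before `floor(x + 0.5)` to guard
  against binary misrepresentation of exact halves.
* `max_drinks = 0` short-circuits the BAC computation to exactly 0 and
  permits any episode duration.
* Band lookups are closed-interval table scans validated to partition
  their domains (0–40, 0–30) with no gaps or overlaps.
* Problem sizes in the test suite — cohorts of 80–300 for properties, one
  10,000-participant cohort for the sampling-error check, 100–200
  repetitions for randomized oracles — were chosen to exercise the binomial
  noise floor while keeping the default suite fast.

## Limitations

The engine computes and renders feedback but does not serve it: there is no
web front end, no email delivery and no clinic IT integration. Feedback
prose and norms are placeholders. The trauma screen is a stand-in. The
generator's severity profiles are synthetic; cross-instrument correlations
beyond monotone coupling are not emulated. Behavioural outcomes (whether
feedback changes drinking) are outside the package's scope — it reproduces
the machinery of a feasibility episode, not efficacy estimates.
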