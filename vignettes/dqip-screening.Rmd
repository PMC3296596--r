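---
title: "Screening primary-care records with explicit medication assessment criteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening primary-care records with explicit medication assessment criteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dqipr)
```

## The instrument

Preventable drug-related morbidity (PDRM) — patient harm attributable to
avoidable failures of medication use — is a major driver of emergency
admissions from primary care. Explicit (criterion-based) medication
assessment instruments make such failures detectable in routine
electronic records: each criterion is a declarative rule over a
patient's demographics, diagnoses, prescriptions and laboratory results
that identifies one high-risk or low-quality prescribing pattern at a
chosen assessment date.

`dqipr` implements one such instrument in executable form: 176 criteria,
52 addressing medication-use *quality* (under-use of beneficial
treatment, wrong first-line selection, insufficient treatment intensity;
categories MQ1–MQ4) and 124 addressing medication-use *safety*
(high-risk drug selection, missing risk-mitigating co-prescription,
excessive dose or duration, compliance hazards, inconsistent laboratory
monitoring; categories MS1–MS8). Every criterion carries the consensus
metadata from its development: the panel necessity label (A/N for
quality, I/N for safety), the improvement topic it belongs to (Q1–Q18,
S1–S29) and that topic's Delphi priority tier. INR-based anticoagulant
monitoring is out of scope (those results typically live in bespoke
systems outside the primary-care record), as is computation of 10-year
cardiovascular risk, which is accepted as an input field.

A flag always encodes the *actionable* state: for safety criteria the
hazardous pattern as stated ("on warfarin and co-prescribed a
macrolide"), for quality criteria the unmet care need ("previous
myocardial infarction and *not* on a statin"). "Unless" exclusions are
negated clauses, so a satisfied exclusion silently clears the flag.

## The temporal model

All criteria are evaluated at a single cohort-wide **index date**.
Dates have day precision and all intervals are half-open `[start, end)`:
a prescription issued on day *d* with 28 days' supply covers days *d*
through *d+27*.

**Exposure episodes.** "Treated with X" is operationalised through
episodes of continuous exposure: consecutive issues of the same drug
code merge into one episode when the gap between the end of one
coverage interval and the next issue date is at most the *grace gap*
(default 28 days, the typical UK repeat-prescription cycle,
configurable). The instrument's duration clauses ("for > 12 weeks",
"for ≥ 4 weeks") measure from the containing episode's start to the
index date. How one-off acute issues relate to "treated with" is not
specified by the instrument itself; the episode model with a grace gap
is this package's operationalisation, and a single issue simply forms a
short episode.

**Windows.** "In the last *N* weeks" windows include the boundary day
(`index − 7N`), which errs toward fewer false monitoring-gap flags.
Ages are exact: "aged ≥ 65" means the 65th birthday falls on or before
the index date. The one nine-month monitoring window (amiodarone
thyroid function) is encoded as 39 weeks to stay in the instrument's
week-based algebra.

## Derived quantities and conventions

Several clauses need quantities the record does not carry directly.
Choices the instrument leaves open are package conventions, shipped as
editable terminology data (`inst/extdata/terminology.json`):

* **CHADS2** — 1 point each for heart failure, hypertension, diabetes
  and age strictly over 75 at index; 2 points for prior stroke/TIA.
  The point weights follow the standard published scheme (the
  instrument itself does not restate them) and are configurable.
* **CKD stage** — a coded stage (highest active code wins) takes
  precedence over the laboratory route; otherwise the latest eGFR is
  banded at the standard cut-points 60/30/15.
* **Dose equivalence** — "simvastatin 40 mg/day or equivalent" and
  "morphine 10 mg/day or equivalent" multiply the prescribed daily dose
  by a shipped factor table (statins in simvastatin-equivalents,
  strong opioids in oral-morphine equivalents). A drug missing from its
  table makes the criterion *not assessable* for that patient rather
  than silently negative.
* **Low-dose aspirin** — aspirin at ≤ 150 mg/day (UK antiplatelet
  convention; unstated in the instrument).
* **Overweight** (metformin first-line criterion) — a coded
  overweight/obesity diagnosis or latest BMI ≥ 25.
* **Micro-albuminuria** — a coded diagnosis, with a latest
  albumin:creatinine ratio above 3 mg/mmol accepted as the laboratory
  route; the code takes precedence.
* **Heart-failure target doses** — per-drug target daily doses for the
  ACE-inhibitor/ARB and beta-blocker titration criteria, shipped as
  data. Drugs without a known target cannot decide the criterion; if no
  active drug has a known target the criterion is not assessable.

**Treatment intensification.** The quality criteria phrased "has
treatment intensified" are evaluated as the *unmet* state at the index
date: the latest BP/HbA1c reading within a 15-month lookback (a
QOF-style review cycle; the instrument states no lookback) exceeds the
stated threshold, the patient is on fewer than the stated number of
distinct drug classes, the reading is at least 12 weeks old (the
practice has had a response window), and no additional drug class was
started between the reading and the index date. The 15-month lookback
and 12-week response window are configurable terminology parameters.
A BP reading is uncontrolled when either the systolic or the diastolic
value exceeds its threshold.

**Three-valued evaluation.** Predicates evaluate TRUE, FALSE or NA.
NA arises when a required input is unavailable (a dose-equivalence
factor, a target dose, a recorded risk score) and surfaces as a flag
with `assessable = FALSE`; such flags are excluded from prevalence
numerators so data gaps are never confounded with true negatives.

## Consensus classifiers

The development process is implemented alongside the instrument so the
published classification rules are executable:

* **Modified RAM.** All ratings are integers 1–9. Two-tailed
  disagreement — at least three ratings 7–9 *and* at least three 1–3 —
  dominates any median. Appropriateness bands the median at 7 and 3.
  Necessity is accepted at median ≥ 7 on the "necessary to do" scale
  and at median ≤ 3 on the "necessary to avoid" scale (the safety-side
  extension of the original method). Acceptance composes the scales:
  quality items must be appropriate (label N if also necessary, else
  A); safety items must be inappropriate (label N/"NecAv" if also
  necessary to avoid, else I).
* **Delphi tiers.** Topics with second-round median 7–9 without
  disagreement (30% or more of ratings in both tails) are priorities;
  medians of 8–9 are high priority; medians below 7 are rejected.
  The median of an even panel is the midpoint of the central pair and
  may be non-integer; tiers are assigned on the computed median without
  rounding (whether the original analysis rounded first is unstated;
  the published integer medians are unaffected either way). When only
  published medians are available, disagreement is taken as false,
  consistent with the panel's report of no disagreement on any topic.

Applying the tier rule to the 47 shipped second-round medians
reproduces every published label — 11 high-priority (7 quality, 4
safety), 27 priority, 9 rejected:

```{r}
med <- delphi_topic_medians()
tiers <- vapply(med$median, function(m) delphi_priority(median = m),
                character(1))
table(tiers)
all(tiers == med$printed_tier)
```

The RAM acceptance *percentages* from the original development
(318/389 appropriate, 275/389 necessary) depend on unpublished rating
matrices and are deliberately not reproduced; the classifier that would
produce them is instead verified by exhaustive enumeration of all
9^5 five-rater vectors against an independent sort-and-count oracle in
the test suite.

## The synthetic cohort generator

Because the instrument's source deposits no patient data, the package
generates its own: for every criterion, a *positive* record is built
mechanically from the predicate tree (every clause satisfied, every
exclusion left unsatisfied) and a *negative* record satisfies all but
one clause, chosen by seed and negated. Single-clause mutation gives
per-clause coverage of every predicate — an encoding error in any
clause breaks a round-trip test — which random negatives would miss.
`generate_cohort()` mixes planted positives (per-topic prevalences,
default 0.01 per topic at n = 500), planted negatives, and benign
background records, and emits the truth table alongside. Background
records may legitimately trigger criteria; they are scored against the
engine itself, never assumed negative.

What the generator does *not* emulate: clinically realistic population
prevalences, correlated comorbidity, realistic visit cadence, or coding
noise. A green round-trip therefore establishes that the encodings and
the engine agree with the published criterion logic — not that the
instrument's real-world yield is estimated.

```{r}
sim <- generate_cohort(sim_config(n_patients = 100, seed = 7))
flags <- screen_cohort(sim$cohort, index_date = as.Date("2012-01-01"))
summarize_flags(flags)$by_domain
```

## Numerical and degenerate-input choices

* Evaluation is a pure function of (record, index date, terminology,
  grace gap); screening twice is byte-identical, and per-patient
  failures are isolated as warnings rather than propagated.
* Empty cohorts, empty event tables and patients with no events are
  all valid and yield empty (never missing) results.
* An observation on the exact day a treatment starts counts as a
  baseline check for "before treatment start" and as monitoring for
  "since treatment start".
* The registry stores three anomalies of the published listing
  verbatim rather than correcting them: the duplicated topic number of
  the heart-failure titration rows, the digoxin U&E-monitoring pair
  filed under topic S8, and safety item 102's quality-domain "A" tag
  (surfaced by `validate_registry()` as a warning finding and counted
  with the non-necessary column, preserving the published 107/17
  split).
* Terminology codes are opaque strings; binding them to a real
  dictionary (dm+d, Read) is deliberately left to the deployer, and the
  first-line antihypertensive class — undefined in the source — ships
  as an editable default (thiazides, ACE inhibitors, ARBs,
  dihydropyridine calcium-channel blockers).

## Limitations

The package screens cross-sectionally at one index date; longitudinal
incidence, per-criterion eligibility denominators and statistical
inference on prevalences are out of scope. Criteria needing
free-text or dispensing information beyond the tabular contract
(e.g. verifying that dose instructions were *communicated*, as opposed
to recorded) are approximated by the record fields provided.
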