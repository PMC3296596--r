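# dqipr

Prescribing-safety screening for primary-care records: an executable
implementation of a 176-criterion explicit medication assessment
instrument, for pharmacoepidemiologists, prescribing-safety researchers
and medicines-governance teams who need to find patients at risk of
preventable drug-related morbidity (PDRM) in routine electronic data.

## What it implements

* **The instrument** — 52 medication-*quality* criteria (under-use,
  wrong first-line selection, insufficient intensity of beneficial
  treatment; categories MQ1–MQ4) and 124 medication-*safety* criteria
  (high-risk selection, missing risk-mitigating co-therapy, excessive
  dose/duration, compliance hazards, inconsistent laboratory
  monitoring; MS1–MS8), each encoded as a declarative predicate tree
  over a patient's conditions, prescriptions and observations, with
  its panel necessity label (A/N, I/N), improvement topic (Q1–Q18,
  S1–S29) and Delphi priority tier as metadata.
* **The temporal algebra** — drug exposure episodes built by merging
  prescription coverage intervals separated by at most a grace gap
  (default 28 days), half-open date intervals, inclusive trailing
  windows, exact birthday arithmetic; plus CHADS2 scoring
  (CHF/hypertension/age > 75/diabetes = 1 point, stroke/TIA = 2),
  CKD staging (coded stage, else eGFR banded at 60/30/15) and
  dose-equivalence arithmetic (simvastatin- and oral-morphine
  equivalents).
* **The consensus classifiers** used to develop the instrument — the
  modified RAND/UCLA appropriateness method (median bands at 7/3, the
  two-tailed "3 or more in each tail" disagreement rule, and the
  "necessary to avoid" safety extension) and the Delphi tier rule
  (median 7–9 = priority, 8–9 = high priority, 30%-in-both-tails
  disagreement).
* **A synthetic cohort generator** — for every criterion it plants a
  positive record mechanically from the predicate tree and
  single-clause-mutated negative records, so the whole instrument is
  testable without real patient data.

## Worked example

A 70-year-old man on warfarin and low-dose aspirin, with no
gastroprotection and no recorded cardiovascular risk score:

```r
library(dqipr)

co <- new_cohort(
  patients = tibble::tibble(patient_id = "p1", sex = "male",
                            birth_date = as.Date("1941-06-15")),
  prescriptions = tibble::tibble(
    patient_id = "p1",
    drug_code  = c("warfarin", "aspirin"),
    issue_date = as.Date(c("2011-11-20", "2011-11-20")),
    days_supply = 56L, daily_dose = c(3, 75), dose_unit = "mg/day",
    strength = NA_real_, dose_instructions_recorded = NA))

flags <- screen_cohort(co, index_date = as.Date("2012-01-01"))
dplyr::select(tibble::as_tibble(flags), patient_id, criterion_id,
              topic_id, category, necessity_label, delphi_priority,
              assessable)
#> # A tibble: 3 × 7
#>   patient_id criterion_id topic_id category necessity_label delphi_priority
#> 1 p1         Q-023        Q6       MQ1      A               priority
#> 2 p1         Q-027        Q7       MQ4      N               priority
#> 3 p1         S-002        S1       MS1      N               high
```

`S-002` is the real screening hit: aged ≥ 65 on warfarin **and**
low-dose aspirin without a gastroprotective agent — a
necessary-to-avoid (N) safety criterion in the high-priority
gastroprotection topic S1. Adding an active proton-pump-inhibitor
prescription clears it. The two quality rows have
`assessable = FALSE`: the statin criteria for high-CVD-risk patients
cannot be decided because the record carries no 10-year CVD risk
score; such rows are excluded from prevalence numerators rather than
treated as true positives or negatives.

Reproducing the published Delphi prioritisation from the shipped
second-round medians:

```r
med <- delphi_topic_medians()
tiers <- vapply(med$median, function(m) delphi_priority(median = m),
                character(1))
table(tiers)
#> tiers
#>     high priority rejected
#>       11       27        9
all(tiers == med$printed_tier)
#> [1] TRUE
```

Synthetic cohorts with ground truth, and a thin CLI
(`inst/cli/dqip.R` with `validate` / `screen` / `simulate` /
`summarize` / `consensus` subcommands), round out the toolchain:

```r
sim   <- generate_cohort(sim_config(n_patients = 500, seed = 42))
flags <- screen_cohort(sim$cohort, index_date = as.Date("2012-01-01"))
summarize_flags(flags)$by_topic
autoplot(flags)
```

## Acceptance script

`scripts/acceptance.R` recomputes the instrument's reproducible
consensus outputs from scratch by running the installed package: it
applies the Delphi tier rule to the 47 shipped second-round topic
medians and reports the resulting topic counts as JSON.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
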