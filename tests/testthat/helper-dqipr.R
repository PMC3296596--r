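# Shared test fixtures, built in code.

IDX <- as.Date("2012-01-01")
TERM <- default_terminology()
REG <- default_criteria()

# single-patient cohort from a plant_case() record
as_cohort <- function(rec) {
  new_cohort(rec$patients, rec$conditions, rec$prescriptions,
             rec$observations)
}

# minimal hand-built patient
mk_patients <- function(id = "p1", sex = "male",
                        birth = as.Date("1942-01-01"), ...) {
  tibble::tibble(patient_id = id, sex = sex, birth_date = birth, ...)
}

mk_rx <- function(id, drug, issue, supply = 28L, dose = 100,
                  unit = "mg/day", strength = NA_real_, instr = NA) {
  tibble::tibble(patient_id = id, drug_code = drug,
                 issue_date = as.Date(issue), days_supply = supply,
                 daily_dose = dose, dose_unit = unit, strength = strength,
                 dose_instructions_recorded = instr)
}

mk_cond <- function(id, code, onset) {
  tibble::tibble(patient_id = id, code = code, onset_date = as.Date(onset),
                 resolved_date = as.Date(NA))
}

mk_obs <- function(id, test, date, value = 1, value2 = NA_real_) {
  tibble::tibble(patient_id = id, test_code = test, date = as.Date(date),
                 value = value, value2 = value2, unit = NA_character_)
}

# random longitudinal record for property tests: a plausible mix of drugs,
# conditions and observations drawn from the instrument's own vocabulary
random_record <- function(seed, id = "r1", index_date = IDX) {
  set.seed(seed)
  drug_pool <- c("warfarin", "aspirin", "clopidogrel", "ibuprofen",
                 "naproxen", "celecoxib", "omeprazole", "furosemide",
                 "spironolactone", "bendroflumethiazide", "ramipril",
                 "losartan", "simvastatin", "atorvastatin", "digoxin",
                 "amiodarone", "methotrexate", "prednisolone", "morphine",
                 "salbutamol", "bisoprolol", "metformin", "gliclazide",
                 "amitriptyline", "diazepam", "temazepam", "zopiclone",
                 "amoxicillin", "levothyroxine")
  cond_pool <- c("htn", "dm2", "af", "chf", "asthma", "copd", "gout",
                 "peptic_ulcer", "stroke", "mi", "angina", "ckd3",
                 "dementia", "osteoporosis", "osteoarthritis")
  age <- sample(5:95, 1)
  n_rx <- sample(0:6, 1)
  n_cond <- sample(0:4, 1)
  n_obs <- sample(0:4, 1)
  patients <- tibble::tibble(
    patient_id = id, sex = sample(c("female", "male"), 1),
    birth_date = index_date %m-% lubridate::years(age) - sample(0:300, 1),
    cvd10y_percent = sample(c(NA_real_, 10, 25), 1),
    housebound = FALSE, nursing_home = FALSE, hysterectomy = FALSE)
  rx <- if (n_rx) mk_rx(id, sample(drug_pool, n_rx, replace = TRUE),
                        index_date - sample(0:500, n_rx, replace = TRUE),
                        supply = sample(c(14L, 28L, 56L), n_rx,
                                        replace = TRUE),
                        dose = sample(c(10, 40, 75, 150, 250), n_rx,
                                      replace = TRUE)) else NULL
  max_onset <- min(3000, (age - 1) * 365)  # keep onset after birth
  conds <- if (n_cond) mk_cond(id, sample(cond_pool, n_cond),
                               index_date - sample(30:max_onset, n_cond,
                                                   replace = TRUE)) else
    NULL
  obs <- if (n_obs) mk_obs(id, sample(c("UE", "FBC", "TFT", "BP",
                                        "HbA1c", "eGFR"), n_obs,
                                      replace = TRUE),
                           index_date - sample(0:600, n_obs,
                                               replace = TRUE),
                           value = sample(c(1, 7.5, 50, 145), n_obs,
                                          replace = TRUE)) else NULL
  new_cohort(patients, conds, rx, obs)
}
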