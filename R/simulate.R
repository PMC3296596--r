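# Synthetic cohort generator. Cases are planted mechanically from each
# criterion's predicate tree: a positive record satisfies every clause
# (exclusions left unsatisfied); a negative record satisfies all but one
# clause, chosen by seed, which is negated (mutation-style, giving
# per-clause coverage of every predicate). All sampling flows from one
# seeded generator so a fixed seed reproduces records byte-identically.

new_builder <- function(index_date, terminology) {
  e <- new.env(parent = emptyenv())
  e$index_date <- index_date
  e$term <- terminology
  e$age_lo <- 50; e$age_hi <- 74
  e$age_fixed <- NA_real_
  e$sex <- NA_character_
  e$flags <- c(housebound = FALSE, nursing_home = FALSE,
               hysterectomy = FALSE)
  e$risk <- c(cvd10y_percent = NA_real_)
  e$conditions <- list()   # list of (code, onset_offset_days)
  e$rx <- list()           # keyed by drug code
  e$extra_rx <- list()     # verbatim extra issues (second strengths)
  e$obs <- list()          # list of (test, offset_days, value, value2)
  e$forbid_drug <- character()
  e$forbid_condition <- character()
  e
}

b_age_range <- function(b, lo = NULL, hi = NULL) {
  if (!is.null(lo)) b$age_lo <- max(b$age_lo, lo)
  if (!is.null(hi)) b$age_hi <- min(b$age_hi, hi)
  if (b$age_lo > b$age_hi) {
    # an explicit clause bound wins over the adult default range
    b$age_lo <- min(b$age_lo, if (!is.null(lo)) lo else b$age_lo)
    b$age_hi <- max(b$age_hi, if (!is.null(hi)) hi else b$age_hi)
    if (!is.null(hi) && is.null(lo)) { b$age_lo <- max(1, hi - 4); b$age_hi <- hi }
    if (!is.null(lo) && is.null(hi)) { b$age_hi <- lo + 9; b$age_lo <- lo }
  }
  invisible(b)
}

b_condition <- function(b, code, onset_offset = 730) {
  b$conditions[[length(b$conditions) + 1]] <- list(code = code,
                                                   onset = onset_offset)
  invisible(b)
}

b_drug <- function(b, code, start_off = NULL, len = NULL, dose = NULL,
                   unit = NULL, strength = NULL, instructions = NULL,
                   overwrite_period = FALSE) {
  cur <- b$rx[[code]] %||% list(code = code, start_off = 56, len = 84,
                                dose = 100, unit = "mg/day",
                                strength = NA_real_, instructions = NA)
  if (!is.null(start_off) && (overwrite_period || is.null(b$rx[[code]]))) {
    cur$start_off <- start_off
    cur$len <- len %||% cur$len
  } else if (!is.null(len) && overwrite_period) {
    cur$len <- len
  }
  if (!is.null(dose)) { cur$dose <- dose; cur$unit <- unit %||% "mg/day" }
  if (!is.null(strength)) cur$strength <- strength
  if (!is.null(instructions)) cur$instructions <- instructions
  b$rx[[code]] <- cur
  invisible(b)
}

b_obs <- function(b, test, offset, value, value2 = NA_real_) {
  b$obs[[length(b$obs) + 1]] <- list(test = test, offset = offset,
                                     value = value, value2 = value2)
  invisible(b)
}

# choose the code a clause materialises; avoids codes the criterion forbids
pick_code <- function(b, set, prefer_target = FALSE) {
  codes <- setdiff(members(b$term, set), b$forbid_drug)
  if (length(codes) == 0) {
    abort(sprintf("cannot plant: all codes of %s are excluded by the criterion",
                  set), class = "dqip_plant_error")
  }
  if (prefer_target) {
    in_tab <- intersect(codes, names(b$term$target_daily_dose))
    if (length(in_tab)) return(in_tab[1])
  }
  codes[1]
}

set_active_codes <- function(b, set) {
  intersect(names(b$rx), members(b$term, set))
}

chads2_factor_sets <- c("CHF", "HYPERTENSION", "DIABETES", "STROKE_TIA")

plant_chads2 <- function(b, target) {
  # reach the target score with condition factors only; cap age at 75 so
  # the age point stays off (no planted criterion combines CHADS2 with an
  # explicit age clause)
  b_age_range(b, hi = 74)
  picks <- switch(as.character(target),
                  "0" = character(),
                  "1" = "HYPERTENSION",
                  "2" = c("HYPERTENSION", "DIABETES"),
                  "3" = c("STROKE_TIA", "HYPERTENSION"),
                  c("STROKE_TIA", "HYPERTENSION", "DIABETES"))
  for (s in picks) b_condition(b, members(b$term, s)[1])
  invisible(b)
}

# --- clause satisfaction -----------------------------------------------

# pass 1: leaves with specific demands; pass 2: bare presence (on_drug)
leaf_pass <- function(p) if (p$op %in% c("on_drug")) 2L else 1L

satisfy <- function(p, b) {
  idx <- b$index_date
  switch(
    p$op,
    all_of = for (a in p$args) satisfy(a, b),
    any_of = satisfy(p$args[[1]], b),
    not = violate(p$args[[1]], b),
    age_ge = b_age_range(b, lo = p$years),
    age_gt = b_age_range(b, lo = p$years + 1),
    age_le = b_age_range(b, hi = p$years),
    age_between = b_age_range(b, lo = p$lo, hi = p$hi),
    sex_is = { b$sex <- p$sex },
    flag_is = { b$flags[[p$flag]] <- TRUE },
    flag_not = { b$flags[[p$flag]] <- FALSE },
    has_condition = b_condition(b, setdiff(members(b$term, p$set),
                                           b$forbid_condition)[1]),
    lacks_condition = { b$forbid_condition <-
      union(b$forbid_condition, members(b$term, p$set)) },
    condition_onset_within_months =
      b_condition(b, members(b$term, p$set)[1],
                  onset_offset = round((p$lo + p$hi) / 2 * 30.4)),
    on_drug = {
      if (length(set_active_codes(b, p$set)) == 0) {
        b_drug(b, pick_code(b, p$set))
      }
    },
    exposure_weeks_gt = b_drug(b, pick_code(b, p$set),
                               start_off = p$weeks * 7 + 28,
                               len = p$weeks * 7 + 56,
                               overwrite_period = TRUE),
    exposure_weeks_ge = b_drug(b, pick_code(b, p$set),
                               start_off = p$weeks * 7 + 14,
                               len = p$weeks * 7 + 42,
                               overwrite_period = TRUE),
    issues_in_window_ge = ,
    issues_in_window_eq = {
      code <- pick_code(b, p$set)
      offs <- round(seq(7, p$weeks * 7 - 7, length.out = p$n))
      for (o in offs) {
        b$extra_rx[[length(b$extra_rx) + 1]] <-
          list(code = code, start_off = o, len = 5, dose = 1,
               unit = "mg/day", strength = NA_real_, instructions = NA)
      }
    },
    never_prescribed = { b$forbid_drug <-
      union(b$forbid_drug, members(b$term, p$set)) },
    daily_dose_ge = b_drug(b, pick_code(b, p$set), dose = p$dose,
                           unit = p$unit),
    daily_dose_gt = b_drug(b, pick_code(b, p$set), dose = p$dose * 2,
                           unit = p$unit),
    daily_dose_le = b_drug(b, pick_code(b, p$set), dose = p$dose / 2,
                           unit = p$unit),
    equivalent_dose_ge = b_drug(b, b$term$dose_equivalence[[p$table]]$reference_drug,
                                dose = p$dose, unit = "mg/day"),
    equivalent_dose_gt = b_drug(b, b$term$dose_equivalence[[p$table]]$reference_drug,
                                dose = p$dose * 2, unit = "mg/day"),
    below_target_dose = {
      code <- pick_code(b, p$set, prefer_target = TRUE)
      b_drug(b, code, dose = b$term$target_daily_dose[[code]] / 2)
    },
    strengths_gt_one = {
      code <- pick_code(b, p$set)
      b_drug(b, code, strength = 2.5)
      b$extra_rx[[length(b$extra_rx) + 1]] <-
        list(code = code, start_off = 40, len = 80, dose = 100,
             unit = "mg/day", strength = 10, instructions = NA)
    },
    no_dose_instructions = {
      code <- pick_code(b, p$set)
      b_drug(b, code, instructions = FALSE)
    },
    no_observation_within = b_obs(b, p$test, p$weeks * 7 + 60, 1),
    no_observation_before_start = invisible(b),  # absence suffices
    no_observation_since_start = {
      # last check predates the treatment start used by the clause
      starts <- map_dbl(p$sets, function(s) {
        codes <- set_active_codes(b, s)
        if (length(codes) == 0) 56 else
          max(map_dbl(codes, function(cd) b$rx[[cd]]$start_off))
      })
      b_obs(b, p$test, min(starts) + 30, 1)
    },
    obs_gt = b_obs(b, p$test, 60, p$value * 2),
    obs_ge = b_obs(b, p$test, 60, p$value),
    chads2_ge = plant_chads2(b, p$score),
    chads2_eq = plant_chads2(b, p$score),
    chads2_between = plant_chads2(b, p$lo),
    ckd_stage_in = b_condition(b, sprintf("ckd%d", min(unlist(p$stages)))),
    risk_score_gt = { b$risk[[p$score_name]] <- p$value + 5 },
    risk_score_ge = { b$risk[[p$score_name]] <- p$value },
    uncontrolled_bp = b_obs(b, "BP", 98, p$systolic + 10,
                            p$diastolic + 5),
    uncontrolled_hba1c = {
      v <- if (!is.null(p$gt)) p$gt + 1 else mean(unlist(p$between))
      b_obs(b, "HbA1c", 98, v)
    },
    abort(sprintf("no planting template for op: %s", p$op),
          class = "dqip_plant_error")
  )
  invisible(b)
}

# --- clause violation ---------------------------------------------------

drop_drug_set <- function(b, set) {
  codes <- members(b$term, set)
  b$rx <- b$rx[setdiff(names(b$rx), codes)]
  b$extra_rx <- keep(b$extra_rx, function(r) !r$code %in% codes)
  b$forbid_drug <- union(b$forbid_drug, codes)
  invisible(b)
}

violate <- function(p, b) {
  idx <- b$index_date
  switch(
    p$op,
    all_of = violate(p$args[[1]], b),
    any_of = for (a in p$args) violate(a, b),
    not = satisfy(p$args[[1]], b),
    age_ge = { b$age_fixed <- p$years - 1 },
    age_gt = { b$age_fixed <- p$years },
    age_le = { b$age_fixed <- p$years + 1 },
    age_between = { b$age_fixed <- max(1, p$lo - 1) },
    sex_is = { b$sex <- setdiff(c("female", "male"), p$sex)[1] },
    flag_is = { b$flags[[p$flag]] <- FALSE },
    flag_not = { b$flags[[p$flag]] <- TRUE },
    has_condition = { b$forbid_condition <-
      union(b$forbid_condition, members(b$term, p$set)) },
    lacks_condition = b_condition(b, members(b$term, p$set)[1]),
    condition_onset_within_months =
      b_condition(b, members(b$term, p$set)[1],
                  onset_offset = round((p$hi + 3) * 30.4)),
    on_drug = drop_drug_set(b, p$set),
    exposure_weeks_gt = b_drug(b, pick_code(b, p$set),
                               start_off = max(7, floor(p$weeks * 7 / 2)),
                               len = max(7, floor(p$weeks * 7 / 2)) + 28,
                               overwrite_period = TRUE),
    exposure_weeks_ge = b_drug(b, pick_code(b, p$set),
                               start_off = max(7, floor(p$weeks * 7 / 2)),
                               len = max(7, floor(p$weeks * 7 / 2)) + 28,
                               overwrite_period = TRUE),
    issues_in_window_ge = drop_drug_set(b, p$set),
    issues_in_window_eq = drop_drug_set(b, p$set),
    never_prescribed = {
      b$forbid_drug <- setdiff(b$forbid_drug, members(b$term, p$set))
      b$extra_rx[[length(b$extra_rx) + 1]] <-
        list(code = members(b$term, p$set)[1], start_off = 365, len = 14,
             dose = (p$min_daily_dose %||% 100) * 1.2, unit = "mg/day",
             strength = NA_real_, instructions = NA)
    },
    daily_dose_ge = b_drug(b, pick_code(b, p$set), dose = p$dose / 2,
                           unit = p$unit),
    daily_dose_gt = b_drug(b, pick_code(b, p$set), dose = p$dose,
                           unit = p$unit),
    daily_dose_le = b_drug(b, pick_code(b, p$set), dose = p$dose * 2,
                           unit = p$unit),
    equivalent_dose_ge = ,
    equivalent_dose_gt = {
      ref <- b$term$dose_equivalence[[p$table]]$reference_drug
      low <- if (p$op == "equivalent_dose_ge") p$dose / 2 else p$dose
      for (cd in set_active_codes(b, p$set)) b_drug(b, cd, dose = 0.1)
      if (ref %in% names(b$rx)) b_drug(b, ref, dose = low)
    },
    below_target_dose = {
      code <- pick_code(b, p$set, prefer_target = TRUE)
      b_drug(b, code, dose = b$term$target_daily_dose[[code]])
    },
    strengths_gt_one = {
      codes <- members(b$term, p$set)
      b$extra_rx <- keep(b$extra_rx, function(r) !r$code %in% codes)
      for (cd in intersect(names(b$rx), codes))
        b_drug(b, cd, strength = 2.5)
    },
    no_dose_instructions = {
      for (cd in set_active_codes(b, p$set))
        b_drug(b, cd, instructions = TRUE)
      if (length(set_active_codes(b, p$set)) == 0)
        b_drug(b, pick_code(b, p$set), instructions = TRUE)
    },
    no_observation_within = b_obs(b, p$test, 14, 1),
    no_observation_before_start = {
      starts <- map_dbl(p$sets, function(s) {
        codes <- set_active_codes(b, s)
        if (length(codes) == 0) 56 else
          max(map_dbl(codes, function(cd) b$rx[[cd]]$start_off))
      })
      b_obs(b, p$test, max(starts) + 30, 1)
    },
    no_observation_since_start = b_obs(b, p$test, 3, 1),
    obs_gt = b_obs(b, p$test, 30, p$value / 2),
    obs_ge = b_obs(b, p$test, 30, p$value / 2),
    chads2_ge = { b$forbid_condition <- union(b$forbid_condition,
      unlist(map(chads2_factor_sets, members, terminology = b$term)))
      b_age_range(b, hi = 74) },
    chads2_eq = {
      plant_chads2(b, p$score + 1)
    },
    chads2_between = {
      plant_chads2(b, p$hi + 1)
    },
    ckd_stage_in = { b$forbid_condition <-
      union(b$forbid_condition, c("ckd3", "ckd4", "ckd5")) },
    risk_score_gt = { b$risk[[p$score_name]] <- p$value - 5 },
    risk_score_ge = { b$risk[[p$score_name]] <- p$value - 5 },
    uncontrolled_bp = b_obs(b, "BP", 90, p$systolic - 10,
                            p$diastolic - 10),
    uncontrolled_hba1c = {
      v <- if (!is.null(p$gt)) p$gt - 1 else unlist(p$between)[1] - 1
      b_obs(b, "HbA1c", 90, v)
    },
    abort(sprintf("no violation template for op: %s", p$op),
          class = "dqip_plant_error")
  )
  invisible(b)
}

# -- build the final single-patient record -------------------------------

build_record <- function(b, patient_id) {
  idx <- b$index_date
  age <- if (!is.na(b$age_fixed)) b$age_fixed else
    sample(seq(b$age_lo, b$age_hi), 1)
  jitter <- sample(0:300, 1)
  birth <- idx %m-% years(age) - jitter
  sex <- if (!is.na(b$sex)) b$sex else sample(c("female", "male"), 1)

  conds <- b$conditions
  conds <- keep(conds, function(cn) !cn$code %in% b$forbid_condition)
  conditions <- if (length(conds)) {
    tibble(patient_id = patient_id,
           code = map_chr(conds, "code"),
           onset_date = idx - map_dbl(conds, "onset"),
           resolved_date = as.Date(NA))
  } else NULL

  rx_rows <- c(unname(b$rx), b$extra_rx)
  rx_rows <- keep(rx_rows, function(r) {
    !r$code %in% b$forbid_drug || r$start_off > 360  # prior-trial issues
  })
  prescriptions <- if (length(rx_rows)) {
    bind_rows(lapply(rx_rows, function(r) {
      tibble(patient_id = patient_id, drug_code = r$code,
             issue_date = idx - r$start_off,
             days_supply = as.integer(r$len %||% 84),
             daily_dose = r$dose, dose_unit = r$unit %||% "mg/day",
             strength = r$strength %||% NA_real_,
             dose_instructions_recorded = r$instructions %||% NA)
    }))
  } else NULL

  observations <- if (length(b$obs)) {
    bind_rows(lapply(b$obs, function(o) {
      tibble(patient_id = patient_id, test_code = o$test,
             date = idx - o$offset, value = o$value, value2 = o$value2,
             unit = NA_character_)
    }))
  } else NULL

  # long prescription coverage can predate a late onset jitter; clamp
  patients <- tibble(patient_id = patient_id, sex = sex,
                     birth_date = birth,
                     cvd10y_percent = b$risk[["cvd10y_percent"]],
                     housebound = b$flags[["housebound"]],
                     nursing_home = b$flags[["nursing_home"]],
                     hysterectomy = b$flags[["hysterectomy"]])
  dates <- c(conditions$onset_date, prescriptions$issue_date,
             observations$date)
  if (length(dates) && min(dates) <= patients$birth_date) {
    patients$birth_date <- min(dates) - 365
  }
  list(patients = patients, conditions = conditions,
       prescriptions = prescriptions, observations = observations)
}

#' Plant a synthetic test case for one criterion
#'
#' A positive case satisfies every clause of the criterion's predicate at
#' the index date (with any "unless" exclusion left unsatisfied); a
#' negative case satisfies all but one clause, chosen by the seed, which
#' is negated -- a single-clause mutation that exercises each part of the
#' encoding.
#'
#' @param criterion One registry row.
#' @param positive Logical: plant a case that should (not) flag.
#' @param seed Integer seed; fixes the record exactly.
#' @param index_date Assessment date the record is built around.
#' @param terminology A `dqip_terminology`.
#' @param patient_id Identifier given to the synthetic patient.
#' @param clause For negatives: index of the clause to negate (default:
#'   chosen by the seed).
#' @return A list of the four cohort tables (single patient) plus
#'   `mutated_clause` (index of the negated clause, `NA` for positives).
#' @export
plant_case <- function(criterion, positive = TRUE, seed = 1,
                       index_date = as.Date("2012-01-01"),
                       terminology = default_terminology(),
                       patient_id = "planted", clause = NULL) {
  set.seed(seed)
  pred <- criterion$predicate[[1]]
  clauses <- if (pred$op == "all_of") pred$args else list(pred)
  b <- new_builder(index_date, terminology)
  mutated <- NA_integer_
  if (positive) {
    ord <- order(map_int(clauses, leaf_pass))
    for (i in ord) satisfy(clauses[[i]], b)
  } else {
    mutated <- clause %||% sample(seq_along(clauses), 1)
    keep_idx <- setdiff(seq_along(clauses), mutated)
    ord <- keep_idx[order(map_int(clauses[keep_idx], leaf_pass))]
    for (i in ord) satisfy(clauses[[i]], b)
    violate(clauses[[mutated]], b)
  }
  rec <- build_record(b, patient_id)
  rec$mutated_clause <- mutated
  rec
}

#' Simulation configuration
#'
#' @param n_patients Cohort size.
#' @param seed Master seed fixing all randomness end-to-end.
#' @param prevalence Named numeric vector: probability that a patient is
#'   planted as a positive case for a criterion of the given topic.
#'   Default: 0.01 for each of the 47 topics.
#' @param negative_fraction Fraction of non-planted patients carrying a
#'   planted *negative* (single-clause-mutated) case rather than pure
#'   background noise.
#' @param index_date Assessment date.
#' @return A `dqip_sim_config` list.
#' @export
sim_config <- function(n_patients = 500, seed = 42, prevalence = NULL,
                       negative_fraction = 0.2,
                       index_date = as.Date("2012-01-01")) {
  topics <- names(topic_priority_map())
  if (is.null(prevalence)) {
    prevalence <- setNames(rep(0.01, length(topics)), topics)
  }
  stopifnot(all(prevalence >= 0 & prevalence <= 1),
            sum(prevalence) <= 1)
  structure(list(n_patients = n_patients, seed = seed,
                 prevalence = prevalence,
                 negative_fraction = negative_fraction,
                 index_date = as.Date(index_date)),
            class = "dqip_sim_config")
}

background_record <- function(index_date, patient_id) {
  # benign background: drugs/observations outside every criterion pattern
  benign <- c("amoxicillin", "levothyroxine", "cetirizine", "latanoprost")
  n_rx <- sample(0:3, 1)
  rx <- if (n_rx > 0) {
    tibble(patient_id = patient_id,
           drug_code = sample(benign, n_rx, replace = TRUE),
           issue_date = index_date - sample(7:400, n_rx),
           days_supply = 28L, daily_dose = 10,
           dose_unit = "mg/day", strength = NA_real_,
           dose_instructions_recorded = NA)
  } else NULL
  obs <- tibble(patient_id = patient_id, test_code = "UE",
                date = index_date - sample(7:100, 1), value = 1,
                value2 = NA_real_, unit = NA_character_)
  age <- sample(20:90, 1)
  list(patients = tibble(patient_id = patient_id,
                         sex = sample(c("female", "male"), 1),
                         birth_date = index_date %m-% years(age) -
                           sample(0:300, 1),
                         cvd10y_percent = NA_real_, housebound = FALSE,
                         nursing_home = FALSE, hysterectomy = FALSE),
       conditions = NULL, prescriptions = rx, observations = obs)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Mixes planted positive cases (per-topic prevalences), planted
#' single-clause-mutated negatives and benign background records. The
#' truth table lists the expected engine outcome for every planted case;
#' background records carry no expectation (they are scored against the
#' engine itself, not assumed negative).
#'
#' @param config A [sim_config()].
#' @param registry Criterion registry to plant from.
#' @param terminology A `dqip_terminology`.
#' @return A list: `cohort` (a `dqip_cohort`), `truth` (tibble
#'   `patient_id`, `criterion_id`, `expected_flag`).
#' @export
generate_cohort <- function(config = sim_config(),
                            registry = default_criteria(),
                            terminology = default_terminology()) {
  set.seed(config$seed)
  idx <- config$index_date
  topics <- names(config$prevalence)
  p_planted <- sum(config$prevalence)
  parts <- vector("list", config$n_patients)
  truth <- list()
  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%05d", i)
    u <- runif(1)
    if (u < p_planted) {
      topic <- sample(topics, 1, prob = config$prevalence)
      cand <- registry[registry$topic_id == topic, ]
      cr <- cand[sample(nrow(cand), 1), ]
      rec <- plant_case(cr, positive = TRUE,
                        seed = sample.int(2^31 - 1, 1), index_date = idx,
                        terminology = terminology, patient_id = pid)
      truth[[length(truth) + 1]] <-
        tibble(patient_id = pid, criterion_id = cr$criterion_id,
               expected_flag = TRUE)
    } else if (runif(1) < config$negative_fraction) {
      cr <- registry[sample(nrow(registry), 1), ]
      rec <- plant_case(cr, positive = FALSE,
                        seed = sample.int(2^31 - 1, 1), index_date = idx,
                        terminology = terminology, patient_id = pid)
      truth[[length(truth) + 1]] <-
        tibble(patient_id = pid, criterion_id = cr$criterion_id,
               expected_flag = FALSE)
    } else {
      rec <- background_record(idx, pid)
    }
    parts[[i]] <- rec
  }
  cohort <- new_cohort(
    patients = bind_rows(map(parts, "patients")),
    conditions = bind_rows(map(parts, "conditions")),
    prescriptions = bind_rows(map(parts, "prescriptions")),
    observations = bind_rows(map(parts, "observations"))
  )
  list(cohort = cohort, truth = bind_rows(truth))
}

#' Write the four cohort tables (and optional truth table) to a directory
#'
#' Files are written in a canonical column and row order so a fixed seed
#' yields byte-identical output.
#'
#' @param cohort A `dqip_cohort`.
#' @param dir Output directory (created if needed).
#' @param truth Optional truth tibble from [generate_cohort()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, truth = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort$patients, file.path(dir, "patients.csv"))
  readr::write_csv(cohort$conditions, file.path(dir, "conditions.csv"))
  readr::write_csv(cohort$prescriptions |> select(-any_of("rx_id")),
                   file.path(dir, "prescriptions.csv"))
  readr::write_csv(cohort$observations, file.path(dir, "observations.csv"))
  if (!is.null(truth)) {
    readr::write_csv(truth, file.path(dir, "truth_table.csv"))
  }
  invisible(dir)
}

#' Generate synthetic panel rating matrices with target classes
#'
#' Rejection-samples a complete panelist-by-item rating matrix whose
#' classification under the consensus rules equals each item's target
#' class. Infeasible targets for the panel size (e.g. two-tailed
#' disagreement with fewer than 6 panelists) are an error.
#'
#' @param targets For `scheme = "ram"`: tibble `item_id`, `domain`,
#'   `target` (one of A, N, I, NecAv, rejected, disagreement). For
#'   `scheme = "delphi"`: tibble `topic_id`, `target` (high, priority,
#'   rejected, disagreement).
#' @param n_panelists Panel size.
#' @param seed Integer seed.
#' @param scheme `"ram"` or `"delphi"`.
#' @return A long ratings tibble suitable for [ram_classify()] /
#'   [delphi_classify()].
#' @export
generate_ratings <- function(targets, n_panelists = 10, seed = 1,
                             scheme = c("ram", "delphi")) {
  scheme <- match.arg(scheme)
  set.seed(seed)
  draw <- function(pool) sample(pool, n_panelists, replace = TRUE)
  disagreement_vec <- function() {
    if (scheme == "ram" && n_panelists < 6) {
      abort(sprintf(
        "disagreement needs >= 3 ratings in each tail: infeasible with %d panelists",
        n_panelists), class = "dqip_rating_error")
    }
    n_lo <- if (scheme == "ram") 3 else ceiling(0.3 * n_panelists)
    if (scheme == "delphi" && n_panelists - n_lo < n_lo + 1) {
      abort(sprintf(
        "delphi disagreement with median >= 7 infeasible with %d panelists",
        n_panelists), class = "dqip_rating_error")
    }
    sample(c(rep(1L, n_lo), rep(9L, n_panelists - n_lo)))
  }
  one_ram <- function(domain, target) {
    for (try in 1:200) {
      app <- switch(target,
                    N = , A = draw(7:9),
                    I = , NecAv = draw(1:3),
                    rejected = draw(4:6),
                    disagreement = disagreement_vec())
      nec <- switch(target,
                    N = draw(7:9), A = draw(4:6),
                    NecAv = draw(1:3), I = draw(4:6),
                    draw(4:6))
      got <- ram_accept(app, nec, domain)
      want <- if (target == "disagreement") "rejected" else target
      app_ok <- target != "disagreement" ||
        ram_appropriateness(app) == "disagreement"
      if (got == want && app_ok) return(list(app = app, nec = nec))
    }
    abort(sprintf("could not realise RAM target '%s' with %d panelists",
                  target, n_panelists), class = "dqip_rating_error")
  }
  one_delphi <- function(target) {
    for (try in 1:200) {
      r <- switch(target,
                  high = draw(8:9),
                  priority = draw(6:8),
                  rejected = draw(3:6),
                  disagreement = disagreement_vec())
      if (delphi_priority(r) == target) return(r)
    }
    abort(sprintf("could not realise Delphi target '%s' with %d panelists",
                  target, n_panelists), class = "dqip_rating_error")
  }
  if (scheme == "ram") {
    bind_rows(lapply(seq_len(nrow(targets)), function(i) {
      rt <- one_ram(targets$domain[i], targets$target[i])
      bind_rows(
        tibble(item_id = targets$item_id[i], domain = targets$domain[i],
               panelist_id = sprintf("R%02d", seq_len(n_panelists)),
               scale = "appropriateness", rating = rt$app),
        tibble(item_id = targets$item_id[i], domain = targets$domain[i],
               panelist_id = sprintf("R%02d", seq_len(n_panelists)),
               scale = "necessity", rating = rt$nec))
    }))
  } else {
    bind_rows(lapply(seq_len(nrow(targets)), function(i) {
      tibble(topic_id = targets$topic_id[i],
             panelist_id = sprintf("R%02d", seq_len(n_panelists)),
             rating = one_delphi(targets$target[i]))
    }))
  }
}
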