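# Criterion evaluation engine. Evaluation is three-valued: a predicate
# evaluates TRUE (flag), FALSE (no flag) or NA (a required input such as a
# dose-equivalence factor or risk score is unavailable -> flag with
# assessable = FALSE, never a crash). Evaluation is a pure function of
# (record, index_date, terminology, grace gap).

mg_per_day <- function(dose, unit) {
  ifelse(unit == "mcg/day", dose / 1000, dose)
}
dose_in_unit <- function(dose, unit, want) {
  if (want == "mcg/day") mg_per_day(dose, unit) * 1000 else
    mg_per_day(dose, unit)
}

# Per-patient evaluation context: everything primitives need, built once.
build_context <- function(cohort, patient_id, index_date, terminology,
                          grace_gap_days = 28, episodes = NULL) {
  p <- cohort$patients[cohort$patients$patient_id == patient_id, ]
  if (nrow(p) != 1) {
    abort(sprintf("unknown patient_id: %s", patient_id),
          class = "dqip_referential_error")
  }
  rx <- cohort$prescriptions[cohort$prescriptions$patient_id == patient_id, ]
  eps <- if (!is.null(episodes)) {
    episodes[episodes$patient_id == patient_id, ]
  } else {
    build_exposure_episodes(rx, grace_gap_days)
  }
  list(
    patient = p,
    conditions = cohort$conditions[cohort$conditions$patient_id ==
                                     patient_id, ],
    prescriptions = rx,
    observations = cohort$observations[cohort$observations$patient_id ==
                                         patient_id, ],
    episodes = eps,
    index_date = index_date,
    age = age_at(p$birth_date, index_date),
    term = terminology
  )
}

codes_of <- function(ctx, set) members(ctx$term, set)

active_codes_in <- function(ctx, set) {
  codes <- codes_of(ctx, set)
  eps <- ctx$episodes
  hit <- eps$drug_code %in% codes & eps$start_date <= ctx$index_date &
    eps$end_date > ctx$index_date
  unique(eps$drug_code[hit])
}

# latest issue at/before index for a drug code
latest_issue <- function(ctx, code) {
  rx <- ctx$prescriptions
  rx <- rx[rx$drug_code == code & rx$issue_date <= ctx$index_date, ]
  if (nrow(rx) == 0) return(rx)
  rx[which.max(rx$issue_date), ]
}

res <- function(value, evidence = character()) {
  list(value = value, evidence = evidence)
}

n_active_classes <- function(ctx, group, date) {
  groups <- ctx$term$class_groups[[group]]
  sum(map_lgl(groups, function(s)
    active_on(ctx$episodes, codes_of(ctx, s), date)))
}

# active set-drug doses in the requested unit; one row per active code
active_doses <- function(ctx, set, unit = "mg/day") {
  codes <- active_codes_in(ctx, set)
  out <- lapply(codes, function(cd) {
    li <- latest_issue(ctx, cd)
    if (nrow(li) == 0) return(NULL)
    tibble(drug_code = cd,
           dose = dose_in_unit(li$daily_dose, li$dose_unit, unit),
           raw_dose = li$daily_dose, raw_unit = li$dose_unit)
  })
  bind_rows(out)
}

eval_pred <- function(p, ctx) {
  idx <- ctx$index_date
  switch(
    p$op,
    all_of = {
      vals <- lapply(p$args, eval_pred, ctx = ctx)
      vs <- map_lgl(vals, "value")
      if (any(!vs, na.rm = TRUE)) return(res(FALSE))
      ev <- unlist(lapply(vals, `[[`, "evidence"))
      if (anyNA(vs)) res(NA, ev) else res(TRUE, ev)
    },
    any_of = {
      vals <- lapply(p$args, eval_pred, ctx = ctx)
      vs <- map_lgl(vals, "value")
      if (any(vs, na.rm = TRUE)) {
        hit <- which(vs)[1]
        return(res(TRUE, vals[[hit]]$evidence))
      }
      if (anyNA(vs)) res(NA) else res(FALSE)
    },
    not = {
      v <- eval_pred(p$args[[1]], ctx)
      res(!v$value, if (isFALSE(v$value))
        sprintf("absent:%s", deparse_pred(p$args[[1]])) else character())
    },
    age_ge = res(ctx$age >= p$years, sprintf("age=%d", ctx$age)),
    age_gt = res(ctx$age > p$years, sprintf("age=%d", ctx$age)),
    age_le = res(ctx$age <= p$years, sprintf("age=%d", ctx$age)),
    age_between = res(ctx$age >= p$lo & ctx$age <= p$hi,
                      sprintf("age=%d", ctx$age)),
    sex_is = res(identical(ctx$patient$sex, p$sex),
                 sprintf("sex=%s", ctx$patient$sex)),
    flag_is = res(isTRUE(ctx$patient[[p$flag]]), sprintf("flag:%s", p$flag)),
    flag_not = res(!isTRUE(ctx$patient[[p$flag]]),
                   sprintf("no-flag:%s", p$flag)),
    has_condition = {
      hit <- intersect(active_condition_codes(ctx$conditions, idx),
                       codes_of(ctx, p$set))
      res(length(hit) > 0, sprintf("condition:%s", hit))
    },
    lacks_condition = {
      hit <- intersect(active_condition_codes(ctx$conditions, idx),
                       codes_of(ctx, p$set))
      res(length(hit) == 0, sprintf("no-condition:%s", p$set))
    },
    condition_onset_within_months = {
      codes <- codes_of(ctx, p$set)
      cd <- ctx$conditions
      lo_edge <- idx %m-% months(as.integer(p$lo))
      hi_edge <- idx %m-% months(as.integer(p$hi))
      hit <- cd$code %in% codes & cd$onset_date >= hi_edge &
        cd$onset_date <= lo_edge
      res(any(hit), sprintf("onset:%s", unique(cd$code[hit])))
    },
    on_drug = {
      act <- active_codes_in(ctx, p$set)
      res(length(act) > 0, sprintf("on:%s", act))
    },
    exposure_weeks_gt = {
      w <- exposure_weeks_at(ctx$episodes, codes_of(ctx, p$set), idx)
      res(w > p$weeks, sprintf("exposure=%.1fw", w))
    },
    exposure_weeks_ge = {
      w <- exposure_weeks_at(ctx$episodes, codes_of(ctx, p$set), idx)
      res(w >= p$weeks, sprintf("exposure=%.1fw", w))
    },
    issues_in_window_ge = {
      n <- count_issues_in_window(ctx$prescriptions, codes_of(ctx, p$set),
                                  p$weeks, idx)
      res(n >= p$n, sprintf("issues=%d/%dw", n, p$weeks))
    },
    issues_in_window_eq = {
      n <- count_issues_in_window(ctx$prescriptions, codes_of(ctx, p$set),
                                  p$weeks, idx)
      res(n == p$n, sprintf("issues=%d/%dw", n, p$weeks))
    },
    never_prescribed = {
      rx <- ctx$prescriptions
      hit <- rx$drug_code %in% codes_of(ctx, p$set) & rx$issue_date <= idx
      if (!is.null(p$min_daily_dose)) {
        hit <- hit & mg_per_day(rx$daily_dose, rx$dose_unit) >=
          p$min_daily_dose
      }
      res(!any(hit), sprintf("no-prior:%s", p$set))
    },
    daily_dose_ge = {
      d <- active_doses(ctx, p$set, p$unit)
      if (nrow(d) == 0) return(res(FALSE))
      if (anyNA(d$dose) && !any(d$dose >= p$dose, na.rm = TRUE))
        return(res(NA))
      res(any(d$dose >= p$dose, na.rm = TRUE),
          sprintf("%s=%g%s", d$drug_code, d$dose, p$unit))
    },
    daily_dose_gt = {
      d <- active_doses(ctx, p$set, p$unit)
      if (nrow(d) == 0) return(res(FALSE))
      if (anyNA(d$dose) && !any(d$dose > p$dose, na.rm = TRUE))
        return(res(NA))
      res(any(d$dose > p$dose, na.rm = TRUE),
          sprintf("%s=%g%s", d$drug_code, d$dose, p$unit))
    },
    daily_dose_le = {
      d <- active_doses(ctx, p$set, p$unit)
      if (nrow(d) == 0) return(res(FALSE))
      if (anyNA(d$dose) && !any(d$dose <= p$dose, na.rm = TRUE))
        return(res(NA))
      res(any(d$dose <= p$dose, na.rm = TRUE),
          sprintf("%s=%g%s", d$drug_code, d$dose, p$unit))
    },
    equivalent_dose_ge = ,
    equivalent_dose_gt = {
      d <- active_doses(ctx, p$set, "mg/day")
      if (nrow(d) == 0) return(res(FALSE))
      eq <- map_dbl(seq_len(nrow(d)), function(i)
        equivalent_daily_dose(ctx$term, p$table, d$drug_code[i], d$dose[i]))
      ok <- if (p$op == "equivalent_dose_ge") eq >= p$dose else eq > p$dose
      if (any(ok, na.rm = TRUE)) {
        res(TRUE, sprintf("%s=%geq", d$drug_code, eq))
      } else if (anyNA(eq)) {
        res(NA)  # a factor was unavailable: not assessable
      } else {
        res(FALSE, sprintf("%s=%geq", d$drug_code, eq))
      }
    },
    below_target_dose = {
      d <- active_doses(ctx, p$set, "mg/day")
      if (nrow(d) == 0) return(res(FALSE))
      targets <- map_dbl(d$drug_code, function(cd)
        ctx$term$target_daily_dose[[cd]] %||% NA_real_)
      known <- !is.na(targets)
      # drugs without a published target cannot decide either way; judge
      # on those with known targets, not assessable when none is known
      if (!any(known)) return(res(NA))
      if (any(d$dose[known] >= targets[known])) return(res(FALSE))
      res(TRUE, sprintf("%s=%g<%g", d$drug_code[known], d$dose[known],
                        targets[known]))
    },
    strengths_gt_one = {
      rx <- ctx$prescriptions
      hit <- rx$drug_code %in% codes_of(ctx, p$set) &
        rx$issue_date <= idx & rx$issue_date + rx$days_supply > idx
      strengths <- unique(rx$strength[hit])
      strengths <- strengths[!is.na(strengths)]
      res(length(strengths) > 1,
          sprintf("strengths=%s", paste(strengths, collapse = "+")))
    },
    no_dose_instructions = {
      codes <- active_codes_in(ctx, p$set)
      if (length(codes) == 0) return(res(FALSE))
      latest <- bind_rows(lapply(codes, latest_issue, ctx = ctx))
      res(!any(latest$dose_instructions_recorded %in% TRUE),
          "no-dose-instructions")
    },
    no_observation_within = {
      obs <- latest_observation(ctx$observations, p$test, idx, p$weeks)
      res(nrow(obs) == 0,
          if (nrow(obs) == 0) sprintf("no-%s/%dw", p$test, p$weeks) else
            character())
    },
    no_observation_before_start = {
      starts <- map(p$sets, function(s) {
        eps <- ctx$episodes
        hit <- eps$drug_code %in% codes_of(ctx, s) &
          eps$start_date <= idx & eps$end_date > idx
        if (!any(hit)) NULL else min(eps$start_date[hit])
      })
      if (any(map_lgl(starts, is.null))) return(res(FALSE))
      start <- min(as.Date(unlist(starts), origin = "1970-01-01"))
      ob <- ctx$observations
      any_before <- any(ob$test_code == p$test & ob$date <= start)
      res(!any_before, sprintf("no-%s-before-%s", p$test, start))
    },
    no_observation_since_start = {
      starts <- map(p$sets, function(s) {
        eps <- ctx$episodes
        hit <- eps$drug_code %in% codes_of(ctx, s) &
          eps$start_date <= idx & eps$end_date > idx
        if (!any(hit)) NULL else min(eps$start_date[hit])
      })
      if (any(map_lgl(starts, is.null))) return(res(FALSE))
      start <- max(as.Date(unlist(starts), origin = "1970-01-01"))
      ob <- ctx$observations
      any_since <- any(ob$test_code == p$test & ob$date >= start &
                         ob$date <= idx)
      res(!any_since, sprintf("no-%s-since-%s", p$test, start))
    },
    obs_gt = {
      o <- latest_observation(ctx$observations, p$test, idx)
      if (nrow(o) == 0) return(res(FALSE))
      res(o$value > p$value, sprintf("%s=%g", p$test, o$value))
    },
    obs_ge = {
      o <- latest_observation(ctx$observations, p$test, idx)
      if (nrow(o) == 0) return(res(FALSE))
      res(o$value >= p$value, sprintf("%s=%g", p$test, o$value))
    },
    chads2_ge = ,
    chads2_eq = ,
    chads2_between = {
      s <- chads2(ctx$conditions, ctx$patient$birth_date, idx, ctx$term)
      val <- switch(p$op,
                    chads2_ge = s >= p$score,
                    chads2_eq = s == p$score,
                    chads2_between = s >= p$lo & s <= p$hi)
      res(val, sprintf("chads2=%d", s))
    },
    ckd_stage_in = {
      st <- ckd_stage(ctx$conditions, ctx$observations, idx, ctx$term)
      res(!is.na(st) && st %in% p$stages, sprintf("ckd=%s", st))
    },
    risk_score_gt = ,
    risk_score_ge = {
      v <- ctx$patient[[p$score_name]]
      if (is.null(v) || is.na(v)) return(res(NA))
      val <- if (p$op == "risk_score_gt") v > p$value else v >= p$value
      res(val, sprintf("%s=%g", p$score_name, v))
    },
    uncontrolled_bp = {
      lw <- ctx$term$params$obs_lookback_weeks
      o <- latest_observation(ctx$observations, "BP", idx, lw)
      if (nrow(o) == 0) return(res(FALSE))
      high <- isTRUE(o$value > p$systolic) ||
        isTRUE(!is.na(o$value2) && o$value2 > p$diastolic)
      if (!high) return(res(FALSE))
      resp_days <- ctx$term$params$intensification_response_weeks * 7
      if (as.numeric(idx - o$date) < resp_days) return(res(FALSE))
      k_now <- n_active_classes(ctx, "antihypertensive_classes", idx)
      k_then <- n_active_classes(ctx, "antihypertensive_classes", o$date)
      res(k_now < p$max_classes && k_now <= k_then,
          sprintf("BP=%g/%g on %d classes", o$value, o$value2, k_now))
    },
    uncontrolled_hba1c = {
      lw <- ctx$term$params$obs_lookback_weeks
      o <- latest_observation(ctx$observations, "HbA1c", idx, lw)
      if (nrow(o) == 0) return(res(FALSE))
      high <- if (!is.null(p$gt)) o$value > p$gt else
        o$value >= p$between[1] & o$value <= p$between[2]
      if (!isTRUE(high)) return(res(FALSE))
      resp_days <- ctx$term$params$intensification_response_weeks * 7
      if (as.numeric(idx - o$date) < resp_days) return(res(FALSE))
      k_now <- n_active_classes(ctx, "antidiabetic_classes", idx)
      k_then <- n_active_classes(ctx, "antidiabetic_classes", o$date)
      res(k_now < p$max_classes && k_now <= k_then,
          sprintf("HbA1c=%g on %d classes", o$value, k_now))
    },
    abort(sprintf("unknown predicate op: %s", p$op),
          class = "dqip_registry_error")
  )
}

#' Evaluate one criterion for one patient
#'
#' @param cohort A `dqip_cohort`.
#' @param criterion One row of a registry tibble.
#' @param patient_id Patient identifier.
#' @param index_date Date of assessment.
#' @param terminology A `dqip_terminology`.
#' @param grace_gap_days Exposure-episode grace gap (days).
#' @return A one-row flag tibble when the criterion fires (or is not
#'   assessable), otherwise a zero-row tibble. `assessable = FALSE` marks
#'   flags whose predicate could not be decided for lack of an input.
#' @export
evaluate_criterion <- function(cohort, criterion, patient_id, index_date,
                               terminology = default_terminology(),
                               grace_gap_days = 28) {
  ctx <- build_context(cohort, patient_id, index_date, terminology,
                       grace_gap_days)
  evaluate_criterion_ctx(criterion, ctx)
}

evaluate_criterion_ctx <- function(criterion, ctx) {
  out <- eval_pred(criterion$predicate[[1]], ctx)
  empty <- tibble(patient_id = character(), criterion_id = character(),
                  index_date = as.Date(character()), assessable = logical(),
                  evidence = list())
  if (isFALSE(out$value)) return(empty)
  tibble(patient_id = ctx$patient$patient_id,
         criterion_id = criterion$criterion_id,
         index_date = ctx$index_date,
         assessable = !is.na(out$value),
         evidence = list(out$evidence))
}

#' Screen a cohort against a criterion registry
#'
#' Evaluates every criterion for every patient at the index date and
#' returns one row per firing (patient, criterion) pair, ordered by
#' patient then criterion id. Per-patient evaluation failures are isolated
#' and reported as warnings, never propagated.
#'
#' @param cohort A `dqip_cohort`.
#' @param registry Registry tibble (default: the shipped 176 criteria).
#' @inheritParams evaluate_criterion
#' @return A `dqip_flags` tibble: `patient_id`, `criterion_id`,
#'   `topic_id`, `domain`, `category`, `necessity_label`,
#'   `delphi_priority`, `index_date`, `assessable`, `evidence`
#'   (list-column).
#' @export
screen_cohort <- function(cohort, registry = default_criteria(), index_date,
                          terminology = default_terminology(),
                          grace_gap_days = 28) {
  index_date <- as.Date(index_date)
  episodes <- build_exposure_episodes(cohort$prescriptions, grace_gap_days)
  rows <- lapply(sort(cohort$patients$patient_id), function(pid) {
    tryCatch({
      ctx <- build_context(cohort, pid, index_date, terminology,
                           grace_gap_days, episodes = episodes)
      bind_rows(lapply(seq_len(nrow(registry)), function(i)
        evaluate_criterion_ctx(registry[i, ], ctx)))
    }, error = function(e) {
      warn(sprintf("patient %s skipped: %s", pid, conditionMessage(e)))
      NULL
    })
  })
  flags <- bind_rows(rows)
  if (nrow(flags) == 0) {
    flags <- tibble(patient_id = character(), criterion_id = character(),
                    index_date = as.Date(character()),
                    assessable = logical(), evidence = list())
  }
  flags <- flags |>
    left_join(registry |>
                select("criterion_id", "topic_id", "domain", "category",
                       "necessity_label", "delphi_priority"),
              by = "criterion_id") |>
    arrange(.data$patient_id, .data$criterion_id)
  attr(flags, "n_patients") <- nrow(cohort$patients)
  attr(flags, "index_date") <- index_date
  class(flags) <- c("dqip_flags", class(flags))
  flags
}

#' Summarise screening flags by topic, category, domain and priority tier
#'
#' Assessable flags only: criteria that could not be assessed for a
#' patient are excluded from numerators and the patient proportion uses
#' the screened cohort size as denominator.
#'
#' @param flags A `dqip_flags` tibble from [screen_cohort()].
#' @param registry The registry screened against.
#' @return Named list of tibbles: `by_topic`, `by_category`, `by_domain`,
#'   `by_priority`, each with flag counts, patients affected and the
#'   proportion of screened patients affected.
#' @export
summarize_flags <- function(flags, registry = default_criteria()) {
  n_pat <- attr(flags, "n_patients") %||%
    length(unique(flags$patient_id))
  ok <- flags |> filter(.data$assessable)
  one <- function(...) {
    ok |>
      group_by(...) |>
      summarise(n_flags = n(),
                n_patients = length(unique(.data$patient_id)),
                .groups = "drop") |>
      mutate(prop_patients = if (n_pat > 0) .data$n_patients / n_pat else 0)
  }
  list(
    by_topic = one(.data$domain, .data$topic_id),
    by_category = one(.data$domain, .data$category),
    by_domain = one(.data$domain),
    by_priority = one(.data$domain, .data$delphi_priority),
    n_screened = n_pat
  )
}

#' Write screening flags as delimited text
#'
#' @param flags A `dqip_flags` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly. Evidence is serialised as JSON per row.
#' @export
write_flags <- function(flags, path) {
  out <- flags |>
    mutate(evidence_json = map_chr(.data$evidence, function(e)
      as.character(jsonlite::toJSON(e)))) |>
    select(-"evidence")
  readr::write_csv(out, path)
  invisible(path)
}
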