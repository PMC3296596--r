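# Predicate expression language for assessment criteria. A predicate is a
# finite tree of named-list nodes: combinators (all_of / any_of / not) over
# a fixed vocabulary of clinical primitives. Trees are data (serialised to
# JSON with the registry), evaluated by the engine and inverted by the
# synthetic-case planter, so every primitive has exactly three behaviours:
# evaluate, satisfy, violate.

leaf <- function(op, ...) {
  node <- c(list(op = op), list(...))
  structure(node, class = "dqip_pred")
}

#' Predicate constructors
#'
#' Constructors for the predicate trees used by assessment criteria. The
#' combinators are `p_all()` (conjunction; its children are the criterion's
#' clauses), `p_any()` (disjunction) and `p_not()` (negation; also the
#' encoding of "unless" exclusion clauses). The leaves cover the clause
#' vocabulary of the instrument: demographics, active conditions, drug
#' exposure (episode membership, duration, dose, issue counts), laboratory
#' monitoring windows, derived scores (CHADS2, CKD stage, 10-year CVD
#' risk) and the treatment-intensification composites.
#'
#' @param ... Child predicate nodes.
#' @return A `dqip_pred` node.
#' @name predicates
NULL

#' @rdname predicates
#' @export
p_all <- function(...) leaf("all_of", args = list(...))
#' @rdname predicates
#' @export
p_any <- function(...) leaf("any_of", args = list(...))
#' @rdname predicates
#' @export
p_not <- function(x) leaf("not", args = list(x))

#' @rdname predicates
#' @param years,lo,hi Age bounds in completed years.
#' @export
age_ge <- function(years) leaf("age_ge", years = years)
#' @rdname predicates
#' @export
age_gt <- function(years) leaf("age_gt", years = years)
#' @rdname predicates
#' @export
age_le <- function(years) leaf("age_le", years = years)
#' @rdname predicates
#' @export
age_between <- function(lo, hi) leaf("age_between", lo = lo, hi = hi)
#' @rdname predicates
#' @param sex `"female"` or `"male"`.
#' @export
sex_is <- function(sex) leaf("sex_is", sex = sex)
#' @rdname predicates
#' @param flag Patient status flag name (`"housebound"`, `"nursing_home"`,
#'   `"hysterectomy"`).
#' @export
flag_is <- function(flag) leaf("flag_is", flag = flag)
#' @rdname predicates
#' @export
flag_not <- function(flag) leaf("flag_not", flag = flag)

#' @rdname predicates
#' @param set A registered condition- or drug-code set id.
#' @export
has_condition <- function(set) leaf("has_condition", set = set)
#' @rdname predicates
#' @export
lacks_condition <- function(set) leaf("lacks_condition", set = set)
#' @rdname predicates
#' @param lo_months,hi_months Onset window bounds: onset between
#'   `hi_months` and `lo_months` months before the index date.
#' @export
condition_onset_within_months <- function(set, lo_months, hi_months) {
  leaf("condition_onset_within_months", set = set, lo = lo_months,
       hi = hi_months)
}

#' @rdname predicates
#' @export
on_drug <- function(set) leaf("on_drug", set = set)
#' @rdname predicates
#' @param weeks Duration / window length in weeks.
#' @export
exposure_weeks_gt <- function(set, weeks) {
  leaf("exposure_weeks_gt", set = set, weeks = weeks)
}
#' @rdname predicates
#' @export
exposure_weeks_ge <- function(set, weeks) {
  leaf("exposure_weeks_ge", set = set, weeks = weeks)
}
#' @rdname predicates
#' @param n Issue count threshold.
#' @export
issues_in_window_ge <- function(set, n, weeks) {
  leaf("issues_in_window_ge", set = set, n = n, weeks = weeks)
}
#' @rdname predicates
#' @export
issues_in_window_eq <- function(set, n, weeks) {
  leaf("issues_in_window_eq", set = set, n = n, weeks = weeks)
}
#' @rdname predicates
#' @param min_daily_dose Optional minimum daily dose (mg/day) for an issue
#'   to count as a prior trial.
#' @export
never_prescribed <- function(set, min_daily_dose = NULL) {
  leaf("never_prescribed", set = set, min_daily_dose = min_daily_dose)
}

#' @rdname predicates
#' @param dose Dose threshold.
#' @param unit Dose unit, `"mg/day"` or `"mcg/day"`.
#' @export
daily_dose_ge <- function(set, dose, unit = "mg/day") {
  leaf("daily_dose_ge", set = set, dose = dose, unit = unit)
}
#' @rdname predicates
#' @export
daily_dose_gt <- function(set, dose, unit = "mg/day") {
  leaf("daily_dose_gt", set = set, dose = dose, unit = unit)
}
#' @rdname predicates
#' @export
daily_dose_le <- function(set, dose, unit = "mg/day") {
  leaf("daily_dose_le", set = set, dose = dose, unit = unit)
}
#' @rdname predicates
#' @param table Dose-equivalence table id.
#' @export
equivalent_dose_ge <- function(set, dose, table) {
  leaf("equivalent_dose_ge", set = set, dose = dose, table = table)
}
#' @rdname predicates
#' @export
equivalent_dose_gt <- function(set, dose, table) {
  leaf("equivalent_dose_gt", set = set, dose = dose, table = table)
}
#' @rdname predicates
#' @export
below_target_dose <- function(set) leaf("below_target_dose", set = set)
#' @rdname predicates
#' @export
strengths_gt_one <- function(set) leaf("strengths_gt_one", set = set)
#' @rdname predicates
#' @export
no_dose_instructions <- function(set) leaf("no_dose_instructions", set = set)

#' @rdname predicates
#' @param test Observation test code (`"UE"`, `"FBC"`, `"TFT"`, `"BP"`,
#'   `"HbA1c"`, `"eGFR"`, `"BMI"`, `"ACR"`).
#' @export
no_observation_within <- function(test, weeks) {
  leaf("no_observation_within", test = test, weeks = weeks)
}
#' @rdname predicates
#' @param sets For the treatment-start monitoring leaves: drug set id(s)
#'   whose episode start anchors the baseline window.
#' @export
no_observation_before_start <- function(test, sets) {
  leaf("no_observation_before_start", test = test, sets = sets)
}
#' @rdname predicates
#' @export
no_observation_since_start <- function(test, sets) {
  leaf("no_observation_since_start", test = test, sets = sets)
}
#' @rdname predicates
#' @param value Observation value threshold.
#' @export
obs_gt <- function(test, value) leaf("obs_gt", test = test, value = value)
#' @rdname predicates
#' @export
obs_ge <- function(test, value) leaf("obs_ge", test = test, value = value)

#' @rdname predicates
#' @param score CHADS2 score bound.
#' @export
chads2_ge <- function(score) leaf("chads2_ge", score = score)
#' @rdname predicates
#' @export
chads2_eq <- function(score) leaf("chads2_eq", score = score)
#' @rdname predicates
#' @export
chads2_between <- function(lo, hi) leaf("chads2_between", lo = lo, hi = hi)
#' @rdname predicates
#' @param stages Integer CKD stages, subset of 3:5.
#' @export
ckd_stage_in <- function(stages) leaf("ckd_stage_in", stages = stages)
#' @rdname predicates
#' @param score_name Risk score field name (`"cvd10y_percent"`).
#' @param value Risk score threshold (percent).
#' @export
risk_score_gt <- function(score_name, value) {
  leaf("risk_score_gt", score_name = score_name, value = value)
}
#' @rdname predicates
#' @export
risk_score_ge <- function(score_name, value) {
  leaf("risk_score_ge", score_name = score_name, value = value)
}

#' @rdname predicates
#' @param systolic,diastolic BP thresholds, mmHg; the latest reading is
#'   uncontrolled when either systolic or diastolic exceeds its threshold.
#' @param max_classes The criterion applies while the patient is on fewer
#'   than `max_classes` distinct antihypertensive / oral antidiabetic drug
#'   classes (`1` encodes "without treatment").
#' @export
uncontrolled_bp <- function(systolic, diastolic, max_classes) {
  leaf("uncontrolled_bp", systolic = systolic, diastolic = diastolic,
       max_classes = max_classes)
}
#' @rdname predicates
#' @param gt HbA1c threshold (%): latest value strictly above fires.
#' @param between Length-2 numeric: latest value within `[lo, hi]` fires.
#' @export
uncontrolled_hba1c <- function(gt = NULL, between = NULL, max_classes) {
  leaf("uncontrolled_hba1c", gt = gt, between = between,
       max_classes = max_classes)
}

# low-dose aspirin = on aspirin at <= the configured ceiling (150 mg/day)
#' @rdname predicates
#' @export
low_dose_aspirin <- function() {
  p_all(on_drug("ASPIRIN"), daily_dose_le("ASPIRIN", 150))
}

#' @export
print.dqip_pred <- function(x, ...) {
  cat(deparse_pred(x), "\n")
  invisible(x)
}

deparse_pred <- function(p) {
  if (p$op %in% c("all_of", "any_of")) {
    inner <- paste(map_chr(p$args, deparse_pred), collapse = ", ")
    sprintf("%s(%s)", toupper(sub("_of", "", p$op)), inner)
  } else if (p$op == "not") {
    sprintf("NOT(%s)", deparse_pred(p$args[[1]]))
  } else {
    params <- p[setdiff(names(p), "op")]
    params <- params[!map_lgl(params, is.null)]
    sprintf("%s(%s)", p$op,
            paste(map_chr(params, function(v)
              paste(format(v), collapse = "|")), collapse = ", "))
  }
}

# All code-set ids referenced anywhere in a predicate tree
pred_set_ids <- function(p) {
  if (p$op %in% c("all_of", "any_of", "not")) {
    unique(unlist(lapply(p$args, pred_set_ids)))
  } else {
    unique(c(p$set, p$sets))
  }
}

pred_to_list <- function(p) {
  if (p$op %in% c("all_of", "any_of", "not")) {
    list(op = p$op, args = lapply(p$args, pred_to_list))
  } else {
    p2 <- unclass(p)
    p2[!vapply(p2, is.null, logical(1))]
  }
}

pred_from_list <- function(x) {
  if (x$op %in% c("all_of", "any_of", "not")) {
    structure(list(op = x$op, args = lapply(x$args, pred_from_list)),
              class = "dqip_pred")
  } else {
    x <- lapply(x, function(v) {
      if (is.list(v)) v <- unlist(v)
      if (is.integer(v)) v <- as.numeric(v)
      v
    })
    structure(x, class = "dqip_pred")
  }
}
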