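#' Read a patient cohort from delimited-text tables
#'
#' A cohort is held as four linked tibbles sharing a `patient_id` key:
#' patients (demographics, optional risk scores and status flags),
#' condition events, prescription events and laboratory/observation events.
#' All dates are ISO-8601 and parsed to day precision.
#'
#' Column contract (mandatory columns marked *):
#' \describe{
#'   \item{patients}{`patient_id`*, `sex`* ("female"/"male"), `birth_date`*;
#'     optional `cvd10y_percent` (numeric, percent), logical flags
#'     `housebound`, `nursing_home`, `hysterectomy`.}
#'   \item{conditions}{`patient_id`*, `code`*, `onset_date`*; optional
#'     `resolved_date`.}
#'   \item{prescriptions}{`patient_id`*, `drug_code`*, `issue_date`*,
#'     `days_supply`*, `daily_dose`*, `dose_unit`* ("mg/day" or "mcg/day");
#'     optional `strength`, `dose_instructions_recorded` (logical).}
#'   \item{observations}{`patient_id`*, `test_code`*, `date`*, `value`*;
#'     optional `value2` (diastolic BP), `unit`.}
#' }
#'
#' A missing `days_supply` value (NA) is imputed with
#' `default_days_supply` and the imputation is reported via a message.
#'
#' @param patients_path,conditions_path,prescriptions_path,observations_path
#'   Paths to the four delimited-text tables (comma-separated).
#' @param default_days_supply Days of coverage imputed when `days_supply`
#'   is missing for a row. Default 28 (typical UK repeat cycle).
#' @return A `dqip_cohort`: a named list of the four validated tibbles.
#' @export
read_cohort <- function(patients_path, conditions_path, prescriptions_path,
                        observations_path, default_days_supply = 28) {
  read1 <- function(path) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  new_cohort(
    patients      = read1(patients_path),
    conditions    = read1(conditions_path),
    prescriptions = read1(prescriptions_path),
    observations  = read1(observations_path),
    default_days_supply = default_days_supply
  )
}

#' Assemble and validate a cohort from in-memory tables
#'
#' @param patients,conditions,prescriptions,observations Data frames
#'   following the column contract of [read_cohort()].
#' @inheritParams read_cohort
#' @return A validated `dqip_cohort` object.
#' @export
new_cohort <- function(patients, conditions = NULL, prescriptions = NULL,
                       observations = NULL, default_days_supply = 28) {
  empty_tbl <- list(
    conditions = tibble(patient_id = character(), code = character(),
                        onset_date = as.Date(character()),
                        resolved_date = as.Date(character())),
    prescriptions = tibble(patient_id = character(), drug_code = character(),
                           issue_date = as.Date(character()),
                           days_supply = integer(), daily_dose = double(),
                           dose_unit = character(), strength = double(),
                           dose_instructions_recorded = logical()),
    observations = tibble(patient_id = character(), test_code = character(),
                          date = as.Date(character()), value = double(),
                          value2 = double(), unit = character())
  )
  conditions    <- conditions %||% empty_tbl$conditions
  prescriptions <- prescriptions %||% empty_tbl$prescriptions
  observations  <- observations %||% empty_tbl$observations

  require_cols <- function(df, cols, table) {
    missing <- setdiff(cols, names(df))
    if (length(missing)) {
      abort(sprintf("cohort schema error: table '%s' lacks column(s): %s",
                    table, paste(missing, collapse = ", ")),
            class = "dqip_schema_error")
    }
  }
  require_cols(patients, c("patient_id", "sex", "birth_date"), "patients")
  require_cols(conditions, c("patient_id", "code", "onset_date"), "conditions")
  require_cols(prescriptions,
               c("patient_id", "drug_code", "issue_date", "days_supply",
                 "daily_dose", "dose_unit"), "prescriptions")
  require_cols(observations, c("patient_id", "test_code", "date", "value"),
               "observations")

  parse_date_col <- function(df, col, table) {
    x <- df[[col]]
    if (inherits(x, "Date")) return(df)
    parsed <- as.Date(as.character(x), format = "%Y-%m-%d")
    bad <- which(!is.na(x) & is.na(parsed))
    if (length(bad)) {
      abort(sprintf("unparseable date in table '%s', column '%s', row %d: '%s'",
                    table, col, bad[1], as.character(x[bad[1]])),
            class = "dqip_parse_error")
    }
    df[[col]] <- parsed
    df
  }
  patients <- parse_date_col(patients, "birth_date", "patients")
  conditions <- parse_date_col(conditions, "onset_date", "conditions")
  if (!"resolved_date" %in% names(conditions)) {
    conditions$resolved_date <- as.Date(NA)
  } else {
    conditions <- parse_date_col(conditions, "resolved_date", "conditions")
  }
  prescriptions <- parse_date_col(prescriptions, "issue_date", "prescriptions")
  observations <- parse_date_col(observations, "date", "observations")

  patients <- as_tibble(patients)
  for (fl in c("housebound", "nursing_home", "hysterectomy")) {
    if (!fl %in% names(patients)) patients[[fl]] <- FALSE
    patients[[fl]] <- as.logical(patients[[fl]]) %in% TRUE
  }
  if (!"cvd10y_percent" %in% names(patients)) {
    patients$cvd10y_percent <- NA_real_
  }
  if (anyDuplicated(patients$patient_id)) {
    abort("duplicate patient_id in patients table",
          class = "dqip_referential_error")
  }
  bad_sex <- setdiff(unique(patients$sex), c("female", "male"))
  if (length(bad_sex)) {
    abort(sprintf("invalid sex value(s): %s", paste(bad_sex, collapse = ", ")),
          class = "dqip_schema_error")
  }

  if (!"strength" %in% names(prescriptions)) prescriptions$strength <- NA_real_
  if (!"dose_instructions_recorded" %in% names(prescriptions)) {
    prescriptions$dose_instructions_recorded <- NA
  }
  n_imputed <- sum(is.na(prescriptions$days_supply))
  if (n_imputed > 0) {
    inform(sprintf("imputed days_supply = %d for %d prescription row(s)",
                   default_days_supply, n_imputed))
    prescriptions$days_supply[is.na(prescriptions$days_supply)] <-
      default_days_supply
  }
  if (nrow(prescriptions) && any(prescriptions$days_supply <= 0)) {
    abort("days_supply must be positive", class = "dqip_schema_error")
  }
  if (!"value2" %in% names(observations)) observations$value2 <- NA_real_
  if (!"unit" %in% names(observations)) observations$unit <- NA_character_

  check_ref <- function(df, table, date_col) {
    unknown <- setdiff(df$patient_id, patients$patient_id)
    if (length(unknown)) {
      abort(sprintf("referential error: table '%s' references unknown patient(s): %s",
                    table, paste(head(unknown, 3), collapse = ", ")),
            class = "dqip_referential_error")
    }
    birth <- patients$birth_date[match(df$patient_id, patients$patient_id)]
    pre_birth <- which(df[[date_col]] < birth)
    if (length(pre_birth)) {
      abort(sprintf("referential error: table '%s' row %d dated before patient birth_date",
                    table, pre_birth[1]),
            class = "dqip_referential_error")
    }
  }
  check_ref(conditions, "conditions", "onset_date")
  check_ref(prescriptions, "prescriptions", "issue_date")
  check_ref(observations, "observations", "date")
  if (nrow(conditions) &&
      any(!is.na(conditions$resolved_date) &
          conditions$resolved_date < conditions$onset_date)) {
    abort("resolved_date before onset_date in conditions table",
          class = "dqip_schema_error")
  }

  prescriptions$rx_id <- seq_len(nrow(prescriptions))

  structure(
    list(patients = patients, conditions = as_tibble(conditions),
         prescriptions = as_tibble(prescriptions),
         observations = as_tibble(observations)),
    class = "dqip_cohort"
  )
}

#' @export
print.dqip_cohort <- function(x, ...) {
  rng <- suppressWarnings(range(c(x$conditions$onset_date,
                                  x$prescriptions$issue_date,
                                  x$observations$date), na.rm = TRUE))
  cat("<dqip_cohort>\n")
  cat(sprintf("  patients:      %d\n", nrow(x$patients)))
  cat(sprintf("  conditions:    %d\n", nrow(x$conditions)))
  cat(sprintf("  prescriptions: %d\n", nrow(x$prescriptions)))
  cat(sprintf("  observations:  %d\n", nrow(x$observations)))
  if (is.finite(suppressWarnings(as.numeric(rng[1])))) {
    cat(sprintf("  event dates:   %s to %s\n", rng[1], rng[2]))
  }
  invisible(x)
}

#' Cohort summary counts
#'
#' @param object A `dqip_cohort`.
#' @param ... Unused.
#' @return A one-row tibble of table sizes and the event date range.
#' @export
summary.dqip_cohort <- function(object, ...) {
  dates <- c(object$conditions$onset_date, object$prescriptions$issue_date,
             object$observations$date)
  tibble(
    n_patients = nrow(object$patients),
    n_conditions = nrow(object$conditions),
    n_prescriptions = nrow(object$prescriptions),
    n_observations = nrow(object$observations),
    first_event = if (length(dates)) min(dates) else as.Date(NA),
    last_event = if (length(dates)) max(dates) else as.Date(NA)
  )
}

#' Build continuous drug exposure episodes from prescription issues
#'
#' Consecutive prescriptions of the same drug code are merged into one
#' episode of continuous exposure when the gap between the end of one
#' coverage interval (`issue_date + days_supply`) and the next issue date
#' is at most `grace_gap_days`. Episodes are half-open day intervals
#' `[start_date, end_date)`.
#'
#' @param prescriptions Tibble of prescription events (one patient's or
#'   many; episodes are built within `patient_id` x `drug_code`).
#' @param grace_gap_days Maximum permitted coverage gap, in days, for two
#'   issues to count as continuous exposure. Default 28, the typical UK
#'   repeat-prescription cycle.
#' @return Tibble with `patient_id`, `drug_code`, `start_date`, `end_date`,
#'   `rx_ids` (list-column of contributing prescription row ids).
#' @export
build_exposure_episodes <- function(prescriptions, grace_gap_days = 28) {
  stopifnot(grace_gap_days >= 0)
  if (is.null(prescriptions) || nrow(prescriptions) == 0) {
    return(tibble(patient_id = character(), drug_code = character(),
                  start_date = as.Date(character()),
                  end_date = as.Date(character()), rx_ids = list()))
  }
  if (!"patient_id" %in% names(prescriptions)) {
    prescriptions$patient_id <- "(single)"
  }
  if (!"rx_id" %in% names(prescriptions)) {
    prescriptions$rx_id <- seq_len(nrow(prescriptions))
  }
  prescriptions |>
    arrange(.data$patient_id, .data$drug_code, .data$issue_date) |>
    group_by(.data$patient_id, .data$drug_code) |>
    group_modify(function(df, key) {
      start <- df$issue_date
      end <- df$issue_date + df$days_supply
      # a new episode begins when the issue follows the running coverage
      # end by more than the grace gap
      run_end <- as.Date(cummax(as.integer(end)), origin = "1970-01-01")
      breaks <- c(TRUE, start[-1] > run_end[-length(run_end)] + grace_gap_days)
      ep <- cumsum(breaks)
      tibble(
        start_date = as.Date(as.vector(tapply(start, ep, min)),
                             origin = "1970-01-01"),
        end_date = as.Date(as.vector(tapply(end, ep, max)),
                           origin = "1970-01-01"),
        rx_ids = unname(lapply(split(df$rx_id, ep), identity))
      )
    }) |>
    ungroup()
}

#' Is the patient exposed to any drug in a set on a given date?
#'
#' @param episodes Episode tibble from [build_exposure_episodes()].
#' @param drug_codes Character vector of drug codes (a resolved code set).
#' @param index_date The date of assessment.
#' @return `TRUE` iff some episode for a code in the set contains
#'   `index_date` (episodes are half-open: start inclusive, end exclusive).
#' @export
active_on <- function(episodes, drug_codes, index_date) {
  any(episodes$drug_code %in% drug_codes &
        episodes$start_date <= index_date &
        episodes$end_date > index_date)
}

#' Weeks of continuous exposure at the index date
#'
#' Length, in weeks, from the start of the episode containing `index_date`
#' to `index_date`, for drugs in the given set. 0 when not currently
#' exposed. When several codes in the set are active the longest-running
#' exposure is returned.
#'
#' @inheritParams active_on
#' @return Numeric weeks (possibly fractional).
#' @export
exposure_weeks_at <- function(episodes, drug_codes, index_date) {
  hit <- episodes$drug_code %in% drug_codes &
    episodes$start_date <= index_date & episodes$end_date > index_date
  if (!any(hit)) return(0)
  max(as.numeric(index_date - episodes$start_date[hit]) / 7)
}

#' Count prescription issues in a trailing window
#'
#' Counts issues with a drug code in the set and
#' `issue_date` in `[index_date - window_weeks*7, index_date]` (the
#' boundary day is included).
#'
#' @param prescriptions Prescription tibble.
#' @inheritParams active_on
#' @param window_weeks Positive window length in weeks.
#' @return Integer count.
#' @export
count_issues_in_window <- function(prescriptions, drug_codes, window_weeks,
                                   index_date) {
  stopifnot(window_weeks > 0)
  sum(prescriptions$drug_code %in% drug_codes &
        prescriptions$issue_date >= index_date - window_weeks * 7 &
        prescriptions$issue_date <= index_date)
}

#' Most recent observation of a test within a lookback window
#'
#' @param observations Observation tibble.
#' @param test_code Test code, e.g. `"UE"`, `"FBC"`, `"TFT"`, `"HbA1c"`,
#'   `"BP"`, `"eGFR"`.
#' @param index_date The date of assessment.
#' @param lookback_weeks Lookback length in weeks; `Inf` for unbounded.
#'   The boundary day (`index_date - lookback_weeks*7`) is included.
#' @return A one-row tibble (the most recent matching observation), or a
#'   zero-row tibble when none qualifies.
#' @export
latest_observation <- function(observations, test_code, index_date,
                               lookback_weeks = Inf) {
  stopifnot(lookback_weeks > 0)
  lo <- if (is.finite(lookback_weeks)) index_date - lookback_weeks * 7 else
    as.Date("0001-01-01")
  hit <- observations |>
    filter(.data$test_code == .env$test_code,
           .data$date >= lo, .data$date <= index_date)
  if (nrow(hit) == 0) return(hit)
  hit |> slice_max(.data$date, n = 1, with_ties = FALSE)
}

#' Age in completed years at a date
#'
#' "Aged >= 65" means the 65th birthday falls on or before the index date.
#'
#' @param birth_date,index_date Dates.
#' @return Integer age in completed years.
#' @export
age_at <- function(birth_date, index_date) {
  floor(lubridate::time_length(lubridate::interval(birth_date, index_date),
                               unit = "years"))
}
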