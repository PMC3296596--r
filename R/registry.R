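# Criterion registry: construction, validation, summaries and file I/O.
# The shipped instrument has 52 quality criteria (Q-001..Q-052) and 124
# safety criteria (S-001..S-124); ids follow the row numbers of the
# instrument's published listing.

# Delphi priority tier of each improvement topic (second-round medians):
# ++ = high (median 8-9), + = priority (median 7), blank = rejected.
topic_priority_map <- function() {
  c(
    Q1 = "rejected", Q2 = "priority", Q3 = "priority", Q4 = "high",
    Q5 = "high", Q6 = "priority", Q7 = "priority", Q8 = "priority",
    Q9 = "priority", Q10 = "priority", Q11 = "high", Q12 = "high",
    Q13 = "rejected", Q14 = "high", Q15 = "high", Q16 = "high",
    Q17 = "priority", Q18 = "rejected",
    S1 = "high", S2 = "rejected", S3 = "high", S4 = "priority",
    S5 = "priority", S6 = "priority", S7 = "priority", S8 = "rejected",
    S9 = "rejected", S10 = "priority", S11 = "rejected", S12 = "rejected",
    S13 = "priority", S14 = "priority", S15 = "priority", S16 = "priority",
    S17 = "priority", S18 = "priority", S19 = "priority", S20 = "high",
    S21 = "high", S22 = "rejected", S23 = "priority", S24 = "priority",
    S25 = "priority", S26 = "priority", S27 = "priority", S28 = "priority",
    S29 = "priority"
  )
}

# derive explicit age / sex restrictions from the predicate's top clauses
derive_restrictions <- function(pred) {
  out <- list(age_min = NA_real_, age_max = NA_real_,
              sex = NA_character_)
  clauses <- if (pred$op == "all_of") pred$args else list(pred)
  for (cl in clauses) {
    if (cl$op == "age_ge") out$age_min <- cl$years
    if (cl$op == "age_gt") out$age_min <- cl$years + 1
    if (cl$op == "age_le") out$age_max <- cl$years
    if (cl$op == "age_between") { out$age_min <- cl$lo; out$age_max <- cl$hi }
    if (cl$op == "sex_is") out$sex <- cl$sex
  }
  out
}

crit <- function(id, domain, category, necessity, topic, event, text, pred) {
  restr <- derive_restrictions(pred)
  tier <- topic_priority_map()[[topic]] %||% "unscored"
  tibble(
    criterion_id = id, domain = domain, category = category,
    necessity_label = necessity, topic_id = topic,
    delphi_priority = tier,
    age_min = restr$age_min, age_max = restr$age_max,
    sex_restriction = restr$sex,
    associated_event = event, source_text = text,
    predicate = list(pred)
  )
}

#' The shipped registry of 176 assessment criteria
#'
#' Returns the full instrument: 52 prescribing-quality criteria (flagging
#' under-use, wrong first-line selection or insufficient intensity of
#' beneficial treatment) and 124 prescribing-safety criteria (high-risk
#' drug use, missing risk-mitigating co-therapy, excessive dose or
#' duration, compliance hazards and inconsistent laboratory monitoring).
#' Each row carries taxonomy metadata (domain, MQ/MS category, panel
#' necessity label, improvement topic and its Delphi priority tier),
#' any age/sex restriction, a plain-language statement and the executable
#' predicate tree. A flag is raised when the predicate holds, so quality
#' criteria encode the *unmet* care state and safety criteria the hazard
#' state, with "unless" exclusions as negated clauses.
#'
#' @return A `dqip_registry` tibble, one row per criterion.
#' @export
default_criteria <- function() {
  reg <- bind_rows(quality_criteria(), safety_criteria())
  class(reg) <- c("dqip_registry", class(reg))
  reg
}

#' Validate a criterion registry
#'
#' Checks structural invariants (unique ids, known categories and
#' necessity labels, every referenced code set resolvable against the
#' terminology) and reports data anomalies carried verbatim from the
#' published instrument (a safety criterion tagged with the quality-domain
#' label "A").
#'
#' @param registry A registry tibble from [default_criteria()] or
#'   [read_criteria()].
#' @param terminology Terminology used to resolve code-set references.
#' @return A tibble of findings with columns `criterion_id`, `severity`
#'   (`"error"`/`"warning"`), `message`; zero rows when fully clean.
#'   Errors abort.
#' @export
validate_registry <- function(registry,
                              terminology = default_terminology()) {
  findings <- list()
  dup <- registry$criterion_id[duplicated(registry$criterion_id)]
  if (length(dup)) {
    abort(sprintf("duplicate criterion_id: %s", paste(dup, collapse = ", ")),
          class = "dqip_registry_error")
  }
  bad_cat <- registry |>
    filter(!(.data$domain == "quality" &
               .data$category %in% paste0("MQ", 1:4)) &
             !(.data$domain == "safety" &
                 .data$category %in% paste0("MS", 1:8)))
  if (nrow(bad_cat)) {
    abort(sprintf("criterion %s has category outside the taxonomy",
                  bad_cat$criterion_id[1]), class = "dqip_registry_error")
  }
  unresolved <- character()
  for (i in seq_len(nrow(registry))) {
    ids <- pred_set_ids(registry$predicate[[i]])
    missing <- ids[!ids %in% names(terminology$code_sets)]
    if (length(missing)) {
      unresolved <- c(unresolved,
                      sprintf("%s: %s", registry$criterion_id[i],
                              paste(missing, collapse = ", ")))
    }
  }
  if (length(unresolved)) {
    abort(paste0("unresolvable code set id(s):\n",
                 paste(unresolved, collapse = "\n")),
          class = "dqip_registry_error")
  }
  anomalies <- registry |>
    filter(.data$domain == "safety" & !.data$necessity_label %in% c("I", "N"))
  for (id in anomalies$criterion_id) {
    findings[[length(findings) + 1]] <- tibble(
      criterion_id = id, severity = "warning",
      message = "safety criterion carries a quality-domain label (stored verbatim)")
  }
  if (length(findings)) bind_rows(findings) else
    tibble(criterion_id = character(), severity = character(),
           message = character())
}

#' Registry contingency summaries
#'
#' Tabulates criteria by domain, MQ/MS category, necessity label, Delphi
#' priority tier and minimum-age restriction; the margins reproduce the
#' published instrument tallies (e.g. 26 quality criteria in MQ1, 20
#' safety criteria in MS8, necessity splits 40/12 and 107/17).
#'
#' @param registry A registry tibble.
#' @return Named list of count tibbles: `by_domain`,
#'   `by_category` (domain x category x necessity), `by_necessity`,
#'   `by_priority`, `by_age_restriction`.
#' @export
registry_summary <- function(registry) {
  reg <- registry |>
    mutate(necessity_group = ifelse(.data$necessity_label == "N",
                                    "necessary", "other"))
  by_category <- reg |>
    count(.data$domain, .data$category, .data$necessity_group) |>
    tidyr::pivot_wider(names_from = "necessity_group", values_from = "n",
                       values_fill = 0L)
  for (col in c("necessary", "other")) {
    if (!col %in% names(by_category)) by_category[[col]] <- 0L
  }
  by_category <- by_category |>
    mutate(total = .data$necessary + .data$other) |>
    arrange(.data$domain, .data$category)
  list(
    by_domain = reg |> count(.data$domain),
    by_category = by_category,
    by_necessity = reg |> count(.data$domain, .data$necessity_label),
    by_priority = reg |> count(.data$domain, .data$delphi_priority),
    by_age_restriction = reg |>
      filter(!is.na(.data$age_min)) |> count(.data$domain, .data$age_min)
  )
}

#' Write / read a criteria registry as JSON
#'
#' The file carries full metadata plus the predicate tree for each
#' criterion; `read_criteria(write_criteria(x))` round-trips identically.
#'
#' @param registry A registry tibble.
#' @param path File path.
#' @return `read_criteria()` returns a `dqip_registry` tibble.
#' @export
write_criteria <- function(registry, path) {
  rows <- lapply(seq_len(nrow(registry)), function(i) {
    r <- registry[i, ]
    list(criterion_id = r$criterion_id, domain = r$domain,
         category = r$category, necessity_label = r$necessity_label,
         topic_id = r$topic_id, delphi_priority = r$delphi_priority,
         age_min = r$age_min, age_max = r$age_max,
         sex_restriction = r$sex_restriction,
         associated_event = r$associated_event,
         source_text = r$source_text,
         predicate = pred_to_list(r$predicate[[1]]))
  })
  jsonlite::write_json(rows, path, auto_unbox = TRUE, pretty = FALSE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_criteria
#' @param terminology Terminology used to validate code-set references.
#' @export
read_criteria <- function(path = system.file("extdata",
                                             c("criteria_quality.json",
                                               "criteria_safety.json"),
                                             package = "dqipr"),
                          terminology = default_terminology()) {
  rows <- do.call(c, lapply(path, jsonlite::read_json))
  reg <- bind_rows(lapply(rows, function(r) {
    tibble(
      criterion_id = r$criterion_id, domain = r$domain,
      category = r$category, necessity_label = r$necessity_label,
      topic_id = r$topic_id, delphi_priority = r$delphi_priority,
      age_min = r$age_min %||% NA_real_,
      age_max = r$age_max %||% NA_real_,
      sex_restriction = r$sex_restriction %||% NA_character_,
      associated_event = r$associated_event,
      source_text = r$source_text,
      predicate = list(pred_from_list(r$predicate))
    )
  }))
  reg$age_min <- as.numeric(reg$age_min)
  reg$age_max <- as.numeric(reg$age_max)
  class(reg) <- c("dqip_registry", class(reg))
  validate_registry(reg, terminology)
  reg
}
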