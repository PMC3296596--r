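# Consensus classifiers: the modified RAND/UCLA appropriateness method
# (appropriateness + necessity scales, including the "necessary to avoid"
# extension for the safety domain) and the Delphi priority-tier rule.
# All ratings are integers on a 1-9 ordinal scale; the median of an even
# panel is the arithmetic midpoint of the central pair and may be
# non-integer.

check_ratings <- function(ratings) {
  if (length(ratings) < 1) {
    abort("at least one rating required", class = "dqip_rating_error")
  }
  if (any(is.na(ratings)) || any(ratings < 1 | ratings > 9) ||
      any(ratings != round(ratings))) {
    abort("ratings must be integers in 1..9 with no missing values",
          class = "dqip_rating_error")
  }
  invisible(ratings)
}

#' Two-tailed panel disagreement rule
#'
#' Disagreement holds when at least three panelists rate 7-9 AND at least
#' three rate 1-3.
#'
#' @param ratings Integer vector of panel ratings (1-9).
#' @return Logical.
#' @export
ram_disagreement <- function(ratings) {
  check_ratings(ratings)
  sum(ratings >= 7) >= 3 && sum(ratings <= 3) >= 3
}

#' Appropriateness classification
#'
#' Disagreement dominates; otherwise the median band decides:
#' 7-9 appropriate, 4-6 uncertain, 1-3 inappropriate.
#'
#' @inheritParams ram_disagreement
#' @return One of `"appropriate"`, `"uncertain"`, `"inappropriate"`,
#'   `"disagreement"`.
#' @export
ram_appropriateness <- function(ratings) {
  check_ratings(ratings)
  if (ram_disagreement(ratings)) return("disagreement")
  med <- median(ratings)
  if (med >= 7) "appropriate" else if (med <= 3) "inappropriate" else
    "uncertain"
}

#' Necessity classification
#'
#' On the "necessary to do" scale an item is necessary when its median is
#' 7-9 without disagreement; on the "necessary to avoid" scale when its
#' median is 1-3 without disagreement. Everything else is not necessary
#' (or disagreement).
#'
#' @inheritParams ram_disagreement
#' @param scale `"do"` or `"avoid"`.
#' @return One of `"necessary_to_do"`, `"necessary_to_avoid"`,
#'   `"not_necessary"`, `"disagreement"`.
#' @export
ram_necessity <- function(ratings, scale = c("do", "avoid")) {
  scale <- match.arg(scale)
  check_ratings(ratings)
  if (ram_disagreement(ratings)) return("disagreement")
  med <- median(ratings)
  if (scale == "do") {
    if (med >= 7) "necessary_to_do" else "not_necessary"
  } else {
    if (med <= 3) "necessary_to_avoid" else "not_necessary"
  }
}

#' Combined acceptance label for a candidate criterion
#'
#' Quality candidates must be appropriate; those also clearly necessary
#' to do are labelled `"N"`, the rest `"A"`. Safety candidates must be
#' inappropriate; those also clearly necessary to avoid are labelled
#' `"NecAv"` (reported with the `"N"` tag), the rest `"I"`. Anything else
#' is rejected.
#'
#' @param appropriateness_ratings,necessity_ratings Integer rating
#'   vectors for the two scales.
#' @param domain `"quality"` or `"safety"`.
#' @return One of `"A"`, `"N"`, `"I"`, `"NecAv"`, `"rejected"`.
#' @export
ram_accept <- function(appropriateness_ratings, necessity_ratings,
                       domain = c("quality", "safety")) {
  domain <- match.arg(domain)
  app <- ram_appropriateness(appropriateness_ratings)
  if (domain == "quality") {
    if (app != "appropriate") return("rejected")
    nec <- ram_necessity(necessity_ratings, "do")
    if (nec == "necessary_to_do") "N" else "A"
  } else {
    if (app != "inappropriate") return("rejected")
    nec <- ram_necessity(necessity_ratings, "avoid")
    if (nec == "necessary_to_avoid") "NecAv" else "I"
  }
}

#' Delphi priority tier
#'
#' A topic with a second-round median of 7-9 without disagreement (30% or
#' more of ratings 1-3 AND 30% or more 7-9) is a priority; a median of 8
#' or 9 makes it high priority; a median below 7 is rejected.
#'
#' Supply either the raw `ratings` or a precomputed `median` (with
#' `disagreement`, default `FALSE`, for the published-medians case where
#' the panel reported no disagreement on any topic).
#'
#' @param ratings Integer rating vector (optional).
#' @param median Precomputed median (optional alternative).
#' @param disagreement Logical; only used with `median`.
#' @return One of `"high"`, `"priority"`, `"rejected"`, `"disagreement"`.
#' @export
delphi_priority <- function(ratings = NULL, median = NULL,
                            disagreement = FALSE) {
  if (!is.null(ratings)) {
    check_ratings(ratings)
    disagreement <- mean(ratings <= 3) >= 0.30 && mean(ratings >= 7) >= 0.30
    median <- stats::median(ratings)
  }
  if (is.null(median)) {
    abort("supply ratings or median", class = "dqip_rating_error")
  }
  if (median < 7) return("rejected")
  if (disagreement) return("disagreement")
  if (median >= 8) "high" else "priority"
}

#' Second-round Delphi medians for the 47 improvement topics
#'
#' The published panel medians (and means) for the 18 quality and 29
#' safety medication-improvement topics, with the tier label as printed
#' (`"high"` = '++', `"priority"` = '+', `"rejected"` = not scored as a
#' priority). The panel reported no disagreement on any topic.
#'
#' @return A tibble: `topic_id`, `domain`, `median`, `mean`,
#'   `printed_tier`.
#' @export
delphi_topic_medians <- function() {
  # printed_tier transcribes the published label column ('++', '+', blank)
  # independently of the median, so tier reproduction is a real check
  q <- tribble(
    ~topic_id, ~median, ~mean, ~printed_tier,
    "Q16", 8, 8.0, "++", "Q15", 8, 7.9, "++", "Q11", 8, 7.9, "++",
    "Q14", 8, 7.7, "++", "Q5", 8, 7.7, "++", "Q12", 8, 7.7, "++",
    "Q4", 8, 7.6, "++",
    "Q8", 7, 7.5, "+", "Q6", 7, 7.4, "+", "Q17", 7, 7.3, "+",
    "Q3", 7, 7.2, "+", "Q10", 7, 7.0, "+", "Q2", 7, 6.9, "+",
    "Q9", 7, 6.8, "+", "Q7", 7, 6.7, "+",
    "Q13", 6, 6.2, "", "Q1", 6, 6.4, "", "Q18", 6, 6.4, ""
  ) |> mutate(domain = "quality")
  s <- tribble(
    ~topic_id, ~median, ~mean, ~printed_tier,
    "S20", 9, 8.4, "++", "S1", 8, 8.2, "++", "S3", 8, 7.9, "++",
    "S21", 8, 7.8, "++",
    "S27", 7, 7.3, "+", "S19", 7, 7.3, "+", "S23", 7, 7.3, "+",
    "S10", 7, 7.2, "+", "S28", 7, 7.1, "+", "S18", 7, 7.1, "+",
    "S24", 7, 7.0, "+", "S6", 7, 7.0, "+", "S14", 7, 6.9, "+",
    "S25", 7, 6.9, "+", "S15", 7, 6.8, "+", "S13", 7, 6.8, "+",
    "S29", 7, 6.7, "+", "S5", 7, 6.6, "+", "S7", 7, 6.6, "+",
    "S17", 7, 6.6, "+", "S4", 7, 6.4, "+", "S16", 7, 6.4, "+",
    "S26", 7, 6.3, "+",
    "S2", 6, 6.6, "", "S9", 6, 6.5, "", "S11", 6, 6.4, "",
    "S12", 6, 6.3, "", "S22", 6, 6.2, "", "S8", 6, 5.8, ""
  ) |> mutate(domain = "safety")
  bind_rows(q, s) |>
    mutate(printed_tier = unname(c(`++` = "high", `+` = "priority",
                                   rejected = "rejected")[
                                     ifelse(.data$printed_tier == "",
                                            "rejected",
                                            .data$printed_tier)])) |>
    select("topic_id", "domain", "median", "mean", "printed_tier")
}

#' Classify a table of panel ratings with the modified RAM rules
#'
#' @param ratings A tibble with columns `item_id`, `panelist_id`, `scale`
#'   (`"appropriateness"` or `"necessity"`), `rating` and `domain`
#'   (`"quality"`/`"safety"`, constant within item).
#' @return A `dqip_ram` tibble: one row per item with `appropriateness`,
#'   `necessity`, `accepted_as` and the medians of both scales.
#' @export
ram_classify <- function(ratings) {
  out <- ratings |>
    group_by(.data$item_id, .data$domain) |>
    group_modify(function(df, key) {
      app <- df$rating[df$scale == "appropriateness"]
      nec <- df$rating[df$scale == "necessity"]
      nec_scale <- if (key$domain == "quality") "do" else "avoid"
      tibble(
        appropriateness = ram_appropriateness(app),
        necessity = ram_necessity(nec, nec_scale),
        accepted_as = ram_accept(app, nec, key$domain),
        median_appropriateness = median(app),
        median_necessity = median(nec)
      )
    }) |>
    ungroup()
  class(out) <- c("dqip_ram", class(out))
  out
}

#' Classify a table of Delphi topic ratings
#'
#' @param ratings A tibble with columns `topic_id`, `panelist_id`,
#'   `rating`.
#' @return A `dqip_delphi` tibble: `topic_id`, `median`, `priority`.
#' @export
delphi_classify <- function(ratings) {
  out <- ratings |>
    group_by(.data$topic_id) |>
    summarise(median = median(.data$rating),
              priority = delphi_priority(.data$rating), .groups = "drop")
  class(out) <- c("dqip_delphi", class(out))
  out
}

#' @export
tidy.dqip_ram <- function(x, ...) as_tibble(x)

#' @export
glance.dqip_ram <- function(x, ...) {
  tibble(
    n_items = nrow(x),
    n_accepted = sum(x$accepted_as != "rejected"),
    n_necessary = sum(x$accepted_as %in% c("N", "NecAv")),
    n_rejected = sum(x$accepted_as == "rejected")
  )
}

#' @export
tidy.dqip_delphi <- function(x, ...) as_tibble(x)

#' @export
glance.dqip_delphi <- function(x, ...) {
  tibble(
    n_topics = nrow(x),
    n_high = sum(x$priority == "high"),
    n_priority = sum(x$priority %in% c("high", "priority")),
    n_rejected = sum(x$priority == "rejected")
  )
}

#' Broom-style generics
#'
#' `tidy()` returns the per-item (or per-topic) classification tibble;
#' `glance()` a one-row acceptance summary.
#'
#' @param x A `dqip_ram` or `dqip_delphi` object.
#' @param ... Unused.
#' @name dqip-broom
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname dqip-broom
#' @export
glance <- function(x, ...) UseMethod("glance")
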