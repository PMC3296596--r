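# Registry structure, summaries and serialisation.

test_that("shipped registry has the published shape", {
  expect_equal(nrow(REG), 176)
  expect_equal(sum(REG$domain == "quality"), 52)
  expect_equal(sum(REG$domain == "safety"), 124)
  expect_equal(length(unique(REG$criterion_id)), 176)
  # every topic maps to at least one criterion and carries a tier
  expect_true(all(table(REG$topic_id) >= 1))
  expect_setequal(unique(REG$delphi_priority),
                  c("high", "priority", "rejected"))
  # criterion tiers agree with the topic medians table
  med <- delphi_topic_medians()
  expect_equal(REG$delphi_priority,
               med$printed_tier[match(REG$topic_id, med$topic_id)])
})

test_that("registry summaries reproduce the taxonomy margins", {
  s <- registry_summary(REG)
  bc <- s$by_category
  get <- function(cat) bc$total[bc$category == cat]
  expect_equal(get("MQ1"), 26)
  expect_equal(get("MQ2"), 4)
  expect_equal(get("MQ3"), 16)
  expect_equal(get("MQ4"), 6)
  expect_equal(get("MS1"), 15)
  expect_equal(get("MS3"), 42)
  expect_equal(get("MS8"), 20)
  # quality criteria restricted to ages 75+ and 80+
  age <- s$by_age_restriction
  expect_equal(age$n[age$domain == "quality" & age$age_min == 75], 8)
  expect_equal(age$n[age$domain == "quality" & age$age_min == 80], 2)
})

test_that("validation flags the verbatim label anomaly and hard errors", {
  v <- validate_registry(REG, TERM)
  expect_equal(v$criterion_id, "S-102")
  expect_equal(v$severity, "warning")
  dup <- dplyr::bind_rows(REG[1, ], REG[1, ])
  expect_error(validate_registry(dup, TERM), "duplicate",
               class = "dqip_registry_error")
  broken <- REG[1, ]
  broken$predicate <- list(p_all(on_drug("NO_SUCH_SET")))
  expect_error(validate_registry(broken, TERM), "NO_SUCH_SET",
               class = "dqip_registry_error")
})

test_that("criteria files round-trip identically", {
  path <- withr::local_tempfile(fileext = ".json")
  write_criteria(REG, path)
  r2 <- read_criteria(path, TERM)
  expect_equal(nrow(r2), 176)
  expect_identical(lapply(REG$predicate, dqipr:::pred_to_list),
                   lapply(r2$predicate, dqipr:::pred_to_list))
  meta <- setdiff(names(REG), "predicate")
  expect_equal(as.data.frame(REG[meta]), as.data.frame(r2[meta]))
})

test_that("the shipped criteria files equal the built-in registry", {
  r2 <- read_criteria(terminology = TERM)
  expect_equal(nrow(r2), 176)
  expect_equal(sum(r2$domain == "quality"), 52)
  expect_identical(lapply(REG$predicate, dqipr:::pred_to_list),
                   lapply(r2$predicate, dqipr:::pred_to_list))
})

test_that("age and sex restrictions are derived from the predicates", {
  q51 <- REG[REG$criterion_id == "Q-051", ]
  expect_equal(q51$age_min, 80)
  expect_equal(q51$sex_restriction, "female")
  s8 <- REG[REG$criterion_id == "S-008", ]
  expect_equal(s8$age_min, 65)
  expect_equal(s8$age_max, 74)
})
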