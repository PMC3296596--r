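# Criterion evaluation and cohort screening.

test_that("gastroprotection criterion fires and its exclusion clears it", {
  # age 70, active warfarin + low-dose aspirin, no gastroprotection
  co <- new_cohort(
    mk_patients("p1", birth = IDX %m-% lubridate::years(70)),
    prescriptions = dplyr::bind_rows(
      mk_rx("p1", "warfarin", IDX - 14, supply = 56L, dose = 3),
      mk_rx("p1", "aspirin", IDX - 14, supply = 56L, dose = 75)))
  s002 <- REG[REG$criterion_id == "S-002", ]
  fl <- evaluate_criterion(co, s002, "p1", IDX)
  expect_equal(nrow(fl), 1)
  expect_true(fl$assessable)
  # an active proton-pump inhibitor satisfies the exclusion
  co2 <- new_cohort(co$patients,
                    prescriptions = dplyr::bind_rows(
                      co$prescriptions[names(co$prescriptions) != "rx_id"],
                      mk_rx("p1", "omeprazole", IDX - 14, supply = 56L)))
  expect_equal(nrow(evaluate_criterion(co2, s002, "p1", IDX)), 0)
  # full-dose aspirin is not low-dose aspirin
  co3 <- new_cohort(co$patients,
                    prescriptions = dplyr::bind_rows(
                      mk_rx("p1", "warfarin", IDX - 14, supply = 56L),
                      mk_rx("p1", "aspirin", IDX - 14, supply = 56L,
                            dose = 300)))
  expect_equal(nrow(evaluate_criterion(co3, s002, "p1", IDX)), 0)
})

test_that("unless-clauses suppress the dual-antiplatelet criterion", {
  # prior stroke, on warfarin: no flag despite no aspirin+dipyridamole
  co <- new_cohort(
    mk_patients("p1", birth = IDX %m-% lubridate::years(70)),
    conditions = mk_cond("p1", "stroke", "2008-05-01"),
    prescriptions = mk_rx("p1", "warfarin", IDX - 14, supply = 56L))
  q030 <- REG[REG$criterion_id == "Q-030", ]
  expect_equal(nrow(evaluate_criterion(co, q030, "p1", IDX)), 0)
  # same patient without any prophylaxis: flag
  co2 <- new_cohort(co$patients, conditions = co$conditions)
  expect_equal(nrow(evaluate_criterion(co2, q030, "p1", IDX)), 1)
})

test_that("missing inputs yield a not-assessable flag, not a crash", {
  # CVD-risk criterion with no recorded risk score and no diabetes:
  # predicate undecidable
  co <- new_cohort(mk_patients("p1", birth = IDX %m-%
                                 lubridate::years(60)))
  q023 <- REG[REG$criterion_id == "Q-023", ]
  fl <- evaluate_criterion(co, q023, "p1", IDX)
  expect_equal(nrow(fl), 1)
  expect_false(fl$assessable)
  # with a low recorded risk the criterion resolves to no-flag
  co2 <- new_cohort(mk_patients("p1", birth = IDX %m-%
                                  lubridate::years(60),
                                cvd10y_percent = 10))
  expect_equal(nrow(evaluate_criterion(co2, q023, "p1", IDX)), 0)
})

test_that("screening a cohort is deterministic and well-ordered", {
  sim <- generate_cohort(sim_config(n_patients = 40, seed = 7))
  f1 <- screen_cohort(sim$cohort, REG, IDX)
  f2 <- screen_cohort(sim$cohort, REG, IDX)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
  expect_false(is.unsorted(f1$patient_id))
  expect_true(all(c("topic_id", "domain", "category",
                    "delphi_priority") %in% names(f1)))
  # empty cohort screens to an empty table
  empty <- new_cohort(mk_patients(character(0), sex = character(0),
                                  birth = as.Date(character(0))))
  expect_equal(nrow(screen_cohort(empty, REG, IDX)), 0)
})

test_that("flag summaries count patients and respect assessability", {
  rec <- plant_case(REG[REG$criterion_id == "S-001", ], TRUE, seed = 3,
                    patient_id = "pA")
  co <- as_cohort(rec)
  fl <- screen_cohort(co, REG, IDX)
  sm <- summarize_flags(fl, REG)
  expect_true("S1" %in% sm$by_topic$topic_id)
  s1 <- sm$by_topic[sm$by_topic$topic_id == "S1", ]
  expect_gte(s1$n_flags, 1)
  expect_equal(sm$n_screened, 1)
  # zero flags give an empty summary
  empty <- new_cohort(mk_patients("p9", birth = IDX %m-%
                                    lubridate::years(30)))
  sm0 <- summarize_flags(screen_cohort(empty, REG, IDX), REG)
  expect_equal(nrow(sm0$by_topic), 0)
})

test_that("flags export to delimited text with JSON evidence", {
  rec <- plant_case(REG[1, ], TRUE, seed = 1, patient_id = "pX")
  fl <- screen_cohort(as_cohort(rec), REG[1, ], IDX)
  path <- withr::local_tempfile(fileext = ".csv")
  write_flags(fl, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$criterion_id, fl$criterion_id)
  expect_true(all(grepl("^\\[", back$evidence_json)))
})

test_that("autoplot methods return ggplot objects", {
  rec <- plant_case(REG[REG$criterion_id == "S-001", ], TRUE, seed = 3,
                    patient_id = "pA")
  fl <- screen_cohort(as_cohort(rec), REG, IDX)
  expect_s3_class(autoplot(fl), "ggplot")
  med <- delphi_topic_medians()
  dl <- delphi_classify(generate_ratings(
    tibble::tibble(topic_id = c("T1", "T2"),
                   target = c("high", "rejected")),
    n_panelists = 10, seed = 1, scheme = "delphi"))
  expect_s3_class(autoplot(dl), "ggplot")
})
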