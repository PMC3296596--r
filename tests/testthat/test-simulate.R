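# Synthetic cohorts and rating matrices with known ground truth.

test_that("planted cases are deterministic under a fixed seed", {
  cr <- REG[REG$criterion_id == "S-025", ]
  a <- plant_case(cr, TRUE, seed = 11)
  b <- plant_case(cr, TRUE, seed = 11)
  expect_identical(a, b)
  c2 <- plant_case(cr, TRUE, seed = 12)
  expect_false(identical(a, c2))
})

test_that("a monitoring-gap template places the stale observation", {
  # potassium-sparing diuretic, last U&E more than 48 weeks ago: flag;
  # a recent U&E clears it
  cr <- REG[REG$criterion_id == "S-025", ]
  pos <- plant_case(cr, TRUE, seed = 2)
  expect_true("spironolactone" %in% pos$prescriptions$drug_code)
  expect_true(all(pos$observations$date < IDX - 48 * 7))
  expect_equal(nrow(evaluate_criterion(as_cohort(pos), cr, "planted",
                                       IDX)), 1)
  neg <- plant_case(cr, FALSE, seed = 2, clause = 2)
  expect_true(any(neg$observations$date >= IDX - 48 * 7))
  expect_equal(nrow(evaluate_criterion(as_cohort(neg), cr, "planted",
                                       IDX)), 0)
})

test_that("generated cohorts reproduce their truth table exactly", {
  sim <- generate_cohort(sim_config(n_patients = 120, seed = 31))
  expect_equal(nrow(sim$cohort$patients), 120)
  expect_gt(nrow(sim$truth), 0)
  flags <- screen_cohort(sim$cohort, REG, IDX)
  hits <- flags |> dplyr::filter(.data$assessable)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    got <- any(hits$patient_id == tr$patient_id &
                 hits$criterion_id == tr$criterion_id)
    expect_equal(got, tr$expected_flag,
                 label = sprintf("%s/%s", tr$patient_id, tr$criterion_id))
  }
})

test_that("cohort files are byte-identical for a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- generate_cohort(sim_config(n_patients = 30, seed = 5))
  s2 <- generate_cohort(sim_config(n_patients = 30, seed = 5))
  write_cohort(s1$cohort, d1, s1$truth)
  write_cohort(s2$cohort, d2, s2$truth)
  for (f in c("patients.csv", "conditions.csv", "prescriptions.csv",
              "observations.csv", "truth_table.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("rating generation meets its targets or errors when infeasible", {
  targets <- tibble::tibble(item_id = c("a", "b"),
                            domain = c("quality", "safety"),
                            target = c("N", "NecAv"))
  r <- generate_ratings(targets, n_panelists = 10, seed = 3)
  expect_equal(nrow(r), 2 * 2 * 10)
  cls <- ram_classify(r)
  expect_setequal(cls$accepted_as, c("N", "NecAv"))
  # two-tailed disagreement impossible with a panel of 4
  bad <- tibble::tibble(item_id = "x", domain = "quality",
                        target = "disagreement")
  expect_error(generate_ratings(bad, n_panelists = 4, seed = 1),
               class = "dqip_rating_error")
  ok <- generate_ratings(bad, n_panelists = 6, seed = 1)
  app <- ok$rating[ok$scale == "appropriateness"]
  expect_equal(ram_appropriateness(app), "disagreement")
  # identical seeds give identical matrices
  expect_identical(generate_ratings(targets, 10, seed = 3),
                   generate_ratings(targets, 10, seed = 3))
})
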