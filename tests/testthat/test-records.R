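# Cohort I/O and the temporal algebra underneath every criterion.

test_that("cohort round-trips through delimited files with validation", {
  dir <- withr::local_tempdir()
  p <- mk_patients(c("p1", "p2"), sex = c("male", "female"),
                   birth = as.Date(c("1940-05-01", "1955-10-10")))
  rx <- mk_rx(rep(c("p1", "p2"), c(3, 2)), "warfarin",
              IDX - c(10, 40, 70, 10, 40))
  readr::write_csv(p, file.path(dir, "patients.csv"))
  readr::write_csv(mk_cond("p1", "af", "2000-01-01"),
                   file.path(dir, "conditions.csv"))
  readr::write_csv(rx, file.path(dir, "prescriptions.csv"))
  readr::write_csv(mk_obs("p2", "UE", "2011-06-01"),
                   file.path(dir, "observations.csv"))
  co <- read_cohort(file.path(dir, "patients.csv"),
                    file.path(dir, "conditions.csv"),
                    file.path(dir, "prescriptions.csv"),
                    file.path(dir, "observations.csv"))
  expect_s3_class(co, "dqip_cohort")
  expect_equal(nrow(co$patients), 2)
  expect_equal(nrow(co$prescriptions), 5)
  expect_true(inherits(co$prescriptions$issue_date, "Date"))
  s <- summary(co)
  expect_equal(s$n_prescriptions, 5)
})

test_that("schema, referential and parse errors are specific", {
  p <- mk_patients("p1")
  # missing mandatory column
  bad_rx <- mk_rx("p1", "aspirin", IDX)[, -4]  # drop days_supply
  expect_error(new_cohort(p, prescriptions = bad_rx),
               "days_supply", class = "dqip_schema_error")
  # event before birth
  expect_error(
    new_cohort(p, observations = mk_obs("p1", "UE", "1930-01-01")),
    class = "dqip_referential_error")
  # unknown patient
  expect_error(new_cohort(p, conditions = mk_cond("ghost", "af", IDX)),
               "unknown patient", class = "dqip_referential_error")
  # unparseable date via file path
  dir <- withr::local_tempdir()
  readr::write_csv(tibble::tibble(patient_id = "p1", sex = "male",
                                  birth_date = "not-a-date"),
                   file.path(dir, "patients.csv"))
  for (f in c("conditions", "prescriptions", "observations")) {
    readr::write_csv(tibble::tibble(), file.path(dir, paste0(f, ".csv")))
  }
  expect_error(
    suppressWarnings(read_cohort(
      file.path(dir, "patients.csv"), file.path(dir, "conditions.csv"),
      file.path(dir, "prescriptions.csv"),
      file.path(dir, "observations.csv"))))
  # days_supply imputation is reported
  na_rx <- mk_rx("p1", "aspirin", IDX, supply = NA_integer_)
  expect_message(new_cohort(p, prescriptions = na_rx), "imputed")
})

test_that("exposure episodes merge across gaps up to the grace period", {
  d0 <- as.Date("2011-01-01")
  # coverage gap 10 days (issues 38 days apart, 28-day supplies): merged
  rx <- mk_rx("p1", "warfarin", c(d0, d0 + 38))
  ep <- build_exposure_episodes(rx, grace_gap_days = 28)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$start_date, d0)
  expect_equal(ep$end_date, d0 + 66)  # last issue + supply
  # issues 60 days apart: coverage gap 32 > 28, two episodes
  rx2 <- mk_rx("p1", "warfarin", c(d0, d0 + 60))
  expect_equal(nrow(build_exposure_episodes(rx2, 28)), 2)
  # single issue: [issue, issue + supply)
  ep3 <- build_exposure_episodes(mk_rx("p1", "aspirin", d0, supply = 28L))
  expect_equal(as.numeric(ep3$end_date - ep3$start_date), 28)
  # empty input
  expect_equal(nrow(build_exposure_episodes(NULL)), 0)
})

test_that("episode building is idempotent and coverage is bounded", {
  for (s in 1:200) {
    set.seed(s)
    n <- sample(1:8, 1)
    rx <- mk_rx("p1", sample(c("a", "b"), n, replace = TRUE),
                as.Date("2011-01-01") + sample(0:300, n, replace = TRUE),
                supply = sample(c(7L, 28L, 56L), n, replace = TRUE))
    ep <- build_exposure_episodes(rx, 28)
    # idempotence: re-merging the episodes changes nothing
    ep_as_rx <- tibble::tibble(
      patient_id = ep$patient_id, drug_code = ep$drug_code,
      issue_date = ep$start_date,
      days_supply = as.integer(ep$end_date - ep$start_date),
      daily_dose = 1, dose_unit = "mg/day", strength = NA_real_,
      dose_instructions_recorded = NA)
    ep2 <- build_exposure_episodes(ep_as_rx, 28)
    expect_equal(ep2[c("drug_code", "start_date", "end_date")],
                 ep[c("drug_code", "start_date", "end_date")])
    # episodes per drug are sorted and non-overlapping
    for (dc in unique(ep$drug_code)) {
      e <- ep[ep$drug_code == dc, ]
      if (nrow(e) > 1) {
        expect_true(all(diff(as.numeric(e$start_date)) > 0))
        expect_true(all(e$start_date[-1] >= e$end_date[-nrow(e)]))
      }
    }
    # total coverage bounds
    cov <- sum(as.numeric(ep$end_date - ep$start_date))
    expect_gte(cov, max(rx$days_supply))
    expect_lte(cov, sum(rx$days_supply + 28))
  }
})

test_that("active_on respects half-open episode intervals", {
  d <- as.Date("2011-03-01")
  ep <- build_exposure_episodes(mk_rx("p1", "digoxin", d, supply = 28L))
  expect_true(active_on(ep, "digoxin", d))
  expect_true(active_on(ep, "digoxin", d + 27))
  expect_false(active_on(ep, "digoxin", d + 28))
  expect_false(active_on(ep, "other", d))
  expect_false(active_on(ep[0, ], "digoxin", d))
})

test_that("exposure duration and issue counts use the stated windows", {
  d <- IDX
  ep <- build_exposure_episodes(mk_rx("p1", "naproxen", d - 91,
                                      supply = 120L))
  expect_equal(exposure_weeks_at(ep, "naproxen", d), 13)
  expect_equal(exposure_weeks_at(ep, "naproxen", d - 91), 0)
  expect_equal(exposure_weeks_at(ep, "other", d), 0)

  rx <- mk_rx("p1", "salbutamol", d - c(14, 42, 77))
  expect_equal(count_issues_in_window(rx, "salbutamol", 12, d), 3)
  # boundary day inclusive
  rx2 <- mk_rx("p1", "salbutamol", d - 84)
  expect_equal(count_issues_in_window(rx2, "salbutamol", 12, d), 1)
  expect_equal(count_issues_in_window(rx2, "other", 12, d), 0)
})

test_that("latest_observation picks the most recent within lookback", {
  obs <- mk_obs("p1", "UE", IDX - c(70, 210) * 1)
  got <- latest_observation(obs, "UE", IDX, 48)
  expect_equal(nrow(got), 1)
  expect_equal(got$date, IDX - 70)
  expect_equal(nrow(latest_observation(mk_obs("p1", "UE", IDX - 350),
                                       "UE", IDX, 48)), 0)
  two <- mk_obs("p1", "UE", IDX - c(70, 210))
  expect_equal(latest_observation(two, "UE", IDX, 48)$date, IDX - 70)
})

test_that("age is exact at birthday boundaries", {
  b <- as.Date("1947-01-01")
  expect_equal(age_at(b, as.Date("2012-01-01")), 65)
  expect_equal(age_at(b, as.Date("2011-12-31")), 64)
})
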