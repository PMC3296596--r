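# Code sets, dose equivalence and derived clinical quantities.

test_that("code set lookup is strict and containments hold", {
  expect_true(all(members(TERM, "COX2") %in% members(TERM, "NSAID_ORAL")))
  expect_true(all(members(TERM, "ALDOSTERONE_ANTAGONIST") %in%
                    members(TERM, "K_SPARING_DIURETIC")))
  expect_error(members(TERM, "NOSUCH"), "NOSUCH",
               class = "dqip_config_error")
})

test_that("every code set referenced by the 176 criteria resolves", {
  ids <- unique(unlist(lapply(REG$predicate, dqipr:::pred_set_ids)))
  expect_gt(length(ids), 80)
  for (id in ids) expect_silent(members(TERM, id))
})

test_that("dose equivalence follows the table factors", {
  expect_equal(equivalent_daily_dose(TERM, "statin_simvastatin",
                                     "simvastatin", 40), 40)
  expect_equal(equivalent_daily_dose(TERM, "statin_simvastatin",
                                     "rosuvastatin", 10), 40)
  expect_true(is.na(equivalent_daily_dose(TERM, "statin_simvastatin",
                                          "notadrug", 10)))
  expect_error(equivalent_daily_dose(TERM, "nosuchtable", "x", 1),
               class = "dqip_config_error")
})

test_that("CHADS2 matches its definition case by case", {
  b60 <- IDX %m-% lubridate::years(60)
  b80 <- IDX %m-% lubridate::years(80)
  no_cond <- mk_cond("p", "x", "2000-01-01")[0, ]
  expect_equal(chads2(no_cond, b60, IDX, TERM), 0L)
  expect_equal(chads2(mk_cond("p", c("htn", "dm2"), "2000-01-01"),
                      b80, IDX, TERM), 3L)
  expect_equal(chads2(mk_cond("p", "stroke", "2000-01-01"), b60, IDX,
                      TERM), 2L)
  # age 76 scores the age point, 75 does not ("age > 75")
  expect_equal(chads2(no_cond, IDX %m-% lubridate::years(76), IDX, TERM),
               1L)
  expect_equal(chads2(no_cond, IDX %m-% lubridate::years(75), IDX, TERM),
               0L)
})

test_that("CHADS2 equals a brute-force sum over all factor combinations", {
  b60 <- IDX %m-% lubridate::years(60)
  b80 <- IDX %m-% lubridate::years(80)
  factors <- c(chf = 1L, htn = 1L, dm1 = 1L, stroke = 2L)
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 5))
  names(grid) <- c(names(factors), "old")
  for (i in seq_len(nrow(grid))) {
    on <- unlist(grid[i, 1:4])
    codes <- names(factors)[on]
    conds <- if (length(codes)) mk_cond("p", codes, "2000-01-01") else
      mk_cond("p", "x", "2000-01-01")[0, ]
    expected <- sum(factors[on]) + as.integer(grid$old[i])
    got <- chads2(conds, if (grid$old[i]) b80 else b60, IDX, TERM)
    expect_equal(got, as.integer(expected))
  }
})

test_that("CHADS2 is monotone as risk factors accumulate", {
  b60 <- IDX %m-% lubridate::years(60)
  codes <- c("chf", "htn", "dm2", "stroke")
  prev <- -1L
  for (k in 0:4) {
    conds <- if (k) mk_cond("p", codes[seq_len(k)], "2000-01-01") else
      mk_cond("p", "x", "2000-01-01")[0, ]
    s <- chads2(conds, b60, IDX, TERM)
    expect_gte(s, prev)
    prev <- s
  }
  expect_equal(prev, 5L)
})

test_that("CKD staging bands eGFR and defers to coded stage", {
  no_cond <- mk_cond("p", "x", "2000-01-01")[0, ]
  st <- function(egfr) ckd_stage(no_cond, mk_obs("p", "eGFR", IDX - 30,
                                                 egfr), IDX, TERM)
  expect_equal(st(45), 3L)
  expect_equal(st(20), 4L)
  expect_equal(st(10), 5L)
  expect_true(is.na(st(75)))
  expect_true(is.na(ckd_stage(no_cond, mk_obs("p", "UE", IDX, 1), IDX,
                              TERM)))
  # coded stage overrides a contradictory eGFR
  expect_equal(ckd_stage(mk_cond("p", "ckd4", "2010-01-01"),
                         mk_obs("p", "eGFR", IDX - 10, 65), IDX, TERM), 4L)
  # monotone non-increasing in eGFR
  stages <- vapply(c(95, 70, 59, 45, 30, 29, 15, 14, 5),
                   function(v) { s <- st(v); if (is.na(s)) 0L else s },
                   integer(1))
  expect_true(all(diff(stages) >= 0))
})

test_that("terminology file round-trips and is validated", {
  path <- withr::local_tempfile(fileext = ".json")
  write_terminology(TERM, path)
  t2 <- read_terminology(path)
  expect_equal(members(t2, "GIP"), members(TERM, "GIP"))
  expect_equal(t2$params$low_dose_aspirin_max_mg, 150)
  # reference factor must be 1
  broken <- TERM
  broken$dose_equivalence$statin_simvastatin$factors$simvastatin <- 2
  write_terminology(broken, path)
  expect_error(read_terminology(path), class = "dqip_config_error")
})
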