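# RAM and Delphi consensus classifiers.

test_that("disagreement needs three or more ratings in both tails", {
  expect_true(ram_disagreement(c(1, 1, 1, 9, 9, 9, 5, 5, 5, 5)))
  expect_false(ram_disagreement(rep(9, 10)))
  expect_false(ram_disagreement(c(1, 1, 9, 9, 5, 5, 5, 5, 5, 5)))
  expect_error(ram_disagreement(c(0, 5)), class = "dqip_rating_error")
  expect_error(ram_disagreement(c(5, 10)), class = "dqip_rating_error")
  expect_error(ram_disagreement(integer(0)), class = "dqip_rating_error")
})

test_that("appropriateness bands the median and disagreement dominates", {
  expect_equal(ram_appropriateness(rep(8, 10)), "appropriate")
  expect_equal(ram_appropriateness(rep(2, 10)), "inappropriate")
  expect_equal(ram_appropriateness(rep(5, 10)), "uncertain")
  # tails of 4 and 3 override the uncertain median
  expect_equal(ram_appropriateness(c(1, 1, 1, 2, 5, 5, 8, 9, 9, 9)),
               "disagreement")
  # even panel: median is the midpoint of the central pair
  expect_equal(ram_appropriateness(c(6, 6, 6, 6, 6, 7, 7, 7, 7, 7)),
               "uncertain")  # median 6.5 < 7
  expect_equal(ram_appropriateness(c(6, 6, 6, 6, 7, 7, 7, 7, 7, 7)),
               "appropriate")  # median 7
})

test_that("necessity uses opposite bands on the do and avoid scales", {
  expect_equal(ram_necessity(rep(9, 10), "do"), "necessary_to_do")
  expect_equal(ram_necessity(rep(1, 10), "avoid"), "necessary_to_avoid")
  expect_equal(ram_necessity(c(6, 6, 6, 6, 6, 7, 7, 7, 7, 7), "do"),
               "not_necessary")  # median 6.5
  expect_equal(ram_necessity(rep(4, 10), "avoid"), "not_necessary")
  expect_equal(ram_necessity(c(1, 1, 1, 9, 9, 9, 2, 2, 2, 2), "do"),
               "disagreement")
})

test_that("acceptance composes the two scales per domain", {
  expect_equal(ram_accept(rep(8, 10), rep(8, 10), "quality"), "N")
  expect_equal(ram_accept(rep(8, 10), rep(5, 10), "quality"), "A")
  expect_equal(ram_accept(rep(5, 10), rep(9, 10), "quality"), "rejected")
  expect_equal(ram_accept(rep(2, 10), rep(2, 10), "safety"), "NecAv")
  expect_equal(ram_accept(rep(2, 10), rep(5, 10), "safety"), "I")
  expect_equal(ram_accept(rep(8, 10), rep(2, 10), "safety"), "rejected")
})

test_that("Delphi tiers follow the median bands", {
  expect_equal(delphi_priority(rep(8, 26)), "high")
  expect_equal(delphi_priority(rep(7, 26)), "priority")
  expect_equal(delphi_priority(rep(6, 26)), "rejected")
  expect_equal(delphi_priority(median = 8), "high")
  expect_equal(delphi_priority(median = 7.5), "priority")
  # >= 30% in both tails with a high median: disagreement
  expect_equal(delphi_priority(c(rep(1, 3), rep(9, 7))), "disagreement")
  expect_error(delphi_priority(), class = "dqip_rating_error")
})

test_that("classifiers are invariant under panelist permutation", {
  set.seed(99)
  for (i in 1:50) {
    r <- sample(1:9, 10, replace = TRUE)
    perm <- sample(r)
    expect_equal(ram_appropriateness(r), ram_appropriateness(perm))
    expect_equal(ram_necessity(r, "do"), ram_necessity(perm, "do"))
    expect_equal(ram_necessity(r, "avoid"), ram_necessity(perm, "avoid"))
    expect_equal(delphi_priority(r), delphi_priority(perm))
  }
})

test_that("rating-table classifiers tidy and glance", {
  targets <- tibble::tibble(
    item_id = sprintf("I%02d", 1:5),
    domain = c("quality", "quality", "safety", "safety", "quality"),
    target = c("N", "A", "NecAv", "I", "rejected"))
  ratings <- generate_ratings(targets, n_panelists = 10, seed = 5,
                              scheme = "ram")
  rc <- ram_classify(ratings)
  expect_equal(rc$accepted_as[match(targets$item_id, rc$item_id)],
               targets$target)
  g <- glance(rc)
  expect_equal(g$n_items, 5)
  expect_equal(g$n_rejected, 1)
  expect_equal(nrow(tidy(rc)), 5)

  dtargets <- tibble::tibble(topic_id = c("T1", "T2", "T3"),
                             target = c("high", "priority", "rejected"))
  dl <- delphi_classify(generate_ratings(dtargets, 26, seed = 2,
                                         scheme = "delphi"))
  expect_equal(dl$priority[match(dtargets$topic_id, dl$topic_id)],
               dtargets$target)
  expect_equal(glance(dl)$n_high, 1)
})
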