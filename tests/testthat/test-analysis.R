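test_that("competition ranking shares minimal ranks and skips after ties", {
  tab <- data.frame(id = c("w", "x", "y", "z"),
                    efficiency = c(0.857, 0.564, 0.564, 0.553))
  rk <- rank_units(tab)
  expect_equal(rk$rank, c(1, 2, 2, 4))      # published tie pattern 6/7/7/9
  expect_equal(rank_units(data.frame(id = c("a", "b", "c"),
                                     efficiency = c(1, 1, 0.5)))$rank,
               c(1, 1, 3))
  expect_equal(rank_units(data.frame(id = "solo", efficiency = 0.4))$rank, 1)
})

test_that("ranking is invariant to input permutation and ties break by id", {
  tab <- data.frame(id = c("d", "b", "a", "c"),
                    efficiency = c(0.5, 0.9, 0.9, 0.2))
  rk1 <- rank_units(tab)
  rk2 <- rank_units(tab[sample(4), ])
  expect_identical(rk1, rk2)
  expect_identical(rk1$id, c("a", "b", "d", "c"))
  expect_equal(rk1$rank, c(1, 1, 3, 4))
  expect_error(rank_units(rbind(tab, tab[1, ])), "duplicate")
})

test_that("era comparison splits inclusively and averages exactly", {
  sch <- rdm_schema(c("x", "y"), c("input", "desirable_output"))
  pan <- rdm_panel(data.frame(id = c("old", "new"),
                              approval_year = c(2005, 2015),
                              x = c(1, 1), y = c(1, 2)), sch)
  res <- data.frame(id = c("old", "new"), efficiency = c(0.2, 0.8))
  era <- era_compare(res, pan, 2010)
  expect_equal(era$pre_mean, 0.2)
  expect_equal(era$post_mean, 0.8)
  expect_equal(era$pre_count + era$post_count, 2)
  expect_true(era$inclusive_post)

  # threshold year itself belongs to the post era
  pan2 <- rdm_panel(data.frame(id = c("a", "b"), approval_year = c(2010, 2009),
                               x = c(1, 1), y = c(1, 2)), sch)
  era2 <- era_compare(data.frame(id = c("a", "b"), efficiency = c(0.6, 0.4)),
                      pan2, 2010)
  expect_equal(era2$post_mean, 0.6)
  expect_equal(era2$pre_mean, 0.4)
})

test_that("an empty era reports an undefined mean with counts intact", {
  sch <- rdm_schema(c("x", "y"), c("input", "desirable_output"))
  pan <- rdm_panel(data.frame(id = c("a", "b"), approval_year = c(2012, 2012),
                              x = c(1, 1), y = c(1, 2)), sch)
  era <- era_compare(data.frame(id = c("a", "b"), efficiency = c(0.3, 0.7)),
                     pan, 2010)
  expect_identical(era$pre_count, 0L)
  expect_true(is.na(era$pre_mean))
  expect_equal(era$post_mean, 0.5)
})

test_that("planted efficiencies and years average as hand-computed", {
  sch <- rdm_schema(c("x", "y"), c("input", "desirable_output"))
  eff <- c(0.1, 0.3, 0.6, 0.8, 1.0)
  yrs <- c(1999, 2005, 2010, 2015, 2020)
  pan <- rdm_panel(data.frame(id = letters[1:5], approval_year = yrs,
                              x = rep(1, 5), y = 1:5), sch)
  era <- era_compare(data.frame(id = letters[1:5], efficiency = eff), pan, 2010)
  expect_equal(era$pre_mean, mean(c(0.1, 0.3)))
  expect_equal(era$post_mean, mean(c(0.6, 0.8, 1.0)))
  expect_equal(era$pre_count, 2L)
  expect_equal(era$post_count, 3L)
})

test_that("units without an approval year are excluded with a warning", {
  sch <- rdm_schema(c("x", "y"), c("input", "desirable_output"))
  pan <- rdm_panel(data.frame(id = c("a", "b", "c"),
                              approval_year = c(2000, NA, 2015),
                              x = c(1, 1, 1), y = 1:3), sch)
  res <- data.frame(id = c("a", "b", "c"), efficiency = c(0.2, 0.5, 0.9))
  expect_warning(era <- era_compare(res, pan, 2010), "without approval year")
  expect_identical(era$excluded, "b")
  expect_equal(era$pre_count + era$post_count, 2)
  expect_warning(tl <- efficiency_timeline(res, pan), "without approval year")
  expect_identical(tl$id, c("a", "c"))
})

test_that("slack summary tallies largest-slack variables over inefficient units", {
  mk <- function(id, largest) {
    structure(list(unit_id = id,
                   raw = c(x = 0), normalized = c(x = 0),
                   largest = largest, lambda = NULL, theta_star = 0.2),
              class = "rdm_slacks")
  }
  reports <- list(mk("a", "dose"), mk("b", "dose"), mk("c", "hba1c"),
                  mk("d", NA_character_))
  sm <- slack_summary(reports)
  expect_equal(unname(sm["dose"]), 2L)
  expect_equal(unname(sm["hba1c"]), 1L)
  expect_equal(sum(sm), 3L)  # the all-zero unit is excluded
  expect_identical(slack_summary(reports[sample(4)]), sm)
  expect_length(slack_summary(list(mk("a", NA_character_))), 0)
})

test_that("slack summary on a real panel counts the planted driver once", {
  pan <- slack_panel()
  run <- lapply(unit_ids(pan), function(id)
    compute_slacks(pan, id, solve_rdm(pan, id)))
  sm <- slack_summary(run)
  expect_equal(unname(sm["y"]), 1L)
  expect_equal(sum(sm), 1L)
})

test_that("the timeline sorts by year then id without aggregation", {
  sch <- rdm_schema(c("x", "y"), c("input", "desirable_output"))
  pan <- rdm_panel(data.frame(id = c("b2", "a1", "c3"),
                              approval_year = c(2017, 1995, 2017),
                              x = c(1, 1, 1), y = 1:3), sch)
  res <- data.frame(id = c("b2", "a1", "c3"), efficiency = c(0.5, 0.6, 0.7))
  tl <- efficiency_timeline(res, pan)
  expect_identical(tl$id, c("a1", "b2", "c3"))
  expect_identical(names(tl), c("approval_year", "id", "efficiency"))
  expect_equal(nrow(tl), 3)
})
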