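test_that("the generator is deterministic under a fixed seed", {
  p1 <- generate_panel(seed = 11)
  p2 <- generate_panel(seed = 11)
  expect_identical(p1, p2)
  p3 <- generate_panel(seed = 12)
  expect_false(identical(p1$data, p3$data))
})

test_that("class draws hit their distributional targets", {
  # Glinides-like class: weight change mean -2.815, sd 0.47
  cp <- class_params("glinide_like", c(2, 3), 0.45, 0.005, -2.815, 0.47,
                     units_per_class = 1000L)
  pan <- generate_panel(list(cp), seed = 5)
  w <- pan$data$weight_change
  se <- 0.47 / sqrt(1000)
  expect_lt(abs(mean(w) - (-2.815)), 3 * se)
  expect_true(any(w < 0))                       # weight-gain class
  expect_true(all(pan$data$hba1c_reduction > 0))
  expect_true(all(pan$data$dose_frequency %in% c(2, 3)))
  expect_true(all(pan$data$mortality_or > 0))
})

test_that("zero-sd classes produce identical units", {
  cp <- class_params("const", 1, 0.8, 0, -2.2, 0, 0.05, 0,
                     units_per_class = 4L, year_range = c(2001L, 2001L))
  pan <- generate_panel(list(cp), seed = 9)
  vals <- pan$data[, c("dose_frequency", "hba1c_reduction", "weight_change",
                       "mortality_or")]
  expect_true(all(vapply(vals, function(v) length(unique(v)) == 1,
                         logical(1))))
})

test_that("default parameters give both model configurations", {
  pan <- generate_panel(seed = 3)
  expect_true("mortality_or" %in% pan$schema$name)
  expect_identical(
    pan$schema$role[pan$schema$name == "mortality_or"], "undesirable_output")
  pan_b <- generate_panel(seed = 3, include_mortality = FALSE)
  expect_false("mortality_or" %in% names(pan_b$data))
  expect_equal(n_units(pan), 38)                # class sizes sum to 38
  expect_error(generate_panel(list(), seed = 1), "non-empty")
})

test_that("planting solves the fixed-point displacement exactly", {
  sch <- rdm_schema(c("x", "y"), c("input", "desirable_output"))
  pan <- rdm_panel(data.frame(id = c("A", "B"), x = c(1, 2), y = c(2, 4)), sch)
  u <- plant_inefficient_unit(pan, c(x = 1.5, y = 3), 0.5, id = "P")
  expect_equal(u$x, 2)            # (1.5 - 0.5*1) / 0.5
  expect_equal(u$y, 2)            # (3 - 0.5*4) / 0.5
  pan2 <- rdm_panel(rbind(pan$data, u), sch)
  expect_theta(pan2, "P", 0.5)

  # theta = 0 reduces to the identity
  u0 <- plant_inefficient_unit(pan, c(x = 1.5, y = 3), 0, id = "Q")
  expect_equal(u0$x, 1.5)
  expect_equal(u0$y, 3)

  expect_error(plant_inefficient_unit(pan, c(x = 1.5, y = 3), 1), "\\[0, 1\\)")
  # an anchor below the input minimum would move the panel extreme
  expect_error(plant_inefficient_unit(pan, c(x = 0.5, y = 3), 0.5),
               "minimum of `x`")
})

test_that("recovery instances return the planted scores", {
  inst <- generate_recovery_instance(5, c(0.25, 0.5, 0.75), seed = 21)
  tab <- as.data.frame(evaluate_all(inst$panel))
  for (id in names(inst$planted)) {
    expect_equal(tab$theta_star[tab$id == id], unname(inst$planted[id]),
                 tolerance = 1e-6)
  }
  # frontier vertices stay efficient
  front <- grep("^frontier", tab$id)
  expect_equal(tab$efficiency[front], rep(1, length(front)))

  expect_identical(generate_recovery_instance(5, c(0.3), seed = 2),
                   generate_recovery_instance(5, c(0.3), seed = 2))
  empty <- generate_recovery_instance(3, numeric(0), seed = 4)
  expect_equal(as.data.frame(evaluate_all(empty$panel))$efficiency,
               rep(1, 3))
})

test_that("vertex-anchored planting can only understate the score", {
  sch <- rdm_schema(c("x", "y"), c("input", "desirable_output"))
  pan <- rdm_panel(data.frame(id = c("A", "B", "C"),
                              x = c(1, 2, 4), y = c(2, 4, 5)), sch)
  # anchor exactly at vertex B
  u <- plant_inefficient_unit(pan, c(x = 2, y = 4), 0.4, id = "V")
  pan2 <- rdm_panel(rbind(pan$data, u), sch)
  res <- solve_rdm(pan2, "V")
  expect_gte(res$theta_star, 0.4 - 1e-9)
})
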