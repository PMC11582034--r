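test_that("ranges follow the min/max definitions per role", {
  sch <- rdm_schema(c("x", "y", "z"),
                    c("input", "desirable_output", "undesirable_output"))
  pan <- rdm_panel(
    data.frame(id = c("u1", "u2", "u3"),
               x = c(1, 2, 3), y = c(2, 4, 4), z = c(0.8, 1.2, 1.0)), sch)
  r <- compute_ranges(pan, "u2")
  expect_equal(unname(r$input), 1)        # 2 - min(1,2,3)
  expect_equal(unname(r$desirable), 0)    # u2 attains the max
  expect_equal(unname(r$undesirable), 0.4)
  # zero exactly at the panel extreme, positive otherwise
  r3 <- compute_ranges(pan, "u3")
  expect_true(all(c(r3$input, r3$desirable, r3$undesirable) >= 0))
  expect_equal(unname(r3$desirable), 0)
  expect_gt(r3$input, 0)
})

test_that("empty roles give empty range vectors, not errors", {
  pan <- random_panel(4, m = 2, s = 1, h = 0, seed = 3)
  r <- compute_ranges(pan, 1)
  expect_length(r$undesirable, 0)
  expect_length(r$input, 2)
})

test_that("the hand-solved fixture gives theta* = 0.5 with an even split", {
  res <- expect_theta(tri_panel(), "C", 0.5)
  expect_equal(res$efficiency, 0.5, tolerance = 1e-9)
  expect_setequal(res$reference_set, c("A", "B"))
  expect_equal(unname(res$lambda[c("A", "B")]), c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(sum(res$lambda), 1, tolerance = 1e-9)
})

test_that("negative desirable outputs are handled (score 1 against the range)", {
  sch <- rdm_schema(c("x", "y"), c("input", "desirable_output"))
  pan <- rdm_panel(data.frame(id = c("A", "B"), x = c(1, 1), y = c(5, -5)), sch)
  res <- expect_theta(pan, "B", 1)   # R_y = 10, lambda_A = 1 binds at theta = 1
  expect_equal(res$efficiency, 0, tolerance = 1e-9)
})

test_that("an undesirable output alone can drive full inefficiency", {
  sch <- rdm_schema(c("x", "y", "z"),
                    c("input", "desirable_output", "undesirable_output"))
  pan <- rdm_panel(data.frame(id = c("A", "B"), x = c(1, 1),
                              y = c(2, 2), z = c(0.8, 1.2)), sch)
  expect_theta(pan, "B", 1)          # R_z = 0.4: 0.8 + 0.4 theta <= 1.2
  expect_theta(pan, "A", 0)
})

test_that("the all-extremes unit is efficient by the zero-range convention", {
  sch <- rdm_schema(c("x", "y"), c("input", "desirable_output"))
  pan <- rdm_panel(data.frame(id = c("best", "other", "worse"),
                              x = c(1, 2, 3), y = c(5, 3, 1)), sch)
  res <- expect_theta(pan, "best", 0)
  expect_equal(res$efficiency, 1)
  expect_identical(res$reference_set, "best")
})

test_that("evaluate_all returns one result per unit in panel order", {
  pan <- tri_panel()
  res <- evaluate_all(pan)
  tab <- as.data.frame(res)
  expect_identical(tab$id, c("A", "B", "C"))
  expect_equal(tab$efficiency, c(1, 1, 0.5), tolerance = 1e-9)
})

test_that("identical units are all efficient", {
  sch <- rdm_schema(c("x", "y"), c("input", "desirable_output"))
  pan <- rdm_panel(data.frame(id = sprintf("u%d", 1:5),
                              x = rep(2, 5), y = rep(3, 5)), sch)
  tab <- as.data.frame(evaluate_all(pan))
  expect_equal(tab$theta_star, rep(0, 5))
  expect_equal(tab$efficiency, rep(1, 5))
})

test_that("intensity weights are a probability vector at every solution", {
  for (seed in 1:10) {
    pan <- random_panel(8, m = 2, s = 2, h = 1, seed = seed)
    for (res in evaluate_all(pan)) {
      expect_equal(sum(res$lambda), 1, tolerance = 1e-8)
      expect_true(all(res$lambda >= 0))
      expect_true(res$theta_star >= 0 && res$theta_star <= 1)
    }
  }
})

test_that("reference weights renormalize above the threshold", {
  res <- solve_rdm(tri_panel(), "C")
  w <- reference_weights(res, 0.01)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_setequal(names(w), c("A", "B"))
  expect_equal(unname(w), c(0.5, 0.5), tolerance = 1e-9)

  eff <- solve_rdm(tri_panel(), "A")
  expect_equal(reference_weights(eff, 0.01), c(A = 1))

  expect_error(reference_weights(res, 0), "0, 1")
  expect_error(reference_weights(res, 1), "0, 1")
  # pigeonhole: threshold below 1/n can never empty the set
  for (seed in 1:5) {
    pan <- random_panel(6, seed = seed)
    for (r in evaluate_all(pan)) {
      expect_gt(length(reference_weights(r, 1 / 6 - 1e-9)), 0)
    }
  }
})

test_that("results are bitwise-identical across repeated runs", {
  pan <- random_panel(12, m = 2, s = 2, h = 1, seed = 7)
  r1 <- evaluate_all(pan)
  r2 <- evaluate_all(pan)
  expect_identical(r1, r2)
})
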