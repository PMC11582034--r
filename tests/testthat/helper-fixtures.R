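# Fixtures shared across the suite. All panels are built in code.

# Hand-solved 3-unit fixture: evaluating C gives theta* = 0.5 with
# references A and B at weight 0.5 each (max over a of min(a, 1 - a)).
tri_panel <- function() {
  rdm_panel(
    data.frame(id = c("A", "B", "C"), x = c(1, 2, 2), y = c(2, 4, 2)),
    rdm_schema(c("x", "y"), c("input", "desirable_output"))
  )
}

# Hand-solved positive-slack fixture (input / desirable / undesirable):
# evaluating o, the undesirable row pins lambda_A = 0, the input row binds
# at theta* = 0.1, and the desirable output retains a residual slack of
# 0.2 raw (0.1 normalized by its range of 2).
slack_panel <- function() {
  rdm_panel(
    data.frame(id = c("A", "B", "o"),
               x = c(1, 1.9, 2), y = c(4, 2.4, 2), z = c(1, 0.5, 0.5)),
    rdm_schema(c("x", "y", "z"),
               c("input", "desirable_output", "undesirable_output"))
  )
}

# Random panel with m inputs, s desirable and h undesirable outputs;
# outputs span negative values.
random_panel <- function(n, m = 1, s = 1, h = 0, seed = 1) {
  set.seed(seed)
  tab <- data.frame(id = sprintf("u%02d", seq_len(n)),
                    stringsAsFactors = FALSE)
  nm <- character(0); role <- character(0)
  for (j in seq_len(m)) {
    v <- paste0("x", j); tab[[v]] <- stats::runif(n, 0.5, 5)
    nm <- c(nm, v); role <- c(role, "input")
  }
  for (r in seq_len(s)) {
    v <- paste0("y", r); tab[[v]] <- stats::rnorm(n, 1, 3)
    nm <- c(nm, v); role <- c(role, "desirable_output")
  }
  if (h > 0) for (f in seq_len(h)) {
    v <- paste0("z", f); tab[[v]] <- stats::rnorm(n, 1, 1.5)
    nm <- c(nm, v); role <- c(role, "undesirable_output")
  }
  rdm_panel(tab, rdm_schema(nm, role))
}

expect_theta <- function(panel, o, expected, tol = 1e-9) {
  res <- solve_rdm(panel, o)
  expect_equal(res$status, "optimal")
  expect_equal(res$theta_star, expected, tolerance = tol)
  invisible(res)
}
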