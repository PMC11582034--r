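#' Solver settings for the range directional model
#'
#' @param lp_eps Pivot / feasibility tolerance of the simplex routine.
#' @param efficiency_tol A unit is declared efficient when its inefficiency
#'   score falls below this tolerance.
#' @param reference_tol Intensity weights below this value are dropped from
#'   the reported reference set.
#' @param zero_range_tol Ranges below this value are treated as exactly zero
#'   (the unit already attains the panel extreme for that variable).
#' @return A list of class `rdm_control`.
#' @export
rdm_control <- function(lp_eps = 1e-9, efficiency_tol = 1e-7,
                        reference_tol = 1e-6, zero_range_tol = 1e-12) {
  stopifnot(lp_eps > 0, efficiency_tol > 0, reference_tol > 0,
            zero_range_tol >= 0)
  structure(list(lp_eps = lp_eps, efficiency_tol = efficiency_tol,
                 reference_tol = reference_tol,
                 zero_range_tol = zero_range_tol),
            class = "rdm_control")
}

#' Ranges of possible improvement for one unit
#'
#' For the evaluated unit o the range directional model defines, per input
#' \eqn{j}, \eqn{R^x_{oj} = x_{oj} - \min_i x_{ij}}; per desirable output
#' \eqn{r}, \eqn{R^y_{or} = \max_i y_{ir} - y_{or}}; and per undesirable
#' output \eqn{f}, \eqn{R^z_{of} = z_{of} - \min_i z_{if}} (an undesirable
#' output improves downward, so its range takes the input form). Each range
#' is the largest contraction/expansion the panel itself evidences, is
#' non-negative by construction even with negative data, and is zero exactly
#' when the unit already attains the panel extreme.
#'
#' @param panel An [rdm_panel()].
#' @param o Unit id (or index) of the evaluated unit.
#' @return A list of class `rdm_ranges` with named numeric vectors
#'   `input`, `desirable`, `undesirable` (empty when the schema has no
#'   variable of that role).
#' @examples
#' sch <- rdm_schema(c("x", "y"), c("input", "desirable_output"))
#' pan <- rdm_panel(data.frame(id = c("A", "B", "C"),
#'                             x = c(1, 2, 2), y = c(2, 4, 2)), sch)
#' compute_ranges(pan, "C")  # R_x = 1, R_y = 2
#' @export
compute_ranges <- function(panel, o) {
  stopifnot(inherits(panel, "rdm_panel"))
  i <- unit_index(panel, o)
  rng <- function(M, sense) {
    if (ncol(M) == 0) return(stats::setNames(numeric(0), character(0)))
    if (sense == "min") M[i, ] - apply(M, 2, min) else apply(M, 2, max) - M[i, ]
  }
  structure(list(
    unit_id = unit_ids(panel)[i],
    input = rng(panel$X, "min"),
    desirable = rng(panel$Y, "max"),
    undesirable = rng(panel$Z, "min")
  ), class = "rdm_ranges")
}

# Assemble the envelopment rows common to phase I and phase II.
# Rows are scaled by the evaluated unit's range where positive (so the
# tableau is invariant to a rescaling of any variable column) and
# sign-normalized afterwards because the simplex backend requires b >= 0.
rdm_rows <- function(panel, i, ranges, ctrl) {
  X <- panel$X; Y <- panel$Y; Z <- panel$Z
  list(
    # sense: -1 => sum(lambda * col) + theta * R <= v_o   (inputs, undesirable)
    #        +1 => sum(lambda * col) - theta * R >= v_o   (desirable)
    cols = cbind(X, Y, Z),
    sense = c(rep(-1L, ncol(X)), rep(1L, ncol(Y)), rep(-1L, ncol(Z))),
    R = c(ranges$input, ranges$desirable, ranges$undesirable),
    rhs = c(X[i, ], Y[i, ], Z[i, ]),
    zero = c(ranges$input, ranges$desirable, ranges$undesirable) <= ctrl$zero_range_tol
  )
}

#' Solve the range directional model for one unit
#'
#' Maximizes the inefficiency score \eqn{\theta} subject to the variable
#' returns-to-scale envelopment constraints
#' \deqn{\sum_i \lambda_i x_{ij} + \theta R^x_{oj} \le x_{oj}, \quad
#'       \sum_i \lambda_i y_{ir} - \theta R^y_{or} \ge y_{or}, \quad
#'       \sum_i \lambda_i z_{if} + \theta R^z_{of} \le z_{of},}
#' \eqn{\sum_i \lambda_i = 1}, \eqn{\lambda \ge 0}, with \eqn{\theta}
#' bounded in \eqn{[0, 1]}. The program has \eqn{n + 1} decision variables
#' and is always feasible (\eqn{\lambda_o = 1}, \eqn{\theta = 0}).
#' Efficiency is \eqn{1 - \theta^*}; a unit on the frontier scores 1.
#'
#' When every range of the evaluated unit is zero the unit is the panel's
#' ideal point; the \eqn{\theta} coefficients all vanish and the score is 0
#' by convention (the unit is efficient).
#'
#' The intensity weights \eqn{\lambda} returned are one optimal vertex;
#' alternate optima may admit different reference decompositions.
#'
#' @inheritParams compute_ranges
#' @param control An [rdm_control()].
#' @return An object of class `rdm_result`: list with `unit_id`,
#'   `theta_star`, `efficiency`, `lambda` (named, sums to 1),
#'   `reference_set`, `ranges`, and `status` (`"optimal"` or
#'   `"numerical_failure"`; an infeasible LP is impossible and raises).
#' @examples
#' sch <- rdm_schema(c("x", "y"), c("input", "desirable_output"))
#' pan <- rdm_panel(data.frame(id = c("A", "B", "C"),
#'                             x = c(1, 2, 2), y = c(2, 4, 2)), sch)
#' solve_rdm(pan, "C")  # theta* = 0.5, references A and B
#' @export
solve_rdm <- function(panel, o, control = rdm_control()) {
  stopifnot(inherits(panel, "rdm_panel"))
  i <- unit_index(panel, o)
  id <- unit_ids(panel)[i]
  n <- n_units(panel)
  ranges <- compute_ranges(panel, i)
  rows <- rdm_rows(panel, i, ranges, control)

  lam0 <- stats::setNames(numeric(n), unit_ids(panel))
  lam0[i] <- 1
  if (all(rows$zero)) {
    # ideal point: theta's coefficient vanishes in every envelopment row
    return(new_rdm_result(id, 0, lam0, "optimal", ranges, control))
  }

  # decision variables v = (theta, lambda_1..lambda_n)
  scale <- ifelse(rows$zero, pmax(apply(abs(rows$cols), 2, max), 1), rows$R)
  coef <- cbind(theta = ifelse(rows$zero, 0, -rows$sense * rows$R) / scale,
                t(rows$cols) / scale)
  rhs <- rows$rhs / scale
  sense <- rows$sense
  # convexity and theta <= 1
  coef <- rbind(coef, c(0, rep(1, n)), c(1, rep(0, n)))
  rhs <- c(rhs, 1, 1)
  sense <- c(sense, 0L, -1L)
  objective <- c(1, rep(0, n))

  sol <- lp_solve(objective, coef, sense, rhs, tol = control$lp_eps)
  if (sol$status == "infeasible") {
    stop("RDM LP reported infeasible for unit `", id,
         "`; the program is always feasible, so this is an internal error",
         call. = FALSE)
  }
  if (sol$status != "optimal") {
    return(new_rdm_result(id, NA_real_, NULL, "numerical_failure",
                          ranges, control))
  }
  theta <- min(max(sol$x[1], 0), 1)
  lambda <- stats::setNames(sol$x[-1], unit_ids(panel))
  lambda[lambda < 0] <- 0
  s <- sum(lambda)
  if (abs(s - 1) > 1e-6) {
    return(new_rdm_result(id, NA_real_, NULL, "numerical_failure",
                          ranges, control))
  }
  lambda <- lambda / s
  new_rdm_result(id, theta, lambda, "optimal", ranges, control)
}

new_rdm_result <- function(id, theta, lambda, status, ranges, control) {
  eff <- if (is.na(theta)) NA_real_ else 1 - theta
  if (!is.na(theta) && theta < control$efficiency_tol) {
    theta <- 0
    eff <- 1
  }
  refs <- if (is.null(lambda)) character(0) else
    names(lambda)[lambda > control$reference_tol]
  structure(list(unit_id = id, theta_star = theta, efficiency = eff,
                 lambda = lambda, reference_set = refs,
                 ranges = ranges, status = status),
            class = "rdm_result")
}

#' @export
print.rdm_result <- function(x, ...) {
  cat("<rdm_result> unit ", x$unit_id, ": theta* = ",
      format(x$theta_star, digits = 6), ", efficiency = ",
      format(x$efficiency, digits = 6), " [", x$status, "]\n", sep = "")
  if (length(x$reference_set)) {
    w <- x$lambda[x$reference_set]
    cat("references:", paste(sprintf("%s (%.3f)", names(w), w),
                             collapse = ", "), "\n")
  }
  invisible(x)
}

#' Evaluate every unit of a panel
#'
#' Solves the range directional LP once per unit, in panel order. The run is
#' deterministic: identical panels and options give identical results.
#'
#' @inheritParams solve_rdm
#' @param on_failure `"error"` (default) aborts naming the failing unit;
#'   `"keep"` retains per-unit `numerical_failure` results.
#' @return An object of class `rdm_result_set`: a list of [solve_rdm()]
#'   results with a data-frame summary via [as.data.frame()].
#' @examples
#' sch <- rdm_schema(c("x", "y"), c("input", "desirable_output"))
#' pan <- rdm_panel(data.frame(id = c("A", "B", "C"),
#'                             x = c(1, 2, 2), y = c(2, 4, 2)), sch)
#' as.data.frame(evaluate_all(pan))
#' @export
evaluate_all <- function(panel, control = rdm_control(),
                         on_failure = c("error", "keep")) {
  stopifnot(inherits(panel, "rdm_panel"))
  on_failure <- match.arg(on_failure)
  out <- vector("list", n_units(panel))
  names(out) <- unit_ids(panel)
  for (i in seq_len(n_units(panel))) {
    res <- solve_rdm(panel, i, control)
    if (res$status != "optimal" && on_failure == "error") {
      stop("solver failure for unit `", res$unit_id, "` (status: ",
           res$status, ")", call. = FALSE)
    }
    out[[i]] <- res
  }
  structure(out, class = "rdm_result_set")
}

#' @export
as.data.frame.rdm_result_set <- function(x, ...) {
  data.frame(
    id = vapply(x, `[[`, character(1), "unit_id"),
    theta_star = vapply(x, `[[`, numeric(1), "theta_star"),
    efficiency = vapply(x, `[[`, numeric(1), "efficiency"),
    status = vapply(x, `[[`, character(1), "status"),
    reference_set = vapply(x, function(r)
      paste(r$reference_set, collapse = ";"), character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' @export
print.rdm_result_set <- function(x, ...) {
  cat("<rdm_result_set> ", length(x), " units\n", sep = "")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Reference decomposition of a benchmarked unit
#'
#' Filters the optimal intensity weights to those above a reporting
#' threshold and renormalizes them to sum to one, giving the linear
#' combination of frontier peers against which the unit is benchmarked
#' (e.g. a drug benchmarked against 0.783 of one peer and 0.217 of
#' another). Because the optimal basis need not be unique, this is one
#' valid decomposition, not the only one.
#'
#' @param result An optimal [solve_rdm()] result.
#' @param threshold Weights at or below this value are dropped; must lie in
#'   (0, 1). Any threshold below 1/n is guaranteed to leave at least one
#'   peer (weights sum to 1).
#' @return Named numeric vector of renormalized weights, sorted decreasing.
#' @export
reference_weights <- function(result, threshold = 0.01) {
  stopifnot(inherits(result, "rdm_result"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1) {
    stop("`threshold` must be a single number in (0, 1)", call. = FALSE)
  }
  if (result$status != "optimal") {
    stop("reference weights require an optimal result", call. = FALSE)
  }
  w <- result$lambda[result$lambda > threshold]
  if (!length(w)) {
    stop("no weight exceeds the threshold; lower `threshold` (any value ",
         "below 1/n always retains a peer)", call. = FALSE)
  }
  sort(w / sum(w), decreasing = TRUE)
}
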