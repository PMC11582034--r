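#' Residual slacks of a benchmarked unit (phase II)
#'
#' After the proportional move by \eqn{\theta^*} along the unit's own
#' range direction, residual gaps to the frontier benchmark may remain.
#' With \eqn{\theta} fixed at \eqn{\theta^*} this second phase maximizes the
#' sum of range-normalized slacks subject to the same intensity-weight
#' constraints:
#' \deqn{s^x_j = x_{oj} - \theta^* R^x_{oj} - \textstyle\sum_i \lambda_i x_{ij},
#' \quad s^y_r = \textstyle\sum_i \lambda_i y_{ir} - \theta^* R^y_{or} - y_{or},}
#' and analogously \eqn{s^z_f} for undesirable outputs, all \eqn{\ge 0}.
#' Normalizing each slack by its variable's range makes slacks dimensionless
#' and comparable across variables measured in different units (doses per
#' day versus percentage points of HbA1c); a variable whose range is zero has
#' its normalized slack defined as 0. The variable carrying the largest
#' normalized slack names the factor that drives the unit's remaining
#' inefficiency. A strongly efficient unit has all slacks zero; a weakly
#' efficient unit (\eqn{\theta^* = 0}) may still carry positive slacks.
#'
#' @inheritParams solve_rdm
#' @param result The optimal [solve_rdm()] result for `o` on `panel`.
#' @return An object of class `rdm_slacks`: list with `unit_id`,
#'   `raw` and `normalized` named slack vectors over all schema variables,
#'   `largest` (variable name with the largest normalized slack, or `NA`
#'   when all slacks are zero), and `lambda` (the phase-II weights).
#' @examples
#' sch <- rdm_schema(c("x", "y"), c("input", "desirable_output"))
#' pan <- rdm_panel(data.frame(id = c("A", "B", "C", "D"),
#'                             x = c(1, 2, 2, 3), y = c(2, 4, 2, 2)), sch)
#' res <- solve_rdm(pan, "D")
#' compute_slacks(pan, "D", res)
#' @export
compute_slacks <- function(panel, o, result, control = rdm_control()) {
  stopifnot(inherits(panel, "rdm_panel"), inherits(result, "rdm_result"))
  i <- unit_index(panel, o)
  id <- unit_ids(panel)[i]
  if (!identical(result$unit_id, id)) {
    stop("`result` is for unit `", result$unit_id,
         "` but `o` resolves to `", id, "`", call. = FALSE)
  }
  if (result$status != "optimal" || is.na(result$theta_star)) {
    stop("slack computation requires an optimal phase-I result", call. = FALSE)
  }
  n <- n_units(panel)
  ranges <- compute_ranges(panel, i)
  rows <- rdm_rows(panel, i, ranges, control)
  p <- length(rows$rhs)
  var_names <- colnames(rows$cols)

  solve_phase2 <- function(theta) {
    # variables: (lambda_1..n, s_1..p); slack of a positive-range row is the
    # normalized slack directly (its row is divided by the range), so the
    # objective is a plain sum over those slacks.
    scale <- ifelse(rows$zero, pmax(apply(abs(rows$cols), 2, max), 1), rows$R)
    lam_block <- t(rows$cols) / scale
    slack_sign <- ifelse(rows$sense == -1L, 1, -1)  # <= rows: sum + s = rhs
    coef <- cbind(lam_block, diag(slack_sign, p, p))
    rhs <- (rows$rhs - ifelse(rows$zero, 0, -rows$sense * rows$R) * theta) /
      scale
    coef <- rbind(coef, c(rep(1, n), rep(0, p)))
    rhs <- c(rhs, 1)
    sense <- rep(0L, p + 1L)
    objective <- c(rep(0, n), ifelse(rows$zero, 0, 1))
    lp_solve(objective, coef, sense, rhs, tol = control$lp_eps)
  }

  theta <- result$theta_star
  sol <- solve_phase2(theta)
  if (sol$status != "optimal" && theta > 0) {
    # a theta* at the edge of LP feasibility tolerance can starve phase II;
    # back off by a hair
    for (back in c(1e-11, 1e-9, 1e-7)) {
      sol <- solve_phase2(max(theta - back, 0))
      if (sol$status == "optimal") break
    }
  }
  if (sol$status != "optimal") {
    stop("phase-II slack LP failed for unit `", id, "` (status: ",
         sol$status, ")", call. = FALSE)
  }
  v <- sol$x
  lambda <- stats::setNames(pmax(v[seq_len(n)], 0), unit_ids(panel))
  lambda <- lambda / sum(lambda)
  s_scaled <- pmax(v[n + seq_len(p)], 0)
  normalized <- ifelse(rows$zero, 0, s_scaled)
  scale <- ifelse(rows$zero, pmax(apply(abs(rows$cols), 2, max), 1), rows$R)
  raw <- s_scaled * scale
  names(raw) <- names(normalized) <- var_names
  largest <- largest_slack(normalized, panel$schema)
  structure(list(unit_id = id, raw = raw, normalized = normalized,
                 largest = largest, lambda = lambda,
                 theta_star = result$theta_star),
            class = "rdm_slacks")
}

# Largest normalized slack; ties within 1e-9 go to the variable earliest in
# schema order (reported via a message so ties are visible in logs).
largest_slack <- function(normalized, schema, tol = 1e-9) {
  normalized <- normalized[schema$name]  # schema order
  mx <- max(normalized)
  if (mx <= tol) return(NA_character_)
  tied <- names(normalized)[normalized >= mx - tol]
  if (length(tied) > 1) {
    message("largest-slack tie between ", paste(tied, collapse = ", "),
            "; attributing to ", tied[1])
  }
  tied[1]
}

#' @export
print.rdm_slacks <- function(x, ...) {
  cat("<rdm_slacks> unit ", x$unit_id, "\n", sep = "")
  print(data.frame(variable = names(x$raw), raw = unname(x$raw),
                   normalized = unname(x$normalized)), row.names = FALSE)
  cat("largest normalized slack:",
      if (is.na(x$largest)) "none (on frontier projection)" else x$largest,
      "\n")
  invisible(x)
}
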