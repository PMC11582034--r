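# Dense two-phase primal simplex with Bland's anti-cycling rule.
#
# The envelopment programs solved here are tiny (a handful of rows, one
# column per unit) but routinely degenerate: identical units duplicate
# rows, zero ranges null out coefficients, and the phase-II slack program
# is equality-constrained. A textbook tableau simplex with Bland's rule is
# exact up to floating point, terminates on degenerate programs, and is
# fully deterministic, which the result contract requires.

#' Solve a small linear program
#'
#' Maximizes `objective %*% x` subject to `coef %*% x (<=|=|>=) rhs` and
#' `x >= 0`, with the row sense given as -1 (`<=`), 0 (`=`) or 1 (`>=`).
#' Two-phase primal simplex; Bland's rule makes cycling impossible and the
#' pivot sequence deterministic.
#'
#' @param objective Objective coefficients (maximized).
#' @param coef Constraint matrix.
#' @param sense Integer vector of row senses (-1, 0, 1).
#' @param rhs Right-hand sides (any sign).
#' @param tol Pivot / feasibility tolerance.
#' @param max_iter Iteration cap across both phases.
#' @return List with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"iteration_limit"`), `x` (solution, structural variables only) and
#'   `value` (objective at `x`).
#' @keywords internal
lp_solve <- function(objective, coef, sense, rhs, tol = 1e-9,
                     max_iter = 20000L) {
  coef <- as.matrix(coef)
  m <- nrow(coef)
  n <- ncol(coef)
  stopifnot(length(objective) == n, length(sense) == m, length(rhs) == m)

  flip <- rhs < 0
  coef[flip, ] <- -coef[flip, , drop = FALSE]
  rhs[flip] <- -rhs[flip]
  sense[flip] <- -sense[flip]

  # standard form: slack (+1) for <=, surplus (-1) for >=
  n_ineq <- sum(sense != 0L)
  A <- cbind(coef, matrix(0, m, n_ineq))
  j <- n
  slack_col <- integer(m)
  for (i in seq_len(m)) {
    if (sense[i] != 0L) {
      j <- j + 1L
      A[i, j] <- if (sense[i] == -1L) 1 else -1
      slack_col[i] <- j
    }
  }
  n_tot <- n + n_ineq

  # initial basis: slack where it enters positively, else artificial
  basis <- integer(m)
  art_rows <- which(sense != -1L)
  n_art <- length(art_rows)
  if (n_art) {
    A <- cbind(A, matrix(0, m, n_art))
    for (k in seq_along(art_rows)) A[art_rows[k], n_tot + k] <- 1
  }
  basis[sense == -1L] <- slack_col[sense == -1L]
  basis[art_rows] <- n_tot + seq_len(n_art)

  T_ <- cbind(A, rhs)   # tableau kept in canonical form wrt the basis
  rhs_col <- ncol(T_)
  iter <- 0L

  run_phase <- function(cost) {
    # cost over all current columns; minimizes
    repeat {
      if (iter >= max_iter) return("iteration_limit")
      cb <- cost[basis]
      red <- cost - as.vector(crossprod(T_[, -rhs_col, drop = FALSE], cb))
      enter <- which(red < -tol)
      if (!length(enter)) return("optimal")
      enter <- enter[1L]                       # Bland: smallest index
      col <- T_[, enter]
      pos <- which(col > tol)
      if (!length(pos)) return("unbounded")
      ratio <- T_[pos, rhs_col] / col[pos]
      cand <- pos[ratio <= min(ratio) + tol]
      leave <- cand[which.min(basis[cand])]    # Bland: smallest basis label
      piv <- T_[leave, enter]
      T_[leave, ] <- T_[leave, ] / piv
      other <- setdiff(seq_len(m), leave)
      T_[other, ] <- T_[other, ] - outer(T_[other, enter], T_[leave, ])
      basis[leave] <- enter
      T_ <<- T_; basis <<- basis; iter <<- iter + 1L
    }
  }

  if (n_art) {
    cost1 <- c(rep(0, n_tot), rep(1, n_art))
    st <- run_phase(cost1)
    if (st != "optimal") return(list(status = st, x = NULL, value = NA_real_))
    phase1_val <- sum(cost1[basis] * T_[, rhs_col])
    if (phase1_val > 1e-7 * (1 + max(abs(rhs)))) {
      return(list(status = "infeasible", x = NULL, value = NA_real_))
    }
    # drive any artificial out of the basis (degenerate rows)
    drop_rows <- integer(0)
    for (i in which(basis > n_tot)) {
      pivcol <- which(abs(T_[i, seq_len(n_tot)]) > tol)
      if (length(pivcol)) {
        enter <- pivcol[1L]
        piv <- T_[i, enter]
        T_[i, ] <- T_[i, ] / piv
        other <- setdiff(seq_len(m), i)
        T_[other, ] <- T_[other, ] - outer(T_[other, enter], T_[i, ])
        basis[i] <- enter
      } else {
        drop_rows <- c(drop_rows, i)           # redundant row
      }
    }
    if (length(drop_rows)) {
      T_ <- T_[-drop_rows, , drop = FALSE]
      basis <- basis[-drop_rows]
      m <- nrow(T_)
    }
    T_ <- T_[, c(seq_len(n_tot), rhs_col), drop = FALSE]
    rhs_col <- n_tot + 1L
  }

  cost2 <- c(-objective, rep(0, n_ineq))
  st <- run_phase(cost2)
  if (st != "optimal") return(list(status = st, x = NULL, value = NA_real_))
  x <- numeric(n_tot)
  x[basis] <- T_[, rhs_col]
  x <- x[seq_len(n)]
  list(status = "optimal", x = x, value = sum(objective * x))
}
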