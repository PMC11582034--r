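# Independent grid-search oracle for the RDM score. Kept free of any LP
# machinery so it can cross-check solve_rdm in tests.

# All lattice points with n non-negative integer parts summing to g.
simplex_compositions <- function(n, g) {
  if (n == 1L) return(matrix(g, ncol = 1L))
  out <- vector("list", g + 1L)
  for (k in 0:g) {
    rest <- simplex_compositions(n - 1L, g - k)
    out[[k + 1L]] <- cbind(k, rest)
  }
  do.call(rbind, out)
}

# Largest feasible theta for each lambda (rows of L), vectorized.
# Positive-range rows bound theta by residual/range; zero-range rows are
# pure envelopment constraints (feasible or not). Result clamped to [0, 1];
# -Inf marks an infeasible lambda.
feasible_theta <- function(L, rows, tol = 1e-9) {
  M <- L %*% rows$cols                      # points x constraint-rows
  th <- rep(1, nrow(L))
  for (k in seq_along(rows$rhs)) {
    resid <- if (rows$sense[k] == -1L) rows$rhs[k] - M[, k] else M[, k] - rows$rhs[k]
    if (rows$zero[k]) {
      th[resid < -tol] <- -Inf
    } else {
      th <- pmin(th, resid / rows$R[k])
    }
  }
  th[th < 0 & is.finite(th)] <- ifelse(th[th < 0 & is.finite(th)] > -tol, 0, -Inf)
  th
}

#' Grid-search approximation of the RDM inefficiency score
#'
#' Searches intensity-weight vectors \eqn{\lambda} on a regular lattice over
#' the unit simplex; for each \eqn{\lambda} the largest feasible
#' \eqn{\theta} is available in closed form as the minimum, over constraints
#' with a positive range, of the scaled residual (zero-range constraints
#' only gate feasibility). The reported value is the maximum over the
#' search, clamped to \eqn{[0, 1]}. It never exceeds the true LP optimum,
#' and approaches it from below as the lattice is refined.
#'
#' When the full lattice at the requested resolution is small it is
#' enumerated exhaustively. Otherwise the search enumerates a coarse full
#' lattice and then refines around the incumbent with shrinking windows down
#' to a final step of `1/grid_points`; because the objective is a concave
#' piecewise-linear function of \eqn{\lambda}, window refinement retains the
#' global maximum to within the grid resolution.
#'
#' Intended as an independent test oracle for [solve_rdm()] on small panels
#' (n of about 6 or fewer).
#'
#' @inheritParams compute_ranges
#' @param grid_points Number of subdivisions per simplex axis at the final
#'   resolution; at least 50 recommended.
#' @param exhaustive_limit Enumerate the full lattice whenever it has at
#'   most this many points.
#' @return Approximate \eqn{\theta^*} (a lower bound up to the feasibility
#'   tolerance).
#' @export
brute_force_theta <- function(panel, o, grid_points = 500L,
                              exhaustive_limit = 2e5) {
  stopifnot(inherits(panel, "rdm_panel"), grid_points >= 1)
  i <- unit_index(panel, o)
  n <- n_units(panel)
  ranges <- compute_ranges(panel, i)
  ctrl <- rdm_control()
  rows <- rdm_rows(panel, i, ranges, ctrl)
  if (all(rows$zero)) return(0)

  best_of <- function(L) {
    th <- feasible_theta(L, rows)
    k <- which.max(th)
    list(theta = th[k], lambda = L[k, ])
  }

  lattice_size <- function(g) choose(g + n - 1, n - 1)
  if (lattice_size(grid_points) <= exhaustive_limit) {
    L <- simplex_compositions(n, as.integer(grid_points)) / grid_points
    return(max(best_of(L)$theta, 0))
  }

  # coarse full pass
  g0 <- as.integer(grid_points)
  while (lattice_size(g0) > exhaustive_limit) g0 <- ceiling(g0 / 2)
  L <- simplex_compositions(n, g0) / g0
  inc <- best_of(L)

  # window refinement around the incumbent, shrinking the step to the target
  offsets <- function(r) {
    d <- as.matrix(expand.grid(rep(list(-r:r), n - 1L)))
    cbind(d, -rowSums(d))
  }
  h <- 1 / g0
  target <- 1 / grid_points
  radius <- 4L
  repeat {
    h <- max(h / 3, target)
    # snap the incumbent onto the h-lattice so boundary points stay reachable
    c0 <- round(inc$lambda / h) * h
    c0[which.max(c0)] <- c0[which.max(c0)] + (1 - sum(c0))
    repeat {
      P <- sweep(offsets(radius) * h, 2, c0, "+")
      P <- P[rowSums(P < -1e-12) == 0, , drop = FALSE]
      P[P < 0] <- 0
      cand <- best_of(P)
      if (cand$theta <= inc$theta + 1e-12) {
        if (cand$theta > inc$theta) inc <- cand
        break
      }
      inc <- cand
      c0 <- inc$lambda  # re-center and keep sweeping at this step
    }
    if (h <= target) break
  }
  max(inc$theta, 0)
}
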