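# Exact minimization: depth-first branch-and-bound over the folded integer
# lattice, plus an exhaustive-enumeration oracle for verification.
#
# Night parity is substituted out before search: one night variable per
# skill stands for both cohorts, halving the dimensionality to six
# variables ordered by decreasing cost per delivered hour
# (nurse night, nurse morning, nurse afternoon, technician night,
# technician morning, technician afternoon).

# fold a 2x4 staff matrix into (Zn, Mn, An, Zt, Mt, At) and back
.fold_vars <- function(instance) {
  ms <- instance$min_staff
  ub <- instance$ub
  list(
    lb = c(max(ms[1L, 3:4]), ms[1L, 1L], ms[1L, 2L],
           max(ms[2L, 3:4]), ms[2L, 1L], ms[2L, 2L]),
    ub = c(max(ub[1L, 3:4]), ub[1L, 1L], ub[1L, 2L],
           max(ub[2L, 3:4]), ub[2L, 1L], ub[2L, 2L])
  )
}

.unfold_x <- function(v) {
  x <- rbind(c(v[2L], v[3L], v[1L], v[1L]),
             c(v[5L], v[6L], v[4L], v[4L]))
  dimnames(x) <- list(.SKILLS, .SHIFTS)
  x
}

# per-variable objective cost and an upper bound on attainable pre-TSI
# hours per unit (continuous relaxation, valid for every variant)
.var_profiles <- function(instance) {
  cm <- instance$cost_matrix
  L <- instance$lengths
  p <- instance$p
  v <- instance$variant
  m <- if (v$night_demand_hours == "both_cohorts") 2L else 1L
  cost <- c(cm[1L, 3L] + cm[1L, 4L], cm[1L, 1L], cm[1L, 2L],
            cm[2L, 3L] + cm[2L, 4L], cm[2L, 1L], cm[2L, 2L])
  if (v$tsi_scope == "per_cell") {
    hcap <- c(m * L[1L, 3L], L[1L, 1L], L[1L, 2L],
              m * L[2L, 3L], L[2L, 1L], L[2L, 2L]) / (1 + p)
  } else {
    best <- if (v$tsi_scope == "per_skill") {
      pmax(L[, 3L], apply(L[, 1:2, drop = FALSE], 1L, max))
    } else {
      rep(max(L), 2L)
    }
    hcap <- c(2 * best[1L], best[1L], best[1L],
              2 * best[2L], best[2L], best[2L]) / (1 + p)
  }
  # staff headcount each folded variable adds under the skill-mix counting
  w <- .prop_weights(v)
  count <- c(w[3L] + w[4L], w[1L], w[2L], w[3L] + w[4L], w[1L], w[2L])
  list(cost = cost, hcap = hcap, count = count)
}

.infeasible_stop <- function(instance, fold) {
  # diagnose with the most accommodating in-bounds candidate: everything at
  # its upper bound (balance kept by capping morning/afternoon jointly)
  ubv <- fold$ub
  for (k in c(2L, 5L)) {
    cap <- min(ubv[k], ubv[k + 1L])
    a <- instance$alpha[[if (k == 2L) 1L else 2L]]
    ubv[k] <- min(ubv[k], cap + a)
    ubv[k + 1L] <- min(ubv[k + 1L], cap + a)
  }
  sol <- staffing_solution(.unfold_x(ubv)[1L, ], .unfold_x(ubv)[2L, ])
  viol <- check_feasibility(sol, instance)
  fam <- if (nrow(viol) > 0L) viol$constraint[[1L]] else "bounds"
  stop(errorCondition(
    sprintf("staffing instance is infeasible within bounds (tightest family: %s)", fam),
    class = c("staffing_infeasible", "nursedim_error"),
    family = fam, violations = viol))
}

# greedy incumbent: start from the forced minima, add capacity on the
# cheapest day cells until demand is met, then nurses until the mix holds
.greedy_incumbent <- function(instance, fold, prof, tol = 1e-6) {
  v <- fold$lb
  add_day <- function(v, k) { # k = 2 for nurses, 5 for technicians
    a <- instance$alpha[[if (k == 2L) 1L else 2L]]
    lo <- if (v[k] <= v[k + 1L]) k else k + 1L
    hi <- if (lo == k) k + 1L else k
    if (abs(v[lo] + 1 - v[hi]) <= a) {
      v[lo] <- v[lo] + 1
    } else {
      v[lo] <- v[lo] + 1
      v[hi] <- v[hi] + 1
    }
    v
  }
  guard <- 0L
  repeat {
    hrs <- .best_hours(.unfold_x(v), instance)
    if (hrs >= instance$H - tol) break
    v <- add_day(v, 5L)
    guard <- guard + 1L
    if (guard > sum(fold$ub) + 8L || any(v > fold$ub)) return(NULL)
  }
  repeat {
    nurses <- sum(v[1:3] * prof$count[1:3])
    total <- nurses + sum(v[4:6] * prof$count[4:6])
    if (nurses >= instance$prop * total - tol) break
    v <- add_day(v, 2L)
    guard <- guard + 1L
    if (guard > 2L * sum(fold$ub) + 16L || any(v > fold$ub)) return(NULL)
  }
  sol <- staffing_solution(.unfold_x(v)[1L, ], .unfold_x(v)[2L, ])
  if (nrow(check_feasibility(sol, instance)) > 0L) return(NULL)
  v
}

# lexicographic candidate comparison: cost, total staff, nurse vector,
# technician vector; TRUE when `a` precedes `b`
.precedes <- function(cost_a, key_a, cost_b, key_b, tol = 1e-9) {
  if (cost_a < cost_b - tol) return(TRUE)
  if (cost_a > cost_b + tol) return(FALSE)
  for (j in seq_along(key_a)) {
    if (key_a[j] < key_b[j]) return(TRUE)
    if (key_a[j] > key_b[j]) return(FALSE)
  }
  FALSE
}

.solution_key <- function(v) {
  x <- .unfold_x(v)
  c(sum(x), x[1L, ], x[2L, ])
}

#' Solve a staffing instance exactly
#'
#' Depth-first branch-and-bound over the six-variable lattice obtained
#' after substituting out night parity. The bound at each node is the cost
#' of the partial assignment, plus the cost of the forced minima of the
#' unassigned cells, plus the residual demand costed at the cheapest
#' remaining rate per delivered hour. Ties between equal-cost optima are
#' broken lexicographically by (cost, total staff, nurse vector,
#' technician vector), making the solver deterministic.
#'
#' @param instance A [build_instance()] result.
#' @param tol Feasibility tolerance.
#' @return A [staffing_solution()] with auxiliary pre-TSI levels and the
#'   objective value. If no assignment within the instance bounds satisfies
#'   all constraints, a condition of class `staffing_infeasible` is raised
#'   carrying the tightest violated constraint family.
#' @examples
#' inst <- build_instance(demand_profile(113.2, 34))
#' solve_staffing(inst)
#' @export
solve_staffing <- function(instance, tol = 1e-6) {
  stopifnot(inherits(instance, "staffing_instance"))
  fold <- .fold_vars(instance)
  prof <- .var_profiles(instance)
  n <- 6L
  # suffix aggregates over unassigned variables
  suff_min_cost <- suff_min_hours <- suff_max_hours <- cheapest <- numeric(n + 1L)
  cheapest[n + 1L] <- Inf
  for (j in n:1) {
    suff_min_cost[j] <- suff_min_cost[j + 1L] + fold$lb[j] * prof$cost[j]
    suff_min_hours[j] <- suff_min_hours[j + 1L] + fold$lb[j] * prof$hcap[j]
    suff_max_hours[j] <- suff_max_hours[j + 1L] + fold$ub[j] * prof$hcap[j]
    rate <- if (prof$hcap[j] > 0) prof$cost[j] / prof$hcap[j] else Inf
    cheapest[j] <- min(cheapest[j + 1L], rate)
  }

  best_v <- NULL
  best_cost <- Inf
  best_key <- NULL
  inc <- .greedy_incumbent(instance, fold, prof, tol)
  if (!is.null(inc)) {
    best_v <- inc
    best_cost <- sum(inc * prof$cost)
    best_key <- .solution_key(inc)
  }

  v <- fold$lb
  descend <- function(pos, cost_so_far, hours_so_far) {
    if (pos > n) {
      x <- .unfold_x(v)
      hrs <- .best_hours(x, instance)
      if (hrs < instance$H - tol) return(invisible())
      nurses <- sum(v[1:3] * prof$count[1:3])
      total <- nurses + sum(v[4:6] * prof$count[4:6])
      if (nurses < instance$prop * total - tol) return(invisible())
      key <- .solution_key(v)
      if (is.null(best_v) ||
          .precedes(cost_so_far, key, best_cost, best_key)) {
        best_v <<- v
        best_cost <<- cost_so_far
        best_key <<- key
      }
      return(invisible())
    }
    # demand unreachable even at full capacity: dead branch
    if (hours_so_far + suff_max_hours[pos] < instance$H - tol) return(invisible())
    # skill mix unreachable once all nurses are fixed
    if (pos == 4L && instance$prop > 0) {
      nurses <- sum(v[1:3] * prof$count[1:3])
      min_techs <- sum(fold$lb[4:6] * prof$count[4:6])
      if (nurses < instance$prop * (nurses + min_techs) - tol) return(invisible())
    }
    lo <- fold$lb[pos]
    hi <- fold$ub[pos]
    if (pos == 3L || pos == 6L) { # afternoon bounded by morning +/- alpha
      a <- instance$alpha[[if (pos == 3L) 1L else 2L]]
      lo <- max(lo, v[pos - 1L] - a)
      hi <- min(hi, v[pos - 1L] + a)
      if (lo > hi) return(invisible())
    }
    for (val in lo:hi) {
      v[pos] <<- val
      cost <- cost_so_far + val * prof$cost[pos]
      hrs <- hours_so_far + val * prof$hcap[pos]
      residual <- max(0, instance$H - hrs - suff_min_hours[pos + 1L])
      lb <- cost + suff_min_cost[pos + 1L] +
        if (residual > 0) residual * cheapest[pos + 1L] else 0
      if (lb > best_cost + 1e-9) next
      descend(pos + 1L, cost, hrs)
    }
    v[pos] <<- fold$lb[pos]
    invisible()
  }
  descend(1L, 0, 0)

  if (is.null(best_v)) .infeasible_stop(instance, fold)
  x <- .unfold_x(best_v)
  staffing_solution(x[1L, ], x[2L, ], y = .best_y(x, instance), cost = best_cost)
}

#' Exhaustive-enumeration oracle
#'
#' Enumerates every integer staffing within the instance bounds (night
#' parity folded in), keeps the feasible ones, and returns the minimum-cost
#' staffing under the same tie-break as [solve_staffing()]. Intended as an
#' independent correctness oracle for tests; it refuses instances whose
#' per-cell bounds exceed `cap`.
#'
#' @param instance A [build_instance()] result.
#' @param cap Maximum admissible per-cell upper bound (default 8).
#' @param tol Feasibility tolerance.
#' @return A [staffing_solution()], or a `staffing_infeasible` condition.
#' @export
solve_oracle <- function(instance, cap = 8L, tol = 1e-6) {
  stopifnot(inherits(instance, "staffing_instance"))
  fold <- .fold_vars(instance)
  if (any(fold$ub > cap)) {
    stop(sprintf("enumeration cap exceeded: per-cell bound %d > cap %d; the oracle is for small test instances only",
                 max(fold$ub), cap), call. = FALSE)
  }
  prof <- .var_profiles(instance)
  grid <- as.matrix(expand.grid(
    Zn = fold$lb[1L]:fold$ub[1L], Mn = fold$lb[2L]:fold$ub[2L],
    An = fold$lb[3L]:fold$ub[3L], Zt = fold$lb[4L]:fold$ub[4L],
    Mt = fold$lb[5L]:fold$ub[5L], At = fold$lb[6L]:fold$ub[6L]))
  # expand to the 8-column skill/shift layout
  X8 <- cbind(grid[, "Mn"], grid[, "An"], grid[, "Zn"], grid[, "Zn"],
              grid[, "Mt"], grid[, "At"], grid[, "Zt"], grid[, "Zt"])
  ok <- abs(grid[, "Mn"] - grid[, "An"]) <= instance$alpha[[1L]] + tol
  ok <- ok & abs(grid[, "Mt"] - grid[, "At"]) <= instance$alpha[[2L]] + tol
  w <- .prop_weights(instance$variant)
  nurses <- X8[, 1:4, drop = FALSE] %*% w
  total <- nurses + X8[, 5:8, drop = FALSE] %*% w
  ok <- ok & (nurses >= instance$prop * total - tol)
  ok <- ok & (.best_hours_rows(X8, instance) >= instance$H - tol)
  if (!any(ok)) .infeasible_stop(instance, fold)
  costs <- drop(grid %*% prof$cost)
  keep <- which(ok)
  staff <- rowSums(X8[keep, , drop = FALSE])
  ord <- order(costs[keep], staff,
               X8[keep, 1L], X8[keep, 2L], X8[keep, 3L], X8[keep, 4L],
               X8[keep, 5L], X8[keep, 6L], X8[keep, 7L], X8[keep, 8L])
  bi <- keep[ord[1L]]
  x <- .unfold_x(grid[bi, ])
  staffing_solution(x[1L, ], x[2L, ], y = .best_y(x, instance), cost = costs[bi])
}
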