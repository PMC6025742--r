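# Phase II model: shifts, costs, parameters, instance, cost and feasibility.

.SKILLS <- c("nurse", "technician")
.SHIFTS <- c("morning", "afternoon", "night1", "night2")
.AGG_SHIFTS <- c("morning", "afternoon", "night")

.skill_shift_matrix <- function(x, what, default) {
  if (is.null(x)) x <- default
  if (is.matrix(x)) {
    if (!all(dim(x) == c(2L, 4L))) {
      stop(sprintf("`%s` matrix must be 2 skills x 4 shifts", what), call. = FALSE)
    }
    dimnames(x) <- list(.SKILLS, .SHIFTS)
    return(x)
  }
  if (length(x) == 1L) x <- rep(x, 8L)
  if (length(x) == 4L) x <- rep(x, each = 1L) # same per skill
  if (length(x) == 4L) {
    m <- rbind(x, x)
  } else if (length(x) == 8L) {
    m <- matrix(x, nrow = 2L, byrow = TRUE)
  } else {
    stop(sprintf("`%s` must be a scalar, length-4, length-8 or 2x4 matrix", what),
         call. = FALSE)
  }
  dimnames(m) <- list(.SKILLS, .SHIFTS)
  m
}

#' Shift structure
#'
#' Shift lengths in hours per skill and shift. The unit works three daily
#' shifts: morning, afternoon, and a 12-hour night worked by two alternating
#' cohorts ("night 1" on odd nights, "night 2" on even nights). Defaults
#' (6, 6, 12, 12) reproduce the published salary costs exactly.
#'
#' @param morning,afternoon,night Shift lengths in hours, applied to both
#'   skills. Both night cohorts share the `night` length.
#' @param lengths Optional explicit 2x4 matrix (skills x shifts) overriding
#'   the scalar arguments; night1 and night2 must be equal per skill.
#' @return An object of class `shift_structure` wrapping the length matrix.
#' @export
shift_structure <- function(morning = 6, afternoon = 6, night = 12,
                            lengths = NULL) {
  if (is.null(lengths)) {
    lengths <- rbind(c(morning, afternoon, night, night),
                     c(morning, afternoon, night, night))
  }
  L <- .skill_shift_matrix(lengths, "lengths", NULL)
  if (any(L <= 0)) stop("shift lengths must be positive", call. = FALSE)
  if (any(abs(L[, "night1"] - L[, "night2"]) > 1e-9)) {
    stop("night1 and night2 lengths must be equal", call. = FALSE)
  }
  structure(list(lengths = L), class = "shift_structure")
}

#' Cost schedule
#'
#' Hourly salary rates per skill plus the night premium. Defaults: nurse
#' 1 monetary unit per hour, technician 60% of that, night work paid 37.5%
#' extra. Both night cohorts are costed in the objective because the pool
#' must contain both.
#'
#' @param nurse_rate,technician_rate Base hourly rates (monetary units).
#' @param night_premium Fractional premium on night-shift hours.
#' @return An object of class `cost_schedule`.
#' @export
cost_schedule <- function(nurse_rate = 1.0, technician_rate = 0.6,
                          night_premium = 0.375) {
  if (nurse_rate <= 0 || technician_rate <= 0) {
    stop("hourly rates must be positive", call. = FALSE)
  }
  if (night_premium < 0) stop("`night_premium` must be non-negative", call. = FALSE)
  structure(list(rates = c(nurse = nurse_rate, technician = technician_rate),
                 night_premium = night_premium),
            class = "cost_schedule")
}

# per-worker cost of one shift, 2x4 matrix
.shift_cost_matrix <- function(shifts, costs) {
  night <- c(0, 0, 1, 1)
  sweep(shifts$lengths, 1, costs$rates, `*`) *
    rep(1 + costs$night_premium * night, each = 2L)
}

#' Model parameters
#'
#' Tunable Phase II parameters: the TSI absence buffer `tsi`, the optional
#' skill-mix fraction `prop` (normally taken from the Phase I demand
#' profile), the morning/afternoon balance bounds `alpha` per skill, and
#' the minimum staff per skill and shift.
#'
#' @param tsi Technical Safety Index as a fraction (default 0.15).
#' @param prop Optional minimum nurse fraction of the workforce in `[0, 1)`;
#'   when `NULL`, [build_instance()] derives it from the demand profile.
#' @param alpha Named (or length-2) non-negative integer vector: maximum
#'   allowed morning/afternoon headcount difference per skill. Default 1.
#' @param min_staff Minimum staff per skill and shift; scalar, length 4
#'   (per shift, both skills), length 8, or a 2x4 matrix. Default 1.
#' @return An object of class `model_parameters`.
#' @export
model_parameters <- function(tsi = 0.15, prop = NULL,
                             alpha = c(nurse = 1, technician = 1),
                             min_staff = 1) {
  if (tsi < 0) stop("`tsi` must be non-negative", call. = FALSE)
  if (!is.null(prop) && (prop < 0 || prop >= 1)) {
    stop("`prop` must lie in [0, 1)", call. = FALSE)
  }
  if (length(alpha) == 1L) alpha <- rep(alpha, 2L)
  alpha <- stats::setNames(as.numeric(alpha), .SKILLS)
  if (any(alpha < 0)) stop("`alpha` must be non-negative", call. = FALSE)
  if (any(abs(alpha - round(alpha)) > 1e-9)) {
    stop("`alpha` must be integer-valued", call. = FALSE)
  }
  ms <- .skill_shift_matrix(min_staff, "min_staff", 1)
  if (any(ms < 0)) stop("`min_staff` must be non-negative", call. = FALSE)
  structure(list(tsi = tsi, prop = prop, alpha = alpha,
                 min_staff = round(ms)),
            class = "model_parameters")
}

#' Model variant flags
#'
#' The published account fixes the constraint families but not every piece
#' of their algebra; these flags select among the readings consistent with
#' it. The default combination is the only one examined under which every
#' published HSJ unit-day staffing vector is feasible for its printed
#' demand.
#'
#' @param tsi_scope Where the TSI links staff to pre-TSI levels:
#'   `"per_cell"` (each skill and shift; default), `"per_skill"`, or
#'   `"global"`.
#' @param aux_integrality Whether pre-TSI auxiliary levels are
#'   `"continuous"` (default) or `"integer"`.
#' @param night_demand_hours Whether night pre-TSI staff contribute hours
#'   for `"both_cohorts"` (default; the night coefficient is doubled) or a
#'   `"single_cohort"`.
#' @param prop_counting Whether the skill-mix ratio counts
#'   `"all_employees"` (default; both night cohorts) or `"per_day_staff"`
#'   (morning, afternoon and one night cohort).
#' @return An object of class `model_variant`.
#' @export
model_variant <- function(tsi_scope = c("per_cell", "per_skill", "global"),
                          aux_integrality = c("continuous", "integer"),
                          night_demand_hours = c("both_cohorts", "single_cohort"),
                          prop_counting = c("all_employees", "per_day_staff")) {
  structure(list(tsi_scope = match.arg(tsi_scope),
                 aux_integrality = match.arg(aux_integrality),
                 night_demand_hours = match.arg(night_demand_hours),
                 prop_counting = match.arg(prop_counting)),
            class = "model_variant")
}

#' Staffing solution
#'
#' Integer staff counts per skill and shift, optional pre-TSI auxiliary
#' levels, and (if known) the objective value.
#'
#' @param nurses,technicians Length-4 non-negative integer vectors over
#'   (morning, afternoon, night1, night2).
#' @param y Optional 2x3 matrix of pre-TSI staff levels over the aggregated
#'   shifts (morning, afternoon, night).
#' @param cost Optional objective value.
#' @return An object of class `staffing_solution`.
#' @export
staffing_solution <- function(nurses, technicians, y = NULL, cost = NULL) {
  if (length(nurses) != 4L || length(technicians) != 4L) {
    stop("`nurses` and `technicians` must have one count per shift (4)",
         call. = FALSE)
  }
  x <- rbind(as.numeric(nurses), as.numeric(technicians))
  dimnames(x) <- list(.SKILLS, .SHIFTS)
  if (any(x < 0)) stop("staff counts must be non-negative", call. = FALSE)
  if (any(abs(x - round(x)) > 1e-9)) {
    stop("staff counts must be integers", call. = FALSE)
  }
  if (!is.null(y)) {
    y <- matrix(as.numeric(y), nrow = 2L,
                dimnames = list(.SKILLS, .AGG_SHIFTS))
    if (any(y < -1e-9)) stop("auxiliary levels must be non-negative", call. = FALSE)
  }
  structure(list(x = round(x), y = y, cost = cost), class = "staffing_solution")
}

#' @export
print.staffing_solution <- function(x, ...) {
  cat("Staffing solution (morning, afternoon, night1, night2):\n")
  print(x$x)
  if (!is.null(x$cost)) cat("Objective cost:", format(x$cost), "m.u.\n")
  invisible(x)
}

#' Salary cost of a staffing
#'
#' The Phase II objective: sum over skills and shifts of staff count times
#' shift length times hourly rate, with the night premium applied to both
#' night cohorts (both are salaried members of the permanent pool).
#'
#' @param solution A [staffing_solution()] or a 2x4 staff-count matrix.
#' @param shifts A [shift_structure()].
#' @param costs A [cost_schedule()].
#' @return Total salary cost in monetary units.
#' @examples
#' evaluate_cost(staffing_solution(c(3, 4, 1, 1), c(6, 6, 1, 1))) # 138
#' @export
evaluate_cost <- function(solution, shifts = shift_structure(),
                          costs = cost_schedule()) {
  x <- if (inherits(solution, "staffing_solution")) solution$x else solution
  sum(x * .shift_cost_matrix(shifts, costs))
}

#' Smallest admissible nurse count
#'
#' Reporting helper for the skill-mix constraint: the smallest integer
#' nurse count `n` with `n >= prop * total_staff`. The constraint itself
#' enters the model as an exact linear inequality, without rounding.
#'
#' @param total_staff Total workforce headcount.
#' @param prop Minimum nurse fraction in `[0, 1)`.
#' @return Integer nurse count.
#' @examples
#' required_nurse_count(23, 0.35) # 9
#' @export
required_nurse_count <- function(total_staff, prop) {
  stopifnot(total_staff >= 0, prop >= 0, prop < 1)
  as.integer(ceiling(prop * total_staff - 1e-9))
}

#' Build a Phase II staffing instance
#'
#' Assembles the fully numeric integer program: demand coverage (pre-TSI
#' hours at least the required care hours), the TSI link between staff and
#' pre-TSI levels, the nurse skill-mix ratio, morning/afternoon balance,
#' night parity, and per-shift minimum cover. Search bounds per cell are
#' the safe envelope `min_staff + ceiling((1 + tsi) * H / min shift length)`.
#'
#' @param demand A [demand_profile()] (or a bare number of care hours,
#'   in which case `params$prop` must be set).
#' @param params A [model_parameters()].
#' @param shifts A [shift_structure()].
#' @param costs A [cost_schedule()].
#' @param variant A [model_variant()].
#' @return An object of class `staffing_instance`.
#' @export
build_instance <- function(demand, params = model_parameters(),
                           shifts = shift_structure(),
                           costs = cost_schedule(),
                           variant = model_variant()) {
  stopifnot(inherits(params, "model_parameters"),
            inherits(shifts, "shift_structure"),
            inherits(costs, "cost_schedule"),
            inherits(variant, "model_variant"))
  if (inherits(demand, "demand_profile")) {
    H <- demand$care_hours
    prop <- if (is.null(params$prop)) demand$nurse_ratio / 100 else params$prop
  } else {
    H <- as.numeric(demand)
    if (is.null(params$prop)) {
      stop("`params$prop` must be set when `demand` is a bare hour count",
           call. = FALSE)
    }
    prop <- params$prop
  }
  if (H < 0) stop("care hours must be non-negative", call. = FALSE)
  if (prop < 0 || prop >= 1) stop("`prop` must lie in [0, 1)", call. = FALSE)
  L <- shifts$lengths
  envelope <- ceiling((1 + params$tsi) * H / min(L))
  ub <- params$min_staff + envelope
  structure(list(H = H, p = params$tsi, prop = prop,
                 alpha = params$alpha, min_staff = params$min_staff,
                 lengths = L,
                 cost_matrix = .shift_cost_matrix(shifts, costs),
                 shifts = shifts, costs = costs, variant = variant,
                 ub = ub),
            class = "staffing_instance")
}

#' @export
print.staffing_instance <- function(x, ...) {
  cat(sprintf("Staffing instance: H = %s h/day, prop = %s, TSI = %s\n",
              format(x$H), format(x$prop), format(x$p)))
  cat(sprintf("variant: %s TSI, %s auxiliaries, %s night hours, %s skill mix\n",
              x$variant$tsi_scope, x$variant$aux_integrality,
              x$variant$night_demand_hours, x$variant$prop_counting))
  invisible(x)
}

# ---- attainable pre-TSI hours -------------------------------------------
#
# Given staff counts x, the best attainable demand-side hours are those of
# the auxiliary levels y maximizing delivered hours subject to the TSI link
# of the active variant. All branches below are closed forms, vectorized
# over rows of an n x 8 matrix (nurse M/A/N1/N2 then technician M/A/N1/N2).

.alloc_hours <- function(B, Ld, LN, m, integer_y) {
  # budget B of pre-TSI staff units; day unit delivers Ld hours, a night
  # unit delivers LN hours and consumes m budget units (both cohorts m = 2)
  if (!integer_y) return(pmax(LN, Ld) * B)
  B <- floor(B + 1e-9)
  if (LN >= Ld) {
    yN <- B %/% m
    m * LN * yN + (B - m * yN) * Ld
  } else {
    B * Ld
  }
}

.best_hours_rows <- function(xm, instance) {
  p <- instance$p
  v <- instance$variant
  L <- instance$lengths
  m <- if (v$night_demand_hours == "both_cohorts") 2L else 1L
  int_y <- v$aux_integrality == "integer"
  if (v$tsi_scope == "per_cell") {
    one_skill <- function(k) {
      o <- (k - 1L) * 4L
      xM <- xm[, o + 1L]; xA <- xm[, o + 2L]
      x1 <- xm[, o + 3L]; x2 <- xm[, o + 4L]
      capN <- if (m == 2L) (x1 + x2) / (2 * (1 + p)) else pmin(x1, x2) / (1 + p)
      if (int_y) {
        L[k, 1L] * floor(xM / (1 + p) + 1e-9) +
          L[k, 2L] * floor(xA / (1 + p) + 1e-9) +
          m * L[k, 3L] * floor(capN + 1e-9)
      } else {
        (L[k, 1L] * xM + L[k, 2L] * xA) / (1 + p) + m * L[k, 3L] * capN
      }
    }
    one_skill(1L) + one_skill(2L)
  } else if (v$tsi_scope == "per_skill") {
    one_skill <- function(k) {
      o <- (k - 1L) * 4L
      B <- (xm[, o + 1L] + xm[, o + 2L] + xm[, o + 3L] + xm[, o + 4L]) / (1 + p)
      .alloc_hours(B, max(L[k, 1:2]), L[k, 3L], m, int_y)
    }
    one_skill(1L) + one_skill(2L)
  } else { # global
    B <- rowSums(xm) / (1 + p)
    .alloc_hours(B, max(L[, 1:2]), max(L[, 3L]), m, int_y)
  }
}

.best_hours <- function(x, instance) {
  .best_hours_rows(matrix(c(x[1L, ], x[2L, ]), nrow = 1L), instance)
}

# auxiliary y (2 x 3) attaining .best_hours(x); used for reporting
.best_y <- function(x, instance) {
  p <- instance$p
  v <- instance$variant
  L <- instance$lengths
  m <- if (v$night_demand_hours == "both_cohorts") 2L else 1L
  int_y <- v$aux_integrality == "integer"
  flr <- function(z) if (int_y) floor(z + 1e-9) else z
  y <- matrix(0, 2L, 3L, dimnames = list(.SKILLS, .AGG_SHIFTS))
  if (v$tsi_scope == "per_cell") {
    for (k in 1:2) {
      y[k, 1L] <- flr(x[k, 1L] / (1 + p))
      y[k, 2L] <- flr(x[k, 2L] / (1 + p))
      y[k, 3L] <- if (m == 2L) flr((x[k, 3L] + x[k, 4L]) / (2 * (1 + p)))
                  else flr(min(x[k, 3:4]) / (1 + p))
    }
  } else {
    alloc <- function(B, k_day, k_night) {
      # greedy split of a pre-TSI budget between night and best day shift
      Ld <- L[k_day[1L], k_day[2L]]; LN <- L[k_night[1L], 3L]
      B <- flr(B)
      if (LN >= Ld) {
        yN <- if (int_y) B %/% m else B / m
        c(day = B - m * yN, night = yN)
      } else {
        c(day = B, night = 0)
      }
    }
    if (v$tsi_scope == "per_skill") {
      for (k in 1:2) {
        day_shift <- which.max(L[k, 1:2])
        a <- alloc(sum(x[k, ]) / (1 + p), c(k, day_shift), c(k, 3L))
        y[k, day_shift] <- a[["day"]]
        y[k, 3L] <- a[["night"]]
      }
    } else {
      k_day <- which(L[, 1:2] == max(L[, 1:2]), arr.ind = TRUE)[1L, ]
      k_night <- which.max(L[, 3L])
      a <- alloc(sum(x) / (1 + p), k_day, c(k_night, 3L))
      y[k_day[1L], k_day[2L]] <- a[["day"]]
      y[k_night, 3L] <- a[["night"]]
    }
  }
  y
}

# staff-count weights for the skill-mix ratio under the active counting rule
.prop_weights <- function(variant) {
  if (variant$prop_counting == "all_employees") c(1, 1, 1, 1) else c(1, 1, 1, 0)
}

#' Check a staffing against an instance
#'
#' Returns the violated constraints of a candidate staffing, one row per
#' violation with the constraint family, the offending cell (where one
#' applies) and the slack by which it fails. An empty data frame means the
#' staffing is feasible. When the solution carries no auxiliary pre-TSI
#' levels, the checker first computes the best attainable levels given the
#' staff counts, so demand and TSI are judged jointly through the `demand`
#' family; explicit levels are checked against both families separately.
#'
#' @param solution A [staffing_solution()].
#' @param instance A [build_instance()] result.
#' @param tol Numeric tolerance for the continuous comparisons.
#' @return A data frame with columns `constraint`, `where`, `slack`.
#' @export
check_feasibility <- function(solution, instance, tol = 1e-6) {
  stopifnot(inherits(solution, "staffing_solution"),
            inherits(instance, "staffing_instance"))
  x <- solution$x
  v <- instance$variant
  p <- instance$p
  L <- instance$lengths
  m <- if (v$night_demand_hours == "both_cohorts") 2L else 1L
  out <- list()
  add <- function(constraint, where, slack) {
    out[[length(out) + 1L]] <<- data.frame(constraint = constraint,
                                           where = where, slack = slack)
  }
  # (6) minimum cover
  short <- instance$min_staff - x
  for (i in 1:2) for (s in 1:4) {
    if (short[i, s] > tol) {
      add("min_cover", paste(.SKILLS[i], .SHIFTS[s], sep = "."), short[i, s])
    }
  }
  # (5) night parity
  for (i in 1:2) {
    d <- abs(x[i, 3L] - x[i, 4L])
    if (d > tol) add("night_parity", .SKILLS[i], d)
  }
  # (4) morning/afternoon balance
  for (i in 1:2) {
    d <- abs(x[i, 1L] - x[i, 2L]) - instance$alpha[[i]]
    if (d > tol) add(paste0("balance_", .SKILLS[i]), .SKILLS[i], d)
  }
  # (3) skill mix
  w <- .prop_weights(v)
  nurses <- sum(x[1L, ] * w)
  total <- nurses + sum(x[2L, ] * w)
  gap <- instance$prop * total - nurses
  if (gap > tol) add("skill_mix", "nurse", gap)
  # (1) demand and (2) TSI
  if (is.null(solution$y)) {
    hrs <- .best_hours(x, instance)
    if (hrs < instance$H - tol) add("demand", "hours", instance$H - hrs)
  } else {
    y <- solution$y
    delivered <- sum(L[, 1L] * y[, 1L] + L[, 2L] * y[, 2L] + m * L[, 3L] * y[, 3L])
    if (delivered < instance$H - tol) add("demand", "hours", instance$H - delivered)
    if (v$aux_integrality == "integer" && any(abs(y - round(y)) > tol)) {
      add("tsi", "integrality", max(abs(y - round(y))))
    }
    link <- function(lhs, rhs, where) {
      if (lhs < (1 + p) * rhs - tol) add("tsi", where, (1 + p) * rhs - lhs)
    }
    if (v$tsi_scope == "per_cell") {
      for (i in 1:2) {
        link(x[i, 1L], y[i, 1L], paste0(.SKILLS[i], ".morning"))
        link(x[i, 2L], y[i, 2L], paste0(.SKILLS[i], ".afternoon"))
        link(x[i, 3L] + x[i, 4L], m * y[i, 3L], paste0(.SKILLS[i], ".night"))
      }
    } else if (v$tsi_scope == "per_skill") {
      for (i in 1:2) {
        link(sum(x[i, ]), y[i, 1L] + y[i, 2L] + m * y[i, 3L], .SKILLS[i])
      }
    } else {
      link(sum(x), sum(y[, 1:2]) + m * sum(y[, 3L]), "all")
    }
  }
  if (length(out) == 0L) {
    data.frame(constraint = character(), where = character(), slack = numeric())
  } else {
    do.call(rbind, out)
  }
}
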