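# What-if analyses: parameter sweeps, multi-day staffing, roster comparison.

.solution_row <- function(sol) {
  data.frame(nurse_morning = sol$x[1L, 1L], nurse_afternoon = sol$x[1L, 2L],
             nurse_night1 = sol$x[1L, 3L], nurse_night2 = sol$x[1L, 4L],
             nurses_total = sum(sol$x[1L, ]),
             technician_morning = sol$x[2L, 1L],
             technician_afternoon = sol$x[2L, 2L],
             technician_night1 = sol$x[2L, 3L],
             technician_night2 = sol$x[2L, 4L],
             technicians_total = sum(sol$x[2L, ]),
             total_staff = sum(sol$x), total_cost = sol$cost)
}

.na_solution_row <- function() {
  r <- .solution_row(staffing_solution(rep(0, 4), rep(0, 4), cost = 0))
  r[1L, ] <- NA
  r
}

#' Parameter sweep (sensitivity analysis)
#'
#' Solves one staffing instance per point of a grid of minimum staff levels
#' and balance parameters, with the balance bound applied equally to both
#' skills as in the published sensitivity analysis. Infeasible grid points
#' are flagged in their row rather than aborting the sweep.
#'
#' @param demand A [demand_profile()].
#' @param params Base [model_parameters()]; `min_staff` and `alpha` are
#'   overridden per grid point.
#' @param min_staff_values Integer vector of minimum staff levels (applied
#'   to every skill and shift).
#' @param alpha_values Integer vector of balance bounds.
#' @param shifts,costs,variant Passed to [build_instance()].
#' @return A data frame of class `staffing_sweep`, one row per grid point,
#'   with the per-shift staffing vectors, totals, cost and a `status`
#'   column (`"optimal"` or `"infeasible"`).
#' @export
staffing_sweep <- function(demand, params = model_parameters(),
                           min_staff_values = 1:3, alpha_values = 1:3,
                           shifts = shift_structure(),
                           costs = cost_schedule(),
                           variant = model_variant()) {
  if (length(min_staff_values) == 0L || length(alpha_values) == 0L) {
    stop("sweep grids must be non-empty", call. = FALSE)
  }
  rows <- list()
  for (ms in min_staff_values) {
    for (a in alpha_values) {
      pars <- model_parameters(tsi = params$tsi, prop = params$prop,
                               alpha = c(a, a), min_staff = ms)
      inst <- build_instance(demand, pars, shifts, costs, variant)
      row <- tryCatch({
        sol <- solve_staffing(inst)
        cbind(data.frame(min_staff = ms, alpha = a),
              .solution_row(sol), status = "optimal")
      }, staffing_infeasible = function(e) {
        cbind(data.frame(min_staff = ms, alpha = a),
              .na_solution_row(), status = "infeasible")
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("staffing_sweep", "data.frame")
  out
}

#' Multi-day staffing report
#'
#' Runs Phase I and Phase II for every day of a census table and tabulates
#' demand, the optimal staffing and costs per day. Per-day failures are
#' recorded in the `status` column; the report is still produced.
#'
#' @param census Census data frame as returned by [read_census_csv()] or
#'   [random_census()].
#' @param standard A [care_standard()].
#' @param params A [model_parameters()].
#' @param ratio_rule Passed to [phase1()].
#' @param shifts,costs,variant Passed to [build_instance()].
#' @return A data frame of class `multiday_report`, one row per day, with
#'   attribute `staff_range` holding the min/max total staff across the
#'   solved days.
#' @export
staffing_multiday <- function(census, standard = care_standard(),
                              params = model_parameters(),
                              ratio_rule = c("weighted", "dominant"),
                              shifts = shift_structure(),
                              costs = cost_schedule(),
                              variant = model_variant()) {
  ratio_rule <- match.arg(ratio_rule)
  if (nrow(census) < 1L) stop("census table has no rows", call. = FALSE)
  rows <- list()
  for (i in seq_len(nrow(census))) {
    cen <- patient_census(census$minimal[i], census$intermediary[i],
                          census$semi_intensive[i], census$intensive[i],
                          census$unclassified[i], unit = census$unit[i],
                          date = census$date[i])
    head <- data.frame(date = census$date[i],
                       patients = sum(cen$counts) + cen$unclassified)
    row <- tryCatch({
      dem <- phase1(cen, standard, ratio_rule)
      inst <- build_instance(dem, params, shifts, costs, variant)
      sol <- solve_staffing(inst)
      cbind(head, data.frame(care_hours = dem$care_hours,
                             nurse_ratio = dem$nurse_ratio),
            .solution_row(sol), status = "optimal")
    }, error = function(e) {
      status <- if (inherits(e, "staffing_infeasible")) "infeasible" else "error"
      cbind(head, data.frame(care_hours = NA_real_, nurse_ratio = NA_real_),
            .na_solution_row(), status = status)
    })
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  solved <- out$status == "optimal"
  attr(out, "staff_range") <- if (any(solved)) range(out$total_staff[solved]) else c(NA, NA)
  class(out) <- c("multiday_report", "data.frame")
  out
}

#' @export
print.multiday_report <- function(x, ...) {
  NextMethod()
  r <- attr(x, "staff_range")
  if (!anyNA(r)) {
    cat(sprintf("Total staff across days: min %d, max %d\n", r[1L], r[2L]))
  }
  invisible(x)
}

#' Compare staffing against an actual roster
#'
#' Per-day surplus of the tabulated staffing over a constant actual roster,
#' per skill and overall. Positive values mean the model asks for more
#' staff than the unit currently holds (a deficit from the unit's side);
#' negative values mean the roster exceeds the model's requirement.
#'
#' @param report A data frame with `nurses_total` and `technicians_total`
#'   columns, e.g. a [staffing_multiday()] report or the reference table
#'   of [hsj_eight_days()].
#' @param actual_nurses,actual_technicians Constant actual roster counts.
#' @return A data frame with per-day model totals, actual totals and
#'   `nurse_surplus`, `technician_surplus`, `total_surplus` (model minus
#'   actual).
#' @export
compare_actual <- function(report, actual_nurses, actual_technicians) {
  stopifnot(actual_nurses >= 0, actual_technicians >= 0)
  data.frame(
    date = if ("date" %in% names(report)) report$date else seq_len(nrow(report)),
    model_nurses = report$nurses_total,
    model_technicians = report$technicians_total,
    model_total = report$nurses_total + report$technicians_total,
    actual_nurses = actual_nurses,
    actual_technicians = actual_technicians,
    actual_total = actual_nurses + actual_technicians,
    nurse_surplus = report$nurses_total - actual_nurses,
    technician_surplus = report$technicians_total - actual_technicians,
    total_surplus = report$nurses_total + report$technicians_total -
      actual_nurses - actual_technicians)
}
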