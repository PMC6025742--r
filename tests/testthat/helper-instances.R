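# shared builders for test instances and the packaged case-study tables

hsj <- hsj_eight_days()

hsj_census_row <- function(i) {
  r <- hsj$census[i, ]
  patient_census(r$minimal, r$intermediary, r$semi_intensive, r$intensive,
                 r$unclassified, unit = r$unit, date = r$date)
}

hsj_reference_solution <- function(i) {
  r <- hsj$reference[i, ]
  staffing_solution(
    c(r$nurse_morning, r$nurse_afternoon, r$nurse_night1, r$nurse_night2),
    c(r$technician_morning, r$technician_afternoon, r$technician_night1,
      r$technician_night2))
}

small_instance <- function(H, prop = 0, tsi = 0.15, alpha = c(1, 1),
                           min_staff = 0, variant = model_variant()) {
  build_instance(demand_profile(H, 0),
                 model_parameters(tsi = tsi, prop = prop, alpha = alpha,
                                  min_staff = min_staff),
                 variant = variant)
}

solve_cost_or_na <- function(inst) {
  tryCatch(solve_staffing(inst)$cost, staffing_infeasible = function(e) NA_real_)
}
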