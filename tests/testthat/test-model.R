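# Phase II model: cost evaluation, instance construction, feasibility.

test_that("salary objective reproduces the published costs exactly", {
  expect_equal(evaluate_cost(staffing_solution(c(3, 4, 1, 1), c(6, 6, 1, 1))),
               138.0)
  expect_equal(evaluate_cost(staffing_solution(c(2, 3, 2, 2), c(5, 5, 2, 2))),
               171.6)
  expect_equal(evaluate_cost(staffing_solution(c(3, 3, 3, 3), c(3, 3, 3, 3))),
               216.0)
  expect_equal(evaluate_cost(staffing_solution(rep(0, 4), rep(0, 4))), 0.0)
})

test_that("cost evaluation is linear in the staffing vector", {
  a <- staffing_solution(c(1, 2, 0, 0), c(3, 0, 1, 1))
  b <- staffing_solution(c(2, 2, 1, 1), c(0, 4, 2, 2))
  ab <- staffing_solution(c(3, 4, 1, 1), c(3, 4, 3, 3))
  expect_equal(evaluate_cost(a) + evaluate_cost(b), evaluate_cost(ab))
})

test_that("cost per delivered hour orders the four worker types", {
  ss <- shift_structure()
  cm <- nursedim:::.shift_cost_matrix(ss, cost_schedule())
  per_hour <- cm / ss$lengths
  expect_equal(unname(per_hour["technician", "morning"]), 0.6)
  expect_equal(unname(per_hour["technician", "night1"]), 0.825)
  expect_equal(unname(per_hour["nurse", "morning"]), 1.0)
  expect_equal(unname(per_hour["nurse", "night1"]), 1.375)
  expect_true(all(diff(c(0.6, 0.825, 1.0, 1.375)) > 0))
})

test_that("instance construction validates parameters", {
  expect_error(model_parameters(alpha = -1), "alpha")
  expect_error(model_parameters(prop = 1.2), "prop")
  expect_error(build_instance(demand_profile(-5, 33)), "non-negative")
  expect_error(demand_profile(10, 120), "nurse_ratio")
  # zero demand, zero minima: the all-zero staffing is optimal
  inst <- build_instance(demand_profile(0, 0),
                         model_parameters(min_staff = 0))
  sol <- solve_staffing(inst)
  expect_equal(sum(sol$x), 0)
  expect_equal(sol$cost, 0)
})

test_that("published day 12-09 staffing is feasible for its printed demand", {
  inst <- build_instance(demand_profile(113.2, 34))
  sol <- staffing_solution(c(2, 3, 1, 1), c(5, 5, 1, 1))
  expect_equal(nrow(check_feasibility(sol, inst)), 0L)
})

test_that("feasibility checker flags each constraint family", {
  inst <- build_instance(demand_profile(100, 33))
  zero <- staffing_solution(rep(0, 4), rep(0, 4))
  fam <- check_feasibility(zero, inst)$constraint
  expect_true("demand" %in% fam)
  expect_true("min_cover" %in% fam)
  inst0 <- build_instance(demand_profile(10, 0),
                          model_parameters(min_staff = 0, alpha = c(1, 1)))
  unbal <- staffing_solution(c(5, 1, 1, 1), c(0, 0, 0, 0))
  expect_true("balance_nurse" %in% check_feasibility(unbal, inst0)$constraint)
  disparate <- staffing_solution(c(1, 1, 2, 1), c(2, 2, 2, 2))
  expect_true("night_parity" %in% check_feasibility(disparate, inst0)$constraint)
  instp <- build_instance(demand_profile(10, 50),
                          model_parameters(min_staff = 0))
  few_nurses <- staffing_solution(c(0, 0, 0, 0), c(2, 2, 0, 0))
  expect_true("skill_mix" %in% check_feasibility(few_nurses, instp)$constraint)
})

test_that("explicit auxiliary levels are checked against demand and TSI", {
  inst <- build_instance(demand_profile(60, 0), model_parameters(min_staff = 0))
  # x supports y = x / 1.15; claiming more than that violates the TSI link
  sol_bad <- staffing_solution(c(2, 2, 0, 0), c(2, 2, 0, 0),
                               y = matrix(c(2, 2, 0, 2, 2, 0), 2, 3,
                                          byrow = TRUE))
  fam <- check_feasibility(sol_bad, inst)$constraint
  expect_true("tsi" %in% fam)
  sol_ok <- staffing_solution(c(3, 3, 1, 1), c(3, 3, 1, 1),
                              y = matrix(c(2, 2, 0.8, 2, 2, 0.8), 2, 3,
                                         byrow = TRUE))
  expect_equal(nrow(check_feasibility(sol_ok, inst)), 0L)
})

test_that("required nurse count is the ceiling of the exact ratio", {
  expect_equal(required_nurse_count(23, 0.35), 9L)
  expect_equal(required_nurse_count(0, 0.5), 0L)
  expect_equal(required_nurse_count(10, 0.0), 0L)
  expect_equal(required_nurse_count(20, 0.35), 7L) # exact boundary
})

test_that("solver output carries auxiliary levels consistent with the checker", {
  inst <- build_instance(demand_profile(113.2, 34))
  sol <- solve_staffing(inst)
  expect_false(is.null(sol$y))
  expect_equal(nrow(check_feasibility(sol, inst)), 0L)
})
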