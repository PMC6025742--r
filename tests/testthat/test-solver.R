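# Exact solver: worked examples, oracle equivalence, invariants.

test_that("small demand without minima is covered at day-technician cost", {
  inst <- small_instance(H = 12, tsi = 0, alpha = c(2, 2))
  sol <- solve_staffing(inst)
  expect_equal(sol$cost, 7.2)
  expect_equal(sum(sol$x["nurse", ]), 0)
  expect_equal(sum(sol$x["technician", ]), 2)
  expect_equal(solve_oracle(inst)$cost, 7.2)
})

test_that("zero demand with unit minima forces one worker per cell", {
  inst <- build_instance(demand_profile(0, 0), model_parameters(min_staff = 1))
  sol <- solve_staffing(inst)
  expect_true(all(sol$x == 1))
  expect_equal(sol$cost,
               evaluate_cost(staffing_solution(rep(1, 4), rep(1, 4))))
  expect_equal(sol$cost, 72.0)
})

test_that("contradictory skill mix raises a typed infeasibility signal", {
  inst <- build_instance(demand_profile(10, 90), model_parameters(min_staff = 1))
  err <- tryCatch(solve_staffing(inst), staffing_infeasible = function(e) e)
  expect_s3_class(err, "staffing_infeasible")
  expect_equal(err$family, "skill_mix")
  err2 <- tryCatch(solve_oracle(inst), staffing_infeasible = function(e) e)
  expect_s3_class(err2, "staffing_infeasible")
})

test_that("oracle refuses instances beyond its enumeration cap", {
  inst <- build_instance(demand_profile(164, 35))
  expect_error(solve_oracle(inst), "cap")
})

test_that("solver and oracle agree on seeded random instances", {
  for (k in 1:40) {
    inst <- random_instance(770000 + k)
    a <- tryCatch(solve_staffing(inst), staffing_infeasible = function(e) NULL)
    b <- tryCatch(solve_oracle(inst), staffing_infeasible = function(e) NULL)
    expect_equal(is.null(a), is.null(b))
    if (!is.null(a)) {
      expect_equal(a$cost, b$cost, tolerance = 1e-9)
      expect_equal(a$x, b$x) # same tie-break, same vector
    }
  }
})

test_that("every returned solution passes the feasibility checker", {
  for (k in 1:25) {
    inst <- random_instance(880000 + k)
    sol <- tryCatch(solve_staffing(inst), staffing_infeasible = function(e) NULL)
    if (is.null(sol)) next
    expect_equal(nrow(check_feasibility(sol, inst)), 0L)
    # night parity and balance hold structurally
    expect_equal(sol$x[, "night1"], sol$x[, "night2"])
    expect_lte(abs(sol$x[1, 1] - sol$x[1, 2]), inst$alpha[["nurse"]])
    expect_lte(abs(sol$x[2, 1] - sol$x[2, 2]), inst$alpha[["technician"]])
  }
})

test_that("repeated solves of one instance return identical vectors", {
  inst <- build_instance(demand_profile(124.4, 34))
  s1 <- solve_staffing(inst)
  s2 <- solve_staffing(inst)
  expect_identical(s1$x, s2$x)
  expect_identical(s1$cost, s2$cost)
})

test_that("optimal cost is monotone in demand, minima, TSI and balance", {
  base <- function(H, tsi = 0.15, min_staff = 1, alpha = 1, prop = 0.34) {
    build_instance(demand_profile(H, 0),
                   model_parameters(tsi = tsi, prop = prop,
                                    alpha = c(alpha, alpha),
                                    min_staff = min_staff))
  }
  for (H in c(20, 60, 110)) {
    c0 <- solve_cost_or_na(base(H))
    expect_lte(c0, solve_cost_or_na(base(H + 15)))       # more demand
    expect_lte(c0, solve_cost_or_na(base(H, min_staff = 2))) # higher minima
    expect_lte(c0, solve_cost_or_na(base(H, tsi = 0.25)))    # bigger buffer
    expect_gte(c0, solve_cost_or_na(base(H, alpha = 3)))     # relaxation
  }
})

test_that("monotonicity holds across seeded random perturbations", {
  for (k in 1:15) {
    inst <- random_instance(990000 + k, vary_variant = FALSE)
    c0 <- solve_cost_or_na(inst)
    if (is.na(c0)) next
    up <- build_instance(demand_profile(inst$H + 5, 0),
                         model_parameters(tsi = inst$p, prop = inst$prop,
                                          alpha = inst$alpha,
                                          min_staff = inst$min_staff))
    c1 <- solve_cost_or_na(up)
    expect_false(is.na(c1))
    expect_gte(c1 + 1e-9, c0)
  }
})
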