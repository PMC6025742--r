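# Phase I: census normalization, care hours, nurse-ratio rules.

test_that("unclassified patients fold into intermediary, conserving totals", {
  cen <- patient_census(minimal = 10, intermediary = 5, unclassified = 3)
  norm <- normalize_census(cen)
  expect_equal(unname(norm$counts[["intermediary"]]), 8L)
  expect_equal(norm$unclassified, 0L)
  expect_equal(sum(norm$counts), sum(cen$counts) + cen$unclassified)
  # idempotent / no-op cases
  expect_equal(normalize_census(norm), norm)
  zero <- normalize_census(patient_census())
  expect_true(all(zero$counts == 0L))
  only_intensive <- patient_census(intensive = 2)
  expect_equal(normalize_census(only_intensive)$counts,
               only_intensive$counts)
})

test_that("negative or fractional counts are rejected naming the field", {
  expect_error(patient_census(minimal = -1), "minimal")
  expect_error(patient_census(unclassified = -2), "unclassified")
  expect_error(patient_census(intermediary = 1.5), "intermediary")
})

test_that("care hours match the published unit-day values", {
  expect_equal(care_hours(patient_census(21, 10, 3, 0)), 164.0)
  expect_equal(care_hours(patient_census(13, 7, 1, 0)), 98.0)
  expect_equal(care_hours(patient_census(0, 0, 0, 0)), 0.0)
  expect_equal(care_hours(patient_census(0, 0, 0, 1)), 17.9)
})

test_that("care hours are linear in the census", {
  a <- patient_census(3, 1, 0, 2)
  b <- patient_census(4, 0, 5, 1)
  ab <- patient_census(7, 1, 5, 3)
  expect_equal(care_hours(a) + care_hours(b), care_hours(ab))
  doubled <- patient_census(6, 2, 0, 4)
  expect_equal(care_hours(doubled), 2 * care_hours(a))
})

test_that("dominant-category rule returns the busiest category's percentage", {
  expect_equal(nurse_ratio_dominant(patient_census(21, 10, 3, 0)), 33)
  expect_equal(nurse_ratio_dominant(patient_census(0, 0, 0, 5)), 52)
  # tied categories share 33; tie toward higher acuity is invisible here
  expect_equal(nurse_ratio_dominant(patient_census(4, 4, 0, 0)), 33)
  # explicit acuity tie-break
  expect_equal(nurse_ratio_dominant(patient_census(3, 0, 3, 0)), 42)
  expect_error(nurse_ratio_dominant(patient_census()), "no patients")
})

test_that("weighted rule reproduces the published 34/35 percentages", {
  expect_equal(nurse_ratio_weighted(patient_census(21, 10, 3, 0)), 35)
  expect_equal(nurse_ratio_weighted(patient_census(17, 7, 1, 0)), 34)
  expect_equal(nurse_ratio_weighted(patient_census(9, 0, 0, 0)), 33)
  expect_error(nurse_ratio_weighted(patient_census()), "zero care hours")
})

test_that("weighted ratio stays within the present categories' percentages", {
  set.seed(42)
  std <- care_standard()
  for (k in 1:50) {
    counts <- rpois(4, 4)
    if (sum(counts) == 0) counts[1] <- 1
    cen <- patient_census(counts[1], counts[2], counts[3], counts[4])
    pct <- std$nurse_pct[counts > 0]
    r <- nurse_ratio_weighted(cen, std)
    expect_gte(r, min(pct))
    expect_lte(r, max(pct))
  }
})

test_that("phase1 bundles hours and the selected ratio", {
  d <- phase1(patient_census(21, 10, 3, 0), ratio_rule = "weighted")
  expect_equal(d$care_hours, 164.0)
  expect_equal(d$nurse_ratio, 35)
  d2 <- phase1(patient_census(15, 8, 2, 0), ratio_rule = "weighted")
  expect_equal(d2$care_hours, 120.6)
  expect_equal(d2$nurse_ratio, 34)
  d3 <- phase1(patient_census(21, 10, 3, 0), ratio_rule = "dominant")
  expect_equal(d3$nurse_ratio, 33)
  expect_error(phase1(patient_census()), "zero care hours|no patients")
})

test_that("care standard validates its invariants", {
  expect_error(care_standard(hours_per_patient = c(5, 4, 9, 17)), "increasing")
  expect_error(care_standard(nurse_pct = c(0, 33, 42, 52)), "nurse_pct")
  expect_error(care_standard(tsi = -0.1), "tsi")
})
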