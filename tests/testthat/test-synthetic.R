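test_that("scenario generation is deterministic in the seed", {
  a <- generate_scenario(scenario_spec(seed = 5, I = 15, J = 20, n_existing = 3))
  b <- generate_scenario(scenario_spec(seed = 5, I = 15, J = 20, n_existing = 3))
  expect_identical(a$instance$centers, b$instance$centers)
  expect_identical(a$instance$distances, b$instance$distances)
  expect_identical(a$existing$beds, b$existing$beds)
  c2 <- generate_scenario(scenario_spec(seed = 6, I = 15, J = 20, n_existing = 3))
  expect_false(identical(a$instance$distances, c2$instance$distances))
})

test_that("generated scenarios honor the demand rate and pass validation", {
  sc <- generate_scenario(scenario_spec(seed = 7))
  inst <- sc$instance
  expect_s3_class(inst, "rcf_instance")   # build_instance already validated
  expect_equal(inst$I, 60)
  expect_equal(inst$J, 120)
  # per-center demand is the rounded rate of elderly
  expect_equal(inst$centers$demand,
               pmax(1, round(0.025 * inst$centers$elderly)))
  # the planted current configuration undersupplies the district
  expect_lt(sc$existing$total_beds, inst$W)
  expect_true(all(inst$distances > 0))
  expect_false(is.null(inst$baseline_accessibility))
})

test_that("road-graph distances are metric-like and exceed crow-fly", {
  sc <- generate_scenario(scenario_spec(seed = 8, I = 12, J = 15,
                                        n_existing = 3, distance_mode = "road"))
  d <- sc$instance$distances
  expect_true(all(is.finite(d)))
  expect_true(all(d > 0))
  # road distances dominate the euclidean ones on average (wiggle + dwell)
  eu <- generate_scenario(scenario_spec(seed = 8, I = 12, J = 15,
                                        n_existing = 3))$instance$distances
  expect_gt(mean(d), mean(eu))
})

test_that("micro instance carries the worked example", {
  inst <- micro_instance()
  expect_equal(inst$W, 30)
  expect_equal(inst$distances,
               matrix(c(1000, 2000, 2000, 1000), 2, 2, byrow = TRUE))
  expect_equal(inst$costs$charge - inst$costs$cost, 800)
  af <- gravity_accessibility(inst, m1_config())
  expect_equal(af$values, c(1.35, 1.575))
  expect_equal(equity_objective(af), 0.028125)
})

test_that("exhaustive oracle enumerates, validates, and is reproducible", {
  or <- oracle_instance(seed = 10, I = 12, J = 10, p = 3)
  expect_equal(nrow(or$optimum$table), choose(10, 3))
  expect_equal(length(or$optimum$open), 3)
  expect_true(or$optimum$feasible)
  expect_equal(or$optimum$F, min(or$optimum$table$F[
    or$optimum$table$capacity_violation == 0]))
  or2 <- oracle_instance(seed = 10, I = 12, J = 10, p = 3)
  expect_identical(or$optimum$open, or2$optimum$open)
  # J = p has a single subset
  single <- enumerate_optimum(or$instance, or$instance$J)
  expect_equal(single$open, seq_len(or$instance$J))
  expect_error(enumerate_optimum(or$instance, 5, limit = 10), "too large")
})

test_that("stronger planted imbalance produces larger assessment gaps", {
  gaps <- vapply(c(1.2, 2.0, 3.5), function(mag) {
    mean(vapply(1:4, function(s) {
      sc <- generate_scenario(scenario_spec(seed = s, I = 30, J = 50,
                                            n_existing = 6,
                                            oversupply = mag,
                                            undersupply = 1 / mag))
      a <- assess_current(sc$instance, sc$existing)
      sum(abs(a$facility$gap))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
})
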