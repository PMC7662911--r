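test_that("equity objective is the squared dispersion around the weighted mean", {
  af <- gravity_accessibility(m1, m1_config())
  expect_equal(equity_objective(af), 0.028125)   # 0.15^2 + 0.075^2
  flat <- list(values = rep(2, 5), weighted_mean = 2)
  expect_equal(equity_objective(flat), 0)
  # translation invariance
  shifted <- list(values = af$values + 3, weighted_mean = af$weighted_mean + 3)
  expect_equal(equity_objective(shifted), equity_objective(af))
})

test_that("efficiency objective averages relative accessibility change", {
  expect_equal(efficiency_objective(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(efficiency_objective(2 * c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(efficiency_objective(c(1.5, 1.0), c(1.0, 2.0)), 0)
  expect_error(efficiency_objective(c(1, 2), c(1, 0)), "positive")
  expect_error(efficiency_objective(c(1, 2), NULL), "baseline")
})

test_that("travel cost matches demand-weighted allocated distance", {
  conf <- size_beds_to_demand(m1, c(1, 2))
  tc <- travel_cost_objective(m1, conf$allocation)
  expect_equal(as.numeric(tc), 30000)
  expect_equal(attr(tc, "per_capita"), 1000)
  # forcing everyone to site 2 is strictly worse
  forced <- allocate_nearest(m1, 2)
  expect_equal(as.numeric(travel_cost_objective(m1, forced)), 40000)
})

test_that("profit objective averages facility margins over open facilities", {
  conf <- size_beds_to_demand(m1, c(1, 2))
  pr <- profit_objective(m1, conf)
  expect_equal(as.numeric(pr), 12000)
  expect_equal(attr(pr, "per_facility"), c(8000, 16000))

  # the published optimized and current configurations: 800 RMB margin,
  # served demand over open facility count
  served_45 <- .profit_fixture(8163, 45)
  expect_equal(as.numeric(profit_objective(served_45$instance, served_45$config)),
               145120)
  served_41 <- .profit_fixture(5729, 41)
  expect_equal(as.numeric(profit_objective(served_41$instance, served_41$config)),
               111785, tolerance = 1e-5)
})

test_that("standardization maps onto [0,1] with smaller-better orientation", {
  M <- cbind(equity = c(0, 5, 10), efficiency = c(1, 2, 3),
             travel_cost = c(3, 2, 1), profit = c(10, 20, 30))
  S <- standardize_objectives(M)
  expect_equal(S[, "equity"], c(0, 0.5, 1))
  expect_equal(S[, "efficiency"], c(1, 0.5, 0))  # maximization flipped
  expect_equal(S[, "travel_cost"], c(1, 0.5, 0))
  expect_equal(S[, "profit"], c(1, 0.5, 0))
  expect_true(all(S >= 0 & S <= 1))
  # single vector and degenerate ranges -> 0.5
  expect_true(all(standardize_objectives(M[1, , drop = FALSE]) == 0.5))
  # a dominating solution standardizes to 0 everywhere
  M2 <- cbind(equity = c(1, 2), efficiency = c(5, 4),
              travel_cost = c(10, 20), profit = c(9, 8))
  expect_equal(unname(standardize_objectives(M2)[1, ]), rep(0, 4))
  # missing efficiency column (no baseline) maps to 0.5
  M3 <- M; M3[, "efficiency"] <- NA
  expect_true(all(standardize_objectives(M3)[, "efficiency"] == 0.5))
})

test_that("comprehensive objective combines weights and adaptive penalty", {
  cs <- comprehensive_objective(c(0.2, 0.4, 0.6, 0.8))
  expect_equal(cs$f, 0.5)
  expect_equal(cs$r, 1)
  expect_equal(cs$affinity, 2)

  # violations always worsen F; equal f, infeasible loses
  v <- structure(list(count = 0, coverage = 0, linkage = 0, capacity = 3,
                      feasible = FALSE), class = "rcf_violations")
  cs_bad <- comprehensive_objective(c(0.2, 0.4, 0.6, 0.8), violations = v,
                                    violation_max = c(1, 1, 1, 3))
  expect_gt(cs_bad$F, cs$F)
  expect_lt(cs_bad$affinity, cs$affinity)
  expect_equal(cs_bad$r, 1 + 1 / 4)

  expect_error(comprehensive_objective(c(0.2, 0.4, 0.6, 0.8),
                                       weights = c(1, 1, 1, 1)), "weights")
})

test_that("with equal weights, F ranks feasible solutions exactly like f", {
  set.seed(5)
  M <- cbind(equity = runif(20), efficiency = runif(20),
             travel_cost = runif(20), profit = runif(20))
  S <- standardize_objectives(M)
  f <- as.numeric(S %*% rep(0.25, 4))
  F <- vapply(seq_len(20), function(k)
    comprehensive_objective(S[k, ])$F, numeric(1))
  expect_equal(order(F), order(f))
})

test_that("objective weights renormalize when the baseline is absent", {
  w <- objective_weights("equal", has_baseline = FALSE)
  expect_equal(w[2], 0)
  expect_equal(sum(w), 1)
  wa <- objective_weights("adaptive",
                          objectives = cbind(equity = c(0, 10),
                                             efficiency = c(1, 1.1),
                                             travel_cost = c(5, 6),
                                             profit = c(2, 2.5)))
  expect_equal(sum(wa), 1)
  expect_gt(wa[2], wa[1])   # tighter range gets more weight
})
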