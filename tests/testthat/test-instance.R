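test_that("build_instance validates inputs and derives total demand", {
  expect_s3_class(m1, "rcf_instance")
  expect_equal(m1$W, 30)
  expect_equal(m1$I, 2)
  expect_equal(m1$J, 2)

  # minimal 1x1 case
  one <- build_instance(
    data.frame(id = "c", x = 0, y = 0, elderly = 10, demand = 5),
    data.frame(id = "s", x = 1, y = 1, max_beds = 10),
    matrix(500, 1, 1))
  expect_equal(c(one$I, one$J), c(1, 1))

  # zero distances are rejected (distance decay undefined at 0)
  expect_error(build_instance(m1$centers, m1$sites,
                              matrix(c(0, 2000, 2000, 1000), 2, 2),
                              beta = 1),
               "positive")
  # dimension mismatch
  expect_error(build_instance(m1$centers, m1$sites, matrix(1, 3, 2)),
               "distance matrix")
  # demand exceeding elderly
  bad <- m1$centers; bad$demand <- bad$elderly + 1
  expect_error(build_instance(bad, m1$sites, m1$distances), "demand")
  # degenerate costs
  expect_error(build_instance(m1$centers, m1$sites, m1$distances,
                              costs = list(charge = 100, cost = 200)),
               "costs")
  # zero total demand
  none <- m1$centers; none$demand <- 0
  expect_error(build_instance(none, m1$sites, m1$distances), "W")
})

test_that("clamp_distances floors co-located pairs", {
  d <- clamp_distances(matrix(c(0, 10, 0.2, 3), 2, 2))
  expect_true(all(d >= 1))
  expect_equal(d[2, 1], 10)
  expect_error(clamp_distances(matrix(1, 1, 1), floor = 0), "positive")
})

test_that("effective distance adds speed-converted dwell time", {
  expect_equal(effective_distance(1000, c(30, 30), 5), 1300)
  expect_equal(effective_distance(1000, numeric(), 99), 1000)
  expect_equal(effective_distance(0, 10, 2), 20)
  expect_error(effective_distance(-1, 10, 2), "non-negative")
  expect_error(effective_distance(10, 10, 0), "positive")
})

test_that("nearest allocation picks the closest open site, ties to lowest index", {
  Z <- allocate_nearest(m1, c(1, 2))
  expect_equal(Z, matrix(c(1, 0, 0, 1), 2, 2))
  # single open site takes everything
  Z2 <- allocate_nearest(m1, 2)
  expect_equal(Z2[, 2], c(1, 1))
  # equidistant -> lowest site index
  tie <- build_instance(m1$centers, m1$sites,
                        matrix(1000, 2, 2), beta = 1)
  expect_equal(allocate_nearest(tie, c(1, 2))[, 1], c(1, 1))
  expect_error(allocate_nearest(m1, integer()), "open")
})

test_that("nearest allocation dominates any other open-site choice per center", {
  for (s in 1:20) {
    pr <- random_pair(s)
    open <- pr$config$open
    Z <- pr$config$allocation
    chosen <- apply(Z, 1, which.max)
    d <- pr$instance$distances
    for (i in seq_len(pr$instance$I))
      expect_true(all(d[i, chosen[i]] <= d[i, open]))
  }
})

test_that("constraint checker reports per-family magnitudes", {
  conf <- size_beds_to_demand(m1, c(1, 2))
  v <- check_constraints(m1, conf)
  expect_true(v$feasible)
  expect_equal(c(v$count, v$coverage, v$linkage, v$capacity), rep(0, 4))

  # declared p off by one -> count family only
  conf2 <- conf; conf2$p <- 3L
  v2 <- check_constraints(m1, conf2)
  expect_equal(v2$count, 1)
  expect_false(v2$feasible)

  # overfull site -> capacity magnitude equals the overflow
  conf3 <- facility_configuration(c(1, 2), c(301, 30), conf$allocation)
  expect_equal(check_constraints(m1, conf3)$capacity, 1)

  # allocation to a closed site -> linkage; row sums broken -> coverage
  Z <- conf$allocation
  conf4 <- facility_configuration(1, c(30, 0), Z)
  v4 <- check_constraints(m1, conf4)
  expect_equal(v4$linkage, 1)

  Z5 <- Z; Z5[1, ] <- 0
  conf5 <- facility_configuration(c(1, 2), c(10, 20), Z5)
  expect_equal(check_constraints(m1, conf5)$coverage, 1)
})

test_that("single perturbations trip exactly one constraint family", {
  # find a random pair whose demand-sized configuration is feasible
  # (random open sets can leave a site with an empty catchment)
  pr <- NULL
  for (s in 1:50) {
    cand <- random_pair(s)
    if (check_constraints(cand$instance, cand$config)$feasible) {
      pr <- cand; break
    }
  }
  expect_false(is.null(pr))
  inst <- pr$instance; conf <- pr$config
  base <- check_constraints(inst, conf)
  expect_true(base$feasible)
  # close one allocated site without reallocating
  j_used <- which(colSums(conf$allocation) > 0)[1]
  conf_a <- conf
  conf_a$open <- setdiff(conf$open, j_used)
  conf_a$p <- length(conf_a$open)
  v <- check_constraints(inst, conf_a)
  expect_true(v$linkage > 0)
  expect_equal(v$count + v$coverage, 0)
})

test_that("demand-sized beds conserve total demand", {
  expect_equal(size_beds_to_demand(m1, c(1, 2))$beds, c(10, 20))
  expect_equal(size_beds_to_demand(m1, 1)$beds, c(30, 0))
  for (s in 1:10) {
    pr <- random_pair(s + 100)
    expect_equal(pr$config$total_beds, pr$instance$W)
  }
})
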