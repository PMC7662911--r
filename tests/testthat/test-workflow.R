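test_that("assessment reproduces the planning-target arithmetic", {
  # 2.5% of 326,520 elderly = 8163 target beds
  n <- 20
  centers <- data.frame(id = paste0("c", 1:n), x = runif(n, 0, 5000),
                        y = runif(n, 0, 5000), elderly = 326520 / n,
                        demand = round(0.025 * 326520 / n))
  sites <- data.frame(id = paste0("s", 1:4), x = c(0, 5000, 0, 5000),
                      y = c(0, 0, 5000, 5000), max_beds = 300)
  set.seed(1)
  d <- clamp_distances(matrix(runif(n * 4, 100, 6000), n, 4))
  inst <- build_instance(centers, sites, d)
  conf <- size_beds_to_demand(inst, 1:4)
  a <- assess_current(inst, conf, target_rate = 0.025)
  expect_equal(a$target_beds, 8163)
  # demand-sized facilities have zero demand-vs-scale gap
  expect_equal(a$facility$gap, rep(0, 4))
  # all demand served at the target rate -> no deficit
  expect_equal(a$bed_deficit, max(0, 8163 - conf$total_beds))
})

test_that("well-supplied centers are not flagged below target", {
  # symmetric district: every center has its own facility at 3x demand,
  # so every center sits at 7.5 beds per 100 elderly, above the 2.5 target
  fx <- .profit_fixture(1000, 10)
  generous <- fx$config
  generous$beds <- generous$beds * 3
  a <- assess_current(fx$instance, generous, radius = 1e6)
  expect_equal(a$share_below_target, 0)
  # and starving the same district puts everyone below target
  starved <- fx$config
  starved$beds <- pmax(1, round(fx$config$beds * 0.05))
  a2 <- assess_current(fx$instance, starved, radius = 1e6)
  expect_equal(a2$share_below_target, 1)
})

test_that("bed adjustment caps facilities and peels overflow from the margin", {
  sc <- small_scenario(3)
  adj <- adjust_scales(sc$instance, sc$existing$open)
  capv <- sc$instance$sites$max_beds
  expect_true(all(adj$beds <= capv))
  # conservation: served + unmet = total demand
  expect_equal(sum(adj$beds) + adj$unmet_total, sc$instance$W)
  expect_true(all(rowSums(adj$served_allocation) <= 1 + 1e-12))

  # explicit overflow: one facility assigned 350 under a 300 cap
  centers <- data.frame(id = c("a", "b"), x = c(0, 100), y = 0,
                        elderly = c(4000, 10000), demand = c(100, 250))
  sites <- data.frame(id = "s", x = 50, y = 0, max_beds = 300)
  inst <- build_instance(centers, sites,
                         clamp_distances(matrix(c(50, 50), 2, 1)))
  adj2 <- adjust_scales(inst, 1)
  expect_equal(adj2$beds[1], 300)
  expect_equal(adj2$unmet_total, 50)
  # the farthest-tied center loses the overflow (tie by order: equal
  # distances peel the later one first under decreasing order)
  expect_equal(sum(adj2$unmet), 50)

  # no overflow -> no unmet demand
  roomy <- adjust_scales(inst, 1, cap = 1000)
  expect_equal(roomy$unmet_total, 0)
})

test_that("minimum facility count is the capacity ceiling", {
  expect_equal(min_new_facilities(1193, 300), 4L)
  expect_equal(min_new_facilities(0, 300), 0L)
  expect_equal(min_new_facilities(301, 300), 2L)
  expect_error(min_new_facilities(10, 0), "positive")
})

test_that("facility-count selection picks the published sweep minimum", {
  counts <- 4:14
  values <- c(0.6722, 0.6323, 0.6012, 0.6283, 0.6501, 0.6766, 0.7149,
              0.7364, 0.7626, 0.7943, 0.8243)
  expect_equal(select_new_count(counts, values), 6)
  expect_equal(select_new_count(7, 0.3), 7)
})

test_that("sweeping the residual problem matches the exhaustive oracle per count", {
  or <- oracle_instance(seed = 9, I = 10, J = 8, p = 2)
  pars <- mia_params(p = 2, N = 25, t_max = 120, seed = 5)
  sw <- sweep_new_count(or$instance, 1:3, pars)
  expect_equal(nrow(sw$table), 3)
  expect_true(sw$p_star %in% 1:3)
  # each per-count winner equals the exhaustive optimum for that count
  for (k in 1:3) {
    opt <- enumerate_optimum(or$instance, k)
    expect_identical(sw$fits[[k]]$configuration$open, opt$open)
  }
})

test_that("new-facility beds cover exactly the unmet demand within caps", {
  sc <- small_scenario(4)
  adj <- adjust_scales(sc$instance, sc$existing$open, cap = 60)
  expect_gt(adj$unmet_total, 0)
  res <- residual_instance(sc$instance, adj$unmet,
                           exclude_sites = sc$existing$open)
  k <- min_new_facilities(adj$unmet_total, 60)
  pars <- mia_params(p = k, N = 20, t_max = 60, seed = 3)
  fit <- mia(res$instance, pars)
  nb <- try(finalize_new_beds(res, fit$configuration$open), silent = TRUE)
  if (!inherits(nb, "try-error")) {
    expect_equal(sum(nb$beds), adj$unmet_total)
    expect_true(all(nb$beds <= sc$instance$sites$max_beds[nb$site]))
    expect_true(all(nb$site %in% res$site_idx))
  }
})

test_that("gini coefficient matches hand-computed Lorenz areas", {
  expect_equal(gini_coefficient(c(1, 1, 1)), 0)
  expect_equal(gini_coefficient(c(0, 1), c(1, 1)), 0.5)
  # scale invariance and weight sensitivity
  set.seed(2)
  v <- runif(10); w <- sample(1:5, 10, replace = TRUE)
  expect_equal(gini_coefficient(3 * v, w), gini_coefficient(v, w))
  expect_error(gini_coefficient(c(0, 0)), "zero")
  expect_error(gini_coefficient(c(-1, 2)), "non-negative")
})

test_that("facilities planted in empty corners are flagged, well-placed ones kept", {
  # a cluster of demand with two facilities in it, plus one in an empty corner
  centers <- data.frame(id = paste0("c", 1:6),
                        x = c(900, 1000, 1100, 950, 1050, 1000),
                        y = c(900, 950, 1000, 1100, 900, 1000),
                        elderly = 2000, demand = 50)
  sites <- data.frame(id = paste0("s", 1:6),
                      x = c(950, 1050, 5000, 900, 1000, 1100),
                      y = c(950, 1050, 5000, 1000, 950, 1000),
                      max_beds = 300)
  d <- clamp_distances(outer(seq_len(6), seq_len(6), function(i, j)
    sqrt((centers$x[i] - sites$x[j])^2 + (centers$y[i] - sites$y[j])^2)))
  inst <- build_instance(centers, sites, d)
  existing <- size_beds_to_demand(inst, c(1, 2, 3))  # site 3 is the corner
  existing$beds[3] <- 100                            # redundant corner beds
  pars <- mia_params(p = 3, N = 25, t_max = 80, seed = 4)
  flags <- identify_unreasonable(inst, existing, pars,
                                 distance_tolerance = 500)
  expect_true(3 %in% flags$flagged)
  expect_false(1 %in% flags$flagged)
  # an infinite tolerance never flags (nothing is "far")
  none <- identify_unreasonable(inst, existing, pars, distance_tolerance = Inf)
  expect_equal(length(none$flagged), 0)
})

test_that("evaluation report is symmetric at identity and signs changes correctly", {
  sc <- small_scenario(5)
  ev <- evaluation_report(sc$instance, sc$existing, sc$existing,
                          beta_before = 1.8, beta_after = 1.8)
  expect_true(all(abs(ev$table$change_pct) < 1e-9))
  expect_equal(ev$efficiency_pct, 0)
  # published profit change: 111,785 -> 145,120 is +29.82%
  expect_equal((145120 - 111785) / 111785 * 100, 29.82, tolerance = 5e-4)
  # published Gini change: 0.5563 -> 0.1225 is a 77.98% reduction
  expect_equal(relative_difference_pct(0.5563, 0.1225), 77.98,
               tolerance = 5e-4)
})

test_that("the three-step plan serves all demand feasibly and improves the district", {
  sc <- generate_scenario(scenario_spec(seed = 21))
  pars <- mia_params(p = 12, N = 40, t_max = 100, seed = 21)
  plan <- plan_configuration(sc$instance, sc$existing, pars)
  expect_true(plan$feasible)
  expect_equal(plan$configuration$total_beds, sc$instance$W)
  expect_true(all(rowSums(plan$configuration$allocation) - 1 < 1e-9))
  ev <- evaluation_report(sc$instance, sc$existing, plan$configuration)
  tab <- ev$table
  g <- function(m, col) tab[tab$metric == m, col]
  expect_lt(g("equity", "after"), g("equity", "before"))
  expect_lt(g("gini", "after"), g("gini", "before"))
  expect_lt(g("travel_per_capita", "after"), g("travel_per_capita", "before"))
})
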