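test_that("selection threshold holds early then ramps to one", {
  expect_equal(selection_threshold(0, 300), 0.3)
  expect_equal(selection_threshold(150, 300), 0.3)
  expect_equal(selection_threshold(300, 300), 1)
  grid <- selection_threshold(0:300, 300)
  expect_true(all(diff(grid) >= 0))
  expect_error(selection_threshold(-1, 300), "out of")
})

test_that("mutation probability follows the periodic cosine with offset", {
  expect_equal(mutation_probability(0, 0.1, 50, 0.05), 0.15)
  grid <- 0:200
  expect_equal(mutation_probability(grid, 0.1, 50, 0.05),
               0.1 * abs(cos(2 * pi * grid / 50)) + 0.05)
  # |cos| has period T/2; never zero thanks to gamma
  expect_equal(mutation_probability(grid, 0.1, 50, 0.05),
               mutation_probability(grid + 25, 0.1, 50, 0.05))
  expect_true(all(mutation_probability(grid, 0.1, 50, 0.05) >= 0.05))
  expect_equal(mutation_probability(12.5, 0.1, 50, 0.05), 0.05)
})

test_that("global-best perturbation fires on schedule with decaying envelope", {
  expect_equal(perturb_global_best(1, t = 7, theta = 5, u = 0.9), 1)
  expect_equal(perturb_global_best(1, t = 10, theta = 5, u = 0.5),
               1 + exp(-2) * 0.25)
  # envelope strictly decreasing over the schedule, bounded by 1 at t = 0
  ts <- seq(0, 100, by = 5)
  env <- exp(-ts / 5)
  expect_true(all(diff(env) < 0))
  expect_lte(perturb_global_best(0, 0, 5, u = 1), 1)
})

test_that("concentration counts Jaccard-similar antibodies", {
  same <- replicate(6, c(1, 4, 7), simplify = FALSE)
  expect_equal(concentration(same, c(1, 4, 7), 0.8, J = 10), 1)
  disjoint <- list(c(1, 2), c(3, 4), c(5, 6), c(7, 8))
  expect_equal(concentration(disjoint, c(1, 2), 0.5, J = 10), 0.25)
  pairs <- list(c(1, 2), c(1, 2), c(3, 4), c(3, 4))
  expect_equal(concentration(pairs, c(1, 2), 1, J = 10), 0.5)
})

test_that("elite recombination repairs to valid antibodies", {
  # identical parents reproduce exactly
  pool <- replicate(4, c(2, 5, 9), simplify = FALSE)
  expect_equal(guo_elite_mutation(pool, J = 12, phi = c(0.3, 0.3, 0.2, 0.2)),
               c(2, 5, 9))
  # vertex weights return the chosen parent
  pool2 <- list(c(1, 3), c(5, 9))
  expect_equal(guo_elite_mutation(pool2, J = 10, phi = c(1, 0)), c(1, 3))
  # hand-computed midpoint with rounding repair
  expect_equal(guo_elite_mutation(pool2, J = 10, phi = c(0.5, 0.5)), c(3, 6))
  # random draws always yield distinct in-range indices
  set.seed(1)
  for (i in 1:200) {
    child <- guo_elite_mutation(list(c(1, 2, 3), c(8, 9, 10), c(4, 5, 6)),
                                J = 10)
    expect_equal(length(unique(child)), 3)
    expect_true(all(child >= 1 & child <= 10))
  }
  expect_error(guo_elite_mutation(list(c(1, 2)), J = 10), "at least 2")
})

test_that("clonal selection conserves the clone budget and favors quality", {
  # uniform scores -> uniform counts (within rounding)
  sel <- clonal_select(rep(2, 10), rep(0.1, 10), sigma = 0.3, n_clones = 10)
  expect_equal(sum(sel$clones), 10)
  expect_true(max(sel$clones) - min(sel$clones) <= 1)
  # a dominant antibody gets the largest share
  aff <- c(10, rep(1, 9))
  sel2 <- clonal_select(aff, c(0, rep(0.5, 9)), sigma = 0.3, n_clones = 10)
  expect_equal(sum(sel2$clones), 10)
  expect_equal(sel2$selected[which.max(sel2$clones)], 1L)
  # conservation at high thresholds too
  sel3 <- clonal_select(runif(15) + 0.1, runif(15), sigma = 0.95, n_clones = 15)
  expect_equal(sum(sel3$clones), 15)
})

test_that("memory bank keeps the best unique antibodies", {
  mem <- update_memory(NULL, list(c(1, 2), c(3, 4), c(5, 6)),
                       F = c(0.3, 0.1, 0.2), capacity = 2)
  expect_equal(mem$encodings, list(c(3, 4), c(5, 6)))
  # a strictly better antibody evicts the worst cell
  mem2 <- update_memory(mem, list(c(7, 8)), F = 0.05, capacity = 2)
  expect_equal(mem2$encodings[[1]], c(7, 8))
  expect_false(any(vapply(mem2$encodings, identical, logical(1), c(5, 6))))
  # duplicates are not stored twice
  mem3 <- update_memory(mem, list(c(3, 4)), F = 0.1, capacity = 2)
  expect_equal(length(mem3$encodings), 2)
})

test_that("population initialization is seeded and respects the encoding", {
  or <- oracle_instance(seed = 5)
  pars <- mia_params(p = 3, N = 20, seed = 99)
  pop1 <- initialize_population(or$instance, pars)
  pop2 <- initialize_population(or$instance, pars)
  expect_identical(pop1, pop2)
  expect_equal(length(pop1), 20)
  for (e in pop1) {
    expect_equal(length(unique(e)), 3)
    expect_true(all(e >= 1 & e <= or$instance$J))
  }
  # J = p collapses to the full site set
  pars2 <- mia_params(p = or$instance$J, N = 5, seed = 1)
  expect_true(all(vapply(initialize_population(or$instance, pars2),
                         identical, logical(1), seq_len(or$instance$J))))
  expect_error(initialize_population(or$instance,
                                     mia_params(p = 99, N = 5)), "J < p")
})

test_that("the optimizer is reproducible and its incumbent never regresses", {
  or <- oracle_instance(seed = 3)
  pars <- mia_params(p = 3, N = 20, t_max = 40, seed = 7)
  f1 <- mia(or$instance, pars)
  f2 <- mia(or$instance, pars)
  expect_identical(f1$configuration$open, f2$configuration$open)
  expect_identical(f1$trace$best_F, f2$trace$best_F)
  expect_true(all(diff(f1$trace$best_F) <= 0))
  expect_true(f1$feasible)
  expect_true(check_constraints(or$instance, f1$configuration)$feasible)
})

test_that("a degenerate single-iteration run returns a valid configuration", {
  or <- oracle_instance(seed = 4)
  f <- mia(or$instance, mia_params(p = 3, N = 10, t_max = 1, seed = 2))
  expect_equal(nrow(f$trace), 1)
  expect_equal(length(f$configuration$open), 3)
  expect_true(check_constraints(or$instance, f$configuration)$feasible)
})

test_that("the optimizer recovers the exhaustive optimum on a small instance", {
  or <- oracle_instance(seed = 1)
  for (s in c(11, 22, 33)) {
    f <- mia(or$instance, mia_params(p = 3, N = 30, t_max = 200, seed = s))
    expect_identical(f$configuration$open, or$optimum$open)
  }
})
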