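#' Parameters for the baseline metaheuristics
#'
#' Textbook forms of a genetic algorithm (tournament selection, one-point
#' crossover with duplicate repair, swap mutation), global-best particle
#' swarm optimization (positions relaxed to real site-index vectors and
#' repaired by rounding), and a standard immune algorithm (fixed selection
#' threshold, constant mutation probability, exchange mutation only), all
#' over the same encoding and scoring as [mia()].
#'
#' @param algorithm `"ga"`, `"pso"`, or `"ia"`.
#' @param p number of facilities.
#' @param N population / swarm size.
#' @param t_max iterations.
#' @param seed integer seed.
#' @param crossover_rate,mutation_rate GA rates in \[0, 1\].
#' @param inertia,cognitive,social PSO velocity weights.
#' @param a_sel fixed IA selection threshold.
#' @param eta,eps_f,weights_mode scalarization settings (see [mia_params()]).
#' @return object of class `baseline_params`.
#' @export
baseline_params <- function(algorithm = c("ga", "pso", "ia"), p, N = 30,
                            t_max = 300, seed = 1,
                            crossover_rate = 0.8, mutation_rate = 0.1,
                            inertia = 0.7, cognitive = 1.5, social = 1.5,
                            a_sel = 0.3, eta = 2, eps_f = 1e-6,
                            weights_mode = c("equal", "adaptive")) {
  algorithm <- match.arg(algorithm)
  if (missing(p) || p < 1) stop("p must be >= 1")
  if (N < 2) stop("N must be >= 2")
  if (any(c(crossover_rate, mutation_rate) < 0) ||
      any(c(crossover_rate, mutation_rate) > 1))
    stop("rates must lie in [0, 1]")
  structure(list(algorithm = algorithm, p = as.integer(p), N = as.integer(N),
                 t_max = as.integer(t_max), seed = as.integer(seed),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate, inertia = inertia,
                 cognitive = cognitive, social = social, a_sel = a_sel,
                 eta = eta, eps_f = eps_f,
                 weights_mode = match.arg(weights_mode)),
            class = "baseline_params")
}

#' Run a baseline optimizer
#'
#' Same contract as [mia()]: seeded, returns the best feasible configuration
#' found (re-scored over all evaluated solutions in one final context) and a
#' per-iteration trace with a non-increasing `best_F`.
#'
#' @param instance an [rcf_instance][build_instance].
#' @param params a [baseline_params] object.
#' @return an object of class `mia_fit` with `algorithm` set accordingly.
#' @export
run_baseline <- function(instance, params) {
  stopifnot(inherits(instance, "rcf_instance"),
            inherits(params, "baseline_params"))
  impl <- switch(params$algorithm, ga = .run_ga, pso = .run_pso, ia = .run_ia)
  .with_seed(params$seed, impl(instance, params))
}

.finish_baseline <- function(instance, evaluator, trace, params) {
  best <- .final_best(evaluator, weights_mode = params$weights_mode,
                      eta = params$eta, eps_f = params$eps_f)
  config <- .encoding_to_config(instance, best$open)
  structure(list(
    configuration = config,
    objectives = objective_vector(instance, config),
    best_F = best$F, feasible = best$feasible,
    trace = as.data.frame(do.call(rbind, trace)),
    params = params, n_evaluated = best$n_evaluated,
    algorithm = params$algorithm
  ), class = "mia_fit")
}

.trace_row <- function(t, incumbent, sc, keep) {
  c(iteration = t, best_F = incumbent, working_best = incumbent,
    mean_F = mean(sc$F[keep]), feasible_fraction = mean(sc$capacity[keep] == 0),
    sigma = NA, pm = NA)
}

.run_ga <- function(instance, params) {
  evaluator <- .make_evaluator(instance)
  J <- instance$J; N <- params$N; p <- params$p
  pop <- .random_subsets(N, J, p)
  trace <- vector("list", params$t_max)
  incumbent <- Inf
  for (t in seq_len(params$t_max)) {
    sc <- .score_population(evaluator, pop, params$weights_mode,
                            eta = params$eta, eps_f = params$eps_f)
    incumbent <- min(incumbent, min(sc$F))
    trace[[t]] <- .trace_row(t, incumbent, sc, seq_len(N))
    elite <- pop[[which.min(sc$F)]]
    tournament <- function() {
      ij <- sample.int(N, 2)
      pop[[ij[which.min(sc$F[ij])]]]
    }
    nxt <- vector("list", N)
    nxt[[1]] <- elite
    k <- 2
    while (k <= N) {
      pa <- tournament(); pb <- tournament()
      if (p >= 2 && stats::runif(1) < params$crossover_rate) {
        cut <- sample.int(p - 1, 1)
        child <- .repair_encoding(c(pa[seq_len(cut)], pb[(cut + 1):p]), J)
      } else child <- pa
      if (stats::runif(1) < params$mutation_rate)
        child <- .swap_mutation(child, J)
      nxt[[k]] <- child
      k <- k + 1
    }
    pop <- nxt
  }
  .finish_baseline(instance, evaluator, trace, params)
}

.run_pso <- function(instance, params) {
  evaluator <- .make_evaluator(instance)
  J <- instance$J; N <- params$N; p <- params$p
  X <- do.call(rbind, .random_subsets(N, J, p))   # N x p, relaxed to real
  V <- matrix(0, N, p)
  pbest <- X
  trace <- vector("list", params$t_max)
  incumbent <- Inf
  gbest <- X[1, ]
  for (t in seq_len(params$t_max)) {
    enc <- lapply(seq_len(N), function(i) .repair_encoding(X[i, ], J))
    pb_enc <- lapply(seq_len(N), function(i) .repair_encoding(pbest[i, ], J))
    gb_enc <- .repair_encoding(gbest, J)
    all_enc <- c(enc, pb_enc, list(gb_enc))
    sc <- .score_population(evaluator, all_enc, params$weights_mode,
                            eta = params$eta, eps_f = params$eps_f)
    Fx <- sc$F[seq_len(N)]; Fpb <- sc$F[N + seq_len(N)]
    Fgb <- sc$F[2 * N + 1]
    improve <- Fx < Fpb
    pbest[improve, ] <- X[improve, ]
    Fpb[improve] <- Fx[improve]
    ib <- which.min(Fpb)
    if (Fpb[ib] < Fgb) gbest <- pbest[ib, ]
    incumbent <- min(incumbent, min(sc$F))
    trace[[t]] <- .trace_row(t, incumbent, sc, seq_len(N))
    R1 <- matrix(stats::runif(N * p), N, p)
    R2 <- matrix(stats::runif(N * p), N, p)
    V <- params$inertia * V +
      params$cognitive * R1 * (pbest - X) +
      params$social * R2 * (matrix(gbest, N, p, byrow = TRUE) - X)
    X <- pmin(pmax(X + V, 1), J)
  }
  .finish_baseline(instance, evaluator, trace, params)
}

.run_ia <- function(instance, params) {
  evaluator <- .make_evaluator(instance)
  J <- instance$J; N <- params$N; p <- params$p
  pop <- .random_subsets(N, J, p)
  trace <- vector("list", params$t_max)
  incumbent <- Inf
  for (t in seq_len(params$t_max)) {
    sc <- .score_population(evaluator, pop, params$weights_mode,
                            eta = params$eta, eps_f = params$eps_f)
    incumbent <- min(incumbent, min(sc$F))
    sim <- .jaccard_cross(pop, pop, J)
    conc <- rowMeans(sim >= 0.8)
    sel <- clonal_select(sc$affinity, conc, params$a_sel, N)
    clones <- list()
    for (i in seq_along(sel$selected)) {
      parent <- pop[[sel$selected[i]]]
      for (cidx in seq_len(sel$clones[i])) {
        clones[[length(clones) + 1L]] <-
          if (stats::runif(1) < params$mutation_rate)
            .swap_mutation(parent, J) else parent
      }
    }
    combined <- c(pop, clones)
    combined <- combined[!duplicated(vapply(combined, paste, character(1),
                                            collapse = ","))]
    sc2 <- .score_population(evaluator, combined, params$weights_mode,
                             eta = params$eta, eps_f = params$eps_f)
    keep <- order(sc2$F)[seq_len(min(N, length(combined)))]
    pop <- combined[keep]
    if (length(pop) < N)
      pop <- c(pop, .random_subsets(N - length(pop), J, p))
    incumbent <- min(incumbent, min(sc2$F))
    trace[[t]] <- .trace_row(t, incumbent, sc2, seq_along(keep))
  }
  .finish_baseline(instance, evaluator, trace, params)
}

#' Compare optimization algorithms on one instance
#'
#' Runs each supplied algorithm, re-scores their best configurations against
#' each other in one shared standardization context (so the comprehensive
#' values are comparable), and reports per-algorithm raw objectives,
#' comprehensive value, iterations to convergence, and the relative
#' difference of every algorithm against the reference (the last `"mia"`
#' entry, or the best performer when none is labelled `mia`), computed as
#' `(other - reference)/other * 100`.
#'
#' @param instance an [rcf_instance][build_instance].
#' @param param_sets named list of [mia_params] and/or [baseline_params]
#'   objects; names label the rows.
#' @param tol convergence tolerance on the best-F trace.
#' @return object of class `rcf_comparison` with a `table` data.frame and
#'   the `fits`.
#' @export
compare_algorithms <- function(instance, param_sets, tol = 1e-6) {
  if (length(param_sets) < 2) stop("need at least two algorithms")
  if (is.null(names(param_sets)))
    names(param_sets) <- vapply(param_sets, function(p)
      if (inherits(p, "mia_params")) "mia" else p$algorithm, character(1))
  fits <- lapply(param_sets, function(pr)
    if (inherits(pr, "mia_params")) mia(instance, pr)
    else run_baseline(instance, pr))
  raw <- t(vapply(fits, function(f) {
    o <- f$objectives
    c(o$equity, o$efficiency, o$travel_cost, o$profit)
  }, numeric(4)))
  colnames(raw) <- .obj_names
  std <- standardize_objectives(raw)
  wts <- objective_weights("equal",
                           has_baseline = !is.null(instance$baseline_accessibility))
  comp <- pmax(as.numeric(std %*% wts), 1e-6)
  iters <- vapply(fits, function(f)
    convergence_iteration(f$trace$best_F, tol), numeric(1))
  ref <- if ("mia" %in% names(fits)) which(names(fits) == "mia")[1]
         else which.min(comp)
  tab <- data.frame(
    algorithm = names(fits),
    equity = raw[, 1], efficiency = raw[, 2],
    travel_cost_per_capita = vapply(fits, function(f)
      f$objectives$travel_cost_per_capita, numeric(1)),
    profit = raw[, 4],
    comprehensive = comp,
    iterations = iters,
    comprehensive_diff_pct = relative_difference_pct(comp, comp[ref]),
    iterations_diff_pct = relative_difference_pct(iters, iters[ref]))
  structure(list(table = tab, fits = fits, reference = names(fits)[ref]),
            class = "rcf_comparison")
}

#' @export
print.rcf_comparison <- function(x, ...) {
  cat("Algorithm comparison (reference:", x$reference, ")\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, 6)
  print(tab, row.names = FALSE)
  invisible(x)
}
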