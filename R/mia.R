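#' Parameters of the modified immune algorithm
#'
#' Collects and validates every tunable of the optimizer. Defaults follow
#' common clonal-selection practice: selection-threshold coefficient 0.3,
#' mutation amplitude 0.1, and a mutation period of one fifth of the run.
#'
#' @param p number of facilities to open (required).
#' @param N antibody population size (>= 2).
#' @param t_max number of iterations.
#' @param seed integer random seed; every run is reproducible from it.
#' @param a_sel threshold coefficient of the variable selection threshold
#'   (the early-stage value; must be in (0, 1)).
#' @param t_ave iteration at which the threshold starts rising; default
#'   `t_max / 2`.
#' @param epsilon amplitude of the periodic mutation probability.
#' @param period period `T` of the mutation-probability cosine; default
#'   `max(4, round(t_max / 5))`.
#' @param gamma mutation-probability offset, `0 < gamma <= epsilon`, keeping
#'   the probability positive at the cosine zeros.
#' @param theta perturbation interval of the global best (>= 1).
#' @param elite_frac fraction of the population forming the elite-parent pool
#'   of the recombination mutation (pool size at least 2).
#' @param memory_size memory-bank capacity; default `ceiling(N / 2)`.
#' @param similarity_threshold Jaccard similarity above which two antibodies
#'   count as the same lineage for concentration and memory damping.
#' @param damping multiplier applied to the selection score of antibodies too
#'   similar to a strictly better memory cell.
#' @param swap_prob probability of a plain exchange mutation for clones that
#'   skip the elite recombination draw.
#' @param eta penalty exponent of the adaptive constraint penalty.
#' @param eps_f positive floor of the scalarized objective.
#' @param weights_mode `"equal"` (default) or `"adaptive"` objective weights.
#' @return object of class `mia_params`.
#' @export
mia_params <- function(p, N = 30, t_max = 300, seed = 1,
                       a_sel = 0.3, t_ave = NULL,
                       epsilon = 0.1, period = NULL, gamma = 0.05,
                       theta = 10, elite_frac = 0.1,
                       memory_size = NULL, similarity_threshold = 0.8,
                       damping = 0.5, swap_prob = 0.05,
                       eta = 2, eps_f = 1e-6,
                       weights_mode = c("equal", "adaptive")) {
  if (missing(p) || p < 1) stop("p (facility count) must be >= 1")
  if (N < 2) stop("N must be >= 2")
  if (t_max < 1) stop("t_max must be >= 1")
  if (a_sel <= 0 || a_sel >= 1) stop("a_sel must be in (0, 1)")
  if (gamma <= 0 || gamma > epsilon) stop("need 0 < gamma <= epsilon")
  if (theta < 1) stop("theta must be >= 1")
  if (is.null(t_ave)) t_ave <- t_max / 2
  if (is.null(period)) period <- max(4, round(t_max / 5))
  if (is.null(memory_size)) memory_size <- ceiling(N / 2)
  structure(list(
    p = as.integer(p), N = as.integer(N), t_max = as.integer(t_max),
    seed = as.integer(seed), a_sel = a_sel, t_ave = t_ave,
    epsilon = epsilon, period = period, gamma = gamma, theta = theta,
    elite_frac = elite_frac, memory_size = as.integer(memory_size),
    similarity_threshold = similarity_threshold, damping = damping,
    swap_prob = swap_prob, eta = eta, eps_f = eps_f,
    weights_mode = match.arg(weights_mode)
  ), class = "mia_params")
}

#' Variable selection threshold
#'
#' The clonal-selection threshold stays at its small early-stage value
#' `a_sel` until `t_ave`, then rises to 1 along a quarter sine wave, so many
#' antibodies are cloned early (exploration) and few late (exploitation).
#'
#' @param t current iteration, `0 <= t <= t_max`.
#' @param t_max maximum iterations.
#' @param a_sel early-stage threshold (default 0.3).
#' @param t_ave start of the ramp; default `t_max / 2`.
#' @return threshold in \[a_sel, 1\], non-decreasing in `t`.
#' @export
selection_threshold <- function(t, t_max, a_sel = 0.3, t_ave = t_max / 2) {
  if (any(t < 0 | t > t_max)) stop("t out of [0, t_max]")
  ifelse(t <= t_ave, a_sel,
         a_sel + (1 - a_sel) * sin((pi / 2) * (t - t_ave) / (t_max - t_ave)))
}

#' Periodically varying mutation probability
#'
#' `P_m(t) = epsilon * |cos(2 pi t / period)| + gamma`: large early, dipping
#' and recovering cyclically, never below `gamma > 0`.
#'
#' @param t iteration (>= 0); vectorized.
#' @param epsilon amplitude.
#' @param period cosine period `T`.
#' @param gamma positive offset.
#' @export
mutation_probability <- function(t, epsilon = 0.1, period = 50, gamma = 0.05) {
  if (any(t < 0)) stop("t must be >= 0")
  epsilon * abs(cos(2 * pi * t / period)) + gamma
}

#' Perturb the working copy of the global best
#'
#' At every `theta`-th iteration the *working* comparison value of the global
#' best is inflated by `exp(-t/theta) * u^2` with `u ~ Uniform(0, 1)`, making
#' it easier for new solutions to displace a stale incumbent early on; the
#' envelope decays with `t` so late-stage convergence is untouched. The
#' archived incumbent itself is never perturbed.
#'
#' @param fit_best current working best comprehensive value.
#' @param t iteration.
#' @param theta perturbation interval.
#' @param u optional uniform draw (for deterministic testing).
#' @return the (possibly) perturbed working value.
#' @export
perturb_global_best <- function(fit_best, t, theta, u = stats::runif(1)) {
  if (t %% theta != 0) return(fit_best)
  fit_best + exp(-t / theta) * u^2
}

#' Concentration of an antibody in a population
#'
#' Fraction of the population whose site-set Jaccard similarity with the
#' given antibody is at least `similarity_threshold`. High concentration
#' marks crowded lineages that clonal selection should down-weight to keep
#' the population diverse.
#'
#' @param population list of encodings (sorted integer site-index vectors).
#' @param antibody one encoding.
#' @param similarity_threshold Jaccard cutoff in (0, 1\].
#' @param J total number of candidate sites (defaults to the largest index
#'   seen).
#' @return value in \[0, 1\].
#' @export
concentration <- function(population, antibody, similarity_threshold = 0.8,
                          J = max(unlist(population), antibody)) {
  if (length(population) == 0) stop("population must be nonempty")
  sim <- .jaccard_cross(list(sort(antibody)), lapply(population, sort), J)
  mean(sim >= similarity_threshold)
}

#' Elite recombination (Guo) mutation
#'
#' Offspring are an affine combination of several elite parents: weights phi
#' are drawn uniformly in \[-0.5, 1.5\] and renormalized to sum to 1
#' (redrawn when the sum is nearly 0), the parents' encodings are combined as
#' real vectors, and the result is repaired to a valid antibody by rounding
#' each coordinate into \[1, J\] and replacing duplicates with the nearest
#' unused site index. With identical parents the offspring reproduces the
#' parent exactly.
#'
#' @param elite_pool list of >= 2 parent encodings (equal length p, sorted).
#' @param J number of candidate sites.
#' @param phi optional weight vector (length of the pool, summing to 1) for
#'   deterministic use; drawn randomly when `NULL`.
#' @return a valid sorted encoding of p distinct indices in \[1, J\].
#' @export
guo_elite_mutation <- function(elite_pool, J, phi = NULL) {
  M <- length(elite_pool)
  if (M < 2) stop("elite pool must hold at least 2 parents")
  P <- vapply(elite_pool, identity, numeric(length(elite_pool[[1]])))
  if (is.null(phi)) {
    repeat {
      phi0 <- stats::runif(M, -0.5, 1.5)
      s <- sum(phi0)
      if (abs(s) > 0.1) { phi <- phi0 / s; break }
    }
  } else {
    if (abs(sum(phi) - 1) > 1e-8) stop("phi must sum to 1")
  }
  raw <- as.numeric(P %*% phi)
  .repair_encoding(raw, J)
}

# Round a real-valued index vector into a valid p-subset of 1..J:
# clamp, round, then resolve duplicates by the nearest unused index
# (outward search, lower index first on ties).
.repair_encoding <- function(raw, J) {
  p <- length(raw)
  r <- pmin(pmax(round(raw), 1), J)
  used <- logical(J)
  out <- integer(p)
  for (k in seq_len(p)) {
    v <- r[k]
    if (!used[v]) { used[v] <- TRUE; out[k] <- v; next }
    for (off in seq_len(J)) {
      lo <- v - off; hi <- v + off
      if (lo >= 1 && !used[lo]) { used[lo] <- TRUE; out[k] <- lo; break }
      if (hi <= J && !used[hi]) { used[hi] <- TRUE; out[k] <- hi; break }
    }
  }
  sort(out)
}

#' Clonal selection: who clones, and how often
#'
#' Selection scores are the product of affinity (normalized to its population
#' maximum) and diversity `(1 - concentration)`, optionally damped for
#' antibodies crowding known memory lineages. Antibodies scoring above the
#' `sigma`-quantile of the scores are selected (so the selected fraction is
#' about `1 - sigma`, shrinking as the threshold rises), and a fixed clone
#' budget is apportioned to them proportionally to score by largest
#' remainder, so clone totals are conserved exactly.
#'
#' @param affinity numeric vector of affinities (> 0).
#' @param conc numeric vector of concentrations in \[0, 1\].
#' @param sigma selection threshold from [selection_threshold()].
#' @param n_clones total clone budget (usually the population size).
#' @param damping_mask optional logical vector: antibodies to damp.
#' @param damping multiplier for damped scores.
#' @return list with `selected` (indices) and `clones` (counts per selected,
#'   summing to `n_clones`).
#' @export
clonal_select <- function(affinity, conc, sigma, n_clones,
                          damping_mask = NULL, damping = 0.5) {
  score <- (affinity / max(affinity)) * (1 - conc)
  if (!is.null(damping_mask)) score[damping_mask] <- score[damping_mask] * damping
  cut <- stats::quantile(score, probs = sigma, names = FALSE, type = 7)
  selected <- which(score > cut)
  if (length(selected) == 0) selected <- which.max(score)
  clones <- .apportion(score[selected], n_clones)
  keep <- clones > 0
  list(selected = selected[keep], clones = clones[keep])
}

#' Update the memory bank with the best antibodies seen
#'
#' The memory holds up to `capacity` distinct encodings ranked by the scores
#' supplied (smaller F is better); incoming antibodies evict strictly worse
#' cells and duplicates are never stored twice.
#'
#' @param memory list with `encodings` (list) and `F` (numeric), or `NULL`.
#' @param encodings list of candidate encodings.
#' @param F comprehensive values of the candidates (same context as the
#'   memory's, typically the current generation re-scoring).
#' @param capacity maximum number of cells.
#' @return updated memory list.
#' @export
update_memory <- function(memory, encodings, F, capacity) {
  enc <- c(if (is.null(memory)) list() else memory$encodings, encodings)
  val <- c(if (is.null(memory)) numeric() else memory$F, F)
  key <- vapply(enc, paste, character(1), collapse = ",")
  keep <- !duplicated(key)
  enc <- enc[keep]; val <- val[keep]
  o <- order(val)
  o <- o[seq_len(min(capacity, length(o)))]
  list(encodings = enc[o], F = val[o])
}

#' Initialize an antibody population
#'
#' Decimal encoding: each antibody is a uniformly random subset of `p`
#' distinct candidate-site indices (stored sorted). Reproducible from the
#' seed in `params`.
#'
#' @param instance an [rcf_instance][build_instance].
#' @param params an [mia_params] object.
#' @return list of `N` encodings.
#' @export
initialize_population <- function(instance, params) {
  if (instance$J < params$p)
    stop("fewer candidate sites than facilities requested (J < p)")
  .with_seed(params$seed, .random_subsets(params$N, instance$J, params$p))
}

#' Optimize a facility configuration with the modified immune algorithm
#'
#' Runs the full loop: initialization, affinity/concentration scoring,
#' memory-bank update, variable-threshold clonal selection, elite
#' recombination mutation under a periodic mutation probability, and
#' periodic perturbation of the working global best. Each antibody is a
#' `p`-subset of candidate sites, completed deterministically to a
#' configuration by nearest allocation and demand-sized beds before scoring
#' with the scalarized four-objective function and adaptive constraint
#' penalty.
#'
#' Standardization bounds are population-relative, so comprehensive values
#' from different generations are not directly comparable; the returned best
#' solution is chosen by re-scoring every distinct solution evaluated during
#' the run in one final context and taking the feasible minimizer. The trace
#' column `best_F` is the running minimum of generation-context values and
#' is non-increasing by construction; `working_best` additionally carries the
#' periodic perturbation.
#'
#' @param instance an [rcf_instance][build_instance].
#' @param params an [mia_params] object (or `p` plus `...` shortcuts).
#' @return object of class `mia_fit`: `configuration` (the best
#'   [rcf_config][facility_configuration]), `objectives`
#'   ([objective_vector]), `best_F` (final-context comprehensive value),
#'   `feasible`, `trace` (per-iteration data.frame), `params`,
#'   `n_evaluated`.
#' @examples
#' \donttest{
#' sc <- generate_scenario(scenario_spec(seed = 1, I = 20, J = 24,
#'                                       n_existing = 4))
#' fit <- mia(sc$instance, mia_params(p = 4, N = 20, t_max = 40, seed = 1))
#' fit
#' }
#' @export
mia <- function(instance, params) {
  stopifnot(inherits(instance, "rcf_instance"), inherits(params, "mia_params"))
  .with_seed(params$seed, .run_mia_impl(instance, params))
}

.run_mia_impl <- function(instance, params) {
  evaluator <- .make_evaluator(instance)
  J <- instance$J
  N <- params$N
  pop <- .random_subsets(N, J, params$p)
  memory <- NULL
  M_elite <- max(2, ceiling(params$elite_frac * N))
  trace <- vector("list", params$t_max)
  incumbent_F <- Inf    # running min of generation-context F (reported)
  working_F <- Inf      # perturbed working comparison value

  for (t in seq_len(params$t_max)) {
    # population and memory scored in one shared context so their F values
    # are comparable within the generation
    mem_enc <- if (is.null(memory)) list() else memory$encodings
    sc_all <- .score_population(evaluator, c(pop, mem_enc),
                                weights_mode = params$weights_mode,
                                eta = params$eta, eps_f = params$eps_f)
    sc <- lapply(sc_all[c("F", "affinity", "capacity")],
                 function(x) x[seq_len(N)])
    mem_F <- sc_all$F[-seq_len(N)]
    memory <- update_memory(list(encodings = mem_enc, F = mem_F),
                            pop, sc$F, params$memory_size)

    # concentration and memory damping
    sim <- .jaccard_cross(pop, pop, J)
    conc <- rowMeans(sim >= params$similarity_threshold)
    msim <- .jaccard_cross(pop, memory$encodings, J)
    better <- t(outer(memory$F, sc$F, "<"))   # N x memory: cell strictly better
    damp_mask <- rowSums(msim >= params$similarity_threshold & better) > 0

    sigma <- selection_threshold(t, params$t_max, params$a_sel, params$t_ave)
    sel <- clonal_select(sc$affinity, conc, sigma, N,
                         damping_mask = damp_mask, damping = params$damping)

    # elite pool: top antibodies by affinity
    elite <- pop[order(sc$F)[seq_len(M_elite)]]
    pm <- mutation_probability(t, params$epsilon, params$period, params$gamma)
    clones <- list()
    for (i in seq_along(sel$selected)) {
      parent <- pop[[sel$selected[i]]]
      for (cidx in seq_len(sel$clones[i])) {
        u <- stats::runif(1)
        child <- if (u < pm) {
          guo_elite_mutation(elite, J)
        } else if (u < pm + params$swap_prob) {
          .swap_mutation(parent, J)
        } else parent
        clones[[length(clones) + 1L]] <- child
      }
    }

    # parents + mutated clones, truncated to N by affinity
    combined <- c(pop, clones)
    key <- vapply(combined, paste, character(1), collapse = ",")
    combined <- combined[!duplicated(key)]
    sc2 <- .score_population(evaluator, combined,
                             weights_mode = params$weights_mode,
                             eta = params$eta, eps_f = params$eps_f)
    o <- order(sc2$F)
    keep <- o[seq_len(min(N, length(o)))]
    if (length(keep) < N)   # refill with random immigrants to hold N
      pop <- c(combined[keep], .random_subsets(N - length(keep), J, params$p))
    else pop <- combined[keep]

    gen_best <- min(sc2$F)
    if (gen_best < working_F) working_F <- gen_best
    incumbent_F <- min(incumbent_F, gen_best)
    working_F <- perturb_global_best(working_F, t, params$theta)

    trace[[t]] <- c(iteration = t, best_F = incumbent_F,
                    working_best = working_F,
                    mean_F = mean(sc2$F[keep]),
                    feasible_fraction = mean(sc2$capacity[keep] == 0),
                    sigma = sigma, pm = pm)
  }

  best <- .final_best(evaluator, weights_mode = params$weights_mode,
                      eta = params$eta, eps_f = params$eps_f)
  config <- .encoding_to_config(instance, best$open)
  structure(list(
    configuration = config,
    objectives = objective_vector(instance, config),
    best_F = best$F,
    feasible = best$feasible,
    trace = as.data.frame(do.call(rbind, trace)),
    params = params,
    n_evaluated = best$n_evaluated,
    algorithm = "mia"
  ), class = "mia_fit")
}

#' @export
print.mia_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d open sites, F = %.6f (%s), %d distinct solutions evaluated over %d iterations\n",
              toupper(x$algorithm), length(x$configuration$open), x$best_F,
              if (x$feasible) "feasible" else "infeasible",
              x$n_evaluated, nrow(x$trace)))
  cat("  open sites:", paste(x$configuration$open, collapse = ", "), "\n")
  print(x$objectives)
  invisible(x)
}

#' @export
summary.mia_fit <- function(object, ...) {
  cat("Facility configuration optimization (", toupper(object$algorithm),
      ")\n\n", sep = "")
  print(object)
  tr <- object$trace
  conv <- convergence_iteration(tr$best_F)
  cat(sprintf("  converged at iteration %d of %d (best_F within 1e-6 of final)\n",
              conv, nrow(tr)))
  cat(sprintf("  final feasible fraction of population: %.2f\n",
              tr$feasible_fraction[nrow(tr)]))
  invisible(object)
}

#' @export
plot.mia_fit <- function(x, ...) {
  tr <- x$trace
  graphics::plot(tr$iteration, tr$best_F, type = "s", lwd = 2,
                 xlab = "iteration", ylab = "comprehensive objective F",
                 main = sprintf("%s convergence", toupper(x$algorithm)), ...)
  graphics::lines(tr$iteration, tr$mean_F, lty = 3, col = "grey40")
  graphics::legend("topright", c("best (incumbent)", "population mean"),
                   lty = c(1, 3), lwd = c(2, 1), col = c("black", "grey40"),
                   bty = "n")
  invisible(x)
}

#' First iteration at which the best objective is within tolerance of final
#'
#' @param best_F non-increasing per-iteration best values.
#' @param tol absolute tolerance (default 1e-6).
#' @export
convergence_iteration <- function(best_F, tol = 1e-6) {
  final <- best_F[length(best_F)]
  which(best_F <= final + tol)[1]
}
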