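#' Equity objective: squared dispersion of accessibility
#'
#' The government's equity goal is minimized dispersion of accessibility
#' across population centers, measured as the sum of squared deviations of
#' per-center accessibility from the demand-weighted mean.
#'
#' @param field an [accessibility_field][gravity_accessibility].
#' @return `sum((A_si - a)^2)` (to be minimized; 0 means perfectly even).
#' @examples
#' inst <- micro_instance()
#' conf <- facility_configuration(c(1, 2), c(15, 30),
#'                                allocate_nearest(inst, c(1, 2)))
#' equity_objective(gravity_accessibility(inst, conf)) # 0.028125
#' @export
equity_objective <- function(field) {
  if (length(field$values) == 0) stop("empty accessibility field")
  sum((field$values - field$weighted_mean)^2)
}

#' Efficiency objective: mean relative accessibility change
#'
#' The configuration efficiency is the mean over centers of the relative
#' change in accessibility versus the pre-optimization baseline:
#' `mean((A_si - A_oi)/A_oi)` (to be maximized). Undefined without a
#' baseline.
#'
#' @param field_after an [accessibility_field][gravity_accessibility] or a
#'   numeric vector of post-optimization accessibility values.
#' @param baseline numeric vector of baseline accessibility `A_oi`, all
#'   positive.
#' @export
efficiency_objective <- function(field_after, baseline) {
  after <- if (inherits(field_after, "accessibility_field"))
    field_after$values else as.numeric(field_after)
  if (is.null(baseline)) stop("efficiency objective requires a baseline")
  if (length(baseline) != length(after)) stop("baseline length mismatch")
  if (any(baseline <= 0)) stop("baseline accessibility must be positive")
  mean((after - baseline) / baseline)
}

#' Travel cost objective: demand-weighted allocated distance
#'
#' Total demand-weighted travel distance over the allocation,
#' `sum_ij w_i d_ij Z_ij` in meter-persons (to be minimized). The per-capita
#' value (divided by the served demand) is attached as attribute
#' `"per_capita"` for reporting in meters per person.
#'
#' @param instance an [rcf_instance][build_instance].
#' @param allocation I x J allocation matrix (binary or fractional rows
#'   summing to at most 1).
#' @export
travel_cost_objective <- function(instance, allocation) {
  w <- instance$centers$demand
  total <- sum(w * rowSums(instance$distances * allocation))
  served <- sum(w * rowSums(allocation))
  structure(total, per_capita = if (served > 0) total / served else NA_real_)
}

#' Profit objective: mean monthly margin per open facility
#'
#' Each facility's monthly profit is the bed margin (charge minus running
#' cost) times the demand it serves, `R_j = (c0 - c1) sum_i w_i Z_ij`. The
#' objective is the mean profit over the open facilities (to be maximized).
#' Division is by the number of open facilities `p`, which reproduces the
#' per-facility unit of the reported values.
#'
#' @param instance an [rcf_instance][build_instance].
#' @param configuration an [rcf_config][facility_configuration].
#' @return mean profit per open facility (currency/month), with per-facility
#'   profits attached as attribute `"per_facility"` (length J, zero at closed
#'   sites).
#' @export
profit_objective <- function(instance, configuration) {
  p <- length(configuration$open)
  if (p == 0) stop("no open facilities")
  margin <- instance$costs$charge - instance$costs$cost
  Rj <- margin * as.numeric(crossprod(configuration$allocation,
                                      instance$centers$demand))
  Rj[-configuration$open] <- 0
  structure(sum(Rj) / p, per_facility = Rj)
}

#' Evaluate all four stakeholder objectives of a configuration
#'
#' @param instance an [rcf_instance][build_instance].
#' @param configuration an [rcf_config][facility_configuration].
#' @param beta decay exponent used for the accessibility-based objectives.
#' @return object of class `objective_vector`: equity, efficiency (`NA` when
#'   the instance carries no baseline accessibility), travel cost (plus per
#'   capita), mean profit (plus per facility), and the accessibility field.
#' @export
objective_vector <- function(instance, configuration, beta = instance$beta) {
  field <- gravity_accessibility(instance, configuration, beta = beta)
  tc <- travel_cost_objective(instance, configuration$allocation)
  pr <- profit_objective(instance, configuration)
  eff <- if (is.null(instance$baseline_accessibility)) NA_real_
         else efficiency_objective(field, instance$baseline_accessibility)
  structure(list(
    equity = equity_objective(field),
    efficiency = eff,
    travel_cost = as.numeric(tc),
    travel_cost_per_capita = attr(tc, "per_capita"),
    profit = as.numeric(pr),
    profit_per_facility = attr(pr, "per_facility"),
    accessibility = field
  ), class = "objective_vector")
}

#' @export
print.objective_vector <- function(x, ...) {
  cat(sprintf("objectives: equity %.4f | efficiency %s | travel %.0f m.persons (%.1f m/person) | profit %.0f /facility/month\n",
              x$equity,
              if (is.na(x$efficiency)) "n/a" else sprintf("%.4f", x$efficiency),
              x$travel_cost, x$travel_cost_per_capita, x$profit))
  invisible(x)
}

# Objective senses: equity and travel cost are minimized, efficiency and
# profit maximized. Order is fixed throughout the package.
.obj_names <- c("equity", "efficiency", "travel_cost", "profit")
.obj_sense <- c(equity = "min", efficiency = "max",
                travel_cost = "min", profit = "max")

#' Standardize raw objective values over a reference population
#'
#' Maps each objective linearly to \[0, 1\] over the given population so that
#' smaller is better for every column: minimization objectives use
#' `(x - min)/(max - min)`, maximization objectives use
#' `(max - x)/(max - min)`. A degenerate column (max = min, or all `NA` as
#' for the efficiency objective without a baseline) maps to 0.5 everywhere.
#'
#' @param objectives numeric matrix (one row per solution) with columns
#'   `equity`, `efficiency`, `travel_cost`, `profit`, or a list of
#'   [objective_vector] objects.
#' @return matrix of standardized values, same shape, all in \[0, 1\].
#' @examples
#' standardize_objectives(cbind(equity = c(0, 5, 10), efficiency = 1,
#'                              travel_cost = 2, profit = 3))[, "equity"]
#' @export
standardize_objectives <- function(objectives) {
  M <- .as_objective_matrix(objectives)
  if (nrow(M) < 1) stop("need at least one objective vector")
  out <- M
  for (l in seq_along(.obj_names)) {
    x <- M[, l]
    if (all(is.na(x))) { out[, l] <- 0.5; next }
    lo <- min(x); hi <- max(x)
    if (hi - lo <= 0) { out[, l] <- 0.5; next }
    out[, l] <- if (.obj_sense[l] == "min") (x - lo) / (hi - lo)
                else (hi - x) / (hi - lo)
  }
  out
}

.as_objective_matrix <- function(objectives) {
  if (is.list(objectives) && !is.data.frame(objectives) &&
      !is.matrix(objectives)) {
    M <- t(vapply(objectives, function(o)
      c(o$equity, o$efficiency, o$travel_cost, o$profit), numeric(4)))
  } else {
    M <- as.matrix(objectives)
  }
  colnames(M) <- .obj_names
  M
}

#' Scalarize standardized objectives with an adaptive constraint penalty
#'
#' The comprehensive objective is `F(x) = f(x) r(x)` with
#' `f(x) = sum_l lambda_l f'_l(x)` the weighted standardized objectives and
#' `r(x) = 1 + (1/G) sum_g (db_g / db_g,max)^eta` an adaptive penalty over
#' the G = 4 constraint families; `db_g,max` is the largest violation of
#' family g in the reference population (floored at 1 so feasible populations
#' divide cleanly). Feasible solutions have `r = 1`. Affinity, the quantity
#' the immune algorithm maximizes, is `A(k) = 1/F(x)`; `f` is floored at a
#' small positive `eps_f` so affinity stays finite.
#'
#' @param standardized numeric length-4 vector of standardized objectives
#'   (see [standardize_objectives()]).
#' @param weights objective weights, non-negative, summing to 1. When the
#'   efficiency objective is unavailable (`NA` standardized entry is not
#'   produced; it is 0.5) callers typically renormalize over the remaining
#'   objectives via [objective_weights()].
#' @param violations an `rcf_violations` report (or `NULL` for feasible).
#' @param eta penalty exponent (default 2).
#' @param eps_f positive floor for `f` (default 1e-6).
#' @param violation_max per-family maxima over the reference population
#'   (named or ordered count/coverage/linkage/capacity); floored at 1.
#' @return object of class `comprehensive_score`: list `f`, `r`, `F`,
#'   `affinity`.
#' @examples
#' comprehensive_objective(c(0.2, 0.4, 0.6, 0.8))$affinity # 2
#' @export
comprehensive_objective <- function(standardized, weights = rep(0.25, 4),
                                    violations = NULL, eta = 2,
                                    eps_f = 1e-6, violation_max = NULL) {
  if (length(standardized) != 4) stop("standardized must have length 4")
  if (length(weights) != 4 || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8)
    stop("weights must be non-negative and sum to 1")
  f <- max(sum(weights * standardized), eps_f)
  if (is.null(violations)) {
    r <- 1
  } else {
    v <- c(violations$count, violations$coverage, violations$linkage,
           violations$capacity)
    vmax <- if (is.null(violation_max)) pmax(v, 1) else pmax(violation_max, 1)
    r <- 1 + mean((v / vmax)^eta)
  }
  Fx <- f * r
  structure(list(f = f, r = r, F = Fx, affinity = 1 / Fx),
            class = "comprehensive_score")
}

#' @export
print.comprehensive_score <- function(x, ...) {
  cat(sprintf("comprehensive score: f = %.6f, penalty r = %.4f, F = %.6f, affinity = %.4f\n",
              x$f, x$r, x$F, x$affinity))
  invisible(x)
}

#' Objective weights, with optional renormalization and adaptive mode
#'
#' Equal weights (0.25 each) are the reproducible default. The adaptive mode
#' weighs each objective inversely to its raw range in the current reference
#' population, `lambda_l` proportional to `1/(range_l + delta)`, renormalized;
#' objectives whose range has collapsed then stop dominating the scalar sum.
#' When no baseline accessibility exists the efficiency objective is dropped
#' and its weight redistributed over the remaining three.
#'
#' @param mode `"equal"` or `"adaptive"`.
#' @param objectives raw objective matrix of the reference population
#'   (required for `"adaptive"`).
#' @param delta small positive stabilizer for the adaptive mode.
#' @param has_baseline whether the efficiency objective is defined.
#' @return numeric length-4 weight vector summing to 1 (efficiency weight 0
#'   when no baseline).
#' @export
objective_weights <- function(mode = c("equal", "adaptive"),
                              objectives = NULL, delta = 1e-9,
                              has_baseline = TRUE) {
  mode <- match.arg(mode)
  if (mode == "equal") {
    w <- rep(0.25, 4)
  } else {
    if (is.null(objectives)) stop("adaptive weights need a reference population")
    M <- .as_objective_matrix(objectives)
    rng <- apply(M, 2, function(x) {
      x <- x[!is.na(x)]
      if (length(x) == 0) return(NA_real_)
      diff(range(x))
    })
    w <- 1 / (rng + delta)
    w[is.na(w)] <- 0
  }
  if (!has_baseline) w[2] <- 0
  if (sum(w) <= 0) w <- c(1, 0, 1, 1) / 3
  w / sum(w)
}
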