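#' Assess the rationality of an existing facility configuration
#'
#' Quantifies the three rationality dimensions of a current configuration:
#' quantity (beds available per 100 elderly within the effective service
#' radius, against the planning target), scale (per-facility gap between the
#' care demand allocated to a facility and its beds), and location (distance
#' from each facility to the nearest model-optimal site, when optimal sites
#' are supplied).
#'
#' @param instance an [rcf_instance][build_instance].
#' @param existing the current [rcf_config][facility_configuration].
#' @param target_rate planning bed rate (default 0.025 beds per elderly).
#' @param radius effective service radius in meters (default 3000, a 1-hour
#'   walking-scale distance for the synthetic districts).
#' @param beta decay exponent for assessing existing configurations
#'   (default 1.8, the value that matches observed travel behavior).
#' @param optimal_sites optional integer site indices of a model-optimal
#'   configuration (e.g. from [mia()]) for the location assessment.
#' @return object of class `rcf_assessment`.
#' @export
assess_current <- function(instance, existing, target_rate = 0.025,
                           radius = 3000, beta = 1.8, optimal_sites = NULL) {
  # gravity accessibility is beds per person of demand; the planning target
  # is per 100 elderly, so convert with each center's demand rate
  bp100 <- beds_per_100_within_radius(instance, existing, radius,
                                      beta = beta) *
    instance$centers$demand / instance$centers$elderly
  target_per_100 <- 100 * target_rate
  open <- existing$open
  Z <- allocate_nearest(instance, open)
  assigned <- as.numeric(crossprod(Z, instance$centers$demand))
  gap <- assigned[open] - existing$beds[open]   # >0 undersupplied
  target_beds <- target_rate * sum(instance$centers$elderly)
  dist_opt <- if (is.null(optimal_sites)) rep(NA_real_, length(open)) else
    vapply(open, function(j)
      min(sqrt((instance$sites$x[optimal_sites] - instance$sites$x[j])^2 +
               (instance$sites$y[optimal_sites] - instance$sites$y[j])^2)),
      numeric(1))
  structure(list(
    beds_per_100 = bp100,
    share_below_target = mean(bp100 < target_per_100),
    target_per_100 = target_per_100,
    facility = data.frame(site = open, beds = existing$beds[open],
                          assigned_demand = assigned[open], gap = gap,
                          dist_to_optimal = dist_opt),
    target_beds = target_beds,
    existing_beds = existing$total_beds,
    bed_deficit = max(0, target_beds - existing$total_beds),
    radius = radius, beta = beta
  ), class = "rcf_assessment")
}

#' @export
print.rcf_assessment <- function(x, ...) {
  cat("Rationality assessment of the existing configuration\n")
  cat(sprintf("  quantity: %.0f%% of centers below the target of %.1f beds/100 elderly (radius %g m)\n",
              100 * x$share_below_target, x$target_per_100, x$radius))
  cat(sprintf("  beds: %g existing vs %g targeted -> deficit %g\n",
              x$existing_beds, x$target_beds, x$bed_deficit))
  cat(sprintf("  scale: %d facilities undersupplied, %d oversupplied (demand vs beds)\n",
              sum(x$facility$gap > 0), sum(x$facility$gap < 0)))
  if (!all(is.na(x$facility$dist_to_optimal)))
    cat(sprintf("  location: facility distance to nearest optimal site %0.f-%0.f m\n",
                min(x$facility$dist_to_optimal), max(x$facility$dist_to_optimal)))
  invisible(x)
}

#' Flag existing facilities with unreasonable locations
#'
#' Optimizes a same-count configuration with [mia()] and flags every existing
#' facility that is (a) farther than `distance_tolerance` from all optimal
#' sites and (b) redundant: closing it would move none of its allocated
#' centers more than `distance_tolerance` farther from service (another open
#' facility is essentially as close).
#'
#' @param instance an [rcf_instance][build_instance].
#' @param existing the current [rcf_config][facility_configuration].
#' @param params an [mia_params] for the optimization run; `p` is forced to
#'   the number of existing facilities.
#' @param distance_tolerance meters (default 500).
#' @return list with `flagged` (site indices), `fit` (the [mia] fit), and
#'   `detail` (per-facility distances and redundancy).
#' @export
identify_unreasonable <- function(instance, existing, params,
                                  distance_tolerance = 500) {
  open <- existing$open
  params$p <- length(open)
  fit <- mia(instance, params)
  opt <- fit$configuration$open
  d_opt <- vapply(open, function(j)
    min(sqrt((instance$sites$x[opt] - instance$sites$x[j])^2 +
             (instance$sites$y[opt] - instance$sites$y[j])^2)), numeric(1))
  assigned <- .nearest_assign(instance$distances, open)
  redundant <- vapply(seq_along(open), function(k) {
    j <- open[k]
    mine <- which(assigned == j)
    if (length(mine) == 0) return(TRUE)
    others <- setdiff(open, j)
    if (length(others) == 0) return(FALSE)
    d_other <- apply(instance$distances[mine, others, drop = FALSE], 1, min)
    max(d_other - instance$distances[mine, j]) <= distance_tolerance
  }, logical(1))
  far <- d_opt > distance_tolerance
  structure(list(flagged = open[far & redundant], fit = fit,
                 detail = data.frame(site = open, dist_to_optimal = d_opt,
                                     far = far, redundant = redundant)),
            class = "rcf_flags")
}

#' @export
print.rcf_flags <- function(x, ...) {
  cat(sprintf("%d facility(ies) flagged as unreasonably located: %s\n",
              length(x$flagged),
              if (length(x$flagged)) paste(x$flagged, collapse = ", ") else "none"))
  invisible(x)
}

#' Adjust retained facilities' bed counts within capacity
#'
#' Allocates every center to its nearest retained facility and sets each
#' facility's beds to the allocated demand capped at its capacity bound. The
#' overflow at a capped facility is peeled from its farthest-allocated
#' centers (the boundary center may be left partially unmet), yielding the
#' per-center unmet demand the new facilities must serve.
#'
#' @param instance an [rcf_instance][build_instance].
#' @param retained_open integer indices of the retained facilities.
#' @param cap optional scalar capacity override; defaults to each site's
#'   `max_beds`.
#' @return list with `beds` (length-J vector), `unmet` (per-center unmet
#'   demand), `unmet_total`, `served_allocation` (fractional I x J matrix of
#'   the served demand shares), and `retained_open`.
#' @export
adjust_scales <- function(instance, retained_open, cap = NULL) {
  open <- sort(unique(as.integer(retained_open)))
  if (length(open) == 0) stop("retained facilities must be nonempty")
  capv <- if (is.null(cap)) instance$sites$max_beds else
    rep(cap, length.out = instance$J)
  w <- instance$centers$demand
  assigned <- .nearest_assign(instance$distances, open)
  unmet <- numeric(instance$I)
  beds <- numeric(instance$J)
  Z <- matrix(0, instance$I, instance$J)
  for (j in open) {
    mine <- which(assigned == j)
    if (length(mine) == 0) next
    load <- sum(w[mine])
    over <- max(0, load - capv[j])
    beds[j] <- load - over
    if (over > 0) {
      far <- mine[order(instance$distances[mine, j], decreasing = TRUE)]
      for (i in far) {
        if (over <= 0) break
        peel <- min(over, w[i])
        unmet[i] <- unmet[i] + peel
        over <- over - peel
      }
    }
    Z[mine, j] <- (w[mine] - unmet[mine]) / w[mine]
  }
  list(beds = beds, unmet = unmet, unmet_total = sum(unmet),
       served_allocation = Z, retained_open = open)
}

#' Minimum number of new facilities for a given unmet demand
#'
#' @param unmet_demand total unmet demand (persons).
#' @param cap beds per new facility bound (> 0).
#' @return `ceiling(unmet_demand / cap)`.
#' @examples
#' min_new_facilities(1193, 300) # 4
#' @export
min_new_facilities <- function(unmet_demand, cap = 300) {
  if (cap <= 0) stop("cap must be positive")
  as.integer(ceiling(max(0, unmet_demand) / cap))
}

#' Restrict an instance to its unmet demand (the residual siting problem)
#'
#' Keeps only centers with unmet demand (their demand becomes the unmet
#' amount) and removes occupied candidate sites, producing the instance on
#' which new facilities are sited. Index maps back to the full instance are
#' returned alongside.
#'
#' @param instance the full [rcf_instance][build_instance].
#' @param unmet per-center unmet demand (length I).
#' @param exclude_sites site indices unavailable to new facilities.
#' @return list with `instance`, `center_idx`, `site_idx`.
#' @export
residual_instance <- function(instance, unmet, exclude_sites = integer()) {
  ci <- which(unmet > 0)
  if (length(ci) == 0) stop("no unmet demand")
  si <- setdiff(seq_len(instance$J), exclude_sites)
  centers <- instance$centers[ci, , drop = FALSE]
  centers$demand <- unmet[ci]
  centers$elderly <- pmax(centers$elderly, centers$demand)
  inst <- build_instance(centers, instance$sites[si, , drop = FALSE],
                         instance$distances[ci, si, drop = FALSE],
                         beta = instance$beta, costs = instance$costs)
  list(instance = inst, center_idx = ci, site_idx = si)
}

#' Sweep the number of new facilities and pick the best count
#'
#' Runs the optimizer for each candidate facility count on the residual
#' problem, then re-scores the per-count best configurations in one shared
#' context so their comprehensive values are comparable; the count with the
#' lowest value wins (infeasible counts are excluded when any feasible one
#' exists).
#'
#' @param residual result of [residual_instance()] or a bare
#'   [rcf_instance][build_instance].
#' @param p_range integer vector of facility counts to try.
#' @param params an [mia_params] template; `p` and `seed` are set per run
#'   (seed offset by p so runs are independent but reproducible).
#' @return object of class `rcf_sweep`: `table` (p, F, feasible), `p_star`,
#'   and `fits` (one [mia] fit per count).
#' @export
sweep_new_count <- function(residual, p_range, params) {
  inst <- if (inherits(residual, "rcf_instance")) residual else residual$instance
  p_range <- sort(unique(as.integer(p_range)))
  if (length(p_range) == 0) stop("empty p range")
  if (max(p_range) > inst$J) stop("p exceeds available candidate sites")
  fits <- lapply(p_range, function(p) {
    pr <- params; pr$p <- as.integer(p); pr$seed <- params$seed + p
    mia(inst, pr)
  })
  raw <- t(vapply(fits, function(f) {
    o <- f$objectives
    c(o$equity, o$efficiency, o$travel_cost, o$profit)
  }, numeric(4)))
  colnames(raw) <- .obj_names
  capv <- vapply(fits, function(f) {
    v <- check_constraints(inst, f$configuration)
    v$capacity + v$count + v$coverage + v$linkage
  }, numeric(1))
  std <- standardize_objectives(raw)
  wts <- objective_weights(params$weights_mode, objectives = raw,
                           has_baseline = !is.null(inst$baseline_accessibility))
  f <- pmax(as.numeric(std %*% wts), params$eps_f)
  r <- 1 + ((capv / max(capv, 1))^params$eta) / 4
  Fv <- f * r
  feas <- capv == 0
  pool <- if (any(feas)) which(feas) else seq_along(p_range)
  p_star <- p_range[pool[which.min(Fv[pool])]]
  structure(list(table = data.frame(p = p_range, F = Fv, feasible = feas),
                 p_star = p_star, fits = fits),
            class = "rcf_sweep")
}

#' @export
print.rcf_sweep <- function(x, ...) {
  cat("facility-count sweep (comprehensive objective per count):\n")
  print(x$table, row.names = FALSE)
  cat("chosen count p* =", x$p_star, "\n")
  invisible(x)
}

#' Pick the facility count with the lowest objective value
#'
#' The argmin step of the count sweep, usable directly on an externally
#' supplied table of counts and objective values.
#'
#' @param p integer counts.
#' @param F objective values (lower is better).
#' @return the count with minimal value (ties to the smaller count).
#' @examples
#' select_new_count(4:14, c(0.6722, 0.6323, 0.6012, 0.6283, 0.6501, 0.6766,
#'                          0.7149, 0.7364, 0.7626, 0.7943, 0.8243)) # 6
#' @export
select_new_count <- function(p, F) {
  o <- order(p)
  p[o][which.min(F[o])]
}

#' Size the newly added facilities' beds to their catchment demand
#'
#' @param residual result of [residual_instance()].
#' @param chosen_sites site indices *within the residual instance*.
#' @return data.frame with `site` (full-instance index), `beds`; errors if a
#'   new facility would exceed its capacity bound.
#' @export
finalize_new_beds <- function(residual, chosen_sites) {
  inst <- residual$instance
  conf <- size_beds_to_demand(inst, chosen_sites)
  beds <- conf$beds[conf$open]
  cap <- inst$sites$max_beds[conf$open]
  if (any(beds > cap))
    stop("capacity violated at new site(s) ",
         paste(residual$site_idx[conf$open][beds > cap], collapse = ", "))
  data.frame(site = residual$site_idx[conf$open], beds = beds)
}

#' Demand-weighted Gini coefficient
#'
#' Inequality of per-capita service (here: accessibility) across population
#' centers, via the Lorenz-curve trapezoid formula with population weights.
#' 0 means every person enjoys the same accessibility; values near 1 mean
#' resources are concentrated on a few.
#'
#' @param values non-negative per-center values (e.g. accessibility), not all
#'   zero.
#' @param weights positive population weights (e.g. care demand).
#' @return Gini coefficient in \[0, 1).
#' @examples
#' gini_coefficient(c(0, 1), c(1, 1)) # 0.5
#' @export
gini_coefficient <- function(values, weights = rep(1, length(values))) {
  if (any(values < 0)) stop("values must be non-negative")
  if (any(weights <= 0)) stop("weights must be positive")
  if (all(values == 0)) stop("values must not all be zero")
  o <- order(values)
  v <- values[o]; w <- weights[o]
  pc <- cumsum(w) / sum(w)
  lc <- cumsum(w * v) / sum(w * v)
  1 - sum(diff(c(0, pc)) * (lc + c(0, lc[-length(lc)])))
}

#' Before/after evaluation of an optimization scheme
#'
#' Computes, for the current and the optimized configuration, the equity
#' value, the demand-weighted Gini coefficient of accessibility, per-capita
#' travel cost, mean facility profit, max and mean distance to the nearest
#' open facility, mean within-radius beds per person, the share of centers
#' whose accessibility-to-mean ratio lies in \[0.9, 1.1\], and the efficiency
#' (mean relative accessibility change, percent). Relative changes are plain
#' relative differences: `(before - after)/before` for minimized metrics and
#' `(after - before)/before` for maximized ones, in percent.
#'
#' @param instance an [rcf_instance][build_instance].
#' @param before,after two [rcf_config][facility_configuration]s.
#' @param radius service radius for the within-radius metric (m).
#' @param beta_before,beta_after decay exponents for the two configurations.
#'   The exponent is re-determined per configuration: an existing
#'   configuration is assessed at the behaviorally calibrated 1.8, while an
#'   optimized configuration (whose facility layout differs greatly) is
#'   evaluated at the equity-optimal 1.
#' @return object of class `rcf_evaluation` with a `table` data.frame.
#' @export
evaluation_report <- function(instance, before, after, radius = 3000,
                              beta_before = 1.8, beta_after = 1) {
  w <- instance$centers$demand
  fb <- gravity_accessibility(instance, before, beta = beta_before)
  fa <- gravity_accessibility(instance, after, beta = beta_after)
  one <- function(conf, field, beta) {
    d_near <- apply(instance$distances[, conf$open, drop = FALSE], 1, min)
    # the model supposes each center is served by its nearest open facility,
    # so travel is evaluated on that basis for both configurations
    c(equity = equity_objective(field),
      gini = gini_coefficient(field$values, w),
      travel_per_capita = sum(w * d_near) / sum(w),
      profit = as.numeric(profit_objective(instance, conf)),
      max_nearest = max(d_near),
      mean_nearest = mean(d_near),
      beds_within_radius = mean(beds_per_100_within_radius(
        instance, conf, radius, beta = beta)) / 100,
      ratio_share = mean(field$values / field$weighted_mean >= 0.9 &
                         field$values / field$weighted_mean <= 1.1))
  }
  b <- one(before, fb, beta_before); a <- one(after, fa, beta_after)
  lower_better <- c(equity = TRUE, gini = TRUE, travel_per_capita = TRUE,
                    profit = FALSE, max_nearest = TRUE, mean_nearest = TRUE,
                    beds_within_radius = FALSE, ratio_share = FALSE)
  change <- ifelse(b == a, 0,
                   ifelse(lower_better, (b - a) / b, (a - b) / b)) * 100
  structure(list(
    table = data.frame(metric = names(b), before = as.numeric(b),
                       after = as.numeric(a), change_pct = as.numeric(change)),
    efficiency_pct = 100 * mean((fa$values - fb$values) / fb$values),
    radius = radius, beta_before = beta_before, beta_after = beta_after
  ), class = "rcf_evaluation")
}

#' @export
print.rcf_evaluation <- function(x, ...) {
  cat("Evaluation of the optimization scheme (before vs after)\n")
  tab <- x$table
  tab$before <- signif(tab$before, 6); tab$after <- signif(tab$after, 6)
  tab$change_pct <- round(tab$change_pct, 2)
  print(tab, row.names = FALSE)
  cat(sprintf("efficiency (mean relative accessibility change): %.2f%%\n",
              x$efficiency_pct))
  invisible(x)
}

#' Relative difference in percent
#'
#' `(reference - value) / reference * 100`: how much smaller `value` is than
#' `reference`, the convention used when comparing algorithms' objective
#' values and iteration counts.
#'
#' @param reference the comparison baseline.
#' @param value the (usually smaller) value.
#' @export
relative_difference_pct <- function(reference, value) {
  (reference - value) / reference * 100
}

#' Three-step planning workflow: relocate, resize, extend
#'
#' The applied pipeline on a district: (1) flag existing facilities with
#' unreasonable locations (redundant and far from model-optimal sites) and
#' adjust the remaining facilities' beds within capacity, which exposes the
#' unmet demand; (2) sweep the number of new facilities from the minimum
#' feasible count upward, optimizing new sites on the residual problem, and
#' keep the count with the best comprehensive objective; (3) size each new
#' facility to the demand of its catchment. The returned final configuration
#' combines retained (resized) and new facilities and serves all demand.
#'
#' @param instance an [rcf_instance][build_instance].
#' @param existing the current [rcf_config][facility_configuration].
#' @param params an [mia_params] template used for both optimization stages
#'   (`p` is set internally).
#' @param distance_tolerance meters, for the relocation flagging.
#' @param p_extra how many counts beyond the minimum to sweep.
#' @param cap optional capacity override for the bed adjustment.
#' @return object of class `rcf_plan`.
#' @export
plan_configuration <- function(instance, existing, params,
                               distance_tolerance = 500, p_extra = 4,
                               cap = NULL) {
  flags <- identify_unreasonable(instance, existing, params,
                                 distance_tolerance)
  retained <- setdiff(existing$open, flags$flagged)
  if (length(retained) == 0) retained <- existing$open
  adj <- adjust_scales(instance, retained, cap = cap)
  # a retained facility whose catchment emptied out serves nobody: close it
  if (any(adj$beds[adj$retained_open] <= 0)) {
    retained <- adj$retained_open[adj$beds[adj$retained_open] > 0]
    adj <- adjust_scales(instance, retained, cap = cap)
  }

  if (adj$unmet_total > 0) {
    res <- residual_instance(instance, adj$unmet,
                             exclude_sites = existing$open)
    cap_min <- min(res$instance$sites$max_beds)
    p_min <- max(1, min_new_facilities(adj$unmet_total, cap_min))
    p_hi <- min(p_min + p_extra, res$instance$J)
    sweep <- sweep_new_count(res, p_min:p_hi, params)
    best_fit <- sweep$fits[[match(sweep$p_star, sweep$table$p)]]
    new_beds <- finalize_new_beds(res, best_fit$configuration$open)
    # combine retained + new into one (possibly fractional) configuration
    open <- sort(c(adj$retained_open, new_beds$site))
    beds <- adj$beds
    beds[new_beds$site] <- new_beds$beds
    Z <- adj$served_allocation
    res_Z <- best_fit$configuration$allocation   # binary, residual indices
    frac <- adj$unmet / instance$centers$demand
    Z[res$center_idx, res$site_idx] <- Z[res$center_idx, res$site_idx] +
      res_Z * frac[res$center_idx]
    config <- facility_configuration(open, beds, Z)
  } else {
    sweep <- NULL; new_beds <- NULL
    config <- facility_configuration(
      adj$retained_open, adj$beds, adj$served_allocation)
  }

  structure(list(
    flagged = flags$flagged, flag_detail = flags$detail,
    retained = adj$retained_open, adjusted_beds = adj$beds,
    unmet_total = adj$unmet_total,
    p_star = if (is.null(sweep)) 0L else sweep$p_star,
    sweep = sweep, new_facilities = new_beds,
    configuration = config,
    feasible = check_constraints(instance, config)$feasible
  ), class = "rcf_plan")
}

#' @export
print.rcf_plan <- function(x, ...) {
  cat("Three-step configuration plan\n")
  cat(sprintf("  step 1: %d facility(ies) relocated away, %d retained and resized; unmet demand %g\n",
              length(x$flagged), length(x$retained), x$unmet_total))
  if (!is.null(x$sweep)) {
    cat(sprintf("  step 2: %d new facility(ies) at sites %s\n", x$p_star,
                paste(x$new_facilities$site, collapse = ", ")))
    cat(sprintf("  step 3: new beds %s (total %g)\n",
                paste(x$new_facilities$beds, collapse = ", "),
                sum(x$new_facilities$beds)))
  } else cat("  steps 2-3: no unmet demand, no new facilities needed\n")
  cat(sprintf("  final configuration: %d facilities, %g beds, %s\n",
              length(x$configuration$open), x$configuration$total_beds,
              if (x$feasible) "feasible" else "INFEASIBLE"))
  invisible(x)
}
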