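#' Build a problem instance for RCF configuration optimization
#'
#' Assembles and validates the complete immutable input of the facility
#' configuration problem: population centers carrying care demand, candidate
#' facility sites with bed-capacity bounds, an origin-destination travel
#' distance matrix, the distance-decay exponent of the gravity accessibility
#' model, and bed charge/cost parameters.
#'
#' @param centers data.frame with columns `id`, `x`, `y` (planar coordinates,
#'   meters), `elderly` (residents aged 60+) and `demand` (count `w_i` of
#'   elderly needing residential care).
#' @param sites data.frame with columns `id`, `x`, `y` and `max_beds`
#'   (capacity bound per site; default district class is 300 beds).
#' @param distances numeric I x J matrix of travel distances in meters,
#'   strictly positive (co-located pairs must be clamped upstream, see
#'   [clamp_distances()]).
#' @param beta distance-decay exponent (> 0). 1 is the usual choice when
#'   optimizing; 1.8 when assessing an existing configuration.
#' @param costs list with `charge` (c0, currency/bed/month) and `cost`
#'   (c1); requires `charge > cost > 0`. Defaults to the surveyed downtown
#'   values 2050 and 1250 RMB/bed/month.
#' @param baseline_accessibility optional numeric vector of per-center
#'   accessibility before optimization (`A_oi`), required only for the
#'   efficiency objective; all entries must be positive.
#'
#' @return An object of class `rcf_instance`: the validated inputs plus
#'   `I`, `J` and the total demand `W = sum(w_i)`.
#' @examples
#' inst <- micro_instance()
#' inst$W # 30
#' @export
build_instance <- function(centers, sites, distances, beta = 1,
                           costs = list(charge = 2050, cost = 1250),
                           baseline_accessibility = NULL) {
  centers <- as.data.frame(centers)
  sites <- as.data.frame(sites)
  need_c <- c("id", "x", "y", "elderly", "demand")
  if (!all(need_c %in% names(centers)))
    stop("centers must have columns: ", paste(need_c, collapse = ", "))
  need_s <- c("id", "x", "y", "max_beds")
  if (!all(need_s %in% names(sites)))
    stop("sites must have columns: ", paste(need_s, collapse = ", "))
  distances <- as.matrix(distances)
  I <- nrow(centers); J <- nrow(sites)
  if (I < 1 || J < 1) stop("need at least one center and one site")
  if (!all(dim(distances) == c(I, J)))
    stop("distance matrix must be ", I, " x ", J,
         ", got ", nrow(distances), " x ", ncol(distances))
  if (anyNA(distances) || any(distances <= 0))
    stop("distances must be strictly positive (clamp co-located pairs, see clamp_distances)")
  if (any(centers$elderly < 0)) stop("elderly counts must be >= 0")
  if (any(centers$demand < 0 | centers$demand > centers$elderly))
    stop("demand must satisfy 0 <= demand <= elderly")
  if (any(sites$max_beds <= 0)) stop("max_beds must be > 0")
  if (!is.numeric(beta) || length(beta) != 1 || beta <= 0)
    stop("beta must be a positive scalar")
  if (is.null(costs$charge) || is.null(costs$cost) ||
      !(costs$charge > costs$cost && costs$cost > 0))
    stop("costs must satisfy charge > cost > 0")
  W <- sum(centers$demand)
  if (W <= 0) stop("total demand W must be positive")
  if (!is.null(baseline_accessibility)) {
    if (length(baseline_accessibility) != I)
      stop("baseline_accessibility must have one entry per center")
    if (any(baseline_accessibility <= 0))
      stop("baseline_accessibility entries must be positive")
  }
  structure(list(
    centers = centers, sites = sites, distances = distances,
    beta = beta, costs = costs,
    baseline_accessibility = baseline_accessibility,
    I = I, J = J, W = W
  ), class = "rcf_instance")
}

#' @export
print.rcf_instance <- function(x, ...) {
  cat("RCF problem instance\n")
  cat(sprintf("  %d population centers, total demand W = %g (elderly %g)\n",
              x$I, x$W, sum(x$centers$elderly)))
  cat(sprintf("  %d candidate sites, capacity bounds %g-%g beds\n",
              x$J, min(x$sites$max_beds), max(x$sites$max_beds)))
  cat(sprintf("  beta = %g; charge c0 = %g, cost c1 = %g per bed/month\n",
              x$beta, x$costs$charge, x$costs$cost))
  if (!is.null(x$baseline_accessibility))
    cat("  baseline accessibility present (efficiency objective enabled)\n")
  invisible(x)
}

#' Clamp a distance matrix to a positive floor
#'
#' Distance-decay weights d^(-beta) diverge at zero distance, so co-located
#' center/site pairs are clamped to a small positive floor before an instance
#' is built.
#'
#' @param distances numeric matrix of distances in meters.
#' @param floor minimum allowed distance (meters), default 1.
#' @return the clamped matrix.
#' @export
clamp_distances <- function(distances, floor = 1) {
  if (floor <= 0) stop("floor must be positive")
  pmax(as.matrix(distances), floor)
}

#' Effective travel distance from road distance and intersection dwell times
#'
#' In congested networks dwell time at intersections is a large share of
#' travel time; it is converted to distance at the prevailing road speed and
#' added to the shortest-path road distance, so that a single distance carries
#' the full travel cost.
#'
#' @param shortest_path_distance road network shortest-path distance (m).
#' @param dwell_times numeric vector of dwell times at traversed
#'   intersections (seconds); may be empty.
#' @param travel_speed average road speed (m/s), > 0.
#' @return effective distance in meters:
#'   `shortest_path_distance + travel_speed * sum(dwell_times)`.
#' @examples
#' effective_distance(1000, c(30, 30), 5) # 1300
#' @export
effective_distance <- function(shortest_path_distance, dwell_times = numeric(),
                               travel_speed = 1) {
  if (length(dwell_times) == 0) dwell_times <- numeric()
  if (any(shortest_path_distance < 0) || any(dwell_times < 0))
    stop("distances and dwell times must be non-negative")
  if (travel_speed <= 0) stop("travel_speed must be positive")
  shortest_path_distance + travel_speed * sum(dwell_times)
}

# Internal: index of the nearest open site per center; ties broken by the
# lowest site index. open must be a sorted integer vector of site indices.
.nearest_assign <- function(distances, open) {
  d <- distances[, open, drop = FALSE]
  open[max.col(-d, ties.method = "first")]
}

#' Allocate every population center to its nearest open facility
#'
#' The service rule of the model: each center is served by the closest open
#' site. Ties are broken by the lowest site index so allocation is
#' deterministic.
#'
#' @param instance an [rcf_instance][build_instance].
#' @param open_sites integer vector of open site indices (1-based).
#' @return binary I x J allocation matrix `Z` with one 1 per row.
#' @export
allocate_nearest <- function(instance, open_sites) {
  open_sites <- sort(unique(as.integer(open_sites)))
  if (length(open_sites) == 0) stop("at least one site must be open")
  if (any(open_sites < 1 | open_sites > instance$J))
    stop("open site indices out of range")
  assigned <- .nearest_assign(instance$distances, open_sites)
  Z <- matrix(0, instance$I, instance$J)
  Z[cbind(seq_len(instance$I), assigned)] <- 1
  Z
}

#' Construct a facility configuration
#'
#' A configuration is the decision variable of the model: which candidate
#' sites are open (`Y`), how many beds each holds (`v`), and the
#' center-to-facility allocation (`Z`). `Z` may be fractional (rows summing
#' to 1) when a center's demand is split, as happens at capacity boundaries
#' in the planning workflow; optimizer-produced configurations are binary.
#'
#' @param open integer vector of open site indices.
#' @param beds numeric vector of beds per site (length J); must be zero at
#'   closed sites.
#' @param allocation numeric I x J matrix with non-negative entries.
#' @param p intended facility count; stored and validated against
#'   `length(open)` by [check_constraints()], defaults to `length(open)`.
#' @return object of class `rcf_config` with derived `total_beds`.
#' @export
facility_configuration <- function(open, beds, allocation, p = length(open)) {
  open <- sort(unique(as.integer(open)))
  beds <- as.numeric(beds)
  if (any(beds[-open] != 0) && length(beds) > length(open))
    stop("beds must be zero at closed sites")
  if (any(beds < 0)) stop("beds must be non-negative")
  allocation <- as.matrix(allocation)
  if (ncol(allocation) != length(beds))
    stop("allocation columns must match beds length")
  structure(list(
    open = open, beds = beds, allocation = allocation,
    p = as.integer(p), total_beds = sum(beds[open])
  ), class = "rcf_config")
}

#' @export
print.rcf_config <- function(x, ...) {
  cat(sprintf("RCF configuration: %d open sites (p = %d), %g beds total\n",
              length(x$open), x$p, x$total_beds))
  cat("  open sites:", paste(utils::head(x$open, 15), collapse = ", "),
      if (length(x$open) > 15) "..." else "", "\n")
  invisible(x)
}

#' Check the model constraints of a configuration
#'
#' Reports per-constraint violation magnitudes for the four constraint
#' families: facility count (`sum(Y) = p`), full coverage (each allocation
#' row sums to 1), linkage (`Z_ij <= Y_j`), and per-site capacity
#' (`0 < v_j <= max_beds_j` at open sites). Never raises on a well-shaped
#' input; magnitudes of zero in every family mean the configuration is
#' feasible.
#'
#' @param instance an [rcf_instance][build_instance].
#' @param configuration an [rcf_config][facility_configuration].
#' @return object of class `rcf_violations`: list with `count`, `coverage`,
#'   `linkage`, `capacity` magnitudes and a `feasible` flag.
#' @examples
#' inst <- micro_instance()
#' conf <- size_beds_to_demand(inst, c(1, 2))
#' check_constraints(inst, conf)$feasible # TRUE
#' @export
check_constraints <- function(instance, configuration) {
  cf <- configuration
  if (nrow(cf$allocation) != instance$I || ncol(cf$allocation) != instance$J)
    stop("configuration dimensions do not match instance")
  Y <- rep(0, instance$J); Y[cf$open] <- 1
  count <- abs(sum(Y) - cf$p)
  coverage <- sum(abs(rowSums(cf$allocation) - 1))
  linkage <- sum(cf$allocation > rep(Y, each = instance$I))
  over <- pmax(0, cf$beds[cf$open] - instance$sites$max_beds[cf$open])
  capacity <- sum(over) + sum(cf$beds[cf$open] <= 0)
  structure(list(count = count, coverage = coverage, linkage = linkage,
                 capacity = capacity,
                 feasible = (count == 0 && coverage < 1e-9 &&
                             linkage == 0 && capacity == 0)),
            class = "rcf_violations")
}

#' @export
print.rcf_violations <- function(x, ...) {
  cat(sprintf(
    "constraint violations: count %g | coverage %g | linkage %g | capacity %g -> %s\n",
    x$count, x$coverage, x$linkage, x$capacity,
    if (x$feasible) "feasible" else "INFEASIBLE"))
  invisible(x)
}

#' Size facility beds to the demand of their nearest-allocation catchments
#'
#' Opens the given sites, allocates every center to its nearest open site,
#' and sets each facility's beds to the total care demand allocated to it.
#' By construction total beds equal total demand W.
#'
#' @inheritParams allocate_nearest
#' @return an [rcf_config][facility_configuration].
#' @export
size_beds_to_demand <- function(instance, open_sites) {
  open_sites <- sort(unique(as.integer(open_sites)))
  Z <- allocate_nearest(instance, open_sites)
  beds <- as.numeric(crossprod(Z, instance$centers$demand))
  facility_configuration(open_sites, beds, Z)
}
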