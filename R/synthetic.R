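#' Specification of a synthetic district scenario
#'
#' Describes a seeded synthetic urban district on which the whole pipeline
#' can run without external data: clustered population centers with lognormal
#' elderly counts, a fixed care-demand rate, candidate sites scattered with
#' density proportional to population, and a deliberately imbalanced
#' "current" facility configuration (a fraction of facilities mislocated in
#' low-demand corners, beds drawn to create over- and undersupply).
#'
#' The defaults are a desk-scale reduction of a dense downtown district:
#' 60 population centers averaging about 1200 elderly each (so per-center
#' care demand at the 2.5% planning rate is around 30, matching the demand
#' density of a real central district), 120 candidate sites, 12 existing
#' facilities, a 300-bed downtown capacity class, and a 6 x 6 km extent.
#'
#' @param seed integer seed; the scenario is fully reproducible from it.
#' @param I number of population centers.
#' @param J number of candidate sites (>= I typical; must be >= n_existing).
#' @param n_existing number of existing facilities.
#' @param extent square district side length (meters).
#' @param n_clusters number of population clusters.
#' @param cluster_spread within-cluster standard deviation (meters).
#' @param elderly_meanlog,elderly_sdlog lognormal parameters of per-center
#'   elderly counts.
#' @param demand_rate fraction of the elderly needing residential care
#'   (default 0.025, the planning target).
#' @param cap bed-capacity bound applied to every site (downtown class 300).
#' @param distance_mode `"euclidean"` or `"road"` (shortest paths on a random
#'   road graph with intersection dwell conversion).
#' @param mislocated_frac fraction of existing facilities planted in
#'   low-demand corners.
#' @param oversupply,undersupply multiplicative bed imbalance magnitudes:
#'   half of the well-located facilities get beds around
#'   `oversupply x assigned demand`, half around `undersupply x`.
#' @param supply_ratio overall share of the care demand the current
#'   configuration can serve; dense urban districts typically sit well below
#'   the planning target (default 0.7).
#' @param dwell_max maximum intersection dwell time (s, road mode).
#' @param speed_range road speed range (m/s, road mode).
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(seed = 1, I = 60, J = 120, n_existing = 12,
                          extent = 6000, n_clusters = 5,
                          cluster_spread = 500,
                          elderly_meanlog = 7, elderly_sdlog = 0.5,
                          demand_rate = 0.025, cap = 300,
                          distance_mode = c("euclidean", "road"),
                          mislocated_frac = 0.15,
                          oversupply = 2.5, undersupply = 0.15,
                          supply_ratio = 0.7,
                          dwell_max = 60, speed_range = c(3, 8)) {
  if (I < 1 || J < 1) stop("I and J must be >= 1")
  if (n_existing > J) stop("more existing facilities than candidate sites")
  if (demand_rate <= 0 || demand_rate > 1) stop("demand_rate must be in (0, 1]")
  if (extent <= 0) stop("extent must be positive")
  structure(list(seed = as.integer(seed), I = as.integer(I), J = as.integer(J),
                 n_existing = as.integer(n_existing), extent = extent,
                 n_clusters = n_clusters, cluster_spread = cluster_spread,
                 elderly_meanlog = elderly_meanlog,
                 elderly_sdlog = elderly_sdlog,
                 demand_rate = demand_rate, cap = cap,
                 distance_mode = match.arg(distance_mode),
                 mislocated_frac = mislocated_frac,
                 oversupply = oversupply, undersupply = undersupply,
                 supply_ratio = supply_ratio,
                 dwell_max = dwell_max, speed_range = speed_range),
            class = "scenario_spec")
}

#' Generate a synthetic district scenario
#'
#' @param spec a [scenario_spec].
#' @return list with `instance` (an [rcf_instance][build_instance] whose
#'   baseline accessibility is the existing configuration's field),
#'   `existing` (the planted current [rcf_config][facility_configuration]),
#'   and `spec`.
#' @examples
#' sc <- generate_scenario(scenario_spec(seed = 3, I = 20, J = 30,
#'                                       n_existing = 4))
#' sc$instance
#' @export
generate_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  .with_seed(spec$seed, .generate_scenario_impl(spec))
}

.generate_scenario_impl <- function(spec) {
  ext <- spec$extent
  # clustered population centers
  cl_xy <- matrix(stats::runif(spec$n_clusters * 2, 0.15 * ext, 0.85 * ext),
                  ncol = 2)
  cl_of <- sample.int(spec$n_clusters, spec$I, replace = TRUE)
  cx <- pmin(pmax(cl_xy[cl_of, 1] +
                  stats::rnorm(spec$I, 0, spec$cluster_spread), 0), ext)
  cy <- pmin(pmax(cl_xy[cl_of, 2] +
                  stats::rnorm(spec$I, 0, spec$cluster_spread), 0), ext)
  elderly <- pmax(10, round(stats::rlnorm(spec$I, spec$elderly_meanlog,
                                          spec$elderly_sdlog)))
  demand <- pmax(1, round(spec$demand_rate * elderly))
  centers <- data.frame(id = sprintf("C%03d", seq_len(spec$I)),
                        x = cx, y = cy, elderly = elderly, demand = demand)

  # candidate sites: most near population, the rest uniform (incl. corners)
  n_near <- round(0.75 * spec$J)
  near_of <- sample.int(spec$I, n_near, replace = TRUE)
  sx <- c(centers$x[near_of] + stats::rnorm(n_near, 0, 400),
          stats::runif(spec$J - n_near, 0, ext))
  sy <- c(centers$y[near_of] + stats::rnorm(n_near, 0, 400),
          stats::runif(spec$J - n_near, 0, ext))
  sites <- data.frame(id = sprintf("S%03d", seq_len(spec$J)),
                      x = pmin(pmax(sx, 0), ext),
                      y = pmin(pmax(sy, 0), ext),
                      max_beds = spec$cap)

  distances <- switch(spec$distance_mode,
    euclidean = clamp_distances(.euclid_matrix(centers, sites)),
    road = clamp_distances(.road_mode_matrix(centers, sites, spec)))

  # existing facilities: a historically sited (arbitrary, spread-out) subset,
  # plus some planted in low-demand corners (the defect the workflow is
  # meant to find)
  n_bad <- round(spec$mislocated_frac * spec$n_existing)
  n_good <- spec$n_existing - n_bad
  local_demand <- as.numeric(crossprod(distances <= 1000, centers$demand))
  good <- .greedy_spread(sites, sample.int(spec$J), n_good,
                         min_gap = ext / 12)
  bad_pool <- setdiff(order(local_demand), good)
  bad <- utils::head(bad_pool, n_bad)
  open <- sort(c(good, bad))

  Z <- allocate_nearest_from(distances, open)
  assigned <- as.numeric(crossprod(Z, centers$demand))
  factor <- rep(1, spec$J)
  half <- sample(good, floor(n_good / 2))
  factor[half] <- spec$oversupply
  factor[setdiff(good, half)] <- spec$undersupply
  factor[bad] <- spec$oversupply      # corner facilities sit oversized
  beds <- pmax(5, round(assigned * factor))
  beds[-open] <- 0
  # rescale to the stated overall supply ratio, keeping the imbalance pattern
  beds[open] <- pmax(5, round(beds[open] * spec$supply_ratio *
                                sum(demand) / sum(beds[open])))
  existing <- facility_configuration(open, beds, Z)

  inst0 <- build_instance(centers, sites, distances, beta = 1)
  baseline <- gravity_accessibility(inst0, existing)$values
  instance <- build_instance(centers, sites, distances, beta = 1,
                             baseline_accessibility = pmax(baseline, 1e-9))
  list(instance = instance, existing = existing, spec = spec)
}

# Nearest allocation straight from a distance matrix (used before an
# instance object exists).
allocate_nearest_from <- function(distances, open) {
  open <- sort(unique(as.integer(open)))
  assigned <- .nearest_assign(distances, open)
  Z <- matrix(0, nrow(distances), ncol(distances))
  Z[cbind(seq_len(nrow(distances)), assigned)] <- 1
  Z
}

.euclid_matrix <- function(centers, sites) {
  outer(seq_len(nrow(centers)), seq_len(nrow(sites)), function(i, j)
    sqrt((centers$x[i] - sites$x[j])^2 + (centers$y[i] - sites$y[j])^2))
}

# Greedy max-min spread: walk a preference ordering, accepting points at
# least min_gap from everything accepted so far.
.greedy_spread <- function(sites, preference, n, min_gap) {
  chosen <- integer(0)
  for (j in preference) {
    if (length(chosen) == n) break
    if (length(chosen) == 0 ||
        min(sqrt((sites$x[chosen] - sites$x[j])^2 +
                 (sites$y[chosen] - sites$y[j])^2)) >= min_gap)
      chosen <- c(chosen, j)
  }
  # relax the gap if the ordering ran out
  for (j in preference) {
    if (length(chosen) == n) break
    if (!(j %in% chosen)) chosen <- c(chosen, j)
  }
  chosen
}

# Road-mode distances: random connected road graph (k-nearest-neighbour
# links plus spanning-tree completion), per-edge dwell converted to distance
# at the edge speed, shortest paths between snapped nodes.
.road_mode_matrix <- function(centers, sites, spec) {
  n_nodes <- max(40, round((spec$I + spec$J) / 2))
  nx <- stats::runif(n_nodes, 0, spec$extent)
  ny <- stats::runif(n_nodes, 0, spec$extent)
  g <- .random_road_graph(nx, ny, k = 4, spec)
  snap_c <- .snap_to_nodes(centers$x, centers$y, nx, ny)
  snap_s <- .snap_to_nodes(sites$x, sites$y, nx, ny)
  uc <- unique(snap_c); us <- unique(snap_s)
  dn_u <- igraph::distances(g, v = uc, to = us, weights = igraph::E(g)$eff)
  dn <- dn_u[match(snap_c, uc), match(snap_s, us), drop = FALSE]
  # add the off-network approach legs so co-snapped pairs stay distinct
  leg_c <- sqrt((centers$x - nx[snap_c])^2 + (centers$y - ny[snap_c])^2)
  leg_s <- sqrt((sites$x - nx[snap_s])^2 + (sites$y - ny[snap_s])^2)
  dn + outer(leg_c, leg_s, "+")
}

.snap_to_nodes <- function(x, y, nx, ny) {
  vapply(seq_along(x), function(i)
    which.min((nx - x[i])^2 + (ny - y[i])^2), integer(1))
}

.random_road_graph <- function(nx, ny, k, spec) {
  n <- length(nx)
  d <- as.matrix(stats::dist(cbind(nx, ny)))
  edges <- NULL
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k + 1)]
    edges <- rbind(edges, cbind(i, nb))
  }
  edges <- unique(t(apply(edges, 1, sort)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  # connect components through their closest node pair
  comp <- igraph::components(g)
  while (comp$no > 1) {
    a <- which(comp$membership == 1)
    b <- which(comp$membership != 1)
    dd <- d[a, b, drop = FALSE]
    ij <- arrayInd(which.min(dd), dim(dd))
    g <- igraph::add_edges(g, c(a[ij[1]], b[ij[2]]))
    edges <- rbind(edges, c(a[ij[1]], b[ij[2]]))
    comp <- igraph::components(g)
  }
  el <- igraph::as_edgelist(g)
  len <- d[el] * 1.2                       # road wiggle over crow-fly
  speed <- stats::runif(nrow(el), spec$speed_range[1], spec$speed_range[2])
  dwell <- stats::runif(nrow(el), 0, spec$dwell_max)
  igraph::E(g)$eff <- len + speed * dwell  # dwell-to-distance conversion
  g
}

#' The fixed worked-example micro instance
#'
#' Two population centers with care demands 10 and 20, two candidate sites,
#' travel distances `[[1000, 2000], [2000, 1000]]` meters, decay exponent 1,
#' and a bed margin of 800 currency units per month. Small enough that every
#' quantity in the package can be verified by hand; used throughout the
#' documentation and tests.
#'
#' @return an [rcf_instance][build_instance].
#' @export
micro_instance <- function() {
  centers <- data.frame(id = c("C1", "C2"), x = c(0, 3000), y = 0,
                        elderly = c(400, 800), demand = c(10, 20))
  sites <- data.frame(id = c("S1", "S2"), x = c(1000, 2000), y = 0,
                      max_beds = 300)
  d <- matrix(c(1000, 2000, 2000, 1000), 2, 2, byrow = TRUE)
  build_instance(centers, sites, d, beta = 1)
}

#' Exhaustively enumerate the best p-subset of candidate sites
#'
#' Brute-force oracle used to validate the metaheuristics: every `p`-subset
#' of sites is completed to a configuration (nearest allocation, demand-sized
#' beds) and scored in one shared context (standardization and penalty maxima
#' over the full enumeration). Limited to `choose(J, p) <= limit` subsets.
#'
#' @param instance an [rcf_instance][build_instance].
#' @param p number of facilities.
#' @param weights_mode objective weighting mode (see [objective_weights()]).
#' @param eta,eps_f scalarization settings, as in [mia_params()].
#' @param limit maximum number of subsets.
#' @return list with `open` (the feasible F-minimizing subset), `F`, `raw`
#'   (its raw objectives), `feasible`, and `table` (per-subset summary).
#' @export
enumerate_optimum <- function(instance, p, weights_mode = "equal",
                              eta = 2, eps_f = 1e-6, limit = 5000) {
  n_comb <- choose(instance$J, p)
  if (n_comb > limit)
    stop("combinatorics too large: choose(J, p) = ", n_comb, " > ", limit)
  subsets <- utils::combn(instance$J, p, simplify = FALSE)
  evaluator <- .make_evaluator(instance)
  sc <- .score_population(evaluator, subsets, weights_mode = weights_mode,
                          eta = eta, eps_f = eps_f)
  feas <- sc$capacity == 0
  pool <- if (any(feas)) which(feas) else seq_along(subsets)
  best <- pool[which.min(sc$F[pool])]
  list(open = subsets[[best]], F = sc$F[best], raw = sc$raw[best, ],
       feasible = feas[best],
       table = data.frame(F = sc$F, capacity_violation = sc$capacity))
}

#' Small seeded instance together with its exhaustive optimum
#'
#' Convenience wrapper for optimizer validation: generates a small scenario
#' and enumerates the true optimum for the given facility count.
#'
#' @param seed integer seed.
#' @param I,J,p problem size (must keep `choose(J, p) <= limit`).
#' @param limit passed to [enumerate_optimum()].
#' @return list with `instance`, `p`, and `optimum` (see
#'   [enumerate_optimum()]).
#' @export
oracle_instance <- function(seed = 1, I = 12, J = 10, p = 3, limit = 5000) {
  sc <- generate_scenario(scenario_spec(
    seed = seed, I = I, J = J, n_existing = min(3, J),
    extent = 3000, n_clusters = 3, cluster_spread = 400))
  list(instance = sc$instance, p = p,
       optimum = enumerate_optimum(sc$instance, p, limit = limit))
}
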