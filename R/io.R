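#' Write point features to a GeoJSON FeatureCollection
#'
#' @param df data.frame with `x`, `y` columns (planar coordinates) and any
#'   further columns written as feature properties.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_points_geojson <- function(df, path) {
  props <- setdiff(names(df), c("x", "y"))
  features <- lapply(seq_len(nrow(df)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(df$x[i], df$y[i])),
         properties = as.list(df[i, props, drop = FALSE]))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read point features from a GeoJSON FeatureCollection
#'
#' @param path a GeoJSON file of Point features.
#' @param required property names that must be present on every feature.
#' @return data.frame with `x`, `y` and one column per property.
#' @export
read_points_geojson <- function(path, required = character()) {
  if (!file.exists(path)) stop("missing file: ", path)
  fc <- jsonlite::read_json(path)
  if (is.null(fc$type) || fc$type != "FeatureCollection")
    stop("malformed GeoJSON (not a FeatureCollection): ", path)
  rows <- lapply(fc$features, function(f) {
    if (is.null(f$geometry) || f$geometry$type != "Point")
      stop("malformed GeoJSON (non-Point feature): ", path)
    cc <- unlist(f$geometry$coordinates)
    c(list(x = cc[1], y = cc[2]), f$properties)
  })
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("GeoJSON ", path, " lacks required properties: ",
         paste(miss, collapse = ", "))
  df
}

#' Write a distance matrix as CSV
#'
#' First column holds center ids, the header row site ids, values are meters.
#'
#' @param distances I x J matrix.
#' @param center_ids,site_ids row/column identifiers.
#' @param path output file.
#' @export
write_distance_csv <- function(distances, center_ids, site_ids, path) {
  df <- data.frame(center = center_ids, distances, check.names = FALSE)
  names(df) <- c("center", site_ids)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a distance matrix CSV, cross-checking identifiers
#'
#' @param path CSV as written by [write_distance_csv()].
#' @param center_ids,site_ids expected identifiers; an id mismatch is an
#'   error.
#' @return numeric matrix in the order of `center_ids` x `site_ids`.
#' @export
read_distance_csv <- function(path, center_ids, site_ids) {
  if (!file.exists(path)) stop("missing file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  got_sites <- names(df)[-1]
  if (!setequal(got_sites, as.character(site_ids)))
    stop("distance CSV site ids do not match the site file: ", path)
  if (!setequal(df[[1]], as.character(center_ids)))
    stop("distance CSV center ids do not match the center file: ", path)
  m <- as.matrix(df[match(as.character(center_ids), df[[1]]),
                    as.character(site_ids), drop = FALSE])
  storage.mode(m) <- "double"
  unname(m)
}

#' Shortest-path distance matrix from a road network edge list
#'
#' Builds an undirected graph from an edge list with per-edge road length,
#' speed and intersection dwell time; each edge's weight is its effective
#' distance (length plus dwell converted to distance at the edge speed,
#' see [effective_distance()]). Returns shortest-path distances between the
#' given node sets.
#'
#' @param edges data.frame with columns `node_u`, `node_v`, `length_m`,
#'   `speed_m_s`, `dwell_s`.
#' @param center_nodes,site_nodes node identifiers of the origins and
#'   destinations.
#' @return numeric distance matrix (meters).
#' @export
road_distance_matrix <- function(edges, center_nodes, site_nodes) {
  need <- c("node_u", "node_v", "length_m", "speed_m_s", "dwell_s")
  if (!all(need %in% names(edges)))
    stop("edge list must have columns: ", paste(need, collapse = ", "))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$node_u),
               to = as.character(edges$node_v)), directed = FALSE)
  w <- edges$length_m + edges$speed_m_s * edges$dwell_s
  igraph::distances(g, v = as.character(center_nodes),
                    to = as.character(site_nodes), weights = w)
}

#' Write a synthetic scenario to an interchange directory
#'
#' Emits `centers.geojson`, `sites.geojson`, `existing.geojson` (open
#' facilities with beds), and `distances.csv`.
#'
#' @param scenario result of [generate_scenario()].
#' @param dir output directory (created if needed).
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  inst <- scenario$instance
  write_points_geojson(inst$centers, file.path(dir, "centers.geojson"))
  write_points_geojson(inst$sites, file.path(dir, "sites.geojson"))
  ex <- scenario$existing
  fac <- data.frame(id = inst$sites$id[ex$open],
                    x = inst$sites$x[ex$open], y = inst$sites$y[ex$open],
                    beds = ex$beds[ex$open])
  write_points_geojson(fac, file.path(dir, "existing.geojson"))
  write_distance_csv(inst$distances, inst$centers$id, inst$sites$id,
                     file.path(dir, "distances.csv"))
  invisible(dir)
}

#' Read a problem instance (and existing configuration) from files
#'
#' Accepts either a configuration list (see [read_config_yaml()]) or a
#' directory produced by [write_scenario()]. The distance matrix is
#' cross-checked against the center and site identifiers; when both a matrix
#' and a road network are configured, the matrix wins with a warning.
#'
#' @param config directory path or configuration list with an `inputs` block
#'   (`centers`, `sites`, `existing`, `distances` and/or `road_edges`) and an
#'   optional `objectives` block (`beta`, `charge`, `cost`).
#' @return list with `instance` and `existing` (`NULL` when no existing
#'   facilities file is configured).
#' @export
read_inputs <- function(config) {
  if (is.character(config)) {
    dir <- config
    config <- list(inputs = list(
      centers = file.path(dir, "centers.geojson"),
      sites = file.path(dir, "sites.geojson"),
      existing = file.path(dir, "existing.geojson"),
      distances = file.path(dir, "distances.csv")))
  }
  inp <- config$inputs
  centers <- read_points_geojson(inp$centers,
                                 required = c("id", "elderly", "demand"))
  sites <- read_points_geojson(inp$sites, required = c("id", "max_beds"))
  if (!is.null(inp$distances) && file.exists(inp$distances)) {
    if (!is.null(inp$road_edges))
      warning("both a distance matrix and a road network configured; the matrix wins")
    d <- read_distance_csv(inp$distances, centers$id, sites$id)
  } else if (!is.null(inp$road_edges)) {
    edges <- utils::read.csv(inp$road_edges)
    d <- road_distance_matrix(edges, centers$road_node, sites$road_node)
  } else stop("no distance matrix or road network configured")
  beta <- config$objectives$beta %||% 1
  costs <- list(charge = config$objectives$charge %||% 2050,
                cost = config$objectives$cost %||% 1250)
  existing <- NULL
  if (!is.null(inp$existing) && file.exists(inp$existing)) {
    fac <- read_points_geojson(inp$existing, required = c("id", "beds"))
    open <- match(fac$id, sites$id)
    if (anyNA(open)) stop("existing facility ids not found among sites")
    beds <- numeric(nrow(sites)); beds[open] <- fac$beds
    Z <- allocate_nearest_from(d, open)
    existing <- facility_configuration(sort(open), beds, Z)
  }
  baseline <- NULL
  inst0 <- build_instance(centers, sites, clamp_distances(d), beta = beta,
                          costs = costs)
  if (!is.null(existing))
    baseline <- pmax(gravity_accessibility(inst0, existing)$values, 1e-9)
  inst <- build_instance(centers, sites, clamp_distances(d), beta = beta,
                         costs = costs, baseline_accessibility = baseline)
  list(instance = inst, existing = existing)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and validate a YAML run configuration
#'
#' Known top-level blocks: `inputs`, `objectives`, `mia`, `workflow`,
#' `output`. Unknown keys are rejected so typos fail loudly.
#'
#' @param path YAML file.
#' @return the configuration list.
#' @export
read_config_yaml <- function(path) {
  if (!file.exists(path)) stop("missing config file: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("inputs", "objectives", "mia", "workflow", "output")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg
}

#' Assemble MIA parameters from a configuration block
#'
#' @param cfg configuration list (the `mia` block is used).
#' @param p facility count.
#' @param seed seed override (defaults to the block's or 1).
#' @export
mia_params_from_config <- function(cfg, p, seed = NULL) {
  m <- cfg$mia %||% list()
  # YAML 1.1 reads a bare key `N` as a boolean; map it back
  names(m)[names(m) %in% c("FALSE", "TRUE")] <- "N"
  do.call(mia_params, c(list(p = p), m[setdiff(names(m), c("p", "seed"))],
                        list(seed = seed %||% m$seed %||% 1L)))
}
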