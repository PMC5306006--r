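#' Build a colony map from node and trail tables
#'
#' A colony map is the spatially embedded network of one polydomous colony
#' at one mapping occasion: nest and tree nodes joined by internest and
#' foraging trails. Trail traffic (ants per cm and total ants, from the
#' trail length needed to find 10 workers) and trail weight (traffic
#' relative to the population of the connected nests) are derived on
#' construction.
#'
#' @param nodes A data frame with columns `node_id`, `kind` (`"nest"` or
#'   `"tree"`), `x`, `y` (planar metres) and, for nests, `population`
#'   (worker count) and optionally `mound_volume` (litres) and
#'   `canopy_cover` (fraction in `[0, 1]`); trees may carry `species`.
#' @param trails A data frame with columns `trail_id`, `endpoint_a`,
#'   `endpoint_b`, `kind` (`"internest"` or `"foraging"`), `length_cm` and
#'   `sample_gap_cm` (trail length needed to find 10 workers, cm).
#' @param colony_id,timepoint Identifiers; `timepoint` uses the
#'   `"YYYY-season"` convention (see [timepoint_key()]).
#' @param calibration Optional monotone function mapping mound volume
#'   (litres) to worker population, used only for nests that have a
#'   `mound_volume` but no `population` (see [population_from_volume()]).
#'
#' @return An object of class `colony_map`: a list with elements
#'   `colony_id`, `timepoint`, `nodes` (tibble) and `trails` (tibble with
#'   derived `ants_per_cm`, `total_ants`, `weight`), plus a `degenerate`
#'   flag that is `TRUE` when the map does not contain two or more nests
#'   connected by internest trails (the working definition of a polydomous
#'   colony).
#' @seealso [flow_betweenness()], [colony_metrics()], [read_colony_maps()]
#' @examples
#' nodes <- data.frame(
#'   node_id = c("n1", "n2", "t1"), kind = c("nest", "nest", "tree"),
#'   x = c(0, 10, 20), y = 0, population = c(1000, 2000, NA)
#' )
#' trails <- data.frame(
#'   trail_id = c("e1", "e2"), endpoint_a = c("n1", "n2"),
#'   endpoint_b = c("n2", "t1"), kind = c("internest", "foraging"),
#'   length_cm = c(1000, 1000), sample_gap_cm = c(20, 10)
#' )
#' colony_map(nodes, trails, colony_id = "demo", timepoint = "2012-summer")
#' @export
colony_map <- function(nodes, trails, colony_id, timepoint,
                       calibration = NULL) {
  nodes <- as_tibble(nodes)
  trails <- as_tibble(trails)
  need_n <- c("node_id", "kind", "x", "y")
  if (!all(need_n %in% names(nodes))) {
    abort(paste("node table is missing column(s):",
                paste(setdiff(need_n, names(nodes)), collapse = ", ")))
  }
  for (opt in c("population", "mound_volume", "canopy_cover")) {
    if (!opt %in% names(nodes)) nodes[[opt]] <- NA_real_
  }
  if (!"species" %in% names(nodes)) nodes$species <- NA_character_
  nodes$species <- as.character(nodes$species)
  nodes$node_id <- as.character(nodes$node_id)
  nodes$kind <- as.character(nodes$kind)
  for (col in c("x", "y", "population", "mound_volume", "canopy_cover")) {
    nodes[[col]] <- as.numeric(nodes[[col]])
  }

  need_t <- c("trail_id", "endpoint_a", "endpoint_b", "kind",
              "length_cm", "sample_gap_cm")
  if (!all(need_t %in% names(trails))) {
    abort(paste("trail table is missing column(s):",
                paste(setdiff(need_t, names(trails)), collapse = ", ")))
  }
  for (col in c("trail_id", "endpoint_a", "endpoint_b", "kind")) {
    trails[[col]] <- as.character(trails[[col]])
  }
  for (col in c("length_cm", "sample_gap_cm")) {
    trails[[col]] <- as.numeric(trails[[col]])
  }

  # fill populations from mound volume where a calibration is available
  needs_pop <- nodes$kind == "nest" & is.na(nodes$population) &
    !is.na(nodes$mound_volume)
  if (any(needs_pop)) {
    nodes$population[needs_pop] <-
      population_from_volume(nodes$mound_volume[needs_pop], calibration)
  }

  map <- structure(
    list(colony_id = as.character(colony_id),
         timepoint = as.character(timepoint),
         nodes = nodes, trails = trails, degenerate = FALSE),
    class = "colony_map"
  )
  validate_colony_map(map)
}

validate_colony_map <- function(map) {
  nodes <- map$nodes
  trails <- map$trails
  timepoint_key(map$timepoint)  # errors on malformed labels

  if (anyDuplicated(nodes$node_id)) {
    abort(paste0("duplicate node_id in map ", map$colony_id, "/",
                 map$timepoint, ": ",
                 paste(unique(nodes$node_id[duplicated(nodes$node_id)]),
                       collapse = ", ")))
  }
  if (!all(nodes$kind %in% c("nest", "tree"))) {
    abort("node kind must be \"nest\" or \"tree\"")
  }
  is_tree <- nodes$kind == "tree"
  if (any(!is.na(nodes$population[is_tree])) ||
      any(!is.na(nodes$canopy_cover[is_tree]))) {
    abort("trees cannot carry a population or canopy cover")
  }
  if (any(nodes$population < 0, na.rm = TRUE)) {
    abort("nest population must be >= 0")
  }
  cc <- nodes$canopy_cover
  if (any(cc < 0 | cc > 1, na.rm = TRUE)) {
    abort("canopy_cover must lie in [0, 1]")
  }

  if (nrow(trails) > 0) {
    known <- nodes$node_id
    missing <- setdiff(c(trails$endpoint_a, trails$endpoint_b), known)
    if (length(missing)) {
      rows <- trails$trail_id[trails$endpoint_a %in% missing |
                                trails$endpoint_b %in% missing]
      abort(paste0("trail(s) reference unknown node(s): ",
                   paste(unique(rows), collapse = ", ")))
    }
    if (!all(trails$kind %in% c("internest", "foraging"))) {
      abort("trail kind must be \"internest\" or \"foraging\"")
    }
    kind_of <- setNames(nodes$kind, nodes$node_id)
    a_tree <- kind_of[trails$endpoint_a] == "tree"
    b_tree <- kind_of[trails$endpoint_b] == "tree"
    if (any(a_tree & b_tree)) {
      abort(paste0("trail(s) joining two trees: ",
                   paste(trails$trail_id[a_tree & b_tree], collapse = ", ")))
    }
    n_trees <- a_tree + b_tree
    bad_f <- trails$kind == "foraging" & n_trees != 1L
    bad_i <- trails$kind == "internest" & n_trees != 0L
    if (any(bad_f | bad_i)) {
      abort(paste0("trail kind inconsistent with endpoints for: ",
                   paste(trails$trail_id[bad_f | bad_i], collapse = ", ")))
    }
    if (any(trails$length_cm <= 0) || any(trails$sample_gap_cm <= 0)) {
      abort("trail length_cm and sample_gap_cm must be > 0")
    }
    if (anyDuplicated(trails$trail_id)) {
      abort("duplicate trail_id within a map")
    }
  }

  # derived traffic and weight
  if (nrow(trails) > 0) {
    traffic <- compute_trail_traffic(trails$sample_gap_cm, trails$length_cm)
    trails$ants_per_cm <- traffic$ants_per_cm
    trails$total_ants <- traffic$total_ants
    # vectorised form of compute_trail_weight() over all trails
    pop_of <- setNames(nodes$population, nodes$node_id)
    pa <- unname(pop_of[trails$endpoint_a])
    pb <- unname(pop_of[trails$endpoint_b])
    inter <- trails$kind == "internest"
    bad_i <- inter & (is.na(pa) | is.na(pb) | pa <= 0 | pb <= 0)
    if (any(bad_i)) {
      abort(paste0("undefined trail weight (trail ",
                   trails$trail_id[which(bad_i)[1]],
                   "): both connected nests need a positive population"))
    }
    nest_pop <- dplyr::coalesce(pa, pb)  # foraging: the one nest endpoint
    bad_f <- !inter & (is.na(nest_pop) | nest_pop <= 0)
    if (any(bad_f)) {
      abort(paste0("undefined trail weight (trail ",
                   trails$trail_id[which(bad_f)[1]],
                   "): the foraging nest needs a positive population"))
    }
    trails$weight <- ifelse(inter,
                            trails$total_ants / ((pa + pb) / 2),
                            trails$total_ants / nest_pop)
  } else {
    trails$ants_per_cm <- numeric(0)
    trails$total_ants <- numeric(0)
    trails$weight <- numeric(0)
  }
  map$trails <- trails

  # polydomy: >= 2 nests joined by internest trails; otherwise flag the map
  internest <- trails[trails$kind == "internest", , drop = FALSE]
  connected_nests <- unique(c(internest$endpoint_a, internest$endpoint_b))
  map$degenerate <- length(connected_nests) < 2L
  map
}

#' @export
print.colony_map <- function(x, ...) {
  n_nest <- sum(x$nodes$kind == "nest")
  n_tree <- sum(x$nodes$kind == "tree")
  cat(sprintf("<colony_map> %s @ %s: %d nests, %d trees, %d trails%s\n",
              x$colony_id, x$timepoint, n_nest, n_tree, nrow(x$trails),
              if (x$degenerate) " [degenerate: not polydomous]" else ""))
  invisible(x)
}

#' Convert a colony map to an igraph object
#'
#' Nodes carry their attributes; edges carry trail kind, length, traffic
#' and weight. The graph is undirected, matching worker traffic on trails.
#'
#' @param map A [colony_map()].
#' @return An undirected `igraph` graph.
#' @export
as_colony_graph <- function(map) {
  stopifnot(inherits(map, "colony_map"))
  verts <- as.data.frame(map$nodes)
  names(verts)[names(verts) == "node_id"] <- "name"
  edges <- as.data.frame(map$trails[, c("endpoint_a", "endpoint_b",
                                        "trail_id", "kind", "length_cm",
                                        "sample_gap_cm", "ants_per_cm",
                                        "total_ants", "weight")])
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}
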