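#' Convert a trail's sampling gap into traffic
#'
#' Trail traffic is recorded in the field as the length of trail needed to
#' find 10 workers. This converts that gap into a density (ants per cm)
#' and a total count over the full trail length. The distance-based
#' measure is independent of walking speed, and hence of ambient
#' temperature.
#'
#' @param sample_gap_cm Trail length needed to find 10 workers (cm), > 0.
#' @param length_cm Total trail length (cm), > 0.
#' @return A tibble with columns `ants_per_cm` and `total_ants`.
#' @examples
#' compute_trail_traffic(10, 500)   # 1 ant/cm, 500 ants
#' compute_trail_traffic(50, 50)    # the gap spans the trail: the 10 counted ants
#' @export
compute_trail_traffic <- function(sample_gap_cm, length_cm) {
  if (any(!is.finite(sample_gap_cm)) || any(!is.finite(length_cm)) ||
      any(sample_gap_cm <= 0) || any(length_cm <= 0)) {
    abort("invalid trail measurement: sample_gap_cm and length_cm must be finite and > 0")
  }
  ants_per_cm <- 10 / sample_gap_cm
  tibble(ants_per_cm = ants_per_cm, total_ants = ants_per_cm * length_cm)
}

#' Trail weight: traffic relative to the connected nest population(s)
#'
#' An internest trail's weight is its total ant count divided by the mean
#' population of the two nests it joins; a foraging trail's weight is its
#' count divided by the population of the (single) foraging nest. Weight
#' measures a trail's importance relative to nest size.
#'
#' @param total_ants Ants on the whole trail (>= 0).
#' @param pop_a,pop_b Populations of the two endpoints (for a foraging
#'   trail the tree endpoint's population is `NA` and ignored).
#' @param kind `"internest"` or `"foraging"`.
#' @param trail_id Optional label used in error messages.
#' @return The scalar weight.
#' @export
compute_trail_weight <- function(total_ants, pop_a, pop_b, kind,
                                 trail_id = NULL) {
  lab <- if (is.null(trail_id)) "" else paste0(" (trail ", trail_id, ")")
  if (kind == "internest") {
    if (is.na(pop_a) || is.na(pop_b) || pop_a <= 0 || pop_b <= 0) {
      abort(paste0("undefined trail weight", lab,
                   ": both connected nests need a positive population"))
    }
    total_ants / ((pop_a + pop_b) / 2)
  } else if (kind == "foraging") {
    pop <- c(pop_a, pop_b)
    pop <- pop[!is.na(pop)]
    if (length(pop) != 1L || pop <= 0) {
      abort(paste0("undefined trail weight", lab,
                   ": the foraging nest needs a positive population"))
    }
    total_ants / pop
  } else {
    abort("trail kind must be \"internest\" or \"foraging\"")
  }
}

#' Estimate a nest population from its mound volume
#'
#' Field surveys of wood ants estimate worker population from nest mound
#' volume via a site-specific mark-release-recapture calibration. No
#' default calibration is shipped: the constants are site properties and
#' must be supplied by the caller as a monotone function of volume.
#'
#' @param volume Mound volume (litres), > 0.
#' @param calibration Function mapping volume to expected worker count.
#' @return Integer population estimate (rounded, floored at 0).
#' @export
population_from_volume <- function(volume, calibration) {
  if (is.null(calibration) || !is.function(calibration)) {
    abort(paste("no population calibration supplied:",
                "provide `calibration`, a monotone function mapping mound",
                "volume (litres) to worker count for your site"))
  }
  if (any(!is.finite(volume)) || any(volume <= 0)) {
    abort("mound volume must be finite and > 0")
  }
  pmax(0, round(as.numeric(calibration(volume))))
}

#' Resource flow through each node, measured as weighted betweenness
#'
#' Resource flow through a nest is quantified as weighted betweenness
#' centrality on the full colony network (nests and trees): the number of
#' shortest paths between node pairs passing through the node, with edge
#' cost taken as `1 / weight` so that strong trails are cheap to traverse.
#' Endpoints of a path do not count towards its intermediaries, each
#' unordered pair counts once, and tied shortest paths split their
#' contribution fractionally. Betweenness is normalised to the largest
#' nest value within the map so that maps of different sizes are
#' comparable; when every raw value is 0 (e.g. no internest trails) all
#' normalised values are 0. Trees sit at the ends of their own branches
#' and always have betweenness 0.
#'
#' Zero-weight trails cannot carry flow: they are excluded from the
#' shortest-path graph (with a message). A disconnected map is handled per
#' connected component, paths only existing within components.
#'
#' @param map A [colony_map()].
#' @return A tibble (`node_id`, `kind`, `betweenness`, `norm_betweenness`,
#'   `flow_category`), one row per node.
#' @examples
#' # a nest feeding three trees is the only intermediary between tree pairs
#' nodes <- data.frame(node_id = c("n", "t1", "t2", "t3"),
#'                     kind = c("nest", rep("tree", 3)),
#'                     x = c(0, 1, 2, 3), y = 0,
#'                     population = c(1000, NA, NA, NA))
#' trails <- data.frame(trail_id = paste0("e", 1:3), endpoint_a = "n",
#'                      endpoint_b = c("t1", "t2", "t3"), kind = "foraging",
#'                      length_cm = 100, sample_gap_cm = 10)
#' m <- colony_map(nodes, trails, "demo", "2012-summer")
#' flow_betweenness(m)
#' @export
flow_betweenness <- function(map) {
  stopifnot(inherits(map, "colony_map"))
  nodes <- map$nodes
  if (nrow(nodes) == 0L) abort("map has no nodes")
  trails <- map$trails

  usable <- trails$weight > 0
  if (nrow(trails) > 0 && any(!usable)) {
    inform(paste0("excluding ", sum(!usable),
                  " zero-weight trail(s) from flow computation in map ",
                  map$colony_id, "/", map$timepoint))
    trails <- trails[usable, , drop = FALSE]
  }

  raw <- setNames(numeric(nrow(nodes)), nodes$node_id)
  if (nrow(trails) > 0) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = trails$endpoint_a, to = trails$endpoint_b),
      directed = FALSE,
      vertices = data.frame(name = nodes$node_id)
    )
    comp_sizes <- igraph::components(g)$csize
    # isolated nodes (e.g. unused trees) carry no paths; only a split
    # among connected nodes is worth flagging
    if (sum(comp_sizes > 1L) > 1L) {
      warn(paste0("map ", map$colony_id, "/", map$timepoint,
                  " is disconnected; flow computed within components"))
    }
    b <- igraph::betweenness(g, directed = FALSE,
                             weights = 1 / trails$weight)
    raw[names(b)] <- as.numeric(b)
  }

  is_nest <- nodes$kind == "nest"
  max_nest <- if (any(is_nest)) max(raw[is_nest]) else 0
  norm <- if (max_nest > 0) raw / max_nest else raw * 0

  tibble(node_id = nodes$node_id, kind = nodes$kind,
         betweenness = unname(raw),
         norm_betweenness = unname(norm),
         flow_category = categorize_flow(unname(norm)))
}

#' Categorise normalised resource flow
#'
#' Nests are binned by normalised betweenness: exactly 0, exactly 1, low
#' (below 0.25), medium (0.25 to 0.75, bounds included) or high (above
#' 0.75). The published category bounds are open at 0.25 and 0.75, so the
#' boundary values are assigned to the inclusive middle bin.
#'
#' @param x Normalised betweenness values in `[0, 1]`.
#' @return A factor with levels `zero`, `low`, `medium`, `high`, `one`.
#' @export
categorize_flow <- function(x) {
  if (any(!is.finite(x)) || any(x < 0 | x > 1)) {
    abort("normalised betweenness must lie in [0, 1]")
  }
  out <- character(length(x))
  out[x == 0] <- "zero"
  out[x == 1] <- "one"
  mid <- x > 0 & x < 1
  out[mid & x < 0.25] <- "low"
  out[mid & x >= 0.25 & x <= 0.75] <- "medium"
  out[mid & x > 0.75] <- "high"
  factor(out, levels = c("zero", "low", "medium", "high", "one"))
}

#' Colony foraging effort
#'
#' The instantaneous number of workers on foraging trails: ants per cm
#' times trail length, summed over every foraging trail in the map. This
#' measures the colony's resource-acquisition effort, not its forager
#' head-count.
#'
#' @param map A [colony_map()].
#' @return A scalar ant count (0, with a warning, if the map has no
#'   foraging trails).
#' @export
colony_foraging_effort <- function(map) {
  stopifnot(inherits(map, "colony_map"))
  f <- map$trails[map$trails$kind == "foraging", , drop = FALSE]
  if (nrow(f) == 0L) {
    warn(paste0("map ", map$colony_id, "/", map$timepoint,
                " has no foraging trails; foraging effort is 0"))
    return(0)
  }
  sum(f$ants_per_cm * f$length_cm)
}

#' Worker to forager ratio
#'
#' Total colony population (the sum of all nest populations) divided by
#' the instantaneous number of workers on foraging trails. A high ratio
#' means low foraging effort per worker; a low ratio means high effort
#' per worker.
#'
#' @param map A [colony_map()].
#' @return Scalar ratio.
#' @export
worker_forager_ratio <- function(map) {
  stopifnot(inherits(map, "colony_map"))
  pops <- map$nodes$population[map$nodes$kind == "nest"]
  if (any(is.na(pops))) {
    abort("all nest populations must be present to compute the worker:forager ratio")
  }
  effort <- suppressWarnings(colony_foraging_effort(map))
  if (effort <= 0) {
    abort(paste0("worker:forager ratio undefined for map ", map$colony_id,
                 "/", map$timepoint, ": foraging effort is 0"))
  }
  sum(pops) / effort
}

#' Straight-line distance from each nest to its nearest tree
#'
#' Linear (Euclidean) distance, not distance along foraging trails, to
#' any tree in the map.
#'
#' @param map A [colony_map()].
#' @return Tibble (`node_id`, `tree_distance_m`); `NA` if the map has no
#'   trees.
#' @export
nest_tree_distance <- function(map) {
  stopifnot(inherits(map, "colony_map"))
  nests <- map$nodes[map$nodes$kind == "nest", , drop = FALSE]
  trees <- map$nodes[map$nodes$kind == "tree", , drop = FALSE]
  d <- if (nrow(trees) == 0L) {
    rep(NA_real_, nrow(nests))
  } else {
    vapply(seq_len(nrow(nests)), function(i) {
      min(sqrt((trees$x - nests$x[i])^2 + (trees$y - nests$y[i])^2))
    }, numeric(1))
  }
  tibble(node_id = nests$node_id, tree_distance_m = d)
}

#' Per-nest and per-colony metrics for one map
#'
#' Combines flow betweenness, nest attributes (size, canopy cover,
#' distance to the nearest tree) and the colony-level worker:forager
#' ratio into one per-nest table.
#'
#' @param map A [colony_map()].
#' @return Tibble with one row per nest: `colony_id`, `timepoint`,
#'   `node_id`, `population`, `canopy_cover`, `tree_distance_m`,
#'   `betweenness`, `norm_betweenness`, `flow_category`,
#'   `foraging_effort`, `wf_ratio`, `degenerate`.
#' @export
colony_metrics <- function(map) {
  stopifnot(inherits(map, "colony_map"))
  flow <- flow_betweenness(map)
  nd <- map$nodes
  is_nest <- nd$kind == "nest"
  ids <- nd$node_id[is_nest]
  pops <- nd$population[is_nest]
  effort <- suppressWarnings(colony_foraging_effort(map))
  wfr <- if (effort > 0 && !any(is.na(pops))) sum(pops) / effort else NA_real_
  td <- nest_tree_distance(map)
  i_flow <- match(ids, flow$node_id)
  tibble(colony_id = map$colony_id, timepoint = map$timepoint,
         foraging_effort = effort, wf_ratio = wfr,
         degenerate = map$degenerate,
         node_id = ids, population = pops,
         canopy_cover = nd$canopy_cover[is_nest],
         tree_distance_m = td$tree_distance_m[match(ids, td$node_id)],
         betweenness = flow$betweenness[i_flow],
         norm_betweenness = flow$norm_betweenness[i_flow],
         flow_category = flow$flow_category[i_flow])
}

#' The lower normalised betweenness of a trail's two endpoints
#'
#' An internest trail joins two nests, each with its own normalised
#' betweenness; the lower of the two values is the trail-level covariate
#' used in trail-survival models.
#'
#' @param trail One row of a map's trail table (internest only).
#' @param flow A [flow_betweenness()] table for the same map.
#' @return Scalar minimum endpoint value.
#' @export
min_endpoint_betweenness <- function(trail, flow) {
  if (trail$kind != "foraging") {
    v <- flow$norm_betweenness[match(c(trail$endpoint_a, trail$endpoint_b),
                                     flow$node_id)]
    if (any(is.na(v))) abort("trail endpoints missing from flow table")
    return(min(v))
  }
  abort("min_endpoint_betweenness applies to internest trails only")
}
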