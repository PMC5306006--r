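#' Read colony maps from node and edge CSV tables
#'
#' The declared dialect: comma-separated, `.` decimal, UTF-8, header row
#' mandatory. The node table carries `colony_id, timepoint, node_id,
#' kind, x, y, population, mound_volume, canopy_cover, species` (optional
#' fields may be empty); the edge table `colony_id, timepoint, trail_id,
#' endpoint_a, endpoint_b, kind, length_cm, sample_gap_cm`. Every type
#' invariant is checked on load; violations raise errors naming the
#' offending trail or node rather than being silently coerced.
#'
#' @param node_csv,edge_csv File paths.
#' @param calibration Optional volume-to-population calibration passed to
#'   [colony_map()].
#' @return A list of [colony_map()] objects, one per
#'   colony-by-timepoint combination present.
#' @export
read_colony_maps <- function(node_csv, edge_csv, calibration = NULL) {
  nodes <- readr::read_csv(node_csv, show_col_types = FALSE,
                           progress = FALSE)
  edges <- readr::read_csv(edge_csv, show_col_types = FALSE,
                           progress = FALSE)
  for (col in c("colony_id", "timepoint")) {
    if (!col %in% names(nodes) || !col %in% names(edges)) {
      abort(paste0("both tables need a `", col, "` column"))
    }
  }
  keys <- nodes |> distinct(.data$colony_id, .data$timepoint)
  purrr::map(seq_len(nrow(keys)), function(i) {
    cid <- keys$colony_id[i]; tp <- keys$timepoint[i]
    colony_map(
      nodes |> filter(.data$colony_id == cid, .data$timepoint == tp) |>
        select(-"colony_id", -"timepoint"),
      edges |> filter(.data$colony_id == cid, .data$timepoint == tp) |>
        select(-"colony_id", -"timepoint"),
      colony_id = cid, timepoint = tp, calibration = calibration)
  })
}

#' Write colony maps to the node/edge CSV dialect
#'
#' @param maps A [colony_map()] or list of them.
#' @param node_csv,edge_csv Output paths.
#' @return Invisibly, the two paths.
#' @export
write_colony_maps <- function(maps, node_csv, edge_csv) {
  if (inherits(maps, "colony_map")) maps <- list(maps)
  nodes <- bind_rows(purrr::map(maps, function(m) {
    m$nodes |> mutate(colony_id = m$colony_id, timepoint = m$timepoint,
                      .before = 1L)
  })) |>
    select("colony_id", "timepoint", "node_id", "kind", "x", "y",
           "population", "mound_volume", "canopy_cover", "species")
  edges <- bind_rows(purrr::map(maps, function(m) {
    m$trails |> mutate(colony_id = m$colony_id, timepoint = m$timepoint,
                       .before = 1L)
  })) |>
    select("colony_id", "timepoint", "trail_id", "endpoint_a",
           "endpoint_b", "kind", "length_cm", "sample_gap_cm")
  readr::write_csv(nodes, node_csv, progress = FALSE)
  readr::write_csv(edges, edge_csv, progress = FALSE)
  invisible(c(node_csv, edge_csv))
}

#' GraphML export/import of a colony map
#'
#' Writes the map as GraphML with all node and trail attributes (metrics
#' included as graph attributes of the nodes and edges), and reads it
#' back losslessly.
#'
#' @param map A [colony_map()].
#' @param path Output `.graphml` path.
#' @return Invisibly, `path`.
#' @export
write_colony_graphml <- function(map, path) {
  g <- as_colony_graph(map)
  igraph::V(g)$colony_id <- map$colony_id
  igraph::V(g)$timepoint <- map$timepoint
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_colony_graphml
#' @export
read_colony_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  vd <- igraph::as_data_frame(g, what = "vertices")
  ed <- igraph::as_data_frame(g, what = "edges")
  nodes <- as_tibble(vd) |>
    rename(node_id = "name") |>
    select("node_id", "kind", "x", "y", "population", "mound_volume",
           "canopy_cover", "species")
  # GraphML has no NA: absent strings come back as the literal "NA"
  nodes$species[nodes$species == "NA"] <- NA_character_
  trails <- as_tibble(ed) |>
    rename(endpoint_a = "from", endpoint_b = "to") |>
    select("trail_id", "endpoint_a", "endpoint_b", "kind", "length_cm",
           "sample_gap_cm")
  colony_map(nodes, trails, colony_id = vd$colony_id[1],
             timepoint = vd$timepoint[1])
}

#' Export a simulation as a plain-text fixture directory
#'
#' Layout: `colony_<id>/t<k>_nodes.csv` and `t<k>_edges.csv` per map,
#' `truth.json` (the planted-event ledger and effect sizes) and
#' `config.yaml`. Reading the fixture back reproduces the in-memory
#' objects.
#'
#' @param sim An `nf_sim` from [simulate_colonies()].
#' @param dir Target directory.
#' @param overwrite Refuse to write into an existing non-empty directory
#'   unless `TRUE`.
#' @return Invisibly, `dir`.
#' @export
export_fixture <- function(sim, dir, overwrite = FALSE) {
  stopifnot(inherits(sim, "nf_sim"))
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite) {
    abort(paste0("directory exists and is not empty: ", dir,
                 " (use overwrite = TRUE)"))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ts in sim$colonies) {
    cdir <- file.path(dir, paste0("colony_", ts$colony_id))
    dir.create(cdir, showWarnings = FALSE)
    for (k in seq_along(ts$maps)) {
      write_colony_maps(ts$maps[[k]],
                        file.path(cdir, paste0("t", k - 1L, "_nodes.csv")),
                        file.path(cdir, paste0("t", k - 1L, "_edges.csv")))
    }
  }
  cfg <- unclass(sim$config)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  jsonlite::write_json(
    list(effect_sizes = cfg[grep("^beta_", names(cfg))],
         seed = cfg$seed,
         events = sim$truth),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' @rdname export_fixture
#' @param max_link_distance Identity-link threshold (m) used when
#'   re-assembling time series from the fixture.
#' @export
read_fixture <- function(dir, max_link_distance = 2) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  config <- do.call(sim_config, cfg[names(cfg) %in% names(formals(sim_config))])
  tj <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  truth <- as_tibble(tj$events)
  if (nrow(truth)) {
    truth$natal <- as.character(truth$natal)
    truth$natal[truth$natal == "NA"] <- NA_character_
  }
  cdirs <- sort(list.dirs(dir, recursive = FALSE))
  colonies <- purrr::map(cdirs, function(cd) {
    nfiles <- sort(list.files(cd, pattern = "_nodes\\.csv$",
                              full.names = TRUE))
    maps <- purrr::map(nfiles, function(nf) {
      read_colony_maps(nf, sub("_nodes\\.csv$", "_edges.csv", nf))[[1]]
    })
    suppressWarnings(suppressMessages(
      colony_timeseries(maps, max_link_distance)))
  })
  structure(list(colonies = colonies, truth = truth, config = config),
            class = "nf_sim")
}
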