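#' Assemble colony maps into an ordered time series
#'
#' Orders one colony's maps by timepoint and resolves nest identity across
#' adjacent maps. Remapping in the field is blind (each map is drawn
#' without reference to earlier ones), so identities are re-established
#' spatially: nests are matched by greedy mutual-nearest-neighbour pairing
#' on Euclidean distance, accepting pairs within `max_link_distance` (wood
#' ant mounds are large and essentially immobile, so a small threshold
#' suffices). Persistent track ids are then chained through the links so
#' that a nest keeps one identity for its whole observed life.
#'
#' @param maps A list of [colony_map()] objects for one colony.
#' @param max_link_distance Largest nest displacement (m) still accepted
#'   as the same nest (default 2).
#' @return A `colony_timeseries`: list with `colony_id`, `maps` (ordered),
#'   `links` (tibble of matched nest pairs per adjacent interval) and
#'   `tracks` (tibble mapping each map's node_id to a persistent
#'   `track_id` and its founding interval).
#' @export
colony_timeseries <- function(maps, max_link_distance = 2) {
  stopifnot(length(maps) >= 1L, all(vapply(maps, inherits, TRUE, "colony_map")))
  ids <- unique(vapply(maps, `[[`, "", "colony_id"))
  if (length(ids) != 1L) {
    abort(paste("all maps must belong to one colony; got:",
                paste(ids, collapse = ", ")))
  }
  keys <- vapply(maps, function(m) timepoint_key(m$timepoint), numeric(1))
  if (anyDuplicated(keys)) abort("duplicate timepoints within a colony")
  maps <- maps[order(keys)]

  links <- purrr::map(seq_len(length(maps) - 1L), function(t) {
    link_identities(maps[[t]], maps[[t + 1L]], max_link_distance) |>
      mutate(interval = t - 1L, .before = 1L)
  }) |> bind_rows()
  if (length(maps) == 1L) {
    links <- tibble(interval = integer(), node_t = character(),
                    node_t1 = character(), distance_m = numeric())
  }

  # chain links into persistent tracks; track_id = id at first appearance
  tracks <- list()
  current <- character(0)  # node_id -> track_id for the previous map
  for (t in seq_along(maps)) {
    nests <- maps[[t]]$nodes$node_id[maps[[t]]$nodes$kind == "nest"]
    tr <- setNames(rep(NA_character_, length(nests)), nests)
    if (t > 1L) {
      lk <- links[links$interval == t - 2L, , drop = FALSE]
      carried <- lk$node_t1 %in% nests & lk$node_t %in% names(current)
      tr[lk$node_t1[carried]] <- unname(current[lk$node_t[carried]])
    }
    new <- is.na(tr)
    tr[new] <- names(tr)[new]
    tracks[[t]] <- tibble(map_index = t - 1L,
                          timepoint = maps[[t]]$timepoint,
                          node_id = names(tr), track_id = unname(tr),
                          founded_at = ifelse(new, t - 1L, NA_integer_))
    current <- tr
  }
  tracks <- bind_rows(tracks) |>
    group_by(.data$track_id) |>
    mutate(founded_at = min(.data$map_index)) |>
    ungroup()

  structure(list(colony_id = ids, maps = maps, links = links,
                 tracks = tracks),
            class = "colony_timeseries")
}

#' @export
print.colony_timeseries <- function(x, ...) {
  cat(sprintf("<colony_timeseries> %s: %d maps (%s to %s), %d nest tracks\n",
              x$colony_id, length(x$maps), x$maps[[1]]$timepoint,
              x$maps[[length(x$maps)]]$timepoint,
              length(unique(x$tracks$track_id))))
  invisible(x)
}

#' Match nest identities between two blind remappings
#'
#' Greedy mutual-nearest-neighbour matching of nests by Euclidean
#' distance: the globally closest unmatched pair is accepted first (so
#' every accepted pair is mutually nearest among what remains), until no
#' pair within `max_distance_m` is left. Distance ties are broken towards
#' the lexicographically smaller node pair. Unmatched nests of the
#' earlier map are abandonment candidates; unmatched nests of the later
#' map are founding candidates.
#'
#' @param map_t,map_t1 Two [colony_map()]s of the same colony at
#'   consecutive timepoints.
#' @param max_distance_m Acceptance threshold in metres.
#' @return Tibble (`node_t`, `node_t1`, `distance_m`).
#' @export
link_identities <- function(map_t, map_t1, max_distance_m = 2) {
  stopifnot(inherits(map_t, "colony_map"), inherits(map_t1, "colony_map"))
  if (map_t$colony_id != map_t1$colony_id) {
    abort("maps to link must come from the same colony")
  }
  a <- map_t$nodes[map_t$nodes$kind == "nest", , drop = FALSE]
  b <- map_t1$nodes[map_t1$nodes$kind == "nest", , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(tibble(node_t = character(), node_t1 = character(),
                  distance_m = numeric()))
  }
  d <- outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j) {
    sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2)
  })
  pairs <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
  pairs$dist <- d[cbind(pairs$i, pairs$j)]
  pairs <- pairs[pairs$dist <= max_distance_m, , drop = FALSE]
  # deterministic greedy order: distance, then node ids
  pairs <- pairs[order(pairs$dist, a$node_id[pairs$i], b$node_id[pairs$j]), ,
                 drop = FALSE]
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (!used_a[i] && !used_b[j]) {
      keep[k] <- TRUE
      used_a[i] <- TRUE
      used_b[j] <- TRUE
    }
  }
  out <- pairs[keep, , drop = FALSE]
  tibble(node_t = a$node_id[out$i], node_t1 = b$node_id[out$j],
         distance_m = out$dist)
}

#' Extract abandonment and founding events from a time series
#'
#' A nest that is present at one map but absent (unlinked) at the next is
#' abandoned in that interval; a nest with no antecedent is newly
#' founded. Nests still present in the final map are right-censored: no
#' event is recorded for them because nothing after the last mapping is
#' observed.
#'
#' @param ts A [colony_timeseries()].
#' @return Tibble (`colony_id`, `interval`, `from_timepoint`,
#'   `to_timepoint`, `node_id`, `track_id`, `event`) with `event` one of
#'   `"abandoned"` (node_id names the nest in the earlier map) or
#'   `"founded"` (node_id names it in the later map). Satisfies the
#'   bookkeeping identity
#'   `nests(t+1) = nests(t) - abandoned(t) + founded(t)`.
#' @export
extract_events <- function(ts) {
  stopifnot(inherits(ts, "colony_timeseries"))
  out <- purrr::map(seq_len(length(ts$maps) - 1L), function(t) {
    m0 <- ts$maps[[t]]; m1 <- ts$maps[[t + 1L]]
    lk <- ts$links[ts$links$interval == t - 1L, , drop = FALSE]
    nests0 <- m0$nodes$node_id[m0$nodes$kind == "nest"]
    nests1 <- m1$nodes$node_id[m1$nodes$kind == "nest"]
    gone <- setdiff(nests0, lk$node_t)
    born <- setdiff(nests1, lk$node_t1)
    bind_rows(
      tibble(node_id = gone, event = "abandoned",
             map_index = t - 1L),
      tibble(node_id = born, event = "founded",
             map_index = t)
    ) |>
      mutate(colony_id = ts$colony_id, interval = t - 1L,
             from_timepoint = m0$timepoint, to_timepoint = m1$timepoint,
             .before = 1L)
  }) |> bind_rows()
  if (nrow(out) == 0L) {
    return(tibble(colony_id = character(), interval = integer(),
                  from_timepoint = character(), to_timepoint = character(),
                  node_id = character(), track_id = character(),
                  event = character()))
  }
  out |>
    left_join(ts$tracks |> select("map_index", "node_id", "track_id"),
              by = c("map_index", "node_id")) |>
    select(-"map_index")
}

#' Classify founder status of nests at one timepoint
#'
#' Newly founded nests are assumed (i) to remain trail-connected to their
#' natal nest and (ii) to have, as natal nest, the nearest nest to which
#' they are attached. Each new nest's natal nest is therefore the
#' trail-connected nest at the smallest Euclidean distance. When that
#' nearest connected nest is itself newly founded, the order of
#' foundation cannot be resolved and the nearest established nest (by
#' Euclidean distance over all established nests, or over trail-connected
#' ones if `possible_metric = "connected"`) is labelled a possible
#' founder. Every other established nest is a nonfounder. A new nest with
#' no trail to any other nest is recorded with no natal nest.
#'
#' @param map_t1 The [colony_map()] in which the new nests first appear.
#' @param new_nests Character vector of newly founded node_ids in
#'   `map_t1`.
#' @param possible_metric `"all"` (default) or `"connected"`; candidate
#'   set for the possible-founder rule.
#' @return Tibble (`node_id`, `status`, `natal`, `natal_of`):
#'   `status` in newly_founded / founder / possible_founder / nonfounder;
#'   `natal` is the inferred natal nest of a new nest (`NA` when
#'   unresolvable or isolated); `natal_of` lists the new nests a
#'   (possible) founder is credited with. A nest that is both a founder
#'   and a possible founder is reported as founder.
#' @export
classify_founders <- function(map_t1, new_nests,
                              possible_metric = c("all", "connected")) {
  stopifnot(inherits(map_t1, "colony_map"))
  possible_metric <- match.arg(possible_metric)
  nodes <- map_t1$nodes
  nests <- nodes$node_id[nodes$kind == "nest"]
  if (!all(new_nests %in% nests)) {
    abort("new_nests must all be nests of map_t1")
  }
  established <- setdiff(nests, new_nests)
  xs <- setNames(nodes$x[match(nests, nodes$node_id)], nests)
  ys <- setNames(nodes$y[match(nests, nodes$node_id)], nests)
  edist <- function(p, q) {
    unname(sqrt((xs[p] - xs[q])^2 + (ys[p] - ys[q])^2))
  }

  tr <- map_t1$trails[map_t1$trails$kind == "internest", , drop = FALSE]
  neighbours <- function(nid) {
    unique(c(tr$endpoint_b[tr$endpoint_a == nid],
             tr$endpoint_a[tr$endpoint_b == nid]))
  }

  natal <- setNames(rep(NA_character_, length(new_nests)), new_nests)
  possible <- setNames(rep(NA_character_, length(new_nests)), new_nests)
  for (nid in new_nests) {
    cand <- neighbours(nid)
    if (length(cand) == 0L) {
      inform(paste0("new nest ", nid, " has no trail to any nest: ",
                    "isolated foundation, natal unknown"))
      next
    }
    dd <- vapply(cand, edist, numeric(1), p = nid)
    nearest <- cand[order(dd, cand)][1L]
    if (nearest %in% new_nests) {
      pool <- if (possible_metric == "connected") {
        intersect(cand, established)
      } else {
        established
      }
      if (length(pool) == 0L) {
        inform(paste0("new nest ", nid, " is connected only to other new ",
                      "nests and no established nest exists: natal unknown"))
      } else {
        dp <- vapply(pool, edist, numeric(1), p = nid)
        possible[nid] <- pool[order(dp, pool)][1L]
      }
    } else {
      natal[nid] <- nearest
    }
  }

  founder_of <- split(names(natal)[!is.na(natal)], natal[!is.na(natal)])
  possible_of <- split(names(possible)[!is.na(possible)],
                       possible[!is.na(possible)])
  status <- setNames(rep("nonfounder", length(established)), established)
  status[names(possible_of)] <- "possible_founder"
  status[names(founder_of)] <- "founder"

  bind_rows(
    tibble(node_id = new_nests, status = "newly_founded",
           natal = unname(natal[new_nests]),
           natal_of = vector("list", length(new_nests))),
    tibble(node_id = established, status = unname(status[established]),
           natal = NA_character_,
           natal_of = purrr::map(established, function(e) {
             unique(c(founder_of[[e]], possible_of[[e]]))
           }))
  )
}

#' Change in a per-nest metric across each interval
#'
#' For every nest linked across an interval, the change in a metric
#' (e.g. normalised betweenness) from the interval's start map to its end
#' map, classified as an increase (positive change) or static-or-decrease
#' (zero or negative).
#'
#' @param ts A [colony_timeseries()].
#' @param metrics Stacked [colony_metrics()] rows for the series' maps.
#' @param covariate Metric column name (default `"norm_betweenness"`).
#' @return Tibble (`colony_id`, `interval`, `node_t`, `node_t1`, `delta`,
#'   `direction`), where the interval's end map is where `node_t1` lives.
#' @export
delta_covariate <- function(ts, metrics, covariate = "norm_betweenness") {
  stopifnot(inherits(ts, "colony_timeseries"))
  if (!covariate %in% names(metrics)) {
    abort(paste0("metric column not found: ", covariate))
  }
  tp <- vapply(ts$maps, `[[`, "", "timepoint")
  value_at <- function(t, nid) {
    m <- metrics[metrics$timepoint == tp[t + 1L] &
                   metrics$colony_id == ts$colony_id, , drop = FALSE]
    m[[covariate]][match(nid, m$node_id)]
  }
  ts$links |>
    mutate(colony_id = ts$colony_id, .before = 1L) |>
    group_by(.data$interval) |>
    mutate(delta = value_at(.data$interval[1] + 1L, .data$node_t1) -
             value_at(.data$interval[1], .data$node_t)) |>
    ungroup() |>
    mutate(direction = ifelse(.data$delta > 0, "increase",
                              "static_or_decrease")) |>
    select("colony_id", "interval", "node_t", "node_t1", "delta",
           "direction")
}
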