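#' Counting-process survival records for nests or internest trails
#'
#' Lays out one row per subject per observed mapping interval in the
#' (start, stop] counting-process format, so covariates may change over a
#' subject's life. Time is measured in mapping intervals (0, 1, 2, ...):
#' intervals are ecologically comparable (each spans either a winter or a
#' summer of the foraging season) whereas calendar gaps are not. A nest
#' present at the first map enters at time 0; a nest founded later enters
#' at its founding index (delayed entry). The event is abandonment; a
#' subject still present at the final map is right-censored there.
#'
#' Nest covariates are measured at the interval's start map: `size` (nest
#' population), `canopy` cover, `tree_dist` (straight-line distance to
#' the nearest tree, m), `betweenness` (normalised), and the colony-level
#' `wf_ratio`. Trail subjects (internest trails, identified across maps by
#' their linked endpoint pair) carry `traffic` (total ants on the trail),
#' `weight`, `min_betweenness` (the lower of the two endpoint values) and
#' `endpoint_lost`, an indicator that one of the trail's nests is itself
#' abandoned in the interval — the survival of the nests a trail joins is
#' always included when modelling trail survival.
#'
#' @param ts A [colony_timeseries()] or a list of them (one per colony).
#' @param metrics Optional pre-computed stacked [colony_metrics()] rows;
#'   computed internally when `NULL`.
#' @param subject `"nest"` or `"trail"`.
#' @return Tibble with columns `subject_id`, `subject_kind`, `colony_id`,
#'   `timepoint`, `season`, `start`, `stop`, `event` (1 = abandoned in
#'   the interval, 0 = survived/censored) plus the covariates above.
#'   Rows with missing covariates are emitted with `NA`s; model fits use
#'   complete cases and report the n used.
#' @export
build_survival_records <- function(ts, metrics = NULL,
                                   subject = c("nest", "trail")) {
  subject <- match.arg(subject)
  if (inherits(ts, "colony_timeseries")) ts <- list(ts)
  stopifnot(all(vapply(ts, inherits, TRUE, "colony_timeseries")))
  if (is.null(metrics)) {
    metrics <- bind_rows(purrr::map(ts, function(s) {
      bind_rows(purrr::map(s$maps, colony_metrics))
    }))
  }
  fn <- if (subject == "nest") nest_records_one else trail_records_one
  bind_rows(purrr::map(ts, fn, metrics = metrics))
}

nest_records_one <- function(ts, metrics) {
  events <- extract_events(ts)
  T_ <- length(ts$maps)
  if (T_ < 2L) {
    return(tibble(subject_id = character(), subject_kind = character(),
                  colony_id = character(), timepoint = character(),
                  season = character(), start = integer(),
                  stop = integer(), event = integer()))
  }
  purrr::map(seq_len(T_ - 1L), function(t) {
    m0 <- ts$maps[[t]]
    met <- metrics[metrics$colony_id == ts$colony_id &
                     metrics$timepoint == m0$timepoint, , drop = FALSE]
    gone <- events$node_id[events$interval == t - 1L &
                             events$event == "abandoned"]
    trk <- ts$tracks[ts$tracks$map_index == t - 1L, , drop = FALSE]
    tibble(
      subject_id = paste0(ts$colony_id, ":",
                          trk$track_id[match(met$node_id, trk$node_id)]),
      subject_kind = "nest",
      colony_id = met$colony_id,
      timepoint = met$timepoint,
      season = timepoint_season(m0$timepoint),
      start = t - 1L, stop = t,
      event = as.integer(met$node_id %in% gone),
      size = met$population,
      canopy = met$canopy_cover,
      tree_dist = met$tree_distance_m,
      betweenness = met$norm_betweenness,
      wf_ratio = met$wf_ratio
    )
  }) |> bind_rows()
}

trail_records_one <- function(ts, metrics) {
  T_ <- length(ts$maps)
  events <- extract_events(ts)
  trail_key_at <- function(t) {
    m <- ts$maps[[t]]
    trk <- ts$tracks[ts$tracks$map_index == t - 1L, , drop = FALSE]
    tr <- m$trails[m$trails$kind == "internest", , drop = FALSE]
    if (nrow(tr) == 0L) return(character(0))
    ta <- trk$track_id[match(tr$endpoint_a, trk$node_id)]
    tb <- trk$track_id[match(tr$endpoint_b, trk$node_id)]
    paste(pmin(ta, tb), pmax(ta, tb), sep = "--")
  }
  purrr::map(seq_len(max(T_ - 1L, 0L)), function(t) {
    if (T_ < 2L) return(NULL)
    m0 <- ts$maps[[t]]
    tr <- m0$trails[m0$trails$kind == "internest", , drop = FALSE]
    if (nrow(tr) == 0L) return(NULL)
    keys_now <- trail_key_at(t)
    keys_next <- trail_key_at(t + 1L)
    met <- metrics[metrics$colony_id == ts$colony_id &
                     metrics$timepoint == m0$timepoint, , drop = FALSE]
    gone <- events$node_id[events$interval == t - 1L &
                             events$event == "abandoned"]
    bm <- met$norm_betweenness[match(tr$endpoint_a, met$node_id)]
    bn <- met$norm_betweenness[match(tr$endpoint_b, met$node_id)]
    tibble(
      subject_id = paste0(ts$colony_id, ":", keys_now),
      subject_kind = "trail",
      colony_id = ts$colony_id,
      timepoint = m0$timepoint,
      season = timepoint_season(m0$timepoint),
      start = t - 1L, stop = t,
      event = as.integer(!keys_now %in% keys_next),
      traffic = tr$total_ants,
      weight = tr$weight,
      min_betweenness = pmin(bm, bn),
      endpoint_lost = as.integer(tr$endpoint_a %in% gone |
                                   tr$endpoint_b %in% gone),
      wf_ratio = met$wf_ratio[1] %||% NA_real_
    )
  }) |> bind_rows()
}
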