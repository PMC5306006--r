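#' Nest counts from a two-year wood ant field survey
#'
#' Per-colony nest counts for thirteen polydomous wood ant (*Formica
#' lugubris*) colonies mapped at five occasions: late summer of a
#' baseline year, then late spring and late summer of each of the two
#' following years. These are the headline bookkeeping numbers of the
#' study design the simulator emulates, and the substrate for
#' [net_nest_change()].
#'
#' @return Tibble (`colony_id`, `timepoint`, `n_nests`), 13 colonies x 5
#'   timepoints.
#' @export
wood_ant_nest_counts <- function() {
  counts <- list(
    I   = c(21, 16, 15, 11, 14),
    IIa = c(4, 3, 4, 4, 4),
    IIb = c(6, 6, 6, 9, 9),
    III = c(12, 12, 8, 9, 16),
    IV  = c(12, 9, 6, 7, 7),
    V   = c(14, 11, 10, 8, 2),
    VI  = c(14, 12, 12, 13, 11),
    VII = c(7, 7, 4, 5, 8),
    VIII = c(6, 3, 4, 6, 4),
    IX  = c(9, 11, 17, 11, 15),
    X   = c(13, 8, 10, 9, 8),
    XI  = c(20, 15, 10, 10, 17),
    XII = c(6, 6, 3, 8, 3)
  )
  tps <- sim_timepoints(2012, 5)
  bind_rows(purrr::imap(counts, function(v, id) {
    tibble(colony_id = id, timepoint = tps, n_nests = v)
  }))
}

#' Net change in nest number per colony
#'
#' The difference (and percentage difference) between the first and last
#' mapping of each colony, summarising two years of abandonment and
#' founding. By the event bookkeeping identity, this equals founded minus
#' abandoned nests summed over all intervals.
#'
#' @param counts Tibble (`colony_id`, `timepoint`, `n_nests`), e.g.
#'   [wood_ant_nest_counts()] or tallies of simulated maps.
#' @return Tibble (`colony_id`, `first`, `last`, `net_change`,
#'   `pct_change`), percentage relative to the first count.
#' @examples
#' net_nest_change(wood_ant_nest_counts())
#' @export
net_nest_change <- function(counts = wood_ant_nest_counts()) {
  counts |>
    group_by(.data$colony_id) |>
    arrange(timepoint_key(.data$timepoint), .by_group = TRUE) |>
    summarise(first = dplyr::first(.data$n_nests),
              last = dplyr::last(.data$n_nests), .groups = "drop") |>
    mutate(net_change = .data$last - .data$first,
           pct_change = 100 * .data$net_change / .data$first)
}

#' Tally nest counts from colony time series
#'
#' @param ts A [colony_timeseries()] or list of them.
#' @return Tibble (`colony_id`, `timepoint`, `n_nests`).
#' @export
count_nests <- function(ts) {
  if (inherits(ts, "colony_timeseries")) ts <- list(ts)
  bind_rows(purrr::map(ts, function(s) {
    bind_rows(purrr::map(s$maps, function(m) {
      tibble(colony_id = m$colony_id, timepoint = m$timepoint,
             n_nests = sum(m$nodes$kind == "nest"))
    }))
  }))
}
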