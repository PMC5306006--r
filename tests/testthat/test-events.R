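test_that("blind remaps link by mutual nearest neighbour within range", {
  fx <- fix_two_maps()
  lk <- link_identities(fx$m0, fx$m1, max_distance_m = 2)
  expect_setequal(lk$node_t, c("A", "B"))
  expect_equal(lk$node_t1[lk$node_t == "A"], "A2")
  expect_equal(lk$node_t1[lk$node_t == "B"], "B2")
  expect_true(all(lk$distance_m <= 2))
  # a tight threshold breaks the links
  lk0 <- link_identities(fx$m0, fx$m1, max_distance_m = 0.1)
  expect_equal(nrow(lk0), 0)
})

test_that("greedy linking resolves competition for one candidate", {
  # two old nests close to a single new nest: only the nearer one links
  mk <- function(xs, ids, tp) {
    n <- tibble::tibble(node_id = c(ids, "t"), kind = c("nest", "nest", "tree")[
      c(seq_along(ids), 3)][seq_len(length(ids) + 1)],
      x = c(xs, 50), y = 0,
      population = c(rep(1000, length(ids)), NA))
    n$kind <- c(rep("nest", length(ids)), "tree")
    tr <- trail_row("f1", ids[1], "t", "foraging", 1000, 100)
    colony_map(n, tr, "comp", tp)
  }
  m0 <- mk(c(0, 1.5), c("p", "q"), "2012-summer")
  m1 <- mk(c(0.4), c("z"), "2013-spring")
  lk <- link_identities(m0, m1, max_distance_m = 2)
  expect_equal(nrow(lk), 1)
  expect_equal(lk$node_t, "p")  # 0.4 m beats 1.1 m
})

test_that("time series orders maps and chains persistent tracks", {
  fx <- fix_two_maps()
  # supply out of order: constructor must sort by timepoint
  ts <- colony_timeseries(list(fx$m1, fx$m0))
  expect_equal(vapply(ts$maps, `[[`, "", "timepoint"),
               c("2012-summer", "2013-spring"))
  trk <- ts$tracks
  # B2 inherits B's track; D starts its own at interval 1
  expect_equal(trk$track_id[trk$node_id == "B2"], "B")
  expect_equal(trk$track_id[trk$node_id == "A2"], "A")
  expect_equal(trk$track_id[trk$node_id == "D"], "D")
  expect_equal(trk$founded_at[trk$node_id == "D"], 1)
  expect_equal(unique(trk$founded_at[trk$node_id %in% c("A", "A2")]), 0)
})

test_that("mixing colonies or duplicate timepoints is an error", {
  fx <- fix_two_maps()
  other <- fx$m1
  other$colony_id <- "someone-else"
  expect_error(colony_timeseries(list(fx$m0, other)), "one colony")
  expect_error(colony_timeseries(list(fx$m0, fx$m0)), "duplicate")
})

test_that("extract_events records abandonment, founding and censoring", {
  fx <- fix_two_maps()
  ts <- colony_timeseries(list(fx$m0, fx$m1))
  ev <- extract_events(ts)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$node_id[ev$event == "abandoned"], "C")
  expect_equal(ev$node_id[ev$event == "founded"], "D")
  expect_equal(unique(ev$interval), 0)
  # survivors A and B are censored: no event rows name them
  expect_false(any(c("A", "B", "A2", "B2") %in% ev$node_id))
})

test_that("bookkeeping identity holds on simulated colonies", {
  sim <- fix_small_sim(3)
  for (ts in sim$colonies) {
    ev <- extract_events(ts)
    n_at <- vapply(ts$maps, function(m) sum(m$nodes$kind == "nest"), 1L)
    for (t in seq_len(length(ts$maps) - 1L)) {
      ab <- sum(ev$interval == t - 1L & ev$event == "abandoned")
      fo <- sum(ev$interval == t - 1L & ev$event == "founded")
      expect_equal(n_at[t + 1L], n_at[t] - ab + fo)
    }
  }
})

test_that("classify_founders credits the nearest connected nest", {
  fx <- fix_two_maps()
  lab <- classify_founders(fx$m1, "D")
  expect_equal(lab$status[lab$node_id == "D"], "newly_founded")
  expect_equal(lab$natal[lab$node_id == "D"], "B2")
  expect_equal(lab$status[lab$node_id == "B2"], "founder")
  expect_equal(lab$status[lab$node_id == "A2"], "nonfounder")
  expect_equal(lab$natal_of[lab$node_id == "B2"][[1]], "D")
})

test_that("ambiguous founding yields possible_founder", {
  # two new nests joined to each other; nearest established nest gets
  # possible_founder for the one whose nearest partner is itself new
  n <- tibble::tibble(
    node_id = c("est1", "est2", "newA", "newB"), kind = "nest",
    x = c(0, 30, 10, 11), y = 0, population = 1000)
  tr <- dplyr::bind_rows(
    trail_row("e1", "est1", "newA", "internest", 1000, 300),
    trail_row("e2", "newA", "newB", "internest", 100, 300),
    trail_row("e3", "est2", "newB", "internest", 1900, 300))
  m <- colony_map(n, tr, "amb", "2013-spring")
  lab <- classify_founders(m, c("newA", "newB"))
  # newB's nearest trail partner is newA (1 m) -> unresolvable; its
  # nearest established nest overall is est1 (11 m vs 19 m)
  expect_equal(lab$status[lab$node_id == "est1"], "possible_founder")
  expect_true(is.na(lab$natal[lab$node_id == "newB"]))
  # newA's nearest partner is newB (1 m), also unresolvable
  expect_equal(sum(lab$status == "possible_founder"), 1)
  # with the connected-only metric, newB's pool is est2 alone
  lab2 <- classify_founders(m, c("newA", "newB"),
                            possible_metric = "connected")
  expect_equal(lab2$status[lab2$node_id == "est2"], "possible_founder")
})

test_that("isolated foundation is reported with natal unknown", {
  n <- tibble::tibble(
    node_id = c("est", "new", "t"), kind = c("nest", "nest", "tree"),
    x = c(0, 20, 5), y = 0, population = c(1000, 500, NA))
  tr <- trail_row("f1", "est", "t", "foraging", 500, 100)
  m <- colony_map(n, tr, "iso", "2013-spring")
  expect_message(lab <- classify_founders(m, "new"), "isolated")
  expect_true(is.na(lab$natal[lab$node_id == "new"]))
  expect_equal(lab$status[lab$node_id == "est"], "nonfounder")
})

test_that("delta_covariate classifies per-interval change", {
  fx <- fix_two_maps()
  ts <- colony_timeseries(list(fx$m0, fx$m1))
  metrics <- dplyr::bind_rows(lapply(ts$maps, colony_metrics))
  d <- delta_covariate(ts, metrics, "population")
  expect_equal(nrow(d), 2)
  expect_equal(d$delta[d$node_t == "A"], -100)  # 1000 -> 900
  expect_equal(d$direction[d$node_t == "A"], "static_or_decrease")
  expect_equal(d$direction[d$node_t == "B"], "increase")
  expect_error(delta_covariate(ts, metrics, "no_such"), "not found")
})
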