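# Hand-built maps used across the unit and acceptance tests. Weights are
# made exact by choosing sample_gap_cm so that total_ants / ref_pop gives
# round numbers.

# a trail table row with the gap chosen to hit a target total ant count
trail_row <- function(id, a, b, kind, length_cm, total_ants) {
  tibble::tibble(trail_id = id, endpoint_a = a, endpoint_b = b,
                 kind = kind, length_cm = length_cm,
                 sample_gap_cm = 10 * length_cm / total_ants)
}

# chain T1 - A - B - C - T2 with equal trail weights.
# Brute force (endpoints excluded, each unordered pair once):
#   raw A = 3 (pairs T1-B, T1-C, T1-T2), raw B = 4, raw C = 3,
#   trees 0; normalised to max nest B: A 0.75, B 1, C 0.75.
fix_chain <- function(timepoint = "2012-summer") {
  nodes <- tibble::tibble(
    node_id = c("T1", "A", "B", "C", "T2"),
    kind = c("tree", "nest", "nest", "nest", "tree"),
    x = 0:4 * 10, y = 0,
    population = c(NA, 1000, 1000, 1000, NA)
  )
  trails <- dplyr::bind_rows(
    trail_row("e1", "T1", "A", "foraging", 1000, 500),
    trail_row("e2", "A", "B", "internest", 1000, 500),
    trail_row("e3", "B", "C", "internest", 1000, 500),
    trail_row("e4", "C", "T2", "foraging", 1000, 500)
  )
  colony_map(nodes, trails, colony_id = "chain", timepoint = timepoint)
}

# one nest feeding three trees: the nest is the sole intermediary for the
# three tree pairs (raw 3, normalised 1); trees 0.
fix_star <- function() {
  nodes <- tibble::tibble(
    node_id = c("hub", "t1", "t2", "t3"),
    kind = c("nest", "tree", "tree", "tree"),
    x = c(0, 10, -10, 0), y = c(0, 0, 0, 10),
    population = c(2000, NA, NA, NA)
  )
  trails <- dplyr::bind_rows(
    trail_row("f1", "hub", "t1", "foraging", 1000, 200),
    trail_row("f2", "hub", "t2", "foraging", 1000, 200),
    trail_row("f3", "hub", "t3", "foraging", 1000, 200)
  )
  colony_map(nodes, trails, colony_id = "star", timepoint = "2012-summer")
}

# a small polydomous map with uneven weights and a tied pair of routes;
# used against the brute-force oracle
fix_diamond <- function() {
  nodes <- tibble::tibble(
    node_id = c("n1", "n2", "n3", "n4", "tr"),
    kind = c(rep("nest", 4), "tree"),
    x = c(0, 10, 10, 20, 30), y = c(0, 10, -10, 0, 0),
    population = c(1000, 1000, 1000, 1000, NA)
  )
  trails <- dplyr::bind_rows(
    trail_row("e1", "n1", "n2", "internest", 1000, 400),
    trail_row("e2", "n1", "n3", "internest", 1000, 400),
    trail_row("e3", "n2", "n4", "internest", 1000, 400),
    trail_row("e4", "n3", "n4", "internest", 1000, 400),
    trail_row("e5", "n4", "tr", "foraging", 1000, 300)
  )
  colony_map(nodes, trails, colony_id = "diamond",
             timepoint = "2012-summer")
}

# random connected small maps (<= 7 nodes) for oracle comparison
fix_random_map <- function(seed, n_nest = 4, n_tree = 2) {
  set.seed(seed)
  n <- n_nest + n_tree
  ids <- c(paste0("n", seq_len(n_nest)), paste0("t", seq_len(n_tree)))
  kind <- c(rep("nest", n_nest), rep("tree", n_tree))
  nodes <- tibble::tibble(
    node_id = ids, kind = kind,
    x = runif(n, 0, 50), y = runif(n, 0, 50),
    population = ifelse(kind == "nest", round(runif(n, 500, 5000)), NA)
  )
  # random spanning tree over the nests plus extra internest edges
  edges <- list()
  for (i in seq_len(n_nest)[-1]) {
    j <- sample(i - 1L, 1)
    edges[[length(edges) + 1L]] <- c(ids[j], ids[i])
  }
  for (k in seq_len(2)) {
    p <- sort(sample(n_nest, 2))
    e <- c(ids[p[1]], ids[p[2]])
    if (!any(vapply(edges, function(x) all(x == e), TRUE))) {
      edges[[length(edges) + 1L]] <- e
    }
  }
  tr <- dplyr::bind_rows(purrr::imap(edges, function(e, i) {
    trail_row(paste0("e", i), e[1], e[2], "internest", 1000,
              round(runif(1, 100, 900)))
  }))
  # each tree forages from one random nest
  fr <- dplyr::bind_rows(purrr::map(seq_len(n_tree), function(i) {
    trail_row(paste0("f", i), ids[sample(n_nest, 1)],
              paste0("t", i), "foraging", 1000, round(runif(1, 100, 900)))
  }))
  colony_map(nodes, dplyr::bind_rows(tr, fr),
             colony_id = paste0("rnd", seed), timepoint = "2012-summer")
}

# two-map series with one abandonment, one founding and two survivors;
# the new nest D is trail-connected to survivor B (its nearest nest)
fix_two_maps <- function() {
  n0 <- tibble::tibble(
    node_id = c("A", "B", "C", "T1"),
    kind = c("nest", "nest", "nest", "tree"),
    x = c(0, 20, 40, 10), y = 0,
    population = c(1000, 2000, 1500, NA)
  )
  t0 <- dplyr::bind_rows(
    trail_row("e1", "A", "B", "internest", 2000, 600),
    trail_row("e2", "B", "C", "internest", 2000, 600),
    trail_row("f1", "A", "T1", "foraging", 1000, 300)
  )
  m0 <- colony_map(n0, t0, "demo", "2012-summer")
  # C abandoned; D founded near B (B is its only trail partner);
  # survivors move by < 1 m under blind remapping
  n1 <- tibble::tibble(
    node_id = c("A2", "B2", "D", "T1"),
    kind = c("nest", "nest", "nest", "tree"),
    x = c(0.4, 20.3, 25, 10), y = c(0.3, -0.2, 6, 0),
    population = c(900, 2100, 400, NA)
  )
  t1 <- dplyr::bind_rows(
    trail_row("e1", "A2", "B2", "internest", 2000, 600),
    trail_row("e2", "B2", "D", "internest", 800, 200),
    trail_row("f1", "A2", "T1", "foraging", 1000, 300)
  )
  m1 <- colony_map(n1, t1, "demo", "2013-spring")
  list(m0 = m0, m1 = m1)
}

# small simulated study used by several suites (cheap but non-trivial)
fix_small_sim <- function(seed = 11) {
  suppressWarnings(simulate_colonies(sim_config(
    n_colonies = 4, n_timepoints = 4,
    initial_nests_range = c(3, 8), trees_per_colony_range = c(3, 6),
    seed = seed)))
}
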