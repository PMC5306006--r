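#' Configuration for the synthetic colony simulator
#'
#' Defaults emulate the structure of a two-year field study of polydomous
#' wood ant colonies: 13 colonies mapped at 5 timepoints (one late-summer
#' baseline, then late spring and late summer of each of the next two
#' years), 2-21 nests per colony initially, nest populations lognormal
#' over roughly 1e2 to 1e6 workers, trees as terminal foraging nodes and
#' trails built by proximity. Abandonment and budding are Bernoulli per
#' nest per interval with logistic linear predictors; the `beta_*` effect
#' sizes plant known dependencies on (z-scored log) nest size, normalised
#' betweenness and its interval change, and default to zero (no planted
#' structure).
#'
#' @param n_colonies,n_timepoints Study dimensions.
#' @param initial_nests_range,trees_per_colony_range Inclusive ranges
#'   sampled uniformly per colony.
#' @param arena_size_m Side of the square arena nests and trees occupy.
#' @param population_meanlog,population_sdlog Lognormal worker counts.
#' @param forage_prob Probability a nest holds a foraging trail to its
#'   nearest unclaimed tree (each tree serves at most one nest, keeping
#'   trees terminal).
#' @param extra_edge_prob Probability, per nest, of one extra internest
#'   trail beyond the spanning tree (gives the trail network redundancy).
#' @param trail_drop_prob Per-interval probability an internest trail is
#'   re-routed away, applied only where removal keeps the colony
#'   connected.
#' @param baseline_abandonment_prob,baseline_budding_prob Per-interval
#'   baselines.
#' @param beta_survival_betweenness,beta_survival_size Log-odds effects
#'   on abandonment.
#' @param beta_bud_betweenness,beta_bud_delta Log-odds effects on
#'   budding.
#' @param pop_drift_sdlog Interval-to-interval multiplicative noise on
#'   nest populations.
#' @param start_year First (summer) mapping year.
#' @param seed Integer RNG seed; every simulator draw descends from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_colonies = 13, n_timepoints = 5,
                       initial_nests_range = c(2, 21),
                       trees_per_colony_range = c(4, 16),
                       arena_size_m = 60,
                       population_meanlog = 9.8, population_sdlog = 1.5,
                       forage_prob = 0.8, extra_edge_prob = 0.3,
                       trail_drop_prob = 0.08,
                       baseline_abandonment_prob = 0.15,
                       baseline_budding_prob = 0.10,
                       beta_survival_betweenness = 0,
                       beta_survival_size = 0,
                       beta_bud_betweenness = 0,
                       beta_bud_delta = 0,
                       pop_drift_sdlog = 0.3,
                       start_year = 2012, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_colonies >= 1, n_timepoints >= 1,
            initial_nests_range[1] >= 1,
            diff(initial_nests_range) >= 0,
            baseline_abandonment_prob >= 0, baseline_abandonment_prob <= 1,
            baseline_budding_prob >= 0, baseline_budding_prob <= 1,
            forage_prob >= 0, forage_prob <= 1)
  structure(cfg, class = "sim_config")
}

sim_timepoints <- function(start_year, n) {
  labs <- paste0(start_year, "-summer")
  y <- start_year
  while (length(labs) < n) {
    y <- y + 1
    labs <- c(labs, paste0(y, "-spring"), paste0(y, "-summer"))
  }
  labs[seq_len(n)]
}

roman <- function(i) as.character(utils::as.roman(i))

#' Simulate dynamic polydomous colony time series with known truth
#'
#' Generates, per colony, an initial map (nests and trees placed
#' uniformly; internest trails as a Euclidean spanning tree plus random
#' redundancy; foraging trails claiming at most one nest per tree) and
#' then iterates intervals: traffic is redrawn, betweenness is recomputed
#' (so flow feeds back dynamically as the network changes), each nest is
#' abandoned with probability
#' `plogis(qlogis(p_ab) + b_bw * betweenness + b_sz * z(log population))`,
#' and each survivor buds with probability
#' `plogis(qlogis(p_bud) + b_bud * betweenness + b_delta * d_betweenness)`,
#' the new nest being placed 3-8 m from its natal nest (never within the
#' identity-link radius of another nest) and trail-connected to it. If an
#' abandonment disconnects the remaining nests, the closest pair of
#' components is re-joined by a new trail — functionally the ants
#' re-routing — and at least one nest always survives so the colony is
#' observable at every mapping. Trees are static throughout (honeydew
#' sources are spatially and temporally stable).
#'
#' @param config A [sim_config()].
#' @return An `nf_sim`: list with `colonies` (list of
#'   [colony_timeseries()]), `truth` (tibble ledger of every planted
#'   abandonment/founding with the probability that generated it, plus
#'   natal nests) and `config`.
#' @export
simulate_colonies <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(config$seed))
  tps <- sim_timepoints(config$start_year, config$n_timepoints)
  colonies <- vector("list", config$n_colonies)
  truth <- list()

  for (ci in seq_len(config$n_colonies)) {
    cid <- roman(ci)
    state <- init_colony_state(cid, config)
    maps <- list(state_to_map(state, cid, tps[1]))
    prev_betw <- NULL
    for (t in seq_len(config$n_timepoints - 1L)) {
      flow <- flow_betweenness(maps[[t]])
      betw <- setNames(flow$norm_betweenness, flow$node_id)
      dbetw <- setNames(rep(0, length(betw)), names(betw))
      if (!is.null(prev_betw)) {
        common <- intersect(names(betw), names(prev_betw))
        dbetw[common] <- betw[common] - prev_betw[common]
      }
      step <- step_colony(state, betw, dbetw, config)
      state <- step$state
      if (nrow(step$ledger)) {
        truth[[length(truth) + 1L]] <- step$ledger |>
          mutate(colony_id = cid, interval = t - 1L, .before = 1L)
      }
      maps[[t + 1L]] <- state_to_map(state, cid, tps[t + 1L])
      prev_betw <- betw
    }
    if (nrow(maps[[config$n_timepoints]]$nodes |>
               filter(.data$kind == "nest")) < 2L) {
      warn(paste0("colony ", cid,
                  " shrank to a single nest during the simulation"))
    }
    colonies[[ci]] <- suppressWarnings(suppressMessages(
      colony_timeseries(maps)))
  }

  truth <- if (length(truth)) bind_rows(truth) else
    tibble(colony_id = character(), interval = integer(),
           node_id = character(), event = character(),
           natal = character(), prob = numeric())
  structure(list(colonies = colonies, truth = truth, config = config),
            class = "nf_sim")
}

#' @export
print.nf_sim <- function(x, ...) {
  cat(sprintf("<nf_sim> %d colonies x %d timepoints (seed %d): %d planted events\n",
              x$config$n_colonies, x$config$n_timepoints, x$config$seed,
              nrow(x$truth)))
  invisible(x)
}

# internal mutable colony state: nests / trees / trails data frames
init_colony_state <- function(cid, cfg) {
  n0 <- sample(seq(cfg$initial_nests_range[1], cfg$initial_nests_range[2]), 1)
  ntree <- sample(seq(cfg$trees_per_colony_range[1],
                      cfg$trees_per_colony_range[2]), 1)
  nests <- tibble(
    node_id = paste0(cid, "_n", seq_len(n0)),
    x = runif(n0, 0, cfg$arena_size_m),
    y = runif(n0, 0, cfg$arena_size_m),
    population = rlnorm(n0, cfg$population_meanlog, cfg$population_sdlog),
    canopy_cover = runif(n0)
  )
  trees <- tibble(
    node_id = paste0(cid, "_t", seq_len(ntree)),
    x = runif(ntree, 0, cfg$arena_size_m),
    y = runif(ntree, 0, cfg$arena_size_m),
    species = sample(c("Pinus sylvestris", "Quercus robur", "Larix decidua",
                       "Betula pendula"), ntree, replace = TRUE)
  )

  # internest backbone: Euclidean minimum spanning tree + optional extras
  edges <- tibble(endpoint_a = character(), endpoint_b = character())
  if (n0 >= 2) {
    d <- as.matrix(dist(nests[, c("x", "y")]))
    g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                             weighted = TRUE)
    igraph::V(g)$name <- nests$node_id
    mst <- igraph::mst(g)
    el <- igraph::as_edgelist(mst)
    edges <- tibble(endpoint_a = el[, 1], endpoint_b = el[, 2])
    extra <- rbinom(n0, 1, cfg$extra_edge_prob) == 1
    for (i in which(extra)) {
      j <- sample(setdiff(seq_len(n0), i), 1)
      a <- sort(c(nests$node_id[i], nests$node_id[j]))
      if (!any(edges$endpoint_a == a[1] & edges$endpoint_b == a[2]) &&
          !any(edges$endpoint_a == a[2] & edges$endpoint_b == a[1])) {
        edges <- bind_rows(edges, tibble(endpoint_a = a[1],
                                         endpoint_b = a[2]))
      }
    }
  }

  # foraging: each nest may claim its nearest unclaimed tree
  claimed <- character(0)
  forage <- list()
  wants <- rbinom(n0, 1, cfg$forage_prob) == 1
  wants[1] <- TRUE  # the colony always forages somewhere
  for (i in seq_len(n0)[wants]) {
    free <- trees[!trees$node_id %in% claimed, , drop = FALSE]
    if (nrow(free) == 0L) break
    dd <- sqrt((free$x - nests$x[i])^2 + (free$y - nests$y[i])^2)
    k <- which.min(dd)
    claimed <- c(claimed, free$node_id[k])
    forage[[length(forage) + 1L]] <- tibble(endpoint_a = nests$node_id[i],
                                            endpoint_b = free$node_id[k])
  }
  forage <- if (length(forage)) bind_rows(forage) else
    tibble(endpoint_a = character(), endpoint_b = character())

  list(nests = nests, trees = trees,
       internest = edges, foraging = forage,
       counter = n0, trail_counter = 0L)
}

# materialise the current state as a colony_map, drawing fresh traffic
state_to_map <- function(state, cid, timepoint) {
  nests <- state$nests
  trees <- state$trees
  pop_of <- setNames(nests$population, nests$node_id)
  pos <- bind_rows(nests[, c("node_id", "x", "y")],
                   trees[, c("node_id", "x", "y")])
  seg_len <- function(a, b) {
    i <- match(a, pos$node_id); j <- match(b, pos$node_id)
    pmax(50, sqrt((pos$x[i] - pos$x[j])^2 + (pos$y[i] - pos$y[j])^2) * 100)
  }
  mk_trails <- function(ep, kind) {
    if (nrow(ep) == 0L) {
      return(tibble(trail_id = character(), endpoint_a = character(),
                    endpoint_b = character(), kind = character(),
                    length_cm = numeric(), sample_gap_cm = numeric()))
    }
    len <- seg_len(ep$endpoint_a, ep$endpoint_b)
    ref_pop <- if (kind == "internest") {
      (pop_of[ep$endpoint_a] + pop_of[ep$endpoint_b]) / 2
    } else {
      pop_of[ep$endpoint_a]
    }
    w <- rlnorm(nrow(ep), log(0.02), 0.7)
    total <- pmax(w * ref_pop, 1)
    tibble(trail_id = NA_character_,
           endpoint_a = ep$endpoint_a, endpoint_b = ep$endpoint_b,
           kind = kind, length_cm = unname(len),
           sample_gap_cm = unname(10 * len / total))
  }
  tr_i <- mk_trails(state$internest, "internest")
  tr_f <- mk_trails(state$foraging, "foraging")
  tr <- bind_rows(tr_i, tr_f)
  tr$trail_id <- paste0(cid, "_e", seq_len(nrow(tr)))
  nests$kind <- "nest"
  nests$mound_volume <- NA_real_
  nests$species <- NA_character_
  trees$kind <- "tree"
  trees$population <- NA_real_
  trees$mound_volume <- NA_real_
  trees$canopy_cover <- NA_real_
  nodes <- bind_rows(nests, trees)
  colony_map(nodes, tr, colony_id = cid, timepoint = timepoint)
}

# advance one interval: abandonment, re-connection, budding
step_colony <- function(state, betw, dbetw, cfg) {
  nests <- state$nests
  ledger <- list()

  lp_z <- if (nrow(nests) > 1 && sd(log(nests$population)) > 0) {
    as.numeric(scale(log(nests$population)))
  } else {
    rep(0, nrow(nests))
  }
  b <- unname(betw[nests$node_id]); b[is.na(b)] <- 0
  p_ab <- plogis(qlogis(cfg$baseline_abandonment_prob) +
                   cfg$beta_survival_betweenness * b +
                   cfg$beta_survival_size * lp_z)
  drop <- rbinom(nrow(nests), 1, p_ab) == 1
  if (all(drop)) drop[which.min(p_ab)] <- FALSE  # the colony persists
  for (i in which(drop)) {
    ledger[[length(ledger) + 1L]] <- tibble(
      node_id = nests$node_id[i], event = "abandoned",
      natal = NA_character_, prob = p_ab[i])
  }
  keep_ids <- nests$node_id[!drop]
  ghosts <- nests[drop, c("x", "y"), drop = FALSE]  # sites just abandoned
  state$nests <- nests[!drop, , drop = FALSE]
  state$internest <- state$internest |>
    filter(.data$endpoint_a %in% keep_ids, .data$endpoint_b %in% keep_ids)
  state$foraging <- state$foraging |>
    filter(.data$endpoint_a %in% keep_ids)

  # stochastic trail turnover where redundancy allows it
  if (nrow(state$internest) > 0 && nrow(state$nests) > 1) {
    for (k in rev(seq_len(nrow(state$internest)))) {
      if (runif(1) < cfg$trail_drop_prob &&
          still_connected(state, drop_edge = k)) {
        state$internest <- state$internest[-k, , drop = FALSE]
      }
    }
  }
  state <- reconnect(state)

  # budding by survivors
  bb <- unname(betw[state$nests$node_id]); bb[is.na(bb)] <- 0
  db <- unname(dbetw[state$nests$node_id]); db[is.na(db)] <- 0
  p_bud <- plogis(qlogis(cfg$baseline_budding_prob) +
                    cfg$beta_bud_betweenness * bb +
                    cfg$beta_bud_delta * db)
  buds <- which(rbinom(length(p_bud), 1, p_bud) == 1)
  for (i in buds) {
    natal <- state$nests$node_id[i]
    pt <- place_bud(state, i, cfg, ghosts = ghosts)
    if (is.null(pt)) next
    state$counter <- state$counter + 1L
    nid <- paste0(sub("_n.*$", "", natal), "_n", state$counter)
    state$nests <- bind_rows(state$nests, tibble(
      node_id = nid, x = pt[1], y = pt[2],
      population = rlnorm(1, cfg$population_meanlog - 1.5,
                          cfg$population_sdlog / 2),
      canopy_cover = runif(1)))
    state$internest <- bind_rows(state$internest,
                                 tibble(endpoint_a = natal,
                                        endpoint_b = nid))
    ledger[[length(ledger) + 1L]] <- tibble(
      node_id = nid, event = "founded", natal = natal, prob = p_bud[i])
  }

  # population drift
  state$nests$population <-
    state$nests$population * exp(rnorm(nrow(state$nests), 0,
                                       cfg$pop_drift_sdlog))

  ledger <- if (length(ledger)) bind_rows(ledger) else
    tibble(node_id = character(), event = character(),
           natal = character(), prob = numeric())
  list(state = state, ledger = ledger)
}

still_connected <- function(state, drop_edge) {
  el <- state$internest[-drop_edge, , drop = FALSE]
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = state$nests["node_id"])
  igraph::count_components(g) == 1L
}

# re-join disconnected internest components by their closest nest pair
reconnect <- function(state) {
  if (nrow(state$nests) < 2L) return(state)
  repeat {
    g <- igraph::graph_from_data_frame(state$internest, directed = FALSE,
                                       vertices = state$nests["node_id"])
    comp <- igraph::components(g)
    if (comp$no == 1L) return(state)
    m1 <- names(comp$membership)[comp$membership == 1]
    m2 <- names(comp$membership)[comp$membership != 1]
    best <- NULL; bd <- Inf
    for (a in m1) for (b in m2) {
      i <- match(a, state$nests$node_id); j <- match(b, state$nests$node_id)
      dd <- sqrt((state$nests$x[i] - state$nests$x[j])^2 +
                   (state$nests$y[i] - state$nests$y[j])^2)
      if (dd < bd) { bd <- dd; best <- c(a, b) }
    }
    state$internest <- bind_rows(state$internest,
                                 tibble(endpoint_a = best[1],
                                        endpoint_b = best[2]))
  }
}

# place a budded nest 3-8 m from its natal nest, clear of every other
# nest and of sites abandoned this interval (so spatial identity linkage
# cannot confuse a new nest with an old one)
place_bud <- function(state, i, cfg, ghosts = NULL, min_clear = 2.5,
                      tries = 30) {
  x0 <- state$nests$x[i]; y0 <- state$nests$y[i]
  for (k in seq_len(tries)) {
    ang <- runif(1, 0, 2 * pi)
    r <- runif(1, 3, 8)
    x <- x0 + r * cos(ang); y <- y0 + r * sin(ang)
    d <- sqrt((state$nests$x - x)^2 + (state$nests$y - y)^2)
    dg <- if (!is.null(ghosts) && nrow(ghosts)) {
      sqrt((ghosts$x - x)^2 + (ghosts$y - y)^2)
    } else {
      Inf
    }
    d_natal <- d[i]
    if (all(d >= min_clear) && all(dg >= min_clear) &&
        d_natal == min(d)) {
      return(c(x, y))
    }
  }
  NULL
}
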