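test_that("colony_map derives traffic and weight from field measures", {
  m <- fix_chain()
  # sample_gap 10 * length / total => ants_per_cm = total / length
  expect_equal(m$trails$ants_per_cm, rep(0.5, 4))
  expect_equal(m$trails$total_ants, rep(500, 4))
  # internest: total / mean(pop_a, pop_b); foraging: total / nest pop
  expect_equal(m$trails$weight, rep(0.5, 4))
  expect_false(m$degenerate)
})

test_that("trail weight uses the right reference population", {
  nodes <- tibble::tibble(
    node_id = c("a", "b", "t"), kind = c("nest", "nest", "tree"),
    x = c(0, 10, 20), y = 0, population = c(1000, 3000, NA))
  trails <- dplyr::bind_rows(
    trail_row("e1", "a", "b", "internest", 1000, 400),
    trail_row("f1", "b", "t", "foraging", 1000, 600))
  m <- colony_map(nodes, trails, "w", "2012-summer")
  expect_equal(m$trails$weight[1], 400 / 2000)  # mean(1000, 3000)
  expect_equal(m$trails$weight[2], 600 / 3000)  # the foraging nest
})

test_that("total_ants is invariant to where along the trail you sample", {
  # the same trail described with double gap and double length keeps
  # density x length consistent: only the ratio matters
  t1 <- compute_trail_traffic(sample_gap_cm = 20, length_cm = 1000)
  t2 <- compute_trail_traffic(sample_gap_cm = 40, length_cm = 2000)
  expect_equal(t1$total_ants, t2$total_ants)
  expect_equal(t2$ants_per_cm, t1$ants_per_cm / 2)
})

test_that("colony_map validates its invariants", {
  m <- fix_chain()
  nodes <- m$nodes; trails <- m$trails[, 1:6]

  dup <- dplyr::bind_rows(nodes, nodes[2, ])
  expect_error(colony_map(dup, trails, "x", "2012-summer"), "duplicate")

  treep <- nodes; treep$population[treep$node_id == "T1"] <- 5
  expect_error(colony_map(treep, trails, "x", "2012-summer"),
               "trees cannot carry")

  ghost <- trails; ghost$endpoint_b[1] <- "nowhere"
  expect_error(colony_map(nodes, ghost, "x", "2012-summer"),
               "unknown node")

  # foraging trail between two nests / internest trail to a tree
  wrongk <- trails; wrongk$kind[2] <- "foraging"
  expect_error(colony_map(nodes, wrongk, "x", "2012-summer"),
               "inconsistent with endpoints")
  wrongk2 <- trails; wrongk2$kind[1] <- "internest"
  expect_error(colony_map(nodes, wrongk2, "x", "2012-summer"),
               "inconsistent with endpoints")

  twotrees <- dplyr::bind_rows(
    trails, trail_row("bad", "T1", "T2", "foraging", 100, 10))
  expect_error(colony_map(nodes, twotrees, "x", "2012-summer"),
               "two trees")

  neg <- trails; neg$length_cm[1] <- -5
  expect_error(colony_map(nodes, neg, "x", "2012-summer"), "> 0")

  badpop <- nodes; badpop$population[badpop$node_id == "A"] <- -1
  expect_error(colony_map(nodes |> dplyr::mutate(
    population = replace(population, node_id == "A", -1)),
    trails, "x", "2012-summer"), ">= 0")

  badcc <- nodes; badcc$canopy_cover <- ifelse(badcc$kind == "nest", 1.4, NA)
  expect_error(colony_map(badcc, trails, "x", "2012-summer"), "\\[0, 1\\]")

  expect_error(colony_map(nodes, trails, "x", "summer-2012"))
})

test_that("weight is undefined without a positive population", {
  nodes <- tibble::tibble(
    node_id = c("a", "b"), kind = "nest", x = c(0, 10), y = 0,
    population = c(1000, NA))
  trails <- trail_row("e1", "a", "b", "internest", 1000, 400)
  expect_error(colony_map(nodes, trails, "x", "2012-summer"),
               "positive population")
})

test_that("populations fill in from mound volume only via a calibration", {
  nodes <- tibble::tibble(
    node_id = c("a", "b"), kind = "nest", x = c(0, 10), y = 0,
    population = c(1000, NA), mound_volume = c(NA, 120))
  trails <- trail_row("e1", "a", "b", "internest", 1000, 300)
  calib <- function(v) 40 * v
  m <- colony_map(nodes, trails, "x", "2012-summer", calibration = calib)
  expect_equal(m$nodes$population[2], 4800)
  expect_error(colony_map(nodes, trails, "x", "2012-summer"),
               "calibration")
  expect_error(population_from_volume(120, NULL), "calibration")
  expect_error(population_from_volume(-2, calib), "> 0")
})

test_that("degenerate maps (not polydomous) are flagged, not rejected", {
  m <- fix_star()
  expect_true(m$degenerate)
  expect_output(print(m), "degenerate")
  expect_output(print(fix_chain()), "3 nests, 2 trees, 4 trails")
})

test_that("as_colony_graph carries nodes, edges and attributes", {
  m <- fix_diamond()
  g <- as_colony_graph(m)
  expect_equal(igraph::vcount(g), nrow(m$nodes))
  expect_equal(igraph::ecount(g), nrow(m$trails))
  expect_setequal(igraph::V(g)$name, m$nodes$node_id)
  expect_equal(sort(igraph::E(g)$weight), sort(m$trails$weight))
})

test_that("timepoint labels order chronologically with spring < summer", {
  tps <- c("2013-summer", "2012-summer", "2013-spring")
  expect_equal(tps[order(vapply(tps, timepoint_key, 1))],
               c("2012-summer", "2013-spring", "2013-summer"))
  expect_equal(timepoint_season("2013-spring"), "spring")
  expect_error(timepoint_key("2013-winter"))
})
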