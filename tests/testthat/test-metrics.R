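test_that("chain betweenness matches the hand calculation", {
  flow <- flow_betweenness(fix_chain())
  got <- setNames(flow$betweenness, flow$node_id)
  expect_equal(got[c("A", "B", "C")], c(A = 3, B = 4, C = 3))
  expect_equal(got[c("T1", "T2")], c(T1 = 0, T2 = 0))
  norm <- setNames(flow$norm_betweenness, flow$node_id)
  expect_equal(norm[c("A", "B", "C")], c(A = 0.75, B = 1, C = 0.75))
})

test_that("a hub nest normalises to 1 and trees are always 0", {
  flow <- flow_betweenness(fix_star())
  expect_equal(flow$norm_betweenness[flow$node_id == "hub"], 1)
  expect_equal(flow$betweenness[flow$node_id == "hub"], 3)
  expect_true(all(flow$betweenness[flow$kind == "tree"] == 0))
})

test_that("tied shortest paths split credit fractionally", {
  # diamond n1-n2-n4 and n1-n3-n4 with equal weights: n2 and n3 each
  # carry half of every path between the two sides
  flow <- flow_betweenness(fix_diamond())
  got <- setNames(flow$betweenness, flow$node_id)
  expect_equal(got[["n2"]], got[["n3"]])
  expect_equal(got[["n2"]] %% 0.5, 0)
  oracle <- oracle_betweenness(fix_diamond())
  expect_equal(got[names(oracle)], oracle)
})

test_that("betweenness is invariant to rescaling all weights", {
  m <- fix_diamond()
  m2 <- m
  m2$trails$sample_gap_cm <- m$trails$sample_gap_cm / 2  # doubles traffic
  m2 <- colony_map(m2$nodes, m2$trails[, 1:6], m$colony_id, m$timepoint)
  expect_equal(m2$trails$weight, 2 * m$trails$weight)
  expect_equal(flow_betweenness(m2)$norm_betweenness,
               flow_betweenness(m)$norm_betweenness)
})

test_that("zero-weight trails are excluded with a message", {
  m <- fix_chain()
  tr <- m$trails[, 1:6]
  m2 <- colony_map(m$nodes, tr, "chain", "2012-summer")
  m2$trails$weight[2] <- 0  # A-B carries no flow
  expect_message(flow <- flow_betweenness(m2), "zero-weight")
  got <- setNames(flow$betweenness, flow$node_id)
  # with A-B cut, only C connects B and T2 to the rest
  expect_equal(got[["A"]], 0)
  expect_equal(got[["C"]], 1)
})

test_that("disconnected maps warn and score within components", {
  n <- tibble::tibble(
    node_id = c("a", "b", "c", "d"), kind = "nest",
    x = c(0, 10, 100, 110), y = 0, population = 1000)
  tr <- dplyr::bind_rows(
    trail_row("e1", "a", "b", "internest", 1000, 300),
    trail_row("e2", "c", "d", "internest", 1000, 300))
  m <- colony_map(n, tr, "split", "2012-summer")
  expect_warning(flow <- flow_betweenness(m), "disconnected")
  expect_true(all(flow$betweenness == 0))
})

test_that("an all-zero map normalises to zero, not NaN", {
  flow <- suppressWarnings(flow_betweenness(fix_star()))
  # the only nest has betweenness 3 here; build a truly flowless map
  n <- tibble::tibble(node_id = c("a", "b"), kind = "nest",
                      x = c(0, 10), y = 0, population = 1000)
  tr <- trail_row("e1", "a", "b", "internest", 1000, 300)
  m <- colony_map(n, tr, "duo", "2012-summer")
  f2 <- flow_betweenness(m)
  expect_equal(f2$norm_betweenness, c(0, 0))
  expect_false(any(is.nan(f2$norm_betweenness)))
})

test_that("flow categories use the published bounds", {
  x <- c(0, 1e-6, 0.2499, 0.25, 0.5, 0.75, 0.7501, 0.9999, 1)
  got <- as.character(categorize_flow(x))
  expect_equal(got, c("zero", "low", "low", "medium", "medium", "medium",
                      "high", "high", "one"))
  expect_error(categorize_flow(1.2), "\\[0, 1\\]")
  expect_error(categorize_flow(-0.1), "\\[0, 1\\]")
})

test_that("foraging effort and worker:forager ratio", {
  m <- fix_chain()
  # two foraging trails, each 0.5 ants/cm x 1000 cm
  expect_equal(colony_foraging_effort(m), 1000)
  expect_equal(worker_forager_ratio(m), 3000 / 1000)
  # no foraging trails: effort 0 with a warning, ratio undefined
  n <- tibble::tibble(node_id = c("a", "b"), kind = "nest",
                      x = c(0, 10), y = 0, population = 1000)
  tr <- trail_row("e1", "a", "b", "internest", 1000, 300)
  m2 <- colony_map(n, tr, "duo", "2012-summer")
  expect_warning(e <- colony_foraging_effort(m2), "no foraging")
  expect_equal(e, 0)
  expect_error(worker_forager_ratio(m2), "undefined")
})

test_that("nest-tree distance is the straight-line minimum", {
  m <- fix_chain()
  d <- nest_tree_distance(m)
  expect_equal(d$tree_distance_m[d$node_id == "A"], 10)
  expect_equal(d$tree_distance_m[d$node_id == "B"], 20)
})

test_that("colony_metrics assembles one row per nest", {
  m <- fix_chain()
  met <- colony_metrics(m)
  expect_equal(nrow(met), 3)
  expect_setequal(met$node_id, c("A", "B", "C"))
  expect_equal(met$wf_ratio, rep(3, 3))
  expect_equal(met$norm_betweenness[met$node_id == "B"], 1)
  expect_false(any(met$degenerate))
  expect_true(all(c("colony_id", "timepoint", "population",
                    "canopy_cover", "tree_distance_m",
                    "flow_category") %in% names(met)))
})

test_that("min_endpoint_betweenness takes the lower endpoint", {
  m <- fix_chain()
  flow <- flow_betweenness(m)
  tr <- m$trails[m$trails$kind == "internest", ][1, ]  # A-B
  expect_equal(min_endpoint_betweenness(tr, flow), 0.75)
  f_tr <- m$trails[m$trails$kind == "foraging", ][1, ]
  expect_error(min_endpoint_betweenness(f_tr, flow), "internest")
})

test_that("property: normalised betweenness lies in [0, 1] with max 1", {
  for (seed in 1:8) {
    m <- fix_random_map(seed)
    flow <- suppressWarnings(suppressMessages(flow_betweenness(m)))
    expect_true(all(flow$norm_betweenness >= 0 &
                      flow$norm_betweenness <= 1))
    nn <- flow$norm_betweenness[flow$kind == "nest"]
    expect_true(max(nn) %in% c(0, 1))
    expect_true(all(flow$betweenness[flow$kind == "tree"] == 0))
  }
})
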