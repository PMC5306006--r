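# Independent oracles. These deliberately avoid the package's own
# machinery (and igraph): betweenness by exhaustive simple-path
# enumeration, the Cox partial likelihood by direct evaluation on a grid.

# Brute-force weighted betweenness with endpoints excluded, each
# unordered pair counted once, tied shortest paths splitting credit
# fractionally. Edge cost = 1 / weight; zero-weight trails carry no flow.
# Only feasible for small maps (<= ~8 nodes).
oracle_betweenness <- function(map, tol = 1e-9) {
  nodes <- map$nodes$node_id
  tr <- map$trails[map$trails$weight > 0, , drop = FALSE]
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(tr))) {
    a <- tr$endpoint_a[i]; b <- tr$endpoint_b[i]
    cost <- 1 / tr$weight[i]
    adj[[a]] <- rbind(adj[[a]], data.frame(to = b, cost = cost))
    adj[[b]] <- rbind(adj[[b]], data.frame(to = a, cost = cost))
  }
  all_paths <- function(from, to) {
    out <- list()
    walk <- function(path, cost) {
      last <- path[length(path)]
      if (last == to) {
        out[[length(out) + 1L]] <<- list(path = path, cost = cost)
        return()
      }
      nb <- adj[[last]]
      if (is.null(nb)) return()
      for (k in seq_len(nrow(nb))) {
        if (!nb$to[k] %in% path) {
          walk(c(path, nb$to[k]), cost + nb$cost[k])
        }
      }
    }
    walk(from, 0)
    out
  }
  score <- setNames(numeric(length(nodes)), nodes)
  pairs <- utils::combn(nodes, 2)
  for (p in seq_len(ncol(pairs))) {
    paths <- all_paths(pairs[1, p], pairs[2, p])
    if (length(paths) == 0L) next
    costs <- vapply(paths, `[[`, 0, "cost")
    best <- paths[costs <= min(costs) + tol]
    for (bp in best) {
      interior <- bp$path[-c(1, length(bp$path))]
      score[interior] <- score[interior] + 1 / length(best)
    }
  }
  score
}

# normalise raw scores the way the package defines it: divide by the
# largest nest value; all-zero maps stay zero
oracle_normalise <- function(raw, map) {
  is_nest <- map$nodes$kind == "nest"
  mx <- if (any(is_nest)) max(raw[map$nodes$node_id[is_nest]]) else 0
  if (mx > 0) raw / mx else raw * 0
}

# Cox partial log-likelihood (Breslow ties) for a single covariate on
# right-censored data (start = 0), evaluated directly from its formula
oracle_cox_loglik <- function(beta, time, status, x) {
  eta <- beta * x
  ll <- 0
  for (i in which(status == 1)) {
    at_risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[at_risk])))
  }
  ll
}

# grid-search maximiser of the partial likelihood
oracle_cox_grid <- function(time, status, x,
                            grid = seq(-5, 5, by = 0.001)) {
  ll <- vapply(grid, oracle_cox_loglik, 0, time = time, status = status,
               x = x)
  grid[which.max(ll)]
}
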