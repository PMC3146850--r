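# Independent oracles used to cross-check the package's graph and test
# machinery. These deliberately use different algorithms from the
# implementation (matrix Floyd-Warshall, exhaustive simple-path
# enumeration, explicit rank formulas, full permutation enumeration).

# dense all-pairs shortest paths by Floyd-Warshall on the adjacency matrix
oracle_floyd_warshall <- function(network) {
  ids <- network$nodes$node_id
  n <- length(ids)
  D <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(D) <- 0
  for (k in seq_len(nrow(network$edges))) {
    i <- network$edges$from[[k]]
    j <- network$edges$to[[k]]
    D[i, j] <- 1
    D[j, i] <- 1
  }
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

# adjacency-list form used by the path enumerator
adj_list <- function(network) {
  ids <- network$nodes$node_id
  adj <- setNames(vector("list", length(ids)), ids)
  for (k in seq_len(nrow(network$edges))) {
    i <- network$edges$from[[k]]
    j <- network$edges$to[[k]]
    adj[[i]] <- union(adj[[i]], j)
    adj[[j]] <- union(adj[[j]], i)
  }
  adj
}

# every simple path between two nodes, by depth-first enumeration
all_simple_paths_between <- function(adj, s, t) {
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == t) {
      out[[length(out) + 1]] <<- path
      return(invisible())
    }
    for (nb in adj[[last]]) {
      if (!nb %in% path) walk(c(path, nb))
    }
  }
  walk(s)
  out
}

# raw betweenness by exhaustive shortest-path enumeration, then divided by
# the maximum nodal value (0 when no node is interior to any geodesic)
oracle_betweenness <- function(network) {
  ids <- network$nodes$node_id
  adj <- adj_list(network)
  b <- setNames(numeric(length(ids)), ids)
  pairs <- utils::combn(ids, 2, simplify = FALSE)
  for (st in pairs) {
    paths <- all_simple_paths_between(adj, st[1], st[2])
    lens <- vapply(paths, length, integer(1))
    geodesics <- paths[lens == min(lens)]
    for (p in geodesics) {
      interior <- setdiff(p, st)
      b[interior] <- b[interior] + 1 / length(geodesics)
    }
  }
  if (max(b) > 0) b <- b / max(b)
  b
}

# clustering coefficient by explicit triangle counting
oracle_clustering <- function(network) {
  ids <- network$nodes$node_id
  adj <- adj_list(network)
  vapply(ids, function(i) {
    nb <- adj[[i]]
    k <- length(nb)
    if (k < 2) return(0)
    m <- 0
    for (pair in utils::combn(nb, 2, simplify = FALSE)) {
      if (pair[2] %in% adj[[pair[1]]]) m <- m + 1
    }
    2 * m / (k * (k - 1))
  }, numeric(1))
}

# tie-corrected Kruskal-Wallis H computed directly from the rank formula
oracle_kw_H <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(x) sum(x)^2 / length(x))) - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# exact permutation p-value for the Kruskal-Wallis test, two groups:
# enumerate every assignment of the pooled values to the group sizes
oracle_kw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  N <- length(pooled)
  H_obs <- oracle_kw_H(pooled, rep(c("a", "b"), c(length(a), length(b))))
  picks <- utils::combn(N, length(a), simplify = FALSE)
  hs <- vapply(picks, function(idx) {
    g <- rep("b", N)
    g[idx] <- "a"
    oracle_kw_H(pooled, g)
  }, numeric(1))
  mean(hs >= H_obs - 1e-12)
}

# exact two-sided rank-sum p-value by enumerating group assignments
oracle_wilcoxon_exact_p <- function(a, b) {
  pooled <- c(a, b)
  N <- length(pooled)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(a)])
  mu <- length(a) * (N + 1) / 2
  picks <- utils::combn(N, length(a), simplify = FALSE)
  ws <- vapply(picks, function(idx) sum(r[idx]), numeric(1))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# random connected undirected graph as a reaction_network: random spanning
# tree plus Bernoulli extra edges
random_connected_network <- function(n, extra_p = 0.08) {
  ids <- sprintf("n%02d", seq_len(n))
  from <- integer(0)
  to <- integer(0)
  for (t in 2:n) {
    from <- c(from, sample.int(t - 1, 1))
    to <- c(to, t)
  }
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < extra_p) {
        from <- c(from, i)
        to <- c(to, j)
      }
    }
  }
  a <- ids[pmin(from, to)]
  b <- ids[pmax(from, to)]
  edges <- unique(tibble::tibble(from = a, to = b))
  reaction_network(tibble::tibble(node_id = ids), edges, directed = FALSE)
}
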