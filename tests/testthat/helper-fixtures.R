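# Small in-code fixtures shared across test files.

# 2x2 planar lattice map with unit spacing
tiny_map <- function(adjacency = NULL) {
  area_map(c("a", "b", "c", "d"),
           rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)),
           adjacency = adjacency)
}

# path graph a - b - c
path_map <- function() {
  area_map(c("a", "b", "c"), rbind(c(0, 0), c(1, 0), c(2, 0)),
           adjacency = rbind(c("a", "b"), c("b", "c")))
}

# single-region map (weights all 1 at distance 0) with n observations
one_region_table <- function(n = 40, p = 2, beta = NULL, sigma = 1,
                             seed = 1) {
  set.seed(seed)
  if (is.null(beta)) beta <- seq_len(p)
  X <- matrix(rnorm(n * p), n, p)
  y <- as.vector(X %*% beta) + rnorm(n, 0, sigma)
  map <- area_map("r1", matrix(c(0, 0), 1, 2))
  list(map = map,
       table = observation_table(y, X, rep("r1", n), map),
       beta = beta, X = X, y = y)
}

# brute-force haversine oracle (independent of geosphere)
haversine_oracle <- function(lon1, lat1, lon2, lat2, r = 6371) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * r * asin(min(1, sqrt(a)))
}

# breadth-first-search hop-count oracle over an edge list
bfs_oracle <- function(ids, edges, from, to) {
  nbr <- lapply(ids, function(i) {
    unique(c(edges[edges[, 1] == i, 2], edges[edges[, 2] == i, 1]))
  })
  names(nbr) <- ids
  dist <- stats::setNames(rep(Inf, length(ids)), ids)
  dist[from] <- 0
  frontier <- from
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) {
      for (u in nbr[[v]]) {
        if (is.infinite(dist[u])) {
          dist[u] <- dist[v] + 1
          nxt <- c(nxt, u)
        }
      }
    }
    frontier <- nxt
  }
  dist[to]
}

# O(n^2) pair-enumeration Rand index oracle
rand_oracle <- function(a, b) {
  n <- length(a)
  agree <- 0
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + 1
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a == same_b) agree <- agree + 1
    }
  }
  agree / tot
}
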