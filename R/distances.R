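#' Pairwise region distance matrix
#'
#' Computes the symmetric, zero-diagonal matrix of distances between region
#' centroids under one of three metrics: Euclidean (planar units),
#' great-circle distance (haversine, mean Earth radius 6371 km, result in
#' km), or graph distance (unweighted shortest-path hop count over the
#' adjacency structure).
#'
#' @param map An [area_map()].
#' @param metric One of `"euclidean"`, `"gcd"`, `"graph"`.
#' @param rescale_max If not `NULL`, the matrix is rescaled so its maximum
#'   entry equals this value (distances enter the model only relative to the
#'   kernel bandwidth, so a global rescale fixes the scale the bandwidth
#'   prior refers to).
#' @return A square numeric matrix with `metric` and any rescale factor
#'   attached as attributes; dimnames are the region ids.
#' @export
distance_matrix <- function(map, metric = c("euclidean", "gcd", "graph"),
                            rescale_max = NULL) {
  stopifnot(inherits(map, "area_map"))
  metric <- match.arg(metric)
  S <- n_regions(map)
  d <- switch(metric,
    euclidean = as.matrix(stats::dist(map$centroids)),
    gcd = {
      if (map$coordinate_system != "lonlat") {
        stop("great-circle distance requires lonlat coordinates")
      }
      m <- matrix(0, S, S)
      for (i in seq_len(S)) {
        # haversine on a sphere of mean radius 6371 km
        m[i, ] <- geosphere::distHaversine(map$centroids[i, , drop = FALSE],
                                           map$centroids, r = 6371) # km
      }
      m <- (m + t(m)) / 2   # enforce exact symmetry
      diag(m) <- 0
      m
    },
    graph = {
      if (is.null(map$adjacency)) {
        stop("graph distance requires an adjacency edge list")
      }
      g <- igraph::graph_from_data_frame(map$adjacency, directed = FALSE,
                                         vertices = map$region_ids)
      m <- igraph::distances(g)
      m <- m[map$region_ids, map$region_ids]
      if (any(!is.finite(m))) {
        bad <- which(!is.finite(m), arr.ind = TRUE)
        bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
        pairs <- apply(utils::head(bad, 5), 1, function(ij) {
          paste(map$region_ids[ij[1]], map$region_ids[ij[2]], sep = " <-> ")
        })
        stop("map is disconnected; unreachable region pairs include: ",
             paste(pairs, collapse = ", "))
      }
      m
    })
  dimnames(d) <- list(map$region_ids, map$region_ids)
  if (!is.null(rescale_max)) {
    stopifnot(rescale_max > 0)
    mx <- max(d)
    if (mx > 0) d <- d * (rescale_max / mx)
  }
  attr(d, "metric") <- metric
  d
}
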