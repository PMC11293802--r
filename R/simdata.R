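#' Synthetic areal study without spatially varying coefficients
#'
#' Emulates the 64-region design: centroids on a regular lattice rescaled so
#' the maximum pairwise distance is 10, three observations per region with
#' i.i.d. standard-normal covariates, and `y = X beta + eps` with
#' `eps ~ N(0, noise_sd^2)`. The true coefficient field is constant across
#' regions (no spatial variation), which is what recovery of a single
#' coefficient vector tests.
#'
#' @param seed Integer seed.
#' @param n_regions Number of regions (perfect square for the default
#'   lattice, or supply `centroids`).
#' @param obs_per_region Observations generated in each region.
#' @param beta True coefficient vector (defines the number of covariates).
#' @param noise_sd Noise standard deviation.
#' @param max_distance Rescale target for the maximum pairwise distance.
#' @param centroids Optional explicit region centroids (n_regions x 2).
#' @return A `synthetic_study`: `map`, `table`, `true_beta` (S x p),
#'   `true_clusters = NULL`, `setting = "louisiana_like"`, `seed`.
#' @export
louisiana_like <- function(seed = 1L, n_regions = 64, obs_per_region = 3,
                           beta = c(2, 0, 0, 4, 8), noise_sd = 1,
                           max_distance = 10, centroids = NULL) {
  if (is.null(centroids)) {
    side <- sqrt(n_regions)
    if (side != round(side)) {
      stop("n_regions must be a perfect square for the default lattice ",
           "(or supply centroids)")
    }
    centroids <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side)))
  }
  stopifnot(nrow(centroids) == n_regions)
  # rescale so the maximum pairwise distance equals max_distance
  mx <- max(stats::dist(centroids))
  centroids <- centroids * (max_distance / mx)
  map <- area_map(sprintf("R%03d", seq_len(n_regions)), centroids)

  set.seed(seed)
  p <- length(beta)
  n <- n_regions * obs_per_region
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("X", seq_len(p))))
  y <- as.vector(X %*% beta) + stats::rnorm(n, 0, noise_sd)
  obs_region <- rep(map$region_ids, each = obs_per_region)
  table <- observation_table(y, X, obs_region, map)

  true_beta <- matrix(beta, n_regions, p, byrow = TRUE,
                      dimnames = list(map$region_ids, colnames(X)))
  structure(list(map = map, table = table, true_beta = true_beta,
                 true_clusters = NULL, setting = "louisiana_like",
                 seed = as.integer(seed),
                 generator = list(n_regions = n_regions,
                                  obs_per_region = obs_per_region,
                                  beta = beta, noise_sd = noise_sd,
                                  max_distance = max_distance)),
            class = "synthetic_study")
}

# Table of per-cluster true coefficient vectors (beta_1..beta_6) for the
# three signal-strength settings of the spatially varying design.
georgia_truth <- list(
  `1` = rbind(c(1, 0,  1, 0, 0.5, 2),
              c(1, 0.7, 0.3, 2, 0, 3),
              c(2, 1, 0.8, 1, 0, 1)),
  `2` = rbind(c(2, 0, 1, 0, 4, 2),
              c(1, 0, 3, 2, 0, 3),
              c(4, 1, 0, 3, 0, 1)),
  `3` = rbind(c(9, 0, -4, 0, 2, 5),
              c(1, 7, 3, 6, 0, -1),
              c(2, 0, 6, 1, 7, 0)))

#' Synthetic areal study with spatially varying (clustered) coefficients
#'
#' Emulates the 159-region design: a jittered lattice of centroids
#' partitioned into three contiguous blocks of sizes 51/49/59 (regions
#' sorted by first, then second coordinate), six spatially correlated
#' covariates drawn from a zero-mean Gaussian process with covariance
#' `exp(-(d/phi)^2)` over the region distance matrix, and one observation
#' per region generated as `y(s) = beta0 + sum_k beta_k(s) X_k(s) + eps`,
#' `eps ~ N(0, 1)`, `beta0 = 0`. Coefficients are cluster-constant, taken
#' from the per-setting truth table (three signal-strength settings).
#'
#' @param setting Signal-strength setting, 1, 2 or 3.
#' @param seed Integer seed.
#' @param n_regions Number of regions.
#' @param phi Gaussian-process range of the covariate fields, in lattice
#'   units; default 1 (neighbouring regions correlate at exp(-1), so the
#'   fields are clearly spatially autocorrelated while keeping enough local
#'   variation that the local coefficients remain identifiable from one
#'   observation per region).
#' @param noise_sd Observation noise standard deviation.
#' @param cluster_sizes Sizes of the three contiguous coefficient clusters.
#' @param smooth_within If `TRUE`, superimposes a small smooth
#'   within-cluster perturbation on the coefficient field (off by default:
#'   the partition defines the truth).
#' @return A `synthetic_study`; `table$X` carries an intercept column plus
#'   the six covariates, `true_beta` is the S x 7 field (intercept column
#'   zero), `true_clusters` the length-S label vector.
#' @export
georgia_like <- function(setting = 3, seed = 1L, n_regions = 159, phi = 1,
                         noise_sd = 1, cluster_sizes = c(51, 49, 59),
                         smooth_within = FALSE) {
  setting <- as.character(setting)
  if (!setting %in% names(georgia_truth)) {
    stop("setting must be 1, 2 or 3")
  }
  stopifnot(sum(cluster_sizes) == n_regions)
  set.seed(seed)

  # jittered lattice of centroids
  side <- ceiling(sqrt(n_regions))
  grid <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side)))
  grid <- grid[seq_len(n_regions), , drop = FALSE]
  centroids <- grid + matrix(stats::runif(2 * n_regions, -0.3, 0.3),
                             n_regions, 2)
  map <- area_map(sprintf("G%03d", seq_len(n_regions)), centroids)
  dmat <- distance_matrix(map, "euclidean")
  if (is.null(phi)) phi <- 1

  # three contiguous blocks by sorted first-then-second coordinate
  ord <- order(centroids[, 1], centroids[, 2])
  true_clusters <- integer(n_regions)
  true_clusters[ord] <- rep(seq_along(cluster_sizes), times = cluster_sizes)

  # spatially correlated covariates: GP with squared-exponential covariance
  K <- exp(-(dmat / phi)^2)
  L <- t(chol(K + diag(1e-8, n_regions)))
  Xc <- L %*% matrix(stats::rnorm(n_regions * 6), n_regions, 6)
  colnames(Xc) <- paste0("X", 1:6)

  truth <- georgia_truth[[setting]]
  true_beta <- cbind(`(Intercept)` = 0,
                     truth[true_clusters, , drop = FALSE])
  colnames(true_beta)[-1] <- colnames(Xc)
  if (smooth_within) {
    pert <- L %*% matrix(stats::rnorm(n_regions * 6, sd = 0.1), n_regions, 6)
    true_beta[, -1] <- true_beta[, -1] + pert
  }
  rownames(true_beta) <- map$region_ids

  X <- cbind(`(Intercept)` = 1, Xc)
  y <- rowSums(X * true_beta) + stats::rnorm(n_regions, 0, noise_sd)
  table <- observation_table(y, X, map$region_ids, map)

  structure(list(map = map, table = table, true_beta = true_beta,
                 true_clusters = true_clusters,
                 setting = paste0("georgia_like_", setting),
                 seed = as.integer(seed),
                 generator = list(setting = as.integer(setting),
                                  n_regions = n_regions, phi = phi,
                                  noise_sd = noise_sd,
                                  cluster_sizes = cluster_sizes,
                                  smooth_within = smooth_within)),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic_study [%s]: %d regions, %d observations, %d covariates (seed %d)\n",
              x$setting, length(x$map$region_ids), length(x$table$y),
              ncol(x$table$X), x$seed))
  if (!is.null(x$true_clusters)) {
    cat(sprintf("  true clusters: sizes %s\n",
                paste(table(x$true_clusters), collapse = "/")))
  }
  invisible(x)
}

#' Impute missing values from contiguous neighbours
#'
#' Continuous variables are replaced by the mean of the non-missing
#' contiguous neighbours; categorical (factor/character) variables by the
#' neighbours' highest-frequency category (ties to the first level).
#' Regions with no neighbours at all are dropped with a warning.
#'
#' @param data Data frame with a `region_id` column; one row per region.
#' @param map An [area_map()] with adjacency.
#' @return The data frame with missing values filled and island rows
#'   dropped; the number of dropped regions is attached as
#'   `attr(, "dropped")`.
#' @export
impute_by_neighbors <- function(data, map) {
  stopifnot(inherits(map, "area_map"), "region_id" %in% names(data))
  if (is.null(map$adjacency)) stop("map has no adjacency structure")
  adj <- map$adjacency
  nbrs <- function(id) unique(c(adj$to[adj$from == id], adj$from[adj$to == id]))

  ids <- as.character(data$region_id)
  islands <- ids[vapply(ids, function(id) length(nbrs(id)) == 0, logical(1))]
  has_na <- vapply(seq_len(nrow(data)),
                   function(i) anyNA(data[i, names(data) != "region_id"]),
                   logical(1))
  drop <- ids %in% islands & has_na
  if (any(drop)) {
    warning(sum(drop), " region(s) with no neighbours could not be imputed ",
            "and were dropped: ", paste(ids[drop], collapse = ", "))
    data <- data[!drop, , drop = FALSE]
    ids <- ids[!drop]
  }

  for (col in setdiff(names(data), "region_id")) {
    v <- data[[col]]
    miss <- which(is.na(v))
    for (i in miss) {
      nb <- intersect(nbrs(ids[i]), ids)
      nv <- v[match(nb, ids)]
      nv <- nv[!is.na(nv)]
      if (!length(nv)) {
        stop("region ", ids[i], ": all neighbours missing for '", col, "'")
      }
      data[i, col] <- if (is.numeric(v)) mean(nv) else names(sort(-table(nv)))[1]
    }
  }
  rownames(data) <- NULL
  attr(data, "dropped") <- sum(drop)
  data
}
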