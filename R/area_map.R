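#' Construct an areal map of regions
#'
#' An `area_map` is the geometry substrate for all distance and weight
#' computations: a set of uniquely identified regions, one centroid per
#' region, and an optional symmetric adjacency (contiguity) structure.
#'
#' @param region_ids Character or integer vector of unique region identifiers.
#' @param centroids Numeric matrix or data frame with one row per region and
#'   two columns (x/y for planar coordinates, lon/lat in decimal degrees for
#'   `coordinate_system = "lonlat"`).
#' @param coordinate_system Either `"planar"` or `"lonlat"`.
#' @param adjacency Optional two-column matrix or data frame of edges between
#'   region ids. Edges are undirected; self-edges are rejected.
#'
#' @return An object of class `area_map` with elements `region_ids`,
#'   `centroids` (matrix, rownames = region ids), `coordinate_system` and
#'   `adjacency` (a symmetric edge data frame or `NULL`).
#' @export
area_map <- function(region_ids, centroids,
                     coordinate_system = c("planar", "lonlat"),
                     adjacency = NULL) {
  coordinate_system <- match.arg(coordinate_system)
  region_ids <- as.character(region_ids)
  if (anyDuplicated(region_ids)) {
    stop("region ids must be unique; duplicated: ",
         paste(unique(region_ids[duplicated(region_ids)]), collapse = ", "))
  }
  centroids <- as.matrix(centroids)
  if (!is.numeric(centroids) || ncol(centroids) != 2L) {
    stop("centroids must be a numeric matrix with two columns")
  }
  if (nrow(centroids) != length(region_ids)) {
    stop("need exactly one centroid per region")
  }
  if (anyNA(centroids)) stop("centroids contain missing values")
  if (coordinate_system == "lonlat") {
    if (any(abs(centroids[, 1]) > 180) || any(abs(centroids[, 2]) > 90)) {
      stop("lonlat centroids must have lon in [-180, 180] and lat in [-90, 90]")
    }
  }
  rownames(centroids) <- region_ids
  colnames(centroids) <- if (coordinate_system == "lonlat") c("lon", "lat") else c("x", "y")

  if (!is.null(adjacency)) {
    adjacency <- as.data.frame(adjacency)
    if (ncol(adjacency) < 2L) stop("adjacency must have two columns (from, to)")
    adjacency <- data.frame(from = as.character(adjacency[[1]]),
                            to   = as.character(adjacency[[2]]),
                            stringsAsFactors = FALSE)
    unknown <- setdiff(unique(c(adjacency$from, adjacency$to)), region_ids)
    if (length(unknown)) {
      stop("adjacency references unknown region ids: ",
           paste(unknown, collapse = ", "))
    }
    if (any(adjacency$from == adjacency$to)) stop("adjacency contains self-edges")
    # store symmetrically, deduplicated
    key <- paste(pmin(adjacency$from, adjacency$to),
                 pmax(adjacency$from, adjacency$to), sep = "\r")
    adjacency <- adjacency[!duplicated(key), , drop = FALSE]
    rownames(adjacency) <- NULL
  }

  structure(list(region_ids = region_ids,
                 centroids = centroids,
                 coordinate_system = coordinate_system,
                 adjacency = adjacency),
            class = "area_map")
}

#' @export
print.area_map <- function(x, ...) {
  cat(sprintf("area_map: %d regions (%s coordinates)%s\n",
              length(x$region_ids), x$coordinate_system,
              if (is.null(x$adjacency)) ""
              else sprintf(", %d adjacency edges", nrow(x$adjacency))))
  invisible(x)
}

n_regions <- function(map) length(map$region_ids)

#' Read an areal map from CSV (and optionally an adjacency edge list)
#'
#' The map CSV must contain a `region_id` column and either `x`/`y` (planar)
#' or `lon`/`lat` (geographic) coordinate columns. The optional adjacency CSV
#' has two columns of region ids.
#'
#' @param map_path Path to the map CSV or a GeoJSON file of polygons (see
#'   [read_area_map_geojson()]).
#' @param adjacency_path Optional path to a two-column edge-list CSV.
#' @return An [area_map()].
#' @export
read_area_map <- function(map_path, adjacency_path = NULL) {
  adjacency <- NULL
  if (!is.null(adjacency_path)) {
    adjacency <- utils::read.csv(adjacency_path, stringsAsFactors = FALSE)
  }
  if (grepl("\\.(geojson|json)$", map_path, ignore.case = TRUE)) {
    return(read_area_map_geojson(map_path, adjacency = adjacency))
  }
  df <- utils::read.csv(map_path, stringsAsFactors = FALSE)
  if (!"region_id" %in% names(df)) stop("map CSV needs a region_id column")
  if (all(c("lon", "lat") %in% names(df))) {
    area_map(df$region_id, cbind(df$lon, df$lat),
             coordinate_system = "lonlat", adjacency = adjacency)
  } else if (all(c("x", "y") %in% names(df))) {
    area_map(df$region_id, cbind(df$x, df$y),
             coordinate_system = "planar", adjacency = adjacency)
  } else {
    stop("map CSV needs x/y or lon/lat columns")
  }
}

#' Read an areal map from GeoJSON polygons
#'
#' Each feature must carry a `region_id` property (or `id`); the region
#' centroid is the area-weighted centroid of the outer polygon ring
#' (the polygon's representative point).
#'
#' @param path Path to a GeoJSON FeatureCollection of Polygon /
#'   MultiPolygon features.
#' @param coordinate_system Coordinate flag passed to [area_map()];
#'   GeoJSON is conventionally lon/lat.
#' @param adjacency Optional adjacency edge data frame.
#' @return An [area_map()].
#' @export
read_area_map_geojson <- function(path, coordinate_system = "lonlat",
                                  adjacency = NULL) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("GeoJSON file has no features")
  ids <- character(0)
  cent <- NULL
  for (f in gj$features) {
    id <- f$properties$region_id
    if (is.null(id)) id <- f$id
    if (is.null(id)) stop("GeoJSON feature lacks a region_id property")
    geom <- f$geometry
    ring <- switch(geom$type,
      Polygon = geom$coordinates[[1]],
      # MultiPolygon: use the largest part's outer ring
      MultiPolygon = {
        parts <- lapply(geom$coordinates, `[[`, 1)
        areas <- vapply(parts, function(r) abs(ring_area(ring_to_matrix(r))),
                        numeric(1))
        parts[[which.max(areas)]]
      },
      stop("unsupported geometry type: ", geom$type))
    ids <- c(ids, as.character(id))
    cent <- rbind(cent, polygon_centroid(ring_to_matrix(ring)))
  }
  area_map(ids, cent, coordinate_system = coordinate_system,
           adjacency = adjacency)
}

ring_to_matrix <- function(ring) {
  do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
}

ring_area <- function(m) {
  # signed shoelace area; ring closed or open
  if (!all(m[1, ] == m[nrow(m), ])) m <- rbind(m, m[1, ])
  x <- m[, 1]; y <- m[, 2]
  n <- nrow(m)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

polygon_centroid <- function(m) {
  if (!all(m[1, ] == m[nrow(m), ])) m <- rbind(m, m[1, ])
  x <- m[, 1]; y <- m[, 2]
  n <- nrow(m)
  cr <- x[-n] * y[-1] - x[-1] * y[-n]
  a <- sum(cr) / 2
  if (abs(a) < 1e-300) return(colMeans(m[-n, , drop = FALSE]))
  cx <- sum((x[-n] + x[-1]) * cr) / (6 * a)
  cy <- sum((y[-n] + y[-1]) * cr) / (6 * a)
  c(cx, cy)
}
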