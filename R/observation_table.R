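#' Construct an observation table
#'
#' Bundles the response vector, design matrix, and observation-to-region
#' assignment for a BGWR fit, together with an optional per-region
#' active-covariate mask (used, e.g., to drop one-hot category columns that
#' are unobserved in a region's neighbourhood).
#'
#' @param y Numeric response vector, length n.
#' @param X Numeric design matrix, n x p. Include an intercept column
#'   yourself if the model should have one.
#' @param obs_region Vector of length n mapping each observation to a region
#'   id of `map`.
#' @param map The [area_map()] the regions refer to.
#' @param covariate_names Optional column names for `X`.
#' @param active_mask Optional S x p logical matrix (rows = regions in map
#'   order); `FALSE` pins that region's coefficient to zero. Default all
#'   active.
#' @return An `observation_table` object.
#' @export
observation_table <- function(y, X, obs_region, map,
                              covariate_names = NULL, active_mask = NULL) {
  stopifnot(inherits(map, "area_map"))
  y <- as.numeric(y)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- length(y)
  if (nrow(X) != n) stop("X must have one row per observation")
  if (anyNA(y) || anyNA(X)) {
    stop("missing values in y or X; impute or drop before modelling")
  }
  obs_region <- as.character(obs_region)
  if (length(obs_region) != n) stop("obs_region must have length n")
  unknown <- setdiff(unique(obs_region), map$region_ids)
  if (length(unknown)) {
    stop("obs_region references unknown region ids: ",
         paste(unknown, collapse = ", "))
  }
  if (!is.null(covariate_names)) {
    stopifnot(length(covariate_names) == ncol(X))
    colnames(X) <- covariate_names
  } else if (is.null(colnames(X))) {
    colnames(X) <- paste0("X", seq_len(ncol(X)))
  }
  S <- n_regions(map)
  if (is.null(active_mask)) {
    active_mask <- matrix(TRUE, S, ncol(X))
  } else {
    active_mask <- as.matrix(active_mask)
    stopifnot(is.logical(active_mask), nrow(active_mask) == S,
              ncol(active_mask) == ncol(X))
  }
  dimnames(active_mask) <- list(map$region_ids, colnames(X))
  if (any(rowSums(active_mask) == 0)) {
    stop("regions with zero active covariates: ",
         paste(map$region_ids[rowSums(active_mask) == 0], collapse = ", "))
  }
  structure(list(y = y, X = X, obs_region = obs_region,
                 covariate_names = colnames(X), active_mask = active_mask,
                 region_index = match(obs_region, map$region_ids)),
            class = "observation_table")
}

#' @export
print.observation_table <- function(x, ...) {
  cat(sprintf("observation_table: %d observations, %d covariates (%s), %d regions used\n",
              length(x$y), ncol(x$X),
              paste(utils::head(x$covariate_names, 6), collapse = ", "),
              length(unique(x$obs_region))))
  invisible(x)
}

#' One-hot encode categorical columns of a data frame
#'
#' Factors/character columns are expanded into 0/1 indicator columns (first
#' level dropped when `drop_first`), leaving numeric columns untouched.
#' Returns the expanded numeric matrix; useful before building per-region
#' active masks for category levels unobserved in a region.
#'
#' @param df Data frame of covariates.
#' @param drop_first Drop each factor's first level (reference coding).
#' @return Numeric matrix.
#' @export
one_hot <- function(df, drop_first = TRUE) {
  stopifnot(is.data.frame(df))
  cols <- lapply(names(df), function(nm) {
    v <- df[[nm]]
    if (is.numeric(v)) {
      m <- matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, nm))
      return(m)
    }
    f <- factor(v)
    lev <- levels(f)
    if (drop_first) lev <- lev[-1]
    if (!length(lev)) return(NULL)
    m <- vapply(lev, function(l) as.numeric(f == l), numeric(length(f)))
    colnames(m) <- paste(nm, lev, sep = "_")
    m
  })
  do.call(cbind, cols[!vapply(cols, is.null, logical(1))])
}
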