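#' Prior specification for the BGWR hierarchy
#'
#' Inverse-gamma priors on the local observation variances sigma2(s)
#' (shape `alpha1`, rate `alpha2`) and on the shared coefficient-prior
#' variance sigma_beta2 (shape `a_beta`, rate `b_beta`); the bandwidth b
#' carries a Uniform(0, D) prior, with D taken from the kernel spec.
#' Defaults are weakly informative (0.01 throughout).
#'
#' @param alpha1,alpha2 Shape/rate of the prior on each sigma2(s).
#' @param a_beta,b_beta Shape/rate of the prior on sigma_beta2.
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(alpha1 = 0.01, alpha2 = 0.01,
                       a_beta = 0.01, b_beta = 0.01) {
  stopifnot(alpha1 > 0, alpha2 > 0, a_beta > 0, b_beta > 0)
  structure(list(alpha1 = alpha1, alpha2 = alpha2,
                 a_beta = a_beta, b_beta = b_beta),
            class = "prior_spec")
}

#' MCMC settings
#'
#' @param iterations Total sweeps.
#' @param burn_in Discarded initial sweeps (must be < iterations).
#' @param thinning Keep every `thinning`-th post-burn-in sweep.
#' @param seed Integer seed; every fit is reproducible from it.
#' @param bandwidth_step Random-walk scale for the bandwidth move;
#'   default D/20 (set when the fit runs).
#' @return An `mcmc_settings` object.
#' @export
mcmc_settings <- function(iterations = 10000, burn_in = 2000, thinning = 1,
                          seed = 1L, bandwidth_step = NULL) {
  stopifnot(iterations >= 1, burn_in >= 0, burn_in < iterations,
            thinning >= 1)
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning),
                 seed = as.integer(seed),
                 bandwidth_step = bandwidth_step),
            class = "mcmc_settings")
}

#' Local weighted least-squares estimate (GWR point estimate)
#'
#' The frequentist GWR estimator for one focal region:
#' `(X' W X)^{-1} X' W y` with `W = diag(w)`. Used as the sampler
#' initializer and as an independent oracle in checks.
#'
#' @param X Design matrix n x p.
#' @param y Response vector.
#' @param w Nonnegative weight vector for the focal region.
#' @param active Optional logical mask over columns; inactive coefficients
#'   are returned as 0.
#' @param ridge Nonnegative ridge added to the normal-matrix diagonal for
#'   stabilization (0 = plain WLS).
#' @return Coefficient vector of length p.
#' @export
gwr_wls_estimate <- function(X, y, w, active = NULL, ridge = 0) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(active)) active <- rep(TRUE, p)
  Xa <- X[, active, drop = FALSE]
  A <- crossprod(Xa, Xa * w)
  if (ridge > 0) diag(A) <- diag(A) + ridge
  bv <- crossprod(Xa, w * y)
  est <- tryCatch(solve(A, bv), error = function(e) {
    stop("singular weighted normal matrix; consider a larger bandwidth ",
         "(weights too concentrated)")
  })
  beta <- numeric(p)
  beta[active] <- est
  names(beta) <- colnames(X)
  beta
}

#' Weighted Gaussian log-likelihood for one focal region
#'
#' Each observation contributes a univariate Gaussian term with mean
#' `x_i' beta_s` and variance `sigma2_s / w_i`: higher weight means higher
#' precision, so nearby observations count more in the local model.
#'
#' @param y,X Response and design matrix.
#' @param beta_s Local coefficient vector.
#' @param sigma2_s Local variance (positive).
#' @param w Positive weight vector (floored upstream for bounded-support
#'   kernels).
#' @return Scalar log-likelihood.
#' @export
log_likelihood_region <- function(y, X, beta_s, sigma2_s, w) {
  if (sigma2_s <= 0) stop("sigma2 must be positive")
  if (any(w <= 0)) stop("weights must be positive (floor zero weights first)")
  r <- y - as.vector(as.matrix(X) %*% beta_s)
  sum(0.5 * log(w) - 0.5 * log(2 * pi * sigma2_s) - w * r^2 / (2 * sigma2_s))
}

WEIGHT_FLOOR <- 1e-12

#' Leave-one-out cross-validation bandwidth for GWR
#'
#' Classical GWR bandwidth selection: for each candidate bandwidth, every
#' observation is predicted from its region's weighted least-squares fit
#' with its own weight zeroed, and the bandwidth minimizing the CV sum of
#' squared prediction errors is returned. Used to initialize the MCMC
#' bandwidth in the basin the data prefer (the weighted pseudo-posterior
#' over the bandwidth can be multimodal, and a random-walk chain started at
#' a global bandwidth may not cross into the localized regime).
#'
#' @param table An [observation_table()].
#' @param map The matching [area_map()].
#' @param kernel Kernel name or [kernel_spec()] (only the kernel shape is
#'   used).
#' @param dist Precomputed distance matrix (else Euclidean).
#' @param grid Candidate bandwidths; default 15 values log-spaced between
#'   2% and 100% of the maximum distance.
#' @param ridge Ridge stabilizer for near-singular local fits.
#' @return The CV-optimal bandwidth (a scalar from `grid`).
#' @export
gwr_cv_bandwidth <- function(table, map, kernel = "exponential", dist = NULL,
                             grid = NULL, ridge = 1e-8) {
  if (inherits(kernel, "kernel_spec")) kernel <- kernel$kernel
  if (is.null(dist)) dist <- distance_matrix(map, "euclidean")
  if (is.null(grid)) {
    mx <- max(dist)
    grid <- exp(seq(log(0.02 * mx), log(mx), length.out = 15))
  }
  X <- table$X
  y <- table$y
  ridx <- table$region_index
  S <- ncol(dist)
  cv <- vapply(grid, function(b) {
    W <- pmax(kernel_weights(dist, kernel_spec(kernel, bandwidth = b)),
              WEIGHT_FLOOR)
    err <- 0
    for (s in seq_len(S)) {
      in_s <- which(ridx == s)
      if (!length(in_s)) next
      w <- W[ridx, s]
      w[in_s] <- 0                       # leave the region's own obs out
      act <- table$active_mask[s, ]
      est <- tryCatch(
        gwr_wls_estimate(X, y, w, active = act,
                         ridge = ridge * sum(w)),
        error = function(e) NULL)
      if (is.null(est)) return(Inf)
      err <- err + sum((y[in_s] - X[in_s, , drop = FALSE] %*% est)^2)
    }
    err
  }, numeric(1))
  grid[which.min(cv)]
}

# n x S matrix of floored kernel weights for every (observation, focal region)
obs_weight_matrix <- function(table, dist, spec, bandwidth) {
  Wreg <- apply(dist, 2, kernel_weights, spec = spec, bandwidth = bandwidth)
  Wreg <- pmax(Wreg, WEIGHT_FLOOR)
  Wreg[table$region_index, , drop = FALSE]
}

#' Fit the vectorized BGWR model by Metropolis-within-Gibbs
#'
#' One sweep per iteration: conjugate multivariate-normal Gibbs draws of each
#' region's coefficient vector, inverse-gamma draws of the local variances
#' and of the shared coefficient-prior variance, and (when the bandwidth is
#' not fixed) a reflected random-walk Metropolis move on the single shared
#' bandwidth, targeting the product over focal regions of the weighted
#' Gaussian likelihoods times the Uniform(0, D) prior.
#'
#' @param table An [observation_table()].
#' @param map The matching [area_map()].
#' @param kernel A [kernel_spec()]; a fixed `bandwidth` skips the bandwidth
#'   move, a prior bound `D` turns estimation on.
#' @param priors A [prior_spec()].
#' @param settings An [mcmc_settings()].
#' @param metric Distance metric passed to [distance_matrix()].
#' @param dist Optional precomputed distance matrix (overrides `metric`).
#' @param bandwidth_target `"averaged"` (default) tempers the bandwidth
#'   move's pseudo-log-likelihood by 1/S — a composite-likelihood correction
#'   so the target carries each datum's information once on average, since
#'   the weighted pseudo-likelihood reuses every observation in all S focal
#'   models; `"joint"` uses the untempered product over focal regions.
#' @param bandwidth_init `"cv"` (default) starts the bandwidth chain at the
#'   leave-one-out CV optimum ([gwr_cv_bandwidth()]), `"midpoint"` at D/2;
#'   a number fixes the start explicitly. The weighted pseudo-posterior
#'   over the bandwidth can be multimodal (global versus localized
#'   regimes), and a random-walk chain only explores the basin it starts
#'   in, so the start matters scientifically.
#' @return A `bgwr_draws` object: `beta` (iterations x regions x covariates),
#'   `sigma2` (iterations x regions), `sigma_beta2`, `bandwidth`,
#'   `accept_rate`, plus the map/table/settings echo.
#' @export
run_bgwr <- function(table, map, kernel, priors = prior_spec(),
                     settings = mcmc_settings(), metric = "euclidean",
                     dist = NULL,
                     bandwidth_target = c("averaged", "joint"),
                     bandwidth_init = c("cv", "midpoint")) {
  bandwidth_target <- match.arg(bandwidth_target)
  stopifnot(inherits(table, "observation_table"), inherits(map, "area_map"),
            inherits(kernel, "kernel_spec"), inherits(priors, "prior_spec"),
            inherits(settings, "mcmc_settings"))
  if (is.null(dist)) dist <- distance_matrix(map, metric)
  estimate_b <- is.null(kernel$bandwidth)
  Dmax <- if (estimate_b) kernel$D else kernel$bandwidth
  b_init <- bandwidth_start(bandwidth_init, estimate_b, kernel, table, map,
                            dist)
  b_step <- if (!is.null(settings$bandwidth_step)) settings$bandwidth_step
            else Dmax / 20

  set.seed(settings$seed)
  out <- cpp_bgwr_mcmc(
    y = table$y, X = table$X, region = table$region_index - 1L,
    D = as.matrix(unclass(dist)), active = table$active_mask * 1L,
    kernel_id = kernel_id(kernel$kernel),
    estimate_b = estimate_b, b_init = b_init, Dmax = Dmax, b_step = b_step,
    ll_scale = if (bandwidth_target == "averaged") 1 / n_regions(map) else 1,
    alpha1 = priors$alpha1, alpha2 = priors$alpha2,
    a_beta = priors$a_beta, b_beta = priors$b_beta,
    n_iter = settings$iterations, burn_in = settings$burn_in,
    thin = settings$thinning)

  beta <- aperm(out$beta, c(3, 1, 2))   # iteration x region x covariate
  dimnames(beta) <- list(NULL, map$region_ids, table$covariate_names)
  colnames(out$sigma2) <- map$region_ids
  structure(list(beta = beta, sigma2 = out$sigma2,
                 sigma_beta2 = as.vector(out$sigma_beta2),
                 bandwidth = as.vector(out$bandwidth),
                 accept_rate = out$accept_rate,
                 kernel = kernel, priors = priors, settings = settings,
                 map = map, table = table),
            class = "bgwr_draws")
}

#' @export
print.bgwr_draws <- function(x, ...) {
  cat(sprintf("bgwr_draws: %d kept draws, %d regions, %d covariates\n",
              dim(x$beta)[1], dim(x$beta)[2], dim(x$beta)[3]))
  if (!is.na(x$accept_rate)) {
    cat(sprintf("  bandwidth: posterior mean %.3f (acceptance %.2f)\n",
                mean(x$bandwidth), x$accept_rate))
    if (x$accept_rate < 0.1 || x$accept_rate > 0.6) {
      cat("  note: bandwidth acceptance outside [0.1, 0.6]; tune bandwidth_step\n")
    }
  }
  invisible(x)
}

# Starting bandwidth: CV-selected (clamped into (0, D)), the prior midpoint,
# or the fixed bandwidth when estimation is off.
bandwidth_start <- function(bandwidth_init, estimate_b, kernel, table, map,
                            dist) {
  if (!estimate_b) return(kernel$bandwidth)
  if (is.numeric(bandwidth_init)) return(min(max(bandwidth_init, 1e-6 * kernel$D),
                                             kernel$D * (1 - 1e-6)))
  bandwidth_init <- match.arg(bandwidth_init, c("cv", "midpoint"))
  if (bandwidth_init == "midpoint") return(kernel$D / 2)
  b <- tryCatch(gwr_cv_bandwidth(table, map, kernel$kernel, dist = dist),
                error = function(e) kernel$D / 2)
  min(max(b, 1e-6 * kernel$D), kernel$D * (1 - 1e-6))
}

#' Posterior summaries of the local coefficients
#'
#' @param draws A `bgwr_draws` (or `bgwr_select_draws`) object.
#' @param level Central credible-interval level in (0, 1), default 0.95.
#' @return Data frame with one row per (region, covariate): posterior mean,
#'   sd, lower/upper empirical quantiles at `(1-level)/2` and
#'   `1-(1-level)/2`, and whether the interval excludes zero.
#' @export
posterior_summary <- function(draws, level = 0.95) {
  stopifnot(inherits(draws, "bgwr_draws"))
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  beta <- draws$beta
  if (dim(beta)[1] < 1) stop("no post-burn-in draws")
  lo <- (1 - level) / 2
  dims <- dim(beta)
  regions <- dimnames(beta)[[2]]
  covs <- dimnames(beta)[[3]]
  out <- expand.grid(region_id = regions, covariate = covs,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  flat <- matrix(beta, nrow = dims[1])   # columns ordered region-major per covariate
  out$mean <- colMeans(flat)
  out$sd <- apply(flat, 2, stats::sd)
  qs <- apply(flat, 2, stats::quantile, probs = c(lo, 1 - lo))
  out$lower <- qs[1, ]
  out$upper <- qs[2, ]
  out$excludes_zero <- out$lower > 0 | out$upper < 0
  out
}
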