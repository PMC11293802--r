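#' Fit a Gaussian mixture model by EM
#'
#' Full-covariance GMM fitted by expectation-maximization, restarted from
#' `restarts` seeded initializations (random responsibility perturbations of
#' a quantile-sliced start) and keeping the best final log-likelihood.
#' Covariance diagonals are floored at 1e-6 for numerical stability. BIC is
#' computed as `-2 logL + q log S` with `q = K-1 + K p + K p(p+1)/2`.
#'
#' @param points S x p numeric matrix (rows are the units to cluster).
#' @param K Number of components (1 <= K < S).
#' @param seed Integer seed.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param restarts Number of seeded restarts.
#' @return A `gmm_fit`: `K`, `weights`, `means` (K x p), `covariances`
#'   (p x p x K), `responsibilities` (S x K), `assignment` (argmax labels),
#'   `log_likelihood`, `loglik_trace`, `bic`.
#' @export
gmm_em_fit <- function(points, K, seed = 1L, tol = 1e-6, max_iter = 500,
                       restarts = 10) {
  points <- as.matrix(points)
  S <- nrow(points)
  p <- ncol(points)
  if (K < 1) stop("K must be at least 1")
  if (K >= S) stop("K must be smaller than the number of points")
  if (!all(is.finite(points))) stop("points must be finite")
  degenerate <- all(apply(points, 2, function(v) diff(range(v)) == 0))
  if (degenerate && K > 1) {
    warning("all points identical; returning a single-component fit")
    K <- 1L
  }

  set.seed(seed)
  best <- NULL
  for (r in seq_len(max(1L, restarts))) {
    fit <- tryCatch(gmm_em_once(points, K, tol, max_iter),
                    error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || fit$log_likelihood > best$log_likelihood)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("all EM restarts failed")
  q <- (K - 1) + K * p + K * p * (p + 1) / 2
  best$bic <- -2 * best$log_likelihood + q * log(S)
  best$K <- K
  best$assignment <- max.col(best$responsibilities, ties.method = "first")
  class(best) <- "gmm_fit"
  best
}

# One EM run from a randomized start (uses the current RNG stream):
# K sampled data points as initial means with the pooled covariance,
# which breaks the symmetry a random partition start cannot.
gmm_em_once <- function(points, K, tol, max_iter) {
  S <- nrow(points)
  p <- ncol(points)
  means <- points[sample.int(S, K), , drop = FALSE]
  pooled <- stats::cov(points) * (S - 1) / S
  if (is.null(dim(pooled))) pooled <- matrix(pooled, 1, 1)
  diag(pooled) <- pmax(diag(pooled), 1e-6)
  pooled <- make_pd(pooled)
  covs <- array(pooled, c(p, p, K))
  w <- rep(1 / K, K)

  ll_trace <- numeric(0)
  ll_old <- -Inf
  R <- NULL
  for (iter in seq_len(max_iter)) {
    # E step
    logd <- vapply(seq_len(K), function(k) {
      dmvnorm_log(points, means[k, ], covs[, , k]) + log(w[k])
    }, numeric(S))
    if (S == 1) logd <- matrix(logd, 1, K)
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    R <- exp(logd - lse)
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1e-12)) break
    ll_old <- ll
    # M step
    nk <- pmax(colSums(R), 1e-10)
    w <- nk / S
    means <- crossprod(R, points) / nk               # K x p
    covs <- array(0, c(p, p, K))
    for (k in seq_len(K)) {
      d <- sweep(points, 2, means[k, ])
      V <- crossprod(d * R[, k], d) / nk[k]
      diag(V) <- pmax(diag(V), 1e-6)
      covs[, , k] <- make_pd(V)
    }
  }
  # spike guard: a full covariance needs at least p+1 effective members;
  # solutions with starved components are spurious likelihood blow-ups
  if (K > 1 && any(colSums(R) < p + 1)) {
    stop("degenerate component (fewer than p+1 effective members)")
  }
  list(weights = w, means = means, covariances = covs,
       responsibilities = R, log_likelihood = ll_trace[length(ll_trace)],
       loglik_trace = ll_trace)
}

dmvnorm_log <- function(X, mu, V) {
  L <- chol(V)
  d <- forwardsolve(t(L), t(sweep(X, 2, mu)))
  -0.5 * (ncol(X) * log(2 * pi) + 2 * sum(log(diag(L))) + colSums(d^2))
}

# clip eigenvalues so a weighted covariance from a starved component stays
# positive-definite (components can momentarily hold < p points)
make_pd <- function(V, floor = 1e-6) {
  ok <- tryCatch({ chol(V); TRUE }, error = function(e) FALSE)
  if (ok) return(V)
  e <- eigen(V, symmetric = TRUE)
  e$vectors %*% (pmax(e$values, floor) * t(e$vectors))
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("gmm_fit: K = %d, logL = %.3f, BIC = %.3f\n",
              x$K, x$log_likelihood, x$bic))
  invisible(x)
}

#' Select the GMM component count by BIC
#'
#' Fits [gmm_em_fit()] for each K in `K_range` and returns the fit with the
#' smallest BIC; ties go to the smaller K.
#'
#' @inheritParams gmm_em_fit
#' @param K_range Candidate component counts (all < S).
#' @return The selected `gmm_fit`, with the full BIC table in `$bic_table`.
#' @export
gmm_select_K <- function(points, K_range = 1:10, seed = 1L, tol = 1e-6,
                         max_iter = 500, restarts = 10) {
  stopifnot(length(K_range) >= 1)
  K_range <- sort(unique(as.integer(K_range)))
  fits <- lapply(K_range, function(K) {
    tryCatch(gmm_em_fit(points, K, seed = seed, tol = tol,
                        max_iter = max_iter, restarts = restarts),
             error = function(e) NULL)
  })
  failed <- vapply(fits, is.null, logical(1))
  if (all(failed)) stop("EM failed for every K in K_range")
  if (any(failed)) {
    warning("EM failed for K = ", paste(K_range[failed], collapse = ", "),
            "; dropped from the BIC comparison")
    fits <- fits[!failed]
    K_range <- K_range[!failed]
  }
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  best <- fits[[which.min(bics)]]          # which.min takes the first (smallest K) tie
  best$bic_table <- data.frame(K = K_range, bic = bics)
  best
}

#' Fit a truncated stick-breaking Dirichlet-process mixture
#'
#' Blocked Gibbs sampler on the truncated stick-breaking representation with
#' an independent Normal-Inverse-Gamma base measure per dimension:
#' assignments z are drawn from their multinomial full conditional, stick
#' fractions from `Beta(1 + n_k, alpha + sum_{l>k} n_l)`, and component
#' means/variances from the conjugate base updates. Base hyperparameters
#' default to the pooled sample moments (prior mean = pooled mean, prior
#' expected variance = pooled variance, kappa0 = 0.1, a0 = 2).
#'
#' @param points S x p matrix of units to cluster.
#' @param alpha Concentration parameter (> 0).
#' @param H Truncation level (>= 2).
#' @param iterations,burn_in Chain length and burn-in.
#' @param seed Integer seed.
#' @param base_params Optional list overriding `m0` (length-p), `kappa0`,
#'   `a0`, `b0` (length-p).
#' @return A `dpmm_draws` object: `z` (draws x S, 1-based labels), `V`,
#'   `C` (draws x H stick fractions and weights), `alpha`, `H`.
#' @export
dpmm_fit <- function(points, alpha = 1, H = 20, iterations = 1000,
                     burn_in = 200, seed = 1L, base_params = NULL) {
  points <- as.matrix(points)
  if (H < 2) stop("truncation H must be at least 2")
  if (alpha <= 0) stop("alpha must be positive")
  stopifnot(burn_in < iterations)
  p <- ncol(points)
  m0 <- if (!is.null(base_params$m0)) base_params$m0 else colMeans(points)
  kappa0 <- if (!is.null(base_params$kappa0)) base_params$kappa0 else 0.1
  a0 <- if (!is.null(base_params$a0)) base_params$a0 else 2
  b0 <- if (!is.null(base_params$b0)) base_params$b0 else {
    v <- apply(points, 2, stats::var)
    pmax((a0 - 1) * v, 1e-8)      # prior mean of sigma2 = pooled variance
  }
  stopifnot(length(m0) == p, length(b0) == p)
  set.seed(seed)
  out <- cpp_dpmm_gibbs(points, as.integer(H), alpha, m0, kappa0, a0, b0,
                        as.integer(iterations), as.integer(burn_in))
  if (isTRUE(out$saturated)) {
    warning("all ", H, " truncation components were occupied; ",
            "consider a larger H")
  }
  structure(list(z = out$z, V = out$V, C = out$C, alpha = alpha, H = H,
                 base = list(m0 = m0, kappa0 = kappa0, a0 = a0, b0 = b0)),
            class = "dpmm_draws")
}

#' @export
print.dpmm_draws <- function(x, ...) {
  occ <- apply(x$z, 1, function(z) length(unique(z)))
  cat(sprintf("dpmm_draws: %d draws over %d units, H = %d, modal clusters = %d\n",
              nrow(x$z), ncol(x$z), x$H,
              as.integer(names(sort(-table(occ))[1]))))
  invisible(x)
}

# relabel so labels appear as 1, 2, ... in order of first appearance
canonical_relabel <- function(z) {
  u <- unique(z[!is.na(z)])
  match(z, u)
}

#' Consensus partition by Dahl's least-squares method
#'
#' Builds the coassignment (membership) matrix of every sampled partition,
#' averages them into the pairwise coassignment probability matrix, and
#' returns the sampled partition whose coassignment matrix has the smallest
#' squared distance to that average (ties to the earliest draw).
#'
#' @param assignment_draws M x S matrix of integer cluster labels (one
#'   sampled partition per row).
#' @return A list with `configuration` (a `cluster_config`:
#'   canonically relabeled assignment, method `"dahl"`, `n_clusters`) and
#'   `coassignment` (`M`, the mean matrix, and the chosen draw index).
#' @export
dahl_configuration <- function(assignment_draws) {
  z <- as.matrix(assignment_draws)
  M <- nrow(z)
  S <- ncol(z)
  if (M < 1) stop("need at least one assignment draw")
  Bbar <- matrix(0, S, S)
  Bs <- vector("list", M)
  for (c in seq_len(M)) {
    B <- outer(z[c, ], z[c, ], `==`) * 1
    Bs[[c]] <- B
    Bbar <- Bbar + B
  }
  Bbar <- Bbar / M
  loss <- vapply(Bs, function(B) sum((B - Bbar)^2), numeric(1))
  pick <- which.min(loss)   # first minimum = smallest draw index
  lab <- canonical_relabel(z[pick, ])
  list(
    configuration = structure(
      list(assignment = lab, method = "dahl",
           n_clusters = length(unique(lab))),
      class = "cluster_config"),
    coassignment = list(M = M, mean_matrix = Bbar, chosen_iteration = pick))
}

#' Consensus partition by the per-region mode
#'
#' Assigns each region its most frequent label across the sampled
#' partitions (ties to the smallest label), optionally skipping missing
#' entries, and reports the per-region relative frequency of every label.
#'
#' @param assignment_draws M x S matrix of labels (may contain `NA` when
#'   `ignore_missing`).
#' @param ignore_missing Skip `NA` entries instead of failing.
#' @return A `cluster_config` with an extra `probabilities` element
#'   (region x label relative-frequency matrix).
#' @export
mode_configuration <- function(assignment_draws, ignore_missing = FALSE) {
  z <- as.matrix(assignment_draws)
  if (nrow(z) < 1) stop("need at least one assignment draw")
  S <- ncol(z)
  labs <- sort(unique(as.vector(z[!is.na(z)])))
  assignment <- integer(S)
  probs <- matrix(0, S, length(labs), dimnames = list(colnames(z), labs))
  for (i in seq_len(S)) {
    zi <- z[, i]
    if (anyNA(zi)) {
      if (!ignore_missing) stop("missing labels for region ", i,
                                " (set ignore_missing = TRUE)")
      zi <- zi[!is.na(zi)]
      if (!length(zi)) stop("region ", i, " has only missing labels")
    }
    tab <- table(factor(zi, levels = labs))
    probs[i, ] <- as.numeric(tab) / length(zi)
    assignment[i] <- labs[which.max(tab)]   # first max = smallest label
  }
  lab <- canonical_relabel(assignment)
  # reorder probability columns to the relabeled order, keeping originals' names
  structure(list(assignment = lab, method = "mode",
                 n_clusters = length(unique(lab)),
                 probabilities = probs),
            class = "cluster_config")
}

#' @export
print.cluster_config <- function(x, ...) {
  cat(sprintf("cluster_config (%s): %d clusters over %d regions; sizes %s\n",
              x$method, x$n_clusters, length(x$assignment),
              paste(table(x$assignment), collapse = "/")))
  invisible(x)
}

#' Two-stage clustering of posterior coefficient surfaces
#'
#' Stage 1 draws `n_samples` posterior iterations (without replacement) from
#' a BGWR fit; each sampled iteration's region x covariate coefficient
#' matrix is clustered — by a GMM with BIC-selected K, or by a DPMM whose
#' assignment draws are condensed with Dahl's or the mode method — giving
#' one partition per sample. Stage 2 canonically relabels every partition
#' (labels in order of first region appearance, optionally
#' Hungarian-aligned to the first sample), stacks them into an
#' `n_samples x S` matrix, and takes the per-region mode ignoring missing
#' entries.
#'
#' @param draws A `bgwr_draws` or `bgwr_select_draws` object.
#' @param n_samples Number of posterior iterations to cluster.
#' @param clusterer `"gmm"` or `"dpmm"`.
#' @param config_method `"dahl"` or `"mode"` (within-sample condensation for
#'   the DPMM route; the GMM route uses its maximum-responsibility labels).
#' @param seed Integer seed.
#' @param covariate Optional single covariate name/index: cluster only that
#'   coefficient surface instead of the full matrix.
#' @param K_range,gmm_restarts GMM route controls.
#' @param alpha,H,dpmm_iterations,dpmm_burn_in DPMM route controls.
#' @param align `"first_appearance"` (default) or `"hungarian"` (greedy
#'   best-overlap alignment of each sample's labels to the first sample's).
#' @return A `cluster_config` (mode over samples), with the stage-1 label
#'   matrix attached as `sample_labels`.
#' @export
two_stage_configuration <- function(draws, n_samples = 500,
                                    clusterer = c("gmm", "dpmm"),
                                    config_method = c("mode", "dahl"),
                                    seed = 1L, covariate = NULL,
                                    K_range = 1:10, gmm_restarts = 3,
                                    alpha = 1, H = 20,
                                    dpmm_iterations = 1000,
                                    dpmm_burn_in = 200,
                                    align = c("first_appearance", "hungarian")) {
  stopifnot(inherits(draws, "bgwr_draws"))
  clusterer <- match.arg(clusterer)
  config_method <- match.arg(config_method)
  align <- match.arg(align)
  M <- dim(draws$beta)[1]
  if (n_samples > M) {
    stop("n_samples (", n_samples, ") exceeds available post-burn-in draws (",
         M, ")")
  }
  if (M < 2) stop("need at least 2 retained draws to cluster")
  set.seed(seed)
  picks <- sort(sample.int(M, n_samples))
  S <- dim(draws$beta)[2]
  labels <- matrix(NA_integer_, n_samples, S)
  for (m in seq_along(picks)) {
    pts <- draws$beta[picks[m], , , drop = TRUE]
    if (is.null(dim(pts))) pts <- matrix(pts, nrow = S)
    if (!is.null(covariate)) pts <- pts[, covariate, drop = FALSE]
    if (clusterer == "gmm") {
      fit <- gmm_select_K(pts, K_range = K_range, seed = seed + m,
                          restarts = gmm_restarts)
      lab <- fit$assignment
    } else {
      dp <- dpmm_fit(pts, alpha = alpha, H = H,
                     iterations = dpmm_iterations, burn_in = dpmm_burn_in,
                     seed = seed + m)
      lab <- if (config_method == "dahl") {
        dahl_configuration(dp$z)$configuration$assignment
      } else {
        mode_configuration(dp$z)$assignment
      }
    }
    labels[m, ] <- canonical_relabel(lab)
  }
  if (align == "hungarian" && n_samples > 1) {
    for (m in 2:n_samples) {
      labels[m, ] <- align_to_reference(labels[m, ], labels[1, ])
    }
  }
  out <- mode_configuration(labels, ignore_missing = TRUE)
  out$sample_labels <- labels
  out$clusterer <- clusterer
  out
}

# Greedy best-overlap relabeling of z against reference labels (a light
# stand-in for full Hungarian matching; exact when overlaps are dominant).
align_to_reference <- function(z, ref) {
  zl <- sort(unique(z))
  rl <- sort(unique(ref))
  overlap <- outer(zl, rl, Vectorize(function(a, b) sum(z == a & ref == b)))
  new_lab <- rep(NA_integer_, max(zl))
  avail_r <- rl
  ord <- order(-apply(overlap, 1, max))
  next_extra <- max(rl)
  for (i in ord) {
    cand <- overlap[i, match(avail_r, rl)]
    if (length(avail_r) && max(cand) > 0) {
      pick <- avail_r[which.max(cand)]
      new_lab[zl[i]] <- pick
      avail_r <- setdiff(avail_r, pick)
    } else {
      next_extra <- next_extra + 1L
      new_lab[zl[i]] <- next_extra
    }
  }
  new_lab[z]
}

#' Rand index between two partitions
#'
#' Proportion of unordered pairs on which the two label vectors agree
#' (either co-clustered in both or separated in both).
#'
#' @param C,C_prime Equal-length label vectors without missing values.
#' @return A number in \[0, 1\]; 1 means the partitions agree on every pair.
#' @export
rand_index <- function(C, C_prime) {
  if (length(C) != length(C_prime)) stop("label vectors differ in length")
  n <- length(C)
  if (n < 2) stop("need at least two labelled units")
  if (anyNA(C) || anyNA(C_prime)) stop("missing labels are not allowed")
  tab <- table(C, C_prime)
  n_pairs <- choose(n, 2)
  a_plus_c <- sum(choose(rowSums(tab), 2))   # co-clustered in C
  a_plus_d <- sum(choose(colSums(tab), 2))   # co-clustered in C'
  a <- sum(choose(tab, 2))                   # co-clustered in both
  b <- n_pairs - a_plus_c - a_plus_d + a     # separated in both
  (a + b) / n_pairs
}
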