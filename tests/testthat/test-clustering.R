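test_that("single-component GMM recovers sample moments", {
  set.seed(1)
  pts <- matrix(rnorm(60, 2, 1.5), 30, 2)
  fit <- gmm_em_fit(pts, K = 1, restarts = 1)
  expect_equal(unname(fit$means[1, ]), colMeans(pts), tolerance = 1e-8)
  # biased (1/S) covariance
  expect_equal(fit$covariances[, , 1], cov(pts) * 29 / 30, tolerance = 1e-6)
  expect_true(all(fit$responsibilities == 1))
})

test_that("EM log-likelihood is nondecreasing and components are recovered", {
  set.seed(2)
  pts <- matrix(c(rnorm(100, 0), rnorm(100, 10)), ncol = 1)
  fit <- gmm_em_fit(pts, K = 2, seed = 3)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  expect_equal(sort(fit$means[, 1]), c(0, 10), tolerance = 0.5)
  expect_true(all(abs(rowSums(fit$responsibilities) - 1) < 1e-8))
  # independent EM oracle: mclust with unconstrained covariance
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  or <- mclust::Mclust(pts, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$means[, 1]), sort(as.vector(or$parameters$mean)),
               tolerance = 0.2)
})

test_that("BIC selects the generative component count", {
  set.seed(4)
  pts <- rbind(matrix(rnorm(200, 0, 1), 100, 2),
               matrix(rnorm(200, 10, 1), 100, 2))
  sel <- gmm_select_K(pts, K_range = 1:6, seed = 5, restarts = 3)
  expect_equal(sel$K, 2L)
  expect_true(all(sel$bic <= sel$bic_table$bic))
  # single spherical cluster -> K = 1
  sel1 <- gmm_select_K(matrix(rnorm(300), 150, 2), K_range = 1:4, seed = 6,
                       restarts = 3)
  expect_equal(sel1$K, 1L)
  # singleton range returns that K regardless
  sel3 <- gmm_select_K(pts, K_range = 3, seed = 7, restarts = 2)
  expect_equal(sel3$K, 3L)
  expect_error(gmm_em_fit(pts, K = 0), "at least 1")
  expect_error(gmm_em_fit(pts[1:3, ], K = 3), "smaller")
})

test_that("stick-breaking identities hold in every emitted DPMM state", {
  set.seed(8)
  pts <- matrix(rnorm(40), 20, 2)
  dp <- dpmm_fit(pts, alpha = 1, H = 8, iterations = 120, burn_in = 20,
                 seed = 9)
  expect_equal(dp$C[, 1], dp$V[, 1], tolerance = 1e-12)
  for (it in c(1, 50, 100)) {
    Ck <- dp$V[it, ] * cumprod(c(1, 1 - dp$V[it, -8]))
    expect_equal(dp$C[it, ], Ck, tolerance = 1e-12)
  }
  # truncation deficit: 1 - sum C = prod(1 - V)
  expect_equal(1 - rowSums(dp$C), apply(1 - dp$V, 1, prod), tolerance = 1e-10)
  expect_true(all(dp$z >= 1 & dp$z <= 8))
})

test_that("a tight cluster collapses the DPMM to one occupied component", {
  set.seed(10)
  pts <- matrix(rnorm(100, 5, 0.01), 100, 1)
  # a base vaguer than the cluster spread, so spurious components pay an
  # Occam penalty (the empirical default base would mimic the single
  # cluster exactly and scatter labels among identical components)
  dp <- dpmm_fit(pts, alpha = 1, H = 10, iterations = 300, burn_in = 100,
                 seed = 11, base_params = list(m0 = 5, kappa0 = 0.1,
                                               a0 = 2, b0 = 1))
  occ <- apply(dp$z, 1, function(z) length(unique(z)))
  expect_equal(as.integer(names(which.max(table(occ)))), 1L)
})

test_that("prior occupied-cluster counts grow with alpha as CRP predicts", {
  # make the likelihood uninformative (all components share a pinned mean
  # and a huge variance) so assignments follow the stick weights alone
  set.seed(12)
  S <- 40
  pts <- matrix(rnorm(S), S, 1)
  occ_mean <- sapply(c(0.1, 1, 10), function(a) {
    dp <- dpmm_fit(pts, alpha = a, H = 30, iterations = 400, burn_in = 100,
                   seed = 13, base_params = list(m0 = 0, kappa0 = 1e8,
                                                 a0 = 2, b0 = 1e6))
    mean(apply(dp$z, 1, function(z) length(unique(z))))
  })
  expect_true(occ_mean[1] < occ_mean[2])
  expect_true(occ_mean[2] < occ_mean[3])
  # Ewens expectation sum(alpha / (alpha + i - 1)) bounds the ordering scale
  ewens <- function(a) sum(a / (a + seq_len(S) - 1))
  expect_lt(abs(occ_mean[1] - ewens(0.1)) / ewens(0.1), 1.5)
})

test_that("Dahl's configuration matches the brute-force least-squares draw", {
  draws <- rbind(c(1, 1, 2, 2),
                 c(1, 2, 2, 2),
                 c(1, 1, 1, 2))
  out <- dahl_configuration(draws)
  # exhaustive oracle over the three candidate draws
  Bs <- lapply(1:3, function(c) outer(draws[c, ], draws[c, ], `==`) * 1)
  Bbar <- Reduce(`+`, Bs) / 3
  loss <- sapply(Bs, function(B) sum((B - Bbar)^2))
  expect_equal(out$coassignment$chosen_iteration, which.min(loss))
  expect_equal(out$configuration$assignment,
               as.integer(factor(draws[which.min(loss), ],
                                 levels = unique(draws[which.min(loss), ]))))
  expect_equal(out$coassignment$mean_matrix, t(out$coassignment$mean_matrix))
  expect_equal(diag(out$coassignment$mean_matrix), rep(1, 4))
  # degenerate consensus: identical draws give a 0/1 mean matrix
  same <- matrix(rep(c(1, 2, 2, 1), 5), 5, 4, byrow = TRUE)
  out2 <- dahl_configuration(same)
  expect_true(all(out2$coassignment$mean_matrix %in% c(0, 1)))
  expect_equal(out2$configuration$assignment, c(1, 2, 2, 1))
  # single draw is returned as-is
  expect_equal(dahl_configuration(matrix(c(2, 1, 1), 1))$configuration$assignment,
               c(1, 2, 2))
})

test_that("Dahl's choice is invariant to label permutation of the draws", {
  set.seed(14)
  draws <- matrix(sample(1:3, 60, TRUE), 6, 10)
  out <- dahl_configuration(draws)
  perm <- c(3, 1, 2)
  out_p <- dahl_configuration(matrix(perm[draws], 6, 10))
  expect_equal(out$configuration$assignment, out_p$configuration$assignment)
  expect_equal(out$coassignment$mean_matrix, out_p$coassignment$mean_matrix)
})

test_that("mode configuration tallies labels, ties to the smallest", {
  draws <- rbind(c(1, 2, 2),
                 c(1, 2, 3),
                 c(2, 2, 3))
  cfg <- mode_configuration(draws)
  expect_equal(cfg$assignment, c(1, 2, 3))
  expect_equal(cfg$probabilities[1, ], c(`1` = 2 / 3, `2` = 1 / 3, `3` = 0))
  # tie 2/2 between labels 2 and 3 in region 3 -> smallest label wins
  draws2 <- rbind(c(1, 1, 2), c(1, 1, 2), c(1, 1, 3), c(1, 1, 3))
  expect_equal(mode_configuration(draws2)$assignment[3], 2L)
  # missing handling
  draws3 <- rbind(c(1, NA), c(1, 2), c(2, 2))
  expect_error(mode_configuration(draws3), "missing")
  cfg3 <- mode_configuration(draws3, ignore_missing = TRUE)
  expect_equal(cfg3$assignment, c(1, 2))
  expect_error(mode_configuration(rbind(c(1, NA), c(1, NA)),
                                  ignore_missing = TRUE), "only missing")
  # random draw matrix against a direct tally
  set.seed(15)
  dr <- matrix(sample(1:4, 200, TRUE), 20, 10)
  cfg4 <- mode_configuration(dr)
  for (i in c(1, 5, 10)) {
    tab <- table(factor(dr[, i], levels = 1:4)) / 20
    expect_equal(unname(cfg4$probabilities[i, ]), as.vector(tab))
  }
})

test_that("rand_index equals the O(n^2) pair-enumeration oracle", {
  expect_equal(rand_index(c(1, 1), c(1, 2)), 0)
  expect_equal(rand_index(c(1, 2, 1), c(1, 2, 1)), 1)
  set.seed(16)
  for (rep in 1:10) {
    a <- sample(1:4, 10, TRUE)
    b <- sample(1:3, 10, TRUE)
    expect_equal(rand_index(a, b), rand_oracle(a, b))
    expect_equal(rand_index(a, b), rand_index(b, a))
    # relabeling invariance
    expect_equal(rand_index(a, b), rand_index(5 - a, b))
  }
  expect_error(rand_index(1:3, 1:4), "length")
  expect_error(rand_index(c(1, NA), c(1, 2)), "missing")
})

test_that("two-stage configuration is invariant to per-sample label permutations", {
  # stage-2 mode over canonically relabeled samples: feed two samples that
  # are the same partition under different labels through the stage-2 path
  labels <- rbind(c(1, 1, 2, 2, 3),
                  c(2, 2, 3, 3, 1),
                  c(3, 3, 1, 1, 2))
  relabeled <- t(apply(labels, 1, bgwr:::canonical_relabel))
  expect_true(all(relabeled[1, ] == relabeled[2, ]))
  expect_true(all(relabeled[1, ] == relabeled[3, ]))
  cfg <- mode_configuration(relabeled)
  expect_equal(cfg$assignment, c(1, 1, 2, 2, 3))
})

test_that("two-stage clustering recovers a planted partition end to end", {
  # build a draws object whose coefficient surfaces carry 2 planted clusters
  set.seed(17)
  S <- 24; p <- 2; M <- 40
  truth <- rep(1:2, each = S / 2)
  centers <- rbind(c(0, 0), c(6, -6))
  beta <- array(0, c(M, S, p),
                dimnames = list(NULL, sprintf("r%02d", 1:S), c("b1", "b2")))
  for (m in 1:M) beta[m, , ] <- centers[truth, ] + rnorm(S * p, sd = 0.3)
  draws <- structure(list(beta = beta), class = "bgwr_draws")
  for (cl in c("gmm", "dpmm")) {
    cfg <- two_stage_configuration(draws, n_samples = 10, clusterer = cl,
                                   config_method = "mode", seed = 18,
                                   K_range = 1:4, gmm_restarts = 2,
                                   dpmm_iterations = 300, dpmm_burn_in = 100)
    expect_equal(rand_index(cfg$assignment, truth), 1,
                 tolerance = 0.051, label = paste("clusterer", cl))
  }
  expect_error(two_stage_configuration(draws, n_samples = 100),
               "exceeds")
})
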