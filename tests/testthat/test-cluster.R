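# Feature building, PCA, Gaussian-mixture EM, and cluster consistency.

# cells x trials x time tensor from per-cluster templates plus noise
make_trial_tensor <- function(n_per = c(10, 10, 10), n_trials = 8,
                              n_time = 20, noise = 0.05, seed = 1,
                              scramble = 0) {
  set.seed(seed)
  tgrid <- seq(0, 4, length.out = n_time)
  templates <- rbind(exp(-(tgrid - 0.5)^2 / 0.3),
                     exp(-(tgrid - 1.5)^2 / 0.3),
                     exp(-(tgrid - 3.0)^2 / 0.3))
  n_cells <- sum(n_per)
  labels <- rep(seq_along(n_per), n_per)
  tens <- array(0, c(n_cells, n_trials, n_time))
  for (c in seq_len(n_cells)) for (tr in seq_len(n_trials)) {
    tmpl <- if (scramble > 0 && c <= scramble)
      templates[sample(3, 1), ] else templates[labels[c], ]
    tens[c, tr, ] <- tmpl + rnorm(n_time, 0, noise)
  }
  list(tensor = tens, labels = labels, time = tgrid)
}

test_that("response matrix z-scores features and handles degenerate columns", {
  tt <- make_trial_tensor()
  rm1 <- build_response_matrix(tt$tensor, time = tt$time)
  expect_equal(unname(colMeans(rm1)), rep(0, ncol(rm1)), tolerance = 1e-12)
  expect_equal(unname(apply(rm1, 2, sd)), rep(1, ncol(rm1)), tolerance = 1e-12)
  # identical cells -> all-zero matrix
  tens_id <- array(rep(1:160, each = 6), c(6, 8, 20))
  expect_message(rm2 <- build_response_matrix(tens_id), "constant")
  expect_true(all(rm2 == 0))
  # a single constant feature column is dropped with a message
  tens3 <- tt$tensor
  tens3[, 1, 1] <- 5  # first sampled feature constant across cells
  expect_message(rm3 <- build_response_matrix(tens3, time = tt$time),
                 "dropping")
  expect_lt(ncol(rm3), ncol(rm1))
  # class separation: between-cluster feature distance > within-cluster
  d <- as.matrix(dist(rm1))
  same <- outer(tt$labels, tt$labels, "==")
  expect_gt(mean(d[!same]), mean(d[same & upper.tri(same)]))
  expect_error(build_response_matrix(tt$tensor[1, , , drop = FALSE]),
               "at least 2")
})

test_that("peak-feature mode extracts per-trial latency and amplitude", {
  tt <- make_trial_tensor(noise = 0)
  rmp <- build_response_matrix(tt$tensor, time = tt$time, mode = "peaks")
  expect_equal(ncol(rmp), 2 * 8)
  # cluster 3 peaks later than cluster 1 in every trial (first latency col)
  raw_lat <- attr(rmp, "center")[1] + rmp[, 1] * attr(rmp, "scale")[1]
  expect_true(all(raw_lat[tt$labels == 3] > raw_lat[tt$labels == 1]))
})

test_that("PCA explains variance as expected on degenerate and isotropic data", {
  # data on a line -> first component 100%
  set.seed(6)
  tvec <- rnorm(40)
  line <- cbind(2 * tvec, -tvec, 3 * tvec)
  p1 <- pca_reduce(line, 2)
  expect_equal(p1$explained[1], 1, tolerance = 1e-12)
  # isotropic cloud -> roughly equal fractions
  iso <- matrix(rnorm(4000 * 4), ncol = 4)
  p2 <- pca_reduce(iso, 2)
  expect_true(all(abs(p2$explained - 0.25) < 0.05))
  # full reconstruction equals input
  x <- matrix(rnorm(60), ncol = 3)
  p <- prcomp(x, center = TRUE)
  recon <- p$x %*% t(p$rotation) + matrix(p$center, nrow(x), 3, byrow = TRUE)
  expect_equal(recon, x, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("GMM-EM recovers well-separated mixtures with thresholded membership", {
  mix <- make_mixture(n = 300, sep = 5, sd = 1, seed = 2)
  fit <- fit_gmm_em(mix$x, k = 3, seed = 7)
  # map fitted components to true labels by majority vote
  correct <- 0L
  for (k in 1:3) {
    members <- fit$assignments == k
    if (!any(members)) next
    truth <- mix$labels[members]
    correct <- correct + max(table(truth))
  }
  expect_gte(correct / 300, 0.95)
  expect_lte(mean(fit$assignments == 0), 0.05)
  # log-likelihood non-decreasing across iterations
  expect_true(all(diff(fit$loglik_trace) >= -1e-8 * abs(fit$loglik)))
  # parameter recovery: means within 0.2 sd of the labeled-oracle estimate
  # (the empirical class means, which themselves carry ~0.14 sd of
  # sampling error at n/3 points per component), weights within 0.05
  perm <- apply(fit$means, 1, function(m)
    which.min(colSums((t(mix$centers) - m)^2)))
  expect_true(all(sort(perm) == 1:3))
  for (j in 1:3) {
    emp <- colMeans(mix$x[mix$labels == perm[j], , drop = FALSE])
    expect_lt(sqrt(sum((fit$means[j, ] - emp)^2)), 0.2)
  }
  expect_true(all(abs(fit$weights - 1 / 3) < 0.05))
})

test_that("GMM agrees with an independent mixture implementation", {
  library(mclust, quietly = TRUE, warn.conflicts = FALSE)
  mix <- make_mixture(n = 300, sep = 5, sd = 1, seed = 2)
  fit <- fit_gmm_em(mix$x, k = 3, seed = 7)
  mc <- mclust::Mclust(mix$x, G = 3, modelNames = "VVV", verbose = FALSE)
  # same partition up to label permutation
  tab <- table(fit$assignments[fit$assignments > 0],
               mc$classification[fit$assignments > 0])
  agree <- sum(apply(tab, 1, max)) / sum(tab)
  expect_gte(agree, 0.98)
  expect_equal(fit$loglik, mc$loglik, tolerance = 0.01 * abs(mc$loglik))
})

test_that("single-component and threshold-sweep behaviour", {
  set.seed(9)
  x <- matrix(rnorm(200), ncol = 2)
  fit1 <- fit_gmm_em(x, k = 1, seed = 1)
  expect_true(all(fit1$assignments == 1L))
  expect_true(all(fit1$responsibilities == 1))
  # overlapping clusters: unclustered fraction grows with the threshold
  mix <- make_mixture(n = 200, sep = 2, sd = 1, seed = 5)
  uncl <- vapply(c(0.5, 0.8, 0.95, 0.99), function(th)
    mean(fit_gmm_em(mix$x, k = 3, likelihood_threshold = th,
                    seed = 11)$assignments == 0), numeric(1))
  expect_true(all(diff(uncl) >= 0))
  expect_error(fit_gmm_em(matrix(rnorm(4), 2), k = 3), "more points")
})

test_that("assignments are invariant to cell permutation and feature rescaling", {
  tt <- make_trial_tensor(seed = 3)
  rm1 <- build_response_matrix(tt$tensor, time = tt$time)
  sc <- pca_reduce(rm1, 2)$scores
  fit <- fit_gmm_em(sc, k = 3, seed = 2)
  # permutation of cells
  set.seed(1); perm <- sample(nrow(sc))
  fitp <- fit_gmm_em(sc[perm, ], k = 3, seed = 2)
  tab <- table(fit$assignments[perm], fitp$assignments)
  agree <- sum(apply(tab, 1, max)) / sum(tab)
  expect_gte(agree, 0.95)
  # affine rescaling of raw features is absorbed by z-scoring
  tens2 <- tt$tensor * 3 + 10
  rm2 <- build_response_matrix(tens2, time = tt$time)
  expect_equal(unclass(rm2), unclass(rm1), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("cluster consistency: perfect templates 1, permuted labels ~chance, scrambled fraction", {
  tt <- make_trial_tensor(noise = 0.02, seed = 4)
  expect_equal(cluster_consistency(tt$tensor, tt$labels)$fraction, 1)
  # random labels -> about chance level (1/3)
  set.seed(8)
  rand <- sample(tt$labels)
  frac_rand <- cluster_consistency(tt$tensor, rand)$fraction
  expect_lt(frac_rand, 0.6)
  # 20% of cells respond with a random template each trial
  tt2 <- make_trial_tensor(n_per = c(20, 20, 20), noise = 0.02, seed = 9,
                           scramble = 12)
  frac <- cluster_consistency(tt2$tensor, tt2$labels)$fraction
  expect_equal(frac, 0.8, tolerance = 0.1)
  # single cluster flagged
  expect_warning(one <- cluster_consistency(tt$tensor, rep(1L, 30)),
                 "single cluster")
  expect_equal(one$fraction, 1)
})
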