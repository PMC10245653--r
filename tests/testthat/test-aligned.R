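# Event-aligned population statistics.

make_aligned <- function(dff_mat, fs, events, window = c(2, 6), ...)
  align_responses(dff_mat, fs, events, window = window, ...)

test_that("aligning a constant trace gives a zero tensor after baseline subtraction", {
  dff <- matrix(0.7, 400, 3)
  al <- make_aligned(dff, 4, c(30, 50, 70))
  expect_true(max(abs(al$tensor)) < 1e-12)
  expect_equal(dim(al$tensor), c(3, 33, 3))
  expect_equal(range(al$time), c(-2, 6))
})

test_that("a transient injected 1 s after each event peaks at +1 s in the grand average", {
  fs <- 4
  t <- (0:1999) / fs
  ev_times <- c(100, 200, 300, 400)
  kern <- function(t0) 0.5 * exp(-(t - t0)^2 / (2 * 0.4^2))
  dff <- rowSums(vapply(ev_times + 1, kern, numeric(length(t))))
  al <- make_aligned(matrix(dff, ncol = 1), fs, ev_times)
  avg <- apply(al$tensor, 2, mean)
  expect_equal(al$time[which.max(avg)], 1, tolerance = 1 / fs + 1e-9)
  # latencies per event too
  lat <- peak_latencies(al)
  expect_equal(lat$latency, rep(1, 4), tolerance = 1 / fs + 1e-9)
})

test_that("events whose window leaves the recording are dropped, empty alignment errors", {
  dff <- matrix(rnorm(100), ncol = 1)
  expect_message(al <- make_aligned(dff, 4, c(1, 12)), "dropping 1 event")
  expect_equal(dim(al$tensor)[1], 1L)
  expect_error(suppressMessages(make_aligned(dff, 4, c(0.5))), "no usable events")
})

test_that("shuffled event times flatten the grand average below the permutation null", {
  set.seed(11)
  fs <- 4
  t <- (0:2399) / fs
  ev_times <- seq(60, 540, by = 60)
  dff <- rowSums(vapply(ev_times + 1,
                        function(t0) 0.4 * exp(-(t - t0)^2 / (2 * 0.4^2)),
                        numeric(length(t)))) + rnorm(length(t), 0, 0.02)
  al <- make_aligned(matrix(dff, ncol = 1), fs, ev_times)
  peak_real <- max(abs(apply(al$tensor, 2, mean)))
  null_peaks <- replicate(200, {
    sh <- runif(length(ev_times), 10, 590)
    max(abs(apply(make_aligned(matrix(dff, ncol = 1), fs, sh)$tensor, 2, mean)))
  })
  expect_gt(peak_real, quantile(null_peaks, 0.95))
  # and a shuffled alignment itself is typically below that same bound
  sh_peak <- null_peaks[1]
  expect_lt(sh_peak, peak_real)
})

test_that("rank ordering is stable and matches a reference sort", {
  dff <- matrix(rnorm(4000), ncol = 2)
  al <- make_aligned(dff, 4, seq(50, 400, by = 50))
  n_ev <- dim(al$tensor)[1]
  # all-equal keys preserve the original order
  ro <- rank_order_raster(al, key = rep(1, n_ev))
  expect_equal(ro$order, seq_len(n_ev))
  # reversed keys reverse the order
  ro2 <- rank_order_raster(al, key = rev(seq_len(n_ev)))
  expect_equal(ro2$order, rev(seq_len(n_ev)))
  # random keys match order()
  set.seed(2)
  k <- rnorm(n_ev)
  expect_equal(rank_order_raster(al, key = k)$order, order(k))
})

test_that("monotone-rising responses pin the latency at the window end and are flagged", {
  dff <- matrix(seq(0, 1, length.out = 400), ncol = 1)
  al <- make_aligned(dff, 4, c(40, 60))
  lat <- peak_latencies(al)
  expect_true(all(lat$boundary))
  expect_equal(lat$latency, rep(6, 2))
})

test_that("Gini matches the pairwise-difference oracle and analytic cases", {
  expect_equal(gini_lorenz(rep(3, 10))$gini, 0)
  expect_equal(gini_lorenz(c(0, 0, 0, 1))$gini, 0.75)
  set.seed(5)
  x <- runif(100)
  expect_equal(gini_lorenz(x)$gini, oracle_gini(x), tolerance = 1e-12)
  # scale invariance and the (n-1)/n bound
  expect_equal(gini_lorenz(7 * x)$gini, gini_lorenz(x)$gini, tolerance = 1e-12)
  for (n in c(2, 5, 20)) {
    worst <- c(rep(0, n - 1), 1)
    expect_equal(gini_lorenz(worst)$gini, (n - 1) / n, tolerance = 1e-12)
    expect_lte(gini_lorenz(runif(n))$gini, (n - 1) / n)
  }
  # Lorenz curve is the cumulative share of sorted values
  lz <- gini_lorenz(c(1, 3))$lorenz
  expect_equal(lz$share, c(0, 0.25, 1))
  expect_error(gini_lorenz(c(0, 0)), "all-zero")
  expect_error(gini_lorenz(c(-1, 2)), "non-negative")
})

test_that("coefficient of variation follows the sample-SD definition", {
  expect_equal(coefficient_of_variation(rep(2, 5)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), sqrt(2) / 2)
  set.seed(8)
  x <- rnorm(50, 10, 2)
  expect_equal(coefficient_of_variation(x), sd(x) / mean(x))
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})

test_that("Fano-factor epochs: zero for identical events, ~1 for Poisson-like, scaling", {
  fs <- 10
  n_t <- 400
  ev <- c(10, 20, 30)
  # identical events -> FF 0 everywhere (absolute dF/F levels, no
  # pre-window subtraction, so epoch means stay positive)
  base <- 0.2 + 0.3 * exp(-((0:(n_t - 1)) / fs %% 10 - 1.5)^2)
  dff <- matrix(rep(base, 2), ncol = 2)
  al <- align_responses(dff, fs, ev, window = c(1, 1),
                        baseline_subtract = FALSE)
  fe <- fano_epochs(al, epochs = list(t0 = c(-0.9, -0.1), t1 = c(0.1, 0.9)))
  expect_equal(fe$ff, c(0, 0), tolerance = 1e-20)
  expect_equal(fe$rff[fe$epoch == "t0"], 0)
  # Poisson-like responses: variance equals mean -> FF ~ 1
  set.seed(4)
  n_ev <- 400
  resp <- rpois(n_ev, 5)
  tensor <- array(rep(resp, times = 21), c(n_ev, 21, 1))
  al2 <- structure(list(tensor = tensor, time = seq(-1, 1, by = 0.1), fs = 10,
                        reference = "onset", window = c(1, 1)),
                   class = "aligned_response")
  fe2 <- fano_epochs(al2, epochs = list(t0 = c(-0.9, -0.1), t1 = c(0.1, 0.9)))
  expect_equal(fe2$ff[1], 1, tolerance = 4 * sqrt(2 / n_ev))
  # doubling responses doubles FF
  al3 <- al2; al3$tensor <- 2 * al2$tensor
  fe3 <- fano_epochs(al3, epochs = list(t0 = c(-0.9, -0.1), t1 = c(0.1, 0.9)))
  expect_equal(fe3$ff, 2 * fe2$ff, tolerance = 1e-12)
  # rFF is expressed in percent relative to the reference epoch
  expect_equal(fe2$rff, (fe2$ff - fe2$ff[1]) / fe2$ff[1] * 100)
})

test_that("synchronization index: identical cells 1, independent cells ~1/N, closed form", {
  n_t <- 2000
  sig <- sin(seq(0, 20, length.out = n_t))
  ident <- matrix(rep(sig, 5), ncol = 5)
  expect_equal(synchronization_index(ident)$si, 1, tolerance = 1e-12)
  set.seed(14)
  indep <- matrix(rnorm(n_t * 25), ncol = 25)
  si_ind <- synchronization_index(indep)$si
  expect_lt(abs(si_ind - 1 / 25), 3 * sqrt(2 / n_t))
  # common signal + noise at known SNR: si -> s^2/(s^2+sigma^2)
  s2 <- var(sig)
  sigma <- 0.3
  noisy <- matrix(rep(sig, 40), ncol = 40) + matrix(rnorm(n_t * 40, 0, sigma), ncol = 40)
  si_mix <- synchronization_index(noisy)$si
  expect_equal(si_mix, s2 / (s2 + sigma^2), tolerance = 0.05)
  # invariance to common constant offset and to cell relabeling
  expect_equal(synchronization_index(noisy + 5)$si, si_mix, tolerance = 1e-12)
  expect_equal(synchronization_index(noisy[, sample(40)])$si, si_mix,
               tolerance = 1e-12)
  expect_error(synchronization_index(matrix(1:10, ncol = 1)), "two cells")
})

test_that("activeness posterior recovers Bayes' rule and the independence null", {
  set.seed(33)
  n <- 20000
  active <- runif(n) < 0.4
  p_ea <- 0.3; p_ei <- 0.05
  events <- ifelse(active, runif(n) < p_ea, runif(n) < p_ei)
  post <- posterior_activeness(events, active, n_boot = 300, n_null = 300,
                               seed = 3)
  closed <- p_ea * 0.4 / (p_ea * 0.4 + p_ei * 0.6)
  ci <- quantile(post$boot_distribution, c(0.025, 0.975))
  expect_gt(closed, ci[1]); expect_lt(closed, ci[2])
  expect_equal(post$posterior, closed, tolerance = 0.05)
  # under the null the posterior collapses to the activeness marginal
  expect_equal(mean(post$null_distribution), mean(active), tolerance = 0.01)
  # events only during active bins -> posterior 1
  ev2 <- active & (runif(n) < 0.2)
  post2 <- posterior_activeness(ev2, active, n_boot = 50, n_null = 50, seed = 1)
  expect_equal(post2$posterior, 1)
  expect_error(posterior_activeness(rep(FALSE, 100), rep(TRUE, 100)),
               "no events")
})

test_that("independent events recover the activeness marginal across replicates", {
  # property: under independence the posterior estimates p_active; the
  # 95% bootstrap interval should cover it in most replicates
  n <- 4000
  hits <- 0L
  for (r in 1:20) {
    set.seed(100 + r)
    active <- runif(n) < 0.24
    events <- runif(n) < 0.09
    post <- posterior_activeness(events, active, n_boot = 200, n_null = 10,
                                 seed = r)
    ci <- quantile(post$boot_distribution, c(0.025, 0.975), na.rm = TRUE)
    if (0.24 >= ci[1] && 0.24 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 17L)
})
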