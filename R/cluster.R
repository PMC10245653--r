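# Clustering of peri-event responses: feature building, PCA, Gaussian
# mixture fitted by EM with responsibility-thresholded membership, and
# across-trial cluster consistency.

#' Build a cell x feature response matrix from per-trial aligned responses
#'
#' Two feature modes: `"traces"` concatenates each cell's per-trial
#' response trace, downsampled to `points_per_trial` samples, giving
#' `trials * points_per_trial` features; `"peaks"` uses each trial's
#' (peak latency, peak amplitude) pair, giving `2 * trials` features.
#' Columns are z-scored; constant columns are dropped with a message;
#' missing trials are imputed by the cell's median feature value.
#'
#' @param trial_tensor cells x trials x time array of peri-event dF/F
#'   (e.g. `aperm(aligned$tensor, c(3, 1, 2))` when every aligned event
#'   is a trial of the same cells).
#' @param time time axis of the third dimension, seconds.
#' @param mode `"traces"` or `"peaks"`.
#' @param points_per_trial downsampled trace length per trial.
#' @return object of class `response_matrix`: z-scored matrix cells x
#'   features with attributes `mode`, `dropped` (constant columns),
#'   `center`, `scale`.
#' @export
build_response_matrix <- function(trial_tensor, time = NULL,
                                  mode = c("traces", "peaks"),
                                  points_per_trial = 20) {
  mode <- match.arg(mode)
  d <- dim(trial_tensor)
  stop_if(length(d) != 3, "`trial_tensor` must be cells x trials x time")
  n_cells <- d[1]; n_trials <- d[2]; n_time <- d[3]
  stop_if(n_cells < 2 || n_trials < 2, "need at least 2 cells and 2 trials")
  if (is.null(time)) time <- seq_len(n_time)
  if (mode == "traces") {
    pick <- unique(round(seq(1, n_time, length.out = min(points_per_trial, n_time))))
    feat <- matrix(NA_real_, n_cells, n_trials * length(pick))
    for (tr in seq_len(n_trials))
      feat[, (tr - 1) * length(pick) + seq_along(pick)] <-
        trial_tensor[, tr, pick]
  } else {
    feat <- matrix(NA_real_, n_cells, 2 * n_trials)
    for (tr in seq_len(n_trials)) {
      tr_mat <- trial_tensor[, tr, , drop = TRUE]
      if (is.null(dim(tr_mat))) tr_mat <- matrix(tr_mat, nrow = n_cells)
      pk <- apply(tr_mat, 1, which.max)
      feat[, 2 * tr - 1] <- time[pk]
      feat[, 2 * tr] <- tr_mat[cbind(seq_len(n_cells), pk)]
    }
  }
  # impute missing trials by the cell's median feature value
  if (anyNA(feat)) {
    n_imp <- sum(!stats::complete.cases(feat))
    message(sprintf("imputing missing features for %d cell(s) by cell median", n_imp))
    for (c in seq_len(n_cells)) {
      miss <- is.na(feat[c, ])
      if (any(miss)) feat[c, miss] <- stats::median(feat[c, ], na.rm = TRUE)
    }
  }
  ctr <- colMeans(feat)
  scl <- apply(feat, 2, stats::sd)
  const <- scl == 0
  if (all(const)) {
    # identical cells: every feature is constant across cells; the
    # z-scored matrix is all zero by convention
    message("all feature columns constant; returning zero matrix")
    feat <- matrix(0, n_cells, ncol(feat))
    return(structure(feat, class = c("response_matrix", class(feat)),
                     mode = mode, dropped = integer(0),
                     center = ctr, scale = rep(1, length(ctr))))
  }
  if (any(const)) message(sprintf("dropping %d constant feature column(s)", sum(const)))
  feat <- scale(feat[, !const, drop = FALSE], center = ctr[!const],
                scale = scl[!const])
  structure(feat, class = c("response_matrix", class(feat)),
            mode = mode, dropped = which(const),
            center = ctr[!const], scale = scl[!const])
}

#' Principal component reduction of a response matrix
#'
#' Column-centered PCA (no rescaling: the matrix is already z-scored);
#' returns the scores on the leading components and the fraction of
#' variance each explains.
#'
#' @param x cells x features matrix.
#' @param n_components number of components kept.
#' @return list with `scores` (cells x n_components), `explained`
#'   (variance fractions, all components), `loadings`.
#' @export
pca_reduce <- function(x, n_components = 2) {
  x <- unclass(as.matrix(x))
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2 / sum(p$sdev^2)
  k <- min(n_components, ncol(p$x))
  scores <- p$x[, seq_len(k), drop = FALSE]
  if (k < n_components) {
    scores <- cbind(scores, matrix(0, nrow(scores), n_components - k))
    ev <- c(ev, rep(0, n_components - k))
  }
  list(scores = scores, explained = ev,
       loadings = p$rotation[, seq_len(k), drop = FALSE])
}

# log of multivariate normal density, full covariance with cholesky
dmvnorm_log <- function(x, mu, sigma) {
  L <- chol(sigma)
  d <- ncol(x)
  xc <- sweep(x, 2, mu)
  q <- backsolve(L, t(xc), transpose = TRUE)
  -0.5 * colSums(q^2) - sum(log(diag(L))) - 0.5 * d * log(2 * pi)
}

# k-means++ style seeding of component means
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (k > 1) for (j in 2:k) {
    d2 <- apply(x, 1, function(r)
      min(colSums((t(centers[seq_len(j - 1), , drop = FALSE]) - r)^2)))
    p <- if (sum(d2) == 0) rep(1 / n, n) else d2 / sum(d2)
    centers[j, ] <- x[sample.int(n, 1, prob = p), ]
  }
  centers
}

#' Fit a Gaussian mixture to component scores by expectation-maximization
#'
#' Full-covariance GMM fitted by EM from `n_init` k-means++ style
#' initializations (best final log-likelihood kept). Convergence when
#' the log-likelihood improves by less than `tol`; the log-likelihood is
#' asserted non-decreasing on every iteration. A cell is assigned to a
#' component only when its posterior responsibility reaches
#' `likelihood_threshold`; otherwise it is left unclustered (assignment
#' 0) — the cells outside the cluster edges.
#'
#' @param scores cells x d matrix (typically the two leading PC scores).
#' @param k number of mixture components.
#' @param likelihood_threshold responsibility needed for membership.
#' @param n_init number of EM restarts.
#' @param seed integer seed for the initializations.
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per restart.
#' @param reg diagonal covariance regularization floor.
#' @return object of class `gmm_fit`: list with `weights`, `means`
#'   (k x d), `covariances` (d x d x k), `responsibilities` (n x k),
#'   `assignments` (0 = unclustered), `loglik`, `loglik_trace`,
#'   `likelihood_threshold`, `seed`, `n_iter`, `converged`.
#' @export
fit_gmm_em <- function(scores, k = 3, likelihood_threshold = 0.95,
                       n_init = 10, seed = 1L, tol = 1e-8,
                       max_iter = 500, reg = 1e-6) {
  x <- unclass(as.matrix(scores))
  check_finite(x, "scores")
  stop_if(k < 1, "`k` must be >= 1")
  n <- nrow(x); d <- ncol(x)
  stop_if(n <= k, "need more points than components")
  run_em <- function() {
    mu <- kmeanspp_centers(x, k)
    sig <- array(0, c(d, d, k))
    gvar <- stats::cov(x) + diag(reg, d)
    for (j in seq_len(k)) sig[, , j] <- gvar
    w <- rep(1 / k, k)
    ll_trace <- numeric(0)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      # E step
      logd <- vapply(seq_len(k), function(j)
        log(w[j]) + dmvnorm_log(x, mu[j, ], sig[, , j]), numeric(n))
      logd <- matrix(logd, n, k)
      mx <- apply(logd, 1, max)
      lse <- mx + log(rowSums(exp(logd - mx)))
      resp <- exp(logd - lse)
      ll <- sum(lse)
      stop_if(it > 1 && ll < ll_old - 1e-8 * max(1, abs(ll_old)),
              "EM log-likelihood decreased: internal error")
      ll_trace <- c(ll_trace, ll)
      if (it > 1 && ll - ll_old < tol) {
        return(list(w = w, mu = mu, sig = sig, resp = resp, ll = ll,
                    ll_trace = ll_trace, n_iter = it, converged = TRUE))
      }
      ll_old <- ll
      # M step
      nk <- colSums(resp)
      w <- nk / n
      for (j in seq_len(k)) {
        # a (near-)empty component keeps its parameters: partial M-step
        # updates preserve the EM monotonicity guarantee
        if (nk[j] < sqrt(.Machine$double.eps)) next
        mu[j, ] <- colSums(resp[, j] * x) / nk[j]
        xc <- sweep(x, 2, mu[j, ])
        s <- crossprod(xc * resp[, j], xc) / nk[j] + diag(reg, d)
        sig[, , j] <- (s + t(s)) / 2
      }
    }
    list(w = w, mu = mu, sig = sig, resp = resp, ll = ll_old,
         ll_trace = ll_trace, n_iter = max_iter, converged = FALSE)
  }
  with_seed(seed, {
    best <- NULL
    for (i in seq_len(n_init)) {
      fit <- run_em()
      if (is.null(best) || fit$ll > best$ll) best <- fit
    }
    assign <- apply(best$resp, 1, which.max)
    top <- best$resp[cbind(seq_len(n), assign)]
    assign[top < likelihood_threshold] <- 0L
    structure(list(weights = best$w, means = best$mu,
                   covariances = best$sig,
                   responsibilities = best$resp,
                   assignments = as.integer(assign),
                   loglik = best$ll, loglik_trace = best$ll_trace,
                   likelihood_threshold = likelihood_threshold,
                   seed = as.integer(seed), n_iter = best$n_iter,
                   converged = best$converged, k = k),
              class = "gmm_fit")
  })
}

#' @export
print.gmm_fit <- function(x, ...) {
  n <- length(x$assignments)
  cat(sprintf("Gaussian mixture (EM), k = %d, log-likelihood %.2f (%d iterations%s)\n",
              x$k, x$loglik, x$n_iter,
              if (x$converged) "" else ", not converged"))
  cat(sprintf("  weights: %s\n", paste(sprintf("%.3f", x$weights), collapse = " ")))
  cat(sprintf("  membership at responsibility >= %.2f: %d/%d clustered, %d unclustered\n",
              x$likelihood_threshold, sum(x$assignments > 0), n,
              sum(x$assignments == 0)))
  invisible(x)
}

#' @export
summary.gmm_fit <- function(object, ...) {
  tab <- table(factor(object$assignments,
                      levels = 0:object$k,
                      labels = c("unclustered", paste0("cluster_", seq_len(object$k)))))
  out <- list(k = object$k, loglik = object$loglik, weights = object$weights,
              means = object$means, counts = tab)
  class(out) <- "summary.gmm_fit"
  out
}

#' @export
print.summary.gmm_fit <- function(x, ...) {
  cat(sprintf("GMM with %d components, log-likelihood %.2f\n", x$k, x$loglik))
  print(x$counts)
  cat("component means:\n"); print(round(x$means, 3))
  invisible(x)
}

#' @export
plot.gmm_fit <- function(x, scores, ...) {
  stop_if(missing(scores), "supply the scores the model was fitted on")
  cols <- c("grey60", grDevices::hcl.colors(x$k, "Dark 3"))
  graphics::plot(scores[, 1], scores[, 2],
                 col = cols[x$assignments + 1L], pch = 19,
                 xlab = "PC1", ylab = "PC2", ...)
  graphics::points(x$means[, 1], x$means[, 2], pch = 3, cex = 2)
  invisible(x)
}

#' Predict component responsibilities for new points
#'
#' @param object a [fit_gmm_em()] result.
#' @param newdata points x d matrix.
#' @param ... unused.
#' @return matrix of posterior responsibilities, points x k.
#' @export
predict.gmm_fit <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  n <- nrow(x)
  logd <- vapply(seq_len(object$k), function(j)
    log(object$weights[j]) +
      dmvnorm_log(x, object$means[j, ], object$covariances[, , j]),
    numeric(n))
  logd <- matrix(logd, n, object$k)
  mx <- apply(logd, 1, max)
  exp(logd - (mx + log(rowSums(exp(logd - mx)))))
}

#' Across-trial consistency of cluster membership
#'
#' A clustered cell "maintains" its temporal features when, in a strict
#' majority of trials, its trial trace correlates better with its own
#' cluster's template (the across-cell mean trace of that cluster on
#' that trial, leaving the cell itself out) than with any other
#' cluster's. Returns the fraction of clustered cells that do.
#'
#' @param trial_tensor cells x trials x time array (as in
#'   [build_response_matrix()]).
#' @param assignments integer vector from [fit_gmm_em()] (0 =
#'   unclustered, excluded).
#' @return list with `fraction`, `consistent` (logical per clustered
#'   cell), `cells` (their indices).
#' @export
cluster_consistency <- function(trial_tensor, assignments) {
  d <- dim(trial_tensor)
  stop_if(length(d) != 3, "`trial_tensor` must be cells x trials x time")
  stop_if(d[2] < 2, "need at least two trials")
  stop_if(length(assignments) != d[1], "one assignment per cell required")
  ids <- sort(unique(assignments[assignments > 0]))
  cells <- which(assignments > 0)
  stop_if(length(cells) == 0, "no clustered cells")
  if (length(ids) == 1) {
    warning("single cluster: consistency is 1 by definition")
    return(list(fraction = 1, consistent = rep(TRUE, length(cells)),
                cells = cells))
  }
  consistent <- vapply(cells, function(c) {
    own <- assignments[c]
    wins <- 0L
    for (tr in seq_len(d[2])) {
      v <- trial_tensor[c, tr, ]
      if (stats::sd(v) == 0) next
      cors <- vapply(ids, function(k) {
        members <- setdiff(which(assignments == k), c)
        if (length(members) == 0) return(-Inf)
        tmpl <- apply(trial_tensor[members, tr, , drop = FALSE], 3, mean)
        if (stats::sd(tmpl) == 0) return(-Inf)
        stats::cor(v, tmpl)
      }, numeric(1))
      if (which.max(cors) == match(own, ids)) wins <- wins + 1L
    }
    wins > d[2] / 2
  }, logical(1))
  list(fraction = mean(consistent), consistent = consistent, cells = cells)
}
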