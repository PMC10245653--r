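# Event-aligned population statistics: triggered averages, rank-ordered
# rasters, latency inequality (Gini/Lorenz) and CV, Fano-factor epochs,
# synchronization index, and the bootstrap Bayesian activeness posterior.

#' Align dF/F around behavioral events
#'
#' Cuts a window around each event reference time from every cell's dF/F,
#' subtracts the per-event, per-cell mean of the pre-reference window as a
#' local baseline, and stacks the snippets into an events x time x cells
#' tensor. Events whose window would leave the recording are dropped with
#' a message.
#'
#' @param dff_mat frames x cells matrix of dF/F (a single vector is
#'   treated as one cell).
#' @param fs imaging rate, Hz.
#' @param events behavior-event data.frame, or numeric vector of
#'   reference times (s).
#' @param reference `"onset"` or `"offset"` column used when `events` is
#'   a data.frame.
#' @param window `c(pre, post)` seconds around the reference (pre > 0
#'   extends before it).
#' @param baseline_subtract subtract each event's pre-window mean (per
#'   cell). Disable when absolute dF/F levels matter, e.g. for
#'   variance-to-mean (Fano) statistics whose pre-event epoch would
#'   otherwise be centered on zero by construction.
#' @return object of class `aligned_response`: list with `tensor`
#'   (events x time x cells), `time` (s relative to reference), `fs`,
#'   `reference`, `window`, `event_times`, `kept` (indices of retained
#'   events).
#' @export
align_responses <- function(dff_mat, fs, events, reference = c("onset", "offset"),
                            window = c(2, 6), baseline_subtract = TRUE) {
  reference <- match.arg(reference)
  if (is.null(dim(dff_mat))) dff_mat <- matrix(dff_mat, ncol = 1)
  ref_times <- if (is.data.frame(events)) events[[reference]] else as.numeric(events)
  stop_if(length(ref_times) == 0, "no events to align")
  stop_if(any(window < 0) || sum(window) <= 0, "invalid window")
  nt <- nrow(dff_mat)
  pre_f <- round(window[1] * fs); post_f <- round(window[2] * fs)
  ref_f <- round(ref_times * fs) + 1L  # 1-based frame of the reference
  ok <- ref_f - pre_f >= 1L & ref_f + post_f <= nt
  if (any(!ok))
    message(sprintf("dropping %d event(s) whose window leaves the recording",
                    sum(!ok)))
  stop_if(!any(ok), "no usable events: every window leaves the recording")
  ref_f <- ref_f[ok]
  n_ev <- length(ref_f); n_cells <- ncol(dff_mat)
  rel <- (-pre_f):post_f
  tensor <- array(NA_real_, c(n_ev, length(rel), n_cells))
  for (e in seq_len(n_ev)) {
    snip <- dff_mat[ref_f[e] + rel, , drop = FALSE]
    if (baseline_subtract && pre_f > 0) {
      base <- colMeans(snip[seq_len(pre_f), , drop = FALSE])
      snip <- sweep(snip, 2, base)
    }
    tensor[e, , ] <- snip
  }
  structure(list(tensor = tensor, time = rel / fs, fs = fs,
                 reference = reference, window = window,
                 event_times = ref_times[ok], kept = which(ok)),
            class = "aligned_response")
}

#' @export
print.aligned_response <- function(x, ...) {
  d <- dim(x$tensor)
  cat(sprintf("Aligned responses: %d events x %d frames x %d cells, %s-aligned, window [-%g, +%g] s\n",
              d[1], d[2], d[3], x$reference, x$window[1], x$window[2]))
  invisible(x)
}

#' @export
plot.aligned_response <- function(x, ...) {
  avg <- apply(x$tensor, 2, mean)
  graphics::plot(x$time, avg, type = "l", xlab = "time from reference (s)",
                 ylab = "mean dF/F", ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

# Per-event population trace: mean across cells -> events x time matrix.
event_mean_traces <- function(aligned) {
  apply(aligned$tensor, c(1, 2), mean)
}

#' Rank-order aligned responses
#'
#' Sorts the per-event population traces by a key (peak latency by
#' default) with a stable sort, ties keeping event order.
#'
#' @param aligned an [align_responses()] result.
#' @param key numeric sort key per event, or `"peak_latency"`.
#' @return list with `order` (event permutation) and `matrix` (ordered
#'   events x time population traces).
#' @export
rank_order_raster <- function(aligned, key = "peak_latency") {
  m <- event_mean_traces(aligned)
  k <- if (is.character(key) && key == "peak_latency")
    peak_latencies(aligned)$latency else as.numeric(key)
  ord <- order(k, seq_along(k))   # stable: ties by event index
  list(order = ord, matrix = m[ord, , drop = FALSE])
}

#' Peak latencies of aligned responses
#'
#' Latency of each event's across-cell mean trace peak relative to the
#' reference. Flat traces yield `NA` latency; peaks pinned at the window
#' end are flagged as boundary hits.
#'
#' @param aligned an [align_responses()] result.
#' @return data.frame with `event`, `latency` (s), `boundary` (logical).
#' @export
peak_latencies <- function(aligned) {
  m <- event_mean_traces(aligned)
  n_ev <- nrow(m)
  lat <- numeric(n_ev); flat <- logical(n_ev); bound <- logical(n_ev)
  for (e in seq_len(n_ev)) {
    v <- m[e, ]
    if (diff(range(v)) < sqrt(.Machine$double.eps)) {
      lat[e] <- NA_real_; flat[e] <- TRUE; next
    }
    i <- which.max(v)
    lat[e] <- aligned$time[i]
    bound[e] <- i == length(v) || i == 1L
  }
  if (any(flat))
    message(sprintf("%d flat event trace(s): latency undefined, excluded", sum(flat)))
  data.frame(event = seq_len(n_ev), latency = lat, boundary = bound)
}

#' Gini coefficient and Lorenz curve of a latency distribution
#'
#' Inequality of a non-negative distribution: `G = sum_ij |x_i - x_j| /
#' (2 n^2 mean(x))`, computed via the equivalent sorted form, with the
#' Lorenz curve as the cumulative share of the sorted values. Gini 0
#' means all latencies equal; larger values mean a less even spread.
#'
#' @param x non-negative numeric values (n >= 2, positive sum).
#' @return list with `gini` and `lorenz` (data.frame `p`, cumulative
#'   population share, and `share`, cumulative value share, starting at 0).
#' @export
gini_lorenz <- function(x) {
  x <- as.numeric(x)
  stop_if(length(x) < 2, "need at least two values")
  stop_if(any(x < 0), "values must be non-negative")
  stop_if(sum(x) == 0, "all-zero input: Gini undefined")
  n <- length(x)
  s <- sort(x)
  gini <- 2 * sum(seq_len(n) * s) / (n * sum(s)) - (n + 1) / n
  lorenz <- data.frame(p = seq(0, 1, length.out = n + 1),
                       share = c(0, cumsum(s) / sum(s)))
  list(gini = gini, lorenz = lorenz)
}

#' Coefficient of variation
#'
#' Sample SD (n-1 denominator) over the mean.
#'
#' @param x numeric values with non-zero mean.
#' @return scalar CV.
#' @export
coefficient_of_variation <- function(x) {
  m <- mean(x)
  stop_if(m == 0, "zero mean: CV undefined")
  stats::sd(x) / m
}

#' Fano factor by peri-event epoch and its fractional change (rFF)
#'
#' For each named epoch (an interval relative to the reference), the
#' response of event i is its mean dF/F over the epoch (averaged across
#' cells); the Fano factor of the epoch is the across-event
#' variance-to-mean ratio of these responses, and rFF is the percent
#' change of each epoch's FF relative to a reference epoch. Lower rFF
#' indicates responses more reliable than a rate-matched random process.
#' Default epochs: `t0` = [-0.9, -0.1] s (pre-event baseline) and
#' `t1` = [+0.1, +0.9] s (post-reference).
#'
#' @param aligned an [align_responses()] result (>= 2 events).
#' @param epochs named list of `c(start, end)` intervals, seconds
#'   relative to the reference.
#' @param reference_epoch name of the epoch rFF is taken against.
#' @return object of class `epoch_stats`: data.frame with `epoch`,
#'   `mean_response`, `ff`, and `rff` (percent; 0 for the reference
#'   epoch; `NA` with a warning where the epoch mean is <= 0).
#' @export
fano_epochs <- function(aligned,
                        epochs = list(t0 = c(-0.9, -0.1), t1 = c(0.1, 0.9)),
                        reference_epoch = "t0") {
  m <- event_mean_traces(aligned)
  stop_if(nrow(m) < 2, "need at least two events")
  stop_if(!reference_epoch %in% names(epochs),
          "`reference_epoch` not among the epochs")
  res <- lapply(names(epochs), function(nm) {
    iv <- epochs[[nm]]
    stop_if(iv[1] < min(aligned$time) - 1e-9 || iv[2] > max(aligned$time) + 1e-9,
            sprintf("epoch '%s' falls outside the aligned window", nm))
    cols <- aligned$time >= iv[1] & aligned$time <= iv[2]
    r <- rowMeans(m[, cols, drop = FALSE])
    mu <- mean(r)
    ff <- if (mu <= 0) {
      warning(sprintf("epoch '%s' has non-positive mean response; FF undefined", nm))
      NA_real_
    } else stats::var(r) / mu
    data.frame(epoch = nm, mean_response = mu, ff = ff)
  })
  out <- do.call(rbind, res)
  ff_ref <- out$ff[out$epoch == reference_epoch]
  out$rff <- (out$ff - ff_ref) / ff_ref * 100
  out$rff[out$epoch == reference_epoch] <- 0   # exactly, by construction
  structure(out, class = c("epoch_stats", "data.frame"))
}

#' Synchronization index of a cell population
#'
#' Coherence-style ratio `SI = var(population mean trace) / mean(per-cell
#' variance)`, clipped to [0, 1]: 1 when all cells carry an identical
#' signal, ~1/N for N independent cells, and `s^2 / (s^2 + sigma^2)` for
#' a shared signal of variance `s^2` plus independent noise of variance
#' `sigma^2`. Zero-variance cells are excluded with a message.
#'
#' @param mat frames x cells matrix of dF/F (or a binary raster,
#'   transposed to frames x cells).
#' @param context optional label carried into the result.
#' @return object of class `sync_result`: list with `si`, `n_cells`,
#'   `context`.
#' @export
synchronization_index <- function(mat, context = NA_character_) {
  mat <- as.matrix(mat)
  v <- apply(mat, 2, stats::var)
  if (any(v == 0)) {
    message(sprintf("excluding %d zero-variance cell(s)", sum(v == 0)))
    mat <- mat[, v > 0, drop = FALSE]
    v <- v[v > 0]
  }
  stop_if(ncol(mat) < 2, "need at least two cells with variance")
  si <- stats::var(rowMeans(mat)) / mean(v)
  structure(list(si = min(1, max(0, si)), n_cells = ncol(mat),
                 context = context),
            class = "sync_result")
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf("Synchronization index: %.3f (%d cells%s)\n", x$si, x$n_cells,
              if (is.na(x$context)) "" else paste0(", ", x$context)))
  invisible(x)
}

#' Bootstrap Bayesian posterior of animal activeness given a calcium event
#'
#' From a binarized astrocyte event series and co-registered activity
#' labels, estimates `P(active)`, `P(event)` and `P(event | active)` and
#' combines them by Bayes' rule into the posterior `P(active | event)`.
#' Uncertainty comes from `n_boot` bootstrap resamples of time bins; the
#' null distribution recomputes the posterior on `n_null` surrogate event
#' series carrying the same marginal event rate but no relation to the
#' activity labels (independently regenerated Bernoulli series, or
#' circular shifts). Under independence the posterior collapses to
#' `P(active)`, so the null distribution is centered on the activeness
#' marginal.
#'
#' @param event_series logical/0-1 vector: an astrocyte event in the bin.
#' @param active logical/0-1 vector of the same length: animal active.
#' @param n_boot bootstrap resamples.
#' @param n_null null-surrogate recomputations.
#' @param null_method `"bernoulli"` (regenerated series) or
#'   `"circular_shift"`.
#' @param seed integer seed for the resampling.
#' @return object of class `posterior_estimate`: list with `p_active`,
#'   `p_event`, `p_event_given_active`, `posterior`, `boot_distribution`,
#'   `null_distribution`, `seed`.
#' @export
posterior_activeness <- function(event_series, active, n_boot = 1000,
                                 n_null = 1000,
                                 null_method = c("bernoulli", "circular_shift"),
                                 seed = 1L) {
  null_method <- match.arg(null_method)
  ev <- as.logical(event_series); ac <- as.logical(active)
  stop_if(length(ev) != length(ac),
          "event series and activity labels must share a time base")
  n <- length(ev)
  post_of <- function(ev, ac) {
    p_a <- mean(ac); p_e <- mean(ev)
    if (p_e == 0 || p_a == 0) return(NA_real_)
    p_e_a <- mean(ev[ac])
    p_e_a * p_a / p_e
  }
  p_active <- mean(ac); p_event <- mean(ev)
  stop_if(p_event == 0, "no events: posterior undefined")
  p_e_given_a <- mean(ev[ac])
  posterior <- post_of(ev, ac)
  with_seed(seed, {
    boot <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      post_of(ev[i], ac[i])
    }, numeric(1))
    null <- vapply(seq_len(n_null), function(b) {
      ev0 <- if (null_method == "bernoulli") runif(n) < p_event
             else { s <- sample.int(n, 1); ev[((seq_len(n) - 1 + s) %% n) + 1] }
      post_of(ev0, ac)
    }, numeric(1))
    structure(list(p_active = p_active, p_event = p_event,
                   p_event_given_active = p_e_given_a, posterior = posterior,
                   boot_distribution = boot, null_distribution = null,
                   seed = as.integer(seed)),
              class = "posterior_estimate")
  })
}

#' @export
print.posterior_estimate <- function(x, ...) {
  ci <- stats::quantile(x$boot_distribution, c(0.025, 0.975), na.rm = TRUE)
  nci <- stats::quantile(x$null_distribution, c(0.025, 0.975), na.rm = TRUE)
  cat(sprintf("P(active)=%.3f  P(event)=%.3f  P(event|active)=%.3f\n",
              x$p_active, x$p_event, x$p_event_given_active))
  cat(sprintf("posterior P(active|event) = %.3f  [boot 95%% CI %.3f, %.3f]\n",
              x$posterior, ci[1], ci[2]))
  cat(sprintf("independence null         = %.3f  [95%% CI %.3f, %.3f]\n",
              mean(x$null_distribution, na.rm = TRUE), nci[1], nci[2]))
  invisible(x)
}
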