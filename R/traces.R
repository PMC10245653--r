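# Trace processing: ROI extraction, F0 baseline estimation by kernel-density
# mode tracking, dF/F, and dual-wavelength hemodynamic correction.

#' Extract per-ROI mean fluorescence traces from an image stack
#'
#' Computes, for every labeled ROI, the per-frame mean of its pixels —
#' the simple mask-mean alternative to factorization-based source
#' extraction. Accepts either an in-memory array or paths to a multi-page
#' TIFF stack plus an integer-label mask TIFF.
#'
#' @param stack numeric array `height x width x frames`, or path to a
#'   multi-page TIFF file (requires the `tiff` package).
#' @param masks integer matrix of ROI labels (0 = background), or path to a
#'   label-image TIFF.
#' @param fs sampling rate of the stack, Hz.
#' @return matrix `frames x ROIs` of mean fluorescence, columns named
#'   `cell_<label>`, with attributes `fs` and `time`.
#' @export
extract_roi_traces <- function(stack, masks, fs = 4) {
  if (is.character(stack)) stack <- read_tiff_stack(stack)
  if (is.character(masks)) masks <- read_tiff_mask(masks)
  stop_if(length(dim(stack)) != 3, "`stack` must be a height x width x frames array")
  stop_if(!all(dim(stack)[1:2] == dim(masks)),
          "mask dimensions must match the stack frames")
  labels <- sort(unique(as.integer(masks[masks > 0])))
  stop_if(length(labels) == 0, "mask contains no ROIs")
  nt <- dim(stack)[3]
  flat <- matrix(stack, ncol = nt)   # pixels x frames
  out <- matrix(NA_real_, nt, length(labels))
  for (k in seq_along(labels)) {
    idx <- which(masks == labels[k])
    stop_if(length(idx) == 0, sprintf("ROI %d has an empty mask", labels[k]))
    out[, k] <- colMeans(flat[idx, , drop = FALSE])
  }
  colnames(out) <- paste0("cell_", labels)
  attr(out, "fs") <- fs
  attr(out, "time") <- (seq_len(nt) - 1) / fs
  out
}

read_tiff_stack <- function(path) {
  stop_if(!requireNamespace("tiff", quietly = TRUE),
          "reading TIFF stacks requires the `tiff` package")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  array(unlist(pages), dim = c(dim(pages[[1]])[1:2], length(pages)))
}

read_tiff_mask <- function(path) {
  stop_if(!requireNamespace("tiff", quietly = TRUE),
          "reading TIFF masks requires the `tiff` package")
  m <- tiff::readTIFF(path, as.is = TRUE)
  matrix(as.integer(round(m)), nrow(m))
}

#' Estimate the slowly varying baseline F0 by kernel-density mode tracking
#'
#' The trace is partitioned into consecutive bins of `bin_frames` frames
#' and the minimum of each bin is taken; over sliding windows of
#' `window_bins` consecutive minima a Gaussian kernel density is estimated
#' and its mode (peak location on a 256-point grid spanning the window
#' range, ties broken toward the lower value) becomes the local baseline
#' estimate; the window modes, anchored at the window-center frames, are
#' interpolated back to frame resolution with modified Akima interpolation
#' (flat extrapolation at the edges). Because calcium transients are
#' one-sided positive, the mode of binned minima tracks the quiescent
#' fluorescence level while ignoring transients and following slow drift
#' such as photobleaching.
#'
#' @param trace numeric vector of raw fluorescence, strictly positive.
#' @param fs sampling rate, Hz (carried through for bookkeeping).
#' @param bin_frames frames per minimum bin.
#' @param window_bins minima per sliding KDE window.
#' @param kde_bandwidth `"auto"` (Silverman's rule per window) or a fixed
#'   numeric bandwidth in trace units.
#' @param debias correct the downward bias of the minimum statistic: a bin
#'   minimum of noisy data sits below the true baseline by about
#'   `E[min of bin_frames N(0,1)] * sigma`; the noise SD is estimated
#'   robustly from first differences and the window modes are shifted back
#'   up by that expectation, so event-free dF/F is centered on zero rather
#'   than inheriting a noise-dependent positive offset.
#' @return object of class `baseline_model`: list with `f0` (per-frame
#'   baseline, same length as `trace`, floored at a small positive value),
#'   `bin_frames`, `window_bins`, `kde_bandwidth`, `fs`.
#' @export
#' @examples
#' tr <- 100 * exp(-(0:2399) / 4000) + rnorm(2400, 0, 0.5)
#' bl <- estimate_baseline(tr, fs = 4)
#' range(bl$f0)
estimate_baseline <- function(trace, fs = 4, bin_frames = 10,
                              window_bins = 25, kde_bandwidth = "auto",
                              debias = TRUE) {
  trace <- as.numeric(trace)
  check_finite(trace, "trace")
  stop_if(any(trace <= 0), "trace must be strictly positive")
  stop_if(bin_frames < 1 || window_bins < 2, "invalid bin/window sizes")
  n <- length(trace)
  stop_if(n < bin_frames * window_bins,
          sprintf("trace too short: need >= %d frames (bin_frames * window_bins), got %d",
                  bin_frames * window_bins, n))
  nb <- floor(n / bin_frames)
  mins <- vapply(seq_len(nb), function(b)
    min(trace[((b - 1) * bin_frames + 1):(b * bin_frames)]), numeric(1))
  nw <- nb - window_bins + 1L
  modes <- numeric(nw)
  for (w in seq_len(nw)) {
    v <- mins[w:(w + window_bins - 1L)]
    rng <- range(v)
    if (diff(rng) < .Machine$double.eps * max(abs(rng), 1)) {
      modes[w] <- v[1]
      next
    }
    bw <- if (identical(kde_bandwidth, "auto")) stats::bw.nrd0(v)
          else as.numeric(kde_bandwidth)
    d <- stats::density(v, bw = bw, n = 256, from = rng[1], to = rng[2])
    modes[w] <- d$x[which.max(d$y)]   # first max = lower value on ties
  }
  if (debias) {
    sigma_hat <- stats::mad(diff(trace)) / sqrt(2)
    modes <- modes + expected_min_depth(bin_frames) * sigma_hat
  }
  # anchor each mode at the center frame of its window (1-based frame units)
  centers <- ((seq_len(nw) - 1) + (window_bins - 1) / 2) * bin_frames +
    (bin_frames + 1) / 2
  f0 <- if (nw == 1) rep(modes, n)
        else interp_makima(centers, modes, seq_len(n))
  # beyond the outermost window centers makima would hold flat, which lags
  # behind drift (e.g. photobleaching); extend with the local end slopes
  if (nw >= 2) {
    frames <- seq_len(n)
    lo <- frames < centers[1]; hi <- frames > centers[nw]
    sl_lo <- (modes[2] - modes[1]) / (centers[2] - centers[1])
    sl_hi <- (modes[nw] - modes[nw - 1]) / (centers[nw] - centers[nw - 1])
    f0[lo] <- modes[1] + sl_lo * (frames[lo] - centers[1])
    f0[hi] <- modes[nw] + sl_hi * (frames[hi] - centers[nw])
  }
  floor_val <- max(.Machine$double.eps, 1e-6 * stats::median(trace))
  f0 <- pmax(f0, floor_val)
  structure(list(f0 = f0, bin_frames = bin_frames, window_bins = window_bins,
                 kde_bandwidth = kde_bandwidth, fs = fs),
            class = "baseline_model")
}

# E[-min] = E[max] of `n` iid standard normals, by quadrature.
expected_min_depth <- function(n) {
  stats::integrate(function(x) x * n * stats::dnorm(x) * stats::pnorm(x)^(n - 1),
                   -Inf, Inf)$value
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf("Baseline model (KDE mode tracking): %d frames, F0 in [%.3g, %.3g]\n",
              length(x$f0), min(x$f0), max(x$f0)))
  cat(sprintf("  bin %d frames, window %d bins, bandwidth %s\n",
              x$bin_frames, x$window_bins,
              if (identical(x$kde_bandwidth, "auto")) "Silverman (per window)"
              else format(x$kde_bandwidth)))
  invisible(x)
}

#' Compute dF/F from a raw trace and its baseline model
#'
#' @param trace numeric vector of raw fluorescence.
#' @param baseline a [estimate_baseline()] result, or a numeric F0 vector
#'   of the same length.
#' @return numeric dF/F vector `(F - F0) / F0`, with attribute
#'   `corrected = FALSE`.
#' @export
compute_dff <- function(trace, baseline) {
  f0 <- if (inherits(baseline, "baseline_model")) baseline$f0
        else as.numeric(baseline)
  stop_if(length(f0) != length(trace),
          "trace and baseline lengths differ")
  stop_if(any(f0 == 0), "baseline contains zeros; dF/F undefined")
  out <- (as.numeric(trace) - f0) / f0
  attr(out, "corrected") <- FALSE
  out
}

#' Correct fluorescence for hemodynamic absorbance using reflectance
#'
#' Blood-volume and oxygenation changes absorb light in both the
#' excitation and emission bands, contaminating the fluorescence with an
#' activity-locked dip. Under a Beer-Lambert-derived model the measured
#' fluorescence relates to the uncontaminated fluorescence as
#' `F_meas = F * (r_ex/r_ex0)^g_ex * (r_em/r_em0)^g_em`, where the
#' reflectance ratios track absorbance in each band and `g_ex`, `g_em`
#' are effective pathlength exponents. The corrector divides this factor
#' out; with exponents matching the contamination it is an exact inverse.
#'
#' @param trace numeric vector of measured raw fluorescence (a.u.).
#' @param refl a [reflectance_traces()] object, already resampled to the
#'   trace time base.
#' @param gamma_ex,gamma_em pathlength exponents (1 by default; 0 disables
#'   the respective band).
#' @param baseline optional [estimate_baseline()] result or F0 vector for
#'   the corrected trace; if supplied, the corrected dF/F is returned with
#'   attribute `corrected = TRUE`, otherwise the corrected raw trace.
#' @return corrected raw trace, or corrected dF/F when `baseline` is given.
#' @export
correct_hemodynamics <- function(trace, refl, gamma_ex = 1, gamma_em = 1,
                                 baseline = NULL) {
  stop_if(!inherits(refl, "reflectance_traces"),
          "`refl` must be a reflectance_traces object")
  stop_if(length(refl$r_ex) != length(trace),
          "reflectance and trace lengths differ after resampling")
  factor <- (refl$r_ex / refl$r_ex0)^gamma_ex *
    (refl$r_em / refl$r_em0)^gamma_em
  f_corr <- as.numeric(trace) / factor
  if (is.null(baseline)) return(f_corr)
  out <- compute_dff(f_corr, baseline)
  attr(out, "corrected") <- TRUE
  out
}
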