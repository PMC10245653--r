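# Shared fixtures: small scripted tracks and traces built in code.

# A track whose centroid follows scripted per-frame (x, y); nose/tail are
# offset along a fixed heading unless given explicitly.
make_track <- function(xy, fs = 30, nose = NULL, tailbase = NULL,
                       arena = c(40, 40), objects = NULL, half = 4) {
  n <- nrow(xy)
  if (is.null(nose)) nose <- cbind(xy[, 1] + half, xy[, 2])
  if (is.null(tailbase)) tailbase <- cbind(xy[, 1] - half, xy[, 2])
  behavior_track(fs = fs, centroid = xy, nose = nose, tailbase = tailbase,
                 arena = arena, objects = objects)
}

# Stationary track of n frames at a point.
still_xy <- function(n, x = 20, y = 20) cbind(rep(x, n), rep(y, n))

# Straight-line track: n frames moving along +x at speed cm/s.
line_xy <- function(n, fs = 30, speed = 5, x0 = 5, y = 20)
  cbind(x0 + speed * (seq_len(n) - 1) / fs, rep(y, n))

# Frame-wise brute-force oracle for immobility runs (> min_s seconds with
# speed < eps): returns data.frame(onset, offset) in seconds.
oracle_immobility <- function(track, min_s, eps = 0.5) {
  sp <- c(NA, sqrt(rowSums(diff(track$centroid)^2)) * track$fs)
  sp[1] <- sp[2]
  still <- sp < eps
  out <- NULL
  i <- 1; n <- length(still)
  while (i <= n) {
    if (still[i]) {
      j <- i
      while (j < n && still[j + 1]) j <- j + 1
      if ((j - i + 1) / track$fs > min_s)
        out <- rbind(out, data.frame(onset = (i - 1) / track$fs,
                                     offset = j / track$fs))
      i <- j + 1
    } else i <- i + 1
  }
  if (is.null(out)) data.frame(onset = numeric(), offset = numeric()) else out
}

# Frame-wise brute-force oracle for object exploration.
oracle_exploration <- function(track, objects, angle_max = 45) {
  n <- nrow(track$nose)
  flag <- rep(NA_integer_, n)
  best <- rep(Inf, n)
  for (o in objects) {
    for (i in seq_len(n)) {
      dvec <- o$center - track$nose[i, ]
      d <- sqrt(sum(dvec^2))
      if (d > o$radius + o$zone_margin) next
      ax <- track$nose[i, ] - track$tailbase[i, ]
      cosang <- if (d == 0 || sum(ax^2) == 0) 1 else
        sum(ax * dvec) / sqrt(sum(ax^2)) / d
      if (cosang >= cos(angle_max * pi / 180) && d < best[i]) {
        flag[i] <- o$id; best[i] <- d
      }
    }
  }
  flag
}

# O(n^2) pairwise-difference Gini oracle.
oracle_gini <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

# Three-cluster 2-D Gaussian mixture with known labels; collinear centers
# `sep` standard deviations apart (adjacent pairs), so each component has
# at most two 5-sigma neighbours and the 0.95-responsibility boundary
# leaves only a few percent of cells unclustered.
make_mixture <- function(n = 300, sep = 5, sd = 1, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(sep, 0), c(2 * sep, 0)) * sd
  lab <- sample(rep(1:3, length.out = n))
  pts <- centers[lab, ] + matrix(rnorm(2 * n, 0, sd), n)
  list(x = pts, labels = lab, centers = centers)
}
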