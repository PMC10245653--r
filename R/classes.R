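# Lightweight S3 containers shared across the pipeline. Conventions fixed
# package-wide: time in seconds, lengths in cm, rates in Hz, frames 0-based
# in files (1-based inside R), behavioral intervals half-open [onset, offset).

#' Dual-wavelength reflectance traces
#'
#' Co-recorded reflectance at the excitation (473 nm) and emission (523 nm)
#' bands, with their reference (uncontaminated baseline) levels, used for
#' hemodynamic correction of fluorescence.
#'
#' @param r_ex,r_em reflectance vectors, strictly positive, equal length.
#' @param r_ex0,r_em0 reference reflectance scalars, strictly positive.
#' @param fs sampling rate, Hz.
#' @return object of class `reflectance_traces`.
#' @export
reflectance_traces <- function(r_ex, r_em, r_ex0 = mean(r_ex),
                               r_em0 = mean(r_em), fs) {
  stop_if(length(r_ex) != length(r_em),
          "excitation and emission reflectance must have equal length")
  stop_if(any(r_ex <= 0) || any(r_em <= 0) || r_ex0 <= 0 || r_em0 <= 0,
          "reflectance values must be strictly positive")
  stop_if(fs <= 0, "`fs` must be > 0")
  check_finite(r_ex); check_finite(r_em)
  structure(list(r_ex = as.numeric(r_ex), r_em = as.numeric(r_em),
                 r_ex0 = r_ex0, r_em0 = r_em0, fs = fs),
            class = "reflectance_traces")
}

#' Keypoint track of a freely moving mouse
#'
#' Frame-wise centroid, nose, and tail-base coordinates (cm) in the arena
#' frame, plus optional object layout for exploration scoring.
#'
#' @param fs tracking rate, Hz.
#' @param centroid,nose,tailbase n x 2 matrices of (x, y) positions, cm.
#' @param arena `c(width, height)`, cm.
#' @param objects optional list of [object_spec()].
#' @return object of class `behavior_track`.
#' @export
behavior_track <- function(fs, centroid, nose, tailbase, arena,
                           objects = NULL) {
  centroid <- as.matrix(centroid); nose <- as.matrix(nose)
  tailbase <- as.matrix(tailbase)
  stop_if(fs <= 0, "`fs` must be > 0")
  stop_if(ncol(centroid) != 2 || ncol(nose) != 2 || ncol(tailbase) != 2,
          "keypoint matrices must have two columns (x, y)")
  stop_if(nrow(nose) != nrow(centroid) || nrow(tailbase) != nrow(centroid),
          "keypoint matrices must have equal row counts")
  structure(list(fs = fs, centroid = centroid, nose = nose,
                 tailbase = tailbase, arena = as.numeric(arena),
                 objects = objects),
            class = "behavior_track")
}

#' @export
print.behavior_track <- function(x, ...) {
  cat(sprintf("Behavior track: %d frames at %g Hz (%.1f s), arena %g x %g cm\n",
              nrow(x$centroid), x$fs, nrow(x$centroid) / x$fs,
              x$arena[1], x$arena[2]))
  invisible(x)
}

#' Object specification for exploration assays
#'
#' @param center `(x, y)` position of the object center, cm.
#' @param radius object radius, cm.
#' @param zone_margin width of the interaction zone around the object, cm.
#' @param id integer object identifier.
#' @return object of class `object_spec`.
#' @export
object_spec <- function(center, radius = 2, zone_margin = 2.5, id = 1L) {
  stop_if(radius < 0, "`radius` must be >= 0")
  stop_if(zone_margin <= 0, "`zone_margin` must be > 0")
  structure(list(center = as.numeric(center), radius = radius,
                 zone_margin = zone_margin, id = as.integer(id)),
            class = "object_spec")
}

# Frame-wise centroid speed, cm/s; first frame repeats the second so the
# vector has track length.
track_speed <- function(track) {
  d <- diff(track$centroid)
  sp <- sqrt(rowSums(d^2)) * track$fs
  c(sp[1], sp)
}

# Construct an empty behavior-event table with the canonical columns.
empty_behavior_events <- function() {
  data.frame(label = character(), onset = numeric(), offset = numeric(),
             dh = numeric(), target_id = integer())
}
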