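# Behavioral event detection from keypoint tracks: locomotion, sleep,
# rearing, object-directed exploration, Q-A transitions, circadian
# structure, and novelty preference.

# Interval conventions: onsets/offsets in seconds, half-open [onset, offset);
# a run of frames i0..i1 (1-based) maps to onset (i0-1)/fs, offset i1/fs.

frames_to_interval <- function(start, end, fs)
  list(onset = (start - 1) / fs, offset = end / fs)

clean_track <- function(track, max_gap = 5L) {
  for (kp in c("centroid", "nose", "tailbase")) {
    m <- track[[kp]]
    m[, 1] <- fill_gaps(m[, 1], max_gap, kp)
    m[, 2] <- fill_gaps(m[, 2], max_gap, kp)
    track[[kp]] <- m
  }
  track
}

#' Locomotion summary from a keypoint track
#'
#' Total path length of the centroid, mean speed over moving frames only,
#' and total movement time. A frame is "moving" when its step speed
#' exceeds `move_thresh`.
#'
#' @param track a [behavior_track()].
#' @param move_thresh movement threshold, cm/s.
#' @param max_gap maximum NA gap (frames) interpolated before erroring.
#' @return object of class `locomotion_summary`: list with `distance`
#'   (cm), `mean_speed` (cm/s over moving frames, `NA` if never moving),
#'   `movement_time` (s), `n_frames`, `fs`.
#' @export
compute_locomotion <- function(track, move_thresh = 0.5, max_gap = 5L) {
  stop_if(!inherits(track, "behavior_track"), "`track` must be a behavior_track")
  stop_if(nrow(track$centroid) < 2, "need at least two frames")
  track <- clean_track(track, max_gap)
  steps <- sqrt(rowSums(diff(track$centroid)^2))
  speed <- steps * track$fs
  moving <- speed > move_thresh
  structure(list(distance = sum(steps),
                 mean_speed = if (any(moving)) mean(speed[moving]) else NA_real_,
                 movement_time = sum(moving) / track$fs,
                 n_frames = nrow(track$centroid), fs = track$fs),
            class = "locomotion_summary")
}

#' @export
print.locomotion_summary <- function(x, ...) {
  cat(sprintf("Locomotion: %.1f cm (%.4f km), moving %.1f s, mean speed %.2f cm/s\n",
              x$distance, x$distance / 1e5, x$movement_time,
              if (is.na(x$mean_speed)) 0 else x$mean_speed))
  invisible(x)
}

#' Score sleep from sustained immobility
#'
#' Maximal runs of frames whose centroid speed stays below `motion_eps`
#' for strictly longer than `immobility_min` seconds are scored as sleep,
#' following the EEG/EMG-validated immobility rule (>40 s).
#'
#' @param track a [behavior_track()].
#' @param immobility_min minimum immobility duration, seconds (exclusive).
#' @param motion_eps immobility speed threshold, cm/s.
#' @return behavior-event data.frame (`label = "sleep"`).
#' @export
detect_sleep <- function(track, immobility_min = 40, motion_eps = 0.5) {
  stop_if(!inherits(track, "behavior_track"), "`track` must be a behavior_track")
  track <- clean_track(track)
  still <- track_speed(track) < motion_eps
  r <- runs_true(still)
  r <- r[(r$end - r$start + 1) / track$fs > immobility_min, , drop = FALSE]
  if (nrow(r) == 0) return(empty_behavior_events())
  iv <- frames_to_interval(r$start, r$end, track$fs)
  data.frame(label = "sleep", onset = iv$onset, offset = iv$offset,
             dh = NA_real_, target_id = NA_integer_)
}

#' Detect rearing from body-length extension
#'
#' Uses the 2-D nose-to-tailbase distance as a proxy for upright truncal
#' extension: relative to a running-median baseline length, a rear starts
#' when the body length exceeds `(1 + extension_thresh)` times baseline
#' and ends when it falls back below `(1 + extension_thresh/2)` times
#' baseline (hysteresis against chatter). `dh` is the maximal absolute
#' extension above baseline during the event.
#'
#' @param track a [behavior_track()].
#' @param extension_thresh relative extension entering a rear (0.25 = 25%).
#' @param min_duration minimum rear duration kept, seconds.
#' @param baseline_window running-median window for baseline length, seconds.
#' @return behavior-event data.frame (`label = "rear"`, `dh` in cm).
#' @export
detect_rearing <- function(track, extension_thresh = 0.25, min_duration = 0.3,
                           baseline_window = 5) {
  stop_if(!inherits(track, "behavior_track"), "`track` must be a behavior_track")
  track <- clean_track(track)
  len <- sqrt(rowSums((track$nose - track$tailbase)^2))
  k <- max(3L, round(baseline_window * track$fs))
  if (k %% 2 == 0) k <- k + 1L
  k <- min(k, if (length(len) %% 2 == 1) length(len) else length(len) - 1L)
  l0 <- stats::runmed(len, k, endrule = "median")
  hi <- len > l0 * (1 + extension_thresh)
  lo <- len > l0 * (1 + extension_thresh / 2)
  inrear <- hysteresis_runs(hi, lo)
  r <- runs_true(inrear)
  r <- r[(r$end - r$start + 1) / track$fs >= min_duration, , drop = FALSE]
  if (nrow(r) == 0) return(empty_behavior_events())
  dh <- vapply(seq_len(nrow(r)), function(i)
    max(len[r$start[i]:r$end[i]] - l0[r$start[i]:r$end[i]]), numeric(1))
  iv <- frames_to_interval(r$start, r$end, track$fs)
  data.frame(label = "rear", onset = iv$onset, offset = iv$offset,
             dh = dh, target_id = NA_integer_)
}

# Hysteresis: state turns on where `hi` is TRUE and stays on while `lo`
# remains TRUE.
hysteresis_runs <- function(hi, lo) {
  state <- logical(length(hi))
  on <- FALSE
  for (i in seq_along(hi)) {
    on <- if (on) lo[i] else hi[i]
    state[i] <- on
  }
  state
}

#' Detect object-directed (inspective) exploration
#'
#' A frame counts as exploratory toward an object when (a) the nose lies
#' within the interaction zone — `radius + zone_margin` (2.5 cm margin by
#' default) of the object center — and (b) the anterior-posterior axis
#' (tailbase to nose) points toward the object: the angle between the
#' axis and the nose-to-center direction is at most `angle_max`. Frames
#' whose nose falls in overlapping zones are assigned to the nearest
#' object center. Consecutive exploratory frames toward the same object
#' merge into one event.
#'
#' @param track a [behavior_track()].
#' @param objects list of [object_spec()]; defaults to `track$objects`.
#' @param angle_max maximal head-axis deviation, degrees.
#' @return behavior-event data.frame (`label = "object_exploration"`,
#'   `target_id` = object id).
#' @export
detect_object_exploration <- function(track, objects = track$objects,
                                      angle_max = 45) {
  stop_if(!inherits(track, "behavior_track"), "`track` must be a behavior_track")
  stop_if(is.null(objects) || length(objects) == 0, "no objects supplied")
  track <- clean_track(track)
  nf <- nrow(track$nose)
  axis <- track$nose - track$tailbase
  target <- rep(NA_integer_, nf)
  bestd <- rep(Inf, nf)
  for (o in objects) {
    dx <- o$center[1] - track$nose[, 1]
    dy <- o$center[2] - track$nose[, 2]
    d <- sqrt(dx^2 + dy^2)
    inzone <- d <= o$radius + o$zone_margin
    dot <- axis[, 1] * dx + axis[, 2] * dy
    na <- sqrt(rowSums(axis^2))
    cosang <- ifelse(na * d > 0, dot / (na * d), 1)  # nose at center: oriented
    oriented <- cosang >= cos(angle_max * pi / 180)
    hit <- inzone & oriented & d < bestd
    target[hit] <- o$id
    bestd[hit] <- d[hit]
  }
  out <- list()
  for (id in sort(unique(target[!is.na(target)]))) {
    r <- runs_true(!is.na(target) & target == id)
    iv <- frames_to_interval(r$start, r$end, track$fs)
    out[[length(out) + 1L]] <- data.frame(
      label = "object_exploration", onset = iv$onset, offset = iv$offset,
      dh = NA_real_, target_id = id)
  }
  if (length(out) == 0) return(empty_behavior_events())
  res <- do.call(rbind, out)
  res[order(res$onset), , drop = FALSE]
}

#' Detect quiescence-to-active (Q-A) transitions
#'
#' A Q-A onset is the first frame with speed at or above `speed_on` that
#' follows at least `quiescence_min` seconds of speed continuously below
#' it — the voluntary transition from behavioral quiescence to movement
#' that drives global arousal-linked astrocyte activation.
#'
#' @param track a [behavior_track()].
#' @param quiescence_min minimum preceding quiescence, seconds.
#' @param speed_on movement-onset speed threshold, cm/s.
#' @return behavior-event data.frame (`label = "qa"`); `onset` is the
#'   transition time, `offset` the end of the triggering movement bout.
#' @export
detect_qa_transitions <- function(track, quiescence_min = 20, speed_on = 0.5) {
  stop_if(!inherits(track, "behavior_track"), "`track` must be a behavior_track")
  track <- clean_track(track)
  speed <- track_speed(track)
  below <- speed < speed_on
  rb <- runs_true(below)
  need <- quiescence_min * track$fs
  out <- list()
  for (i in seq_len(nrow(rb))) {
    if ((rb$end[i] - rb$start[i] + 1) >= need && rb$end[i] < length(speed)) {
      on_frame <- rb$end[i] + 1L
      # movement bout extends while speed stays at/above threshold
      j <- on_frame
      while (j < length(speed) && speed[j + 1L] >= speed_on) j <- j + 1L
      iv <- frames_to_interval(on_frame, j, track$fs)
      out[[length(out) + 1L]] <- data.frame(
        label = "qa", onset = iv$onset, offset = iv$offset,
        dh = NA_real_, target_id = NA_integer_)
    }
  }
  if (length(out) == 0) return(empty_behavior_events())
  do.call(rbind, out)
}

#' Hourly circadian activity profile and phase split
#'
#' Bins activity into hours, reports the raw hourly active fraction, the
#' peak-aligned profile (rotated so the maximum sits at index 1), and an
#' active/inactive phase split defined as the contiguous 12-hour window
#' (circular) with the greatest summed activity.
#'
#' @param activity logical/0-1 vector of per-sample activity, or a
#'   [behavior_track()] from which activity is derived as speed >=
#'   `move_thresh`.
#' @param fs sample rate of `activity`, Hz (taken from the track if one
#'   is given).
#' @param move_thresh speed threshold when deriving activity, cm/s.
#' @return list with `hourly` (active fraction per full hour), `aligned`
#'   (rotated so `aligned[1]` is the peak), `peak_hour` (0-based hour of
#'   the raw maximum), `phase` (factor "active"/"inactive" per hour), and
#'   `degenerate` (TRUE when the phase split is tied/flat).
#' @export
circadian_profile <- function(activity, fs = 1, move_thresh = 0.5) {
  if (inherits(activity, "behavior_track")) {
    fs <- activity$fs
    activity <- track_speed(activity) >= move_thresh
  }
  act <- as.numeric(activity)
  per_hour <- round(3600 * fs)
  n_full <- floor(length(act) / per_hour)
  stop_if(n_full < 24, "need at least 24 full hours of samples")
  if (length(act) > n_full * per_hour)
    warning("partial final hour dropped")
  act <- act[seq_len(n_full * per_hour)]
  hourly <- colMeans(matrix(act, per_hour, n_full))
  peak <- which.max(hourly)
  aligned <- hourly[((seq_len(n_full) - 1 + peak - 1) %% n_full) + 1]
  # best contiguous 12-h window on the 24-h circle
  h24 <- hourly[seq_len(24)]
  sums <- vapply(0:23, function(s)
    sum(h24[((s + 0:11) %% 24) + 1]), numeric(1))
  degenerate <- max(sums) - min(sums) < sqrt(.Machine$double.eps)
  if (degenerate) warning("flat activity: active/inactive split is degenerate")
  s0 <- which.max(sums) - 1L
  phase <- rep("inactive", n_full)
  phase[((s0 + 0:11) %% 24) + 1] <- "active"
  list(hourly = hourly, aligned = aligned, peak_hour = peak - 1L,
       phase = factor(phase, levels = c("active", "inactive")),
       degenerate = degenerate)
}

#' Novelty preference from exploration events
#'
#' Fractions of exploration time on the novel vs. familiar object and the
#' discriminability index, defined as the normalized difference
#' `d' = (T_novel - T_familiar) / (T_novel + T_familiar)`.
#'
#' @param events behavior-event data.frame (uses `label ==
#'   "object_exploration"`, `target_id`, and interval durations), or a
#'   named numeric vector of exploration times.
#' @param familiar_id,novel_id object identifiers.
#' @return list with `t_novel`, `t_familiar` (s), `fraction_novel`,
#'   `fraction_familiar`, and `dprime`.
#' @export
novelty_preference <- function(events, familiar_id = 1L, novel_id = 2L) {
  if (is.data.frame(events)) {
    ex <- events[events$label == "object_exploration", , drop = FALSE]
    dur <- ex$offset - ex$onset
    t_f <- sum(dur[ex$target_id == familiar_id])
    t_n <- sum(dur[ex$target_id == novel_id])
  } else {
    stop_if(length(events) != 2,
            "numeric input must be c(familiar, novel) exploration times")
    nm <- names(events)
    if (!is.null(nm) && all(c("familiar", "novel") %in% nm)) {
      t_f <- as.numeric(events[["familiar"]])
      t_n <- as.numeric(events[["novel"]])
    } else {
      t_f <- as.numeric(events[1]); t_n <- as.numeric(events[2])
    }
  }
  total <- t_n + t_f
  stop_if(total == 0, "zero total exploration time; preference undefined")
  list(t_novel = t_n, t_familiar = t_f,
       fraction_novel = t_n / total, fraction_familiar = t_f / total,
       dprime = (t_n - t_f) / total)
}
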