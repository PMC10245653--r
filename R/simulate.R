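#' Simulation configuration for a synthetic fiberscope session
#'
#' Bundles and validates every parameter of the synthetic-data generator:
#' imaging and tracking rates, GCaMP-like transient kinetics, photobleaching,
#' noise, the latency of global arousal transients after movement onset,
#' the cluster structure of novelty responses, hemodynamic contamination
#' depth, circadian modulation, and the arena geometry.
#'
#' Transients are difference-of-exponentials kernels
#' `A * (exp(-t/tau_d) - exp(-t/tau_r))`, normalized so `A` is the
#' amplitude at the kernel maximum. The slow defaults (0.5 s rise, 3 s
#' decay) mimic store-driven astrocyte GCaMP3 transients; they are exposed
#' here because the kinetics are configuration, not measured constants.
#'
#' @param n_cells number of simulated astrocytes.
#' @param duration session length, seconds.
#' @param fs_imaging imaging sampling rate, Hz.
#' @param fs_track keypoint tracking rate, Hz.
#' @param transient_rise,transient_decay kernel time constants, seconds.
#' @param baseline_level mean baseline fluorescence, a.u.
#' @param baseline_jitter fractional per-cell spread of the baseline level.
#' @param bleach_tau photobleaching exponential time constant, seconds.
#' @param noise_sd additive Gaussian noise SD, a.u.
#' @param qa_latency latency of the global arousal transient after each
#'   quiescence-to-active (Q-A) movement onset, seconds.
#' @param qa_amplitude dF/F amplitude of Q-A transients.
#' @param spont_rate per-cell spontaneous transient rate, Hz (default
#'   0.0035 Hz = 0.21 events/cell/min, the active-phase event rate this
#'   kind of recording shows).
#' @param spont_amplitude dF/F amplitude of spontaneous transients.
#' @param cluster_spec data.frame with columns `fraction`, `latency`,
#'   `amplitude`: subpopulations responding to novelty exploration at
#'   distinct peri-event latencies. Fractions must sum to <= 1; the
#'   remainder of cells respond inconsistently (unclustered).
#' @param hemo_depth fractional reflectance dip during activity (0 = none).
#' @param gamma_ex,gamma_em pathlength exponents of the hemodynamic
#'   forward model (see [correct_hemodynamics()]).
#' @param circadian_period circadian period, hours.
#' @param circadian_depth modulation depth of activity probability, 0..1.
#' @param peak_hour circadian hour of maximal activity.
#' @param activity_base baseline probability of being active per sample.
#' @param arena `c(width, height)` of the arena, cm.
#' @param body_length nose-to-tailbase distance, cm.
#' @param speed_mean locomotion speed when moving, cm/s.
#' @param n_qa,n_rear,n_explore,n_sleep counts of scripted behavioral events.
#' @param rear_extension fractional body-length extension during rears.
#' @param rear_duration rear duration, seconds.
#' @param explore_duration object-exploration bout duration, seconds.
#' @param track_jitter SD of optional keypoint jitter, cm (0 = noise-free).
#' @param seed integer seed; identical seeds give bit-identical sessions.
#' @return an object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_cells = 25,
                       duration = 600,
                       fs_imaging = 4,
                       fs_track = 30,
                       transient_rise = 0.5,
                       transient_decay = 3.0,
                       baseline_level = 100,
                       baseline_jitter = 0.1,
                       bleach_tau = 2000,
                       noise_sd = 1,
                       qa_latency = 1.0,
                       qa_amplitude = 0.5,
                       spont_rate = 0.0035,
                       spont_amplitude = 0.4,
                       cluster_spec = data.frame(
                         fraction  = c(0.35, 0.30, 0.20),
                         latency   = c(0.5, 1.5, 3.0),
                         amplitude = c(0.50, 0.35, 0.25)),
                       hemo_depth = 0.05,
                       gamma_ex = 1,
                       gamma_em = 1,
                       circadian_period = 24,
                       circadian_depth = 0.9,
                       peak_hour = 6,
                       activity_base = 0.4,
                       arena = c(40, 40),
                       body_length = 8,
                       speed_mean = 5,
                       n_qa = 6,
                       n_rear = 5,
                       n_explore = 8,
                       n_sleep = 1,
                       rear_extension = 0.4,
                       rear_duration = 1.5,
                       explore_duration = 2.0,
                       track_jitter = 0,
                       seed = 1L) {
  cfg <- as.list(environment())
  num <- vapply(cfg, is.numeric, logical(1)) & !names(cfg) %in% "cluster_spec"
  bad <- names(cfg)[num][!vapply(cfg[num], function(x) all(is.finite(x)), logical(1))]
  stop_if(length(bad) > 0,
          "non-finite config values: ", paste(bad, collapse = ", "))
  pos <- c("n_cells", "duration", "fs_imaging", "fs_track", "transient_rise",
           "transient_decay", "baseline_level", "bleach_tau", "qa_latency",
           "circadian_period", "body_length", "speed_mean", "rear_duration",
           "explore_duration")
  for (p in pos) stop_if(any(cfg[[p]] <= 0), sprintf("`%s` must be > 0", p))
  neg <- c("noise_sd", "hemo_depth", "spont_rate", "track_jitter",
           "baseline_jitter", "n_qa", "n_rear", "n_explore", "n_sleep")
  for (p in neg) stop_if(any(cfg[[p]] < 0), sprintf("`%s` must be >= 0", p))
  stop_if(transient_decay <= transient_rise,
          "`transient_decay` must exceed `transient_rise`")
  cs <- cfg$cluster_spec
  stop_if(!is.data.frame(cs) ||
            !all(c("fraction", "latency", "amplitude") %in% names(cs)),
          "`cluster_spec` needs columns fraction, latency, amplitude")
  stop_if(sum(cs$fraction) > 1 + 1e-12, "cluster fractions must sum to <= 1")
  stop_if(any(!is.finite(unlist(cs))), "non-finite values in `cluster_spec`")
  cfg$arena <- as.numeric(arena)
  stop_if(length(cfg$arena) != 2 || any(cfg$arena <= 0),
          "`arena` must be two positive numbers (width, height)")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic session configuration\n")
  cat(sprintf("  %d cells, %.0f s at %g Hz imaging / %g Hz tracking\n",
              x$n_cells, x$duration, x$fs_imaging, x$fs_track))
  cat(sprintf("  kinetics: rise %.2g s, decay %.2g s; noise SD %.3g a.u.\n",
              x$transient_rise, x$transient_decay, x$noise_sd))
  cat(sprintf("  behavior: %d Q-A, %d rears, %d explorations, %d sleep bouts\n",
              x$n_qa, x$n_rear, x$n_explore, x$n_sleep))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

# Difference-of-exponentials transient sampled at times t >= 0 (t relative
# to onset), unit peak amplitude.
transient_kernel <- function(t, rise, decay) {
  tp <- log(decay / rise) * rise * decay / (decay - rise)
  pk <- exp(-tp / decay) - exp(-tp / rise)
  ifelse(t < 0, 0, (exp(-t / decay) - exp(-t / rise)) / pk)
}

# Time from transient onset to kernel peak.
transient_peak_delay <- function(rise, decay) {
  log(decay / rise) * rise * decay / (decay - rise)
}

# ---- behavioral script ------------------------------------------------------

# Build the segment script for one session. Returns a data.frame of segments
# (type, duration, target) whose total fits within cfg$duration.
session_script <- function(cfg) {
  seg <- function(type, duration, target = NA_integer_)
    data.frame(type = type, duration = duration, target = target)
  pieces <- list(seg("active", 10))
  for (i in seq_len(cfg$n_qa)) {
    pieces[[length(pieces) + 1L]] <- seg("quiet", 30)
    pieces[[length(pieces) + 1L]] <- seg("active", 20)
  }
  for (i in seq_len(cfg$n_rear)) {
    pieces[[length(pieces) + 1L]] <- seg("active", 5)
    pieces[[length(pieces) + 1L]] <- seg("rear", cfg$rear_duration)
    pieces[[length(pieces) + 1L]] <- seg("active", 5)
  }
  for (i in seq_len(cfg$n_explore)) {
    target <- if (i %% 4 == 0) 1L else 2L  # object 2 = novel, favoured 3:1
    pieces[[length(pieces) + 1L]] <- seg("active", 4)
    pieces[[length(pieces) + 1L]] <- seg("explore", cfg$explore_duration, target)
    pieces[[length(pieces) + 1L]] <- seg("active", 4)
  }
  for (i in seq_len(cfg$n_sleep)) {
    pieces[[length(pieces) + 1L]] <- seg("active", 5)
    pieces[[length(pieces) + 1L]] <- seg("sleep", 60)
    pieces[[length(pieces) + 1L]] <- seg("active", 5)
  }
  script <- do.call(rbind, pieces)
  total <- sum(script$duration)
  stop_if(total > cfg$duration,
          sprintf("duration %.0f s too short for the scripted events (need %.0f s)",
                  cfg$duration, total))
  if (total < cfg$duration)
    script <- rbind(script, data.frame(type = "active",
                                       duration = cfg$duration - total,
                                       target = NA_integer_))
  script$onset <- cumsum(c(0, script$duration))[seq_len(nrow(script))]
  script
}

default_objects <- function(cfg) {
  w <- cfg$arena[1]; h <- cfg$arena[2]
  list(object_spec(center = c(0.25 * w, 0.25 * h), radius = 2, id = 1L),
       object_spec(center = c(0.75 * w, 0.75 * h), radius = 2, id = 2L))
}

# Generate keypoint tracks frame by frame from the segment script.
script_to_track <- function(cfg, script) {
  nf <- round(cfg$duration * cfg$fs_track)
  dt <- 1 / cfg$fs_track
  objects <- default_objects(cfg)
  half <- cfg$body_length / 2
  margin <- 4
  cx <- cfg$arena[1] / 2; cy <- cfg$arena[2] / 2
  centroid <- matrix(NA_real_, nf, 2)
  heading <- numeric(nf)
  extension <- rep(1, nf)       # body-length multiplier (rearing)
  explore_target <- rep(NA_integer_, nf)
  pos <- c(cx, cy); ang <- 0
  frame_of <- function(t) pmin(nf, floor(t * cfg$fs_track) + 1L)
  for (s in seq_len(nrow(script))) {
    i0 <- frame_of(script$onset[s])
    i1 <- if (s < nrow(script)) frame_of(script$onset[s + 1]) - 1L else nf
    if (i1 < i0) next
    type <- script$type[s]
    if (type == "active") {
      for (i in i0:i1) {
        ang <- ang + rnorm(1, 0, 0.4)
        step <- cfg$speed_mean * dt
        cand <- pos + step * c(cos(ang), sin(ang))
        # reflect off walls (with margin so the nose stays inside)
        if (cand[1] < margin || cand[1] > cfg$arena[1] - margin) {
          ang <- pi - ang; cand <- pos + step * c(cos(ang), sin(ang))
        }
        if (cand[2] < margin || cand[2] > cfg$arena[2] - margin) {
          ang <- -ang; cand <- pos + step * c(cos(ang), sin(ang))
        }
        # steer clear of object interaction zones while roaming, so only
        # scripted visits count as exploration (nose stays outside the
        # zone with a safety buffer)
        for (ob in objects) {
          nose_cand <- cand + half * c(cos(ang), sin(ang))
          dd <- sqrt(sum((nose_cand - ob$center)^2))
          if (dd < ob$radius + ob$zone_margin + 1.5) {
            away <- pos - ob$center
            ang <- atan2(away[2], away[1])
            cand <- pos + step * c(cos(ang), sin(ang))
          }
        }
        pos <- pmin(pmax(cand, margin), cfg$arena - margin)
        centroid[i, ] <- pos; heading[i] <- ang
      }
    } else if (type == "explore") {
      obj <- objects[[script$target[s]]]
      # nose parked 1 cm inside the interaction zone, axis through the center
      dir <- (obj$center - pos); dir <- dir / sqrt(sum(dir^2))
      nose <- obj$center - dir * (obj$radius + 1)
      ang <- atan2(dir[2], dir[1])
      pos <- nose - dir * half
      centroid[i0:i1, 1] <- pos[1]; centroid[i0:i1, 2] <- pos[2]
      heading[i0:i1] <- ang
      explore_target[i0:i1] <- obj$id
    } else { # quiet, sleep, rear: stationary
      centroid[i0:i1, 1] <- pos[1]; centroid[i0:i1, 2] <- pos[2]
      heading[i0:i1] <- ang
      if (type == "rear") extension[i0:i1] <- 1 + cfg$rear_extension
    }
  }
  nose <- centroid + half * extension * cbind(cos(heading), sin(heading))
  tailbase <- centroid - half * extension * cbind(cos(heading), sin(heading))
  if (cfg$track_jitter > 0) {
    centroid <- centroid + matrix(rnorm(2 * nf, 0, cfg$track_jitter), nf)
    nose <- nose + matrix(rnorm(2 * nf, 0, cfg$track_jitter), nf)
    tailbase <- tailbase + matrix(rnorm(2 * nf, 0, cfg$track_jitter), nf)
  }
  behavior_track(fs = cfg$fs_track, centroid = centroid, nose = nose,
                 tailbase = tailbase, arena = cfg$arena, objects = objects)
}

# Ground-truth behavior events from the script (half-open [onset, offset)).
script_to_events <- function(cfg, script) {
  ev <- list()
  add <- function(label, onset, offset, dh = NA_real_, target = NA_integer_)
    ev[[length(ev) + 1L]] <<- data.frame(label = label, onset = onset,
                                         offset = offset, dh = dh,
                                         target_id = target)
  for (s in seq_len(nrow(script))) {
    on <- script$onset[s]; off <- on + script$duration[s]
    type <- script$type[s]
    if (type == "rear")
      add("rear", on, off, dh = cfg$body_length * cfg$rear_extension)
    else if (type == "explore")
      add("object_exploration", on, off, target = script$target[s])
    else if (type == "sleep")
      add("sleep", on, off)
    else if (type == "active") {
      add("active_bout", on, off)
      if (s > 1 && script$type[s - 1] %in% c("quiet", "sleep") &&
          script$duration[s - 1] >= 20)
        add("qa", on, off)
    }
  }
  out <- do.call(rbind, ev)
  out[order(out$onset), , drop = FALSE]
}

# ---- session generator ------------------------------------------------------

#' Simulate a complete fiberscope recording session with ground truth
#'
#' Generates per-cell fluorescence traces, dual-wavelength reflectance,
#' keypoint tracks, and the full ground truth needed to validate every
#' downstream stage: true baselines, true transient times, true behavior
#' intervals, and true cluster labels.
#'
#' The forward model per cell is
#' `F_meas(t) = F0(t) * (1 + dF/F(t)) * (r_ex/r_ex0)^g_ex * (r_em/r_em0)^g_em + noise`,
#' with `F0(t)` an exponentially bleaching baseline and dF/F a sum of
#' difference-of-exponentials transients. Global arousal transients follow
#' each scripted Q-A movement onset by `qa_latency`; exploration of the
#' novel object triggers cluster-specific responses at the latencies in
#' `cluster_spec`; unassigned cells respond at a latency re-drawn on every
#' trial (inconsistent cells). Reflectance channels dip below their
#' reference during movement in proportion to `hemo_depth`, emulating
#' activity-locked hemodynamic absorbance.
#'
#' @param config a [sim_config()].
#' @return an object of class `astro_session`: a list with elements
#'   `traces` (frames x cells measured fluorescence, a.u.), `time`
#'   (seconds), `fs`, `reflectance` (a `reflectance_traces` list),
#'   `track` (a `behavior_track`), `config`, and `ground_truth` with
#'   `true_baseline` (frames x cells), `true_dff` (frames x cells, clean),
#'   `true_events` (data.frame: cell, onset, peak_time, amplitude, source),
#'   `true_behavior` (data.frame of labeled intervals), and `true_cluster`
#'   (integer per cell, 0 = unclustered).
#' @export
#' @examples
#' sess <- simulate_session(sim_config(n_cells = 5, duration = 520, seed = 7))
#' dim(sess$traces)
#' head(sess$ground_truth$true_behavior)
simulate_session <- function(config) {
  stop_if(!inherits(config, "sim_config"), "`config` must be a sim_config")
  cfg <- config
  with_seed(cfg$seed, {
    script <- session_script(cfg)
    track <- script_to_track(cfg, script)
    behavior <- script_to_events(cfg, script)

    nt <- round(cfg$duration * cfg$fs_imaging)
    time <- (seq_len(nt) - 1L) / cfg$fs_imaging

    # cluster labels: contiguous blocks by fraction, remainder unclustered
    n_per <- floor(cfg$cluster_spec$fraction * cfg$n_cells)
    labels <- rep(0L, cfg$n_cells)
    at <- 1L
    for (k in seq_len(nrow(cfg$cluster_spec))) {
      if (n_per[k] > 0) labels[at:(at + n_per[k] - 1L)] <- k
      at <- at + n_per[k]
    }

    # assemble the event list (cell, onset, amplitude, source)
    evs <- list()
    qa_on <- behavior$onset[behavior$label == "qa"]
    for (on in qa_on)
      evs[[length(evs) + 1L]] <- data.frame(
        cell = seq_len(cfg$n_cells),
        onset = on + cfg$qa_latency,
        amplitude = cfg$qa_amplitude * runif(cfg$n_cells, 0.8, 1.2),
        source = "qa")
    novel_id <- 2L
    ex <- behavior[behavior$label == "object_exploration" &
                     behavior$target_id == novel_id, , drop = FALSE]
    for (on in ex$onset) {
      lat <- numeric(cfg$n_cells); amp <- numeric(cfg$n_cells)
      for (k in seq_len(nrow(cfg$cluster_spec))) {
        lat[labels == k] <- cfg$cluster_spec$latency[k]
        amp[labels == k] <- cfg$cluster_spec$amplitude[k]
      }
      un <- labels == 0L
      lat[un] <- runif(sum(un), 0, 4)
      amp[un] <- mean(cfg$cluster_spec$amplitude)
      evs[[length(evs) + 1L]] <- data.frame(
        cell = seq_len(cfg$n_cells), onset = on + lat,
        amplitude = amp * runif(cfg$n_cells, 0.9, 1.1), source = "novelty")
    }
    if (cfg$spont_rate > 0) {
      n_sp <- rpois(cfg$n_cells, cfg$spont_rate * cfg$duration)
      for (c in which(n_sp > 0))
        evs[[length(evs) + 1L]] <- data.frame(
          cell = c,
          onset = sort(runif(n_sp[c], 0, cfg$duration - 5 * cfg$transient_decay)),
          amplitude = cfg$spont_amplitude * runif(n_sp[c], 0.8, 1.2),
          source = "spontaneous")
    }
    events <- if (length(evs)) do.call(rbind, evs) else
      data.frame(cell = integer(), onset = numeric(),
                 amplitude = numeric(), source = character())
    events <- events[events$onset >= 0 & events$onset <= cfg$duration, , drop = FALSE]
    events <- events[order(events$cell, events$onset), , drop = FALSE]
    rownames(events) <- NULL
    events$peak_time <- events$onset +
      transient_peak_delay(cfg$transient_rise, cfg$transient_decay)

    dff <- matrix(0, nt, cfg$n_cells)
    for (i in seq_len(nrow(events))) {
      c <- events$cell[i]
      dff[, c] <- dff[, c] + events$amplitude[i] *
        transient_kernel(time - events$onset[i],
                         cfg$transient_rise, cfg$transient_decay)
    }

    base_lvl <- cfg$baseline_level *
      (1 + cfg$baseline_jitter * runif(cfg$n_cells, -1, 1))
    f0 <- outer(exp(-time / cfg$bleach_tau), base_lvl)

    # hemodynamic absorbance driver: moving-state indicator, smoothed and
    # resampled (nearest neighbour) to the imaging time base
    moving <- track_speed(track) >= 0.5
    sm <- stats::filter(as.numeric(moving), rep(1 / 31, 31), sides = 2)
    sm[is.na(sm)] <- 0
    tr_time <- (seq_along(sm) - 1L) / cfg$fs_track
    a <- sm[pmax(1L, findInterval(time + 1e-9, tr_time))]
    r_ex0 <- 1; r_em0 <- 1
    r_ex <- r_ex0 * (1 - cfg$hemo_depth * a)
    r_em <- r_em0 * (1 - 0.6 * cfg$hemo_depth * a)
    refl <- reflectance_traces(r_ex = r_ex, r_em = r_em,
                               r_ex0 = r_ex0, r_em0 = r_em0,
                               fs = cfg$fs_imaging)

    f_clean <- f0 * (1 + dff)
    hemo <- (r_ex / r_ex0)^cfg$gamma_ex * (r_em / r_em0)^cfg$gamma_em
    traces <- f_clean * hemo
    if (cfg$noise_sd > 0)
      traces <- traces + matrix(rnorm(length(traces), 0, cfg$noise_sd), nt)

    colnames(traces) <- colnames(dff) <- colnames(f0) <-
      paste0("cell_", seq_len(cfg$n_cells))
    structure(list(
      traces = traces, time = time, fs = cfg$fs_imaging,
      reflectance = refl, track = track, config = cfg,
      ground_truth = list(true_baseline = f0, true_dff = dff,
                          true_events = events, true_behavior = behavior,
                          true_cluster = labels, absorbance = as.numeric(a))),
      class = "astro_session")
  })
}

#' @export
print.astro_session <- function(x, ...) {
  cat(sprintf("Synthetic fiberscope session: %d cells x %.0f s (%g Hz)\n",
              ncol(x$traces), max(x$time) + 1 / x$fs, x$fs))
  cat(sprintf("  %d true calcium transients, %d behavior intervals, seed %d\n",
              nrow(x$ground_truth$true_events),
              nrow(x$ground_truth$true_behavior), x$config$seed))
  invisible(x)
}

#' Simulate circadian-scale activity with sinusoidally modulated probability
#'
#' Produces a long (>= 24 h equivalent, optionally time-compressed via
#' `fs`) activity series whose per-hour amount of movement follows
#' `activity_base * (1 + circadian_depth * cos(...))`, peaking at
#' `peak_hour`: each hour receives its profile-determined count of active
#' samples (so hourly activity is free of binomial sampling noise) at
#' random positions within the hour. A keypoint track consistent with the
#' labels is generated alongside, and a 60-s immobility bout (sleep by
#' the >40 s rule) is scripted into the trough phase so sleep scoring
#' always has a positive case.
#'
#' @param config a [sim_config()]; `circadian_period`, `circadian_depth`,
#'   `peak_hour` and `activity_base` control the modulation.
#' @param hours simulated span in hours (>= 24).
#' @param fs sample rate of the activity series and track, Hz (1 Hz keeps
#'   24 h tractable; the time base is real seconds).
#' @return list with `track` (a `behavior_track`), and `ground_truth`
#'   containing `active` (logical per sample), `hourly` (fraction of
#'   active samples per hour), and `peak_hour`.
#' @export
simulate_circadian <- function(config, hours = 24, fs = 1) {
  stop_if(!inherits(config, "sim_config"), "`config` must be a sim_config")
  stop_if(config$circadian_period <= 0, "circadian period must be > 0")
  stop_if(hours < 24, "need at least 24 h of (compressed-time) data")
  cfg <- config
  with_seed(cfg$seed + 1L, {
    per_hour <- round(3600 * fs)
    n_hours <- ceiling(hours)
    n <- round(hours * 3600 * fs)
    hr <- (seq_len(n) - 1L) / (3600 * fs)
    # the *amount* of activity per hour follows the circadian profile
    # exactly (deterministic count); only its placement within the hour is
    # random — so hourly profiles are free of binomial sampling noise
    active <- logical(n)
    for (h in seq_len(n_hours) - 1L) {
      p_h <- cfg$activity_base *
        (1 + cfg$circadian_depth *
           cos(2 * pi * (h - cfg$peak_hour) / cfg$circadian_period))
      p_h <- min(1, max(0, p_h))
      idx0 <- h * per_hour
      span <- min(per_hour, n - idx0)
      if (span <= 0) break
      n_act <- round(span * p_h)
      if (n_act > 0)
        active[idx0 + sample.int(span, n_act)] <- TRUE
    }
    # scripted 60-s immobility bout at the trough
    trough <- (cfg$peak_hour + cfg$circadian_period / 2) %% 24
    i0 <- round(trough * 3600 * fs) + 1L
    i1 <- min(n, i0 + round(60 * fs) - 1L)
    if (cfg$circadian_depth > 0) active[i0:i1] <- FALSE
    # track: random walk while active, frozen while inactive
    dt <- 1 / fs
    ang <- cumsum(rnorm(n, 0, 0.3))
    step <- ifelse(active, cfg$speed_mean * dt, 0)
    margin <- 4
    x <- margin + (cumsum(step * cos(ang)) %% (cfg$arena[1] - 2 * margin))
    y <- margin + (cumsum(step * sin(ang)) %% (cfg$arena[2] - 2 * margin))
    half <- cfg$body_length / 2
    centroid <- cbind(x, y)
    nose <- centroid + half * cbind(cos(ang), sin(ang))
    tailbase <- centroid - half * cbind(cos(ang), sin(ang))
    hourly <- tapply(as.numeric(active), floor(hr), mean)
    list(track = behavior_track(fs = fs, centroid = centroid, nose = nose,
                                tailbase = tailbase, arena = cfg$arena),
         ground_truth = list(active = active,
                             hourly = as.numeric(hourly),
                             peak_hour = cfg$peak_hour))
  })
}

#' Render a synthetic session as an image stack with disk-shaped ROIs
#'
#' Places each cell as a disk on a pixel grid and fills it with that cell's
#' measured fluorescence per frame, over a constant background. The
#' companion integer label mask identifies each ROI. Used to exercise the
#' mask-mean trace-extraction path against the generator's own traces.
#'
#' @param session an `astro_session`.
#' @param npix image side length in pixels.
#' @param radius ROI disk radius in pixels.
#' @param background background intensity, a.u.
#' @return list with `stack` (npix x npix x frames array) and `masks`
#'   (npix x npix integer label matrix, 0 = background).
#' @export
render_roi_stack <- function(session, npix = 48, radius = 3, background = 10) {
  stop_if(!inherits(session, "astro_session"), "`session` must be an astro_session")
  n_cells <- ncol(session$traces)
  nt <- nrow(session$traces)
  side <- ceiling(sqrt(n_cells))
  stop_if(npix < side * (2 * radius + 2), "`npix` too small for the ROI grid")
  masks <- matrix(0L, npix, npix)
  centers <- expand.grid(gx = seq_len(side), gy = seq_len(side))[seq_len(n_cells), ]
  spacing <- npix / (side + 1)
  for (c in seq_len(n_cells)) {
    cx <- centers$gx[c] * spacing; cy <- centers$gy[c] * spacing
    for (i in seq_len(npix)) for (j in seq_len(npix))
      if ((i - cy)^2 + (j - cx)^2 <= radius^2) masks[i, j] <- c
  }
  stack <- array(background, dim = c(npix, npix, nt))
  for (c in seq_len(n_cells)) {
    idx <- which(masks == c)
    for (f in seq_len(nt)) {
      frame <- stack[, , f]
      frame[idx] <- session$traces[f, c]
      stack[, , f] <- frame
    }
  }
  list(stack = stack, masks = masks)
}
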