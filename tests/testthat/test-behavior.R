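# Behavioral detectors against frame-wise brute-force oracles on scripted
# noise-free trajectories.

test_that("locomotion summary: stationary, straight line, and random walk", {
  fs <- 30
  still <- make_track(still_xy(300), fs = fs)
  loc0 <- compute_locomotion(still)
  expect_equal(loc0$distance, 0)
  expect_equal(loc0$movement_time, 0)
  # straight line of exactly 30 cm
  line <- make_track(line_xy(301, fs = fs, speed = 3), fs = fs)
  loc1 <- compute_locomotion(line)
  expect_equal(loc1$distance, 30, tolerance = 1e-12)
  expect_equal(loc1$mean_speed, 3, tolerance = 1e-12)
  # random walk equals the brute-force pairwise step sum
  set.seed(4)
  xy <- cbind(cumsum(rnorm(500, 0, 0.2)) + 20, cumsum(rnorm(500, 0, 0.2)) + 20)
  rw <- make_track(xy, fs = fs)
  loc2 <- compute_locomotion(rw)
  brute <- sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2))
  expect_equal(loc2$distance, brute, tolerance = 1e-12)
  expect_error(compute_locomotion(make_track(still_xy(1))), "two frames")
})

test_that("NaN keypoints are interpolated up to the gap limit", {
  xy <- line_xy(100)
  xy[50, 1] <- NA
  tr <- make_track(xy, fs = 30)
  expect_silent(compute_locomotion(tr))
  xy[40:60, 1] <- NA
  expect_error(compute_locomotion(make_track(xy, fs = 30)), "gap")
})

test_that("sleep scoring applies the strict >40 s immobility rule", {
  fs <- 10
  move <- function(n) line_xy(n, fs = fs, speed = 5)
  hold <- function(n, at) cbind(rep(at[1], n), rep(at[2], n))
  # 60-s immobile bout embedded in movement -> exactly one sleep event
  a <- move(100)
  xy <- rbind(a, hold(600, a[100, ]), move(100) + 10)
  sl <- detect_sleep(make_track(xy, fs = fs))
  expect_equal(nrow(sl), 1L)
  expect_gte(sl$offset[1] - sl$onset[1], 60)
  # 30-s bout -> none
  xy2 <- rbind(a, hold(300, a[100, ]), move(100) + 10)
  expect_equal(nrow(detect_sleep(make_track(xy2, fs = fs))), 0L)
  # exactly 40 s is not >40 s
  xy3 <- rbind(a, hold(400, a[100, ]), move(100) + 10)
  expect_equal(nrow(detect_sleep(make_track(xy3, fs = fs))), 0L)
  # two 50-s bouts separated by motion -> two events, matching the oracle
  xy4 <- rbind(a, hold(500, a[100, ]), move(60) + 10,
               hold(500, a[100, ] + c(10.2, 10)), move(50) + 30)
  tr4 <- make_track(xy4, fs = fs)
  sl4 <- detect_sleep(tr4)
  or4 <- oracle_immobility(tr4, 40)
  expect_equal(nrow(sl4), 2L)
  expect_equal(sl4$onset, or4$onset)
  expect_equal(sl4$offset, or4$offset)
})

test_that("sleep count is monotone non-increasing in the immobility threshold", {
  fs <- 10
  set.seed(12)
  segs <- list()
  at <- c(20, 20)
  for (i in 1:8) {
    n_hold <- sample(c(200, 450, 700), 1)
    segs[[length(segs) + 1]] <- cbind(rep(at[1], n_hold), rep(at[2], n_hold))
    mv <- line_xy(80, fs = fs, speed = 4, x0 = at[1], y = at[2])
    segs[[length(segs) + 1]] <- mv
    at <- mv[80, ]
  }
  tr <- make_track(do.call(rbind, segs), fs = fs)
  counts <- vapply(c(10, 20, 40, 60, 80),
                   function(m) nrow(detect_sleep(tr, immobility_min = m)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("rearing is detected from body-length extension with exact onsets", {
  fs <- 30
  n <- 3000
  xy <- still_xy(n)
  base_half <- 4
  nose <- cbind(xy[, 1] + base_half, xy[, 2])
  tail <- cbind(xy[, 1] - base_half, xy[, 2])
  # inject 7 rears of 40% extension, 1.5 s each
  starts <- seq(200, 2800, length.out = 7)
  for (s in starts) {
    idx <- s:(s + 45 - 1)
    nose[idx, 1] <- xy[idx, 1] + base_half * 1.4
    tail[idx, 1] <- xy[idx, 1] - base_half * 1.4
  }
  tr <- make_track(xy, fs = fs, nose = nose, tailbase = tail)
  rears <- detect_rearing(tr, extension_thresh = 0.25, min_duration = 0.5)
  expect_equal(nrow(rears), 7L)
  expect_equal(rears$onset, (starts - 1) / fs, tolerance = 1.01 / fs)
  expect_equal(rears$dh, rep(8 * 0.4, 7), tolerance = 1e-6)
  expect_true(all(rears$offset - rears$onset >= 1.4))
  # constant body length -> none; sub-threshold extension -> none
  expect_equal(nrow(detect_rearing(make_track(xy, fs = fs))), 0L)
  nose10 <- cbind(xy[, 1] + base_half * 1.1, xy[, 2])
  tr10 <- make_track(xy, fs = fs, nose = nose10, tailbase = tail * 0 + tail)
  expect_equal(nrow(detect_rearing(tr10, extension_thresh = 0.25)), 0L)
})

test_that("object exploration needs the nose in the zone and the axis oriented", {
  fs <- 30
  obj <- object_spec(center = c(30, 20), radius = 2, zone_margin = 2.5, id = 1L)
  # nose inside zone, axis pointing at the center: exploratory
  xy <- still_xy(30, x = 22, y = 20)
  nose <- cbind(rep(26.5, 30), rep(20, 30))   # 3.5 cm from center, inside 4.5
  tail <- cbind(rep(18, 30), rep(20, 30))
  tr <- make_track(xy, fs = fs, nose = nose, tailbase = tail)
  ev <- detect_object_exploration(tr, list(obj))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$onset, 0)
  expect_equal(ev$offset, 1)
  # axis pointing 180 degrees away: not exploratory
  tr2 <- make_track(xy, fs = fs, nose = tail, tailbase = nose)
  expect_equal(nrow(detect_object_exploration(tr2, list(obj))), 0L)
})

test_that("a scripted approach-orient-leave trajectory matches the brute-force oracle", {
  fs <- 30
  obj <- object_spec(center = c(30, 20), radius = 2, zone_margin = 2.5, id = 1L)
  obj2 <- object_spec(center = c(10, 20), radius = 2, zone_margin = 2.5, id = 2L)
  # approach from x=15 to x=27 (nose leads), pause, turn away, leave
  n1 <- 60; n2 <- 30; n3 <- 60
  cx <- c(seq(15, 23, length.out = n1), rep(23, n2), seq(23, 15, length.out = n3))
  xy <- cbind(cx, rep(20, length(cx)))
  heading <- c(rep(0, n1 + n2 %/% 2), rep(pi, n2 - n2 %/% 2 + n3))
  nose <- xy + 4 * cbind(cos(heading), sin(heading))
  tail <- xy - 4 * cbind(cos(heading), sin(heading))
  tr <- make_track(xy, fs = fs, nose = nose, tailbase = tail,
                   objects = list(obj, obj2))
  ev <- detect_object_exploration(tr)
  flag <- oracle_exploration(tr, list(obj, obj2))
  for (id in 1:2) {
    runs <- astroca:::runs_true(!is.na(flag) & flag == id)
    evi <- ev[ev$target_id == id, ]
    expect_equal(nrow(evi), nrow(runs))
    expect_equal(evi$onset, (runs$start - 1) / fs)
    expect_equal(evi$offset, runs$end / fs)
  }
})

test_that("Q-A transitions require sustained quiescence before movement onset", {
  fs <- 10
  move <- function(n, x0) line_xy(n, fs = fs, speed = 5, x0 = x0)
  hold <- function(n, at) cbind(rep(at[1], n), rep(at[2], n))
  # always moving -> none
  expect_equal(nrow(detect_qa_transitions(make_track(move(600, 5), fs = fs))), 0L)
  # 30 s still then sustained motion, quiescence_min = 20 -> one transition
  xy <- rbind(hold(300, c(5, 20)), move(200, 5))
  qa <- detect_qa_transitions(make_track(xy, fs = fs), quiescence_min = 20)
  expect_equal(nrow(qa), 1L)
  expect_equal(qa$onset, 300 / fs, tolerance = 1.01 / fs)
  # two separated bouts -> two transitions
  xy2 <- rbind(hold(300, c(5, 20)), move(150, 5),
               hold(250, c(80, 20)), move(150, 8))
  qa2 <- detect_qa_transitions(make_track(xy2, fs = fs), quiescence_min = 20)
  expect_equal(nrow(qa2), 2L)
  # oracle: onsets follow >= 20 s of sub-threshold speed
  sp <- astroca:::track_speed(make_track(xy2, fs = fs))
  for (on in qa2$onset) {
    i <- round(on * fs) + 1
    expect_true(all(sp[(i - 20 * fs):(i - 1)] < 0.5))
    expect_gte(sp[i], 0.5)
  }
})

test_that("generator-scripted behavior is recovered event-for-event", {
  sess <- simulate_session(sim_config(n_cells = 2, duration = 560, seed = 19))
  gt <- sess$ground_truth$true_behavior
  sl <- detect_sleep(sess$track)
  gt_sl <- gt[gt$label == "sleep", ]
  expect_equal(nrow(sl), nrow(gt_sl))
  expect_equal(sl$onset, gt_sl$onset, tolerance = 0.2)
  rr <- detect_rearing(sess$track)
  gt_rr <- gt[gt$label == "rear", ]
  expect_equal(nrow(rr), nrow(gt_rr))
  expect_equal(rr$onset, gt_rr$onset, tolerance = 1 / sess$track$fs + 1e-9)
  ex <- detect_object_exploration(sess$track)
  gt_ex <- gt[gt$label == "object_exploration", ]
  expect_equal(nrow(ex), nrow(gt_ex))
  expect_equal(ex$target_id, gt_ex$target_id[order(gt_ex$onset)])
  qa <- detect_qa_transitions(sess$track)
  gt_qa <- gt[gt$label == "qa", ]
  expect_equal(nrow(qa), nrow(gt_qa))
  expect_equal(qa$onset, gt_qa$onset, tolerance = 0.2)
})

test_that("circadian profile aligns its peak and splits phases", {
  cfg <- sim_config(circadian_depth = 1, peak_hour = 6, seed = 23)
  sim <- simulate_circadian(cfg, hours = 24.5, fs = 1)
  expect_warning(prof <- circadian_profile(sim$ground_truth$active, fs = 1),
                 "partial final hour")
  expect_equal(prof$peak_hour, 6L)
  expect_equal(which.max(prof$aligned), 1L)
  expect_equal(sum(prof$phase == "active"), 12L)
  expect_false(prof$degenerate)
  # active phase is the contiguous 12 h holding the activity maximum
  expect_equal(as.character(prof$phase[7]), "active")
})

test_that("degenerate circadian inputs are flagged", {
  expect_warning(prof <- circadian_profile(rep(1, 24 * 3600), fs = 1),
                 "degenerate")
  expect_true(prof$degenerate)
  expect_warning(prof0 <- circadian_profile(rep(0, 24 * 3600), fs = 1),
                 "degenerate")
  expect_equal(prof0$hourly, rep(0, 24))
  expect_error(circadian_profile(rep(1, 3600), fs = 1), "24")
})

test_that("novelty preference reproduces the normalized-difference d-prime", {
  # equal exploration
  eq <- novelty_preference(c(10, 10))
  expect_equal(eq$fraction_novel, 0.5)
  expect_equal(eq$dprime, 0)
  # the 76/24 split gives d' = 0.52 exactly
  np <- novelty_preference(c(familiar = 24, novel = 76))
  expect_equal(np$fraction_novel, 0.76)
  expect_equal(np$fraction_familiar, 0.24)
  expect_equal(np$dprime, 0.52)
  # novel only
  no <- novelty_preference(c(0, 5))
  expect_equal(no$fraction_novel, 1)
  expect_equal(no$dprime, 1)
  expect_error(novelty_preference(c(0, 0)), "zero total")
  # event-table input
  ev <- data.frame(label = "object_exploration",
                   onset = c(0, 10, 20), offset = c(2, 16, 22),
                   dh = NA, target_id = c(1L, 2L, 2L))
  np2 <- novelty_preference(ev, familiar_id = 1L, novel_id = 2L)
  expect_equal(np2$t_familiar, 2)
  expect_equal(np2$t_novel, 8)
  expect_equal(np2$dprime, 0.6)
})
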