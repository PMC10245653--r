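# End-to-end pipeline over a synthetic (or file-based) session: simulate ->
# preprocess -> detect events -> detect behavior -> align -> stats ->
# cluster, writing every intermediate as CSV/JSON with provenance headers.

#' Run the full analysis pipeline on a synthetic session
#'
#' Executes the requested stages in order and writes their outputs under
#' `out_dir`. Outputs carry a provenance header (package version and
#' seed) and contain no timestamps, so a rerun with the same
#' configuration is byte-identical. Any stage failure aborts with the
#' stage name.
#'
#' Stages and products:
#' \describe{
#'   \item{simulate}{`traces_raw.csv`, `keypoints.csv`, `reflectance.csv`,
#'     `ground_truth.json`}
#'   \item{preprocess}{`dff.csv` (hemodynamics-corrected, baseline from
#'     kernel-density mode tracking)}
#'   \item{detect}{`calcium_events.csv`, `raster.csv`}
#'   \item{behavior}{`behavior_events.csv`}
#'   \item{align}{`aligned_qa.csv` (long format: event, time, cell, dff)}
#'   \item{stats}{`stats.json` (latency Gini/CV, rFF epochs, SI, activeness
#'     posterior)}
#'   \item{cluster}{`clusters.csv`, `cluster_model.json`}
#' }
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param stages character vector of stages to run (order fixed).
#' @return named list of written file paths, invisibly; also the in-memory
#'   `results` list as attribute `"results"`.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "preprocess", "detect",
                                    "behavior", "align", "stats", "cluster")) {
  stop_if(!inherits(config, "sim_config"), "`config` must be a sim_config")
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(); res <- list()
  seed <- config$seed
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  sess <- stage("simulate", simulate_session(config))
  res$session <- sess
  if ("simulate" %in% stages) {
    paths$traces <- file.path(out_dir, "traces_raw.csv")
    write_traces_csv(sess$traces, sess$fs, paths$traces, seed)
    paths$keypoints <- file.path(out_dir, "keypoints.csv")
    write_keypoints_csv(sess$track, paths$keypoints, seed)
    paths$reflectance <- file.path(out_dir, "reflectance.csv")
    write_csv_prov(data.frame(time = sess$time,
                              r_ex = sess$reflectance$r_ex,
                              r_em = sess$reflectance$r_em),
                   paths$reflectance, seed)
    paths$ground_truth <- file.path(out_dir, "ground_truth.json")
    gt <- sess$ground_truth
    jsonlite::write_json(list(true_events = gt$true_events,
                              true_behavior = gt$true_behavior,
                              true_cluster = gt$true_cluster),
                         paths$ground_truth, auto_unbox = TRUE, digits = NA)
  }

  if (!any(c("preprocess", "detect", "behavior", "align", "stats",
             "cluster") %in% stages))
    return(invisible(structure(paths, results = res)))

  dff <- stage("preprocess", {
    out <- matrix(NA_real_, nrow(sess$traces), ncol(sess$traces))
    for (c in seq_len(ncol(sess$traces))) {
      corr <- correct_hemodynamics(sess$traces[, c], sess$reflectance,
                                   config$gamma_ex, config$gamma_em)
      bl <- estimate_baseline(corr, fs = sess$fs)
      out[, c] <- compute_dff(corr, bl)
    }
    colnames(out) <- colnames(sess$traces)
    out
  })
  res$dff <- dff
  if ("preprocess" %in% stages) {
    paths$dff <- file.path(out_dir, "dff.csv")
    write_traces_csv(dff, sess$fs, paths$dff, seed)
  }

  events <- stage("detect", detect_events_matrix(dff, fs = sess$fs))
  res$events <- events
  if ("detect" %in% stages) {
    paths$events <- file.path(out_dir, "calcium_events.csv")
    write_events_csv(events, paths$events, seed)
    raster <- build_raster(events, ncol(dff), config$duration, bin_width = 1)
    paths$raster <- file.path(out_dir, "raster.csv")
    write_csv_prov(as.data.frame(raster), paths$raster, seed)
    res$raster <- raster
  }

  behav <- stage("behavior", {
    rbind(detect_sleep(sess$track),
          detect_rearing(sess$track),
          detect_object_exploration(sess$track),
          detect_qa_transitions(sess$track))
  })
  res$behavior <- behav
  if ("behavior" %in% stages) {
    paths$behavior <- file.path(out_dir, "behavior_events.csv")
    write_events_csv(behav, paths$behavior, seed)
  }

  qa <- behav[behav$label == "qa", , drop = FALSE]
  aligned <- if (nrow(qa) > 0)
    stage("align", align_responses(dff, sess$fs, qa, "onset", c(2, 6)))
  else NULL
  res$aligned <- aligned
  if ("align" %in% stages && !is.null(aligned)) {
    d <- dim(aligned$tensor)
    long <- data.frame(
      event = rep(seq_len(d[1]), times = d[2] * d[3]),
      time = rep(rep(aligned$time, each = d[1]), times = d[3]),
      cell = rep(seq_len(d[3]), each = d[1] * d[2]),
      dff = as.numeric(aligned$tensor))
    paths$aligned <- file.path(out_dir, "aligned_qa.csv")
    write_csv_prov(long, paths$aligned, seed)
  }

  if ("stats" %in% stages) {
    stats_out <- stage("stats", {
      out <- list()
      if (!is.null(aligned) && dim(aligned$tensor)[1] >= 2) {
        lat <- peak_latencies(aligned)
        lat_ok <- lat$latency[!is.na(lat$latency)]
        if (length(lat_ok) >= 2 && sum(lat_ok >= 0) == length(lat_ok) &&
            sum(lat_ok) > 0)
          out$gini_onset_latency <- gini_lorenz(lat_ok)$gini
        if (length(lat_ok) >= 2 && mean(lat_ok) != 0)
          out$cv_onset_latency <- coefficient_of_variation(lat_ok)
        # Fano epochs need positive-mean responses; use the ratio F/F0 =
        # 1 + dF/F so the pre-event epoch is well-defined too
        al_ff <- align_responses(dff + 1, sess$fs, qa, "onset", c(2, 6),
                                 baseline_subtract = FALSE)
        fe <- fano_epochs(al_ff)
        out$rff <- as.list(stats::setNames(fe$rff, fe$epoch))
      }
      out$si_session <- synchronization_index(dff)$si
      if (nrow(events) > 0) {
        raster <- build_raster(events, ncol(dff), config$duration, bin_width = 1)
        ev_series <- as.integer(colSums(raster) > 0)
        sp <- track_speed(sess$track)
        sec_idx <- pmin(length(sp), round(seq_len(ncol(raster)) * sess$track$fs))
        active <- sp[sec_idx] >= 0.5
        post <- posterior_activeness(ev_series, active, seed = seed)
        out$posterior_active_given_event <- post$posterior
        out$posterior_null_mean <- mean(post$null_distribution, na.rm = TRUE)
      }
      out
    })
    res$stats <- stats_out
    paths$stats <- file.path(out_dir, "stats.json")
    jsonlite::write_json(stats_out, paths$stats, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }

  if ("cluster" %in% stages) {
    cl <- stage("cluster", {
      novel <- behav[behav$label == "object_exploration" &
                       !is.na(behav$target_id) & behav$target_id == 2L, ,
                     drop = FALSE]
      if (nrow(novel) < 2) return(NULL)
      al <- align_responses(dff, sess$fs, novel, "onset", c(1, 5))
      tens <- aperm(al$tensor, c(3, 1, 2))   # cells x trials x time
      rm_mat <- build_response_matrix(tens, time = al$time)
      pca <- pca_reduce(rm_mat, 2)
      gmm <- fit_gmm_em(pca$scores, k = nrow(config$cluster_spec),
                        seed = seed)
      list(pca = pca, gmm = gmm, tensor = tens)
    })
    res$cluster <- cl
    if (!is.null(cl)) {
      paths$clusters <- file.path(out_dir, "clusters.csv")
      resp_max <- apply(cl$gmm$responsibilities, 1, max)
      write_csv_prov(data.frame(cell_id = seq_along(cl$gmm$assignments),
                                cluster = cl$gmm$assignments,
                                max_responsibility = resp_max),
                     paths$clusters, seed)
      paths$cluster_model <- file.path(out_dir, "cluster_model.json")
      jsonlite::write_json(
        list(weights = cl$gmm$weights, means = cl$gmm$means,
             covariances = apply(cl$gmm$covariances, 3, identity),
             likelihood_threshold = cl$gmm$likelihood_threshold,
             seed = cl$gmm$seed,
             explained_variance = cl$pca$explained[1:2]),
        paths$cluster_model, digits = NA, pretty = TRUE)
    }
  }
  invisible(structure(paths, results = res))
}
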