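#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]. Validated up front;
#' persisted verbatim (as JSON) into the output directory.
#'
#' @param n_participants cohort size to simulate.
#' @param seed master seed; every stage derives its randomness from it.
#' @param fs sampling rate in Hz.
#' @param watch_duration_s,decision_duration_s phase durations in seconds.
#' @param network_amp network-component amplitude (micromolar sd).
#' @param n_edges_watch,n_edges_decision mean ground-truth edge counts for
#'   the watch and decision phases; per-participant counts jittered by
#'   `edge_jitter`.
#' @param edge_jitter max absolute jitter on edge counts.
#' @param edge_strength requested partial-correlation strength.
#' @param cutoff_hz,filter_order low-pass filter design.
#' @param spike_z artifact-repair threshold.
#' @param dpf_760,dpf_850 differential pathlength factors.
#' @param distance_mm source-detector separation.
#' @param cbsi_scope `"per_period"` or `"global"`.
#' @param threshold connectivity criterion.
#' @param screen_outliers apply the 3-SD cell screen to the ROI table.
#' @param behavior list of behavior-generation coefficients (see
#'   [recovery_experiment()]).
#' @param noise a [noise_spec()].
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(n_participants = 5, seed = 1, fs = 8.9,
                            watch_duration_s = 120, decision_duration_s = 60,
                            network_amp = 1,
                            n_edges_watch = 12, n_edges_decision = 5,
                            edge_jitter = 3, edge_strength = 0.5,
                            cutoff_hz = 0.4, filter_order = 4, spike_z = 5,
                            dpf_760 = 7.25, dpf_850 = 6.38, distance_mm = 30,
                            cbsi_scope = "per_period", threshold = 0.28,
                            screen_outliers = TRUE,
                            behavior = list(beta_d_watch4 = 8,
                                            beta_d_decision2 = -8,
                                            beta_c = 2, r2 = 0.3,
                                            intercept = 4.7),
                            noise = noise_spec()) {
  cfg <- as.list(environment())
  stopifnot(n_participants >= 1, fs > 0, watch_duration_s > 0,
            decision_duration_s > 0, threshold > 0, threshold < 1,
            cutoff_hz > 0, cutoff_hz < fs / 2,
            cbsi_scope %in% c("per_period", "global"))
  structure(cfg, class = "pipeline_config")
}

#' Packaged demonstration configuration
#'
#' A small cohort with shortened phase durations so the full pipeline runs
#' in seconds while exercising every stage.
#' @param seed master seed.
#' @return A `pipeline_config`.
#' @export
demo_config <- function(seed = 1) {
  pipeline_config(n_participants = 5, seed = seed,
                  watch_duration_s = 120, decision_duration_s = 60)
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Stages, in fixed order: (1) simulate ground-truth networks and
#' hemodynamics per participant, forward-model them to raw optical
#' recordings, and write them to disk; (2) load the recordings back and
#' preprocess (OD, artifact repair, low-pass, mBLL, CBSI); (3) segment into
#' the six task periods and compute ROI averages (with optional outlier
#' screen); (4) estimate and threshold per-period connectivity networks;
#' (5) compute the metrics table, per-period summaries, connection
#' frequency maps with arc diagrams, and the two brain-behavior
#' regressions on simulated distances. A manifest records the package
#' version, the config, and an MD5 hash of every tabular artifact; rerun
#' with the same config is bit-identical on those artifacts.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return Invisibly, a list with `manifest` (also written as
#'   `manifest.json`), `metrics`, `roi`, `regressions`, `frequency_map`.
#' @export
run_pipeline <- function(config = demo_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  raw_dir <- file.path(out_dir, "raw")
  mont <- default_montage()
  mont$source_detector_distance_mm <- config$distance_mm
  ids <- sprintf("p%02d", seq_len(config$n_participants))

  stage <- function(name, pid, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, if (!is.na(pid)) paste0(" [", pid, "]"),
           " failed: ", conditionMessage(e), call. = FALSE))
  }

  # -- stage 1: simulate & write raw recordings ----------------------------
  truths <- list()
  set.seed(config$seed)
  pj <- matrix(sample(-config$edge_jitter:config$edge_jitter,
                      2 * config$n_participants, replace = TRUE), ncol = 2)
  for (i in seq_along(ids)) {
    pid <- ids[i]
    truths[[pid]] <- stage("synthetic_data", pid, {
      tw <- make_ground_truth(15, strength = config$edge_strength,
                              n_edges = max(0, config$n_edges_watch + pj[i, 1]),
                              seed = (config$seed * 1000L + 2L * i) %%
                                .Machine$integer.max)
      td <- make_ground_truth(15, strength = config$edge_strength,
                              n_edges = max(0, config$n_edges_decision + pj[i, 2]),
                              seed = (config$seed * 1000L + 2L * i + 1L) %%
                                .Machine$integer.max)
      sc <- scenario_spec(fs = config$fs,
                          watch_duration_s = config$watch_duration_s,
                          decision_duration_s = config$decision_duration_s,
                          network_amp = config$network_amp,
                          period_truth = list(watch = tw, decision = td),
                          seed = (config$seed * 100L + i) %%
                            .Machine$integer.max)
      hemo <- simulate_hemodynamics(tw, noise = config$noise, scenario = sc)
      rec <- simulate_optics(hemo, montage = mont,
                             dpf_760 = config$dpf_760,
                             dpf_850 = config$dpf_850,
                             distance_mm = config$distance_mm,
                             participant = list(
                               id = pid,
                               experience = if (i %% 2 == 0) "experienced"
                                            else "inexperienced",
                               distraction = if (i %% 4 < 2) "distraction"
                                             else "no_distraction"))
      write_recording(rec, raw_dir, stem = pid)
      write_ground_truth(tw, file.path(raw_dir, paste0(pid, "_truth_watch.json")))
      write_ground_truth(td, file.path(raw_dir, paste0(pid, "_truth_decision.json")))
      list(watch = tw, decision = td)
    })
  }

  # -- stages 2-4: load, preprocess, segment, connect ----------------------
  roi_rows <- list(); networks <- list()
  for (pid in ids) {
    rec <- stage("io_montage", pid,
                 load_recording(file.path(raw_dir, pid), montage = mont))
    hemo <- stage("preprocess", pid,
                  preprocess_recording(rec,
                                       filter = filter_spec(config$cutoff_hz,
                                                            config$filter_order),
                                       spike_z = config$spike_z,
                                       dpf_760 = config$dpf_760,
                                       dpf_850 = config$dpf_850,
                                       distance_mm = config$distance_mm,
                                       cbsi_scope = config$cbsi_scope))
    seg <- stage("segmentation", pid,
                 segment_periods(rec$events, rec$fs, nrow(hemo$hbo)))
    roi_rows[[pid]] <- stage("segmentation", pid,
                             roi_average(hemo, seg, mont, participant_id = pid))
    nets <- stage("connectivity", pid,
                  period_networks(hemo, seg, criterion = config$threshold,
                                  participant = pid))
    networks <- c(networks, nets)
  }
  roi <- do.call(rbind, roi_rows); rownames(roi) <- NULL
  if (isTRUE(config$screen_outliers) && config$n_participants >= 2) {
    screened <- screen_outliers(roi, "mean_cbsi_hbo", c("period", "roi"))
    roi <- screened$table
  }

  # -- stage 5: metrics, maps, regressions ---------------------------------
  metrics <- stage("graph_metrics", NA, metrics_table(networks))
  fmap <- stage("group_stats", NA, frequency_map(networks))
  arc_files <- stage("group_stats", NA,
                     arc_diagram(fmap, mont, file.path(out_dir, "figures")))
  regressions <- list(); behavior_tabs <- list()
  for (per in c("watch4", "decision2")) {
    beta_d <- if (per == "watch4") config$behavior$beta_d_watch4
              else config$behavior$beta_d_decision2
    slice <- metrics[metrics$period == per, ]
    reg <- tryCatch({
      sd_eps <- noise_sd_for_r2(slice, beta_d, config$behavior$beta_c,
                                config$behavior$r2)
      beh <- simulate_behavior(slice,
                               list(intercept = config$behavior$intercept,
                                    beta_d = beta_d,
                                    beta_c = config$behavior$beta_c,
                                    sd = sd_eps),
                               seed = config$seed + match(per, period_names()))
      response <- switch(per, watch4 = "distance_spotted_nm",
                         decision2 = "distance_maneuver_nm")
      names(beh)[2] <- response
      beh[[response]] <- pmax(beh[[response]], 0)
      behavior_tabs[[per]] <- beh
      behavior_regression(metrics, beh, period = per)
    }, error = function(e) {
      message("regression for ", per, " skipped: ", conditionMessage(e))
      NULL
    })
    regressions[[per]] <- reg
  }

  # -- write tabular artifacts --------------------------------------------
  tab <- function(df, name) {
    path <- file.path(out_dir, name)
    data.table::fwrite(df, path, sep = "\t")
    path
  }
  metrics_out <- metrics[, c("participant_id", "period", "density", "clustering")]
  paths <- c(
    tab(roi, "roi_averages.tsv"),
    tab(metrics_out, "metrics.tsv"),
    tab(metrics_summary(metrics), "metrics_summary.tsv"),
    unlist(lapply(names(regressions), function(per) {
      if (is.null(regressions[[per]])) return(character(0))
      r <- regressions[[per]]
      tab(cbind(period = per, r$coefficients,
                r_squared = r$r_squared, adj_r_squared = r$adj_r_squared,
                f = r$f_statistic, n = r$n),
          paste0("regression_", per, ".tsv"))
    })),
    unlist(lapply(names(behavior_tabs), function(per)
      tab(behavior_tabs[[per]], paste0("behavior_", per, ".tsv")))),
    arc_files$counts, arc_files$legend
  )
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  raw_files <- sort(list.files(raw_dir, full.names = TRUE))
  manifest <- list(
    package_version = as.character(utils::packageVersion("fnirsconn")),
    config_md5 = unname(tools::md5sum(cfg_path)),
    inputs = data.frame(file = basename(raw_files),
                        md5 = unname(tools::md5sum(raw_files))),
    artifacts = data.frame(file = basename(paths),
                           md5 = unname(tools::md5sum(paths))),
    counts = list(n_participants = config$n_participants,
                  n_networks = length(networks),
                  n_metric_rows = nrow(metrics),
                  n_roi_rows = nrow(roi))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, metrics = metrics, roi = roi,
                 regressions = regressions, frequency_map = fmap,
                 truths = truths))
}
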