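#' Run the full analysis pipeline from a configuration
#'
#' Executes, per condition: scene simulation (or localization-CSV loading),
#' optional frame rendering and localization (or the ground-truth
#' localization shortcut), drift estimation and correction, cluster
#' segmentation, and photophysics summaries; then the two-condition
#' comparison when exactly two conditions and a `reference` are configured.
#' Every stage writes its output into the run directory, along with a config
#' echo and a log; a stage failure aborts with the stage name while earlier
#' outputs remain on disk.
#'
#' @param config a `pipeline_config`, or the path of a YAML config file.
#' @param out output directory (overrides `config$out`).
#' @param seed global seed (overrides `config$seed`); per-stage seeds are
#'   derived from it deterministically.
#' @return the run directory path, invisibly; the comparison report (when
#'   produced) is returned as attribute `"comparison"`.
#' @export
run_pipeline <- function(config, out = NULL, seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    config <- validate_pipeline_config(config)
  }
  out <- out %||% config$out %||% stop_invalid("no output directory configured")
  seed <- seed %||% config$seed %||% 1L
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  logf <- function(...) {
    cat(format(Sys.time(), "%H:%M:%S "), sprintf(...), "\n",
        file = log_path, sep = "", append = TRUE)
  }
  cat("", file = log_path)
  logf("smlmpipe %s; global seed %d", as.character(utils::packageVersion("smlmpipe")), seed)
  yaml::write_yaml(unclass(config), file.path(out, "config_echo.yaml"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      logf("stage '%s' FAILED: %s", name, conditionMessage(e))
      stop(errorCondition(
        paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
        class = c("smlmpipe_stage_error", "error")))
    })
  }
  camera <- do.call(camera_model, config$camera %||% list())
  blink_default <- config$blink %||% list()
  loc_cfg <- config$localize %||% list()
  drift_cfg <- config$drift %||% list()
  clu_cfg <- do.call(cluster_config, config$cluster %||% list())
  photo_cfg <- config$photophysics %||% list()

  conditions <- config$conditions %||% stop_invalid("config has no conditions")
  summaries <- list()
  sets <- list()
  ci <- 0L
  for (cname in names(conditions)) {
    ci <- ci + 1L
    cond <- conditions[[cname]]
    cdir <- file.path(out, cname)
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    cond_seed <- seed + 1000L * ci

    if (!is.null(cond$locs)) {
      table <- stage("read_localizations", read_localizations(cond$locs))
      logf("[%s] loaded %d localizations from %s", cname, nrow(table), cond$locs)
    } else {
      sim_args <- cond$simulate %||% config$simulate %||% list()
      sim_args$seed <- NULL
      params <- do.call(scene_params, sim_args)
      blink <- do.call(blink_model, cond$blink %||% blink_default)
      scene <- stage("simulate", {
        sc <- generate_scene(params, seed = cond_seed)
        simulate_blinking(sc, blink, camera, seed = cond_seed + 1L)
      })
      logf("[%s] simulated %d molecules, %d events", cname,
           nrow(scene$molecules), nrow(scene$events))
      if (isTRUE(loc_cfg$use_ground_truth)) {
        table <- stage("localize", ground_truth_table(
          scene, precision_nm = loc_cfg$precision_nm %||% 10,
          seed = cond_seed + 2L))
      } else {
        stack <- stage("render", render_frames(scene, camera,
                                               seed = cond_seed + 2L))
        write_frame_stack(stack, file.path(cdir, "frames.tif"))
        table <- stage("localize", localize_stack(
          stack, threshold_counts = loc_cfg$threshold_counts %||% 50,
          min_separation_px = loc_cfg$min_separation_px %||% 5,
          fit_window_px = loc_cfg$fit_window_px %||% 7))
      }
      logf("[%s] %d localizations", cname, nrow(table))
    }
    write_localizations(table, file.path(cdir, "locs.csv"))

    if (!identical(drift_cfg$enabled, FALSE)) {
      est <- stage("drift", estimate_drift(
        table, n_subsets = drift_cfg$n_subsets %||% 10,
        recon_bin_nm = drift_cfg$recon_bin_nm %||% 20))
      table <- correct_drift(table, est)
      write_drift(est$trajectory, file.path(cdir, "drift.csv"))
      write_localizations(table, file.path(cdir, "locs_corrected.csv"))
      k <- nrow(est$subsets)
      logf("[%s] drift corrected; last-subset displacement (%.1f, %.1f) nm",
           cname, est$subsets$dx_nm[k], est$subsets$dy_nm[k])
    }

    cs <- stage("cluster", cluster_field(table, clu_cfg))
    write_cluster_set(cs, cdir)
    logf("[%s] %d clusters (reference area %.2f um^2)", cname,
         nrow(cs$clusters), cs$reference_area_um2)
    sets[[cname]] <- cs

    photo <- stage("photophysics", {
      trace <- event_rate_trace(table, photo_cfg$bin_frames %||% 50)
      ps <- photon_stats(table)
      rf <- tryCatch(fit_off_rate(trace, photo_cfg$frame_rate_hz %||% 33),
                     error = function(e) NULL)
      list(photon_mean = ps$mean, photon_median = ps$median,
           photon_sd = ps$sd, n_events = ps$n_events,
           k_off_per_frame = if (is.null(rf)) NA else rf$k_off_per_frame,
           k_off_per_s = if (is.null(rf)) NA else rf$k_off_per_s)
    })
    jsonlite::write_json(photo, file.path(cdir, "photo.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  }

  report <- NULL
  if (length(sets) == 2 && !is.null(config$reference)) {
    ref <- config$reference
    other <- setdiff(names(sets), ref)
    report <- stage("quantify", compare_conditions(
      list(sets[[ref]]), list(sets[[other]]), labels = c(ref, other)))
    write_comparison(report, file.path(out, "comparison.json"))
    logf("comparison written: %s vs %s", other, ref)
  }
  summary_df <- do.call(rbind, lapply(names(sets), function(cname) {
    s <- summarize_condition(list(sets[[cname]]), cname)
    data.frame(condition = cname, n_clusters = s$n_clusters,
               mean_n_loc = s$mean["n_loc"], sem_n_loc = s$sem["n_loc"],
               mean_area_nm2 = s$mean["area_nm2"],
               mean_density_per_nm2 = s$mean["density_per_nm2"],
               clusters_per_um2 = s$clusters_per_um2_mean)
  }))
  utils::write.csv(summary_df, file.path(out, "summary.csv"), row.names = FALSE)
  logf("done")
  structure(invisible(out), comparison = report)
}
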