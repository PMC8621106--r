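# File formats: localization CSV (native dialect plus common SMLM dialects),
# multi-page TIFF frame stacks, cluster tables, pipeline config.

#' Write a localization table to CSV
#'
#' Native interchange dialect with header
#' `frame,x_nm,y_nm,photons,sigma_nm,background`; coordinates are written at
#' 0.01 nm precision.
#'
#' @param table a [localization_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path) {
  df <- as.data.frame(table)[, c("frame", "x_nm", "y_nm", "photons",
                                 "sigma_nm", "background")]
  for (col in c("x_nm", "y_nm")) df[[col]] <- round(df[[col]], 2)
  for (col in c("photons", "sigma_nm", "background")) {
    df[[col]] <- round(df[[col]], 4)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a localization table from CSV
#'
#' Understands the native dialect (`frame,x_nm,y_nm,...`), ThunderSTORM-style
#' exports (`"x [nm]"`, `"y [nm]"`, `"intensity [photon]"`, `"sigma [nm]"`,
#' `"offset [photon]"`), and Picasso-style exports (`x`, `y` in camera
#' pixels with `photons`, `sx`/`sy`, `bg`), normalizing columns and units to
#' the native nm schema.
#'
#' @param path CSV file.
#' @param dialect `"auto"` (default), `"native"`, `"thunderstorm"` or
#'   `"picasso"`.
#' @param pixel_size_nm camera pixel size, required to convert pixel-unit
#'   dialects (default 160 nm).
#' @return a [localization_table()].
#' @export
read_localizations <- function(path, dialect = c("auto", "native",
                                                 "thunderstorm", "picasso"),
                               pixel_size_nm = 160) {
  dialect <- match.arg(dialect)
  fmt_error <- function(...) {
    stop(errorCondition(paste0(...), class = c("smlmpipe_format_error", "error")))
  }
  if (!file.exists(path)) fmt_error("file not found: ", path)
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) fmt_error("cannot parse ", path, ": ",
                                               conditionMessage(e)))
  if (nrow(df) == 0 || ncol(df) == 0) fmt_error("no localization rows in ", path)
  nm <- names(df)
  if (dialect == "auto") {
    dialect <- if (all(c("x_nm", "y_nm") %in% nm)) "native"
    else if (any(grepl("^x \\[nm\\]$", nm))) "thunderstorm"
    else if (all(c("x", "y") %in% nm)) "picasso"
    else fmt_error("unrecognized localization CSV dialect in ", path)
  }
  pick <- function(cands, target, required = FALSE, scale = 1) {
    hit <- cands[cands %in% nm]
    if (length(hit) == 0) {
      if (required) fmt_error("missing mandatory column '", cands[1], "' in ", path)
      return(rep(NA_real_, nrow(df)))
    }
    as.numeric(df[[hit[1]]]) * scale
  }
  out <- switch(dialect,
    native = data.frame(
      frame = pick("frame", required = TRUE),
      x_nm = pick("x_nm", required = TRUE),
      y_nm = pick("y_nm", required = TRUE),
      photons = pick("photons"), sigma_nm = pick("sigma_nm"),
      background = pick("background")),
    thunderstorm = data.frame(
      frame = pick(c("frame", "frame "), required = TRUE),
      x_nm = pick("x [nm]", required = TRUE),
      y_nm = pick("y [nm]", required = TRUE),
      photons = pick("intensity [photon]"),
      sigma_nm = pick("sigma [nm]"),
      background = pick(c("offset [photon]", "bkgstd [photon]"))),
    picasso = data.frame(
      frame = pick("frame", required = TRUE),
      x_nm = pick("x", required = TRUE, scale = pixel_size_nm),
      y_nm = pick("y", required = TRUE, scale = pixel_size_nm),
      photons = pick("photons"),
      sigma_nm = pick(c("sx", "lpx"), scale = pixel_size_nm),
      background = pick("bg")))
  localization_table(out, pixel_size_nm = pixel_size_nm,
                     source = paste0(dialect, ":", basename(path)))
}

#' Write a frame stack as a 16-bit multi-page TIFF
#'
#' Counts are rounded and clamped to \[0, 65535\].
#'
#' @param stack a `frame_stack`.
#' @param path output TIFF file.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  n <- dim(stack$frames)[3]
  pages <- lapply(seq_len(n), function(f) {
    m <- round(stack$frames[, , f])
    m[m < 0] <- 0; m[m > 65535] <- 65535
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF as a frame stack
#'
#' @param path TIFF file.
#' @param camera a [camera_model()] describing the acquisition (pixel size,
#'   gain, nominal PSF).
#' @return a `frame_stack`.
#' @export
read_frame_stack <- function(path, camera = camera_model()) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  frames <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) frames[, , f] <- pages[[f]]
  camera$frame_count <- length(pages)
  structure(list(frames = frames, camera = camera, n_clipped = 0L),
            class = "frame_stack")
}

#' Write a cluster set to CSV files
#'
#' `clusters.csv` carries one row per cluster
#' (`cluster_id,n_loc,area_nm2,density_per_nm2,centroid_x_nm,centroid_y_nm`)
#' and `assignments.csv` the localization-to-cluster map.
#'
#' @param cluster_set a `cluster_set`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cluster_set <- function(cluster_set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cl <- cluster_set$clusters
  for (col in c("area_nm2", "centroid_x_nm", "centroid_y_nm")) {
    cl[[col]] <- round(cl[[col]], 2)
  }
  cl$density_per_nm2 <- signif(cl$density_per_nm2, 6)
  utils::write.csv(cl, file.path(dir, "clusters.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cluster_set$assignments, file.path(dir, "assignments.csv"),
                   row.names = FALSE, quote = FALSE)
  meta <- list(reference_area_um2 = cluster_set$reference_area_um2,
               n_unclustered = cluster_set$n_unclustered,
               n_below_threshold = cluster_set$n_below_threshold,
               config = unclass(cluster_set$config))
  jsonlite::write_json(meta, file.path(dir, "cluster_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cluster set written by [write_cluster_set()]
#'
#' @param dir directory containing `clusters.csv`, `assignments.csv`,
#'   `cluster_meta.json`.
#' @return a `cluster_set`.
#' @export
read_cluster_set <- function(dir) {
  cl <- utils::read.csv(file.path(dir, "clusters.csv"))
  asg <- utils::read.csv(file.path(dir, "assignments.csv"))
  meta <- jsonlite::read_json(file.path(dir, "cluster_meta.json"),
                              simplifyVector = TRUE)
  cfg <- do.call(cluster_config, meta$config[setdiff(names(meta$config), NULL)])
  structure(list(clusters = cl, assignments = asg, config = cfg,
                 reference_area_um2 = meta$reference_area_um2,
                 n_unclustered = meta$n_unclustered,
                 n_below_threshold = meta$n_below_threshold),
            class = "cluster_set")
}

#' Write a drift trajectory to CSV
#'
#' @param trajectory a `drift_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_drift <- function(trajectory, path) {
  df <- as.data.frame(trajectory)
  df$dx_nm <- round(df$dx_nm, 3); df$dy_nm <- round(df$dy_nm, 3)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# known configuration keys per section; unknown keys are rejected
pipeline_sections <- function() {
  list(
    seed = NULL, out = NULL, reference = NULL, conditions = NULL,
    simulate = c("roi_width_nm", "roi_height_nm", "cluster_rate",
                 "molecules_per_cluster_mean", "cluster_sigma_nm",
                 "background_molecule_rate", "scene_type", "origami_sites",
                 "origami_structures", "origami_size_nm", "min_center_sep_nm",
                 "seed"),
    blink = c("k_on", "k_off", "activation_period", "activation_boost",
              "mean_photons_per_frame", "initial_on_fraction"),
    camera = c("pixel_size_nm", "psf_sigma_nm", "em_gain", "read_noise",
               "baseline", "frame_count", "exposure_ms"),
    localize = c("threshold_counts", "min_separation_px", "fit_window_px",
                 "use_ground_truth", "precision_nm"),
    drift = c("n_subsets", "recon_bin_nm", "inject", "inject_magnitude",
              "enabled"),
    cluster = c("bin_nm", "kernel_px", "density_threshold", "connectivity",
                "scale_factor", "min_molecules", "max_iterations",
                "convergence_tol", "area_method"),
    photophysics = c("bin_frames", "frame_rate_hz")
  )
}

#' Read and validate a pipeline configuration file
#'
#' YAML file with per-stage sections (`simulate`, `blink`, `camera`,
#' `localize`, `drift`, `cluster`, `photophysics`), a `conditions` block
#' naming the scenes to generate or the localization CSVs to load, a global
#' `seed` and an output directory. Unknown keys are rejected.
#'
#' @param path YAML config file.
#' @return a validated nested list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg a nested list following the config schema.
#' @export
validate_pipeline_config <- function(cfg) {
  known <- pipeline_sections()
  bad <- setdiff(names(cfg), names(known))
  if (length(bad)) stop_invalid("unknown config section(s): ",
                                paste(bad, collapse = ", "))
  for (sec in names(cfg)) {
    if (is.null(known[[sec]])) next
    extra <- setdiff(names(cfg[[sec]]), known[[sec]])
    if (length(extra)) {
      stop_invalid("unknown key(s) in config section '", sec, "': ",
                   paste(extra, collapse = ", "))
    }
  }
  if (!is.null(cfg$conditions)) {
    for (cname in names(cfg$conditions)) {
      cond <- cfg$conditions[[cname]]
      extra <- setdiff(names(cond), c("simulate", "blink", "locs"))
      if (length(extra)) {
        stop_invalid("unknown key(s) in condition '", cname, "': ",
                     paste(extra, collapse = ", "))
      }
      if (!is.null(cond$simulate)) {
        extra <- setdiff(names(cond$simulate), known$simulate)
        if (length(extra)) {
          stop_invalid("unknown simulate key(s) in condition '", cname, "': ",
                       paste(extra, collapse = ", "))
        }
      }
    }
  }
  structure(cfg, class = c("pipeline_config", "list"))
}
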