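#' Generate a ground-truth emitter field
#'
#' Draws cluster centers from a homogeneous Poisson point process at
#' `cluster_rate` clusters per square micrometer, molecule counts per cluster
#' from a Poisson distribution truncated at >= 1 with the requested mean,
#' isotropic Gaussian molecule offsets about each center, and uniform
#' background molecules. For `origami_grid` scenes, a regular grid of
#' calibration structures is laid out instead, each carrying exactly
#' `origami_sites` labeling sites scattered uniformly over the structure
#' footprint.
#'
#' @param params a [scene_params()] object.
#' @param seed RNG seed; defaults to `params$seed`. The same seed always
#'   yields the same scene.
#' @return an object of class `ground_truth_scene`: a list with
#'   `molecules` (data.frame `x_nm`, `y_nm`, `cluster` where 0 marks
#'   background), `cluster_centers` (data.frame `x_nm`, `y_nm`), `params`,
#'   and placeholders for `events` and `drift` filled by later stages.
#' @export
generate_scene <- function(params, seed = params$seed) {
  if (!inherits(params, "scene_params")) stop_invalid("params must be a scene_params object")
  with_seed(seed, {
    w <- params$roi_width_nm; h <- params$roi_height_nm
    area_um2 <- (w / 1000) * (h / 1000)
    if (params$scene_type == "origami_grid") {
      n_struct <- params$origami_structures
      if (n_struct == 0L) {
        centers <- data.frame(x_nm = numeric(0), y_nm = numeric(0))
      } else {
        # jittered grid layout keeps structures apart
        ncol_g <- ceiling(sqrt(n_struct))
        nrow_g <- ceiling(n_struct / ncol_g)
        gx <- (rep(seq_len(ncol_g), times = nrow_g) - 0.5) * w / ncol_g
        gy <- (rep(seq_len(nrow_g), each = ncol_g) - 0.5) * h / nrow_g
        centers <- data.frame(x_nm = gx[seq_len(n_struct)],
                              y_nm = gy[seq_len(n_struct)])
      }
      n_per <- rep(params$origami_sites, nrow(centers))
      half <- params$origami_size_nm / 2
      off_x <- stats::runif(sum(n_per), -half, half)
      off_y <- stats::runif(sum(n_per), -half, half)
    } else {
      n_clusters <- stats::rpois(1, params$cluster_rate * area_um2)
      centers <- data.frame(x_nm = stats::runif(n_clusters, 0, w),
                            y_nm = stats::runif(n_clusters, 0, h))
      sep <- params$min_center_sep_nm
      if (sep > 0 && n_clusters > 1) {
        keep <- rep(TRUE, n_clusters)
        for (i in seq_len(n_clusters)[-1]) {
          prev <- which(keep[seq_len(i - 1)])
          tries <- 0L
          while (length(prev) > 0 && tries < 200L) {
            d2 <- (centers$x_nm[prev] - centers$x_nm[i])^2 +
              (centers$y_nm[prev] - centers$y_nm[i])^2
            if (min(d2) >= sep^2) break
            centers$x_nm[i] <- stats::runif(1, 0, w)
            centers$y_nm[i] <- stats::runif(1, 0, h)
            tries <- tries + 1L
          }
          if (tries >= 200L) keep[i] <- FALSE
        }
        centers <- centers[keep, , drop = FALSE]
        rownames(centers) <- NULL
      }
      if (nrow(centers) > 0) {
        lam <- params$molecules_per_cluster_mean
        # Poisson truncated at >= 1 by inversion
        n_per <- stats::qpois(stats::runif(nrow(centers), stats::dpois(0, lam), 1), lam)
        n_per <- pmax(n_per, 1L)
      } else n_per <- integer(0)
      off_x <- stats::rnorm(sum(n_per), 0, params$cluster_sigma_nm)
      off_y <- stats::rnorm(sum(n_per), 0, params$cluster_sigma_nm)
    }
    lab <- rep(seq_len(nrow(centers)), times = n_per)
    mol <- data.frame(
      x_nm = rep(centers$x_nm, times = n_per) + off_x,
      y_nm = rep(centers$y_nm, times = n_per) + off_y,
      cluster = as.integer(lab)
    )
    n_bg <- if (params$scene_type == "clustered") {
      stats::rpois(1, params$background_molecule_rate * area_um2)
    } else 0L
    if (n_bg > 0) {
      mol <- rbind(mol, data.frame(x_nm = stats::runif(n_bg, 0, w),
                                   y_nm = stats::runif(n_bg, 0, h),
                                   cluster = 0L))
    }
    structure(list(molecules = mol, cluster_centers = centers,
                   params = params, events = NULL, drift = NULL),
              class = "ground_truth_scene")
  })
}

#' @export
print.ground_truth_scene <- function(x, ...) {
  cat("ground_truth_scene:", nrow(x$molecules), "molecules in",
      nrow(x$cluster_centers), "clusters;",
      if (is.null(x$events)) "no" else nrow(x$events), "emission events\n")
  invisible(x)
}

#' Simulate two-state blinking for every molecule in a scene
#'
#' Advances each molecule's ON/OFF Markov chain once per frame over the
#' camera's acquisition. The OFF->ON probability is `k_on`, multiplied by
#' `activation_boost` on activation frames (frame index divisible by
#' `activation_period`); the ON->OFF probability is `k_off`. Each ON frame
#' contributes one emission event with a Poisson photon count.
#'
#' @param scene a `ground_truth_scene`.
#' @param blink a [blink_model()].
#' @param camera a [camera_model()] (supplies `frame_count`).
#' @param seed RNG seed for reproducible event lists.
#' @return the scene with `events` filled: a data.frame with columns
#'   `molecule`, `frame` (0-based), `photons`.
#' @export
simulate_blinking <- function(scene, blink, camera, seed = NULL) {
  if (!inherits(scene, "ground_truth_scene")) stop_invalid("scene must be a ground_truth_scene")
  n_mol <- nrow(scene$molecules)
  n_frames <- camera$frame_count
  with_seed(seed, {
    if (n_mol == 0L) {
      ev <- data.frame(molecule = integer(0), frame = integer(0), photons = integer(0))
    } else {
      p_off <- min(blink$k_off, 1)
      p_on_base <- min(blink$k_on, 1)
      p_on_boost <- min(blink$k_on * blink$activation_boost, 1)
      on <- stats::runif(n_mol) < blink$initial_on_fraction
      mol_idx <- vector("list", n_frames)
      for (f in seq_len(n_frames) - 1L) {
        if (any(on)) mol_idx[[f + 1L]] <- which(on)
        p_on <- if (f %% blink$activation_period == 0L) p_on_boost else p_on_base
        u <- stats::runif(n_mol)
        on <- ifelse(on, u >= p_off, u < p_on)
      }
      counts <- lengths(mol_idx)
      frames <- rep(seq_len(n_frames) - 1L, times = counts)
      molecules <- unlist(mol_idx, use.names = FALSE)
      if (is.null(molecules)) molecules <- integer(0)
      ev <- data.frame(molecule = molecules, frame = frames,
                       photons = stats::rpois(length(molecules),
                                              blink$mean_photons_per_frame))
    }
    scene$events <- ev
    scene$blink <- blink
    scene$camera <- camera
    scene
  })
}

#' Build a stage-drift trajectory
#'
#' @param kind `"linear"` (constant per-frame step along x of size
#'   `magnitude`), `"random_walk"` (i.i.d. Gaussian steps of SD `magnitude`
#'   per frame on both axes), or `"piecewise"` (a few linear segments with
#'   random directions, speed `magnitude` nm/frame).
#' @param magnitude drift scale in nm per frame (>= 0).
#' @param frame_count number of frames the trajectory covers.
#' @param seed RNG seed for the stochastic kinds.
#' @param n_segments segment count for the piecewise kind.
#' @return an object of class `drift_trajectory`: data.frame with columns
#'   `frame` (0-based), `dx_nm`, `dy_nm`; displacement at frame 0 is (0, 0).
#' @export
make_drift <- function(kind = c("linear", "piecewise", "random_walk"),
                       magnitude, frame_count, seed = NULL, n_segments = 4) {
  if (is.character(kind)) {
    if (!kind[1] %in% c("linear", "piecewise", "random_walk")) {
      stop_invalid("unknown drift kind: ", kind[1])
    }
    kind <- kind[1]
  } else stop_invalid("kind must be a character string")
  check_scalar(magnitude, "magnitude", 0)
  check_scalar(frame_count, "frame_count", 1)
  f <- seq_len(frame_count) - 1L
  with_seed(seed, {
    if (kind == "linear") {
      dx <- f * magnitude; dy <- rep(0, frame_count)
    } else if (kind == "random_walk") {
      dx <- c(0, cumsum(stats::rnorm(frame_count - 1L, 0, magnitude)))
      dy <- c(0, cumsum(stats::rnorm(frame_count - 1L, 0, magnitude)))
    } else {
      bounds <- unique(round(seq(0, frame_count, length.out = n_segments + 1)))
      ang <- stats::runif(length(bounds) - 1L, 0, 2 * pi)
      step_x <- step_y <- numeric(frame_count)
      for (s in seq_along(ang)) {
        idx <- (bounds[s] + 1):bounds[s + 1]
        step_x[idx] <- magnitude * cos(ang[s])
        step_y[idx] <- magnitude * sin(ang[s])
      }
      dx <- cumsum(step_x) - step_x[1]
      dy <- cumsum(step_y) - step_y[1]
    }
    structure(data.frame(frame = f, dx_nm = dx, dy_nm = dy),
              kind = kind, class = c("drift_trajectory", "data.frame"))
  })
}

#' Ground-truth localization table for a simulated scene
#'
#' Converts a scene's emission events directly into a localization table:
#' one row per ON frame of each molecule, at the molecule's true position
#' plus isotropic Gaussian localization error of SD `precision_nm`, plus the
#' scene drift at that frame if `drift` is supplied. This bypasses the
#' imaging and fitting round trip and is the reference input for testing the
#' drift, cluster, quantify, and photophysics stages against known truth.
#'
#' @param scene a `ground_truth_scene` with events (see
#'   [simulate_blinking()]).
#' @param precision_nm localization error SD in nm (default 10).
#' @param drift optional `drift_trajectory` added to the true positions.
#' @param seed RNG seed for the localization jitter.
#' @return a `localization_table` (see [localization_table()]); the extra
#'   column `molecule` carries the ground-truth molecule index.
#' @export
ground_truth_table <- function(scene, precision_nm = 10, drift = NULL, seed = NULL) {
  if (is.null(scene$events)) stop_invalid("scene has no emission events; run simulate_blinking() first")
  ev <- scene$events
  with_seed(seed, {
    x <- scene$molecules$x_nm[ev$molecule] + stats::rnorm(nrow(ev), 0, precision_nm)
    y <- scene$molecules$y_nm[ev$molecule] + stats::rnorm(nrow(ev), 0, precision_nm)
    if (!is.null(drift)) {
      x <- x + drift$dx_nm[ev$frame + 1L]
      y <- y + drift$dy_nm[ev$frame + 1L]
    }
    df <- data.frame(frame = ev$frame, x_nm = x, y_nm = y,
                     photons = ev$photons,
                     sigma_nm = rep(precision_nm, nrow(ev)),
                     background = rep(0, nrow(ev)),
                     molecule = ev$molecule)
    localization_table(df,
                       pixel_size_nm = if (!is.null(scene$camera)) scene$camera$pixel_size_nm else NA_real_,
                       frame_count = if (!is.null(scene$camera)) scene$camera$frame_count else max(ev$frame) + 1L,
                       source = "ground_truth",
                       roi_width_nm = scene$params$roi_width_nm,
                       roi_height_nm = scene$params$roi_height_nm)
  })
}
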