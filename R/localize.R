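#' Detect candidate single-molecule spots in one frame
#'
#' Candidates are strict local maxima (8-neighborhood) whose counts exceed
#' the per-frame median background plus `threshold_counts` — a fixed
#' counts-per-pixel threshold applied identically to every frame, made
#' robust to baseline drift by the median-background reference. Maxima
#' closer than `min_separation_px` are merged, keeping the brighter one.
#'
#' @param frame_image numeric matrix of camera counts (rows index y).
#' @param threshold_counts counts above the per-frame median required at the
#'   peak pixel (> 0).
#' @param min_separation_px minimum center-to-center distance between
#'   retained candidates, in pixels.
#' @return data.frame with columns `row`, `col` (1-based matrix indices) and
#'   `value` (peak counts), ordered by decreasing brightness.
#' @export
detect_spots <- function(frame_image, threshold_counts, min_separation_px = 5) {
  check_scalar(threshold_counts, "threshold_counts", 0, strict = TRUE)
  empty <- data.frame(row = integer(0), col = integer(0), value = numeric(0))
  if (!is.matrix(frame_image) || length(frame_image) == 0) return(empty)
  nr <- nrow(frame_image); nc <- ncol(frame_image)
  if (nr < 3 || nc < 3) return(empty)
  bg <- stats::median(frame_image)
  core <- frame_image[2:(nr - 1), 2:(nc - 1)]
  is_max <- core > bg + threshold_counts
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (core > frame_image[2:(nr - 1) + dr, 2:(nc - 1) + dc])
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  cand <- data.frame(row = idx[, 1] + 1L, col = idx[, 2] + 1L,
                     value = core[is_max])
  cand <- cand[order(-cand$value), , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(cand)) > i)
    if (length(later)) {
      d2 <- (cand$row[later] - cand$row[i])^2 + (cand$col[later] - cand$col[i])^2
      keep[later[d2 < min_separation_px^2]] <- FALSE
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# integrated-Gaussian model over a pixel window; rows/cols are 0-based pixel
# indices, center (cx, cy) in continuous pixel units
integrated_gaussian <- function(rows, cols, cx, cy, n, sigma, bg) {
  fx <- diff(stats::pnorm(c(cols, max(cols) + 1), mean = cx, sd = sigma))
  fy <- diff(stats::pnorm(c(rows, max(rows) + 1), mean = cy, sd = sigma))
  bg + n * outer(fy, fx)
}

#' Fit an integrated 2D Gaussian to a detected spot
#'
#' Least-squares fit of the integrated (per-pixel CDF mass) Gaussian model
#' with parameters center, integrated signal, PSF width and flat background,
#' initialized from the windowed centroid and local statistics. The default
#' `"wls"` method weights residuals by the inverse shot-noise variance of
#' the camera model (counts variance `em_gain * model + read_noise^2`),
#' which keeps the localization precision near the shot-noise bound; plain
#' unweighted `"ls"` is available. The fit is rejected (`fit_ok = FALSE`,
#' never an error) on non-convergence, a center farther than 2 px from the
#' candidate or outside the window, non-positive signal, or a fitted width
#' outside \[0.5, 2.5\] times the nominal PSF width.
#'
#' @param frame_image numeric matrix of camera counts.
#' @param candidate one row of [detect_spots()] output (list or data.frame
#'   with `row`, `col`).
#' @param camera a [camera_model()]; supplies pixel size, nominal PSF width,
#'   gain and baseline.
#' @param fit_window_px odd window side in pixels (default 7); shrunk at the
#'   frame border.
#' @param frame 0-based frame index stored in the result.
#' @param method `"wls"` (shot-noise-weighted least squares, default) or
#'   `"ls"` (unweighted).
#' @return one-row data.frame: `frame`, `x_nm`, `y_nm`, `photons`,
#'   `sigma_nm`, `background` (counts/pixel above camera baseline), `fit_ok`.
#' @export
fit_gaussian_spot <- function(frame_image, candidate, camera,
                              fit_window_px = 7, frame = 0L,
                              method = c("wls", "ls")) {
  method <- match.arg(method)
  half <- floor(fit_window_px / 2)
  nr <- nrow(frame_image); nc <- ncol(frame_image)
  r0 <- candidate$row[1]; c0 <- candidate$col[1]
  rows <- max(1L, r0 - half):min(nr, r0 + half)
  cols <- max(1L, c0 - half):min(nc, c0 + half)
  win <- frame_image[rows, cols, drop = FALSE] - camera$baseline
  fail <- data.frame(frame = frame, x_nm = NA_real_, y_nm = NA_real_,
                     photons = NA_real_, sigma_nm = NA_real_,
                     background = NA_real_, fit_ok = FALSE)
  if (length(win) < 9) return(fail)
  # 0-based pixel indices of the window within the frame
  prow <- rows - 1L; pcol <- cols - 1L
  bg0 <- max(0, min(win))
  sub <- pmax(win - bg0, 0)
  tot <- sum(sub)
  if (tot <= 0) return(fail)
  cx0 <- sum(t(sub) * (pcol + 0.5)) / tot
  cy0 <- sum(sub * (prow + 0.5)) / tot
  s0 <- camera$psf_sigma_nm / camera$pixel_size_nm
  par0 <- c(cx = cx0, cy = cy0, n = tot, sigma = s0, bg = bg0)
  res_fn <- function(p) {
    mdl <- integrated_gaussian(prow, pcol, p[1], p[2], p[3], p[4], p[5])
    r <- mdl - win
    if (method == "wls") {
      v <- pmax(camera$em_gain * mdl + camera$read_noise^2, 1)
      r <- r / sqrt(v)
    }
    as.vector(r)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, fn = res_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0, 9)) return(fail)
  p <- fit$par
  cx <- p[["cx"]]; cy <- p[["cy"]]; n <- p[["n"]]; sg <- abs(p[["sigma"]])
  in_window <- cx >= min(pcol) && cx <= max(pcol) + 1 &&
    cy >= min(prow) && cy <= max(prow) + 1
  near_cand <- abs(cx - (c0 - 0.5)) <= 2 && abs(cy - (r0 - 0.5)) <= 2
  width_ok <- sg >= 0.5 * s0 && sg <= 2.5 * s0
  if (!in_window || !near_cand || !width_ok || n <= 0) return(fail)
  data.frame(frame = frame,
             x_nm = cx * camera$pixel_size_nm,
             y_nm = cy * camera$pixel_size_nm,
             photons = n / camera$em_gain,
             sigma_nm = sg * camera$pixel_size_nm,
             background = p[["bg"]] / camera$em_gain,
             fit_ok = TRUE)
}

#' Localize every frame of a stack
#'
#' Runs [detect_spots()] and [fit_gaussian_spot()] on each frame with one
#' fixed threshold across the whole acquisition, keeping only converged fits.
#' Each accepted fit is one blinking event; events are never linked or merged
#' across frames.
#'
#' @param stack a `frame_stack` (see [render_frames()] /
#'   [read_frame_stack()]).
#' @param threshold_counts detection threshold in counts above the per-frame
#'   median.
#' @param min_separation_px candidate merge radius in pixels.
#' @param fit_window_px fit window side (odd, default 7).
#' @param method fitting method passed to [fit_gaussian_spot()].
#' @return a [localization_table()].
#' @export
localize_stack <- function(stack, threshold_counts, min_separation_px = 5,
                           fit_window_px = 7, method = c("wls", "ls")) {
  method <- match.arg(method)
  camera <- stack$camera
  n_frames <- dim(stack$frames)[3]
  out <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    img <- stack$frames[, , f]
    cand <- detect_spots(img, threshold_counts, min_separation_px)
    if (nrow(cand) == 0) next
    fits <- lapply(seq_len(nrow(cand)), function(i) {
      fit_gaussian_spot(img, cand[i, ], camera, fit_window_px, frame = f - 1L,
                        method = method)
    })
    fits <- do.call(rbind, fits)
    out[[f]] <- fits[fits$fit_ok, , drop = FALSE]
  }
  df <- do.call(rbind, out)
  if (is.null(df)) {
    df <- data.frame(frame = integer(0), x_nm = numeric(0), y_nm = numeric(0),
                     photons = numeric(0), sigma_nm = numeric(0),
                     background = numeric(0), fit_ok = logical(0))
  }
  rownames(df) <- NULL
  localization_table(df[, c("frame", "x_nm", "y_nm", "photons", "sigma_nm",
                            "background")],
                     pixel_size_nm = camera$pixel_size_nm,
                     frame_count = n_frames,
                     source = "localize_stack",
                     roi_width_nm = dim(stack$frames)[2] * camera$pixel_size_nm,
                     roi_height_nm = dim(stack$frames)[1] * camera$pixel_size_nm)
}
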