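#' Render a frame stack from simulated emission events
#'
#' Forward camera model: each emission event is rendered as an integrated 2D
#' Gaussian PSF (per-pixel mass from the Gaussian CDF, not point-sampled)
#' centered on the molecule position plus the drift displacement of its
#' frame. Expected per-pixel photons are Poisson-sampled, multiplied by the
#' EM gain, and corrupted with Gaussian read noise on top of the baseline
#' offset; `noiseless = TRUE` skips both noise sources for forward-model
#' checks. Pixel p spans `[p * pixel_size, (p + 1) * pixel_size)` nm
#' (half-open), with the ROI origin at the top-left corner.
#'
#' @param scene a `ground_truth_scene` with emission events.
#' @param camera a [camera_model()].
#' @param drift optional `drift_trajectory`; events are displaced by it.
#' @param noiseless logical; render expected counts without Poisson or read
#'   noise.
#' @param n_frames optionally render only the first `n_frames` frames.
#' @param seed RNG seed for the noise draws.
#' @return an object of class `frame_stack`: list with `frames` (3D array
#'   `[row, col, frame]`, rows indexing y), `camera`, and `n_clipped` (events
#'   whose PSF center fell outside the ROI, clipped with a warning).
#' @export
render_frames <- function(scene, camera, drift = NULL, noiseless = FALSE,
                          n_frames = NULL, seed = NULL) {
  if (is.null(scene$events)) stop_invalid("scene has no emission events; run simulate_blinking() first")
  px <- camera$pixel_size_nm
  nx <- max(1L, ceiling(scene$params$roi_width_nm / px))
  ny <- max(1L, ceiling(scene$params$roi_height_nm / px))
  if (is.null(n_frames)) n_frames <- camera$frame_count
  ev <- scene$events[scene$events$frame < n_frames, , drop = FALSE]
  frames <- array(0, dim = c(ny, nx, n_frames))
  n_clipped <- 0L
  if (nrow(ev) > 0) {
    x <- scene$molecules$x_nm[ev$molecule]
    y <- scene$molecules$y_nm[ev$molecule]
    if (!is.null(drift)) {
      x <- x + drift$dx_nm[ev$frame + 1L]
      y <- y + drift$dy_nm[ev$frame + 1L]
    }
    inside <- x >= 0 & x < scene$params$roi_width_nm &
      y >= 0 & y < scene$params$roi_height_nm
    n_clipped <- sum(!inside)
    if (n_clipped > 0) {
      warning(n_clipped, " emission event(s) outside the ROI were clipped")
    }
    x <- x[inside]; y <- y[inside]
    phot <- ev$photons[inside]; frm <- ev$frame[inside]
    s_px <- camera$psf_sigma_nm / px
    half <- ceiling(4 * s_px)  # +/-4 sigma window holds >99.99% of the mass
    for (i in seq_along(x)) {
      cx <- x[i] / px; cy <- y[i] / px  # continuous pixel coordinates
      c0 <- floor(cx); r0 <- floor(cy)
      cols <- max(0, c0 - half):min(nx - 1L, c0 + half)
      rows <- max(0, r0 - half):min(ny - 1L, r0 + half)
      fx <- diff(stats::pnorm(c(cols, max(cols) + 1), mean = cx, sd = s_px))
      fy <- diff(stats::pnorm(c(rows, max(rows) + 1), mean = cy, sd = s_px))
      frames[rows + 1L, cols + 1L, frm[i] + 1L] <-
        frames[rows + 1L, cols + 1L, frm[i] + 1L] + phot[i] * outer(fy, fx)
    }
  }
  with_seed(seed, {
    if (noiseless) {
      frames <- frames * camera$em_gain + camera$baseline
    } else {
      n <- length(frames)
      frames <- array(stats::rpois(n, frames) * camera$em_gain +
                        stats::rnorm(n, 0, camera$read_noise) + camera$baseline,
                      dim = dim(frames))
      frames[frames < 0] <- 0
    }
    structure(list(frames = frames, camera = camera, n_clipped = n_clipped),
              class = "frame_stack")
  })
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat("frame_stack: ", d[3], " frame(s) of ", d[2], " x ", d[1],
      " px (", x$camera$pixel_size_nm, " nm/px)\n", sep = "")
  invisible(x)
}
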