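# 2D cross-correlation of equally sized matrices via zero-padded FFT;
# returns the (dx, dy) shift of b relative to a, in bins, refined to sub-bin
# precision with a 3-point parabolic fit around the peak
xcorr_shift <- function(a, b) {
  nr <- nrow(a); nc <- ncol(a)
  pr <- 2L * nr; pc <- 2L * nc
  pa <- matrix(0, pr, pc); pb <- matrix(0, pr, pc)
  pa[1:nr, 1:nc] <- a
  pb[1:nr, 1:nc] <- b
  cc <- Re(stats::fft(stats::fft(pa) * Conj(stats::fft(pb)), inverse = TRUE))
  peak <- which.max(cc)
  pi_r <- (peak - 1L) %% pr
  pi_c <- (peak - 1L) %/% pr
  # lag l in [-(n-1), n-1] mapped onto the circular index
  lag_r <- if (pi_r > pr / 2) pi_r - pr else pi_r
  lag_c <- if (pi_c > pc / 2) pi_c - pc else pi_c
  para <- function(m1, m0, p1) {
    den <- m1 - 2 * m0 + p1
    if (den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (m1 - p1) / den))
  }
  at <- function(r, c) cc[(r %% pr) + 1L, (c %% pc) + 1L]
  dr <- para(at(pi_r - 1L, pi_c), at(pi_r, pi_c), at(pi_r + 1L, pi_c))
  dc <- para(at(pi_r, pi_c - 1L), at(pi_r, pi_c), at(pi_r, pi_c + 1L))
  # cc peaks at the lag by which a must be shifted to overlay b: b ~ a
  # translated by -lag, so the displacement of b relative to a is -lag
  c(dx = -(lag_c + dc), dy = -(lag_r + dr))
}

# bin a set of coordinates into a 2D histogram over a fixed extent
bin_histogram <- function(x, y, bin_nm, width_nm, height_nm) {
  nx <- max(1L, ceiling(width_nm / bin_nm))
  ny <- max(1L, ceiling(height_nm / bin_nm))
  cx <- pmin(pmax(floor(x / bin_nm), 0), nx - 1L)
  cy <- pmin(pmax(floor(y / bin_nm), 0), ny - 1L)
  tb <- tabulate(cy * nx + cx + 1L, nbins = nx * ny)
  # linear index cy * nx + cx is row-major
  matrix(tb, nrow = ny, ncol = nx, byrow = TRUE)
}

#' Estimate stage drift from temporal subsets of a localization table
#'
#' Splits the acquisition into `n_subsets` equal frame ranges, reconstructs
#' each subset as a 2D histogram at `recon_bin_nm`, and estimates each
#' subset's rigid displacement relative to the first subset as the argmax of
#' their image cross-correlation, refined to sub-bin precision by 3-point
#' parabolic interpolation. The per-frame trajectory interpolates linearly
#' between subset midpoints and extrapolates the end segments linearly.
#'
#' @param table a [localization_table()].
#' @param n_subsets number of temporal subsets (>= 2; default 10).
#' @param recon_bin_nm reconstruction bin size in nm (default 20).
#' @return an object of class `drift_estimate`: list with `subsets`
#'   (data.frame `first_frame`, `last_frame`, `mid_frame`, `dx_nm`, `dy_nm`)
#'   and `trajectory` (a `drift_trajectory` covering every frame).
#' @export
estimate_drift <- function(table, n_subsets = 10, recon_bin_nm = 20) {
  check_scalar(n_subsets, "n_subsets", 2)
  check_scalar(recon_bin_nm, "recon_bin_nm", 0, strict = TRUE)
  if (nrow(table) == 0) {
    stop(errorCondition("cannot estimate drift from an empty table",
                        class = c("smlmpipe_estimation_error", "error")))
  }
  n_frames <- max(attr(table, "frame_count"), max(table$frame) + 1L)
  bounds <- round(seq(0, n_frames, length.out = n_subsets + 1))
  ext <- table_extent(table)
  pad <- 4 * recon_bin_nm
  usable <- list()
  for (s in seq_len(n_subsets)) {
    sel <- table$frame >= bounds[s] & table$frame < bounds[s + 1]
    if (!any(sel)) {
      warning("drift subset ", s, " contains no localizations; skipped")
      next
    }
    hist_s <- bin_histogram(table$x_nm[sel], table$y_nm[sel], recon_bin_nm,
                            ext[1] + pad, ext[2] + pad)
    usable[[length(usable) + 1L]] <- list(
      s = s, hist = hist_s,
      mid = (bounds[s] + bounds[s + 1] - 1) / 2)
  }
  if (length(usable) < 2) {
    stop(errorCondition("fewer than 2 usable subsets for drift estimation",
                        class = c("smlmpipe_estimation_error", "error")))
  }
  ref <- usable[[1]]$hist
  sub <- data.frame(first_frame = bounds[vapply(usable, `[[`, 0, "s")],
                    last_frame = bounds[vapply(usable, `[[`, 0, "s") + 1] - 1,
                    mid_frame = vapply(usable, `[[`, 0, "mid"),
                    dx_nm = 0, dy_nm = 0)
  for (i in seq_along(usable)[-1]) {
    sh <- xcorr_shift(ref, usable[[i]]$hist)
    sub$dx_nm[i] <- sh["dx"] * recon_bin_nm
    sub$dy_nm[i] <- sh["dy"] * recon_bin_nm
  }
  f <- 0:(n_frames - 1L)
  interp_ends <- function(v) {
    if (nrow(sub) == 1) return(rep(v[1], length(f)))
    out <- stats::approx(sub$mid_frame, v, xout = f, rule = 2)$y
    # linear extrapolation beyond the first/last subset midpoints
    k <- nrow(sub)
    slope1 <- (v[2] - v[1]) / (sub$mid_frame[2] - sub$mid_frame[1])
    slopek <- (v[k] - v[k - 1]) / (sub$mid_frame[k] - sub$mid_frame[k - 1])
    lo <- f < sub$mid_frame[1]; hi <- f > sub$mid_frame[k]
    out[lo] <- v[1] + slope1 * (f[lo] - sub$mid_frame[1])
    out[hi] <- v[k] + slopek * (f[hi] - sub$mid_frame[k])
    out
  }
  traj <- structure(data.frame(frame = f,
                               dx_nm = interp_ends(sub$dx_nm),
                               dy_nm = interp_ends(sub$dy_nm)),
                    kind = "estimated",
                    class = c("drift_trajectory", "data.frame"))
  structure(list(subsets = sub, trajectory = traj, recon_bin_nm = recon_bin_nm),
            class = "drift_estimate")
}

#' @export
print.drift_estimate <- function(x, ...) {
  k <- nrow(x$subsets)
  cat("drift_estimate:", k, "subsets; total displacement (",
      sprintf("%.1f", x$subsets$dx_nm[k]), ",",
      sprintf("%.1f", x$subsets$dy_nm[k]), ") nm\n")
  invisible(x)
}

#' Remove estimated drift from a localization table
#'
#' Subtracts the estimated per-frame trajectory from every localization's
#' coordinates. The row count never changes; frames outside the trajectory
#' are clamped to the nearest defined frame (with a message).
#'
#' @param table a [localization_table()].
#' @param estimate a `drift_estimate` (or a `drift_trajectory`).
#' @return the corrected [localization_table()].
#' @export
correct_drift <- function(table, estimate) {
  traj <- if (inherits(estimate, "drift_estimate")) estimate$trajectory else estimate
  idx <- table$frame + 1L
  out_of_range <- idx < 1L | idx > nrow(traj)
  if (any(out_of_range)) {
    message(sum(out_of_range), " localization(s) outside the drift trajectory; clamped")
    idx <- pmin(pmax(idx, 1L), nrow(traj))
  }
  table$x_nm <- table$x_nm - traj$dx_nm[idx]
  table$y_nm <- table$y_nm - traj$dy_nm[idx]
  table
}

#' Apply (inject) a drift trajectory into a localization table
#'
#' Adds the trajectory's per-frame displacement to every localization; the
#' inverse of [correct_drift()] for the same trajectory. Used to construct
#' drift-injection round-trip benchmarks.
#'
#' @param table a [localization_table()].
#' @param trajectory a `drift_trajectory`.
#' @return the displaced [localization_table()].
#' @export
apply_drift <- function(table, trajectory) {
  idx <- pmin(pmax(table$frame + 1L, 1L), nrow(trajectory))
  table$x_nm <- table$x_nm + trajectory$dx_nm[idx]
  table$y_nm <- table$y_nm + trajectory$dy_nm[idx]
  table
}
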