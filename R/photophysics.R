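# Blinking-kinetics controls: temporal decay of the event rate (effective
# k_OFF) and photon-count statistics, used to check that two substrates
# leave the fluorophore photocycle unchanged.

#' Events-per-bin time trace of a localization table
#'
#' @param table a [localization_table()].
#' @param bin_frames frames per time bin (>= 1).
#' @return data.frame with `bin` (0-based), `frame_start`, `count`; counts
#'   sum to the table row count.
#' @export
event_rate_trace <- function(table, bin_frames = 50) {
  check_scalar(bin_frames, "bin_frames", 1)
  n_frames <- max(attr(table, "frame_count"),
                  if (nrow(table)) max(table$frame) + 1L else 1L)
  n_bins <- ceiling(n_frames / bin_frames)
  counts <- tabulate(floor(table$frame / bin_frames) + 1L, nbins = n_bins)
  data.frame(bin = seq_len(n_bins) - 1L,
             frame_start = (seq_len(n_bins) - 1L) * bin_frames,
             count = counts)
}

#' Fit the blinking OFF-rate from an event-rate decay
#'
#' Nonlinear least-squares fit of `N(t) = A * exp(-k * t) + c` to the
#' initial decay of the events-per-bin trace; the offset absorbs the
#' steady-state re-activation level. The fit window runs from the global
#' maximum bin to the first bin whose count comes within 10% of the tail
#' plateau (the mean of the last tenth of the trace). `k` is reported per
#' frame and, through `frame_rate_hz`, per second.
#'
#' @param trace output of [event_rate_trace()].
#' @param frame_rate_hz acquisition frame rate (default 33 Hz).
#' @param bin_frames frames per trace bin (taken from the trace spacing when
#'   omitted).
#' @return an object of class `rate_fit`: list with `k_off_per_frame`,
#'   `k_off_per_s`, `amplitude`, `offset`, `stderr` (named, per-frame
#'   scale), `k_stderr_eff` and `k_ci95` (standard error and 95% CI of the
#'   rate after correcting for the blinking autocorrelation of neighboring
#'   bins), `frames_used`, `fitted` (per-bin fitted values over the
#'   window). The fit is weighted by the inverse Poisson variance of the
#'   bin counts.
#' @export
fit_off_rate <- function(trace, frame_rate_hz = 33, bin_frames = NULL) {
  if (is.null(bin_frames)) {
    bin_frames <- if (nrow(trace) > 1) diff(trace$frame_start[1:2]) else 1
  }
  nz <- sum(trace$count > 0)
  if (nz < 10) {
    stop(errorCondition("need at least 10 nonzero bins to fit a decay rate",
                        class = c("smlmpipe_fit_error", "error")))
  }
  i_max <- which.max(trace$count)
  tail_n <- max(1L, floor(nrow(trace) / 10))
  plateau <- mean(utils::tail(trace$count, tail_n))
  span <- trace$count[i_max] - plateau
  past <- which(seq_len(nrow(trace)) > i_max &
                  trace$count <= plateau + 0.1 * span)
  i_end <- if (length(past)) past[1] else nrow(trace)
  if (i_end - i_max + 1 < 5) i_end <- min(nrow(trace), i_max + 9L)
  win <- trace[i_max:i_end, , drop = FALSE]
  t_frames <- win$frame_start - win$frame_start[1]
  y <- win$count
  c0 <- max(plateau, 0)
  a0 <- max(y[1] - c0, .Machine$double.eps)
  pos <- which(y - c0 > a0 * 0.05)
  k0 <- if (length(pos) > 2) {
    fit0 <- stats::lm(log(y[pos] - c0 + 1e-9) ~ t_frames[pos])
    max(1e-6, -stats::coef(fit0)[2])
  } else 1 / max(t_frames[length(t_frames)], 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-k * t_frames) + c,
                      start = list(A = a0, k = k0, c = c0),
                      lower = c(A = 0, k = 0, c = 0),
                      weights = 1 / pmax(y, 1),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    stop(errorCondition(
      paste0("off-rate fit did not converge: ", conditionMessage(fit),
             " [window bins ", i_max, "-", i_end, ", peak ", max(y), "]"),
      class = c("smlmpipe_fit_error", "error")))
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  out <- structure(list(
    k_off_per_frame = unname(est["k"]),
    k_off_per_s = unname(est["k"]) * frame_rate_hz,
    amplitude = unname(est["A"]), offset = unname(est["c"]),
    stderr = c(A = unname(se[1]), k = unname(se[2]), c = unname(se[3])),
    k_stderr_eff = {
      # neighboring bins share the same ON molecules: counts decorrelate
      # over one mean ON dwell (1/k frames), so the independent-bin error
      # is inflated by sqrt(dwell / bin) to the effective sample size
      dwell_bins <- if (est[["k"]] > 0) 1 / (est[["k"]] * bin_frames) else 1
      unname(se[2]) * sqrt(max(1, dwell_bins))
    },
    frames_used = c(win$frame_start[1], win$frame_start[nrow(win)] + bin_frames - 1),
    fitted = stats::fitted(fit)
  ), class = "rate_fit")
  out$k_ci95 <- out$k_off_per_frame + c(-1.96, 1.96) * out$k_stderr_eff
  out
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("rate_fit: k_off = %.4g /frame (%.4g /s), A = %.1f, offset = %.1f\n",
              x$k_off_per_frame, x$k_off_per_s, x$amplitude, x$offset))
  invisible(x)
}

#' Photon-count statistics of localized events
#'
#' @param table a [localization_table()] with a `photons` column.
#' @return list with `mean`, `median`, `sd`, `n_events` over events with a
#'   finite photon count.
#' @export
photon_stats <- function(table) {
  ph <- table$photons[is.finite(table$photons)]
  if (length(ph) == 0) {
    stop(errorCondition("no events with photon counts",
                        class = c("smlmpipe_empty_condition", "error")))
  }
  list(mean = mean(ph), median = stats::median(ph), sd = stats::sd(ph),
       n_events = length(ph))
}

#' Compare per-structure event counts between two calibration acquisitions
#'
#' Segments each table with [cluster_field()] (each origami structure
#' becomes one cluster), extracts the per-structure localization-event
#' counts, and compares the two distributions with a two-sample KS test —
#' the substrate-equivalence check run on DNA-origami standards.
#'
#' @param table_a,table_b localization tables from `origami_grid` scenes.
#' @param config a [cluster_config()] used for both tables.
#' @return list with `mean_a`, `sem_a`, `mean_b`, `sem_b`, `n_a`, `n_b`,
#'   `D`, `p`, and `counts_a`/`counts_b` (per-structure event counts).
#' @export
compare_origami_counts <- function(table_a, table_b,
                                   config = cluster_config()) {
  counts <- lapply(list(table_a, table_b), function(tb) {
    cs <- cluster_field(tb, config)
    cs$clusters$n_loc
  })
  if (length(counts[[1]]) < 3 || length(counts[[2]]) < 3) {
    stop_invalid("need at least 3 segmented structures per condition")
  }
  ks <- ks_two_sample(counts[[1]], counts[[2]])
  list(mean_a = mean(counts[[1]]), sem_a = sem(counts[[1]]),
       mean_b = mean(counts[[2]]), sem_b = sem(counts[[2]]),
       n_a = length(counts[[1]]), n_b = length(counts[[2]]),
       D = ks$D, p = ks$p,
       counts_a = counts[[1]], counts_b = counts[[2]])
}
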