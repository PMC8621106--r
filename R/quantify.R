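# Per-condition summaries, percent changes between substrates, and the
# two-condition statistics (two-sample KS on per-cluster distributions,
# unpaired Student's t on per-field cluster densities).

sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Summarize the clusters of one experimental condition
#'
#' Pools clusters across fields of view for the distribution metrics
#' (localizations per cluster, area, density: mean +/- SEM), and computes
#' clusters per square micrometer field by field (n_clusters divided by that
#' field's reference area) before averaging across fields.
#'
#' @param cluster_sets a `cluster_set` or list of `cluster_set`s (one per
#'   field of view).
#' @param label condition name.
#' @return an object of class `condition_summary`: list with `label`,
#'   `n_clusters`, `n_fields`, `mean`/`sem` (named vectors over `n_loc`,
#'   `area_nm2`, `density_per_nm2`), `clusters_per_um2` (per-field vector),
#'   `clusters_per_um2_mean`/`_sem`, and `samples` (the pooled per-cluster
#'   data.frame).
#' @export
summarize_condition <- function(cluster_sets, label = "") {
  if (inherits(cluster_sets, "cluster_set")) cluster_sets <- list(cluster_sets)
  pooled <- do.call(rbind, lapply(cluster_sets, function(s) s$clusters))
  if (is.null(pooled) || nrow(pooled) == 0) {
    stop(errorCondition("no clusters in any field for condition summary",
                        class = c("smlmpipe_empty_condition", "error")))
  }
  per_field <- vapply(cluster_sets, function(s) {
    if (s$reference_area_um2 > 0) nrow(s$clusters) / s$reference_area_um2 else NA_real_
  }, 0)
  metrics <- c(n_loc = "n_loc", area_nm2 = "area_nm2",
               density_per_nm2 = "density_per_nm2")
  means <- vapply(metrics, function(m) mean(pooled[[m]], na.rm = TRUE), 0)
  sems <- vapply(metrics, function(m) {
    v <- pooled[[m]][!is.na(pooled[[m]])]
    sem(v)
  }, 0)
  structure(list(label = label, n_clusters = nrow(pooled),
                 n_fields = length(cluster_sets),
                 mean = means, sem = sems,
                 clusters_per_um2 = per_field,
                 clusters_per_um2_mean = mean(per_field, na.rm = TRUE),
                 clusters_per_um2_sem = if (sum(!is.na(per_field)) > 1) sem(per_field[!is.na(per_field)]) else NA_real_,
                 samples = pooled),
            class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat("condition '", x$label, "': ", x$n_clusters, " clusters over ",
      x$n_fields, " field(s)\n", sep = "")
  cat(sprintf("  N_loc/cluster  %.1f +/- %.1f\n", x$mean["n_loc"], x$sem["n_loc"]))
  cat(sprintf("  area (nm^2)    %.1f +/- %.1f\n", x$mean["area_nm2"], x$sem["area_nm2"]))
  cat(sprintf("  density /nm^2  %.3f +/- %.3f\n", x$mean["density_per_nm2"],
              x$sem["density_per_nm2"]))
  cat(sprintf("  clusters/um^2  %.1f\n", x$clusters_per_um2_mean))
  invisible(x)
}

#' Signed percent change between two condition means
#'
#' `100 * (test - reference) / reference`, reported both exactly and rounded
#' to the nearest integer (half away from zero), the form figure captions
#' print.
#'
#' @param reference_mean mean of the reference condition (non-zero).
#' @param test_mean mean of the test condition.
#' @return list with `percent` (exact) and `rounded` (integer).
#' @export
percent_change <- function(reference_mean, test_mean) {
  check_scalar(reference_mean, "reference_mean")
  check_scalar(test_mean, "test_mean")
  if (reference_mean == 0) stop_invalid("reference mean must be non-zero")
  pc <- 100 * (test_mean - reference_mean) / reference_mean
  list(percent = pc, rounded = as.integer(round_half_away(pc)))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided KS statistic `D = sup |ECDF_a - ECDF_b|` with the asymptotic
#' p-value (the regime of the per-cluster sample sizes this pipeline
#' produces); `exact = TRUE` switches to the exact small-sample p-value.
#'
#' @param sample_a,sample_b numeric vectors of length >= 2.
#' @param exact use the exact p-value computation.
#' @return list with `D`, `p`.
#' @export
ks_two_sample <- function(sample_a, sample_b, exact = FALSE) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stop_invalid("both samples must have at least 2 values")
  }
  kt <- suppressWarnings(stats::ks.test(sample_a, sample_b, exact = exact))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Unpaired two-tailed Student's t-test (pooled variance)
#'
#' @param sample_a,sample_b numeric vectors of length >= 2.
#' @return list with `t`, `p`, `df`, and `degenerate` (TRUE when the pooled
#'   variance is zero: equal means give t = 0, p = 1; unequal means give
#'   p = 0 with the flag set).
#' @export
t_test_unpaired <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stop_invalid("both samples must have at least 2 values")
  }
  df <- length(sample_a) + length(sample_b) - 2
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    if (mean(sample_a) == mean(sample_b)) {
      return(list(t = 0, p = 1, df = df, degenerate = TRUE))
    }
    return(list(t = sign(mean(sample_b) - mean(sample_a)) * Inf, p = 0,
                df = df, degenerate = TRUE))
  }
  tt <- stats::t.test(sample_a, sample_b, var.equal = TRUE,
                      alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Compare two conditions cluster-wise and field-wise
#'
#' Assembles the full two-condition report: percent change of the four
#' summary metrics, two-sample KS tests on the pooled per-cluster
#' distributions of localizations, area and density, an unpaired Student's
#' t-test on the per-field clusters-per-area values, and significance flags
#' at p < 0.05.
#'
#' @param reference,test `condition_summary` objects (or lists of
#'   `cluster_set`s, summarized with the given labels).
#' @param labels length-2 character labels used when raw cluster sets are
#'   passed.
#' @param alpha significance level; default 0.05.
#' @return an object of class `comparison_report`.
#' @export
compare_conditions <- function(reference, test,
                               labels = c("reference", "test"),
                               alpha = 0.05) {
  if (!inherits(reference, "condition_summary")) {
    reference <- summarize_condition(reference, labels[1])
  }
  if (!inherits(test, "condition_summary")) {
    test <- summarize_condition(test, labels[2])
  }
  metrics <- c("n_loc", "area_nm2", "density_per_nm2")
  pc <- lapply(metrics, function(m) {
    percent_change(reference$mean[[m]], test$mean[[m]])
  })
  names(pc) <- metrics
  pc$clusters_per_um2 <- percent_change(reference$clusters_per_um2_mean,
                                        test$clusters_per_um2_mean)
  ks <- lapply(metrics, function(m) {
    a <- reference$samples[[m]]; b <- test$samples[[m]]
    ks_two_sample(a[!is.na(a)], b[!is.na(b)])
  })
  names(ks) <- metrics
  tt <- if (sum(!is.na(reference$clusters_per_um2)) >= 2 &&
            sum(!is.na(test$clusters_per_um2)) >= 2) {
    t_test_unpaired(reference$clusters_per_um2[!is.na(reference$clusters_per_um2)],
                    test$clusters_per_um2[!is.na(test$clusters_per_um2)])
  } else NULL
  structure(list(
    reference = reference$label, test = test$label,
    percent_change = pc, ks = ks, t_test = tt,
    significant = c(
      vapply(ks, function(k) k$p < alpha, TRUE),
      clusters_per_um2 = if (!is.null(tt)) tt$p < alpha else NA),
    alpha = alpha,
    summaries = list(reference = reference, test = test)
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report: ", x$test, " vs ", x$reference, "\n", sep = "")
  lab <- c(n_loc = "N_loc/cluster", area_nm2 = "cluster area",
           density_per_nm2 = "cluster density",
           clusters_per_um2 = "clusters/um^2")
  for (m in names(lab)) {
    pcm <- x$percent_change[[m]]
    star <- if (!is.na(x$significant[m]) && isTRUE(x$significant[[m]])) " *" else ""
    p <- if (m == "clusters_per_um2") {
      if (is.null(x$t_test)) NA_real_ else x$t_test$p
    } else x$ks[[m]]$p
    cat(sprintf("  %-16s %+d%% (exact %+.2f%%), p = %.3g%s\n",
                lab[m], pcm$rounded, pcm$percent, p, star))
  }
  invisible(x)
}

#' Serialize a comparison report to JSON
#'
#' @param report a `comparison_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(report, path) {
  out <- list(
    reference = report$reference, test = report$test, alpha = report$alpha,
    percent_change = lapply(report$percent_change, function(p) {
      list(percent = p$percent, rounded = p$rounded)
    }),
    ks = report$ks, t_test = report$t_test,
    significant = as.list(report$significant),
    summaries = lapply(report$summaries, function(s) {
      list(label = s$label, n_clusters = s$n_clusters, n_fields = s$n_fields,
           mean = as.list(s$mean), sem = as.list(s$sem),
           clusters_per_um2_mean = s$clusters_per_um2_mean,
           clusters_per_um2_sem = s$clusters_per_um2_sem)
    }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
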