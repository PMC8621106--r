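# fixtures built in code: small scenes, tables and oracles shared by tests

# scene of well-separated clusters with exactly one emission event per
# molecule (all ON at frame 0, switched off after one frame)
one_shot_scene <- function(seed, roi_nm = 4000, cluster_rate = 5,
                           mol_mean = 50, sigma_nm = 12, bg_rate = 5,
                           min_sep_nm = 300, frame_count = 4) {
  p <- scene_params(roi_width_nm = roi_nm, roi_height_nm = roi_nm,
                    cluster_rate = cluster_rate,
                    molecules_per_cluster_mean = mol_mean,
                    cluster_sigma_nm = sigma_nm,
                    background_molecule_rate = bg_rate,
                    min_center_sep_nm = min_sep_nm)
  sc <- generate_scene(p, seed = seed)
  cam <- camera_model(frame_count = frame_count)
  bl <- blink_model(k_on = 0, k_off = 1, initial_on_fraction = 1,
                    activation_boost = 1)
  simulate_blinking(sc, bl, cam, seed = seed + 1L)
}

# hand-built localization table
make_table <- function(x, y, frame = 0L, photons = 1000, roi = NULL) {
  n <- length(x)
  localization_table(
    data.frame(frame = rep_len(frame, n), x_nm = x, y_nm = y,
               photons = rep_len(photons, n), sigma_nm = rep_len(10, n),
               background = rep_len(0, n)),
    roi_width_nm = if (is.null(roi)) NA_real_ else roi[1],
    roi_height_nm = if (is.null(roi)) NA_real_ else roi[2])
}

# exhaustive 2-means oracle: best SSD over all 2-block partitions
exhaustive_two_means <- function(xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  stopifnot(n <= 20)
  best <- NULL
  best_ssd <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    a <- bitwAnd(code, 2^(0:(n - 1))) > 0
    ca <- colMeans(xy[a, , drop = FALSE])
    cb <- colMeans(xy[!a, , drop = FALSE])
    ssd <- sum(sweep(xy[a, , drop = FALSE], 2, ca)^2) +
      sum(sweep(xy[!a, , drop = FALSE], 2, cb)^2)
    if (ssd < best_ssd) {
      best_ssd <- ssd
      best <- a
    }
  }
  list(partition = best, ssd = best_ssd)
}

# brute-force flood fill (recursive, 4- or 8-connectivity) for CC oracle
flood_fill_labels <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 4) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else {
    o <- expand.grid(dr = -1:1, dc = -1:1)
    o <- o[!(o$dr == 0 & o$dc == 0), ]
    split(as.matrix(o), seq_len(nrow(o)))
  }
  cur <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || lab[r, c] != 0L) next
    cur <- cur + 1L
    stack <- list(c(r, c))
    lab[r, c] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (o in offs) {
        rr <- p[1] + o[1]; cc <- p[2] + o[2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# compare two labelings up to label permutation
same_partition <- function(a, b) {
  identical(unname(as.integer(factor(a, levels = unique(a)))),
            unname(as.integer(factor(b, levels = unique(b)))))
}

# match localizations to ground-truth event positions within tol_nm;
# returns recall and precision
match_events <- function(table, scene, tol_nm = 50) {
  truth_x <- scene$molecules$x_nm[scene$events$molecule]
  truth_y <- scene$molecules$y_nm[scene$events$molecule]
  truth_f <- scene$events$frame
  matched_truth <- rep(FALSE, nrow(scene$events))
  matched_loc <- rep(FALSE, nrow(table))
  for (i in seq_len(nrow(table))) {
    cand <- which(truth_f == table$frame[i] & !matched_truth)
    if (!length(cand)) next
    d2 <- (truth_x[cand] - table$x_nm[i])^2 + (truth_y[cand] - table$y_nm[i])^2
    j <- which.min(d2)
    if (d2[j] <= tol_nm^2) {
      matched_truth[cand[j]] <- TRUE
      matched_loc[i] <- TRUE
    }
  }
  c(recall = mean(matched_truth), precision = mean(matched_loc))
}
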