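# Distance-based segmentation of localization clusters:
# bin -> density map -> constant-threshold mask -> connected components ->
# local-maxima seeding -> iterative nearest-centroid refinement.

#' Bin localizations into a discrete localization image
#'
#' Pixel value = number of localizations whose coordinates fall into that
#' half-open `bin_nm` x `bin_nm` bin; the image sum always equals the table
#' row count. The grid covers `[0, roi_width) x [0, roi_height)` from the
#' table metadata (data bounding box when absent).
#'
#' @param table a [localization_table()].
#' @param bin_nm bin (analysis pixel) size in nm; default 20.
#' @return an object of class `localization_image`: list with `counts`
#'   (matrix, rows index y), `bin_nm`, and `origin_nm` (always c(0, 0)).
#' @export
bin_localizations <- function(table, bin_nm = 20) {
  check_scalar(bin_nm, "bin_nm", 0, strict = TRUE)
  ext <- table_extent(table)
  nx <- max(1L, ceiling((ext[[1]] + 1e-9) / bin_nm))
  ny <- max(1L, ceiling((ext[[2]] + 1e-9) / bin_nm))
  counts <- matrix(0, ny, nx)
  if (nrow(table) > 0) {
    cx <- pmin(pmax(floor(table$x_nm / bin_nm), 0), nx - 1L)
    cy <- pmin(pmax(floor(table$y_nm / bin_nm), 0), ny - 1L)
    counts <- matrix(tabulate(cy * nx + cx + 1L, nbins = nx * ny),
                     nrow = ny, ncol = nx, byrow = TRUE)
  }
  structure(list(counts = counts, bin_nm = bin_nm, origin_nm = c(0, 0)),
            class = "localization_image")
}

#' Local density map by square-kernel filtering
#'
#' Unnormalized moving-window sum: the value at bin b is the total number of
#' localizations in the `kernel_px` x `kernel_px` window centered on b
#' (zero-padded at the borders), i.e. local counts per window, the unit the
#' constant threshold is expressed in.
#'
#' @param image a `localization_image` from [bin_localizations()].
#' @param kernel_px odd kernel side in bins; default 7.
#' @return an object of class `density_map`: list with `density` (matrix),
#'   `kernel_px`, `bin_nm`.
#' @export
density_map <- function(image, kernel_px = 7) {
  check_scalar(kernel_px, "kernel_px", 1)
  if (kernel_px %% 2 == 0) stop_invalid("kernel_px must be odd")
  m <- image$counts
  half <- (kernel_px - 1L) / 2L
  # separable box sum via padded cumulative sums
  box1d <- function(mat, k, margin) {
    if (k == 0) return(mat)
    if (margin == 1L) mat <- t(mat)
    n <- ncol(mat)
    pad <- cbind(matrix(0, nrow(mat), k), mat, matrix(0, nrow(mat), k))
    cs <- t(apply(pad, 1, cumsum))
    out <- cs[, (1 + 2 * k):(n + 2 * k), drop = FALSE] -
      cbind(0, cs[, seq_len(n - 1), drop = FALSE])
    if (margin == 1L) t(out) else out
  }
  dens <- box1d(box1d(m, half, 2L), half, 1L)
  structure(list(density = dens, kernel_px = as.integer(kernel_px),
                 bin_nm = image$bin_nm),
            class = "density_map")
}

#' Binarize a density map at a constant threshold
#'
#' Pixels are 1 exactly where the local density is strictly larger than the
#' threshold. The mask only locates candidate regions; all subsequent
#' analysis runs on the raw localization coordinates.
#'
#' @param map a `density_map`.
#' @param density_threshold threshold in localizations per kernel window
#'   (>= 0).
#' @return an object of class `binary_mask`: list with `mask` (logical
#'   matrix), `threshold`, `bin_nm`.
#' @export
binarize_density <- function(map, density_threshold) {
  check_scalar(density_threshold, "density_threshold", 0)
  structure(list(mask = map$density > density_threshold,
                 threshold = density_threshold, bin_nm = map$bin_nm),
            class = "binary_mask")
}

#' Label connected components of a binary mask
#'
#' Breadth-first flood fill with 4- or 8-pixel adjacency.
#'
#' @param mask a `binary_mask` or a logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix of region labels (0 = background), with attribute
#'   `n_regions`.
#' @export
connected_components <- function(mask, connectivity = 8) {
  if (inherits(mask, "binary_mask")) mask <- mask$mask
  if (!connectivity %in% c(4, 8)) stop_invalid("connectivity must be 4 or 8")
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  offs <- if (connectivity == 4) {
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  } else {
    cbind(dr = rep(-1:1, times = 3), dc = rep(-1:1, each = 3))[-5, ]
  }
  todo <- which(mask)
  lab <- 0L
  for (start in todo) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    frontier <- start
    labels[start] <- lab
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      c <- (frontier - 1L) %/% nr + 1L
      nbr_r <- rep(r, each = nrow(offs)) + offs[, "dr"]
      nbr_c <- rep(c, each = nrow(offs)) + offs[, "dc"]
      ok <- nbr_r >= 1L & nbr_r <= nr & nbr_c >= 1L & nbr_c <= nc
      nbr <- unique((nbr_c[ok] - 1L) * nr + nbr_r[ok])
      nbr <- nbr[mask[nbr] & labels[nbr] == 0L]
      labels[nbr] <- lab
      frontier <- nbr
    }
  }
  attr(labels, "n_regions") <- lab
  labels
}

#' Seed centroids from density-map local maxima inside a region
#'
#' Strict local maxima of the density map (8-neighborhood, comparing only
#' bins inside the region) are candidate seeds; a flat plateau of equal
#' maximal values contributes a single seed at its centroid. Seeds closer
#' than `scale_factor * bin_nm` are then iteratively merged to their
#' density-weighted mean, so the scale factor sets the minimum seed
#' separation and with it the degree of segmentation.
#'
#' @param map a `density_map`.
#' @param region_pixels 2-column matrix (`row`, `col`) of the region's bins,
#'   1-based.
#' @param scale_factor minimum seed separation in units of `bin_nm`.
#' @return data.frame with `x_nm`, `y_nm` (bin-center coordinates) and
#'   `weight` (summed density); zero rows when the region is empty.
#' @export
seed_centroids <- function(map, region_pixels, scale_factor = 5) {
  empty <- data.frame(x_nm = numeric(0), y_nm = numeric(0), weight = numeric(0))
  if (is.null(region_pixels) || nrow(region_pixels) == 0) return(empty)
  dens <- map$density
  nr <- nrow(dens); nc <- ncol(dens)
  in_region <- matrix(FALSE, nr, nc)
  in_region[cbind(region_pixels[, 1], region_pixels[, 2])] <- TRUE
  vals <- dens[cbind(region_pixels[, 1], region_pixels[, 2])]
  is_max <- rep(TRUE, nrow(region_pixels))
  for (i in seq_len(nrow(region_pixels))) {
    r <- region_pixels[i, 1]; c <- region_pixels[i, 2]
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc || !in_region[rr, cc]) next
      if (dens[rr, cc] > vals[i]) { is_max[i] <- FALSE; break }
    }
    if (!is_max[i]) next
  }
  cand <- region_pixels[is_max, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  cvals <- vals[is_max]
  # group equal-valued adjacent candidates into one plateau seed
  cand_mask <- matrix(FALSE, nr, nc)
  cand_mask[cbind(cand[, 1], cand[, 2])] <- TRUE
  plab <- connected_components(cand_mask, 8)
  seeds <- do.call(rbind, lapply(seq_len(attr(plab, "n_regions")), function(l) {
    px <- which(plab == l, arr.ind = TRUE)
    w <- dens[px]
    data.frame(x_nm = (mean(px[, 2]) - 0.5) * map$bin_nm,
               y_nm = (mean(px[, 1]) - 0.5) * map$bin_nm,
               weight = sum(w))
  }))
  # merge seeds closer than the scale-factor separation (closest pair first)
  min_sep <- scale_factor * map$bin_nm
  repeat {
    if (nrow(seeds) < 2) break
    d <- as.matrix(stats::dist(seeds[, c("x_nm", "y_nm")]))
    diag(d) <- Inf
    if (min(d) >= min_sep) break
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    w <- seeds$weight[c(i, j)]
    seeds$x_nm[i] <- sum(seeds$x_nm[c(i, j)] * w) / sum(w)
    seeds$y_nm[i] <- sum(seeds$y_nm[c(i, j)] * w) / sum(w)
    seeds$weight[i] <- sum(w)
    seeds <- seeds[-j, , drop = FALSE]
  }
  rownames(seeds) <- NULL
  seeds
}

#' Assign localizations to seeds and refine centroids iteratively
#'
#' Lloyd-style iteration on raw coordinates: each localization joins its
#' nearest centroid (ties to the lowest cluster index), centroids move to
#' their members' mean, and the loop stops when the relative change of the
#' total sum of squared localization-to-centroid distances falls below
#' `convergence_tol` (or at `max_iterations`). Clusters left empty are
#' dropped from the result.
#'
#' @param xy 2-column matrix or data.frame of localization coordinates (nm).
#' @param seeds data.frame with `x_nm`, `y_nm` initial centroids (>= 1 row).
#' @param max_iterations iteration cap; default 100.
#' @param convergence_tol relative SSD change for convergence; default 1e-6.
#' @return list with `assignment` (integer per localization), `centroids`
#'   (data.frame `x_nm`, `y_nm`), `ssd` (per-iteration SSD trace),
#'   `iterations`.
#' @export
assign_and_refine <- function(xy, seeds, max_iterations = 100,
                              convergence_tol = 1e-6) {
  if (nrow(seeds) < 1) stop_invalid("at least one seed is required")
  xy <- as.matrix(as.data.frame(xy)[, 1:2])
  cx <- seeds$x_nm; cy <- seeds$y_nm
  n <- nrow(xy); k <- length(cx)
  ssd_trace <- numeric(0)
  ssd_prev <- Inf
  assignment <- integer(n)
  for (it in seq_len(max_iterations)) {
    d2 <- outer(xy[, 1], cx, `-`)^2 + outer(xy[, 2], cy, `-`)^2
    assignment <- max.col(-d2, ties.method = "first")
    ssd <- sum(d2[cbind(seq_len(n), assignment)])
    ssd_trace <- c(ssd_trace, ssd)
    for (j in seq_len(k)) {
      mem <- assignment == j
      if (any(mem)) {
        cx[j] <- mean(xy[mem, 1]); cy[j] <- mean(xy[mem, 2])
      }
    }
    if (is.finite(ssd_prev) &&
        (ssd_prev == 0 || abs(ssd_prev - ssd) / max(ssd_prev, .Machine$double.eps) < convergence_tol)) {
      break
    }
    ssd_prev <- ssd
  }
  keep <- sort(unique(assignment))
  remap <- integer(k); remap[keep] <- seq_along(keep)
  list(assignment = remap[assignment],
       centroids = data.frame(x_nm = cx[keep], y_nm = cy[keep]),
       ssd = ssd_trace, iterations = length(ssd_trace))
}

#' Segment a localization field into clusters
#'
#' Full distance-based segmentation: binning at `config$bin_nm`, square
#' kernel density map, constant-threshold binarization, connected candidate
#' regions, per-region local-maxima seeding and iterative centroid
#' refinement on the raw localizations, then removal of clusters with fewer
#' than `min_molecules` members. Per-cluster area is the convex hull of the
#' member localizations (occupied-bin area for degenerate clusters, or
#' throughout when `area_method = "bins"`), and density is n_loc / area.
#'
#' @param table a drift-corrected [localization_table()].
#' @param config a [cluster_config()].
#' @param reference_area_um2 area (in square micrometers) over which
#'   clusters-per-area is normalized; the default is the area of the
#'   morphological closing of the binary-mask support, a footprint proxy for
#'   the labeled cell region.
#' @return an object of class `cluster_set`: list with `clusters`
#'   (data.frame `cluster_id`, `n_loc`, `area_nm2`, `density_per_nm2`,
#'   `centroid_x_nm`, `centroid_y_nm`), `assignments` (data.frame `loc`,
#'   `cluster_id`; 0 = unassigned), `config`, `reference_area_um2`,
#'   `n_unclustered` (in candidate regions but not in a kept cluster) and
#'   `n_below_threshold` (outside every candidate region).
#' @export
cluster_field <- function(table, config = cluster_config(),
                          reference_area_um2 = NULL) {
  empty_clusters <- data.frame(cluster_id = integer(0), n_loc = integer(0),
                               area_nm2 = numeric(0),
                               density_per_nm2 = numeric(0),
                               centroid_x_nm = numeric(0),
                               centroid_y_nm = numeric(0))
  if (nrow(table) == 0) {
    return(structure(list(clusters = empty_clusters,
                          assignments = data.frame(loc = integer(0),
                                                   cluster_id = integer(0)),
                          config = config,
                          reference_area_um2 = reference_area_um2 %||% 0,
                          n_unclustered = 0L, n_below_threshold = 0L),
                     class = "cluster_set"))
  }
  img <- bin_localizations(table, config$bin_nm)
  dmap <- density_map(img, config$kernel_px)
  mask <- binarize_density(dmap, config$density_threshold)
  labels <- connected_components(mask, config$connectivity)
  if (is.null(reference_area_um2)) {
    reference_area_um2 <- mask_footprint_um2(mask$mask, config$bin_nm)
  }
  nx <- ncol(img$counts); ny <- nrow(img$counts)
  bx <- pmin(pmax(floor(table$x_nm / config$bin_nm), 0), nx - 1L) + 1L
  by <- pmin(pmax(floor(table$y_nm / config$bin_nm), 0), ny - 1L) + 1L
  loc_region <- labels[cbind(by, bx)]
  assignment <- integer(nrow(table))
  clusters <- list()
  next_id <- 0L
  for (reg in seq_len(attr(labels, "n_regions"))) {
    loc_idx <- which(loc_region == reg)
    if (length(loc_idx) == 0) next
    region_pixels <- which(labels == reg, arr.ind = TRUE)
    seeds <- seed_centroids(dmap, region_pixels, config$scale_factor)
    if (nrow(seeds) == 0) next
    fit <- assign_and_refine(table[loc_idx, c("x_nm", "y_nm")], seeds,
                             config$max_iterations, config$convergence_tol)
    for (j in seq_len(nrow(fit$centroids))) {
      mem <- loc_idx[fit$assignment == j]
      if (length(mem) < config$min_molecules) next
      next_id <- next_id + 1L
      assignment[mem] <- next_id
      xy <- cbind(table$x_nm[mem], table$y_nm[mem])
      area <- cluster_area(xy, config)
      clusters[[next_id]] <- data.frame(
        cluster_id = next_id, n_loc = length(mem), area_nm2 = area,
        density_per_nm2 = if (is.finite(area) && area > 0) length(mem) / area else NA_real_,
        centroid_x_nm = mean(xy[, 1]), centroid_y_nm = mean(xy[, 2]))
    }
  }
  cl <- if (length(clusters)) do.call(rbind, clusters) else empty_clusters
  structure(list(
    clusters = cl,
    assignments = data.frame(loc = seq_len(nrow(table)),
                             cluster_id = assignment),
    config = config,
    reference_area_um2 = reference_area_um2,
    n_unclustered = sum(assignment == 0L & loc_region > 0L),
    n_below_threshold = sum(loc_region == 0L)
  ), class = "cluster_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# convex-hull area with occupied-bin fallback for degenerate clusters
cluster_area <- function(xy, config) {
  bin_area <- function() {
    bx <- floor(xy[, 1] / config$bin_nm)
    by <- floor(xy[, 2] / config$bin_nm)
    nrow(unique(cbind(bx, by))) * config$bin_nm^2
  }
  if (config$area_method == "bins") return(bin_area())
  a <- hull_area(xy)
  if (is.na(a)) bin_area() else a
}

# area of the morphological closing (dilate then erode, 3x3 structuring
# element) of the mask support, in square micrometers
mask_footprint_um2 <- function(mask, bin_nm) {
  if (!any(mask)) return(0)
  shift_or <- function(m, combine) {
    out <- m
    nr <- nrow(m); nc <- ncol(m)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      sh <- matrix(if (identical(combine, `|`)) FALSE else TRUE, nr, nc)
      rs <- max(1, 1 + dr):min(nr, nr + dr)
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      sh[rs, cs] <- m[rs - dr, cs - dc]
      out <- combine(out, sh)
    }
    out
  }
  closed <- shift_or(shift_or(mask, `|`), `&`)
  sum(closed) * (bin_nm / 1000)^2
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", nrow(x$clusters), "clusters;",
      x$n_unclustered, "unclustered;", x$n_below_threshold,
      "below threshold; reference area",
      sprintf("%.2f", x$reference_area_um2), "um^2\n")
  invisible(x)
}
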