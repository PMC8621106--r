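# distance-based cluster segmentation: binning, density map, mask,
# components, seeding, refinement, full field segmentation

test_that("binning uses half-open 20 nm bins and conserves counts", {
  tab <- make_table(c(10, 30, 31, 33), c(10, 30, 35, 30), roi = c(100, 100))
  img <- bin_localizations(tab, 20)
  expect_equal(img$counts[1, 1], 1)  # (10,10) -> bin (0,0)
  expect_equal(img$counts[2, 2], 3)  # three localizations in bin (1,1)
  expect_equal(sum(img$counts), nrow(tab))
  # empty table: all-zero image
  img0 <- bin_localizations(make_table(numeric(0), numeric(0), roi = c(100, 100)), 20)
  expect_true(all(img0$counts == 0))
})

test_that("density map is an unnormalized 7x7 moving sum with zero padding", {
  tab <- make_table(90, 90, roi = c(400, 400))  # bin (4,4) of a 20x20 grid
  img <- bin_localizations(tab, 20)
  dm <- density_map(img, 7)
  expect_equal(sum(dm$density == 1), 49)
  expect_equal(dm$density[5, 5], 1)
  expect_equal(dm$density[2, 2], 1)
  expect_equal(dm$density[1, 1], 0)  # 3 bins away: outside the kernel
  # uniform image: interior value is 49, total mass is 49x minus borders
  imgu <- img; imgu$counts[] <- 1
  dmu <- density_map(imgu, 7)
  expect_equal(dmu$density[10, 10], 49)
  interior <- dmu$density[4:17, 4:17]
  expect_true(all(interior == 49))
})

test_that("binarization is strict and mask counts match construction", {
  tab <- make_table(c(50, 52, 55, 250), c(50, 51, 52, 250), roi = c(400, 400))
  dm <- density_map(bin_localizations(tab, 20), 7)
  expect_true(all(!binarize_density(dm, max(dm$density))$mask))
  m0 <- binarize_density(dm, 0)
  expect_equal(m0$mask, dm$density > 0)
  k <- sum(dm$density > 2)
  expect_equal(sum(binarize_density(dm, 2)$mask), k)
})

test_that("connected components honor 4- vs 8-connectivity", {
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE
  lab8 <- connected_components(m, 8)
  lab4 <- connected_components(m, 4)
  expect_equal(attr(lab8, "n_regions"), 1L)
  expect_equal(attr(lab4, "n_regions"), 2L)
  empty <- connected_components(matrix(FALSE, 4, 4), 8)
  expect_equal(attr(empty, "n_regions"), 0L)
})

test_that("component labeling matches a brute-force flood fill", {
  set.seed(61)
  for (i in 1:6) {
    m <- matrix(runif(20 * 20) < 0.35, 20, 20)
    for (conn in c(4, 8)) {
      got <- connected_components(m, conn)
      want <- flood_fill_labels(m, conn)
      expect_true(same_partition(got[m], want[m]))
      expect_equal(attr(got, "n_regions"), max(want))
    }
  }
})

test_that("component labeling agrees with EBImage for 4-connectivity", {
  set.seed(67)
  m <- matrix(runif(30 * 30) < 0.4, 30, 30)
  got <- connected_components(m, 4)
  want <- EBImage::bwlabel(m * 1)
  expect_true(same_partition(got[m], want[m]))
})

test_that("seeding finds blob maxima and merges by the scale factor", {
  # single peaked blob: one seed at the peak bin center
  tab <- make_table(rep(110, 5), rep(110, 5), roi = c(600, 600))
  dm <- density_map(bin_localizations(tab, 20), 7)
  labels <- connected_components(dm$density > 0, 8)
  reg <- which(labels == 1, arr.ind = TRUE)
  seeds <- seed_centroids(dm, reg, scale_factor = 2)
  expect_equal(nrow(seeds), 1)
  expect_equal(c(seeds$x_nm, seeds$y_nm), c(110, 110))
  # two unequal blobs 7 bins apart in one region (equal point masses would
  # flatten into a single density plateau): 2 seeds at small scale, 1 merged
  tab2 <- make_table(c(rep(110, 8), rep(250, 6)),
                     c(rep(110, 8), rep(110, 6)), roi = c(600, 600))
  dm2 <- density_map(bin_localizations(tab2, 20), 7)
  lab2 <- connected_components(dm2$density > 0, 8)
  reg2 <- which(lab2 == 1, arr.ind = TRUE)
  expect_equal(attr(lab2, "n_regions"), 1L)
  expect_equal(nrow(seed_centroids(dm2, reg2, scale_factor = 2)), 2)
  expect_equal(nrow(seed_centroids(dm2, reg2, scale_factor = 8)), 1)
  # empty region: no seeds
  expect_equal(nrow(seed_centroids(dm2, reg2[0, , drop = FALSE], 2)), 0)
})

test_that("refinement reduces to the mean for one seed and never raises SSD", {
  set.seed(71)
  xy <- cbind(rnorm(40, 100, 10), rnorm(40, 200, 10))
  one <- assign_and_refine(xy, data.frame(x_nm = 0, y_nm = 0))
  expect_equal(unique(one$assignment), 1L)
  expect_equal(c(one$centroids$x_nm, one$centroids$y_nm),
               c(mean(xy[, 1]), mean(xy[, 2])))
  # SSD monotonicity on a harder instance
  xy2 <- rbind(cbind(rnorm(60, 0, 30), rnorm(60, 0, 30)),
               cbind(rnorm(60, 120, 30), rnorm(60, 40, 30)))
  fit <- assign_and_refine(xy2, data.frame(x_nm = c(-20, 30), y_nm = c(0, 10)))
  expect_true(all(diff(fit$ssd) <= 1e-9))
})

test_that("two-blob refinement matches the exhaustive 2-means optimum", {
  set.seed(73)
  for (rep in 1:4) {
    xy <- rbind(cbind(rnorm(7, 0, 20), rnorm(7, 0, 20)),
                cbind(rnorm(7, 500, 20), rnorm(7, 0, 20)))
    oracle <- exhaustive_two_means(xy)
    seeds <- data.frame(x_nm = c(100, 400), y_nm = c(0, 0))
    fit <- assign_and_refine(xy, seeds)
    expect_true(same_partition(fit$assignment, as.integer(oracle$partition)))
  }
})

test_that("cluster_field recovers well-separated synthetic clusters", {
  sc <- one_shot_scene(79, roi_nm = 4000, cluster_rate = 4, mol_mean = 50,
                       bg_rate = 5, min_sep_nm = 350)
  tab <- ground_truth_table(sc, precision_nm = 10, seed = 80)
  cs <- cluster_field(tab, cluster_config())
  n_true <- nrow(sc$cluster_centers)
  expect_equal(nrow(cs$clusters), n_true)
  true_mean <- mean(table(sc$molecules$cluster[sc$molecules$cluster > 0]))
  expect_lt(abs(mean(cs$clusters$n_loc) - true_mean) / true_mean, 0.1)
  # disjointness and conservation
  expect_equal(sum(cs$clusters$n_loc) + cs$n_unclustered + cs$n_below_threshold,
               nrow(tab))
  expect_equal(sum(cs$assignments$cluster_id > 0), sum(cs$clusters$n_loc))
})

test_that("clusters below the minimum-molecule threshold are discarded", {
  # one big cluster and one pair of localizations
  tab <- make_table(c(rnorm(30, 500, 10), 1500, 1505),
                    c(rnorm(30, 500, 10), 1500, 1505), roi = c(2000, 2000))
  cfg <- cluster_config(density_threshold = 1, min_molecules = 3)
  cs <- cluster_field(tab, cfg)
  expect_equal(nrow(cs$clusters), 1)
  expect_equal(cs$clusters$n_loc, 30)
  expect_equal(cs$n_unclustered, 2)
})

test_that("segmentation degree responds monotonically to its parameters", {
  sc <- one_shot_scene(83, roi_nm = 3000, cluster_rate = 8, mol_mean = 30,
                       min_sep_nm = 120)
  tab <- ground_truth_table(sc, precision_nm = 10, seed = 84)
  n_at <- function(scale) {
    nrow(cluster_field(tab, cluster_config(scale_factor = scale))$clusters)
  }
  expect_gte(n_at(3), n_at(6))
  expect_gte(n_at(6), n_at(12))
  # raising the density threshold shrinks the candidate mask (nesting):
  # every supra-threshold bin at a high threshold is supra-threshold at a
  # low one, so no new candidate area ever appears
  img <- bin_localizations(tab, 20)
  dm <- density_map(img, 7)
  m2 <- binarize_density(dm, 2)$mask
  m8 <- binarize_density(dm, 8)$mask
  m20 <- binarize_density(dm, 20)$mask
  expect_true(all(m2[m8]))
  expect_true(all(m8[m20]))
  # raising min_molecules never increases cluster count
  n_mol <- function(mm) {
    nrow(cluster_field(tab, cluster_config(min_molecules = mm))$clusters)
  }
  expect_gte(n_mol(3), n_mol(10))
  expect_gte(n_mol(10), n_mol(25))
})

test_that("cluster area falls back to occupied bins for degenerate clusters", {
  # collinear points: hull degenerate, bins area = 3 bins x 400 nm^2
  tab <- make_table(c(110, 130, 150), rep(110, 3), roi = c(400, 400))
  cfg <- cluster_config(density_threshold = 0, min_molecules = 3)
  cs <- cluster_field(tab, cfg)
  expect_equal(cs$clusters$area_nm2, 3 * 400)
  # bins method on request
  tabs <- make_table(rnorm(50, 200, 15), rnorm(50, 200, 15), roi = c(400, 400))
  a_bins <- cluster_field(tabs, cluster_config(area_method = "bins",
                                               density_threshold = 1))$clusters$area_nm2
  bx <- floor(tabs$x_nm / 20); by <- floor(tabs$y_nm / 20)
  expect_equal(a_bins, nrow(unique(cbind(bx, by))) * 400)
})

test_that("empty tables produce an empty cluster set", {
  cs <- cluster_field(make_table(numeric(0), numeric(0), roi = c(1000, 1000)))
  expect_equal(nrow(cs$clusters), 0)
  expect_equal(cs$n_below_threshold, 0L)
})
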