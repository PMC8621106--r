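# synthetic scene generator, blinking kinetics, drift, frame rendering

test_that("zero-rate scenes are empty and invalid parameters error", {
  p <- scene_params(cluster_rate = 0, background_molecule_rate = 0)
  sc <- generate_scene(p, seed = 1)
  expect_equal(nrow(sc$molecules), 0)
  expect_equal(nrow(sc$cluster_centers), 0)
  expect_error(scene_params(roi_width_nm = 0), class = "smlmpipe_invalid_parameter")
  expect_error(scene_params(cluster_rate = -1), class = "smlmpipe_invalid_parameter")
})

test_that("cluster count follows the Poisson law of the configured rate", {
  # 10 x 10 um^2 at 10 clusters/um^2: expect 1000, check within 4 sigma
  p <- scene_params(roi_width_nm = 10000, roi_height_nm = 10000,
                    cluster_rate = 10, molecules_per_cluster_mean = 2,
                    cluster_sigma_nm = 10, background_molecule_rate = 0)
  sc <- generate_scene(p, seed = 42)
  expect_lt(abs(nrow(sc$cluster_centers) - 1000), 4 * sqrt(1000))
  # molecule counts: truncated Poisson >= 1, mean close to nominal
  counts <- table(sc$molecules$cluster)
  expect_true(all(counts >= 1))
})

test_that("per-cluster molecule counts converge to the configured mean", {
  p <- scene_params(roi_width_nm = 8000, roi_height_nm = 8000,
                    cluster_rate = 8, molecules_per_cluster_mean = 20,
                    background_molecule_rate = 0)
  sc <- generate_scene(p, seed = 7)
  counts <- as.integer(table(sc$molecules$cluster))
  # 4-sigma band around the truncated-Poisson mean (~ 20 at lambda = 20)
  expect_lt(abs(mean(counts) - 20), 4 * sqrt(20 / length(counts)))
})

test_that("origami scenes carry exactly sites x structures molecules", {
  p <- scene_params(scene_type = "origami_grid", origami_sites = 86,
                    origami_structures = 4)
  sc <- generate_scene(p, seed = 3)
  expect_equal(nrow(sc$molecules), 4 * 86)
  expect_equal(as.integer(table(sc$molecules$cluster)), rep(86L, 4))
})

test_that("scene generation is deterministic under a fixed seed", {
  p <- scene_params(seed = 99, roi_width_nm = 3000, roi_height_nm = 3000)
  expect_identical(generate_scene(p), generate_scene(p))
})

test_that("blinking produces no events without activation paths", {
  sc <- generate_scene(scene_params(roi_width_nm = 2000, roi_height_nm = 2000,
                                    cluster_rate = 5,
                                    molecules_per_cluster_mean = 5), seed = 5)
  cam <- camera_model(frame_count = 100)
  bl <- blink_model(k_on = 0, initial_on_fraction = 0)
  sc <- simulate_blinking(sc, bl, cam, seed = 6)
  expect_equal(nrow(sc$events), 0)
})

test_that("ON dwell times follow the geometric law of k_off", {
  p <- scene_params(roi_width_nm = 12000, roi_height_nm = 12000,
                    cluster_rate = 0, background_molecule_rate = 30)
  sc <- generate_scene(p, seed = 11)
  cam <- camera_model(frame_count = 400)
  k_off <- 0.2
  bl <- blink_model(k_on = 0.01, k_off = k_off, initial_on_fraction = 0.3,
                    activation_boost = 1)
  sc <- simulate_blinking(sc, bl, cam, seed = 12)
  # extract ON-run lengths per molecule
  ev <- sc$events[order(sc$events$molecule, sc$events$frame), ]
  new_run <- c(TRUE, diff(ev$frame) != 1 | diff(ev$molecule) != 0)
  runs <- rle(cumsum(new_run))$lengths
  # drop runs touching the acquisition ends (censored dwells)
  expect_gt(length(runs), 1e4)
  expect_lt(abs(mean(runs) - 1 / k_off), 4 * sqrt((1 - k_off) / k_off^2 / length(runs)) + 0.1)
  ks <- suppressWarnings(stats::ks.test(runs, stats::rgeom(1e5, k_off) + 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("blinking event lists are reproducible under a fixed seed", {
  sc <- generate_scene(scene_params(roi_width_nm = 2000, roi_height_nm = 2000,
                                    cluster_rate = 10), seed = 8)
  cam <- camera_model(frame_count = 50)
  bl <- blink_model()
  a <- simulate_blinking(sc, bl, cam, seed = 13)
  b <- simulate_blinking(sc, bl, cam, seed = 13)
  expect_identical(a$events, b$events)
})

test_that("activation frames boost the switch-on probability", {
  p <- scene_params(roi_width_nm = 10000, roi_height_nm = 10000,
                    cluster_rate = 0, background_molecule_rate = 20)
  sc <- generate_scene(p, seed = 20)
  cam <- camera_model(frame_count = 800)
  bl <- blink_model(k_on = 0.002, k_off = 1, initial_on_fraction = 0,
                    activation_period = 4, activation_boost = 50)
  sc <- simulate_blinking(sc, bl, cam, seed = 21)
  # with k_off = 1 every event reflects the switch-on of the previous frame;
  # frames just after activation frames should dominate
  post_act <- sum(sc$events$frame %% 4 == 1)
  other <- sum(sc$events$frame %% 4 != 1)
  expect_gt(post_act, 3 * other)
})

test_that("make_drift covers the contract cases", {
  z <- make_drift("linear", 0, 10)
  expect_equal(z$dx_nm, rep(0, 10))
  lin <- make_drift("linear", 2, 10)
  expect_equal(c(lin$dx_nm[10], lin$dy_nm[10]), c(18, 0))
  expect_equal(c(lin$dx_nm[1], lin$dy_nm[1]), c(0, 0))
  rw1 <- make_drift("random_walk", 1, 50, seed = 4)
  rw2 <- make_drift("random_walk", 1, 50, seed = 4)
  expect_identical(rw1, rw2)
  expect_equal(c(rw1$dx_nm[1], rw1$dy_nm[1]), c(0, 0))
  pw <- make_drift("piecewise", 0.5, 100, seed = 5)
  expect_equal(nrow(pw), 100)
  expect_error(make_drift("wobble", 1, 10), class = "smlmpipe_invalid_parameter")
})

test_that("noiseless rendering conserves photons and respects baseline", {
  p <- scene_params(roi_width_nm = 3200, roi_height_nm = 3200,
                    cluster_rate = 0, background_molecule_rate = 0)
  sc <- generate_scene(p, seed = 1)
  cam <- camera_model(frame_count = 2, em_gain = 1, baseline = 7, read_noise = 0)
  # no events: all frames at baseline
  sc$events <- data.frame(molecule = integer(0), frame = integer(0),
                          photons = integer(0))
  st <- render_frames(sc, cam, noiseless = TRUE)
  expect_true(all(st$frames == 7))
  # one event well inside the ROI: photon mass conserved to < 0.1%
  sc$molecules <- data.frame(x_nm = 1600, y_nm = 1600, cluster = 1L)
  sc$events <- data.frame(molecule = 1L, frame = 0L, photons = 1000)
  cam0 <- camera_model(frame_count = 1, em_gain = 1, baseline = 0, read_noise = 0)
  st <- render_frames(sc, cam0, noiseless = TRUE)
  expect_lt(abs(sum(st$frames) - 1000) / 1000, 0.001)
})

test_that("rendered centroid tracks an injected linear drift", {
  p <- scene_params(roi_width_nm = 4800, roi_height_nm = 4800,
                    cluster_rate = 0, background_molecule_rate = 0)
  sc <- generate_scene(p, seed = 1)
  sc$molecules <- data.frame(x_nm = 2000, y_nm = 2400, cluster = 1L)
  sc$events <- data.frame(molecule = c(1L, 1L), frame = c(0L, 100L),
                          photons = c(2000, 2000))
  cam <- camera_model(frame_count = 101, em_gain = 1, baseline = 0, read_noise = 0)
  dr <- make_drift("linear", 1, 101)
  st <- render_frames(sc, cam, drift = dr, noiseless = TRUE)
  centroid_x <- function(m) {
    px <- cam$pixel_size_nm
    sum(m * matrix((seq_len(ncol(m)) - 0.5) * px, nrow(m), ncol(m), byrow = TRUE)) / sum(m)
  }
  shift <- centroid_x(st$frames[, , 101]) - centroid_x(st$frames[, , 1])
  expect_lt(abs(shift - 100), 1)
})

test_that("events rendered outside the ROI are clipped with a warning", {
  p <- scene_params(roi_width_nm = 800, roi_height_nm = 800,
                    cluster_rate = 0, background_molecule_rate = 0)
  sc <- generate_scene(p, seed = 1)
  sc$molecules <- data.frame(x_nm = c(400, 2000), y_nm = c(400, 400),
                             cluster = c(1L, 2L))
  sc$events <- data.frame(molecule = c(1L, 2L), frame = c(0L, 0L),
                          photons = c(500, 500))
  cam <- camera_model(frame_count = 1, em_gain = 1, baseline = 0, read_noise = 0)
  expect_warning(st <- render_frames(sc, cam, noiseless = TRUE), "clipped")
  expect_equal(st$n_clipped, 1L)
})

test_that("ground-truth tables are deterministic and drift-aware", {
  sc <- one_shot_scene(31, roi_nm = 2000, cluster_rate = 3, mol_mean = 10)
  t1 <- ground_truth_table(sc, precision_nm = 5, seed = 2)
  t2 <- ground_truth_table(sc, precision_nm = 5, seed = 2)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  dr <- make_drift("linear", 1, 4)
  t3 <- ground_truth_table(sc, precision_nm = 5, drift = dr, seed = 2)
  expect_equal(t3$x_nm - t1$x_nm, dr$dx_nm[t1$frame + 1L])
})
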