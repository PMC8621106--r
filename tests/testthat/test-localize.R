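# spot detection and integrated-Gaussian fitting

render_single_spot <- function(x_px, y_px, photons, camera, roi_px = 20,
                               noiseless = TRUE, seed = NULL) {
  px <- camera$pixel_size_nm
  p <- scene_params(roi_width_nm = roi_px * px, roi_height_nm = roi_px * px,
                    cluster_rate = 0, background_molecule_rate = 0)
  sc <- generate_scene(p, seed = 1)
  sc$molecules <- data.frame(x_nm = x_px * px, y_nm = y_px * px, cluster = 1L)
  sc$events <- data.frame(molecule = 1L, frame = 0L, photons = photons)
  render_frames(sc, camera, noiseless = noiseless, seed = seed)
}

test_that("an all-baseline frame yields no candidates", {
  frame <- matrix(100, 30, 30)
  expect_equal(nrow(detect_spots(frame, 50)), 0)
})

test_that("detection finds rendered spots at their peak pixels", {
  cam <- camera_model(frame_count = 1, em_gain = 1, baseline = 10, read_noise = 0)
  st <- render_single_spot(5.5, 7.5, 1000, cam)
  cand <- detect_spots(st$frames[, , 1], 20)
  expect_equal(nrow(cand), 1)
  expect_equal(c(cand$row, cand$col), c(8, 6))  # pixel [5,6) x [7,8) is (row 8, col 6)
  # two spots 20 px apart are both kept
  st2 <- render_single_spot(5.5, 7.5, 1000, camera_model(frame_count = 1,
                                                         em_gain = 1, baseline = 10,
                                                         read_noise = 0), roi_px = 40)
  fr <- st2$frames[, , 1]
  fr2 <- matrix(10, 40, 40)
  fr2 <- fr2 + (fr - 10) + rbind(matrix(0, 20, 40), (fr - 10)[1:20, ])
  cand2 <- detect_spots(fr2, 20)
  expect_equal(nrow(cand2), 2)
})

test_that("close candidates are merged keeping the brighter", {
  fr <- matrix(0, 20, 20)
  fr[10, 10] <- 100
  fr[10, 12] <- 80
  fr[3, 3] <- 90
  cand <- detect_spots(fr, 10, min_separation_px = 5)
  expect_equal(nrow(cand), 2)
  expect_true(any(cand$row == 10 & cand$col == 10))
  expect_false(any(cand$col == 12))
})

test_that("noiseless fits recover center and photons almost exactly", {
  cam <- camera_model(frame_count = 1, em_gain = 1, baseline = 0, read_noise = 0)
  st <- render_single_spot(5.30, 7.80, 1000, cam)
  cand <- detect_spots(st$frames[, , 1], 10)
  fit <- fit_gaussian_spot(st$frames[, , 1], cand[1, ], cam)
  expect_true(fit$fit_ok)
  expect_lt(abs(fit$x_nm / cam$pixel_size_nm - 5.30), 0.01)
  expect_lt(abs(fit$y_nm / cam$pixel_size_nm - 7.80), 0.01)
  expect_lt(abs(fit$photons - 1000) / 1000, 0.01)
  # symmetric spot on a pixel center fits at that pixel center
  st2 <- render_single_spot(10.5, 10.5, 800, cam)
  cand2 <- detect_spots(st2$frames[, , 1], 10)
  fit2 <- fit_gaussian_spot(st2$frames[, , 1], cand2[1, ], cam)
  expect_lt(abs(fit2$x_nm / cam$pixel_size_nm - 10.5), 1e-6)
  expect_lt(abs(fit2$y_nm / cam$pixel_size_nm - 10.5), 1e-6)
})

test_that("degenerate fit input returns fit_ok = FALSE, never an error", {
  cam <- camera_model(frame_count = 1)
  flat <- matrix(cam$baseline, 20, 20)
  fit <- fit_gaussian_spot(flat, data.frame(row = 10, col = 10), cam)
  expect_false(fit$fit_ok)
})

test_that("localization precision scales like sigma over sqrt(N)", {
  # 120 Poisson-noise spots at two photon levels: SD ratio ~ sqrt(N2/N1)
  cam <- camera_model(frame_count = 1, em_gain = 1, baseline = 0, read_noise = 0)
  errs <- function(photons, n, seed0) {
    e <- vapply(seq_len(n), function(i) {
      st <- render_single_spot(9.3, 9.7, photons, cam, noiseless = FALSE,
                               seed = seed0 + i)
      cand <- detect_spots(st$frames[, , 1], photons / 50)
      if (nrow(cand) == 0) return(NA_real_)  # rare tied peak pixels
      fit <- fit_gaussian_spot(st$frames[, , 1], cand[1, ], cam)
      if (!fit$fit_ok) return(NA_real_)
      fit$x_nm - 9.3 * cam$pixel_size_nm
    }, 0)
    e[!is.na(e)]
  }
  sd_lo <- sd(errs(500, 120, 100))
  sd_hi <- sd(errs(2000, 120, 900))
  expect_lt(abs(sd_lo / sd_hi - 2), 0.8)
})

test_that("localize_stack handles empty stacks and is deterministic", {
  cam <- camera_model(frame_count = 1, em_gain = 1, baseline = 0, read_noise = 0)
  empty <- structure(list(frames = array(0, c(20, 20, 2)), camera = cam,
                          n_clipped = 0L), class = "frame_stack")
  tab <- localize_stack(empty, threshold_counts = 50)
  expect_equal(nrow(tab), 0)
  st <- render_single_spot(5.5, 7.5, 1000, cam, noiseless = FALSE, seed = 3)
  t1 <- localize_stack(st, threshold_counts = 100)
  t2 <- localize_stack(st, threshold_counts = 100)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("sparse acquisitions are localized with high recall and precision", {
  # isolated emitters >= 800 nm apart: the sparse regime the method assumes
  p <- scene_params(roi_width_nm = 4000, roi_height_nm = 4000,
                    cluster_rate = 2, molecules_per_cluster_mean = 1,
                    cluster_sigma_nm = 0, background_molecule_rate = 0,
                    min_center_sep_nm = 800)
  sc <- generate_scene(p, seed = 17)
  # keep molecules away from the border so every PSF is fully imaged
  keep <- sc$molecules$x_nm > 500 & sc$molecules$x_nm < 3500 &
    sc$molecules$y_nm > 500 & sc$molecules$y_nm < 3500
  sc$molecules <- sc$molecules[keep, , drop = FALSE]
  cam <- camera_model(frame_count = 150)
  bl <- blink_model(k_on = 0.005, k_off = 0.5, initial_on_fraction = 0.2,
                    activation_boost = 1)
  sc <- simulate_blinking(sc, bl, cam, seed = 18)
  st <- render_frames(sc, cam, seed = 19)
  tab <- localize_stack(st, threshold_counts = 400)
  m <- match_events(tab, sc, tol_nm = 50)
  expect_gte(m["recall"], 0.9)
  expect_gte(m["precision"], 0.9)
})

test_that("no two accepted localizations in a frame are closer than the merge radius", {
  sc <- one_shot_scene(23, roi_nm = 3000, cluster_rate = 2, mol_mean = 3,
                       sigma_nm = 200, bg_rate = 3)
  cam <- camera_model(frame_count = 4)
  # wide clusters straddle the ROI edge; clipping there is expected
  st <- suppressWarnings(render_frames(sc, cam, seed = 24))
  min_sep <- 5
  tab <- localize_stack(st, threshold_counts = 400, min_separation_px = min_sep)
  px <- cam$pixel_size_nm
  for (f in unique(tab$frame)) {
    sub <- tab[tab$frame == f, ]
    if (nrow(sub) < 2) next
    d <- as.matrix(dist(cbind(sub$x_nm, sub$y_nm))) / px
    diag(d) <- Inf
    expect_gte(min(d), min_sep - 2)  # fitted centers may move < 2 px off the peaks
  }
})
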