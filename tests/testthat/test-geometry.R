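profile_from <- function(intensities, row = 0) {
  structure(list(station_row = as.integer(row),
                 distances_px = as.numeric(seq_along(intensities) - 1),
                 intensities = as.numeric(intensities)),
            class = "distance_intensity_profile")
}

test_that("max-opacification image is the post-baseline enhancement maximum", {
  const <- seq_from_means(rep(4, 6), rows = 8, cols = 8)
  expect_equal(max_opacification_image(const, n_pre = 2),
               matrix(0, 8, 8))
  fr <- array(0, c(4, 8, 8))
  fr[3, 5, 5] <- 9
  seq <- image_sequence(fr, 0.25, 0.03, "DSA")
  img <- max_opacification_image(seq, n_pre = 2)
  expect_equal(img[5, 5], 9)
  expect_equal(sum(img != 0), 1)
  expect_error(max_opacification_image(seq, n_pre = 4), "n_pre")
})

test_that("edge detection interpolates the threshold crossing sub-pixel", {
  p <- profile_from(c(0, 0, 100, 100, 100, 0, 0))
  e <- detect_edges(p, threshold_frac = 0.12)
  expect_equal(unname(e), c(1.12, 4.88), tolerance = 1e-12)
  # symmetric profile: midpoint at the centre of symmetry
  ps <- profile_from(c(0, 10, 40, 90, 40, 10, 0))
  es <- detect_edges(ps, threshold_frac = 0.12)
  expect_equal(mean(es), 3)
  expect_error(detect_edges(profile_from(rep(0, 5))), "no above-threshold")
  expect_error(detect_edges(p, threshold_frac = 1.2), "threshold_frac")
})

test_that("edge positions are invariant to positive rescaling", {
  set.seed(8)
  y <- pmax(0, 30 * exp(-((0:40) - 17)^2 / 40) + rnorm(41, 0, 0.5))
  e1 <- detect_edges(profile_from(y), 0.12)
  e2 <- detect_edges(profile_from(y * 57.3), 0.12)
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("segment selection prefers the previous centerline, else width", {
  two <- profile_from(c(0, 50, 50, 0, 0, 0, 80, 80, 80, 0))
  wide <- detect_edges(two, 0.12)            # widest segment by default
  expect_gt(mean(wide), 5)
  near <- detect_edges(two, 0.12, prev_center_px = 1.6)
  expect_lt(mean(near), 3)
})

test_that("circular chord profiles give the analytic 12% threshold width", {
  for (diam in c(8, 14, 20, 30)) {
    R <- diam / 2
    x <- 0:59
    ctr <- 30.3
    chord <- 2 * sqrt(pmax(R^2 - (x - ctr)^2, 0))
    e <- detect_edges(profile_from(chord), 0.12)
    width <- e[2] - e[1]
    expect_lt(abs(width - diam * sqrt(1 - 0.12^2)), 1, label = paste("d =", diam))
  }
})

test_that("profiles step between the roi centre rows, end rows forced", {
  img <- matrix(1, 120, 30)
  r1 <- roi(8, 13, 10, 20)    # centre row 10
  r2 <- roi(108, 113, 10, 20) # centre row 110
  prof <- extract_profiles(img, r1, r2, spacing_px = 25)
  expect_equal(vapply(prof, `[[`, numeric(1), "station_row"),
               c(10, 35, 60, 85, 110))
  wide <- extract_profiles(img, r1, r2, spacing_px = 500)
  expect_equal(vapply(wide, `[[`, numeric(1), "station_row"), c(10, 110))
  expect_error(extract_profiles(img, r1, r1), "same row")
  expect_error(extract_profiles(img, r1, r2, spacing_px = 0), "spacing")
})

test_that("straight-tube geometry reproduces collinear length and area", {
  # synthetic image: vertical band of width 10 px between rows 10 and 210
  img <- matrix(0, 221, 60)
  img[11:211, 26:35] <- 100
  r1 <- roi(8, 13, 25, 36)
  r2 <- roi(208, 213, 25, 36)
  geom <- build_geometry(img, r1, r2, spacing_px = 25, threshold_frac = 0.12,
                         pixel_spacing_cm = 0.03)
  expect_equal(geom$path_length_cm, 200 * 0.03)
  # all stations identical: area = pi * (d * p / 2)^2 with sub-pixel width
  d_px <- geom$diameters_px[1]
  expect_equal(geom$mean_area_cm2, pi * (d_px * 0.03 / 2)^2)
  expect_true(all(geom$centerline_px > geom$left_edge_px &
                  geom$centerline_px < geom$right_edge_px))
})

test_that("threshold-coincident samples give exact widths and areas", {
  # shoulders sit exactly at the 12% threshold, so the interpolated edges
  # land on the shoulder samples: width = 35 - 24 = 11 px at every station
  img <- matrix(0, 120, 60)
  img[, 26:35] <- 100
  img[, 25] <- 12; img[, 36] <- 12
  geom <- build_geometry(img, roi(0, 5, 20, 40), roi(115, 120, 20, 40),
                         spacing_px = 25, threshold_frac = 0.12,
                         pixel_spacing_cm = 0.03)
  expect_equal(unique(round(geom$diameters_px, 9)), 11)
  expect_equal(geom$mean_area_cm2, pi * (11 * 0.03 / 2)^2)
})

test_that("tapered tube mean area averages station areas (Jensen direction)", {
  img <- matrix(0, 201, 80)
  rows <- 1:201
  half <- (12 - (rows - 1) / 200 * 4) / 2  # diameter 12 -> 8 px
  for (r in rows) {
    lo <- ceiling(40 - half[r]); hi <- floor(40 + half[r])
    img[r, lo:hi] <- 100
  }
  geom <- build_geometry(img, roi(0, 3, 30, 50), roi(198, 201, 30, 50),
                         spacing_px = 25, threshold_frac = 0.12,
                         pixel_spacing_cm = 0.03)
  manual <- mean(pi * (geom$diameters_px * 0.03 / 2)^2)
  expect_equal(geom$mean_area_cm2, manual)
  # mean of areas exceeds area of mean diameter for a varying bore
  expect_gt(geom$mean_area_cm2,
            pi * (mean(geom$diameters_px) * 0.03 / 2)^2)
})

test_that("rendered phantom footprint and geometry match ground truth", {
  cfg <- phantom_config(true_flow_ml_min = 600, seed = 5, noise_sigma_frac = 0)
  ph <- render_sequence(cfg)
  img <- max_opacification_image(ph$sequence)
  band <- img > 0.5 * max(img)
  # the bright band must lie within the analytic tube mask (1 px dilation)
  mask <- ph$truth$tube_mask
  grown <- mask
  grown[-1, ] <- grown[-1, ] | mask[-nrow(mask), ]
  grown[-nrow(mask), ] <- grown[-nrow(mask), ] | mask[-1, ]
  grown[, -1] <- grown[, -1] | mask[, -ncol(mask)]
  grown[, -ncol(mask)] <- grown[, -ncol(mask)] | mask[, -1]
  expect_true(all(grown[band]))
  # diameter recovery within 1 px on the straight tube
  rois <- default_rois(ph$truth)
  geom <- build_geometry(img, rois[[1]], rois[[2]], pixel_spacing_cm = 0.03)
  true_d_px <- cfg$diameter_cm / cfg$pixel_spacing_cm
  expect_lt(abs(mean(geom$diameters_px) - true_d_px), 1)
})

test_that("loop geometry tracks the curved centerline arc length", {
  cfg <- phantom_config("loop", true_flow_ml_min = 500, seed = 6,
                        noise_sigma_frac = 0)
  ph <- render_sequence(cfg)
  img <- max_opacification_image(ph$sequence)
  rois <- default_rois(ph$truth)
  geom <- build_geometry(img, rois[[1]], rois[[2]], pixel_spacing_cm = 0.03)
  true_len <- diff(ph$truth$roi_s_cm)
  expect_lt(abs(geom$path_length_cm - true_len) / true_len, 0.02)
  # every station midpoint lies inside the rendered tube mask
  for (i in seq_along(geom$station_rows)) {
    r <- geom$station_rows[i] + 1L
    c <- round(geom$centerline_px[i]) + 1L
    expect_true(ph$truth$tube_mask[r, c])
  }
})

test_that("geometry exports station table and centerline", {
  img <- matrix(0, 120, 60); img[, 26:35] <- 100
  geom <- build_geometry(img, roi(0, 5, 20, 40), roi(115, 120, 20, 40),
                         spacing_px = 50, threshold_frac = 0.12,
                         pixel_spacing_cm = 0.03)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_geometry_csv(geom, p1, p2)
  st <- read.csv(p1)
  expect_equal(nrow(st), length(geom$station_rows))
  expect_true(all(c("left_px", "right_px", "center_px", "diameter_px")
                  %in% names(st)))
  expect_equal(nrow(read.csv(p2)), nrow(st))
})

test_that("diameter recovery stays within 1 px under DSA noise (median)", {
  errs <- vapply(1:5, function(s) {
    ph <- render_sequence(phantom_config(true_flow_ml_min = 600, seed = 70 + s))
    img <- max_opacification_image(ph$sequence)
    rois <- default_rois(ph$truth)
    geom <- build_geometry(img, rois[[1]], rois[[2]], pixel_spacing_cm = 0.03)
    abs(mean(geom$diameters_px) - 20)
  }, numeric(1))
  expect_lt(median(errs), 1)
})
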