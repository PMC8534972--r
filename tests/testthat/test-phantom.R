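test_that("default protocol injects exactly 10 mL", {
  cfg <- phantom_config()
  expect_identical(injected_volume_ml(cfg), 10)
})

test_that("config invariants are enforced", {
  expect_error(phantom_config(true_flow_ml_min = -5), "positive")
  expect_error(phantom_config(injection_delay_s = 4, injection_duration_s = 5),
               "total duration")
  expect_error(phantom_config(image_shape = c(20, 20)), "image_shape")
})

test_that("frame count is duration times sampling rate", {
  expect_equal(dim(render_sequence(phantom_config(sampling_rate_per_s = 6,
                                                  seed = 1))$sequence)[1], 48)
  expect_equal(dim(render_sequence(phantom_config(sampling_rate_per_s = 10,
                                                  modality = "FLUORO",
                                                  seed = 1))$sequence)[1], 80)
  expect_equal(dim(render_sequence(phantom_config(sampling_rate_per_s = 3,
                                                  seed = 1))$sequence)[1], 24)
})

test_that("path arc lengths follow the generating geometry", {
  # straight: 300 px at 0.03 cm/px spans 9 cm
  p <- make_path("straight", c(332, 64), 0.03, margin_px = 16)
  expect_equal(path_arc_length_cm(p), 299 * 0.03)
  # angular in a wide image: full 120-degree bend, legs add, each leg =
  # half-height / cos(30 deg)
  pa <- make_path("angular", c(332, 240), 0.03, margin_px = 16)
  expect_equal(attr(pa, "bend_angle_deg"), 120, tolerance = 1e-6)
  leg <- (299 / 2) / cos(pi / 6)
  expect_equal(path_arc_length_cm(pa), 2 * leg * 0.03, tolerance = 1e-3)
  # loop: arc-length contribution of the circular arc is radius x sweep
  pl <- make_path("loop", c(960, 160), 0.03, margin_px = 16)
  rad <- attr(pl, "arc_radius_px")
  sweep <- attr(pl, "arc_sweep_rad")
  expect_gt(rad, 10)
  legs_px <- (diff(range(pl$row)) - 2 * rad * sin(sweep / 2))
  expect_equal(path_arc_length_cm(pl) / 0.03 - legs_px, rad * sweep,
               tolerance = 1e-3)
  direct <- sum(sqrt(diff(pl$row)^2 + diff(pl$col)^2)) * 0.03
  expect_equal(path_arc_length_cm(pl), direct, tolerance = 1e-3)
  expect_error(make_path("straight", c(40, 40), 0.03, margin_px = 30),
               "bounds")
})

test_that("rows progress monotonically along every shape", {
  for (sh in c("straight", "angular", "loop")) {
    p <- make_path(sh, c(960, 160), 0.03)
    expect_true(all(diff(p$row) >= -1e-9), info = sh)
  }
})

test_that("pure advection delays the inlet pulse by exactly s / v", {
  cfg <- phantom_config(dispersion_coeff_cm2_s = 0, true_flow_ml_min = 600)
  v <- mean_velocity_cm_s(cfg)
  c0 <- cfg$injection_rate_ml_s /
    (cfg$injection_rate_ml_s + cfg$true_flow_ml_min / 60)
  s <- 7
  # inside the pulse window shifted by s / v
  expect_equal(bolus_concentration(cfg, s, 1 + s / v + 0.5), c0)
  expect_equal(bolus_concentration(cfg, s, 1 + s / v - 0.01), 0)
  expect_equal(bolus_concentration(cfg, s, 1 + 3 + s / v + 0.01), 0)
  # causality: nothing anywhere before the injection delay
  expect_true(all(bolus_concentration(cfg, seq(0, 25, 0.5), 0.99) == 0))
})

test_that("dispersed bolus conserves mass while fully inside the tube", {
  cfg <- phantom_config(true_flow_ml_min = 300, injection_duration_s = 0.2,
                        injection_delay_s = 1, dispersion_coeff_cm2_s = 0.1)
  s <- seq(0, 28, by = 0.005)
  m <- vapply(c(1.5, 1.8, 2.1), function(t)
    pracma::trapz(s, bolus_concentration(cfg, s, t)), numeric(1))
  expect_lt(max(abs(m / m[1] - 1)), 0.01)
})

test_that("same seed and config give bit-identical sequences", {
  a <- render_sequence(phantom_config(seed = 33))
  b <- render_sequence(phantom_config(seed = 33))
  expect_identical(a$sequence$frames, b$sequence$frames)
  c <- render_sequence(phantom_config(seed = 34))
  expect_false(identical(a$sequence$frames, c$sequence$frames))
})

test_that("noise-free DSA frames are zero before the injection delay", {
  ph <- render_sequence(phantom_config(noise_sigma_frac = 0, seed = 2))
  dt <- ph$sequence$frame_interval_s
  pre <- which((seq_len(dim(ph$sequence)[1]) - 1) * dt < 1)
  expect_true(all(ph$sequence$frames[pre, , ] == 0))
})

test_that("ground-truth transit equals arc separation over mean velocity", {
  cfg <- phantom_config(true_flow_ml_min = 750, dispersion_coeff_cm2_s = 0,
                        seed = 3)
  ph <- render_sequence(cfg)
  v <- mean_velocity_cm_s(cfg)
  expect_equal(true_transit_s(ph$truth), diff(ph$truth$roi_s_cm) / v)
  expect_equal(arrival_time_s(ph$truth, ph$truth$roi_s_cm[1]),
               1 + ph$truth$roi_s_cm[1] / v)
  # velocity consistency: flow / (60 * area)
  expect_equal(v, cfg$true_flow_ml_min / 60 / ph$truth$area_cm2)
})

test_that("bolus front reaches ROI-1 when the ground truth says it should", {
  cfg <- phantom_config(true_flow_ml_min = 400, seed = 4, noise_sigma_frac = 0)
  ph <- render_sequence(cfg)
  rois <- default_rois(ph$truth)
  tdc <- baseline_correct(extract_tdc(ph$sequence, rois[[1]]))
  t_star <- arrival_time_s(ph$truth, ph$truth$roi_s_cm[1])
  onset <- tdc$times_s[match(TRUE, tdc$values > 0.05 * max(tdc$values))]
  expect_lt(abs(onset - t_star), ph$sequence$frame_interval_s)
})

test_that("downstream peak is delayed and broader than upstream", {
  ph <- render_sequence(phantom_config(true_flow_ml_min = 600, seed = 12))
  rois <- default_rois(ph$truth)
  t1 <- baseline_correct(extract_tdc(ph$sequence, rois[[1]]))
  t2 <- baseline_correct(extract_tdc(ph$sequence, rois[[2]]))
  expect_gte(t2$times_s[which.max(t2$values)], t1$times_s[which.max(t1$values)])
  width_above_half <- function(td)
    sum(td$values > 0.5 * max(td$values)) * td$delta_t_s
  expect_gte(width_above_half(t2), width_above_half(t1))
})

test_that("fluoroscopy is darker-vessel, noisier, and polarity-consistent", {
  dsa <- render_sequence(phantom_config(seed = 9, modality = "DSA"))
  fl <- render_sequence(phantom_config(seed = 9, modality = "FLUORO",
                                       sampling_rate_per_s = 6))
  expect_gt(fl$truth$config$noise_sigma_frac,
            3 * 0.02 - 1e-12)  # at least 3x the DSA default
  # vessel darkens the fluoroscopic frame at peak opacification (t ~ 2.3 s)
  mid <- 15
  mask <- fl$truth$tube_mask
  expect_lt(mean(fl$sequence$frames[mid, , ][mask]),
            mean(fl$sequence$frames[mid, , ][!mask]))
  # after inversion + baseline, both modalities give positive boluses
  r1 <- default_rois(fl$truth)[[1]]
  tdc_fl <- baseline_correct(extract_tdc(fl$sequence, r1))
  expect_gt(max(tdc_fl$values), 0)
})

test_that("recirculation option adds a delayed secondary rise", {
  base <- phantom_config(seed = 15, noise_sigma_frac = 0)
  rec <- phantom_config(seed = 15, noise_sigma_frac = 0, recirculation = TRUE)
  s_probe <- 5
  t <- seq(0, 8, by = 0.05)
  cb <- bolus_concentration(base, rep(s_probe, length(t)), t)
  cr <- bolus_concentration(rec, rep(s_probe, length(t)), t)
  expect_true(all(cr >= cb - 1e-12))
  expect_gt(max(cr - cb), 0)
  expect_gt(t[which.max(cr - cb)], t[which.max(cb)])
})
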