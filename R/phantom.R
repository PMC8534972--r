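# Synthetic flow phantom: a contrast bolus power-injected into a silicone-tube
# circuit carrying a known steady flow, imaged as a DSA or fluoroscopic
# sequence. Bulk (plug) transport with an explicit longitudinal-dispersion
# knob; projection rendering through a circular tube; seeded noise.

TUBE_SHAPES <- c("straight", "angular", "loop")

#' Configure a synthetic flow phantom
#'
#' Defaults encode the standard acquisition protocol: contrast injected at
#' 10/3 mL/s (3.33 cc/s nominal) for 3 s — 10 mL total — after a 1 s delay,
#' imaged for 8 s. DSA sequences are subtracted (zero background, low noise);
#' fluoroscopic sequences are unsubtracted (bright background, vessel dark,
#' noise floor 3x the DSA default).
#'
#' @param tube_shape `"straight"`, `"angular"` or `"loop"`.
#' @param true_flow_ml_min carrier flow (mL/min); patent dialysis access spans
#'   roughly 300-1000 mL/min.
#' @param diameter_cm tube inner diameter (cm).
#' @param injection_rate_ml_s contrast injection rate (mL/s).
#' @param injection_duration_s injection duration (s).
#' @param injection_delay_s delay between acquisition start and injection (s).
#' @param total_duration_s acquisition duration (s).
#' @param sampling_rate_per_s frames (DSA) or pulses (fluoroscopy) per second;
#'   the protocol uses 3 or 6 F/s and 4 or 10 P/s.
#' @param modality `"DSA"` or `"FLUORO"`.
#' @param noise_sigma_frac frame-noise SD as a fraction of the peak vessel
#'   signal; `NULL` selects the modality default (0.02 DSA, 0.06 FLUORO).
#' @param dispersion_coeff_cm2_s longitudinal dispersion coefficient D
#'   (cm^2/s); Gaussian spreading of variance 2 D t.
#' @param pixel_spacing_cm isotropic pixel spacing (cm/px).
#' @param image_shape `c(rows, cols)` of the rendered frames.
#' @param seed integer; fixes all randomness of the rendering.
#' @param recirculation if `TRUE`, a delayed low-amplitude second pass is
#'   injected to exercise the first-pass isolation role of curve fitting.
#' @param fluoro_poisson if `TRUE`, adds a Poisson component to the
#'   fluoroscopic noise.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(tube_shape = c("straight", "angular", "loop"),
                           true_flow_ml_min = 600,
                           diameter_cm = 0.6,
                           injection_rate_ml_s = 10 / 3,
                           injection_duration_s = 3,
                           injection_delay_s = 1,
                           total_duration_s = 8,
                           sampling_rate_per_s = 6,
                           modality = c("DSA", "FLUORO"),
                           noise_sigma_frac = NULL,
                           dispersion_coeff_cm2_s = 20,
                           pixel_spacing_cm = 0.03,
                           image_shape = c(960L, 160L),
                           seed = 1L,
                           recirculation = FALSE,
                           fluoro_poisson = FALSE) {
  tube_shape <- match.arg(tube_shape)
  modality <- match.arg(modality)
  if (is.null(noise_sigma_frac))
    noise_sigma_frac <- if (modality == "DSA") 0.02 else 0.06
  pos <- c(true_flow = true_flow_ml_min, diameter = diameter_cm,
           rate = injection_rate_ml_s, duration = injection_duration_s,
           total = total_duration_s, fs = sampling_rate_per_s,
           px = pixel_spacing_cm)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("all rates, durations and dimensions must be positive")
  if (injection_delay_s < 0 || noise_sigma_frac < 0 ||
      dispersion_coeff_cm2_s < 0)
    stop("delay, noise and dispersion must be non-negative")
  if (injection_delay_s + injection_duration_s > total_duration_s)
    stop("injection delay + duration must not exceed the total duration")
  if (length(image_shape) != 2L || any(image_shape < 32L))
    stop("image_shape must be c(rows, cols), at least 32 px each")
  structure(list(tube_shape = tube_shape,
                 true_flow_ml_min = true_flow_ml_min,
                 diameter_cm = diameter_cm,
                 injection_rate_ml_s = injection_rate_ml_s,
                 injection_duration_s = injection_duration_s,
                 injection_delay_s = injection_delay_s,
                 total_duration_s = total_duration_s,
                 sampling_rate_per_s = sampling_rate_per_s,
                 modality = modality,
                 noise_sigma_frac = noise_sigma_frac,
                 dispersion_coeff_cm2_s = dispersion_coeff_cm2_s,
                 pixel_spacing_cm = pixel_spacing_cm,
                 image_shape = as.integer(image_shape),
                 seed = as.integer(seed),
                 recirculation = isTRUE(recirculation),
                 fluoro_poisson = isTRUE(fluoro_poisson)),
            class = "phantom_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf(
    "phantom_config: %s tube, %.0f mL/min, %s at %g samples/s, seed %d\n",
    x$tube_shape, x$true_flow_ml_min, x$modality, x$sampling_rate_per_s,
    x$seed))
  cat(sprintf("  injection %.3g mL/s x %g s after %g s delay; %g s total\n",
              x$injection_rate_ml_s, x$injection_duration_s,
              x$injection_delay_s, x$total_duration_s))
  invisible(x)
}

#' Total injected contrast volume of a protocol
#'
#' @param cfg a [phantom_config()].
#' @return volume in mL (`rate x duration`).
#' @export
injected_volume_ml <- function(cfg) {
  cfg$injection_rate_ml_s * cfg$injection_duration_s
}

cross_section_cm2 <- function(cfg) pi * (cfg$diameter_cm / 2)^2

#' Mean carrier velocity of a phantom (cm/s)
#'
#' `flow / (60 * cross-sectional area)`.
#'
#' @param cfg a [phantom_config()].
#' @return velocity in cm/s.
#' @export
mean_velocity_cm_s <- function(cfg) {
  cfg$true_flow_ml_min / 60 / cross_section_cm2(cfg)
}

# ---- centerline path --------------------------------------------------------

#' Parametric tube centerline for a phantom shape
#'
#' Returns the centerline finely sampled along arc length:
#' * `straight` — a vertical segment;
#' * `angular` — two equal legs meeting at an interior angle of 120 degrees
#'   (legs 30 degrees off vertical), flattened automatically when the image
#'   is too narrow for the full bend (the realised angle is stored in the
#'   `bend_angle_deg` attribute);
#' * `loop` — vertical segment, right-bulging circular arc sweeping ±60
#'   degrees about the horizontal mid-axis, vertical segment (radius and
#'   sweep in the `arc_radius_px` / `arc_sweep_rad` attributes).
#'
#' Rows progress monotonically from top to bottom in every shape — and the
#' tube axis never turns more than 60 degrees from vertical — so row-wise
#' geometry scanning is well defined everywhere along the path.
#'
#' @param shape one of `"straight"`, `"angular"`, `"loop"`.
#' @param image_shape `c(rows, cols)` in pixels.
#' @param pixel_spacing_cm cm per pixel.
#' @param margin_px clearance kept to the image border (must exceed the tube
#'   radius at render time).
#' @param step_px sampling step along the path.
#' @return an object of class `phantom_path`: data frame fields `s_cm`, `row`,
#'   `col` plus attributes `arc_length_cm` and `shape` (and the
#'   shape-specific attributes above).
#' @export
make_path <- function(shape, image_shape, pixel_spacing_cm,
                      margin_px = 16, step_px = 0.5) {
  shape <- match.arg(shape, TUBE_SHAPES)
  nr <- image_shape[1]; nc <- image_shape[2]
  r0 <- margin_px
  r1 <- nr - 1 - margin_px
  cmax <- nc - 1 - margin_px
  if (r1 <= r0 || cmax <= margin_px)
    stop("path exceeds image bounds: image too small for margin")
  attrs <- list()
  pts <- switch(shape,
    straight = {
      c0 <- (nc - 1) / 2
      data.frame(row = c(r0, r1), col = c(c0, c0))
    },
    angular = {
      # two equal legs meeting at 120 degrees (each 30 degrees off vertical);
      # narrower images flatten the bend to keep the path inside the frame
      half <- (r1 - r0) / 2
      dx <- min(half * tan(pi / 6), 0.9 * (cmax - margin_px))
      c0 <- (nc - 1) / 2
      attrs$bend_angle_deg <- 180 - 2 * atan2(dx, half) * 180 / pi
      data.frame(row = c(r0, r0 + half, r1),
                 col = c(c0 - dx / 2, c0 + dx / 2, c0 - dx / 2))
    },
    loop = {
      # leg / arc / leg with the arc sweeping +/- 60 degrees to the right
      theta_m <- pi / 3
      c0 <- (nc - 1) / 3
      rad <- min((cmax - c0) / (1 - cos(theta_m)), (r1 - r0) / 3 / sin(theta_m))
      mid <- (r0 + r1) / 2
      cc <- c0 - rad * cos(theta_m)   # arc centre col; arc joins legs at c0
      th <- seq(-theta_m, theta_m, length.out = 241)
      attrs$arc_radius_px <- rad
      attrs$arc_sweep_rad <- 2 * theta_m
      data.frame(row = c(r0, mid + rad * sin(th), r1),
                 col = c(c0, cc + rad * cos(th), c0))
    })
  if (any(pts$col < margin_px - 1e-9) || any(pts$col > cmax + 1e-9) ||
      any(pts$row < 0) || any(pts$row > nr - 1))
    stop("path exceeds image bounds")
  # resample at step_px along the polyline
  seg <- sqrt(diff(pts$row)^2 + diff(pts$col)^2)
  cum <- c(0, cumsum(seg))
  total_px <- cum[length(cum)]
  s_px <- seq(0, total_px, by = step_px)
  if (s_px[length(s_px)] < total_px) s_px <- c(s_px, total_px)
  row <- approx(cum, pts$row, xout = s_px)$y
  col <- approx(cum, pts$col, xout = s_px)$y
  out <- data.frame(s_cm = s_px * pixel_spacing_cm, row = row, col = col)
  attr(out, "arc_length_cm") <- total_px * pixel_spacing_cm
  attr(out, "shape") <- shape
  for (nm in names(attrs)) attr(out, nm) <- attrs[[nm]]
  class(out) <- c("phantom_path", "data.frame")
  out
}

#' Arc length of a phantom path
#'
#' @param path a [make_path()] result.
#' @return total centerline arc length in cm.
#' @export
path_arc_length_cm <- function(path) attr(path, "arc_length_cm")

# ---- bolus transport --------------------------------------------------------

#' Relative iodine concentration along the tube
#'
#' Injection is a rectangular pulse of rate `injection_rate_ml_s` over
#' `[delay, delay + duration]`, diluted by the carrier flow to an inlet
#' concentration `Qi / (Qi + Q)`, advected at the mean velocity `v = Q / A`,
#' and spread longitudinally by Gaussian dispersion of variance `2 D t` (each
#' bolus edge smeared by its own age). Concentration is clamped non-negative.
#'
#' @param cfg a [phantom_config()].
#' @param s path positions (cm from inlet); recycled against `t`.
#' @param t times (s from acquisition start).
#' @return relative concentration in `[0, 1]` at each `(s, t)`.
#' @export
bolus_concentration <- function(cfg, s, t) {
  stopifnot(inherits(cfg, "phantom_config"))
  v <- mean_velocity_cm_s(cfg)
  qi <- cfg$injection_rate_ml_s
  qc <- cfg$true_flow_ml_min / 60
  c0 <- qi / (qi + qc)
  conc <- edge_pair_conc(s, t, v, cfg$injection_delay_s,
                         cfg$injection_duration_s, cfg$dispersion_coeff_cm2_s)
  if (cfg$recirculation) {
    # delayed, dispersed low-amplitude second pass
    conc <- conc + 0.25 * edge_pair_conc(s, t + 0, v,
                                         cfg$injection_delay_s + 4,
                                         cfg$injection_duration_s,
                                         4 * max(cfg$dispersion_coeff_cm2_s, 0.5))
  }
  pmax(c0 * conc, 0)
}

# smoothed rectangle between the advected front and back edges; each edge
# carries the Gaussian spread of its own age so the integral over s is exactly
# v * (time contrast has been flowing), i.e. mass is conserved.
edge_pair_conc <- function(s, t, v, delay, duration, D) {
  n <- max(length(s), length(t))
  s <- rep_len(as.numeric(s), n)
  t <- rep_len(as.numeric(t), n)
  tf <- t - delay          # age of the front edge
  tb <- t - delay - duration
  sf <- v * tf
  sb <- pmax(v * tb, 0)    # back edge leaves the inlet only after the injection
  smooth_step <- function(edge_s, age) {
    out <- numeric(n)
    act <- age > 0
    if (!any(act)) return(out)
    if (D > 0) {
      sig <- sqrt(2 * D * age[act])
      out[act] <- 0.5 * (1 + pracma::erf((edge_s[act] - s[act]) /
                                           (sqrt(2) * sig)))
    } else {
      out[act] <- as.numeric(edge_s[act] >= s[act])  # sharp edge
    }
    out
  }
  smooth_step(sf, tf) - smooth_step(sb, tb)
}

#' Ground-truth bolus arrival time at a path position
#'
#' `delay + s / v` under pure advection.
#'
#' @param truth a `phantom_truth` from [render_sequence()].
#' @param s_cm path position(s) in cm.
#' @return arrival time(s) in seconds.
#' @export
arrival_time_s <- function(truth, s_cm) {
  truth$injection_delay_s + s_cm / truth$mean_velocity_cm_s
}

# ---- rendering --------------------------------------------------------------

#' Render a phantom into an image sequence with ground truth
#'
#' Each pixel's signal is the projection chord length of the circular tube at
#' the pixel's offset from the centerline, times the local relative contrast
#' concentration. DSA frames start from a zero (subtracted) background with
#' additive Gaussian noise; fluoroscopic frames darken a bright constant
#' background and carry a 3x noise floor (optionally plus a Poisson
#' component). All randomness is fixed by `cfg$seed`.
#'
#' @param cfg a [phantom_config()].
#' @return list with elements `sequence` (an [image_sequence()]) and `truth`
#'   (class `phantom_truth`: `true_flow_ml_min`, `tube_mask`,
#'   `centerline`, `arc_length_cm`, `mean_velocity_cm_s`,
#'   `injection_delay_s`, `area_cm2`, `rois` — default ROIs at 20% and 80% of
#'   arc length — and `roi_s_cm`, their path positions).
#' @export
render_sequence <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  nr <- cfg$image_shape[1]; nc <- cfg$image_shape[2]
  radius_px <- cfg$diameter_cm / 2 / cfg$pixel_spacing_cm
  margin <- ceiling(radius_px) + 4
  path <- make_path(cfg$tube_shape, cfg$image_shape, cfg$pixel_spacing_cm,
                    margin_px = margin)
  geom <- rasterize_tube(path, nr, nc, radius_px)
  # geom: idx (pixel linear index), chord_px, s_cm
  n_fr <- round(cfg$total_duration_s * cfg$sampling_rate_per_s)
  dt <- 1 / cfg$sampling_rate_per_s
  times <- (seq_len(n_fr) - 1) * dt
  qi <- cfg$injection_rate_ml_s
  qc <- cfg$true_flow_ml_min / 60
  peak_signal <- 2 * radius_px * qi / (qi + qc)
  sigma <- cfg$noise_sigma_frac * peak_signal
  background <- if (cfg$modality == "FLUORO") 2 * peak_signal else 0
  frames <- array(0, c(n_fr, nr, nc))
  set.seed(cfg$seed)
  for (i in seq_len(n_fr)) {
    fr <- matrix(background, nr, nc)
    sig <- geom$chord_px * bolus_concentration(cfg, geom$s_cm, times[i])
    if (cfg$modality == "DSA") fr[geom$idx] <- fr[geom$idx] + sig
    else fr[geom$idx] <- fr[geom$idx] - sig
    if (sigma > 0) fr <- fr + rnorm(nr * nc, 0, sigma)
    if (cfg$modality == "FLUORO" && cfg$fluoro_poisson)
      fr <- fr + (rpois(nr * nc, lambda = 4) - 4) * (sigma / 2)
    frames[i, , ] <- fr
  }
  seqc <- image_sequence(frames, dt, cfg$pixel_spacing_cm, cfg$modality)
  mask <- matrix(FALSE, nr, nc)
  mask[geom$idx] <- geom$chord_px > 0
  L <- path_arc_length_cm(path)
  roi_s <- c(0.2, 0.8) * L
  rois <- lapply(seq_along(roi_s), function(k) {
    i <- which.min(abs(path$s_cm - roi_s[k]))
    half <- 5L
    roi(max(0, round(path$row[i]) - half),
        min(nr, round(path$row[i]) + half + 1L),
        max(0, round(path$col[i]) - half),
        min(nc, round(path$col[i]) + half + 1L),
        label = sprintf("ROI%d", k))
  })
  truth <- structure(list(true_flow_ml_min = cfg$true_flow_ml_min,
                          tube_mask = mask,
                          centerline = path,
                          arc_length_cm = L,
                          area_cm2 = cross_section_cm2(cfg),
                          mean_velocity_cm_s = mean_velocity_cm_s(cfg),
                          injection_delay_s = cfg$injection_delay_s,
                          rois = rois,
                          roi_s_cm = roi_s,
                          config = cfg),
                     class = "phantom_truth")
  list(sequence = seqc, truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(
    "phantom_truth: %.0f mL/min, arc length %.3g cm, velocity %.3g cm/s\n",
    x$true_flow_ml_min, x$arc_length_cm, x$mean_velocity_cm_s))
  cat(sprintf("  ROIs at s = %.3g and %.3g cm (true transit %.3g s)\n",
              x$roi_s_cm[1], x$roi_s_cm[2],
              diff(x$roi_s_cm) / x$mean_velocity_cm_s))
  invisible(x)
}

#' Ground-truth transit time between the default ROIs
#'
#' @param truth a `phantom_truth`.
#' @return arc-length separation / mean velocity, in seconds.
#' @export
true_transit_s <- function(truth) {
  diff(truth$roi_s_cm) / truth$mean_velocity_cm_s
}

# Map each pixel near the path to its perpendicular offset and path position,
# and precompute the projection chord. The straight tube is handled in closed
# form; curved paths are rasterised by stamping windows along the path and
# keeping the nearest path sample per pixel.
rasterize_tube <- function(path, nr, nc, radius_px) {
  shape <- attr(path, "shape")
  psp <- path$s_cm[2] - path$s_cm[1]
  if (identical(shape, "straight")) {
    c0 <- path$col[1]
    cols <- which(abs((0:(nc - 1)) - c0) < radius_px)
    rows <- seq(ceiling(min(path$row)), floor(max(path$row)))
    pix <- expand.grid(row = rows, col = cols - 1L)
    d <- abs(pix$col - c0)
    keep <- d < radius_px
    pix <- pix[keep, ]
    d <- d[keep]
    s_cm <- approx(path$row, path$s_cm, xout = pix$row)$y
    idx <- pix$row + 1L + (pix$col) * nr
    return(list(idx = idx, chord_px = 2 * sqrt(radius_px^2 - d^2),
                s_cm = s_cm))
  }
  dmin <- matrix(Inf, nr, nc)
  sbest <- matrix(NA_real_, nr, nc)
  w <- ceiling(radius_px) + 1L
  for (k in seq_len(nrow(path))) {
    rr <- max(1L, floor(path$row[k]) - w + 1L):min(nr, ceiling(path$row[k]) + w + 1L)
    cc <- max(1L, floor(path$col[k]) - w + 1L):min(nc, ceiling(path$col[k]) + w + 1L)
    dr <- (rr - 1L) - path$row[k]
    dc <- (cc - 1L) - path$col[k]
    d2 <- outer(dr^2, dc^2, `+`)
    sub <- dmin[rr, cc]
    upd <- d2 < sub
    if (any(upd)) {
      sub[upd] <- d2[upd]
      dmin[rr, cc] <- sub
      sb <- sbest[rr, cc]
      sb[upd] <- path$s_cm[k]
      sbest[rr, cc] <- sb
    }
  }
  sel <- which(dmin < radius_px^2)
  list(idx = sel, chord_px = 2 * sqrt(radius_px^2 - dmin[sel]),
       s_cm = sbest[sel])
}

#' Default phantom ROIs
#'
#' The two measurement ROIs exported with the ground truth, centred on the
#' path at 20% and 80% of arc length.
#'
#' @param truth a `phantom_truth`.
#' @return list of two [roi()]s.
#' @export
default_rois <- function(truth) truth$rois
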