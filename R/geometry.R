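# Vessel geometry from the contrast-enhanced image: row-wise distance-intensity
# profiles, threshold edge detection with sub-pixel interpolation, centerline,
# traversal distance, and mean circular cross-sectional area.

#' Maximum-opacification image of a sequence
#'
#' Pixelwise maximum over the post-baseline, polarity-normalised frames minus
#' the mean pre-contrast frame. This is the most contrast-enhanced, noise
#' averaged view of the vessel and is what the geometry extraction analyses.
#'
#' @param seq an [image_sequence()].
#' @param n_pre number of pre-contrast frames (default: frames within the 1 s
#'   injection delay).
#' @return a rows x cols numeric matrix.
#' @export
max_opacification_image <- function(seq,
                                    n_pre = max(1L, floor(1 / seq$frame_interval_s))) {
  stopifnot(inherits(seq, "image_sequence"))
  nt <- n_frames(seq)
  if (n_pre >= nt) stop("n_pre must be smaller than the frame count")
  d <- dim(seq$frames)
  fr <- matrix(seq$frames, nrow = d[1])  # frames as rows, pixels as columns
  if (seq$modality == "FLUORO") fr <- -fr
  base <- colMeans(fr[seq_len(n_pre), , drop = FALSE])
  mx <- fr[n_pre + 1L, ]
  for (i in seq_len(nt - n_pre - 1L) + n_pre + 1L) mx <- pmax(mx, fr[i, ])
  matrix(mx - base, d[2], d[3])
}

#' Row-wise distance-intensity profiles between two ROIs
#'
#' One profile per scan row, stepping by `spacing_px` from the centre row of
#' `roi1` towards the centre row of `roi2`; both end rows are always included
#' so the sampled path spans ROI to ROI.
#'
#' @param img 2-D contrast-positive image ([max_opacification_image()]).
#' @param roi1,roi2 [roi()]s centred on the path at distinct rows.
#' @param spacing_px station separation in pixels (default 25).
#' @return list of `distance_intensity_profile` objects with fields
#'   `station_row` (0-based), `distances_px`, `intensities`.
#' @export
extract_profiles <- function(img, roi1, roi2, spacing_px = 25) {
  stopifnot(is.matrix(img))
  if (spacing_px <= 0) stop("spacing_px must be positive")
  r1 <- roi_center_row(roi1)
  r2 <- roi_center_row(roi2)
  if (r1 == r2) stop("ROIs lie on the same row: no path to scan")
  step <- if (r2 > r1) spacing_px else -spacing_px
  rows <- seq(r1, r2, by = step)
  if (rows[length(rows)] != r2) rows <- c(rows, r2)
  lapply(rows, function(r) {
    structure(list(station_row = as.integer(r),
                   distances_px = as.numeric(0:(ncol(img) - 1L)),
                   intensities = as.numeric(img[r + 1L, ])),
              class = "distance_intensity_profile")
  })
}

#' Detect vessel edges on one distance-intensity profile
#'
#' The threshold is `threshold_frac` times the maximum opacification
#' (`max_value`, by default the profile's own maximum). Contiguous
#' above-threshold runs are candidate vessel segments; the segment whose
#' midpoint is nearest `prev_center_px` (or the widest, if none is given) is
#' selected, and each edge is located by linear sub-pixel interpolation of the
#' threshold crossing. Relative thresholding makes the result invariant to any
#' positive rescaling of the image.
#'
#' @param profile a `distance_intensity_profile`.
#' @param threshold_frac edge threshold as a fraction of `max_value`
#'   (default 0.12, the settled cut-off; 0.05 is the initial heuristic).
#' @param prev_center_px optional centerline position of the previous station,
#'   used to disambiguate self-overlapping paths (loops).
#' @param max_value reference maximum opacification; defaults to the profile
#'   maximum, but [build_geometry()] passes the global image maximum.
#' @return named numeric `c(left_px, right_px)` (sub-pixel, 0-based).
#' @export
detect_edges <- function(profile, threshold_frac = 0.12,
                         prev_center_px = NULL, max_value = NULL) {
  stopifnot(inherits(profile, "distance_intensity_profile"))
  if (threshold_frac <= 0 || threshold_frac >= 1)
    stop("threshold_frac must lie in (0, 1)")
  x <- profile$distances_px
  y <- profile$intensities
  if (max(y) <= 0) stop("no above-threshold run: profile has no signal")
  if (is.null(max_value)) max_value <- max(y)
  thr <- threshold_frac * max_value
  above <- y >= thr
  if (!any(above)) stop("no above-threshold run at this station")
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(start = starts[r$values], end = ends[r$values])
  cross <- function(i_out, i_in) {
    # linear interpolation of the threshold crossing between samples
    if (i_out < 1L || i_out > length(y)) return(x[i_in])
    x[i_out] + (thr - y[i_out]) / (y[i_in] - y[i_out]) * (x[i_in] - x[i_out])
  }
  seg$left <- mapply(function(s, e) cross(s - 1L, s), seg$start, seg$end)
  seg$right <- mapply(function(s, e) cross(e + 1L, e), seg$start, seg$end)
  seg$mid <- (seg$left + seg$right) / 2
  pick <- if (!is.null(prev_center_px)) which.min(abs(seg$mid - prev_center_px))
          else which.max(seg$right - seg$left)
  c(left_px = seg$left[pick], right_px = seg$right[pick])
}

#' Extract full vessel geometry between two ROIs
#'
#' Runs [extract_profiles()] and [detect_edges()] station by station (chaining
#' each station's centerline position into the next for loop disambiguation),
#' then assembles the centerline polyline, per-station diameters, traversal
#' distance, and the mean circular cross-sectional area:
#' per-station area \eqn{\pi (d_{px} \cdot p / 2)^2} with `p` the pixel
#' spacing, averaged arithmetically over stations.
#'
#' @inheritParams extract_profiles
#' @param threshold_frac see [detect_edges()].
#' @param pixel_spacing_cm isotropic pixel spacing (cm/px).
#' @return an object of class `vessel_geometry`.
#' @export
build_geometry <- function(img, roi1, roi2, spacing_px = 25,
                           threshold_frac = 0.12, pixel_spacing_cm) {
  stopifnot(is.matrix(img), pixel_spacing_cm > 0)
  profiles <- extract_profiles(img, roi1, roi2, spacing_px)
  gmax <- max(img)
  if (gmax <= 0) stop("image has no positive opacification")
  prev <- NULL
  edges <- matrix(NA_real_, nrow = length(profiles), ncol = 2)
  for (i in seq_along(profiles)) {
    e <- detect_edges(profiles[[i]], threshold_frac, prev_center_px = prev,
                      max_value = gmax)
    edges[i, ] <- e
    prev <- mean(e)
  }
  if (nrow(edges) < 2L)
    stop("fewer than 2 valid stations: cannot form a centerline")
  rows <- vapply(profiles, function(p) as.numeric(p$station_row), numeric(1))
  centers <- rowMeans(edges)
  diam_px <- edges[, 2] - edges[, 1]
  if (any(diam_px <= 0)) stop("degenerate station width")
  seg_len <- sqrt(diff(rows)^2 + diff(centers)^2)
  path_length_cm <- sum(seg_len) * pixel_spacing_cm
  areas_cm2 <- pi * (diam_px * pixel_spacing_cm / 2)^2
  structure(list(station_rows = rows,
                 left_edge_px = edges[, 1],
                 right_edge_px = edges[, 2],
                 centerline_px = centers,
                 diameters_px = diam_px,
                 mean_area_cm2 = mean(areas_cm2),
                 path_length_cm = path_length_cm,
                 threshold_frac = threshold_frac,
                 pixel_spacing_cm = pixel_spacing_cm),
            class = "vessel_geometry")
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat(sprintf(
    "vessel_geometry: %d stations, mean diameter %.3g px, mean area %.4g cm^2\n",
    length(x$station_rows), mean(x$diameters_px), x$mean_area_cm2))
  cat(sprintf("  centerline path length %.4g cm (threshold %.3g of max)\n",
              x$path_length_cm, x$threshold_frac))
  invisible(x)
}

#' @export
as.data.frame.vessel_geometry <- function(x, ...) {
  data.frame(station_row = x$station_rows,
             left_px = x$left_edge_px,
             right_px = x$right_edge_px,
             center_px = x$centerline_px,
             diameter_px = x$diameters_px)
}

#' Write geometry stations (and optionally the centerline) as CSV
#'
#' @param geom a `vessel_geometry`.
#' @param path destination for the station table.
#' @param centerline_path optional destination for a two-column
#'   `(row, col)` centerline point list.
#' @return `path`, invisibly.
#' @export
write_geometry_csv <- function(geom, path, centerline_path = NULL) {
  write.csv(as.data.frame(geom), path, row.names = FALSE)
  if (!is.null(centerline_path))
    write.csv(data.frame(row = geom$station_rows, col = geom$centerline_px),
              centerline_path, row.names = FALSE)
  invisible(path)
}
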