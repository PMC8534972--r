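# Volumetric flow from transit time, traversal distance, and mean
# cross-sectional area, plus the end-to-end measurement orchestrator.

#' Volumetric flow from area, distance, and transit time
#'
#' Plug-flow indicator transport: \deqn{Q = \bar A \cdot d / \tau \cdot 60}
#' with area in cm^2, distance in cm, transit time in s, and the factor 60
#' converting mL/s to mL/min. A zero transit time signals a degenerate
#' measurement and is an error.
#'
#' @param mean_area_cm2 mean cross-sectional area (cm^2).
#' @param path_length_cm centerline traversal distance (cm).
#' @param tau_s bolus transit time (s).
#' @return flow in mL/min.
#' @export
compute_flow <- function(mean_area_cm2, path_length_cm, tau_s) {
  if (!is.finite(mean_area_cm2) || mean_area_cm2 <= 0)
    stop("mean_area_cm2 must be positive")
  if (!is.finite(path_length_cm) || path_length_cm <= 0)
    stop("path_length_cm must be positive")
  if (!is.finite(tau_s) || tau_s <= 0)
    stop("degenerate measurement: transit time must be positive")
  mean_area_cm2 * path_length_cm / tau_s * 60
}

#' Measure volumetric flow from an angiographic sequence
#'
#' End-to-end pipeline: extract and baseline-correct the time-density curves
#' at the two ROIs, fit the chosen reference model, estimate the transit time
#' (PP or CC), extract vessel geometry from the maximum-opacification image,
#' and combine everything with [compute_flow()]. Each stage failure is
#' re-raised with its stage label.
#'
#' @param seq an [image_sequence()].
#' @param roi1,roi2 upstream and downstream [roi()]s on the bolus flight path.
#' @param algorithm `"cc"` or `"pp"`.
#' @param fit_model `"gamma_variate"`, `"lagged_normal"`, `"polynomial"` or
#'   `"none"`.
#' @param config optional named list overriding defaults: `threshold_frac`
#'   (0.12), `spacing_px` (25), `upsample` (100), `n_pre` (samples within the
#'   1 s injection delay).
#' @return an object of class `flow_result`: `flow_ml_min`, `tau_s`,
#'   `path_length_cm`, `mean_area_cm2`, and full provenance (`algorithm`,
#'   `fit_model`, `sampling_rate`, `modality`, `config`, per-stage objects).
#' @export
measure_flow <- function(seq, roi1, roi2, algorithm = c("cc", "pp"),
                         fit_model = c("gamma_variate", "lagged_normal",
                                       "polynomial", "none"),
                         config = list()) {
  algorithm <- match.arg(algorithm)
  fit_model <- match.arg(fit_model)
  stopifnot(inherits(seq, "image_sequence"))
  cfg <- utils::modifyList(
    list(threshold_frac = 0.12, spacing_px = 25, upsample = 100L,
         n_pre = NULL), config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  tdc1 <- stage("tdc", extract_tdc(seq, roi1))
  tdc2 <- stage("tdc", extract_tdc(seq, roi2))
  n_pre <- cfg$n_pre %||% default_n_pre(tdc1)
  tdc1 <- stage("baseline", baseline_correct(tdc1, n_pre))
  tdc2 <- stage("baseline", baseline_correct(tdc2, n_pre))
  f1 <- stage("curvefit", fit_tdc(tdc1, fit_model))
  f2 <- stage("curvefit", fit_tdc(tdc2, fit_model))
  tt <- stage("transit", transit_time(f1, f2, algorithm,
                                      upsample = cfg$upsample))
  img <- stage("geometry", max_opacification_image(seq, n_pre))
  geom <- stage("geometry", build_geometry(img, roi1, roi2,
                                           spacing_px = cfg$spacing_px,
                                           threshold_frac = cfg$threshold_frac,
                                           pixel_spacing_cm = seq$pixel_spacing_cm))
  flow <- stage("flow", compute_flow(geom$mean_area_cm2, geom$path_length_cm,
                                     tt$tau_s))
  structure(list(flow_ml_min = flow,
                 tau_s = tt$tau_s,
                 path_length_cm = geom$path_length_cm,
                 mean_area_cm2 = geom$mean_area_cm2,
                 algorithm = toupper(algorithm),
                 fit_model = fit_model,
                 sampling_rate = 1 / seq$frame_interval_s,
                 modality = seq$modality,
                 config = cfg[c("threshold_frac", "spacing_px", "upsample")],
                 n_pre = n_pre,
                 rois = list(roi1 = unclass(roi1), roi2 = unclass(roi2)),
                 transit = tt,
                 geometry = geom,
                 fits = list(f1, f2)),
            class = "flow_result")
}

#' @export
print.flow_result <- function(x, ...) {
  cat(sprintf("flow_result: %.1f mL/min (%s + %s, %s at %g samples/s)\n",
              x$flow_ml_min, x$algorithm, x$fit_model, x$modality,
              x$sampling_rate))
  cat(sprintf("  tau = %.4g s, distance = %.4g cm, mean area = %.4g cm^2\n",
              x$tau_s, x$path_length_cm, x$mean_area_cm2))
  invisible(x)
}

#' @export
summary.flow_result <- function(object, ...) {
  print(object)
  cat(sprintf("  edge threshold %.3g, station spacing %g px, upsample x%d\n",
              object$config$threshold_frac, object$config$spacing_px,
              as.integer(object$config$upsample)))
  invisible(object)
}

#' Serialize a flow result (with provenance) to JSON
#'
#' The record carries every setting needed to reproduce the measurement:
#' algorithm, fit model, ROIs, thresholds, spacing, upsampling, sampling rate
#' and modality. [read_flow_result()] restores it.
#'
#' @param x a `flow_result`.
#' @param path optional destination file.
#' @return JSON string (invisibly when written to `path`).
#' @export
write_flow_result <- function(x, path = NULL) {
  stopifnot(inherits(x, "flow_result"))
  rec <- x[c("flow_ml_min", "tau_s", "path_length_cm", "mean_area_cm2",
             "algorithm", "fit_model", "sampling_rate", "modality",
             "config", "n_pre", "rois")]
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Re-load a serialized flow result
#'
#' @param path JSON file written by [write_flow_result()].
#' @return a `flow_result` (provenance fields only; stage objects are not
#'   serialized).
#' @export
read_flow_result <- function(path) {
  rec <- jsonlite::fromJSON(path)
  structure(rec, class = "flow_result")
}
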