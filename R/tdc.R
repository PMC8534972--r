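# Time-density curves: the sampled indicator-dilution signal P(t) at a ROI.

#' Extract a time-density curve at a region of interest
#'
#' The curve value at each frame is the unweighted spatial mean intensity over
#' the ROI, so amplitude is ROI-size invariant. For `FLUORO` sequences the sign
#' is inverted (contrast attenuates the beam, darkening the vessel) so that
#' bolus passage is always contrast-positive. No baseline correction is applied
#' here; see [baseline_correct()].
#'
#' @param seq an [image_sequence()].
#' @param roi an [roi()] inside the frame bounds.
#' @return an object of class `tdc` with fields `times_s`, `values`,
#'   `delta_t_s`, `roi_label`.
#' @export
extract_tdc <- function(seq, roi) {
  stopifnot(inherits(seq, "image_sequence"), inherits(roi, "roi"))
  check_roi_in(roi, dim(seq$frames))
  rows <- (roi$row_start + 1L):roi$row_end
  cols <- (roi$col_start + 1L):roi$col_end
  vals <- apply(seq$frames[, rows, cols, drop = FALSE], 1, mean)
  if (seq$modality == "FLUORO") vals <- -vals
  new_tdc(times_s = (seq_len(n_frames(seq)) - 1) * seq$frame_interval_s,
          values = as.numeric(vals),
          delta_t_s = seq$frame_interval_s,
          roi_label = roi$label)
}

new_tdc <- function(times_s, values, delta_t_s, roi_label = "",
                    baseline_corrected = FALSE) {
  stopifnot(length(times_s) == length(values), delta_t_s > 0,
            all(is.finite(values)))
  if (length(times_s) > 1 &&
      max(abs(diff(times_s) - delta_t_s)) > 1e-9 * delta_t_s)
    stop("tdc times must increase in constant steps of delta_t_s")
  structure(list(times_s = as.numeric(times_s), values = as.numeric(values),
                 delta_t_s = as.numeric(delta_t_s),
                 roi_label = as.character(roi_label),
                 baseline_corrected = isTRUE(baseline_corrected)),
            class = "tdc")
}

#' @export
print.tdc <- function(x, ...) {
  cat(sprintf(
    "time-density curve%s: %d samples at %.4g s, peak %.4g at t = %.3g s%s\n",
    if (nzchar(x$roi_label)) paste0(" '", x$roi_label, "'") else "",
    length(x$values), x$delta_t_s, max(x$values),
    x$times_s[which.max(x$values)],
    if (x$baseline_corrected) ", baseline-corrected" else ""))
  invisible(x)
}

#' @export
length.tdc <- function(x) length(x$values)

#' @export
as.data.frame.tdc <- function(x, ...) {
  data.frame(time_s = x$times_s, value = x$values)
}

#' Subtract the pre-contrast baseline from a time-density curve
#'
#' Subtracts the mean of the first `n_pre` (pre-contrast) samples. The default
#' window covers the injector's initial delay: `floor(1 s / delta_t)` samples,
#' at least one.
#'
#' @param tdc a [extract_tdc()] curve.
#' @param n_pre number of pre-contrast samples, `1 <= n_pre < length(tdc)`.
#' @return a baseline-corrected `tdc`.
#' @export
baseline_correct <- function(tdc, n_pre = default_n_pre(tdc)) {
  stopifnot(inherits(tdc, "tdc"))
  if (n_pre < 1 || n_pre >= length(tdc$values))
    stop("n_pre out of range: need 1 <= n_pre < curve length")
  new_tdc(tdc$times_s, tdc$values - mean(tdc$values[seq_len(n_pre)]),
          tdc$delta_t_s, tdc$roi_label, baseline_corrected = TRUE)
}

#' Default pre-contrast sample count for a curve
#'
#' Samples falling within the 1 s injection delay of the standard protocol:
#' `max(1, floor(1 / delta_t))`.
#'
#' @param tdc a `tdc` object.
#' @param delay_s injection delay (s), default 1.
#' @return integer sample count.
#' @export
default_n_pre <- function(tdc, delay_s = 1) {
  as.integer(max(1, min(length(tdc$values) - 1,
                        floor(delay_s / tdc$delta_t_s + 1e-9))))
}

#' Write a time-density curve as two-column CSV
#'
#' @param tdc a `tdc` object.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_tdc_csv <- function(tdc, path) {
  write.csv(as.data.frame(tdc), path, row.names = FALSE)
  invisible(path)
}
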