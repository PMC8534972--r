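# Evaluation statistics: absolute percent quantification error, mean +/- SEM
# with 95% CI, Bland-Altman bias and limits of agreement, Pearson correlation,
# paired t tests, and the scenario benchmark harness.

#' Absolute percent quantification error
#'
#' `100 * |measured - reference| / reference`, the absolute percent deviation
#' from the ground-truth (in-line flow sensor) measurement.
#'
#' @param measured measured flow(s).
#' @param reference reference flow(s), strictly positive.
#' @return percent error(s).
#' @export
absolute_percent_error <- function(measured, reference) {
  if (any(reference <= 0)) stop("reference flow must be positive")
  100 * abs(measured - reference) / reference
}

#' Mean, SEM and 95% CI of quantification errors
#'
#' SEM uses the sample SD (n - 1); the confidence interval is the normal
#' approximation `mean +/- 1.96 * SEM`, matching the 1.96 convention of the
#' limits of agreement.
#'
#' @param errors numeric vector of percent errors, `n >= 2`.
#' @return list with `mean`, `sem`, `ci_low`, `ci_high`, `n`.
#' @export
summarize_errors <- function(errors) {
  errors <- errors[is.finite(errors)]
  n <- length(errors)
  if (n < 2) stop("need at least 2 error values")
  m <- mean(errors)
  sem <- sd(errors) / sqrt(n)
  list(mean = m, sem = sem,
       ci_low = m - 1.96 * sem, ci_high = m + 1.96 * sem, n = n)
}

#' Bland-Altman agreement statistics
#'
#' Differences are `measured - reference`; bias is their mean and the limits
#' of agreement are `bias +/- 1.96 * SD(differences)`. Pearson's r of measured
#' versus reference and the percent-error summary ([summarize_errors()]) are
#' included.
#'
#' @param measured,reference paired flow measurements (equal length, n >= 2).
#' @return an object of class `agreement_stats` with fields `bias_ml_min`,
#'   `loa_low_ml_min`, `loa_high_ml_min`, `pearson_r`, `mqe_mean_pct`,
#'   `mqe_sem_pct`, `mqe_ci_low_pct`, `mqe_ci_high_pct`, `n`.
#' @export
bland_altman <- function(measured, reference) {
  if (length(measured) != length(reference))
    stop("measured and reference must have equal length")
  keep <- is.finite(measured) & is.finite(reference)
  measured <- measured[keep]; reference <- reference[keep]
  n <- length(measured)
  if (n < 2) stop("need at least 2 paired measurements")
  d <- measured - reference
  bias <- mean(d)
  sdd <- sd(d)
  r <- if (sd(measured) == 0 || sd(reference) == 0) NA_real_
       else stats::cor(measured, reference)
  mqe <- summarize_errors(absolute_percent_error(measured, reference))
  structure(list(bias_ml_min = bias,
                 loa_low_ml_min = bias - 1.96 * sdd,
                 loa_high_ml_min = bias + 1.96 * sdd,
                 pearson_r = r,
                 mqe_mean_pct = mqe$mean,
                 mqe_sem_pct = mqe$sem,
                 mqe_ci_low_pct = mqe$ci_low,
                 mqe_ci_high_pct = mqe$ci_high,
                 n = n),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("agreement (n = %d):\n", x$n))
  cat(sprintf("  bias %.1f mL/min, LOA [%.1f, %.1f]\n",
              x$bias_ml_min, x$loa_low_ml_min, x$loa_high_ml_min))
  cat(sprintf("  |MQE| %.1f +/- %.1f %% (95%% CI [%.1f, %.1f]), r = %.3f\n",
              x$mqe_mean_pct, x$mqe_sem_pct, x$mqe_ci_low_pct,
              x$mqe_ci_high_pct, x$pearson_r))
  invisible(x)
}

#' Paired two-sided t test between per-case errors of two methods
#'
#' Both error vectors must come from the same measurement cases, in the same
#' order. Zero within-pair variance is degenerate: identical lists give
#' `t = 0, p = 1`; a constant nonzero difference is reported as `p = 0` with
#' `degenerate = TRUE`.
#'
#' @param errors_a,errors_b paired error vectors.
#' @return list with `t_statistic`, `p_value`, `df`, `degenerate`.
#' @export
paired_t_test <- function(errors_a, errors_b) {
  if (length(errors_a) != length(errors_b))
    stop("mismatched cases: error vectors differ in length")
  if (length(errors_a) < 2) stop("need at least 2 paired cases")
  d <- errors_a - errors_b
  if (sd(d) == 0) {
    if (all(d == 0))
      return(list(t_statistic = 0, p_value = 1,
                  df = length(d) - 1, degenerate = TRUE))
    return(list(t_statistic = sign(mean(d)) * Inf, p_value = 0,
                df = length(d) - 1, degenerate = TRUE))
  }
  tt <- t.test(errors_a, errors_b, paired = TRUE)
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

# ---- benchmark harness ------------------------------------------------------

#' Simulate-and-measure benchmark over a scenario grid
#'
#' For every imaging condition (rows of `conditions`) and every replicate, a
#' phantom with a randomly drawn true flow is rendered once, and every method
#' (rows of `methods`) measures it — so method comparisons are paired on
#' identical acquisitions, as in a bench experiment where all algorithms read
#' the same images. Geometry and curve fits are shared across methods where
#' the settings coincide. Failed measurements are recorded per row (status
#' column), never imputed.
#'
#' @param conditions data frame with columns `shape`, `modality`,
#'   `sampling_rate` (and optionally `noise_sigma_frac`, `dispersion`, or a
#'   fixed `flow_ml_min` that suppresses the random flow draw).
#' @param methods data frame with columns `algorithm` (`"cc"`/`"pp"`) and
#'   `fit_model`.
#' @param n_reps replicates per condition.
#' @param seed master seed; replicate seeds are derived deterministically.
#' @param flow_range_ml_min range of the uniform true-flow draw.
#' @return data frame, one row per condition x replicate x method, with the
#'   true and estimated flow and the absolute percent error.
#' @export
run_benchmark <- function(conditions, methods, n_reps = 50, seed = 1,
                          flow_range_ml_min = c(300, 1000)) {
  stopifnot(is.data.frame(conditions), is.data.frame(methods),
            all(c("shape", "modality", "sampling_rate") %in% names(conditions)),
            all(c("algorithm", "fit_model") %in% names(methods)))
  out <- list()
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions[ci, ]
    for (rep in seq_len(n_reps)) {
      rep_seed <- as.integer(seed) + 7919L * (ci - 1L) + rep
      set.seed(rep_seed)
      flow <- if (!is.null(cond$flow_ml_min) && is.finite(cond$flow_ml_min))
        cond$flow_ml_min
      else runif(1, flow_range_ml_min[1], flow_range_ml_min[2])
      args <- list(tube_shape = as.character(cond$shape),
                   true_flow_ml_min = flow,
                   sampling_rate_per_s = cond$sampling_rate,
                   modality = as.character(cond$modality),
                   seed = rep_seed)
      if (!is.null(cond$noise_sigma_frac) && is.finite(cond$noise_sigma_frac))
        args$noise_sigma_frac <- cond$noise_sigma_frac
      if (!is.null(cond$dispersion) && is.finite(cond$dispersion))
        args$dispersion_coeff_cm2_s <- cond$dispersion
      cfg <- do.call(phantom_config, args)
      ph <- render_sequence(cfg)
      rois <- default_rois(ph$truth)
      shared <- prepare_measurement(ph$sequence, rois[[1]], rois[[2]])
      for (mi in seq_len(nrow(methods))) {
        alg <- as.character(methods$algorithm[mi])
        fm <- as.character(methods$fit_model[mi])
        res <- tryCatch({
          est <- shared_measure(shared, alg, fm)
          list(est = est, status = "ok", message = "")
        }, error = function(e)
          list(est = NA_real_, status = "error",
               message = conditionMessage(e)))
        out[[length(out) + 1L]] <- data.frame(
          condition = ci, shape = as.character(cond$shape),
          modality = as.character(cond$modality),
          sampling_rate = cond$sampling_rate,
          algorithm = toupper(alg), fit_model = fm,
          rep = rep, seed = rep_seed,
          true_flow = flow, est_flow = res$est,
          error_pct = if (is.finite(res$est))
            absolute_percent_error(res$est, flow) else NA_real_,
          status = res$status, message = res$message,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

# One-time per-acquisition work shared by all methods: TDC extraction,
# baseline correction, geometry; fits are cached per model.
prepare_measurement <- function(seq, roi1, roi2, config = list()) {
  cfg <- utils::modifyList(
    list(threshold_frac = 0.12, spacing_px = 25, upsample = 100L,
         n_pre = NULL), config)
  tdc1 <- extract_tdc(seq, roi1)
  tdc2 <- extract_tdc(seq, roi2)
  n_pre <- cfg$n_pre %||% default_n_pre(tdc1)
  tdc1 <- baseline_correct(tdc1, n_pre)
  tdc2 <- baseline_correct(tdc2, n_pre)
  img <- max_opacification_image(seq, n_pre)
  geom <- build_geometry(img, roi1, roi2, spacing_px = cfg$spacing_px,
                         threshold_frac = cfg$threshold_frac,
                         pixel_spacing_cm = seq$pixel_spacing_cm)
  env <- new.env(parent = emptyenv())
  list(tdc1 = tdc1, tdc2 = tdc2, geom = geom, cfg = cfg, fits = env)
}

shared_measure <- function(shared, algorithm, fit_model) {
  key <- fit_model
  if (is.null(shared$fits[[key]]))
    shared$fits[[key]] <- list(fit_tdc(shared$tdc1, fit_model),
                               fit_tdc(shared$tdc2, fit_model))
  fits <- shared$fits[[key]]
  tt <- transit_time(fits[[1]], fits[[2]], algorithm,
                     upsample = shared$cfg$upsample)
  compute_flow(shared$geom$mean_area_cm2, shared$geom$path_length_cm, tt$tau_s)
}

#' Per-scenario agreement summary of a benchmark table
#'
#' Groups the [run_benchmark()] output by condition and method and computes
#' [bland_altman()] statistics (plus failure counts) per group.
#'
#' @param results a [run_benchmark()] data frame.
#' @return data frame with one row per condition x method.
#' @export
summarize_benchmark <- function(results) {
  grp <- interaction(results$condition, results$algorithm,
                     results$fit_model, drop = TRUE)
  rows <- lapply(split(results, grp), function(g) {
    ok <- g$status == "ok" & is.finite(g$est_flow)
    base <- g[1, c("condition", "shape", "modality", "sampling_rate",
                   "algorithm", "fit_model")]
    if (sum(ok) < 2) {
      return(cbind(base, n = sum(ok), n_failed = sum(!ok),
                   bias_ml_min = NA, loa_low_ml_min = NA, loa_high_ml_min = NA,
                   pearson_r = NA, mqe_mean_pct = NA, mqe_sem_pct = NA,
                   mqe_ci_low_pct = NA, mqe_ci_high_pct = NA))
    }
    ba <- bland_altman(g$est_flow[ok], g$true_flow[ok])
    cbind(base, n = ba$n, n_failed = sum(!ok),
          bias_ml_min = ba$bias_ml_min, loa_low_ml_min = ba$loa_low_ml_min,
          loa_high_ml_min = ba$loa_high_ml_min, pearson_r = ba$pearson_r,
          mqe_mean_pct = ba$mqe_mean_pct, mqe_sem_pct = ba$mqe_sem_pct,
          mqe_ci_low_pct = ba$mqe_ci_low_pct,
          mqe_ci_high_pct = ba$mqe_ci_high_pct)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
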