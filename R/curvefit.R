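# Parametric reference curves fitted to a time-density curve by coarse-to-fine
# RMSE minimisation. The fitted object is the package's model class: it is
# continuously evaluable, which is what gives the transit-time algorithms
# sub-frame resolution.

FIT_MODELS <- c("gamma_variate", "lagged_normal", "polynomial", "none")

#' Evaluate a gamma-variate curve
#'
#' \deqn{C(t) = K_a (t - AT)^{\alpha} e^{-(t - AT)/\beta}} for `t >= AT`, and 0
#' before the appearance time `AT`. The maximum lies at `AT + alpha * beta`;
#' the area under the curve is `Ka * beta^(alpha + 1) * gamma(alpha + 1)`.
#'
#' @param times evaluation times (s).
#' @param Ka scale (> 0, intensity units).
#' @param AT contrast appearance time (s, >= 0).
#' @param alpha shape (> 0, dimensionless).
#' @param beta decay scale (> 0, s).
#' @return curve values at `times`.
#' @export
gamma_variate <- function(times, Ka, AT, alpha, beta) {
  stopifnot(Ka > 0, alpha > 0, beta > 0, AT >= 0)
  dt <- times - AT
  out <- numeric(length(times))
  pos <- dt > 0
  out[pos] <- Ka * exp(alpha * log(dt[pos]) - dt[pos] / beta)
  out
}

#' Evaluate a lagged normal (exponentially modified Gaussian) curve
#'
#' Convolution of a Gaussian (mean `mu`, SD `sigma`) with a single exponential
#' of rate `lam`, scaled to total area `A`:
#' \deqn{C(t) = \frac{A}{2} K [1 + \mathrm{erf}(L)]}
#' with \eqn{K = \lambda e^{-\lambda t + \lambda\mu + \lambda^2\sigma^2/2}} and
#' \eqn{L = (t - \mu - \lambda\sigma^2)/\sqrt{2\sigma^2}}. The distribution's
#' mean is `mu + 1/lam`, its variance `sigma^2 + 1/lam^2`. Evaluation switches
#' to a scaled-complementary-error-function form where the direct exponent
#' would overflow (large `lam`).
#'
#' @param times evaluation times (s).
#' @param A area under the curve (> 0, intensity * s).
#' @param mu Gaussian mean (s).
#' @param sigma Gaussian SD (> 0, s).
#' @param lam exponential rate (> 0, 1/s).
#' @return curve values at `times`.
#' @export
lagged_normal <- function(times, A, mu, sigma, lam) {
  stopifnot(A > 0, sigma > 0, lam > 0)
  A * emg_density(times, mu, sigma, lam)
}

# scaled complementary error function exp(x^2) erfc(x); pracma's version
# loses to 0 * Inf beyond ~27, where the asymptotic series is already exact
# to machine precision
erfcx_safe <- function(x) {
  out <- numeric(length(x))
  big <- x > 25
  if (any(!big)) out[!big] <- pracma::erfcx(x[!big])
  if (any(big)) {
    xi2 <- 1 / (2 * x[big]^2)
    out[big] <- (1 - xi2 * (1 - 3 * xi2)) / (x[big] * sqrt(pi))
  }
  out
}

# unit-area EMG density; numerically stable for large lam
emg_density <- function(t, mu, sigma, lam) {
  L <- (t - mu - lam * sigma^2) / (sqrt(2) * sigma)
  out <- numeric(length(t))
  lo <- L <= 0
  # erfc-scaled branch: C = (lam/2) erfcx(-L) exp(-(t-mu)^2 / (2 sigma^2))
  if (any(lo))
    out[lo] <- 0.5 * lam * erfcx_safe(-L[lo]) *
      exp(-(t[lo] - mu)^2 / (2 * sigma^2))
  if (any(!lo)) {
    th <- t[!lo]
    out[!lo] <- 0.5 * lam * exp(-lam * (th - mu) + 0.5 * lam^2 * sigma^2) *
      (1 + pracma::erf(L[!lo]))
  }
  out
}

#' Fit a reference curve to a time-density curve
#'
#' Dispatches on `model`:
#' * `"gamma_variate"`, `"lagged_normal"`: coarse parameter grid followed by
#'   pattern-search refinement of the nonlinear parameters, minimising the
#'   root-mean-square error (RMSE) against the samples; the linear scale
#'   (`Ka` resp. `A`) is solved in closed form at every candidate.
#' * `"polynomial"`: ordinary least squares of a degree-`degree` polynomial
#'   (default 6) over `fit_window`; negative evaluations are clamped to 0.
#' * `"none"`: the raw samples wrapped with piecewise-linear evaluation
#'   (`rmse = 0`), zero outside the sampled window.
#'
#' The curve should be baseline-corrected ([baseline_correct()]) and must have
#' a positive peak; an all-zero or non-positive curve raises a "no bolus"
#' error.
#'
#' @param tdc a [extract_tdc()] curve, baseline-corrected.
#' @param model one of `"gamma_variate"`, `"lagged_normal"`, `"polynomial"`,
#'   `"none"`.
#' @param degree polynomial degree (polynomial model only).
#' @param fit_window `c(t_start, t_end)` fit window in seconds (polynomial
#'   model only); default the full acquisition.
#' @return an object of class `tdc_fit` with elements `model`, `params`,
#'   `rmse`, `tdc`.
#' @seealso [predict.tdc_fit()], [transit_time()]
#' @examples
#' t <- seq(0, 8, by = 0.1)
#' y <- gamma_variate(t, Ka = 2, AT = 1, alpha = 3, beta = 0.5)
#' fit <- fit_tdc(new_tdc_from_samples(t, y), "gamma_variate")
#' coef(fit)
#' @export
fit_tdc <- function(tdc, model = c("gamma_variate", "lagged_normal",
                                   "polynomial", "none"),
                    degree = 6L, fit_window = NULL) {
  stopifnot(inherits(tdc, "tdc"))
  model <- match.arg(model)
  switch(model,
         gamma_variate = fit_gamma_variate(tdc),
         lagged_normal = fit_lagged_normal(tdc),
         polynomial = fit_polynomial(tdc, degree = degree,
                                     fit_window = fit_window),
         none = fit_none(tdc))
}

#' Build a time-density curve directly from samples
#'
#' Convenience constructor for curves that did not come from an image (oracle
#' data, CSV imports). Times must be evenly spaced.
#'
#' @param times_s sample times (s), evenly spaced.
#' @param values curve values.
#' @param roi_label optional label.
#' @return a `tdc` object (marked baseline-corrected).
#' @export
new_tdc_from_samples <- function(times_s, values, roi_label = "") {
  dt <- if (length(times_s) > 1) diff(times_s)[1] else 1
  new_tdc(times_s, values, dt, roi_label, baseline_corrected = TRUE)
}

new_tdc_fit <- function(model, params, rmse, tdc, extra = list()) {
  structure(c(list(model = model, params = params, rmse = rmse, tdc = tdc),
              extra),
            class = "tdc_fit")
}

check_bolus <- function(tdc) {
  if (max(tdc$values) <= 0)
    stop("no bolus: curve has no positive peak")
  invisible(TRUE)
}

rms <- function(x) sqrt(mean(x^2))

# ---- coarse-to-fine RMSE minimisation --------------------------------------

# Pattern search: from x0, probe +/- step on each coordinate, take the best
# improving move; when none improves, shrink every step by `shrink`. Descent is
# monotone by construction. Stops when steps fall below step_tol (relative to
# their starting size) or the improvement stalls.
pattern_search <- function(f, x0, step0, lower, upper,
                           shrink = 5, step_tol = 1e-7, max_eval = 50000L) {
  x <- x0
  fx <- f(x)
  step <- step0
  evals <- 0L
  k <- length(x)
  while (evals < max_eval && any(step / step0 > step_tol)) {
    best_f <- fx
    best_x <- x
    for (i in seq_len(k)) {
      for (s in c(-1, 1)) {
        xc <- x
        xc[i] <- min(upper[i], max(lower[i], xc[i] + s * step[i]))
        if (xc[i] == x[i]) next
        fc <- f(xc)
        evals <- evals + 1L
        if (fc < best_f - 1e-15) { best_f <- fc; best_x <- xc }
      }
    }
    if (best_f < fx - 1e-12 * max(fx, 1e-30)) {
      x <- best_x
      fx <- best_f
    } else if (best_f < fx) {
      x <- best_x
      fx <- best_f
      step <- step / shrink
    } else {
      step <- step / shrink
    }
  }
  list(par = x, value = fx, evals = evals)
}

# RMSE of the best linear scale of shape g against y; scale must be positive.
linear_scale_rmse <- function(y, g) {
  den <- sum(g * g)
  if (!is.finite(den) || den <= 0) return(list(scale = NA_real_, rmse = Inf))
  sc <- sum(y * g) / den
  if (!is.finite(sc) || sc <= 0) return(list(scale = NA_real_, rmse = Inf))
  list(scale = sc, rmse = rms(y - sc * g))
}

#' @rdname fit_tdc
#' @export
fit_gamma_variate <- function(tdc) {
  stopifnot(inherits(tdc, "tdc"))
  check_bolus(tdc)
  t <- tdc$times_s - tdc$times_s[1]
  y <- tdc$values
  t_end <- t[length(t)]
  peak <- max(y)
  tpk <- t[which.max(y)]
  onset <- t[match(TRUE, y > 0.05 * peak)]  # 5%-of-peak onset heuristic

  obj <- function(p) {  # p = (AT, alpha, beta)
    g <- numeric(length(t))
    dt <- t - p[1]
    pos <- dt > 0
    if (!any(pos)) return(Inf)
    g[pos] <- exp(p[2] * log(dt[pos]) - dt[pos] / p[3])
    linear_scale_rmse(y, g)$rmse
  }

  at_grid <- sort(unique(c(seq(0, max(tpk - 1e-3, 0), length.out = 12), onset)))
  alpha_grid <- c(0.5, 1, 1.5, 2, 2.5, 3, 4, 5, 6, 8)
  best <- NULL
  for (at in at_grid) {
    for (al in alpha_grid) {
      b0 <- (tpk - at) / al
      if (!is.finite(b0) || b0 <= 0) next
      for (bf in c(0.5, 0.75, 1, 1.5, 2.25)) {
        p <- c(at, al, b0 * bf)
        v <- obj(p)
        # ties broken by smallest AT (grid is AT-ascending, keep strict <)
        if (is.null(best) || v < best$value) best <- list(par = p, value = v)
      }
    }
  }
  if (is.null(best) || !is.finite(best$value))
    stop("gamma-variate fit failed to bracket a finite-RMSE solution")
  step0 <- c(max(tdc$delta_t_s, tpk / 12), 0.75, 0.25 * best$par[3])
  ref <- pattern_search(obj, best$par, step0,
                        lower = c(0, 1e-3, 1e-4),
                        upper = c(t_end - 1e-6, 60, 10 * t_end))
  if (ref$value > best$value) ref <- best  # descent is monotone regardless
  p <- ref$par
  g <- numeric(length(t))
  dt <- t - p[1]
  g[dt > 0] <- exp(p[2] * log(dt[dt > 0]) - dt[dt > 0] / p[3])
  sc <- linear_scale_rmse(y, g)
  params <- list(Ka = sc$scale, AT = p[1] + tdc$times_s[1],
                 alpha = p[2], beta = p[3])
  new_tdc_fit("gamma_variate", params, sc$rmse, tdc)
}

#' @rdname fit_tdc
#' @export
fit_lagged_normal <- function(tdc) {
  stopifnot(inherits(tdc, "tdc"))
  check_bolus(tdc)
  t <- tdc$times_s
  y <- tdc$values
  yp <- pmax(y, 0)
  w <- sum(yp)
  m1 <- sum(t * yp) / w
  v2 <- max(sum((t - m1)^2 * yp) / w, (tdc$delta_t_s / 2)^2)
  s0 <- sqrt(v2)

  obj <- function(p) {  # p = (mu, sigma, log(lam))
    h <- emg_density(t, p[1], p[2], exp(p[3]))
    linear_scale_rmse(y, h)$rmse
  }

  best <- NULL
  for (lam in c(0.25, 0.5, 1, 2, 4, 8, 16) / s0) {
    mu0 <- m1 - 1 / lam
    sig0 <- sqrt(max(v2 - 1 / lam^2, (0.05 * s0)^2))
    for (sf in c(0.6, 1, 1.6)) {
      for (dm in c(-0.3, 0, 0.3) * s0) {
        p <- c(mu0 + dm, sig0 * sf, log(lam))
        v <- obj(p)
        if (is.null(best) || v < best$value ||
            (v == best$value && p[1] < best$par[1]))  # ties: smallest mu
          if (is.null(best) || v < best$value) best <- list(par = p, value = v)
      }
    }
  }
  if (is.null(best) || !is.finite(best$value))
    stop("lagged-normal fit failed to bracket a finite-RMSE solution")
  t_end <- t[length(t)]
  ref <- pattern_search(obj, best$par, c(0.25 * s0, 0.25 * s0, 0.5),
                        lower = c(t[1] - t_end, 1e-4, log(1e-3)),
                        upper = c(2 * t_end, 2 * t_end, log(1e4)))
  if (ref$value > best$value) ref <- best
  p <- ref$par
  h <- emg_density(t, p[1], p[2], exp(p[3]))
  sc <- linear_scale_rmse(y, h)
  params <- list(A = sc$scale, mu = p[1], sigma = p[2], lam = exp(p[3]))
  new_tdc_fit("lagged_normal", params, sc$rmse, tdc)
}

#' @rdname fit_tdc
#' @export
fit_polynomial <- function(tdc, degree = 6L, fit_window = NULL) {
  stopifnot(inherits(tdc, "tdc"))
  degree <- as.integer(degree)
  if (degree < 1L) stop("degree must be >= 1")
  if (is.null(fit_window)) fit_window <- range(tdc$times_s)
  if (fit_window[1] >= fit_window[2]) stop("fit_window must satisfy t_start < t_end")
  sel <- tdc$times_s >= fit_window[1] & tdc$times_s <= fit_window[2]
  if (sum(sel) < degree + 2L)
    stop("insufficient samples in fit window: need at least degree + 2")
  t <- tdc$times_s[sel]
  y <- tdc$values[sel]
  # fit in a centred/scaled basis for conditioning, then expand to raw powers
  ctr <- mean(fit_window)
  hw <- diff(fit_window) / 2
  ts <- (t - ctr) / hw
  X <- outer(ts, 0:degree, `^`)
  b <- qr.coef(qr(X), y)
  coefs <- scaled_poly_to_raw(b, ctr, hw)
  params <- list(coefficients = coefs, fit_window = fit_window)
  fitted_eval <- eval_poly_clamped(params, t)
  new_tdc_fit("polynomial", params, rms(y - fitted_eval), tdc,
              extra = list(degree = degree))
}

# expand sum_j b_j ((t - c)/h)^j into ascending raw powers of t
scaled_poly_to_raw <- function(b, ctr, hw) {
  deg <- length(b) - 1L
  out <- numeric(deg + 1L)
  for (j in 0:deg) {
    # ((t - c)/h)^j = h^-j * sum_k C(j,k) (-c)^(j-k) t^k
    k <- 0:j
    out[k + 1L] <- out[k + 1L] + b[j + 1L] * choose(j, k) * (-ctr)^(j - k) / hw^j
  }
  out
}

eval_poly_clamped <- function(params, times) {
  co <- params$coefficients
  inw <- times >= params$fit_window[1] & times <= params$fit_window[2]
  out <- numeric(length(times))
  if (any(inw)) {
    v <- outer(times[inw], seq_along(co) - 1L, `^`) %*% co
    out[inw] <- pmax(as.numeric(v), 0)  # clamped non-negative
  }
  out
}

fit_none <- function(tdc) {
  new_tdc_fit("none", NULL, 0, tdc)
}

# ---- methods ----------------------------------------------------------------

#' Evaluate a fitted reference curve at arbitrary times
#'
#' Pointwise model evaluation: the gamma variate is 0 before its appearance
#' time, the polynomial is 0 outside its fit window and clamped non-negative,
#' and the `"none"` model interpolates the raw samples linearly (0 outside the
#' sampled window, consistent with baseline-zero curves).
#'
#' @param object a `tdc_fit`.
#' @param times evaluation times (s); default the source sample times.
#' @param ... unused.
#' @return curve values at `times`.
#' @export
predict.tdc_fit <- function(object, times = object$tdc$times_s, ...) {
  p <- object$params
  switch(object$model,
    gamma_variate = gamma_variate(times, p$Ka, p$AT, p$alpha, p$beta),
    lagged_normal = lagged_normal(times, p$A, p$mu, p$sigma, p$lam),
    polynomial = eval_poly_clamped(p, times),
    none = approx(object$tdc$times_s, object$tdc$values, xout = times,
                  yleft = 0, yright = 0)$y)
}

#' @export
coef.tdc_fit <- function(object, ...) {
  if (object$model == "none") return(numeric(0))
  if (object$model == "polynomial")
    return(setNames(object$params$coefficients,
                    paste0("a", seq_along(object$params$coefficients))))
  unlist(object$params)
}

#' @export
residuals.tdc_fit <- function(object, ...) {
  object$tdc$values - predict(object)
}

#' @export
print.tdc_fit <- function(x, ...) {
  cat(sprintf("tdc_fit: %s model, rmse = %.4g\n", x$model, x$rmse))
  if (x$model != "none") {
    co <- coef(x)
    cat("  ", paste(sprintf("%s = %.4g", names(co), co), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.tdc_fit <- function(object, ...) {
  peak_t <- switch(object$model,
    gamma_variate = object$params$AT + object$params$alpha * object$params$beta,
    {
      grid <- seq(min(object$tdc$times_s), max(object$tdc$times_s),
                  length.out = 2001)
      grid[which.max(predict(object, grid))]
    })
  auc <- switch(object$model,
    gamma_variate = with(object$params, Ka * beta^(alpha + 1) * gamma(alpha + 1)),
    lagged_normal = object$params$A,
    NA_real_)
  out <- list(model = object$model, params = object$params, rmse = object$rmse,
              peak_time_s = peak_t, auc = auc,
              n = length(object$tdc$values))
  class(out) <- "summary.tdc_fit"
  out
}

#' @export
print.summary.tdc_fit <- function(x, ...) {
  cat(sprintf("Reference-curve fit (%s)\n", x$model))
  cat(sprintf("  samples: %d, rmse: %.4g\n", x$n, x$rmse))
  cat(sprintf("  peak time: %.4g s", x$peak_time_s))
  if (is.finite(x$auc)) cat(sprintf(", area under curve: %.4g", x$auc))
  cat("\n")
  invisible(x)
}

#' Simulate noisy time-density curves from a fitted model
#'
#' Draws replicate curves as the fitted values plus Gaussian noise with the
#' fit's residual RMSE — the parametric picture of "what another acquisition
#' of this bolus would look like".
#'
#' @param object a `tdc_fit`.
#' @param nsim number of replicate curves.
#' @param seed optional seed, set locally.
#' @param ... unused.
#' @return a matrix, one column per replicate, rows at the source sample
#'   times.
#' @export
simulate.tdc_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  matrix(mu + rnorm(length(mu) * nsim, 0, object$rmse),
         nrow = length(mu), ncol = nsim)
}

#' @export
plot.tdc_fit <- function(x, n_grid = 400, ...) {
  t <- x$tdc$times_s
  grid <- seq(min(t), max(t), length.out = n_grid)
  plot(t, x$tdc$values, xlab = "time (s)", ylab = "intensity (a.u.)",
       main = sprintf("%s fit (rmse %.3g)", x$model, x$rmse), ...)
  lines(grid, predict(x, grid), col = "firebrick", lwd = 2)
  invisible(x)
}

#' Export a fit as a JSON record
#'
#' @param fit a `tdc_fit`.
#' @param path optional destination; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to `path`).
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "tdc_fit"))
  js <- jsonlite::toJSON(list(model = fit$model, params = fit$params,
                              rmse = fit$rmse),
                         auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
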