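#' @export
print.turnover_fit <- function(x, digits = 4, ...) {
  cat("Isotope incorporation model: C(t) = Cn + (C0 - Cn) * exp(-(k + m) t)\n")
  cat(sprintf("  fit window: days %g-%g, n = %d observations\n",
              x$window[1], x$window[2], x$n_obs))
  cat(sprintf("  k  = %.*f day^-1 (supplied)\n", digits, x$k))
  cat(sprintf("  m  = %.*f day^-1 (SE %.*f)%s\n", digits, x$m, digits, x$m_se,
              if (x$boundary) "  [boundary]" else ""))
  cat(sprintf("  Cn = %.2f permil (%s), C0 = %.2f permil\n",
              x$cn, if (x$cn_estimated) "estimated" else "fixed", x$c0))
  cat(sprintf("  t50 = %.1f days;  contribution k/m = %.0f%% / %.0f%%\n",
              x$t50, x$k_contribution_pct, x$m_contribution_pct))
  invisible(x)
}

#' @export
coef.turnover_fit <- function(object, ...) {
  out <- c(k = object$k, m = object$m)
  if (object$cn_estimated) out <- c(out, cn = object$cn)
  out
}

#' @export
fitted.turnover_fit <- function(object, ...) {
  predict_d15n(object$c0, object$cn, object$k, object$m, object$data$day)
}

#' @export
residuals.turnover_fit <- function(object, ...) {
  object$data$d15n - fitted(object)
}

#' Predict delta-15N from a fitted turnover model
#'
#' @param object A `turnover_fit`.
#' @param newdata Data frame with a `day` column (default: the fitted days).
#' @param type `"full"` for the growth + turnover prediction, or
#'   `"growth_only"` for the trajectory with `m = 0`.
#' @param ... Unused.
#' @return Numeric vector of predicted \eqn{\delta^{15}}N (permil).
#' @export
predict.turnover_fit <- function(object, newdata = NULL,
                                 type = c("full", "growth_only"), ...) {
  type <- match.arg(type)
  day <- if (is.null(newdata)) object$data$day else newdata$day
  if (is.null(day)) stopf("`newdata` must have a `day` column")
  predict_d15n(object$c0, object$cn, object$k,
               if (type == "full") object$m else 0, day)
}

#' @export
summary.turnover_fit <- function(object, ...) {
  structure(list(fit = object,
                 residual_sd = object$sigma,
                 df_residual = object$n_obs - 1L - object$cn_estimated),
            class = "summary.turnover_fit")
}

#' @export
print.summary.turnover_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual SSE = %.4f permil^2, residual SD = %.3f permil on %d df\n",
              x$fit$sse, x$residual_sd, x$df_residual))
  invisible(x)
}

#' Plot a fitted turnover model
#'
#' Observed \eqn{\delta^{15}}N values, the fitted incorporation curve
#' (growth + metabolic turnover, rate `k + m`) and the curve attributable
#' to growth alone (`m = 0`), visualising how much of the isotopic shift
#' tissue accretion explains by itself.
#'
#' @param x A `turnover_fit`.
#' @param main Plot title.
#' @param ... Passed to `plot()`.
#' @return `x`, invisibly.
#' @export
plot.turnover_fit <- function(x, main = "Isotopic incorporation", ...) {
  tt <- seq(0, max(x$data$day), length.out = 200)
  full <- predict_d15n(x$c0, x$cn, x$k, x$m, tt)
  konly <- predict_d15n(x$c0, x$cn, x$k, 0, tt)
  ylim <- range(x$data$d15n, full, konly, x$cn)
  plot(x$data$day, x$data$d15n, pch = 18, col = "steelblue4",
       xlab = "Days after diet switch", ylab = expression(delta^15 * N ~ "(permil)"),
       ylim = ylim, main = main, ...)
  lines(tt, full, col = "darkorange2", lwd = 2)
  lines(tt, konly, col = "forestgreen", lwd = 2, lty = 2)
  legend("bottomright", bty = "n",
         legend = c("observed", "growth + turnover (k + m)", "growth only (k)"),
         pch = c(18, NA, NA), lty = c(NA, 1, 2), lwd = c(NA, 2, 2),
         col = c("steelblue4", "darkorange2", "forestgreen"))
  invisible(x)
}

#' Simulate replicate series from a fitted turnover model
#'
#' Draws new \eqn{\delta^{15}}N observations at the fitted time points from
#' the fitted curve plus Gaussian noise at the residual standard deviation.
#'
#' @param object A `turnover_fit`.
#' @param nsim Number of replicate series.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of `nsim` [isotope_series()] objects.
#' @export
simulate.turnover_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  lapply(seq_len(nsim), function(i)
    isotope_series(object$data$day, mu + rnorm(length(mu), 0, object$sigma),
                   treatment = "simulated", c0 = object$c0, cn = object$cn))
}

#' Bootstrap a turnover fit
#'
#' Case-resampling bootstrap: within each time point, observations are
#' resampled with replacement and the model refit, giving sampling
#' distributions for `m` and `t50` and percentile confidence intervals.
#' Replicates whose resample retains fewer than 3 distinct time points are
#' skipped and counted (this cannot happen with within-time-point
#' resampling, but the guard keeps degenerate inputs honest).
#'
#' @param fit A [fit_turnover()] result.
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @param level Confidence level for the percentile intervals.
#' @return An object of class `turnover_boot`: list with vectors `m` and
#'   `t50`, the percentile intervals `m_ci` and `t50_ci`, `m_se` (bootstrap
#'   SD), and `n_skipped`.
#' @export
bootstrap_turnover <- function(fit, n_boot = 1000, seed = 1, level = 0.95) {
  stopifnot(inherits(fit, "turnover_fit"))
  if (n_boot < 100) stopf("`n_boot` must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  dat <- fit$data
  by_day <- split(seq_len(nrow(dat)), dat$day)
  m_draws <- rep(NA_real_, n_boot)
  skipped <- 0L
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(by_day, function(i) i[sample.int(length(i),
                                                          replace = TRUE)]))
    res <- dat[idx, ]
    if (sum(!duplicated(res$day)) < 3L) { skipped <- skipped + 1L; next }
    fb <- tryCatch(
      fit_turnover(res, k = fit$k, window = fit$window, c0 = fit$c0,
                   cn = if (fit$cn_estimated) NULL else fit$cn,
                   estimate_cn = fit$cn_estimated,
                   m_starts = unique(c(fit$m, 0.01))),
      error = function(e) NULL)
    if (is.null(fb)) { skipped <- skipped + 1L; next }
    m_draws[b] <- fb$m
  }
  m_ok <- m_draws[!is.na(m_draws)]
  t50_ok <- log(2) / (fit$k + m_ok)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  structure(list(m = m_ok, t50 = t50_ok,
                 m_ci = quantile(m_ok, probs, names = FALSE),
                 t50_ci = quantile(t50_ok, probs, names = FALSE),
                 m_se = sd(m_ok), level = level,
                 n_boot = n_boot, n_skipped = skipped),
            class = "turnover_boot")
}

#' @export
print.turnover_boot <- function(x, ...) {
  cat(sprintf("Turnover bootstrap (%d replicates, %d skipped)\n",
              x$n_boot, x$n_skipped))
  cat(sprintf("  m   : SD %.4f, %g%% CI [%.4f, %.4f] day^-1\n",
              x$m_se, 100 * x$level, x$m_ci[1], x$m_ci[2]))
  cat(sprintf("  t50 : %g%% CI [%.2f, %.2f] days\n",
              100 * x$level, x$t50_ci[1], x$t50_ci[2]))
  invisible(x)
}

#' Confidence intervals for a turnover fit
#'
#' Percentile bootstrap intervals for `m` and `t50` via
#' [bootstrap_turnover()].
#'
#' @param object A `turnover_fit`.
#' @param parm Ignored (both parameters are returned).
#' @param level Confidence level.
#' @param n_boot,seed Passed to [bootstrap_turnover()].
#' @param ... Unused.
#' @return Matrix with rows `m` and `t50` and the two interval bounds.
#' @export
confint.turnover_fit <- function(object, parm, level = 0.95,
                                 n_boot = 1000, seed = 1, ...) {
  bt <- bootstrap_turnover(object, n_boot = n_boot, seed = seed, level = level)
  out <- rbind(m = bt$m_ci, t50 = bt$t50_ci)
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  out
}
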