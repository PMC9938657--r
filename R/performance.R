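#' Zootechnical performance metrics
#'
#' Scalar formulas used to summarise an aquaculture feeding trial:
#' weight gain, specific growth rate, feed conversion ratio, feed saving
#' and survival.  All are exact textbook formulas; rounding is left to the
#' presentation layer.
#'
#' @param fw,iw Final and initial weight (g); must be positive where logs
#'   are taken.
#' @param days Trial length (days, > 0).
#' @param fi Cumulative feed offered per shrimp (g).
#' @param fi_treatment,fi_control Cumulative feed intake per shrimp (g) in a
#'   restricted treatment and in the control.
#' @param final_n,initial_n Final and initial number of shrimp; the
#'   individuals removed for sampling must already be excluded from
#'   `initial_n`.
#'
#' @return A numeric vector.
#' @name performance_metrics
NULL

#' @describeIn performance_metrics Weight gain
#'   `100 * (FW - IW) / IW` (%).
#' @export
weight_gain_pct <- function(fw, iw) {
  if (any(iw <= 0)) stopf("initial weight must be > 0")
  100 * (fw - iw) / iw
}

#' @describeIn performance_metrics Specific growth rate
#'   `100 * (ln FW - ln IW) / days` (% day^-1; natural logarithm).
#' @export
specific_growth_rate <- function(fw, iw, days) {
  if (any(fw <= 0) || any(iw <= 0)) stopf("weights must be > 0")
  if (any(days <= 0)) stopf("`days` must be > 0")
  100 * (log(fw) - log(iw)) / days
}

#' @describeIn performance_metrics Feed conversion ratio `FI / (FW - IW)`;
#'   `NaN` with a warning when no weight was gained.
#' @export
feed_conversion_ratio <- function(fi, fw, iw) {
  out <- fi / (fw - iw)
  if (any(fw <= iw)) {
    warning("FCR undefined where final weight does not exceed initial weight",
            call. = FALSE)
    out[fw <= iw] <- NaN
  }
  out
}

#' @describeIn performance_metrics Feed saving of a treatment relative to
#'   the control, `100 * (FI_control - FI_treatment) / FI_control` (%).
#' @export
feed_saving_pct <- function(fi_treatment, fi_control) {
  if (any(fi_control <= 0)) stopf("control feed intake must be > 0")
  100 * (fi_control - fi_treatment) / fi_control
}

#' @describeIn performance_metrics Survival
#'   `100 * final_n / initial_n` (%).
#' @export
survival_pct <- function(final_n, initial_n) {
  if (any(final_n < 0) || any(initial_n < 0)) stopf("counts must be >= 0")
  if (any(initial_n <= 0)) stopf("`initial_n` must be > 0")
  if (any(final_n > initial_n))
    stopf("`final_n` cannot exceed `initial_n` after sampling adjustment")
  100 * final_n / initial_n
}

#' Per-tank performance records from weight and feed tables
#'
#' Computes, for every tank, initial and final mean weight, weight gain,
#' SGR, cumulative feed intake per shrimp, FCR and survival -- one record
#' per tank, the unit of replication for the trial's statistics.
#'
#' @param weights Long data frame with columns `treatment`, `tank`, `day`,
#'   `weight` (and optionally `individual`), e.g. from [simulate_weights()].
#' @param feed Long data frame with columns `treatment`, `tank`, `day`,
#'   `offered_g`, e.g. from [simulate_feed()]; may be `NULL`, in which case
#'   `fi` and `fcr` are `NA`.
#' @param survival Optional named vector of survival percentages per
#'   treatment (default 100 for all).
#' @param t_start,t_end Days defining the trial window; default the first
#'   and last day present in `weights`.
#' @return Data frame of class `performance_records`, one row per tank,
#'   with columns `treatment`, `tank`, `initial_weight`, `final_weight`,
#'   `wg_pct`, `sgr`, `fi`, `fcr`, `survival_pct`.
#' @seealso [performance_summary()] for the treatment-level mean +/- SD view.
#' @export
performance_table <- function(weights, feed = NULL, survival = NULL,
                              t_start = min(weights$day),
                              t_end = max(weights$day)) {
  need <- c("treatment", "tank", "day", "weight")
  if (!all(need %in% names(weights)))
    stopf("`weights` must have columns %s", paste(need, collapse = ", "))
  for (d in c(t_start, t_end))
    if (!d %in% weights$day) stopf("day %g is not present in `weights`", d)

  w0 <- weights[weights$day == t_start, ]
  wf <- weights[weights$day == t_end, ]
  iw <- aggregate(weight ~ treatment + tank, w0, mean)
  fw <- aggregate(weight ~ treatment + tank, wf, mean)
  n0 <- aggregate(weight ~ treatment + tank, w0, length)
  rec <- merge(iw, fw, by = c("treatment", "tank"),
               suffixes = c("_initial", "_final"))
  rec <- merge(rec, setNames(n0, c("treatment", "tank", "n_shrimp")),
               by = c("treatment", "tank"))
  names(rec)[names(rec) == "weight_initial"] <- "initial_weight"
  names(rec)[names(rec) == "weight_final"] <- "final_weight"

  rec$wg_pct <- weight_gain_pct(rec$final_weight, rec$initial_weight)
  rec$sgr <- specific_growth_rate(rec$final_weight, rec$initial_weight,
                                  t_end - t_start)
  if (!is.null(feed)) {
    fi <- aggregate(offered_g ~ treatment + tank, feed, sum)
    rec <- merge(rec, fi, by = c("treatment", "tank"))
    rec$fi <- rec$offered_g / rec$n_shrimp
    rec$offered_g <- NULL
    rec$fcr <- feed_conversion_ratio(rec$fi, rec$final_weight, rec$initial_weight)
  } else {
    rec$fi <- NA_real_
    rec$fcr <- NA_real_
  }
  rec$survival_pct <- if (is.null(survival)) 100 else {
    miss <- setdiff(unique(rec$treatment), names(survival))
    if (length(miss)) stopf("no survival value for treatment %s", miss[1])
    unname(survival[rec$treatment])
  }
  rec$n_shrimp <- NULL
  rec <- rec[order(rec$treatment, rec$tank), ]
  rownames(rec) <- NULL
  class(rec) <- c("performance_records", "data.frame")
  rec
}

#' Treatment-level performance summary (mean +/- SD over tanks)
#'
#' Averages per-tank records within treatment, the tank being the
#' experimental unit (n = number of tanks).  Set `pooled = TRUE` to instead
#' recompute ratio metrics from pooled treatment means (mean FW, mean IW,
#' mean FI); pooled and per-tank summaries differ slightly because the mean
#' of per-tank ratios is not the ratio of means.
#'
#' @param records Output of [performance_table()].
#' @param pooled Recompute WG/SGR/FCR from treatment-mean weights instead of
#'   averaging per-tank values.  Default `FALSE`.
#' @return Data frame with one row per treatment: mean and SD of each
#'   metric, plus `n_tanks`.
#' @export
performance_summary <- function(records, pooled = FALSE) {
  metrics <- c("initial_weight", "final_weight", "wg_pct", "sgr", "fi",
               "fcr", "survival_pct")
  mean_df <- aggregate(records[metrics], list(treatment = records$treatment),
                       mean)
  sd_df <- aggregate(records[metrics], list(treatment = records$treatment),
                     sd)
  n_df <- aggregate(list(n_tanks = records$tank),
                    list(treatment = records$treatment),
                    function(x) length(unique(x)))
  if (pooled) {
    mean_df$wg_pct <- weight_gain_pct(mean_df$final_weight, mean_df$initial_weight)
    mean_df$fcr <- feed_conversion_ratio(mean_df$fi, mean_df$final_weight,
                                         mean_df$initial_weight)
  }
  names(sd_df)[-1] <- paste0(names(sd_df)[-1], "_sd")
  out <- merge(merge(mean_df, sd_df, by = "treatment"), n_df, by = "treatment")
  out[order(out$treatment), ]
}

#' Interval specific growth rate per tank
#'
#' SGR computed from per-tank mean weights at two sampling days, used to
#' contrast growth during the restriction week with growth during the
#' refeeding window.
#'
#' @param weights Long weight table as in [performance_table()].
#' @param t_start,t_end Days bounding the interval; both must be present in
#'   the table.
#' @return Data frame with columns `treatment`, `tank`, `sgr` (% day^-1).
#' @export
interval_sgr <- function(weights, t_start, t_end) {
  if (t_end <= t_start) stopf("`t_end` must exceed `t_start`")
  for (d in c(t_start, t_end))
    if (!d %in% weights$day) stopf("day %g is not present in `weights`", d)
  w1 <- aggregate(weight ~ treatment + tank,
                  weights[weights$day == t_start, ], mean)
  w2 <- aggregate(weight ~ treatment + tank,
                  weights[weights$day == t_end, ], mean)
  m <- merge(w1, w2, by = c("treatment", "tank"), suffixes = c("_1", "_2"))
  data.frame(treatment = m$treatment, tank = m$tank,
             sgr = specific_growth_rate(m$weight_2, m$weight_1,
                                        t_end - t_start))
}
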