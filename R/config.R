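#' Define a feeding-regime treatment
#'
#' A treatment is a feeding regime applied from day 0 of the trial: an
#' optional restriction phase (a fraction of the satiation ration withheld
#' for `restriction_days`), a compensatory refeeding window during which
#' growth runs above the baseline rate, and satiation feeding thereafter.
#' Growth is piecewise exponential with one instantaneous rate per phase.
#'
#' @param name Treatment label (e.g. `"Control"`, `"T3"`).
#' @param restriction_days Length of the restriction phase in days (>= 0).
#' @param restriction_fraction Fraction of the satiation ration withheld
#'   during restriction; `0.70` means the animals receive 30% of the
#'   control ration.
#' @param base_k Exponential growth rate (day^-1) under normal satiation
#'   feeding.  The default 0.0583 takes a 0.44 g juvenile to ~3.38 g in
#'   35 days.
#' @param restricted_k Growth rate (day^-1) during the restriction phase;
#'   must not exceed `base_k`.
#' @param compensatory_k Growth rate (day^-1) during the refeeding recovery
#'   window; must be at least `base_k`.
#' @param recovery_end_day Day on which compensatory growth ends and the
#'   rate returns to `base_k`.
#' @param true_m Metabolic nitrogen turnover rate (day^-1) used when
#'   simulating isotope series for this regime.
#' @param d15n_enrichment Optional additive \eqn{\delta^{15}}N offset (permil)
#'   applied during the restriction phase, emulating enrichment by nutrient
#'   recycling under restriction.  Default 0 (off).
#' @param feed_fraction Baseline daily ration as a fraction of tank biomass.
#' @param refeed_fraction Daily ration fraction during the hyperphagic
#'   refeeding window (end of restriction to `hyperphagia_end_day`).
#' @param hyperphagia_end_day Last day of elevated intake after refeeding.
#' @param survival_pct Expected survival (%) for this regime; survival is a
#'   configuration constant, not a simulated process.
#'
#' @return An object of class `treatment_config`.
#' @seealso [default_treatments()], [sim_config()]
#' @export
treatment_config <- function(name,
                             restriction_days = 0,
                             restriction_fraction = 0.70,
                             base_k = 0.0583,
                             restricted_k = if (restriction_days > 0) 0.030 else base_k,
                             compensatory_k = base_k,
                             recovery_end_day = if (restriction_days > 0) 28 else restriction_days,
                             true_m = 0.033,
                             d15n_enrichment = 0,
                             feed_fraction = 0.11,
                             refeed_fraction = feed_fraction,
                             hyperphagia_end_day = 14,
                             survival_pct = 100) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stopf("`name` must be a non-empty string")
  check_number(restriction_days, "restriction_days", nonneg = TRUE)
  check_number(restriction_fraction, "restriction_fraction")
  if (restriction_fraction < 0 || restriction_fraction > 1)
    stopf("`restriction_fraction` must lie in [0, 1] (got %g)", restriction_fraction)
  check_number(base_k, "base_k")
  check_number(restricted_k, "restricted_k")
  check_number(compensatory_k, "compensatory_k")
  if (restricted_k > base_k)
    stopf("`restricted_k` (%g) must not exceed `base_k` (%g)", restricted_k, base_k)
  if (compensatory_k < base_k)
    stopf("`compensatory_k` (%g) must be at least `base_k` (%g)", compensatory_k, base_k)
  check_number(recovery_end_day, "recovery_end_day", nonneg = TRUE)
  if (recovery_end_day < restriction_days)
    stopf("`recovery_end_day` (%g) must be >= `restriction_days` (%g)",
          recovery_end_day, restriction_days)
  check_number(true_m, "true_m", nonneg = TRUE)
  check_number(d15n_enrichment, "d15n_enrichment")
  check_number(feed_fraction, "feed_fraction", nonneg = TRUE)
  check_number(refeed_fraction, "refeed_fraction", nonneg = TRUE)
  check_number(hyperphagia_end_day, "hyperphagia_end_day", nonneg = TRUE)
  check_number(survival_pct, "survival_pct", nonneg = TRUE)
  if (survival_pct > 100) stopf("`survival_pct` cannot exceed 100")

  structure(
    list(name = name,
         restriction_days = restriction_days,
         restriction_fraction = restriction_fraction,
         base_k = base_k,
         restricted_k = restricted_k,
         compensatory_k = compensatory_k,
         recovery_end_day = recovery_end_day,
         true_m = true_m,
         d15n_enrichment = d15n_enrichment,
         feed_fraction = feed_fraction,
         refeed_fraction = refeed_fraction,
         hyperphagia_end_day = hyperphagia_end_day,
         survival_pct = survival_pct),
    class = "treatment_config")
}

#' @export
print.treatment_config <- function(x, ...) {
  cat(sprintf("<treatment_config> %s\n", x$name))
  if (x$restriction_days > 0) {
    cat(sprintf("  restriction : %g days at %.0f%% of ration\n",
                x$restriction_days, 100 * (1 - x$restriction_fraction)))
    cat(sprintf("  growth k    : restricted %.4f, compensatory %.4f (to day %g), base %.4f day^-1\n",
                x$restricted_k, x$compensatory_k, x$recovery_end_day, x$base_k))
  } else {
    cat(sprintf("  growth k    : %.4f day^-1 (no restriction)\n", x$base_k))
  }
  cat(sprintf("  turnover m  : %.4f day^-1 (simulation truth)\n", x$true_m))
  invisible(x)
}

#' The three regimes of the compensatory growth trial
#'
#' Returns the default `Control`, `T3` and `T6` treatment configurations:
#' satiation feeding throughout, and 70% feed restriction for 3 or 6 days
#' followed by refeeding.  Growth-phase rates are calibrated so that, with
#' zero noise, final weights are ~3.38, 3.47 and 3.23 g from a 0.44 g start
#' and restricted groups dip below the control early and converge by day 35;
#' simulation turnover rates are 0.033, 0.018 and 0.008 day^-1.
#'
#' @return A named list of three [treatment_config()] objects.
#' @export
default_treatments <- function() {
  list(
    Control = treatment_config("Control", true_m = 0.033),
    T3 = treatment_config("T3", restriction_days = 3, compensatory_k = 0.0627,
                          true_m = 0.018, refeed_fraction = 0.13,
                          survival_pct = 97),
    T6 = treatment_config("T6", restriction_days = 6, compensatory_k = 0.0639,
                          true_m = 0.008, refeed_fraction = 0.14,
                          survival_pct = 93)
  )
}

#' Trial-level simulation settings
#'
#' Holds the cohort structure and observation model shared by all
#' treatments: tank layout, initial weights, the sampling schedule, the
#' isotopic baseline and asymptote, and noise levels.
#'
#' @param n_tanks Replicate tanks per treatment.
#' @param shrimp_per_tank Shrimp stocked per tank.
#' @param initial_weight_mean,initial_weight_sd Mean and SD (g) of
#'   individual initial weights (drawn from a normal truncated at 0).
#' @param sampling_days Integer days on which weights and muscle
#'   \eqn{\delta^{15}}N are sampled; strictly increasing, starting at 0.
#' @param trial_days Trial length in days.
#' @param d15n_baseline Muscle \eqn{\delta^{15}}N (permil) at day 0, set by
#'   the pre-conditioning diet.
#' @param d15n_asymptote Muscle \eqn{\delta^{15}}N (permil) at equilibrium
#'   with the trial diet.
#' @param d15n_noise_sd SD (permil) of additive Gaussian noise on simulated
#'   \eqn{\delta^{15}}N observations.
#' @param isotope_reps Individuals sampled per treatment per sampling day
#'   for isotope analysis.
#' @param weight_noise_sd SD of multiplicative lognormal observation noise
#'   on weights (on the log scale).
#' @param seed Integer seed controlling the generator stream.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_tanks = 3,
                       shrimp_per_tank = 12,
                       initial_weight_mean = 0.44,
                       initial_weight_sd = 0.03,
                       sampling_days = c(0, 3, 6, 9, 14, 21, 28, 35),
                       trial_days = 35,
                       d15n_baseline = 8.53,
                       d15n_asymptote = 14.31,
                       d15n_noise_sd = 0.2,
                       isotope_reps = 3,
                       weight_noise_sd = 0.05,
                       seed = 1L) {
  check_number(n_tanks, "n_tanks", positive = TRUE)
  check_number(shrimp_per_tank, "shrimp_per_tank", positive = TRUE)
  check_number(initial_weight_mean, "initial_weight_mean", positive = TRUE)
  check_number(initial_weight_sd, "initial_weight_sd", nonneg = TRUE)
  if (!is.numeric(sampling_days) || length(sampling_days) < 2L)
    stopf("`sampling_days` must be a numeric vector of at least 2 days")
  if (sampling_days[1] != 0)
    stopf("`sampling_days` must start at day 0")
  if (any(diff(sampling_days) <= 0))
    stopf("`sampling_days` must be strictly increasing")
  check_number(trial_days, "trial_days", positive = TRUE)
  if (max(sampling_days) > trial_days)
    stopf("`sampling_days` extend beyond `trial_days`")
  check_number(d15n_baseline, "d15n_baseline")
  check_number(d15n_asymptote, "d15n_asymptote")
  if (d15n_asymptote == d15n_baseline)
    stopf("`d15n_asymptote` must differ from `d15n_baseline`")
  check_number(d15n_noise_sd, "d15n_noise_sd", nonneg = TRUE)
  check_number(isotope_reps, "isotope_reps", positive = TRUE)
  check_number(weight_noise_sd, "weight_noise_sd", nonneg = TRUE)
  check_number(seed, "seed")

  structure(
    list(n_tanks = as.integer(n_tanks),
         shrimp_per_tank = as.integer(shrimp_per_tank),
         initial_weight_mean = initial_weight_mean,
         initial_weight_sd = initial_weight_sd,
         sampling_days = as.numeric(sampling_days),
         trial_days = trial_days,
         d15n_baseline = d15n_baseline,
         d15n_asymptote = d15n_asymptote,
         d15n_noise_sd = d15n_noise_sd,
         isotope_reps = as.integer(isotope_reps),
         weight_noise_sd = weight_noise_sd,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d tanks x %d shrimp, W0 ~ N(%.2f, %.2f^2) g, %g-day trial\n",
              x$n_tanks, x$shrimp_per_tank, x$initial_weight_mean,
              x$initial_weight_sd, x$trial_days))
  cat(sprintf("  sampling days: %s\n", paste(x$sampling_days, collapse = ", ")))
  cat(sprintf("  d15N: %.2f -> %.2f permil, noise sd %.2f, %d reps/day, seed %d\n",
              x$d15n_baseline, x$d15n_asymptote, x$d15n_noise_sd,
              x$isotope_reps, x$seed))
  invisible(x)
}

#' Instantaneous growth rate of a regime at time t
#'
#' @param treatment A [treatment_config()].
#' @param t Vector of times (days).
#' @return Growth rate k (day^-1) applying at each `t`.
#' @export
phase_rate <- function(treatment, t) {
  stopifnot(inherits(treatment, "treatment_config"))
  ifelse(t < treatment$restriction_days, treatment$restricted_k,
         ifelse(t < treatment$recovery_end_day, treatment$compensatory_k,
                treatment$base_k))
}

#' Cumulative log growth of a regime
#'
#' Integral of the piecewise-constant growth rate from 0 to `t`, so that the
#' noise-free weight trajectory is `W0 * exp(log_growth(treatment, t))`.
#'
#' @inheritParams phase_rate
#' @return Dimensionless cumulative log growth at each `t`.
#' @export
log_growth <- function(treatment, t) {
  stopifnot(inherits(treatment, "treatment_config"))
  if (any(t < 0)) stopf("times must be >= 0")
  rd <- treatment$restriction_days
  red <- treatment$recovery_end_day
  treatment$restricted_k * pmin(t, rd) +
    treatment$compensatory_k * pmax(0, pmin(t, red) - rd) +
    treatment$base_k * pmax(0, t - red)
}
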