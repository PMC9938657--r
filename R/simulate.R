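#' Construct a delta-15N time series
#'
#' The input container for [fit_turnover()]: observed muscle
#' \eqn{\delta^{15}}N values (permil) against time since the diet switch,
#' together with the isotopic baseline `c0` and (optionally) the asymptote
#' `cn` of the new diet.
#'
#' @param day Numeric vector of sampling times (days, >= 0).
#' @param d15n Numeric vector of observed \eqn{\delta^{15}}N values (permil).
#' @param treatment Label for the series.
#' @param c0 Baseline \eqn{\delta^{15}}N at day 0 (permil).
#' @param cn Asymptotic \eqn{\delta^{15}}N (permil), or `NULL` if it is to be
#'   co-estimated during fitting.
#' @return A data frame of class `isotope_series` with columns `day` and
#'   `d15n` and attributes `treatment`, `c0`, `cn`.
#' @export
isotope_series <- function(day, d15n, treatment = "series", c0, cn = NULL) {
  if (length(day) != length(d15n))
    stopf("`day` and `d15n` must have the same length")
  if (any(!is.finite(day)) || any(day < 0))
    stopf("`day` must be finite and >= 0")
  if (any(!is.finite(d15n)))
    stopf("`d15n` values must be finite")
  check_number(c0, "c0")
  if (!is.null(cn)) check_number(cn, "cn")
  structure(data.frame(day = as.numeric(day), d15n = as.numeric(d15n)),
            treatment = treatment, c0 = c0, cn = cn,
            class = c("isotope_series", "data.frame"))
}

#' Simulate individual weight trajectories
#'
#' Each individual's weight follows the regime's piecewise-exponential
#' trajectory `W0 * exp(log_growth(t))`, with initial weights drawn from a
#' normal distribution truncated at zero and multiplicative lognormal
#' observation noise per weighing.
#'
#' @param treatment A [treatment_config()].
#' @param sim A [sim_config()].
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @return Long data frame with columns `treatment`, `tank`, `individual`,
#'   `day`, `weight` (g), one row per (tank, day, individual).
#' @export
simulate_weights <- function(treatment, sim, seed = sim$seed) {
  stopifnot(inherits(treatment, "treatment_config"), inherits(sim, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n_ind <- sim$n_tanks * sim$shrimp_per_tank

  w0 <- rnorm(n_ind, sim$initial_weight_mean, sim$initial_weight_sd)
  bad <- which(w0 <= 0)
  while (length(bad)) {  # truncate the initial-weight distribution at 0
    w0[bad] <- rnorm(length(bad), sim$initial_weight_mean, sim$initial_weight_sd)
    bad <- which(w0 <= 0)
  }

  days <- sim$sampling_days
  g <- log_growth(treatment, days)
  out <- expand.grid(individual = seq_len(sim$shrimp_per_tank),
                     tank = seq_len(sim$n_tanks),
                     day = days, KEEP.OUT.ATTRS = FALSE)
  idx <- (out$tank - 1L) * sim$shrimp_per_tank + out$individual
  noise <- if (sim$weight_noise_sd > 0)
    exp(rnorm(nrow(out), 0, sim$weight_noise_sd)) else 1
  out$weight <- w0[idx] * exp(g[match(out$day, days)]) * noise
  data.frame(treatment = treatment$name,
             tank = sprintf("%s_tank%d", treatment$name, out$tank),
             individual = out$individual,
             day = out$day,
             weight = out$weight)
}

#' Simulate a delta-15N incorporation series
#'
#' Evaluates the incorporation model with the regime's phase-appropriate
#' growth rate, i.e. \eqn{C(t) = C_n + (C_0 - C_n) e^{-(G(t) + m t)}} where
#' `G(t)` is the cumulative log growth of the regime, and adds i.i.d.
#' Gaussian observation noise.  An optional additive enrichment offset
#' (`treatment$d15n_enrichment`) applies during the restriction phase.
#'
#' @inheritParams simulate_weights
#' @return An [isotope_series()] with `isotope_reps` values per sampling day.
#' @export
simulate_isotopes <- function(treatment, sim, seed = sim$seed) {
  stopifnot(inherits(treatment, "treatment_config"), inherits(sim, "sim_config"))
  if (sim$d15n_noise_sd < 0) stopf("`d15n_noise_sd` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  days <- rep(sim$sampling_days, each = sim$isotope_reps)
  # incorporation model with time-varying k: exponent is the cumulative
  # growth + turnover exposure G(t) + m*t rather than (k + m)*t
  expo <- log_growth(treatment, days) + treatment$true_m * days
  mu <- sim$d15n_asymptote +
    (sim$d15n_baseline - sim$d15n_asymptote) * exp(-expo)
  mu <- mu + treatment$d15n_enrichment * (days < treatment$restriction_days)
  obs <- mu + if (sim$d15n_noise_sd > 0) rnorm(length(mu), 0, sim$d15n_noise_sd) else 0
  isotope_series(day = days, d15n = obs, treatment = treatment$name,
                 c0 = sim$d15n_baseline, cn = sim$d15n_asymptote)
}

#' Simulate daily feed offered per tank
#'
#' Deterministic ration schedule: each day's offered feed is a fraction of
#' the tank's (noise-free, expected) biomass.  The fraction equals
#' `feed_fraction * (1 - restriction_fraction)` during restriction,
#' `refeed_fraction` from the end of restriction through
#' `hyperphagia_end_day` (hyperphagia), and `feed_fraction` otherwise.
#'
#' @inheritParams simulate_weights
#' @param weights Optional weight table for this treatment (from
#'   [simulate_weights()]); when given, each tank's biomass trajectory is
#'   interpolated (log-linearly) from its own mean weights, so feed intake
#'   varies between replicate tanks.  Otherwise the noise-free expected
#'   biomass is used and all tanks receive identical rations.
#' @return Long data frame with columns `treatment`, `tank`, `day`,
#'   `offered_g`; days run 0 to `trial_days - 1`.
#' @export
simulate_feed <- function(treatment, sim, weights = NULL) {
  stopifnot(inherits(treatment, "treatment_config"), inherits(sim, "sim_config"))
  days <- seq(0, sim$trial_days - 1)
  frac <- ifelse(days < treatment$restriction_days,
                 treatment$feed_fraction * (1 - treatment$restriction_fraction),
                 ifelse(days <= treatment$hyperphagia_end_day &
                          treatment$restriction_days > 0,
                        treatment$refeed_fraction,
                        treatment$feed_fraction))
  if (is.null(weights)) {
    biomass <- sim$shrimp_per_tank * sim$initial_weight_mean *
      exp(log_growth(treatment, days))
    out <- do.call(rbind, lapply(seq_len(sim$n_tanks), function(i)
      data.frame(tank = sprintf("%s_tank%d", treatment$name, i),
                 day = days, offered_g = frac * biomass)))
  } else {
    wt <- weights[weights$treatment == treatment$name, ]
    if (!nrow(wt)) stopf("`weights` has no rows for treatment \"%s\"", treatment$name)
    out <- do.call(rbind, lapply(split(wt, wt$tank), function(tk) {
      mw <- aggregate(weight ~ day, tk, mean)
      logw <- stats::approx(mw$day, log(mw$weight), xout = days, rule = 2)$y
      data.frame(tank = tk$tank[1], day = days,
                 offered_g = frac * sim$shrimp_per_tank * exp(logw))
    }))
  }
  rownames(out) <- NULL
  data.frame(treatment = treatment$name, out)
}

#' Default synthetic taxa profile for OTU simulation
#'
#' A named probability vector over OTUs with a `taxonomy` attribute
#' (semicolon-separated phylum;class;order;family;genus lineages).  The
#' community is dominated by Proteobacteria (~90% of reads), with smaller
#' Bacteroidota, Firmicutes and Actinobacteriota fractions, and geometric
#' rank-abundance decay within each phylum -- the broad structure reported
#' for the shrimp digestive tract.
#'
#' @param n_otus Total number of OTUs across the four phyla.
#' @return Named numeric probability vector summing to 1, with attribute
#'   `taxonomy`.
#' @export
default_taxa_profile <- function(n_otus = 60) {
  check_number(n_otus, "n_otus", positive = TRUE)
  if (n_otus < 8) stopf("`n_otus` must be at least 8")
  phyla <- data.frame(
    phylum = c("Proteobacteria", "Bacteroidota", "Firmicutes", "Actinobacteriota"),
    class = c("Gammaproteobacteria", "Bacteroidia", "Bacilli", "Actinobacteria"),
    order = c("Vibrionales", "Flavobacteriales", "Lactobacillales", "Micrococcales"),
    family = c("Vibrionaceae", "Flavobacteriaceae", "Streptococcaceae", "Microbacteriaceae"),
    share = c(0.90, 0.05, 0.03, 0.02))
  n_per <- pmax(2L, round(n_otus * phyla$share))
  n_per[1] <- n_otus - sum(n_per[-1])
  probs <- character(0); taxonomy <- character(0); p <- numeric(0)
  for (i in seq_len(nrow(phyla))) {
    w <- 0.7^(seq_len(n_per[i]) - 1)        # geometric rank-abundance decay
    w <- phyla$share[i] * w / sum(w)
    p <- c(p, w)
    taxonomy <- c(taxonomy, sprintf("%s;%s;%s;%s;Genus_%s%02d",
                                    phyla$phylum[i], phyla$class[i],
                                    phyla$order[i], phyla$family[i],
                                    substr(phyla$phylum[i], 1, 3), seq_len(n_per[i])))
  }
  names(p) <- sprintf("Otu%03d", seq_along(p))
  structure(p / sum(p), taxonomy = taxonomy)
}

#' Construct an OTU count table
#'
#' @param counts Non-negative integer matrix, OTUs in rows, samples in
#'   columns.
#' @param taxonomy Character vector of semicolon-separated lineage strings
#'   (phylum;class;order;family;genus), one per OTU.  Missing lower ranks
#'   may be `"unclassified"`.
#' @param sample_meta Optional data frame of per-sample metadata (e.g.
#'   treatment, day), one row per sample column.
#' @return An object of class `otu_counts`.
#' @export
otu_counts <- function(counts, taxonomy, sample_meta = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("`counts` must be non-negative integers")
  if (length(taxonomy) != nrow(counts))
    stopf("`taxonomy` must have one lineage per OTU row (%d != %d)",
          length(taxonomy), nrow(counts))
  if (!is.null(sample_meta) && nrow(sample_meta) != ncol(counts))
    stopf("`sample_meta` must have one row per sample column")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("Otu%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("S%d", seq_len(ncol(counts)))
  structure(list(counts = counts, taxonomy = as.character(taxonomy),
                 sample_meta = sample_meta),
            class = "otu_counts")
}

#' @export
print.otu_counts <- function(x, ...) {
  cat(sprintf("<otu_counts> %d OTUs x %d samples, depth %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(colSums(x$counts)), collapse = "/")))
  invisible(x)
}

#' Simulate an OTU count table
#'
#' Draws per-sample community compositions from a Dirichlet distribution
#' centred on `taxa_profile` (concentration `overdispersion`; smaller values
#' give more sample-to-sample variation) and then counts from a multinomial
#' at fixed sequencing depth -- the standard Dirichlet-multinomial model for
#' overdispersed amplicon counts.
#'
#' @param n_samples Number of samples (columns).
#' @param taxa_profile Named probability vector over OTUs summing to 1
#'   (within 1e-6), e.g. [default_taxa_profile()].
#' @param depth Sequencing depth per sample (column sum).
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @param overdispersion Dirichlet concentration parameter.
#' @param sample_meta Optional per-sample metadata data frame.
#' @return An [otu_counts()] object; every column sums to `depth`.
#' @export
simulate_otu_table <- function(n_samples, taxa_profile = default_taxa_profile(),
                               depth = 5000, seed = NULL,
                               overdispersion = 200, sample_meta = NULL) {
  check_number(n_samples, "n_samples", positive = TRUE)
  check_number(depth, "depth", positive = TRUE)
  check_number(overdispersion, "overdispersion", positive = TRUE)
  if (abs(sum(taxa_profile) - 1) > 1e-6)
    stopf("`taxa_profile` must sum to 1 (got %.8f)", sum(taxa_profile))
  if (any(taxa_profile < 0)) stopf("`taxa_profile` must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  counts <- vapply(seq_len(n_samples), function(j) {
    g <- rgamma(length(taxa_profile), shape = taxa_profile * overdispersion)
    if (sum(g) == 0) g[which.max(taxa_profile)] <- 1
    rmultinom(1, size = depth, prob = g / sum(g))[, 1]
  }, numeric(length(taxa_profile)))
  counts <- matrix(counts, nrow = length(taxa_profile))  # keep dims for 1 OTU
  rownames(counts) <- names(taxa_profile)
  colnames(counts) <- sprintf("S%d", seq_len(n_samples))
  taxonomy <- attr(taxa_profile, "taxonomy")
  if (is.null(taxonomy)) taxonomy <- names(taxa_profile)
  otu_counts(counts, taxonomy, sample_meta)
}

#' Simulate a full trial cohort
#'
#' Generates weights, feed, isotope series and (optionally) OTU tables for
#' every treatment from a single seed, in a fixed order, so the whole
#' dataset is reproducible from `(treatments, sim, seed)` alone.
#'
#' @param treatments Named list of [treatment_config()]s; default
#'   [default_treatments()].
#' @param sim A [sim_config()].
#' @param otus If `TRUE`, also simulate an OTU table per treatment
#'   (4 samples at depth 5000 from [default_taxa_profile()]).
#' @return A list of class `cohort_dataset` with elements `weights`, `feed`
#'   (row-bound data frames), `isotopes` (named list of [isotope_series()])
#'   and `otus` (named list of [otu_counts()] or `NULL`).
#' @export
simulate_cohort <- function(treatments = default_treatments(),
                            sim = sim_config(), otus = FALSE) {
  stopifnot(inherits(sim, "sim_config"))
  if (is.null(names(treatments)))
    names(treatments) <- vapply(treatments, `[[`, "", "name")
  weights <- list(); feed <- list(); iso <- list(); otu <- list()
  for (i in seq_along(treatments)) {
    tr <- treatments[[i]]
    weights[[i]] <- simulate_weights(tr, sim, seed = substream_seed(sim$seed, 10 * i + 1))
    feed[[i]] <- simulate_feed(tr, sim, weights = weights[[i]])
    iso[[tr$name]] <- simulate_isotopes(tr, sim, seed = substream_seed(sim$seed, 10 * i + 2))
    if (otus)
      otu[[tr$name]] <- simulate_otu_table(
        4, seed = substream_seed(sim$seed, 10 * i + 3),
        sample_meta = data.frame(treatment = rep(tr$name, 4), day = 35))
  }
  structure(list(weights = do.call(rbind, weights),
                 feed = do.call(rbind, feed),
                 isotopes = iso,
                 otus = if (otus) otu else NULL,
                 treatments = treatments, sim = sim),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d treatments (%s), %d weight rows, %d feed rows\n",
              length(x$treatments), paste(names(x$treatments), collapse = ", "),
              nrow(x$weights), nrow(x$feed)))
  invisible(x)
}
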