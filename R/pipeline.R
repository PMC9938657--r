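#' Table-3-shaped turnover report across treatments
#'
#' For every treatment: growth rate `k` over the fit window (from per-
#' treatment mean weights), the fitted metabolic turnover rate `m` with
#' bootstrap uncertainty, the growth/turnover contribution split and the
#' residence half-time `t50` with its bootstrap interval.  Treatments are
#' declared significantly different in `m` when the percentile interval of
#' the bootstrap difference excludes zero, and lettered accordingly.
#'
#' @param isotopes Named list of [isotope_series()] (one per treatment).
#' @param weights Long weight table covering the same treatments.
#' @param window Fit window in days, default `c(7, 35)`.
#' @param estimate_cn Co-estimate the asymptote, see [fit_turnover()].
#' @param n_boot Bootstrap replicates per treatment.
#' @param seed Integer seed for the bootstrap.
#' @param alpha Significance level for the letter display.
#' @return List with `table` (one row per treatment: `k`, `m`, `m_se`,
#'   `m_lwr`, `m_upr`, `k_contribution_pct`, `m_contribution_pct`, `t50`,
#'   `t50_lwr`, `t50_upr`, `letters`), `fits` and `boots` (named lists).
#' @export
turnover_report <- function(isotopes, weights, window = c(7, 35),
                            estimate_cn = FALSE, n_boot = 500, seed = 1,
                            alpha = 0.05) {
  trt <- names(isotopes)
  if (is.null(trt)) stopf("`isotopes` must be a named list (one series per treatment)")
  fits <- list(); boots <- list(); rows <- list()
  for (i in seq_along(trt)) {
    name <- trt[i]
    wt <- weights[weights$treatment == name, ]
    if (!nrow(wt)) stopf("no weights for treatment \"%s\"", name)
    k <- window_growth_rate(wt, window)
    fit <- fit_turnover(isotopes[[name]], k = k, window = window,
                        estimate_cn = estimate_cn)
    bt <- bootstrap_turnover(fit, n_boot = n_boot,
                             seed = substream_seed(seed, i))
    fits[[name]] <- fit
    boots[[name]] <- bt
    rows[[name]] <- data.frame(
      treatment = name, k = k, m = fit$m, m_se = bt$m_se,
      m_lwr = bt$m_ci[1], m_upr = bt$m_ci[2],
      k_contribution_pct = fit$k_contribution_pct,
      m_contribution_pct = fit$m_contribution_pct,
      t50 = fit$t50, t50_lwr = bt$t50_ci[1], t50_upr = bt$t50_ci[2])
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  if (length(trt) >= 2) {
    pr <- utils::combn(trt, 2)
    pairs <- data.frame(group1 = pr[1, ], group2 = pr[2, ])
    pairs$significant <- vapply(seq_len(ncol(pr)), function(j) {
      a <- boots[[pr[1, j]]]$m; b <- boots[[pr[2, j]]]$m
      nmin <- min(length(a), length(b))
      d <- a[seq_len(nmin)] - b[seq_len(nmin)]
      ci <- quantile(d, c(alpha / 2, 1 - alpha / 2), names = FALSE)
      ci[1] > 0 || ci[2] < 0
    }, TRUE)
    means <- setNames(tab$m, tab$treatment)
    tab$letters <- compact_letter_display(pairs, means)[tab$treatment]
  } else {
    tab$letters <- "a"
  }
  list(table = tab, fits = fits, boots = boots)
}

#' Growth rate over a day window from a weight table
#'
#' Fits the exponential growth model over the sampling days inside the
#' window by regressing the log of the mean weight on day; the slope is
#' `k` (day^-1).  With exactly two days this reduces to [growth_rate_k()].
#'
#' @param weights Weight table (one treatment) with columns `day`, `weight`.
#' @param window Length-2 numeric, inclusive day window.
#' @return Growth rate k (day^-1).
#' @export
window_growth_rate <- function(weights, window = c(7, 35)) {
  mw <- aggregate(weight ~ day, weights[weights$day >= window[1] &
                                          weights$day <= window[2], ], mean)
  if (nrow(mw) < 2)
    stopf("need at least 2 sampling days inside the window [%g, %g]",
          window[1], window[2])
  unname(coef(stats::lm(log(weight) ~ day, data = mw))["day"])
}

# ---- tabular I/O ------------------------------------------------------

#' Read trial tables from CSV
#'
#' Readers for the package's tidy CSV schemas: weights
#' (`treatment, tank, individual, day, weight`), feed
#' (`treatment, tank, day, offered_g`) and isotopes
#' (`treatment, day, d15n` plus baseline/asymptote columns `c0`, `cn`).
#'
#' @param path CSV file path.
#' @return `read_weights_csv` and `read_feed_csv`: data frames;
#'   `read_isotopes_csv`: named list of [isotope_series()].
#' @name trial_io
#' @export
read_weights_csv <- function(path) {
  x <- utils::read.csv(path)
  need <- c("treatment", "tank", "day", "weight")
  if (!all(need %in% names(x)))
    stopf("%s must have columns %s", path, paste(need, collapse = ", "))
  x
}

#' @rdname trial_io
#' @export
read_feed_csv <- function(path) {
  x <- utils::read.csv(path)
  need <- c("treatment", "tank", "day", "offered_g")
  if (!all(need %in% names(x)))
    stopf("%s must have columns %s", path, paste(need, collapse = ", "))
  x
}

#' @rdname trial_io
#' @export
read_isotopes_csv <- function(path) {
  x <- utils::read.csv(path)
  need <- c("treatment", "day", "d15n", "c0", "cn")
  if (!all(need %in% names(x)))
    stopf("%s must have columns %s", path, paste(need, collapse = ", "))
  lapply(split(x, x$treatment), function(d)
    isotope_series(d$day, d$d15n, treatment = d$treatment[1],
                   c0 = d$c0[1], cn = d$cn[1]))
}

#' Write an OTU table as TSV
#'
#' Rows are OTUs with a `taxonomy` column, remaining columns are samples --
#' the layout emitted by amplicon pipelines.
#'
#' @param otu An [otu_counts()] object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_otu_tsv <- function(otu, path) {
  stopifnot(inherits(otu, "otu_counts"))
  df <- data.frame(otu_id = rownames(otu$counts), taxonomy = otu$taxonomy,
                   otu$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an OTU TSV written by [write_otu_tsv()]
#'
#' @param path TSV path.
#' @return An [otu_counts()] object.
#' @export
read_otu_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!all(c("otu_id", "taxonomy") %in% names(df)))
    stopf("%s must have `otu_id` and `taxonomy` columns", path)
  counts <- as.matrix(df[, setdiff(names(df), c("otu_id", "taxonomy")), drop = FALSE])
  rownames(counts) <- df$otu_id
  otu_counts(counts, df$taxonomy)
}

# ---- pipeline ---------------------------------------------------------

#' Default pipeline configuration
#'
#' @return Named list of the options [run_pipeline()] understands, at their
#'   defaults: simulate a three-regime cohort, fit over days 7-35 with the
#'   asymptote fixed, 500 bootstrap replicates, alpha 0.05.
#' @export
default_run_config <- function() {
  list(simulate = TRUE,
       weights_csv = NULL, feed_csv = NULL, isotopes_csv = NULL,
       otu_tsv = NULL,
       simulate_otus = FALSE,
       window = c(7, 35),
       estimate_cn = FALSE,
       n_boot = 500,
       alpha = 0.05,
       sim = list())
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> performance -> turnover -> group
#' comparison -> diversity, writing report tables and a structured log to
#' `out_dir`.  Outputs: `weights.csv`, `feed.csv`, `isotopes.csv` (when
#' simulating), `performance.tsv`/`performance.json` (per-tank records and
#' mean +/- SD summary with letters), `turnover.tsv`/`turnover.json`
#' (k, m, contributions, t50 with bootstrap intervals and letters),
#' `decomposition_<treatment>.csv`, `diversity.tsv` and
#' `relative_abundance_phylum.tsv` (when OTU data are present) and
#' `run_log.json` echoing the fully resolved configuration, so any run is
#' reproducible from its log alone.  TSV tables carry presentation rounding
#' (WG and contributions to integers, t50 to one decimal); the JSON twins
#' keep full precision.
#'
#' @param config A list overriding entries of [default_run_config()], or a
#'   path to a YAML/JSON file of the same shape.
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed; mandatory when simulating.
#' @return Invisibly, a list with the in-memory results (`performance`,
#'   `turnover`, `comparisons`, `diversity`, `log`).
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_run_config(), config)
  if (isTRUE(cfg$simulate) && is.null(seed))
    stopf("`seed` is mandatory when simulating")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(seed = seed, package_version = as.character(utils::packageVersion("isoturn")),
              config = cfg, stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stopf("stage \"%s\" failed: %s", name, conditionMessage(e)))
    log$stages[[name]] <<- "ok"
    res
  }

  # ---- inputs
  otu <- NULL
  if (isTRUE(cfg$simulate)) {
    inputs <- stage("simulate", {
      sim_args <- utils::modifyList(cfg$sim, list(seed = seed))
      sim <- do.call(sim_config, sim_args)
      cohort <- simulate_cohort(default_treatments(), sim,
                                otus = isTRUE(cfg$simulate_otus))
      utils::write.csv(cohort$weights, file.path(out_dir, "weights.csv"),
                       row.names = FALSE)
      utils::write.csv(cohort$feed, file.path(out_dir, "feed.csv"),
                       row.names = FALSE)
      iso_df <- do.call(rbind, lapply(cohort$isotopes, function(s)
        data.frame(treatment = attr(s, "treatment"), day = s$day,
                   d15n = s$d15n, c0 = attr(s, "c0"), cn = attr(s, "cn"))))
      utils::write.csv(iso_df, file.path(out_dir, "isotopes.csv"),
                       row.names = FALSE)
      if (!is.null(cohort$otus)) {
        for (nm in names(cohort$otus))
          write_otu_tsv(cohort$otus[[nm]],
                        file.path(out_dir, sprintf("otus_%s.tsv", nm)))
      }
      survival <- vapply(cohort$treatments, `[[`, 0, "survival_pct")
      names(survival) <- names(cohort$treatments)
      list(weights = cohort$weights, feed = cohort$feed,
           isotopes = cohort$isotopes,
           otus = cohort$otus, survival = survival)
    })
    otu <- if (!is.null(inputs$otus)) inputs$otus[[1]] else NULL
    if (length(inputs$otus) > 1) {
      counts <- do.call(cbind, lapply(names(inputs$otus), function(nm) {
        m <- inputs$otus[[nm]]$counts
        colnames(m) <- paste(nm, colnames(m), sep = "_")
        m
      }))
      meta <- do.call(rbind, lapply(inputs$otus, `[[`, "sample_meta"))
      otu <- otu_counts(counts, inputs$otus[[1]]$taxonomy, meta)
    }
  } else {
    inputs <- stage("load", {
      if (is.null(cfg$weights_csv) || is.null(cfg$isotopes_csv))
        stopf("`weights_csv` and `isotopes_csv` are required when not simulating")
      list(weights = read_weights_csv(cfg$weights_csv),
           feed = if (!is.null(cfg$feed_csv)) read_feed_csv(cfg$feed_csv),
           isotopes = read_isotopes_csv(cfg$isotopes_csv),
           otus = NULL, survival = NULL)
    })
    if (!is.null(cfg$otu_tsv)) otu <- stage("load_otus", read_otu_tsv(cfg$otu_tsv))
  }

  # ---- performance
  perf <- stage("performance", {
    rec <- performance_table(inputs$weights, inputs$feed,
                             survival = inputs$survival)
    summ <- performance_summary(rec)
    list(records = rec, summary = summ)
  })

  # ---- group comparisons on per-tank metrics
  comparisons <- stage("compare", {
    out <- list()
    for (metric in c("wg_pct", "sgr", "fi", "fcr")) {
      v <- perf$records[[metric]]
      if (all(is.na(v))) next
      gc <- group_compare(v, perf$records$treatment, alpha = cfg$alpha)
      out[[metric]] <- list(f_stat = gc$f_stat, df = c(gc$df_between, gc$df_within),
                            p_value = gc$p_value,
                            means = as.list(gc$group_means),
                            letters = as.list(gc$letters))
    }
    out
  })

  # ---- turnover
  turn <- stage("turnover", {
    trep <- turnover_report(inputs$isotopes, inputs$weights,
                            window = cfg$window, estimate_cn = cfg$estimate_cn,
                            n_boot = cfg$n_boot, seed = substream_seed(seed, 777),
                            alpha = cfg$alpha)
    for (nm in names(trep$fits))
      utils::write.csv(decompose_turnover(trep$fits[[nm]]),
                       file.path(out_dir, sprintf("decomposition_%s.csv", nm)),
                       row.names = FALSE)
    trep
  })

  # ---- diversity (optional)
  diversity <- NULL
  if (!is.null(otu)) {
    diversity <- stage("diversity", {
      div <- alpha_diversity(otu)
      utils::write.table(div, file.path(out_dir, "diversity.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      ra <- relative_abundance(otu, "phylum")
      utils::write.table(data.frame(phylum = rownames(ra), round(ra, 4),
                                    check.names = FALSE),
                         file.path(out_dir, "relative_abundance_phylum.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      div
    })
  } else {
    log$stages[["diversity"]] <- "skipped (no OTU input)"
  }

  # ---- write reports
  stage("write_reports", {
    summ <- perf$summary
    pres <- data.frame(
      treatment = summ$treatment,
      wg_pct = round(summ$wg_pct), wg_sd = round(summ$wg_pct_sd),
      sgr = round(summ$sgr, 2), sgr_sd = round(summ$sgr_sd, 2),
      fi = round(summ$fi, 2), fi_sd = round(summ$fi_sd, 2),
      fcr = round(summ$fcr, 2), fcr_sd = round(summ$fcr_sd, 2),
      survival_pct = round(summ$survival_pct), n_tanks = summ$n_tanks)
    utils::write.table(pres, file.path(out_dir, "performance.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(records = perf$records, summary = summ, comparisons = comparisons),
      file.path(out_dir, "performance.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")

    tt <- turn$table
    pres_t <- data.frame(
      treatment = tt$treatment,
      k = round(tt$k, 3), m = round(tt$m, 3),
      k_contribution_pct = round(tt$k_contribution_pct),
      m_contribution_pct = round(tt$m_contribution_pct),
      t50 = round(tt$t50, 1),
      t50_lwr = round(tt$t50_lwr, 1), t50_upr = round(tt$t50_upr, 1),
      letters = tt$letters)
    utils::write.table(pres_t, file.path(out_dir, "turnover.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(tt, file.path(out_dir, "turnover.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    NULL
  })

  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(performance = perf, turnover = turn,
                 comparisons = comparisons, diversity = diversity, log = log))
}
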