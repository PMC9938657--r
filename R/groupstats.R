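#' One-way analysis of variance
#'
#' Classical between/within decomposition for a single grouping factor,
#' the comparison used throughout the trial for performance metrics,
#' digestive-enzyme style endpoints and turnover parameters.
#'
#' @param values Numeric vector of measurements.
#' @param group Grouping labels, same length as `values`.
#' @return List with `f_stat`, `df_between`, `df_within`, `p_value` and
#'   `group_means` (named, in group order).
#' @export
one_way_anova <- function(values, group) {
  group <- as.character(group)
  check_groups(values, group)
  g <- factor(group)
  fit <- aov(values ~ g)
  tab <- anova(fit)
  list(f_stat = tab$`F value`[1],
       df_between = tab$Df[1],
       df_within = tab$Df[2],
       p_value = tab$`Pr(>F)`[1],
       group_means = tapply(values, g, mean))
}

# internal: shared validation for grouped samples
check_groups <- function(values, group) {
  if (length(values) != length(group))
    stopf("`values` and `group` must have the same length")
  if (any(!is.finite(values))) stopf("`values` must be finite")
  n <- table(group)
  if (length(n) < 2L) stopf("need at least 2 groups")
  small <- names(n)[n < 2]
  if (length(small))
    stopf("group \"%s\" has fewer than 2 values", small[1])
  invisible(TRUE)
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise mean differences with studentized-range intervals and
#' adjusted p-values at the within-group degrees of freedom; unequal group
#' sizes use the Tukey-Kramer denominator.
#'
#' @inheritParams one_way_anova
#' @param alpha Significance level in (0, 1).
#' @return Data frame with columns `group1`, `group2`, `diff`, `lwr`,
#'   `upr`, `p_adj`, `significant`.
#' @export
tukey_hsd <- function(values, group, alpha = 0.05) {
  group <- as.character(group)
  check_groups(values, group)
  if (alpha <= 0 || alpha >= 1) stopf("`alpha` must be in (0, 1)")
  g <- factor(group)
  tk <- TukeyHSD(aov(values ~ g), conf.level = 1 - alpha)$g
  pair <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(group1 = vapply(pair, `[`, "", 1L),
             group2 = vapply(pair, `[`, "", 2L),
             diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
             p_adj = tk[, "p adj"],
             significant = tk[, "p adj"] < alpha,
             row.names = NULL)
}

#' Compact letter display from pairwise comparisons
#'
#' Assigns letters to groups such that two groups share at least one letter
#' if and only if their pairwise comparison was not significant.  Letter
#' classes are formed by insert-and-absorb and then, for up to 10 groups,
#' reduced to a provably minimal clique cover of the non-significance graph
#' by exhaustive search over maximal cliques.  Letters are assigned in
#' order of descending group mean, ties broken by group label.
#'
#' @param pairs Data frame with columns `group1`, `group2`, `significant`
#'   covering every unordered pair of groups, e.g. from [tukey_hsd()].
#' @param means Named numeric vector of group means (names = groups);
#'   used for letter ordering.
#' @return Named character vector of letter strings, one per group.
#' @export
compact_letter_display <- function(pairs, means) {
  groups <- names(means)
  if (is.null(groups)) stopf("`means` must be a named vector")
  need <- utils::combn(sort(groups), 2)
  have <- unique(apply(cbind(pairs$group1, pairs$group2), 1,
                       function(p) paste(sort(p), collapse = "\r")))
  missing <- apply(need, 2, paste, collapse = "\r")
  missing <- setdiff(missing, have)
  if (length(missing))
    stopf("pairwise table is missing pair: %s",
          gsub("\r", " vs ", missing[1]))

  sig <- pairs[pairs$significant, c("group1", "group2"), drop = FALSE]
  classes <- cld_insert_absorb(groups, sig)
  if (length(groups) <= 10L) {
    exact <- cld_minimal_cover(groups, sig)
    if (length(exact) < length(classes)) classes <- exact
  }

  # order classes so the highest-mean groups take the earliest letters
  ord <- order(-vapply(classes, function(cl) max(means[cl]), 0),
               vapply(classes, function(cl) min(cl), ""))
  classes <- classes[ord]
  letters_out <- vapply(groups, function(gp) {
    paste(letters[which(vapply(classes, function(cl) gp %in% cl, TRUE))],
          collapse = "")
  }, "")
  letters_out
}

# internal: insert-and-absorb letter classes
cld_insert_absorb <- function(groups, sig_pairs) {
  classes <- list(groups)
  for (i in seq_len(nrow(sig_pairs))) {
    a <- sig_pairs$group1[i]; b <- sig_pairs$group2[i]
    new <- list()
    for (cl in classes) {
      if (a %in% cl && b %in% cl)
        new <- c(new, list(setdiff(cl, a), setdiff(cl, b)))
      else new <- c(new, list(cl))
    }
    new <- new[vapply(new, length, 0L) > 0]
    # absorb classes contained in another class
    keep <- rep(TRUE, length(new))
    for (j in seq_along(new)) {
      if (!keep[j]) next
      for (l in seq_along(new)) {
        if (j == l || !keep[l]) next
        if (all(new[[j]] %in% new[[l]]) &&
            (length(new[[j]]) < length(new[[l]]) || j > l)) {
          keep[j] <- FALSE
          break
        }
      }
    }
    classes <- new[keep]
  }
  classes
}

# internal: minimal clique cover of the non-significance graph by
# exhaustive search (feasible for <= 10 groups).  Every group must appear
# in a class, every non-significant pair must share a class, and no class
# may contain a significant pair.
cld_minimal_cover <- function(groups, sig_pairs) {
  n <- length(groups)
  sig_key <- if (nrow(sig_pairs)) {
    paste(pmin(sig_pairs$group1, sig_pairs$group2),
          pmax(sig_pairs$group1, sig_pairs$group2))
  } else character(0)
  is_clique <- function(cl) {
    if (length(cl) < 2) return(TRUE)
    pr <- utils::combn(sort(cl), 2)
    !any(paste(pr[1, ], pr[2, ]) %in% sig_key)
  }
  # all clique subsets, then keep the maximal ones
  subsets <- lapply(seq_len(2^n - 1), function(mask)
    groups[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
  cliques <- Filter(is_clique, subsets)
  maximal <- Filter(function(cl) {
    !any(vapply(cliques, function(other)
      length(other) > length(cl) && all(cl %in% other), TRUE))
  }, cliques)
  nonsig <- utils::combn(sort(groups), 2)
  nonsig_keys <- setdiff(paste(nonsig[1, ], nonsig[2, ]), sig_key)
  covers <- function(sel) {
    cls <- maximal[sel]
    if (!all(groups %in% unlist(cls))) return(FALSE)
    for (key in nonsig_keys) {
      pr <- strsplit(key, " ", fixed = TRUE)[[1]]
      if (!any(vapply(cls, function(cl) all(pr %in% cl), TRUE))) return(FALSE)
    }
    TRUE
  }
  for (size in seq_along(maximal)) {
    combos <- utils::combn(length(maximal), size, simplify = FALSE)
    for (sel in combos) if (covers(sel)) return(maximal[sel])
  }
  maximal  # unreachable: the full set always covers
}

#' Compare groups: ANOVA, Tukey HSD and letters in one call
#'
#' The trial's standard comparison: one-way ANOVA, then Tukey multiple
#' comparisons at level `alpha`, then a compact letter display ordered by
#' descending group mean.
#'
#' @inheritParams tukey_hsd
#' @return Object of class `group_comparison`: list with `f_stat`,
#'   `df_between`, `df_within`, `p_value`, `group_means`, `tukey`
#'   (the pairwise table), `letters` and `alpha`.
#' @examples
#' x <- c(1, 2, 3, 2, 3, 4, 6, 7, 8)
#' g <- rep(c("A", "B", "C"), each = 3)
#' group_compare(x, g)
#' @export
group_compare <- function(values, group, alpha = 0.05) {
  a <- one_way_anova(values, group)
  tk <- tukey_hsd(values, group, alpha = alpha)
  lett <- compact_letter_display(tk, a$group_means)
  structure(c(a, list(tukey = tk, letters = lett, alpha = alpha)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  p_txt <- if (x$p_value < 0.001) "p < 0.001" else sprintf("p = %.3f", x$p_value)
  cat(sprintf("One-way ANOVA: F_%d,%d = %.2f, %s (alpha = %g)\n",
              x$df_between, x$df_within, x$f_stat, p_txt, x$alpha))
  ord <- order(-x$group_means)
  for (gp in names(x$group_means)[ord])
    cat(sprintf("  %-10s mean = %10.4f  %s\n", gp, x$group_means[gp],
                x$letters[gp]))
  invisible(x)
}
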