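# Shared fixtures and independent oracles used across the suite.

# noise-free trial settings (weights and isotopes deterministic)
zero_noise_sim <- function(...) {
  sim_config(initial_weight_sd = 0, weight_noise_sd = 0, d15n_noise_sd = 0, ...)
}

# brute-force 1-D grid search minimiser of the incorporation-model SSE;
# independent of the package's optimiser
grid_search_m <- function(day, d15n, k, c0, cn, grid = seq(0, 0.2, by = 1e-5)) {
  pred <- outer(grid, day, function(m, t) cn + (c0 - cn) * exp(-(k + m) * t))
  sse <- rowSums((sweep(pred, 2, d15n))^2)
  grid[which.min(sse)]
}

# textbook one-way ANOVA F from first principles
manual_anova_f <- function(values, group) {
  g <- split(values, group)
  grand <- mean(values)
  ssb <- sum(vapply(g, function(x) length(x) * (mean(x) - grand)^2, 0))
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), 0))
  df1 <- length(g) - 1
  df2 <- length(values) - length(g)
  (ssb / df1) / (ssw / df2)
}

# permutation null of the pairwise studentized-range-style statistic:
# returns TRUE if the observed |mean difference| of the pair is extreme
# at level alpha under group-label permutation (within the full sample)
perm_pair_significant <- function(values, group, pair, alpha = 0.05,
                                  n_perm = 4000, seed = 99) {
  set.seed(seed)
  keep <- group %in% pair
  v <- values[keep]; g <- group[keep]
  obs <- abs(mean(v[g == pair[1]]) - mean(v[g == pair[2]]))
  null <- replicate(n_perm, {
    gp <- sample(g)
    abs(mean(v[gp == pair[1]]) - mean(v[gp == pair[2]]))
  })
  mean(null >= obs) < alpha
}

# exhaustive minimal letter count: smallest number of subsets of groups
# such that every group is covered, every non-significant pair shares a
# subset, and no subset contains a significant pair.  Searches over ALL
# subsets (not just maximal cliques), so it is independent of the
# implementation's search space.
exhaustive_min_letters <- function(groups, sig_pairs) {
  n <- length(groups)
  all_subsets <- lapply(seq_len(2^n - 1), function(mask)
    groups[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
  key <- function(a, b) paste(min(a, b), max(a, b))
  sig_keys <- if (nrow(sig_pairs))
    mapply(key, sig_pairs$group1, sig_pairs$group2) else character(0)
  ok_subset <- vapply(all_subsets, function(s) {
    if (length(s) < 2) return(TRUE)
    pr <- combn(s, 2)
    !any(mapply(key, pr[1, ], pr[2, ]) %in% sig_keys)
  }, TRUE)
  candidates <- all_subsets[ok_subset]
  pairs_all <- combn(groups, 2)
  nonsig <- Filter(Negate(is.null), lapply(seq_len(ncol(pairs_all)), function(j) {
    p <- pairs_all[, j]
    if (key(p[1], p[2]) %in% sig_keys) NULL else p
  }))
  valid <- function(sel) {
    cls <- candidates[sel]
    if (!all(groups %in% unlist(cls))) return(FALSE)
    all(vapply(nonsig, function(p)
      any(vapply(cls, function(cl) all(p %in% cl), TRUE)), TRUE))
  }
  for (size in 1:n) {
    for (sel in combn(length(candidates), size, simplify = FALSE))
      if (valid(sel)) return(size)
  }
  n
}

# random significance pattern that is realisable (transitively consistent
# is not required for CLD, any symmetric pattern is allowed)
random_sig_pairs <- function(groups, p_sig, seed) {
  set.seed(seed)
  pr <- combn(groups, 2)
  data.frame(group1 = pr[1, ], group2 = pr[2, ],
             significant = runif(ncol(pr)) < p_sig)
}
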