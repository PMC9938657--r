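#' Shannon diversity index of one sample
#'
#' Entropy of the OTU relative-abundance distribution,
#' \eqn{H = -\sum p_i \log p_i} over OTUs with positive counts.  Natural
#' log (nats) by default; set `base = 2` for bits.
#'
#' @param x Non-negative count (or abundance) vector for one sample.
#' @param base Logarithm base.
#' @return Shannon index; `NA` with a warning for an all-zero sample.
#' @export
shannon_index <- function(x, base = exp(1)) {
  if (any(x < 0)) stopf("counts must be >= 0")
  if (sum(x) == 0) {
    warning("Shannon index undefined for an all-zero sample", call. = FALSE)
    return(NA_real_)
  }
  unname(vegan::diversity(x, index = "shannon", base = base))
}

#' Chao1 richness estimator of one sample
#'
#' Nonparametric estimate of total OTU richness from singleton and
#' doubleton counts.  The default is the bias-corrected form
#' \eqn{S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))}, which is defined even
#' without doubletons; `bias_corrected = FALSE` gives the classic
#' \eqn{S_{obs} + F_1^2 / (2 F_2)}, which is `NA` (with a warning) when
#' there are singletons but no doubletons.
#'
#' @param x Non-negative integer count vector for one sample.
#' @param bias_corrected Use the bias-corrected form (default `TRUE`).
#' @return Estimated richness; always `>= sum(x > 0)` when defined.
#' @export
chao1_richness <- function(x, bias_corrected = TRUE) {
  if (any(x < 0) || any(x != round(x))) stopf("counts must be non-negative integers")
  if (sum(x) == 0) {
    warning("Chao1 undefined for an all-zero sample", call. = FALSE)
    return(NA_real_)
  }
  if (bias_corrected)
    return(unname(vegan::estimateR(as.integer(x))["S.chao1"]))
  s_obs <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f1 > 0 && f2 == 0) {
    warning("classic Chao1 undefined without doubletons; use bias_corrected = TRUE",
            call. = FALSE)
    return(NA_real_)
  }
  if (f1 == 0) s_obs else s_obs + f1^2 / (2 * f2)
}

#' Per-sample alpha diversity of an OTU table
#'
#' @param otu An [otu_counts()] object.
#' @param base Log base for the Shannon index.
#' @param bias_corrected Chao1 form, see [chao1_richness()].
#' @return Data frame with one row per sample: `sample`, `s_obs`,
#'   `shannon`, `chao1`, joined with the table's sample metadata if present.
#' @export
alpha_diversity <- function(otu, base = exp(1), bias_corrected = TRUE) {
  stopifnot(inherits(otu, "otu_counts"))
  out <- data.frame(
    sample = colnames(otu$counts),
    s_obs = colSums(otu$counts > 0),
    shannon = apply(otu$counts, 2, shannon_index, base = base),
    chao1 = apply(otu$counts, 2, chao1_richness, bias_corrected = bias_corrected),
    row.names = NULL)
  if (!is.null(otu$sample_meta)) out <- cbind(out, otu$sample_meta)
  out
}

#' Relative abundances aggregated at a taxonomic rank
#'
#' Sums counts over OTUs sharing the same lineage prefix at the requested
#' rank (taxonomy strings are semicolon-separated
#' phylum;class;order;family;genus; absent lower ranks are treated as
#' `"unclassified"`), then divides by the per-sample total, so each column
#' sums to 1.
#'
#' @param otu An [otu_counts()] object.
#' @param rank One of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`.
#' @return Numeric matrix, taxa at `rank` in rows, samples in columns,
#'   columns summing to 1.
#' @export
relative_abundance <- function(otu, rank = "phylum") {
  stopifnot(inherits(otu, "otu_counts"))
  ranks <- c("phylum", "class", "order", "family", "genus")
  if (!rank %in% ranks)
    stopf("unknown rank \"%s\"; must be one of %s", rank,
          paste(ranks, collapse = ", "))
  level <- match(rank, ranks)
  labels <- vapply(strsplit(otu$taxonomy, ";", fixed = TRUE), function(parts) {
    if (length(parts) >= level) parts[level] else "unclassified"
  }, "")
  agg <- rowsum(otu$counts, group = labels)
  totals <- colSums(agg)
  if (any(totals == 0)) stopf("relative abundance undefined for all-zero samples")
  sweep(agg, 2, totals, "/")
}

#' Rarefy an OTU table to even depth
#'
#' Optional seeded subsampling without replacement to a common depth; the
#' estimators themselves never rarefy implicitly.
#'
#' @param otu An [otu_counts()] object.
#' @param depth Target depth; must not exceed the smallest sample total.
#' @param seed Integer seed.
#' @return A rarefied [otu_counts()] object.
#' @export
rarefy_counts <- function(otu, depth, seed = 1) {
  stopifnot(inherits(otu, "otu_counts"))
  check_number(depth, "depth", positive = TRUE)
  if (depth > min(colSums(otu$counts)))
    stopf("`depth` (%g) exceeds the smallest sample total (%g)",
          depth, min(colSums(otu$counts)))
  set.seed(seed)
  rar <- t(vegan::rrarefy(t(otu$counts), sample = depth))
  otu_counts(rar, otu$taxonomy, otu$sample_meta)
}
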