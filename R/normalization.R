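#' Median-of-ratios size factors
#'
#' Per-sample scaling constants from the classical median-of-ratios method:
#' reference taxa are those with nonzero counts in every sample; each
#' sample's factor is the median, over reference taxa, of the ratio of its
#' count to the taxon's geometric mean across samples. Raw counts divided by
#' these factors are depth-corrected.
#'
#' If no taxon is nonzero everywhere, a pseudo-reference fallback adds 0.5
#' to all counts and uses every taxon, with a message (controllable via
#' `fallback`).
#'
#' @param table A `count_table`.
#' @param fallback Allow the +0.5 pseudo-reference fallback when no
#'   all-nonzero reference taxon exists (default TRUE).
#' @return Named numeric vector of size factors, one per sample, all > 0.
#' @export
size_factors <- function(table, fallback = TRUE) {
  m <- table$counts
  ref <- rowSums(m == 0) == 0
  if (!any(ref)) {
    if (!fallback) {
      stop("no taxon has nonzero counts in every sample; ",
           "table too sparse for median-of-ratios without pseudocounts")
    }
    message("size_factors: no all-nonzero reference taxon; ",
            "falling back to +0.5 pseudo-reference")
    m <- m + 0.5
    ref <- rep(TRUE, nrow(m))
  }
  mr <- m[ref, , drop = FALSE]
  geo <- exp(rowMeans(log(mr)))
  s <- apply(mr / geo, 2, stats::median)
  if (any(!is.finite(s)) || any(s <= 0)) stop("degenerate size factors")
  s
}

#' Divide counts by per-sample size factors
#'
#' @param table A `count_table`.
#' @param s Named size-factor vector covering every sample (from
#'   [size_factors()]).
#' @return Real-valued matrix of normalized counts (taxa x samples).
#' @export
normalize_counts <- function(table, s = size_factors(table)) {
  miss <- setdiff(sample_ids(table), names(s))
  if (length(miss)) stop("size factors missing for samples: ",
                         paste(miss, collapse = ", "))
  sweep(table$counts, 2, s[sample_ids(table)], "/")
}

#' Group-merged relative abundance at a taxonomic rank
#'
#' Samples are pooled (counts summed) within each group defined by the
#' metadata keys, counts agglomerated to `rank`, and each group column
#' divided by its total so it sums to 1. Taxa whose summed fraction across
#' all groups is below `prune_below` are then removed.
#'
#' @param table A `count_table`.
#' @param meta A `cohort_metadata` covering the table's samples.
#' @param group_by Character vector of metadata column names (e.g.
#'   `c("sex", "treatment", "timepoint")`).
#' @param rank Taxonomic rank for agglomeration.
#' @param prune_below Total-fraction pruning threshold (default 0.01).
#' @return Matrix of fractions, rank-level taxa x groups.
#' @export
relative_abundance <- function(table, meta, group_by, rank = "phylum",
                               prune_below = 0.01) {
  rank <- match.arg(rank, RANKS)
  bad <- setdiff(group_by, names(meta))
  if (length(bad)) stop("unknown metadata keys: ", paste(bad, collapse = ", "))
  meta <- meta[match(sample_ids(table), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stop("metadata does not cover all samples")
  grp <- interaction(meta[group_by], sep = "/", drop = TRUE)

  agg <- agglomerate(table, rank)
  merged <- t(rowsum(t(agg$counts), group = grp))
  frac <- sweep(merged, 2, colSums(merged), "/")
  keep <- rowSums(frac) >= prune_below
  frac[keep, , drop = FALSE]
}

#' Abundance quartiles from pre-treatment raw counts
#'
#' Each taxon's mean raw count across the pre-treatment samples is ranked;
#' quartile 1 holds the least abundant quarter of taxa, quartile 4 the most
#' abundant. Ties break by stable taxon order.
#'
#' @param pre_table A `count_table` restricted to pre-timepoint samples.
#' @return Named integer vector in 1..4, one entry per taxon.
#' @export
abundance_quartiles <- function(pre_table) {
  m <- pre_table$counts
  if (nrow(m) == 0 || ncol(m) == 0) stop("empty count table")
  mu <- rowMeans(m)
  n <- length(mu)
  ord <- order(mu)  # stable: ties keep original taxon order
  sizes <- diff(floor(n * 0:4 / 4))
  q <- integer(n)
  q[ord] <- rep(1:4, times = sizes)
  stats::setNames(q, rownames(m))
}
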