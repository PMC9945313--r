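#' Prevalence filter
#'
#' Keeps taxa with nonzero counts in at least `ceiling(min_frac * n)` of
#' the table's samples.
#'
#' @param table A `count_table`.
#' @param min_frac Minimum fraction of samples with a nonzero count
#'   (default 0.10).
#' @return A filtered `count_table`.
#' @export
prevalence_filter <- function(table, min_frac = 0.10) {
  stopifnot(min_frac > 0, min_frac <= 1)
  need <- ceiling(min_frac * ncol(table$counts))
  keep <- rowSums(table$counts > 0) >= need
  subset_count_table(table, taxa = which(keep))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties). Pairs with a
#' missing value in either vector are dropped first.
#'
#' @param x,y Paired numeric vectors.
#' @return rho in \[-1, 1\], or `NA` (with a `"constant"` attribute) when
#'   either vector is constant after pair deletion.
#' @export
spearman_rho <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need >= 4 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(structure(NA_real_, constant = TRUE))
  }
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

#' Bonett-Wright confidence interval for Spearman's rho
#'
#' Fisher transform with standard error
#' \eqn{\sqrt{(1 + \rho^2/2) / (n - 3)}}:
#' \eqn{\tanh(\mathrm{atanh}(\rho) \pm z_{crit} \cdot SE)}.
#'
#' @param rho Spearman correlation, |rho| < 1.
#' @param n Number of pairs (> 3).
#' @param level Confidence level, e.g. 0.95 or 0.99.
#' @return Numeric c(lo, hi).
#' @export
bonett_wright_ci <- function(rho, n, level = 0.95) {
  if (n <= 3) stop("need n > 3")
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  se <- sqrt((1 + rho^2 / 2) / (n - 3))
  zc <- stats::qnorm(1 - (1 - level) / 2)
  tanh(atanh(rho) + c(-1, 1) * zc * se)
}

#' Community-level significance gate
#'
#' Per-taxon "nonzero" flag = the Bonett-Wright CI at `level` excludes 0.
#' A community-level association with the phenotype is declared when the
#' fraction of flagged taxa exceeds the level's alpha (0.05 at 0.95, 0.01
#' at 0.99) — i.e. more taxa correlate than chance alone would flag. When
#' the verdict is false the individual flags are rejected wholesale and the
#' significant-taxa list comes back empty.
#'
#' @param rhos Named numeric vector of per-taxon rho values (NAs allowed;
#'   they count toward the denominator as unflagged).
#' @param n Pairs used per taxon (scalar or vector matching `rhos`).
#' @param level Confidence level (0.95 or 0.99).
#' @return List: `verdict`, `fraction_nonzero`, `significant` (character
#'   vector of taxon ids, empty when verdict is false), `flags` (logical
#'   per taxon).
#' @export
community_gate <- function(rhos, n, level = 0.95) {
  if (length(rhos) == 0) stop("need >= 1 taxon")
  n <- rep_len(n, length(rhos))
  flags <- vapply(seq_along(rhos), function(i) {
    if (is.na(rhos[i])) return(FALSE)
    if (abs(rhos[i]) >= 1) return(TRUE)  # degenerate perfect correlation
    ci <- bonett_wright_ci(rhos[i], n[i], level)
    ci[1] > 0 || ci[2] < 0
  }, logical(1))
  names(flags) <- names(rhos)
  frac <- mean(flags)
  verdict <- frac > (1 - level)
  list(verdict = verdict, fraction_nonzero = frac,
       significant = if (verdict) names(rhos)[flags] else character(0),
       flags = flags)
}

#' Gated taxon-phenotype Spearman correlations
#'
#' For each phenotype, correlates every taxon's per-animal features — its
#' post-treatment normalized abundance and its paired pre-to-post log2fc —
#' with the phenotype across animals (pairwise-complete), attaches
#' Bonett-Wright CIs at 0.95 and 0.99, and applies [community_gate()] per
#' phenotype and level.
#'
#' @param table A `count_table` (apply [prevalence_filter()] first).
#' @param phenotypes data.frame with `animal_id` plus numeric phenotype
#'   columns.
#' @param meta A `cohort_metadata`.
#' @param s Size factors for `table` (default: computed).
#' @param features Which per-taxon features to use (default both).
#' @return List: `long` (data.frame taxon, feature_kind, phenotype, rho, n,
#'   ci95_lo/hi, ci99_lo/hi, flag95, flag99), `gates` (per phenotype x
#'   level verdict/fraction), `wide` (taxa-with-feature x phenotype rho
#'   matrix rounded to 1 decimal, gated cells only).
#' @export
correlate_features <- function(table, phenotypes, meta,
                               s = size_factors(table),
                               features = c("post_abundance", "log2fc")) {
  features <- match.arg(features, several.ok = TRUE)
  norm <- normalize_counts(table, s)
  paired <- paired_log2fc(norm, meta)
  animals <- intersect(paired$animals$animal_id, phenotypes$animal_id)
  if (length(animals) == 0) stop("no shared animal ids")
  meta_post <- meta[meta$timepoint == "post" & meta$animal_id %in% animals, ]
  meta_post <- meta_post[match(animals, meta_post$animal_id), ]

  feat <- list()
  if ("post_abundance" %in% features) {
    feat$post <- norm[, meta_post$sample_id, drop = FALSE]
    colnames(feat$post) <- animals
  }
  if ("log2fc" %in% features) {
    feat$log2fc <- paired$l2fc[, animals, drop = FALSE]
  }
  phen_cols <- setdiff(names(phenotypes), "animal_id")
  phen <- phenotypes[match(animals, phenotypes$animal_id), , drop = FALSE]

  rows <- list()
  for (ph in phen_cols) {
    y <- phen[[ph]]
    for (kind in names(feat)) {
      f <- feat[[kind]]
      for (tx in rownames(f)) {
        x <- f[tx, ]
        ok <- stats::complete.cases(x, y)
        if (sum(ok) < 4) next
        rho <- spearman_rho(x, y)
        n_ok <- sum(ok)
        if (is.na(rho)) {
          ci95 <- ci99 <- c(NA_real_, NA_real_)
          f95 <- f99 <- FALSE
        } else if (abs(rho) >= 1) {  # perfect monotone pair: point interval
          ci95 <- ci99 <- c(rho, rho)
          f95 <- f99 <- TRUE
        } else {
          ci95 <- bonett_wright_ci(rho, n_ok, 0.95)
          ci99 <- bonett_wright_ci(rho, n_ok, 0.99)
          f95 <- ci95[1] > 0 || ci95[2] < 0
          f99 <- ci99[1] > 0 || ci99[2] < 0
        }
        rows[[length(rows) + 1]] <- data.frame(
          taxon = tx, feature_kind = kind, phenotype = ph,
          rho = as.numeric(rho), n = n_ok,
          ci95_lo = ci95[1], ci95_hi = ci95[2],
          ci99_lo = ci99[1], ci99_hi = ci99[2],
          flag95 = f95, flag99 = f99, stringsAsFactors = FALSE)
      }
    }
  }
  long <- do.call(rbind, rows)
  if (is.null(long)) stop("no correlatable (taxon, phenotype) pairs")

  gates <- do.call(rbind, lapply(phen_cols, function(ph) {
    sub <- long[long$phenotype == ph, ]
    g95 <- community_gate(stats::setNames(sub$rho, paste(sub$taxon, sub$feature_kind)),
                          sub$n, 0.95)
    g99 <- community_gate(stats::setNames(sub$rho, paste(sub$taxon, sub$feature_kind)),
                          sub$n, 0.99)
    data.frame(phenotype = ph,
               verdict95 = g95$verdict, fraction95 = g95$fraction_nonzero,
               verdict99 = g99$verdict, fraction99 = g99$fraction_nonzero,
               stringsAsFactors = FALSE)
  }))

  # wide, publication-style: rho to 1 decimal, only gated+flagged cells
  long$feature_label <- paste0(long$taxon, " (",
                               ifelse(long$feature_kind == "post", "post", "log2fc"),
                               ")")
  wide <- matrix(NA_real_, nrow = length(unique(long$feature_label)),
                 ncol = length(phen_cols),
                 dimnames = list(unique(long$feature_label), phen_cols))
  for (ph in phen_cols) {
    if (!gates$verdict95[gates$phenotype == ph]) next
    sub <- long[long$phenotype == ph & long$flag95, ]
    wide[sub$feature_label, ph] <- round(sub$rho, 1)
  }
  list(long = long[, setdiff(names(long), "feature_label")],
       gates = gates, wide = wide)
}
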