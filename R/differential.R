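#' Per-animal paired log2 fold changes, pre to post
#'
#' For every animal with both timepoints,
#' \eqn{l = \log_2((post + c) / (pre + c))} on size-factor-normalized
#' counts, with pseudocount `c` guarding zeros. Animals missing a timepoint
#' are excluded with a warning.
#'
#' @param norm Normalized count matrix (taxa x samples) from
#'   [normalize_counts()].
#' @param meta A `cohort_metadata`.
#' @param pseudocount Positive constant `c` (default 0.5).
#' @return List with `l2fc` (taxa x animals matrix) and `animals`
#'   (data.frame animal_id, sex, treatment).
#' @export
paired_log2fc <- function(norm, meta, pseudocount = 0.5) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  meta <- meta[meta$sample_id %in% colnames(norm), , drop = FALSE]
  tp <- split(meta, meta$animal_id)
  has_both <- vapply(tp, function(m) all(c("pre", "post") %in% m$timepoint),
                     logical(1))
  if (any(!has_both)) {
    warning("excluding animals missing a timepoint: ",
            paste(names(tp)[!has_both], collapse = ", "))
  }
  tp <- tp[has_both]
  if (length(tp) == 0) stop("no animal has both timepoints")
  l2fc <- vapply(tp, function(m) {
    pre <- norm[, m$sample_id[m$timepoint == "pre"]]
    post <- norm[, m$sample_id[m$timepoint == "post"]]
    log2((post + pseudocount) / (pre + pseudocount))
  }, numeric(nrow(norm)))
  rownames(l2fc) <- rownames(norm)
  animals <- do.call(rbind, lapply(tp, function(m) {
    data.frame(animal_id = m$animal_id[1], sex = m$sex[1],
               treatment = m$treatment[1], stringsAsFactors = FALSE)
  }))
  rownames(animals) <- NULL
  list(l2fc = l2fc, animals = animals)
}

#' Selection criteria for the vole-by-vole procedure
#'
#' Defaults are the procedure's published thresholds: each counted animal
#' must change by at least `|0.693|` log2 units individually, at least 5 of
#' 8 animals (a supermajority; rescaled as `ceiling(5/8 * n)` for other
#' group sizes) must do so in the same direction, and the group mean over
#' ALL animals must reach `|1.25|` in that direction. Family-level displays
#' additionally use a stricter `|1.8|` group-average threshold.
#'
#' @param theta_ind Per-animal |log2fc| threshold (default 0.693).
#' @param theta_avg Group-average |log2fc| threshold (default 1.25).
#' @param supermajority Minimum same-direction animals; `NULL` (default)
#'   means `ceiling(5/8 * group size)` computed at selection time.
#' @param family_display_avg Stricter average threshold for family-level
#'   reporting (default 1.8).
#' @return List of class `vbv_criteria`.
#' @export
vbv_criteria <- function(theta_ind = 0.693, theta_avg = 1.25,
                         supermajority = NULL, family_display_avg = 1.8) {
  stopifnot(theta_ind >= 0, theta_avg >= 0)
  structure(list(theta_ind = theta_ind, theta_avg = theta_avg,
                 supermajority = supermajority,
                 family_display_avg = family_display_avg),
            class = "vbv_criteria")
}

#' Vole-by-vole paired differential-representation selection
#'
#' A taxon is selected "up" in a group when (a) at least `supermajority`
#' animals individually have \eqn{l \ge} `theta_ind`, and (b) the mean
#' log2fc over ALL the group's animals is \eqn{\ge} `theta_avg`; mirrored
#' for "down". Animals crossing the individual threshold in the opposite
#' direction of the group mean do not count toward the supermajority.
#'
#' @param paired Result of [paired_log2fc()], or a bare taxa-x-animals
#'   log2fc matrix (then `sex`/`treatment` are ignored and all columns form
#'   the group).
#' @param sex,treatment Cell selector applied to `paired$animals`.
#' @param criteria A [vbv_criteria()].
#' @param quartiles Optional named quartile vector from
#'   [abundance_quartiles()] carried into the output.
#' @return data.frame (one row per selected taxon): taxon, direction,
#'   n_supermajority, mean_log2fc, quartile.
#' @export
vbv_select <- function(paired, sex = NULL, treatment = NULL,
                       criteria = vbv_criteria(), quartiles = NULL) {
  if (is.matrix(paired)) {
    l <- paired
  } else {
    keep <- rep(TRUE, nrow(paired$animals))
    if (!is.null(sex)) keep <- keep & paired$animals$sex == sex
    if (!is.null(treatment)) keep <- keep & paired$animals$treatment == treatment
    l <- paired$l2fc[, keep, drop = FALSE]
  }
  n_animals <- ncol(l)
  super <- criteria$supermajority
  if (is.null(super)) super <- ceiling(5 / 8 * n_animals)
  if (n_animals < super) stop("group smaller than the supermajority cutoff")

  n_up <- rowSums(l >= criteria$theta_ind)
  n_dn <- rowSums(l <= -criteria$theta_ind)
  mu <- rowMeans(l)
  sel_up <- n_up >= super & mu >= criteria$theta_avg
  sel_dn <- n_dn >= super & mu <= -criteria$theta_avg

  out <- data.frame(
    taxon = c(rownames(l)[sel_up], rownames(l)[sel_dn]),
    direction = c(rep("up", sum(sel_up)), rep("down", sum(sel_dn))),
    n_supermajority = c(n_up[sel_up], n_dn[sel_dn]),
    mean_log2fc = c(mu[sel_up], mu[sel_dn]),
    stringsAsFactors = FALSE)
  out <- out[order(match(out$taxon, rownames(l))), , drop = FALSE]
  out$quartile <- if (is.null(quartiles)) rep(NA_integer_, nrow(out)) else
    unname(quartiles[out$taxon])
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' \eqn{padj_i = \min_{j: p_j \ge p_i} (m \, p_j / rank_j)}, capped at 1.
#' Order-preserving; `padj >= p` elementwise.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  padj <- pmin(1, cummin(m / (m:1) * p[ord]))[order(ord)]
  padj
}

# moment-based per-taxon NB dispersion on normalized counts, shrunk halfway
# toward the trend alpha = a0 + a1/mean fitted across taxa (a crude stand-in
# for full empirical-Bayes machinery; calibration-tested, not tool-equivalent)
estimate_dispersions <- function(norm, groups) {
  mu_all <- rowMeans(norm)
  raw <- vapply(seq_len(nrow(norm)), function(i) {
    num <- 0; den <- 0
    for (g in unique(groups)) {
      x <- norm[i, groups == g]
      if (length(x) > 1) {
        num <- num + (length(x) - 1) * (stats::var(x) - mean(x))
        den <- den + (length(x) - 1) * mean(x)^2
      }
    }
    if (den == 0) return(0)
    max(num / den, 0)
  }, numeric(1))
  keep <- mu_all > 0 & raw > 0
  trend <- if (sum(keep) >= 10) {
    df <- data.frame(a = raw[keep], inv_mu = 1 / mu_all[keep])
    fit <- stats::lm(a ~ inv_mu, data = df)
    as.numeric(stats::predict(fit, newdata = data.frame(inv_mu = 1 / pmax(mu_all, 1e-8))))
  } else rep(max(mean(raw[raw > 0]), 0.01, na.rm = TRUE), length(raw))
  trend <- pmax(trend, 1e-4)
  pmax((raw + trend) / 2, 1e-4)
}

#' Whole-group differential representation test
#'
#' A simplified per-taxon negative-binomial Wald test on size-factor
#' normalized counts: group means on the normalized scale, log2 ratio with
#' pseudocount, delta-method standard error using a moment-based dispersion
#' shrunk toward a mean-dispersion trend, p from the t distribution with
#' `n1 + n2 - 2` df, then Benjamini-Hochberg adjustment. The reported
#' passing set applies `padj < alpha_adj` AND `|log2fc| >= min_abs_l2fc`.
#' This is a calibration-tested approximation, not a clone of any specific
#' differential-abundance tool.
#'
#' @param norm Normalized count matrix (taxa x samples).
#' @param meta A `cohort_metadata` covering the columns of `norm`.
#' @param contrast One of `"pre_vs_post"`, `"live_vs_HK"`, `"F_vs_M"`.
#'   Positive log2fc = higher in the second level named.
#' @param alpha_adj BH-adjusted p cutoff (default 0.1).
#' @param min_abs_l2fc Effect-size filter on |log2fc| (default 0.693).
#' @param pseudocount Added to group means before the ratio (default 0.5).
#' @return data.frame: taxon, log2fc, p, padj, passes.
#' @export
group_test <- function(norm, meta, contrast = c("pre_vs_post", "live_vs_HK",
                                                "F_vs_M"),
                       alpha_adj = 0.1, min_abs_l2fc = 0.693,
                       pseudocount = 0.5) {
  contrast <- match.arg(contrast)
  meta <- meta[match(colnames(norm), meta$sample_id), , drop = FALSE]
  key <- switch(contrast, pre_vs_post = meta$timepoint,
                live_vs_HK = meta$treatment, F_vs_M = meta$sex)
  levels2 <- switch(contrast, pre_vs_post = c("pre", "post"),
                    live_vs_HK = c("live", "HK"), F_vs_M = c("F", "M"))
  i1 <- which(key == levels2[1]); i2 <- which(key == levels2[2])
  if (length(i1) < 2 || length(i2) < 2) stop("each contrast level needs >= 2 samples")

  disp <- estimate_dispersions(norm, key)
  m1 <- rowMeans(norm[, i1, drop = FALSE])
  m2 <- rowMeans(norm[, i2, drop = FALSE])
  l2fc <- log2((m2 + pseudocount) / (m1 + pseudocount))
  # delta method on log group means: Var(mean) ~ (mu + alpha mu^2)/n
  v1 <- (m1 + disp * m1^2) / length(i1) / (m1 + pseudocount)^2
  v2 <- (m2 + disp * m2^2) / length(i2) / (m2 + pseudocount)^2
  se <- sqrt(v1 + v2) / log(2)
  t_stat <- ifelse(se > 0, l2fc / se, 0)
  df <- length(i1) + length(i2) - 2
  p <- 2 * stats::pt(-abs(t_stat), df = df)
  padj <- bh_adjust(p)
  data.frame(taxon = rownames(norm), log2fc = l2fc, p = p, padj = padj,
             passes = padj < alpha_adj & abs(l2fc) >= min_abs_l2fc,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Post-treatment live-vs-HK contrast within one sex
#'
#' [group_test()] restricted to the post-timepoint samples of one sex,
#' contrasting treatments. Sign convention: positive log2fc = higher
#' relative abundance in HK-treated animals.
#'
#' @param norm Normalized count matrix.
#' @param meta A `cohort_metadata`.
#' @param sex `"F"` or `"M"`.
#' @inheritParams group_test
#' @return data.frame as [group_test()].
#' @export
posttreatment_contrast <- function(norm, meta, sex, alpha_adj = 0.1,
                                   min_abs_l2fc = 0.693) {
  meta_sub <- meta[meta$timepoint == "post" & meta$sex == sex, , drop = FALSE]
  if (nrow(meta_sub) == 0) stop("no post samples for sex ", sex)
  norm_sub <- norm[, meta_sub$sample_id, drop = FALSE]
  group_test(norm_sub, meta_sub, contrast = "live_vs_HK",
             alpha_adj = alpha_adj, min_abs_l2fc = min_abs_l2fc)
}
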