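#' Mann-Whitney U test with the |Z|/sqrt(N) effect size
#'
#' Two-tailed test for two independent samples. `U` is reported under the
#' min convention, `Z` is the continuity-corrected normal approximation
#' (tie-corrected sigma when ties exist), and the effect size is
#' `r = |Z| / sqrt(n1 + n2)`. Exact p comes from the exact U distribution
#' when `mode = "exact"`, or automatically when `n1 + n2 <= 20` with no
#' ties; otherwise the normal approximation is used.
#'
#' @param x,y Numeric samples.
#' @param mode `"auto"`, `"normal_cc"`, or `"exact"`.
#' @return List: `U`, `Z`, `p`, `r`, `n1`, `n2`, `exact`.
#' @export
mann_whitney <- function(x, y, mode = c("auto", "normal_cc", "exact")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r_all <- rank(c(x, y))
  u1 <- sum(r_all[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u <- min(u1, n1 * n2 - u1)
  ties <- any(duplicated(c(x, y)))
  z <- mw_z(u, n1, n2, c(x, y))
  use_exact <- mode == "exact" || (mode == "auto" && n <= 20 && !ties)
  if (use_exact) {
    if (ties) warning("exact p requested with ties; p is conservative")
    p <- min(1, 2 * stats::pwilcox(u, n1, n2))
  } else {
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(U = u, Z = z, p = p, r = abs(z) / sqrt(n), n1 = n1, n2 = n2,
       exact = use_exact)
}

mw_sigma <- function(n1, n2, pooled = NULL) {
  n <- n1 + n2
  if (is.null(pooled) || !any(duplicated(pooled))) {
    sqrt(n1 * n2 * (n + 1) / 12)
  } else {
    t_sizes <- table(pooled)
    tie_term <- sum(t_sizes^3 - t_sizes) / (n * (n - 1))
    sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
  }
}

mw_z <- function(u, n1, n2, pooled = NULL) {
  (n1 * n2 / 2 - u - 0.5) / mw_sigma(n1, n2, pooled)
}

#' Effect size r from a printed Mann-Whitney U
#'
#' `r = |n1 n2 / 2 - U - 0.5| / (sigma_U * sqrt(n1 + n2))` — the absolute
#' continuity-corrected Z over the square root of the total sample size,
#' with the no-ties `sigma_U = sqrt(n1 n2 (n1 + n2 + 1) / 12)`. This is the
#' convention that reproduces published (U, n, r) triples such as
#' (0, 8, 8) -> 0.83 and (121, 16, 16) -> 0.04.
#'
#' @param u U statistic (min convention), in \[0, n1*n2\].
#' @param n1,n2 Group sizes.
#' @return Effect size r in \[0, 1\].
#' @export
effect_size_r <- function(u, n1, n2) {
  if (u < 0 || u > n1 * n2) stop("U out of [0, n1*n2]")
  abs(n1 * n2 / 2 - u - 0.5) / (mw_sigma(n1, n2) * sqrt(n1 + n2))
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-tailed. Zero differences are dropped; `W` is the sum of ranks of
#' positive differences (mid-ranks on tied |differences|). Exact p from the
#' exact signed-rank distribution for `n <= 25` without ties; normal
#' approximation with continuity correction otherwise.
#'
#' @param pre,post Paired numeric vectors.
#' @return List: `W`, `p`, `n` (pairs after dropping zeros), `exact`.
#' @export
wilcoxon_signed_rank <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre and post must pair up")
  d <- post - pre
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25 && !ties) {
    w_min <- min(w, n * (n + 1) / 2 - w)
    p <- min(1, 2 * stats::psignrank(w_min, n))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie_sizes <- table(r)
    sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                  sum(tie_sizes^3 - tie_sizes) / 48)
    z <- (abs(w - mu) - 0.5) / sig
    p <- 2 * stats::pnorm(-z)
    exact <- FALSE
  }
  list(W = w, p = p, n = n, exact = exact)
}

#' Delta-delta-Ct qPCR fold changes
#'
#' Per (animal, timepoint): `dCt = Ct_target - Ct_reference`. Per animal:
#' `ddCt = dCt_post - dCt_pre` and `fold_change = 2^(-ddCt)`, so a drop in
#' dCt (more target relative to the universal reference) is a fold increase.
#' The group mean is the arithmetic mean of the per-animal fold changes.
#'
#' @param qpcr data.frame as from [read_qpcr()] / [generate_qpcr()].
#' @param assay Assay label to quantify.
#' @param meta Optional `cohort_metadata` used to attach sex/treatment to
#'   each animal and to compute per-cell group means.
#' @return List: `per_animal` (data.frame animal_id, dct_pre, dct_post,
#'   ddct, fold_change, plus sex/treatment when `meta` given),
#'   `group_mean` (overall, or per sex-by-treatment cell when `meta` given).
#' @export
ddct_fold_change <- function(qpcr, assay, meta = NULL) {
  q <- qpcr[qpcr$assay == assay, , drop = FALSE]
  if (nrow(q) == 0) stop("no rows for assay ", assay)
  if (any(!is.finite(q$ct_reference))) {
    bad <- q$animal_id[!is.finite(q$ct_reference)][1]
    stop("missing reference Ct for animal ", bad)
  }
  q$dct <- q$ct_target - q$ct_reference
  per <- do.call(rbind, lapply(split(q, q$animal_id), function(qa) {
    if (!all(c("pre", "post") %in% qa$timepoint)) {
      stop("animal ", qa$animal_id[1], " missing a timepoint for assay ", assay)
    }
    dct_pre <- qa$dct[qa$timepoint == "pre"]
    dct_post <- qa$dct[qa$timepoint == "post"]
    data.frame(animal_id = qa$animal_id[1], dct_pre = dct_pre,
               dct_post = dct_post, ddct = dct_post - dct_pre,
               fold_change = 2^(-(dct_post - dct_pre)),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  if (!is.null(meta)) {
    key <- unique(meta[, c("animal_id", "sex", "treatment")])
    per <- merge(per, key, by = "animal_id", sort = FALSE)
    gm <- stats::aggregate(fold_change ~ sex + treatment, data = per, FUN = mean)
    names(gm)[names(gm) == "fold_change"] <- "mean_fold_change"
  } else {
    gm <- mean(per$fold_change)
  }
  list(per_animal = per, group_mean = gm)
}

#' Anxiety composite from behavioral z-scores
#'
#' Averages the per-animal z-scores of two anxiety-related measures:
#' percent time in the open arms of the elevated plus maze and duration in
#' the center of the open field. Each column is standardized over the
#' included animals (mean 0, SD 1) before averaging.
#'
#' @param phenotypes data.frame with `animal_id` and the two columns named
#'   by `epm_col` / `of_col`.
#' @param epm_col,of_col Column names (defaults `"EPM_open_pct"`,
#'   `"OF_center_s"`).
#' @return data.frame: animal_id, z_epm, z_of, composite.
#' @export
anxiety_zscore <- function(phenotypes, epm_col = "EPM_open_pct",
                           of_col = "OF_center_s") {
  miss <- setdiff(c(epm_col, of_col), names(phenotypes))
  if (length(miss)) stop("missing phenotype columns: ", paste(miss, collapse = ", "))
  ok <- stats::complete.cases(phenotypes[[epm_col]], phenotypes[[of_col]])
  if (sum(ok) < 2) stop("need >= 2 animals with both measures")
  p <- phenotypes[ok, , drop = FALSE]
  zf <- function(v) {
    if (stats::sd(v) == 0) stop("zero-variance phenotype column")
    (v - mean(v)) / stats::sd(v)
  }
  z_epm <- zf(p[[epm_col]])
  z_of <- zf(p[[of_col]])
  data.frame(animal_id = p$animal_id, z_epm = z_epm, z_of = z_of,
             composite = (z_epm + z_of) / 2, stringsAsFactors = FALSE)
}

#' Two-way ANOVA (sex x treatment), Type II sums of squares
#'
#' @param values Numeric response.
#' @param sex,treatment Factors (or coercible), one level set each with
#'   >= 2 levels.
#' @return data.frame with rows sex, treatment, interaction: df, SS, F, p;
#'   residual df in attribute `"df_resid"`.
#' @export
two_way_anova <- function(values, sex, treatment) {
  sex <- factor(sex); treatment <- factor(treatment)
  if (nlevels(sex) < 2 || nlevels(treatment) < 2) {
    stop("both factors need >= 2 levels")
  }
  if (stats::var(values) == 0) stop("zero variance in response")
  rss <- function(f) sum(stats::resid(stats::lm(f))^2)
  full <- stats::lm(values ~ sex * treatment)
  rss_full <- sum(stats::resid(full)^2)
  df_resid <- full$df.residual
  mse <- rss_full / df_resid
  ss_sex <- rss(values ~ treatment) - rss(values ~ sex + treatment)
  ss_trt <- rss(values ~ sex) - rss(values ~ sex + treatment)
  ss_int <- rss(values ~ sex + treatment) - rss_full
  df_sex <- nlevels(sex) - 1
  df_trt <- nlevels(treatment) - 1
  df_int <- df_sex * df_trt
  f <- c(ss_sex / df_sex, ss_trt / df_trt, ss_int / df_int) / mse
  out <- data.frame(term = c("sex", "treatment", "interaction"),
                    df = c(df_sex, df_trt, df_int),
                    SS = c(ss_sex, ss_trt, ss_int),
                    F = f,
                    p = stats::pf(f, c(df_sex, df_trt, df_int), df_resid,
                                  lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  attr(out, "df_resid") <- df_resid
  out
}

#' Student-Newman-Keuls post hoc letters
#'
#' Stepwise studentized-range comparisons on the ordered group means: the
#' critical value for a stretch of `r` ordered means uses the studentized
#' range with parameter `r`, and a stretch inside an already non-significant
#' stretch is never declared significant. Groups sharing a letter do not
#' differ.
#'
#' @param values Numeric response.
#' @param groups Group labels.
#' @param alpha Familywise level per stretch (default 0.05).
#' @return data.frame: group, mean, n, letters — ordered by decreasing
#'   mean. Letter assignment is invariant to the input order of groups.
#' @export
snk_posthoc <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  ng <- table(groups)
  if (length(ng) < 2) stop("need >= 2 groups")
  if (any(ng < 2)) stop("every group needs >= 2 observations")
  means <- tapply(values, groups, mean)
  k <- length(means)
  grand <- tapply(values, groups, mean)[groups]
  df_err <- length(values) - k
  mse <- sum((values - grand)^2) / df_err
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]; n <- as.numeric(ng[names(means)][ord])

  # non-significant stretches, largest ranges first; containment blocks tests
  ns <- list()
  covered <- function(i, j) any(vapply(ns, function(iv) iv[1] <= i && j <= iv[2],
                                       logical(1)))
  for (span in k:2) {
    for (i in 1:(k - span + 1)) {
      j <- i + span - 1
      if (covered(i, j)) next
      se <- sqrt(mse / 2 * (1 / n[i] + 1 / n[j]))
      q <- (m[i] - m[j]) / se
      p <- stats::ptukey(q, span, df_err, lower.tail = FALSE)
      if (p >= alpha) ns[[length(ns) + 1]] <- c(i, j)
    }
  }
  # letters: each maximal NS stretch gets one; uncovered groups get their own
  letter_sets <- ns
  for (i in 1:k) if (!covered(i, i)) letter_sets[[length(letter_sets) + 1]] <- c(i, i)
  letter_sets <- letter_sets[order(vapply(letter_sets, `[`, numeric(1), 1))]
  lab <- vapply(seq_len(k), function(i) {
    paste(letters[which(vapply(letter_sets,
                               function(iv) iv[1] <= i && i <= iv[2],
                               logical(1)))], collapse = "")
  }, character(1))
  data.frame(group = names(m), mean = as.numeric(m), n = n, letters = lab,
             row.names = NULL, stringsAsFactors = FALSE)
}
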