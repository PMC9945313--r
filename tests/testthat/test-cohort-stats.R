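test_that("effect_size_r reproduces published (U, n, r) triples", {
  cases <- list(c(0, 8, 8, 0.83), c(28, 8, 8, 0.09), c(121, 16, 16, 0.04),
                c(68, 16, 16, 0.40), c(40.5, 16, 16, 0.58),
                c(58, 16, 16, 0.46), c(9, 8, 8, 0.59), c(7, 8, 8, 0.64))
  for (cs in cases) {
    expect_equal(round(effect_size_r(cs[1], cs[2], cs[3]), 2), cs[4],
                 info = paste("U =", cs[1]))
  }
  expect_error(effect_size_r(100, 8, 8), "out of")
  # dead center: r collapses toward 0
  expect_lt(effect_size_r(32, 8, 8), 0.02)
})

test_that("mann_whitney agrees with enumeration, wilcox.test and symmetry", {
  set.seed(15)
  for (i in 1:20) {
    x <- rnorm(5); y <- rnorm(4) + runif(1, -1, 1)
    res <- mann_whitney(x, y, mode = "exact")
    expect_equal(res$p, oracle_mw_exact_p(x, y), tolerance = 1e-12)
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE))
    expect_equal(res$p, wt$p.value, tolerance = 1e-12)
    expect_equal(res$U, min(wt$statistic, length(x) * length(y) - wt$statistic),
                 ignore_attr = TRUE)
  }
  # identical multisets: U at center, r ~ 0
  res0 <- mann_whitney(1:8, 1:8, mode = "normal_cc")
  expect_equal(res0$U, 32)
  expect_lt(res0$r, 0.02)
  expect_error(mann_whitney(numeric(0), 1:3), "empty")

  # exact vs normal-cc p within 0.02 across U at n1 = n2 = 8, except at the
  # exact center where capping the two-sided p at 1 makes the gap ~0.04
  for (u in 0:32) {
    p_exact <- min(1, 2 * stats::pwilcox(u, 8, 8))
    z <- (32 - u - 0.5) / sqrt(8 * 8 * 17 / 12)
    p_norm <- 2 * stats::pnorm(-abs(z))
    expect_lt(abs(p_exact - p_norm), if (u <= 30) 0.02 else 0.05)
  }
})

test_that("wilcoxon signed-rank matches enumeration and published worked case", {
  # n = 8 all one direction: W = 36, exact two-tailed p = 2/256
  res <- wilcoxon_signed_rank(rep(0, 8), c(1, 2, 3, 4, 5, 6, 7, 8))
  expect_equal(res$W, 36)
  expect_equal(res$p, 2 / 256)
  expect_equal(round(res$p, 3), 0.008)

  set.seed(25)
  for (i in 1:15) {
    pre <- rnorm(8); post <- pre + rnorm(8, sd = 1.5)
    res <- wilcoxon_signed_rank(pre, post)
    expect_equal(res$p, oracle_signrank_p(post - pre), tolerance = 1e-12)
    # swapping pre/post reflects W, keeps p
    swap <- wilcoxon_signed_rank(post, pre)
    expect_equal(swap$W, res$n * (res$n + 1) / 2 - res$W)
    expect_equal(swap$p, res$p)
  }
  # antisymmetric differences: W central, p ~ 1
  d <- c(1, -1, 2, -2, 3, -3, 4, -4)
  expect_gt(wilcoxon_signed_rank(rep(0, 8), d)$p, 0.9)
  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)), "zero")
})

test_that("ddct_fold_change implements 2^(-ddct) with arithmetic group means", {
  q <- data.frame(animal_id = rep(c("a1", "a2", "a3"), each = 2),
                  timepoint = rep(c("pre", "post"), 3),
                  assay = "lr",
                  ct_target = c(23, 23, 26, 23, 21.5, 19),
                  ct_reference = c(15, 15, 20, 20, 15.5, 15.5))
  res <- ddct_fold_change(q, "lr")
  per <- stats::setNames(res$per_animal$fold_change, res$per_animal$animal_id)
  expect_equal(per[["a1"]], 1)        # dct unchanged
  expect_equal(per[["a2"]], 8)        # dct drops 3 cycles
  expect_equal(per[["a3"]], 2^2.5)    # dct 6.0 -> 3.5
  expect_equal(res$group_mean, mean(c(1, 8, 2^2.5)))

  # adding a constant to every Ct changes nothing
  q2 <- q; q2$ct_target <- q2$ct_target + 7; q2$ct_reference <- q2$ct_reference + 7
  expect_equal(ddct_fold_change(q2, "lr")$per_animal$fold_change,
               res$per_animal$fold_change)
  expect_error(ddct_fold_change(q, "nope"), "no rows")
  q3 <- q[-2, ]
  expect_error(ddct_fold_change(q3, "lr"), "missing a timepoint")
})

test_that("anxiety_zscore standardizes then averages", {
  p <- data.frame(animal_id = paste0("a", 1:4),
                  EPM_open_pct = c(10, 20, 30, 40),
                  OF_center_s = c(5, 1, 9, 13))
  res <- anxiety_zscore(p)
  expect_equal(mean(res$z_epm), 0, tolerance = 1e-12)
  expect_equal(stats::sd(res$z_of), 1, tolerance = 1e-12)
  z1 <- (p$EPM_open_pct - mean(p$EPM_open_pct)) / stats::sd(p$EPM_open_pct)
  z2 <- (p$OF_center_s - mean(p$OF_center_s)) / stats::sd(p$OF_center_s)
  expect_equal(res$composite, (z1 + z2) / 2)

  # location invariance
  p2 <- p; p2$EPM_open_pct <- p2$EPM_open_pct + 100
  expect_equal(anxiety_zscore(p2)$composite, res$composite)
  p3 <- p; p3$EPM_open_pct <- rep(3, 4)
  expect_error(anxiety_zscore(p3), "zero-variance")
})

test_that("two_way_anova gives calibrated p under the null, power under effects", {
  sex <- rep(rep(c("F", "M"), each = 8), 2)
  trt <- rep(c("live", "HK"), each = 16)
  # planted additive sex effect only
  set.seed(35)
  y <- rnorm(32) + ifelse(sex == "F", 3, 0)
  res <- two_way_anova(y, sex, trt)
  expect_lt(res$p[res$term == "sex"], 1e-4)
  expect_gt(res$p[res$term == "interaction"], 0.05)
  expect_equal(attr(res, "df_resid"), 28)

  # null calibration: type-I close to 0.05 for each term
  set.seed(36)
  ps <- t(vapply(1:400, function(i) two_way_anova(rnorm(32), sex, trt)$p,
                 numeric(3)))
  rates <- colMeans(ps < 0.05)
  expect_true(all(rates > 0.02 & rates < 0.09))

  # matches base aov on balanced data (Type II = sequential when balanced)
  set.seed(37)
  yy <- rnorm(32)
  mine <- two_way_anova(yy, sex, trt)
  ref <- summary(stats::aov(yy ~ factor(sex) * factor(trt)))[[1]]
  expect_equal(mine$F, ref$`F value`[1:3], tolerance = 1e-10)
  expect_error(two_way_anova(rep(1, 32), sex, trt), "zero variance")
  expect_error(two_way_anova(rnorm(4), rep("F", 4), rep(c("a", "b"), 2)),
               ">= 2 levels")
})

test_that("snk_posthoc letters separate shifted groups, share letters otherwise", {
  set.seed(45)
  g <- rep(c("a", "b", "c"), each = 6)
  y_null <- rnorm(18)
  res_null <- snk_posthoc(y_null, g)
  expect_true(all(res_null$letters == res_null$letters[1]))

  y_sep <- y_null + ifelse(g == "b", 10, 0)
  res_sep <- snk_posthoc(y_sep, g)
  expect_false(res_sep$letters[res_sep$group == "b"] %in%
                 res_sep$letters[res_sep$group != "b"])

  # invariant to group input order
  ord <- sample(18)
  res_perm <- snk_posthoc(y_sep[ord], g[ord])
  expect_equal(res_perm, res_sep)
  expect_error(snk_posthoc(rnorm(3), c("a", "b", "b")), ">= 2 observations")
})
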