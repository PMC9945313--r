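mk_l2fc <- function(values) {
  matrix(values, nrow = 1, dimnames = list("tx", paste0("a", seq_along(values))))
}

test_that("paired log2fc computes per-animal ratios with pseudocount", {
  co <- small_cohort(seed = 51, n_taxa = 10, n_per_cell = 2)
  norm <- normalize_counts(co$table)
  paired <- paired_log2fc(norm, co$meta)
  expect_equal(dim(paired$l2fc), c(10, 8))

  # post == pre -> all zero
  pre_ids <- co$meta$sample_id[co$meta$timepoint == "pre"]
  post_ids <- co$meta$sample_id[co$meta$timepoint == "post"]
  norm2 <- norm
  norm2[, post_ids] <- norm2[, match(sub("_post", "_pre", post_ids),
                                     colnames(norm2))]
  expect_true(all(paired_log2fc(norm2, co$meta)$l2fc == 0))

  # pre = 0, post = 7, c = 0.5 -> log2(15)
  norm3 <- norm
  norm3["taxon_001", pre_ids[1]] <- 0
  norm3["taxon_001", paste0(sub("_pre", "", pre_ids[1]), "_post")] <- 7
  p3 <- paired_log2fc(norm3, co$meta, pseudocount = 0.5)
  animal <- sub("_pre", "", pre_ids[1])
  expect_equal(p3$l2fc["taxon_001", animal], log2(15))
  expect_error(paired_log2fc(norm, co$meta, pseudocount = 0), "> 0")

  # excluded animals are warned about
  meta_m <- cohort_metadata(co$meta[co$meta$sample_id != post_ids[1], ])
  expect_warning(paired_log2fc(norm[, meta_m$sample_id], meta_m), "missing a timepoint")
})

test_that("vbv_select applies the supermajority AND group-average rules", {
  crit <- vbv_criteria()  # 0.693 / 1.25 / 5-of-8
  # supermajority passes (6 >= 5) but mean 1.075 < 1.25 -> rejected
  expect_equal(nrow(vbv_select(mk_l2fc(c(rep(1.5, 6), rep(-0.2, 2))),
                               criteria = crit)), 0)
  # mean 1.2 -> rejected
  expect_equal(nrow(vbv_select(mk_l2fc(c(rep(1.5, 6), rep(0.3, 2))),
                               criteria = crit)), 0)
  # mean 1.3 -> selected up with 6 supermajority animals
  sel <- vbv_select(mk_l2fc(c(rep(1.6, 6), rep(0.4, 2))), criteria = crit)
  expect_equal(sel$direction, "up")
  expect_equal(sel$n_supermajority, 6)
  expect_equal(sel$mean_log2fc, 1.3)
  # all zero -> nothing
  expect_equal(nrow(vbv_select(mk_l2fc(rep(0, 8)), criteria = crit)), 0)
  # group smaller than the cutoff -> error
  expect_error(vbv_select(mk_l2fc(rep(2, 4)),
                          criteria = vbv_criteria(supermajority = 5)),
               "smaller than the supermajority")
})

test_that("vbv_select is antisymmetric and order-invariant", {
  set.seed(61)
  shift <- rnorm(20, 0, 2)  # per-taxon shifts so some taxa are selected
  l <- matrix(rnorm(20 * 8, rep(shift, 8), 0.5), 20, 8,
              dimnames = list(paste0("t", 1:20), paste0("a", 1:8)))
  sel <- vbv_select(l)
  expect_gt(nrow(sel), 0)
  flip <- vbv_select(-l)
  expect_equal(sel$taxon, flip$taxon)
  expect_equal(sel$mean_log2fc, -flip$mean_log2fc)
  expect_equal(ifelse(sel$direction == "up", "down", "up"), flip$direction)

  perm <- vbv_select(l[sample(20), sample(8)])
  expect_setequal(perm$taxon, sel$taxon)
  expect_equal(perm[match(sel$taxon, perm$taxon), "mean_log2fc"],
               sel$mean_log2fc)
})

test_that("vbv_select equals the brute-force oracle on random instances", {
  set.seed(71)
  for (i in 1:300) {
    n_tx <- sample(3:8, 1); n_an <- sample(5:9, 1)
    shift <- stats::rnorm(n_tx, 0, 1.5)
    l <- matrix(stats::rnorm(n_tx * n_an, shift, 1), n_tx, n_an,
                dimnames = list(paste0("t", 1:n_tx), paste0("a", 1:n_an)))
    t_ind <- stats::runif(1, 0.3, 1.2)
    t_avg <- stats::runif(1, 0.5, 1.8)
    super <- sample(2:n_an, 1)
    got <- vbv_select(l, criteria = vbv_criteria(t_ind, t_avg, super))
    want <- oracle_vbv(l, t_ind, t_avg, super)
    expect_identical(sort(got$taxon), sort(as.character(names(want))))
    for (k in seq_len(nrow(got))) {
      expect_equal(got$direction[k], unname(want[[got$taxon[k]]]["dir"]))
      expect_equal(got$n_supermajority[k],
                   as.numeric(want[[got$taxon[k]]]["n"]))
    }
  }
})

test_that("bh_adjust matches the step-up oracle and stats::p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(81)
  for (i in 1:40) {
    p <- stats::runif(sample(1:100, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_equal(adj, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
  }
})

test_that("group_test calls a strong planted effect and stays quiet on nulls", {
  # power: true 8-fold change, low dispersion
  hits <- vapply(1:60, function(s) {
    co <- generate_cohort(cohort_design(n_taxa = 30, dispersion = 0.3, seed = 900 + s),
                          effects = list(planted_effect("taxon_007", "F", "live", mu = 3,
                                                        sigma = 0.1)))
    keep <- co$meta$sex == "F" & co$meta$treatment == "live"
    meta_f <- cohort_metadata(co$meta[keep, ])
    tab_f <- subset_count_table(co$table, samples = meta_f$sample_id)
    res <- group_test(normalize_counts(tab_f), meta_f, "pre_vs_post")
    res$passes[res$taxon == "taxon_007"] && res$log2fc[res$taxon == "taxon_007"] > 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # null calibration: no planted effects -> empty passing set in >= 95%
  null_empty <- vapply(1:100, function(s) {
    co <- generate_cohort(cohort_design(n_taxa = 30, seed = 2000 + s))
    keep <- co$meta$sex == "M" & co$meta$treatment == "HK"
    meta_m <- cohort_metadata(co$meta[keep, ])
    tab_m <- subset_count_table(co$table, samples = meta_m$sample_id)
    res <- group_test(normalize_counts(tab_m), meta_m, "pre_vs_post")
    sum(res$passes) == 0
  }, logical(1))
  expect_gte(mean(null_empty), 0.95)

  # degenerate: identical groups -> log2fc 0, nothing passes
  co <- small_cohort(seed = 3000, n_taxa = 12, n_per_cell = 2)
  norm <- normalize_counts(co$table)
  pre_ids <- co$meta$sample_id[co$meta$timepoint == "pre"]
  norm[, sub("_pre", "_post", pre_ids)] <- norm[, pre_ids]
  res0 <- group_test(norm, co$meta, "pre_vs_post")
  expect_true(all(res0$log2fc == 0))
  expect_false(any(res0$passes))
})

test_that("posttreatment_contrast signs HK-higher taxa positive", {
  co <- generate_cohort(cohort_design(n_taxa = 30, dispersion = 0.3, seed = 77),
                        effects = list(planted_effect("taxon_012", "F", "HK",
                                                      mu = 3, sigma = 0.1)))
  res <- posttreatment_contrast(normalize_counts(co$table), co$meta, "F")
  row <- res[res$taxon == "taxon_012", ]
  expect_true(row$passes)
  expect_gt(row$log2fc, 0.693)
  expect_error(posttreatment_contrast(normalize_counts(co$table),
                                      co$meta[co$meta$sex == "M", ], "F"),
               "no post samples")
})
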