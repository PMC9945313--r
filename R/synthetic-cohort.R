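#' Describe a synthetic study design
#'
#' Defaults mirror the design the analysis machinery assumes: 8 animals per
#' sex per treatment arm, each sampled pre and post, with heavy-tailed taxon
#' abundances and large between-animal dispersion.
#'
#' @param n_per_cell Animals per sex-by-treatment cell (default 8).
#' @param n_taxa Number of taxa in the community (default 100).
#' @param dispersion Between-animal log-scale SD of per-taxon abundance
#'   multipliers (default 1.0; large on purpose — individual variation is a
#'   defining feature of these cohorts).
#' @param community_sdlog SD of the log-normal rank-abundance profile shared
#'   by all animals (default 1.5; heavier tail = steeper rank-abundance).
#' @param depth_range Per-sample sequencing depth bounds, drawn uniformly
#'   (default 20000-60000 reads) to force unequal size factors.
#' @param seed Integer RNG seed.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_per_cell = 8, n_taxa = 100, dispersion = 1.0,
                          community_sdlog = 1.5,
                          depth_range = c(20000, 60000), seed = 1) {
  stopifnot(n_per_cell >= 2, n_taxa >= 4, dispersion >= 0,
            all(depth_range > 0), length(depth_range) == 2)
  structure(list(n_per_cell = n_per_cell, n_taxa = n_taxa,
                 dispersion = dispersion, community_sdlog = community_sdlog,
                 depth_range = sort(depth_range), seed = as.integer(seed)),
            class = "cohort_design")
}

#' Plant a treatment effect on designated taxa
#'
#' @param taxa Character vector of taxon ids to perturb.
#' @param sex,treatment Target cell (`"F"`/`"M"`, `"live"`/`"HK"`).
#' @param mu Mean per-animal log2 fold change pre to post.
#' @param sigma SD of the per-animal log2 fold change.
#' @param fraction Fraction of the cell's animals affected (default 1).
#' @return A list of class `planted_effect`.
#' @export
planted_effect <- function(taxa, sex, treatment, mu, sigma = 0.2, fraction = 1.0) {
  stopifnot(fraction >= 0, fraction <= 1, is.finite(mu))
  structure(list(taxa = taxa, sex = sex, treatment = treatment,
                 mu = mu, sigma = sigma, fraction = fraction),
            class = "planted_effect")
}

#' Plant a monotone taxon-phenotype association
#'
#' The phenotype is built from the taxon's per-animal pre-to-post log2 fold
#' change through a Gaussian copula targeting Spearman correlation `rho`.
#'
#' @param taxon Taxon id.
#' @param phenotype Phenotype column name.
#' @param rho Target Spearman correlation, in (-1, 1).
#' @param noise_sd Extra Gaussian noise SD on the phenotype scale (default 1).
#' @return A list of class `planted_association`.
#' @export
planted_association <- function(taxon, phenotype, rho, noise_sd = 1) {
  stopifnot(rho > -1, rho < 1)
  structure(list(taxon = taxon, phenotype = phenotype, rho = rho,
                 noise_sd = noise_sd), class = "planted_association")
}

#' Generate a synthetic paired pre/post cohort
#'
#' Baseline taxon abundances come from a log-normal community profile shared
#' across animals; each animal gets per-taxon multiplicative log-normal
#' random effects (SD = `design$dispersion`). Post-treatment expected
#' abundances equal pre abundances shifted by any planted per-animal log2
#' fold changes; observed counts are multinomial resamples at a per-sample
#' depth drawn uniformly from `design$depth_range`. Everything is
#' deterministic given `design$seed`.
#'
#' @param design A [cohort_design()].
#' @param effects List of [planted_effect()] objects.
#' @param associations List of [planted_association()] objects.
#' @param n_null_phenotypes Pure-noise phenotype columns to add (default 2).
#' @return A list with elements `table` (`count_table`, all samples),
#'   `meta` (`cohort_metadata`), `tree` (`phylo`), `phenotypes` (data.frame),
#'   `qpcr` (data.frame, probiotic target assay), and `truth` (planted
#'   per-animal log2fc matrix and association list, for test harnesses).
#' @export
generate_cohort <- function(design, effects = list(), associations = list(),
                            n_null_phenotypes = 2) {
  stopifnot(inherits(design, "cohort_design"))
  taxa <- sprintf("taxon_%03d", seq_len(design$n_taxa))
  for (e in effects) {
    bad <- setdiff(e$taxa, taxa)
    if (length(bad)) stop("planted effect references unknown taxon: ", bad[1])
  }
  for (a in associations) {
    if (!a$taxon %in% taxa) stop("planted association references unknown taxon: ", a$taxon)
  }

  with_seed(design$seed, {
    n_cell <- design$n_per_cell
    cells <- expand.grid(sex = c("F", "M"), treatment = c("live", "HK"),
                         stringsAsFactors = FALSE)
    animals <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      data.frame(animal_id = sprintf("%s_%s_%02d", cells$sex[i],
                                     cells$treatment[i], seq_len(n_cell)),
                 sex = cells$sex[i], treatment = cells$treatment[i],
                 stringsAsFactors = FALSE)
    }))
    n_animals <- nrow(animals)
    animals$cage_id <- sprintf("cage_%02d", rep(seq_len(ceiling(n_animals / 2)),
                                                each = 2)[seq_len(n_animals)])

    # shared heavy-tailed community profile + per-animal multiplicative effects
    base <- stats::rlnorm(design$n_taxa, meanlog = 0, sdlog = design$community_sdlog)
    animal_fx <- matrix(stats::rlnorm(design$n_taxa * n_animals, 0, design$dispersion),
                        nrow = design$n_taxa,
                        dimnames = list(taxa, animals$animal_id))
    lambda_pre <- base * animal_fx

    # planted treatment effects -> true per-animal log2fc, zero elsewhere
    true_l2fc <- matrix(0, design$n_taxa, n_animals, dimnames = dimnames(animal_fx))
    for (e in effects) {
      in_cell <- which(animals$sex == e$sex & animals$treatment == e$treatment)
      n_aff <- round(e$fraction * length(in_cell))
      affected <- in_cell[seq_len(n_aff)]
      for (tx in e$taxa) {
        true_l2fc[tx, affected] <- stats::rnorm(n_aff, e$mu, e$sigma)
      }
    }
    lambda_post <- lambda_pre * 2^true_l2fc

    sample_counts <- function(lambda, suffix) {
      depth <- round(stats::runif(n_animals, design$depth_range[1],
                                  design$depth_range[2]))
      m <- vapply(seq_len(n_animals), function(j) {
        stats::rmultinom(1, size = depth[j], prob = lambda[, j])[, 1]
      }, numeric(design$n_taxa))
      colnames(m) <- paste0(animals$animal_id, "_", suffix)
      rownames(m) <- taxa
      m
    }
    counts <- cbind(sample_counts(lambda_pre, "pre"),
                    sample_counts(lambda_post, "post"))

    meta <- rbind(
      data.frame(sample_id = paste0(animals$animal_id, "_pre"), animals,
                 timepoint = "pre", stringsAsFactors = FALSE),
      data.frame(sample_id = paste0(animals$animal_id, "_post"), animals,
                 timepoint = "post", stringsAsFactors = FALSE)
    )
    meta <- cohort_metadata(meta[, c("sample_id", "animal_id", "sex",
                                     "treatment", "timepoint", "cage_id")])

    lineage <- stats::setNames(synthetic_lineages(design$n_taxa), taxa)
    tab <- count_table(counts, lineage)
    tree <- generate_tree(taxa, seed = split_seed(design$seed, 1L))

    phen <- build_phenotypes(animals$animal_id, true_l2fc, associations,
                             n_null_phenotypes)
    fc <- 2^pmax(colMeans(true_l2fc[unique(unlist(lapply(effects, `[[`, "taxa"))),
                                    , drop = FALSE]), 0)
    if (length(effects) == 0) fc <- rep(1, n_animals)
    names(fc) <- animals$animal_id
    qpcr <- generate_qpcr(meta, fc, noise_sd = 0.1,
                          seed = split_seed(design$seed, 2L))

    list(table = tab, meta = meta, tree = tree, phenotypes = phen, qpcr = qpcr,
         truth = list(log2fc = true_l2fc, effects = effects,
                      associations = associations))
  })
}

# plausible-looking lineages: a few synthetic phyla/families so rank
# agglomeration has something to do
synthetic_lineages <- function(n) {
  phyla <- c("Firmicutes", "Bacteroidota", "Actinobacteriota", "Proteobacteria")
  p <- rep_len(phyla, n)
  fam <- sprintf("family_%02d", rep_len(seq_len(max(4, ceiling(n / 5))), n))
  sprintf("p__%s;c__class_x;o__order_x;f__%s;g__genus_%03d;s__species_%03d",
          p, fam, seq_len(n), seq_len(n))
}

build_phenotypes <- function(animal_ids, true_l2fc, associations, n_null) {
  n <- length(animal_ids)
  phen <- data.frame(animal_id = animal_ids, stringsAsFactors = FALSE)
  for (a in associations) {
    driver <- true_l2fc[a$taxon, ] + stats::rnorm(n, 0, 0.05)
    z <- stats::qnorm(rank(driver) / (n + 1))  # normal scores: copula link
    y <- a$rho * z + sqrt(1 - a$rho^2) * stats::rnorm(n)
    phen[[a$phenotype]] <- y * a$noise_sd + 10
  }
  for (k in seq_len(n_null)) {
    phen[[sprintf("null_phenotype_%d", k)]] <- stats::rnorm(n)
  }
  phen
}

#' Generate a random rooted bifurcating tree over taxa
#'
#' Topology from [ape::rtree()]; branch lengths i.i.d. exponential(rate 1).
#'
#' @param taxa Character vector of >= 2 taxon ids (become the leaf labels).
#' @param seed Integer seed.
#' @return An [ape::phylo] rooted binary tree.
#' @export
generate_tree <- function(taxa, seed = 1) {
  n <- length(taxa)
  if (n < 2) stop("need >= 2 taxa to build a tree")
  with_seed(seed, {
    tr <- ape::rtree(n, rooted = TRUE)
    tr$tip.label <- taxa[as.integer(sub("^t", "", tr$tip.label))]
    tr$edge.length <- stats::rexp(nrow(tr$edge))
    validate_tree(tr)
  })
}

#' Generate a qPCR Ct table realizing target per-animal fold changes
#'
#' Inverts the delta-delta-Ct model: for each animal the post-timepoint
#' target-vs-reference Ct difference is lowered by `log2(fold_change)`
#' cycles relative to pre, so [ddct_fold_change()] recovers the targets up
#' to the injected Ct noise.
#'
#' @param meta A `cohort_metadata` (one pre and one post row per animal).
#' @param fold_changes Named numeric vector (by animal_id) of positive
#'   target fold changes.
#' @param noise_sd Gaussian noise SD added to each target-assay Ct value,
#'   in cycles (default 0 = exact recovery). Reference-assay noise is not
#'   modelled separately: it cancels within each timepoint's dCt, so target
#'   Ct noise is the one knob controlling recovery error (SD of the
#'   recovered log2 fold change = `noise_sd * sqrt(2)`).
#' @param assay Assay label (default `"L_reuteri"`).
#' @param seed Integer seed.
#' @return data.frame with columns animal_id, timepoint, assay, ct_target,
#'   ct_reference.
#' @export
generate_qpcr <- function(meta, fold_changes, noise_sd = 0,
                          assay = "L_reuteri", seed = 1) {
  if (any(fold_changes <= 0)) stop("fold changes must be positive")
  animals <- intersect(unique(meta$animal_id), names(fold_changes))
  if (length(animals) == 0) stop("no animals shared between meta and fold_changes")
  with_seed(seed, {
    out <- do.call(rbind, lapply(animals, function(a) {
      ct_ref <- 15 + stats::rnorm(2, 0, 0.2)   # reference assay, both timepoints
      dct_pre <- 8                              # arbitrary baseline offset
      dct_post <- dct_pre - log2(fold_changes[[a]])
      data.frame(animal_id = a, timepoint = c("pre", "post"), assay = assay,
                 ct_target = ct_ref + c(dct_pre, dct_post) +
                   stats::rnorm(2, 0, noise_sd),
                 ct_reference = ct_ref,
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}
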