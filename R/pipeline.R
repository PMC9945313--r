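#' Default end-to-end run configuration
#'
#' Every default equals the procedure's published threshold, so a bare run
#' reproduces the published analysis pipeline on any input: BH-adjusted p
#' cutoff 0.1 with |log2fc| >= 0.693 for the whole-group test, the
#' vole-by-vole criteria (0.693 / 1.25 / 5-of-8, family display 1.8),
#' 10% prevalence for correlations at the 0.95 and 0.99 levels, and 999
#' permutations for PERMANOVA and dispersion tests.
#'
#' @param input Named list of file paths: `counts`, `metadata`, `tree`,
#'   `qpcr`, `phenotypes` (tree/qpcr/phenotypes optional — stages needing
#'   them are skipped when absent).
#' @param outdir Output directory.
#' @param seed Integer seed (mandatory; permutation stages refuse to run
#'   without one).
#' @param ranks Taxonomic ranks for the differential stages.
#' @param n_perm Permutations for PERMANOVA / betadisper.
#' @param vbv A [vbv_criteria()].
#' @param alpha_adj,min_abs_l2fc Whole-group test thresholds.
#' @param min_prevalence Correlation prevalence filter fraction.
#' @return List of class `run_config`.
#' @export
run_config <- function(input, outdir, seed, ranks = c("species", "family"),
                       n_perm = 999, vbv = vbv_criteria(),
                       alpha_adj = 0.1, min_abs_l2fc = 0.693,
                       min_prevalence = 0.10) {
  if (missing(seed) || is.null(seed)) {
    stop("run_config: a seed is mandatory for reproducible permutation tests")
  }
  structure(list(input = input, outdir = outdir, seed = as.integer(seed),
                 ranks = ranks, n_perm = n_perm, vbv = vbv,
                 alpha_adj = alpha_adj, min_abs_l2fc = min_abs_l2fc,
                 min_prevalence = min_prevalence),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; `vbv` is a
#' mapping with keys theta_ind, theta_avg, supermajority,
#' family_display_avg.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config must set a seed")
  vbv <- if (is.null(y$vbv)) vbv_criteria() else do.call(vbv_criteria, y$vbv)
  run_config(input = y$input, outdir = y$outdir, seed = y$seed,
             ranks = y$ranks %||% c("species", "family"),
             n_perm = y$n_perm %||% 999, vbv = vbv,
             alpha_adj = y$alpha_adj %||% 0.1,
             min_abs_l2fc = y$min_abs_l2fc %||% 0.693,
             min_prevalence = y$min_prevalence %||% 0.10)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# order-insensitive FNV-style hash of the analysis-relevant settings
config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(
    config[setdiff(names(config), c("input", "outdir"))])), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%010d", h)
}

#' Run the full analysis pipeline
#'
#' Sequence: validate -> normalize -> alpha diversity -> beta diversity +
#' PERMANOVA + dispersion -> qPCR delta-delta-Ct + rank tests -> whole-group
#' and vole-by-vole differential representation per sex-by-treatment cell
#' and rank -> post-treatment live-vs-HK contrasts -> gated correlations.
#' All outputs are TSV under `config$outdir`; a `manifest.json` records
#' inputs, the config hash, the seed, and every file written. Idempotent
#' given identical inputs, config and seed.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (list).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(config$outdir, name)
    write_tsv(df, path)
    outputs <<- c(outputs, name)
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      manifest <- list(status = "failed", failed_stage = name,
                       error = conditionMessage(e), outputs = outputs)
      jsonlite::write_json(manifest,
                           file.path(config$outdir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  tab <- stage("read", read_count_table(config$input$counts))
  meta <- stage("read", read_metadata(config$input$metadata))
  tree <- if (!is.null(config$input$tree)) stage("read", read_newick(config$input$tree))
  qpcr <- if (!is.null(config$input$qpcr)) stage("read", read_qpcr(config$input$qpcr))
  phen <- if (!is.null(config$input$phenotypes)) {
    stage("read", read_phenotypes(config$input$phenotypes))
  }

  stage("validate", {
    rep <- validate_cohort(tab, meta)
    emit(data.frame(check = names(rep)[1:4],
                    findings = vapply(rep[1:4], paste, character(1), collapse = "; ")),
         "validation.tsv")
  })

  s <- stage("normalize", size_factors(tab))
  norm <- normalize_counts(tab, s)
  stage("normalize", {
    emit(data.frame(sample_id = names(s), size_factor = unname(s)),
         "size_factors.tsv")
  })

  stage("alpha", emit(alpha_diversity(tab), "alpha_diversity.tsv"))

  stage("beta", {
    metrics <- c("bray_curtis", if (!is.null(tree)) c("unifrac", "weighted_unifrac"))
    perm_rows <- list()
    for (met in metrics) {
      d <- beta_diversity(tab, met, tree = tree)
      emit(data.frame(sample_id = rownames(d), as.data.frame(d),
                      check.names = FALSE),
           sprintf("beta_%s.tsv", met))
      meta_o <- meta[match(rownames(d), meta$sample_id), ]
      for (v in c("sex", "treatment", "timepoint")) {
        pr <- permanova(d, stats::setNames(meta_o[[v]], meta_o$sample_id),
                        n_perm = config$n_perm,
                        seed = split_seed(config$seed, 10L), variable = v)
        bd <- betadisper(d, stats::setNames(meta_o[[v]], meta_o$sample_id),
                         n_perm = config$n_perm,
                         seed = split_seed(config$seed, 11L))
        perm_rows[[length(perm_rows) + 1]] <- data.frame(
          metric = met, variable = v, R2 = pr$R2, F = pr$F, p = pr$p,
          dispersion_F = bd$F, dispersion_p = bd$p,
          n_perm = config$n_perm, seed = config$seed)
      }
    }
    emit(do.call(rbind, perm_rows), "permanova.tsv")
  })

  if (!is.null(qpcr)) stage("qpcr", {
    for (assay in unique(qpcr$assay)) {
      dd <- ddct_fold_change(qpcr, assay, meta)
      emit(dd$per_animal, sprintf("ddct_%s.tsv", assay))
      emit(dd$group_mean, sprintf("ddct_%s_group_means.tsv", assay))
      fc_by_cell <- split(dd$per_animal$fold_change,
                          paste(dd$per_animal$sex, dd$per_animal$treatment))
      cells <- names(fc_by_cell)
      mw_rows <- list()
      for (i in seq_along(cells)) for (j in seq_len(i - 1)) {
        mw <- mann_whitney(fc_by_cell[[cells[i]]], fc_by_cell[[cells[j]]])
        mw_rows[[length(mw_rows) + 1]] <- data.frame(
          assay = assay, groups = paste(cells[i], "vs", cells[j]),
          U = mw$U, p = mw$p, r = mw$r)
      }
      emit(do.call(rbind, mw_rows), sprintf("ddct_%s_mw_tests.tsv", assay))
    }
  })

  stage("differential", {
    pre_ids <- meta$sample_id[meta$timepoint == "pre"]
    for (rank in config$ranks) {
      tab_r <- agglomerate(tab, rank)
      s_r <- size_factors(tab_r)
      norm_r <- normalize_counts(tab_r, s_r)
      quart <- abundance_quartiles(subset_count_table(tab_r, samples = pre_ids))
      paired <- paired_log2fc(norm_r, meta)
      crit <- config$vbv
      if (rank == "family") {
        crit <- vbv_criteria(crit$theta_ind, crit$family_display_avg,
                             crit$supermajority, crit$family_display_avg)
      }
      vbv_rows <- list()
      for (sx in c("F", "M")) for (tr in c("live", "HK")) {
        sel <- vbv_select(paired, sex = sx, treatment = tr, criteria = crit,
                          quartiles = quart)
        if (nrow(sel)) {
          sel$sex <- sx; sel$treatment <- tr
          vbv_rows[[length(vbv_rows) + 1]] <- sel
        }
      }
      vbv_out <- if (length(vbv_rows)) do.call(rbind, vbv_rows) else
        data.frame(taxon = character(0), direction = character(0),
                   n_supermajority = integer(0), mean_log2fc = numeric(0),
                   quartile = integer(0), sex = character(0),
                   treatment = character(0))
      emit(vbv_out, sprintf("vbv_%s.tsv", rank))
      emit(group_test(norm_r, meta, "pre_vs_post",
                      alpha_adj = config$alpha_adj,
                      min_abs_l2fc = config$min_abs_l2fc),
           sprintf("group_test_pre_vs_post_%s.tsv", rank))
      for (sx in c("F", "M")) {
        emit(posttreatment_contrast(norm_r, meta, sx,
                                    alpha_adj = config$alpha_adj,
                                    min_abs_l2fc = config$min_abs_l2fc),
             sprintf("posttreatment_%s_%s.tsv", sx, rank))
      }
    }
  })

  if (!is.null(phen)) stage("correlate", {
    filt <- prevalence_filter(tab, config$min_prevalence)
    res <- correlate_features(filt, phen, meta)
    emit(res$long, "correlations_long.tsv")
    emit(res$gates, "correlation_gates.tsv")
    emit(data.frame(feature = rownames(res$wide), res$wide, check.names = FALSE),
         "correlations_wide.tsv")
  })

  manifest <- list(status = "ok", inputs = config$input,
                   config_hash = config_hash(config), seed = config$seed,
                   outputs = outputs)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Write a synthetic cohort to disk
#'
#' Materializes [generate_cohort()] output as the five TSV/Newick inputs
#' [run_all()] consumes, plus a JSON sidecar of planted ground truth for
#' test harnesses.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory.
#' @return Named list of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(counts = file.path(dir, "counts.tsv"),
                metadata = file.path(dir, "metadata.tsv"),
                tree = file.path(dir, "tree.nwk"),
                qpcr = file.path(dir, "qpcr.tsv"),
                phenotypes = file.path(dir, "phenotypes.tsv"))
  write_count_table(cohort$table, paths$counts)
  write_metadata(cohort$meta, paths$metadata)
  write_newick(cohort$tree, paths$tree)
  write_tsv(cohort$qpcr, paths$qpcr)
  write_tsv(cohort$phenotypes, paths$phenotypes)
  truth <- list(
    log2fc = cohort$truth$log2fc,
    effects = lapply(cohort$truth$effects, unclass),
    associations = lapply(cohort$truth$associations, unclass))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  paths
}
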