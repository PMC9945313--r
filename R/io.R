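#' Read cohort sample metadata from TSV
#'
#' Required columns: `sample_id`, `animal_id`, `sex` (`F`/`M`), `treatment`
#' (`live`/`HK`), `timepoint` (`pre`/`post`), `cage_id`.
#'
#' @param path File path.
#' @return A data.frame of class `cohort_metadata`.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  cohort_metadata(df)
}

#' Validate and classify a metadata data.frame
#'
#' @param df data.frame with the columns listed in [read_metadata()].
#' @return The data.frame, classed `cohort_metadata`.
#' @export
cohort_metadata <- function(df) {
  need <- c("sample_id", "animal_id", "sex", "treatment", "timepoint", "cage_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  if (!all(df$sex %in% c("F", "M"))) stop("sex must be F or M")
  if (!all(df$treatment %in% c("live", "HK"))) stop("treatment must be live or HK")
  if (!all(df$timepoint %in% c("pre", "post"))) stop("timepoint must be pre or post")
  dup <- duplicated(df[, c("animal_id", "timepoint")])
  if (any(dup)) {
    stop("animal ", df$animal_id[dup][1], " has more than one ",
         df$timepoint[dup][1], " sample")
  }
  class(df) <- c("cohort_metadata", "data.frame")
  df
}

#' @rdname read_metadata
#' @param meta A `cohort_metadata`.
#' @param path Output path.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a rooted phylogenetic tree in Newick format
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] that enforce
#' the invariants UniFrac needs: unique leaf labels and finite non-negative
#' branch lengths.
#'
#' @param path File path.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  validate_tree(tr)
}

#' @rdname read_newick
#' @param tree An [ape::phylo] tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

validate_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels in tree")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("branch lengths must be finite and >= 0")
  }
  tree
}

#' Read a qPCR cycle-threshold table from TSV
#'
#' Columns: `animal_id`, `timepoint`, `assay`, `ct_target`, `ct_reference`
#' (reference = universal 16S assay). Ct values are cycles.
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_qpcr <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("animal_id", "timepoint", "assay", "ct_target", "ct_reference")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("qPCR table missing columns: ", paste(miss, collapse = ", "))
  ct <- c(df$ct_target, df$ct_reference)
  if (any(!is.finite(ct))) stop("Ct values must be finite")
  df
}

#' Read a per-animal phenotype table from TSV
#'
#' First column `animal_id`; remaining columns numeric phenotypes (missing
#' values as NA). Units are whatever each phenotype was measured in.
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (names(df)[1] != "animal_id") stop("first phenotype column must be animal_id")
  if (anyDuplicated(df$animal_id)) stop("duplicate animal_id in phenotype table")
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Check a count table against its cohort metadata and study design
#'
#' Report-based validation: never raises on well-formed inputs. The report
#' lists orphan samples (in the table but not the metadata, or vice versa),
#' animals missing one timepoint, and sex-by-treatment design cells with
#' fewer animals than expected.
#'
#' @param table A `count_table`.
#' @param meta A `cohort_metadata`.
#' @param n_per_cell Expected animals per sex-by-treatment cell (default 8).
#' @return A list with character-vector elements `orphan_samples`,
#'   `orphan_metadata`, `unpaired_animals`, `incomplete_cells`, and logical
#'   `ok` (TRUE iff all empty).
#' @export
validate_cohort <- function(table, meta, n_per_cell = 8) {
  s_tab <- sample_ids(table)
  s_met <- meta$sample_id
  orphan_samples <- setdiff(s_tab, s_met)
  orphan_meta <- setdiff(s_met, s_tab)

  tp <- split(meta$timepoint, meta$animal_id)
  unpaired <- names(tp)[!vapply(tp, function(t) all(c("pre", "post") %in% t), logical(1))]

  animals <- unique(meta[, c("animal_id", "sex", "treatment")])
  cells <- expand.grid(sex = c("F", "M"), treatment = c("live", "HK"),
                       stringsAsFactors = FALSE)
  n_cell <- mapply(function(s, tr) sum(animals$sex == s & animals$treatment == tr),
                   cells$sex, cells$treatment)
  short <- n_cell < n_per_cell
  incomplete <- sprintf("%s/%s: %d of %d animals", cells$sex, cells$treatment,
                        n_cell, n_per_cell)[short]

  rep <- list(orphan_samples = orphan_samples,
              orphan_metadata = orphan_meta,
              unpaired_animals = sort(unpaired),
              incomplete_cells = incomplete)
  rep$ok <- all(lengths(rep[1:4]) == 0)
  rep
}
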