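#' Construct a taxa-by-sample count table
#'
#' The count table is the unit every analysis stage consumes: a non-negative
#' integer matrix with taxa as rows and samples as columns, plus an optional
#' taxonomic lineage string per taxon (ranks separated by `";"`, ordered
#' phylum through species, rank prefixes such as `"g__"` allowed).
#'
#' @param counts Numeric matrix of non-negative integers. Row names are taxon
#'   ids, column names are sample ids; both must be unique.
#' @param lineage Optional character vector of lineage strings, one per taxon
#'   (named by taxon id or in row order). Defaults to the taxon ids.
#' @return An object of class `count_table`: a list with elements `counts`
#'   (integer-valued matrix) and `lineage` (named character vector).
#' @export
count_table <- function(counts, lineage = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count table requires taxon row names and sample column names")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate taxon ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (any(!is.finite(counts))) stop("counts must be finite")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8)) stop("counts must be integral")
  counts <- round(counts)
  storage.mode(counts) <- "double"  # doubles hold exact integers past .Machine$integer.max
  if (is.null(lineage)) {
    lineage <- stats::setNames(rownames(counts), rownames(counts))
  } else {
    if (length(lineage) != nrow(counts)) stop("one lineage per taxon required")
    if (is.null(names(lineage))) names(lineage) <- rownames(counts)
    lineage <- lineage[rownames(counts)]
    if (anyNA(names(lineage))) stop("lineage names must match taxon ids")
  }
  structure(list(counts = counts, lineage = lineage), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d taxa x %d samples, total %s reads\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Taxon and sample accessors
#' @param x A `count_table`.
#' @return Character vector of ids.
#' @export
taxa_ids <- function(x) rownames(x$counts)

#' @rdname taxa_ids
#' @export
sample_ids <- function(x) colnames(x$counts)

#' Subset a count table by taxa and/or samples
#'
#' @param x A `count_table`.
#' @param taxa,samples Character vectors of ids (or logical/integer indices).
#' @return A `count_table`.
#' @export
subset_count_table <- function(x, taxa = NULL, samples = NULL) {
  m <- x$counts
  if (!is.null(taxa)) m <- m[taxa, , drop = FALSE]
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  count_table(m, x$lineage[rownames(m)])
}

RANKS <- c("phylum", "class", "order", "family", "genus", "species")

strip_rank_prefix <- function(x) sub("^[a-zA-Z]__", "", trimws(x))

#' Truncate a lineage string at a taxonomic rank
#'
#' Lineages are `";"`-separated rank labels ordered phylum through species.
#' Ranks unclassified at the requested depth propagate the deepest classified
#' label with an `"unclassified"` marker, mirroring common amplicon practice.
#'
#' @param lineage Character vector of lineage strings.
#' @param rank One of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`, `"species"`.
#' @return Character vector of labels at the requested rank.
#' @export
lineage_at_rank <- function(lineage, rank) {
  rank <- match.arg(rank, RANKS)
  k <- match(rank, RANKS)
  vapply(strsplit(lineage, ";", fixed = TRUE), function(parts) {
    parts <- strip_rank_prefix(parts)
    parts <- parts[nzchar(parts)]
    if (length(parts) == 0) return("unclassified")
    if (length(parts) >= k) return(parts[k])
    paste(parts[length(parts)], "unclassified")
  }, character(1))
}

#' Agglomerate a count table to a taxonomic rank
#'
#' Sums counts of taxa sharing the same lineage label at `rank`.
#'
#' @param x A `count_table`.
#' @param rank Taxonomic rank; see [lineage_at_rank()].
#' @return A `count_table` whose taxon ids are rank-level labels.
#' @export
agglomerate <- function(x, rank) {
  lab <- lineage_at_rank(x$lineage, rank)
  groups <- unique(lab)
  m <- rowsum(x$counts, group = factor(lab, levels = groups))
  count_table(m, stats::setNames(groups, groups))
}

#' Read a taxa-by-sample count table from TSV
#'
#' First column: taxon id (or full lineage string, used as both id and
#' lineage); an optional second column named `lineage` carries the lineage
#' separately; remaining columns: integer counts per sample.
#'
#' @param path File path.
#' @return A `count_table`.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("count table needs a taxon column plus >=1 sample")
  ids <- df[[1]]
  lineage <- stats::setNames(ids, ids)
  if (ncol(df) >= 2 && names(df)[2] == "lineage") {
    lineage <- stats::setNames(df[[2]], ids)
    df <- df[-2]
  }
  num <- df[-1]
  for (j in seq_along(num)) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    bad <- which(is.na(v) & !is.na(num[[j]]))
    if (length(bad)) {
      stop(sprintf("malformed numeric cell at row %d, column '%s': '%s'",
                   bad[1], names(num)[j], num[[j]][bad[1]]))
    }
    num[[j]] <- v
  }
  m <- as.matrix(num)
  rownames(m) <- ids
  count_table(m, lineage)
}

#' Write a count table to TSV
#'
#' A `lineage` column is written after the taxon ids whenever any lineage
#' differs from its id, so rank information survives a round trip.
#'
#' @param x A `count_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  df <- data.frame(taxon = taxa_ids(x), x$counts, check.names = FALSE)
  if (!identical(unname(x$lineage), taxa_ids(x))) {
    df <- data.frame(taxon = taxa_ids(x), lineage = unname(x$lineage),
                     x$counts, check.names = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
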