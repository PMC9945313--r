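#' Alpha diversity metrics
#'
#' Three per-sample summaries on one vector of taxon counts:
#' * `chao1()` — bias-corrected Chao1 richness,
#'   \eqn{S_{obs} + F_1(F_1-1) / (2(F_2+1))}, where \eqn{F_1} and \eqn{F_2}
#'   are the singleton and doubleton counts. Always \eqn{\ge S_{obs}};
#'   equality iff \eqn{F_1 \le 1}.
#' * `shannon_ens()` — Shannon diversity expressed as an effective number of
#'   species, \eqn{\exp(-\sum p_i \ln p_i)} (richness-weighted).
#' * `inv_simpson()` — inverse Simpson, \eqn{1 / \sum p_i^2}
#'   (evenness-weighted).
#'
#' @param counts Non-negative integer vector of per-taxon counts for one
#'   sample; must not be all zero.
#' @return A single number (taxa, or effective taxa).
#' @name alpha_diversity
NULL

check_counts_vec <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("all-zero sample")
  counts
}

#' @rdname alpha_diversity
#' @export
chao1 <- function(counts) {
  counts <- check_counts_vec(counts)
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("chao1 requires integer counts")
  }
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' @rdname alpha_diversity
#' @export
shannon_ens <- function(counts) {
  counts <- check_counts_vec(counts)
  p <- counts[counts > 0] / sum(counts)
  exp(-sum(p * log(p)))
}

#' @rdname alpha_diversity
#' @export
inv_simpson <- function(counts) {
  counts <- check_counts_vec(counts)
  p <- counts / sum(counts)
  1 / sum(p^2)
}

#' Per-sample alpha diversity table
#'
#' @param table A `count_table`.
#' @param rank Optional taxonomic rank to agglomerate to first (default:
#'   none, i.e. the table's own taxon units).
#' @return data.frame with columns sample_id, chao1, shannon_ens,
#'   inv_simpson.
#' @export
alpha_diversity <- function(table, rank = NULL) {
  if (!is.null(rank)) table <- agglomerate(table, rank)
  m <- table$counts
  data.frame(sample_id = colnames(m),
             chao1 = apply(m, 2, chao1),
             shannon_ens = apply(m, 2, shannon_ens),
             inv_simpson = apply(m, 2, inv_simpson),
             row.names = NULL, stringsAsFactors = FALSE)
}
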