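#' Bray-Curtis dissimilarity between two count vectors
#'
#' \eqn{\sum_i |x_i - y_i| / \sum_i (x_i + y_i)}: abundance-based,
#' phylogeny-blind, in \[0, 1\].
#'
#' @param x,y Non-negative count (or normalized-count) vectors on the same
#'   taxon index; not both all-zero.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must share a taxon index")
  if (sum(x) + sum(y) == 0) stop("both samples are all-zero")
  sum(abs(x - y)) / sum(x + y)
}

# edges x tips incidence: does tip t descend from edge e?
# walk each tip up to the root through the child -> parent edge map.
edge_tip_incidence <- function(tree) {
  n_tip <- length(tree$tip.label)
  parent_of <- integer(max(tree$edge))
  edge_of <- integer(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  inc <- matrix(FALSE, nrow(tree$edge), n_tip,
                dimnames = list(NULL, tree$tip.label))
  for (tip in seq_len(n_tip)) {
    node <- tip
    while (node != root) {
      inc[edge_of[node], tip] <- TRUE
      node <- parent_of[node]
    }
  }
  inc
}

match_tree_taxa <- function(x, tree) {
  if (is.null(names(x))) stop("count vectors must be named by taxon id")
  miss <- setdiff(names(x), tree$tip.label)
  if (length(miss)) stop("taxa missing from tree: ", paste(miss, collapse = ", "))
  out <- stats::setNames(numeric(length(tree$tip.label)), tree$tip.label)
  out[names(x)] <- x
  out
}

#' Unweighted UniFrac distance
#'
#' Fraction of total branch length leading exclusively to taxa present
#' (count > 0) in only one of the two samples, over branch length leading to
#' taxa present in either.
#'
#' @param x,y Named count vectors (names = taxon ids, all present as tree
#'   leaves).
#' @param tree Rooted [ape::phylo] tree with branch lengths.
#' @return Distance in \[0, 1\].
#' @export
unweighted_unifrac <- function(x, y, tree) {
  validate_tree(tree)
  x <- match_tree_taxa(x, tree) > 0
  y <- match_tree_taxa(y, tree) > 0
  inc <- edge_tip_incidence(tree)
  in_x <- inc %*% x > 0
  in_y <- inc %*% y > 0
  len <- tree$edge.length
  denom <- sum(len[in_x | in_y])
  if (denom == 0) stop("no branch length subtends either sample")
  sum(len[xor(in_x, in_y)]) / denom
}

#' Weighted UniFrac distance
#'
#' Raw form: \eqn{\sum_b \ell_b |A_b - B_b|}, where \eqn{A_b} is the
#' fraction of sample x's reads descending from branch b. Normalized form
#' (default) divides by \eqn{\sum_b \ell_b (A_b + B_b)} — the maximum the
#' raw value can attain for this tree and these totals — scaling to
#' \[0, 1\].
#'
#' @inheritParams unweighted_unifrac
#' @param normalized Return the \[0, 1\]-scaled form (default TRUE).
#' @return Distance (in \[0, 1\] when normalized).
#' @export
weighted_unifrac <- function(x, y, tree, normalized = TRUE) {
  validate_tree(tree)
  x <- match_tree_taxa(x, tree)
  y <- match_tree_taxa(y, tree)
  if (sum(x) == 0 || sum(y) == 0) stop("zero-total sample")
  px <- x / sum(x)
  py <- y / sum(y)
  inc <- edge_tip_incidence(tree)
  a <- as.numeric(inc %*% px)
  b <- as.numeric(inc %*% py)
  raw <- sum(tree$edge.length * abs(a - b))
  if (!normalized) return(raw)
  denom <- sum(tree$edge.length * (a + b))
  if (denom == 0) stop("no branch length subtends either sample")
  raw / denom
}

#' All-pairs beta-diversity distance matrix
#'
#' @param table A `count_table`.
#' @param metric One of `"bray_curtis"`, `"unifrac"`, `"weighted_unifrac"`.
#' @param tree Rooted tree (required for the UniFrac metrics).
#' @return Symmetric numeric matrix with zero diagonal, sample ids as
#'   dimnames, and the metric name in attribute `"metric"`.
#' @export
beta_diversity <- function(table, metric = c("bray_curtis", "unifrac",
                                             "weighted_unifrac"),
                           tree = NULL) {
  metric <- match.arg(metric)
  m <- table$counts
  n <- ncol(m)
  if (metric != "bray_curtis") {
    if (is.null(tree)) stop("UniFrac metrics require a tree")
    validate_tree(tree)
    miss <- setdiff(rownames(m), tree$tip.label)
    if (length(miss)) stop("taxa missing from tree: ", paste(miss, collapse = ", "))
    # shared incidence across pairs; vectorized over samples
    inc <- edge_tip_incidence(tree)[, rownames(m), drop = FALSE]
    len <- tree$edge.length
    if (metric == "unifrac") {
      pres <- inc %*% (m > 0) > 0             # edges x samples
      d <- matrix(0, n, n)
      for (j in seq_len(n - 1)) for (k in (j + 1):n) {
        d[j, k] <- d[k, j] <-
          sum(len[xor(pres[, j], pres[, k])]) / sum(len[pres[, j] | pres[, k]])
      }
    } else {
      p <- sweep(m, 2, colSums(m), "/")
      ab <- inc %*% p                          # edges x samples
      d <- matrix(0, n, n)
      for (j in seq_len(n - 1)) for (k in (j + 1):n) {
        d[j, k] <- d[k, j] <- sum(len * abs(ab[, j] - ab[, k])) /
          sum(len * (ab[, j] + ab[, k]))
      }
    }
  } else {
    d <- matrix(0, n, n)
    for (j in seq_len(n - 1)) for (k in (j + 1):n) {
      d[j, k] <- d[k, j] <- bray_curtis(m[, j], m[, k])
    }
  }
  dimnames(d) <- list(colnames(m), colnames(m))
  attr(d, "metric") <- metric
  d
}
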