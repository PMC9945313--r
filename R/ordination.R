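check_distance_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  if (any(d < 0)) stop("distances must be >= 0")
  d
}

#' Principal coordinates analysis (classical metric MDS)
#'
#' Double-centers the squared distances, eigendecomposes, and returns
#' coordinates for the positive-eigenvalue axes ordered by decreasing
#' eigenvalue. Negative eigenvalues (non-Euclidean distances) are reported
#' but their axes are not part of `$coordinates`.
#'
#' @param d Symmetric distance matrix (zero diagonal).
#' @return List with `coordinates` (samples x axes), `eigenvalues` (all,
#'   decreasing), and `negative_axes` (samples x axes built from
#'   `sqrt(-eigenvalue)`, used internally by [betadisper()]).
#' @export
pcoa <- function(d) {
  d <- check_distance_matrix(d)
  n <- nrow(d)
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% (d^2) %*% j
  b <- (b + t(b)) / 2
  e <- eigen(b, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  neg <- which(e$values < -tol)
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]),
                                                    length(pos))
  rownames(coords) <- rownames(d)
  if (length(pos)) colnames(coords) <- paste0("PCo", seq_along(pos))
  neg_axes <- e$vectors[, neg, drop = FALSE] %*% diag(sqrt(-e$values[neg]),
                                                      length(neg))
  rownames(neg_axes) <- rownames(d)
  list(coordinates = coords, eigenvalues = e$values, negative_axes = neg_axes)
}

permanova_ss <- function(d2, groups) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1) {
      sub <- d2[idx, idx]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  c(total = ss_total, within = ss_within, between = ss_total - ss_within)
}

#' Single-factor PERMANOVA
#'
#' Partitions the distance matrix's sum of squares by a grouping factor:
#' \eqn{SS_{total} = \frac{1}{N}\sum_{j<k} d_{jk}^2},
#' \eqn{SS_{within} = \sum_g \frac{1}{n_g}\sum_{j<k \in g} d_{jk}^2},
#' pseudo-F \eqn{= \frac{SS_{between}/(a-1)}{SS_{within}/(N-a)}}, and
#' \eqn{R^2 = SS_{between}/SS_{total}}. Significance by free permutation of
#' the group labels; p uses the `(1 + count) / (1 + n_perm)` convention, so
#' its resolution is `1/(n_perm + 1)`.
#'
#' @param d Distance matrix with sample-id dimnames.
#' @param labels Factor (or vector) of group labels, one per sample, in the
#'   matrix's sample order (or named by sample id).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream (required).
#' @return List with `variable`, `R2`, `F`, `p`, `n_perm`, `seed`, `df`.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = 1,
                      variable = deparse(substitute(labels))) {
  d <- check_distance_matrix(d)
  if (!is.null(names(labels)) && !is.null(rownames(d))) {
    labels <- labels[rownames(d)]
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(d)) stop("one label per sample required")
  tab <- table(labels)
  if (length(tab) < 2) stop("need >= 2 groups")
  if (any(tab == 0)) stop("empty group")
  n <- nrow(d)
  a <- length(tab)
  d2 <- d^2
  if (sum(d2) == 0) {
    warning("all distances are zero; PERMANOVA undefined")
    return(list(variable = variable, R2 = 0, F = NA_real_, p = NA_real_,
                n_perm = n_perm, seed = seed,
                df = c(between = a - 1, within = n - a)))
  }
  f_stat <- function(gr) {
    ss <- permanova_ss(d2, gr)
    (ss["between"] / (a - 1)) / (ss["within"] / (n - a))
  }
  ss <- permanova_ss(d2, labels)
  f_obs <- unname((ss["between"] / (a - 1)) / (ss["within"] / (n - a)))
  r2 <- unname(ss["between"] / ss["total"])
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm),
               function(i) unname(f_stat(sample(labels))) >= f_obs - 1e-12,
               logical(1)))
  })
  list(variable = variable, R2 = r2, F = f_obs,
       p = (1 + hits) / (1 + n_perm), n_perm = n_perm, seed = seed,
       df = c(between = a - 1, within = n - a))
}

#' Homogeneity of multivariate dispersion
#'
#' Embeds the samples by PCoA (retaining negative-eigenvalue axes as
#' imaginary components: squared distances on those axes are subtracted),
#' computes each sample's distance to its group centroid, and tests equality
#' of mean dispersion with a one-way F whose null distribution comes from
#' permuting group labels. Centroids (not spatial medians) are used.
#' Singleton groups get a zero distance to their own centroid but are
#' excluded from the F test with a warning.
#'
#' @inheritParams permanova
#' @return List with `distances` (named per sample), `group_means`, `F`,
#'   `p`, `n_perm`, `seed`.
#' @export
betadisper <- function(d, labels, n_perm = 999, seed = 1) {
  d <- check_distance_matrix(d)
  if (!is.null(names(labels)) && !is.null(rownames(d))) {
    labels <- labels[rownames(d)]
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(d)) stop("one label per sample required")
  if (sum(d^2) == 0) {
    warning("all distances are zero; dispersion test undefined")
    return(list(distances = stats::setNames(numeric(nrow(d)), rownames(d)),
                group_means = tapply(numeric(nrow(d)), labels, mean),
                F = NA_real_, p = NA_real_, n_perm = n_perm, seed = seed))
  }
  emb <- pcoa(d)
  re <- emb$coordinates
  im <- emb$negative_axes

  dist_to_centroid <- function(gr) {
    out <- numeric(length(gr))
    for (g in unique(gr)) {
      idx <- which(gr == g)
      c_re <- colMeans(re[idx, , drop = FALSE])
      d2 <- colSums((t(re[idx, , drop = FALSE]) - c_re)^2)
      if (ncol(im) > 0) {
        c_im <- colMeans(im[idx, , drop = FALSE])
        d2 <- d2 - colSums((t(im[idx, , drop = FALSE]) - c_im)^2)
      }
      out[idx] <- sqrt(pmax(d2, 0))
    }
    out
  }
  anova_f <- function(z, gr) {
    keep <- gr %in% names(which(table(gr) > 1))
    z <- z[keep]; gr <- gr[keep]
    k <- length(unique(gr))
    if (k < 2) return(NA_real_)
    grand <- mean(z)
    mg <- tapply(z, gr, mean)
    ng <- tapply(z, gr, length)
    ss_b <- sum(ng * (mg - grand)^2)
    ss_w <- sum((z - mg[gr])^2)
    (ss_b / (k - 1)) / (ss_w / (length(z) - k))
  }

  if (any(table(labels) == 1)) {
    warning("singleton group(s) excluded from the dispersion F test")
  }
  z_obs <- dist_to_centroid(labels)
  f_obs <- anova_f(z_obs, labels)
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      gr <- sample(labels)
      f <- anova_f(dist_to_centroid(gr), gr)
      !is.na(f) && f >= f_obs - 1e-12
    }, logical(1)))
  })
  list(distances = stats::setNames(z_obs, rownames(d)),
       group_means = tapply(z_obs, labels, mean),
       F = f_obs, p = (1 + hits) / (1 + n_perm),
       n_perm = n_perm, seed = seed)
}
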