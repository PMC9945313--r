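# Independent brute-force oracles. These re-derive each statistic from its
# definition by an intentionally different route than the implementation.

# UniFrac via per-branch enumeration using phangorn's descendant lists
oracle_unifrac <- function(x, y, tree, weighted = FALSE, normalized = TRUE) {
  tips <- tree$tip.label
  x <- x[tips]; y <- y[tips]
  uniq <- 0; tot <- 0
  px <- x / sum(x); py <- y / sum(y)
  raw <- 0; denom <- 0
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    desc <- if (child <= length(tips)) child else
      phangorn::Descendants(tree, child, "tips")[[1]]
    len <- tree$edge.length[e]
    if (weighted) {
      a <- sum(px[desc]); b <- sum(py[desc])
      raw <- raw + len * abs(a - b)
      denom <- denom + len * (a + b)
    } else {
      in_x <- any(x[desc] > 0); in_y <- any(y[desc] > 0)
      if (xor(in_x, in_y)) uniq <- uniq + len
      if (in_x || in_y) tot <- tot + len
    }
  }
  if (weighted) { if (normalized) raw / denom else raw } else uniq / tot
}

# PERMANOVA sums of squares straight from the definitional double loop
oracle_permanova_r2_f <- function(d, labels) {
  n <- nrow(d)
  ss_total <- 0
  for (j in 1:(n - 1)) for (k in (j + 1):n) ss_total <- ss_total + d[j, k]^2
  ss_total <- ss_total / n
  ss_within <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    acc <- 0
    if (length(idx) > 1) {
      for (a in 1:(length(idx) - 1)) for (b in (a + 1):length(idx)) {
        acc <- acc + d[idx[a], idx[b]]^2
      }
    }
    ss_within <- ss_within + acc / length(idx)
  }
  a <- length(unique(labels))
  ss_b <- ss_total - ss_within
  c(R2 = ss_b / ss_total,
    F = (ss_b / (a - 1)) / (ss_within / (n - a)))
}

# BH step-up by the literal min-over-larger-p definition
oracle_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    min(1, min(m * p[p >= p[i]] / r[p >= p[i]]))
  }, numeric(1))
}

# vole-by-vole selection by per-taxon loop
oracle_vbv <- function(l, theta_ind, theta_avg, super) {
  out <- list()
  for (tx in rownames(l)) {
    v <- l[tx, ]
    mu <- mean(v)
    if (sum(v >= theta_ind) >= super && mu >= theta_avg) {
      out[[tx]] <- c(dir = "up", n = sum(v >= theta_ind))
    } else if (sum(v <= -theta_ind) >= super && mu <= -theta_avg) {
      out[[tx]] <- c(dir = "down", n = sum(v <= -theta_ind))
    }
  }
  out
}

# exact two-tailed Mann-Whitney p by enumerating every group assignment
oracle_mw_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r_all <- rank(pooled)
  u_of <- function(idx) {
    u1 <- sum(r_all[idx]) - n1 * (n1 + 1) / 2
    min(u1, n1 * n2 - u1)
  }
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, u_of)
  # min-U folds both tails already: P(U_min <= u_obs) is the two-sided p
  min(1, mean(us <= u_obs))
}

# exact two-tailed signed-rank p by enumerating all 2^n sign patterns
oracle_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  m <- n * (n + 1) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% r
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# small deterministic count table fixture
tiny_table <- function() {
  m <- matrix(c(10, 20, 4, 8, 6, 18), nrow = 3, byrow = TRUE,
              dimnames = list(c("tA", "tB", "tC"), c("s1", "s2")))
  count_table(m)
}

# balanced synthetic cohort, small enough for fast tests
small_cohort <- function(seed = 1, n_taxa = 30, n_per_cell = 8, ...) {
  generate_cohort(cohort_design(n_per_cell = n_per_cell, n_taxa = n_taxa,
                                seed = seed), ...)
}
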