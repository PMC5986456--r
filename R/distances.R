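#' Jensen-Shannon distance between two relative-abundance vectors
#'
#' Returns `sqrt(JSD(p, q))` with logarithms in `base` (default 2, so the
#' range is \[0, 1\]). Zero entries contribute zero by the `0 * log 0 = 0`
#' convention.
#'
#' @param p,q nonnegative vectors of equal length, each summing to 1 within
#'   1e-9.
#' @param base logarithm base (the enterotyping literature varies; 2 gives the
#'   metric form bounded by 1).
#' @return scalar distance.
#' @export
jsd_distance <- function(p, q, base = 2) {
  if (length(p) != length(q)) stopf("length mismatch: %d vs %d",
                                    length(p), length(q))
  if (any(p < 0) || any(q < 0)) stopf("negative entries in input vectors")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    stopf("inputs must each sum to 1 (got %.6g and %.6g)", sum(p), sum(q))
  m <- (p + q) / 2
  kl <- function(a) {
    nz <- a > 0
    sum(a[nz] * (log(a[nz] / m[nz]) / log(base)))
  }
  sqrt(pmax(0, (kl(p) + kl(q)) / 2))
}

#' Bray-Curtis dissimilarity
#'
#' `1 - 2 * sum(min(x, y)) / (sum(x) + sum(y))`.
#'
#' @param x,y nonnegative vectors of equal length, not both all-zero.
#' @return scalar dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stopf("length mismatch")
  if (any(x < 0) || any(y < 0)) stopf("negative entries")
  s <- sum(x) + sum(y)
  if (s == 0) stopf("both vectors are all-zero")
  1 - 2 * sum(pmin(x, y)) / s
}

# Per-branch leaf-descendant abundance profiles: returns list(b = branch
# lengths, P = branches x samples matrix of subtree abundances). One
# post-order accumulation; tree leaves absent from the table count as zero.
branch_abundances <- function(table, tree) {
  validate_tree(tree)
  taxa <- taxon_ids(table)
  unmapped <- setdiff(taxa, tree$tip.label)
  if (length(unmapped))
    stopf("taxa not mapped to any tree leaf: %s",
          paste(unmapped, collapse = ", "))
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  n_samp <- nrow(table$values)
  P <- matrix(0, nrow = n_node, ncol = n_samp)
  tip_ix <- match(taxa, tree$tip.label)
  P[tip_ix, ] <- t(table$values)
  tr <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
    P[parent, ] <- P[parent, ] + P[child, ]
  }
  # one row per edge, abundance of the subtree below the edge's child
  list(b = tr$edge.length, P = P[tr$edge[, 2L], , drop = FALSE])
}

#' Generalized UniFrac distance matrix
#'
#' For each sample pair (A, B) the distance is
#' `sum_i b_i (pA_i + pB_i)^alpha |pA_i - pB_i| / (pA_i + pB_i)` divided by
#' `sum_i b_i (pA_i + pB_i)^alpha`, summing over all branches i with
#' `pA_i + pB_i > 0`, where `p_X_i` is the total relative abundance of leaves
#' below branch i in sample X. `alpha = 1` recovers the weighted-UniFrac-style
#' normalization; `alpha = 0.5` (default) is the usual variance-stabilized
#' compromise.
#'
#' @param table relative-mode [abundance_table] whose taxa all map to tree
#'   leaves.
#' @param tree rooted `phylo` tree with branch lengths.
#' @param alpha abundance weighting exponent in \[0, 1\].
#' @return a [dist_matrix].
#' @export
generalized_unifrac <- function(table, tree, alpha = 0.5) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$mode != "relative") stopf("generalized UniFrac needs a relative table")
  if (alpha < 0 || alpha > 1) stopf("alpha must be in [0, 1]")
  ba <- branch_abundances(table, tree)
  n <- nrow(table$values)
  D <- matrix(0, n, n, dimnames = list(sample_ids(table), sample_ids(table)))
  if (n > 1L) for (i in seq_len(n - 1L)) {
    rest <- seq(i + 1L, n)
    A <- ba$P[, i]
    B <- ba$P[, rest, drop = FALSE]
    S <- B + A
    W <- ba$b * S^alpha            # branches x m
    W[S == 0] <- 0                 # skip empty branches even when alpha = 0
    ratio <- abs(B - A) / S
    ratio[S == 0] <- 0
    den <- colSums(W)
    if (any(den == 0))
      stopf("pair (%s, %s): no branch carries abundance", sample_ids(table)[i],
            sample_ids(table)[rest][which(den == 0)[1]])
    D[i, rest] <- D[rest, i] <- colSums(W * ratio) / den
  }
  dist_matrix(D)
}

gunifrac_pair <- function(pa, pb, b, alpha) {
  s <- pa + pb
  keep <- s > 0
  if (!any(keep)) stopf("no branch carries abundance for this pair")
  w <- b[keep] * s[keep]^alpha
  den <- sum(w)
  if (den == 0) return(0)
  sum(w * abs(pa[keep] - pb[keep]) / s[keep]) / den
}

#' Construct a validated distance matrix
#'
#' Symmetric (within 1e-12) nonnegative matrix with zero diagonal over sample
#' ids.
#'
#' @param m square numeric matrix with matching dimnames.
#' @return object of class `dist_matrix` (a plain matrix underneath).
#' @export
dist_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stopf("distance matrix must be square")
  if (is.null(rownames(m))) {
    ids <- paste0("S", seq_len(nrow(m)))
    dimnames(m) <- list(ids, ids)
  }
  if (!identical(rownames(m), colnames(m)))
    stopf("row and column ids differ")
  if (any(abs(m - t(m)) > 1e-12)) stopf("matrix is not symmetric")
  if (any(diag(m) != 0)) stopf("diagonal must be zero")
  if (any(m < 0)) stopf("negative dissimilarities")
  m <- (m + t(m)) / 2
  class(m) <- c("dist_matrix", "matrix", "array")
  m
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix over %d samples (mean off-diagonal %.4g)\n",
              nrow(x), if (nrow(x) > 1) mean(x[upper.tri(x)]) else 0))
  invisible(x)
}

#' Pairwise distance matrix under a named metric
#'
#' @param table relative-mode [abundance_table].
#' @param metric `"jsd"`, `"bray_curtis"` or `"gunifrac"`.
#' @param tree required for `"gunifrac"`.
#' @param alpha generalized-UniFrac exponent.
#' @param base JSD logarithm base.
#' @return a [dist_matrix].
#' @export
pairwise_matrix <- function(table, metric = c("jsd", "bray_curtis", "gunifrac"),
                            tree = NULL, alpha = 0.5, base = 2) {
  metric <- match.arg(metric)
  stopifnot(inherits(table, "abundance_table"))
  if (metric == "gunifrac") {
    if (is.null(tree)) stopf("metric 'gunifrac' requires a tree")
    return(generalized_unifrac(table, tree, alpha))
  }
  if (table$mode != "relative" && metric == "jsd")
    stopf("metric 'jsd' needs a relative table")
  X <- table$values
  n <- nrow(X)
  D <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  if (metric == "jsd") {
    # H(m) - (H(p) + H(q))/2 formulation, vectorized one row at a time
    lb <- log(base)
    H <- function(M) {
      L <- ifelse(M > 0, log(M) / lb, 0)
      -rowSums(M * L)
    }
    h <- H(X)
    if (n > 1L) for (i in seq_len(n - 1L)) {
      rest <- seq(i + 1L, n)
      M <- (X[rest, , drop = FALSE] +
              matrix(X[i, ], length(rest), ncol(X), byrow = TRUE)) / 2
      jsd <- pmax(0, H(M) - (h[rest] + h[i]) / 2)
      D[i, rest] <- D[rest, i] <- sqrt(jsd)
    }
  } else {
    rs <- rowSums(X)
    if (n > 1L) for (i in seq_len(n - 1L)) {
      rest <- seq(i + 1L, n)
      mins <- rowSums(pmin(X[rest, , drop = FALSE],
                           matrix(X[i, ], length(rest), ncol(X), byrow = TRUE)))
      tot <- rs[rest] + rs[i]
      if (any(tot == 0))
        stopf("pair (%s, %s): both vectors all-zero", rownames(X)[i],
              rownames(X)[rest][which(tot == 0)[1]])
      D[i, rest] <- D[rest, i] <- 1 - 2 * mins / tot
    }
  }
  dist_matrix(D)
}

#' Write / read a distance matrix as square TSV
#' @param d a [dist_matrix].
#' @param path file path.
#' @export
write_dist_tsv <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), unclass(d), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dist_tsv
#' @export
read_dist_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  dist_matrix(m)
}
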