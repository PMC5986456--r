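# Shared fixtures and independent oracles. Every oracle here recomputes the
# target quantity by a route independent of the package implementation
# (explicit enumeration, closed forms, or direct definitions).

# ---- fixtures -------------------------------------------------------------

tiny_table <- function() {
  vals <- matrix(c(10, 20, 30, 40,
                   5, 5, 45, 45,
                   1, 2, 3, 4), nrow = 3, byrow = TRUE,
                 dimnames = list(c("s1", "s2", "s3"),
                                 c("Bacteroides", "Prevotella", "Blautia",
                                   "Dorea")))
  lin <- data.frame(
    kingdom = "Bacteria",
    phylum = c("Bacteroidetes", "Bacteroidetes", "Firmicutes", "Firmicutes"),
    family = c("Bacteroidaceae", "Prevotellaceae", "Lachnospiraceae",
               "Lachnospiraceae"),
    genus = c("Bacteroides", "Prevotella", "Blautia", "Dorea"),
    stringsAsFactors = FALSE)
  abundance_table(vals, lineage = lin, mode = "counts")
}

tiny_tsv <- function(path) {
  writeLines(c(
    "lineage\ts1\ts2\ts3",
    "k__Bacteria;p__Bacteroidetes;f__Bacteroidaceae;g__Bacteroides\t10\t5\t1",
    "k__Bacteria;p__Bacteroidetes;f__Prevotellaceae;g__Prevotella\t20\t5\t2",
    "k__Bacteria;p__Firmicutes;f__Lachnospiraceae;g__Blautia\t30\t45\t3",
    "k__Bacteria;p__Firmicutes;f__Lachnospiraceae;g__Dorea\t40\t45\t4"),
    path)
  path
}

toy_tree3 <- function() {
  # 3 leaves, printed branch lengths
  ape::read.tree(text = "((A:0.5,B:0.25):0.75,C:1.0):0;")
}

random_rel_table <- function(n, p, seed = 1, prefix = "S") {
  withr::with_seed(seed, {
    m <- matrix(stats::rgamma(n * p, 1), n, p)
    m <- m / rowSums(m)
    dimnames(m) <- list(paste0(prefix, seq_len(n)), paste0("t", seq_len(p)))
    abundance_table(m, mode = "relative")
  })
}

# ---- oracles --------------------------------------------------------------

# JSD by direct elementwise summation of the two KL terms
jsd_oracle <- function(p, q, base = 2) {
  m <- (p + q) / 2
  term <- function(a) {
    out <- 0
    for (i in seq_along(a)) {
      if (a[i] > 0) out <- out + a[i] * log(a[i] / m[i], base = base)
    }
    out
  }
  sqrt((term(p) + term(q)) / 2)
}

# generalized UniFrac by explicit per-branch enumeration (recursive descent)
gunifrac_oracle <- function(tree, pa, pb, alpha) {
  ntip <- length(tree$tip.label)
  tips_below <- function(node) {
    if (node <= ntip) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  num <- den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- tips_below(tree$edge[e, 2])
    wa <- sum(pa[tree$tip.label[tips]])
    wb <- sum(pb[tree$tip.label[tips]])
    s <- wa + wb
    if (s > 0) {
      w <- tree$edge.length[e] * s^alpha
      num <- num + w * abs(wa - wb) / s
      den <- den + w
    }
  }
  num / den
}

# exhaustive PAM: minimal total distance-to-medoid cost over all medoid sets
pam_oracle_cost <- function(d, k) {
  n <- nrow(d)
  sets <- utils::combn(n, k)
  min(apply(sets, 2, function(m)
    sum(apply(d[, m, drop = FALSE], 1, min))))
}

# Calinski-Harabasz from raw Euclidean coordinates
ch_oracle <- function(X, labels) {
  n <- nrow(X)
  k <- length(unique(labels))
  grand <- colMeans(X)
  tot <- sum(sweep(X, 2, grand)^2)
  within <- sum(vapply(unique(labels), function(g) {
    Xg <- X[labels == g, , drop = FALSE]
    sum(sweep(Xg, 2, colMeans(Xg))^2)
  }, numeric(1)))
  ((tot - within) / (k - 1)) / (within / (n - k))
}

# PERMANOVA sums of squares by explicit pair enumeration
permanova_oracle <- function(d, groups) {
  n <- nrow(d)
  k <- length(unique(groups))
  sst <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) sst <- sst + d[i, j]^2
  sst <- sst / n
  ssw <- 0
  for (g in unique(groups)) {
    ix <- which(groups == g)
    acc <- 0
    if (length(ix) > 1) {
      for (a in seq_len(length(ix) - 1)) for (b in seq(a + 1, length(ix)))
        acc <- acc + d[ix[a], ix[b]]^2
    }
    ssw <- ssw + acc / length(ix)
  }
  ssb <- sst - ssw
  list(F = (ssb / (k - 1)) / (ssw / (n - k)), R2 = ssb / sst,
       omega2 = (ssb - (k - 1) * ssw / (n - k)) / (sst + ssw / (n - k)))
}

# BH by its step-up definition on sorted p-values
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m * sorted[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# two-sided Fisher p by direct enumeration with choose()
fisher_oracle <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  prob <- vapply(xs, function(x)
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1), numeric(1))
  p_obs <- prob[xs == m[1, 1]]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
mw_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r_obs <- sum(rank(pooled)[seq_len(n1)])
  sets <- utils::combn(length(pooled), n1)
  rs <- apply(sets, 2, function(ix) sum(rank(pooled)[ix]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(rs - mu) >= abs(r_obs - mu) - 1e-9)
}
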