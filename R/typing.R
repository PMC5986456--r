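#' Partitioning around medoids (deterministic)
#'
#' Classical k-medoids on a precomputed dissimilarity matrix. Small instances
#' (`choose(n, k) <= 5000`) are solved exactly by enumerating every medoid
#' set — BUILD+SWAP is a descent heuristic for precisely this objective and
#' can stall in single-swap local optima even on tiny inputs, as does the
#' canonical reference implementation. Larger instances use greedy BUILD
#' seeding followed by best-improvement SWAP descent. There is no randomness:
#' ties break to the lowest sample index, so results depend only on the
#' matrix.
#'
#' @param dist a [dist_matrix].
#' @param k number of clusters (2..n allowed; k = n yields cost 0).
#' @return a `typing_result`: `k`, `labels` (1..k, named by sample, clusters
#'   numbered by ascending medoid index), `medoids` (sample ids), `cost`.
#' @export
pam_fit <- function(dist, k) {
  d <- unclass(dist_matrix(dist))
  n <- nrow(d)
  if (k < 1 || k > n) stopf("k = %d outside 1..%d", k, n)
  ids <- rownames(d)

  if (choose(n, k) <= 5000) {
    sets <- utils::combn(n, k)
    costs <- apply(sets, 2L, function(m)
      sum(.rowMins(d[, m, drop = FALSE])))
    med <- sets[, which.min(costs)]      # combn order -> lowest indices win
    return(finish_pam(d, med, k, ids))
  }

  # BUILD
  med <- which.min(colSums(d))
  dn <- d[, med]
  while (length(med) < k) {
    cand <- setdiff(seq_len(n), med)
    gain <- vapply(cand, function(c) sum(pmax(dn - d[, c], 0)), numeric(1))
    best <- cand[which.max(gain)]          # which.max -> lowest index on ties
    med <- c(med, best)
    dn <- pmin(dn, d[, best])
  }

  nearest_info <- function(med) {
    dm <- d[, med, drop = FALSE]
    ord1 <- max.col(-dm, ties.method = "first")
    dn <- dm[cbind(seq_len(n), ord1)]
    ds <- if (length(med) > 1L) {
      dm2 <- dm
      dm2[cbind(seq_len(n), ord1)] <- Inf
      dm2[cbind(seq_len(n), max.col(-dm2, ties.method = "first"))]
    } else rep(Inf, n)
    list(dn = dn, n1 = med[ord1], ds = ds)
  }

  # SWAP: cost change of swapping medoid m for candidate h, all pairs per pass
  if (k < n) repeat {
    ni <- nearest_info(med)
    cand <- setdiff(seq_len(n), med)
    best <- list(delta = -1e-12, m = NA, h = NA)
    for (h in cand) {
      dh <- d[, h]
      A <- pmin(dh - ni$dn, 0)
      sumA <- sum(A)
      byA <- rowsum_by(A, ni$n1, med)
      byB <- rowsum_by(pmin(dh, ni$ds) - ni$dn, ni$n1, med)
      delta <- sumA - byA + byB            # per medoid in `med` order
      dmin <- min(delta)
      ties <- which(delta <= dmin + 1e-12)
      i <- ties[which.min(med[ties])]      # ties -> lowest medoid index
      if (dmin < best$delta - 1e-12) {     # ties across h keep the lowest h
        best <- list(delta = dmin, m = med[i], h = h)
      }
    }
    if (is.na(best$m) || best$delta >= -1e-12) break
    med[med == best$m] <- best$h
  }
  finish_pam(d, med, k, ids)
}

.rowMins <- function(m) m[cbind(seq_len(nrow(m)),
                                max.col(-m, ties.method = "first"))]

finish_pam <- function(d, med, k, ids) {
  n <- nrow(d)
  med <- sort(med)
  dm <- d[, med, drop = FALSE]
  lab <- max.col(-dm, ties.method = "first")
  cost <- sum(dm[cbind(seq_len(n), lab)])
  structure(list(k = k, labels = stats::setNames(lab, ids),
                 medoids = ids[med], cost = cost, quality = NULL),
            class = "typing_result")
}

rowsum_by <- function(x, groups, levels) {
  out <- numeric(length(levels))
  agg <- rowsum(x, group = groups)
  out[match(as.integer(rownames(agg)), levels)] <- agg[, 1L]
  out
}

#' @export
print.typing_result <- function(x, ...) {
  cat(sprintf("typing_result: k = %d, sizes = %s, cost = %.4g\n", x$k,
              paste(tabulate(x$labels, x$k), collapse = "/"), x$cost))
  invisible(x)
}

#' Calinski-Harabasz index of a labelled distance matrix
#'
#' The index is computed on the classical-MDS (principal coordinates)
#' embedding of the distance matrix, retaining every axis with a positive
#' eigenvalue: `(trace(B)/(k-1)) / (trace(W)/(n-k))` with B and W the
#' between/within scatter of the embedded points. For genuinely Euclidean
#' distances this equals the coordinate-based definition.
#'
#' @param dist a [dist_matrix].
#' @param labels cluster assignment (>= 2 non-empty clusters, k < n).
#' @return scalar index (larger = better separated).
#' @export
calinski_harabasz <- function(dist, labels) {
  d <- unclass(dist_matrix(dist))
  n <- nrow(d)
  labels <- as.integer(factor(labels))
  if (length(labels) != n) stopf("labels length != matrix size")
  k <- length(unique(labels))
  if (k < 2) stopf("need at least 2 clusters")
  if (k >= n) stopf("index undefined for k = n")
  X <- pcoa_embed(d)
  grand <- colMeans(X)
  tot <- sum(sweep(X, 2L, grand)^2)
  within <- 0
  for (g in unique(labels)) {
    Xg <- X[labels == g, , drop = FALSE]
    within <- within + sum(sweep(Xg, 2L, colMeans(Xg))^2)
  }
  between <- tot - within
  (between / (k - 1)) / (within / (n - k))
}

# classical MDS retaining positive-eigenvalue axes
pcoa_embed <- function(d, tol = 1e-9) {
  n <- nrow(d)
  D2 <- d^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D2 %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values), 1)
  if (!any(keep)) stopf("no positive eigenvalue in PCoA embedding")
  e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]),
                                           nrow = sum(keep))
}

#' Mean silhouette width of a labelled distance matrix
#'
#' Standard silhouette per sample averaged over samples; members of singleton
#' clusters contribute 0 by convention.
#'
#' @inheritParams calinski_harabasz
#' @return scalar in \[-1, 1\].
#' @export
mean_silhouette <- function(dist, labels) {
  d <- unclass(dist_matrix(dist))
  n <- nrow(d)
  labels <- as.integer(factor(labels))
  if (length(labels) != n) stopf("labels length != matrix size")
  ks <- unique(labels)
  if (length(ks) < 2) stopf("need at least 2 clusters")
  sizes <- tabulate(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    g <- labels[i]
    if (sizes[g] == 1L) { s[i] <- 0; next }
    a <- sum(d[i, labels == g]) / (sizes[g] - 1L)
    b <- min(vapply(setdiff(ks, g), function(h) mean(d[i, labels == h]),
                    numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# shared k-sweep: PAM for each k, quality by criterion, pick the best
typing_sweep <- function(d, k_range, criterion = c("ch", "silhouette")) {
  criterion <- match.arg(criterion)
  n <- nrow(d)
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) > n - 1L) {
    warnf("k range truncated to 2..%d (n = %d)", n - 1L, n)
    k_range <- k_range[k_range <= n - 1L]
  }
  k_range <- k_range[k_range >= 2L]
  if (!length(k_range)) stopf("no admissible k in range for n = %d", n)
  fits <- lapply(k_range, function(k) pam_fit(d, k))
  qual <- vapply(seq_along(k_range), function(i) {
    if (criterion == "ch") calinski_harabasz(d, fits[[i]]$labels)
    else mean_silhouette(d, fits[[i]]$labels)
  }, numeric(1))
  best <- which(qual >= max(qual) - 1e-12)[1L]   # ties -> smaller k
  out <- fits[[best]]
  out$quality <- stats::setNames(qual, k_range)
  out$criterion <- criterion
  out
}

#' Enterotype a genus-level relative abundance table
#'
#' Builds the Jensen-Shannon distance matrix, runs PAM for each k in
#' `k_range`, and selects the k maximizing the Calinski-Harabasz index (ties
#' go to the smaller k).
#'
#' @param table genus-level relative [abundance_table].
#' @param k_range candidate cluster counts (truncated with a warning when the
#'   sample count is too small).
#' @param base JSD logarithm base.
#' @return a `typing_result` with per-k quality scores in `$quality`.
#' @export
enterotype <- function(table, k_range = 2:10, base = 2) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$mode != "relative") stopf("enterotype needs a relative table")
  d <- pairwise_matrix(table, "jsd", base = base)
  out <- typing_sweep(unclass(d), k_range, "ch")
  out$dist <- d
  out
}

#' Permatype: bootstrap stability refinement of enterotypes
#'
#' Fits the base enterotype, then re-clusters bootstrap resamples of the
#' cohort (with the base k), maps each replicate's clusters onto the base
#' clusters by maximal overlap, and scores every sample by the fraction of
#' replicates (containing it) that agree with its base assignment. Samples at
#' or above `threshold` keep their base label and form the shrunken core
#' clusters; the rest are unclassified. Deterministic given `seed`; resampling
#' is indexed by sorted sample id so the result does not depend on input
#' sample order.
#'
#' @param table genus-level relative [abundance_table].
#' @param n_bootstrap number of bootstrap replicates (>= 10).
#' @param threshold stability cut-off in \[0, 1\].
#' @param seed RNG seed.
#' @param k_range candidate k for the base fit.
#' @param base JSD logarithm base.
#' @return a `permatype_result`: `base` (typing_result), `stability`,
#'   `core_labels`, `unclassified`, `n_skipped`, plus the run parameters.
#' @export
permatype <- function(table, n_bootstrap = 100, threshold = 0.8, seed = 1,
                      k_range = 2:10, base = 2) {
  stopifnot(inherits(table, "abundance_table"))
  if (n_bootstrap < 10) stopf("n_bootstrap must be >= 10")
  ord <- order(sample_ids(table))
  tab <- table
  tab$values <- tab$values[ord, , drop = FALSE]
  d_full <- unclass(pairwise_matrix(tab, "jsd", base = base))
  base_fit <- typing_sweep(d_full, k_range, "ch")
  k0 <- base_fit$k
  n <- nrow(d_full)
  base_lab <- base_fit$labels

  appearances <- numeric(n)
  agreements <- numeric(n)
  n_skipped <- 0L
  with_seed(seed, {
    for (b in seq_len(n_bootstrap)) {
      draw <- sample.int(n, n, replace = TRUE)
      uniq <- sort(unique(draw))
      if (length(uniq) <= k0) { n_skipped <- n_skipped + 1L; next }
      fit <- pam_fit(d_full[uniq, uniq, drop = FALSE], k0)
      mapping <- match_clusters(fit$labels, base_lab[uniq], k0)
      if (anyNA(mapping)) { n_skipped <- n_skipped + 1L; next }
      mapped <- mapping[fit$labels]
      appearances[uniq] <- appearances[uniq] + 1
      agreements[uniq] <- agreements[uniq] + (mapped == base_lab[uniq])
    }
  })
  if (n_skipped > 0.2 * n_bootstrap)
    stopf("%d of %d bootstrap replicates unmatched", n_skipped, n_bootstrap)
  stability <- ifelse(appearances > 0, agreements / appearances, NA_real_)
  names(stability) <- names(base_lab)
  core <- !is.na(stability) & stability >= threshold
  structure(list(base = base_fit,
                 stability = stability,
                 core_labels = base_lab[core],
                 unclassified = names(base_lab)[!core],
                 n_bootstrap = n_bootstrap, n_skipped = n_skipped,
                 threshold = threshold, seed = seed),
            class = "permatype_result")
}

# greedy maximal-overlap assignment of replicate clusters to base clusters;
# ties by larger replicate cluster, then lower indices
match_clusters <- function(rep_lab, base_lab, k) {
  C <- matrix(0L, k, k)
  for (i in seq_along(rep_lab)) {
    C[rep_lab[i], base_lab[i]] <- C[rep_lab[i], base_lab[i]] + 1L
  }
  sizes <- tabulate(rep_lab, k)
  mapping <- rep(NA_integer_, k)
  used_r <- used_b <- logical(k)
  for (step in seq_len(k)) {
    Cm <- C
    Cm[used_r, ] <- -1L
    Cm[, used_b] <- -1L
    mx <- max(Cm)
    if (mx < 0) break
    hits <- which(Cm == mx, arr.ind = TRUE)
    if (nrow(hits) > 1L) {
      o <- order(-sizes[hits[, 1L]], hits[, 1L], hits[, 2L])
      hits <- hits[o, , drop = FALSE]
    }
    r <- hits[1L, 1L]; b <- hits[1L, 2L]
    mapping[r] <- b
    used_r[r] <- TRUE
    used_b[b] <- TRUE
  }
  mapping
}

#' @export
print.permatype_result <- function(x, ...) {
  cat(sprintf(
    "permatype_result: k = %d, core sizes = %s, unclassified = %d/%d (threshold %.2f)\n",
    x$base$k, paste(tabulate(x$core_labels, x$base$k), collapse = "/"),
    length(x$unclassified), length(x$stability), x$threshold))
  invisible(x)
}

#' Rank driver taxa of each cluster
#'
#' Scores each taxon per cluster by mean relative abundance inside the cluster
#' minus mean in all other clusters, descending.
#'
#' @param typing a `typing_result` (or labels vector named by sample id).
#' @param table the [abundance_table] the labels refer to.
#' @param top_m how many taxa to return per cluster (full ranking if larger
#'   than the taxon count).
#' @return named list of per-cluster data.frames (taxon, score).
#' @export
driver_taxa <- function(typing, table, top_m = 5) {
  labels <- if (inherits(typing, "typing_result")) typing$labels else typing
  stopifnot(inherits(table, "abundance_table"))
  ix <- match(names(labels), sample_ids(table))
  if (anyNA(ix)) stopf("labels name samples absent from the table")
  vals <- table$values[ix, , drop = FALSE]
  ks <- sort(unique(labels))
  if (any(tabulate(labels) == 0)) stopf("empty cluster")
  m <- min(top_m, ncol(vals))
  out <- lapply(ks, function(g) {
    inside <- colMeans(vals[labels == g, , drop = FALSE])
    outside <- colMeans(vals[labels != g, , drop = FALSE])
    score <- inside - outside
    o <- order(-score)
    data.frame(taxon = colnames(vals)[o][seq_len(m)],
               score = score[o][seq_len(m)], row.names = NULL)
  })
  names(out) <- paste0("cluster_", ks)
  out
}

#' Permatype transition analysis with Fisher's exact test
#'
#' Builds the before-to-after cluster transition matrix over subjects and
#' tests, for a focus cluster, whether baseline membership is associated with
#' staying in the baseline cluster (2x2 two-sided Fisher exact test by
#' hypergeometric enumeration).
#'
#' @param before_labels,after_labels cluster labels named by sample id (e.g.
#'   permatype core labels; samples without a label are dropped and counted).
#' @param design a [paired_design].
#' @param focus_cluster cluster index to contrast against all others.
#' @return list with `contingency` (2x2), `fisher_p`, `transition` (k x k),
#'   `n_subjects`, `n_dropped`.
#' @export
transition_analysis <- function(before_labels, after_labels, design,
                                focus_cluster) {
  stopifnot(inherits(design, "paired_design"))
  bl <- before_labels[design$sample_before]
  al <- after_labels[design$sample_after]
  ok <- !is.na(bl) & !is.na(al)
  n_dropped <- sum(!ok)
  if (!any(ok)) stopf("no subject has labels for both samples")
  bl <- as.integer(bl[ok]); al <- as.integer(al[ok])
  ks <- sort(unique(c(bl, al)))
  transition <- table(factor(bl, levels = ks), factor(al, levels = ks),
                      dnn = c("before", "after"))
  if (!any(bl == focus_cluster))
    stopf("focus cluster %s is empty at baseline", focus_cluster)
  stayed <- bl == al
  focus <- bl == focus_cluster
  cont <- matrix(c(sum(focus & stayed), sum(focus & !stayed),
                   sum(!focus & stayed), sum(!focus & !stayed)),
                 nrow = 2, byrow = TRUE,
                 dimnames = list(c("focus", "other"), c("stayed", "moved")))
  list(contingency = cont, fisher_p = fisher_exact_2x2(cont),
       transition = unclass(transition), n_subjects = sum(ok),
       n_dropped = n_dropped)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact enumeration over the hypergeometric distribution with all margins
#' fixed; the two-sided p-value sums the probabilities of every table at most
#' as probable as the observed one.
#'
#' @param m 2x2 integer matrix.
#' @return p-value in (0, 1\].
#' @export
fisher_exact_2x2 <- function(m) {
  m <- as.matrix(m)
  stopifnot(all(dim(m) == 2L), all(m >= 0))
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  if (n == 0) stopf("empty table")
  lo <- max(0L, r1 + c1 - n); hi <- min(r1, c1)
  x <- lo:hi
  probs <- stats::dhyper(x, c1, n - c1, r1)
  p_obs <- stats::dhyper(m[1, 1], c1, n - c1, r1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}
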