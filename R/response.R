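#' Per-subject paired dissimilarity
#'
#' Distance between each subject's before and after profiles under the chosen
#' metric (generalized UniFrac by default). Subjects missing either sample are
#' dropped with a warning and recorded in attribute `"dropped_subjects"`.
#'
#' @param table relative [abundance_table] holding both samples of each
#'   subject.
#' @param design a [paired_design].
#' @param tree rooted `phylo` tree (required for `"gunifrac"`).
#' @param metric `"gunifrac"`, `"jsd"` or `"bray_curtis"`.
#' @param alpha generalized-UniFrac exponent.
#' @return named numeric vector (subject id -> dissimilarity).
#' @export
paired_dissimilarity <- function(table, design, tree = NULL,
                                 metric = c("gunifrac", "jsd", "bray_curtis"),
                                 alpha = 0.5) {
  metric <- match.arg(metric)
  stopifnot(inherits(table, "abundance_table"),
            inherits(design, "paired_design"))
  if (table$mode != "relative") stopf("paired_dissimilarity needs a relative table")
  design <- validate_design(design, sample_ids(table))
  bi <- match(design$sample_before, sample_ids(table))
  ai <- match(design$sample_after, sample_ids(table))
  out <- if (metric == "gunifrac") {
    if (is.null(tree)) stopf("metric 'gunifrac' requires a tree")
    ba <- branch_abundances(table, tree)
    vapply(seq_len(nrow(design)), function(i)
      gunifrac_pair(ba$P[, bi[i]], ba$P[, ai[i]], ba$b, alpha), numeric(1))
  } else if (metric == "jsd") {
    vapply(seq_len(nrow(design)), function(i)
      jsd_distance(table$values[bi[i], ], table$values[ai[i], ]), numeric(1))
  } else {
    vapply(seq_len(nrow(design)), function(i)
      bray_curtis(table$values[bi[i], ], table$values[ai[i], ]), numeric(1))
  }
  names(out) <- design$subject_id
  attr(out, "dropped_subjects") <- attr(design, "dropped_subjects")
  out
}

#' Split a cohort into responders and non-responders
#'
#' Clusters the per-subject paired dissimilarities (PAM over Euclidean
#' distances of the scalars, k chosen from `k_range` by maximal average
#' silhouette width, ties to the smaller k). When k = 2 the cluster with the
#' lower mean dissimilarity is labelled `non_responder` and the other
#' `responder`; for k > 2 the full solution is returned with
#' `binary = FALSE` and no responder labels.
#'
#' @param dissimilarities named numeric vector (subject -> paired
#'   dissimilarity).
#' @param k_range candidate cluster counts.
#' @return a `response_result`: `dissimilarity`, `k_selected`, `labels`
#'   (responder/non_responder or cluster index), `binary`, `group_stats`,
#'   `silhouette` (per k).
#' @export
cluster_response <- function(dissimilarities, k_range = 2:10) {
  x <- dissimilarities
  if (is.null(names(x))) names(x) <- paste0("subj", seq_along(x))
  if (length(unique(x)) == 1L)
    stopf("all dissimilarities identical: no cluster structure")
  d <- abs(outer(x, x, "-"))
  dimnames(d) <- list(names(x), names(x))
  fit <- typing_sweep(d, k_range, "silhouette")
  k <- fit$k
  if (k == 2L) {
    m <- tapply(x, fit$labels, mean)
    resp_cluster <- as.integer(names(m)[which.max(m)])
    labels <- ifelse(fit$labels == resp_cluster, "responder", "non_responder")
    names(labels) <- names(x)
    stats_df <- data.frame(
      group = c("non_responder", "responder"),
      n = c(sum(labels == "non_responder"), sum(labels == "responder")),
      mean = c(mean(x[labels == "non_responder"]),
               mean(x[labels == "responder"])),
      sd = c(stats::sd(x[labels == "non_responder"]),
             stats::sd(x[labels == "responder"])))
    binary <- TRUE
  } else {
    labels <- fit$labels
    stats_df <- data.frame(group = as.character(seq_len(k)),
                           n = as.vector(tabulate(fit$labels, k)),
                           mean = as.vector(tapply(x, fit$labels, mean)),
                           sd = as.vector(tapply(x, fit$labels, stats::sd)))
    binary <- FALSE
  }
  structure(list(dissimilarity = x, k_selected = k, labels = labels,
                 binary = binary, group_stats = stats_df,
                 silhouette = fit$quality),
            class = "response_result")
}

#' @export
print.response_result <- function(x, ...) {
  cat(sprintf("response_result: k = %d%s\n", x$k_selected,
              if (x$binary) sprintf(" (%d non-responders, %d responders)",
                                    x$group_stats$n[1], x$group_stats$n[2])
              else " (no binary labelling)"))
  invisible(x)
}

#' Baseline-microbiota classification of the responder split
#'
#' Repeated stratified random train/test splits; per split an
#' ensemble-of-randomized-decision-trees classifier (bagged CART: bootstrap
#' resampling plus random feature subsets at each node) is fit on the training
#' samples and the area under the ROC curve is measured on the test samples.
#' Feature selection is expected to have been done by the caller on the full
#' data (the original protocol; optimistically biased, see the vignette). A
#' split whose test set contains a single class is re-drawn and counted;
#' if more than half the draws fail the evaluation errors.
#'
#' @param features numeric matrix, baseline samples x selected taxa.
#' @param labels two-level vector (e.g. responder/non_responder), aligned with
#'   the rows of `features`.
#' @param n_splits number of random splits.
#' @param train_fraction fraction of samples used for training.
#' @param seed RNG seed.
#' @param n_trees,mtry,max_depth,min_node ensemble settings (recorded in the
#'   result metadata).
#' @return a `classifier_eval`: `auc` (per split), `mean_auc`, `roc` (per
#'   split data.frames), `n_redraws`, `settings`, `seed`.
#' @export
evaluate_baseline_classifier <- function(features, labels, n_splits = 10,
                                         train_fraction = 0.7, seed = 1,
                                         n_trees = 100, mtry = NULL,
                                         max_depth = 4, min_node = 5) {
  features <- as.matrix(features)
  y <- as.integer(factor(labels)) - 1L
  if (length(unique(y)) != 2L) stopf("labels must have exactly two classes")
  if (min(table(y)) < 2L) stopf("need >= 2 samples per class")
  n <- nrow(features)
  if (length(y) != n) stopf("labels length != feature rows")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(features))))
  pos_level <- levels(factor(labels))[2L]

  res <- with_seed(seed, {
    aucs <- numeric(n_splits)
    rocs <- vector("list", n_splits)
    redraws <- 0L
    for (s in seq_len(n_splits)) {
      repeat {
        train <- unlist(lapply(split(seq_len(n), y), function(ix)
          sample(ix, max(1L, round(train_fraction * length(ix))))))
        test <- setdiff(seq_len(n), train)
        if (length(unique(y[test])) == 2L && length(unique(y[train])) == 2L)
          break
        redraws <- redraws + 1L
        if (redraws > 0.5 * n_splits * 10)
          stopf("too many single-class splits (%d re-draws)", redraws)
      }
      forest <- grow_forest(features[train, , drop = FALSE], y[train],
                            n_trees, mtry, max_depth, min_node)
      prob <- predict_forest(forest, features[test, , drop = FALSE])
      aucs[s] <- auc_rank(prob, y[test])
      rocs[[s]] <- roc_points(prob, y[test])
    }
    list(aucs = aucs, rocs = rocs, redraws = redraws)
  })
  structure(list(auc = res$aucs, mean_auc = mean(res$aucs), roc = res$rocs,
                 n_splits = n_splits, train_fraction = train_fraction,
                 n_redraws = res$redraws, positive_class = pos_level,
                 settings = list(model = "bagged randomized CART",
                                 n_trees = n_trees, mtry = mtry,
                                 max_depth = max_depth, min_node = min_node),
                 seed = seed),
            class = "classifier_eval")
}

#' @export
print.classifier_eval <- function(x, ...) {
  cat(sprintf("classifier_eval: mean AUC = %.3f over %d splits (%s)\n",
              x$mean_auc, x$n_splits, x$settings$model))
  invisible(x)
}

# ---- minimal randomized-tree ensemble (no tree package in scope) ----

grow_forest <- function(X, y, n_trees, mtry, max_depth, min_node) {
  n <- nrow(X)
  lapply(seq_len(n_trees), function(t) {
    boot <- sample.int(n, n, replace = TRUE)
    grow_tree(X[boot, , drop = FALSE], y[boot], mtry, max_depth, min_node)
  })
}

# node: list(leaf, prob) or list(leaf=FALSE, var, cut, left, right)
grow_tree <- function(X, y, mtry, depth_left, min_node) {
  n <- length(y)
  p1 <- mean(y)
  if (depth_left == 0L || n < 2L * min_node || p1 == 0 || p1 == 1)
    return(list(leaf = TRUE, prob = p1))
  vars <- sample.int(ncol(X), min(mtry, ncol(X)))
  best <- list(score = Inf, var = NA, cut = NA)
  for (v in vars) {
    xv <- X[, v]
    o <- order(xv)
    xs <- xv[o]; ys <- y[o]
    cum1 <- cumsum(ys)
    i <- seq_len(n - 1L)
    valid <- xs[i] < xs[i + 1L]
    nl <- i; nr <- n - i
    ok <- valid & nl >= min_node & nr >= min_node
    if (!any(ok)) next
    l1 <- cum1[i]; r1 <- cum1[n] - l1
    gini <- nl * (l1 / nl) * (1 - l1 / nl) + nr * (r1 / nr) * (1 - r1 / nr)
    gini[!ok] <- Inf
    j <- which.min(gini)
    if (gini[j] < best$score) {
      best <- list(score = gini[j], var = v, cut = (xs[j] + xs[j + 1L]) / 2)
    }
  }
  if (!is.finite(best$score)) return(list(leaf = TRUE, prob = p1))
  go_left <- X[, best$var] <= best$cut
  list(leaf = FALSE, var = best$var, cut = best$cut,
       left = grow_tree(X[go_left, , drop = FALSE], y[go_left], mtry,
                        depth_left - 1L, min_node),
       right = grow_tree(X[!go_left, , drop = FALSE], y[!go_left], mtry,
                         depth_left - 1L, min_node))
}

predict_tree <- function(tree, X) {
  out <- numeric(nrow(X))
  rec <- function(node, ix) {
    if (!length(ix)) return()
    if (node$leaf) { out[ix] <<- node$prob; return() }
    left <- X[ix, node$var] <= node$cut
    rec(node$left, ix[left])
    rec(node$right, ix[!left])
  }
  rec(tree, seq_len(nrow(X)))
  out
}

predict_forest <- function(forest, X) {
  rowMeans(vapply(forest, function(tr) predict_tree(tr, X),
                  numeric(nrow(X))))
}

# AUC as the normalized Mann-Whitney statistic (ties get half credit)
auc_rank <- function(score, y) {
  r <- rank(score)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

roc_points <- function(score, y) {
  o <- order(-score)
  tp <- cumsum(y[o] == 1L) / sum(y == 1L)
  fp <- cumsum(y[o] == 0L) / sum(y == 0L)
  data.frame(fpr = c(0, fp), tpr = c(0, tp))
}

#' Differential-abundance screen between response groups
#'
#' Per-taxon two-sided Mann-Whitney (Wilcoxon rank-sum) test between the two
#' groups with Benjamini-Hochberg adjustment and the sign of the median
#' difference. Constant taxa get p = 1 by convention.
#'
#' @param table_baseline relative [abundance_table] of baseline samples.
#' @param labels two-level vector aligned with the samples (or named by
#'   sample id).
#' @return data.frame: taxon, p, adjusted_p, direction (-1/0/1 sign of
#'   group-1-vs-group-2 median difference, groups in factor-level order).
#' @export
group_marker_test <- function(table_baseline, labels) {
  stopifnot(inherits(table_baseline, "abundance_table"))
  if (!is.null(names(labels)))
    labels <- labels[sample_ids(table_baseline)]
  f <- factor(labels)
  if (nlevels(f) != 2L) stopf("need exactly two groups")
  X <- table_baseline$values
  g1 <- f == levels(f)[1L]
  res <- apply(X, 2L, function(x) {
    if (length(unique(x)) == 1L) return(c(1, 0))
    p <- suppressWarnings(stats::wilcox.test(x[g1], x[!g1])$p.value)
    c(p, sign(stats::median(x[g1]) - stats::median(x[!g1])))
  })
  data.frame(taxon = colnames(X), p = res[1L, ],
             adjusted_p = bh_adjust(res[1L, ]), direction = res[2L, ],
             row.names = NULL)
}
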