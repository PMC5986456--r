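#' Shannon diversity index
#'
#' `-sum(p_i log_base p_i)` over nonzero entries after normalizing the input
#' to proportions. Base 2 by default (bits).
#'
#' @param x nonnegative counts or proportions, sum > 0.
#' @param base logarithm base.
#' @return scalar index.
#' @export
shannon <- function(x, base = 2) {
  if (any(x < 0)) stopf("negative entries")
  s <- sum(x)
  if (s == 0) stopf("all-zero input")
  p <- x[x > 0] / s
  -sum(p * log(p) / log(base))
}

#' Chao1 richness estimator (bias-corrected)
#'
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` with F1/F2 the singleton/doubleton
#' counts. Defined on integer counts only (undefined on relative data).
#'
#' @param counts integer count vector.
#' @return scalar richness estimate.
#' @export
chao1 <- function(counts) {
  if (!is_count_vector(counts)) stopf("chao1 requires nonnegative integer counts")
  counts <- round(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Rarefy counts to a fixed depth
#'
#' Subsamples each count vector without replacement to exactly `depth` reads.
#' Samples with fewer reads than `depth` are dropped and reported in attribute
#' `"dropped_samples"`. Deterministic given `seed`.
#'
#' @param x integer count vector, or a counts-mode [abundance_table].
#' @param depth target depth.
#' @param seed RNG seed.
#' @return rarefied vector or table.
#' @export
rarefy <- function(x, depth, seed = 1) {
  if (inherits(x, "abundance_table")) {
    if (x$mode != "counts") stopf("rarefy requires a counts table")
    tot <- rowSums(x$values)
    keep <- tot >= depth
    if (!any(keep)) stopf("no sample reaches depth %d", depth)
    if (!all(keep))
      warnf("dropping %d sample(s) below depth %d: %s", sum(!keep), depth,
            paste(sample_ids(x)[!keep], collapse = ", "))
    vals <- with_seed(seed, t(apply(x$values[keep, , drop = FALSE], 1L,
                                    rarefy_vector, depth = depth)))
    colnames(vals) <- taxon_ids(x)
    out <- abundance_table(vals, lineage = x$lineage, mode = "counts",
                           lineage_string = x$lineage_string)
    attr(out, "dropped_samples") <- sample_ids(x)[!keep]
    return(out)
  }
  if (!is_count_vector(x)) stopf("rarefy requires nonnegative integer counts")
  if (sum(x) < depth) stopf("row sum %d below depth %d", sum(x), depth)
  with_seed(seed, rarefy_vector(round(x), depth))
}

rarefy_vector <- function(counts, depth) {
  pool <- rep.int(seq_along(counts), counts)
  drawn <- sample(pool, depth)
  out <- tabulate(drawn, nbins = length(counts))
  names(out) <- names(counts)
  out
}

#' Centered log-ratio transform
#'
#' `log(x_i + pc) - mean(log(x + pc))`; the output always sums to zero. The
#' pseudocount makes the transform defined in the presence of zeros at the
#' price of only approximate scale invariance.
#'
#' @param x nonnegative vector (typically counts).
#' @param pseudocount positive offset, default 0.5.
#' @return vector of the same length summing to 0.
#' @export
clr <- function(x, pseudocount = 0.5) {
  if (any(x < 0)) stopf("negative entries")
  if (pseudocount <= 0) stopf("pseudocount must be > 0")
  lx <- log(x + pseudocount)
  lx - mean(lx)
}

#' Paired compositional differential-abundance test
#'
#' CLR-transforms each sample, then per taxon applies the Wilcoxon signed-rank
#' test to the per-subject after-minus-before CLR differences (exact for up to
#' 25 informative pairs, normal approximation with continuity correction
#' above), with Benjamini-Hochberg adjustment across taxa. Taxa whose
#' differences are all zero get p = 1.
#'
#' @param table_before,table_after counts-mode [abundance_table]s over the
#'   same taxa.
#' @param design a [paired_design] mapping subjects to samples of the two
#'   tables.
#' @param pseudocount CLR pseudocount.
#' @return data.frame: taxon, p, adjusted_p, median_clr_diff.
#' @export
paired_clr_test <- function(table_before, table_after, design,
                            pseudocount = 0.5) {
  stopifnot(inherits(table_before, "abundance_table"),
            inherits(table_after, "abundance_table"),
            inherits(design, "paired_design"))
  if (!identical(taxon_ids(table_before), taxon_ids(table_after)))
    stopf("tables must share the same taxa")
  bi <- match(design$sample_before, sample_ids(table_before))
  ai <- match(design$sample_after, sample_ids(table_after))
  if (anyNA(bi) || anyNA(ai)) stopf("design references missing samples")
  if (nrow(design) < 6L) stopf("need >= 6 subjects")
  CB <- t(apply(table_before$values[bi, , drop = FALSE], 1L, clr,
                pseudocount = pseudocount))
  CA <- t(apply(table_after$values[ai, , drop = FALSE], 1L, clr,
                pseudocount = pseudocount))
  Dm <- CA - CB
  res <- apply(Dm, 2L, function(dd) {
    nz <- dd[dd != 0]
    if (!length(nz)) return(c(1, 0))
    exact <- length(nz) <= 25
    p <- suppressWarnings(stats::wilcox.test(dd, mu = 0, exact = exact,
                                             correct = TRUE)$p.value)
    c(p, stats::median(dd))
  })
  data.frame(taxon = taxon_ids(table_before), p = res[1L, ],
             adjusted_p = bh_adjust(res[1L, ]), median_clr_diff = res[2L, ],
             row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stopf("p-values must be in [0, 1]")
  m <- length(pvalues)
  if (m <= 1L) return(pvalues)
  o <- order(pvalues, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * pvalues[o]))[ro]
}

#' Cooperatives: connected components of a co-occurrence graph
#'
#' A cooperative is a connected component with at least `min_size` (default 3,
#' i.e. "more than two") member taxa. Self-loops are dropped with a warning.
#' When an abundance table is supplied, each cooperative is named after the
#' family of its highest-mean-abundance member (`"<family>-dominant"`).
#'
#' @param edge_list data.frame with columns source, target (and optionally
#'   weight), referencing taxon ids.
#' @param min_size minimal component size to keep.
#' @param table optional [abundance_table] used for naming.
#' @return a `cooperative_set`: named list of taxon-id vectors plus the edge
#'   list.
#' @export
cooperatives <- function(edge_list, min_size = 3, table = NULL) {
  edge_list <- as.data.frame(edge_list)
  if (nrow(edge_list) == 0L) {
    return(structure(list(components = list(), edges = edge_list),
                     class = "cooperative_set"))
  }
  self <- edge_list[[1L]] == edge_list[[2L]]
  if (any(self)) {
    warnf("dropping %d self-loop(s)", sum(self))
    edge_list <- edge_list[!self, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(edge_list, directed = FALSE)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- Filter(function(m) length(m) >= min_size, members)
  members <- lapply(members, sort)
  if (!is.null(table) && length(members)) {
    nm <- vapply(members, function(m) {
      ix <- match(m, taxon_ids(table))
      present <- !is.na(ix)
      if (!any(present)) return("unknown-dominant")
      top <- ix[present][which.max(colMeans(
        table$values[, ix[present], drop = FALSE]))]
      fam <- if (!is.null(table$lineage) &&
                 "family" %in% colnames(table$lineage))
        table$lineage$family[top] else NA_character_
      if (is.na(fam)) fam <- taxon_ids(table)[top]
      paste0(fam, "-dominant")
    }, character(1))
    names(members) <- make.unique(nm, sep = "#")
  } else if (length(members)) {
    names(members) <- paste0("cooperative_", seq_along(members))
  }
  structure(list(components = members, edges = edge_list),
            class = "cooperative_set")
}

#' @export
print.cooperative_set <- function(x, ...) {
  cat(sprintf("cooperative_set: %d component(s) of sizes %s\n",
              length(x$components),
              paste(vapply(x$components, length, integer(1)), collapse = "/")))
  invisible(x)
}

#' Per-sample summed abundance of each cooperative
#'
#' @param coops a `cooperative_set`.
#' @param table relative [abundance_table].
#' @return samples x cooperatives matrix of summed member abundances.
#' @export
cooperative_abundance <- function(coops, table) {
  stopifnot(inherits(coops, "cooperative_set"),
            inherits(table, "abundance_table"))
  if (!length(coops$components)) stopf("no cooperatives to summarize")
  out <- vapply(coops$components, function(m) {
    ix <- match(m, taxon_ids(table))
    if (all(is.na(ix)))
      stopf("all members of a cooperative are missing from the table")
    if (anyNA(ix))
      warnf("skipping %d missing member(s): %s", sum(is.na(ix)),
            paste(m[is.na(ix)], collapse = ", "))
    rowSums(table$values[, ix[!is.na(ix)], drop = FALSE])
  }, numeric(nrow(table$values)))
  if (is.null(dim(out)))
    out <- matrix(out, nrow = nrow(table$values),
                  dimnames = list(sample_ids(table), names(coops$components)))
  rownames(out) <- sample_ids(table)
  out
}
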