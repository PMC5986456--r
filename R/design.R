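#' Construct a paired before/after design
#'
#' Maps each subject to its baseline and follow-up sample. Every sample id may
#' appear in at most one record and the two samples of a subject must differ.
#'
#' @param subject_id,sample_before,sample_after character vectors of equal
#'   length.
#' @return an object of class `paired_design` (a validated data.frame).
#' @export
paired_design <- function(subject_id, sample_before, sample_after) {
  df <- data.frame(subject_id = as.character(subject_id),
                   sample_before = as.character(sample_before),
                   sample_after = as.character(sample_after),
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stopf("empty pairing manifest")
  if (anyDuplicated(df$subject_id))
    stopf("duplicate subject ids: %s",
          paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  if (any(df$sample_before == df$sample_after))
    stopf("subject(s) with identical before/after sample: %s",
          paste(df$subject_id[df$sample_before == df$sample_after],
                collapse = ", "))
  all_samples <- c(df$sample_before, df$sample_after)
  if (anyDuplicated(all_samples))
    stopf("sample id(s) appear in more than one record: %s",
          paste(unique(all_samples[duplicated(all_samples)]), collapse = ", "))
  class(df) <- c("paired_design", "data.frame")
  df
}

#' Read a pairing manifest TSV
#'
#' Expects a 3-column TSV with header `subject_id, sample_before,
#' sample_after`.
#'
#' @param path file to read.
#' @return a [paired_design].
#' @export
load_pairs <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("subject_id", "sample_before", "sample_after")
  if (!all(need %in% colnames(df)))
    stopf("pairing manifest must have columns: %s", paste(need, collapse = ", "))
  paired_design(df$subject_id, df$sample_before, df$sample_after)
}

#' Write a pairing manifest TSV
#' @param design a [paired_design].
#' @param path output file.
#' @export
write_pairs <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Check that a design's samples exist in a table; returns the design restricted
# to complete pairs, with the dropped subjects reported via attribute/warning.
validate_design <- function(design, table_samples) {
  ok <- design$sample_before %in% table_samples &
    design$sample_after %in% table_samples
  if (!all(ok))
    warnf("dropping %d subject(s) with missing pair member: %s", sum(!ok),
          paste(design$subject_id[!ok], collapse = ", "))
  out <- design[ok, , drop = FALSE]
  if (nrow(out) == 0L) stopf("no subject has both samples in the table")
  attr(out, "dropped_subjects") <- design$subject_id[!ok]
  out
}

#' Load a rooted phylogenetic tree with branch lengths (newick)
#'
#' Thin wrapper over [ape::read.tree()] that validates the tree contract used
#' by generalized UniFrac: rooted, unique leaf labels, nonnegative branch
#' lengths on every edge.
#'
#' @param path newick file.
#' @return an `ape::phylo` object.
#' @export
load_tree <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tree <- ape::read.tree(path)
  validate_tree(tree)
  tree
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stopf("not a phylo tree")
  if (is.null(tree$edge.length)) stopf("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stopf("tree has negative branch lengths")
  if (anyDuplicated(tree$tip.label))
    stopf("duplicate leaf labels: %s",
          paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                collapse = ", "))
  if (!ape::is.rooted(tree)) stopf("tree must be rooted")
  invisible(tree)
}
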