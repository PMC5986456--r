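TAXO_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus",
                "species")
RANK_PREFIXES <- c(kingdom = "k__", phylum = "p__", class = "c__",
                   order = "o__", family = "f__", genus = "g__",
                   species = "s__")

#' Construct a validated abundance table
#'
#' An abundance table holds a samples-by-taxa nonnegative matrix together with
#' a ranked taxonomic lineage per taxon and a mode flag distinguishing raw
#' counts from relative (per-sample sum one) profiles.
#'
#' @param values numeric matrix, samples in rows, taxa in columns; dimnames
#'   supply sample and taxon identifiers.
#' @param lineage optional data.frame of ranked lineages (columns among
#'   kingdom..species, `NA` for unclassified levels), one row per taxon.
#' @param mode `"counts"`, `"relative"`, or `"auto"` (detect: rows all summing
#'   to 1 within 1e-6 are taken as relative).
#' @param lineage_string optional character vector of the original lineage
#'   strings (kept verbatim for lossless TSV round-trips).
#' @return an object of class `abundance_table`.
#' @export
abundance_table <- function(values, lineage = NULL,
                            mode = c("auto", "counts", "relative"),
                            lineage_string = NULL) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (nrow(values) == 0L || ncol(values) == 0L)
    stopf("empty abundance table (%d samples x %d taxa)",
          nrow(values), ncol(values))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("T", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stopf("duplicate sample ids: %s",
          paste(unique(rownames(values)[duplicated(rownames(values))]),
                collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stopf("duplicate taxon ids: %s",
          paste(unique(colnames(values)[duplicated(colnames(values))]),
                collapse = ", "))
  if (!is.numeric(values) || any(!is.finite(values)) || any(values < 0))
    stopf("abundance values must be finite and nonnegative")
  rs <- rowSums(values)
  if (mode == "auto")
    mode <- if (all(abs(rs - 1) <= 1e-6)) "relative" else "counts"
  if (mode == "relative") {
    if (any(abs(rs - 1) > 1e-9))
      stopf("relative mode requires every row to sum to 1 (worst: %s = %.3g)",
            rownames(values)[which.max(abs(rs - 1))], rs[which.max(abs(rs - 1))])
  }
  if (!is.null(lineage)) {
    lineage <- as.data.frame(lineage, stringsAsFactors = FALSE)
    if (nrow(lineage) != ncol(values))
      stopf("lineage has %d rows but table has %d taxa",
            nrow(lineage), ncol(values))
    bad <- setdiff(colnames(lineage), TAXO_RANKS)
    if (length(bad))
      stopf("unknown lineage ranks: %s", paste(bad, collapse = ", "))
    lineage <- lineage[, intersect(TAXO_RANKS, colnames(lineage)), drop = FALSE]
    rownames(lineage) <- colnames(values)
  }
  if (!is.null(lineage_string) && length(lineage_string) != ncol(values))
    stopf("lineage_string length mismatch")
  structure(list(values = values, lineage = lineage, mode = mode,
                 lineage_string = lineage_string),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa (%s mode)%s\n",
              nrow(x$values), ncol(x$values), x$mode,
              if (is.null(x$lineage)) ", no lineages" else ""))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

sample_ids <- function(table) rownames(table$values)
taxon_ids <- function(table) colnames(table$values)

#' Parse Greengenes-style lineage strings
#'
#' Splits strings such as `"k__Bacteria;p__Firmicutes;...;g__Blautia"` into a
#' ranked lineage data.frame. Empty names after a rank prefix (and entirely
#' missing ranks) are flagged unclassified (`NA`).
#'
#' @param strings character vector of lineage strings.
#' @param delim field delimiter, default `";"`.
#' @param prefixes named character vector mapping rank names to prefixes.
#' @return data.frame with one column per rank present anywhere in the input.
#' @export
parse_lineage <- function(strings, delim = ";", prefixes = RANK_PREFIXES) {
  out <- matrix(NA_character_, nrow = length(strings),
                ncol = length(TAXO_RANKS),
                dimnames = list(NULL, TAXO_RANKS))
  for (i in seq_along(strings)) {
    parts <- trimws(strsplit(strings[[i]], delim, fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    for (p in parts) {
      hit <- which(startsWith(p, prefixes))
      if (length(hit) != 1L)
        stopf("malformed lineage in row %d: field '%s' has no recognised rank prefix",
              i, p)
      nm <- substring(p, nchar(prefixes[hit]) + 1L)
      out[i, names(prefixes)[hit]] <- if (nzchar(nm)) nm else NA_character_
    }
  }
  keep <- colSums(!is.na(out)) > 0L
  if (!any(keep))
    stopf("no rank could be parsed from any lineage string")
  as.data.frame(out[, keep, drop = FALSE], stringsAsFactors = FALSE)
}

format_lineage <- function(lineage, delim = ";", prefixes = RANK_PREFIXES) {
  apply(lineage, 1L, function(row) {
    ranks <- names(row)
    paste0(prefixes[ranks], ifelse(is.na(row), "", row), collapse = delim)
  })
}

#' Load an abundance table from TSV or BIOM
#'
#' The TSV dialect is taxa rows by sample columns with the first column
#' holding a delimited lineage string (Greengenes-style `k__...;p__...`
#' prefixes by default). BIOM 2.x (HDF5) files are read through the
#' `biomformat` package. Tables whose sample sums are all 1 (within 1e-6) are
#' flagged relative, otherwise counts.
#'
#' @param path file to read.
#' @param format `"tsv"` or `"biom"`.
#' @param lineage_delim delimiter inside the lineage string (TSV only).
#' @param sep column separator of the TSV file.
#' @return an [abundance_table].
#' @export
load_table <- function(path, format = c("tsv", "biom"), lineage_delim = ";",
                       sep = "\t") {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stopf("reading BIOM requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))   # taxa x samples
    obs <- biomformat::observation_metadata(b)
    lin_str <- NULL
    if (!is.null(obs) && length(obs)) {
      lin_str <- vapply(seq_len(nrow(m)), function(i) {
        md <- obs[i, , drop = TRUE]
        paste(unlist(md), collapse = lineage_delim)
      }, character(1))
    }
    values <- t(m)
    lineage <- if (!is.null(lin_str)) parse_lineage(lin_str, lineage_delim)
    return(abundance_table(values, lineage = lineage, mode = "auto",
                           lineage_string = lin_str))
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          comment.char = "", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("TSV table needs a lineage column plus >=1 sample")
  lin_str <- as.character(df[[1L]])
  values <- t(as.matrix(df[, -1L, drop = FALSE]))
  colnames(values) <- make_taxon_ids(lin_str)
  lineage <- parse_lineage(lin_str, lineage_delim)
  abundance_table(values, lineage = lineage, mode = "auto",
                  lineage_string = lin_str)
}

# taxon id = most resolved classified rank name, disambiguated when repeated
make_taxon_ids <- function(lin_str) {
  ids <- vapply(lin_str, function(s) {
    parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    nm <- sub("^[a-z]__", "", parts)
    nm <- nm[nzchar(nm)]
    if (length(nm)) nm[length(nm)] else "unclassified"
  }, character(1), USE.NAMES = FALSE)
  make.unique(ids, sep = "#")
}

#' Write an abundance table as TSV (taxa rows x sample columns)
#'
#' Inverse of [load_table()]: the first column carries the lineage string
#' (verbatim if the table was read from file), the remaining columns the
#' per-sample values at full precision.
#'
#' @param table an [abundance_table].
#' @param path output file.
#' @export
write_table_tsv <- function(table, path) {
  lin <- table$lineage_string
  if (is.null(lin)) {
    lin <- if (!is.null(table$lineage)) format_lineage(table$lineage)
    else taxon_ids(table)
  }
  df <- data.frame(lineage = lin, t(table$values), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' @param table an [abundance_table] in counts mode.
#' @return the table with every row divided by its sum, mode `"relative"`.
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$mode == "relative") return(table)
  rs <- rowSums(table$values)
  if (any(rs == 0))
    stopf("all-zero sample(s): %s",
          paste(sample_ids(table)[rs == 0], collapse = ", "))
  abundance_table(table$values / rs, lineage = table$lineage,
                  mode = "relative", lineage_string = table$lineage_string)
}

#' Aggregate taxa at a taxonomic rank
#'
#' Taxa sharing the named rank (and all higher ranks) are summed. Taxa
#' unclassified at the rank are pooled per nearest classified ancestor with an
#' `"_u"` suffix (e.g. all genus-unclassified members of family F become
#' `"F_u"`).
#'
#' @param table an [abundance_table] with lineages.
#' @param rank one of kingdom, phylum, class, order, family, genus, species.
#' @return aggregated [abundance_table] at the requested rank.
#' @export
aggregate_rank <- function(table, rank) {
  stopifnot(inherits(table, "abundance_table"))
  if (is.null(table$lineage)) stopf("table has no lineages")
  rank <- match.arg(rank, TAXO_RANKS)
  if (!rank %in% colnames(table$lineage))
    stopf("rank '%s' missing from lineage schema (%s)", rank,
          paste(colnames(table$lineage), collapse = ", "))
  lin <- table$lineage
  upto <- TAXO_RANKS[seq_len(match(rank, TAXO_RANKS))]
  upto <- intersect(upto, colnames(lin))
  name_at <- lin[[rank]]
  # pool unclassified-at-rank taxa under their nearest classified ancestor
  display <- name_at
  for (i in which(is.na(name_at))) {
    anc <- rev(unlist(lin[i, setdiff(upto, rank), drop = TRUE]))
    anc <- anc[!is.na(anc)]
    display[i] <- paste0(if (length(anc)) anc[[1]] else "unclassified", "_u")
  }
  # group key = full classified path down to the rank, so same-named taxa in
  # different parents stay separate
  keymat <- lin[, upto, drop = FALSE]
  keymat[[rank]] <- display
  key <- apply(keymat, 1L, function(r) paste(ifelse(is.na(r), "", r),
                                             collapse = "|"))
  groups <- split(seq_len(ncol(table$values)), key)
  ord <- order(vapply(groups, min, integer(1)))
  groups <- groups[ord]
  vals <- vapply(groups, function(ix)
    rowSums(table$values[, ix, drop = FALSE]), numeric(nrow(table$values)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(table$values))
  new_lin <- do.call(rbind, lapply(groups, function(ix) {
    row <- lin[ix[[1]], upto, drop = FALSE]
    row[[rank]] <- display[ix[[1]]]
    row
  }))
  ids <- make.unique(vapply(groups, function(ix) display[ix[[1]]],
                            character(1)), sep = "#")
  colnames(vals) <- ids
  rownames(vals) <- sample_ids(table)
  rownames(new_lin) <- ids
  abundance_table(vals, lineage = new_lin, mode = table$mode,
                  lineage_string = format_lineage(new_lin))
}

#' Low-abundance taxon prevalence filter
#'
#' Retains exactly the taxa whose relative abundance reaches `min_frac` in at
#' least `min_samples` samples (default: 0.2% in 15 samples). `min_samples =
#' 0` is treated as "at least one sample". The removed taxa are attached as
#' attribute `"removed_taxa"`. Rows are renormalized to sum 1 after the drop
#' (the removed mass is small by construction).
#'
#' @param table relative-mode [abundance_table].
#' @param min_frac relative-abundance threshold.
#' @param min_samples prevalence threshold (number of samples).
#' @return filtered [abundance_table].
#' @export
prevalence_filter <- function(table, min_frac = 0.002, min_samples = 15) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$mode != "relative") stopf("prevalence_filter needs a relative table")
  n <- nrow(table$values)
  if (min_samples > n)
    stopf("min_samples (%d) exceeds the number of samples (%d)",
          min_samples, n)
  eff <- max(1L, as.integer(min_samples))
  hits <- colSums(table$values >= min_frac)
  keep <- hits >= eff
  if (!any(keep)) stopf("prevalence filter removed every taxon")
  out <- table$values[, keep, drop = FALSE]
  rs <- rowSums(out)
  if (any(rs == 0))
    stopf("sample(s) left empty by the filter: %s",
          paste(sample_ids(table)[rs == 0], collapse = ", "))
  res <- abundance_table(out / rs,
                         lineage = table$lineage[keep, , drop = FALSE],
                         mode = "relative",
                         lineage_string = table$lineage_string[keep])
  attr(res, "removed_taxa") <- taxon_ids(table)[!keep]
  res
}

#' Bacteroidetes:Firmicutes ratio per sample
#'
#' Ratio of summed relative abundances of the two phyla. Samples with zero
#' Firmicutes get `NA` (undefined, excluded from downstream rank tests) rather
#' than an error.
#'
#' @param table [abundance_table] with phylum-level lineages.
#' @param numerator,denominator phylum names (defaults Bacteroidetes,
#'   Firmicutes).
#' @return named numeric vector, one entry per sample.
#' @export
bf_ratio <- function(table, numerator = "Bacteroidetes",
                     denominator = "Firmicutes") {
  stopifnot(inherits(table, "abundance_table"))
  if (is.null(table$lineage) || !"phylum" %in% colnames(table$lineage))
    stopf("table lineages do not resolve the phylum rank")
  phy <- table$lineage$phylum
  num_ix <- which(!is.na(phy) & phy == numerator)
  den_ix <- which(!is.na(phy) & phy == denominator)
  if (!length(num_ix)) stopf("phylum '%s' absent from every lineage", numerator)
  if (!length(den_ix)) stopf("phylum '%s' absent from every lineage", denominator)
  num <- rowSums(table$values[, num_ix, drop = FALSE])
  den <- rowSums(table$values[, den_ix, drop = FALSE])
  out <- ifelse(den > 0, num / den, NA_real_)
  names(out) <- sample_ids(table)
  out
}
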