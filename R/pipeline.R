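#' Configuration for a full pipeline run
#'
#' Inputs are either file paths (`table`, `pairs`, `tree`: combined TSV
#' abundance table holding both time points, pairing manifest, newick tree) or
#' `synthetic = TRUE`, in which case a synthetic cohort is generated from
#' `cohort` (defaults to [cohort_config()] reseeded from the master seed).
#' All stage seeds are derived from `seed` by a fixed counter scheme, so one
#' master seed fixes the whole run.
#'
#' @param table,pairs,tree input paths (ignored when `synthetic`).
#' @param synthetic generate the cohort instead of reading files.
#' @param cohort optional [cohort_config] for the synthetic branch.
#' @param rank aggregation rank for typing (default genus).
#' @param min_frac,min_samples prevalence-filter thresholds.
#' @param metric,alpha paired-dissimilarity metric settings.
#' @param k_range candidate cluster counts for typing and response.
#' @param n_bootstrap,threshold permatyping settings.
#' @param n_permutations PERMANOVA permutations.
#' @param marker_alpha adjusted-p cut-off for baseline classifier features.
#' @param seed master seed.
#' @param out_dir output directory (created; timestamp-free layout).
#' @return a `run_config` list.
#' @export
run_config <- function(table = NULL, pairs = NULL, tree = NULL,
                       synthetic = is.null(table), cohort = NULL,
                       rank = "genus", min_frac = 0.002, min_samples = 15,
                       metric = "gunifrac", alpha = 0.5, k_range = 2:10,
                       n_bootstrap = 100, threshold = 0.8,
                       n_permutations = 2000, marker_alpha = 0.1,
                       seed = 1, out_dir = tempfile("permatyper_run_")) {
  if (!synthetic) {
    for (p in c(table, pairs, tree)) {
      if (is.null(p) || !file.exists(p))
        stopf("input file missing: %s", if (is.null(p)) "(unset)" else p)
    }
  }
  structure(list(table = table, pairs = pairs, tree = tree,
                 synthetic = synthetic, cohort = cohort, rank = rank,
                 min_frac = min_frac, min_samples = min_samples,
                 metric = metric, alpha = alpha, k_range = k_range,
                 n_bootstrap = n_bootstrap, threshold = threshold,
                 n_permutations = n_permutations, marker_alpha = marker_alpha,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages: load/generate -> prevalence filter -> rank aggregation ->
#' enterotyping + permatyping -> responder discovery (paired dissimilarity,
#' clustering, marker screen, baseline classifier) -> paired PERMANOVA ->
#' summary statistics (alpha diversity, B:F ratio) -> report. Stage outputs
#' are written under `config$out_dir`; the summary JSON contains no
#' timestamps, so identical config + seed reproduces it byte for byte (wall
#' clock goes to the JSONL run log only).
#'
#' @param config a [run_config].
#' @return a `run_report`: `summary`, `paths`, `wall_clock`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.jsonl")
  if (file.exists(log_path)) file.remove(log_path)
  wall <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stopf("stage '%s' failed: %s (completed stages: %s)", name,
            conditionMessage(e), paste(names(wall), collapse = ", ")))
    dt <- proc.time()[["elapsed"]] - t0
    wall[[name]] <<- dt
    cat(jsonlite::toJSON(list(stage = name, seconds = round(dt, 3)),
                         auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE)
    message(sprintf("[%s] done in %.1fs", name, dt))
    res
  }

  inputs <- stage("load", {
    if (config$synthetic) {
      cc <- config$cohort
      if (is.null(cc)) cc <- cohort_config(seed = derive_seed(config$seed, 4L),
                                           tree_seed = derive_seed(config$seed, 5L))
      cohort <- generate_cohort(cc)
      vals <- rbind(cohort$table_before$values, cohort$table_after$values)
      tab <- abundance_table(vals, lineage = cohort$table_before$lineage,
                             mode = "counts")
      list(table = tab, design = cohort$design, tree = cohort$tree,
           cohort = cohort)
    } else {
      tab <- load_table(config$table)
      if (tab$mode == "relative")
        stopf("pipeline expects a counts table")
      list(table = tab, design = load_pairs(config$pairs),
           tree = load_tree(config$tree), cohort = NULL)
    }
  })
  if (config$metric == "gunifrac" && is.null(inputs$tree))
    stopf("metric 'gunifrac' requires a tree")

  filtered <- stage("filter", {
    rel <- to_relative(inputs$table)
    prevalence_filter(rel, config$min_frac, config$min_samples)
  })
  genus <- stage("aggregate", aggregate_rank(filtered, config$rank))
  write_table_tsv(genus, file.path(config$out_dir, "genus_table.tsv"))

  typing <- stage("typing", {
    ent <- enterotype(genus, config$k_range)
    perm <- permatype(genus, n_bootstrap = config$n_bootstrap,
                      threshold = config$threshold,
                      seed = derive_seed(config$seed, 1L),
                      k_range = config$k_range)
    utils::write.table(
      data.frame(sample_id = names(ent$labels), enterotype = ent$labels,
                 stability = perm$stability[names(ent$labels)],
                 permatype = ifelse(names(ent$labels) %in% names(perm$core_labels),
                                    perm$core_labels[names(ent$labels)], NA)),
      file.path(config$out_dir, "typing.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    list(enterotype = ent, permatype = perm)
  })

  response <- stage("response", {
    diss <- paired_dissimilarity(
      to_relative(inputs$table), inputs$design,
      tree = if (config$metric == "gunifrac") inputs$tree,
      metric = config$metric, alpha = config$alpha)
    rr <- cluster_response(diss, config$k_range)
    utils::write.table(
      data.frame(subject_id = names(diss), dissimilarity = diss,
                 label = rr$labels[names(diss)]),
      file.path(config$out_dir, "response.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    rr
  })

  classifier <- stage("classifier", {
    if (!response$binary) NULL else {
      baseline_ix <- match(inputs$design$sample_before, sample_ids(filtered))
      baseline <- abundance_table(
        filtered$values[baseline_ix, , drop = FALSE] /
          rowSums(filtered$values[baseline_ix, , drop = FALSE]),
        lineage = filtered$lineage, mode = "relative")
      markers <- group_marker_test(baseline,
                                   stats::setNames(response$labels,
                                                   sample_ids(baseline)))
      utils::write.table(markers, file.path(config$out_dir, "markers.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      feat <- markers$taxon[markers$adjusted_p < config$marker_alpha]
      eval <- if (length(feat) >= 2L) {
        evaluate_baseline_classifier(
          baseline$values[, feat, drop = FALSE], response$labels,
          seed = derive_seed(config$seed, 2L))
      }
      list(markers = markers, eval = eval)
    }
  })

  pmv <- stage("permanova", {
    rel <- to_relative(inputs$table)
    d <- pairwise_matrix(rel, "bray_curtis")
    groups <- ifelse(rownames(d) %in% inputs$design$sample_before,
                     "before", "after")
    names(groups) <- rownames(d)
    permanova(d, groups, n_permutations = config$n_permutations,
              pairing = inputs$design, seed = derive_seed(config$seed, 3L))
  })

  summaries <- stage("stats", {
    rel <- to_relative(inputs$table)
    sh <- apply(rel$values, 1L, shannon)
    bf <- bf_ratio(rel)
    before_ids <- inputs$design$sample_before
    after_ids <- inputs$design$sample_after
    list(shannon_before = c(mean = mean(sh[before_ids]),
                            sd = stats::sd(sh[before_ids])),
         shannon_after = c(mean = mean(sh[after_ids]),
                           sd = stats::sd(sh[after_ids])),
         bf_before = c(mean = mean(bf[before_ids], na.rm = TRUE),
                       sd = stats::sd(bf[before_ids], na.rm = TRUE)),
         bf_after = c(mean = mean(bf[after_ids], na.rm = TRUE),
                      sd = stats::sd(bf[after_ids], na.rm = TRUE)))
  })

  summary <- list(
    package_version = as.character(utils::packageVersion("permatyper")),
    seed = config$seed,
    n_samples = nrow(inputs$table$values),
    n_subjects = nrow(inputs$design),
    n_taxa_filtered = ncol(filtered$values),
    k_enterotype = typing$enterotype$k,
    enterotype_sizes = as.vector(tabulate(typing$enterotype$labels,
                                          typing$enterotype$k)),
    permatype_core_sizes = as.vector(tabulate(typing$permatype$core_labels,
                                              typing$permatype$base$k)),
    permatype_unclassified = length(typing$permatype$unclassified),
    response_k = response$k_selected,
    response_groups = if (response$binary) response$group_stats else NULL,
    classifier_mean_auc = if (!is.null(classifier$eval))
      classifier$eval$mean_auc else NULL,
    permanova = list(pseudo_F = pmv$pseudo_F, R2 = pmv$R2,
                     p_value = pmv$p_value, omega2 = pmv$omega2),
    stats = summaries,
    config = config[c("rank", "min_frac", "min_samples", "metric", "alpha",
                      "n_bootstrap", "threshold", "n_permutations", "seed")])
  summary_path <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  structure(list(summary = summary,
                 paths = list(out_dir = config$out_dir, summary = summary_path,
                              log = log_path),
                 wall_clock = wall, config = config,
                 objects = list(typing = typing, response = response,
                                classifier = classifier, permanova = pmv)),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %d samples, k_enterotype = %d, outputs in %s\n",
              x$summary$n_samples, x$summary$k_enterotype,
              x$paths$out_dir))
  invisible(x)
}
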