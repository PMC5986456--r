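#' Random rooted tree with branch lengths
#'
#' Coalescent-style topology with independent exponential branch lengths
#' (mean 0.1); deterministic given `seed`. Supplies the branch lengths needed
#' by generalized UniFrac in tests and synthetic cohorts.
#'
#' @param n_leaves number of leaves (>= 2).
#' @param seed RNG seed.
#' @param labels optional leaf labels (length `n_leaves`).
#' @return an `ape::phylo` tree.
#' @export
random_tree <- function(n_leaves, seed = 1, labels = NULL) {
  if (n_leaves < 2) stopf("n_leaves must be >= 2")
  tree <- with_seed(seed, {
    tr <- ape::rcoal(n_leaves)
    tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 10)
    tr
  })
  if (!is.null(labels)) {
    stopifnot(length(labels) == n_leaves)
    tree$tip.label <- labels
  }
  validate_tree(tree)
  tree
}

#' Configuration of a synthetic paired cohort
#'
#' Defaults describe the emulated study: 215 subjects sampled before and
#' after a two-week diet intervention, three planted genus-level community
#' types, a bimodal paired-shift magnitude (non-responders 0.19 +- 0.03,
#' responders 0.30 +- 0.05 generalized-UniFrac units, 130/85 split),
#' responders biased toward higher baseline Bacteroidetes:Firmicutes ratios,
#' and an intervention signature that depresses Bacteroidetes while raising
#' Firmicutes/Actinobacteria/Euryarchaeota.
#'
#' @param n_subjects cohort size.
#' @param n_taxa number of genus-level taxa.
#' @param n_types number of planted community types.
#' @param concentration Dirichlet precision of baseline profiles around their
#'   type centroid (higher = tighter types).
#' @param responder_fraction fraction of subjects in the high-shift group.
#' @param shift_means,shift_sds per-group (non-responder, responder) mean/sd
#'   of the paired generalized-UniFrac dissimilarity.
#' @param bf_ratio_means per-group mean baseline Bacteroidetes:Firmicutes
#'   ratio.
#' @param mixture_fraction fraction of subjects whose baseline is a 50/50
#'   blend of two type centroids (planted "unstable" samples).
#' @param effect_r2 nominal fraction of total variance attributable to the
#'   intervention; recorded for reference, the realized value is measured and
#'   stored in the truth (per-subject shift targets take precedence).
#' @param sequencing_depth multinomial read depth per sample.
#' @param alpha generalized-UniFrac exponent used for calibration.
#' @param tree_seed,seed RNG seeds (tree topology / everything else).
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 215, n_taxa = 120, n_types = 3,
                          concentration = 60,
                          responder_fraction = 85 / 215,
                          shift_means = c(0.19, 0.30),
                          shift_sds = c(0.03, 0.05),
                          bf_ratio_means = c(0.08, 0.20),
                          mixture_fraction = 0.2,
                          effect_r2 = 0.04,
                          sequencing_depth = 20000,
                          alpha = 0.5, tree_seed = 42, seed = 1) {
  if (responder_fraction < 0 || responder_fraction > 1 ||
      mixture_fraction < 0 || mixture_fraction > 1)
    stopf("fractions must be in [0, 1]")
  if (length(shift_means) != 2L || length(shift_sds) != 2L)
    stopf("shift_means and shift_sds must have length 2")
  if (is.unsorted(shift_means)) stopf("shift_means must be ordered")
  if (n_types < 1 || n_types > 3) stopf("1..3 planted types supported")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_taxa = as.integer(n_taxa), n_types = as.integer(n_types),
                 concentration = concentration,
                 responder_fraction = responder_fraction,
                 shift_means = shift_means, shift_sds = shift_sds,
                 bf_ratio_means = bf_ratio_means,
                 mixture_fraction = mixture_fraction,
                 effect_r2 = effect_r2,
                 sequencing_depth = as.integer(sequencing_depth),
                 alpha = alpha, tree_seed = as.integer(tree_seed),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# gut-like taxonomy: names, phyla, families; driver genera for the 3 types
make_taxonomy <- function(n_taxa) {
  drivers <- data.frame(
    genus = c("Oscillibacter", "Prevotella", "Bacteroides", "Roseburia",
              "Lachnospiraceae_u", "Dorea", "Blautia", "Staphylococcus",
              "Faecalibacterium", "Bifidobacterium", "Methanobrevibacter",
              "Akkermansia"),
    family = c("Ruminococcaceae", "Prevotellaceae", "Bacteroidaceae",
               "Lachnospiraceae", "Lachnospiraceae", "Lachnospiraceae",
               "Lachnospiraceae", "Staphylococcaceae", "Ruminococcaceae",
               "Bifidobacteriaceae", "Methanobacteriaceae",
               "Akkermansiaceae"),
    phylum = c("Firmicutes", "Bacteroidetes", "Bacteroidetes", "Firmicutes",
               "Firmicutes", "Firmicutes", "Firmicutes", "Firmicutes",
               "Firmicutes", "Actinobacteria", "Euryarchaeota",
               "Verrucomicrobia"),
    stringsAsFactors = FALSE)
  if (n_taxa < nrow(drivers) + 8)
    stopf("n_taxa must be >= %d", nrow(drivers) + 8)
  n_extra <- n_taxa - nrow(drivers)
  pool <- c(Firmicutes = 0.55, Bacteroidetes = 0.20, Actinobacteria = 0.10,
            Proteobacteria = 0.08, Verrucomicrobia = 0.03,
            Euryarchaeota = 0.04)
  counts <- round(pool * n_extra)
  counts[counts < 1] <- 1
  while (sum(counts) > n_extra) counts[which.max(counts)] <- counts[which.max(counts)] - 1L
  while (sum(counts) < n_extra) counts[which.max(pool)] <- counts[which.max(pool)] + 1L
  extra <- do.call(rbind, lapply(names(counts), function(ph) {
    i <- seq_len(counts[[ph]])
    data.frame(genus = sprintf("%s_g%02d", substr(ph, 1, 4), i),
               family = sprintf("%s_f%02d", substr(ph, 1, 4), (i - 1) %/% 5 + 1),
               phylum = ph, stringsAsFactors = FALSE)
  }))
  tax <- rbind(drivers, extra)
  tax$genus <- make.unique(tax$genus, sep = "x")
  tax
}

# rank-abundance base profile shaped to gut-like phylum proportions
base_centroid <- function(tax) {
  phylum_mass <- c(Firmicutes = 0.834, Bacteroidetes = 0.068,
                   Actinobacteria = 0.034, Proteobacteria = 0.03,
                   Verrucomicrobia = 0.014, Euryarchaeota = 0.02)
  w <- numeric(nrow(tax))
  for (ph in names(phylum_mass)) {
    ix <- which(tax$phylum == ph)
    decay <- 0.75^seq_along(ix)             # geometric rank-abundance
    w[ix] <- phylum_mass[[ph]] * decay / sum(decay)
  }
  w / sum(w)
}

type_centroids <- function(tax, n_types) {
  base <- base_centroid(tax)
  boost <- list(c("Oscillibacter", "Prevotella", "Faecalibacterium"),
                c("Bacteroides", "Roseburia", "Lachnospiraceae_u"),
                c("Dorea", "Blautia", "Staphylococcus"))
  lapply(seq_len(n_types), function(t) {
    w <- base
    w[match(boost[[t]], tax$genus)] <- w[match(boost[[t]], tax$genus)] * 12
    w / sum(w)
  })
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

# branch indicator matrix for fast single-pair generalized UniFrac
branch_matrix <- function(tree, taxa) {
  n_tip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  n_node <- n_tip + tr$Nnode
  children <- matrix(FALSE, n_node, n_tip)
  children[cbind(seq_len(n_tip), seq_len(n_tip))] <- TRUE
  for (e in seq_len(nrow(tr$edge))) {
    children[tr$edge[e, 1L], ] <- children[tr$edge[e, 1L], ] |
      children[tr$edge[e, 2L], ]
  }
  M <- children[tr$edge[, 2L], match(taxa, tr$tip.label), drop = FALSE]
  storage.mode(M) <- "double"
  list(b = tr$edge.length, M = M)
}

gunifrac_profiles <- function(bm, p, q, alpha) {
  gunifrac_pair(drop(bm$M %*% p), drop(bm$M %*% q), bm$b, alpha)
}

#' Generate a synthetic paired cohort with recorded ground truth
#'
#' Baseline genus profiles are Dirichlet draws around planted type centroids
#' (responder baselines biased toward higher Bacteroidetes:Firmicutes
#' ratios); follow-up profiles perturb the baseline along a planted
#' intervention direction (Bacteroidetes down, Firmicutes /
#' Actinobacteria / Euryarchaeota up, plus subject-specific jitter) with the
#' mixing weight bisected per subject so the realized paired generalized
#' UniFrac dissimilarity matches a target drawn from the subject's group
#' distribution. Counts are multinomial at the configured depth. Everything
#' planted is recorded in `truth`.
#'
#' @param config a [cohort_config].
#' @return list with `table_before`, `table_after` (counts-mode
#'   [abundance_table]s), `design` ([paired_design]), `tree`, `truth`
#'   (per-subject data.frame), `realized_r2` (intervention variance fraction,
#'   generalized UniFrac PERMANOVA decomposition) and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  tax <- make_taxonomy(config$n_taxa)
  tree <- random_tree(config$n_taxa, config$tree_seed, labels = tax$genus)
  bm <- branch_matrix(tree, tax$genus)
  centroids <- type_centroids(tax, config$n_types)
  n <- config$n_subjects

  is_b <- tax$phylum == "Bacteroidetes"
  is_f <- tax$phylum == "Firmicutes"
  shift_mult <- rep(1, nrow(tax))
  shift_mult[is_b] <- 0.1
  shift_mult[is_f] <- 1.25
  shift_mult[tax$phylum %in% c("Actinobacteria", "Euryarchaeota")] <- 2

  out <- with_seed(config$seed, {
    n_resp <- round(config$responder_fraction * n)
    responder <- logical(n)
    responder[sample.int(n, n_resp)] <- TRUE
    n_mix <- round(config$mixture_fraction * n)
    is_mixture <- logical(n)
    if (n_mix > 0) is_mixture[sample.int(n, n_mix)] <- TRUE
    type <- sample.int(config$n_types, n, replace = TRUE)
    type2 <- if (config$n_types > 1)
      ((type + sample.int(config$n_types - 1L, n, replace = TRUE) - 1L) %%
         config$n_types) + 1L else type

    # per-group shift targets by stratified quantile sampling: marginally
    # N(mean, sd) but with balanced quantiles, so realized group moments match
    # the stated ones even at modest cohort sizes
    target <- numeric(n)
    for (g in 1:2) {
      ix <- which(responder == (g == 2L))
      if (!length(ix)) next
      qq <- stats::qnorm((seq_along(ix) - 0.5) / length(ix),
                         config$shift_means[[g]], config$shift_sds[[g]])
      target[ix] <- sample(qq)
    }
    target <- pmin(0.85, pmax(0.03, target))

    before <- matrix(0, n, nrow(tax))
    after <- matrix(0, n, nrow(tax))
    planted <- numeric(n)
    for (i in seq_len(n)) {
      cen <- if (is_mixture[i]) {
        (centroids[[type[i]]] + centroids[[type2[i]]]) / 2
      } else centroids[[type[i]]]
      # plant the group-specific baseline B:F ratio at the centroid
      bf_target <- stats::rlnorm(1,
        meanlog = log(config$bf_ratio_means[[responder[i] + 1L]]),
        sdlog = 0.5)
      r0 <- sum(cen[is_b]) / sum(cen[is_f])
      cen[is_b] <- cen[is_b] * bf_target / r0
      cen <- cen / sum(cen)
      p <- rdirichlet1(config$concentration * cen)

      t_i <- target[[i]]
      # redraw the subject-specific jitter until the direction has enough
      # headroom; genuinely unreachable targets still error
      d_max <- -Inf
      for (try in seq_len(20L)) {
        jitter <- exp(stats::rnorm(nrow(tax), 0, 1.6))
        m <- p * shift_mult * jitter
        m <- m / sum(m)
        d_max <- gunifrac_profiles(bm, p, m, config$alpha)
        if (d_max >= t_i) break
      }
      if (d_max < t_i)
        stopf("subject %d: target dissimilarity %.3f unreachable (attainable range [0, %.3f])",
              i, t_i, d_max)
      lo <- 0; hi <- 1
      for (it in seq_len(20L)) {
        w <- (lo + hi) / 2
        q <- (1 - w) * p + w * m
        if (gunifrac_profiles(bm, p, q, config$alpha) < t_i) lo <- w else hi <- w
      }
      w <- (lo + hi) / 2
      q <- (1 - w) * p + w * m
      before[i, ] <- p
      after[i, ] <- q
      planted[i] <- gunifrac_profiles(bm, p, q, config$alpha)
    }
    counts_before <- t(vapply(seq_len(n), function(i)
      stats::rmultinom(1, config$sequencing_depth, before[i, ])[, 1L],
      numeric(nrow(tax))))
    counts_after <- t(vapply(seq_len(n), function(i)
      stats::rmultinom(1, config$sequencing_depth, after[i, ])[, 1L],
      numeric(nrow(tax))))
    list(responder = responder, is_mixture = is_mixture, type = type,
         counts_before = counts_before, counts_after = counts_after,
         target = target, planted = planted)
  })

  subj <- sprintf("P%03d", seq_len(n))
  lineage <- data.frame(kingdom = ifelse(tax$phylum == "Euryarchaeota",
                                         "Archaea", "Bacteria"),
                        phylum = tax$phylum, family = tax$family,
                        genus = tax$genus, stringsAsFactors = FALSE)
  mk_table <- function(counts, suffix) {
    rownames(counts) <- paste0(subj, suffix)
    colnames(counts) <- tax$genus
    abundance_table(counts, lineage = lineage, mode = "counts")
  }
  table_before <- mk_table(out$counts_before, "_T0")
  table_after <- mk_table(out$counts_after, "_T1")
  design <- paired_design(subj, paste0(subj, "_T0"), paste0(subj, "_T1"))

  # realized dissimilarity as seen in the emitted count tables
  rel_b <- out$counts_before / rowSums(out$counts_before)
  rel_a <- out$counts_after / rowSums(out$counts_after)
  realized <- vapply(seq_len(n), function(i)
    gunifrac_profiles(bm, rel_b[i, ], rel_a[i, ], config$alpha), numeric(1))

  # realized intervention variance fraction (before-vs-after gUniFrac SS)
  all_rel <- rbind(rel_b, rel_a)
  rownames(all_rel) <- c(paste0(subj, "_T0"), paste0(subj, "_T1"))
  colnames(all_rel) <- tax$genus
  full <- abundance_table(all_rel, lineage = lineage, mode = "relative")
  D <- generalized_unifrac(full, tree, config$alpha)
  realized_r2 <- permanova_stats(unclass(D)^2, rep(1:2, each = n))$R2

  truth <- data.frame(subject_id = subj, type = out$type,
                      is_mixture = out$is_mixture, responder = out$responder,
                      target_dissim = out$target,
                      planted_dissim = out$planted,
                      realized_dissim = realized,
                      stringsAsFactors = FALSE)
  list(table_before = table_before, table_after = table_after,
       design = design, tree = tree, truth = truth,
       shift_direction = stats::setNames(sign(log(shift_mult)), tax$genus),
       realized_r2 = realized_r2, config = config)
}
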