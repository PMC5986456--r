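test_that("pam_fit separates tight pairs and equals brute force on small instances", {
  x <- c(0, 0.1, 10, 10.1)
  d <- dist_matrix(as.matrix(dist(x)))
  fit <- pam_fit(d, 2)
  expect_equal(unname(fit$labels[1]), unname(fit$labels[2]))
  expect_equal(unname(fit$labels[3]), unname(fit$labels[4]))
  expect_true(fit$labels[1] != fit$labels[3])
  # k = n: every sample its own medoid, cost 0
  expect_equal(pam_fit(d, 4)$cost, 0)
  expect_error(pam_fit(d, 5), "outside")

  # exhaustive-search oracle on random instances, n <= 8
  withr::with_seed(11, for (rep in 1:12) {
    n <- sample(4:8, 1)
    k <- sample(2:3, 1)
    m <- matrix(stats::runif(n * n), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    d <- dist_matrix(m)
    expect_equal(pam_fit(d, k)$cost, pam_oracle_cost(unclass(d), k),
                 tolerance = 1e-12)
  })
})

test_that("typing_result invariants hold", {
  tab <- random_rel_table(12, 5, seed = 3)
  d <- pairwise_matrix(tab, "jsd")
  fit <- pam_fit(d, 3)
  expect_setequal(unique(fit$labels), 1:3)
  # each medoid belongs to its own cluster
  for (i in seq_along(fit$medoids)) {
    expect_equal(unname(fit$labels[fit$medoids[i]]), i)
  }
})

test_that("calinski_harabasz equals the coordinate definition on Euclidean data", {
  withr::with_seed(5, {
    X <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 4), 10, 2))
    labels <- rep(1:2, each = 10)
    d <- dist_matrix(as.matrix(dist(X)))
    expect_equal(calinski_harabasz(d, labels), ch_oracle(X, labels),
                 tolerance = 1e-8)
    # correct labels beat random relabelings
    ch_true <- calinski_harabasz(d, labels)
    for (i in 1:10) {
      expect_gt(ch_true, calinski_harabasz(d, sample(labels)))
    }
    expect_error(calinski_harabasz(d, seq_len(20)), "k = n")
    expect_error(calinski_harabasz(d, rep(1, 20)), "2 clusters")
  })
})

test_that("mean_silhouette behaves at separation, randomness and singletons", {
  x <- c(rnorm(8, 0, 0.01), rnorm(8, 5, 0.01))
  d <- dist_matrix(as.matrix(dist(x)))
  expect_gt(mean_silhouette(d, rep(1:2, each = 8)), 0.9)
  # random labels on structureless data stay near the permutation mean 0
  withr::with_seed(8, {
    ds <- dist_matrix(as.matrix(dist(runif(20))))
    sils <- replicate(50, mean_silhouette(ds, sample(rep(1:2, 10))))
    expect_lt(abs(mean(sils)), 0.1)
  })
  # singleton cluster contributes 0
  d3 <- dist_matrix(as.matrix(dist(c(0, 0.1, 9))))
  lab <- c(1, 1, 2)
  s_all <- mean_silhouette(d3, lab)
  expect_equal(s_all * 3 - 0,
               sum(vapply(1:2, function(i) {
                 a <- as.matrix(dist(c(0, 0.1, 9)))[i, setdiff(1:2, i)]
                 b <- mean(as.matrix(dist(c(0, 0.1, 9)))[i, 3])
                 (b - a) / max(a, b)
               }, numeric(1))), tolerance = 1e-12)
})

test_that("enterotype recovers planted k and is invariant to taxon order", {
  co <- generate_cohort(cohort_config(n_subjects = 60, mixture_fraction = 0,
                                      seed = 21))
  rel <- to_relative(co$table_before)
  ent <- enterotype(rel)
  expect_equal(ent$k, 3)
  expect_gte(adjusted_rand_index(ent$labels, co$truth$type), 0.95)
  # planted k = 2
  co2 <- generate_cohort(cohort_config(n_subjects = 50, n_types = 2,
                                       mixture_fraction = 0, seed = 22))
  ent2 <- enterotype(to_relative(co2$table_before))
  expect_equal(ent2$k, 2)
  expect_gte(adjusted_rand_index(ent2$labels, co2$truth$type), 0.95)
  # taxon-column permutation leaves the result unchanged
  perm <- sample(ncol(rel$values))
  rel_p <- abundance_table(rel$values[, perm], lineage = rel$lineage[perm, ],
                           mode = "relative")
  ent_p <- enterotype(rel_p)
  expect_identical(ent_p$labels, ent$labels)
  # k range truncation warns, degenerate duplicated input errors cleanly
  small <- random_rel_table(5, 4, seed = 1)
  expect_warning(enterotype(small), "truncated")
})

test_that("permatype stability logic, thresholds and determinism", {
  co <- generate_cohort(cohort_config(n_subjects = 60, mixture_fraction = 0,
                                      seed = 31))
  rel <- to_relative(co$table_before)
  pt <- permatype(rel, n_bootstrap = 40, seed = 5)
  # perfectly separated planted clusters: nothing unclassified at 0.8
  expect_length(pt$unclassified, 0)
  expect_true(all(pt$stability >= 0 & pt$stability <= 1, na.rm = TRUE))
  # core labels are a restriction of the base labels
  expect_identical(pt$core_labels,
                   pt$base$labels[names(pt$core_labels)])
  expect_setequal(c(names(pt$core_labels), pt$unclassified),
                  names(pt$stability))
  # boundaries
  pt0 <- permatype(rel, n_bootstrap = 40, threshold = 0, seed = 5)
  expect_length(pt0$unclassified, 0)
  pt2 <- permatype(rel, n_bootstrap = 40, threshold = 1.01, seed = 5)
  expect_length(pt2$core_labels, 0)
  # determinism + sample-order invariance
  ptb <- permatype(rel, n_bootstrap = 40, seed = 5)
  expect_identical(pt$stability, ptb$stability)
  ord <- sample(nrow(rel$values))
  rel_o <- abundance_table(rel$values[ord, ], lineage = rel$lineage,
                           mode = "relative")
  pto <- permatype(rel_o, n_bootstrap = 40, seed = 5)
  expect_identical(pto$stability, pt$stability)
  expect_error(permatype(rel, n_bootstrap = 5), ">= 10")
})

test_that("permatype flags planted mixtures as unstable", {
  co <- generate_cohort(cohort_config(n_subjects = 90, mixture_fraction = 0.25,
                                      seed = 33))
  rel <- to_relative(co$table_before)
  pt <- permatype(rel, n_bootstrap = 60, seed = 7)
  uncl <- names(pt$stability) %in% pt$unclassified
  mix <- co$truth$is_mixture[match(sub("_T0", "", names(pt$stability)),
                                   co$truth$subject_id)]
  expect_gt(sum(uncl[mix]), 0)
  rate_mix <- mean(uncl[mix])
  rate_pure <- mean(uncl[!mix])
  expect_gte(rate_mix, 2 * max(rate_pure, 1 / sum(!mix)))
})

test_that("driver_taxa ranks planted drivers first", {
  co <- generate_cohort(cohort_config(n_subjects = 60, mixture_fraction = 0,
                                      seed = 41))
  rel <- to_relative(co$table_before)
  ent <- enterotype(rel)
  drivers <- driver_taxa(ent, rel, top_m = 5)
  planted <- list(c("Oscillibacter", "Prevotella", "Faecalibacterium"),
                  c("Bacteroides", "Roseburia", "Lachnospiraceae_u"),
                  c("Dorea", "Blautia", "Staphylococcus"))
  # map clusters to planted types via majority vote, then check top drivers
  for (k in 1:3) {
    type_k <- as.integer(names(which.max(
      table(co$truth$type[ent$labels == k]))))
    expect_true(drivers[[k]]$taxon[1] %in% planted[[type_k]])
  }
  # identical clusters give ~0 scores
  dup <- abundance_table(rbind(a = c(0.5, 0.5), b = c(0.5, 0.5),
                               c = c(0.5, 0.5), d = c(0.5, 0.5)),
                         mode = "relative")
  sc <- driver_taxa(stats::setNames(c(1, 1, 2, 2), c("a", "b", "c", "d")),
                    dup, top_m = 10)
  expect_true(all(abs(sc$cluster_1$score) < 1e-12))
  expect_equal(nrow(sc$cluster_1), 2)   # top_m larger than taxon count
})

test_that("transition_analysis builds the 2x2 and matches the Fisher oracle", {
  before <- stats::setNames(c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2),
                            paste0("P", 1:10, "_T0"))
  after <- stats::setNames(c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
                           paste0("P", 1:10, "_T1"))
  des <- paired_design(paste0("P", 1:10), paste0("P", 1:10, "_T0"),
                       paste0("P", 1:10, "_T1"))
  res <- transition_analysis(before, after, des, focus_cluster = 1)
  expect_equal(unname(res$contingency),
               matrix(c(5, 0, 0, 5), 2, byrow = TRUE))
  expect_equal(res$fisher_p, fisher_oracle(res$contingency), tolerance = 1e-12)
  expect_equal(res$fisher_p, 2 / choose(10, 5), tolerance = 1e-12)
  # everyone stays -> p = 1
  res2 <- transition_analysis(before, stats::setNames(before,
                                                      names(after)), des, 1)
  expect_equal(sum(res2$contingency[, "moved"]), 0)
  expect_equal(res2$fisher_p, 1)
  expect_error(transition_analysis(before, after, des, focus_cluster = 9),
               "empty at baseline")
})

test_that("fisher_exact_2x2 equals enumeration oracle on random tables", {
  withr::with_seed(13, for (i in 1:25) {
    m <- matrix(rpois(4, 5), 2, 2)
    if (sum(m) == 0) m[1, 1] <- 1
    expect_equal(fisher_exact_2x2(m), fisher_oracle(m), tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(m),
                 stats::fisher.test(m)$p.value, tolerance = 1e-7)
  })
})
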