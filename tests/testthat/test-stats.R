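test_that("shannon closed forms and invariances", {
  expect_equal(shannon(rep(1, 4)), 2)
  expect_equal(shannon(c(5, 0, 0)), 0)
  expect_equal(shannon(c(0.5, 0.25, 0.25)), 1.5)
  expect_equal(shannon(rep(1, 8), base = exp(1)), log(8))
  # zero-padding invariance
  expect_equal(shannon(c(0.2, 0.8, 0, 0, 0)), shannon(c(0.2, 0.8)))
  expect_error(shannon(c(0, 0)), "all-zero")
})

test_that("chao1 closed forms", {
  expect_equal(chao1(c(5, 10, 3)), 3)                 # no singletons
  expect_equal(chao1(c(1, 1, 2)), 3.5)                # 3 + 2*1/(2*2)
  x <- c(1, 1, 2, 7)
  expect_equal(chao1(c(x, 3)), chao1(x) + 1)          # F1, F2 unchanged
  expect_error(chao1(c(0.5, 1)), "integer")
})

test_that("rarefy subsamples exactly and matches hypergeometric expectation", {
  x <- c(a = 10, b = 0, c = 30)
  expect_equal(rarefy(x, 40, seed = 1), x)            # depth = total
  r1 <- rarefy(x, 1, seed = 2)
  expect_equal(sum(r1), 1)
  expect_error(rarefy(x, 41), "below depth")
  # mean over seeds approximates original proportions
  means <- rowMeans(vapply(1:400, function(s) rarefy(x, 10, seed = s),
                           numeric(3)))
  expect_equal(unname(means / 10), unname(x / sum(x)), tolerance = 0.03)
  # table mode drops shallow samples with a warning
  tab <- abundance_table(rbind(deep = c(50, 50), shallow = c(2, 1)),
                         mode = "counts")
  expect_warning(rt <- rarefy(tab, 20, seed = 3), "dropping")
  expect_equal(unname(rowSums(rt$values)), 20)
  expect_equal(attr(rt, "dropped_samples"), "shallow")
})

test_that("clr properties", {
  expect_equal(clr(rep(7, 5)), rep(0, 5))
  withr::with_seed(2, for (i in 1:10) {
    x <- rpois(20, 50)
    expect_equal(sum(clr(x)), 0, tolerance = 1e-9)
  })
  # approximate scale invariance for large counts
  x <- c(1000, 2000, 4000)
  expect_equal(clr(x), clr(2 * x), tolerance = 1e-3)
  expect_error(clr(c(-1, 2)), "negative")
  expect_error(clr(c(1, 2), pseudocount = 0), "pseudocount")
})

test_that("paired_clr_test: null, planted single effect, simulation recovery", {
  # continuous abundances: integer counts produce tied CLR differences, which
  # push wilcox.test off its exact path
  n <- 20; p <- 12
  withr::with_seed(3, counts <- matrix(rgamma(n * p, 50, 0.5), n, p))
  dimnames(counts) <- list(paste0("P", 1:n, "_T0"), paste0("t", 1:p))
  before <- abundance_table(counts, mode = "counts")
  after_vals <- counts
  rownames(after_vals) <- paste0("P", 1:n, "_T1")
  after <- abundance_table(after_vals, mode = "counts")
  des <- paired_design(paste0("P", 1:n), rownames(counts),
                       rownames(after_vals))
  null_res <- paired_clr_test(before, after, des)
  expect_true(all(null_res$p == 1))
  expect_true(all(null_res$adjusted_p == 1))

  # planted increase in taxon 1 for every subject -> minimal exact p 2/2^n
  shifted <- counts
  shifted[, 1] <- shifted[, 1] * 10
  rownames(shifted) <- paste0("P", 1:n, "_T1")
  after2 <- abundance_table(shifted, mode = "counts")
  res2 <- paired_clr_test(before, after2, des)
  expect_equal(res2$p[1], 2 / 2^n, tolerance = 1e-12)
  expect_gt(res2$median_clr_diff[1], 0)
  expect_equal(which.min(res2$adjusted_p), 1L)
})

test_that("bh_adjust equals p.adjust and the exhaustive definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::with_seed(4, for (i in 1:20) {
    p <- runif(sample(2:12, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"), tolerance = 1e-12)
  })
  # adjusted values non-decreasing in raw rank order
  p <- c(0.001, 0.2, 0.01, 0.8)
  expect_true(!is.unsorted(bh_adjust(p)[order(p)]))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("cooperatives keep only components above the size threshold", {
  edges <- data.frame(source = c("a", "b", "x", "p", "p"),
                      target = c("b", "c", "y", "p", "q"))
  expect_warning(cs <- cooperatives(edges), "self-loop")
  expect_length(cs$components, 1)
  expect_setequal(cs$components[[1]], c("a", "b", "c"))
  # empty edge list
  expect_length(cooperatives(data.frame(source = character(),
                                        target = character()))$components, 0)
  # path of 5 -> one component of 5
  path5 <- data.frame(source = letters[1:4], target = letters[2:5])
  expect_equal(lengths(cooperatives(path5)$components), c(cooperative_1 = 5L))
  # family-based naming when a table is given
  rel <- to_relative(tiny_table())
  cs2 <- cooperatives(data.frame(source = c("Bacteroides", "Blautia"),
                                 target = c("Prevotella", "Bacteroides")),
                      table = rel)
  expect_match(names(cs2$components)[1], "-dominant$")
})

test_that("cooperative_abundance sums members and respects partitions", {
  rel <- to_relative(tiny_table())
  all_tax <- cooperatives(data.frame(
    source = taxon_ids(rel)[-1], target = taxon_ids(rel)[-4]), min_size = 3)
  ca <- cooperative_abundance(all_tax, rel)
  expect_equal(unname(ca[, 1]), rep(1, 3), tolerance = 1e-12)
  # pair cooperative equals the sum of its two columns
  expect_warning(single <- cooperatives(
    data.frame(source = c("Blautia", "Blautia"), target = c("Blautia", "Dorea")),
    min_size = 2), "self-loop")
  ca2 <- cooperative_abundance(single, rel)
  expect_equal(unname(ca2[, 1]),
               unname(rowSums(rel$values[, c("Blautia", "Dorea")])))
  # partition columns sum to 1
  part <- structure(list(components = list(g1 = c("Bacteroides", "Prevotella"),
                                           g2 = c("Blautia", "Dorea")),
                         edges = NULL), class = "cooperative_set")
  expect_equal(unname(rowSums(cooperative_abundance(part, rel))), rep(1, 3),
               tolerance = 1e-12)
  missing <- structure(list(components = list(bad = c("nope1", "nope2")),
                            edges = NULL), class = "cooperative_set")
  expect_error(cooperative_abundance(missing, rel), "missing")
})

test_that("planted cooperative enrichment is detectable across types", {
  co <- generate_cohort(cohort_config(n_subjects = 60, mixture_fraction = 0,
                                      seed = 51))
  rel <- to_relative(co$table_before)
  coop <- structure(list(components = list(
    type1_drivers = c("Oscillibacter", "Prevotella", "Faecalibacterium")),
    edges = NULL), class = "cooperative_set")
  ab <- cooperative_abundance(coop, rel)
  in1 <- co$truth$type == 1
  p <- stats::wilcox.test(ab[in1, 1], ab[!in1, 1])$p.value
  expect_lt(p, 0.001)
  expect_gt(mean(ab[in1, 1]), mean(ab[!in1, 1]))
})
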