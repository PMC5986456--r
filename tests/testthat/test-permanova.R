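test_that("permanova matches the brute-force SS oracle on a 6-sample toy", {
  withr::with_seed(1, {
    x <- c(0.1, 0.2, 0.3, 1.1, 1.3, 1.2)
    d <- dist_matrix(as.matrix(dist(x)))
    g <- rep(c("a", "b"), each = 3)
    res <- permanova(d, g, n_permutations = 199, seed = 1)
    oracle <- permanova_oracle(unclass(d), g)
    expect_equal(res$pseudo_F, oracle$F, tolerance = 1e-12)
    expect_equal(res$R2, oracle$R2, tolerance = 1e-12)
    expect_equal(res$omega2_raw, oracle$omega2, tolerance = 1e-12)
  })
  # agreement with vegan on a random instance (independent implementation)
  withr::with_seed(2, {
    X <- matrix(rnorm(40), 20, 2)
    g <- rep(c("a", "b"), each = 10)
    d <- dist_matrix(as.matrix(dist(X)))
    res <- permanova(d, g, n_permutations = 99, seed = 1)
    ad <- vegan::adonis2(dist(X) ~ g, permutations = 99)
    expect_equal(res$pseudo_F, ad$F[1], tolerance = 1e-8)
    expect_equal(res$R2, ad$R2[1], tolerance = 1e-8)
  })
})

test_that("permanova separated groups give the minimal p", {
  withr::with_seed(3, {
    x <- c(rnorm(10, 0, 0.01), rnorm(10, 50, 0.01))
    d <- dist_matrix(as.matrix(dist(x)))
    res <- permanova(d, rep(1:2, each = 10), n_permutations = 199, seed = 4)
    expect_equal(res$p_value, 1 / 200)
    expect_gt(res$omega2, 0.9)
  })
})

test_that("permanova p is invariant to relabeling and sample order", {
  withr::with_seed(5, {
    x <- rnorm(16)
    d <- unclass(dist_matrix(as.matrix(dist(x))))
    g <- rep(c("a", "b"), each = 8)
    r1 <- permanova(dist_matrix(d), g, n_permutations = 99, seed = 7)
    r2 <- permanova(dist_matrix(d), ifelse(g == "a", "z", "y"),
                    n_permutations = 99, seed = 7)
    expect_equal(r1$p_value, r2$p_value)
    expect_equal(r1$pseudo_F, r2$pseudo_F)
    ord <- sample(16)
    r3 <- permanova(dist_matrix(d[ord, ord]), g[ord],
                    n_permutations = 99, seed = 7)
    expect_equal(r1$pseudo_F, r3$pseudo_F, tolerance = 1e-12)
    expect_equal(r1$R2, r3$R2, tolerance = 1e-12)
  })
})

test_that("paired permutation scheme validates and runs", {
  withr::with_seed(6, {
    n <- 12
    x <- rnorm(n)
    ids <- paste0(rep(paste0("P", 1:(n / 2)), each = 2), c("_T0", "_T1"))
    d <- as.matrix(dist(x))
    dimnames(d) <- list(ids, ids)
    des <- paired_design(paste0("P", 1:(n / 2)),
                         paste0("P", 1:(n / 2), "_T0"),
                         paste0("P", 1:(n / 2), "_T1"))
    g <- stats::setNames(rep(c("before", "after"), n / 2), ids)
    res <- permanova(dist_matrix(d), g, n_permutations = 99, pairing = des,
                     seed = 2)
    expect_equal(res$scheme, "paired")
    expect_true(res$p_value > 0 && res$p_value <= 1)
    # both samples of one subject in the same group -> error
    gbad <- g
    gbad[c("P1_T0", "P1_T1")] <- "before"
    gbad[c("P2_T0", "P2_T1")] <- "after"
    expect_error(permanova(dist_matrix(d), gbad, pairing = des),
                 "pairing ids not matching groups")
  })
})

test_that("permanova type-I error is controlled (free and paired schemes)", {
  withr::with_seed(8, {
    rej_free <- rej_paired <- 0
    nsim <- 200
    n <- 20
    ids <- paste0(rep(paste0("P", 1:(n / 2)), each = 2), c("_T0", "_T1"))
    des <- paired_design(paste0("P", 1:(n / 2)),
                         paste0("P", 1:(n / 2), "_T0"),
                         paste0("P", 1:(n / 2), "_T1"))
    g <- stats::setNames(rep(c("before", "after"), n / 2), ids)
    for (i in seq_len(nsim)) {
      d <- as.matrix(dist(matrix(rnorm(n * 3), n, 3)))
      dimnames(d) <- list(ids, ids)
      pf <- permanova(dist_matrix(d), g, n_permutations = 99)
      pp <- permanova(dist_matrix(d), g, n_permutations = 99, pairing = des)
      if (pf$p_value <= 0.05) rej_free <- rej_free + 1
      if (pp$p_value <= 0.05) rej_paired <- rej_paired + 1
    }
    expect_gte(rej_free / nsim, 0.02)
    expect_lte(rej_free / nsim, 0.08)
    expect_gte(rej_paired / nsim, 0.02)
    expect_lte(rej_paired / nsim, 0.08)
  })
})

test_that("power config validation and omega2 reachability error", {
  expect_error(power_config(1.2, 0.06, 0.006, 70), "mean_dissim")
  expect_error(power_config(0.5, 0, 0.006, 70), "sd_dissim")
  expect_error(power_config(0.5, 0.06, -1, 70), "omega2_target")
  cfg <- power_config(0.52, 0.06, 0.9, n_subjects = 20, n_reps = 5,
                      n_permutations = 49, n_calibration = 10)
  expect_error(simulate_power(cfg), "unreachable")
})

test_that("simulate_power: type-I at omega2 = 0, saturation at large effects", {
  cfg0 <- power_config(0.52, 0.06, 0, n_subjects = 20, n_reps = 300,
                       n_permutations = 99, seed = 3)
  est0 <- simulate_power(cfg0)
  se <- max(est0$monte_carlo_se, sqrt(0.05 * 0.95 / 300))
  expect_lte(abs(est0$power - 0.05), 3 * se)
  cfg1 <- power_config(0.52, 0.06, 0.1, n_subjects = 20, n_reps = 100,
                       n_permutations = 99, seed = 4)
  est1 <- simulate_power(cfg1)
  expect_gte(est1$power, 0.99)
  # determinism
  expect_equal(simulate_power(cfg1)$power, est1$power)
})

test_that("required_sample_size boundaries and monotone smoothing", {
  # target 0 -> smallest grid value without simulation effort mattering
  n0 <- required_sample_size(0.52, 0.06, 0.05, target_power = 0,
                             n_grid = c(10, 20, 30), n_reps = 20,
                             n_permutations = 49, seed = 5)
  expect_equal(as.integer(n0), 10L)
  # very large effect saturates at the smallest grid value
  nbig <- required_sample_size(0.52, 0.06, 0.15, target_power = 0.8,
                               n_grid = c(10, 20), n_reps = 60,
                               n_permutations = 99, seed = 6)
  expect_equal(as.integer(nbig), 10L)
  # unreachable target errors with the max power
  expect_error(
    required_sample_size(0.52, 0.06, 0.0001, target_power = 0.99,
                         n_grid = c(10, 16), n_reps = 30,
                         n_permutations = 49, seed = 7),
    "no grid point")
  # smoothed power is non-decreasing by construction
  expect_true(!is.unsorted(attr(nbig, "power_smoothed")))
})

test_that("estimated power increases with n and omega2", {
  pw <- sapply(c(0.003, 0.03), function(o2) {
    sapply(c(20, 60), function(n) {
      simulate_power(power_config(0.52, 0.06, o2, n_subjects = n,
                                  n_reps = 120, n_permutations = 99,
                                  seed = 11))$power
    })
  })
  # rows: n = 20, 60; cols: omega2 = 0.003, 0.03
  expect_gt(pw[2, 2], pw[1, 1])
  expect_gte(pw[2, 1], pw[1, 1] - 0.05)
  expect_gte(pw[1, 2], pw[1, 1] - 0.05)
})
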