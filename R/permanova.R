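#' PERMANOVA on a distance matrix
#'
#' Distance-based multivariate ANOVA: total sum of squares
#' `SST = sum(d^2)/n` over unordered pairs, within-group sums analogously per
#' group, `pseudo-F = (SSB/(k-1)) / (SSW/(n-k))`, `R2 = SSB/SST`. Significance
#' by label permutation with the add-one convention, so p is never 0 and has
#' resolution `1/(n_permutations+1)`. The bias-adjusted effect size
#' `omega^2 = (SSB - (k-1) SSW/(n-k)) / (SST + SSW/(n-k))` is truncated at 0
#' (raw value kept in `$omega2_raw`).
#'
#' With a `pairing` design the permutation scheme is restricted: each
#' subject's before/after samples swap group labels independently (the
#' `2^subjects` scheme for paired tests); every sample must then belong to a
#' pairing record and the two samples of a subject must sit in different
#' groups.
#'
#' @param dist a [dist_matrix].
#' @param groups group labels, aligned with the matrix rows (or named by
#'   sample id).
#' @param n_permutations number of label permutations.
#' @param pairing optional [paired_design] switching to the paired scheme.
#' @param seed optional RNG seed for the permutations.
#' @return a `permanova_result` list: `pseudo_F`, `R2`, `p_value`, `omega2`,
#'   `omega2_raw`, `df`, `n_permutations`, `scheme`.
#' @export
permanova <- function(dist, groups, n_permutations = 2000, pairing = NULL,
                      seed = NULL) {
  d <- unclass(dist_matrix(dist))
  n <- nrow(d)
  if (!is.null(names(groups))) groups <- groups[rownames(d)]
  if (length(groups) != n) stopf("groups length != number of samples")
  g <- as.integer(factor(groups))
  k <- length(unique(g))
  if (k < 2) stopf("need at least 2 groups")
  if (any(tabulate(g) < 2)) stopf("every group needs >= 2 samples")
  D2 <- d^2
  obs <- permanova_stats(D2, g, k)

  swap_pairs <- NULL
  if (!is.null(pairing)) {
    stopifnot(inherits(pairing, "paired_design"))
    bi <- match(pairing$sample_before, rownames(d))
    ai <- match(pairing$sample_after, rownames(d))
    if (anyNA(bi) || anyNA(ai))
      stopf("pairing references samples absent from the matrix")
    covered <- sort(c(bi, ai))
    if (!identical(covered, seq_len(n)))
      stopf("paired scheme requires every sample to belong to one pair")
    if (any(g[bi] == g[ai]))
      stopf("pairing ids not matching groups: subjects %s have both samples in one group",
            paste(pairing$subject_id[g[bi] == g[ai]], collapse = ", "))
    swap_pairs <- cbind(bi, ai)
  }

  fperm <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(p) {
      gp <- if (is.null(swap_pairs)) {
        g[sample.int(n)]
      } else {
        gp <- g
        flip <- stats::runif(nrow(swap_pairs)) < 0.5
        tmp <- gp[swap_pairs[flip, 1L]]
        gp[swap_pairs[flip, 1L]] <- gp[swap_pairs[flip, 2L]]
        gp[swap_pairs[flip, 2L]] <- tmp
        gp
      }
      permanova_stats(D2, gp, k)$F
    }, numeric(1))
  })
  p <- (1 + sum(fperm >= obs$F - 1e-12)) / (n_permutations + 1)
  structure(list(pseudo_F = obs$F, R2 = obs$R2, p_value = p,
                 omega2 = max(0, obs$omega2_raw), omega2_raw = obs$omega2_raw,
                 df = c(between = k - 1L, within = n - k),
                 n_permutations = n_permutations,
                 scheme = if (is.null(pairing)) "free" else "paired"),
            class = "permanova_result")
}

# SS decomposition for one labelling
permanova_stats <- function(D2, g, k = length(unique(g))) {
  n <- nrow(D2)
  sst <- sum(D2[upper.tri(D2)]) / n
  ssw <- 0
  for (lev in unique(g)) {
    ix <- which(g == lev)
    ssw <- ssw + sum(D2[ix, ix]) / (2 * length(ix))
  }
  ssb <- sst - ssw
  msw <- ssw / (n - k)
  list(F = (ssb / (k - 1)) / msw, R2 = ssb / sst,
       omega2_raw = (ssb - (k - 1) * msw) / (sst + msw))
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA (%s permutations, %s scheme): pseudo-F = %.4g, R2 = %.4g, omega2 = %.4g, p = %.4g\n",
    x$n_permutations, x$scheme, x$pseudo_F, x$R2, x$omega2, x$p_value))
  invisible(x)
}

#' Configuration for PERMANOVA power simulation
#'
#' The simulated world is a two-group before/after comparison of `n_subjects`
#' subjects, each contributing one sample to each group (so the distance
#' matrix has `2 * n_subjects` samples). Latent profiles live in a
#' `latent_dim`-dimensional Euclidean space; the between-group centroid offset
#' is calibrated by bisection so the realized omega^2 matches
#' `omega2_target`, and the realized pairwise dissimilarities are affinely
#' mapped to the target mean and standard deviation.
#'
#' @param mean_dissim,sd_dissim target mean and sd of pairwise dissimilarity
#'   (e.g. 0.52 and 0.06 for healthy-gut genus profiles).
#' @param omega2_target effect size (fraction of distance-based variance).
#' @param n_subjects subjects (= samples per group).
#' @param alpha_level rejection level.
#' @param n_reps Monte-Carlo replicates.
#' @param n_permutations permutations per replicate.
#' @param seed master RNG seed.
#' @param latent_dim latent Euclidean dimension.
#' @param n_calibration replicates per bisection step.
#' @return a `power_config` list.
#' @export
power_config <- function(mean_dissim, sd_dissim, omega2_target, n_subjects,
                         alpha_level = 0.05, n_reps = 500,
                         n_permutations = 200, seed = 1, latent_dim = 10,
                         n_calibration = 100) {
  if (mean_dissim <= 0 || mean_dissim >= 1) stopf("mean_dissim must be in (0,1)")
  if (sd_dissim <= 0) stopf("sd_dissim must be > 0")
  if (omega2_target < 0) stopf("omega2_target must be >= 0")
  if (n_subjects < 3) stopf("need n_subjects >= 3")
  structure(list(mean_dissim = mean_dissim, sd_dissim = sd_dissim,
                 omega2_target = omega2_target, alpha_level = alpha_level,
                 n_subjects = as.integer(n_subjects),
                 n_reps = as.integer(n_reps),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), latent_dim = as.integer(latent_dim),
                 n_calibration = as.integer(n_calibration)),
            class = "power_config")
}

# one simulated squared-distance matrix (2*n_subjects samples, offset delta)
simulate_d2 <- function(n, latent_dim, delta, mean_t, sd_t) {
  X <- matrix(stats::rnorm(n * latent_dim), n, latent_dim)
  half <- n %/% 2
  X[seq(half + 1L, n), 1L] <- X[seq(half + 1L, n), 1L] + delta
  Dv <- stats::dist(X)
  a <- sd_t / stats::sd(Dv)
  b <- mean_t - a * mean(Dv)
  D <- as.matrix(pmax(a * Dv + b, 1e-9))
  diag(D) <- 0
  D^2
}

# mean raw omega2 of the true labelling over `reps` simulated matrices
realized_omega2 <- function(n, latent_dim, delta, mean_t, sd_t, reps) {
  half <- n %/% 2
  g <- rep(1:2, c(half, n - half))
  mean(vapply(seq_len(reps), function(i)
    permanova_stats(simulate_d2(n, latent_dim, delta, mean_t, sd_t), g)$omega2_raw,
    numeric(1)))
}

# deterministic pre-run bisection on the group offset
calibrate_offset <- function(config) {
  n <- 2L * config$n_subjects
  if (config$omega2_target == 0)
    return(list(delta = 0, achieved = 0))
  f <- function(delta) with_seed(derive_seed(config$seed, 7L),
    realized_omega2(n, config$latent_dim, delta, config$mean_dissim,
                    config$sd_dissim, config$n_calibration))
  hi <- 1
  while (f(hi) < config$omega2_target) {
    hi <- hi * 2
    if (hi > 64) {
      stopf("omega2_target %.4g unreachable; attainable range is [0, %.4g]",
            config$omega2_target, f(64))
    }
  }
  lo <- 0
  for (i in seq_len(16L)) {
    mid <- (lo + hi) / 2
    if (f(mid) < config$omega2_target) lo <- mid else hi <- mid
  }
  delta <- (lo + hi) / 2
  list(delta = delta, achieved = f(delta))
}

#' Simulate PERMANOVA power
#'
#' Monte-Carlo power of the two-group PERMANOVA at the configured effect size
#' and dissimilarity distribution (see [power_config()] for the generating
#' model). Deterministic given the config seed.
#'
#' @param config a [power_config].
#' @return a `power_estimate`: `power`, `monte_carlo_se`, the calibration
#'   record and the config echo.
#' @export
simulate_power <- function(config) {
  stopifnot(inherits(config, "power_config"))
  calib <- calibrate_offset(config)
  n <- 2L * config$n_subjects
  half <- n %/% 2
  z <- c(rep(1, half), rep(0, n - half))
  P <- config$n_permutations
  rejections <- with_seed(derive_seed(config$seed, 11L), {
    vapply(seq_len(config$n_reps), function(r) {
      D2 <- simulate_d2(n, config$latent_dim, calib$delta,
                        config$mean_dissim, config$sd_dissim)
      tot <- sum(D2)
      M <- D2 %*% z
      s11 <- drop(z %*% M) / 2
      s12 <- sum(M) - 2 * s11
      s22 <- tot / 2 - s11 - s12
      sst <- tot / (2 * n)
      ssw <- s11 / half + s22 / (n - half)
      fobs <- (sst - ssw) / (ssw / (n - 2))
      Z <- vapply(seq_len(P), function(p) sample(z), numeric(n))
      Mp <- D2 %*% Z
      s11p <- colSums(Z * Mp) / 2
      s12p <- colSums(Mp) - 2 * s11p
      s22p <- tot / 2 - s11p - s12p
      sswp <- s11p / half + s22p / (n - half)
      fp <- (sst - sswp) / (sswp / (n - 2))
      p_val <- (1 + sum(fp >= fobs - 1e-12)) / (P + 1)
      as.numeric(p_val <= config$alpha_level)
    }, numeric(1))
  })
  power <- mean(rejections)
  structure(list(power = power,
                 monte_carlo_se = sqrt(power * (1 - power) / config$n_reps),
                 calibration = calib, config = config),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("power = %.3f (MC se %.3f) at n_subjects = %d, omega2 = %.4g\n",
              x$power, x$monte_carlo_se, x$config$n_subjects,
              x$config$omega2_target))
  invisible(x)
}

#' Minimal sample size reaching a target power
#'
#' Estimates power on an ascending grid of subject counts, smooths the
#' estimates by isotonic regression (power is monotone in n), and returns the
#' smallest grid value whose smoothed power reaches `target_power`.
#'
#' @inheritParams power_config
#' @param target_power required power.
#' @param n_grid ascending integer grid of subject counts.
#' @return smallest adequate n (integer), with attributes `power` (raw
#'   estimates) and `power_smoothed`.
#' @export
required_sample_size <- function(mean_dissim, sd_dissim, omega2_target,
                                 alpha_level = 0.05, target_power = 0.8,
                                 n_grid = seq(30, 110, 10), n_reps = 500,
                                 n_permutations = 200, seed = 1,
                                 latent_dim = 10, n_calibration = 100) {
  if (is.unsorted(n_grid, strictly = TRUE)) stopf("n_grid must be ascending")
  powers <- vapply(seq_along(n_grid), function(i) {
    cfg <- power_config(mean_dissim, sd_dissim, omega2_target,
                        n_subjects = n_grid[i], alpha_level = alpha_level,
                        n_reps = n_reps, n_permutations = n_permutations,
                        seed = derive_seed(seed, i), latent_dim = latent_dim,
                        n_calibration = n_calibration)
    simulate_power(cfg)$power
  }, numeric(1))
  smoothed <- stats::isoreg(n_grid, powers)$yf
  hit <- which(smoothed >= target_power)
  if (!length(hit))
    stopf("no grid point reaches power %.2f (max smoothed power %.3f at n = %d)",
          target_power, max(smoothed), n_grid[which.max(smoothed)])
  out <- as.integer(n_grid[hit[1L]])
  attr(out, "power") <- stats::setNames(powers, n_grid)
  attr(out, "power_smoothed") <- stats::setNames(smoothed, n_grid)
  out
}
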