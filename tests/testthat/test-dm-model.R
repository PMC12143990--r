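test_that("the Dirichlet-multinomial likelihood has the right special cases", {
  # a sample with total count zero contributes nothing
  Y <- rbind(c(0, 0), c(3, 1))
  P <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(dm_log_likelihood(Y, P, 10),
               dm_log_likelihood(Y[2, , drop = FALSE],
                                 P[2, , drop = FALSE], 10))
  # a single draw reduces to the categorical probability, independent of alpha
  for (a in c(0.5, 3, 100)) {
    expect_equal(dm_log_likelihood(rbind(c(1, 0)), rbind(c(0.5, 0.5)), a),
                 log(0.5))
  }
  expect_error(dm_log_likelihood(rbind(c(1, 0)), rbind(c(0.5, 0.5)), 0),
               class = "crypticsplice_domain_error")
  expect_error(dm_log_likelihood(rbind(c(1, 0)), rbind(c(0.7, 0.6)), 1),
               class = "crypticsplice_domain_error")
})

test_that("Dirichlet-multinomial masses sum to one over all outcomes", {
  # oracle: exhaustive enumeration of compositions of n into J parts
  compositions <- function(n, J) {
    if (J == 1L) return(matrix(n, ncol = 1))
    out <- NULL
    for (k in 0:n) {
      rest <- compositions(n - k, J - 1L)
      out <- rbind(out, cbind(k, rest))
    }
    out
  }
  for (spec in list(list(n = 3, p = c(0.5, 0.3, 0.2), a = 10),
                    list(n = 4, p = c(0.7, 0.3), a = 2.5),
                    list(n = 2, p = c(0.2, 0.3, 0.5), a = 77))) {
    cc <- compositions(spec$n, length(spec$p))
    total <- sum(apply(cc, 1, function(y) {
      exp(dm_log_likelihood(matrix(y, nrow = 1),
                            matrix(spec$p, nrow = 1), spec$a))
    }))
    expect_equal(total, 1, tolerance = 1e-9)
  }
})

test_that("the cluster fit recovers pooled proportions and null symmetry", {
  set.seed(10)
  # identical empirical proportions in both groups, large counts ->
  # group coefficients near zero
  Y <- matrix(rep(c(600L, 400L), each = 24), ncol = 2)
  X <- cbind(intercept = 1, group = rep(c(1, 0), each = 12))
  fit <- fit_dm_cluster(Y, X)
  expect_true(fit$converged)
  expect_lt(abs(fit$beta[1, "group"]), 0.05)

  # J = 2 intercept-only fit vs a 1-D grid-search oracle over
  # (logit p, log alpha)
  n <- rep(80L, 30)
  set.seed(11)
  p_true <- 0.35; a_true <- 20
  Y2 <- t(vapply(n, function(ni) {
    pp <- rgamma(2, a_true * c(p_true, 1 - p_true))
    pp <- pp / sum(pp)
    as.integer(stats::rmultinom(1, ni, pp))
  }, integer(2)))
  fit2 <- fit_dm_cluster(Y2, matrix(1, nrow(Y2), 1,
                                    dimnames = list(NULL, "intercept")))
  grid_ll <- function(lp, la) {
    p <- 1 / (1 + exp(-lp))
    P <- matrix(c(p, 1 - p), nrow(Y2), 2, byrow = TRUE)
    dm_log_likelihood(Y2, P, exp(la))
  }
  grid <- expand.grid(lp = seq(-3, 3, by = 0.01),
                      la = seq(log(1), log(200), by = 0.05))
  ll <- mapply(grid_ll, grid$lp, grid$la)
  best_p <- 1 / (1 + exp(-grid$lp[which.max(ll)]))
  fitted_p <- 1 / (1 + exp(-fit2$beta[1, 1]))
  expect_lt(abs(fitted_p - best_p), 0.02)
  pooled <- sum(Y2[, 1]) / sum(Y2)
  expect_lt(abs(fitted_p - pooled), 0.02)

  expect_error(fit_dm_cluster(Y2, cbind(intercept = 1, dup = 1)),
               class = "crypticsplice_domain_error")
})

test_that("the group-effect sign is recovered reliably on planted signal", {
  hits <- 0L
  reps <- 60L
  set.seed(12)
  X <- cbind(intercept = 1, group = rep(c(1, 0), each = 20))
  for (r in seq_len(reps)) {
    p0 <- c(0.3, 0.7); p1 <- c(0.5, 0.5)     # delta PSI 0.2 on junction 1
    Y <- t(vapply(seq_len(40), function(i) {
      p <- if (i <= 20) p1 else p0
      pp <- rgamma(2, 30 * p); pp <- pp / sum(pp)
      as.integer(stats::rmultinom(1, rnbinom(1, mu = 100, size = 5) + 5, pp))
    }, integer(2)))
    tst <- test_cluster(Y, X)
    if (is.finite(tst$effect_sizes[1]) && tst$effect_sizes[1] > 0) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / reps, 0.95)
})

test_that("likelihood-ratio testing behaves and maps effects to all junctions", {
  set.seed(13)
  X <- cbind(intercept = 1, group = rep(c(1, 0), each = 10))
  Y <- matrix(rpois(60, 40), ncol = 3)
  tst <- test_cluster(Y, X)
  expect_true(tst$p_value >= 0 && tst$p_value <= 1)
  expect_equal(tst$df, 2L)
  expect_length(tst$effect_sizes, 3L)
  # reference junction takes minus the sum: effects sum to zero
  expect_equal(sum(tst$effect_sizes), 0, tolerance = 1e-8)
  # a cluster with one informative junction cannot be tested
  Y0 <- cbind(Y[, 1], 0L)
  expect_true(is.nan(test_cluster(Y0, X)$p_value))
})

test_that("BH adjustment matches its closed form and a brute-force oracle", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(0.2), 0.2)
  set.seed(14)
  p <- runif(100)
  # oracle: direct step-up definition with cummin
  o <- order(p); m <- length(p)
  q_oracle <- numeric(m)
  q_oracle[o] <- rev(cummin(rev(p[o] * m / seq_len(m))))
  expect_equal(adjust_fdr(p), pmin(q_oracle, 1))
  # NA propagation keeps missing tests out of the family
  p2 <- c(0.01, NA, 0.02)
  q2 <- adjust_fdr(p2)
  expect_true(is.na(q2[2]))
  expect_equal(q2[c(1, 3)], adjust_fdr(c(0.01, 0.02)))
})

test_that("PSI computation matches published group arithmetic", {
  # counts (30, 70) in one sample -> PSI (0.3, 0.7)
  one <- compute_psi(rbind(c(30, 70)), is_case = TRUE)
  expect_equal(one$psi_case, c(0.3, 0.7))
  # per-sample PSIs in a cluster sum to one; group means subtract to
  # the published difference when group PSIs are 0.431 and 0.210
  Y <- rbind(c(431, 569), c(210, 790))
  psi <- compute_psi(Y, is_case = c(TRUE, FALSE))
  expect_equal(psi$delta_psi[1], 0.221, tolerance = 1e-12)
  # zero-total samples are excluded, empty group gives NaN
  Y2 <- rbind(c(0, 0), c(10, 30))
  psi2 <- compute_psi(Y2, is_case = c(TRUE, FALSE))
  expect_true(all(is.nan(psi2$psi_case)))
  expect_equal(psi2$psi_control, c(0.25, 0.75))
})

test_that("significance calling combines cluster FDR and junction delta PSI", {
  r <- tibble::tibble(q_value = c(0.04, 0.04, 0.06, NA),
                      delta_psi = c(0.12, 0.08, 0.30, 0.5))
  expect_equal(call_significant(r)$significant, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("differential splicing returns coherent per-junction results", {
  cfg <- sim_config(seed = 30, n_clusters = 30, signal_fraction = 0.5,
                    delta_psi_grid = 0.3)
  sim <- simulate_junction_counts(cfg)
  cl <- cluster_introns(filter_junctions(sim$counts[, -1]))
  res <- differential_splicing(cl, sim$metadata, "case", "control")
  # PSIs within a sample's cluster sum to one -> group means do too
  sums <- res |>
    dplyr::group_by(cluster_id) |>
    dplyr::summarise(s = sum(psi_case), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))
  # q monotone non-decreasing in p rank at cluster level
  cl_p <- dplyr::distinct(res, cluster_id, p_value, q_value) |>
    dplyr::filter(!is.na(p_value)) |>
    dplyr::arrange(p_value)
  expect_true(all(diff(cl_p$q_value) > -1e-12))
  # effect-size sign agrees with delta PSI sign on significant junctions
  sig <- dplyr::filter(res, significant, is.finite(effect_size),
                       abs(delta_psi) > 0.05)
  expect_gte(mean(sign(sig$effect_size) == sign(sig$delta_psi)), 0.95)
})
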