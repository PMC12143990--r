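#' Dirichlet-multinomial log-likelihood for a cluster
#'
#' Log probability mass of per-sample junction counts within one intron
#' cluster under a Dirichlet-multinomial with sample-specific usage
#' proportions and a shared concentration. For sample i with counts
#' \eqn{y_i} (total \eqn{n_i}) and proportions \eqn{p_i}, the Dirichlet
#' parameters are \eqn{a_{ij} = \alpha p_{ij}} and the mass is the standard
#' compound multinomial-Dirichlet density; samples with total count zero
#' contribute zero. The multinomial coefficient is included so that masses
#' over all outcomes of fixed total sum to one.
#'
#' @param counts Numeric matrix, samples x junctions, non-negative integers.
#' @param proportions Numeric matrix, samples x junctions, rows on the simplex.
#' @param alpha Positive scalar concentration.
#' @return Scalar log-likelihood (sum over samples).
#' @export
dm_log_likelihood <- function(counts, proportions, alpha) {
  counts <- as.matrix(counts); proportions <- as.matrix(proportions)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0) {
    abort("alpha must be a positive scalar", class = "crypticsplice_domain_error")
  }
  if (any(counts < 0)) {
    abort("counts must be non-negative", class = "crypticsplice_domain_error")
  }
  if (!isTRUE(all.equal(rowSums(proportions), rep(1, nrow(proportions)),
                        tolerance = 1e-6)) || any(proportions < 0)) {
    abort("proportion rows must lie on the simplex",
          class = "crypticsplice_domain_error")
  }
  n <- rowSums(counts)
  a <- alpha * proportions
  # guard: p == 0 with y == 0 contributes 0; p == 0 with y > 0 gives -Inf
  term <- lgamma(counts + a) - lgamma(a)
  term[a == 0 & counts == 0] <- 0
  coef <- lgamma(n + 1) - rowSums(lgamma(counts + 1))
  sum(coef + lgamma(alpha) - lgamma(n + alpha) + rowSums(term))
}

softmax_rows <- function(eta) {
  m <- apply(eta, 1L, max)
  e <- exp(eta - m)
  e / rowSums(e)
}

# negative log-likelihood and gradient in the packed parameterization
# theta = (vec(beta[J-1, P]), log alpha); reference junction J has beta = 0.
dm_nll <- function(theta, Y, X) {
  N <- nrow(Y); J <- ncol(Y); P <- ncol(X)
  beta <- matrix(theta[seq_len((J - 1L) * P)], nrow = J - 1L, ncol = P)
  alpha <- exp(theta[length(theta)])
  eta <- cbind(X %*% t(beta), 0)
  p <- softmax_rows(eta)
  a <- alpha * p
  n <- rowSums(Y)
  term <- lgamma(Y + a) - lgamma(a)
  ll <- sum(lgamma(alpha) - lgamma(n + alpha) + rowSums(term))
  -ll
}

dm_nll_grad <- function(theta, Y, X) {
  N <- nrow(Y); J <- ncol(Y); P <- ncol(X)
  beta <- matrix(theta[seq_len((J - 1L) * P)], nrow = J - 1L, ncol = P)
  alpha <- exp(theta[length(theta)])
  eta <- cbind(X %*% t(beta), 0)
  p <- softmax_rows(eta)
  a <- alpha * p
  n <- rowSums(Y)
  g <- digamma(Y + a) - digamma(a)            # N x J, d ll / d a_ij
  gbar <- rowSums(p * g)                       # N
  # d ll / d eta_ij = alpha * p_ij * (g_ij - gbar_i); reference column dropped
  deta <- alpha * p * (g - gbar)
  dbeta <- t(deta[, seq_len(J - 1L), drop = FALSE]) %*% X   # (J-1) x P
  dlogalpha <- alpha * sum(digamma(alpha) - digamma(n + alpha) + gbar)
  -c(as.vector(dbeta), dlogalpha)
}

#' Fit a Dirichlet-multinomial GLM to one intron cluster
#'
#' Maximizes the Dirichlet-multinomial log-likelihood over per-junction
#' covariate coefficients (softmax link, last junction as reference) and a
#' shared log concentration. Intercepts are initialized at pooled empirical
#' logit proportions (pseudocount 0.5), other coefficients at zero, and
#' `log(alpha)` at `log(10)`; optimization is quasi-Newton (BFGS) with
#' analytic gradients, relative-tolerance 1e-10, at most `maxit` iterations.
#'
#' @param counts Samples x junctions count matrix (>= 2 junctions; junctions
#'   with zero total count should be dropped by the caller).
#' @param design Samples x covariates design matrix including an intercept
#'   column. Collinear columns are an error.
#' @param alpha Optional fixed concentration. By default the concentration
#'   is estimated jointly with the coefficients; passing a value holds it
#'   fixed, which [test_cluster()] uses to profile the nuisance
#'   concentration under the null model.
#' @param maxit Maximum number of quasi-Newton iterations.
#' @return An object of class `dm_cluster_fit` with elements `beta`
#'   ((J-1) x P coefficient matrix, reference junction implicit at zero),
#'   `alpha`, `loglik` (including the data-dependent multinomial coefficient
#'   so fits are comparable across models), `converged`, `n_iter`, and the
#'   dimension bookkeeping needed by [tidy()]/[glance()].
#' @export
fit_dm_cluster <- function(counts, design, alpha = NULL, maxit = 500L) {
  Y <- as.matrix(counts)
  X <- as.matrix(design)
  if (ncol(Y) < 2L) {
    abort("a cluster needs at least two junctions",
          class = "crypticsplice_domain_error")
  }
  if (qr(X)$rank < ncol(X)) {
    bad <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
    abort(paste0("design matrix is rank deficient; check columns: ",
                 paste(bad, collapse = ", ")),
          class = "crypticsplice_domain_error")
  }
  J <- ncol(Y); P <- ncol(X)
  pooled <- colSums(Y) + 0.5
  pooled <- pooled / sum(pooled)
  beta0 <- matrix(0, nrow = J - 1L, ncol = P)
  beta0[, 1L] <- log(pooled[-J]) - log(pooled[J])
  fixed_alpha <- !is.null(alpha)
  if (fixed_alpha && (!is.numeric(alpha) || alpha <= 0)) {
    abort("fixed alpha must be positive", class = "crypticsplice_domain_error")
  }
  # bounds keep the fit in the numerically meaningful region: softmax
  # linear predictors within +-30, concentration within [1e-3, 1e6] (the
  # upper cap is the effectively-multinomial limit; beyond it lgamma
  # differences lose all precision)
  if (fixed_alpha) {
    la <- log(alpha)
    theta0 <- as.vector(beta0)
    fn <- function(th) dm_nll(c(th, la), Y, X)
    gr <- function(th) head(dm_nll_grad(c(th, la), Y, X), -1L)
    lower <- rep(-30, length(theta0))
    upper <- rep(30, length(theta0))
  } else {
    theta0 <- c(as.vector(beta0), log(10))
    fn <- function(th) dm_nll(th, Y, X)
    gr <- function(th) dm_nll_grad(th, Y, X)
    lower <- c(rep(-30, length(theta0) - 1L), log(1e-3))
    upper <- c(rep(30, length(theta0) - 1L), log(1e6))
  }
  fit <- tryCatch(
    optim(theta0, fn = fn, gr = gr, method = "L-BFGS-B",
          lower = lower, upper = upper,
          control = list(maxit = maxit, factr = 1e5)),
    error = function(e) NULL
  )
  converged <- !is.null(fit) && fit$convergence == 0L && is.finite(fit$value)
  if (is.null(fit)) {
    beta <- matrix(NA_real_, J - 1L, P)
    alpha <- NA_real_; ll <- NaN; iters <- NA_integer_
  } else {
    beta <- matrix(fit$par[seq_len((J - 1L) * P)], J - 1L, P)
    colnames(beta) <- colnames(X)
    if (!fixed_alpha) alpha <- exp(fit$par[length(fit$par)])
    n <- rowSums(Y)
    coef_const <- sum(lgamma(n + 1) - rowSums(lgamma(Y + 1)))
    ll <- if (converged) -fit$value + coef_const else NaN
    iters <- fit$counts[["function"]]
  }
  structure(
    list(beta = beta, alpha = alpha, loglik = ll,
         converged = converged, n_iter = iters,
         n_samples = nrow(Y), n_junctions = J,
         junction_names = colnames(Y), covariate_names = colnames(X)),
    class = "dm_cluster_fit"
  )
}

#' @export
print.dm_cluster_fit <- function(x, ...) {
  cat("Dirichlet-multinomial cluster fit\n")
  cat("  junctions:", x$n_junctions, " samples:", x$n_samples, "\n")
  cat("  alpha:", format(x$alpha, digits = 4),
      " loglik:", format(x$loglik, digits = 6),
      " converged:", x$converged, "\n")
  invisible(x)
}

#' Tidy a Dirichlet-multinomial cluster fit
#'
#' @param x A `dm_cluster_fit`.
#' @param ... Unused.
#' @return A tibble with one row per (junction, covariate) coefficient; the
#'   reference junction's implicit zero coefficients are included.
#' @method tidy dm_cluster_fit
#' @export
tidy.dm_cluster_fit <- function(x, ...) {
  J <- x$n_junctions
  jn <- x$junction_names %||% paste0("junction_", seq_len(J))
  cv <- x$covariate_names %||% paste0("x", seq_len(ncol(x$beta)))
  full <- rbind(x$beta, 0)
  tibble(
    junction = rep(jn, times = length(cv)),
    term = rep(cv, each = J),
    estimate = as.vector(full)
  )
}

#' One-line model summary of a Dirichlet-multinomial cluster fit
#'
#' @param x A `dm_cluster_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `alpha`, `logLik`, `converged`, `n_iter`,
#'   `n_samples`, `n_junctions`, and the parameter count `df`.
#' @method glance dm_cluster_fit
#' @export
glance.dm_cluster_fit <- function(x, ...) {
  tibble(
    alpha = x$alpha, logLik = x$loglik, converged = x$converged,
    n_iter = x$n_iter, n_samples = x$n_samples, n_junctions = x$n_junctions,
    df = length(x$beta) + 1L
  )
}

#' Likelihood-ratio test for a group effect in one cluster
#'
#' Fits the Dirichlet-multinomial GLM with and without the group column and
#' compares them with a likelihood-ratio chi-square test on `J - 1` degrees
#' of freedom. The concentration is treated as a nuisance parameter: it is
#' estimated once in the null fit and held fixed in the full fit, so the
#' two models differ only in the group coefficients being tested. (With
#' the concentration re-estimated in both models the statistic is visibly
#' inflated at cohort-scale sample sizes; profiling it at the null
#' estimate restores uniform null p-values.) Group
#' effect sizes are the fitted group coefficients mapped back to all J
#' junctions in the centred, sum-zero representation (the reference
#' junction's implicit zero is included before centring), so each
#' junction's sign carries its usage directionality.
#'
#' @param counts Samples x junctions count matrix.
#' @param design Full design matrix including the group column.
#' @param group_col Name of the group column in `design`.
#' @return A list with `p_value`, `effect_sizes` (length J), `df`, `lrt`,
#'   `fit_full`, `fit_null`. Non-convergence of either fit yields `p_value
#'   = NaN` (the cluster is excluded downstream).
#' @export
test_cluster <- function(counts, design, group_col = "group") {
  design <- as.matrix(design)
  if (!group_col %in% colnames(design)) {
    abort(paste0("design has no column '", group_col, "'"),
          class = "crypticsplice_domain_error")
  }
  Y <- as.matrix(counts)
  keep <- colSums(Y) > 0
  Y <- Y[, keep, drop = FALSE]
  J <- ncol(Y)
  if (J < 2L) {
    return(list(p_value = NaN, effect_sizes = rep(NaN, ncol(counts)),
                df = NA_integer_, fit_full = NULL, fit_null = NULL))
  }
  fit_null <- fit_dm_cluster(Y, design[, colnames(design) != group_col,
                                       drop = FALSE])
  fit_full <- if (fit_null$converged) {
    fit_dm_cluster(Y, design, alpha = fit_null$alpha)
  } else {
    fit_dm_cluster(Y, design)
  }
  effects <- rep(NaN, ncol(counts))
  lrt <- NaN
  if (fit_full$converged && fit_null$converged) {
    lrt <- max(0, 2 * (fit_full$loglik - fit_null$loglik))
    p <- pchisq(lrt, df = J - 1L, lower.tail = FALSE)
    b <- c(fit_full$beta[, group_col], 0)
    # centre to the symmetric sum-zero representation: softmax coefficients
    # are only identified relative to the reference junction, and the
    # centred log-effects carry the directionality of every junction
    eff <- b - mean(b)
    effects[keep] <- eff
  } else {
    p <- NaN
  }
  list(p_value = p, effect_sizes = effects, df = J - 1L, lrt = lrt,
       fit_full = fit_full, fit_null = fit_null)
}

# one parametric-bootstrap draw of the null LRT for a cluster: counts are
# re-simulated from the fitted null model (fitted per-sample proportions,
# profiled concentration, observed totals) and the same test is re-run
dm_bootstrap_lrt <- function(Y, X, group_col, fit_null, n_reps = 1L) {
  Xn <- X[, colnames(X) != group_col, drop = FALSE]
  eta <- cbind(Xn %*% t(fit_null$beta), 0)
  P <- softmax_rows(eta)
  a <- fit_null$alpha * P
  totals <- rowSums(Y)
  out <- numeric(0)
  for (r in seq_len(n_reps)) {
    Ystar <- matrix(0L, nrow(Y), ncol(Y))
    for (i in seq_len(nrow(Y))) {
      if (totals[i] == 0) next
      g <- rgamma(ncol(Y), shape = a[i, ], rate = 1)
      if (sum(g) == 0) g[which.max(a[i, ])] <- 1
      Ystar[i, ] <- stats::rmultinom(1L, totals[i], g / sum(g))
    }
    keep <- colSums(Ystar) > 0
    if (sum(keep) < 2L) next
    tst <- test_cluster(Ystar[, keep, drop = FALSE], X,
                        group_col = group_col)
    if (is.finite(tst$p_value)) {
      lrt <- stats::qchisq(tst$p_value, df = tst$df, lower.tail = FALSE)
      out <- c(out, lrt / tst$df)
    }
  }
  out
}

#' Benjamini-Hochberg adjustment tolerating missing tests
#'
#' Applies BH step-up correction over the non-missing p-values only;
#' missing values (failed fits) are propagated as `NA` and do not enter the
#' testing family.
#'
#' @param p Numeric vector of p-values with possible `NA`/`NaN` entries.
#' @return Numeric vector of q-values, `NA` where `p` was missing.
#' @export
adjust_fdr <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- is.finite(p)
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

#' Per-junction percent-spliced-in by group
#'
#' Computes, per sample, each junction's share of its cluster total
#' (samples with zero cluster total are excluded), then averages within
#' case and control groups. `delta_psi` is the case minus control group mean.
#'
#' @param counts Samples x junctions count matrix for one cluster.
#' @param is_case Logical vector, one entry per sample.
#' @return A tibble with one row per junction: `psi_case`, `psi_control`,
#'   `delta_psi`. A group with no informative sample yields `NaN` PSIs.
#' @export
compute_psi <- function(counts, is_case) {
  Y <- as.matrix(counts)
  n <- rowSums(Y)
  psi <- Y / ifelse(n > 0, n, NA_real_)
  grp_mean <- function(sel) {
    rows <- psi[sel & n > 0, , drop = FALSE]
    if (nrow(rows) == 0L) return(rep(NaN, ncol(Y)))
    colMeans(rows)
  }
  pc <- grp_mean(is_case)
  pk <- grp_mean(!is_case)
  tibble(
    junction = colnames(Y) %||% paste0("junction_", seq_len(ncol(Y))),
    psi_case = pc, psi_control = pk, delta_psi = pc - pk
  )
}

#' Flag differentially spliced events
#'
#' An event (junction) is flagged significant when its cluster passes the
#' FDR threshold and its own |delta PSI| exceeds the effect threshold.
#'
#' @param results A results tibble with columns `q_value` and `delta_psi`.
#' @param fdr_threshold Cluster-level FDR cutoff.
#' @param dpsi_threshold Minimum |delta PSI| (strict inequality).
#' @return `results` with a logical `significant` column.
#' @export
call_significant <- function(results, fdr_threshold = 0.05,
                             dpsi_threshold = 0.1) {
  mutate(results,
         significant = !is.na(.data$q_value) &
           .data$q_value < fdr_threshold &
           abs(.data$delta_psi) > dpsi_threshold)
}
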