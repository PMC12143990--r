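#' Build a design matrix from sample covariates
#'
#' Encodes the comparison and adjustment covariates the way the differential
#' splicing test expects: intercept; `group` as 1 for case samples and 0 for
#' controls; `sex` as 0/1; continuous covariates (age at death, RIN)
#' standardized to zero mean and unit variance; cell-proportion principal
#' components, when present, appended unstandardized.
#'
#' @param metadata Tibble with one row per sample: `sample`, `group`, and any
#'   of `age_at_death`, `sex`, `RIN`, plus optional `PC1..PCk` columns.
#' @param case,control Labels of the two `group` levels being compared.
#' @param covariates Character vector of adjustment covariates to include.
#' @param cell_pcs Optional tibble (`sample`, `PC1`, ...) of cell-proportion
#'   principal components, as returned by [derive_proportion_covariates()].
#' @return A list with `design` (matrix, rownames = sample ids), `is_case`
#'   (logical), and `samples`.
#' @export
build_design <- function(metadata, case, control,
                         covariates = c("age_at_death", "sex", "RIN"),
                         cell_pcs = NULL) {
  md <- filter(metadata, .data$group %in% c(case, control))
  if (nrow(md) == 0L) {
    abort("no samples with the requested group labels",
          class = "crypticsplice_validation_error")
  }
  if (!is.null(cell_pcs)) {
    md <- left_join(md, cell_pcs, by = "sample")
  }
  used <- c("group", covariates, grep("^PC\\d+$", names(md), value = TRUE))
  used <- intersect(used, names(md))
  if (anyNA(md[used])) {
    abort("missing values in used covariates",
          class = "crypticsplice_validation_error")
  }
  X <- matrix(1, nrow = nrow(md), ncol = 1L,
              dimnames = list(md$sample, "intercept"))
  X <- cbind(X, group = as.numeric(md$group == case))
  for (cv in covariates) {
    if (!cv %in% names(md)) next
    v <- md[[cv]]
    if (cv == "sex") {
      v <- as.numeric(factor(v)) - 1
    } else {
      s <- sd(v)
      v <- if (s > 0) (v - mean(v)) / s else v - mean(v)
    }
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  for (pc in grep("^PC\\d+$", names(md), value = TRUE)) {
    X <- cbind(X, md[[pc]])
    colnames(X)[ncol(X)] <- pc
  }
  list(design = X, is_case = md$group == case, samples = md$sample)
}

#' Cluster-level differential splicing analysis
#'
#' Runs the Dirichlet-multinomial likelihood-ratio test on every intron
#' cluster, adjusting for the requested covariates, then attaches
#' Benjamini-Hochberg q-values (one test per cluster), per-junction group
#' PSIs and delta PSI, and the significance call. Clusters whose full or
#' null fit fails to converge, or with fewer than `min_informative` samples
#' with non-zero cluster total in either group, are dropped from the testing
#' family (their p and q are `NA`).
#'
#' @param clustered Clustered junction tibble from [cluster_introns()].
#' @param metadata Sample metadata tibble (`sample`, `group`, covariates).
#' @param case,control Group labels to compare (`delta_psi` is case minus
#'   control).
#' @param covariates Adjustment covariates passed to [build_design()].
#' @param cell_pcs Optional cell-proportion PC covariates.
#' @param fdr_threshold,dpsi_threshold Thresholds for the significance call.
#' @param min_informative Minimum informative samples per group.
#' @param bartlett Apply the bootstrap Bartlett correction (see Details).
#' @param bartlett_reps Parametric-bootstrap replicates per cluster used to
#'   estimate the correction factor.
#'
#' @details
#' At cohort-scale sample sizes the likelihood-ratio statistic is known to
#' run slightly hot (its null expectation exceeds its degrees of freedom by
#' an O(1/N) factor). The correction estimates that factor from the data by
#' parametric bootstrap: each tested cluster re-simulates counts from its
#' fitted null model (fitted proportions, profiled concentration, observed
#' totals) and re-runs the test; the family-wide mean of bootstrap LRT/df
#' is the Bartlett factor by which every observed statistic is deflated
#' before the chi-square tail is taken. The factor is pooled across the
#' whole testing family (the inflation is multiplicative and shared), and
#' the correction is skipped for families yielding fewer than 50 bootstrap
#' draws, where the factor itself would be too noisy. The bootstrap draws
#' use the session RNG; set a seed for exact reproducibility.
#'
#' @return A tibble of class `splice_results`, one row per junction, with
#'   cluster test statistics and per-junction effect sizes and PSIs; the
#'   estimated Bartlett factor is attached as attribute
#'   `bartlett_factor`.
#' @export
differential_splicing <- function(clustered, metadata, case, control,
                                  covariates = c("age_at_death", "sex", "RIN"),
                                  cell_pcs = NULL,
                                  fdr_threshold = 0.05,
                                  dpsi_threshold = 0.1,
                                  min_informative = 3L,
                                  bartlett = TRUE,
                                  bartlett_reps = 3L) {
  dsn <- build_design(metadata, case, control, covariates, cell_pcs)
  smp <- intersect(dsn$samples, sample_cols(clustered))
  if (length(smp) < 2L) {
    abort("metadata samples do not match count columns",
          class = "crypticsplice_validation_error")
  }
  keep <- dsn$samples %in% smp
  X <- dsn$design[keep, , drop = FALSE]
  is_case <- dsn$is_case[keep]
  smp <- dsn$samples[keep]

  groups <- clustered |>
    group_by(.data$cluster_id) |>
    group_split()
  rows <- vector("list", length(groups))
  tested <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    g <- groups[[k]]
    Y <- t(as.matrix(g[smp]))
    colnames(Y) <- paste(g$chrom, g$start, g$end, sep = ":")
    totals <- rowSums(Y)
    psi <- compute_psi(Y, is_case)
    enough <- sum(totals > 0 & is_case) >= min_informative &&
      sum(totals > 0 & !is_case) >= min_informative
    lrt <- NaN; df <- NA_integer_; eff <- rep(NaN, ncol(Y))
    if (enough) {
      tst <- test_cluster(Y, X, group_col = "group")
      if (is.finite(tst$p_value)) {
        lrt <- tst$lrt; df <- tst$df
        keep_j <- colSums(Y) > 0
        tested[[k]] <- list(Y = Y[, keep_j, drop = FALSE],
                            fit_null = tst$fit_null)
      }
      eff <- tst$effect_sizes
    }
    rows[[k]] <- tibble(
      cluster_id = g$cluster_id[1L],
      chrom = g$chrom, start = g$start, end = g$end, strand = g$strand,
      lrt = lrt, df = df, effect_size = eff,
      psi_case = psi$psi_case, psi_control = psi$psi_control,
      delta_psi = psi$delta_psi
    )
  }
  per_cluster <- list_rbind(rows)

  b <- 1
  if (isTRUE(bartlett)) {
    ratios <- unlist(lapply(tested, function(t) {
      if (is.null(t)) return(NULL)
      dm_bootstrap_lrt(t$Y, X, "group", t$fit_null, n_reps = bartlett_reps)
    }))
    if (length(ratios) >= 50L) b <- mean(ratios)
  }
  per_cluster <- per_cluster |>
    mutate(p_value = ifelse(is.finite(.data$lrt),
                            pchisq(.data$lrt / b, df = .data$df,
                                   lower.tail = FALSE),
                            NA_real_)) |>
    select(-"lrt", -"df") |>
    relocate("p_value", .after = "strand")

  cluster_p <- per_cluster |>
    distinct(.data$cluster_id, .data$p_value) |>
    mutate(q_value = adjust_fdr(.data$p_value)) |>
    select("cluster_id", "q_value")

  res <- per_cluster |>
    left_join(cluster_p, by = "cluster_id") |>
    relocate("q_value", .after = "p_value") |>
    call_significant(fdr_threshold, dpsi_threshold)
  attr(res, "bartlett_factor") <- b
  class(res) <- c("splice_results", class(res))
  res
}

#' Write a differential splicing results table
#'
#' @param results A `splice_results` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_splice_results <- function(results, path) {
  readr::write_tsv(as_tibble(results), path, progress = FALSE)
  invisible(path)
}
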