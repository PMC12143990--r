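#' Validate a marker set
#'
#' @param markers Tibble with columns `cell_type` and `gene`; marker lists
#'   must be disjoint across types with at least three markers per type.
#' @return `markers`, invisibly, or an error.
#' @export
validate_marker_set <- function(markers) {
  if (anyDuplicated(markers$gene)) {
    abort("marker gene lists must be disjoint across cell types",
          class = "crypticsplice_validation_error")
  }
  n <- count(markers, .data$cell_type)
  if (any(n$n < 3L)) {
    abort(paste0("cell type with fewer than 3 markers: ",
                 paste(n$cell_type[n$n < 3L], collapse = ", ")),
          class = "crypticsplice_validation_error")
  }
  invisible(markers)
}

#' Estimate cell-type proportions from bulk expression
#'
#' Marker-based deconvolution in the digital-sorting spirit: expression is
#' library-size normalized to counts per million (no log transform; the
#' mixing model is linear), each cell type is summarized by the mean CPM of
#' its marker genes, giving a samples-by-types signal matrix \eqn{Y} with
#' \eqn{y_{st} \approx c_t p_{st}} for unknown per-type scales \eqn{c_t}
#' and mixing proportions \eqn{p_{st}}. The sum-to-one constraint across
#' types turns this into a non-negative least-squares problem
#' \eqn{\min_{w \ge 0} \lVert Y w - 1 \rVert^2} in \eqn{w_t = 1/c_t};
#' proportions are then \eqn{p_{st} = y_{st} w_t}, clamped at zero and
#' renormalized so each sample's proportions sum to one exactly.
#'
#' @param expression Gene-by-sample counts: a tibble whose first column is
#'   `gene` followed by one column per sample (or a matrix with gene
#'   rownames).
#' @param markers Marker tibble (`cell_type`, `gene`).
#' @return A tibble of class `cell_proportions`: `sample` plus one
#'   proportion column per cell type, with the marker-mean signal matrix in
#'   attribute `signal`.
#' @export
estimate_cell_proportions <- function(expression, markers) {
  validate_marker_set(markers)
  if (is.data.frame(expression)) {
    genes <- expression$gene
    mat <- as.matrix(expression[setdiff(names(expression), "gene")])
    rownames(mat) <- genes
  } else {
    mat <- as.matrix(expression)
  }
  libsize <- colSums(mat)
  if (any(libsize == 0)) {
    abort("sample with zero total expression",
          class = "crypticsplice_validation_error")
  }
  cpm <- t(t(mat) / libsize) * 1e6
  types <- unique(markers$cell_type)
  missing <- types[vapply(types, function(tp) {
    !any(markers$gene[markers$cell_type == tp] %in% rownames(cpm))
  }, logical(1))]
  if (length(missing) > 0L) {
    abort(paste0("no measured markers for cell type: ",
                 paste(missing, collapse = ", ")),
          class = "crypticsplice_validation_error")
  }
  Y <- vapply(types, function(tp) {
    g <- intersect(markers$gene[markers$cell_type == tp], rownames(cpm))
    colMeans(cpm[g, , drop = FALSE])
  }, numeric(ncol(cpm)))
  Y <- matrix(Y, ncol = length(types),
              dimnames = list(colnames(cpm), types))
  # w >= 0 minimizing ||Y w - 1||^2 (one inverse scale per cell type)
  fn <- function(w) sum((Y %*% w - 1)^2)
  gr <- function(w) as.vector(2 * t(Y) %*% (Y %*% w - 1))
  w0 <- rep(1 / max(Y), length(types))
  opt <- optim(w0, fn, gr, method = "L-BFGS-B", lower = 0,
               control = list(maxit = 500))
  P <- sweep(Y, 2L, opt$par, `*`)
  P[P < 0] <- 0
  rs <- rowSums(P)
  if (any(rs == 0)) {
    abort("sample with no marker signal in any cell type",
          class = "crypticsplice_validation_error")
  }
  P <- P / rs
  out <- bind_cols(tibble(sample = rownames(Y)), as_tibble(P))
  attr(out, "signal") <- Y
  class(out) <- c("cell_proportions", class(out))
  out
}

#' Derive principal-component covariates from cell proportions
#'
#' Performs a PCA of the column-centered proportion matrix and returns the
#' smallest number of leading components whose cumulative share of variance
#' reaches `variance_target`, capped at four (proportions over five types
#' lie on a four-dimensional simplex, so at most four components carry
#' variance). The scores are intended as covariates in the differential
#' splicing design, absorbing composition differences between groups.
#'
#' @param proportions A [estimate_cell_proportions()] tibble (or any
#'   samples-by-types proportion tibble with a `sample` column).
#' @param variance_target Cumulative variance share to reach.
#' @return A tibble `sample`, `PC1`, ..., `PCk` with attribute
#'   `variance_explained` (shares for all components) and `k`.
#' @export
derive_proportion_covariates <- function(proportions, variance_target = 0.8) {
  P <- as.matrix(proportions[setdiff(names(proportions), "sample")])
  if (nrow(P) < 3L) {
    abort("need at least 3 samples for proportion PCA",
          class = "crypticsplice_validation_error")
  }
  if (all(apply(P, 2L, sd) < 1e-12)) {
    abort("zero-variance proportion matrix: no informative components",
          class = "crypticsplice_validation_error")
  }
  pca <- prcomp(P, center = TRUE, scale. = FALSE)
  share <- pca$sdev^2 / sum(pca$sdev^2)
  k <- min(which(cumsum(share) >= variance_target))
  k <- min(k, 4L, length(share))
  scores <- pca$x[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  out <- bind_cols(tibble(sample = proportions$sample), as_tibble(scores))
  attr(out, "variance_explained") <- share
  attr(out, "k") <- k
  out
}

#' Read a marker list TSV
#'
#' @param path TSV with columns `cell_type`, `gene`.
#' @return A validated marker tibble.
#' @export
read_marker_set <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_marker_set(m)
  m
}
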