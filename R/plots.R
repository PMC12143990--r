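#' Volcano plot of differential splicing results
#'
#' One point per junction: case-minus-control delta PSI against the
#' cluster-level evidence, with the significance call (cluster FDR and
#' |delta PSI| thresholds) highlighted.
#'
#' @param object A `splice_results` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot splice_results
#' @export
autoplot.splice_results <- function(object, ...) {
  d <- as_tibble(object) |>
    filter(!is.na(.data$p_value))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta_psi,
                                  y = -log10(pmax(.data$p_value, 1e-300)),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "#1b9e77"),
                                 name = "significant") +
    ggplot2::labs(x = expression(Delta * PSI~"(case - control)"),
                  y = expression(-log[10]~"cluster p"),
                  title = "Differential splicing") +
    ggplot2::theme_minimal()
}

#' Cell-type proportion plot
#'
#' Boxplots of estimated proportions per cell type, split by group when
#' sample metadata are supplied.
#'
#' @param object A `cell_proportions` tibble.
#' @param metadata Optional tibble with `sample` and `group`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cell_proportions
#' @export
autoplot.cell_proportions <- function(object, metadata = NULL, ...) {
  d <- as_tibble(object) |>
    pivot_longer(-"sample", names_to = "cell_type", values_to = "proportion")
  if (!is.null(metadata)) {
    d <- left_join(d, select(metadata, "sample", "group"), by = "sample")
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$cell_type,
                                         y = .data$proportion,
                                         fill = .data$group))
  } else {
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$cell_type,
                                         y = .data$proportion))
  }
  p + ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "estimated proportion",
                  title = "Cell-type composition") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' PSI strip plot for one cluster
#'
#' Per-sample PSI values of every junction in a cluster, split by group;
#' the per-junction group means drawn as crossbars.
#'
#' @param clustered Clustered junction tibble.
#' @param cluster One `cluster_id`.
#' @param metadata Sample metadata with `sample` and `group`.
#' @return A ggplot object.
#' @export
plot_cluster_psi <- function(clustered, cluster, metadata) {
  g <- filter(clustered, .data$cluster_id == cluster)
  if (nrow(g) == 0L) {
    abort(paste0("unknown cluster: ", cluster),
          class = "crypticsplice_validation_error")
  }
  smp <- sample_cols(g)
  Y <- t(as.matrix(g[smp]))
  tot <- rowSums(Y)
  d <- as_tibble(Y / ifelse(tot > 0, tot, NA_real_),
                 .name_repair = ~ paste(g$chrom, g$start, g$end, sep = ":")) |>
    mutate(sample = smp) |>
    pivot_longer(-"sample", names_to = "junction", values_to = "psi") |>
    left_join(select(metadata, "sample", "group"), by = "sample") |>
    filter(!is.na(.data$psi))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$psi,
                                  colour = .data$group)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 0.9) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3, colour = "black") +
    ggplot2::facet_wrap(~junction) +
    ggplot2::labs(x = NULL, y = "PSI", title = cluster) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
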