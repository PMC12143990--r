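#' Junction filtering configuration
#'
#' Bundles the thresholds applied to a junction-count table before intron
#' clustering. `min_anchor_bp` records the anchor length used upstream when
#' junctions were extracted from alignments; it is carried for provenance and
#' logging only, since read-level data are no longer available at this stage.
#'
#' @param min_anchor_bp Integer, anchor length (bp) on each side of a junction
#'   used by the upstream extraction step. Recorded, not re-checked.
#' @param max_intron_length Integer, maximum allowed intron length in bp.
#' @param min_junction_reads Integer, minimum total split-read support for a
#'   junction, summed across all samples.
#' @return A list of class `junction_filter_config`.
#' @export
#' @examples
#' junction_filter_config(min_junction_reads = 30)
junction_filter_config <- function(min_anchor_bp = 8L,
                                   max_intron_length = 500000L,
                                   min_junction_reads = 50L) {
  for (v in c(min_anchor_bp, max_intron_length, min_junction_reads)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      abort("all junction filter thresholds must be positive scalars",
            class = "crypticsplice_validation_error")
    }
  }
  structure(
    list(min_anchor_bp = as.integer(min_anchor_bp),
         max_intron_length = as.integer(max_intron_length),
         min_junction_reads = as.integer(min_junction_reads)),
    class = "junction_filter_config"
  )
}

junction_key_cols <- c("chrom", "start", "end", "strand")

sample_cols <- function(junctions) {
  setdiff(names(junctions), c(junction_key_cols, "cluster_id"))
}

validate_junctions <- function(junctions, max_intron_length = NULL) {
  smp <- sample_cols(junctions)
  if (length(smp) == 0L) {
    abort("junction table has no sample count columns",
          class = "crypticsplice_validation_error")
  }
  if (any(!junctions$strand %in% c("+", "-"))) {
    bad <- which(!junctions$strand %in% c("+", "-"))[1L]
    abort(paste0("unstranded or invalid strand in row ", bad,
                 "; junctions must be stranded ('+' or '-')"),
          class = "crypticsplice_validation_error")
  }
  if (any(junctions$start >= junctions$end)) {
    bad <- which(junctions$start >= junctions$end)[1L]
    abort(paste0("row ", bad, ": start must be < end"),
          class = "crypticsplice_validation_error")
  }
  counts <- as.matrix(junctions[smp])
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    abort("sample counts must be non-negative integers",
          class = "crypticsplice_validation_error")
  }
  key <- paste(junctions$chrom, junctions$start, junctions$end, junctions$strand)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    abort(paste0("duplicate junction key: ", dup),
          class = "crypticsplice_validation_error")
  }
  if (!is.null(max_intron_length) &&
      any(junctions$end - junctions$start + 1L > max_intron_length)) {
    abort("junction exceeds maximum intron length",
          class = "crypticsplice_validation_error")
  }
  invisible(junctions)
}

#' Read a splice-junction count table
#'
#' Reads a per-sample split-read count table, one junction per row. Two
#' coordinate dialects are supported: `tsv_1based_closed` stores the first and
#' last intronic base directly (1-based, fully closed, the convention used
#' throughout this package and in printed event coordinates); the
#' `bed_0based_halfopen` dialect stores BED-style 0-based half-open intervals,
#' for which `start + 1` is the first intronic base and `end` the last, and is
#' converted on read.
#'
#' @param path Path to a TSV file with columns `chrom`, `start`, `end`,
#'   `strand` followed by one count column per sample. The BED dialect may
#'   also carry `name` and `score` columns (dropped on read).
#' @param dialect Coordinate dialect of the file.
#' @return A tibble of junctions in 1-based closed coordinates satisfying the
#'   junction invariants (stranded, `start < end`, non-negative integer
#'   counts, unique keys).
#' @export
read_junction_counts <- function(path,
                                 dialect = c("tsv_1based_closed",
                                             "bed_0based_halfopen")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("junction count file not found: ", path),
          class = "crypticsplice_validation_error")
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  prob <- readr::problems(tab)
  if (nrow(prob) > 0L) {
    abort(paste0("malformed junction file at line ", prob$row[1L] + 1L,
                 ": ", prob$expected[1L]),
          class = "crypticsplice_parse_error")
  }
  need <- c("chrom", "start", "end", "strand")
  if (!all(need %in% names(tab))) {
    abort(paste0("missing required columns: ",
                 paste(setdiff(need, names(tab)), collapse = ", ")),
          class = "crypticsplice_parse_error")
  }
  tab <- tab |>
    select(-any_of(c("name", "score"))) |>
    mutate(chrom = as.character(.data$chrom),
           start = as.integer(.data$start),
           end = as.integer(.data$end),
           strand = as.character(.data$strand)) |>
    relocate(all_of(need))
  if (dialect == "bed_0based_halfopen") {
    tab <- mutate(tab, start = .data$start + 1L)
  }
  if (nrow(tab) > 0L) validate_junctions(tab)
  tab
}

#' Filter junctions on intron length and read support
#'
#' Retains junctions whose intron length (`end - start + 1`) does not exceed
#' `config$max_intron_length` and whose total split-read count across all
#' samples is at least `config$min_junction_reads`. Row order is preserved.
#'
#' @param junctions A junction tibble as returned by [read_junction_counts()].
#' @param config A [junction_filter_config()].
#' @return The filtered junction tibble (possibly empty).
#' @export
filter_junctions <- function(junctions, config = junction_filter_config()) {
  if (nrow(junctions) == 0L) return(junctions)
  validate_junctions(junctions)
  smp <- sample_cols(junctions)
  total <- rowSums(as.matrix(junctions[smp]))
  len <- junctions$end - junctions$start + 1L
  junctions[len <= config$max_intron_length &
              total >= config$min_junction_reads, , drop = FALSE]
}

#' Cluster introns by shared splice sites
#'
#' Groups junctions into intron clusters: connected components of the graph
#' whose vertices are junctions on the same chromosome and strand and whose
#' edges connect junctions sharing a start or an end coordinate. Singleton
#' components are discarded (a cluster is a set of overlapping spliced events
#' and needs at least two junctions to be informative about relative usage).
#'
#' Cluster ids are deterministic: `clu_<chrom>_<k>` with `k` assigned in
#' coordinate order of each cluster's leftmost junction within the chromosome,
#' independent of input row order.
#'
#' @param junctions A filtered junction tibble.
#' @param by Linking rule: `"shared_site"` (default) links junctions sharing a
#'   splice-site coordinate; `"overlap"` additionally links junctions whose
#'   intronic intervals merely overlap.
#' @return The junction tibble restricted to clustered junctions, with a
#'   `cluster_id` column, ordered by chromosome, cluster and coordinates.
#' @export
cluster_introns <- function(junctions, by = c("shared_site", "overlap")) {
  by <- match.arg(by)
  if (nrow(junctions) == 0L) {
    return(mutate(junctions, cluster_id = character(0)))
  }
  validate_junctions(junctions)
  jx <- mutate(junctions, .row = dplyr::row_number())

  edge_groups <- function(keys) {
    # consecutive pairs within each identical-key group (chains suffice for
    # connectivity; no need for full cliques)
    grp <- split(jx$.row, keys)
    grp <- grp[lengths(grp) > 1L]
    if (length(grp) == 0L) return(NULL)
    do.call(rbind, lapply(grp, function(v) cbind(v[-length(v)], v[-1L])))
  }
  edges <- rbind(
    edge_groups(paste(jx$chrom, jx$strand, jx$start, sep = "\r")),
    edge_groups(paste(jx$chrom, jx$strand, jx$end, sep = "\r"))
  )
  if (by == "overlap") {
    ov <- jx |>
      group_by(.data$chrom, .data$strand) |>
      group_map(function(g, key) {
        if (nrow(g) < 2L) return(NULL)
        gr <- IRanges::IRanges(g$start, g$end)
        hits <- IRanges::findOverlaps(gr, gr)
        i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
        keep <- i < j
        if (!any(keep)) return(NULL)
        cbind(g$.row[i[keep]], g$.row[j[keep]])
      })
    edges <- rbind(edges, do.call(rbind, ov))
  }

  g <- igraph::make_empty_graph(n = nrow(jx), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0L) {
    g <- igraph::add_edges(g, t(edges))
  }
  comp <- igraph::components(g)$membership

  jx <- jx |>
    mutate(.comp = comp) |>
    group_by(.data$.comp) |>
    filter(dplyr::n() >= 2L) |>
    ungroup()
  if (nrow(jx) == 0L) {
    out <- junctions[0, , drop = FALSE]
    return(mutate(out, cluster_id = character(0)))
  }
  ids <- jx |>
    group_by(.data$chrom, .data$.comp) |>
    summarise(.min_start = min(.data$start), .min_end = min(.data$end),
              .groups = "drop") |>
    arrange(.data$chrom, .data$.min_start, .data$.min_end) |>
    group_by(.data$chrom) |>
    mutate(cluster_id = paste0("clu_", .data$chrom, "_", dplyr::row_number())) |>
    ungroup() |>
    select(".comp", "cluster_id")
  jx |>
    left_join(ids, by = ".comp") |>
    arrange(.data$chrom, .data$cluster_id, .data$start, .data$end) |>
    select(-".comp", -".row") |>
    relocate("cluster_id")
}

#' Write clustered junction counts in Leafcutter style
#'
#' Serializes a clustered junction table with row keys
#' `chrom:start:end:cluster_id` followed by per-sample counts.
#'
#' @param clustered Output of [cluster_introns()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_counts <- function(clustered, path) {
  smp <- sample_cols(clustered)
  out <- tibble(
    junction = paste(clustered$chrom, clustered$start, clustered$end,
                     clustered$cluster_id, sep = ":")
  ) |> bind_cols(clustered[smp])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
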