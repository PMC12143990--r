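#' Read a study event list
#'
#' @param path TSV with columns `study`, `gene`, `chrom`, `posA`, `posB`,
#'   `semantics` (`junction_ends` or `event_span`).
#' @param coordinate_offset Integer added to both positions on read, for
#'   resolving off-by-one dialect differences between studies.
#' @return A normalized study event tibble (genes upper-cased,
#'   `posA < posB`).
#' @export
read_study_events <- function(path, coordinate_offset = 0L) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  normalize_study_events(d, coordinate_offset)
}

#' Normalize a study event list
#'
#' Upper-cases gene symbols, applies a per-study coordinate offset, and
#' orients coordinate pairs so `posA < posB`.
#'
#' @param events Study event tibble.
#' @param coordinate_offset Integer added to both positions.
#' @return The normalized tibble.
#' @export
normalize_study_events <- function(events, coordinate_offset = 0L) {
  lo <- as.integer(pmin(events$posA, events$posB)) +
    as.integer(coordinate_offset)
  hi <- as.integer(pmax(events$posA, events$posB)) +
    as.integer(coordinate_offset)
  events |>
    mutate(gene = toupper(.data$gene), posA = lo, posB = hi)
}

#' Genes shared by two study event lists
#'
#' @param list_a,list_b Study event tibbles.
#' @return Sorted character vector of genes with at least one event in each
#'   list (symbols compared upper-case).
#' @export
match_gene_level <- function(list_a, list_b) {
  sort(intersect(unique(toupper(list_a$gene)),
                 unique(toupper(list_b$gene))))
}

#' Match two junction-ends events at coordinate level
#'
#' `perfect` when both positions agree exactly, `partial` when exactly one
#' does, `none` otherwise (including events on different chromosomes, which
#' warn).
#'
#' @param event_a,event_b One-row study event tibbles (or lists) with
#'   `chrom`, `posA`, `posB`.
#' @return `"perfect"`, `"partial"`, or `"none"`.
#' @export
match_event_coordinates <- function(event_a, event_b) {
  if (event_a$chrom != event_b$chrom) {
    warn("events on different chromosomes never match")
    return("none")
  }
  hits <- (event_a$posA == event_b$posA) + (event_a$posB == event_b$posB)
  c("none", "partial", "perfect")[hits + 1L]
}

#' Match a span-semantics event against junction coordinate positions
#'
#' For studies whose coordinates mark the two outer ends of the whole
#' splicing event rather than one junction's ends, a perfect match is
#' declared when both span ends occur among the coordinate positions of
#' the compared dataset's events for that gene; a partial match when
#' exactly one end occurs.
#'
#' @param span_event One-row tibble/list with `gene`, `chrom`, `posA`,
#'   `posB`.
#' @param junction_events Study event tibble with `junction_ends`
#'   semantics.
#' @return `"perfect"`, `"partial"`, or `"none"`.
#' @export
match_span_semantics <- function(span_event, junction_events) {
  ev <- filter(junction_events,
               toupper(.data$gene) == toupper(span_event$gene),
               .data$chrom == span_event$chrom)
  if (nrow(ev) == 0L) return("none")
  pool <- unique(c(ev$posA, ev$posB))
  hits <- (span_event$posA %in% pool) + (span_event$posB %in% pool)
  c("none", "partial", "perfect")[hits + 1L]
}

best_level <- function(levels) {
  if ("perfect" %in% levels) "perfect"
  else if ("partial" %in% levels) "partial"
  else "none"
}

match_pair_gene <- function(ev_a, ev_b) {
  span_a <- any(ev_a$semantics == "event_span")
  span_b <- any(ev_b$semantics == "event_span")
  lv <- character(0)
  if (span_a && !span_b) {
    lv <- vapply(seq_len(nrow(ev_a)), function(i)
      match_span_semantics(ev_a[i, ], ev_b), character(1))
  } else if (span_b && !span_a) {
    lv <- vapply(seq_len(nrow(ev_b)), function(i)
      match_span_semantics(ev_b[i, ], ev_a), character(1))
  } else {
    for (i in seq_len(nrow(ev_a))) for (j in seq_len(nrow(ev_b))) {
      if (ev_a$chrom[i] != ev_b$chrom[j]) next
      hits <- (ev_a$posA[i] == ev_b$posA[j]) + (ev_a$posB[i] == ev_b$posB[j])
      lv <- c(lv, c("none", "partial", "perfect")[hits + 1L])
    }
  }
  best_level(lv)
}

#' Match a pair of study event lists
#'
#' For every gene present in both lists, reports the best coordinate-level
#' match over all event pairs (span-semantics lists are compared with the
#' span rule against the other list's coordinate positions).
#'
#' @param list_a,list_b Normalized study event tibbles.
#' @return A tibble `gene`, `level` (perfect/partial/none), sorted by gene.
#' @export
match_study_pair <- function(list_a, list_b) {
  a <- normalize_study_events(list_a)
  b <- normalize_study_events(list_b)
  genes <- match_gene_level(a, b)
  if (length(genes) == 0L) {
    return(tibble(gene = character(0), level = character(0)))
  }
  tibble(
    gene = genes,
    level = vapply(genes, function(g) {
      match_pair_gene(filter(a, .data$gene == g), filter(b, .data$gene == g))
    }, character(1), USE.NAMES = FALSE)
  )
}

#' Summarize cross-study splice-event matching
#'
#' Computes, for every pair of studies, the shared genes and their best
#' match level, plus the multi-study intersection: genes whose events match
#' perfectly in *all* pairwise comparisons count as `n_triple_perfect`
#' (for three studies), and per-pair perfect counts are split into shared
#' and pair-unique.
#'
#' @param studies Named list of two or more study event tibbles.
#' @return A list of class `crossmatch_summary` with `pairwise` (tibble:
#'   `study_a`, `study_b`, `gene`, `level`), `counts` (per-pair
#'   `n_shared_genes`, `n_perfect`, `n_partial`, `n_perfect_unique`), and
#'   `n_triple_perfect` plus `triple_perfect_genes` when three or more
#'   studies are compared.
#' @export
summarize_cross_study <- function(studies) {
  if (length(studies) < 2L) {
    abort("need at least two study lists", class = "crypticsplice_validation_error")
  }
  nm <- names(studies) %||% paste0("study", seq_along(studies))
  chrom_styles <- vapply(studies, function(s)
    any(grepl("^chr", s$chrom)), logical(1))
  if (length(unique(chrom_styles)) > 1L) {
    warn("chromosome naming styles differ between studies")
  }
  pairs <- utils::combn(seq_along(studies), 2L)
  pairwise <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    match_study_pair(studies[[i]], studies[[j]]) |>
      mutate(study_a = nm[i], study_b = nm[j], .before = 1L)
  }) |> list_rbind()
  counts <- pairwise |>
    group_by(.data$study_a, .data$study_b) |>
    summarise(n_shared_genes = dplyr::n(),
              n_perfect = sum(.data$level == "perfect"),
              n_partial = sum(.data$level == "partial"),
              .groups = "drop")
  out <- list(pairwise = pairwise, counts = counts)
  if (length(studies) >= 3L) {
    perfect_by_gene <- pairwise |>
      filter(.data$level == "perfect") |>
      distinct(.data$gene, .data$study_a, .data$study_b)
    n_pairs <- ncol(pairs)
    triple <- perfect_by_gene |>
      count(.data$gene) |>
      filter(.data$n == n_pairs)
    out$triple_perfect_genes <- sort(triple$gene)
    out$n_triple_perfect <- nrow(triple)
    out$counts <- out$counts |>
      left_join(
        pairwise |>
          filter(.data$level == "perfect",
                 !.data$gene %in% triple$gene) |>
          count(.data$study_a, .data$study_b, name = "n_perfect_unique"),
        by = c("study_a", "study_b")
      ) |>
      mutate(n_perfect_unique = ifelse(is.na(.data$n_perfect_unique), 0L,
                                       .data$n_perfect_unique))
  }
  class(out) <- "crossmatch_summary"
  out
}

#' @export
print.crossmatch_summary <- function(x, ...) {
  cat("cross-study splice-event matching\n")
  print(x$counts)
  if (!is.null(x$n_triple_perfect)) {
    cat("genes perfect across all studies:", x$n_triple_perfect, "\n")
    if (x$n_triple_perfect > 0L) {
      cat(" ", paste(x$triple_perfect_genes, collapse = ", "), "\n")
    }
  }
  invisible(x)
}
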