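#' Derive cryptic-exon intervals from cluster topology
#'
#' Within each cluster, pairs of exon-inclusion junctions whose novel ends
#' flank a gap define the cryptic exon: the entering junction ends at
#' `ce_start - 1` and the exiting junction starts at `ce_end + 1`. An EI
#' junction with no partner is a terminal-exon candidate (entering junction
#' only).
#'
#' @param events Annotated event tibble with `cluster_id`, `event_type`,
#'   `start`, `end`, `gene`, `strand`, `chrom`.
#' @return A tibble of unique cryptic exon candidates: `gene`, `chrom`,
#'   `strand`, `ce_start`, `ce_end` (`NA` end for terminal candidates),
#'   `intron_start`, `intron_end`, `has_exit_junction`, `cluster_id`.
#' @export
infer_cryptic_exons <- function(events) {
  ei <- filter(events, .data$event_type == "EI")
  if (nrow(ei) == 0L) {
    return(tibble(gene = character(0), chrom = character(0),
                  strand = character(0), ce_start = integer(0),
                  ce_end = integer(0), intron_start = integer(0),
                  intron_end = integer(0), has_exit_junction = logical(0),
                  cluster_id = character(0)))
  }
  ei |>
    group_by(.data$cluster_id, .data$gene, .data$chrom, .data$strand) |>
    group_map(function(g, key) {
      g <- arrange(g, .data$start, .data$end)
      used <- rep(FALSE, nrow(g))
      out <- list()
      for (x in seq_len(nrow(g))) {
        if (used[x]) next
        partner <- which(!used & g$start > g$end[x] + 1L)
        if (length(partner) > 0L) {
          y <- partner[1L]
          used[c(x, y)] <- TRUE
          out[[length(out) + 1L]] <- tibble(
            ce_start = g$end[x] + 1L, ce_end = g$start[y] - 1L,
            intron_start = g$start[x], intron_end = g$end[y],
            has_exit_junction = TRUE)
        } else {
          used[x] <- TRUE
          out[[length(out) + 1L]] <- tibble(
            ce_start = g$end[x] + 1L, ce_end = NA_integer_,
            intron_start = g$start[x], intron_end = NA_integer_,
            has_exit_junction = FALSE)
        }
      }
      bind_cols(key[rep(1L, length(out)), ], list_rbind(out))
    }) |>
    list_rbind() |>
    relocate("gene", "chrom", "strand")
}

#' Predict peptides for a table of cryptic events
#'
#' Runs transcript surgery and in-silico translation for every cryptic
#' event that can be mapped onto its gene's reference transcript: exon
#' inclusions are reconstructed from the cluster's inferred cryptic exon,
#' exon skips from the skipping junction, and alternative splice sites from
#' the shifted junction. Events that cannot be reconstructed (terminal
#' exons with unknown 3' extent, intergenic events, non-coding genes,
#' inconsistent geometry) are reported with `NA` peptides and the reason.
#'
#' @param cryptic_events Cryptic event tibble (from
#'   [select_cryptic_events()] after [classify_event_type()]).
#' @param index A [build_splice_index()].
#' @param genome A `DNAStringSet`.
#' @return A tibble, one row per unique event: gene, type, coordinates,
#'   `peptide`, `consequence`, `structural`, `ptc`, `note`.
#' @export
predict_event_peptides <- function(cryptic_events, index, genome) {
  exons <- infer_cryptic_exons(cryptic_events)
  other <- cryptic_events |>
    filter(.data$event_type %in% c("ES", "A5SS", "A3SS"),
           .data$gene != "intergenic") |>
    distinct(.data$gene, .data$chrom, .data$strand, .data$start, .data$end,
             .data$event_type, .data$cluster_id)
  rows <- list()
  emit <- function(gene, chrom, strand, type, start, end, ce_start, ce_end,
                   has_exit) {
    note <- NA_character_
    pep <- cons <- NA_character_; ptc <- NA
    struct <- classify_structural_category(
      type, ce_length = if (!is.na(ce_end)) ce_end - ce_start + 1L
        else NA_integer_,
      has_exit_junction = has_exit)
    res <- tryCatch({
      ref <- select_reference_transcript(gene, index)
      if (!ref$coding) {
        note <- "non-coding gene"
      } else if (type == "EI" && !has_exit) {
        note <- "terminal exon: 3' extent unknown, peptide not predicted"
      } else {
        ev <- if (type == "EI") {
          splice_event("EI", start, end, ce_start, ce_end)
        } else {
          splice_event(type, start, end)
        }
        ct <- build_cryptic_transcript(ref, ev, genome)
        pr <- predict_peptide(ct, genome)
        pep <- pr$peptide
        cons <- classify_protein_consequence(pr)
        ptc <- pr$ptc
        struct <- classify_structural_category(
          type, ce_length = if (!is.na(ce_end)) ce_end - ce_start + 1L
            else NA_integer_,
          has_exit_junction = has_exit,
          stop_in_novel = isTRUE(pr$stop_in_novel))
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) note <- res
    tibble(gene = gene, chrom = chrom, strand = strand, event_type = type,
           start = start, end = end, ce_start = ce_start, ce_end = ce_end,
           peptide = pep, consequence = cons, structural = struct,
           ptc = ptc, note = note)
  }
  for (i in seq_len(nrow(exons))) {
    e <- exons[i, ]
    rows[[length(rows) + 1L]] <- emit(
      e$gene, e$chrom, e$strand, "EI", e$intron_start, e$intron_end,
      e$ce_start, e$ce_end, e$has_exit_junction)
  }
  for (i in seq_len(nrow(other))) {
    o <- other[i, ]
    rows[[length(rows) + 1L]] <- emit(
      o$gene, o$chrom, o$strand, o$event_type, o$start, o$end,
      NA_integer_, NA_integer_, TRUE)
  }
  if (length(rows) == 0L) {
    return(tibble(gene = character(0), chrom = character(0),
                  strand = character(0), event_type = character(0),
                  start = integer(0), end = integer(0),
                  ce_start = integer(0), ce_end = integer(0),
                  peptide = character(0), consequence = character(0),
                  structural = character(0), ptc = logical(0),
                  note = character(0)))
  }
  list_rbind(rows)
}

#' Classify cassette directionality for every cluster
#'
#' @param results A `splice_results` tibble.
#' @return A tibble `cluster_id`, `cassette_direction`.
#' @export
classify_cluster_cassettes <- function(results) {
  results |>
    group_by(.data$cluster_id) |>
    group_map(function(g, key) {
      tibble(cluster_id = key$cluster_id,
             cassette_direction = classify_cassette(
               select(g, "chrom", "start", "end", "strand"),
               g$effect_size))
    }) |>
    list_rbind()
}
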