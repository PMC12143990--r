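#' Build a splice-site index from a reference annotation
#'
#' Derives, from the exon features of a GTF, the annotated intron set (gaps
#' between consecutive exons of each transcript, 1-based closed on intronic
#' bases), strand-aware donor and acceptor site sets (the donor is the 5'
#' intron end in transcription direction, so the genomic start on `+` and
#' the genomic end on `-`), exon intervals per transcript, gene spans for
#' gene assignment, and per-transcript CDS bounds and MANE tags used for
#' peptide prediction.
#'
#' @param gtf Path to a GTF file, or a `GRanges` already imported from one.
#' @param provenance Free-text label of the annotation source.
#' @param mane_tag Attribute value marking the representative transcript.
#' @return A list of class `splice_site_index` with tibbles `introns`,
#'   `donors`, `acceptors`, `exons`, `genes`, `transcripts`.
#' @export
build_splice_index <- function(gtf, provenance = NULL,
                               mane_tag = "MANE_Select") {
  gr <- if (methods::is(gtf, "GRanges")) gtf else rtracklayer::import(gtf)
  meta <- as_tibble(S4Vectors::mcols(gr))
  tab <- tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    type = as.character(meta$type),
    gene_id = meta$gene_id,
    transcript_id = if ("transcript_id" %in% names(meta))
      meta$transcript_id else NA_character_,
    tag = if ("tag" %in% names(meta)) as.character(meta$tag)
      else NA_character_
  )
  exons <- tab |>
    filter(.data$type == "exon") |>
    arrange(.data$transcript_id, .data$start)
  if (nrow(exons) == 0L) {
    abort("annotation contains no exon features",
          class = "crypticsplice_validation_error")
  }
  overl <- exons |>
    group_by(.data$transcript_id) |>
    summarise(bad = any(.data$start[-1L] <= .data$end[-dplyr::n()]),
              .groups = "drop") |>
    filter(.data$bad)
  if (nrow(overl) > 0L) {
    abort(paste0("transcript with overlapping exons: ",
                 overl$transcript_id[1L]),
          class = "crypticsplice_validation_error")
  }
  introns <- exons |>
    group_by(.data$transcript_id, .data$gene_id, .data$chrom, .data$strand) |>
    reframe(istart = .data$end[-dplyr::n()] + 1L,
            iend = .data$start[-1L] - 1L) |>
    rename(start = "istart", end = "iend") |>
    filter(.data$end >= .data$start) |>
    distinct(.data$chrom, .data$start, .data$end, .data$strand,
             .keep_all = TRUE)
  donors <- introns |>
    mutate(pos = ifelse(.data$strand == "+", .data$start, .data$end)) |>
    distinct(.data$chrom, .data$strand, .data$pos)
  acceptors <- introns |>
    mutate(pos = ifelse(.data$strand == "+", .data$end, .data$start)) |>
    distinct(.data$chrom, .data$strand, .data$pos)
  genes <- tab |>
    filter(.data$type == "gene") |>
    select("gene_id", "chrom", "start", "end", "strand")
  if (nrow(genes) == 0L) {
    genes <- exons |>
      group_by(.data$gene_id, .data$chrom, .data$strand) |>
      summarise(start = min(.data$start), end = max(.data$end),
                .groups = "drop") |>
      relocate("gene_id", "chrom", "start", "end", "strand")
  }
  cds_rows <- filter(tab, .data$type == "CDS", !is.na(.data$transcript_id))
  cds <- if (nrow(cds_rows) == 0L) {
    tibble(transcript_id = character(0),
           cds_genomic_start = integer(0), cds_genomic_end = integer(0))
  } else {
    cds_rows |>
      group_by(.data$transcript_id) |>
      summarise(cds_genomic_start = min(.data$start),
                cds_genomic_end = max(.data$end), .groups = "drop")
  }
  transcripts <- exons |>
    group_by(.data$transcript_id, .data$gene_id, .data$chrom, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end),
              n_exons = dplyr::n(),
              mane = any(!is.na(.data$tag) &
                           stringr::str_detect(.data$tag,
                                               stringr::fixed(mane_tag))),
              .groups = "drop") |>
    left_join(cds, by = "transcript_id")
  structure(
    list(introns = introns, donors = donors, acceptors = acceptors,
         exons = select(exons, "chrom", "start", "end", "strand",
                        "gene_id", "transcript_id"),
         genes = genes, transcripts = transcripts,
         provenance = provenance %||% "unspecified"),
    class = "splice_site_index"
  )
}

#' @export
print.splice_site_index <- function(x, ...) {
  cat("splice-site index (", x$provenance, ")\n", sep = "")
  cat("  introns:", nrow(x$introns), " donors:", nrow(x$donors),
      " acceptors:", nrow(x$acceptors), " genes:", nrow(x$genes), "\n")
  invisible(x)
}

assign_genes <- function(junctions, index) {
  if (nrow(junctions) == 0L) return(character(0))
  jr <- GenomicRanges::GRanges(junctions$chrom,
                               IRanges::IRanges(junctions$start,
                                                junctions$end))
  gn <- GenomicRanges::GRanges(index$genes$chrom,
                               IRanges::IRanges(index$genes$start,
                                                index$genes$end))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(jr, gn, type = "within"))
  out <- rep("intergenic", nrow(junctions))
  if (length(hits) > 0L) {
    ov <- tibble(
      q = S4Vectors::queryHits(hits),
      gene = index$genes$gene_id[S4Vectors::subjectHits(hits)],
      width = pmin(junctions$end[S4Vectors::queryHits(hits)],
                   index$genes$end[S4Vectors::subjectHits(hits)]) -
        pmax(junctions$start[S4Vectors::queryHits(hits)],
             index$genes$start[S4Vectors::subjectHits(hits)]) + 1L
    ) |>
      group_by(.data$q) |>
      arrange(dplyr::desc(.data$width), .data$gene, .by_group = TRUE) |>
      slice(1L) |>
      ungroup()
    out[ov$q] <- ov$gene
  }
  out
}

#' Annotate junction novelty against the splice-site index
#'
#' Classifies each junction relative to the reference: `annotated` when its
#' intron pair is in the annotated intron set; otherwise `novel_acceptor`
#' (known donor, unannotated acceptor position), `novel_donor` (the
#' converse), `novel_pair` (both positions unannotated), or
#' `novel_combination` (both positions known splice sites but never paired
#' in an annotated intron; these are typically exon-skipping junctions and
#' are not counted among the three genuinely novel-site categories). Genes
#' are assigned by containment of both junction ends in a gene span, ties
#' broken by the largest overlap, otherwise `intergenic`.
#'
#' @param junctions Junction tibble (`chrom`, `start`, `end`, `strand`).
#' @param index A [build_splice_index()] result.
#' @return `junctions` with `status`, `annotated` (logical), and `gene`
#'   columns.
#' @export
annotate_junction_novelty <- function(junctions, index) {
  key <- function(d) paste(d$chrom, d$strand, d$start, d$end, sep = "\r")
  site_key <- function(chrom, strand, pos) paste(chrom, strand, pos, sep = "\r")
  intron_set <- key(index$introns)
  donor_set <- site_key(index$donors$chrom, index$donors$strand,
                        index$donors$pos)
  acceptor_set <- site_key(index$acceptors$chrom, index$acceptors$strand,
                           index$acceptors$pos)
  donor_pos <- ifelse(junctions$strand == "+", junctions$start,
                      junctions$end)
  acceptor_pos <- ifelse(junctions$strand == "+", junctions$end,
                         junctions$start)
  donor_known <- site_key(junctions$chrom, junctions$strand, donor_pos) %in%
    donor_set
  acceptor_known <- site_key(junctions$chrom, junctions$strand,
                             acceptor_pos) %in% acceptor_set
  pair_known <- key(junctions) %in% intron_set
  status <- dplyr::case_when(
    pair_known ~ "annotated",
    donor_known & acceptor_known ~ "novel_combination",
    donor_known & !acceptor_known ~ "novel_acceptor",
    !donor_known & acceptor_known ~ "novel_donor",
    TRUE ~ "novel_pair"
  )
  junctions |>
    mutate(status = status,
           annotated = status == "annotated",
           gene = assign_genes(junctions, index))
}

#' Classify cassette-exon directionality from effect sizes
#'
#' A cluster is a cassette candidate only when it has exactly three introns
#' in a parent/child geometry: one parent intron spanning both children,
#' the children sharing the parent's outer boundaries and separated by a
#' gap (the cassette exon). Directionality then follows the sign rule: a
#' positive parent effect with two negative child effects means the exon is
#' skipped in cases; the reverse pattern means it is included; any other
#' sign pattern is `complex`.
#'
#' @param cluster Tibble of one cluster's junctions (`chrom`, `start`,
#'   `end`, `strand`).
#' @param effect_sizes Numeric vector aligned with `cluster` rows.
#' @return One of `"skipped"`, `"included"`, `"complex"`, `"not_cassette"`.
#' @export
classify_cassette <- function(cluster, effect_sizes) {
  if (nrow(cluster) != 3L) return("not_cassette")
  ord <- order(cluster$end - cluster$start, decreasing = TRUE)
  parent <- cluster[ord[1L], ]
  kids <- cluster[ord[-1L], ] |> arrange(.data$start)
  geom <- parent$start == kids$start[1L] &&
    parent$end == kids$end[2L] &&
    kids$end[1L] < kids$start[2L] - 1L
  if (!isTRUE(geom)) return("not_cassette")
  ep <- effect_sizes[ord[1L]]
  ek <- effect_sizes[ord[-1L]]
  if (any(!is.finite(c(ep, ek)))) return("complex")
  if (ep > 0 && all(ek < 0)) return("skipped")
  if (ep < 0 && all(ek > 0)) return("included")
  "complex"
}

skips_annotated_exon <- function(junctions, index) {
  if (nrow(junctions) == 0L) return(logical(0))
  jr <- GenomicRanges::GRanges(junctions$chrom,
                               IRanges::IRanges(junctions$start,
                                                junctions$end),
                               strand = junctions$strand)
  ex <- GenomicRanges::GRanges(index$exons$chrom,
                               IRanges::IRanges(index$exons$start,
                                                index$exons$end),
                               strand = index$exons$strand)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(ex, jr, type = "within"))
  out <- logical(nrow(junctions))
  out[unique(S4Vectors::subjectHits(hits))] <- TRUE
  out
}

#' Classify splice event types
#'
#' Assigns each junction an event type relative to the reference:
#' * `ES` for junctions whose intron fully contains at least one annotated
#'   exon (exon skipping), including annotated pairs and novel combinations
#'   of known sites;
#' * `A5SS` / `A3SS` for a novel donor or acceptor lying within
#'   `alt_ss_window` bp of the annotated site it replaces (a splice-site
#'   shift), whether the shift falls inside the flanking exon or just
#'   inside the intron;
#' * `EI` (cryptic exon inclusion) when the novel end falls strictly inside
#'   an annotated intron farther than `alt_ss_window` from the replaced
#'   annotated site, or when two junctions of the same cluster flank a
#'   novel exonic island inside one annotated intron;
#' * `complex` otherwise (including junctions without a gene assignment).
#'
#' @param junctions Annotated junction tibble (needs `status` and `gene`
#'   from [annotate_junction_novelty()]; a `cluster_id` column, when
#'   present, enables the exonic-island rule).
#' @param index A [build_splice_index()].
#' @param alt_ss_window Distance (bp) separating an alternative splice site
#'   from a cryptic-exon boundary; the reference never states this rule, so
#'   it is an explicit, configurable surrogate.
#' @return `junctions` with an `event_type` column.
#' @export
classify_event_type <- function(junctions, index, alt_ss_window = 100L) {
  if (nrow(junctions) == 0L) {
    return(mutate(junctions, event_type = character(0)))
  }
  jx <- junctions
  if (!"status" %in% names(jx)) jx <- annotate_junction_novelty(jx, index)
  skip <- skips_annotated_exon(jx, index)

  # novel end position per junction (for single-novel-site junctions)
  donor_pos <- ifelse(jx$strand == "+", jx$start, jx$end)
  acceptor_pos <- ifelse(jx$strand == "+", jx$end, jx$start)
  novel_pos <- dplyr::case_when(
    jx$status == "novel_donor" ~ donor_pos,
    jx$status == "novel_acceptor" ~ acceptor_pos,
    TRUE ~ NA_integer_
  )
  # host annotated intron of each novel position (strictly inside)
  intr <- index$introns
  inside_intron <- rep(FALSE, nrow(jx))
  far_from_replaced <- rep(FALSE, nrow(jx))
  has_np <- which(!is.na(novel_pos))
  if (length(has_np) > 0L && nrow(intr) > 0L) {
    pr <- GenomicRanges::GRanges(jx$chrom[has_np],
                                 IRanges::IRanges(novel_pos[has_np],
                                                  novel_pos[has_np]),
                                 strand = jx$strand[has_np])
    ir <- GenomicRanges::GRanges(intr$chrom,
                                 IRanges::IRanges(intr$start, intr$end),
                                 strand = intr$strand)
    hits <- suppressWarnings(GenomicRanges::findOverlaps(pr, ir))
    if (length(hits) > 0L) {
      h <- tibble(q = S4Vectors::queryHits(hits),
                  s = S4Vectors::subjectHits(hits)) |>
        mutate(
          j = has_np[.data$q],
          pos = novel_pos[.data$j],
          # the replaced annotated site plays the same role (donor/acceptor)
          # as the novel one within the host intron
          replaced = ifelse(
            (jx$status[.data$j] == "novel_donor") ==
              (jx$strand[.data$j] == "+"),
            intr$start[.data$s], intr$end[.data$s]),
          strictly_inside = .data$pos > intr$start[.data$s] &
            .data$pos < intr$end[.data$s],
          dist = abs(.data$pos - .data$replaced)
        ) |>
        filter(.data$strictly_inside) |>
        group_by(.data$j) |>
        summarise(far = any(.data$dist > alt_ss_window), .groups = "drop")
      inside_intron[h$j] <- TRUE
      far_from_replaced[h$j] <- h$far
    }
  }

  # exonic-island rule: two cluster junctions whose novel ends flank a gap
  island <- rep(FALSE, nrow(jx))
  if ("cluster_id" %in% names(jx)) {
    cand <- which(jx$status %in% c("novel_donor", "novel_acceptor") &
                    inside_intron)
    if (length(cand) > 1L) {
      for (cl in unique(jx$cluster_id[cand])) {
        ii <- cand[jx$cluster_id[cand] == cl]
        if (length(ii) < 2L) next
        # an entering junction's novel end + an exiting junction's novel end
        # delimiting a short island inside the same intron
        for (x in ii) for (y in ii) {
          if (x == y) next
          if (jx$end[x] < jx$start[y] - 1L &&
              jx$start[y] - jx$end[x] < 10000L) {
            island[c(x, y)] <- TRUE
          }
        }
      }
    }
  }

  event_type <- dplyr::case_when(
    jx$gene == "intergenic" ~ "complex",
    skip & jx$status %in% c("annotated", "novel_combination") ~ "ES",
    jx$status == "annotated" ~ "complex",
    jx$status == "novel_combination" ~ "complex",
    jx$status %in% c("novel_donor", "novel_acceptor") &
      (island | (inside_intron & far_from_replaced)) ~ "EI",
    jx$status == "novel_donor" ~ "A5SS",
    jx$status == "novel_acceptor" ~ "A3SS",
    TRUE ~ "complex"
  )
  mutate(jx, event_type = event_type)
}

#' Select cryptic splicing events
#'
#' Filters a joined results-plus-annotation table down to cryptic events:
#' junctions not annotated in the reference, in a significant cluster, and
#' elevated in cases. `strict` additionally requires the case-minus-control
#' PSI difference to exceed `dpsi_threshold` (the headline event list);
#' `relaxed` accepts any positive difference (the cross-study comparison
#' list).
#'
#' @param results Tibble with `status`, `q_value`, `delta_psi` columns.
#' @param mode `"strict"` or `"relaxed"`.
#' @param fdr_threshold Cluster FDR cutoff.
#' @param dpsi_threshold Strict-mode delta-PSI cutoff.
#' @return The filtered tibble with a `cryptic` flag column set to `TRUE`.
#' @export
select_cryptic_events <- function(results, mode = c("strict", "relaxed"),
                                  fdr_threshold = 0.05,
                                  dpsi_threshold = 0.1) {
  mode <- match.arg(mode)
  floor_dpsi <- if (mode == "strict") dpsi_threshold else 0
  results |>
    filter(.data$status != "annotated",
           !is.na(.data$q_value), .data$q_value < fdr_threshold,
           .data$delta_psi > floor_dpsi) |>
    mutate(cryptic = TRUE)
}

#' Read binding-site intervals from a BED file
#'
#' @param path BED file (0-based half-open; converted to 1-based closed).
#' @param source_label Provenance label stored alongside the intervals.
#' @return A tibble `chrom`, `start`, `end`, `source`.
#' @export
read_binding_sites <- function(path, source_label = basename(path)) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    source = source_label
  )
}

#' Annotate proximity of events to protein binding sites
#'
#' An event is `close` to a binding site when the genomic gap between the
#' event interval and the nearest site interval is at most `window` bp
#' (overlap counts as distance zero). Events on chromosomes with no sites
#' at all are labelled `no_site_in_gene`.
#'
#' @param events Tibble with `chrom`, `start`, `end`.
#' @param sites Binding-site tibble from [read_binding_sites()].
#' @param window Maximum gap in bp to call `close`.
#' @return `events` with `binding_distance` and `binding_proximity` columns.
#' @export
annotate_binding_proximity <- function(events, sites, window = 500L) {
  if (nrow(events) == 0L) {
    return(mutate(events, binding_distance = integer(0),
                  binding_proximity = character(0)))
  }
  er <- GenomicRanges::GRanges(events$chrom,
                               IRanges::IRanges(events$start, events$end))
  prox <- rep("no_site_in_gene", nrow(events))
  dist <- rep(NA_integer_, nrow(events))
  if (nrow(sites) > 0L) {
    sr <- GenomicRanges::GRanges(sites$chrom,
                                 IRanges::IRanges(sites$start, sites$end))
    shared <- events$chrom %in% sites$chrom
    if (any(shared)) {
      hits <- suppressWarnings(
        GenomicRanges::distanceToNearest(er[shared], sr))
      d <- rep(NA_integer_, sum(shared))
      d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
      dist[shared] <- d
      prox[shared] <- ifelse(is.na(d), "no_site_in_gene",
                             ifelse(d <= window, "close", "not_close"))
    }
  }
  mutate(events, binding_distance = dist, binding_proximity = prox)
}
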