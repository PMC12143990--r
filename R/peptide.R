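#' Read a genome FASTA
#'
#' @param path FASTA path.
#' @return A `DNAStringSet` named by the first word of each header.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

# transcript coordinate of a genomic position within an exon chain
# (exons: tibble with genomic start/end, ascending; strand-aware)
tx_coord <- function(exons, strand, gpos) {
  widths <- exons$end - exons$start + 1L
  vapply(gpos, function(p) {
    e <- which(exons$start <= p & exons$end >= p)
    if (length(e) == 0L) return(NA_integer_)
    e <- e[1L]
    if (strand == "+") {
      sum(widths[seq_len(e - 1L)]) + (p - exons$start[e] + 1L)
    } else {
      n <- nrow(exons)
      sum(widths[seq_len(n - e)][rev(seq_len(n - e))]) * 0L +
        sum(widths[setdiff(seq_len(n), seq_len(e))]) +
        (exons$end[e] - p + 1L)
    }
  }, integer(1))
}

#' Select the reference transcript of a gene
#'
#' Prefers the MANE-tagged transcript; otherwise the transcript with the
#' longest CDS; ties broken deterministically by transcript id. A gene with
#' no coding transcript yields a non-coding model (its events get an `NA`
#' protein consequence downstream).
#'
#' @param gene Gene id.
#' @param index A [build_splice_index()].
#' @return A list of class `transcript_model`: `transcript_id`, `gene`,
#'   `chrom`, `strand`, `exons` (genomic, ascending), `coding`,
#'   `cds_tx_start` (transcript coordinate of the start codon), `mane`.
#' @export
select_reference_transcript <- function(gene, index) {
  tx <- filter(index$transcripts, .data$gene_id == gene)
  if (nrow(tx) == 0L) {
    abort(paste0("gene has no transcripts: ", gene),
          class = "crypticsplice_validation_error")
  }
  tx <- tx |>
    mutate(cds_len = ifelse(is.na(.data$cds_genomic_start), 0L,
                            .data$cds_genomic_end -
                              .data$cds_genomic_start + 1L)) |>
    arrange(dplyr::desc(.data$mane), dplyr::desc(.data$cds_len),
            .data$transcript_id)
  pick <- tx[1L, ]
  exons <- index$exons |>
    filter(.data$transcript_id == pick$transcript_id) |>
    arrange(.data$start) |>
    select("start", "end")
  coding <- !is.na(pick$cds_genomic_start)
  cds_tx_start <- NA_integer_
  if (coding) {
    gstart <- if (pick$strand == "+") pick$cds_genomic_start
      else pick$cds_genomic_end
    cds_tx_start <- tx_coord(exons, pick$strand, gstart)
  }
  structure(
    list(transcript_id = pick$transcript_id, gene = gene,
         chrom = pick$chrom, strand = pick$strand, exons = exons,
         coding = coding, cds_tx_start = cds_tx_start, mane = pick$mane),
    class = "transcript_model"
  )
}

#' cDNA sequence of a transcript model
#'
#' Concatenates the exon sequences (reverse-complemented for minus-strand
#' transcripts so the result reads 5' to 3').
#'
#' @param model A `transcript_model`.
#' @param genome A `DNAStringSet` from [read_genome()].
#' @return A character scalar.
#' @export
transcript_cdna <- function(model, genome) {
  chrom_seq <- genome[[model$chrom]]
  parts <- vapply(seq_len(nrow(model$exons)), function(e) {
    as.character(Biostrings::subseq(chrom_seq, model$exons$start[e],
                                    model$exons$end[e]))
  }, character(1))
  s <- paste(parts, collapse = "")
  if (model$strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

#' Describe a splice event for transcript surgery
#'
#' @param type One of `"EI"`, `"ES"`, `"A5SS"`, `"A3SS"`, or `"null"` (no
#'   modification; round-trip check).
#' @param start,end 1-based closed intronic coordinates of the event
#'   junction.
#' @param ce_start,ce_end Cryptic exon interval (EI only).
#' @return A list of class `splice_event`.
#' @export
splice_event <- function(type, start = NA_integer_, end = NA_integer_,
                         ce_start = NA_integer_, ce_end = NA_integer_) {
  type <- match.arg(type, c("EI", "ES", "A5SS", "A3SS", "null"))
  if (type == "EI" && (is.na(ce_start) || is.na(ce_end))) {
    abort("EI events need the cryptic exon interval (ce_start, ce_end)",
          class = "crypticsplice_validation_error")
  }
  structure(list(type = type, start = start, end = end,
                 ce_start = ce_start, ce_end = ce_end),
            class = "splice_event")
}

#' Build a cryptic transcript by exon-chain surgery
#'
#' Applies a splice event to a reference transcript model: exon inclusion
#' inserts the cryptic exon between its flanking exons; exon skipping
#' removes the exon(s) fully contained in the event junction's intron;
#' alternative 5'/3' splice sites move the affected exon boundary to the
#' novel site (an extension pulls former intronic sequence into the mRNA, a
#' truncation removes exonic sequence). The modified chain is re-validated
#' and the modified region is recorded both in reference-transcript
#' coordinates (`ref_mod_start`, `ref_mod_end`; zero-length for pure
#' deletions) and as the novel interval of the new transcript.
#'
#' @param reference A `transcript_model`.
#' @param event A [splice_event()].
#' @param genome A `DNAStringSet`.
#' @return A list of class `cryptic_transcript`: `exons`, `cdna`, `event`,
#'   `novel_tx_start`, `novel_tx_end` (novel-sequence interval in the new
#'   transcript, zero-length deletions have `novel_tx_end < novel_tx_start`),
#'   `ref_mod_start`, `ref_mod_end`, `length_delta`, and the `reference`.
#' @export
build_cryptic_transcript <- function(reference, event, genome) {
  ex <- reference$exons
  strand <- reference$strand
  introns <- tibble(start = ex$end[-nrow(ex)] + 1L,
                    end = ex$start[-1L] - 1L)
  fail <- function(msg) abort(msg, class = "crypticsplice_construction_error")

  if (event$type == "null") {
    new_ex <- ex
    ref_mod <- c(NA_integer_, NA_integer_)
    novel_genomic <- NULL
  } else if (event$type == "EI") {
    host <- which(introns$start <= event$ce_start &
                    introns$end >= event$ce_end)
    if (length(host) == 0L) fail("cryptic exon not inside any intron")
    new_ex <- bind_rows(ex, tibble(start = event$ce_start,
                                   end = event$ce_end)) |>
      arrange(.data$start)
    # insertion point in reference tx coords: first base of the 3' flank
    flank3 <- if (strand == "+") ex$start[host + 1L] else ex$end[host]
    ins_at <- tx_coord(ex, strand, flank3)
    ref_mod <- c(ins_at, ins_at - 1L)   # zero-length in reference
    novel_genomic <- c(event$ce_start, event$ce_end)
  } else if (event$type == "ES") {
    drop <- which(ex$start > event$start & ex$end < event$end)
    if (length(drop) == 0L) fail("skipped exon not found in transcript")
    rm_tx <- sort(tx_coord(ex, strand,
                           c(ex$start[drop], ex$end[drop])))
    new_ex <- ex[-drop, , drop = FALSE]
    ref_mod <- c(min(rm_tx), max(rm_tx))
    novel_genomic <- NULL
  } else {
    # alternative splice site: event junction shares exactly one end with
    # an annotated intron of the chain; the other end moves
    share_start <- which(introns$start == event$start)
    share_end <- which(introns$end == event$end)
    if (length(share_end) == 1L &&
        (length(share_start) == 0L ||
         introns$start[share_end] != event$start)) {
      i <- share_end
      old <- ex$end[i]; new <- event$start - 1L
      if (new < ex$start[i]) fail("novel site removes the entire exon")
      new_ex <- ex; new_ex$end[i] <- new
      if (new > old) {
        ref_mod <- c(tx_coord(ex, strand, old) + ifelse(strand == "+", 1L, 0L),
                     NA)
        novel_genomic <- c(old + 1L, new)
      } else {
        rng <- sort(tx_coord(ex, strand, c(new + 1L, old)))
        ref_mod <- rng
        novel_genomic <- NULL
      }
    } else if (length(share_start) == 1L) {
      i <- share_start
      old <- ex$start[i + 1L]; new <- event$end + 1L
      if (new > ex$end[i + 1L]) fail("novel site removes the entire exon")
      new_ex <- ex; new_ex$start[i + 1L] <- new
      if (new < old) {
        ref_mod <- c(tx_coord(ex, strand, old) + ifelse(strand == "+", 0L, 1L),
                     NA)
        novel_genomic <- c(new, old - 1L)
      } else {
        rng <- sort(tx_coord(ex, strand, c(old, new - 1L)))
        ref_mod <- rng
        novel_genomic <- NULL
      }
    } else {
      fail("event junction shares no end with an annotated intron")
    }
    # extensions are zero-length in the reference (pure insertions)
    if (is.na(ref_mod[2L])) ref_mod[2L] <- ref_mod[1L] - 1L
  }

  if (any(new_ex$start > new_ex$end) ||
      any(new_ex$start[-1L] <= new_ex$end[-nrow(new_ex)])) {
    fail("modified exon chain is invalid")
  }

  model2 <- reference
  model2$exons <- new_ex
  cdna <- transcript_cdna(model2, genome)

  if (is.null(novel_genomic)) {
    # deletion: novel interval is the zero-length junction point in the new tx
    if (event$type == "null") {
      novel <- c(NA_integer_, NA_integer_)
    } else {
      at <- ref_mod[1L]
      novel <- c(at, at - 1L)
    }
  } else {
    nr <- sort(tx_coord(new_ex, strand, novel_genomic))
    novel <- nr
  }
  structure(
    list(exons = new_ex, cdna = cdna, event = event,
         novel_tx_start = novel[1L], novel_tx_end = novel[2L],
         ref_mod_start = ref_mod[1L], ref_mod_end = ref_mod[2L],
         length_delta = nchar(cdna) -
           sum(ex$end - ex$start + 1L),
         reference = reference),
    class = "cryptic_transcript"
  )
}

translate_from <- function(seq, at) {
  n <- nchar(seq)
  if (is.na(at) || at > n - 2L) {
    return(list(peptide = "", stop_found = FALSE, stop_at = NA_integer_))
  }
  sub <- substr(seq, at, n)
  sub <- substr(sub, 1L, 3L * (nchar(sub) %/% 3L))
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                           no.init.codon = TRUE))
  stop_idx <- as.integer(regexpr("*", aa, fixed = TRUE))
  if (stop_idx > 0L) {
    list(peptide = substr(aa, 1L, stop_idx - 1L), stop_found = TRUE,
         stop_at = at + 3L * (stop_idx - 1L))  # tx coord of stop codon base 1
  } else {
    list(peptide = aa, stop_found = FALSE, stop_at = NA_integer_)
  }
}

longest_orf <- function(seq, min_codons = 30L) {
  starts <- gregexpr("ATG", seq, fixed = TRUE)[[1L]]
  if (starts[1L] == -1L) return(NULL)
  best <- NULL
  for (at in starts) {
    tr <- translate_from(seq, at)
    len <- nchar(tr$peptide)
    if (len >= min_codons && (is.null(best) || len > nchar(best$peptide))) {
      best <- c(tr, list(start_at = at))
    }
  }
  best
}

#' Predict the peptide encoded by a cryptic transcript
#'
#' Translates the modified transcript: when the reference start codon
#' context is retained (the three start-codon bases are untouched by the
#' modification) translation begins at its mapped position and proceeds to
#' the first stop; otherwise the longest ATG-initiated open reading frame
#' of at least `min_codons` codons is used, and if none exists the
#' consequence is `NA` (non-coding outcome). The premature-termination
#' flag is set when the new stop codon lies 5' of the position homologous
#' to the reference stop.
#'
#' @param cryptic A `cryptic_transcript`.
#' @param genome A `DNAStringSet` (used for the reference translation).
#' @param min_codons Minimum ORF length for the fallback scan.
#' @return A list of class `peptide_prediction`: `peptide`,
#'   `reference_peptide`, `ptc` (premature termination), `stop_in_novel`
#'   (stop codon inside the novel interval), `start_retained`, `orf_found`.
#' @export
predict_peptide <- function(cryptic, genome, min_codons = 30L) {
  ref <- cryptic$reference
  if (!ref$coding) {
    return(structure(list(peptide = NA_character_,
                          reference_peptide = NA_character_,
                          ptc = NA, stop_in_novel = NA,
                          start_retained = NA, orf_found = FALSE),
                     class = "peptide_prediction"))
  }
  ref_cdna <- transcript_cdna(ref, genome)
  ref_tr <- translate_from(ref_cdna, ref$cds_tx_start)
  delta <- cryptic$length_delta
  ms <- cryptic$ref_mod_start; me <- cryptic$ref_mod_end
  cds <- ref$cds_tx_start

  if (cryptic$event$type == "null" || is.na(ms)) {
    new_start <- cds; start_retained <- TRUE
  } else if (ms > cds + 2L) {
    new_start <- cds; start_retained <- TRUE
  } else if (me < cds && ms <= me) {
    new_start <- cds + delta; start_retained <- TRUE
  } else if (ms <= me) {
    start_retained <- FALSE; new_start <- NA_integer_
  } else {
    # zero-length reference interval (insertion at position ms)
    if (ms > cds + 2L) {
      new_start <- cds; start_retained <- TRUE
    } else if (ms <= cds) {
      new_start <- cds + delta; start_retained <- TRUE
    } else {
      start_retained <- FALSE; new_start <- NA_integer_
    }
  }

  if (start_retained) {
    tr <- translate_from(cryptic$cdna, new_start)
    orf_found <- nchar(tr$peptide) > 0L
  } else {
    tr <- longest_orf(cryptic$cdna, min_codons)
    orf_found <- !is.null(tr)
    if (!orf_found) {
      return(structure(list(peptide = NA_character_,
                            reference_peptide = ref_tr$peptide,
                            ptc = NA, stop_in_novel = NA,
                            start_retained = FALSE, orf_found = FALSE),
                       class = "peptide_prediction"))
    }
  }

  # homologous position of the reference stop in the new transcript
  ref_stop <- ref_tr$stop_at
  hom_stop <- if (is.na(ref_stop)) NA_integer_ else {
    if (!is.na(ms) && ms <= ref_stop) ref_stop + delta else ref_stop
  }
  ptc <- isTRUE(tr$stop_found) && !is.na(hom_stop) && tr$stop_at < hom_stop
  stop_in_novel <- isTRUE(tr$stop_found) &&
    !is.na(cryptic$novel_tx_start) &&
    cryptic$novel_tx_end >= cryptic$novel_tx_start &&
    tr$stop_at >= cryptic$novel_tx_start &&
    tr$stop_at <= cryptic$novel_tx_end + 2L
  structure(
    list(peptide = tr$peptide, reference_peptide = ref_tr$peptide,
         ptc = ptc, stop_in_novel = stop_in_novel,
         start_retained = start_retained, orf_found = orf_found),
    class = "peptide_prediction"
  )
}

common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(a, "")[[1L]][seq_len(n)]
  bv <- strsplit(b, "")[[1L]][seq_len(n)]
  d <- which(av != bv)
  if (length(d) == 0L) n else d[1L] - 1L
}

common_suffix_len <- function(a, b) {
  ra <- paste(rev(strsplit(a, "")[[1L]]), collapse = "")
  rb <- paste(rev(strsplit(b, "")[[1L]]), collapse = "")
  common_prefix_len(ra, rb)
}

#' Classify the protein consequence of a cryptic transcript
#'
#' Compares the predicted peptide with the reference peptide: `no_change`
#' when identical (events confined to untranslated regions);
#' `truncated_proteoform` when translation terminates inside the novel
#' sequence; `sequence_missing` when both termini are preserved around an
#' internal deletion (one junction-hybrid residue, from a codon straddling
#' the splice, is tolerated); `sequence_inserted` when both termini are
#' preserved around an internal in-frame insertion (the neoepitope-bearing
#' cryptic peptides); `alt_N_terminal` when the N-terminal region changes
#' but the downstream sequence is preserved; `alt_C_terminal` when
#' translation runs past the modification into a different C-terminus; and
#' `NA` when no peptide could be predicted.
#'
#' @param prediction A `peptide_prediction` from [predict_peptide()].
#' @return A single string (one of the consequence labels above).
#' @export
classify_protein_consequence <- function(prediction) {
  pep <- prediction$peptide; ref <- prediction$reference_peptide
  if (is.na(pep) || is.na(ref) || !prediction$orf_found) return(NA_character_)
  if (identical(pep, ref)) return("no_change")
  if (isTRUE(prediction$stop_in_novel)) return("truncated_proteoform")
  lcp <- common_prefix_len(pep, ref)
  lcs <- common_suffix_len(pep, ref)
  if (nchar(pep) < nchar(ref) && lcp > 0L && lcs > 0L &&
      lcp + lcs >= nchar(pep) - 1L) {
    return("sequence_missing")
  }
  if (nchar(pep) > nchar(ref) && lcp > 0L && lcs > 0L &&
      lcp + lcs >= nchar(ref) - 1L) {
    return("sequence_inserted")
  }
  if (lcs > lcp) "alt_N_terminal" else "alt_C_terminal"
}

#' Classify the structural category of a cryptic event
#'
#' Maps an event and its transcript context onto the six structural
#' categories used to describe cryptic splicing: cryptic exons divide into
#' in-frame (length divisible by three, no stop in the insertion frame),
#' out-of-frame (which always carry a premature stop within the novel
#' sequence), terminal exons (an entering junction without an exiting
#' junction in the cluster, ending the transcript early), and initial
#' exons (replacing the first exon); splice-site shifts and exon skips map
#' to their own categories.
#'
#' @param event_type `"EI"`, `"ES"`, `"A5SS"` or `"A3SS"`.
#' @param ce_length Cryptic exon length in nt (EI only).
#' @param has_exit_junction Does the cluster contain a junction leaving the
#'   cryptic exon on its 3' side?
#' @param at_transcript_start Does the cryptic exon replace the first exon?
#' @param stop_in_novel Stop codon inside the cryptic exon (from
#'   [predict_peptide()]).
#' @return One of `"in_frame_exon"`, `"out_of_frame_exon"`,
#'   `"terminal_exon"`, `"initial_exon"`, `"alternative_splice_site"`,
#'   `"exon_skipping"`.
#' @export
classify_structural_category <- function(event_type, ce_length = NA_integer_,
                                         has_exit_junction = TRUE,
                                         at_transcript_start = FALSE,
                                         stop_in_novel = FALSE) {
  if (event_type %in% c("A5SS", "A3SS")) return("alternative_splice_site")
  if (event_type == "ES") return("exon_skipping")
  if (event_type != "EI") return(NA_character_)
  if (at_transcript_start) return("initial_exon")
  if (!has_exit_junction) return("terminal_exon")
  if (!is.na(ce_length) && ce_length %% 3L == 0L && !isTRUE(stop_in_novel)) {
    return("in_frame_exon")
  }
  "out_of_frame_exon"
}
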