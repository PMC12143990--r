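# a hand-built 4-exon plus-strand gene with a known CDS, written into a
# small genome so every surgery outcome can be checked by string arithmetic;
# the exon-2/exon-3 boundary sits on a codon boundary (transcript position
# 111 = 12 nt UTR + 99 CDS nt) so insertions there are frame-clean
toy_gene <- function(dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  set.seed(99)
  # transcript: 12 nt 5'UTR + ATG + 60 codons + TAA + 15 nt 3'UTR = 213 nt
  body <- paste(sample(setdiff(names(Biostrings::GENETIC_CODE),
                               c("TAA", "TAG", "TGA")), 60, replace = TRUE),
                collapse = "")
  cdna <- paste0("CCACCTTCTAGA", "ATG", body, "TAA", "CCGGAATTCGATCCA")
  stopifnot(nchar(cdna) == 213L)
  exon_len <- c(60L, 51L, 42L, 60L)
  starts <- c(1001L, 1501L, 2001L, 2501L)
  ends <- starts + exon_len - 1L
  genome_str <- paste(rep("A", 3600), collapse = "")
  off <- cumsum(c(0L, exon_len))
  for (e in 1:4) {
    frag <- substr(cdna, off[e] + 1L, off[e + 1L])
    substr(genome_str, starts[e], ends[e]) <- frag
  }
  fa <- file.path(dir, "toy.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(genome_str, "chrT")), fa)
  # CDS spans transcript 13..198 (stop codon included)
  cds <- rbind(c(1013L, ends[1]),
               c(starts[2], ends[2]),
               c(starts[3], ends[3]),
               c(starts[4], starts[4] + 44L))
  gtf <- write_toy_gtf(list(list(
    gene = "TOY", tx = "TOY.t1", chrom = "chrT", strand = "+",
    exons = cbind(starts, ends), cds = cds, mane = TRUE)),
    file.path(dir, "toy.gtf"))
  list(fa = fa, gtf = gtf, cdna = cdna, starts = starts, ends = ends,
       exon_len = exon_len, cds = cds)
}

test_that("reference transcript selection prefers MANE then longest CDS", {
  gtf <- write_toy_gtf(list(
    list(gene = "G", tx = "G.t1", chrom = "chr1", strand = "+",
         exons = rbind(c(1, 300)), cds = rbind(c(31, 330))),
    list(gene = "G", tx = "G.t2", chrom = "chr1", strand = "+",
         exons = rbind(c(1, 600)), cds = rbind(c(31, 480))),
    list(gene = "H", tx = "H.t1", chrom = "chr1", strand = "+",
         exons = rbind(c(1000, 1300)))
  ))
  idx <- build_splice_index(gtf)
  expect_equal(select_reference_transcript("G", idx)$transcript_id, "G.t2")
  # non-coding gene -> NA sentinel model
  h <- select_reference_transcript("H", idx)
  expect_false(h$coding)
  # MANE beats CDS length
  gtf2 <- write_toy_gtf(list(
    list(gene = "G", tx = "G.t1", chrom = "chr1", strand = "+",
         exons = rbind(c(1, 300)), cds = rbind(c(31, 330)), mane = TRUE),
    list(gene = "G", tx = "G.t2", chrom = "chr1", strand = "+",
         exons = rbind(c(1, 600)), cds = rbind(c(31, 480)))
  ))
  expect_equal(
    select_reference_transcript("G", build_splice_index(gtf2))$transcript_id,
    "G.t1")
})

test_that("transcript surgery matches hand string arithmetic", {
  toy <- toy_gene()
  genome <- read_genome(toy$fa)
  idx <- build_splice_index(toy$gtf)
  ref <- select_reference_transcript("TOY", idx)
  ref_cdna <- transcript_cdna(ref, genome)
  expect_equal(ref_cdna, toy$cdna)
  expect_equal(ref$cds_tx_start, 13L)

  # null event round trip is byte-identical
  null_ct <- build_cryptic_transcript(ref, splice_event("null"), genome)
  expect_identical(null_ct$cdna, toy$cdna)

  # EI of a 30 nt exon inside intron 2: +30 nt, the inserted block appears
  # verbatim between the flanks (oracle: substring surgery)
  ce <- c(1700L, 1729L)
  ei <- build_cryptic_transcript(
    ref, splice_event("EI", toy$ends[2] + 1L, toy$starts[3] - 1L,
                      ce[1], ce[2]), genome)
  expect_equal(nchar(ei$cdna), nchar(toy$cdna) + 30L)
  ce_seq <- as.character(Biostrings::subseq(genome[["chrT"]], ce[1], ce[2]))
  hand <- paste0(substr(toy$cdna, 1, 111), ce_seq,
                 substr(toy$cdna, 112, nchar(toy$cdna)))
  expect_identical(ei$cdna, hand)
  expect_equal(c(ei$novel_tx_start, ei$novel_tx_end), c(112L, 141L))

  # ES of exon 3 (42 nt): flanks juxtaposed exactly
  es <- build_cryptic_transcript(
    ref, splice_event("ES", toy$ends[2] + 1L, toy$starts[4] - 1L), genome)
  hand_es <- paste0(substr(toy$cdna, 1, 111),
                    substr(toy$cdna, 154, nchar(toy$cdna)))
  expect_identical(es$cdna, hand_es)

  # A3SS moving the acceptor of intron 1 12 nt into the intron: 12 formerly
  # intronic nt become exonic
  a3 <- build_cryptic_transcript(
    ref, splice_event("A3SS", toy$ends[1] + 1L, toy$starts[2] - 13L),
    genome)
  intronic <- as.character(Biostrings::subseq(genome[["chrT"]],
                                              toy$starts[2] - 12L,
                                              toy$starts[2] - 1L))
  hand_a3 <- paste0(substr(toy$cdna, 1, 60), intronic,
                    substr(toy$cdna, 61, nchar(toy$cdna)))
  expect_identical(a3$cdna, hand_a3)

  # inconsistent event -> construction error
  expect_error(build_cryptic_transcript(
    ref, splice_event("ES", 10L, 20L), genome),
    class = "crypticsplice_construction_error")
})

test_that("minus-strand surgery reverse-complements correctly", {
  # mirror the toy gene: reverse-complement the genome, flip coordinates;
  # the cDNA and every derived peptide must be identical
  toy <- toy_gene()
  dir <- tempfile(); dir.create(dir)
  L <- 3600L
  plus <- read_genome(toy$fa)[["chrT"]]
  fa <- file.path(dir, "rc.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(
      as.character(Biostrings::reverseComplement(plus)), "chrT")), fa)
  flip <- function(x) L - x + 1L
  flip_iv <- function(m) {
    out <- cbind(flip(m[, 2]), flip(m[, 1]))
    out[rev(seq_len(nrow(out))), , drop = FALSE]
  }
  gtf <- write_toy_gtf(list(list(
    gene = "TOY", tx = "TOY.t1", chrom = "chrT", strand = "-",
    exons = flip_iv(cbind(toy$starts, toy$ends)),
    cds = flip_iv(toy$cds), mane = TRUE)), file.path(dir, "rc.gtf"))
  refm <- select_reference_transcript("TOY", build_splice_index(gtf))
  genome_m <- read_genome(fa)
  expect_equal(transcript_cdna(refm, genome_m), toy$cdna)
  expect_equal(refm$cds_tx_start, 13L)

  ce <- c(1700L, 1729L)
  refp <- select_reference_transcript("TOY", build_splice_index(toy$gtf))
  genome_p <- read_genome(toy$fa)
  eip <- build_cryptic_transcript(
    refp, splice_event("EI", toy$ends[2] + 1L, toy$starts[3] - 1L,
                       ce[1], ce[2]), genome_p)
  eim <- build_cryptic_transcript(
    refm, splice_event("EI", flip(toy$starts[3] - 1L), flip(toy$ends[2] + 1L),
                       flip(ce[2]), flip(ce[1])), genome_m)
  expect_identical(eim$cdna, eip$cdna)
  pp <- predict_peptide(eip, genome_p)
  pm <- predict_peptide(eim, genome_m)
  expect_identical(pm$peptide, pp$peptide)
  expect_identical(pm$ptc, pp$ptc)
})

test_that("translation matches the in-frame arithmetic of small insertions", {
  toy <- toy_gene()
  genome <- read_genome(toy$fa)
  idx <- build_splice_index(toy$gtf)
  ref <- select_reference_transcript("TOY", idx)
  pr0 <- predict_peptide(build_cryptic_transcript(ref, splice_event("null"),
                                                  genome), genome)
  expect_identical(pr0$peptide, pr0$reference_peptide)
  expect_false(pr0$ptc)

  # 33 nt in-frame insertion with no stop in any register: ref + 11 residues
  chrom <- as.character(genome[["chrT"]])
  substr(chrom, 1700, 1732) <- paste(rep("GCA", 11), collapse = "")
  g2 <- Biostrings::DNAStringSet(stats::setNames(chrom, "chrT"))
  ei33 <- build_cryptic_transcript(
    ref, splice_event("EI", toy$ends[2] + 1L, toy$starts[3] - 1L,
                      1700L, 1732L), g2)
  pr33 <- predict_peptide(ei33, g2)
  expect_equal(nchar(pr33$peptide), nchar(pr33$reference_peptide) + 11L)
  expect_false(pr33$ptc)
  expect_equal(classify_protein_consequence(pr33), "sequence_inserted")

  # 40 nt insertion: frameshift; stop position equals the brute-force scan
  ei40 <- build_cryptic_transcript(
    ref, splice_event("EI", toy$ends[2] + 1L, toy$starts[3] - 1L,
                      1700L, 1739L), genome)
  pr40 <- predict_peptide(ei40, genome)
  o <- oracle_translate(ei40$cdna, 13L)
  expect_identical(pr40$peptide, o$peptide)
  expect_equal(isTRUE(pr40$ptc), o$stop_found &&
                 o$stop_at < 13L + 3L * nchar(pr40$reference_peptide))
})

test_that("translation agrees with the independent scanner on random toys", {
  set.seed(123)
  for (r in 1:100) {
    n <- sample(60:240, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                 collapse = "")
    at <- sample(seq_len(n - 10L), 1)
    mine <- crypticsplice:::translate_from(seq, at)
    oracle <- oracle_translate(seq, at)
    expect_identical(mine$peptide, oracle$peptide)
    expect_identical(mine$stop_found, oracle$stop_found)
    expect_identical(mine$stop_at, oracle$stop_at)
  }
})

test_that("protein consequences and structural categories follow the rules", {
  mk <- function(pep, ref, stop_in_novel = FALSE, orf = TRUE) {
    structure(list(peptide = pep, reference_peptide = ref, ptc = FALSE,
                   stop_in_novel = stop_in_novel, start_retained = TRUE,
                   orf_found = orf), class = "peptide_prediction")
  }
  expect_equal(classify_protein_consequence(mk("MAV", "MAV")), "no_change")
  expect_equal(classify_protein_consequence(mk("MAXY", "MAVKLY",
                                               stop_in_novel = TRUE)),
               "truncated_proteoform")
  expect_equal(classify_protein_consequence(mk("MAKLY", "MAVWKLY")),
               "sequence_missing")
  expect_equal(classify_protein_consequence(mk("MAVPRST", "MAVKLWID")),
               "alt_C_terminal")
  expect_equal(classify_protein_consequence(mk("MTTKLWID", "MAVKLWID")),
               "alt_N_terminal")
  expect_equal(classify_protein_consequence(mk(NA_character_, "MAV",
                                               orf = FALSE)),
               NA_character_)

  expect_equal(classify_structural_category("A5SS"),
               "alternative_splice_site")
  expect_equal(classify_structural_category("ES"), "exon_skipping")
  expect_equal(classify_structural_category("EI", ce_length = 24L),
               "in_frame_exon")
  expect_equal(classify_structural_category("EI", ce_length = 40L),
               "out_of_frame_exon")
  expect_equal(classify_structural_category("EI", ce_length = 24L,
                                            has_exit_junction = FALSE),
               "terminal_exon")
  expect_equal(classify_structural_category("EI", ce_length = 24L,
                                            at_transcript_start = TRUE),
               "initial_exon")
  # an in-frame length whose exon carries an in-register stop still
  # disrupts the protein
  expect_equal(classify_structural_category("EI", ce_length = 24L,
                                            stop_in_novel = TRUE),
               "out_of_frame_exon")
})

test_that("out-of-frame cryptic exons always carry a premature stop", {
  cfg <- sim_config(seed = 61, n_genes = 12)
  ann <- simulate_annotation_and_genome(cfg, dir = tempfile())
  idx <- build_splice_index(ann$gtf)
  genome <- read_genome(ann$fasta)
  oof <- dplyr::filter(ann$truth, structural == "out_of_frame_exon")
  expect_gt(nrow(oof), 0)
  for (i in seq_len(nrow(oof))) {
    e <- oof[i, ]
    ref <- select_reference_transcript(e$gene, idx)
    ct <- build_cryptic_transcript(
      ref, splice_event("EI", e$intron_start, e$intron_end,
                        e$ce_start, e$ce_end), genome)
    pr <- predict_peptide(ct, genome)
    expect_true(pr$ptc)
    expect_true(pr$stop_in_novel)
    expect_equal(classify_protein_consequence(pr), "truncated_proteoform")
  }
})
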