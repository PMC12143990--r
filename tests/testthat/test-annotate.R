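two_exon_index <- function(strand = "+") {
  gtf <- write_toy_gtf(list(list(
    gene = "G1", tx = "G1.t1", chrom = "chr1", strand = strand,
    exons = rbind(c(1, 100), c(201, 300)))))
  build_splice_index(gtf)
}

test_that("the splice index derives introns and strand-aware sites", {
  idx <- two_exon_index("+")
  expect_equal(idx$introns$start, 101L)
  expect_equal(idx$introns$end, 200L)
  expect_equal(idx$donors$pos, 101L)
  expect_equal(idx$acceptors$pos, 200L)
  # strand symmetry: donor is the 5' intron end in transcription direction
  idxm <- two_exon_index("-")
  expect_equal(idxm$donors$pos, 200L)
  expect_equal(idxm$acceptors$pos, 101L)
})

test_that("the splice index matches a hand-enumerated intron set", {
  genes <- list(
    list(gene = "A", tx = "A.t1", chrom = "chr1", strand = "+",
         exons = rbind(c(1, 50), c(151, 220), c(301, 400))),
    list(gene = "A", tx = "A.t2", chrom = "chr1", strand = "+",
         exons = rbind(c(1, 50), c(301, 400))),
    list(gene = "B", tx = "B.t1", chrom = "chr1", strand = "-",
         exons = rbind(c(1000, 1100), c(1301, 1400))),
    list(gene = "C", tx = "C.t1", chrom = "chr2", strand = "+",
         exons = rbind(c(10, 60), c(101, 160), c(201, 260), c(301, 360))),
    list(gene = "D", tx = "D.t1", chrom = "chr2", strand = "+",
         exons = rbind(c(1000, 1050), c(1101, 1150)))
  )
  idx <- build_splice_index(write_toy_gtf(genes))
  # oracle: manual enumeration of the gaps between consecutive exons
  expected <- tibble::tribble(
    ~chrom, ~start, ~end, ~strand,
    "chr1",   51L, 150L, "+",
    "chr1",  221L, 300L, "+",
    "chr1",   51L, 300L, "+",
    "chr1", 1101L, 1300L, "-",
    "chr2",   61L, 100L, "+",
    "chr2",  161L, 200L, "+",
    "chr2",  261L, 300L, "+",
    "chr2", 1051L, 1100L, "+"
  )
  got <- dplyr::arrange(idx$introns[, c("chrom", "start", "end", "strand")],
                        chrom, start, end)
  expect_equal(got, dplyr::arrange(expected, chrom, start, end))
  expect_error(build_splice_index(write_toy_gtf(list(list(
    gene = "Z", tx = "Z.t1", chrom = "chr1", strand = "+",
    exons = rbind(c(1, 100), c(50, 200)))))),
    class = "crypticsplice_validation_error")
})

test_that("junction novelty classification covers every category", {
  idx <- build_splice_index(write_toy_gtf(list(
    list(gene = "A", tx = "A.t1", chrom = "chr1", strand = "+",
         exons = rbind(c(1, 100), c(201, 300), c(401, 500))),
    list(gene = "A", tx = "A.t2", chrom = "chr1", strand = "+",
         exons = rbind(c(1, 100), c(401, 500)))
  )))
  jx <- tibble::tibble(
    chrom = "chr1",
    start = c(101L, 101L, 150L, 301L, 150L),
    end = c(200L, 250L, 200L, 400L, 170L),
    strand = "+"
  )
  ann <- annotate_junction_novelty(jx, idx)
  expect_equal(ann$status,
               c("annotated",         # exact annotated intron
                 "novel_acceptor",    # known donor, unannotated acceptor
                 "novel_donor",       # unannotated donor, known acceptor
                 "annotated",         # the skip intron is annotated via A.t2
                 "novel_pair"))       # both ends unannotated
  # both ends known but pair unannotated -> novel_combination, not novel_*
  jx2 <- tibble::tibble(chrom = "chr1", start = 101L, end = 400L,
                        strand = "+")
  idx2 <- build_splice_index(write_toy_gtf(list(
    list(gene = "A", tx = "A.t1", chrom = "chr1", strand = "+",
         exons = rbind(c(1, 100), c(201, 300), c(401, 500)))
  )))
  expect_equal(annotate_junction_novelty(jx2, idx2)$status,
               "novel_combination")
  expect_equal(ann$gene, rep("A", 5))
  # a junction outside any gene is intergenic, not an error
  far <- annotate_junction_novelty(
    tibble::tibble(chrom = "chr9", start = 10L, end = 20L, strand = "+"),
    idx)
  expect_equal(far$gene, "intergenic")
})

test_that("novelty is reference-monotone under index growth", {
  small <- build_splice_index(write_toy_gtf(list(
    list(gene = "A", tx = "A.t1", chrom = "chr1", strand = "+",
         exons = rbind(c(1, 100), c(201, 300)))
  )))
  big <- build_splice_index(write_toy_gtf(list(
    list(gene = "A", tx = "A.t1", chrom = "chr1", strand = "+",
         exons = rbind(c(1, 100), c(201, 300))),
    list(gene = "A", tx = "A.t2", chrom = "chr1", strand = "+",
         exons = rbind(c(1, 100), c(151, 180), c(201, 300)))
  )))
  jx <- random_junction_table(20, seed = 3)
  s1 <- annotate_junction_novelty(jx, small)$status
  s2 <- annotate_junction_novelty(jx, big)$status
  expect_true(all(!(s1 == "annotated" & s2 != "annotated")))
})

test_that("cassette directionality equals the exhaustive sign truth table", {
  cassette <- tibble::tibble(
    chrom = "chr1", strand = "+",
    start = c(101L, 101L, 261L),
    end = c(400L, 200L, 400L)
  )   # parent spans children; exon island 201-260
  # spec'd sign rule as an independent truth table over {-,0,+}^3
  signs <- c(-1, 0, 1)
  for (sp in signs) for (s1 in signs) for (s2 in signs) {
    eff <- c(sp * 0.3, s1 * 0.2, s2 * 0.1)
    expected <- if (sp > 0 && s1 < 0 && s2 < 0) "skipped"
      else if (sp < 0 && s1 > 0 && s2 > 0) "included"
      else "complex"
    expect_equal(classify_cassette(cassette, eff), expected)
  }
  # quoted examples
  expect_equal(classify_cassette(cassette, c(0.3, -0.2, -0.1)), "skipped")
  expect_equal(classify_cassette(cassette, c(-0.3, 0.2, 0.1)), "included")
  # geometry failures
  four <- dplyr::bind_rows(cassette, tibble::tibble(
    chrom = "chr1", strand = "+", start = 900L, end = 1000L))
  expect_equal(classify_cassette(four, c(1, -1, -1, 0)), "not_cassette")
  nogap <- cassette; nogap$end[2] <- 260L
  expect_equal(classify_cassette(nogap, c(0.3, -0.2, -0.1)), "not_cassette")
})

test_that("event types follow the skip / shift / cryptic-exon rules", {
  # gene with 4 exons; intron 2 is 5 kb for the cryptic-exon case
  idx <- build_splice_index(write_toy_gtf(list(
    list(gene = "A", tx = "A.t1", chrom = "chr1", strand = "+",
         exons = rbind(c(1, 100), c(5101, 5200), c(5301, 5400),
                       c(5501, 5600)))
  )))
  jx <- tibble::tibble(
    chrom = "chr1",
    start = c(101L, 101L, 3101L, 86L, 101L),
    end = c(5300L, 3000L, 5100L, 5100L, 5085L),
    strand = "+",
    cluster_id = c("c1", "c2", "c2", "c3", "c4")
  )
  ev <- classify_event_type(jx, idx)
  expect_equal(ev$event_type[1], "ES")     # skips exon 2 entirely
  expect_equal(ev$event_type[2], "EI")     # novel acceptor 2.9 kb inside
  expect_equal(ev$event_type[3], "EI")     # exiting junction of the island
  expect_equal(ev$event_type[4], "A5SS")   # donor 15 bp inside flanking exon
  expect_equal(ev$event_type[5], "A3SS")   # acceptor 15 bp short of the site
  # intergenic junctions are never typed
  far <- classify_event_type(
    tibble::tibble(chrom = "chr1", start = 90000L, end = 91000L,
                   strand = "+"), idx)
  expect_equal(far$event_type, "complex")
})

test_that("cryptic event selection applies the strict and relaxed rules", {
  r <- tibble::tibble(
    status = c("novel_pair", "novel_acceptor", "annotated", "novel_donor"),
    q_value = c(0.001, 0.01, 1e-10, 0.2),
    delta_psi = c(0.218, 0.05, 0.3, 0.4)
  )
  expect_equal(nrow(select_cryptic_events(r, "strict")), 1L)
  strict <- select_cryptic_events(r, "strict")
  expect_equal(strict$status, "novel_pair")
  relaxed <- select_cryptic_events(r, "relaxed")
  expect_setequal(relaxed$status, c("novel_pair", "novel_acceptor"))
  # annotated junctions are never cryptic however strong the signal
  expect_false(any(relaxed$status == "annotated"))
})

test_that("binding proximity uses the gap distance with a 500 bp window", {
  events <- tibble::tibble(chrom = "chr1", start = 2000L, end = 3000L)
  # overlap -> distance 0 -> close
  s0 <- tibble::tibble(chrom = "chr1", start = 2500L, end = 2600L,
                       source = "x")
  expect_equal(annotate_binding_proximity(events, s0)$binding_proximity,
               "close")
  # gap exactly 500 -> close, 501 -> not close
  s500 <- tibble::tibble(chrom = "chr1", start = 3501L, end = 3600L,
                         source = "x")
  a500 <- annotate_binding_proximity(events, s500)
  expect_equal(a500$binding_distance, 500L)
  expect_equal(a500$binding_proximity, "close")
  s501 <- tibble::tibble(chrom = "chr1", start = 3502L, end = 3600L,
                         source = "x")
  expect_equal(annotate_binding_proximity(events, s501)$binding_proximity,
               "not_close")
  # no sites on the chromosome at all
  s_other <- tibble::tibble(chrom = "chr7", start = 1L, end = 100L,
                            source = "x")
  expect_equal(annotate_binding_proximity(events, s_other)$binding_proximity,
               "no_site_in_gene")
  # symmetric in interval order and invariant to site permutation
  sites <- tibble::tibble(chrom = "chr1",
                          start = c(100L, 3400L, 9000L),
                          end = c(200L, 3450L, 9100L),
                          source = "x")
  set.seed(2)
  d1 <- annotate_binding_proximity(events, sites)$binding_distance
  d2 <- annotate_binding_proximity(events, sites[sample(3), ])$binding_distance
  expect_equal(d1, d2)
  # flipping which table is "event" and which is "site" keeps the distance
  flip <- annotate_binding_proximity(sites[2, c("chrom", "start", "end")],
                                     dplyr::mutate(events, source = "y"))
  expect_equal(flip$binding_distance, d1)
})
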