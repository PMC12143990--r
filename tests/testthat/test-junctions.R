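test_that("junction reading round-trips both coordinate dialects", {
  # header-only file -> empty table
  p <- write_tsv_file(toy_junctions()[0, ])
  expect_equal(nrow(read_junction_counts(p)), 0L)

  # identity read-back of a single row
  one <- tibble::tibble(chrom = "chr1", start = 1000L, end = 2000L,
                        strand = "+", a = 5L, b = 7L)
  got <- read_junction_counts(write_tsv_file(one))
  expect_equal(got$start, 1000L)
  expect_equal(got$end, 2000L)
  expect_equal(got$a, 5L)

  # same introns supplied in both dialects -> identical internal coordinates;
  # oracle: by-hand conversion (BED start+1 = first intronic base, end = last)
  tsv <- tibble::tibble(chrom = "chr1",
                        start = c(101L, 501L, 901L),
                        end = c(200L, 700L, 1100L),
                        strand = c("+", "-", "+"),
                        s1 = c(10L, 20L, 30L))
  bed <- dplyr::mutate(tsv, start = start - 1L)
  a <- read_junction_counts(write_tsv_file(tsv, "a.tsv"))
  b <- read_junction_counts(write_tsv_file(bed, "b.tsv"),
                            dialect = "bed_0based_halfopen")
  expect_equal(a, b)
})

test_that("junction validation rejects malformed tables", {
  d <- toy_junctions()
  expect_error(read_junction_counts(write_tsv_file(dplyr::bind_rows(d, d[1, ]))),
               class = "crypticsplice_validation_error")
  d2 <- d; d2$strand[2] <- "."
  expect_error(read_junction_counts(write_tsv_file(d2, "s.tsv")),
               class = "crypticsplice_validation_error")
  d3 <- d; d3$start[1] <- d3$end[1]
  expect_error(read_junction_counts(write_tsv_file(d3, "c.tsv")),
               class = "crypticsplice_validation_error")
  expect_error(read_junction_counts(file.path(tempdir(), "absent.tsv")),
               class = "crypticsplice_validation_error")
})

test_that("filtering applies the support and intron-length thresholds", {
  d <- toy_junctions()          # totals: 55, 50, 75, 55
  cfg <- junction_filter_config(min_junction_reads = 50L)
  expect_equal(nrow(filter_junctions(d, cfg)), 4L)

  d$s1[2] <- 19L                # total 49 < 50 -> removed
  kept <- filter_junctions(d, cfg)
  expect_equal(nrow(kept), 3L)
  expect_false(any(kept$start == 1000L & kept$end == 3000L))

  # intron of length 500001 bp removed at the 500 kb cap
  d2 <- toy_junctions()
  d2$end[3] <- d2$start[3] + 500000L   # length 500001
  kept2 <- filter_junctions(d2, junction_filter_config())
  expect_false(any(kept2$end - kept2$start + 1L > 500000L))
  expect_equal(nrow(kept2), 3L)

  # all passing -> identical to input, order preserved
  expect_equal(filter_junctions(toy_junctions(), cfg), toy_junctions())
  expect_error(junction_filter_config(min_junction_reads = 0),
               class = "crypticsplice_validation_error")
})

test_that("intron clustering groups shared splice sites and drops singletons", {
  d <- toy_junctions()
  cl <- cluster_introns(d)
  # junctions 1 and 2 share a start; 3 and 4 are singletons
  expect_equal(nrow(cl), 2L)
  expect_equal(dplyr::n_distinct(cl$cluster_id), 1L)
  expect_true(all(cl$start == 1000L & cl$chrom == "chr1"))

  # same coordinates on different chromosomes never cluster
  d2 <- tibble::tibble(chrom = c("chr1", "chr2"), start = 1000L,
                       end = 2000L, strand = "+", s1 = c(60L, 60L))
  expect_equal(nrow(cluster_introns(d2)), 0L)
})

test_that("clustering matches a brute-force union-find oracle", {
  for (seed in 1:5) {
    d <- random_junction_table(10, seed = seed)
    cl <- cluster_introns(d)
    comp <- oracle_cluster(d)
    sizes <- table(comp)
    keep <- comp %in% as.integer(names(sizes)[sizes >= 2])
    # same junctions retained
    key <- function(x) paste(x$chrom, x$start, x$end, x$strand)
    expect_setequal(key(cl), key(d[keep, ]))
    # same partition: joint key of (oracle component, assigned cluster) must
    # be a bijection on retained junctions
    m <- match(key(d[keep, ]), key(cl))
    tab <- table(comp[keep], cl$cluster_id[m])
    expect_true(all(rowSums(tab > 0) == 1))
    expect_true(all(colSums(tab > 0) == 1))
  }
})

test_that("clustering is permutation-invariant and filter->cluster idempotent", {
  d <- random_junction_table(12, seed = 42)
  cl <- cluster_introns(d)
  set.seed(1)
  shuffled <- d[sample(nrow(d)), ]
  cl2 <- cluster_introns(shuffled)
  expect_equal(dplyr::arrange(cl, chrom, start, end),
               dplyr::arrange(cl2, chrom, start, end))

  cfg <- junction_filter_config(min_junction_reads = 1L)
  once <- cluster_introns(filter_junctions(d, cfg))
  twice <- cluster_introns(filter_junctions(dplyr::select(once, -cluster_id),
                                            cfg))
  expect_equal(once, twice)
})

test_that("cluster counts serialize in Leafcutter style", {
  cl <- cluster_introns(toy_junctions())
  p <- file.path(withr::local_tempdir(), "cc.tsv")
  write_cluster_counts(cl, p)
  out <- readr::read_tsv(p, show_col_types = FALSE)
  expect_equal(names(out)[1], "junction")
  expect_match(out$junction[1], "^chr1:1000:[0-9]+:clu_chr1_1$")
})
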