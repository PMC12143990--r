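# small builders shared across tests

toy_junctions <- function() {
  tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(1000L, 1000L, 5000L, 1000L),
    end = c(2000L, 3000L, 6000L, 2000L),
    strand = c("+", "+", "+", "+"),
    s1 = c(30L, 20L, 40L, 25L),
    s2 = c(25L, 30L, 35L, 30L)
  )
}

write_tsv_file <- function(d, name = "jx.tsv") {
  p <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  readr::write_tsv(d, p)
  p
}

# GTF writer for hand-built annotations: genes is a list of lists with
# gene, tx, chrom, strand, exons (2-col matrix), optional cds, mane
write_toy_gtf <- function(genes, path = tempfile(fileext = ".gtf")) {
  lines <- character(0)
  for (g in genes) {
    span <- range(g$exons)
    tag <- if (isTRUE(g$mane)) ' tag "MANE_Select";' else ""
    lines <- c(lines,
      sprintf('%s\ttoy\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
              g$chrom, span[1], span[2], g$strand, g$gene),
      sprintf(paste0('%s\ttoy\ttranscript\t%d\t%d\t.\t%s\t.\t',
                     'gene_id "%s"; transcript_id "%s";%s'),
              g$chrom, span[1], span[2], g$strand, g$gene, g$tx, tag))
    for (i in seq_len(nrow(g$exons))) {
      lines <- c(lines, sprintf(
        paste0('%s\ttoy\texon\t%d\t%d\t.\t%s\t.\t',
               'gene_id "%s"; transcript_id "%s";%s'),
        g$chrom, g$exons[i, 1], g$exons[i, 2], g$strand, g$gene, g$tx, tag))
    }
    if (!is.null(g$cds)) {
      for (i in seq_len(nrow(g$cds))) {
        lines <- c(lines, sprintf(
          paste0('%s\ttoy\tCDS\t%d\t%d\t.\t%s\t.\t',
                 'gene_id "%s"; transcript_id "%s";'),
          g$chrom, g$cds[i, 1], g$cds[i, 2], g$strand, g$gene, g$tx))
      }
    }
  }
  writeLines(lines, path)
  path
}

# independent three-frame translation scanner used as oracle: translates
# from a given position using the codon table directly
oracle_translate <- function(seq, at) {
  code <- Biostrings::GENETIC_CODE
  aa <- character(0)
  pos <- at
  while (pos + 2L <= nchar(seq)) {
    codon <- substr(seq, pos, pos + 2L)
    r <- unname(code[codon])
    if (is.na(r)) r <- "X"
    if (r == "*") {
      return(list(peptide = paste(aa, collapse = ""), stop_found = TRUE,
                  stop_at = pos))
    }
    aa <- c(aa, r)
    pos <- pos + 3L
  }
  list(peptide = paste(aa, collapse = ""), stop_found = FALSE,
       stop_at = NA_integer_)
}

# brute-force O(n^2) union-find over shared splice sites
oracle_cluster <- function(jx) {
  n <- nrow(jx)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    if (jx$chrom[i] == jx$chrom[j] && jx$strand[i] == jx$strand[j] &&
        (jx$start[i] == jx$start[j] || jx$end[i] == jx$end[j])) {
      parent[find(i)] <- find(j)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

random_junction_table <- function(n, n_samples = 2, seed = 1) {
  set.seed(seed)
  starts <- sample(seq(1000L, 5000L, by = 500L), n, replace = TRUE)
  ends <- starts + sample(seq(500L, 2000L, by = 250L), n, replace = TRUE)
  d <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = starts, end = ends,
    strand = sample(c("+", "-"), n, replace = TRUE)
  )
  d <- dplyr::distinct(d, chrom, start, end, strand)
  for (s in paste0("s", seq_len(n_samples))) {
    d[[s]] <- sample(0:100, nrow(d), replace = TRUE)
  }
  d
}
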