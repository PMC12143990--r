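#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator. Defaults emulate the
#' junction-count structure of a bulk-brain differential splicing study:
#' moderately deep clusters (negative-binomial totals around 100 reads),
#' Dirichlet-multinomial overdispersion (concentration 30), group inclusion
#' differences on a 0 to 0.3 delta-PSI grid, twenty samples per group, and
#' five brain cell types mixed with a lower neuronal share in cases.
#'
#' @param seed Integer seed; every generator draws from a stream derived
#'   from it, so outputs are reproducible.
#' @param n_case,n_control Samples per group.
#' @param n_clusters Number of intron clusters (abstract count simulation).
#' @param junctions_range Inclusive range for junctions per cluster.
#' @param alpha Dirichlet-multinomial concentration of the generator.
#' @param delta_psi_grid Planted inclusion differences cycled over signal
#'   clusters.
#' @param signal_fraction Fraction of clusters carrying a non-zero planted
#'   delta PSI.
#' @param total_mean,total_size Negative-binomial mean and size of per-sample
#'   cluster totals.
#' @param n_genes Genes in the toy annotation.
#' @param cryptic_types Event types injected into the toy annotation,
#'   recycled over the genes selected to carry a cryptic event.
#' @param markers_per_type Marker genes per cell type.
#' @param mixture_concentration Dirichlet concentration of cell mixtures.
#' @param noise_cv Multiplicative (log-normal) noise CV on bulk expression.
#' @param confound_strength Logit shift per unit neuronal-proportion
#'   deviation applied to composition-sensitive null clusters (0 = off).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_case = 20L, n_control = 20L,
                       n_clusters = 100L,
                       junctions_range = c(2L, 4L),
                       alpha = 30,
                       delta_psi_grid = c(0.1, 0.2, 0.3),
                       signal_fraction = 0.5,
                       total_mean = 100, total_size = 5,
                       n_genes = 16L,
                       cryptic_types = c("EI", "EI_oof", "ES", "A5SS", "A3SS",
                                         "EI_terminal"),
                       markers_per_type = 8L,
                       mixture_concentration = 50,
                       noise_cv = 0.1,
                       confound_strength = 0) {
  stopifnot(n_case > 0, n_control > 0, n_clusters > 0,
            all(junctions_range >= 2L), alpha > 0,
            all(delta_psi_grid >= 0 & delta_psi_grid < 1),
            total_mean > 0, total_size > 0, n_genes > 0)
  structure(as.list(environment()), class = "sim_config")
}

# deterministic sub-stream seeds (< 2^31)
sim_seed <- function(config, offset) {
  (as.integer(config$seed) * 97L + offset) %% 2147483647L
}

rdirichlet_one <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

sim_sample_metadata <- function(config) {
  n <- config$n_case + config$n_control
  tibble(
    sample = sprintf("S%03d", seq_len(n)),
    group = rep(c("case", "control"), c(config$n_case, config$n_control)),
    age_at_death = round(rnorm(n, 70, 8), 1),
    sex = ifelse(runif(n) < 0.5, "M", "F"),
    RIN = round(pmin(10, pmax(6, rnorm(n, 8.2, 0.7))), 1)
  )
}

#' Simulate Dirichlet-multinomial junction counts
#'
#' Generates clustered junction counts with known per-cluster group usage.
#' Each cluster draws per-sample totals from a negative binomial and splits
#' them Dirichlet-multinomially around group-specific proportions; signal
#' clusters shift the first junction's usage up by a planted delta PSI in
#' cases only. When `composition` is supplied together with a positive
#' `confound_strength`, null clusters become composition-sensitive: each
#' sample's first-junction usage is logit-shifted in proportion to its
#' neuronal-share deviation, so any group difference in composition leaks
#' into apparent splicing differences (used to exercise cell-proportion
#' adjustment).
#'
#' @param config A [sim_config()].
#' @param composition Optional tibble (`sample`, `neurons`) of true neuronal
#'   proportions aligned with the generated samples.
#' @return A list with `counts` (clustered junction tibble), `metadata`
#'   (sample covariates), and `truth` (per-cluster planted delta PSI and
#'   flags).
#' @export
simulate_junction_counts <- function(config, composition = NULL) {
  set.seed(sim_seed(config, 11L))
  md <- sim_sample_metadata(config)
  n <- nrow(md)
  is_case <- md$group == "case"
  n_signal <- round(config$n_clusters * config$signal_fraction)
  dpsi <- rep(0, config$n_clusters)
  if (n_signal > 0) {
    dpsi[seq_len(n_signal)] <-
      rep_len(config$delta_psi_grid, n_signal)
  }
  comp_dev <- NULL
  if (!is.null(composition) && config$confound_strength > 0) {
    z <- composition$neurons[match(md$sample, composition$sample)]
    comp_dev <- z - mean(z)
  }

  rows <- vector("list", config$n_clusters)
  truth <- vector("list", config$n_clusters)
  for (k in seq_len(config$n_clusters)) {
    J <- config$junctions_range[1] +
      sample.int(config$junctions_range[2] - config$junctions_range[1] + 1L,
                 1L) - 1L
    repeat {
      p0 <- rdirichlet_one(rep(2, J))
      if (p0[1] + dpsi[k] <= 0.9 && all(p0 > 0.01)) break
    }
    p_case <- p0
    p_case[1] <- p0[1] + dpsi[k]
    p_case[-1] <- p0[-1] * (1 - p_case[1]) / (1 - p0[1])

    totals <- rnbinom(n, size = config$total_size, mu = config$total_mean)
    Y <- matrix(0L, nrow = n, ncol = J)
    for (i in seq_len(n)) {
      if (totals[i] == 0L) next
      p_i <- if (is_case[i]) p_case else p0
      if (!is.null(comp_dev) && dpsi[k] == 0) {
        lg <- log(p_i[1] / (1 - p_i[1])) +
          config$confound_strength * comp_dev[i]
        p1 <- 1 / (1 + exp(-lg))
        p_i <- c(p1, p_i[-1] * (1 - p1) / (1 - p_i[1]))
      }
      pp <- rdirichlet_one(config$alpha * p_i)
      Y[i, ] <- stats::rmultinom(1L, totals[i], pp)
    }
    B <- 100000L * k
    rows[[k]] <- bind_cols(
      tibble(cluster_id = paste0("clu_chr_sim_", k),
             chrom = "chr_sim",
             start = rep(B, J),
             end = B + 500L + 200L * seq_len(J),
             strand = "+"),
      as_tibble(t(Y), .name_repair = ~ md$sample)
    )
    truth[[k]] <- tibble(
      cluster_id = paste0("clu_chr_sim_", k),
      true_delta_psi = dpsi[k],
      signal = dpsi[k] > 0,
      composition_driven = !is.null(comp_dev) && dpsi[k] == 0
    )
  }
  list(counts = list_rbind(rows), metadata = md, truth = list_rbind(truth))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_codons <- function(n_codons) {
  codons <- setdiff(names(Biostrings::GENETIC_CODE),
                    c("TAA", "TAG", "TGA"))
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}

#' Simulate a toy genome and annotation with injectable cryptic exons
#'
#' Builds a small genome (one synthetic chromosome) and a matching GTF:
#' each gene has one MANE-tagged coding transcript with 3 to 8 exons
#' (30 nt UTRs, ATG...stop CDS written into the sequence) and canonical
#' GT..AG intron dinucleotides, half on each strand. A subset of genes
#' carries a reserved cryptic event whose coordinates and expected
#' classifications are recorded as ground truth: cryptic exons (in-frame
#' exons made of stop-free codons, out-of-frame exons with a premature stop
#' written at the in-frame offset of the insertion phase, terminal exons
#' with only an entering junction) are placed strictly inside an annotated
#' intron, more than 100 bp from either annotated splice site, with AG/GT
#' splice dinucleotides written into the genome; alternative splice sites
#' shift an annotated donor or acceptor by less than 100 bp; exon skips
#' remove one internal exon.
#'
#' @param config A [sim_config()].
#' @param dir Directory in which to write `genome.fa` and `annotation.gtf`.
#' @return A list with paths `fasta` and `gtf`, the `truth` event tibble,
#'   and the `genes` layout tibble.
#' @export
simulate_annotation_and_genome <- function(config, dir = tempdir()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(sim_seed(config, 23L))
  chrom <- "chrS1"
  cursor <- 1001L
  gene_rows <- list(); gtf <- character(0); truth <- list()
  genome_parts <- list(list(seq = random_dna(1000L), at = 1L))
  types <- rep_len(config$cryptic_types, config$n_genes)
  has_event <- seq_len(config$n_genes) <= ceiling(config$n_genes * 0.75)

  for (g in seq_len(config$n_genes)) {
    gene_id <- sprintf("GENE%03d", g)
    strand <- if (g %% 2L == 0L) "-" else "+"
    n_exons <- sample(3:8, 1L)
    # transcript sequence: 30 nt 5'UTR + ATG + codons + TAA + 30 nt 3'UTR
    n_codons <- sample(60:140, 1L)
    cdna <- paste0(random_dna(30L), "ATG", random_codons(n_codons), "TAA",
                   random_dna(30L))
    total_len <- nchar(cdna)
    # split into exons: cut points away from the ends
    cuts <- sort(sample(seq(40L, total_len - 40L), n_exons - 1L))
    while (any(diff(c(0L, cuts, total_len)) < 20L)) {
      cuts <- sort(sample(seq(40L, total_len - 40L), n_exons - 1L))
    }
    ev_type <- if (has_event[g]) types[g] else NA_character_
    if (!is.na(ev_type) && ev_type == "ES") {
      # make the skipped exon's length a codon multiple so its excision is
      # in frame (the "sequence missing" consequence); the skipped genomic
      # exon is transcript exon n-skip+1 on '-'
      gskip <- min(3L, n_exons - 1L)
      txs <- if (strand == "+") gskip else n_exons - gskip + 1L
      len_skip <- cuts[txs] - cuts[txs - 1L]
      cuts[txs] <- cuts[txs] + (3L - len_skip %% 3L) %% 3L
    }
    exon_len <- diff(c(0L, cuts, total_len))
    intron_len <- sample(400:1500, n_exons - 1L, replace = TRUE)

    # genomic layout left to right; on '-' the transcript's first exon sits
    # rightmost, so genomic slot widths are the reversed exon lengths
    slot_len <- if (strand == "+") exon_len else rev(exon_len)
    starts <- integer(n_exons); ends <- integer(n_exons)
    pos <- cursor
    for (e in seq_len(n_exons)) {
      starts[e] <- pos
      ends[e] <- pos + slot_len[e] - 1L
      pos <- ends[e] + 1L + (if (e < n_exons) intron_len[e] else 0L)
    }
    gene_start <- starts[1L]; gene_end <- ends[n_exons]

    # build the gene's genomic sequence
    glen <- gene_end - gene_start + 1L
    gseq <- random_dna(glen)
    tx_exon_seq <- substring(cdna, cumsum(c(1L, exon_len))[seq_len(n_exons)],
                             cumsum(exon_len))
    put <- function(seq, at, frag) {
      substr(seq, at, at + nchar(frag) - 1L) <- frag
      seq
    }
    for (e in seq_len(n_exons)) {
      frag <- tx_exon_seq[e]
      if (strand == "-") {
        frag <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(frag)))
      }
      # on '-', exon e (5'->3') occupies the e-th interval from the right
      idx <- if (strand == "+") e else n_exons - e + 1L
      gseq <- put(gseq, starts[idx] - gene_start + 1L, frag)
    }
    # intron splice dinucleotides
    for (e in seq_len(n_exons - 1L)) {
      i_start <- ends[e] + 1L; i_end <- starts[e + 1L] - 1L
      if (strand == "+") {
        gseq <- put(gseq, i_start - gene_start + 1L, "GT")
        gseq <- put(gseq, i_end - gene_start, "AG")
      } else {
        gseq <- put(gseq, i_start - gene_start + 1L, "CT")
        gseq <- put(gseq, i_end - gene_start, "AC")
      }
    }

    # cryptic event injection
    ev_type <- if (has_event[g]) types[g] else NA_character_
    if (!is.na(ev_type)) {
      # CDS transcript coordinates (1-based in cdna): 31 .. 30+3*(n_codons+2)
      cds_start_tx <- 31L
      intr <- if (n_exons > 2L) 2L else 1L   # host intron (between exon intr, intr+1)
      i_start <- ends[intr] + 1L; i_end <- starts[intr + 1L] - 1L
      if (ev_type %in% c("EI", "EI_oof", "EI_terminal")) {
        # insertion phase: genomic intron `intr` separates transcript exons
        # intr/intr+1 on '+' but n-intr/n-intr+1 on '-'
        tx_intr <- if (strand == "+") intr else n_exons - intr
        tx_before <- sum(exon_len[seq_len(tx_intr)])
        phase <- (tx_before - 30L) %% 3L   # codon offset at insertion
        in_frame <- ev_type == "EI"
        ce_len <- if (in_frame) 24L else 40L
        margin <- 150L
        ce_start <- i_start + margin
        ce_end <- ce_start + ce_len - 1L
        if (ce_end > i_end - margin) {
          # widen the host intron is not possible post hoc; clamp margin
          ce_start <- i_start + 120L
          ce_end <- ce_start + ce_len - 1L
        }
        ce_seq_tx <- if (in_frame) {
          paste(rep("GCT", ce_len / 3L), collapse = "")
        } else {
          s <- random_codons(ceiling(ce_len / 3) + 2L)
          s <- substr(s, 1L, ce_len)
          # write a stop at the first in-frame offset >= 7 of the shifted frame
          off <- ((3L - phase) %% 3L) + 7L
          off <- off - ((off - 1L + phase) %% 3L)  # align to codon boundary
          while (((off - 1L + phase) %% 3L) != 0L) off <- off + 1L
          substr(s, off, off + 2L) <- "TAA"
          s
        }
        frag <- ce_seq_tx
        if (strand == "-") {
          frag <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(frag)))
        }
        gseq <- put(gseq, ce_start - gene_start + 1L, frag)
        # splice dinucleotides flanking the cryptic exon (genome strand-aware)
        if (strand == "+") {
          gseq <- put(gseq, ce_start - gene_start - 1L, "AG")  # acceptor before
          gseq <- put(gseq, ce_end - gene_start + 2L, "GT")    # donor after
        } else {
          # minus-strand introns read CT..AC on the genome (revcomp of GT..AG)
          gseq <- put(gseq, ce_start - gene_start - 1L, "AC")
          gseq <- put(gseq, ce_end - gene_start + 2L, "CT")
        }
        truth[[length(truth) + 1L]] <- tibble(
          gene = gene_id, event_type = "EI",
          injected = ev_type,
          chrom = chrom, strand = strand,
          intron_start = i_start, intron_end = i_end,
          ce_start = ce_start, ce_end = ce_end,
          structural = dplyr::case_when(
            ev_type == "EI_terminal" ~ "terminal_exon",
            in_frame ~ "in_frame_exon",
            TRUE ~ "out_of_frame_exon"
          ),
          phase = phase
        )
      } else if (ev_type == "ES") {
        skip <- intr + 1L
        if (skip >= n_exons) skip <- n_exons - 1L
        # skipping junction joins intron before and after exon `skip`
        truth[[length(truth) + 1L]] <- tibble(
          gene = gene_id, event_type = "ES", injected = "ES",
          chrom = chrom, strand = strand,
          intron_start = ends[skip - 1L] + 1L,
          intron_end = starts[skip + 1L] - 1L,
          ce_start = starts[skip], ce_end = ends[skip],
          structural = "exon_skipping", phase = NA_integer_
        )
      } else if (ev_type %in% c("A5SS", "A3SS")) {
        # shift < alt_ss_window into the host intron; 31 nt so the exon
        # extension shifts the reading frame (the typical alternative-site
        # consequence); which genomic end moves depends on strand (donor =
        # 5' intron end in transcription direction)
        shift <- 31L
        donor_end <- if (strand == "+") "start" else "end"
        move_donor <- ev_type == "A5SS"
        if ((donor_end == "start") == move_donor) {
          ns <- i_start + shift; ne <- i_end
          if (strand == "+") {
            gseq <- put(gseq, ns - gene_start + 1L, "GT")
          } else {
            gseq <- put(gseq, ns - gene_start + 1L, "CT")
          }
        } else {
          ns <- i_start; ne <- i_end - shift
          if (strand == "+") {
            gseq <- put(gseq, ne - gene_start, "AG")
          } else {
            gseq <- put(gseq, ne - gene_start, "AC")
          }
        }
        truth[[length(truth) + 1L]] <- tibble(
          gene = gene_id, event_type = ev_type, injected = ev_type,
          chrom = chrom, strand = strand,
          intron_start = ns, intron_end = ne,
          ce_start = NA_integer_, ce_end = NA_integer_,
          structural = "alternative_splice_site", phase = NA_integer_
        )
      }
    }

    genome_parts[[length(genome_parts) + 1L]] <-
      list(seq = gseq, at = gene_start)
    genome_parts[[length(genome_parts) + 1L]] <-
      list(seq = random_dna(800L), at = gene_end + 1L)
    tx_id <- paste0(gene_id, ".t1")
    gtf <- c(gtf,
      sprintf(paste0("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\t",
                     "gene_id \"%s\"; gene_name \"%s\";"),
              chrom, gene_start, gene_end, strand, gene_id, gene_id),
      sprintf(paste0("%s\tsim\ttranscript\t%d\t%d\t.\t%s\t.\t",
                     "gene_id \"%s\"; transcript_id \"%s\"; ",
                     "tag \"MANE_Select\";"),
              chrom, gene_start, gene_end, strand, gene_id, tx_id))
    # CDS occupies transcript coords 31..(30 + 3*(n_codons+2)), stop included
    cds_tx <- c(31L, 30L + 3L * (n_codons + 2L))
    off <- 0L
    for (e in seq_len(n_exons)) {
      idx <- if (strand == "+") e else n_exons - e + 1L
      gtf <- c(gtf, sprintf(
        paste0("%s\tsim\texon\t%d\t%d\t.\t%s\t.\t",
               "gene_id \"%s\"; transcript_id \"%s\"; exon_number \"%d\"; ",
               "tag \"MANE_Select\";"),
        chrom, starts[idx], ends[idx], strand, gene_id, tx_id, e))
      lo <- max(cds_tx[1L], off + 1L)
      hi <- min(cds_tx[2L], off + exon_len[e])
      if (lo <= hi) {
        if (strand == "+") {
          gs <- starts[idx] + (lo - off - 1L)
          ge <- starts[idx] + (hi - off - 1L)
        } else {
          gs <- ends[idx] - (hi - off - 1L)
          ge <- ends[idx] - (lo - off - 1L)
        }
        gtf <- c(gtf, sprintf(
          paste0("%s\tsim\tCDS\t%d\t%d\t.\t%s\t.\t",
                 "gene_id \"%s\"; transcript_id \"%s\";"),
          chrom, gs, ge, strand, gene_id, tx_id))
      }
      off <- off + exon_len[e]
    }
    gene_rows[[g]] <- tibble(
      gene = gene_id, chrom = chrom, strand = strand,
      start = gene_start, end = gene_end,
      n_exons = n_exons, cds_tx_start = 31L,
      cds_tx_end = 30L + 3L * (n_codons + 2L),
      exon_starts = list(starts), exon_ends = list(ends)
    )
    cursor <- gene_end + 801L
  }

  genome_len <- cursor + 1000L
  genome <- paste(rep("N", genome_len), collapse = "")
  for (part in genome_parts) {
    substr(genome, part$at, part$at + nchar(part$seq) - 1L) <- part$seq
  }
  genome <- gsub("N", "A", genome, fixed = TRUE)
  fasta <- file.path(dir, "genome.fa")
  gtf_path <- file.path(dir, "annotation.gtf")
  seqs <- Biostrings::DNAStringSet(setNames(genome, chrom))
  Biostrings::writeXStringSet(seqs, fasta)
  writeLines(gtf, gtf_path)
  list(fasta = fasta, gtf = gtf_path,
       truth = if (length(truth)) list_rbind(truth) else tibble(),
       genes = list_rbind(gene_rows))
}

#' Simulate annotation-linked junction counts
#'
#' Builds clustered junction counts whose cluster geometry realizes the
#' cryptic events injected by [simulate_annotation_and_genome()]: exon
#' inclusion clusters carry the annotated host intron plus two cryptic
#' junctions flanking the cryptic exon, exon skips carry the two annotated
#' introns plus the skipping junction, alternative splice sites pair the
#' annotated and the shifted intron, and terminal exons carry only the
#' entering junction. Cases have the cryptic junction usage raised by a
#' planted delta PSI; genes without an event contribute null clusters.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [simulate_annotation_and_genome()].
#' @param delta_psi Planted inclusion difference for cryptic junctions.
#' @return A list with `counts`, `metadata`, and per-junction `truth`.
#' @export
simulate_event_counts <- function(config, annotation, delta_psi = 0.25) {
  set.seed(sim_seed(config, 37L))
  md <- sim_sample_metadata(config)
  n <- nrow(md); is_case <- md$group == "case"
  genes <- annotation$genes
  truth <- annotation$truth
  rows <- list(); jx_truth <- list()

  emit_cluster <- function(gene, coords, p_ctrl, p_case, cryptic_flags,
                           types) {
    J <- nrow(coords)
    totals <- rnbinom(n, size = config$total_size, mu = config$total_mean)
    Y <- matrix(0L, n, J)
    for (i in seq_len(n)) {
      if (totals[i] == 0L) next
      p_i <- if (is_case[i]) p_case else p_ctrl
      pp <- rdirichlet_one(config$alpha * p_i)
      Y[i, ] <- stats::rmultinom(1L, totals[i], pp)
    }
    bind_cols(coords, as_tibble(t(Y), .name_repair = ~ md$sample)) |>
      mutate(gene = gene, cryptic = cryptic_flags, true_type = types,
             .after = "strand")
  }

  for (g in seq_len(nrow(genes))) {
    gn <- genes[g, ]
    ev <- filter(truth, .data$gene == gn$gene)
    starts <- gn$exon_starts[[1]]; ends <- gn$exon_ends[[1]]
    if (nrow(ev) == 1L) {
      tp <- ev$injected
      if (tp %in% c("EI", "EI_oof")) {
        coords <- tibble(
          chrom = ev$chrom,
          start = c(ev$intron_start, ev$intron_start, ev$ce_end + 1L),
          end = c(ev$intron_end, ev$ce_start - 1L, ev$intron_end),
          strand = ev$strand
        )
        d <- delta_psi
        p_ctrl <- c(0.96, 0.02, 0.02)
        p_case <- c(0.96 - d, 0.02 + d / 2, 0.02 + d / 2)
        rows[[length(rows) + 1L]] <- emit_cluster(
          gn$gene, coords, p_ctrl, p_case,
          c(FALSE, TRUE, TRUE), c(NA, "EI", "EI"))
      } else if (tp == "EI_terminal") {
        coords <- tibble(
          chrom = ev$chrom,
          start = c(ev$intron_start, ev$intron_start),
          end = c(ev$intron_end, ev$ce_start - 1L),
          strand = ev$strand
        )
        d <- delta_psi
        rows[[length(rows) + 1L]] <- emit_cluster(
          gn$gene, coords, c(0.97, 0.03), c(0.97 - d, 0.03 + d),
          c(FALSE, TRUE), c(NA, "EI"))
      } else if (tp == "ES") {
        coords <- tibble(
          chrom = ev$chrom,
          start = c(ev$intron_start, ev$intron_start, ev$ce_end + 1L),
          end = c(ev$ce_start - 1L, ev$intron_end, ev$intron_end),
          strand = ev$strand
        )
        d <- delta_psi
        p_ctrl <- c(0.48, 0.04, 0.48)
        p_case <- c(0.48 - d / 2, 0.04 + d, 0.48 - d / 2)
        rows[[length(rows) + 1L]] <- emit_cluster(
          gn$gene, coords, p_ctrl, p_case,
          c(FALSE, TRUE, FALSE), c(NA, "ES", NA))
      } else if (tp %in% c("A5SS", "A3SS")) {
        intr <- if (gn$n_exons > 2L) 2L else 1L
        # annotated host intron in genomic coords
        ann <- c(ends[intr] + 1L, starts[intr + 1L] - 1L)
        coords <- tibble(
          chrom = ev$chrom,
          start = c(ann[1], ev$intron_start),
          end = c(ann[2], ev$intron_end),
          strand = ev$strand
        )
        d <- delta_psi
        rows[[length(rows) + 1L]] <- emit_cluster(
          gn$gene, coords, c(0.95, 0.05), c(0.95 - d, 0.05 + d),
          c(FALSE, TRUE), c(NA, tp))
      }
    } else {
      # null cluster: two annotated introns sharing the gene's middle exon
      if (gn$n_exons >= 3L) {
        intr <- 2L
        coords <- tibble(
          chrom = gn$chrom,
          start = c(ends[intr - 1L] + 1L, ends[intr - 1L] + 1L),
          end = c(starts[intr] - 1L, starts[intr + 1L] - 1L),
          strand = gn$strand
        )
        rows[[length(rows) + 1L]] <- emit_cluster(
          gn$gene, coords, c(0.7, 0.3), c(0.7, 0.3),
          c(FALSE, FALSE), c(NA, NA))
      }
    }
  }
  counts <- list_rbind(rows)
  jx_truth <- counts |> select("chrom", "start", "end", "strand",
                               "gene", "cryptic", "true_type")
  counts <- select(counts, -"gene", -"cryptic", -"true_type")
  list(counts = counts, metadata = md, truth = jx_truth)
}

#' Simulate marker-structured bulk expression mixtures
#'
#' Draws per-sample cell-type proportions from group-specific Dirichlet
#' distributions (cases centered on a lower neuronal share, higher
#' endothelial and microglial shares, mirroring neurodegeneration-driven
#' composition shifts), builds marker-pure expression profiles, and mixes
#' them with multiplicative log-normal noise.
#'
#' @param config A [sim_config()].
#' @param metadata Optional sample metadata to align groups with; defaults
#'   to a fresh draw of [sim_config()] samples.
#' @return A list with `expression` (gene x sample tibble), `markers`
#'   (tibble `cell_type`, `gene`), and `proportions` (true mixing weights).
#' @export
simulate_cell_mixture <- function(config, metadata = NULL) {
  set.seed(sim_seed(config, 53L))
  if (is.null(metadata)) metadata <- sim_sample_metadata(config)
  types <- c("neurons", "oligodendrocytes", "astrocytes", "microglia",
             "endothelial")
  base <- list(
    control = c(0.22, 0.40, 0.237, 0.033, 0.11),
    case = c(0.16, 0.40, 0.263, 0.037, 0.14)
  )
  n <- nrow(metadata)
  P <- t(vapply(seq_len(n), function(i) {
    b <- base[[metadata$group[i]]] %||% base$control
    rdirichlet_one(config$mixture_concentration * b)
  }, numeric(5)))
  colnames(P) <- types

  m <- config$markers_per_type
  markers <- tibble(
    cell_type = rep(types, each = m),
    gene = paste0(rep(toupper(substr(types, 1, 3)), each = m), "_M",
                  rep(seq_len(m), times = length(types)))
  )
  # marker-pure profiles: expression level of a marker in its own type
  level <- exp(rnorm(nrow(markers), log(200), 0.4))
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  expr <- matrix(0, nrow(markers) + 40L, n)
  for (i in seq_len(n)) {
    own <- P[i, markers$cell_type]
    noise <- exp(rnorm(nrow(markers), -sdlog^2 / 2, sdlog))
    expr[seq_len(nrow(markers)), i] <- level * own * noise
  }
  # background genes expressed everywhere (library-size ballast)
  bg_level <- exp(rnorm(40L, log(150), 0.5))
  for (i in seq_len(n)) {
    expr[nrow(markers) + seq_len(40L), i] <-
      bg_level * exp(rnorm(40L, -sdlog^2 / 2, sdlog))
  }
  genes <- c(markers$gene, paste0("BG_", seq_len(40L)))
  expression <- bind_cols(tibble(gene = genes),
                          as_tibble(round(expr * 10) ,
                                    .name_repair = ~ metadata$sample))
  list(expression = expression, markers = markers,
       proportions = bind_cols(tibble(sample = metadata$sample),
                               as_tibble(P)))
}

#' Simulate cross-study cryptic event lists with planted matches
#'
#' Emits three study event lists with a planted match structure: a set of
#' genes whose event coordinates agree exactly across all three studies
#' (triple-perfect), sets agreeing between one pair only, partial matches
#' sharing exactly one coordinate, gene-level-only overlaps, and unmatched
#' fillers. The third study uses event-span semantics (its two positions are
#' the outer ends of the whole event rather than one junction's ends), as
#' some published lists do.
#'
#' @param config A [sim_config()].
#' @param planted Named list of planted counts: `triple`, `perfect_ab`,
#'   `perfect_ac`, `partial_ab`, `partial_ac`, `gene_only_ab`,
#'   `gene_only_ac`, `unmatched_each`. The default mirrors the overlap
#'   structure reported for published TDP-43 splicing datasets (3 events
#'   shared by all three studies, 13 shared only by the first pair, one by
#'   the second pair, 9 and 5 partial matches, 52 and 24 shared genes).
#' @return A list with `studies` (named list of three study tibbles:
#'   `study`, `gene`, `chrom`, `posA`, `posB`, `semantics`) and `truth`.
#' @export
simulate_external_study_lists <- function(config,
                                          planted = list(
                                            triple = 3L,
                                            perfect_ab = 13L,
                                            perfect_ac = 1L,
                                            partial_ab = 9L,
                                            partial_ac = 5L,
                                            gene_only_ab = 27L,
                                            gene_only_ac = 15L,
                                            unmatched_each = 10L)) {
  set.seed(sim_seed(config, 71L))
  mk <- function(i, tag) sprintf("%s%03d", tag, i)
  gi <- 0L
  base_pos <- function(i) 1000000L + 50000L * i
  a <- list(); b <- list(); c3 <- list(); truth <- list()
  add <- function(lst, study, gene, x, y, semantics = "junction_ends") {
    c(lst, list(tibble(study = study, gene = gene, chrom = "chr1",
                       posA = x, posB = y, semantics = semantics)))
  }
  triple_names <- c("STMN2", "KCNQ2", "RAP1GAP")
  for (i in seq_len(planted$triple)) {
    gi <- gi + 1L
    gene <- if (i <= length(triple_names)) triple_names[i] else mk(gi, "TRP")
    x <- base_pos(gi); y <- x + 4000L
    a <- add(a, "brain", gene, x, y)
    b <- add(b, "kd_neurons", gene, x, y)
    c3 <- add(c3, "sorted_nuclei", gene, x, y, "event_span")
    truth <- c(truth, list(tibble(gene = gene, planted = "triple")))
  }
  for (i in seq_len(planted$perfect_ab)) {
    gi <- gi + 1L; gene <- mk(gi, "PAB")
    x <- base_pos(gi); y <- x + 3000L
    a <- add(a, "brain", gene, x, y)
    b <- add(b, "kd_neurons", gene, x, y)
    truth <- c(truth, list(tibble(gene = gene, planted = "perfect_ab")))
  }
  for (i in seq_len(planted$perfect_ac)) {
    gi <- gi + 1L; gene <- if (i == 1L) "EPB41L1" else mk(gi, "PAC")
    x <- base_pos(gi); y <- x + 3000L
    a <- add(a, "brain", gene, x, y)
    c3 <- add(c3, "sorted_nuclei", gene, x, y, "event_span")
    truth <- c(truth, list(tibble(gene = gene, planted = "perfect_ac")))
  }
  for (i in seq_len(planted$partial_ab)) {
    gi <- gi + 1L; gene <- mk(gi, "QAB")
    x <- base_pos(gi)
    a <- add(a, "brain", gene, x, x + 2000L)
    b <- add(b, "kd_neurons", gene, x, x + 2600L)
    truth <- c(truth, list(tibble(gene = gene, planted = "partial_ab")))
  }
  for (i in seq_len(planted$partial_ac)) {
    gi <- gi + 1L; gene <- mk(gi, "QAC")
    x <- base_pos(gi)
    a <- add(a, "brain", gene, x, x + 2000L)
    c3 <- add(c3, "sorted_nuclei", gene, x, x + 2600L, "event_span")
    truth <- c(truth, list(tibble(gene = gene, planted = "partial_ac")))
  }
  for (i in seq_len(planted$gene_only_ab)) {
    gi <- gi + 1L; gene <- mk(gi, "GAB")
    x <- base_pos(gi)
    a <- add(a, "brain", gene, x, x + 2000L)
    b <- add(b, "kd_neurons", gene, x + 5000L, x + 8000L)
    truth <- c(truth, list(tibble(gene = gene, planted = "gene_only_ab")))
  }
  for (i in seq_len(planted$gene_only_ac)) {
    gi <- gi + 1L; gene <- mk(gi, "GAC")
    x <- base_pos(gi)
    a <- add(a, "brain", gene, x, x + 2000L)
    c3 <- add(c3, "sorted_nuclei", gene, x + 5000L, x + 8000L, "event_span")
    truth <- c(truth, list(tibble(gene = gene, planted = "gene_only_ac")))
  }
  for (i in seq_len(planted$unmatched_each)) {
    gi <- gi + 1L
    x <- base_pos(gi)
    a <- add(a, "brain", mk(gi, "UA"), x, x + 2000L)
    b <- add(b, "kd_neurons", mk(gi, "UB"), x + 100L, x + 2100L)
    c3 <- add(c3, "sorted_nuclei", mk(gi, "UC"), x + 200L, x + 2200L,
              "event_span")
  }
  list(
    studies = list(
      brain = list_rbind(a),
      kd_neurons = list_rbind(b),
      sorted_nuclei = list_rbind(c3)
    ),
    truth = list_rbind(truth)
  )
}
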