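#' Pipeline configuration
#'
#' Paths and thresholds for the end-to-end analysis: junction counts,
#' reference annotation and genome, sample metadata, optional bulk
#' expression plus marker lists for cell-composition adjustment, optional
#' binding-site intervals and external study lists. All headline
#' thresholds live here: cluster FDR 0.05, |delta PSI| 0.1, binding
#' proximity window 500 bp, proportion-PC cumulative variance target 0.8,
#' and the 100 bp window separating alternative splice sites from cryptic
#' exons.
#'
#' @param counts Junction count TSV (see [read_junction_counts()]).
#' @param metadata Sample metadata TSV (`sample`, `group`, covariates).
#' @param out_dir Output directory (created if missing).
#' @param gtf,fasta Reference annotation / genome (optional stages).
#' @param expression,markers Bulk expression and marker TSVs for
#'   cell-composition adjustment.
#' @param binding_bed Binding-site BED.
#' @param study_lists Character vector of study event TSVs (cross-study
#'   matching runs when two or more are given).
#' @param case,control Group labels compared.
#' @param fdr,dpsi,binding_window,variance_target,alt_ss_window Thresholds.
#' @param mode Cryptic selection mode, `"strict"` or `"relaxed"`.
#' @param adjust_cell_types Add proportion PCs to the design.
#' @param counts_dialect Coordinate dialect of the counts file.
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, metadata, out_dir,
                            gtf = NULL, fasta = NULL,
                            expression = NULL, markers = NULL,
                            binding_bed = NULL, study_lists = NULL,
                            case = "case", control = "control",
                            fdr = 0.05, dpsi = 0.1,
                            binding_window = 500L,
                            variance_target = 0.8,
                            alt_ss_window = 100L,
                            mode = c("strict", "relaxed"),
                            adjust_cell_types = FALSE,
                            counts_dialect = "tsv_1based_closed",
                            seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(fdr > 0, fdr < 1, dpsi >= 0, dpsi < 1,
            binding_window >= 0, variance_target > 0, variance_target <= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

pipeline_inputs <- function(config) {
  paths <- c(counts = config$counts, metadata = config$metadata,
             gtf = config$gtf, fasta = config$fasta,
             expression = config$expression, markers = config$markers,
             binding_bed = config$binding_bed)
  if (!is.null(config$study_lists)) {
    paths <- c(paths, setNames(config$study_lists,
                               paste0("study_", seq_along(config$study_lists))))
  }
  paths[!vapply(paths, is.null, logical(1))]
}

#' Run the full differential splicing pipeline
#'
#' Orchestrates the stages: read/filter/cluster junctions, Dirichlet-
#' multinomial testing (optionally adjusted by cell-proportion PCs
#' estimated from bulk expression), annotation against the reference,
#' cryptic event selection, cassette classification, binding-site
#' proximity, peptide prediction, and cross-study matching. All declared
#' outputs are written to `config$out_dir` together with a machine-readable
#' run manifest (input hashes, thresholds, seed).
#'
#' Validation failures (missing inputs, malformed tables) signal a
#' condition of class `crypticsplice_validation_error`; stage failures
#' signal `crypticsplice_runtime_error` carrying the stage name. These map
#' onto conventional exit codes 2 and 3 for shell callers.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the result objects and output paths.
#' @export
run_pipeline <- function(config) {
  inputs <- pipeline_inputs(config)
  missing <- inputs[!file.exists(unlist(inputs))]
  if (length(missing) > 0L) {
    abort(paste0("missing input file(s): ",
                 paste(names(missing), "=", unlist(missing),
                       collapse = ", ")),
          class = "crypticsplice_validation_error")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, crypticsplice_validation_error = function(e) stop(e),
             error = function(e) {
               abort(paste0("stage '", name, "' failed: ",
                            conditionMessage(e)),
                     class = "crypticsplice_runtime_error")
             })
  }
  out <- list()

  clustered <- stage("cluster", {
    jx <- read_junction_counts(config$counts, dialect = config$counts_dialect)
    jx <- filter_junctions(jx)
    cluster_introns(jx)
  })
  out$clustered_path <- file.path(config$out_dir, "cluster_counts.tsv")
  write_cluster_counts(clustered, out$clustered_path)

  metadata <- stage("metadata", {
    readr::read_tsv(config$metadata, show_col_types = FALSE,
                    progress = FALSE)
  })

  cell_pcs <- NULL
  if (isTRUE(config$adjust_cell_types)) {
    cell <- stage("celltypes", {
      expr <- readr::read_tsv(config$expression, show_col_types = FALSE,
                              progress = FALSE)
      markers <- read_marker_set(config$markers)
      props <- estimate_cell_proportions(expr, markers)
      list(proportions = props,
           pcs = derive_proportion_covariates(props,
                                              config$variance_target))
    })
    cell_pcs <- cell$pcs
    out$proportions <- cell$proportions
    readr::write_tsv(as_tibble(cell$proportions),
                     file.path(config$out_dir, "cell_proportions.tsv"),
                     progress = FALSE)
  }

  results <- stage("test", {
    differential_splicing(clustered, metadata,
                          case = config$case, control = config$control,
                          cell_pcs = cell_pcs,
                          fdr_threshold = config$fdr,
                          dpsi_threshold = config$dpsi)
  })
  out$results <- results
  out$results_path <- file.path(config$out_dir, "splice_results.tsv")
  write_splice_results(results, out$results_path)

  if (!is.null(config$gtf)) {
    annotated <- stage("annotate", {
      index <- build_splice_index(config$gtf)
      ann <- annotate_junction_novelty(results, index)
      ann <- classify_event_type(ann, index,
                                 alt_ss_window = config$alt_ss_window)
      list(index = index, events = ann)
    })
    index <- annotated$index
    events <- annotated$events
    cassettes <- classify_cluster_cassettes(results)
    events <- left_join(events, cassettes, by = "cluster_id")
    out$events <- events
    readr::write_tsv(as_tibble(events),
                     file.path(config$out_dir, "events.tsv"),
                     progress = FALSE)

    cryptic <- stage("cryptic", {
      select_cryptic_events(events, mode = config$mode,
                            fdr_threshold = config$fdr,
                            dpsi_threshold = config$dpsi)
    })
    if (!is.null(config$binding_bed)) {
      sites <- stage("binding", read_binding_sites(config$binding_bed))
      cryptic <- annotate_binding_proximity(cryptic, sites,
                                            window = config$binding_window)
    }
    out$cryptic <- cryptic
    readr::write_tsv(as_tibble(cryptic),
                     file.path(config$out_dir, "cryptic_events.tsv"),
                     progress = FALSE)

    if (!is.null(config$fasta) && nrow(cryptic) > 0L) {
      peptides <- stage("peptides", {
        genome <- read_genome(config$fasta)
        predict_event_peptides(cryptic, index, genome)
      })
      out$peptides <- peptides
      readr::write_tsv(peptides,
                       file.path(config$out_dir, "peptides.tsv"),
                       progress = FALSE)
    }
  }

  if (!is.null(config$study_lists) && length(config$study_lists) >= 2L) {
    xm <- stage("crossmatch", {
      studies <- lapply(config$study_lists, read_study_events)
      names(studies) <- vapply(studies, function(s) s$study[1L], character(1))
      summarize_cross_study(studies)
    })
    out$crossmatch <- xm
    jsonlite::write_json(
      list(counts = xm$counts,
           n_triple_perfect = xm$n_triple_perfect %||% NULL,
           triple_perfect_genes = xm$triple_perfect_genes %||% NULL),
      file.path(config$out_dir, "crossmatch_summary.json"),
      auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package = "crypticsplice",
    version = as.character(utils::packageVersion("crypticsplice")),
    seed = config$seed,
    thresholds = list(fdr = config$fdr, dpsi = config$dpsi,
                      binding_window = config$binding_window,
                      variance_target = config$variance_target,
                      alt_ss_window = config$alt_ss_window,
                      mode = config$mode,
                      adjust_cell_types = config$adjust_cell_types),
    comparison = list(case = config$case, control = config$control),
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  out$manifest_path <- file.path(config$out_dir, "manifest.json")
  invisible(out)
}
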