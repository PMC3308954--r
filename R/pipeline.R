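#' Run the full genome-mining pipeline
#'
#' Orchestrates translated search, spliced gene-model prediction, precursor
#' extraction, homology-transfer segmentation, and feature profiling into
#' one reproducible run. Every stage writes its standard output file into
#' `outdir`; a JSON manifest records inputs, configuration and seed.
#' Each predicted precursor is re-searched against the genome (reciprocal
#' confirmation); a prediction whose top re-hit does not overlap its own
#' locus is flagged, never dropped.
#'
#' @param genome named character vector, `DNAStringSet`, or FASTA path
#' @param queries named character vector, `AAStringSet`, or FASTA path
#' @param references optional named list of [reference_annotation()] objects
#'   used for segmentation (keyed by query id; a single unnamed reference is
#'   used for all queries)
#' @param config a `run_config`
#' @param outdir output directory (created if missing); `NULL` skips writing
#' @return object of class `run_report`: per-locus outcomes
#'   (`full_precursor`, `partial`, `mature_only`, `none`), stage counts and
#'   output paths
#' @export
run_pipeline <- function(genome, queries, references = NULL,
                         config = default_config(), outdir = NULL) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- read_fasta(genome, "dna")
  if (is.character(queries) && length(queries) == 1 && file.exists(queries))
    queries <- read_fasta(queries, "protein")
  genome <- as_dna_vector(genome)
  queries <- as_protein_vector(queries)
  if (methods::is(references, "reference_annotation"))
    references <- list(references)

  hits <- search_contigs(queries, genome, config)
  models <- if (nrow(hits)) build_gene_models(hits, genome, queries, config)
    else list()
  ok <- vapply(models, function(m) m$status == "ok", logical(1))

  precursors <- character(0)
  outcomes <- list()
  features <- list()
  segments_rows <- list()
  for (k in seq_along(models)) {
    m <- models[[k]]
    if (!ok[k]) {
      outcomes[[k]] <- locus_row(m, "none", FALSE)
      next
    }
    prec <- model_to_precursor(m)
    precursors[names(prec)] <- unname(prec)
    # reciprocal confirmation: the precursor must re-locate its own locus
    re_hits <- search_contigs(stats::setNames(unname(prec), "reciprocal"),
                              genome, config)
    reciprocal_ok <- nrow(re_hits) > 0 &&
      re_hits$contig_id[1] == m$contig_id &&
      re_hits$send[1] > min(m$exons[, 1]) &&
      re_hits$sstart[1] < max(m$exons[, 2])

    ref <- reference_for(references, m$query_id)
    outcome <- if (m$complete) "full_precursor" else "partial"
    if (!is.null(ref)) {
      ann <- tryCatch(transfer_segments(prec, ref, config),
                      error = function(e) NULL)
      if (!is.null(ann)) {
        segs <- ann$segments
        segs$id <- names(prec)
        segments_rows[[length(segments_rows) + 1]] <- segs
        if (!m$complete && nrow(ann$mature) &&
            all(nchar(ann$mature$seq) > 0))
          outcome <- "mature_only"
        for (r in seq_len(nrow(segs)))
          features[[length(features) + 1]] <- peptide_features(
            substr(ann$seq, segs$start[r] + 1L, segs$end[r]),
            id = names(prec), role = segs$role[r],
            amidated = segs$role[r] == "mature" &&
              any(ann$mature$start == segs$start[r] & ann$mature$amidated))
      }
    }
    outcomes[[k]] <- locus_row(m, outcome, reciprocal_ok)
  }

  report <- if (length(outcomes)) do.call(rbind, outcomes) else
    data.frame(query_id = character(0), contig_id = character(0),
               strand = character(0), score = numeric(0),
               outcome = character(0), reciprocal_ok = logical(0),
               stringsAsFactors = FALSE)

  paths <- list()
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths$hits <- file.path(outdir, "hits.tsv")
    write.table(hits, paths$hits, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths$models <- file.path(outdir, "models.gff3")
    write_gff3(models, Biostrings::DNAStringSet(genome), paths$models)
    if (length(precursors)) {
      paths$precursors <- file.path(outdir, "precursors.faa")
      write_fasta(precursors, paths$precursors)
    }
    if (length(segments_rows)) {
      paths$segments <- file.path(outdir, "segments.tsv")
      segdf <- do.call(rbind, segments_rows)
      write.table(segdf, paths$segments, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    paths$features <- file.path(outdir, "features.tsv")
    write_feature_table(if (length(features)) do.call(rbind, features)
                        else NULL, paths$features)
    paths$report <- file.path(outdir, "report.tsv")
    write.table(report, paths$report, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths$manifest <- file.path(outdir, "manifest.json")
    write_manifest(paths$manifest,
                   inputs = list(n_contigs = length(genome),
                                 n_queries = length(queries)),
                   config = config, seed = config$seed)
  }

  structure(list(report = report,
                 counts = c(hits = nrow(hits),
                            models = sum(ok),
                            precursors = length(precursors)),
                 models = models, hits = hits, precursors = precursors,
                 paths = paths),
            class = "run_report")
}

locus_row <- function(model, outcome, reciprocal_ok) {
  data.frame(query_id = model$query_id, contig_id = model$contig_id,
             strand = model$strand,
             score = if (!is.null(attr(model, "hit_score")))
               attr(model, "hit_score") else model$score,
             outcome = outcome,
             reciprocal_ok = reciprocal_ok, stringsAsFactors = FALSE)
}

reference_for <- function(references, query_id) {
  if (is.null(references)) return(NULL)
  if (!is.null(references[[query_id]])) return(references[[query_id]])
  if (is.null(names(references)) && length(references) >= 1)
    return(references[[1]])
  NULL
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report:", x$counts["hits"], "hit(s),", x$counts["models"],
      "model(s),", x$counts["precursors"], "precursor(s)\n")
  if (nrow(x$report)) print(x$report)
  invisible(x)
}
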