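#' Extend a translated-search hit to a single-exon ORF candidate
#'
#' Walks the hit's reading frame 5' to the nearest in-frame ATG (stopping
#' unsuccessfully at an in-frame stop codon) and 3' to the first in-frame
#' stop. When no start codon is found before a stop (or the frame runs off
#' the contig edge), the candidate is flagged partial and the hit boundary
#' is used instead.
#'
#' @param hit one row of the data.frame returned by [search_contigs()]
#' @param contig the contig sequence (character or `DNAString`)
#' @return list with `contig_id`, `strand`, `frame`, `interval` (forward-
#'   strand 0-based half-open DNA interval, including the stop codon when
#'   found), `protein` (translation, stop excluded) and `partial`
#' @export
identify_orf <- function(hit, contig) {
  contig <- toupper(as.character(contig))
  L <- nchar(contig)
  frame <- hit$frame
  w <- if (frame > 0) contig else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(contig)))
  off <- abs(frame) - 1L
  n_cod <- (L - off) %/% 3L
  pep <- strsplit(as.character(Biostrings::translate(
    Biostrings::subseq(Biostrings::DNAString(w), start = off + 1L,
                       width = 3L * n_cod), if.fuzzy.codon = "X")),
    "")[[1]]
  p1 <- hit$fpstart        # 0-based first hit residue
  p2 <- hit$fpend - 1L     # 0-based last hit residue

  partial5 <- FALSE
  start_res <- p1
  p <- p1
  found <- FALSE
  while (p >= 0) {
    if (pep[p + 1] == "*" && p < p1) break
    if (pep[p + 1] == "M") { start_res <- p; found <- TRUE; break }
    p <- p - 1L
  }
  if (!found) { partial5 <- TRUE; start_res <- p1 }

  partial3 <- FALSE
  end_res <- p2            # last coding residue (stop excluded)
  stop_at <- NA_integer_
  p <- p2 + 1L
  while (p < n_cod) {
    if (pep[p + 1] == "*") { stop_at <- p; break }
    p <- p + 1L
  }
  if (is.na(stop_at)) {
    partial3 <- TRUE
    end_res <- n_cod - 1L
  } else {
    end_res <- stop_at - 1L
  }

  protein <- paste(pep[(start_res + 1):(end_res + 1)], collapse = "")
  # frame-peptide residue span including the stop codon when present
  span_end <- if (is.na(stop_at)) end_res + 1L else stop_at + 1L
  wa <- off + 3L * start_res
  wb <- off + 3L * span_end
  interval <- if (frame > 0) c(wa, wb) else c(L - wb, L - wa)
  list(contig_id = hit$contig_id, strand = hit$strand, frame = frame,
       interval = interval, protein = protein,
       partial = partial5 || partial3,
       partial5 = partial5, partial3 = partial3)
}

#' Spliced alignment of a query protein to genomic DNA
#'
#' The GeneWise analogue: dynamic programming over (query residue, DNA
#' position) with codon-match states, affine protein gaps and intron states
#' in all three codon phases. Introns must start with the canonical donor GT,
#' end with the acceptor AG, and have a length inside
#' `[config$intron_min, config$intron_max]`; each intron costs a flat
#' `config$intron_open` penalty. The alignment is local in both query and
#' DNA. Score = sum of BLOSUM62 codon-match scores minus affine protein gap
#' costs minus the intron penalties.
#'
#' @param query query protein (character)
#' @param region DNA region to align against, forward-strand sequence
#' @param config a `run_config`
#' @param region_offset forward-strand position of `region`'s first base in
#'   its contig (0-based); exon coordinates are reported in contig space
#' @param strand `"+"` or `"-"`; for `"-"` the reverse complement of
#'   `region` is aligned and coordinates are mirrored back
#' @param contig_id,query_id ids carried into the model
#' @return object of class `gene_model`: `exons` (forward-strand 0-based
#'   half-open intervals, in transcription order), `introns` (data.frame
#'   with donor/acceptor dinucleotides and lengths), `translation` (spliced
#'   CDS translation), `score`, `qstart`/`qend` (query residues covered),
#'   `complete` (covers the full query), and `status` (`"ok"` or
#'   `"no_prediction"` when no positive-scoring model exists)
#' @export
spliced_align <- function(query, region, config = default_config(),
                          region_offset = 0L, strand = "+",
                          contig_id = "contig", query_id = "query") {
  if (!nzchar(query)) stop("query must be non-empty")
  region <- toupper(as.character(region))
  if (nchar(region) < 3) stop("region must be at least one codon long")
  mat <- config$matrix
  work <- if (strand == "+") region else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(region)))
  r <- .spliced_align_cpp(encode_protein(query, mat), encode_dna(work), mat,
                          codon_lookup(mat),
                          as.integer(config$gap_open),
                          as.integer(config$gap_ext),
                          as.integer(config$intron_open),
                          as.integer(config$intron_min),
                          as.integer(config$intron_max))
  if (r$score <= 0) {
    return(structure(list(contig_id = contig_id, query_id = query_id,
                          strand = strand, exons = NULL, introns = NULL,
                          translation = "", score = 0, qstart = 0L,
                          qend = 0L, complete = FALSE,
                          status = "no_prediction"),
                     class = "gene_model"))
  }
  Lr <- nchar(work)
  ex_work <- cbind(r$exon_start, r$exon_end)   # work-strand coords, 5'->3'
  # splice on the working (coding) strand, then translate
  cds <- paste(vapply(seq_len(nrow(ex_work)), function(k)
    substr(work, ex_work[k, 1] + 1L, ex_work[k, 2]), character(1)),
    collapse = "")
  translation <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds), if.fuzzy.codon = "X"))
  introns <- NULL
  if (nrow(ex_work) > 1) {
    istart <- ex_work[-nrow(ex_work), 2]
    iend <- ex_work[-1, 1]
    introns <- data.frame(
      donor = substr(rep(work, length(istart)), istart + 1L, istart + 2L),
      acceptor = substr(rep(work, length(istart)), iend - 1L, iend),
      length = iend - istart, stringsAsFactors = FALSE)
  }
  # map exons back to forward-strand contig coordinates
  if (strand == "+") {
    exons <- ex_work + region_offset
  } else {
    exons <- cbind(Lr - ex_work[, 2], Lr - ex_work[, 1]) + region_offset
  }
  colnames(exons) <- c("start", "end")
  structure(list(contig_id = contig_id, query_id = query_id, strand = strand,
                 exons = exons, introns = introns,
                 translation = translation, score = r$score,
                 qstart = r$qstart, qend = r$qend,
                 complete = r$qstart == 0L && r$qend == nchar(query),
                 status = "ok"),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model:", x$query_id, "on", x$contig_id, x$strand, "\n")
  if (x$status != "ok") { cat("  no prediction\n"); return(invisible(x)) }
  cat("  score", x$score, "|", nrow(x$exons), "exon(s)",
      if (!is.null(x$introns)) paste0("| intron length(s) ",
                                      paste(x$introns$length, collapse = ",")),
      "\n")
  cat("  translation:", x$translation, "\n")
  invisible(x)
}

#' Extract the precursor protein from a gene model
#'
#' @param model a `gene_model`
#' @return named character vector of length 1 (name `contigid_queryid`) with
#'   attribute `partial` set when the model does not cover the full query
#' @export
model_to_precursor <- function(model) {
  if (model$status != "ok" || !nzchar(model$translation))
    stop("model has no prediction; cannot extract a precursor")
  out <- stats::setNames(model$translation,
                         paste(model$contig_id, model$query_id, sep = "_"))
  attr(out, "partial") <- !model$complete
  out
}

#' Build gene models for a table of hits
#'
#' Hits are grouped by (query, contig, strand) — the exons of one gene
#' surface as separate non-overlapping hits — and the spliced aligner runs
#' on the union span of each group padded by the maximum intron length on
#' both sides (capped at the contig bounds).
#'
#' @param hits data.frame from [search_contigs()]
#' @param contigs named character vector or `DNAStringSet`
#' @param queries named character vector or `AAStringSet`
#' @param config a `run_config`
#' @return list of `gene_model` objects, one per (query, contig, strand)
#'   group, in order of each group's best hit; each model carries the group's
#'   best hit score as attribute `hit_score`
#' @export
build_gene_models <- function(hits, contigs, queries,
                              config = default_config()) {
  contigs <- as_dna_vector(contigs)
  queries <- as_protein_vector(queries)
  if (nrow(hits) == 0) return(list())
  key <- paste(hits$query_id, hits$contig_id, hits$strand, sep = "\r")
  groups <- split(seq_len(nrow(hits)), key)
  # keep the order of each group's best (first, since hits are score-sorted)
  groups <- groups[order(vapply(groups, min, integer(1)))]
  lapply(groups, function(idx) {
    h <- hits[idx, , drop = FALSE]
    L <- nchar(contigs[[h$contig_id[1]]])
    a <- max(0L, min(h$sstart) - config$intron_max)
    b <- min(L, max(h$send) + config$intron_max)
    region <- substr(contigs[[h$contig_id[1]]], a + 1L, b)
    m <- spliced_align(queries[[h$query_id[1]]], region, config,
                       region_offset = a, strand = h$strand[1],
                       contig_id = h$contig_id[1], query_id = h$query_id[1])
    attr(m, "hit_score") <- max(h$score)
    m
  })
}
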