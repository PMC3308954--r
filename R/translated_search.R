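#' Six-frame translation of a contig
#'
#' Translates a DNA contig in all six reading frames. Frames +1..+3 read the
#' forward strand at offsets 0..2; frames -1..-3 read the reverse complement
#' at the same offsets. Codons containing N translate to X; stop codons are
#' emitted as `*` (frames are deliberately not split at stops, so the
#' coordinate map stays intact).
#'
#' @param seq contig sequence (character or `DNAString`)
#' @param id contig id carried into the result
#' @return list of six `frame_peptide` records, each with fields `contig_id`,
#'   `frame` (+1,+2,+3,-1,-2,-3), `peptide` and `contig_len`; residue i of a
#'   frame maps to the forward-strand codon interval given by
#'   [codon_interval()]
#' @export
six_frame_translate <- function(seq, id = "contig") {
  seq <- toupper(as.character(seq))
  L <- nchar(seq)
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  if (L < 3) {
    warning("contig ", id, " shorter than one codon; empty frames")
    return(lapply(frames, function(f)
      structure(list(contig_id = id, frame = f, peptide = "",
                     contig_len = L), class = "frame_peptide")))
  }
  fwd <- Biostrings::DNAString(seq)
  rev <- Biostrings::reverseComplement(fwd)
  lapply(frames, function(f) {
    src <- if (f > 0) fwd else rev
    off <- abs(f) - 1L
    n_cod <- (L - off) %/% 3L
    pep <- if (n_cod == 0) "" else as.character(Biostrings::translate(
      Biostrings::subseq(src, start = off + 1L, width = 3L * n_cod),
      if.fuzzy.codon = "X"))
    structure(list(contig_id = id, frame = f, peptide = pep, contig_len = L),
              class = "frame_peptide")
  })
}

#' Forward-strand codon interval of a frame-peptide residue
#'
#' @param frame one of +1,+2,+3,-1,-2,-3
#' @param contig_len contig length in bases
#' @param i residue index within the frame peptide (1-based)
#' @return length-2 integer vector, the 0-based half-open DNA interval of the
#'   codon on the forward strand (width 3 always)
#' @export
codon_interval <- function(frame, contig_len, i) {
  off <- abs(frame) - 1L
  if (frame > 0) {
    s <- off + 3L * (i - 1L)
    c(s, s + 3L)
  } else {
    # position in the reverse complement, mirrored back
    s_rc <- off + 3L * (i - 1L)
    c(contig_len - (s_rc + 3L), contig_len - s_rc)
  }
}

#' Exact local alignment of two protein sequences
#'
#' Smith-Waterman with affine gaps (a gap of length k costs
#' `gap_open + k * gap_ext`). The optimum may be empty (score 0, no hit)
#' when every alignment scores negatively. Ties are broken deterministically:
#' lowest subject start, then lowest query start, then shortest alignment.
#'
#' @param query,subject amino-acid strings
#' @param matrix substitution matrix (default [default_matrix()])
#' @param gap_open,gap_ext affine gap penalties (protein BLAST defaults 11/1)
#' @return list with `score`, `qstart`/`qend` and `sstart`/`send` (0-based
#'   half-open residue intervals), aligned strings `qaln`/`saln`, and
#'   `pident` (percent identity over all alignment columns, gaps included)
#' @export
local_align <- function(query, subject, matrix = NULL,
                        gap_open = 11L, gap_ext = 1L) {
  if (!nzchar(query) || !nzchar(subject))
    stop("query and subject must be non-empty")
  if (is.null(matrix)) matrix <- default_matrix()
  q <- encode_protein(query, matrix)
  s <- encode_protein(subject, matrix)
  r <- .sw_local_cpp(q, s, matrix, as.integer(gap_open), as.integer(gap_ext))
  if (r$score <= 0)
    return(list(score = 0L, qstart = 0L, qend = 0L, sstart = 0L, send = 0L,
                qaln = "", saln = "", pident = NA_real_))
  aln <- apply_moves(query, subject, r$qstart, r$sstart, r$qmoves, r$smoves)
  ident <- sum(strsplit(aln$qaln, "")[[1]] == strsplit(aln$saln, "")[[1]] &
                 strsplit(aln$qaln, "")[[1]] != "-")
  list(score = r$score, qstart = r$qstart, qend = r$qend,
       sstart = r$sstart, send = r$send,
       qaln = aln$qaln, saln = aln$saln,
       pident = 100 * ident / nchar(aln$qaln))
}

# Expand the move templates returned by the C++ aligners into aligned strings.
apply_moves <- function(query, subject, q0, s0, qmoves, smoves) {
  qm <- strsplit(qmoves, "")[[1]]
  qc <- strsplit(query, "")[[1]]
  sc <- strsplit(subject, "")[[1]]
  qa <- character(length(qm)); sa <- character(length(qm))
  qi <- q0; si <- s0
  for (k in seq_along(qm)) {
    if (qm[k] == "M") {
      qi <- qi + 1L; si <- si + 1L
      qa[k] <- qc[qi]; sa[k] <- sc[si]
    } else if (qm[k] == "-") {      # gap in query, subject consumed
      si <- si + 1L
      qa[k] <- "-"; sa[k] <- sc[si]
    } else {                         # gap in subject, query consumed
      qi <- qi + 1L
      qa[k] <- qc[qi]; sa[k] <- "-"
    }
  }
  list(qaln = paste(qa, collapse = ""), saln = paste(sa, collapse = ""))
}

#' Translated search of protein queries against contigs
#'
#' The tBLASTn analogue: every contig is translated in six frames and each
#' query is locally aligned against every frame. Hits at or above
#' `config$min_score` are mapped back to forward-strand DNA coordinates via
#' the frame coordinate map. Overlapping hits of the same
#' (query, contig, strand) whose DNA intervals overlap at least 50% of the
#' shorter are merged, keeping the higher-scoring one (a deterministic stand-
#' in for manual curation of redundant hits).
#'
#' @param queries named character vector or `AAStringSet` of query proteins
#' @param contigs named character vector or `DNAStringSet` of contigs
#' @param config a `run_config` (see [default_config()])
#' @return data.frame of hits sorted by descending score with columns
#'   `query_id`, `contig_id`, `frame`, `strand`, `score`, `pident`,
#'   `qstart`, `qend` (query residues, 0-based half-open), `sstart`, `send`
#'   (forward-strand DNA, 0-based half-open), `fpstart`, `fpend`
#'   (frame-peptide residues), `qaln`, `saln`
#' @export
search_contigs <- function(queries, contigs, config = default_config()) {
  queries <- as_protein_vector(queries)
  contigs <- as_dna_vector(contigs)
  mat <- config$matrix
  rows <- list()
  for (cid in names(contigs)) {
    L <- nchar(contigs[[cid]])
    if (L < 3) next
    frames <- six_frame_translate(contigs[[cid]], cid)
    for (fp in frames) {
      if (!nzchar(fp$peptide)) next
      for (qid in names(queries)) {
        hit <- local_align(queries[[qid]], fp$peptide, mat,
                           config$gap_open, config$gap_ext)
        if (hit$score < config$min_score) next
        dna <- frame_to_dna(fp$frame, L, hit$sstart, hit$send)
        rows[[length(rows) + 1]] <- data.frame(
          query_id = qid, contig_id = cid, frame = fp$frame,
          strand = if (fp$frame > 0) "+" else "-",
          score = hit$score, pident = hit$pident,
          qstart = hit$qstart, qend = hit$qend,
          sstart = dna[1], send = dna[2],
          fpstart = hit$sstart, fpend = hit$send,
          qaln = hit$qaln, saln = hit$saln,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(empty_hits())
  hits <- do.call(rbind, rows)
  hits <- merge_overlapping_hits(hits)
  hits <- hits[order(-hits$score, hits$contig_id, hits$sstart), ]
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(query_id = character(0), contig_id = character(0),
             frame = integer(0), strand = character(0), score = integer(0),
             pident = numeric(0), qstart = integer(0), qend = integer(0),
             sstart = integer(0), send = integer(0), fpstart = integer(0),
             fpend = integer(0), qaln = character(0), saln = character(0),
             stringsAsFactors = FALSE)
}

# Forward-strand DNA interval covered by frame-peptide residues [a,b)
frame_to_dna <- function(frame, contig_len, a, b) {
  off <- abs(frame) - 1L
  if (frame > 0) {
    c(off + 3L * a, off + 3L * b)
  } else {
    c(contig_len - (off + 3L * b), contig_len - (off + 3L * a))
  }
}

# Collapse hits of the same (query, contig, strand) whose DNA intervals
# overlap >= 50% of the shorter interval; the higher score wins.
merge_overlapping_hits <- function(hits) {
  keep <- rep(TRUE, nrow(hits))
  ord <- order(-hits$score)
  for (a_i in seq_along(ord)) {
    i <- ord[a_i]
    if (!keep[i]) next
    for (b_i in seq_along(ord)) {
      if (b_i <= a_i) next
      j <- ord[b_i]
      if (!keep[j]) next
      if (hits$query_id[i] != hits$query_id[j] ||
          hits$contig_id[i] != hits$contig_id[j] ||
          hits$strand[i] != hits$strand[j]) next
      ov <- min(hits$send[i], hits$send[j]) - max(hits$sstart[i], hits$sstart[j])
      shorter <- min(hits$send[i] - hits$sstart[i],
                     hits$send[j] - hits$sstart[j])
      if (ov > 0 && shorter > 0 && ov >= 0.5 * shorter) keep[j] <- FALSE
    }
  }
  hits[keep, , drop = FALSE]
}

as_dna_vector <- function(x) {
  if (methods::is(x, "XStringSet")) x <- as.character(x)
  if (!is.character(x) || is.null(names(x)))
    stop("expected a named character vector or DNAStringSet of contigs")
  x
}
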