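#' Global alignment of two protein sequences
#'
#' Needleman-Wunsch with affine gaps; end gaps are penalised (no free end
#' gaps). Ties prefer the diagonal move.
#'
#' @param a,b amino-acid strings
#' @inheritParams local_align
#' @return list with `score`, aligned strings `aaln`/`baln` and `pident`
#'   (percent identity over all alignment columns)
#' @export
global_align <- function(a, b, matrix = NULL, gap_open = 11L, gap_ext = 1L) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  if (is.null(matrix)) matrix <- default_matrix()
  r <- .nw_global_cpp(encode_protein(a, matrix), encode_protein(b, matrix),
                      matrix, as.integer(gap_open), as.integer(gap_ext))
  aln <- apply_moves(a, b, 0L, 0L, r$qmoves, r$smoves)
  ac <- strsplit(aln$qaln, "")[[1]]
  bc <- strsplit(aln$saln, "")[[1]]
  ident <- sum(ac == bc & ac != "-")
  list(score = r$score, aaln = aln$qaln, baln = aln$saln,
       pident = 100 * ident / length(ac))
}

#' Transfer reference segment boundaries onto a target precursor
#'
#' Globally aligns the target against an annotated reference and maps every
#' segment boundary through the alignment (homology transfer, the classical
#' way signal/pro/mature boundaries are assigned when no experimental data
#' exist). A boundary landing in a target gap is moved to the nearest
#' following target position and flagged `gap-adjusted`; boundaries that map
#' through aligned columns are flagged `aligned`.
#'
#' @param target target precursor (character, or named length-1 vector)
#' @param ref a `reference_annotation` (see [reference_annotation()])
#' @param config a `run_config`; `min_transfer_identity` is the percent-
#'   identity floor below which the transfer is refused as non-homologous
#' @return object of class `precursor_annotation` with the target sequence,
#'   transferred `segments` (role, start, end, confidence) and `mature`
#'   peptides (see [split_multipeptide_precursor()])
#' @export
transfer_segments <- function(target, ref, config = default_config()) {
  id <- if (!is.null(names(target))) names(target)[1] else "target"
  target <- unname(as.character(target)[1])
  aln <- global_align(target, ref$seq, config$matrix,
                      config$gap_open, config$gap_ext)
  if (aln$pident < config$min_transfer_identity)
    stop("alignment identity ", round(aln$pident, 1),
         "% below the homology floor (", config$min_transfer_identity,
         "%); annotation refused")
  map <- boundary_map(aln$aaln, aln$baln)
  n <- nchar(target)
  segs <- ref$segments
  out <- data.frame(role = segs$role,
                    start = integer(nrow(segs)), end = integer(nrow(segs)),
                    start_conf = character(nrow(segs)),
                    end_conf = character(nrow(segs)),
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(segs))) {
    s <- map_ref_boundary(map, segs$start[k], n)
    e <- map_ref_boundary(map, segs$end[k], n)
    out$start[k] <- s$pos; out$start_conf[k] <- s$conf
    out$end[k] <- e$pos; out$end_conf[k] <- e$conf
  }
  # enforce monotone, non-overlapping transferred segments
  out <- out[out$end > out$start, , drop = FALSE]
  ann <- structure(list(id = id, seq = target, segments = out,
                        identity = aln$pident, mature = NULL),
                   class = "precursor_annotation")
  ann$mature <- split_multipeptide_precursor(ann, ref, config)
  ann
}

# For each reference position r (0..nchar(ref)) the corresponding target
# position; positions inside target gaps get the next target position and
# are marked adjusted.
boundary_map <- function(target_aln, ref_aln) {
  tc <- strsplit(target_aln, "")[[1]]
  rc <- strsplit(ref_aln, "")[[1]]
  n_ref <- sum(rc != "-")
  # starts[r+1] = target position of the column holding ref residue r; when
  # the target has a gap there this is the next target position (flagged)
  starts <- integer(n_ref + 1L)
  starts_adj <- logical(n_ref + 1L)
  ti <- 0L; ri <- 0L
  for (k in seq_along(tc)) {
    if (rc[k] != "-") {
      starts[ri + 1L] <- ti
      starts_adj[ri + 1L] <- tc[k] == "-"
      ri <- ri + 1L
    }
    if (tc[k] != "-") ti <- ti + 1L
  }
  starts[n_ref + 1L] <- sum(tc != "-")
  starts_adj[n_ref + 1L] <- FALSE
  list(starts = starts, adjusted = starts_adj, n_ref = n_ref)
}

map_ref_boundary <- function(map, r, n_target) {
  r <- min(r, map$n_ref)
  pos <- min(map$starts[r + 1L], n_target)
  list(pos = pos,
       conf = if (map$adjusted[r + 1L]) "gap-adjusted" else "aligned")
}

#' Find dibasic cleavage sites and glycine amidation signals
#'
#' Scans a precursor for the prohormone-convertase dibasic motifs (KR, RR,
#' KK by default) and for G\[R/K\]\[R/K\] amidation signals. A
#' G\[R/K\]\[R/K\] occurrence marks the residue immediately before the Gly
#' as an amide donor boundary: the Gly is consumed to amidate the mature
#' peptide's C-terminus.
#'
#' @param precursor amino-acid string
#' @param cleavage_motifs,amidation_motifs motif sets (defaults as in
#'   [default_config()])
#' @return data.frame with `position` (0-based start of the motif), `motif`,
#'   and `type` (`"cleavage"` or `"amidation"`); for amidation rows
#'   `boundary` holds the 0-based position just after the amidated residue
#'   (i.e. the Gly position)
#' @export
find_cleavage_and_amidation <- function(precursor,
                                        cleavage_motifs = c("KR", "RR", "KK"),
                                        amidation_motifs = c("GRK", "GKR")) {
  rows <- list()
  for (m in cleavage_motifs) {
    hits <- find_all(precursor, m)
    for (p in hits)
      rows[[length(rows) + 1]] <- data.frame(
        position = p, motif = m, type = "cleavage", boundary = p,
        stringsAsFactors = FALSE)
  }
  for (m in amidation_motifs) {
    hits <- find_all(precursor, m)
    for (p in hits)
      rows[[length(rows) + 1]] <- data.frame(
        position = p, motif = m, type = "amidation", boundary = p,
        stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(position = integer(0), motif = character(0),
                      type = character(0), boundary = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$position), , drop = FALSE]
}

# all (overlapping) 0-based start positions of fixed motif `m` in `s`
find_all <- function(s, m) {
  out <- integer(0)
  from <- 1L
  repeat {
    p <- regexpr(m, substr(s, from, nchar(s)), fixed = TRUE)
    if (p == -1L) break
    out <- c(out, from + p - 2L)
    from <- from + p
  }
  out
}

#' Extract mature peptides from a transferred annotation
#'
#' One mature peptide per transferred `mature` segment. When a dibasic
#' cleavage or amidation motif lies within `config$motif_window` residues of
#' a transferred boundary, the motif evidence overrides the transferred
#' position (logged via a message): an N-flanking dibasic site moves the
#' start to just after the motif, a C-flanking dibasic/amidation motif moves
#' the end to just before it. A peptide is flagged amidated when a
#' G\[R/K\]\[R/K\] signal immediately follows its C-terminus.
#'
#' @param ann a `precursor_annotation`
#' @param ref the `reference_annotation` the segments came from
#' @param config a `run_config`
#' @return data.frame with `seq`, `start`, `end` (0-based half-open),
#'   `amidated`, `n_motif`, `c_motif`
#' @export
split_multipeptide_precursor <- function(ann, ref, config = default_config()) {
  segs <- ann$segments[ann$segments$role == "mature", , drop = FALSE]
  if (nrow(segs) == 0)
    return(data.frame(seq = character(0), start = integer(0),
                      end = integer(0), amidated = logical(0),
                      n_motif = character(0), c_motif = character(0),
                      stringsAsFactors = FALSE))
  motifs <- find_cleavage_and_amidation(ann$seq, config$cleavage_motifs,
                                        config$amidation_motifs)
  n <- nchar(ann$seq)
  w <- config$motif_window
  out <- lapply(seq_len(nrow(segs)), function(k) {
    s <- segs$start[k]; e <- segs$end[k]
    n_motif <- NA_character_; c_motif <- NA_character_
    # N flank: a cleavage motif ending at s' with |s' - s| <= w
    cand <- motifs[motifs$type == "cleavage", , drop = FALSE]
    if (nrow(cand)) {
      ends <- cand$position + nchar(cand$motif)
      ok <- abs(ends - s) <= w
      if (any(ok)) {
        j <- which(ok)[which.min(abs(ends[ok] - s))]
        if (ends[j] != s)
          message("mature start moved by motif evidence: ", s, " -> ",
                  ends[j], " (", cand$motif[j], ")")
        s <- ends[j]
        n_motif <- cand$motif[j]
      }
    }
    # C flank: a cleavage or amidation motif starting at e' with |e'-e| <= w
    if (nrow(motifs)) {
      ok <- abs(motifs$position - e) <= w & motifs$position > s
      if (any(ok)) {
        j <- which(ok)[which.min(abs(motifs$position[ok] - e))]
        if (motifs$position[j] != e)
          message("mature end moved by motif evidence: ", e, " -> ",
                  motifs$position[j], " (", motifs$motif[j], ")")
        e <- motifs$position[j]
        c_motif <- motifs$motif[j]
      }
    }
    amid <- FALSE
    if (e < n && substr(ann$seq, e + 1L, e + 1L) == "G") {
      tail3 <- substr(ann$seq, e + 1L, e + 3L)
      amid <- grepl("^G[RK][RK]", tail3) ||
        (e + 1L == n)  # precursor ends on the donor Gly itself
    }
    data.frame(seq = substr(ann$seq, s + 1L, e),
               start = s, end = e, amidated = amid,
               n_motif = n_motif, c_motif = c_motif,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.precursor_annotation <- function(x, ...) {
  cat("precursor_annotation:", x$id, "(", nchar(x$seq), "aa,",
      round(x$identity, 1), "% identity to reference )\n")
  print(x$segments)
  if (!is.null(x$mature) && nrow(x$mature)) {
    cat("mature peptides:\n")
    print(x$mature[, c("seq", "start", "end", "amidated")])
  }
  invisible(x)
}
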