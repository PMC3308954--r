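#' Progressive multiple sequence alignment
#'
#' ClustalW-style progressive alignment: pairwise distances from k-mer
#' (k = 3) cosine dissimilarity, a UPGMA guide tree (average-linkage
#' clustering), then profile-profile global alignment with affine gaps at
#' each internal node. Deterministic for a fixed input order; no random
#' component.
#'
#' @param seqs named character vector or `AAStringSet` (>= 1 sequence; a
#'   single sequence is passed through unchanged)
#' @param matrix substitution matrix (default [default_matrix()])
#' @param gap_open,gap_ext affine gap penalties; the default opening cost is
#'   stiffer than the pairwise-search default because profile alignment of
#'   divergent protein families accumulates spurious gaps under search-grade
#'   costs (the classical progressive aligners raise protein gap penalties
#'   for the same reason)
#' @return object of class `msa`: `ids`, `aln` (named character vector of
#'   equal-length gapped rows), `ncol`, and `sum_of_pairs` score
#' @export
progressive_align <- function(seqs, matrix = NULL,
                              gap_open = 15L, gap_ext = 1L) {
  seqs <- as_protein_vector(seqs)
  if (is.null(matrix)) matrix <- default_matrix()
  ids <- names(seqs)
  if (length(seqs) == 1) {
    out <- structure(list(ids = ids, aln = seqs, ncol = nchar(seqs[[1]]),
                          sum_of_pairs = 0), class = "msa")
    return(out)
  }
  D <- kmer_distance(seqs, k = 3L)
  tree <- stats::hclust(stats::as.dist(D), method = "average")  # UPGMA
  # alignments per node; leaves are single rows
  node_aln <- list()
  for (step in seq_len(nrow(tree$merge))) {
    pick <- function(idx) {
      if (idx < 0) stats::setNames(seqs[[-idx]], ids[[-idx]])
      else node_aln[[idx]]
    }
    a1 <- pick(tree$merge[step, 1])
    a2 <- pick(tree$merge[step, 2])
    node_aln[[step]] <- merge_alignments(a1, a2, matrix, gap_open, gap_ext)
  }
  aln <- node_aln[[nrow(tree$merge)]]
  aln <- aln[ids[ids %in% names(aln)]]  # restore input order
  out <- structure(list(ids = names(aln), aln = aln,
                        ncol = nchar(aln[[1]]),
                        sum_of_pairs = NA_real_), class = "msa")
  out$sum_of_pairs <- sum_of_pairs(out, matrix, gap_open, gap_ext)
  out
}

# cosine dissimilarity on k-mer count vectors (k shrinks for short inputs)
kmer_distance <- function(seqs, k = 3L) {
  k <- max(1L, min(k, min(nchar(seqs))))
  counts <- lapply(seqs, function(s) {
    n <- nchar(s)
    kmers <- substring(s, 1:(n - k + 1), k:n)
    table(kmers)
  })
  m <- length(seqs)
  D <- matrix(0, m, m, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    u <- counts[[i]]; v <- counts[[j]]
    shared <- intersect(names(u), names(v))
    dot <- sum(as.numeric(u[shared]) * as.numeric(v[shared]))
    den <- sqrt(sum(as.numeric(u)^2)) * sqrt(sum(as.numeric(v)^2))
    D[i, j] <- D[j, i] <- 1 - (if (den > 0) dot / den else 0)
  }
  D
}

# column count profile of an alignment: rows = matrix alphabet + gap
alignment_profile <- function(aln, matrix) {
  A <- nrow(matrix)
  nc <- nchar(aln[[1]])
  prof <- matrix(0L, A + 1L, nc)
  for (s in aln) {
    ch <- strsplit(s, "")[[1]]
    idx <- match(ch, rownames(matrix))
    idx[ch == "-"] <- A + 1L
    for (j in seq_len(nc)) prof[idx[j], j] <- prof[idx[j], j] + 1L
  }
  prof
}

merge_alignments <- function(a1, a2, matrix, gap_open, gap_ext) {
  p1 <- alignment_profile(a1, matrix)
  p2 <- alignment_profile(a2, matrix)
  r <- .profile_align_cpp(p1, p2, matrix, gap_open, gap_ext)
  moves <- strsplit(r$moves, "")[[1]]
  expand <- function(aln, own) {
    vapply(aln, function(s) {
      ch <- strsplit(s, "")[[1]]
      out <- character(length(moves))
      i <- 0L
      for (k in seq_along(moves)) {
        if (moves[k] %in% own) { i <- i + 1L; out[k] <- ch[i] }
        else out[k] <- "-"
      }
      paste(out, collapse = "")
    }, character(1))
  }
  c(expand(a1, c("M", "Q")), expand(a2, c("M", "S")))
}

#' Sum-of-pairs score of a multiple alignment
#'
#' Sum over all row pairs of the induced pairwise alignment score
#' (substitution scores plus affine gap costs; columns where both rows have
#' gaps are dropped from the pair projection).
#'
#' @param msa an `msa` object
#' @param matrix substitution matrix
#' @param gap_open,gap_ext affine gap penalties
#' @return numeric score
#' @export
sum_of_pairs <- function(msa, matrix = NULL, gap_open = 11L, gap_ext = 1L) {
  if (is.null(matrix)) matrix <- default_matrix()
  rows <- lapply(msa$aln, function(s) strsplit(s, "")[[1]])
  m <- length(rows)
  total <- 0
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    a <- rows[[i]]; b <- rows[[j]]
    keep <- !(a == "-" & b == "-")
    a <- a[keep]; b <- b[keep]
    in_gap_a <- FALSE; in_gap_b <- FALSE
    for (k in seq_along(a)) {
      if (a[k] == "-") {
        total <- total - (if (in_gap_a) gap_ext else gap_open + gap_ext)
        in_gap_a <- TRUE; in_gap_b <- FALSE
      } else if (b[k] == "-") {
        total <- total - (if (in_gap_b) gap_ext else gap_open + gap_ext)
        in_gap_b <- TRUE; in_gap_a <- FALSE
      } else {
        total <- total + matrix[a[k], b[k]]
        in_gap_a <- FALSE; in_gap_b <- FALSE
      }
    }
  }
  total
}

#' Percent identity of two sequences
#'
#' 100 x identities / alignment columns (gaps included in the denominator,
#' the BLAST convention), under either a global (Needleman-Wunsch) or local
#' (Smith-Waterman) alignment.
#'
#' @param a,b amino-acid strings
#' @param mode `"global"` or `"local"`
#' @inheritParams local_align
#' @return numeric percentage in \[0, 100\] (`NA` for an empty local
#'   optimum)
#' @export
percent_identity <- function(a, b, mode = c("global", "local"),
                             matrix = NULL, gap_open = 11L, gap_ext = 1L) {
  mode <- match.arg(mode)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  if (mode == "global")
    global_align(a, b, matrix, gap_open, gap_ext)$pident
  else
    local_align(a, b, matrix, gap_open, gap_ext)$pident
}

#' Per-column information content of an alignment (sequence logo)
#'
#' Column frequencies are computed over the 20 standard residues, gaps (and
#' X/stop symbols) excluded from the denominator. Information content is
#' `log2(20) - H` with `H` the Shannon entropy of the column frequencies;
#' no small-sample correction is applied. Letter heights are
#' frequency x information, the quantities a sequence-logo rendering draws.
#'
#' @param msa an `msa` object (or any list with an `aln` character vector)
#' @return object of class `logo_matrix`: `freq` (20 x ncol), `info`
#'   (bits per column, in \[0, log2(20)\]), `heights` (20 x ncol),
#'   `all_gap` (logical flag per column)
#' @export
logo <- function(msa) {
  aln <- msa$aln
  if (length(aln) < 2) stop("logo requires an alignment of >= 2 rows")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  nc <- nchar(aln[[1]])
  rows <- lapply(aln, function(s) strsplit(s, "")[[1]])
  freq <- matrix(0, 20, nc, dimnames = list(aa, NULL))
  info <- numeric(nc)
  all_gap <- logical(nc)
  for (j in seq_len(nc)) {
    col <- vapply(rows, `[`, character(1), j)
    col <- col[col %in% aa]
    if (length(col) == 0) { all_gap[j] <- TRUE; info[j] <- 0; next }
    tab <- table(factor(col, levels = aa))
    f <- as.numeric(tab) / length(col)
    freq[, j] <- f
    nz <- f[f > 0]
    info[j] <- log2(20) + sum(nz * log2(nz))
  }
  structure(list(freq = freq, info = info, heights = sweep(freq, 2, info, `*`),
                 all_gap = all_gap), class = "logo_matrix")
}

#' Write a logo matrix as TSV
#' @param lg a `logo_matrix`
#' @param path output path
#' @export
write_logo <- function(lg, path) {
  df <- data.frame(column = seq_along(lg$info), info = lg$info,
                   all_gap = lg$all_gap, t(lg$freq), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map a residue position through a multiple alignment
#'
#' Finds the alignment column holding a given residue of one record and
#' reports, for every record, the residue index at that column (`NA` where
#' the record has a gap). Residue positions are 1-based, the convention used
#' when the field numbers mature-peptide positions.
#'
#' @param msa an `msa` object
#' @param record_id id of the source record
#' @param pos 1-based residue position within the source record
#' @return list with `column` (1-based alignment column) and `positions`
#'   (named integer vector, `NA` = gap)
#' @export
map_position <- function(msa, record_id, pos) {
  if (!record_id %in% names(msa$aln)) stop("unknown record: ", record_id)
  src <- strsplit(msa$aln[[record_id]], "")[[1]]
  res_idx <- cumsum(src != "-")
  col <- which(src != "-" & res_idx == pos)
  if (length(col) != 1) stop("position ", pos, " outside record ", record_id)
  out <- vapply(msa$aln, function(s) {
    ch <- strsplit(s, "")[[1]]
    if (ch[col] == "-") NA_integer_ else as.integer(sum(ch[1:col] != "-"))
  }, integer(1))
  list(column = col, positions = out)
}

#' Write an alignment as aligned FASTA
#' @param msa an `msa` object
#' @param path output path
#' @export
write_alignment <- function(msa, path) {
  write_fasta(msa$aln, path)
}

#' @export
print.msa <- function(x, ...) {
  cat("msa:", length(x$aln), "sequences x", x$ncol, "columns; SP score",
      round(x$sum_of_pairs, 1), "\n")
  for (id in names(x$aln)) cat(sprintf("  %-20s %s\n", id, x$aln[[id]]))
  invisible(x)
}
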