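#' Default protein scoring matrix
#'
#' Returns the BLOSUM62 substitution matrix with the stop symbol `*` scoring
#' -1000 against every residue. Translated frames are not split at stop
#' codons; instead the prohibitive stop score makes local alignments
#' terminate naturally at stops while preserving the frame coordinate map.
#'
#' @param stop_score score assigned to any pair involving `*` (default -1000)
#' @return integer matrix with identical row and column names
#' @export
default_matrix <- function(stop_score = -1000L) {
  mat <- get_blosum62()
  mat["*", ] <- stop_score
  mat[, "*"] <- stop_score
  mat
}

# BLOSUM62 as shipped with the package (standard NCBI table).
get_blosum62 <- function() {
  path <- system.file("extdata", "BLOSUM62.txt", package = "antmine")
  if (nzchar(path)) return(read_score_matrix(path))
  # fall back to Biostrings' copy (identical table) when called from source
  data("BLOSUM62", package = "Biostrings", envir = environment())
  m <- get("BLOSUM62", envir = environment())
  storage.mode(m) <- "integer"
  m
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the whitespace-separated matrix format used by BLAST (`#` comment
#' lines, a header row of single-letter codes, one labelled row per residue).
#'
#' @param path file path
#' @return integer matrix with row/column names
#' @export
read_score_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  lab <- vapply(rows, `[`, character(1), 1L)
  vals <- t(vapply(rows, function(r) as.integer(r[-1]), integer(length(header))))
  dimnames(vals) <- list(lab, header)
  if (!identical(rownames(vals), colnames(vals)))
    vals <- vals[, rownames(vals), drop = FALSE]
  vals
}

# Encode an amino-acid string as 0-based row indices into `mat`.
# Unknown residues are a hard error naming the offending character.
encode_protein <- function(seq, mat) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(chars, rownames(mat))
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stop("residue(s) not present in the scoring matrix: ",
         paste(bad, collapse = ", "))
  }
  idx - 1L
}

# Encode DNA as A=0 C=1 G=2 T=3, other=4 (N).
encode_dna <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(chars, c("A", "C", "G", "T"))
  idx[is.na(idx)] <- 5L
  idx - 1L
}

# 125-entry lookup: codon index b1*25+b2*5+b3 (bases A,C,G,T,N) -> 0-based
# row of `mat` for the translated residue; any N-containing codon maps to X.
codon_lookup <- function(mat) {
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T", "N")
  out <- integer(125)
  xrow <- match("X", rownames(mat)) - 1L
  for (b1 in 0:4) for (b2 in 0:4) for (b3 in 0:4) {
    cod <- paste0(bases[b1 + 1], bases[b2 + 1], bases[b3 + 1])
    aa <- if (grepl("N", cod)) "X" else unname(gc[cod])
    row <- match(aa, rownames(mat)) - 1L
    if (is.na(row)) row <- xrow
    out[b1 * 25 + b2 * 5 + b3 + 1] <- row
  }
  out
}
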