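# Shared fixtures and independent reference oracles for the test suite.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_peptide <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

random_dna_test <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                            replace = TRUE), collapse = "")

# Brute-force local alignment score via explicit enumeration of every gapped
# local alignment (compiled enumerator; no DP state sharing).
bf_local <- function(q, s, mat = default_matrix(),
                     gap_open = 11L, gap_ext = 1L) {
  antmine:::.bf_local_score_cpp(antmine:::encode_protein(q, mat),
                                antmine:::encode_protein(s, mat),
                                mat, gap_open, gap_ext)
}

bf_global <- function(q, s, mat = default_matrix(),
                      gap_open = 11L, gap_ext = 1L) {
  antmine:::.bf_global_cpp(antmine:::encode_protein(q, mat),
                           antmine:::encode_protein(s, mat),
                           mat, gap_open, gap_ext)
}

# Exhaustive three-sequence MSA oracle: enumerate every gapped alignment of
# at most `maxcols` columns (column types = non-empty subsets of rows) and
# return the best sum-of-pairs score under the package's SP definition.
bf_msa3 <- function(s1, s2, s3, maxcols = max(nchar(c(s1, s2, s3))) + 2L,
                    mat = default_matrix(), gap_open = 15L, gap_ext = 1L) {
  ch <- lapply(c(s1, s2, s3), function(s) strsplit(s, "")[[1]])
  lens <- lengths(ch)
  moves <- list(c(1), c(2), c(3), c(1, 2), c(1, 3), c(2, 3), c(1, 2, 3))
  best <- -Inf
  rec <- function(pos, cols) {
    nleft <- lens - pos
    if (all(nleft == 0L)) {
      aln <- vapply(1:3, function(r)
        paste(vapply(cols, `[`, character(1), r), collapse = ""),
        character(1))
      sp <- sum_of_pairs(list(aln = stats::setNames(aln, c("a", "b", "c"))),
                         mat, gap_open, gap_ext)
      if (sp > best) best <<- sp
      return()
    }
    if (length(cols) + max(nleft) > maxcols) return()
    for (mv in moves) {
      if (any(nleft[mv] == 0L)) next
      col <- rep("-", 3)
      for (r in mv) col[r] <- ch[[r]][pos[r] + 1L]
      p2 <- pos
      p2[mv] <- p2[mv] + 1L
      rec(p2, c(cols, list(col)))
    }
  }
  rec(c(0L, 0L, 0L), list())
  best
}
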