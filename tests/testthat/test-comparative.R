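test_that("identical sequences align gap-free at 100% identity", {
  msa <- progressive_align(c(a = "MKWCNN", b = "MKWCNN"))
  expect_equal(msa$aln[["a"]], "MKWCNN")
  expect_equal(msa$aln[["b"]], "MKWCNN")
  expect_equal(percent_identity("MKWCNN", "MKWCNN"), 100)
})

test_that("progressive alignment is near-optimal on exhaustive instances", {
  trios <- list(c("MKWC", "MKWC", "MKW"),
                c("MKAC", "MKC", "MKGC"),
                c("WCNDE", "WCNE", "WCDE"))
  for (tr in trios) {
    msa <- progressive_align(stats::setNames(tr, c("a", "b", "c")))
    opt <- bf_msa3(tr[1], tr[2], tr[3])
    expect_gte(msa$sum_of_pairs, 0.95 * opt)
    expect_lte(msa$sum_of_pairs, opt + 1e-9)  # oracle is a true optimum
  }
})

test_that("de-gapping an alignment reproduces every input sequence", {
  set.seed(81)
  base <- random_peptide(30)
  seqs <- stats::setNames(
    c(base, vapply(1:4, function(i) diverge_query(base, 0.2, seed = 81 + i),
                   character(1))),
    paste0("s", 1:5))
  msa <- progressive_align(seqs)
  expect_true(all(nchar(msa$aln) == msa$ncol))
  degap <- gsub("-", "", msa$aln, fixed = TRUE)
  expect_equal(unname(degap[names(seqs)]), unname(seqs))
})

test_that("percent identity matches hand values and the brute-force oracle", {
  expect_equal(percent_identity("AAAA", "AATT"), 50)
  set.seed(82)
  for (i in 1:40) {
    a <- random_peptide(sample(2:6, 1))
    b <- random_peptide(sample(2:6, 1))
    g <- global_align(a, b)
    bf <- bf_global(a, b)
    expect_equal(g$score, bf$score, info = paste(a, b))
    ident <- round(g$pident * nchar(g$aaln) / 100)
    expect_gte(ident, bf$ident_min)
    expect_lte(ident, bf$ident_max)
  }
})

test_that("logo information content follows the entropy formula and bounds", {
  aln <- list(aln = c(a = "CA", b = "CW"))
  class(aln) <- "msa"
  lg <- logo(aln)
  expect_equal(lg$info[1], log2(20), tolerance = 1e-9)   # fully conserved
  expect_equal(lg$info[2], log2(20) - 1, tolerance = 1e-9)  # 0.5/0.5 split
  # a column uniform over all 20 residues carries no information
  uni <- list(aln = stats::setNames(AA20, paste0("r", 1:20)))
  class(uni) <- "msa"
  expect_equal(logo(uni)$info[1], 0, tolerance = 1e-9)
  # all-gap columns are flagged and carry zero information
  gp <- list(aln = c(a = "A-", b = "C-"))
  class(gp) <- "msa"
  lg2 <- logo(gp)
  expect_true(lg2$all_gap[2])
  expect_equal(lg2$info[2], 0)
  # frequencies sum to 1 on occupied columns; bounds hold
  set.seed(83)
  seqs <- stats::setNames(vapply(1:6, function(i) random_peptide(12),
                                 character(1)), paste0("s", 1:6))
  lg3 <- logo(progressive_align(seqs))
  expect_true(all(lg3$info >= -1e-9 & lg3$info <= log2(20) + 1e-9))
  occ <- !lg3$all_gap
  expect_true(all(abs(colSums(lg3$freq[, occ, drop = FALSE]) - 1) < 1e-9))
})

test_that("adding an identical row never decreases column information", {
  seqs <- stats::setNames(c("MKWCND", "MKACNE", "MKWCDD"), paste0("s", 1:3))
  m1 <- progressive_align(seqs)
  m2 <- list(aln = c(m1$aln, dup = m1$aln[[1]]))
  class(m2) <- "msa"
  expect_true(all(logo(m2)$info >= logo(m1)$info - 1e-9))
})

test_that("map_position shifts across gap columns and inverts", {
  msa <- list(aln = c(r1 = "A--BC", r2 = "AXYBC"))
  class(msa) <- "msa"
  mp <- map_position(msa, "r1", 2)   # the B of r1
  expect_equal(mp$column, 4)
  expect_equal(unname(mp$positions["r2"]), 4L)   # shifted by the 2-gap run
  back <- map_position(msa, "r2", 4)
  expect_equal(unname(back$positions["r1"]), 2L)
  gap <- map_position(msa, "r2", 2)  # X sits opposite a gap
  expect_true(is.na(gap$positions["r1"]))
  expect_error(map_position(msa, "r1", 99), "outside")
  expect_error(map_position(msa, "zz", 1), "unknown")
})

test_that("conserved template positions stay conserved in a planted family", {
  fam <- vapply(1:10, function(i) {
    p <- make_precursor("defensin", seed = 900 + i)
    s <- p$annotation$segments
    substr(p$protein, s$start[3] + 1, s$end[3])
  }, character(1))
  names(fam) <- paste0("def", 1:10)
  msa <- progressive_align(fam)
  lg <- logo(msa)
  cys_cols <- which(lg$freq["C", ] == 1)
  expect_equal(length(cys_cols), 6)
  expect_equal(lg$info[cys_cols], rep(log2(20), 6), tolerance = 1e-9)
  # the conserved Cys maps to a Cys in every family member
  first_cys <- which(strsplit(fam[["def1"]], "")[[1]] == "C")[1]
  mp <- map_position(msa, "def1", first_cys)
  res <- vapply(names(fam), function(id)
    substr(fam[[id]], mp$positions[id], mp$positions[id]), character(1))
  expect_true(all(res == "C"))
})
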