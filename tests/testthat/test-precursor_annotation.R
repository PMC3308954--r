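test_that("transferring a reference onto itself returns its own segments", {
  for (arch in c("defensin", "inotocin", "multipeptide")) {
    prec <- make_precursor(arch, seed = 61)
    ann <- transfer_segments(stats::setNames(prec$protein, "self"),
                             prec$annotation)
    expect_equal(ann$segments$start, prec$annotation$segments$start)
    expect_equal(ann$segments$end, prec$annotation$segments$end)
    expect_true(all(ann$segments$start_conf == "aligned"))
    expect_true(all(diff(ann$segments$start) > 0))  # boundary monotonicity
  }
})

test_that("an insertion inside the signal stretches the transferred boundary", {
  # hand-constructed homologs: identical except two residues inserted at
  # signal position 10; the signal boundary must move 19 -> 21
  ref_seq <- paste0("MKLLAVLFAVFALSACSAQ", "EEDDAAKR", "GKWDCKGNRC")
  ref <- reference_annotation("ref", ref_seq, data.frame(
    role = c("signal", "pro", "mature"),
    start = c(0L, 19L, 27L), end = c(19L, 27L, 37L)))
  target <- paste0(substr(ref_seq, 1, 10), "GG", substr(ref_seq, 11, nchar(ref_seq)))
  ann <- transfer_segments(stats::setNames(target, "t"), ref)
  expect_equal(ann$segments$end[ann$segments$role == "signal"], 21L)
  expect_equal(ann$segments$start[ann$segments$role == "mature"], 29L)
  expect_equal(ann$mature$seq[1], "GKWDCKGNRC")
})

test_that("non-homologous targets are refused below the identity floor", {
  prec <- make_precursor("defensin", seed = 62)
  junk <- paste(rep("WHWHWHWHWH", 10), collapse = "")
  expect_error(transfer_segments(stats::setNames(junk, "t"), prec$annotation),
               "refused")
})

test_that("cleavage and amidation motifs are located exhaustively", {
  expect_equal(nrow(find_cleavage_and_amidation("AAAA")), 0)
  kr <- find_cleavage_and_amidation("KRKR")
  expect_equal(kr$position[kr$motif == "KR"], c(0L, 2L))
  # overlapping dibasics are all reported
  kk <- find_cleavage_and_amidation("KKRR")
  expect_setequal(paste(kk$motif, kk$position),
                  c("KK 0", "KR 1", "RR 2"))
  # GRK amidation signal after a mature peptide ending in G
  m <- find_cleavage_and_amidation("CPRGGRKR")
  expect_true(any(m$motif == "GRK" & m$position == 4L))
})

test_that("multipeptide precursors split into the planted peptides", {
  mp <- make_precursor("multipeptide", seed = 63,
                       peptide_lengths = c(8L, 9L, 10L))
  ann <- transfer_segments(stats::setNames(mp$protein, "t"), mp$annotation)
  segs <- mp$annotation$segments
  planted <- vapply(which(segs$role == "mature"), function(i)
    substr(mp$protein, segs$start[i] + 1, segs$end[i]), character(1))
  expect_equal(ann$mature$seq, planted)
  expect_true(all(ann$mature$amidated))
  # amidated flag implies a Gly immediately after the mature C-terminus
  glys <- substr(rep(mp$protein, nrow(ann$mature)),
                 ann$mature$end + 1, ann$mature$end + 1)
  expect_true(all(glys == "G"))
})

test_that("motif evidence within the window overrides transferred boundaries", {
  # reference mature starts right after KR at positions 25-26; in the target
  # the convertase site sits two residues earlier (no indel), so homology
  # transfer lands two residues downstream of the true cleavage point and
  # the KR evidence must snap the boundary back, with a log message
  ref_seq <- paste0("MAVLAVLFAVFALSACSAQ", "EEDDAAKR", "GKWDCKGNRC")
  ref <- reference_annotation("ref", ref_seq, data.frame(
    role = c("signal", "pro", "mature"),
    start = c(0L, 19L, 27L), end = c(19L, 27L, 37L)))
  target <- paste0("MAVLAVLFAVFALSACSAQ", "EEDDKRAA", "GKWDCKGNRC")
  expect_message(
    ann <- transfer_segments(stats::setNames(target, "t"), ref),
    "motif evidence")
  expect_equal(ann$mature$start, 25L)  # right after the target KR
  expect_equal(substr(ann$seq, ann$mature$start - 1, ann$mature$start),
               "KR")
})

test_that("inotocin-like precursors yield an amidated nonapeptide", {
  ino <- make_precursor("inotocin", seed = 64)
  ann <- transfer_segments(stats::setNames(ino$protein, "t"), ino$annotation)
  expect_equal(nchar(ann$mature$seq[1]), 9)
  expect_true(ann$mature$amidated[1])
  cys <- which(strsplit(ann$mature$seq[1], "")[[1]] == "C")
  expect_equal(cys, c(1L, 6L))
  # neurophysin domain carries the 12 conserved cysteines
  segs <- ann$segments
  neuro <- substr(ino$protein, segs$start[segs$role == "neurophysin"] + 1,
                  segs$end[segs$role == "neurophysin"])
  expect_equal(cys_network(neuro)$count, 12)
})
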