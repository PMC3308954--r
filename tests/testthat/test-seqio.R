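test_that("read_fasta parses, validates and normalizes DNA records", {
  f <- withr::local_tempfile(fileext = ".fna")
  writeLines(c(">c1 a test contig", "ACGT"), f)
  x <- read_fasta(f, "dna")
  expect_equal(names(x), "c1")
  expect_equal(as.character(x[[1]]), "ACGT")
  expect_equal(S4Vectors::mcols(x)$description, "a test contig")

  writeLines(c(">c1", "acgtr"), f)
  expect_warning(y <- read_fasta(f, "dna"), "mapped to N")
  expect_equal(as.character(y[[1]]), "ACGTN")

  writeLines(c(">q", "MK", ">q", "MR"), f)
  expect_error(read_fasta(f, "protein"), "duplicate.*q")

  writeLines(character(0), f)
  expect_error(read_fasta(f, "dna"), "empty")

  writeLines(c(">q1", "MKJB"), f)
  expect_error(read_fasta(f, "protein"), "illegal protein residue")
})

test_that("FASTA round-trip preserves ids and sequences exactly", {
  set.seed(11)
  seqs <- stats::setNames(
    vapply(1:8, function(i) random_peptide(sample(5:60, 1)), character(1)),
    paste0("rec", 1:8))
  f <- withr::local_tempfile(fileext = ".faa")
  write_fasta(seqs, f)
  back <- read_fasta(f, "protein")
  expect_equal(names(back), names(seqs))
  expect_equal(as.character(back), unname(seqs), ignore_attr = TRUE)
})

test_that("GFF3 output uses 1-based inclusive coordinates and valid structure", {
  contigs <- Biostrings::DNAStringSet(c(c1 = paste(rep("A", 100), collapse = "")))
  m1 <- structure(list(contig_id = "c1", query_id = "q", strand = "+",
                       exons = matrix(c(10L, 40L), ncol = 2,
                                      dimnames = list(NULL, c("start", "end"))),
                       introns = NULL, translation = "M", score = 5,
                       qstart = 0L, qend = 1L, complete = TRUE, status = "ok"),
                  class = "gene_model")
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(list(m1), contigs, f)
  lines <- readLines(f)
  cds <- grep("\tCDS\t", lines, value = TRUE)
  expect_length(cds, 1)
  parts <- strsplit(cds, "\t")[[1]]
  expect_equal(as.integer(parts[4:5]), c(11L, 40L))
  expect_equal(parts[7], "+")

  m2 <- m1
  m2$exons <- matrix(c(10L, 60L, 40L, 90L), ncol = 2)
  write_gff3(list(m2), contigs, f)
  lines <- readLines(f)
  cds <- grep("\tCDS\t", lines, value = TRUE)
  expect_length(cds, 2)
  parents <- vapply(cds, function(l)
    sub(".*Parent=([^;]+).*", "\\1", strsplit(l, "\t")[[1]][9]), character(1))
  expect_length(unique(parents), 1)
  starts <- vapply(cds, function(l)
    as.integer(strsplit(l, "\t")[[1]][4]), integer(1))
  ends <- vapply(cds, function(l)
    as.integer(strsplit(l, "\t")[[1]][5]), integer(1))
  expect_true(all(starts <= ends))

  write_gff3(list(), contigs, f)
  expect_equal(readLines(f), "##gff-version 3")

  m3 <- m1
  m3$exons <- matrix(c(10L, 500L), ncol = 2)
  expect_error(write_gff3(list(m3), contigs, f), "outside contig")
})

test_that("feature tables round-trip and tolerate empty input", {
  rows <- rbind(peptide_features("GKWDCMGNRTQFIG", "p1", "mature"),
                peptide_features("KRKR", "p2", "pro"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(rows, f)
  back <- read_feature_table(f)
  expect_equal(back$id, rows$id)
  expect_equal(back$net_charge, rows$net_charge)
  expect_equal(back$n_cys, rows$n_cys)
  expect_equal(back$length, rows$length)

  write_feature_table(NULL, f)
  empty <- read_feature_table(f)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("id", "role", "net_charge") %in% names(empty)))
})

test_that("config validation enforces the documented invariants", {
  cfg <- default_config()
  expect_s3_class(cfg, "run_config")
  expect_true(cfg$intron_min < cfg$intron_max)
  expect_error(default_config(gap_open = -1L))
  expect_error(default_config(intron_min = 500L, intron_max = 100L))

  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# comment", "min_score = 55", "intron_max = 5000",
               "cleavage_motifs = KR,RR"), f)
  cfg2 <- read_config(f)
  expect_equal(cfg2$min_score, 55L)
  expect_equal(cfg2$intron_max, 5000L)
  expect_equal(cfg2$cleavage_motifs, c("KR", "RR"))
})

test_that("reference annotations load from sidecar TSV with validation", {
  prot <- c(refA = "MAAAAKRGGGGCCCC")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("record_id\trole\tstart\tend",
               "refA\tsignal\t0\t5",
               "refA\tpro\t5\t7",
               "refA\tmature\t7\t15"), f)
  refs <- read_reference_annotation(f, prot)
  expect_named(refs, "refA")
  expect_equal(refs$refA$segments$role, c("signal", "pro", "mature"))

  writeLines(c("record_id\trole\tstart\tend", "refA\tsignal\t2\t5"), f)
  expect_error(read_reference_annotation(f, prot), "signal segment")
  writeLines(c("record_id\trole\tstart\tend", "refB\tsignal\t0\t5"), f)
  expect_error(read_reference_annotation(f, prot), "not in reference")
})

test_that("run manifest is valid JSON and records seed and config", {
  f <- withr::local_tempfile(fileext = ".json")
  write_manifest(f, inputs = list(genome = "g.fna"), config = default_config(),
                 seed = 99L)
  m <- jsonlite::read_json(f)
  expect_equal(m$seed, 99L)
  expect_equal(m$package, "antmine")
  expect_equal(m$inputs$genome, "g.fna")
  expect_equal(m$config$gap_open, 11L)
})
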