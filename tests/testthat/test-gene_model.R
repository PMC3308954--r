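test_that("identify_orf extends hits to start and stop codons", {
  # ATG at [2,5), hit codon AAA, stop TAA included in the interval
  h <- data.frame(contig_id = "c", frame = 3L, strand = "+",
                  fpstart = 1L, fpend = 2L)
  o <- identify_orf(h, "CCATGAAATAACC")
  expect_equal(o$interval, c(2L, 11L))
  expect_equal(o$protein, "MK")
  expect_false(o$partial)

  # no downstream stop before the contig edge -> partial
  h2 <- data.frame(contig_id = "c", frame = 1L, strand = "+",
                   fpstart = 0L, fpend = 2L)
  o2 <- identify_orf(h2, "ATGAAAGGG")
  expect_true(o2$partial)
  expect_true(o2$partial3)

  # upstream in-frame stop before any ATG -> partial with hit start kept
  h3 <- data.frame(contig_id = "c", frame = 1L, strand = "+",
                   fpstart = 1L, fpend = 3L)
  o3 <- identify_orf(h3, "TAAAAAGGGTGACC")
  expect_true(o3$partial5)
  expect_equal(o3$interval[1], 3L)
})

test_that("identify_orf recovers a planted intronless precursor verbatim", {
  prec <- make_precursor("defensin", seed = 31)
  pg <- plant_gene(prec, seed = 31, n_introns = 0)
  q <- stats::setNames(prec$protein, "q1")
  hits <- search_contigs(q, pg$contig, default_config())
  o <- identify_orf(hits[1, ], pg$contig[[1]])
  expect_equal(o$protein, prec$protein)
  expect_false(o$partial)
})

test_that("spliced alignment of an intronless gene matches the local score", {
  prec <- make_precursor("defensin", seed = 32)
  pg <- plant_gene(prec, seed = 32, n_introns = 0)
  cfg <- default_config(intron_max = 1000L)
  q <- stats::setNames(prec$protein, "q1")
  hits <- search_contigs(q, pg$contig, cfg)
  m <- build_gene_models(hits[1, ], pg$contig, q, cfg)[[1]]
  expect_equal(m$status, "ok")
  expect_null(m$introns)
  expect_equal(m$score, hits$score[1])
  expect_equal(m$translation, prec$protein)
  expect_true(m$complete)
})

test_that("a planted two-exon gene is recovered with exact boundaries", {
  prec <- make_precursor("defensin", seed = 33)
  pg <- plant_gene(prec, seed = 33, n_introns = 1, intron_lengths = 250L,
                   phases = 1L)
  cfg <- default_config(intron_max = 1000L)
  q <- stats::setNames(prec$protein, "q1")
  hits <- search_contigs(q, pg$contig, cfg)
  m <- build_gene_models(hits[1, ], pg$contig, q, cfg)[[1]]
  expect_equal(nrow(m$exons), 2)
  expect_equal(unname(m$exons), unname(pg$truth$exons))
  expect_equal(m$introns$length, 250)
  expect_equal(m$introns$donor, "GT")
  expect_equal(m$introns$acceptor, "AG")
  expect_equal(m$translation, prec$protein)
})

test_that("splice consistency and score dominance hold across random genes", {
  cfg <- default_config(intron_max = 1200L)
  for (s in c(41, 42, 43, 44)) {
    prec <- make_precursor("defensin", seed = s)
    set.seed(s)
    k <- sample(0:2, 1)
    pg <- plant_gene(prec, seed = s, n_introns = k)
    q <- stats::setNames(prec$protein, "q1")
    hits <- search_contigs(q, pg$contig, cfg)
    m <- build_gene_models(hits[1, ], pg$contig, q, cfg)[[1]]
    # removing introns and translating reproduces the stored translation
    expect_equal(splice_and_translate(pg$contig[[1]], m$exons, m$strand),
                 m$translation)
    # spliced optimum dominates the best single-exon (frame) alignment
    best_frame <- max(vapply(six_frame_translate(pg$contig[[1]], "c"),
                             function(f) local_align(prec$protein,
                                                     f$peptide)$score,
                             numeric(1)))
    expect_gte(m$score, best_frame)
    # intron count never exceeds what was planted at divergence 0
    expect_equal(if (is.null(m$introns)) 0L else nrow(m$introns), k)
  }
})

test_that("regions without homology yield no prediction", {
  # poly-A DNA codes only lysine; tryptophan never scores positively there
  m <- spliced_align("WWWWWWWWWW", strrep("A", 300), default_config())
  expect_equal(m$status, "no_prediction")
  expect_error(model_to_precursor(m), "no prediction")
})

test_that("model_to_precursor names records and flags partial models", {
  prec <- make_precursor("defensin", seed = 34)
  pg <- plant_gene(prec, seed = 34, n_introns = 0)
  cfg <- default_config()
  q <- stats::setNames(prec$protein, "myquery")
  hits <- search_contigs(q, pg$contig, cfg)
  m <- build_gene_models(hits[1, ], pg$contig, q, cfg)[[1]]
  p <- model_to_precursor(m)
  expect_equal(names(p), paste(m$contig_id, "myquery", sep = "_"))
  expect_false(attr(p, "partial"))

  # truncate the query's C-terminal half: model covers a prefix only
  half <- substr(prec$protein, 1, 40)
  m2 <- spliced_align(prec$protein,
                      substr(pg$contig[[1]], 1,
                             pg$truth$exons[1, 1] + 120L),
                      cfg, contig_id = "trunc", query_id = "myquery")
  if (m2$status == "ok" && !m2$complete) {
    p2 <- model_to_precursor(m2)
    expect_true(attr(p2, "partial"))
    expect_true(grepl(substr(p2, 1, 10), prec$protein, fixed = TRUE))
  }
  expect_true(nchar(half) == 40)  # guard: fixture as intended
})
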