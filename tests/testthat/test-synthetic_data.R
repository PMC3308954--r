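test_that("defensin precursors satisfy their architecture exactly", {
  prec <- make_precursor("defensin", seed = 91)
  segs <- prec$annotation$segments
  expect_equal(segs$role, c("signal", "pro", "mature"))
  expect_equal(nchar(prec$protein), 97)
  signal <- substr(prec$protein, 1, segs$end[1])
  pro <- substr(prec$protein, segs$start[2] + 1, segs$end[2])
  mature <- substr(prec$protein, segs$start[3] + 1, segs$end[3])
  expect_equal(substr(signal, 1, 1), "M")
  expect_equal(net_charge(pro), -4L)
  expect_equal(net_charge(mature), 6L)
  cn <- cys_network(mature)
  expect_equal(cn$count, 6)
  expect_true(cn$csab)
  # conserved anchors: Asp at mature position 4, Arg at position 42
  expect_equal(substr(mature, 4, 4), "D")
  expect_equal(substr(mature, 42, 42), "R")
  # pro-domain ends at a KR convertase site
  expect_equal(substr(pro, nchar(pro) - 1, nchar(pro)), "KR")
})

test_that("inotocin precursors carry the nonapeptide/GRK/neurophysin layout", {
  prec <- make_precursor("inotocin", seed = 92)
  segs <- prec$annotation$segments
  expect_equal(nchar(prec$protein), 150)
  mat <- segs[segs$role == "mature", ]
  expect_equal(mat$end - mat$start, 9L)
  nona <- substr(prec$protein, mat$start + 1, mat$end)
  expect_equal(which(strsplit(nona, "")[[1]] == "C"), c(1L, 6L))
  expect_equal(substr(prec$protein, mat$end + 1, mat$end + 3), "GRK")
  neuro <- segs[segs$role == "neurophysin", ]
  expect_equal(cys_network(substr(prec$protein, neuro$start + 1,
                                  neuro$end))$count, 12)
})

test_that("generation is deterministic and rejects unsatisfiable targets", {
  a <- make_precursor("defensin", seed = 93)
  b <- make_precursor("defensin", seed = 93)
  expect_identical(a$protein, b$protein)
  expect_identical(a$annotation$segments, b$annotation$segments)
  c1 <- plant_gene(a, seed = 93, n_introns = 2)
  c2 <- plant_gene(a, seed = 93, n_introns = 2)
  expect_identical(c1$contig, c2$contig)
  expect_identical(c1$truth$exons, c2$truth$exons)
  expect_error(make_precursor("defensin", seed = 1, pro_len = 5L,
                              pro_charge = -10L), "unsatisfiable")
  expect_error(make_precursor("defensin", seed = 1, mature_len = 40L,
                              mature_charge = 40L), "unsatisfiable")
})

test_that("diverge_query substitutes the exact number of positions", {
  p <- random_peptide(40)
  expect_identical(diverge_query(p, 0, seed = 1), p)
  d <- diverge_query(p, 0.5, seed = 2)
  expect_equal(nchar(d), 40)
  diffs <- sum(strsplit(p, "")[[1]] != strsplit(d, "")[[1]])
  expect_equal(diffs, 20)
  # at modest divergence the gap-free global identity equals 100*(1-d)
  p2 <- random_peptide(60)
  d2 <- diverge_query(p2, 0.15, seed = 3)
  expect_equal(percent_identity(p2, d2), 100 * (1 - 0.15), tolerance = 1e-9)
})

test_that("planted genes pass the splice-and-translate consistency check", {
  for (s in c(94, 95)) {
    prec <- make_precursor("defensin", seed = s)
    for (gc in c(0.25, 0.75)) {
      pg <- plant_gene(prec, seed = s, n_introns = 2, gc = gc)
      expect_identical(splice_and_translate(pg$contig[[1]], pg$truth$exons,
                                            pg$truth$strand),
                       prec$protein)
      expect_true(all(pg$truth$introns$length ==
                        pg$truth$introns$end - pg$truth$introns$start))
      # canonical splice sites on the planted strand
      for (k in seq_len(nrow(pg$truth$introns))) {
        expect_equal(substr(pg$contig[[1]], pg$truth$introns$start[k] + 1,
                            pg$truth$introns$start[k] + 2), "GT")
        expect_equal(substr(pg$contig[[1]], pg$truth$introns$end[k] - 1,
                            pg$truth$introns$end[k]), "AG")
      }
    }
  }
})

test_that("planted genes are recovered across backgrounds and strands", {
  cfg <- default_config(intron_max = 1200L)
  prec <- make_precursor("defensin", seed = 96)
  q <- stats::setNames(prec$protein, "q1")
  for (gc in c(0.25, 0.75)) {
    pg <- plant_gene(prec, seed = 96, n_introns = 1, gc = gc)
    hits <- search_contigs(q, pg$contig, cfg)
    m <- build_gene_models(hits[1, ], pg$contig, q, cfg)[[1]]
    expect_equal(m$translation, prec$protein)
  }
  pg <- plant_gene(prec, seed = 97, n_introns = 1, strand = "-")
  hits <- search_contigs(q, pg$contig, cfg)
  expect_equal(hits$strand[1], "-")
  m <- build_gene_models(hits[1, ], pg$contig, q, cfg)[[1]]
  expect_equal(m$translation, prec$protein)
})

test_that("recovery accuracy is monotone non-increasing in divergence", {
  cfg <- default_config(intron_max = 1200L)
  acc <- vapply(c(0, 0.15, 0.3), function(d) {
    g <- synth_genome(12, divergence = d, seed = 271)
    mean(evaluate_recovery(g, cfg)$mature_accuracy)
  }, numeric(1))
  expect_true(all(diff(acc) <= 0.02))   # small slack for finite samples
  expect_gte(acc[1], 0.99)
})
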