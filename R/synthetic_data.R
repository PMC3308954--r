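#' Construct a synthetic precursor protein of a known architecture
#'
#' Builds a precursor that satisfies an architecture template exactly, with
#' a matching reference annotation, so downstream stages can be tested
#' against ground truth:
#'
#' * `defensin`: signal peptide (hydrophobic core) + anionic pro-domain
#'   ending in a KR convertase site + cationic Cys-rich mature domain with
#'   the CSab six-cysteine spacing, a conserved Asp at mature position 4 and
#'   Arg at position 42 (43-residue mature domain; 97-residue precursor).
#' * `inotocin`: signal + disulfide-bonded nonapeptide (Cys at positions 1
#'   and 6) + GRK amidation/cleavage signal + a 12-cysteine neurophysin
#'   domain (150-residue precursor).
#' * `multipeptide`: signal + pro-domain + several mature peptides, each
#'   released by dibasic cleavage and amidated via a donor glycine
#'   (allatostatin-style).
#'
#' @param architecture one of `"defensin"`, `"inotocin"`, `"multipeptide"`
#' @param seed integer seed; identical seed + parameters give identical
#'   output
#' @param signal_len,pro_len signal/pro-domain lengths (defensin and
#'   multipeptide)
#' @param pro_charge,mature_charge formal net-charge targets (defensin)
#' @param mature_len defensin mature-domain length
#' @param cys_spacing defensin inter-cysteine spacing vector (5 gaps)
#' @param peptide_lengths mature-peptide lengths (multipeptide)
#' @return list with `protein`, `annotation` (a [reference_annotation()]),
#'   `architecture` and `id`
#' @export
make_precursor <- function(architecture = c("defensin", "inotocin",
                                            "multipeptide"),
                           seed = 1L,
                           signal_len = 24L, pro_len = 30L,
                           pro_charge = -4L, mature_charge = 6L,
                           mature_len = 43L,
                           cys_spacing = c(10L, 4L, 9L, 6L, 1L),
                           peptide_lengths = c(8L, 8L, 8L, 7L, 30L, 9L, 28L)) {
  architecture <- match.arg(architecture)
  set.seed(seed)
  id <- sprintf("synthetic_%s_%d", architecture, seed)
  neutral <- c("S", "T", "N", "Q", "G", "A", "P", "L", "V")
  hydroph <- c("A", "V", "L", "I", "F")

  make_signal <- function(len) {
    if (len < 8) stop("signal length must be >= 8")
    core <- sample(hydroph, 8, replace = TRUE)
    rest <- sample(c(hydroph, "S", "T", "G", "W", "M"), len - 9,
                   replace = TRUE)
    c("M", core, rest)
  }
  make_pro <- function(len, charge) {
    # ends with the KR convertase site (+2); balance with acidic/basic fill
    if (len < 4) stop("pro-domain length must be >= 4")
    free <- len - 2L
    need_neg <- 2L - charge
    need_pos <- 0L
    if (need_neg < 0) { need_pos <- -need_neg; need_neg <- 0L }
    if (need_neg + need_pos > free)
      stop("pro-domain charge target unsatisfiable at length ", len)
    fill <- c(sample(c("D", "E"), need_neg, replace = TRUE),
              sample(c("K", "R"), need_pos, replace = TRUE),
              sample(neutral, free - need_neg - need_pos, replace = TRUE))
    c(sample(fill), "K", "R")
  }

  if (architecture == "defensin") {
    if (length(cys_spacing) != 4 + 1) stop("cys_spacing must have 5 gaps")
    cys_pos <- cumsum(c(5L, cys_spacing + 1L))   # 1-based mature positions
    if (max(cys_pos) > mature_len)
      stop("cysteine template does not fit in mature length ", mature_len)
    mature <- rep(NA_character_, mature_len)
    mature[cys_pos] <- "C"
    if (is.na(mature[4])) mature[4] <- "D"
    if (mature_len >= 42 && is.na(mature[42])) mature[42] <- "R"
    base_charge <- net_charge(paste(mature[!is.na(mature)], collapse = ""))
    need <- mature_charge - base_charge
    free <- which(is.na(mature))
    if (abs(need) > length(free))
      stop("mature charge target unsatisfiable at length ", mature_len)
    charged <- sample(free, abs(need))
    mature[charged] <- sample(if (need >= 0) c("K", "R") else c("D", "E"),
                              abs(need), replace = TRUE)
    still <- which(is.na(mature))
    pool <- c("A", "V", "F", "I", "L", "W", "Y", "G", "S", "T", "N", "Q",
              "P", "H", "M")
    mature[still] <- sample(pool, length(still), replace = TRUE)
    protein <- paste(c(make_signal(signal_len), make_pro(pro_len, pro_charge),
                       mature), collapse = "")
    segments <- data.frame(
      role = c("signal", "pro", "mature"),
      start = c(0L, signal_len, signal_len + pro_len),
      end = c(signal_len, signal_len + pro_len,
              signal_len + pro_len + mature_len))
  } else if (architecture == "inotocin") {
    sig_len <- 25L
    nona <- c("C", "L", "I", "T", "N", "C", "P", "R", "G")
    neuro_len <- 113L
    cys_n <- round(seq(4, neuro_len - 4, length.out = 12))
    neuro <- rep(NA_character_, neuro_len)
    neuro[cys_n] <- "C"
    neuro[is.na(neuro)] <- sample(neutral, sum(is.na(neuro)), replace = TRUE)
    protein <- paste(c(make_signal(sig_len), nona, c("G", "R", "K"), neuro),
                     collapse = "")
    segments <- data.frame(
      role = c("signal", "mature", "pro", "neurophysin"),
      start = c(0L, sig_len, sig_len + 9L, sig_len + 12L),
      end = c(sig_len, sig_len + 9L, sig_len + 12L, sig_len + 12L + neuro_len))
  } else {
    pool <- c("A", "G", "S", "T", "N", "Q", "P", "L", "F", "Y", "I", "V",
              "M", "W", "H", "D", "E")
    parts <- list(make_signal(signal_len), make_pro(pro_len, pro_charge))
    roles <- data.frame(role = c("signal", "pro"),
                        start = c(0L, signal_len),
                        end = c(signal_len, signal_len + pro_len))
    cursor <- signal_len + pro_len
    for (len in peptide_lengths) {
      pep <- sample(pool, len, replace = TRUE)
      parts[[length(parts) + 1]] <- c(pep, "G", "K", "R")
      roles <- rbind(roles, data.frame(role = "mature", start = cursor,
                                       end = cursor + len))
      cursor <- cursor + len + 3L
    }
    protein <- paste(unlist(parts), collapse = "")
    segments <- roles
  }
  list(protein = protein,
       annotation = reference_annotation(id, protein, segments),
       architecture = architecture, id = id)
}

#' Substitute residues to emulate a diverged cross-species query
#'
#' Exactly `round(divergence * nchar(protein))` positions are substituted
#' (no indels), preferring BLOSUM62-positive exchanges with probability 0.7
#' so the result behaves like a homolog rather than random noise.
#'
#' @param protein amino-acid string
#' @param divergence fraction of positions to substitute, in \[0, 1)
#' @param seed integer seed
#' @param matrix substitution matrix used to pick conservative exchanges
#' @return the diverged protein string
#' @export
diverge_query <- function(protein, divergence, seed = 1L, matrix = NULL) {
  stopifnot(divergence >= 0, divergence < 1)
  if (divergence == 0) return(protein)
  if (is.null(matrix)) matrix <- default_matrix()
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ch <- strsplit(protein, "")[[1]]
  n_sub <- round(divergence * length(ch))
  pos <- sample(length(ch), n_sub)
  for (p in pos) {
    a <- ch[p]
    others <- setdiff(aa, a)
    conservative <- others[matrix[a, others] > 0]
    ch[p] <- if (length(conservative) && stats::runif(1) < 0.7)
      sample(conservative, 1) else sample(others, 1)
  }
  paste(ch, collapse = "")
}

#' Plant a precursor gene in a synthetic contig
#'
#' Reverse-translates the precursor (uniform synonymous codon choice),
#' interrupts the coding sequence with GT..AG introns at the requested
#' phases, appends a stop codon, and embeds the gene in random background
#' DNA of a given GC content. The emitted ground truth is verified
#' internally by splicing the introns back out and re-translating.
#'
#' @param precursor the list returned by [make_precursor()] (or a plain
#'   protein string)
#' @param seed integer seed
#' @param n_introns number of introns (ignored when `intron_lengths` given)
#' @param intron_lengths intron lengths in bases (>= intron_min of the
#'   config; default sampled in 80..800)
#' @param phases intron phases (0, 1 or 2; default sampled)
#' @param flank background DNA length on each side of the gene
#' @param gc background GC fraction
#' @param strand strand to plant on (`"+"` or `"-"`)
#' @param contig_id id of the emitted contig
#' @return list with `contig` (named character), `truth` (gene interval,
#'   exon/intron coordinates, precursor, segment annotation) — all
#'   coordinates 0-based half-open forward strand
#' @export
plant_gene <- function(precursor, seed = 1L, n_introns = 1L,
                       intron_lengths = NULL, phases = NULL,
                       flank = 1000L, gc = 0.4, strand = "+",
                       contig_id = NULL) {
  ann <- NULL
  if (is.list(precursor)) { ann <- precursor$annotation
    prot_id <- precursor$id; protein <- precursor$protein }
  else { protein <- precursor; prot_id <- "planted" }
  if (is.null(contig_id)) contig_id <- paste0("contig_", prot_id, "_", seed)
  set.seed(seed)
  if (is.null(intron_lengths))
    intron_lengths <- if (n_introns > 0) sample(80:800, n_introns, replace = TRUE)
      else integer(0)
  n_introns <- length(intron_lengths)
  if (is.null(phases)) phases <- sample(0:2, n_introns, replace = TRUE)
  stopifnot(length(phases) == n_introns, all(phases %in% 0:2))

  cds <- reverse_translate(protein)
  n_cod <- nchar(protein)
  if (n_introns > 0) {
    # every exon keeps >= min_exon codons: spliceosomal genes do not carry
    # near-zero-length exons, and a terminal exon shorter than the intron
    # penalty is not identifiable by any homology score
    min_exon <- 10L
    if (n_cod < (n_introns + 1L) * min_exon)
      stop("precursor too short for ", n_introns, " introns")
    repeat {
      codon_slots <- sort(sample(min_exon:(n_cod - min_exon), n_introns))
      if (n_introns == 1 || all(diff(codon_slots) >= min_exon)) break
    }
    cut_points <- 3L * codon_slots + phases   # CDS base offset of each cut
  } else cut_points <- integer(0)

  # assemble gene: exon pieces interleaved with introns
  pieces <- list(); exon_rel <- list()
  prev <- 0L; gpos <- 0L
  introns_rel <- list()
  cuts <- c(cut_points, nchar(cds))
  for (k in seq_along(cuts)) {
    piece <- substr(cds, prev + 1L, cuts[k])
    pieces[[length(pieces) + 1]] <- piece
    exon_rel[[length(exon_rel) + 1]] <- c(gpos, gpos + nchar(piece))
    gpos <- gpos + nchar(piece)
    if (k < length(cuts)) {
      ilen <- intron_lengths[k]
      if (ilen < 8) stop("intron length must be >= 8")
      intron <- paste0("GT", random_dna(ilen - 4L, gc), "AG")
      pieces[[length(pieces) + 1]] <- intron
      introns_rel[[length(introns_rel) + 1]] <-
        c(gpos, gpos + ilen, phases[k])
      gpos <- gpos + ilen
    }
    prev <- cuts[k]
  }
  gene <- paste(unlist(pieces), collapse = "")
  stop_codon <- sample(c("TAA", "TAG", "TGA"), 1)
  gene <- paste0(gene, stop_codon)

  left <- random_dna(sample(round(flank / 2):flank, 1), gc)
  right <- random_dna(flank, gc)
  fwd <- paste0(left, gene, right)
  gene_start <- nchar(left)
  L <- nchar(fwd)
  exons <- do.call(rbind, exon_rel) + gene_start
  introns <- if (length(introns_rel))
    data.frame(start = vapply(introns_rel, `[`, numeric(1), 1) + gene_start,
               end = vapply(introns_rel, `[`, numeric(1), 2) + gene_start,
               phase = vapply(introns_rel, `[`, numeric(1), 3),
               length = intron_lengths)
    else NULL
  if (strand == "-") {
    contig_seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(fwd)))
    exons <- cbind(L - exons[, 2], L - exons[, 1])
    exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
    if (!is.null(introns)) {
      introns <- data.frame(start = L - introns$end, end = L - introns$start,
                            phase = introns$phase, length = introns$length)
      introns <- introns[rev(seq_len(nrow(introns))), , drop = FALSE]
    }
  } else contig_seq <- fwd
  colnames(exons) <- c("start", "end")
  # forward-check: splice and translate must reproduce the precursor
  spliced <- splice_and_translate(contig_seq, exons, strand)
  if (spliced != protein)
    stop("internal error: planted gene fails the splice-and-translate check")
  truth <- list(contig_id = contig_id, strand = strand,
                exons = exons, introns = introns,
                precursor = protein, annotation = ann, query_id = prot_id)
  list(contig = stats::setNames(contig_seq, contig_id), truth = truth)
}

#' Splice exons out of a contig and translate
#'
#' @param contig_seq contig sequence (character)
#' @param exons matrix of forward-strand 0-based half-open exon intervals
#' @param strand `"+"` or `"-"`
#' @return the protein translation of the spliced CDS
#' @export
splice_and_translate <- function(contig_seq, exons, strand = "+") {
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  cds <- paste(vapply(seq_len(nrow(exons)), function(k)
    substr(contig_seq, exons[k, 1] + 1L, exons[k, 2]), character(1)),
    collapse = "")
  d <- Biostrings::DNAString(cds)
  if (strand == "-") d <- Biostrings::reverseComplement(d)
  as.character(Biostrings::translate(d, if.fuzzy.codon = "X"))
}

reverse_translate <- function(protein) {
  gc_tab <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc_tab), unname(gc_tab))
  ch <- strsplit(protein, "")[[1]]
  codons <- vapply(ch, function(a) {
    opts <- by_aa[[a]]
    if (is.null(opts)) stop("cannot reverse-translate residue ", a)
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1))
  paste(codons, collapse = "")
}

random_dna <- function(n, gc = 0.4) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

#' Generate a synthetic genome with planted precursor genes
#'
#' One contig per gene. Each gene's query is the planted precursor diverged
#' by `divergence` substitutions, emulating a cross-species search.
#'
#' @param n_genes number of genes/contigs
#' @param architecture passed to [make_precursor()]
#' @param divergence query divergence passed to [diverge_query()]
#' @param max_introns introns per gene are drawn uniformly from
#'   `0:max_introns`
#' @param seed master seed; per-gene seeds are derived deterministically
#' @param ... further arguments passed to [plant_gene()]
#' @return list with `contigs` (named character vector), `queries` (named
#'   character vector) and `truth` (list of per-gene ground truths)
#' @export
synth_genome <- function(n_genes = 10L,
                         architecture = "defensin",
                         divergence = 0, max_introns = 2L, seed = 1L, ...) {
  contigs <- character(0)
  queries <- character(0)
  truth <- list()
  for (i in seq_len(n_genes)) {
    s <- (seed * 1000L + i * 7L) %% 2147483647L
    prec <- make_precursor(architecture, seed = s)
    set.seed(s + 1L)
    k <- sample(0:max_introns, 1)
    planted <- plant_gene(prec, seed = s + 2L, n_introns = k,
                          contig_id = sprintf("ctg%03d", i), ...)
    qid <- sprintf("query%03d", i)
    q <- diverge_query(prec$protein, divergence, seed = s + 3L)
    contigs[sprintf("ctg%03d", i)] <- unname(planted$contig)
    queries[qid] <- q
    planted$truth$query_id <- qid
    truth[[i]] <- planted$truth
  }
  list(contigs = contigs, queries = queries, truth = truth)
}

#' Benchmark pipeline recovery against planted ground truth
#'
#' Runs search + spliced alignment per planted gene and scores recovery:
#' exact exon-boundary agreement, exact precursor-sequence recovery among
#' complete models, and per-residue accuracy over the mature domain.
#'
#' @param genome the list returned by [synth_genome()]
#' @param config a `run_config`
#' @return data.frame with one row per gene: `hit_found`, `exons_exact`,
#'   `complete`, `precursor_exact`, `mature_accuracy`
#' @export
evaluate_recovery <- function(genome, config = default_config()) {
  out <- lapply(seq_along(genome$truth), function(i) {
    tr <- genome$truth[[i]]
    cid <- tr$contig_id
    qid <- tr$query_id
    contig <- genome$contigs[cid]
    query <- genome$queries[qid]
    hits <- search_contigs(query, contig, config)
    row <- data.frame(gene = i, hit_found = FALSE, exons_exact = FALSE,
                      complete = FALSE, precursor_exact = FALSE,
                      mature_accuracy = 0)
    if (nrow(hits) == 0) return(row)
    row$hit_found <- TRUE
    models <- build_gene_models(hits, contig, query, config)
    model <- models[[which.max(vapply(models, `[[`, numeric(1), "score"))]]
    if (model$status != "ok") return(row)
    me <- model$exons[order(model$exons[, 1]), , drop = FALSE]
    te <- tr$exons[order(tr$exons[, 1]), , drop = FALSE]
    row$exons_exact <- nrow(me) == nrow(te) &&
      all(me == te)
    row$complete <- model$complete
    row$precursor_exact <- identical(model$translation, tr$precursor)
    row$mature_accuracy <- mature_domain_accuracy(model, tr, config)
    row
  })
  do.call(rbind, out)
}

# fraction of planted mature-domain residues recovered identically by the
# model translation (aligned globally against the planted precursor)
mature_domain_accuracy <- function(model, tr, config) {
  if (is.null(tr$annotation)) return(NA_real_)
  segs <- tr$annotation$segments
  mseg <- segs[segs$role == "mature", , drop = FALSE][1, ]
  if (!nzchar(model$translation)) return(0)
  aln <- global_align(model$translation, tr$precursor, config$matrix,
                      config$gap_open, config$gap_ext)
  mc <- strsplit(aln$aaln, "")[[1]]
  tc <- strsplit(aln$baln, "")[[1]]
  ti <- 0L
  good <- 0L
  for (k in seq_along(tc)) {
    if (tc[k] != "-") {
      ti <- ti + 1L
      if (ti > mseg$start && ti <= mseg$end && mc[k] == tc[k])
        good <- good + 1L
    }
  }
  good / (mseg$end - mseg$start)
}
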