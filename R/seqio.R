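#' Read a FASTA file of contigs or proteins
#'
#' DNA records are uppercased and any IUPAC code outside A/C/G/T/N is mapped
#' to N with a warning. Protein records must use the 20 standard residues
#' plus X and `*`; anything else is a hard error.
#'
#' @param path FASTA file path
#' @param alphabet `"dna"` for contigs, `"protein"` for precursor queries
#' @return a [Biostrings::DNAStringSet] or [Biostrings::AAStringSet]; names
#'   are record ids (first header token), descriptions are kept in
#'   `mcols(x)$description`
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) stop("empty FASTA file: ", path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) stop("record with empty id in ", path)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate record id(s): ", paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(raw))
  if (any(nchar(seqs) == 0)) stop("zero-length sequence in ", path)
  if (alphabet == "dna") {
    cleaned <- gsub("[^ACGTN]", "N", seqs)
    changed <- cleaned != seqs
    if (any(changed))
      warning(sum(changed), " record(s) contained non-ACGTN characters; ",
              "mapped to N", call. = FALSE)
    out <- Biostrings::DNAStringSet(cleaned)
  } else {
    ok <- grepl("^[ACDEFGHIKLMNPQRSTVWYX*]+$", seqs)
    if (!all(ok)) {
      bad <- unique(unlist(strsplit(gsub("[ACDEFGHIKLMNPQRSTVWYX*]", "",
                                         seqs[!ok]), "")))
      stop("illegal protein residue(s) in ", path, ": ",
           paste(bad, collapse = ", "))
    }
    out <- Biostrings::AAStringSet(seqs)
  }
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = desc)
  out
}

#' Write sequences to FASTA
#'
#' @param x a named `XStringSet` or named character vector
#' @param path output path
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) {
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop("sequences must be named")
    x <- Biostrings::BStringSet(x)
  }
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' Emits gene/mRNA/CDS rows with 1-based inclusive coordinates; internal
#' coordinates are 0-based half-open and are converted only here. Intron
#' lengths are recoverable from the gaps between CDS rows of one mRNA.
#'
#' @param models list of `gene_model` objects (see [spliced_align()])
#' @param contigs the contig set the models refer to (for bounds checking)
#' @param path output path
#' @export
write_gff3 <- function(models, contigs, path) {
  models <- Filter(function(m) m$status == "ok", models)
  if (length(models) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  lens <- stats::setNames(Biostrings::width(contigs), names(contigs))
  rows <- list()
  for (k in seq_along(models)) {
    m <- models[[k]]
    if (!m$contig_id %in% names(lens))
      stop("model references unknown contig: ", m$contig_id)
    ex <- m$exons
    if (any(ex[, 1] < 0) || any(ex[, 2] > lens[[m$contig_id]]))
      stop("model coordinates outside contig ", m$contig_id)
    gid <- sprintf("gene%04d", k)
    ord <- order(ex[, 1])
    ex <- ex[ord, , drop = FALSE]
    # CDS phase: bases of the previous codon carried over, in transcription
    # order (reversed for minus-strand models)
    tx <- if (m$strand == "-") rev(seq_len(nrow(ex))) else seq_len(nrow(ex))
    carried <- cumsum(c(0L, (ex[tx, 2] - ex[tx, 1])))[seq_len(nrow(ex))]
    phase_tx <- (3L - carried %% 3L) %% 3L
    phase <- integer(nrow(ex)); phase[tx] <- phase_tx
    gene_start <- min(ex[, 1]); gene_end <- max(ex[, 2])
    rows[[length(rows) + 1]] <- data.frame(
      seqid = m$contig_id, start = gene_start + 1L, end = gene_end,
      strand = m$strand, type = "gene", phase = NA_integer_,
      ID = gid, Parent = NA_character_,
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      seqid = m$contig_id, start = gene_start + 1L, end = gene_end,
      strand = m$strand, type = "mRNA", phase = NA_integer_,
      ID = paste0(gid, ".t1"), Parent = gid,
      stringsAsFactors = FALSE)
    for (e in seq_len(nrow(ex)))
      rows[[length(rows) + 1]] <- data.frame(
        seqid = m$contig_id, start = ex[e, 1] + 1L, end = ex[e, 2],
        strand = m$strand, type = "CDS", phase = phase[e],
        ID = paste0(gid, ".cds"), Parent = paste0(gid, ".t1"),
        stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqid,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  gr$type <- df$type
  gr$phase <- ifelse(df$type == "CDS", df$phase, NA_integer_)
  gr$ID <- df$ID
  gr$Parent <- IRanges::CharacterList(
    lapply(df$Parent, function(p) if (is.na(p)) character(0) else p))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a peptide feature table
#'
#' One TSV row per peptide segment with a fixed column order; see
#' [peptide_features()] for the column semantics.
#'
#' @param rows data.frame of feature rows
#' @param path output path
#' @export
write_feature_table <- function(rows, path) {
  cols <- feature_columns()
  if (is.null(rows) || nrow(rows) == 0)
    rows <- stats::setNames(
      as.data.frame(lapply(cols, function(x) character(0))), cols)
  rows <- rows[, cols, drop = FALSE]
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a peptide feature table written by [write_feature_table()]
#' @param path TSV path
#' @return data.frame
#' @export
read_feature_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df
}

feature_columns <- function() {
  c("id", "role", "length", "net_charge", "n_positive", "n_negative",
    "n_cys", "pro_count", "pro_fraction", "hydrophobic_fraction",
    "csab", "amidated")
}

#' Read reference segment annotations
#'
#' Sidecar TSV with columns `record_id`, `role`, `start`, `end` (0-based
#' half-open residue intervals). Roles are `signal`, `pro`, `mature`,
#' `neurophysin` or `copeptin`.
#'
#' @param path TSV path
#' @param proteins named character vector or `AAStringSet` of the annotated
#'   reference proteins
#' @return named list of `reference_annotation` objects
#' @export
read_reference_annotation <- function(path, proteins) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("record_id", "role", "start", "end")
  if (!all(need %in% names(df)))
    stop("reference annotation TSV must have columns: ",
         paste(need, collapse = ", "))
  proteins <- as_protein_vector(proteins)
  out <- list()
  for (id in unique(df$record_id)) {
    if (!id %in% names(proteins))
      stop("annotated record not in reference FASTA: ", id)
    seg <- df[df$record_id == id, c("role", "start", "end")]
    out[[id]] <- reference_annotation(id, proteins[[id]], seg)
  }
  out
}

#' Construct a reference annotation
#'
#' @param id record id
#' @param seq precursor protein sequence
#' @param segments data.frame with columns `role`, `start`, `end` (0-based
#'   half-open, ordered, non-overlapping; a `signal` segment must start at 0)
#' @return object of class `reference_annotation`
#' @export
reference_annotation <- function(id, seq, segments) {
  segments <- segments[order(segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  n <- nchar(seq)
  if (any(segments$start < 0) || any(segments$end > n) ||
      any(segments$end <= segments$start))
    stop("segment interval outside sequence for ", id)
  if (nrow(segments) > 1 &&
      any(segments$start[-1] < segments$end[-nrow(segments)]))
    stop("overlapping segments for ", id)
  if ("signal" %in% segments$role &&
      segments$start[segments$role == "signal"][1] != 0)
    stop("signal segment must start at position 0 for ", id)
  structure(list(id = id, seq = seq, segments = segments),
            class = "reference_annotation")
}

as_protein_vector <- function(x) {
  if (methods::is(x, "XStringSet")) x <- as.character(x)
  if (!is.character(x) || is.null(names(x)))
    stop("expected a named character vector or XStringSet of proteins")
  x
}

#' Default run configuration
#'
#' Central tunables of the pipeline. Alignment defaults follow protein BLAST
#' (BLOSUM62, affine gap 11/1); the intron model is canonical GT-AG with a
#' flat opening penalty and a permitted length range.
#'
#' @param ... named overrides of any default
#' @return a validated `run_config` list
#' @export
default_config <- function(...) {
  cfg <- list(
    gap_open = 11L, gap_ext = 1L,
    min_score = 40L,
    intron_min = 40L, intron_max = 20000L, intron_open = 20L,
    donor = "GT", acceptor = "AG",
    cleavage_motifs = c("KR", "RR", "KK"),
    amidation_motifs = c("GRK", "GKR"),
    min_transfer_identity = 20,
    motif_window = 3L,
    seed = 1L,
    matrix = NULL)
  over <- list(...)
  cfg[names(over)] <- over
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(cfg$gap_open >= 0, cfg$gap_ext >= 0, cfg$intron_open >= 0,
            cfg$intron_min < cfg$intron_max, cfg$intron_min >= 4)
  if (is.null(cfg$matrix)) cfg$matrix <- default_matrix()
  structure(cfg, class = "run_config")
}

#' Read a plain-text key=value configuration file
#'
#' Lines of the form `key = value`; `#` comments allowed. Numeric values are
#' coerced, comma-separated values become vectors, `matrix` may name a
#' substitution-matrix file in NCBI text format.
#'
#' @param path config file path
#' @return a validated `run_config`
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & grepl("=", lines)]
  over <- list()
  for (l in lines) {
    kv <- strsplit(l, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    if (key == "matrix") { over$matrix <- read_score_matrix(val); next }
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    over[[key]] <- if (!anyNA(num)) {
      if (all(num == round(num))) as.integer(num) else num
    } else parts
  }
  do.call(default_config, over)
}

#' Write a JSON run manifest
#'
#' Records input paths, configuration (minus the matrix body), seed and
#' package version so a run can be reproduced exactly.
#'
#' @param path output JSON path
#' @param inputs named list/vector of input file paths
#' @param config a `run_config`
#' @param seed integer seed used for the run
#' @export
write_manifest <- function(path, inputs, config, seed) {
  cfg <- unclass(config)
  cfg$matrix <- NULL
  obj <- list(
    package = "antmine",
    version = as.character(packageVersion("antmine")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    inputs = as.list(inputs),
    config = cfg)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
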