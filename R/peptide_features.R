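#' Formal net charge of a peptide
#'
#' Counting scheme: +1 per Arg or Lys, -1 per Asp or Glu; His and the
#' termini are ignored. This integer scheme is the one under which the
#' published mature-defensin charges (+6/+5/+3/+5) and pro-domain charges
#' (-4/-3/-3/-4) are reproduced exactly; pH-dependent schemes would differ.
#' Additive over concatenation.
#'
#' @param seq amino-acid string (may be empty)
#' @return integer net charge in elementary charges
#' @export
net_charge <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  as.integer(sum(ch %in% c("R", "K")) - sum(ch %in% c("D", "E")))
}

#' Cysteine count, spacing and CSab classification
#'
#' Reports the cysteine network of a peptide: count, the spacing vector
#' (number of residues between consecutive cysteines) and whether the
#' peptide matches the cysteine-stabilized alpha-beta (CSab) spacing
#' template of insect defensins. The default template
#' `C-X(4-16)-C-X(2-5)-C-X(8-12)-C-X(4-8)-C-X(1)-C` is this package's
#' operationalization of the family's mature-domain alignments and is
#' configurable. When flagged, the disulfide pairing is reported by homology
#' convention as CI-CIV, CII-CV, CIII-CVI (never computed from structure).
#'
#' @param seq amino-acid string
#' @param spacing_ranges 5x2 matrix of inclusive bounds for the five
#'   inter-cysteine spacings
#' @return list with `count`, `spacing` (integer vector of length
#'   `count - 1`), `csab` (logical) and `pairing` (character, only when
#'   flagged)
#' @export
cys_network <- function(seq,
                        spacing_ranges = default_csab_ranges()) {
  pos <- which(strsplit(seq, "")[[1]] == "C")
  count <- length(pos)
  spacing <- if (count >= 2) diff(pos) - 1L else integer(0)
  csab <- count == 6L &&
    all(spacing >= spacing_ranges[, 1] & spacing <= spacing_ranges[, 2])
  list(count = count, spacing = spacing, csab = csab,
       pairing = if (csab) "1-4,2-5,3-6" else NA_character_)
}

#' Default CSab spacing template
#' @return 5x2 integer matrix of inclusive spacing bounds
#' @export
default_csab_ranges <- function() {
  matrix(c(4L, 16L,
           2L, 5L,
           8L, 12L,
           4L, 8L,
           1L, 1L), ncol = 2, byrow = TRUE,
         dimnames = list(paste0("gap", 1:5), c("min", "max")))
}

#' Residue-class composition of a peptide
#'
#' Counts over fixed residue classes: proline; hydrophobic (A,V,F,I,L,M,W,
#' Y,C); positive (R,K); negative (D,E). Fractions are count/length.
#'
#' @param seq amino-acid string
#' @return list with `pro_count`, `pro_fraction`, `hydrophobic_fraction`,
#'   `n_positive`, `n_negative`
#' @export
composition <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  list(pro_count = sum(ch == "P"),
       pro_fraction = if (n) sum(ch == "P") / n else 0,
       hydrophobic_fraction =
         if (n) sum(ch %in% c("A", "V", "F", "I", "L", "M", "W", "Y", "C")) / n
         else 0,
       n_positive = sum(ch %in% c("R", "K")),
       n_negative = sum(ch %in% c("D", "E")))
}

#' Charge complementarity of a pro-domain and its mature peptide
#'
#' Defensin pro-domains are anionic and 'neutralize' the strongly cationic
#' mature peptide during biosynthesis; the neutralization ratio quantifies
#' how much of the mature charge the pro-domain offsets.
#'
#' @param pro_seq,mature_seq amino-acid strings (non-empty)
#' @return list with `pro_charge`, `mature_charge` and `ratio`
#'   (`-pro_charge / mature_charge`; `NA` when the mature charge is 0)
#' @export
charge_complementarity <- function(pro_seq, mature_seq) {
  if (!nzchar(pro_seq) || !nzchar(mature_seq))
    stop("both sequences must be non-empty")
  pc <- net_charge(pro_seq)
  mc <- net_charge(mature_seq)
  list(pro_charge = pc, mature_charge = mc,
       ratio = if (mc == 0) NA_real_ else -pc / mc)
}

#' Feature profile of one peptide segment
#'
#' Combines length, formal charge, cysteine network, composition and the
#' amidation flag into one row of the feature table written by
#' [write_feature_table()].
#'
#' @param seq amino-acid string
#' @param id peptide id
#' @param role segment role (`signal`, `pro`, `mature`, ...)
#' @param amidated logical amidation flag (from precursor annotation)
#' @return one-row data.frame
#' @export
peptide_features <- function(seq, id, role = "mature", amidated = FALSE) {
  cys <- cys_network(seq)
  comp <- composition(seq)
  data.frame(id = id, role = role, length = nchar(seq),
             net_charge = net_charge(seq),
             n_positive = comp$n_positive, n_negative = comp$n_negative,
             n_cys = cys$count,
             pro_count = comp$pro_count,
             pro_fraction = round(comp$pro_fraction, 4),
             hydrophobic_fraction = round(comp$hydrophobic_fraction, 4),
             csab = cys$csab, amidated = amidated,
             stringsAsFactors = FALSE)
}
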