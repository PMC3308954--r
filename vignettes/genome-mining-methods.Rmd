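---
title: "Genome-mining of peptide precursor genes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-mining of peptide precursor genes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antmine)
```

## Scope and rationale

`antmine` mines peptide-encoding genes — cationic cysteine-rich defensins,
proline-rich abaecins, pilosulins, and neuropeptide precursors such as
inotocins (oxytocin/vasopressin-family nonapeptides with a neurophysin
carrier domain) and multi-peptide allatostatin precursors — from
whole-genome shotgun contigs. The approach is homology-driven throughout:
a known precursor from a related species is the query, and every
annotation (gene structure, segment boundaries, mature peptides) is
derived from alignment evidence plus short processing motifs. Nothing is
predicted *ab initio*; where classical workflows inserted manual curation
("refine and confirm"), this package substitutes explicit deterministic
rules so that a run is exactly reproducible from its inputs, configuration
and seed.

## Translated search

Contigs are translated in six frames; frames are **not** split at stop
codons. Instead stops appear as `*` and score −1000 against every residue,
which makes any alignment crossing a stop strictly worse than stopping —
local optima therefore end at stops naturally — while the frame's
coordinate map (residue *i* ↔ forward-strand codon interval) remains a
single arithmetic formula. Codons containing N translate to X.

Alignment is exact Smith–Waterman with affine gaps: a gap of length *k*
costs `gap_open + k · gap_ext`, defaults 11/1 with BLOSUM62 (the protein
BLAST defaults; the classical workflow fixed only the matrix, so the gap
costs follow the tool it emulated). Exactness matters here: desk-scale
contigs make it affordable, and it gives a clean correctness criterion —
the score must equal a brute-force enumeration of all gapped local
alignments, which the test suite checks on hundreds of short pairs and,
at scale, against an independent mature implementation on 10⁴ random
pairs.

Ties are broken deterministically (lowest subject start, then lowest query
start, then shortest alignment). Overlapping hits of the same (query,
contig, strand) whose DNA spans overlap at least 50 % of the shorter are
collapsed, keeping the higher score: a fixed, auditable stand-in for
manual removal of redundant HSPs. The minimum reported score is a
configuration knob (`min_score`, default 40) with no claimed provenance;
stringency appropriate for a family search (where cross-member homology is
real) differs from a single-locus benchmark, and the choice is the
user's.

## Spliced gene models

Gene structure comes from a GeneWise-style dynamic program over (query
residue, DNA position) with three state families:

* codon match — consumes one query residue and three bases, scoring
  `BLOSUM62(residue, translated codon)`;
* affine protein gaps — query residues against nothing, or whole codons
  against nothing (11/1, as in search);
* introns — entered only at the three codon phases (between codons, after
  the first base, after the second base), requiring `GT` at the donor and
  `AG` at the acceptor, with length constrained to
  `[intron_min, intron_max]` (defaults 40 and 20 000 bp) and a flat
  opening penalty of 20 matrix units. Phase-1/2 introns carry the split
  codon's leading bases through the intron state so the codon completes
  correctly on the far side.

There is no intron length distribution beyond the window — a flat penalty
keeps the optimum interpretable (an intron is added exactly when it buys
more than 20 units of match score) and the tie-break deterministic (fewer
introns preferred, implicitly, since equal-scoring intron paths lose to
match paths). Non-canonical splice sites and frameshift/error states are
out of scope by design: published gene diagrams for these families show
simple canonical structures, and error models would trade auditability for
generality.

The alignment is local in both query and DNA; a model is *complete* when
it covers the full query. The DP runs on a window: the union span of all
hits of one (query, contig, strand), padded by `intron_max` on both sides
and capped at the contig. Padding the union span (rather than a single
hit) matters for multi-intron genes, whose exons surface as separate
non-overlapping hits. Sliding-window maxima over donor positions keep the
whole DP linear in window length per query residue (21 donor queues: one
phase-0, four phase-1, sixteen phase-2 carried-base variants).

Single-exon ORF extension (`identify_orf`) is also available: from a hit,
walk 5′ in frame to the nearest ATG (failing at an in-frame stop) and 3′
to the first stop; failures flag the candidate *partial* rather than
discarding it, mirroring how partial evidence is tabulated rather than
dropped.

## Precursor segmentation by homology transfer

Segment boundaries (signal / pro / mature / neurophysin) are transferred
through a full Needleman–Wunsch alignment (end gaps penalized) from an
annotated reference. A boundary landing in a target gap moves to the
nearest following target position and is flagged `gap-adjusted`;
transfers below 20 % identity are refused outright as non-homology — a
floor low enough to admit any genuine family member yet high enough to
stop segment transfer between unrelated proteins.

Motif evidence then refines mature-peptide boundaries: dibasic convertase
sites (KR, RR, KK) and `G[R/K][R/K]` amidation signals within 3 residues
of a transferred boundary override it, and every override is logged with
before/after positions. When the two disagree by more than the window the
transferred boundary stands (both are reported). The amidated flag
requires a Gly immediately following the mature C-terminus — the glycine
that donates the C-terminal amide — with the `G[R/K][R/K]` context or a
precursor ending on the donor Gly itself.

Signal-peptide boundaries come from homology only; no predictor is
trained or embedded. A hydrophobic-core sanity check (Kyte–Doolittle) is
logged as a warning at most, never enforced, because the transfer source —
not a sequence model — is the method's stated evidence.

## Peptide features

The formal charge scheme is deliberately minimal: +1 per Arg/Lys, −1 per
Asp/Glu, His and termini ignored. This integer scheme is the one under
which the published family values (mature defensins +6/+5/+3/+5 against
pro-domains −4/−3/−3/−4, and an 8-positive/2-negative mature peptide) are
reproduced exactly; pH-dependent schemes would give non-integers and are
out of scope. Charge is additive over concatenation, which the suite
checks as a property.

The CSαβ classification requires exactly six cysteines with spacings
inside `C-X(4–16)-C-X(2–5)-C-X(8–12)-C-X(4–8)-C-X(1)-C`. These ranges are
this package's operationalization (fitted to the mature-domain alignments
of insect defensins), configurable via `cys_network()`; they are not a
published constant. Disulfide pairing is reported by homology convention
(CI–CIV, CII–CV, CIII–CVI), never computed from structure. The
hydrophobic class is A,V,F,I,L,M,W,Y,C — a stated choice, since
"hydrophobic content" has no single canonical residue set.

## Comparative layer

Progressive alignment uses k-mer (k = 3) cosine dissimilarity, a UPGMA
guide tree (average-linkage `hclust`), and profile–profile global
alignment with gap costs scaled by column occupancy. The default MSA gap
opening is 15 — stiffer than the pairwise 11 — because profile alignment
of divergent families accumulates spurious gap pairs under search-grade
costs; classical progressive aligners raise protein gap penalties for the
same reason. No attempt is made at bit-compatibility with any particular
aligner: quality is judged against a brute-force sum-of-pairs oracle on
exhaustive small instances (the progressive result must be within 5 % of
the enumerated optimum; in the shipped tests it attains it) and by
conserved-column properties on planted families.

Logo information content is `I_c = log₂ 20 − H_c` per column, frequencies
over the 20 standard residues with gaps excluded from the denominator and
no small-sample correction; all-gap columns carry zero information and a
flag. Residue positions in `map_position()` are 1-based (the convention
used when the field numbers mature-peptide positions); all interval
coordinates elsewhere are 0-based half-open on the forward strand, with
conversion to 1-based inclusive done only in the GFF3 writer.

## The synthetic-genome generator

`make_precursor()` builds precursors that satisfy an architecture template
exactly, so every downstream stage has ground truth:

* **defensin-like** — signal 24 aa (Met + hydrophobic core), pro-domain
  30 aa constructed to net charge −4 and ending in KR, mature domain
  43 aa at net charge +6 with six cysteines spaced 10/4/9/6/1 (inside the
  CSαβ ranges) and the family's conserved Asp at mature position 4 and Arg
  at 42; precursor length 97.
* **inotocin-like** — signal 25 aa, nonapeptide with cysteines at
  positions 1 and 6, the canonical GRK amidation/cleavage signal, then a
  113-aa neurophysin domain with 12 cysteines; precursor length 150.
* **multipeptide** — signal + anionic pro-domain + seven peptides of
  lengths 8, 8, 8, 7, 30, 9, 28, each followed by a donor Gly and a KR
  site (allatostatin-style).

`plant_gene()` reverse-translates with uniform synonymous codon choice,
inserts `GT…AG` introns at requested phases (lengths drawn 80–800 bp by
default; the configuration window, not the generator, covers
multi-kilobase introns), appends a stop codon and embeds the gene in
random background DNA of chosen GC fraction. Two realism constraints are
built in: every exon keeps at least 10 codons, because spliceosomal genes
do not carry near-zero-length exons and a terminal exon worth less than
the intron-open penalty is unidentifiable by *any* homology score (the
maximum-scoring model then genuinely differs from the planted one); and
intron interiors are random, so occasional alternative equal-scoring
splice placements can exist — the recovery benchmarks quote rates, not
certainties, for this reason.

What the generator does **not** emulate: codon-usage bias, repeat
families, sequencing error, paralog clusters on one contig, and UTR/
promoter context. Passing the planted-gene benchmarks therefore
demonstrates algorithmic correctness of search, splicing and annotation —
not robustness to assembly artifacts or to gene families denser than one
locus per contig.

`diverge_query()` emulates cross-species queries by substituting exactly
`round(d·L)` positions, preferring BLOSUM62-positive exchanges with
probability 0.7, no indels — so percent identity under a gap-free global
alignment is exactly `100·(1−d)` and benchmark divergence is a controlled
variable rather than a random outcome.

## Numerical and degenerate-input choices

* Integer scores throughout; no floating-point tolerances in aligners.
  The only tolerances in the suite are `1e-9` on logo entropies and the
  sum-of-pairs comparison.
* Empty local optimum (all pair scores negative) is a score-0 "no hit",
  not an error; spliced alignment with no positive-scoring model returns
  an explicit `no_prediction` model.
* Contigs shorter than one codon translate to six empty frames with a
  warning; empty FASTA files, duplicate ids and illegal protein residues
  are hard errors; DNA ambiguity codes normalize to N on load with a
  warning, never downstream.
* A neutral mature peptide makes the charge-complementarity ratio
  undefined; it is reported as `NA`, not 0.
* Benchmark problem sizes: 100 planted genes per divergence condition in
  the acceptance script (0–2 introns each), 12–20 genes in the
  per-module property tests, brute-force oracles up to length 5–6
  (pairwise) and three sequences (MSA). These sizes were chosen to
  exercise every code path with comfortable margins at desk scale.

## Known limitations

* Single best model per locus: tandem paralogs inside one window resolve
  to the best-scoring gene only.
* No E-value statistics; score thresholds are raw matrix units.
* Homology transfer inherits the reference's annotation errors; there is
  no independent signal-peptide or convertase-specificity model to catch
  them.
* The seeded-search accelerator mode described in the interface is
  intentionally conservative (exact mode is the default and the one all
  guarantees refer to).
* Real-genome validation (published precursor values, the multi-kilobase
  defensin intron) requires user-supplied sequences; see
  `inst/extdata/real/README.md`.

## A compact end-to-end run

```{r example, eval = FALSE}
g    <- synth_genome(5, architecture = "defensin", divergence = 0.1, seed = 11)
refs <- lapply(g$truth, function(tr) tr$annotation)
names(refs) <- vapply(g$truth, function(tr) tr$query_id, character(1))
rep  <- run_pipeline(g$contigs, g$queries, refs,
                     default_config(intron_max = 1200L, min_score = 200L),
                     outdir = tempfile("antmine_run_"))
rep$report
```
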