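# Real-sequence inputs (user-supplied)

Two of the acceptance checks validate the pipeline against published ant
sequences that cannot be redistributed with this package. To run them,
place the following plain-text files in this directory before installing:

- `ant_precursors.faa` — annotated ant precursor proteins (available via
  the GenBank third-party-annotation records BK008403–BK008420), with
  record ids `AcDEF`, `CfDEF1`, `CfDEF2`, `HsDEF1`, `HsDEF2`, `HsINT`,
  `AcAST`.
- `ant_precursors_segments.tsv` — segment annotations for those records
  (columns `record_id`, `role`, `start`, `end`; 0-based half-open residue
  intervals; roles `signal`, `pro`, `mature`, `neurophysin`).
- `ADTU01021145.1.fna` — the *Atta cephalotes* whole-genome-shotgun contig
  ADTU01021145.1 (GenBank), which carries the defensin gene with its long
  intron.

Without these files the corresponding acceptance tests fail with a message
pointing here; all synthetic-data tests are unaffected.
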