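# Reference sequences (not bundled)

This directory is where `pmfspot::reference_registry()` looks for the
public reference sequences used by the accession-dependent acceptance
checks: `OBP1.fasta`, `OBP2.fasta`, `VEG_RM.fasta`, `VEG_VNO.fasta`,
`SAL.fasta`, `EOGT.fasta`, `EOGT_cDNA.fasta`.

They are single public database records and are deliberately not
redistributed with the package. Fetch them once with

    bash scripts/fetch_references.sh

from the repository root (network required), or drop equivalently named
FASTA files here / into the directory named by
`options(pmfspot.reference_dir = ...)`. Until then, the acceptance tests
that compare against published sequence-derived values fail with an
explicit message; everything else runs on synthetic sequences.
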