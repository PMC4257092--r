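#!/usr/bin/env bash
# One-time fetch of the reference sequences named in
# pmfspot::reference_registry(). Network access required; run from the
# repository root. The files land in inst/extdata/reference/ (or set
# options(pmfspot.reference_dir=...) to point elsewhere for an installed
# package). None of these files are bundled with the package; the
# accession-derived acceptance checks stay red until they exist.
#
# Note on mature chains: the lipocalin entries below are deposited as
# mature sequences (porcine OBP NP_998961 is the 158-residue chain, SAL
# P81608 the protein-sequenced 175-residue chain). If a database revision
# ships a precursor instead, trim the signal peptide in the FASTA or adjust
# the registry before running the acceptance checks.
set -euo pipefail

dest="inst/extdata/reference"
mkdir -p "$dest"

efetch="https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi"

curl -fsS "$efetch?db=protein&id=NP_998961&rettype=fasta&retmode=text" \
  > "$dest/OBP1.fasta"
curl -fsS "$efetch?db=protein&id=AAO18367.1&rettype=fasta&retmode=text" \
  > "$dest/VEG_RM.fasta"
curl -fsS "$efetch?db=protein&id=AAB34720.1&rettype=fasta&retmode=text" \
  > "$dest/VEG_VNO.fasta"
curl -fsS "https://rest.uniprot.org/uniprotkb/P81608.fasta" \
  > "$dest/SAL.fasta"
# OBP2 splice variant exists only in Ensembl
curl -fsS "https://rest.ensembl.org/sequence/id/ENSSSCP00000028674?type=protein" \
  -H "Content-type: text/x-fasta" > "$dest/OBP2.fasta"
# EOGT: the cloned 1696-bp cDNA and its translation
curl -fsS "$efetch?db=nuccore&id=JX546149&rettype=fasta&retmode=text" \
  > "$dest/EOGT_cDNA.fasta"
curl -fsS "$efetch?db=nuccore&id=JX546149&rettype=fasta_cds_aa&retmode=text" \
  > "$dest/EOGT.fasta"

echo "fetched $(ls "$dest" | wc -l) files into $dest"
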