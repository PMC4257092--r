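# pmfspot

Peptide mass fingerprinting (PMF) and proteoform inference for
two-dimensional electrophoresis (2-DE) spots, in R.

Secreted proteomes such as nasal mucus resolve a handful of gene products
— odorant-binding lipocalins among them — into dozens of 2-DE spots:
full-length monomers, N-terminally truncated forms, chains missing the
encoded C-terminal lysine (des-Lys), SDS-resistant dimers, and
modification-bearing variants. `pmfspot` implements the computation that
turns a spot's MALDI-TOF peak list into a proteoform call:

1. **In-silico tryptic digestion** with ≤ 2 missed cleavages, Keil rule,
   and variable modifications (propionamide-Cys +71.03711 Da,
   oxidation-Met +15.99491 Da), reporting monoisotopic [M+H]⁺ in the
   500–4000 Da reflector window.
2. **Theoretical pI and MW**: Henderson–Hasselbalch net charge with the
   Bjellqvist (ProtParam) pKa set, solved by bisection; average-mass MW;
   (pI, kDa) spot-coordinate prediction with dimer doubling.
3. **Two-point recalibration** through internal reference ions
   (m/z 842.51 / 2211.10 trypsin-autolysis anchors) and **greedy
   one-to-one matching** of peaks to theoretical peptides at 50 ppm,
   scored as matched-peptide count with % sequence coverage.
4. **Ranked identification** over a candidate set with mixture flagging
   (≥ 2 candidates accepted at ≥ 4 matched peptides), and near-isobaric
   **ambiguity scanning** (e.g. splice variants distinguishable only by a
   ~0.12 Da peptide mass gap).
5. **Proteoform inference**: terminal status (PRESENT/ABSENT/UNDETERMINED,
   with absence only callable when the terminal fragment was observable),
   des-Lys two-hypothesis test, and gel-position flags
   (TRUNCATED/DIMER/CONSISTENT).
6. A **seeded simulator** (proteomes, proteoform families, peak lists with
   ppm error, dropout, contaminant peaks, miscalibrated calibrants, mixture
   spots) plus recovery scoring, so the whole pipeline is testable offline.

## Worked example

A synthetic world with four proteins; one spot generated from an
N-terminally truncated form of `SYN02` (first 13 residues lost at a
tryptic boundary), under 10 ppm mass error, 20% peptide dropout and 5
contaminant peaks:

```r
library(pmfspot)
cfg <- sim_config(seed = 7, n_proteins = 4, error_ppm_sd = 10,
                  dropout = 0.2, n_noise_peaks = 5)
sim <- simulate_proteome(cfg)
candidates <- lapply(sim$proteins, function(p) digest(proteoform(p), cfg$digest))

prot <- sim$proteins[[2]]
short_form <- apply_truncation(proteoform(prot),
                               c(cleavage_sites(prot$sequence)[1] + 1L,
                                 nchar(prot$sequence)))
#> <proteoform> SYN02 [14-192] x1 (ΔN1-13)

spot <- simulate_spot(short_form, cfg, "spot08")
id <- identify_spot(spot$peaklist, candidates)
identification_table(id)[1:2, ]
#>   spot_id rank    id accession matched coverage_pct accepted mixture_flag
#> 1  spot08    1 SYN02                44           73     TRUE        FALSE
#> 2  spot08    2 SYN04                 3           18    FALSE        FALSE

annotation_table(annotate_spot(id, spot$observed_gel))
#>   spot_id candidate n_status c_status inferred_start inferred_end   gel_flag
#> 1  spot08     SYN02   ABSENT  PRESENT             14          192 CONSISTENT
```

Reading the output: the spot identifies as `SYN02` (44 matched peptides,
73% coverage; the runner-up decoy picked up 3 chance matches and is not
accepted). No matched peptide overlaps the observable first tryptic
fragment, so the N-terminus is called **ABSENT** and the evidence hull
starts exactly at the true truncation point (residue 14); the C-terminal
peptide was matched, so the C-terminus is **PRESENT** — short forms lose
their N-terminus, never their C-terminus. The gel flag stays CONSISTENT
because a 13-residue loss on a 192-residue chain is within the 15% MW
deficit threshold for calling TRUNCATED from gel position alone.

A command-line entry point wires the same stages
(`digest`, `pi`, `calibrate`, `match`, `identify`, `annotate`, `simulate`,
`run`), e.g.:

```sh
Rscript -e 'pmfspot::pmfspot_main()' simulate --seed 3 --out sim
Rscript -e 'pmfspot::pmfspot_main()' run sim/proteome.fasta sim/spot*.tsv \
        --spots sim/spots.tsv --out results
```

Exit codes: 0 success, 2 malformed input, 3 empty candidate set.

## Layout

* `R/` — domain types and FASTA/registry I/O (`seqmodel`), mass and pI
  calculus (`masscalc`), digestion (`digest`), peak matching
  (`pmf_match`), proteoform inference (`proteoform_infer`), simulator
  (`synthetic_data`, `experiments`), pipeline/CLI (`cli`).
* `inst/extdata/tables/` — residue masses, pKa set, modification deltas
  as auditable TSV.
* `tests/testthat/` — unit and property tests with independent brute-force
  oracles; `test-acceptance.R` holds the acceptance criteria.
* `scripts/acceptance.R`, `scripts/fetch_references.sh` — see above.
* `vignettes/pmfspot-methods.Rmd` — model, assumptions, parameter
  rationale, simulator scope, limitations.
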