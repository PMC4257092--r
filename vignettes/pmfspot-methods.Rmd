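---
title: "Peptide mass fingerprinting and proteoform inference with pmfspot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peptide mass fingerprinting and proteoform inference with pmfspot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmfspot)
```

## The problem

Nasal-mucus and other secreted proteomes separated on two-dimensional gels
typically resolve one gene product into many spots: full-length chains,
N-terminally truncated forms, chains lacking the genome-encoded C-terminal
lysine (des-Lys), SDS-resistant dimers, and modification-bearing variants.
Peptide mass fingerprinting (PMF) identifies the protein in each excised
spot by matching the MALDI-TOF masses of its tryptic peptides against an
in-silico digest of candidate sequences; the *pattern* of matched and
missing peptides, together with the spot's gel position, then says *which
form* of the protein the spot contains. `pmfspot` implements this whole
chain of reasoning as composable, tested functions, and ships a seeded
simulator so every stage can be exercised without instrument data.

## The model, stage by stage

### In-silico digestion

Trypsin cleaves after Lys or Arg; by default the Keil convention is
applied (no cleavage before Pro, `no_p_rule = TRUE`). Peptides with up to
`max_missed = 2` missed cleavages are enumerated — every run of at most
three consecutive fully-cut fragments — matching common PMF search
practice for partially digested gel spots. Two variable modifications are
enumerated by default, reflecting what in-gel tryptic digests of
acrylamide gels actually contain:

* **propionamide** on Cys (+71.03711 Da), the acrylamide adduct, treated
  all-or-none per peptide (gel-exposed cysteines tend to react together);
* **oxidation** on Met (+15.99491 Da), up to two per peptide.

Carbamidomethyl-Cys, phospho and HexNAc deltas are shipped in the same
auditable TSV for MS/MS-style parameter sets and for the simulator, but
are not enumerated by default. The per-peptide state cap (64) prunes
deterministically, keeping lowest-count states, so fingerprints are
byte-stable. Reported masses are monoisotopic `[M+H]+` (proton
1.007276 Da), filtered to the 500–4000 Da reflector window.

Spans are always reported in **mature-chain coordinates of the parent
protein**, so a truncated proteoform's fingerprint aligns with the
full-length one. Precursor (signal-peptide) numbering is never exposed;
every interval the package prints is directly comparable across forms.

### Isoelectric point and gel coordinates

Net charge is the standard Henderson–Hasselbalch composition model
(positive: N-terminus, His, Lys, Arg; negative: C-terminus, Asp, Glu, Cys,
Tyr) with the Bjellqvist pKa set used by the ExPASy ProtParam family,
including residue-specific terminal pKa values. That set is the default
because published theoretical pI values for these proteins were computed
with ProtParam; reproducing them fixes the scale. The pI is found by
bisection on pH ∈ [0, 14] to `tol = 1e-3` (the charge is strictly
decreasing in pH, so the root is unique); the result is stable under
refinement and invariant under permutation of interior residues, because
the model sees only composition and terminal residue classes. Fixed
modifications contribute mass but no charge, again matching ProtParam
behavior. Predicted spot position pairs this pI with the average-mass MW
in kDa; dimers double MW and keep pI.

Theoretical MW claims are evaluated as **average** masses: the values this
package is checked against were produced by ProtParam-style tools, which
report average masses for whole chains. (The acceptance harness computes
both kinds, so if a fetched reference showed the printed value was
monoisotopic the discrepancy would be visible immediately.)

### Calibration and matching

MALDI spectra are recalibrated by the affine map through two internal
reference ions — conventionally matrix-cluster or trypsin-autolysis peaks
near m/z 842.51 and 2211.10 — which the map sends exactly onto their true
masses. Matching is greedy one-to-one nearest-mass assignment: all
(peak, peptide-state) pairs within tolerance, ranked by absolute error,
each peak and each (span, state) used at most once. Greedy was chosen over
optimal assignment because it is reproducible, trivially explainable, and
on realistic instances (peaks scattered near their true peptides) it
coincides with the exhaustive optimum — the test suite checks that
equivalence against a brute-force oracle on every instance with ≤ 8 peaks.
The default tolerance is 50 ppm, the only tolerance figure available from
the instrument settings this package models; it is a config key
(`match.tolerance` equivalent: `tol`/`tol_unit`).

The score is the matched-peptide count with coverage as tie information —
the "coverage % (peptides matched)" statistic of classic PMF tables — and
deliberately not a probabilistic (Mascot-style) score, which is out of
scope. A candidate is *accepted* at `min_matched = 4`; two accepted
candidates flag a mixture spot. Ties rank by coverage, then accession
string, so identification output is deterministic.

### Proteoform inference

Terminal status is called against the **full-length** fingerprint:

* N-terminus `PRESENT` iff a matched peptide starts at mature position 1;
* `ABSENT` iff no matched peptide overlaps the first tryptic fragment
  *and* that fragment was observable (at least one modification state
  inside the mass window and length bounds);
* `UNDETERMINED` otherwise — absence of evidence only counts as evidence
  of absence when the instrument could have seen the peptide.

The C-terminus is symmetric with the last fragment. The inferred span is
the *evidence hull* (min matched start, max matched end): PMF cannot see
inside unmatched regions, so truncation breakpoints are resolved only to
tryptic-fragment granularity, and a terminal `ABSENT` call carries an
`EXACT_BOUNDARY_UNKNOWN` note. A truncation whose breakpoint is not a
tryptic boundary (or sits in a run of single Lys/Arg fragments too light
for the mass window) is reported at the nearest observable boundary — the
biology of the short forms may be sharper than the mass spectrum can
prove.

The des-Lys call is a direct two-hypothesis test: the zero-missed
C-terminal peptide with and without the terminal Lys/Arg are both built,
and the peak list is asked which has support within tolerance
(`FULL` / `DES_K` / `BOTH` / `NEITHER`).

Gel-position consistency uses three mutually exclusive flags per accepted
candidate: `DIMER` when observed MW over predicted monomer MW falls in
[1.8, 2.2]; `TRUNCATED` when the observed MW deficit exceeds 15% *and* the
N-terminus was called `ABSENT`; `CONSISTENT` otherwise. Both bands are
config keys. Apparent MW from SDS gels is log-scale and can overshoot —
anomalously migrating dimers may sit near 2.7× the monomer — so the band
is deliberately a knob rather than a constant; widening it to cover such
spots is a per-study decision.

## The simulator: what it emulates and what it does not

`sim_config()` states the simulated world explicitly: multiplicative
Gaussian mass error in ppm (reflector-instrument convention; default
10 ppm SD), independent peptide dropout (default 0.2), uniform contaminant
peaks over the mass window (default 5), optional internal calibrant ions
under an affine miscalibration (slope 1.0002, offset −0.3 Da — enough to
push peaks many ppm off so two-point recalibration is exercised
meaningfully), and gel-coordinate noise of 0.05 pI units and 5% relative
MW, chosen so the default annotation thresholds separate a true >15%
truncation deficit from measurement scatter. Proteins are i.i.d. random
chains with a slight Lys/Arg over-weighting and a floor of three cleavage
sites, so tryptic fingerprints always exist.

The simulator does **not** model ionization efficiency or intensity,
isotope envelopes, charge states beyond +1, glycoform ladders, or
correlated dropout (hydrophobic stretches failing together). A green
recovery test therefore establishes that the *inference logic* is sound
under the stated noise model — not that real gel spots of real proteomes
will identify at the same rates. Conversely the per-spot ground truth
records everything emitted and dropped, so failures are attributable.

Under the stated world, the seeded experiments (also run by
`scripts/acceptance.R`) give: top-1 identification rate 1.00 over 200
replicates (10 ppm, 20% dropout, 5 decoys); N-truncation ABSENT-plus-hull
recovery 0.93–0.96 across seeds (≥ 0.90 required); and zero false
C-terminal ABSENT calls at zero noise. That last check is deterministic:
with no dropout and no mass error, every C-terminal peptide is present and
matched, so a false absence would be a logic bug, not bad luck.

## Numerical choices

* Residue masses, pKa values and modification deltas ship as plain TSV
  under `inst/extdata/tables/` so they can be audited and swapped.
* Water 18.010565/18.0153 Da (mono/avg), proton 1.007276 Da, fixed in code
  for bit-stable tests.
* Peak lists collapse m/z duplicates closer than 1e-6 Da (keeping maximum
  intensity), as an instrument would merge them into one centroid.
* Coverage uses the mature chain of the candidate's parent protein as
  denominator and is rounded to integer only for display.
* Bisection tolerance 1e-3 pH; all acceptance comparisons on pI use ±0.02.

## Reference sequences and offline behavior

The accession registry (`reference_registry()`) names the public database
entries whose published theoretical values (pI 4.23/4.89/5.07, MW
17835/19916 Da, diagnostic peptide masses 1498.7424/1498.6227/2296.0714,
mature lengths 158/175/509, cDNA 1696 bp) anchor the accession-dependent
acceptance checks. Those FASTA files are fetched once with
`scripts/fetch_references.sh` and are not bundled; on a machine without
them the corresponding acceptance tests fail with an explicit message
rather than silently passing on stand-in data, and the test suite's other
~770 assertions run entirely on synthetic sequences. The registry stores
both VEG variants (Leu141 RM form and Pro141 VNO form) so a user with the
sequences can record which reproduces the published pI.

## Known limitations

* Semi-tryptic and non-specific cleavage, protease mixtures, and MS/MS
  fragment matching are out of scope.
* The greedy matcher's optimality is validated, not proven; pathological
  peak layouts could in principle make it drop one assignment relative to
  the optimum (ambiguities are surfaced by `ambiguity_scan()` instead of
  multi-assignment).
* pI ignores modification charge effects (phosphate would shift it); this
  mirrors the tool the published values came from.
* Truncation breakpoints are evidence hulls, not molecular termini.
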