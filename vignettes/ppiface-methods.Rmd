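---
title: "Methods: catalog-based interface prediction and contact-distance validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: catalog-based interface prediction and contact-distance validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiface)
```

## The method

`ppiface` is a knowledge-based tool. It does not score, fold, or learn: it
answers the binary question *do these two proteins carry a matched
complement of catalogued interaction signatures, and — if a dimer model is
available — are those signatures close enough in space to interact?*

The pipeline has two halves.

**Bottom-up (sequence only).** Each protein is annotated with located
domains (Pfam accessions with 1-based inclusive residue ranges, from
InterProScan TSV or the InterPro API) and located motifs (ELM class
occurrences, from an ELM-style TSV or the package's own regex scanner).
Candidates are the cross-protein region pairs whose identifiers appear in
the catalogs: a pair of Pfam IDs in the DDI catalog, or an
(ELM class, Pfam domain) record in the DMI catalog. A candidate is emitted
only when each protein contributes one half of the pair. The output is
occurrence-level — one row per region pair with both coordinate ranges —
so it can directly drive cropping of the sequences for structure
prediction of just the putative interface.

**Top-down (with a dimer model).** Each candidate's two regions are mapped
onto two chains of a PDB-format model. The contact statistic is the
minimum alpha-carbon distance between the regions,

$$d(A, B) \;=\; \min_{i \in A,\; j \in B} \lVert \mathbf{r}^{CA}_i - \mathbf{r}^{CA}_j \rVert,$$

and the candidate passes a cutoff $c$ iff $d \le c$. One CA per residue is
a deliberate coarse-graining: it is the granularity at which interaction
catalogs are annotated, it is robust to side-chain placement errors in
predicted models, and it matches contact-map semantics. Residue pairs with
$d_{ij} \le c$ are reported as labeled contacts (chain, residue number,
amino acid, distance, sorted by distance).

### Assumptions

- Catalog completeness bounds recall: an interface whose domain pair or
  motif class is absent from the snapshot is invisible to the method.
- Annotation coordinates equal structure residue numbers up to an additive
  per-chain offset. For AlphaFold-style models (chains numbered from 1 in
  sequence coordinates) the default offset 0 is exact; renumbered
  experimental structures need an explicit offset in the `chain_map`.
- The model shows the binding-competent conformation. A correct candidate
  on a wrong model fails the filter; that is a property of the model, not
  of the candidate.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| contact cutoff | user-set; 6 is a practical single-cutoff choice | Å | tight enough to exclude incidental proximity, loose enough for CA coarse-graining |
| sweep | 11 → 4, step 1 | Å | 11 Å is the CA–CA interaction ceiling used by coarse-grained elastic-network models; interfaces are not observed below 4 Å |
| `keep_analyses` | `"Pfam"` | — | catalogs key on Pfam IDs, so other InterProScan analyses carry no catalog signal |
| `overlapping` (scanner) | `TRUE` | — | SLiM occurrences can overlap; a non-overlapping scan silently loses candidates (flag gives parity with non-overlapping locators) |
| crop `flank` | 0 | residues | region cropping is exact by default; flanking context is an explicit user choice |
| chain offsets | 0 | residues | exact for AlphaFold-style numbering |

Pass/fail uses `<=` with no epsilon, in double precision. A candidate whose
minimum distance equals the cutoff at full precision passes; the test suite
carries an exact-boundary case. Å values are formatted to 3 decimals in
file output (PDB coordinate precision); internal comparisons always use
full precision.

## Numerical and parsing choices

- **Unordered DDI pairs.** Physical interaction is symmetric, so `(A,B)`
  and `(B,A)` are one catalog entry, stored lexicographically sorted.
  Self-pairs are kept (homotypic interactions exist). A consequence: a
  pair count computed this way may differ from counts derived from ordered
  treatments of the same source snapshots.
- **Pfam version suffixes** (`PF00001.21`) are stripped on ingest; source
  releases differ in whether they carry them. Rows that do not normalize
  to `PF` + 5 digits are skipped and counted, not fatal.
- **Scanner anchoring.** Overlapping matches are found with a zero-width
  lookahead wrapper over the class pattern, so `^` and `$` anchor to the
  full sequence, not to a suffix. Zero-length matches are discarded.
  Sequences are uppercased; `X` matches only an explicit `X` or a `.`
  wildcard (standard regex semantics, documented rather than
  special-cased).
- **PDB ingest.** Only the first model of a multi-model file is read.
  HETATM records are dropped unless the residue is a standard amino acid.
  Alternate locations resolve to the highest-occupancy conformer, ties
  broken by altloc letter; surviving duplicate CAs keep the first record
  with a warning. Insertion-coded residues are kept and addressed by
  (number, icode), but range selection is by residue number only — a
  documented limitation.
- **Degenerate inputs.** An empty residue selection has no defined
  distance: `min_region_distance` raises a classed condition rather than
  returning a large sentinel, and `filter_by_distance` reports such
  candidates as a third category, `unevaluable`, distinct from pass and
  fail. Identical selections (a homodimer misconfiguration) give 0 Å
  rather than an error, since the chain map already forbids mapping both
  proteins to one chain.
- **Determinism.** Candidate tables sort by (interaction kind, start_a,
  start_b, ids); contact lists by (distance, residue numbers); catalogs
  serialize in lexicographic order. Identical inputs give byte-identical
  outputs.

## Open design points, and the choices made

- *Does a candidate need one contacting pair or several?* One: the
  statistic is the minimum distance, and `n_contacts` is reported so users
  can apply a stricter count themselves. This is the natural reading of a
  contact-distance filter and keeps pass/fail equivalent to "the labeled
  contact list is non-empty" (a tested invariant).
- *Are repeated occurrences of one catalogued pair collapsed?*
  No — occurrence-level rows are kept, because the top-down stage needs
  concrete coordinates per copy (e.g. each ankyrin repeat separately).
- *No 4 Å floor is enforced.* The absence of observed interfaces below
  4 Å is an empirical regularity, not an algorithmic constraint; the sweep
  default simply stops there.
- *Prediction with no domains on either side* raises the capability error
  even if only one side has motifs: with no domain anywhere, neither a DDI
  nor a DMI is expressible. Fully empty annotation bundles are rejected
  earlier, as a validation error.
- *Statelessness.* Every prediction call takes all inputs explicitly and
  the CLI is one-shot; there is no session state to go stale between
  protein pairs.

## What the synthetic fixtures emulate — and what they do not

`toy_fixture_spec()` + `make_toy_fixture()` build a two-chain dimer in
which every inter-region minimum distance is planted by construction:
regions are straight CA traces at the canonical 3.8 Å spacing, the two
regions of a pair share an x-grid and are separated along y by exactly the
target distance (so the minimum is attained at the aligned residues and is
exact at PDB 3-decimal precision), and successive pairs are separated by
100 Å blocks so cross-pair distances cannot interfere. Planted interfaces
draw their distances from 4.5–5.5 Å — inside a 6 Å filter — and decoys
from 20–30 Å, with the 20 Å floor enforced at generation time. Decoy pairs
*are* catalogued: they must be emitted by the bottom-up stage and rejected
only by geometry, which is exactly the separation of concerns the two
stages claim. All randomness is consumed in the spec constructor under one
seed; the generators are pure functions of the spec, and one seed yields
byte-identical PDB text.

What this does **not** emulate: real backbone geometry (no folds, no
clashes), partially resolved or renumbered chains, noisy or alternative
model conformations, catalog incompleteness, and motif overprediction on
disordered sequence. Passing the fixture suite therefore demonstrates the
correctness of the bookkeeping and the geometry — catalog membership,
occurrence pairing, coordinate mapping, distance computation, filtering,
labeling — not the field performance of the method on predicted models,
which is capped by catalog and model quality.

## Verification sizes

The test and acceptance suites run at fixed sizes chosen to exercise the
properties thoroughly while staying quick: 50 seeded fixtures for
planted-interface recovery and decoy rejection (at 6 Å); 200 random region
pairs up to 50×50 residues for exact agreement between the vectorized
distance path and an exhaustive double-loop oracle; sweep nesting
(pass(d₁) ⊆ pass(d₂) for d₁ ≤ d₂ over 11…4 Å) on every fixture; and 100
random 120-residue sequences × 5 toy motif classes for scanner/oracle
equivalence, including overlapping matches (`"AAAA"` against `"AA"` gives
3). The whole suite completes in well under a minute on one CPU.

## Known limitations

- CA–CA distance is a proxy; hydrogen-bond and salt-bridge geometry are
  not evaluated.
- mmCIF input is not supported; convert to PDB first.
- Range selection ignores insertion codes (see above).
- DOMINE-style confidence classes are ingested but not interpreted; the
  method is binary catalog membership, with no ranking of candidates.
- The ELM/InterPro fetchers are minimal REST clients behind an explicit
  network flag; batch retrieval and caching are out of scope.
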