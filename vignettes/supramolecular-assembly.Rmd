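---
title: "Assembling supramolecular complex models from interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling supramolecular complex models from interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppicomplex)
```

## The modeling problem

Most cellular machines are non-covalent assemblies of many protein
subunits, but experimental structures overwhelmingly cover single chains
or binary complexes.  Interaction databases, on the other hand, record
hundreds of thousands of binary protein-protein interactions with no
geometry at all.  `ppicomplex` bridges the two: it extracts *structure
elements* — experimentally determined binary complexes whose chains are
homologous to a recorded interacting pair — and stitches them into
multi-subunit models by iteratively superposing shared subunits.  The
models are then annotated: which subunit contacts are experimentally
templated, which are predicted or newly suggested, which recorded
interactions are actually indirect, which interface sites are mutually
exclusive alternatives, and where amino-acid variants fall on the
assembled surfaces.

## Procedure and assumptions

1. **Element extraction.** Every recorded interaction `(A, B)` is
   classified against the structure library.  Chains with sequence
   identity strictly above 25% to a partner (computed by Smith-Waterman
   local alignment over aligned columns only) are homologues; a pair is
   *complex*-category when homologues of both partners are co-determined
   in one entry.  Coverage is deliberately not a filter — partial
   structures are usable templates, and quality control happens later at
   the superposition gate.  Among candidate chain pairs the one with the
   highest average identity becomes the element; ties break
   lexicographically and runners-up are kept in provenance.
2. **Modelable sub-networks.** Single-linkage clustering (connected
   components) of the element-bearing interaction graph yields the
   sub-networks; node degree is the number of distinct partners, a
   homodimer self-loop contributing one.
3. **Iterative assembly.** A model is seeded with the start node's
   highest-degree edge.  Repeatedly, the placed subunit with the largest
   degree (not yet exhausted) anchors the next superpositions: for every
   unused element incident to the anchor's protein, the element's shared
   chain is structurally aligned onto the anchor.  The placement is
   accepted only if the alignment passes the gate below; it is discarded
   as an *alternative interface* if the introduced subunit sterically
   hinders the model; otherwise the partner is placed.  Iteration ends
   when no element can introduce anything.  Target sequences are mapped
   onto template chains by alignment; no comparative modeling of the
   subunits is attempted.
4. **Interfaces.** A subunit pair with buried surface area above
   250 Å² is an interface; sites on one subunit used by several
   partners are merged into one alternative-capable site when they share
   at least 10% of buried area.
5. **Annotation.** Interfaces realized by an element during assembly are
   *experimentally determined*; detected contacts whose pair is recorded
   but untemplated are *model-predicted*; contacts recorded nowhere are
   *model-suggested*.  Recorded interactions between placed subunits that
   share no interface are flagged *indirect*.
6. **Evaluation and variants.** Models spanning several template entries
   are compared against reference complexes (virtual blind test, l-rms
   convention with CAPRI classes).  Models are extrapolated to homologous
   subunit combinations, and variants are mapped to interface / surface /
   interior / disordered environments with enrichment statistics.

The core assumption throughout is rigid-body transferability: a binary
complex geometry observed for homologues is assumed to hold for the
target pair, and error control is purely geometric (the acceptance gate
and the clash test), not energetic.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `min_identity` | 0.25 | exclusive homology threshold (fraction identical over aligned columns) |
| `min_score` | 25 | Smith-Waterman score floor below which an alignment is treated as absent |
| gate: high band | identity > 0.30 and TM > 0.5 | accept superposition |
| gate: low band | 0.25 ≤ identity ≤ 0.30 and TM > 0.6 | accept superposition |
| `clash_max_pairs`, `clash_dist` | 10 pairs, 3.0 Å | candidate rejected when ≥ 10 Cα pairs sit closer than 3 Å to the existing model |
| interface area | 250 Å² | larger per-subunit buried area must exceed this |
| overlap fraction | 0.10 | shared buried area / smaller interface area; at or above this, sites merge |
| SASA probe, points | 1.4 Å, 960 | Shrake-Rupley probe radius and sphere samples per atom |
| buried-residue cutoff | 0.1 Å² | minimum per-residue area loss to count as interface residue |
| relative accessibility | 0.1 | below this (residue SASA / Gly-X-Gly maximum) a residue is interior |
| CAPRI bounds | 1 / 5 / 10 Å | closed upper limits of high / medium / acceptable |

The identity bands of the gate are read strictly: identity exactly 0.30
falls in the stricter band, identity exactly 0.25 is admitted to it.
The score floor exists because a local alignment of unrelated sequences
always produces some short positive-scoring hit, which would make any
identity threshold meaningless; 25 is roughly the shortest identity run
that is unlikely by chance between unrelated proteins.

## Numerical choices

* **Superposition** is closed-form least squares via SVD, with a
  reflection-only optimum corrected to a proper rotation.  The test
  suite cross-checks it against an independent quaternion-eigenvector
  solver.
* **TM-score** uses the standard normalization
  `d0 = 1.24 (L - 15)^(1/3) - 1.8`, floored at 0.5 Å, with `L` the
  length of the anchor (fixed) chain — recorded per superposition so the
  convention is auditable.  The maximization runs an exhaustive
  fragment-seed search (every contiguous window of length ≥ 5, each
  refined by keep-close-pairs / re-superpose iteration with cutoff
  `max(d0, 3.5)` Å).  This is affordable because chains here are short;
  the search stops early once the theoretical maximum is reached.
* **Structural alignment** is sequence-guided: residue correspondence
  comes from the local sequence alignment and is refined by dropping
  pairs beyond `2 d0` and re-superposing (≤ 10 rounds).  This
  deliberately simplified aligner provides the score semantics the gate
  needs; it does not attempt sequence-independent alignment, so exact
  agreement with full structural aligners is not promised.  The one
  place that needs a sequence-free comparison — classifying
  alternative-interface partners as same-fold — falls back to rank-order
  residue pairing when sequences cannot be aligned.
* **SASA** is an internal Shrake-Rupley implementation (deterministic
  golden-spiral point lattice, standard van der Waals radii, probe
  1.4 Å).  Values are not DSSP-exact.  At matched 10,000-point density
  the suite bounds the per-residue deviation from an independent
  rotated-lattice oracle at 2%; the 960-point default trades up to a
  few percent of per-residue discretization (total areas within ~0.3%)
  for an order-of-magnitude speedup.  Buried-area computations reuse
  cached isolated-chain atom areas and recompute only atoms close
  enough to a partner to be occluded.
* **Interface overlap** uses the smaller interface as denominator, and
  the 250 Å² test uses the larger of the two per-subunit buried areas;
  both are stated conventions where the definitions are genuinely open.
* **Deduplication** of models grown from different starting points is by
  protein multiset plus the set of geometric contacts (pairs with ≥ 3 Cα
  pairs within 8 Å).  Template-usage sets would distinguish models that
  differ only in which redundant cycle edge went unused; geometry does
  not.
* **Degenerate inputs**: residues without atoms are retained as
  disordered and classify as such; multi-model structure files
  contribute model 1 only; alternate locations keep the
  highest-occupancy conformer; selenomethionine maps to M, other
  non-standard residues to X with atoms retained.

## The synthetic-data generator

Real structural data cannot ship with tests, so every stage is
exercised on generated fixtures with known ground truth.  Each protein
chain is an idealized four-helix bundle (helices on an 8.5 Å square,
up-down-up-down, ideal backbone plus Cβ) with coordinate-less loops and
a tail.  That shape is the smallest one that provides all the molecular
environments at once: a genuinely buried core (relative accessibility of
inward residues ≈ 0.03–0.05), four flat contact faces, exposed surface,
and disordered stretches.  Complexes are laid out on a lattice —
star, path, ring (a closed walk on a two-row lattice), complete
(path geometry with a complete interaction table) and two-blocks (two
branches competing for one site) — with edge-to-edge contacts burying
≈ 400 Å² per side at a 16 Å center distance, comfortably above the
interface threshold and safely outside the steric-clash regime.

Each ground-truth contact is emitted as its own two-chain "crystal"
entry under a random rigid frame, so assembly must genuinely re-derive
the complex by superposition.  Sequences are random 19-letter strings
(no proline, whose conservative partner would score negatively);
candidates are re-drawn until no spurious homology (> 25% local-alignment
identity, checked for full sequences and coordinate-bearing
subsequences in all combinations) exists between distinct proteins, so
the planted homology relations are the only ones present.  Planted
homologues are produced by substituting evenly spaced interior positions
with conservative partners (BLOSUM62 ≥ 0), which keeps local alignments
full-length and makes the realized identity equal the planted fraction.
Interaction tables can be made supersets (extra non-contact pairs,
tagged with co-complex detection methods) and subsets (a dropped
redundant edge, or a dropped entry with the record kept) of the true
contacts, exercising the indirect, model-suggested and model-predicted
paths.

What the generator does **not** emulate: side-chain chemistry and
packing, flexible linkers, domain motions, partial-coverage templates
with shifted alignments, crystallographic artifacts, and noisy
interaction data beyond the planted superset/subset edits.  Passing
tests therefore demonstrate the correctness of the algorithmic machinery
under rigid, well-separated geometry — not modeling accuracy on real
complexes, which depends on template quality and the rigid-body
assumption in ways no synthetic fixture can certify.

## Problem sizes

The suite runs complexes of 3–8 subunits with chains of ~61 residues
(~240 heavy atoms), 25 seeded recovery cases across all five topologies,
1,000 random point sets for the superposition oracle, 10,000-point
dense sampling for the surface-area oracle, exhaustive hypergeometric
enumeration up to margins of 30, and 100 seeded replicates of a
2,000-variant enrichment cohort.  These sizes keep every oracle exact
or near-exact while exercising each code path.

## Known limitations

* Homology is decided by a single local alignment; profile methods
  would be more sensitive and BLAST-identical numbers are not expected.
* The simplified structural aligner cannot rescue pairs whose sequences
  do not align, so remote homologs that only TM-align would pair are
  missed by the gate.
* One element places at most one copy of a protein per model; genuinely
  polymeric assemblies need distinct network nodes per copy.
* Interface areas are Cβ-level approximations on fixtures; on real
  all-atom structures values will differ from DSSP by the documented
  SASA tolerance.
* Enrichment tests treat variants as independent observations, as the
  source tables do.
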