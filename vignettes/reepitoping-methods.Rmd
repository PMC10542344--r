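---
title: "Re-epitoping methods: interface accounting, focused libraries, and epitope prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Re-epitoping methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reepitope)
```

## The problem this package addresses

Re-epitoping is the redirection of a mature antibody to a new, unrelated
antigen with as few mutations as possible. A mature antibody that is close
to its germline V genes keeps much of a germline antibody's structural
plasticity: many of its paratope residues are unmutated germline residues
that can, in principle, be reused against a different epitope. The
engineering recipe this package supports has four computational legs:

1. **Interface accounting.** Quantify the template's existing
   antibody-antigen interface (paratope and epitope at a 5 Å heavy-atom
   cutoff, buried surface area, shape complementarity) and, once a
   redesigned complex is solved, measure how much of the paratope is
   conserved between the old and new complexes, position by position in a
   common numbering scheme, with the germline status of each conserved
   position.
2. **Focused library design.** Represent a small library that varies a
   handful of structurally chosen positions with restricted residue choices
   (plus optional single-residue insertions), and compute its exact size and
   its variants' identity to the template — the quantities that justify the
   word "focused".
3. **Epitope prediction.** Two random-forest classifiers: a pairwise one
   (antibody position × antigen residue interaction likelihood, from
   sequence and antigen-surface features) and a pose-level one (native-like
   versus decoy rigid-body docking poses, from interface features). Their
   agreement nominates a candidate epitope for the template on the new
   antigen.
4. **Developability guarding.** Spatial aggregation propensity (SAP)
   scoring of exposed hydrophobic patches, to pick surface positions whose
   mutation to polar residues improves behaviour in solution.

Everything is driven from flat tibbles (one row per atom, per residue
position, per scored pair), so results compose with ordinary dplyr
pipelines.

## Structure handling

Structures load from PDB or mmCIF through `bio3d` into a plain atom tibble.
Loading applies three normalisations, chosen to match how heavy-atom
contact criteria are used on deposited X-ray models:

* waters, ions and non-polymer ligands are dropped (only residues with a
  3-to-1 amino-acid mapping are kept, including MSE and similar modified
  residues), because buffer components sitting in an interface would
  otherwise create spurious 5 Å contacts;
* hydrogens are dropped even if present — deposited X-ray models are
  heavy-atom models and the contact conventions here are heavy-atom
  conventions;
* for alternate locations only the highest-occupancy altloc is kept, ties
  resolved in favour of altloc `A` and then lexicographically.

Author residue numbering with insertion codes is the canonical residue
coordinate system throughout; 1-based sequence indices are derived, never
primary.

## Contacts, interface area, and shape complementarity

A residue pair is **in contact** iff *any* heavy-atom pair across the two
sides is at distance ≤ the cutoff (default 5.0 Å, inclusive, no per-atom
radii). The production implementation bins atoms into a spatial grid of
cell size equal to the cutoff; the defining exhaustive O(n²) double loop is
retained as `method = "brute"` and the test suite asserts the two agree
exactly on every fixture.

**SASA** is Shrake–Rupley sphere sampling: each atom is expanded by the
probe radius (1.4 Å, water-sized) and covered with a deterministic
golden-spiral point set (240 points per atom wherever an area in physical
units is reported; doubling the count moves an isolated sphere's area by
well under 1%). Element radii are a Bondi-style table shipped in the
package (`C` 1.70, `N` 1.55, `O` 1.52, `S` 1.80, …, fallback to carbon).
Because the point sphere is fixed in the global frame, SASA is exactly
translation-invariant but rotation-invariant only to the sampling
resolution — the tests assert exactness under translation and agreement at
sampling tolerance under rotation.

**Buried surface area** is reported under both conventions in one row:
`delta_sasa` = SASA(A) + SASA(B) − SASA(AB), and `delta_sasa_half` =
half of that (the per-complex "interface area" convention). Published
interface areas use either convention without saying so; reporting both,
labelled, lets a user pin whichever matches an external number, and the
per-side burials sum to `delta_sasa` exactly because all three SASA terms
share one sampling.

**Shape complementarity** follows the Lawrence–Colman idea on dot surfaces:
exposed van der Waals surface points (with outward normals) are built for
each side in isolation, restricted to an interface band (points within
`band` of the facing side's surface, default 6 Å), and each point is scored
against its nearest facing point as `(n_a · −n_b) · exp(−w · d²)` with
`w = 0.5 Å⁻²`; the statistic is the median over both directions. On this
per-atom surface definition the ideally complementary construction is a
pair of concentric spheres (an atom nested in a dense shell at van der
Waals contact), which scores above 0.9; inserting a gap drops the score
sharply, and the tests assert both.

## Antibody numbering and germline comparison

Numbering is **alignment transfer**: the reference germline FASTA carries
IMGT scheme numbers in its headers (`numbers=1,2,3,…`, one per residue, so
IMGT gaps are simply absent), the query chain is aligned to its
best-matching reference (BLOSUM62, the full germline span aligned, the
query free to extend), and scheme numbers transfer across the alignment.
Query insertions receive insertion letters on the preceding number. Query
residues beyond reference coverage — the CDR3 tail and FR4 — are numbered
sequentially from the last transferred number rather than with the
symmetric IMGT CDR3 gapping; this is a declared simplification that is
exact for V regions at or near germline, which is the regime this toolkit
targets (near-germline templates are what make re-epitoping plausible in
the first place). Region labels are a pure function of the scheme number
(CDR1 27–38, CDR2 56–65, CDR3 105–117).

Germline assignment returns the highest-identity gene (ties to the
alphabetically first name), with identity computed over the germline span
only — the query's CDR3/J tail is excluded — and gaps counted as
mismatches. Positions beyond V-gene coverage are flagged *uncovered*, never
*germline*: a CDR3 position cannot be credited to the germline V gene.

Reference sequences are user-supplied (germline databases are licensed for
redistribution only by their providers); the package ships only synthetic
stand-in germlines, generated by the fixtures module with recorded ground
truth.

## Focused libraries

A library specification is a template sequence, a set of varied positions
with explicit allowed-residue strings, and optional insertion slots. The
exact size is the product over varied positions of the number of distinct
allowed residues (singleton sets contribute 1) times `k + 1` per optional
insertion of `k` residues (`k` if mandatory). Counting is at the protein
level; degenerate codons are supported as annotations whose translated set
(stops excluded) must equal the position's allowed set, with `NNS`/`NNK`
expanding to all 20 amino acids plus a stop flag.

Identity statistics use `100 × matches / aligned length` with insertions
counted as non-matches: the minimum is closed-form (every position that can
change does, every lengthening insertion taken), the mean averages the
exact per-stratum identity over the uniform grid, and both are verified
against full-enumeration oracles in the tests. One representational caveat
is documented rather than hidden: with several optional insertions, two
insertion states can in principle collide into the same string when an
inserted residue duplicates the adjacent template residue; the closed-form
size is the grid product, and the shipped specifications avoid the
degenerate case.

The shipped example specification reproduces the *count structure* of a
first-generation focused library — 16 positions at two allowed residues
each plus one optional single-residue insertion in heavy CDR3, i.e.
2¹⁶ × 2 = 131,072 protein variants on a 231-residue Fv — on a synthetic
template (the file is named accordingly), since the literal template and
residue choices are readable only from a figure and belong in a
user-editable spec file.

## The pose classifier

The docking engine itself is out of scope; poses are rigid placements of an
antibody relative to a fixed antigen, produced by the decoy generator or
supplied by the user, with optional engine scores. Near decoys perturb the
native placement (default ≤ 3° rotation, ≤ 0.5 Å translation); far decoys
are uniform random orientations on a sphere around the antigen with clash
rejection (no heavy-atom pair under 2 Å). Poses are labelled by **fnat**,
the fraction of native residue contacts preserved: native-like at
fnat ≥ 0.5, decoy at ≤ 0.1, ambiguous in between and excluded from
training (configurable, recorded in model metadata).

The feature vector has four groups, in a fixed versioned schema:
interface size (residue counts per side, buried area), interface amino-acid
composition (20 fractions per side), specific interactions (N/O
donor–acceptor heavy-atom pairs ≤ 3.5 Å; opposite formal-charge side-chain
group pairs ≤ 4.0 Å — an angle-free hydrogen-bond surrogate, appropriate
for hydrogen-free X-ray models), and the engine score's placement within
its docking run (rank fraction, z-score, percentile; neutral constants
0.5/0/0.5 when no run scores exist). The forest is 500 trees by default,
√p features per split, with a mandatory seed; cross-validation folds are
grouped by source complex so no complex straddles folds, and AUC is the
rank statistic on held-out poses (cross-checked against an independent ROC
implementation in the tests).

Panel screening scores each antibody's poses, keeps the best, sorts the
panel by best score with ties broken by antibody id, and reports each hit's
implied epitope (antigen residues within 5 Å of the best pose).

## The pairwise classifier

Corpus curation implements three filters and a redundancy rule: keep
entries with resolution strictly better than 3.0 Å, a protein antigen, and
a paired (not single-chain) antibody; then treat two entries as redundant
iff their antigens exceed 95% sequence identity *and* their
antigen-binding regions exceed 85%, keeping the best-resolution member of
each redundant group (ties to the lexicographically first id). The
antigen-binding-region definition used for redundancy is approximated by
the IMGT CDRs with two flanking positions, since the original server-based
definition is not reproducible offline. The survivor set is independent of
input order, and curation is idempotent.

Pairs are featurised from sequence and antigen surface: one-hot antibody
and antigen residue types, antibody chain × region one-hots, the antigen
residue's relative side-chain exposure, the ±2 sequence context as
physico-chemical descriptors (hydropathy, formal charge, volume), and
three pair complementarity terms (charge product, hydropathy product,
volume sum). The exact feature list of the original classifier is not
public, so this schema is a declared, versioned reconstruction; persisted
models refuse features from another schema version. Negatives are a seeded
per-entry subsample of non-contact cells at a stated ratio. Heavy and
light chains are trained separately, fourfold grouped by entry.

Scoring a query antibody against an antigen structure excludes buried
antigen residues (relative side-chain exposure below 0.05) from the
columns, reports the full position × surface-residue probability matrix,
and derives an epitope patch from the top-k pairs expanded with spatial
neighbours among the top-scoring residues, with a surface-contiguity flag.
Glycine deserves a note: it has no side-chain heavy atoms, so its relative
side-chain exposure is zero and it is excluded from the scored surface by
the threshold — the correct reading of a side-chain exposure criterion.

## SAP scoring

For every side-chain heavy atom, each side-chain atom within the radius
(default 5 Å, the original convention) contributes its residue's relative
side-chain exposure — observed side-chain SASA over a fully-exposed
reference area — times its residue's hydrophobicity. The hydrophobicity
scale is Black–Mould, normalised and zero-centred at glycine, so polar
residues contribute negatively and a fully buried neighbourhood scores
zero. The per-residue score is the maximum over its atoms (hotspots are
local maxima); the mean is also reported. The reference areas are a
standard published table of fully-exposed side-chain areas shipped as
package data. Two declared departures from the proprietary implementations
this reconstructs: the per-atom contribution uses the whole residue's
exposure ratio rather than per-atom areas, and no vendor-specific surface
definition is imitated. Hotspot ranking attaches polar substitution
suggestions from a fixed table (Y→N/S, W→S/N/F, F→S/Y, …), and scores can
be painted into a PDB B-factor column for any viewer.

## The synthetic-data generators

The fixtures module makes every stage testable without downloads, and each
generator is a pure function of its seed and spec:

* **Toy complexes** place compact 4–5-atom residue clusters so that exactly
  the planted residue pairs have heavy atoms within 4.6 Å and every other
  cross-chain pair is beyond 7 Å; the 5 Å contact set of the generated
  structure therefore *equals* the planted set, with margins that make the
  oracle immune to floating-point jitter. Boundary behaviour at exactly
  5.0 Å is tested separately with hand-placed atoms.
* **Toy antibodies** are random near-germline V regions with IMGT-style
  numbering recorded in the synthetic reference headers, planted
  substitutions recorded as ground truth, and a fixed tail beyond V-gene
  coverage.
* **Pair corpora** plant a learnable signal: contacts are enriched by a
  stated factor on stated residue-type pairs, sequences are
  composition-biased toward those types so the signal is concentrated
  rather than diluted over rare cells, and the per-cell contact probability
  scales with the cube of the antigen residue's exposure (contacts happen
  at exposed residues — a property the features can express). A pure
  type-pair enrichment at factor 10 has a Bayes-optimal AUC near 0.78,
  which no classifier can beat; the concentrated design places the
  Bayes limit near 0.9 so a forest that genuinely learns the signal clears
  0.85 while label shuffling stays in the null band. Setting enrichment
  to 1 *and* the exposure exponent to 0 gives a corpus with no learnable
  signal at all.

What the fixtures deliberately do not imitate: real antibody fold geometry,
water-mediated interactions, crystal packing. Passing tests therefore
validate code contracts — counting, geometry, learning machinery — not
biophysical accuracy on real complexes; the checks against deposited
structures exist for that and require the user to supply the files.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely at desk scale by
design: toy complexes of 8–10 residues per chain, pair corpora of 10–16
entries (a few hundred to ~1,500 labelled pairs), forests of 100–400
trees, SASA at 240 points per atom (60–120 in inner loops of pose
featurisation and exposure scoring), and one full enumeration of the
131,072-variant example library. All stochastic steps take explicit seeds
and restore the caller's RNG state; rerunning any generator or trainer
with the same seed reproduces results exactly, which is what the
determinism tests assert. Distance comparisons use inclusive cutoffs with
a 1e-12 slack against representation error; ties are always broken by an
explicit stated rule (altloc `A` then lexicographic; argmax by lowest row
then column; panel ranks by antibody id; redundancy survivors by
resolution then id), never by platform-dependent sort order.

## Known limitations

* IMGT CDR3 insertion numbering is sequential, not symmetric; antibodies
  far from germline should be numbered with a profile-based tool instead.
* The Sc statistic uses per-atom dot surfaces, not a solvent-excluded
  molecular surface; absolute values on real interfaces depend on the
  band and weight parameters, which is why both are exposed and documented.
* The pairwise feature schema is a reconstruction; published performance
  numbers for the original classifier depend on a specific structure-
  database snapshot and are not reproducible offline, so the pipeline
  exposes the corpus builder for users with their own downloaded corpus.
* SAP here is an open reconstruction for ranking exposed hydrophobic
  patches; it is not a reimplementation of any vendor tool, and specific
  hotspot identities from proprietary implementations are qualitative
  anchors only.
* The unit of structure is the asymmetric-unit content as deposited: no
  symmetry expansion, no assembly generation, no refinement.
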