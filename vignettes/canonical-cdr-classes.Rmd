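---
title: "Canonical CDR classes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canonical CDR classes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdrcanon)
```

## The problem

T-cell receptors and antibodies recognise antigen through six
hypervariable loops, the complementarity-determining regions (CDR1/2/3 of
each chain). Although CDR sequences are extremely diverse, their backbone
conformations are not: most loops fall into a limited set of recurring
shapes, the *canonical classes*. Knowing the class of a loop supports
structural annotation of repertoire sequencing data, template selection in
modelling, and comparisons between the TCR and antibody structural
repertoires. cdrcanon implements that analysis stack end to end:
quality-filtered loop extraction from IMGT-renumbered structures,
length-independent structural clustering, convention-compliant class
naming, sequence-based class prediction, CDR3 torso geometry, and
conformational-variability statistics — together with a synthetic loop
generator that provides planted ground truth so the whole stack is
testable without downloading any structure.

## Loop extraction and quality control

Inputs are IMGT-renumbered PDB files (the convention used by the curated
TCR/antibody structure databases) or plain PDB files plus a sidecar table
mapping author numbering to IMGT positions; the package consumes the
numbering and never computes it. The IMGT windows are CDR1 27–38, CDR2
56–65 and CDR3 105–117; each loop is taken with five framework anchor
residues on each side.

A loop is retained only if

* the structure's resolution is at most **2.8 Å** (no recorded
  resolution, e.g. NMR, counts as failing — the reference data are
  crystallographic),
* all backbone atoms (N, CA, C, O) are present across the loop + anchor
  span,
* no backbone B-factor exceeds **80**, and
* every consecutive peptide C–N bond is shorter than **1.37 Å**
  (continuity; longer bonds are chain breaks).

Each rejection carries a single machine-readable code
(`RESOLUTION`, `MISSING_BACKBONE`, `HIGH_BFACTOR`, `CHAIN_BREAK`,
`MISSING_ANCHORS`) so filters can be audited individually. Alternate
locations keep the highest-occupancy conformer (ties: first in file).
β/heavy and α/light chains are treated as equivalent pairs when TCR and
antibody loops are analysed jointly, reflecting their shared VDJ / VJ
recombination origins.

## Length-independent clustering

Loop shapes are compared by a dynamic-time-warping (DTW) score: the ten
anchors of one loop are Kabsch-superposed onto the other's (40 backbone
atoms), the two CDR residue series are aligned by DTW with diagonal,
horizontal and vertical steps, and the local cost of matching two
residues is the RMS of their four backbone-atom distances. The score is
the optimal path's total cost divided by its length, which keeps the
units in Å and makes scores comparable across loop lengths — effectively
a length-independent RMSD. The dynamic program minimises total path cost;
the path length for normalisation comes from backtracking with a
deterministic tie preference (diagonal, then vertical, then horizontal).
Ties are measure-zero on real coordinates, so the choice does not affect
results in practice, but it makes reruns bit-identical.

Pairwise DTW matrices are clustered with DBSCAN on the precomputed
distances, radius `eps` and `min_pts = 5` (the minimum cluster size of
five). For TCR-only clustering `eps = 1.0 Å`; for joint TCR/antibody
clustering the per-CDR radii are a1/L1 0.82, a2/L2 1.0, a3/L3 0.91,
b1/H1 0.8 and b2/H2 0.63 Å. Our DBSCAN is deterministic: core points are
points with at least `min_pts` neighbours within `eps` (self included),
clusters are connected components of core points, and border points are
assigned to the cluster of their first core neighbour in input order.
Border assignment is the only order-sensitive part of textbook DBSCAN;
pinning it buys reproducibility at no statistical cost.

Designation then applies the validity rules. TCR-only: a cluster with
five or more structures and at least two unique sequences is a
*canonical class*; with five or more structures but a single unique
sequence it is a *pseudo-class* (named with a trailing `*`); anything
else is unclustered. Joint mode: a valid cluster needs at least six
unique sequences. We keep `min_pts = 5` in joint mode and enforce the
six-unique-sequences rule at designation, which matches the "valid
cluster" phrasing of the source method; on the planted fixtures the two
readings coincide. Names follow the field convention: CDR label(s), the
sorted set of observed loop lengths, and a letter assigned by decreasing
unique-sequence count (ties: member count, then smallest member id), e.g.
`α1-6-B` or, jointly, `α1,L1-11,12-A`. Class representatives are medoids
(minimum summed distance to the other members; ties to the smallest id).

Catalogs from different datasets are matched by shared member
(`structure:chain` identity) or, when the foreign representative was
filtered out, by a sequence-identical proxy within 1.0 Å backbone RMSD.

## Sequence-based prediction

For each canonical class a position-specific scoring matrix is built
over its *unique* sequences: the probability `p(a, i)` of residue `a` at
IMGT position `i` gives the score `s(a, i) = log2(p(a, i) / 0.05)`, with
a flat background of 0.05 per residue and no pseudocounts. A query of
length `l` is scored only against classes containing that length; its
score `P_c` is the sum of per-position scores, with never-observed
(position, residue) pairs contributing exactly −1. The query is assigned
to the best-scoring class when `P_c > 1` — except CDRα3, where
`P_c ≥ l` is required — and an exact sequence match to any class
short-circuits scoring (this is the *only* route into a pseudo-class).
Ties between classes go to the larger training set, then name order.
Variable-length classes share the IMGT frame: shorter loops are gapped
symmetrically toward the apex, and CDR3 insertions are labelled
111.1, 111.2, …, 112.2, 112.1 in loop order.

Leave-one-out cross-validation rebuilds the held-out sequence's class
PSSM without it and counts: true positive (assigned to its own class),
false positive (assigned elsewhere, including unclustered sequences that
gain an assignment), true negative (unclustered stays unassigned), false
negative (class member stays unassigned); accuracy is (TP + TN) / total.
For blind structural tests, an assignment counts as correct when the
native loop is within **1.0 Å** backbone RMSD (inclusive) of any member
of the assigned class. Repertoire records are pre-filtered to productive
rearrangements with CDR1 and CDR2 of at least five residues and CDR3 of
at least eight (all inclusive).

## CDR3 torso geometry

The base ("torso") of CDR3 adopts one of two geometries. At IMGT
position 116 we compute the pseudo bond angle τ116 (CA of 115/116/117)
and the pseudo dihedral α116 (CA of 115/116/117/118; 118 is the first
C-anchor residue), both in degrees with the IUPAC torsion convention
(cis = 0). A loop is classified **kinked** iff α116 > 0, otherwise
**extended**; the boundary α116 = 0 is assigned to extended. The loop
anchor transform (LAT) builds a local frame at residues 105 and 117 —
origin at CA, z toward the carbonyl carbon, y perpendicular to z in the
N–CA–C plane, x completing a right-handed frame — and reports the
6-degree-of-freedom transform carrying frame(105) to frame(117):
translation (X, Y, Z) in frame(105) coordinates and z-y-z intrinsic
Euler angles (φ, ψ, θ). Any fixed Euler convention works provided the
transform round-trips; ours is recorded here and checked by a
round-trip test. Near the gimbal singularity (ψ ≈ 0° or 180°) only
φ + θ is determined; we report θ = 0 there. Torso φ/ψ covers the first
three (T1–T3) and last four (T4–T7) CDR3 residues, computed in the
context of the anchors so T1's φ is defined.

## Conformational variability

Loops of one CDR type sharing an identical sequence (case-insensitive)
form a group; groups with at least two structures are analysed for (a)
the number of distinct cluster labels occupied (unclustered counts as a
label) and (b) the maximum pairwise backbone RMSD. The RMSD fit is on
the loop backbone itself by default — the question is whether the loop
*conformations* differ, independently of anchor placement — with the
anchor-based fit available via `fit_on`. Groups below 1 Å are reported
as "similar" by default (configurable).

## The synthetic generator

Synthetic loops are built from per-residue φ/ψ torsion profiles by NeRF
chain construction with idealized bond geometry (N–CA 1.458, CA–C 1.525,
C–N 1.329, C=O 1.231 Å; trans ω), giving CA–CA spacings of ≈ 3.8 Å. The
generator's self-consistency is asserted by round-tripping measured φ/ψ
against the template torsions.

* **Planted clusters** (`make_cluster_set`): `k` families with distinct
  CDR torsion profiles and identical extended anchors, so anchors
  superpose while CDRs differ. Member-to-member conformational noise is
  Gaussian in *torsion space* (default SD 2°), which bends the loop while
  keeping bonds ideal; independent Cartesian noise of useful magnitude
  would break the 1.37 Å continuity filter by construction (the ideal
  C–N bond leaves only 0.04 Å slack). Calibration is asserted at
  generation: template pairs must exceed 3 × eps in DTW and every
  intra-family pair must stay below eps / 2, otherwise generation fails
  loudly. Sequences come from disjoint per-family alphabets, with knobs
  for pseudo-class fixtures (one unique sequence) and a planted
  two-conformation sequence shared across families.
* **Torso fixtures** (`make_torso`): 13-residue CDR3 loops with jittered
  torsions; when a sampled geometry has the wrong α116 sign the loop is
  mirrored (a chirality flip negates all pseudo-dihedrals and preserves
  bond lengths). Geometries with |α116| within 10° of the boundary are
  resampled so planted classes are unambiguous.
* **Sequence classes** (`make_sequence_classes`): each class is a
  consensus plus enumerated single-position (then two-position)
  mutations within its own disjoint alphabet. This makes class
  membership recoverable *by construction* when any one member is held
  out — a random draw from a small alphabet does not guarantee that —
  plus decoys from a further disjoint alphabet.

What the generator does **not** emulate: real loops have correlated
backbone geometry, side chains, crystal contacts, non-ideal bond
lengths, experimental coordinate error that is neither isotropic nor
independent, and cluster shapes far from the clean planted separation.
Passing the planted tests therefore demonstrates the correctness of the
algorithms (distances, clustering, scoring, geometry), not the
biological completeness of any catalog built from real data.

## Numerical choices and degenerate inputs

* Backbone atom set is {N, CA, C, O} throughout (superposition, RMSD,
  DTW cost); "backbone" is unqualified in the source method and the
  carbonyl oxygen is part of the rigid peptide unit.
* Kabsch uses SVD with the determinant correction, so reflections are
  never returned; rank-deficient (collinear) point sets are an error.
* Torsions through collinear points and zero-length frame vectors are
  errors, not NaNs; φ/ψ across a chain break are NA.
* Probabilities in PSSMs are per position over the sequences covering
  that position, so columns always sum to 1 even in mixed-length
  classes.
* PCA of one-hot matrices is on the covariance (not correlation) of the
  0/1 features, with a fixed sign convention (largest-magnitude loading
  positive) so reruns and row permutations give identical coordinates.
* All generators take explicit seeds and restore the caller's RNG
  state; identical seeds give bit-identical fixtures and artifacts.

## Problem sizes

The test-suite and acceptance-script fixtures use 3 planted families of
7 loops (CDR length 8), 200 random short-loop pairs for the exhaustive
DTW cross-check (CDR lengths ≤ 5, where path enumeration is exact and
fast), 2 × 10 sequences + 5 decoys for cross-validation, and 100 seeds
per torso class. These sizes exercise every code path and keep the whole
suite in the minutes range on a single CPU; all of them scale up by
argument.

## Known limitations

* IMGT insertion handling beyond the CDR3 111/112 scheme is not
  implemented (other windows error on over-length loops).
* Receptor class and chain type are metadata inputs; no sequence-based
  chain typing is attempted.
* The joint-mode eps values are fixed configuration constants; no
  OPTICS-style radius selection is performed.
* Binding-state effects on conformation are recorded as metadata only
  and never inferred from coordinates.

## A worked example

```{r example}
ds <- make_cluster_set(k = 3, per_family = 7, seed = 1)
cl <- cluster_loops(ds$loops, eps = 1.0)
cl$catalog

pssms <- build_class_pssms(cl$catalog, cdr = "a1")
queries <- vapply(ds$loops[c(1, 8, 15)], function(l) l$sequence,
                  character(1))
predict_canonical(queries, "a1", cl$catalog, pssms)

torso_geometry(make_torso("extended", seed = 1))$torso_class
```
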