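---
title: "Predicting fatty-acid-binding pockets: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting fatty-acid-binding pockets: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fabpocket)
```

## The problem

Several nucleoporins — the building blocks of the nuclear pore complex —
associate with lipid droplets, and their structures harbour candidate
cavities that could accommodate a fatty-acid (FA) tail. fabpocket
implements the computational side of that question as a reusable pipeline:
given a protein structure, find its cavities, describe each one numerically,
and decide with a trained classifier whether it looks like an FA-binding
pocket. Two models trained on different curated sets (an all-species set
and a human-only set) are combined by a strict consensus rule, and a
negative-pool procedure estimates how often the models cry wolf.

A *cavity* is the structural hole in the protein; a *pocket* is the
computational construct we use to analyse it — here, a cluster of alpha
spheres. Pocket size and shape therefore depend on the detection
parameters, which is why they are explicit, recorded objects in this
package.

## Cavity detection

An **alpha sphere** is a sphere tangent to four atoms that contains no atom
centre. Small alpha spheres sit in the packed interior; very large ones
hug the convex hull; spheres of intermediate radius line clefts and buried
cavities. Detection proceeds in three steps:

1. **Enumeration.** Every empty circumsphere of four heavy atoms — in
   general position, exactly the Delaunay tetrahedra of the atom centres —
   with radius in `[min_alpha_radius, max_alpha_radius]` is kept. The
   radius band is inclusive on both ends; the "no atom strictly inside"
   test uses a 1e-6 Å tolerance. The enumeration is done in compiled code
   with pairwise pruning at `2 * max_alpha_radius` (four points on a
   sphere of radius *r* are pairwise within *2r*), and the test suite
   checks it against a brute-force enumeration of all four-atom subsets.
2. **Clustering.** Sphere centres are single-linkage clustered: pockets
   are the connected components of the graph with an edge wherever two
   centres are at most `cluster_distance` apart. The suite checks this
   against an independent union-find partition.
3. **Finalization.** Clusters with fewer than `min_spheres_per_pocket`
   spheres are dropped; survivors get their lining residues (the owners of
   the defining atoms), per-chain author-numbered spans, and an apolar
   fraction (a sphere is apolar when at least `apolar_probe_count` of its
   four defining atoms are carbon or sulfur).

Defaults are `detection_params(min_alpha_radius = 4, max_alpha_radius =
6.2, cluster_distance = 6, min_spheres_per_pocket = 15, apolar_probe_count
= 3)`. The 4 Å minimum radius and 6 Å clustering distance are deliberately
larger than generic pocket-finding defaults: FA cavities are long and
moderately wide, and the coarser settings make one elongated cavity come
out as one pocket instead of several fragments. 6.2 Å is the conventional
upper radius for surface-bounded spheres. We run a single clustering pass
at the 6 Å distance; multi-stage refinements used by some detectors are
intentionally not reproduced, because a single well-specified pass is
exactly checkable against the connected-components oracle.

Degenerate four-point combinations (near-coplanar, tetrahedron volume
≤ 1e-9 Å³) are skipped; on near-cospherical inputs the enumeration asserts
only set-level properties, not a particular tetrahedron identity.
Hydrogens are excluded everywhere; only the first model of multi-model
files is read; ligands and waters never enter the detection atom set, so a
cavity is always detected as empty space — the condition an apo structure
presents at prediction time.

## Secondary structure

The classifier consumes only coarse helix/strand/coil composition
fractions over a pocket's lining residues, so fabpocket uses a
deterministic dihedral-region assigner rather than a hydrogen-bond-energy
method: φ from C(i−1)–N(i)–CA(i)–C(i), ψ from N(i)–CA(i)–C(i)–N(i+1);
helix for φ ∈ [−100, −30] and ψ ∈ [−80, −5]; strand for φ ∈ [−180, −80]
and ψ ∈ [90, 180] ∪ [−180, −170]; coil otherwise. Helix runs shorter than
4 and strand runs shorter than 3 are demoted to coil. Chain breaks
(consecutive Cα–Cα distance above 4.5 Å) and termini leave dihedrals
missing, which maps to coil. This is a known approximation: it agrees
with energy-based assigners on regular elements and disagrees in their
fraying edges, which perturbs the three composition fractions only
slightly. On ideal generated geometries the interior labels are exact,
and the suite verifies dihedral recovery to 0.5°.

## The descriptor vector

Each pocket becomes a fixed-order 14-descriptor vector
(`feature_schema()`, version `fab-features-1`): sphere count, mean and
maximum sphere radius, apolar sphere fraction, Monte-Carlo union-of-spheres
volume, compactness (mean pairwise centre distance), mean Kyte–Doolittle
hydrophobicity of the lining, polar / charged / aromatic lining-residue
fractions (classes {S,T,N,Q,Y,C,H}, {D,E,K,R}, {F,W,Y,H}), helix / strand
/ coil lining fractions, and the lining-residue count. The schema version
travels with every trained model, and prediction refuses mismatched
schemas. Nonstandard residues count toward fractions but carry no
hydrophobicity weight. The volume term is a seeded Monte-Carlo estimate
(≥ 10⁴ samples in the bounding box) with its binomial standard error
reported; every other descriptor is exact and rigid-motion invariant.

No public enumeration of a reference feature set exists for this kind of
pocket classifier, so this schema is declared as the package's own
contract: it spans exactly the two computations the pipeline performs —
alpha-sphere geometry and secondary-structure composition — plus standard
physicochemistry of the lining.

## Labels, training and the consensus rule

Curated training tables (TSV, column-mapped by name) list FA-bound
structures; the packaged `*.synthetic.tsv` stand-ins reproduce the
composition of the published curated sets (340 human-protein records; 70
records spanning 52 species) so the loaders and counts are exercised
offline. For a positive structure, the bound FA is removed from the
detection input and a pocket is labelled 1 when at least 3 of its sphere
centres lie within 3 Å of a ligand heavy atom; the structure's remaining
pockets are discarded rather than auto-labelled 0, because they are merely
unverified. Negative-table structures contribute all their pockets as
class 0. Both contact thresholds are exposed.

The classifier is a multilayer perceptron: one hidden layer of 32 logistic
units, cross-entropy loss, L2 weight decay 1e-4, at most 500 quasi-Newton
iterations (`nnet`), with per-column z-score normalization fitted on
training rows only (zero-variance columns pass through unscaled, with a
warning). Regularization is by decay plus the iteration cap; a held-out
early-stopping split was considered and rejected because the BFGS
optimizer converges rather than cycles, decay controls capacity directly,
and a validation split on small pocket sets wastes scarce positives.
Training is deterministic given the seed, which is recorded in the model.

Evaluation uses stratified 5-fold cross-validation with a recorded fold
seed — stratification keeps fold class balance within one example, which
matters because pocket sets are imbalanced. The model is refitted from
scratch per fold, normalization included, and the report carries per-fold,
mean and pooled accuracies (the mean-vs-pooled distinction is reported
explicitly since either convention is defensible).

A pocket's score lies in [0, 1]; it is called positive only when the score
**strictly exceeds** 0.5 — a score of exactly 0.5 is negative. The
consensus call requires positivity under both models, so the consensus set
is exactly the intersection of the two positive sets; on any evaluation
pool the consensus false-positive rate is therefore bounded by the smaller
per-model FPR. The FPR estimator samples a negative pool (ligand-bound
structures whose ligand codes survive the FA exclusion list), re-detects
pockets with the training-time parameters and ligand-removal convention,
and reports per-model and consensus positive counts and percentages with
the sampling manifest and seed.

## The synthetic generator

Because the pipeline's real inputs are external databases, the package
generates its own study material:

* **Cages** (`make_cage()`): atoms jittered through a spherical wall
  between `cavity_radius` and `cavity_radius + shell_thickness`, an
  atom-free mouth cone around +z, threaded by nearest neighbour into
  pseudo-alanine residues so the dihedral code runs; elements drawn from
  `element_mix`; optional pseudo-ligand inside the cavity — an acyl chain
  (tetrahedral zigzag, exact 1.5 Å bonds; a straight chain of 8 carbons
  would not fit the default cavity) or a planar ring with 1.4 Å edges,
  the aromatic/cyclic decoy class that pocket classifiers are prone to
  call positive. Output is deterministic per seed, byte-for-byte.
* **Feature matrices** (`simulate_features()`): class-conditional
  Gaussians over the 14-feature schema; the first
  `round(informative_fraction × 14)` columns separate by `effect_size`
  pooled standard deviations, the rest are identical across classes;
  optional exchangeable correlation; fraction columns clipped to [0, 1].

What the cages emulate is the geometry the detector cares about — a buried
cavity of controllable radius and mouth behind a packed wall — and the
element composition the apolarity descriptor cares about. What they do not
emulate: real backbone geometry (the pseudo-residues have no realistic
φ/ψ, so cage SS fractions are mostly coil), side chains, residue diversity
(everything is ALA), or solvent. Passing tests on cages therefore
demonstrate the correctness of the geometry, plumbing and learning
machinery under controlled separation — not transferability to real
proteins, which depends on the curated training sets.

Demo conditions (fixed once): positive cages are carbon-rich (C 0.9 /
O 0.1, cavity 5.2 Å) with an 8-carbon acyl ligand; negative decoys are
polar (C 0.35 / N 0.33 / O 0.32, cavity 4.5 Å) with a 6-membered ring or
no ligand; 150–180 wall atoms and a 15° mouth. The contrast mimics the
real one — FA cavities are hydrophobic, decoy cavities less so — and gives
the demonstrated margin its separation.

## The demonstration run

`run_demo(seed = 42)` generates 30 positive and 30 negative training
cages, builds the labeled dataset, trains two models differing only by
seed, cross-validates both, predicts on 10 held-out acyl cages (reporting
the consensus-positive rate of their ligand-contacting cavity pockets),
and estimates FPR on a 40-cage ring-decoy pool. Every stage seed derives
from the master seed, so the report reproduces exactly. Problem sizes
were chosen to exercise each stage with enough pockets for stable rates
while a full run stays comfortably in the minutes range on one core.

```{r demo, eval = FALSE}
report <- run_demo(seed = 42)
report
```

## Numerical choices and degenerate inputs

* Radius filter inclusive on both ends; inside-test strict with 1e-6 Å
  tolerance; tetrahedron volume gate 1e-9 Å³.
* Altloc duplicates resolve to highest occupancy, ties to altloc "A",
  then lexicographic; duplicate-keyed records without altlocs (pseudo-atom
  dumps) are preserved as-is.
* Pocket ranking: sphere count descending, ties by mean radius descending;
  output is invariant to atom input order (spheres are canonically
  sorted), which the suite verifies by shuffling.
* Unknown elements default to the 1.70 Å carbon radius with a warning;
  zero-variance feature columns pass through normalization unscaled.
* Scores are clamped to [0, 1]; threshold ties are negative by the strict
  rule.

## External validation and limitations

With structures fetched from the PDB and models trained on the real
curated sets, the predicted pockets on the nucleoporin structures 4HMC
(Nup157) and 2QX5 (Nic96) can be compared against the reported spans
(residues 594–762 and 281–434 in author numbering). That check needs
downloads and the original curated training data, so it lives outside the
test suite and is not a gate; nothing in the package or its tests touches
the network.

Known limitations: the feature set is this package's own 14-descriptor
contract, not a reproduction of any published classifier's internals; the
dihedral SS assigner approximates energy-based methods; single-pass
clustering can split very irregular cavities that multi-stage refinement
would merge; and synthetic cages cannot certify performance on real
proteins.
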