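---
title: "Cubane iron-sulfur cluster geometry: model, restraints and validation"
author: "sf4kit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cubane iron-sulfur cluster geometry: model, restraints and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sf4kit)
```

## The geometric model

The Fe₄S₄ cluster (PDB chemical component `SF4`) places four irons and
four inorganic sulfurs at alternating vertices of a distorted cube. Every
bond is heterogeneous, so the bond graph is the *cubane graph*: the
complete bipartite graph K₄,₄ minus a perfect matching — each iron bonds
exactly three sulfurs, and the sulfur it does *not* bond sits across the
body diagonal.

`sf4kit` parameterizes the cluster as **two concentric, oppositely
oriented regular tetrahedra**: irons at `a·(±1, ±1, ±1)` vertices with an
even number of minus signs, sulfurs at the inverted vertices scaled by
`b`. Writing `d` for the Fe–S bond, `θ₁` for the Fe–S–Fe angle at a
sulfur and `θ₂` for the S–Fe–S angle at an iron:

```
d  = sqrt((a + b)² + 2 (a − b)²)
θ₁ = 2 asin(√2 a / d)
θ₂ = 2 asin(√2 b / d)
```

Two limiting shapes matter in practice:

* **cubic** (`a = b`): the perfect cube, both angle classes exactly 90°.
  This is the geometry long encoded in legacy refinement dictionaries
  (edge 2.135 ± 0.020 Å).
* **rhomboid** (`a < b`): the shape actually observed in accurate
  small-molecule structures — the sulfur tetrahedron is larger, giving
  Fe–S–Fe ≈ 73.7° and S–Fe–S ≈ 104.2° while keeping a single Fe–S bond
  class at 2.289 Å.

Not every target triple `(d, θ₁, θ₂)` is realizable: eliminating the two
scales leaves the constraint `(h₁ + h₂)² + 2 (h₁ − h₂)² = 1` with
`hᵢ = sin(θᵢ/2)/√2`. The pooled small-molecule targets satisfy it to
≈ 2 × 10⁻⁴, and — worth stressing, because it is often misstated — the
all-90° pair satisfies it *exactly*: the perfect cube is a member of the
two-tetrahedra family, not an infeasible request. A genuinely
irreconcilable triple (say 73.66° with 90°) leaves a large residual and
`build_rhomboid()` raises a geometry-infeasible error reporting it.

`build_rhomboid()` fits the two scales to the three targets by
unweighted least squares (Ångström and degree residuals on equal
footing), starting from the closed-form solution; with consistent
targets the fit is exact to ≈ 0.01° / 10⁻⁴ Å. Acceptance tolerances of
0.005 Å and 0.05° on the realized means reflect this head-room.

## Restraint dictionaries

A component dictionary holds 12 bond restraints, 24 angle restraints
(12 per class) and 4 chiral restraints, serialized in monomer-library
CIF dialect (`chem_comp_bond` / `chem_comp_angle` / `chem_comp_chir`
loops). Values print at 3 decimals (Å) and 2 decimals (degrees), the
precision of the source statistics; reads return exactly the printed
values, so write → read round-trips at printed precision.

The tunable numbers and their defaults:

| parameter | value | σ | units | role |
|---|---|---|---|---|
| S–Fe bond | 2.289 | 0.024 | Å | internal bond target (rhomboid) |
| Fe–S–Fe | 73.66 | 0.87 | ° | angle at sulfur (rhomboid) |
| S–Fe–S | 104.18 | 1.24 | ° | angle at iron (rhomboid) |
| Fe–S_AA | 2.268 | 0.017 | Å | link bond to cysteine SG |
| S–Fe–S_AA | 114.24 | 5.75 | ° | external angle at a linked iron |
| cubic edge | 2.135 | 0.020 | Å | legacy cubic bond target |

The cubic set's angle σ values are not published anywhere; we reuse the
rhomboid class σs (0.87 / 1.24°) so that RMSD comparisons between the
two sets weight every term identically and isolate the effect of the
target *values*. The large external-angle σ (5.75°) reflects genuine
conformational freedom of the cysteine approach, not measurement error.

**Chirality.** With each iron's three sulfurs ordered by ascending name,
the signed volume `(S_i−Fe)·((S_j−Fe)×(S_k−Fe))` is fixed by the
reference handedness — but it *alternates* across centers (−, +, −, + at
FE1…FE4), because the tetrahedral symmetry carries FE1's ordered triple
onto odd arrangements at FE2 and FE4. The dictionary therefore stores a
per-center sign, not one global sign. Mirroring the cluster flips all
four simultaneously, which is what the restraints are there to prevent.

## Atom naming and its degeneracy

All four irons are chemically identical, so deposited atom names are
arbitrary up to an automorphism of the cubane graph. Element-preserving
automorphisms must preserve the antipodal Fe/S matching, which forces
the same index permutation on both element sets: 24 relabelings in all.
Exactly the 12 with even permutation parity are realized by proper
rotations of the cluster.

This has a consequence that shapes the whole module: **the ideal cluster
is exactly invariant under the proper 12**, so a chirality-preserving
relabeling of a model is an equally correct naming and produces exactly
tied superposition RMSDs — there is nothing to detect and nothing to
fix. The observable pathology is the other coset: a chirality-*breaking*
relabeling (for example swapping FE1/FE2 together with S1/S2) makes the
names imply the mirror handedness, which no rotation can reconcile with
the restraints; refinement then distorts the cluster.

`best_mapping()` therefore scans all 24 relabelings, each scored by a
proper-rotation-only Kabsch superposition of the ideal template
(`det(R) = +1` enforced through the SVD; reflections are never applied
to coordinates). Because the identity exactly ties any proper
relabeling, the winner is either the identity (naming consistent) or a
chirality-breaking corrective relabeling, flagged via
`rotation_proper = FALSE`. Ties are broken by the lexicographically
smallest relabeling, which makes the result deterministic; "recovery" of
an applied permutation is consequently defined *up to the proper
symmetry group* — the strongest property the geometry admits. A model
counts as misnamed when the winning relabeling is non-identity and beats
the identity fit by more than 0.1 Å RMSD.

## Link detection

Coordinating sulfurs sit on each iron's local threefold axis — the
direction from the centroid of its three bonded sulfurs through the
iron. Placing a sulfur there at 2.268 Å reproduces the observed external
angle (≈ 114.3°, within 0.5° of the pooled 114.24°) by construction; the
cone-angle closed form ties the external angle to the internal S–Fe–S
class.

`detect_links()` pairs each iron with its nearest cysteine SG within a
cutoff, greedily by distance so no sulfur serves two irons. The cutoff
default of 3.0 Å is this package's choice (no published value exists):
it sits ≈ 40σ above the 2.268 Å bond yet safely below nonbonded
sulfur–sulfur contacts (≈ 3.6 Å). Non-cysteine sulfurs (e.g. MET SD) can
be linked with `any_sulfur = TRUE`; the cysteine bond target is then
applied as a flagged approximation because amended per-residue values
are not published.

## Validation metric

`rmsd_to_restraints()` reports the root-mean-square of raw
(measured − target) deviations over the 12 bonds and 24 angles —
unweighted, in Å and degrees, matching how cluster geometry quality is
conventionally plotted; `sigma_weighted = TRUE` gives the normalized
variant. Two closed-form anchors pin the scale: an ideal rhomboid
cluster scored against the cubic dictionary shows a bond RMSD of
exactly |2.289 − 2.135| = 0.154 Å and an angle RMSD of
√((12·14.18² + 12·16.34²)/24) = 15.30°.

Classification calls a cluster `misnamed` (naming check above), else
`cubic` or `rhomboid` by whichever set gives the smaller *angle* RMSD —
the angle targets separate the shapes by ~15°, an order of magnitude
more discriminating than the 0.154 Å bond difference. A perfect cube is
invariant under all 24 relabelings, so misnaming is undefined (and
undetectable) for exactly cubic clusters; the classifier reports those
as `cubic`.

## Corpus mining

Entry filters mirror standard refinement-suitability screens: resolution
≤ 3.55 Å, structure factors deposited, not twinned, completeness ≥ 90%,
R_work < 30%, R_free < 35% and R_free − R_work ≥ 1.5% (a guard against
wrongly deposited cross-validation sets). All thresholds are inclusive
exactly as written; a very-high-resolution screen keeps entries strictly
better than 1 Å. Statistics pool **per measurement**: each cluster
contributes its 12 bonds and 24 angles individually, and σ is the sample
standard deviation (n − 1). Pooled moments merge exactly across corpus
partitions, which the tests verify against the closed-form combination.

## The synthetic generator

`generate_cluster_model()` emulates the observed geometry distribution:
per model it draws one bond and two angle targets from Gaussians at the
pooled means/σs (2.289/0.024 Å, 73.66/0.87°, 104.18/1.24°; cubic models
use 2.135/0.020 Å with fixed 90° angles), rebuilds the cluster through
the least-squares construction, applies a random rigid motion, and
optionally adds Cartesian jitter, a chirality-breaking name permutation,
and four cysteine SG sulfurs at N(2.268, 0.017) Å along the threefold
axes. Noise lives in *internal-coordinate* space so that mined means are
unbiased estimates of the generator parameters: the drawn bond is
reproduced exactly (scale is a free parameter of the construction),
while drawn angle pairs are projected onto the one-parameter feasible
shape family — angle means therefore carry a small (< 0.1°)
deterministic projection bias and attenuated σ, which the test suite
accounts for explicitly. Metadata (resolution, R factors, completeness)
is drawn uniformly from configurable ranges spanning the filter
thresholds.

Reproducibility: one master seed, per-model substreams derived from
(seed, index), so any model regenerates independently and on-disk
corpora are byte-identical across runs.

What the generator does *not* emulate: refinement against diffraction
data (no maps, no R factors computed from a model), anisotropic or
correlated coordinate error, partial occupancy, alternate conformations,
or crystal-contact distortion. Passing tests therefore demonstrate the
correctness of the geometry/restraint machinery on distribution-faithful
synthetic clusters, not the behaviour of deposited models under
re-refinement.

## Problem sizes and numerical choices

The statistics-recovery checks use 1000 single-cluster models (12 000
pooled bond measurements), classification mixtures 120–150 models, and
the naming recovery 100 seeded trials at 0.05 Å coordinate noise —
sizes at which binomial and √N bands are decisive while the whole suite
runs in about a minute. Other numerics: all internal math in double
precision; angles clamped into [−1, 1] before `acos`; the two-scale fit
runs BFGS at `reltol = 1e-15` from the closed-form start; the Fe–S bond
criterion is 2.41 Å (mean + 5σ, configurable); superposition ties break
lexicographically; degenerate inputs (zero-length angle arms, non-finite
coordinates, incomplete clusters, zero-σ statistics) raise typed errors
rather than propagating NaN.

## Known limitations

* Single-bond-class templates only: deposited clusters are sometimes
  described as compressed along one axis (two bond classes); the
  dictionary and templates here implement the one-class reading of the
  pooled statistics.
* No torsion or planarity restraints, and no whole-model metrics — the
  scope is the cluster and its links.
* Misnaming is undetectable for exactly cubic clusters (full Td
  symmetry) and weakly determined near them.
* The cysteine link reuses one bond target for all sulfur donors; amended
  per-residue values are not public.
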