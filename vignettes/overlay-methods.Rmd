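---
title: "Methods: overlay generation, scoring and comparison in ligover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: overlay generation, scoring and comparison in ligover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope and assumptions

`ligover` aligns flexible ligands presumed to share a binding mode. Three
assumptions shape the whole design:

1. **Conformers are input, not output.** Each ligand arrives as a set of
   low-energy conformers (multi-conformer SD file); the program selects and
   mildly adjusts them (torsion driving, small rigid-body moves) but never
   re-minimises geometry and never changes bond angles. If the binding
   conformation is absent from the input ensemble, no stage of the
   algorithm can recreate it.
2. **Protonation states are fixed.** Ligands must be supplied in the
   protonation/tautomer state they are expected to adopt; feature
   assignment trusts the formal charges and hydrogen counts in the file.
3. **A common pharmacophore of at least three points exists.** Overlay
   generation is anchored on triplets of fitting points common to every
   ligand. When no triplet type spans all ligands the generator stops with
   an explicit error and the supermolecule (stepwise) device
   (`merge_to_supermolecule`) must be used on a subset first.

# The pipeline

## Features and fitting points

Donors, acceptors and custom features are assigned by SMARTS definitions
(`inst/extdata/feature_defs.yaml`). Each donor/acceptor definition carries
a *strength* — `strong` is reserved for ionised groups, thiol and activated
C–H donors and thiocarbonyl S acceptors are `weak`, everything else
`medium` — and a *geometry class* used to place **virtual points**:
hypothetical positions of the complementary protein atom, at the
hydrogen-bond distance from the feature atom. The classes are `linear` (one
point on the sp axis — nitriles), `trigonal` (one point along the sp²
lone-pair bisector — pyridine-type N), `planar_arc` (an in-plane arc
spanning the two sp² lone pairs plus intermediates — carbonyls),
`cone`/`tetrahedral_cone` (points evenly spaced on a cone base — ionised
oxygens, sp³ O/N) and `none`. Donors with explicit hydrogens instead get
one point along each X–H direction.

The package matches SMARTS with its own subset engine (elements, aromatic
symbols, `#n`, charge, `Hn`, `Xn`, `Dn`, `R`/`rn`, the `!`/`&`/`,`/`;`
logic, branches and ring closures). Definitions restricted to this subset
are validated when the file is loaded, so configuration errors surface
before any computation. Recursive SMARTS are intentionally rejected.

Hydrophobes are perceived structurally: every ring of up to 7 atoms is one
hydrophobe (directional when at least three ring atoms are *delocalisable*,
which we define as aromatic or carrying a double bond — the count is
standard, the atom test is our choice); t-Bu and –CF3 groups and acyclic
amide/C=C/C=N/N=N linkages are classed as stated; remaining hydrophobic
atoms (carbons, plus attached halogens, with no charged or donor/acceptor
heteroatom neighbour — this default is our own operational definition of
"other hydrophobic portions" and lives in code, overridable by excluding
atoms) are partitioned into segments of at most four atoms. Segmentation
enumerates all compositions of the chain and keeps the one with minimal
segment-size variance, breaking ties by fewer segments and then by more
uniform centroid spacing in the first conformer. Feature assignment is
purely topological, so one feature list (and hence one fitting-point
indexing) is valid for every conformer of a ligand; only coordinates vary.

## Rotatable bonds and torsion driving

Rotatable bonds are the acyclic, non-aromatic single bonds matched by the
rules file (`inst/extdata/rotatable_rules.yaml`); methyl groups are
excluded and ester C(=O)–O torsions are constrained to trans ± 5°
(requests outside an allowed range raise a classed rejection condition
that the annealing and genetic stages use to veto moves). Driving rotates
the side of the bond with fewer atoms (ties: the side containing the lower
minimum atom index). Which side moves is pure convention — any consistent
choice yields the same overlays up to rigid motion — but fixing it makes
torsion driving deterministic and idempotent. Conformations are not
re-minimised after driving.

## Triplet counting and alignment fingerprints

Triplets are typed by the multiset of feature kinds (both hydrophobe
classes count as one "hydrophobe" kind) and the distance bins of the three
sides. Two bin schemes are always run and pooled — 0.5–3.0–5.0–7.0–9.0–
11.0–13.0 Å and 0.5–3.5–6.0–8.5–11.5–13.5 Å — so a distance falling just
either side of a bin boundary cannot hide a common triplet type. Types are
ranked by the number of ligands containing them (`L`, descending), ties by
the mean proportion of conformations (`P̄`, descending, averaged over all
ligands with absent ligands contributing 0), then by type code for
determinism. Up to `N = min(M, 25)` types with `L` equal to the ligand
count seed fingerprints.

Canonicalisation numbers the triplet points (acceptors before donors
before hydrophobes; within equal kinds, by the stated bin-order rules),
and the canonical frame puts the centroid at the origin, point 1 on +x and
point 2 in the xy plane with y ≥ 0. Degenerate triplets contribute one
fingerprint row per valid ordering — we allow rows from different
orderings of the same physical triplet to coexist in one search, since
they are genuinely distinct alignments. Triplets with a triangle height
below 0.1 Å are discarded as collinear (the frame would be ill-defined).

Non-base fitting points are hashed to the nearest node of a 1.5 Å grid
(plus the six axial neighbours when smearing is on, the default). The grid
is anchored at the floor of the row bounding box with a one-cell pad;
results can therefore shift by sub-grid amounts if the input coordinates
are globally translated, which is harmless because every row of one
fingerprint shares the same grid. Empty columns are removed (the
column-to-grid-cell map is retained).

The greedy search biases its `P = 200` starting rows toward rows with many
on-bits in highly occupied columns — implemented as the top-`P` rows by
the sum of column occupancies over their on-bits, reused cyclically with
fresh random ligand orders when `P` exceeds the row count. Per step the
row maximising `B = wA − O` is taken, ties at random. Duplicate
chromosomes (same conformers, mapping and torsions) are removed from the
pool before filtering: they would only waste the filter budget.

## Chromosomes and decoding

A chromosome stores per ligand a conformer index, optional torsion values
and optional rigid-body terms (three intrinsic x–y–z Euler angles about
the ligand centroid, then a translation — the rotation centre is our
choice; the convention is fixed so that refined states stay serialisable),
plus a shared fitting-point mapping table. Decoding places the first
ligand as supplied and Kabsch-fits each subsequent ligand's mapped points
onto the running per-column centroids of the already-placed ligands.
With incomplete tables, placement starts from the pair sharing the most
complete columns and proceeds greedily by usable-column count; if no order
gives at least three usable columns the chromosome is invalid. Kabsch
superposition carries a determinant correction so reflections are
impossible and chirality is always preserved.

## Scoring

*Leader cluster analysis* follows the nearest-neighbour-list procedure
exactly: each point's NNL holds itself plus the nearest point of every
other ligand within 1.5 Å; the longest NNL (ties: smallest mean square
distance between members) becomes a cluster, its members are struck from
the remaining NNLs, and the process repeats. NNLs are not refilled.

`HB` uses, per cluster, the ramps f: 1.0→0.3 over spreads 0.15–0.75 Å²
and g: 1.0→0.3 over 0.5–1.5 Å². The similarity factor is S = (m/n)² with
the effective count m = n − 0.5·(members off the modal strength) − 0.5 per
strong/weak pair, floored at 1 — the published definition fixes only the
endpoints ("equal strengths keep m = n, lower otherwise"), and this choice
penalises adjacent-strength mixing mildly and strong-with-weak strongly.
Virtual points are clustered with the same leader procedure, tagged by
parent atom so a cluster holds at most one point per atom; tied largest
clusters are each evaluated and the highest-scoring one kept. The
occlusion factor samples the segment between atom-cluster centroid and
virtual-cluster centroid every 0.5 Å (strictly between); a sample inside
any hydrophobe-member atom's 0.85-scaled vdW sphere is occluded and
X = 1 − 0.9·(occluded fraction), clamped to [0.1, 1]. Only hydrophobic
atoms form the occlusion envelope — the published description mentions the
"hydrophobic envelope", and including donors/acceptors would make clusters
occlude themselves. Atoms contributing to both a donor and an acceptor
cluster (hydroxyls) count only their better-scoring cluster. `HY` uses
f: 1.0→0.0 over 0–1.25 Å² and g: 2.0→0.0 as the mean unsigned cosine of
inter-planar angles falls 1.0→0.8 (unsigned, so antiparallel normals count
as coplanar); singleton clusters take c = 1.

`E` sums, per ligand, one torsional term per acyclic single heavy-atom
bond plus repulsive-only Lennard-Jones terms over pairs three or more
bonds apart, with radii scaled by 0.85 and the single worst clash forgiven
when below 150 kcal/mol. The worst-clash exemption is applied per ligand
(E is a per-ligand sum, and a bad contact in one ligand should not mask
one in another). The parameter table
(`inst/extdata/tripos_minimal.csv`) is a minimal set of vdW
radii/epsilons and representative torsion barriers for common organic atom
types; missing parameters contribute zero with a one-time warning, and the
term is deliberately pluggable — full force-field coverage is out of
scope.

`V` places a lattice anchored at absolute cell centres over the overlay
and counts cells: cells wholly inside a sphere count 1 and cells crossing
a surface are sub-sampled (3³ points) against the whole union. Plain
midpoint counting at the default 0.5 Å grid fluctuates by several percent
on single-atom-sized objects depending on how spheres align with the
lattice; the boundary sub-sampling removes that resonance (single spheres
and two-sphere unions agree with closed forms to a few tenths of a
percent) while interior counting is unchanged. Halving the grid changes V
on test overlays by well under 1 %.

## Filtering

Pareto ranks are 1 + (number of dominating solutions); with score
constraints, any constraint breaker is additionally dominated by every
non-breaker. Percentile constraints use the nearest-rank method: "best
30 %" keeps the ⌈0.3·n⌉ best solutions' threshold value in the favourable
direction. The default objective set is V, HB, HY — energy is excluded
because generated overlays use conformers exactly as supplied. Borda
tallies use average ranks for ties, so they are invariant to the order of
the pool. Diversity selection is greedy on the consensus coefficient with
a 0.05 floor and a cap of 20 solutions.

## Refinement and multiplication

Annealing maximises F = HB − 0.5·V + HY − 0.3·E with Metropolis
acceptance, geometric cooling (T₀ = 0.5, factor 0.95, 100 moves per level,
50 levels, early stop after 500 consecutive rejections) and move
magnitudes of ±30° per torsion, ±0.25 Å per axis and ±5° about a random
axis through the ligand centroid; the starting temperature is low because
the aim is local improvement. The best state visited is returned, so the
reported F never decreases. Conformer indices are frozen during
refinement: ring flips and nitrogen inversions live in the input ensemble,
not in the annealer. The refined state is re-expressed as the source
chromosome plus per-ligand rigid terms (Euler decomposition of the net
transform), so it round-trips through JSON.

Multiplication holds the mapping table extracted from the seed overlay's
full and partial pharmacophore points (clusters of at least two
contributors; singleton clusters carry no cross-ligand information) and
evolves torsions and rigid terms: 40 % single-torsion mutation, 30 %
single-ligand torsion crossover, 30 % single-ligand rigid mutation,
tournament size 2, population and children 150 by default, selection by
Pareto rank on (V, HB, HY, E) with niching on the crude
squared-distance-matrix dissimilarity (threshold 1.0 Å², niche capacity 2
— the published description says only "once a niche is full"). None of
the operator probabilities are published; all live in `moga_config()`.

## Solution analysis

`D_P` matches same-kind pharmacophore points greedily by descending
Tanimoto coefficient (ties: larger weight, then point order) and applies
the stated formula literally, including the asymmetry between matched
weights and the squared sizes of unmatched points. Two empty
pharmacophores compare as identical (D_P = 0). `D_G` enumerates
symmetry-equivalent probe pairings per ligand (equivalence by iterated
neighbourhood refinement — a practical approximation to full graph
automorphism, capped at 5 000 pairings with an identity-pairing fallback),
keeps the lowest-rmsd pairing, Kabsch-fits the whole overlay and averages
the q-ramp (0 below 0.5 Å, linear to 1 at 3.5 Å). The two-step procedure
is directional as described, so we symmetrise by averaging the two
directions; this preserves the [0, 1] range and D(A, A) = 0 and makes
D_G — and hence D_C = √(D_P·D_G) — exactly symmetric. SMACOF runs stress
majorisation (Guttman transform) from a classical-scaling start, at most
300 iterations, relative tolerance 1e−6; raw stress is non-increasing at
every iteration by construction. The maps are a reading aid; no clusters
are computed from them automatically.

# The synthetic toy generator

`make_toy_set()` builds para-disubstituted benzene scaffolds carrying an
amine donor and a carbonyl acceptor, so every ligand realises the same
planted three-point pharmacophore (donor, acceptor, ring centroid; sides
≈ 3.7–6.9 Å, comfortably inside both bin schemes) in one "true"
conformer. Ligands are distinguished by decoy substituents (a ring methyl;
an anisole-type ether that adds a decoy acceptor and an extra rotor), and
conformers are enumerated on a 120° torsion grid around the true torsions,
so the binding conformer is guaranteed present — the real-world failure
mode where the conformer generator misses the bound ring pucker is
deliberately out of scope. A two-point variant (ligands spun about the
donor–acceptor axis so the rings diverge) is emitted with a
"stepwise-required" flag.

What passing tests on this material does show: the fingerprint machinery
finds planted common triplets, the filter surfaces the correct mapping
within the top 20, and recovery is stable across seeds. What it does not
show: behaviour on real ensembles with thousands of conformers, imperfect
protonation, conformer sets that miss the bound geometry, or feature
definitions beyond the shipped defaults.

# Problem sizes and defaults in the test suite

The shipped defaults are the production values (25 fingerprints per bin
scheme, 200 solutions per fingerprint, population/children 150). The test
suite and the acceptance script exercise the same code paths at reduced
search sizes chosen as the package's own test design — typically 6
fingerprint types × 20 greedy runs for generation, 10-chromosome/3-
generation genetic runs, and annealing budgets of a few hundred moves —
because the toy sets are small enough that these budgets already saturate
recovery (the acceptance replicates recover the planted pharmacophore in
10/10 seeds). Determinism: every stochastic stage consumes the R RNG
seeded from the run configuration, so identical seeds give digest-equal
outputs.

# Known limitations

* Feature perception trusts the input file's bonds, charges and hydrogens;
  aromaticity is taken from aromatic bond flags plus Kekulé 5/6-ring
  perception, and pyrrole-type NH aromatics need explicit hydrogens.
* The SMARTS subset excludes recursive patterns and stereochemistry.
* The energy term uses a minimal parameter set and one torsion term per
  bond; it ranks conformers usefully but is not a published force field.
* The stepwise supermolecule device generates and merges fitting points
  with full provenance, but choosing the order of stepwise merges is the
  user's job (automating it is explicitly future work).
* The gradient-based refiner that supersedes annealing in speed is out of
  scope; only the annealer is provided.
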