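---
title: "Methods: TM rotation, contact analysis and consensus pharmacophores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TM rotation, contact analysis and consensus pharmacophores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrtraj)
```

# Scope and model

Class-A GPCR activation is accompanied by rotations of the transmembrane
helices (notably TM5/TM6), loss of the Asp–Arg ionic pair of the conserved
DRY motif (the "arginine cage"), and a growing network of polar contacts
with the bound chemokine. `gpcrtraj` provides the measurement side of that
story for trajectories supplied as multi-MODEL PDB, plus the ligand-side
analysis: clustering docked antagonist poses and summarising their chemical
features into a consensus protein–ligand interaction model.

The package deliberately contains no simulation or docking engine. Every
analysis is testable against synthetic fixtures with planted ground truth,
generated by the package itself.

# TM rotation angles

## Construction

For a segment (residue range on a chain, defaults are the CXCR3 assignments
TM1 54–80 through TM7 299–321, with optional extensions 148–150 for the DRY
motif and 234–235 for TM5):

1. the frame is superposed onto the reference frame by a least-squares rigid
   fit (Kabsch, proper rotation) over the Cα atoms of **all** TM segments —
   loops are excluded because they are the most mobile part of the receptor;
2. the helix axis is the first principal component of the centred reference
   Cαs, oriented N→C, with the segment centroid as origin;
3. each residue's Cα is projected onto the plane perpendicular to the axis;
4. the per-residue signed angle between reference and frame projections
   (right-hand rule about the axis) is averaged with a circular mean and
   wrapped to (−180°, 180°].

A cross-check estimator (`method = "kabsch_twist"`) extracts the twist
component of the per-helix Kabsch rotation about the same axis; the two
agree within 2° on all fixtures. Rotations are reported against the
reference frame (frame 1, the 0-ns conformation); a frame-to-frame `delta`
mode exists for rate-style plots.

## What the estimator can and cannot resolve

Two intrinsic properties, both visible in the tests:

* **Global-fit absorption.** Because the rotated helix participates in the
  global superposition, a small fraction (~0.5 %) of a planted rotation is
  absorbed into the global fit: a noiseless 15° plant reads 14.92°, and up
  to ~0.2° leaks into the other helices. Noiseless tests therefore assert
  recovery within 0.3° rather than exactly.
* **Noise floor.** At the canonical Cα helix radius (2.3 Å), i.i.d.
  coordinate noise of σ = 0.2 Å on both the reference and the analysed frame
  produces per-residue tangential phase noise of √2·σ/2.3 ≈ 7.0°. The
  circular mean over a 20–27-residue TM leaves a standard error of
  1.4–1.6°, so the maximum error over 160 independent estimates (20 seeds ×
  8 planted angles) concentrates near 4°. The acceptance criterion asking
  for a 2° bound on that maximum is therefore not attainable in this stated
  world and is reported red, with the measured value (~4.3°) in the
  acceptance report; it would hold at σ ≈ 0.09 Å or for ~120-residue
  helices. The bound that the estimator does meet, established by
  Monte-Carlo before freezing the test, is 5°.

# Contact analysis

Detector defaults follow the conventions of the common contact-enumeration
tools: donor–acceptor ≤ 3.5 Å for hydrogen bonds (with a D–H…A ≥ 120°
criterion applied only when explicit hydrogens exist), nonpolar carbon pairs
≤ 3.9 Å for hydrophobic contacts (aggregated per residue pair, minimum
distance kept), and charged-group N/O pairs ≤ 4.0 Å for salt bridges. All
cutoffs are fields of `interaction_criteria()`.

Typing rules for hydrogen-free protein models are table-driven (standard
residue chemistry: backbone N except proline, Ser/Thr/Tyr hydroxyls,
Asn/Gln/Arg/Lys/Trp/His NH groups as donors; oxygens and neutral His ring
nitrogens as acceptors). Nonpolar carbons are carbons with no N/O of the
same residue within bonding distance (1.75 Å), which excludes carbonyl C and
Cα automatically; for Cα-only or coarse-grained data every C-typed site
counts, documented as a fallback. An oppositely charged donor/acceptor pair
is classified as a salt bridge only — it is not double-reported as a
hydrogen bond. His protonation is ambiguous, so His participation in the
positive class is off by default (`his_positive`).

The arginine-cage tracker reports, per frame, whether the Asp148–Arg149 pair
(configurable) forms a salt bridge, in the same presence/absence layout as
the published per-100-ns tables.

# Conformational and pose clustering

Pairwise frame RMSD (Cα by default, with or without superposition) feeds the
GROMOS algorithm: repeatedly take the unassigned frame with the most
unassigned neighbours within the cutoff as a new cluster representative,
remove the cluster, repeat; removed members never count as neighbours again;
ties break to the lowest label. Published cutoff presets are 0.2/0.4/0.51/
0.6 nm; the matrix records its units (nm for trajectories, Å for poses) to
prevent unit bugs. "cluster1" is the largest cluster and its representative
is the most-representative conformation.

Docking poses of one ligand share the receptor frame, so pose RMSD is
computed **without** superposition, on heavy atoms, with no symmetry
correction (a documented limitation), and clustered with GROMOS at 2 Å. The
representative pose is the member of the largest cluster closest to the
cluster's coordinate centroid.

# Consensus pharmacophore model

Features are extracted from each ligand's representative pose with rule-based
typing: HAc — N/O with an available lone pair, not positively charged, not
an amide nitrogen; HDn — N/O carrying a hydrogen (explicit or implied by
valence); PIn — protonatable amine/guanidinium/amidinium or formal charge
> 0, one feature per group; NIn — carboxylate/sulfonate/phosphate or formal
charge < 0, at the oxygen-set centroid; Arm — smallest aromatic ring
centroids; Hph — centroids of connected sets of ≥ 3 nonpolar non-aromatic
carbons. Atoms consumed by a charged group are not re-typed as HAc/HDn
(ionised groups are typed by their charge). Default radii: 1.0 Å for point
features, 1.5 Å for ring/hydrophobic centroids.

Features are clustered **per type** ("nature"), with the metric
`‖Δposition‖ + λ·|Δradius|` ("position" and "size", λ = 1 by default), using
a deterministic PAM: BUILD adds the cost-minimising medoid greedily, SWAP
applies the single best cost-reducing swap until a local optimum, all ties to
the lowest index. The number of clusters per type maximises the mean
silhouette over k = 2…8, **with a fallback to k = 1 when the best silhouette
is below 0.7** — the strong-structure bound of Kaufman & Rousseeuw. The
fallback matters: splitting a single 10-point Gaussian blob can reach
silhouettes up to ~0.6, while genuinely separated feature clusters score
≥ 0.85 even at 10 σ separation, so 0.7 cleanly prefers a false merge over a
false split, the right bias for consensus elements.

Deterministic single-swap PAM is a local optimiser: on structureless
uniform-random point sets it can stall above the exhaustive optimum — at
exactly the same cost, in our checks, as the canonical R `cluster::pam`
implementation. On clustered data of the kind this pipeline produces
(well-separated feature blobs, k at the value `choose_k` selects) it attains
the exhaustive optimum, which is what the oracle tests assert.

Each consensus element carries its type, centroid, radius (medoid radius
plus the cluster's RMS spatial spread), support (number of distinct
contributing ligands; elements under `min_support`, default 10 % of ligands,
are pruned) and the receptor residues with any atom within 5 Å — the same
element → residue-list layout as the published tables. `compare_models()`
matches same-type elements between two models by nearest centroid under a
match radius. pKi (5–9.7 in the source antagonist set) is carried as
metadata and available as a filter; it does not weight the clustering.

# Synthetic data: the stated world

The generators emulate the statistical and geometric structure the analyses
assume, not force-field physics:

* **Helices/bundles** — canonical α-helix geometry (rise 1.5 Å/residue,
  twist 100°/residue, Cα radius 2.3 Å), Cα traces or ideal N-CA-C-O
  backbones (φ = −57°, ψ = −47° via natural-extension chain building).
  Bundles place one helix per TM range on a circle with alternating
  orientation; residue numbering follows the published inclusive ranges.
* **Rotation trajectories** — scheduled per-TM rotations about each helix's
  own fitted axis, optional random whole-body rigid motion per frame, then
  i.i.d. Gaussian coordinate noise (σ = 0.2 Å in the acceptance fixtures, a
  plausible per-frame thermal jitter scale); frame 1 is the 0° reference.
* **Complexes** — the chemokine-like chain is rigidly placed on a scheduled
  centre-of-mass distance (±0.01 Å by construction); planted contacts are
  realised at kind-specific distances safely inside the detector cutoffs
  (salt bridge 3.0 Å, H-bond 2.9 Å, hydrophobic 3.6 Å) and parked at
  cutoff + 1.5 Å when scheduled absent, with a compensating shift of the
  remaining chain atoms keeping the COM on schedule.
* **Pose libraries** — each planted cluster contributes `n_members` ligands,
  one template fragment each (carbonyl → HAc, amine → HDn and a co-located
  HAc, benzene → Arm, butane → Hph, charged amine → PIn, carboxylate →
  NIn), scattered around the centroid (sd 0.3 Å) with randomly oriented
  copies jittered into poses (sd 0.3 Å) and optional displaced decoys.

Everything is bitwise deterministic under a fixed seed, and every fixture is
returned together with its truth table. A green test therefore establishes
that the estimators recover *planted* geometry/typing under Gaussian noise —
not that they reproduce any particular published trajectory, which was never
deposited.

# Numerical choices and degenerate inputs

* Angles are always reported in (−180°, 180°]; the circular mean uses
  `atan2(Σsin, Σcos)`.
* Kabsch uses SVD with a determinant sign correction, so reflections are
  never returned; identical point sets give RMSD ~1e-15.
* Residue ranges are 1-based and inclusive, taken verbatim from the PDB
  resid column; insertion codes are rejected.
* Selections parse totally: syntax errors raise, an empty match is legal.
* `phi_psi` skips residues with missing backbone atoms (warning) and omits
  termini; `ramachandran_summary` errors on empty input; percentages sum to
  100 exactly.
* The default Ramachandran map is a coarse polygon set (core α, β with its
  ψ wrap-around, left-handed α, plus allowed margins) shipped as replaceable
  JSON; (0°, 0°) is an outlier, (−57°, −47°) is favored. Contour-based maps
  (e.g. MolProbity's) give *comparable, not identical* percentages — out of
  scope by design.
* GROMOS on a cutoff smaller than every positive distance yields singletons;
  larger than the maximum yields one cluster; both are tested.
* PAM with k = n gives zero cost; k = 1 reduces BUILD to an exhaustive scan.

# Known limitations

* PDB and SDF V2000 only (mmCIF, XTC/DCD, MOL2 are out of scope; the
  trajectory contract accepts adapters).
* Pose RMSD has no graph-symmetry correction, so symmetric ligands can
  over-estimate pose distances.
* Feature typing is rule-based on elements/charges/bonds, a deliberate
  approximation of full cheminformatics perception; the rules are exposed
  rather than hidden behind a toolkit.
* The rotation estimator's noise floor (above) bounds what per-frame
  rotations mean quantitatively at high thermal noise; trends across frames
  are robust well below it.
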