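---
title: "PhoreScreen methods: pharmacophore screening and pose fingerprint analysis"
author: "PhoreScreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PhoreScreen methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PhoreScreen)
```

PhoreScreen implements a ligand-based discovery chain for receptors without
experimental structures, of the kind used against peptide-binding GPCRs whose
known antagonists form a single chemical series: structure–activity analysis
of the series, a common-feature pharmacophore as the screening query,
enrichment-validated virtual screening, and structure-based post-processing of
docked poses by the interactions they form. This vignette explains the models
and procedures, the parameters that matter, what the synthetic generators do
and do not emulate, and the design choices made where the method left room.

## 1. Activity classes and matched pairs

Compounds are classified from calcium-mobilization IC50 values with strict
cutoffs: **active** below 0.05 µM, **inactive** above 1 µM, everything between
— boundary values included — **excluded**. The excluded band is deliberate: a
20-fold gray zone keeps weak binders from polluting either class.

Matched-pair analysis presumes a fixed shared scaffold. A
`scaffoldTemplate()` names the core substructure and its labeled variable
positions (A1, D, L2, Q in the default). Each molecule is decomposed by
subgraph isomorphism (VF2, element- and charge-colored) into core plus
per-position substituents; an (active, inactive) pair is *matched* when the
substituents are graph-isomorphic at all positions but exactly one. We
deliberately use a declared template rather than generic maximum-common-
substructure pairing: with a fixed series the template is unambiguous,
deterministic, and orders of magnitude cheaper, at the cost of skipping
(and logging) molecules that do not contain the core.

`positionFeatureRules()` aggregates pairs per position: a feature kind is
flagged **required** when it is present in every active-side substituent at
that position and absent from at least one inactive counterpart. The
asymmetry matters — a kind can be required for activity even if some
inactives happen to carry it at another cost — and the reported evidence
lists the supporting pair ids so the rule can be audited.

## 2. Feature perception and protonation

The perception rules are fixed and deliberately conventional (Catalyst-like),
because everything downstream — models, mapping, screening — must agree on
them:

- **HBD**: N/O bearing at least one hydrogen (implicit or explicit).
- **HBA**: N/O with a lone pair, excluding amide N, aromatic N–H, and any
  nitrogen of a positively charged group; carbonyl oxygens carry a direction
  along C=O.
- **POS_IONIZABLE**: each group carrying +1 after protonation (guanidinium,
  amidinium, protonated amine), centroid of the group.
- **AROMATIC**: each smallest aromatic ring; centroid with the ring normal as
  an (axial) direction.
- **HYDROPHOBIC**: contiguous non-aromatic carbon-only fragments of ≥ 3 atoms
  none of which touches a heteroatom; fragment centroid. Aromatic carbons are
  excluded so ring and hydrophobic features never double-count.

Protonation is rule-based at pH 7.5 with a fixed pKa table (guanidine 13.6,
amidine 11.6, aliphatic amine 10.6, carboxylic acid 4.8) — no per-molecule
pKa prediction. Hydrogens are carried as per-atom implicit counts, with
explicit H atoms honored when present; this is sufficient because every rule
above needs only donor hydrogen counts, and the toy complexes are heavy-atom
constructs. The hydrogen-bond D–H⋯A angle criterion (≥ 120°) is therefore
applied only when an explicit donor hydrogen exists; otherwise the
donor–acceptor distance decides, as in common interaction-fingerprint
practice.

All coordinates are ångströms; distance cutoffs are strict inequalities
unless stated otherwise (the 4 Å contact cutoff is strict; the interaction
criteria below use ≤).

## 3. Conformers

Conformer sets are generated by seeded random torsion driving: every
rotatable bond (acyclic single bond between non-terminal heavy atoms,
excluding amide C–N) receives a random torsion per sample, the smaller branch
rotates, and each pose is scored with a soft Lennard-Jones-like nonbonded
term over atom pairs three or more bonds apart. Poses are deduplicated at
0.5 Å heavy-atom RMSD (after superposition), energy-sorted, and kept up to
`nMax = 50` within a `window = 20` kcal/mol of the minimum — the window and
set size of a standard "best-quality" conformer protocol. The seed is a
mandatory argument: conformer generation is the one stochastic step inside
molecule preparation, and reproducibility is a contract, not an option.
This scheme is the package's own (a distance-geometry embedder would need
3D coordinates anyway for the energy model used here); the energy scale is
nominal kcal/mol, adequate for windowing and dedup, and no force-field
accuracy is claimed. SMILES input obtains a starting 3D geometry from
OpenBabel when ChemmineOB is installed.

## 4. Pharmacophore models, mapping, fit

A model is k features with centers, tolerance radii (default 1.6 Å, the
common Catalyst sphere), optional unit directions with a 45° angular
tolerance, a minimum interfeature distance (1.0 Å) and a maximum number of
omittable features (0). Defaults follow the screening protocol the package
emulates: minimum interference distance 1 Å, zero omitted features.

`mapLigand()` searches all conformers and all kind-compatible injective
assignments of model features to perceived ligand features; each assignment
is scored after Kabsch least-squares superposition of the matched ligand
centroids onto the model centers. An assignment is admissible when every
non-omitted feature lies within its tolerance sphere and satisfies the
angular check where both sides carry directions (ring normals are compared
axially, so a flipped ring is equivalent). The fit value is

$$\mathrm{fit} = \sum_f \max\!\left(0,\; 1 - (d_f/r_f)^2\right),$$

maximal (= k) at zero displacement. This functional form is chosen because
it reproduces the one property the emulated protocol states outright — a
four-feature model has a maximal FitValue of 4 — while decaying smoothly and
monotonically to zero at the tolerance radius. Ties between assignments
break to the lower conformer energy, then lexicographic assignment order;
determinism is part of the contract and is tested.

`buildCommonFeatureModel()` is a bounded reimplementation of the
common-feature idea, not the published HipHop search: it enumerates
k-subsets of the most active reference's features (k descending) and keeps a
subset when every other reference offers a kind-matched assignment whose
pairwise distance matrix agrees within twice the tolerance. Models are
ranked by size, then by mean cross-reference distance discrepancy, and at
most ten are emitted. Emitted models are **positional only**: the subset
search validates distance-matrix consistency, not direction consistency, so
copying the lead reference's (arbitrary) feature orientations into the model
would impose constraints nothing has checked. Directions can still be set on
a model explicitly, and mapping honors them.

## 5. Screening, decoys, enrichment

Library preparation mirrors the emulated protocol: molecules are retained
when every property (MW, logP estimate, H-bond donors/acceptors, rotatable
bonds, formal charge) lies within ± 4 SD of the reference actives' means, and
— when the charge rule is on — the net formal charge is neutral or positive.
The logP here is an atomic-contribution estimate with a small declared table;
it is used only inside this consistency window, where the same estimator is
applied to references and candidates, so absolute accuracy is immaterial.

Decoys are drawn property-matched (so enrichment cannot come from trivial
property separation) but guaranteed not to present the model's feature
arrangement. `screenLibrary()` maps every molecule and ranks by fit;
molecules that cannot be mapped are "not retrieved" and enter the ROC at
score −∞. The ROC sweeps unique fit thresholds downward (tied scores enter
together), the AUC is the trapezoid area, and the **full-recall cutoff** is
the minimum fit among actives — the highest threshold retrieving 100% of
them, with ties kept on the ≥ side, matching a `FitValue ≥ cutoff` hit rule.

Similarity uses a hashed linear-path fingerprint (2048 bits, paths up to 7
bonds, canonical path direction, deterministic polynomial hash) and the
Tanimoto coefficient SA/(SA+SB+SC); two empty fingerprints score 0 by
convention. The fingerprint is declared and fixed so thresholds quoted
against it are internally consistent; it is not any vendor fingerprint.

## 6. Complexes, interactions, fingerprints, clustering

Receptor–ligand complexes are parsed from PDB (bio3d) with ligand
connectivity inferred from covalent-radius distances when CONECT records are
absent; waters are skipped. Interaction criteria live in one config block:

| interaction | criterion |
|---|---|
| contact | heavy-atom pair < 4.0 Å (strict) |
| hydrogen bond | donor–acceptor ≤ 3.5 Å, D–H⋯A ≥ 120° when H present |
| charged (salt bridge) | opposite-charge group centroids ≤ 5.5 Å |
| π–π | ring centroids ≤ 5.5 Å at ≤ 30° interplanar, or 60–120° at ≤ 6.0 Å |
| π-cation | cation centroid ≤ 6.0 Å from ring centroid, ≤ 30° off the normal |

The per-pose interaction fingerprint has three channels per binding-site
residue — HBOND, CHARGED, and a merged PI channel (π–π and π-cation
together, following the emulated analysis, which clustered the two π types
as one category; the merge is recorded in the output metadata). Every set
bit implies at least one sub-4 Å heavy-atom contact, and all detections are
invariant under rigid motion of the whole complex; both are tested
properties. Van der Waals-only contacts are reported by `findContacts()` but
not fingerprinted.

Fingerprints are compared by normalized Hamming distance (fraction of
differing coordinates) and clustered agglomeratively; **average linkage** is
the default (the emulated clustergram's settings are unstated, and average
linkage is the least shape-biased of the standard choices for binary data).
Dendrograms export as Newick via ape.

Pose filters encode the three structure-based constraints used to
post-process docked poses: (1) a charged interaction with the acidic anchor
(the Glu 2.61 role), (2) at least one hydrogen bond with a cationic anchor
(Arg 3.32 / Arg 6.58 roles), (3) at least two π interactions with those
anchors. Roles map to concrete residue ids in the rule list, so the filters
apply to any receptor numbering, and each failing pose reports the first
violated constraint.

Redocking validation offers symmetry-aware heavy-atom ligand RMSD (Kabsch on
shared receptor Cα, identity when receptor frames already coincide; minimum
over ligand graph automorphisms, so a benzene rotated 60° scores 0) and
contact/residue recovery — the fraction of the reference complex's sub-4 Å
contacts and interacting residues reproduced by the docked pose.

## 7. The synthetic generators: what they emulate, and what not

The generators stand in for inputs the original study drew from a patent
series, ZINC and DrugBank, none of which ships with the package.

**Actives** (`genActives`) are multi-fragment *feature carriers*: one
chemical fragment per model feature — a tetramethylguanidinium-like cation
(one donor NH2, mirroring a guanidine-bearing antagonist series), a ketone
acceptor, benzene, an alkane chain — each rigidly placed so its perceived
feature centroid lands on the model center plus a uniform jitter bounded by
`noise` (default 0.2 Å), with random fragment orientation. Chain length
(3–6 carbons) and an optional inert ethane fragment vary the property
profile so the ±4 SD window is meaningful. IC50 annotations are drawn below
0.05 µM. The fragments are deliberately disconnected: exact geometric
control of the planted features for an arbitrary model geometry is what the
parameter-recovery tests need, and it is not achievable with a connected
scaffold without a force field. The cation carries a single donor because a
fragment with several features at fixed mutual distances would form a
rotation-invariant feature cluster that trivially dominates the
common-feature subset search — a degenerate geometry rather than a
discovered one.

**Decoys** (`genDecoys`) reuse the same fragment palette — hence match the
actives' property window by construction, which the generator can also
assert against supplied reference statistics — but scatter the fragments at
random positions (4–10 Å from the first, ≥ 3 Å apart) and resample until
`mapLigand` rejects the candidate with zero omissions. Decoys are therefore
*guaranteed* non-mappers, which makes the synthetic enrichment ROC
essentially perfect. This is the intended study condition (recall at the
full-recall cutoff), not a claim about real libraries: against ZINC-like
decoys some would map with intermediate fits, the ROC would bow, and the
cutoff would discriminate rather than merely separate.

**Matched pairs** (`genMatchedPairs`) build connected molecules on a benzene
core with four labeled positions, drawing substituents from a small palette;
the active side of each pair carries the rule's planted feature kinds at the
planted position, the inactive side a substituent lacking them, all other
positions identical within the pair. Coordinates come from a crude radial
embedding — sufficient because the SAR analysis consumes only feature
*kinds*, never geometry.

**Toy complexes** (`genToyComplex`) place isolated side-chain fragments
(Glu, Asp, Arg, Lys, Cys, Ser, Thr, Asn, Met, Phe analogs; no backbone)
around a fixed five-fragment ligand so that `detectInteractions` yields
exactly the requested bits: pattern residues sit at interaction geometry,
all other site residues on a 16 Å shell. One Arg can realize a π-cation and
a hydrogen bond simultaneously (stacking over the ring while donating to an
auxiliary carbonyl) — necessary because the three pose constraints demand
one hydrogen bond plus two π interactions from just two cationic anchors.
Every generated complex is verified internally against its requested
fingerprint before being returned, so an unsatisfiable pattern fails loudly
rather than silently drifting. The small coordinate jitter (±0.05 Å) sits
well inside all criterion margins. What these complexes do **not** emulate:
backbone sterics, side-chain flexibility, solvation, or docking-score
physics — they exercise the detection geometry, not docking.

All generators derive one RNG substream per (seed, purpose) pair, so adding
a generator call never reshuffles another's output, and identical seeds give
byte-identical files across runs.

## 8. Numerical choices and degenerate inputs

- Kabsch superposition via SVD with a determinant guard (no reflections).
- Assignment ties in mapping: lower conformer energy, then lexicographic
  order. Clustering ties follow `stats::hclust`.
- The ±kSD window comparison allows 1e-9 slack so zero-variance properties
  (e.g. formal charge over a homogeneous series) accept equality.
- Zero actives make the ROC undefined (error); a reference complex with no
  contacts makes recovery undefined (error); a single pose skips clustering
  with a warning but still fingerprints and filters.
- Unmapped molecules are excluded from hit lists and scored −∞ in ROC.
- Automorphism enumeration for symmetry-aware RMSD is capped at 5000
  mappings — far above anything a drug-sized ligand produces.

## 9. Problem sizes used by the packaged experiments

The packaged tests and the acceptance script run the screening emulation at
56 actives + 500 decoys (0.2 Å noise), the clustering recovery at 20 + 20
poses with 5% bit-flip noise, and SAR recovery at 13 pairs — sizes chosen to
mirror the emulated study's active count and to keep the full suite
comfortably within a desktop run. Passing them demonstrates parameter
recovery under the generators' assumptions (rigid fragments, exact
perception, guaranteed decoys); it does not measure performance on real
screening libraries or real docked poses.

## 10. Known limitations

- The fit function is a declared stand-in for an unpublished vendor formula;
  only its ceiling property is anchored.
- logP is a coarse estimate; do not compare its absolute values with other
  software.
- Aromaticity perception covers benzene-like six-membered rings (and
  order-4 SDF bonds); exotic aromatic systems should arrive with explicit
  aromatic flags.
- The conformer energy model has no electrostatics or torsional terms;
  conformer sets are diverse and reproducible rather than physically ranked.
- Tautomers, stereochemistry enumeration, and pKa prediction are out of
  scope; input stereo is taken as given.
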