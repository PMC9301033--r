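---
title: "Interaction-fingerprint-guided scoring and fragment growing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction-fingerprint-guided scoring and fragment growing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifpgrow)
```

## The problem

Docking scoring functions reward bulk: larger molecules make more
non-specific contacts and earn better scores, so generative pipelines that
rank candidates by docking score drift toward heavy, promiscuous
compounds. When crystal structures of known binders are available, a
knowledge-based alternative is to reward *reproducing the known binding
mode* instead of raw interaction count. `ifpgrow` implements that idea as
a scoring function over residue-wise interaction fingerprints, embeds it
in a generational fragment-growing loop, and ships the surrounding
benchmark analytics (cross-docking success rates, pharmacophore filtering,
shape/electrostatic similarity) needed to evaluate such runs.

## The fingerprint and the score

For a receptor with $r$ polymer residues (file order defines the index),
a ligand pose is encoded as a bit vector of length $8r$. Residue $i$
contributes eight bits, one per interaction class, at positions
$8i + c$:

| channel $c$ | class |
|---|---|
| 0 | hydrophobic contact |
| 1 | aromatic face-to-face |
| 2 | aromatic edge-to-face |
| 3 | hydrogen bond, protein donor |
| 4 | hydrogen bond, protein acceptor |
| 5 | salt bridge, protein positively charged |
| 6 | salt bridge, protein negatively charged |
| 7 | metal coordination |

Given the fingerprint $A$ of a reference crystallographic complex and the
fingerprint $B$ of a query pose in the same receptor, the score is

$$\mathrm{IFP_{CS}}(A, B) \;=\; -\,\frac{A \cdot B}{\lVert A\rVert\,\lVert B\rVert},$$

minus the cosine similarity of the two bit vectors. Because the vectors
are non-negative the score lies in $[-1, 0]$: $-1$ means the query
reproduces the reference binding mode exactly, $0$ means no shared
interaction. The sign flip makes the score a drop-in replacement for
docking scores in selection machinery that favors the most negative
values. A pose with *no* detected interaction has an all-zero fingerprint;
its similarity is defined as 0 (the worst score) rather than an error, so
degenerate candidates remain rankable inside a population.

```{r}
cx <- make_toy_complex(fixture_spec(
  data.frame(residue = 0:4, channel = c(0, 1, 2, 3, 4))))
fp <- reference_fingerprint(cx$receptor, cx$ligand)
fp
ifp_cs(fp, fp)
```

## Geometric contact detection

The paperless part of any fingerprint is the geometry. All criteria are
exposed in `contact_params()` (distances in Å, angles in degrees) with
defaults in line with common fingerprint practice:

* hydrophobic: aliphatic C/S pairs within 4.0;
* aromatic: ring-centroid distance ≤ 5.0 with interplane angle ≤ 30°
  (face-to-face) or within [60°, 90°] (edge-to-face) — the two windows are
  disjoint by construction, so no ring pair can fire both channels;
* hydrogen bond: donor–acceptor heavy-atom distance ≤ 3.5, plus a
  D–H⋯A angle ≥ 120° whenever the donor hydrogen is explicit
  (distance-only otherwise — a deliberate degradation so that
  hydrogen-free PDB inputs still work);
* salt bridge: charged-group centroid distance ≤ 4.0, with groups
  perceived from formal charges plus carboxylate / ammonium / guanidinium
  templates (inputs are assumed protonated upstream; no pKa model);
* metal: metal ion to ligand N/O within 2.8.

One design choice deserves emphasis: **aromatic-ring carbons are excluded
from the hydrophobic role.** At every edge-to-face geometry that satisfies
the centroid cutoff, ring atoms of the two partners are inevitably within
hydrophobic range, so counting aromatic carbons as hydrophobic would make
channel 0 fire for essentially every stacking interaction. Keeping the
channels disjoint makes fingerprints sharper and makes the synthetic
fixtures' ground truth exact. Users who want the more inclusive convention
can widen it by adding contacts at the role-assignment level.

A group satisfying both hydrogen-bond directions (e.g. a hydroxyl meeting
a serine) legitimately sets both channels 3 and 4. Multiple atom pairs
satisfying one (residue, channel) predicate collapse to a single bit; the
closest pair is reported in the contact table.

## The growing loop

`run_evolution()` is an elitist generational algorithm:

1. generation 0 scores the seed molecules;
2. each later generation draws survivors (the `n_survivors` most negative
   scores, ties broken by canonical SMILES so runs are reproducible),
   produces `n_mutants` fragment attachments and `n_crossovers`
   recombinations, collapses duplicate children by canonical SMILES, and
   carries `n_elites` members unchanged;
3. every molecule's score is the best (most negative) score over the
   poses returned by a pluggable pose provider.

Mutation attaches one library fragment by a single bond at a
hydrogen-bearing heavy atom on each side. Crossover cleaves each parent at
one synthetically sensible acyclic single bond — a reduced BRICS-style
rule set: the bond must join two heavy atoms and have ring or heteroatom
context — and joins one fragment of each parent at the cut points. Both
operators work on implicit-hydrogen topology records and are valence
checked; an operator that cannot apply returns a *skip signal* rather than
an error, and a generation consisting only of skips terminates the run
early. With at least one elite the best score per generation is
non-increasing by construction, which the test suite verifies as a
property.

No physicochemical filters are applied by default beyond an optional
heavy-atom cap: silent Lipinski/PAINS-style gates would shape the
population in ways the user did not ask for.

## Pose providers

Docking engines are deliberately outside the package. The
`pose_provider` contract (`propose(molecule, receptor, seed)`) has two
implementations: `read_pose_file()` adapts SDF pose files written by any
external engine, and `toy_pose_provider()` generates deterministic
desk-scale poses by embedding a conformer, mapping the molecule onto a
reference ligand via element-colored subgraph matching (falling back to
principal-axes alignment when no common substructure exists), and adding
seeded Gaussian jitter to poses 2..n. Pose 1 of the reference molecule
reproduces the reference conformer exactly, which is what makes the
end-to-end self-score test possible.

Conformer embedding runs through a bundled RDKit helper with a fixed
per-molecule seed. This was a deliberate choice after testing the
alternatives: OpenBabel's 3D builder seeds its rotor search from the wall
clock, so identical inputs produce different conformers across calls,
which would break the package's reproducibility contract (identical runs
from identical `(config, seed)`). Embedded conformers are cached per
canonical SMILES.

## Pharmacophore model

`build_pharmacophore()` collects ligand-side anchors from each complex's
detected contacts — acceptor atoms engaged through channel 3, donor atoms
through channel 4, ring centroids (with normals) through channels 1/2 —
clusters them across complexes by single linkage, and keeps clusters
whose occupancy reaches the retention threshold (default 50%). Matching
is a binary AND over all features: a pose passes only if every feature
has a matching-role ligand point within `radius + tolerance` (aromatic
features also require the ring normal within 30° of the feature normal).
The all-features choice is deliberate: the filter is used as a gate, and
partial matches are reported per feature but never pass. Single-linkage
clustering and the sorted feature table make the model independent of
complex input order.

Defaults (merge radius 1.5 Å, match tolerance 1.0 Å, 30° normal
tolerance) are exposed in the builder and matcher; they are conventional
values for feature clustering at crystallographic coordinate accuracy,
not fitted quantities.

## Shape and electrostatic similarity

`et_combo()` is an openly declared substitute for commercial
field-similarity tools on the same 0–2 scale: a Gaussian-overlap shape
Tanimoto (heavy atoms, Grant–Pickup parameterization from van der Waals
radii, first-order overlaps) plus a charge-weighted Gaussian Tanimoto on
Gasteiger partial charges (all atoms). Anti-correlated electrostatics are
clamped to zero, and two charge-free molecules score 0 by convention.
Poses are compared in the frame they arrive in; there is no overlay
optimization, matching the use case of comparing docked poses against
aligned crystal ligands. Numerical agreement with any particular
commercial implementation is not claimed — the analytics need a
self-consistent similarity on the familiar scale, not a replica.

## Cross-docking analytics

`heavy_atom_rmsd()` is computed in the docked frame (no re-superposition)
and minimized over the automorphisms of the element-colored heavy-atom
graph, so symmetry-equivalent poses (a flipped phenyl, a rotated
carboxylate) score 0 as they should at a 2 Å success gate. Automorphisms
come from closing the generator set returned by graph isomorphism
machinery; the closure is capped at 10,000 permutations, beyond which the
identity mapping is used with a warning. A docking run counts as a
success when its best-pose RMSD is *strictly below* the threshold
(default 2.0 Å — a cell at exactly 2.0 fails), success fractions are
computed per receptor and protocol over non-missing cells, and the
consensus is the arithmetic mean across protocols with ties in the
receptor ranking broken by receptor id.

## The synthetic fixture generator

`make_toy_complex()` builds a substituted-benzene ligand and places
idealized residue templates (standard bond lengths and angles, not real
PDB fragments) at ideal interaction geometry for every planted
(residue, channel) pair: a leucine-like side chain 3.8 Å from a methyl
group, a phenyl ring stacked parallel at 4.3 Å or perpendicular at 4.7 Å,
backbone donors/acceptors at 2.9 Å with collinear hydrogens, charged
groups at 3.8 Å centroid separation, a zinc ion at 2.1 Å. Because the
construction *is* the oracle, the detected contact set must equal the
planted list exactly, and the suite asserts that for every channel.
Template partial charges give the electrostatic similarity tests nonzero
signal. Geometric noise (`sigma`) perturbs receptor atoms under a seed;
recovery degrades with noise on average, which is tested as a trend, not
per seed.

What the fixtures do **not** emulate: real protein fold geometry, solvent,
induced fit, crowded pockets where channels compete, or the conformational
strain of real ligands. Passing tests on fixtures therefore demonstrate
the correctness of the geometry, encoding, arithmetic and search
machinery — not docking accuracy on real systems.

`make_fragment_library()` draws from a curated pool of drug-like
fragments, gated by default to 100–150 Da — the conventional seed-fragment
window for de novo growing.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on synthetic
complexes at desk scale: 24 complexes for pharmacophore statistics
(matching the usual size of a curated crystal-structure set for a single
kinase target), 20-fragment libraries and 5-generation runs for the
end-to-end growing demonstration, and 2–3 generations for determinism and
elitism properties. These sizes were chosen to exercise every code path
while keeping a full check runnable on a laptop; production runs scale
the same entry points up through the JSON run configuration.

Other conventions worth knowing: cosine similarity with an all-zero
vector is 0, never an exception; "exceeds a threshold" in enrichment
analytics is read as ≥ and is configurable; mean molecular weight is
reported over pharmacophore passers only while enrichment fractions use
the whole generation (two different denominators, deliberately); the mean
MW of an empty passer set is `NA`, never 0; selection ties break on
lexicographic canonical SMILES; subgraph-mapping ties break on the
lexicographically smallest mapping.

## Limitations

* Contact geometry uses fixed cutoffs, not scoring-function-grade
  interpolation; fingerprints are binary, not counts or strengths.
* The fingerprint spans *all* residues of the supplied receptor. Users
  who want binding-site-only fingerprints should pre-truncate the
  receptor; reference and query receptors must share the residue count.
* The crossover rule set is a reduced BRICS-style approximation, not the
  full published rule table.
* Charged-group perception relies on formal charges and residue
  templates; unusual protonation states must be prepared upstream.
* The toy pose provider is a test instrument, not a docking surrogate:
  it knows the answer (the reference pose) and adds noise around it.
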