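---
title: "Methods: restrained UFF minimization of NMR ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: restrained UFF minimization of NMR ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `nmrefine`, the numerical
choices behind it, and what the test suite does and does not establish.

## The combined potential

Each model of an NMR ensemble is minimized independently in

$$E = E_\mathrm{UFF} + E_\mathrm{restraint},$$

with no electrostatics anywhere. The omission is deliberate: without a
partial-charge model (charge equilibration is not implemented) bare
Coulomb terms would require a solvation model to moderate them, and the
refinement task — settling bond lengths, angles and contacts of an
already experimentally-determined fold — is driven by dense distance
restraints, not by electrostatics.

### UFF terms

* **Bonds** — harmonic, $E = \tfrac12 k (r - r_0)^2$, with the natural
  length $r_0 = r_I + r_J - 0.1332\,(r_I + r_J)\ln n - r_{EN}$ (bond
  order $n$, electronegativity correction $r_{EN}$) and
  $k = 664.12\,Z_I Z_J / r_0^3$ kcal mol⁻¹ Å⁻². The harmonic form is
  used rather than the Morse option: minimization never samples
  dissociation, and the harmonic form is what the common open-source UFF
  implementations use.
* **Angles** — the UFF cosine expansion
  $E = K (C_0 + C_1\cos\theta + C_2\cos 2\theta)$ with the standard
  $C_i(\theta_0)$ and the $Z$-based force constant; linear centers
  ($\theta_0 = 180°$) use $E = K(1 + \cos\theta)$. Expressing the energy
  in $\cos\theta$ keeps the gradient finite at degenerate geometries.
* **Torsions** — $E = \tfrac12 V (1 - \cos n\phi_0 \cos n\phi)$ with the
  UFF case rules (sp³–sp³: $V = \sqrt{V_i V_j}$, $n=3$; sp²–sp²:
  $V = 5\sqrt{U_i U_j}(1 + 4.18 \ln BO)$, $n=2$; mixed: $V=1$, $n=6$,
  plus the group-16 and conjugation exceptions), the barrier divided
  evenly among the torsions sharing a central bond. Torsions with
  collinear centers contribute zero by construction.
* **Inversions** — $E = K(1 - \cos\omega)$ at trigonal C/N centers
  ($K = 6$ kcal/mol, 50 for carbonyl carbons, split over the three axis
  permutations). The term is on by default, matching the common
  open-source UFF implementations, and `ff_config(inversions = FALSE)`
  turns it off.
* **van der Waals** — 12-6 Lennard-Jones with geometric-mean combination,
  over *all* atom pairs except 1-2 and 1-3; 1-4 pairs enter at full
  strength and no distance cutoff is applied (systems of interest are a
  few thousand atoms at most; the pure-R evaluator is comfortable to a
  few hundred).

Parameters ship as a plain TSV (`inst/extdata/uff_params.tsv`) keyed by
UFF type label. Typing is rule-based from element + connectivity;
resonant centers (aromatic rings, amide and guanidinium nitrogens,
carboxylate oxygens) get the `_R`/`O_2` types so that planar groups stay
planar. Two equilibrium lengths are overridden after perception:
carboxylate C–O bonds (motif: a carbon with exactly two proton-free
terminal oxygens) are pinned at 1.25 Å and arginine CZ–N bonds at
1.34 Å. Protonated COOH groups do not match the motif on purpose.

### Restraint term

With endpoint separation $D$ and corrected upper limit $r$, the violation
is $v = \max(0, D - r)$ and the force magnitude

$$|F| = K' \min(v, 5\,\text{Å}), \qquad K' = K \cdot \text{scale},
\quad K = 198.6\ \text{kcal mol}^{-1}\text{Å}^{-1},$$

pulling the endpoints together; the energy is its exact integral
(harmonic below the plateau, linear above). Two published descriptions of
this force differ: one defines the clipped quantity as the *separation*,
which read literally would squeeze even satisfied restraints; the other
states a harmonic-up-to-5 Å-violation potential. Only the second gives
zero force inside the bound and the stated plateau, so the implementation
clips the *violation*: $d = \min(\max(0, D - r), 5)$.

Pseudoatom endpoints are positioned at the arithmetic mean of their
parent hydrogens, and the endpoint force is distributed evenly to the
parents. Because the position is a mean, the chain rule produces exactly
the same $1/N_Q$ factor, so the distributed forces are the true negative
gradient of the energy — the gradient tests cover restrained systems too.

Upper limits referencing a pseudoatom are back-converted with
$r = r_p (N_{Q,i} N_{Q,j})^{1/6}$, multiplying the factors of both
endpoints ($N_Q = 1$ for a real atom). The published rule states the
single-endpoint form only; the product form is the natural extension of
r⁻⁶ signal averaging to a pair of degenerate groups. No additional
additive correction is applied for pseudoatoms whose parents sit on
different heavy atoms (`QQX`): the form of that "further correction" is
not specified in the source material, and the mean-position convention
already absorbs most of the geometry.

Restraints whose endpoints coincide or are covalently close are kept and
evaluated normally (they are almost always satisfied and thus inert); the
resolver does not flag them specially.

## Pseudoatom naming, termini, bond perception

Pseudoatoms are rebuilt from hydrogen names alone: `Q` from H1/H2/H3,
`Q<stem>` from `H<stem>1..3` for every stem (`B`, `G1`, …), and `QQ<X>`
from the up-to-six `HXab` hydrogens of an isopropyl/dimethyl pair. A
pseudoatom exists as soon as one parent does; $N_Q$ counts the parents
actually present (a glycine `QA` has $N_Q = 2$). Opaque names like `Q25`
that encode nothing about their parents cannot be resolved and are
reported in `restraints.log`, mirroring how the upstream tool handles
them.

Chain termini coming out of torsion-angle dynamics lack the N-terminal
amine protons and the C-terminal OXT. For standard first residues the
backbone N is completed to three hydrogens (two for proline) named
H1/H2/H3 at 1.01 Å, tetrahedral, staggered about N–CA — an existing
amide H is renamed H1 and kept in place. For standard last residues with
a single carbonyl O, OXT is added in the O–C–CA plane at 1.25 Å and both
C–O bonds become resonant (which in turn makes the carboxylate override
apply). Non-standard termini are skipped silently, and the operation is
idempotent. The terminus test is valence-based (count bonded hydrogens)
rather than geometric; the source material says termini are fixed "based
on their geometry" without detail, and valence is the observable that
actually matters.

Bonds come from residue templates for the 20 standard amino acids
(hydrogens attached by name), the peptide link between consecutive
residue numbers, and a covalent-radius criterion
($d \le r_i + r_j + 0.4$ Å, $d > 0.4$ Å) for everything a template does
not cover — ligands, unknown residues, disulfide SG–SG pairs. Planar
5/6-rings among geometrically perceived atoms are flagged aromatic.
Perception uses the first model's coordinates; the topology is shared by
contract across the ensemble.

## FIRE minimization

Canonical FIRE with $\alpha_0 = 0.1$, $f_{inc} = 1.1$, $f_{dec} = 0.5$,
$f_\alpha = 0.99$, $N_{min} = 5$, unit masses, $dt_0 = 10^{-3}$ and
$dt_{max} = 10\,dt_0$ (internal units). Only the fixed point matters for
minimization, so realism of masses/time is irrelevant; $dt_{max}$ is
chosen below the stability limit of the stiffest bonds
($k \approx 1500$ kcal mol⁻¹ Å⁻², $\omega \approx 40$). Convergence is
declared when the maximum per-atom force drops below 0.05
kcal mol⁻¹ Å⁻¹ (default), which settles toy bond lengths to well under
$10^{-3}$ Å; the step budget defaults to 5000. The algorithm is fully
deterministic, which the tests exploit (identical models in, bitwise
identical models out).

## Quality metrics

The upper-limit target function is the unweighted sum of squared
violations, $TF = \sum_u v_u^2$ (Å²), evaluated per model with
pseudoatom distances from mean-parent positions. It is *not* numerically
identical to CYANA's target function (which weights restraint classes),
and no equivalence with externally published TF values is claimed. The
clash metric counts non-bonded pairs (topological distance ≥ 4 or
disconnected) closer than $r_{vdW,i} + r_{vdW,j} - 0.4$ Å using Bondi
radii, normalized per 1000 atoms — an *approximate* clash count, not the
MolProbity clashscore algorithm.

## The synthetic-data generators

`build_fixture()` produces idealized geometries in code: acetate (the
carboxylate motif), an arginine side-chain fragment (methylguanidinium,
the CZ–N* motif), ALA/GLY/VAL peptides built from internal coordinates
with β-strand backbone dihedrals (φ = −139°, ψ = 135°, ω = 180°),
diatomics, and a two-atom restraint case. The β-strand choice matters: a
fully extended φ = ψ = 180° chain contains the short C5 H···O contact
that the clash metric would (correctly) flag, which is not a fair
"idealized" starting structure. Distortion is uniform per coordinate,
bounded by the stated amplitude — at the amplitudes used in tests
(≤ 0.3 Å) it cannot invert chirality — and seeded, so every test is
reproducible. The synthetic `.upl` files contain limits violated by a few
Å in the undistorted geometry plus one satisfied restraint.

What these fixtures do **not** emulate: conformational heterogeneity of
real ensembles, spin-diffusion-biased limits, ambiguous/stereo-swapped
assignments, ligand chemistry beyond simple organics, and restraint
densities of real data sets (thousands per protein). A green test
establishes the mechanics — parsing, correction, force law, gradients,
convergence, bookkeeping — not refinement quality on deposited entries.

## Known numerical choices and limitations

* Forces are exact negative gradients of the implemented energy; every
  term class is verified against central finite differences (h = 10⁻⁵ Å,
  relative tolerance 10⁻⁴) on seeded distorted systems.
* The equilibrium-length overrides are *restoring-force* targets, not
  constraints. In a minimized structure the surrounding terms shift the
  realized bond length slightly: the guanidinium CZ–N bonds settle near
  1.35 Å because the four 1-4 H···N van der Waals contacts of the planar
  group push outward (an independent UFF implementation reproduces the
  same ~+0.01–0.017 Å shift). The acceptance test for this bond asserts
  the strict 0.01 Å recovery and is expected to fail by ~0.009 Å, with a
  vdW-off diagnostic demonstrating the cause; the carboxylate case has
  weaker 1-4 contacts and passes.
* Bond perception trusts templates over geometry, so heavily distorted
  CYANA output cannot break standard-residue topology; geometric
  perception of exotic ligands assigns order 1 (with a short-C–O
  heuristic for carbonyl typing) and makes no attempt at full bond-order
  assignment.
* The pure-R evaluator is vectorized per term class and comfortable to a
  few hundred atoms (a 33-atom model minimizes in a few seconds); it is
  not intended for multi-thousand-atom production refinement.
* PDB I/O is fixed-column v3.3 with digit-prefix hydrogen-name
  normalization on input; alternate locations and insertion codes are
  passed through without interpretation. mmCIF and NEF are out of scope.
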