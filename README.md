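# nmrefine

Restrained energy minimization of NMR structure ensembles with the
Universal Force Field (UFF) and NOE-derived upper-distance restraints.

## The problem

Solution-NMR structures are usually calculated with torsion-angle dynamics
(e.g. in CYANA), which holds bond lengths and angles rigid and knows
nothing about van der Waals preferences beyond hard-sphere repulsion. The
resulting ensembles are also chemically incomplete: the N-terminal amine
protons and the C-terminal OXT oxygen are missing, and protein–ligand
complexes often cannot be refined at all because no biomolecular force
field has parameters for the ligand. `nmrefine` post-processes such
ensembles: every model is energy-minimized in the *combined* potential of

* the **Universal Force Field** — a rule-based force field with roughly one
  atom type per element and hybridization whose bond, angle, torsion,
  inversion and 12-6 van der Waals parameters are generated by combination
  rules, so *any* molecule (ligand, cofactor, non-standard residue) is
  parametrized on the fly; electrostatics are deliberately omitted, and
* the **NOE upper-distance restraints** in CYANA `.upl` format, applied as
  a flat-bottom potential: zero inside the limit *r*, harmonic in the
  violation *v* = max(0, D − r) with force magnitude *K·v* (default
  *K* = 198.6 kcal mol⁻¹ Å⁻¹, user-scalable), and a constant force
  *K*·5 Å beyond a 5 Å violation.

Pseudoatoms (`Q`, `QX`, `QQX`) are reconstructed from hydrogen naming
rules, positioned at the arithmetic mean of their parent protons, with the
r⁻⁶-averaged limit back-converted as *r* = *r*ₚ·*N*_Q^(1/6); restraint
forces on a pseudoatom are distributed evenly to its parents. Two bonds
with partial double-bond character that a generic force field handles
poorly are pinned: carboxylate C–O at 1.25 Å and arginine CZ–N* at
1.34 Å. Minimization uses FIRE (fast inertial relaxation engine), which
is deterministic and handles restraint-induced energy landscapes well.

## Worked example

```r
library(nmrefine)

# a strained 3-model alanine tripeptide plus synthetic .upl text
f    <- build_fixture("ala_tripeptide", distortion = 0.3, seed = 7,
                      n_models = 3)
sys  <- prepare_system(f$ensemble)        # bonds, UFF types, termini, overrides
rset <- read_upl(f$upl, sys$ensemble$atoms)

sys
#> typed system: 33 atoms, 32 bonds, 3 model(s), 2 bond override(s)
rset
#> restraint set: 4 resolved, 0 unresolved

target_function(sys$ensemble, rset)       # sum of squared violations, A^2
#> 7.861 8.377 9.173

out <- minimize_ensemble(sys, rset)
target_function(out$ensemble, rset)
#> 1e-04 1e-04 1e-04

out$reports[[1]][c("E_initial", "E_final", "iterations", "converged")]
#> E 1883.68 -> 21.44 kcal/mol in 573 iterations (converged: TRUE)

write_ensemble(out$ensemble, "minimized.pdb")
```

The 33 atoms include the added N-terminal H1/H2/H3 and C-terminal OXT; the
2 bond overrides are the two C–O bonds of the newly completed terminal
carboxylate. The target function drops from ~8 Å² per model to ~0 because
all four upper limits can be satisfied simultaneously here; on real data
satisfied and violated restraints trade off against the force field.

## Command line

```sh
Rscript -e 'nmrefine::run_cli()' --pdb in.pdb --upl restraints.upl \
    --out minimized.pdb --report-dir reports --scale-k 1.0
```

writes the minimized multi-model PDB plus `restraints.log` (one line per
restraint entry that could not be matched to an atom or pseudoatom),
`violations.tsv` (per-restraint, per-model distances and violations) and
`summary.txt` (bookkeeping counts, per-model energies and convergence).
`--report-only` evaluates violations without minimizing;
`--no-fix-termini` disables terminus completion.

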