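Package: nmrefine
Title: Restrained Energy Minimization of NMR Structure Ensembles with the
    Universal Force Field
Version: 0.1.0
Authors@R:
    person("nmrefine", "developers", email = "nmrefine@example.org",
           role = c("aut", "cre"))
Description: Refines multi-model NMR structure ensembles (e.g. CYANA output)
    by energy minimization in the Universal Force Field (UFF) combined with
    NOE-derived upper-distance restraints in CYANA .upl format. Implements
    covalent bond perception from residue templates and covalent radii, UFF
    atom typing, chemically correct fixing of protein termini (N-terminal
    amine protons, C-terminal OXT), pseudoatom construction from hydrogen
    naming rules with the r^-6 upper-limit correction r_p * N_Q^(1/6), a
    flat-bottom restraint potential with a constant-force plateau, analytic
    UFF energies and forces (bond, angle, torsion, inversion, van der Waals;
    no electrostatics), FIRE minimization, restraint-violation reporting and
    a simple steric-clash metric, plus multi-model PDB input/output and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
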