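# Reference numbers below were frozen from an independent UFF
# implementation (hand evaluation of the published combination rules,
# cross-checked numerically).

test_that("equilibrium bond lengths reproduce the combination rules", {
  expect_equal(equilibrium_bond_length("H_", "H_"), 0.708, tolerance = 1e-9)
  expect_equal(equilibrium_bond_length("C_3", "C_3"), 1.514,
               tolerance = 1e-9)
  expect_equal(equilibrium_bond_length("C_3", "H_"), 1.1094008,
               tolerance = 1e-6)
  expect_equal(equilibrium_bond_length("C_R", "C_R", 1.5), 1.3792564,
               tolerance = 1e-6)
  expect_equal(equilibrium_bond_length("N_3", "N_3"), 1.4, tolerance = 1e-9)
  # overrides returned verbatim
  expect_identical(equilibrium_bond_length("C_2", "O_2", 1.5,
                                           override = 1.25), 1.25)
  expect_identical(equilibrium_bond_length("C_R", "N_R", 1.33,
                                           override = 1.34), 1.34)
  expect_error(equilibrium_bond_length("C_9", "H_"), "unknown UFF")
})

test_that("force constants match the Z-based formulas", {
  expect_equal(nmrefine:::uff_bond_k("C_3", "C_3", 1.514), 699.5918,
               tolerance = 1e-5)
  expect_equal(nmrefine:::uff_bond_k("H_", "H_", 0.708), 948.6517,
               tolerance = 1e-5)
  expect_equal(
    nmrefine:::uff_angle_k("C_3", "C_3", "H_", 1.514, 1.1094008,
                           109.47 * pi / 180),
    117.3187, tolerance = 1e-5)
})

test_that("diatomic energies sit at their analytic minima", {
  # harmonic bond at equilibrium: zero energy, zero force
  r0 <- equilibrium_bond_length("H_", "H_")
  f <- build_fixture("diatomic", elements = c("H", "H"), distance = r0)
  sys <- prepare_system(f$ensemble, fix_termini = FALSE)
  rep_ <- energy_forces(sys)
  expect_equal(rep_$E_bond, 0, tolerance = 1e-12)
  expect_lt(max(abs(rep_$forces)), 1e-9)
  # two neon atoms at x_IJ: vdW minimum, E = -D_IJ
  f2 <- build_fixture("diatomic", elements = c("Ne", "Ne"),
                      distance = 3.243)
  sys2 <- prepare_system(f2$ensemble, fix_termini = FALSE)
  expect_equal(length(sys2$bonds$i), 0L)   # no covalent bond
  rep2 <- energy_forces(sys2)
  expect_equal(rep2$E_vdw, -0.042, tolerance = 1e-9)
  expect_lt(max(abs(rep2$forces)), 1e-9)
})

test_that("analytic forces match finite differences on seeded systems", {
  cases <- expand.grid(kind = c("acetate", "methylguanidinium",
                                "gly_dipeptide"),
                       seed = c(3, 17, 51), stringsAsFactors = FALSE)
  for (k in seq_len(nrow(cases))) {
    f <- build_fixture(cases$kind[k], distortion = 0.15,
                       seed = cases$seed[k])
    sys <- prepare_system(f$ensemble,
                          fix_termini = cases$kind[k] != "acetate")
    rset <- if (!is.null(f$upl)) read_upl(f$upl, sys$ensemble$atoms)
    expect_lt(fd_force_relerr(sys, rset), 1e-4,
              label = paste(cases$kind[k], cases$seed[k], "rel err"))
  }
})

test_that("net force and torque vanish; energy is rigid-motion invariant", {
  f <- build_fixture("valine_residue", distortion = 0.2, seed = 5)
  sys <- prepare_system(f$ensemble)
  rep_ <- energy_forces(sys)
  expect_lt(max(abs(colSums(rep_$forces))), 1e-8)
  # rigid translation + rotation leaves the energy unchanged
  pos <- sys$ensemble$coords[[1]]
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  pos2 <- sweep(pos %*% t(R), 2, c(5, -3, 2), "+")
  ener <- total_energy_fn(sys)
  expect_equal(ener(pos2), ener(pos), tolerance = 1e-10)
})

test_that("term switches decompose the total energy exactly", {
  f <- build_fixture("methylguanidinium", distortion = 0.1, seed = 8)
  sys <- prepare_system(f$ensemble, fix_termini = FALSE)
  full <- energy_forces(sys, config = ff_config())
  for (term in c("bonds", "angles", "torsions", "inversions", "vdw")) {
    args <- list(bonds = TRUE, angles = TRUE, torsions = TRUE,
                 inversions = TRUE, vdw = TRUE)
    args[[term]] <- FALSE
    off <- energy_forces(sys, config = do.call(ff_config, args))
    efield <- c(bonds = "E_bond", angles = "E_angle",
                torsions = "E_torsion", inversions = "E_inversion",
                vdw = "E_vdw")[[term]]
    expect_equal(full$E_total - off$E_total, full[[efield]],
                 tolerance = 1e-10)
    expect_equal(off[[efield]], 0)
  }
  expect_equal(full$E_total,
               full$E_bond + full$E_angle + full$E_torsion +
                 full$E_inversion + full$E_vdw + full$E_restraint)
})
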