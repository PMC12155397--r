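test_that("geometric perception follows the covalent-radius cutoff", {
  # oracle: r_cov(H) = 0.31, cutoff 0.31*2 + 0.4 = 1.02 A
  f <- build_fixture("diatomic", elements = c("H", "H"), distance = 0.74)
  g <- perceive_bonds(f$ensemble)
  expect_equal(length(g$i), 1L)
  f2 <- build_fixture("diatomic", elements = c("H", "H"), distance = 2.0)
  expect_equal(length(perceive_bonds(f2$ensemble)$i), 0L)
  # atoms closer than 0.4 A are never bonded (corrupt-overlap guard)
  f3 <- build_fixture("diatomic", elements = c("H", "H"), distance = 0.2)
  expect_equal(length(perceive_bonds(f3$ensemble)$i), 0L)
})

test_that("ALA template yields its full edge set", {
  f <- build_fixture("ala_tripeptide")
  ens <- f$ensemble
  g <- perceive_bonds(ens)
  at <- ens$atoms
  # middle residue: N-H, N-CA, CA-HA, CA-CB, CA-C, CB-HB1/2/3, C-O = 9 edges
  mid <- which(at$resno == 2L)
  in_mid <- (g$i %in% mid) & (g$j %in% mid)
  expect_equal(sum(in_mid), 9L)
  bond_names <- apply(cbind(at$name[g$i[in_mid]], at$name[g$j[in_mid]]), 1,
                      function(x) paste(sort(x), collapse = "-"))
  expect_setequal(bond_names, c("H-N", "CA-N", "CA-HA", "CA-CB", "C-CA",
                                "CB-HB1", "CB-HB2", "CB-HB3", "C-O"))
  # peptide links across residues 1-2 and 2-3
  pep <- which(at$resno[g$i] != at$resno[g$j])
  expect_equal(length(pep), 2L)
  expect_true(all(g$order[pep] == nmrefine:::.BO_AMIDE))
})

test_that("perception is independent of atom ordering", {
  f <- build_fixture("acetate")
  ens <- f$ensemble
  set.seed(21)
  perm <- sample(nrow(ens$atoms))
  at2 <- ens$atoms[perm, ]
  at2$serial <- seq_len(nrow(at2))
  class(at2) <- class(ens$atoms)
  ens2 <- new_ensemble(at2, ens$coords[[1]][perm, ])
  g1 <- perceive_bonds(ens)
  g2 <- perceive_bonds(ens2)
  key <- function(g, at) sort(apply(
    cbind(at$name[g$i], at$name[g$j]), 1,
    function(x) paste(sort(x), collapse = "-")))
  expect_identical(key(g1, ens$atoms), key(g2, at2))
})

test_that("UFF typing covers sp3/sp2/aromatic/resonant centers", {
  # methane-like: acetate methyl carbon is sp3, carboxylate C sp2
  f <- build_fixture("acetate")
  sys <- prepare_system(f$ensemble, fix_termini = FALSE)
  at <- sys$ensemble$atoms
  expect_identical(sys$uff_types[atom_idx(at, "C1")], "C_3")
  expect_identical(sys$uff_types[atom_idx(at, "C2")], "C_2")
  expect_identical(sys$uff_types[atom_idx(at, "O1")], "O_2")
  expect_true(all(sys$uff_types[at$element == "H"] == "H_"))
  # benzene ring detected geometrically and typed resonant
  bz <- benzene_ensemble()
  g <- perceive_bonds(bz)
  expect_equal(sum(g$aromatic), 6L)
  ty <- assign_uff_types(bz, g)
  expect_true(all(ty[1:6] == "C_R"))
  # guanidinium N and amide N are resonant
  f2 <- build_fixture("methylguanidinium")
  sys2 <- prepare_system(f2$ensemble, fix_termini = FALSE)
  at2 <- sys2$ensemble$atoms
  expect_identical(sys2$uff_types[atom_idx(at2, "CZ")], "C_R")
  expect_true(all(sys2$uff_types[at2$name %in% c("NE", "NH1", "NH2")] == "N_R"))
  f3 <- build_fixture("ala_tripeptide")
  sys3 <- prepare_system(f3$ensemble)
  at3 <- sys3$ensemble$atoms
  expect_identical(sys3$uff_types[atom_idx(at3, "N", 2)], "N_R")
  expect_identical(sys3$uff_types[atom_idx(at3, "N", 1)], "N_3")
  expect_error(
    assign_uff_types(
      new_ensemble(atom_table(1, "U1", "U", "LIG", 1, het = TRUE),
                   matrix(0, 1, 3)),
      bond_graph(natoms = 1)),
    "typing error")
})

test_that("fix_termini adds H1-H3 and OXT, skips non-standard, idempotent", {
  f <- build_fixture("ala_tripeptide")
  sys <- prepare_system(f$ensemble, fix_termini = FALSE)
  fixed <- fix_termini(sys)
  at <- fixed$ensemble$atoms
  iN <- atom_idx(at, "N", 1)
  hyd <- bond_neighbors(fixed$bonds, iN)
  hyd <- hyd[at$element[hyd] == "H"]
  expect_setequal(at$name[hyd], c("H1", "H2", "H3"))
  xyz <- fixed$ensemble$coords[[1]]
  for (h in hyd) expect_equal(pair_dist(xyz, iN, h), 1.01, tolerance = 1e-6)
  iC <- atom_idx(at, "C", 3)
  ox <- bond_neighbors(fixed$bonds, iC)
  ox <- ox[at$element[ox] == "O"]
  expect_equal(length(ox), 2L)
  expect_true("OXT" %in% at$name[ox])
  expect_equal(pair_dist(xyz, iC, atom_idx(at, "OXT", 3)), 1.25,
               tolerance = 1e-6)
  # idempotent
  fixed2 <- fix_termini(fixed)
  expect_equal(nrow(fixed2$ensemble$atoms), nrow(at))
  expect_identical(fixed2$ensemble$coords[[1]], fixed$ensemble$coords[[1]])
  # non-standard chain end is skipped silently
  at_ns <- sys$ensemble$atoms
  at_ns$resname[at_ns$resno == 3L] <- "XXX"
  class(at_ns) <- class(sys$ensemble$atoms)
  ens_ns <- new_ensemble(at_ns, sys$ensemble$coords)
  sys_ns <- new_typed_system(ens_ns, sys$bonds, sys$uff_types)
  fixed_ns <- fix_termini(sys_ns)
  expect_false("OXT" %in% fixed_ns$ensemble$atoms$name)
  expect_true("H1" %in% fixed_ns$ensemble$atoms$name)  # N-term still fixed
})

test_that("bond overrides match the carboxylate and arginine motifs", {
  f <- build_fixture("acetate")
  sys <- prepare_system(f$ensemble, fix_termini = FALSE)
  expect_equal(nrow(sys$overrides), 2L)
  expect_true(all(sys$overrides$r0 == 1.25))
  f2 <- build_fixture("methylguanidinium")
  sys2 <- prepare_system(f2$ensemble, fix_termini = FALSE)
  expect_equal(nrow(sys2$overrides), 3L)
  expect_true(all(sys2$overrides$r0 == 1.34))
  at2 <- sys2$ensemble$atoms
  cz <- atom_idx(at2, "CZ")
  expect_true(all(sys2$overrides$i == cz | sys2$overrides$j == cz))
  # peptide without charged termini: no motif, no overrides
  f3 <- build_fixture("ala_tripeptide")
  sys3 <- prepare_system(f3$ensemble, fix_termini = FALSE)
  expect_equal(nrow(sys3$overrides), 0L)
  # protonated acid (add H on O2) must NOT be rewritten
  f4 <- build_fixture("acetate")
  at4 <- rbind(f4$ensemble$atoms,
               data.frame(serial = 8L, name = "HO2", element = "H",
                          resname = "ACT", resno = 1L, chain = "A",
                          het = TRUE))
  class(at4) <- class(f4$ensemble$atoms)
  o2 <- atom_idx(f4$ensemble$atoms, "O2")
  hpos <- f4$ensemble$coords[[1]][o2, ] + c(0.6, 0.74, 0)
  ens4 <- new_ensemble(at4, rbind(f4$ensemble$coords[[1]], hpos))
  sys4 <- prepare_system(ens4, fix_termini = FALSE)
  expect_equal(nrow(sys4$overrides), 0L)
})
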