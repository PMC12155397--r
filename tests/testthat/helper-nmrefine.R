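# shared helpers: finite-difference force oracle and tiny hand-built systems

# total energy (UFF + optional restraints) as a plain function of coordinates
total_energy_fn <- function(sys, rset = NULL, ff_cfg = ff_config(),
                            r_cfg = restraint_config()) {
  terms <- nmrefine:::compile_terms(sys, ff_cfg)
  function(pos) {
    r <- nmrefine:::eval_terms(pos, terms, ff_cfg)
    e <- r$E_bond + r$E_angle + r$E_torsion + r$E_inversion + r$E_vdw
    if (!is.null(rset)) e <- e + restraint_term(pos, rset, r_cfg)$energy
    e
  }
}

total_forces <- function(sys, pos = sys$ensemble$coords[[1]], rset = NULL,
                         ff_cfg = ff_config(), r_cfg = restraint_config()) {
  terms <- nmrefine:::compile_terms(sys, ff_cfg)
  r <- nmrefine:::eval_terms(pos, terms, ff_cfg)
  F <- r$forces
  if (!is.null(rset)) F <- F + restraint_term(pos, rset, r_cfg)$forces
  F
}

# central finite-difference forces; relative error against analytic
fd_force_relerr <- function(sys, rset = NULL, ff_cfg = ff_config(),
                            h = 1e-5) {
  pos <- sys$ensemble$coords[[1]]
  ener <- total_energy_fn(sys, rset, ff_cfg)
  Fan <- total_forces(sys, pos, rset, ff_cfg)
  Ffd <- Fan * 0
  for (i in seq_len(nrow(pos))) {
    for (c in 1:3) {
      pp <- pos; pp[i, c] <- pp[i, c] + h
      pm <- pos; pm[i, c] <- pm[i, c] - h
      Ffd[i, c] <- -(ener(pp) - ener(pm)) / (2 * h)
    }
  }
  max(abs(Fan - Ffd) / pmax(1, abs(Fan), abs(Ffd)))
}

# hand-built benzene (regular hexagon, C-C 1.39, C-H 1.09) as a hetero
# residue so that perception runs fully geometric
benzene_ensemble <- function() {
  ang <- 2 * pi * (0:5) / 6
  cxy <- cbind(1.39 * cos(ang) / (2 * sin(pi / 6)), 0, 0)  # placeholder
  rring <- 1.39 / (2 * sin(pi / 6))
  C <- cbind(rring * cos(ang), rring * sin(ang), 0)
  H <- cbind((rring + 1.09) * cos(ang), (rring + 1.09) * sin(ang), 0)
  at <- atom_table(serial = 1:12,
                   name = c(paste0("C", 1:6), paste0("H", 1:6)),
                   element = rep(c("C", "H"), each = 6),
                   resname = "BNZ", resno = 1L, chain = "A", het = TRUE)
  new_ensemble(at, rbind(C, H))
}

# minimal water-like 3-atom graph for model-level tests
water_graph <- function() bond_graph(i = c(1, 1), j = c(2, 3), natoms = 3)

pair_dist <- function(pos, i, j) sqrt(sum((pos[i, ] - pos[j, ])^2))

atom_idx <- function(atoms, name, resno = NULL) {
  hit <- atoms$name == name
  if (!is.null(resno)) hit <- hit & atoms$resno == resno
  which(hit)
}
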