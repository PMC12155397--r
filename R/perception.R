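## Bond perception, UFF atom typing, terminus fixing and the two ad-hoc
## bond-length overrides (carboxylate C-O 1.25 A, arginine CZ-N* 1.34 A).

# tolerance added to the sum of covalent radii for geometric perception
.COV_TOL <- 0.4

#' Perceive covalent bonds
#'
#' Standard amino-acid residues get their bonds from internal residue
#' templates (plus the peptide link between consecutive residue numbers on
#' a chain, and hydrogens attached by name). Atoms not covered by a
#' template (ligands, unknown residues) are bonded geometrically: a bond
#' exists iff the first-model distance is within
#' `r_cov(i) + r_cov(j) + 0.4` Angstrom and above 0.4 Angstrom. CYS SG
#' pairs are also screened geometrically so that disulfides are found.
#' Planar 5/6-rings among geometric atoms are flagged aromatic.
#'
#' @param ensemble an ensemble; the first model's coordinates are used.
#' @return a [bond_graph()].
#' @export
perceive_bonds <- function(ensemble) {
  at <- ensemble$atoms
  xyz <- ensemble$coords[[1L]]
  n <- nrow(at)
  bi <- integer(); bj <- integer(); bo <- numeric(); bar <- logical()
  add <- function(i, j, order = 1, aromatic = FALSE) {
    bi <<- c(bi, i); bj <<- c(bj, j)
    bo <<- c(bo, order); bar <<- c(bar, aromatic)
  }

  templated <- rep(FALSE, n)
  res_key <- paste(at$chain, at$resno)
  for (rk in unique(res_key)) {
    idx <- which(res_key == rk)
    resname <- at$resname[idx[1L]]
    if (!is_standard_residue(resname)) next
    nm <- at$name[idx]
    tmpl <- residue_template(resname)
    matched <- rep(FALSE, length(idx))
    for (b in seq_len(nrow(tmpl))) {
      ia <- match(tmpl$a[b], nm); ib <- match(tmpl$b[b], nm)
      if (!is.na(ia) && !is.na(ib)) {
        add(idx[ia], idx[ib], tmpl$order[b], tmpl$aromatic[b])
        matched[c(ia, ib)] <- TRUE
      }
    }
    heavy <- nm[at$element[idx] != "H"]
    isH <- at$element[idx] == "H"
    for (k in which(isH)) {
      par <- hydrogen_parent(nm[k], heavy)
      if (!is.na(par)) {
        add(idx[k], idx[match(par, nm)], 1, FALSE)
        matched[k] <- TRUE
      }
    }
    templated[idx[matched]] <- TRUE
  }

  # peptide links C(i)-N(i+1), same chain, consecutive residue numbers
  for (ch in unique(at$chain)) {
    sel <- which(at$chain == ch & !at$het)
    resnos <- sort(unique(at$resno[sel]))
    for (r in resnos) {
      if (!((r + 1L) %in% resnos)) next
      ci <- sel[at$resno[sel] == r & at$name[sel] == "C"]
      ni <- sel[at$resno[sel] == r + 1L & at$name[sel] == "N"]
      if (length(ci) == 1L && length(ni) == 1L &&
          is_standard_residue(at$resname[ci]) &&
          is_standard_residue(at$resname[ni])) {
        add(ci, ni, .BO_AMIDE, FALSE)
      }
    }
  }

  # geometric perception for everything a template did not cover,
  # plus SG-SG disulfide screening
  geo <- which(!templated | (at$name == "SG" & at$element == "S"))
  if (length(geo) >= 1L) {
    cand_j <- seq_len(n)
    rc <- covalent_radius(at$element)
    for (gi in geo) {
      js <- cand_j[cand_j > gi | !(cand_j %in% geo)]
      js <- setdiff(js, gi)
      d <- sqrt(colSums((t(xyz[js, , drop = FALSE]) - xyz[gi, ])^2))
      cut <- rc[gi] + rc[js] + .COV_TOL
      hit <- js[d <= cut & d > .COV_TOL]
      # both-templated pairs are only eligible through the SG-SG rule
      for (jj in hit) {
        if (templated[gi] && templated[jj] &&
            !(at$name[gi] == "SG" && at$name[jj] == "SG")) next
        if (templated[gi] && templated[jj] && at$resno[gi] == at$resno[jj] &&
            at$chain[gi] == at$chain[jj]) next
        add(min(gi, jj), max(gi, jj), 1, FALSE)
      }
    }
  }

  g <- bond_graph(bi, bj, bo, bar, natoms = n)
  deg <- tabulate(c(g$i, g$j), nbins = n)
  if (any(deg > 6L)) {
    k <- which.max(deg)
    stop("perception error: atom ", at$name[k], " (residue ", at$resno[k],
         ") has ", deg[k], " bonds; coordinates look corrupt")
  }
  mark_geometric_aromatics(g, at, xyz, templated)
}

# flag planar 5/6-membered rings of C/N/O/S among non-templated atoms as
# aromatic (order 1.5); small-molecule heuristic, not electron counting
mark_geometric_aromatics <- function(graph, atoms, xyz, templated) {
  n <- graph$natoms
  cand_edge <- which(!templated[graph$i] & !templated[graph$j])
  if (length(cand_edge) == 0L) return(graph)
  adj <- adjacency_list(graph)
  deg <- lengths(adj)
  for (e in cand_edge) {
    i <- graph$i[e]; j <- graph$j[e]
    ring <- shortest_cycle_through(adj, i, j, maxlen = 6L)
    if (is.null(ring) || !(length(ring) %in% c(5L, 6L))) next
    if (!all(atoms$element[ring] %in% c("C", "N", "O", "S"))) next
    if (any(deg[ring] > 3L)) next
    pts <- xyz[ring, , drop = FALSE]
    pts <- sweep(pts, 2, colMeans(pts))
    if (svd(pts)$d[3] > 0.15 * sqrt(length(ring))) next  # planarity
    on_ring <- (graph$i %in% ring) & (graph$j %in% ring)
    graph$order[on_ring & graph$order < .BO_AROMATIC] <- .BO_AROMATIC
    graph$aromatic[on_ring] <- TRUE
  }
  graph
}

# shortest cycle containing edge (i, j): BFS from i to j avoiding the edge
shortest_cycle_through <- function(adj, i, j, maxlen = 6L) {
  prev <- rep(NA_integer_, length(adj))
  prev[i] <- 0L
  frontier <- i
  for (d in seq_len(maxlen - 1L)) {
    nxt <- integer()
    for (u in frontier) {
      for (v in adj[[u]]) {
        if (u == i && v == j) next
        if (!is.na(prev[v])) next
        prev[v] <- u
        nxt <- c(nxt, v)
        if (v == j) {
          path <- v
          while (prev[path[1L]] != 0L) path <- c(prev[path[1L]], path)
          return(path)
        }
      }
    }
    if (length(nxt) == 0L) return(NULL)
    frontier <- nxt
  }
  NULL
}

#' Assign UFF atom types
#'
#' Each atom is mapped to a UFF type label from its element and
#' connectivity: sp3/sp2/sp from the neighbor count, aromatic/resonant
#' centers (rings, amide and guanidinium N, carboxylate O) typed as
#' `*_R`/`O_2`. Elements absent from the parameter table raise an error
#' naming the atom; known elements without a specific rule fall back to
#' the element's generic UFF type.
#'
#' @param ensemble an ensemble.
#' @param bonds a [bond_graph()].
#' @return character vector of UFF type labels, one per atom.
#' @export
assign_uff_types <- function(ensemble, bonds) {
  at <- ensemble$atoms
  xyz1 <- ensemble$coords[[1L]]
  n <- nrow(at)
  adj <- adjacency_list(bonds)
  deg <- lengths(adj)
  omax <- rep(1, n)              # highest bond order at the atom
  arom <- rep(FALSE, n)
  for (k in seq_along(bonds$i)) {
    for (x in c(bonds$i[k], bonds$j[k])) {
      omax[x] <- max(omax[x], bonds$order[k])
      arom[x] <- arom[x] || bonds$aromatic[k]
    }
  }
  el <- at$element
  # helper predicates on the graph
  terminal_O <- function(x) el[x] == "O" & deg[x] == 1L
  is_carbonyl_C <- function(x) {
    el[x] == "C" && deg[x] == 3L && any(vapply(adj[[x]], terminal_O, TRUE))
  }
  types <- character(n)
  for (k in seq_len(n)) {
    e <- el[k]
    nb <- adj[[k]]
    types[k] <- switch(
      e,
      H = "H_",
      C = {
        if (deg[k] >= 4L) "C_3"
        else if (arom[k]) "C_R"
        else if (deg[k] == 3L) {
          nN <- sum(el[nb] == "N")
          if (nN == 3L) "C_R" else "C_2"   # guanidinium carbon is resonant
        }
        else if (deg[k] >= 1L && omax[k] >= 1.2) "C_1"
        else "C_3"
      },
      N = {
        amide <- any(vapply(nb, function(x)
          el[x] == "C" && is_carbonyl_C(x), TRUE))
        guanid <- any(vapply(nb, function(x)
          el[x] == "C" && sum(el[adj[[x]]] == "N") >= 2L, TRUE))
        if (arom[k] || omax[k] > 1.2 && omax[k] < 1.9 || amide || guanid) "N_R"
        else if (deg[k] >= 3L) "N_3"
        else if (omax[k] >= 2.5) "N_1"
        else if (omax[k] >= 1.9 || deg[k] == 2L) "N_2"
        else "N_3"
      },
      O = {
        # terminal O: resonant/double bond order, carboxylate membership,
        # or a short C-O distance (geometric graphs carry order 1 only)
        short_CO <- deg[k] == 1L && el[nb[1L]] == "C" &&
          sqrt(sum((xyz1[k, ] - xyz1[nb[1L], ])^2)) <= 1.32
        carbox <- deg[k] == 1L && el[nb[1L]] == "C" &&
          sum(el[adj[[nb[1L]]]] == "O" & deg[adj[[nb[1L]]]] == 1L) >= 2L
        if (arom[k]) "O_R"
        else if (deg[k] <= 1L && (omax[k] > 1.2 || short_CO || carbox)) "O_2"
        else "O_3"
      },
      S = {
        if (arom[k]) "S_R"
        else if (deg[k] <= 1L && omax[k] >= 1.9) "S_2"
        else "S_3+2"
      },
      Fe = if (deg[k] >= 5L) "Fe6+2" else "Fe3+2",
      {
        tab <- uff_param_table()
        row <- tab[tab$element == e & tab$default == 1L, , drop = FALSE]
        if (nrow(row) == 0L) {
          stop("typing error: element ", e, " of atom ", at$name[k],
               " (residue ", at$resno[k], ") is not in the UFF table")
        }
        row$type[1L]
      })
  }
  types
}

#' Construct a typed system
#'
#' Low-level constructor bundling an ensemble, its bond graph, per-atom
#' UFF types and the bond-length override table. Most users should call
#' [prepare_system()] instead.
#'
#' @param ensemble an ensemble.
#' @param bonds a [bond_graph()].
#' @param types character vector of UFF type labels, one per atom.
#' @param overrides data.frame with columns `i`, `j`, `r0`.
#' @return an object of class `"typed_system"`.
#' @export
new_typed_system <- function(ensemble, bonds, types,
                             overrides = data.frame(i = integer(),
                                                    j = integer(),
                                                    r0 = numeric())) {
  structure(list(ensemble = ensemble, bonds = bonds, uff_types = types,
                 overrides = overrides),
            class = "typed_system")
}

#' @export
print.typed_system <- function(x, ...) {
  cat(sprintf(
    "typed system: %d atoms, %d bonds, %d model(s), %d bond override(s)\n",
    nrow(x$ensemble$atoms), length(x$bonds$i), n_models(x$ensemble),
    nrow(x$overrides)))
  invisible(x)
}

#' Fix protein chain termini
#'
#' CYANA output typically lacks the N-terminal amine protons and the
#' C-terminal OXT oxygen. For each chain whose first residue is a standard
#' amino acid and whose backbone N carries fewer than 3 hydrogens (2 for
#' proline), hydrogens H1/H2/H3 are added at 1.01 Angstrom in tetrahedral
#' geometry staggered about the N-CA bond (an existing lone amide H is
#' renamed H1 and kept in place). For each chain whose last residue is
#' standard and whose backbone C has a single bonded oxygen, OXT is added
#' in the O-C-CA plane at 1.25 Angstrom, completing the carboxylate (both
#' C-O bonds become resonant). Non-standard termini are silently skipped.
#' Added atoms get the next free serial numbers; the bond graph and UFF
#' types are updated. Idempotent.
#'
#' @param system a typed system from [prepare_system()] or
#'   [new_typed_system()].
#' @return the updated typed system.
#' @export
fix_termini <- function(system) {
  ens <- system$ensemble
  at <- ens$atoms
  bonds <- system$bonds
  adj <- adjacency_list(bonds)
  nm <- n_models(ens)

  add_rows <- list()    # list of (atom row, per-model positions, bond to)
  for (ch in unique(at$chain)) {
    sel <- which(at$chain == ch & !at$het)
    if (length(sel) == 0L) next
    resnos <- sort(unique(at$resno[sel]))

    ## --- N terminus
    first <- sel[at$resno[sel] == resnos[1L]]
    resname <- at$resname[first[1L]]
    if (is_standard_residue(resname)) {
      iN <- first[at$name[first] == "N"]
      iCA <- first[at$name[first] == "CA"]
      iC <- first[at$name[first] == "C"]
      if (length(iN) == 1L && length(iCA) == 1L && length(iC) == 1L) {
        hyd <- adj[[iN]][at$element[adj[[iN]]] == "H"]
        target <- if (resname == "PRO") 2L else 3L
        if (length(hyd) < target) {
          # rename existing amide H (if any) to H1 and keep its position
          if (length(hyd) >= 1L) {
            at$name[hyd] <- paste0("H", seq_along(hyd))
          }
          free <- setdiff(paste0("H", seq_len(target)), at$name[first])
          need <- target - length(hyd)
          # reference dihedral: existing H if present, else backbone C
          for (m_new in seq_len(need)) {
            nmname <- free[m_new]
            pos <- vector("list", nm)
            for (mod in seq_len(nm)) {
              xyz <- ens$coords[[mod]]
              refs <- if (length(hyd) >= 1L) xyz[hyd[1L], ] else xyz[iC, ]
              base_phi <- measure_dihedral(refs, xyz[iN, ], xyz[iCA, ],
                                           xyz[iC, ])
              if (length(hyd) == 0L) base_phi <- base_phi + pi
              phi <- base_phi + 2 * pi * m_new / 3
              pos[[mod]] <- place_internal(xyz[iN, ], xyz[iCA, ], xyz[iC, ],
                                           r = 1.01,
                                           theta = 109.47 * pi / 180,
                                           phi = phi)
            }
            add_rows[[length(add_rows) + 1L]] <-
              list(name = nmname, element = "H", resname = resname,
                   resno = at$resno[iN], chain = ch, bond_to = iN,
                   order = 1, pos = pos)
          }
        }
      }
    }

    ## --- C terminus
    last <- sel[at$resno[sel] == resnos[length(resnos)]]
    resname <- at$resname[last[1L]]
    if (is_standard_residue(resname)) {
      iC <- last[at$name[last] == "C"]
      iCA <- last[at$name[last] == "CA"]
      if (length(iC) == 1L && length(iCA) == 1L) {
        oxy <- adj[[iC]][at$element[adj[[iC]]] == "O"]
        if (length(oxy) == 1L) {
          iO <- oxy
          pos <- vector("list", nm)
          for (mod in seq_len(nm)) {
            xyz <- ens$coords[[mod]]
            e1 <- unit(xyz[iCA, ] - xyz[iC, ])
            vO <- xyz[iO, ] - xyz[iC, ]
            e2 <- unit(vO - sum(vO * e1) * e1)
            ang <- 117 * pi / 180
            pos[[mod]] <- xyz[iC, ] + 1.25 * (cos(ang) * e1 - sin(ang) * e2)
          }
          add_rows[[length(add_rows) + 1L]] <-
            list(name = "OXT", element = "O", resname = resname,
                 resno = at$resno[iC], chain = ch, bond_to = iC,
                 order = .BO_RESONANT, pos = pos)
          # existing carbonyl O becomes resonant carboxylate O
          k <- which((bonds$i == iC & bonds$j == iO) |
                     (bonds$j == iC & bonds$i == iO))
          bonds$order[k] <- .BO_RESONANT
        }
      }
    }
  }

  if (length(add_rows) == 0L && identical(at$name, ens$atoms$name)) {
    return(system)
  }

  next_serial <- max(at$serial) + seq_along(add_rows)
  for (k in seq_along(add_rows)) {
    r <- add_rows[[k]]
    at <- rbind(at, data.frame(serial = next_serial[k], name = r$name,
                               element = r$element, resname = r$resname,
                               resno = r$resno, chain = r$chain,
                               het = FALSE, stringsAsFactors = FALSE))
  }
  class(at) <- c("nmr_atoms", "data.frame")
  coords <- ens$coords
  if (length(add_rows)) {
    for (mod in seq_len(nm)) {
      extra <- do.call(rbind, lapply(add_rows, function(r) r$pos[[mod]]))
      coords[[mod]] <- rbind(coords[[mod]], extra)
    }
  }
  n_new <- nrow(at)
  bi <- c(bonds$i, vapply(add_rows, function(r) r$bond_to, 1L))
  bj <- c(bonds$j,
          if (length(add_rows)) nrow(ens$atoms) + seq_along(add_rows)
          else integer())
  bo <- c(bonds$order, vapply(add_rows, function(r) r$order, 1))
  bar <- c(bonds$aromatic, rep(FALSE, length(add_rows)))
  ens2 <- new_ensemble(at, coords)
  bonds2 <- bond_graph(bi, bj, bo, bar, natoms = n_new)
  types2 <- assign_uff_types(ens2, bonds2)
  new_typed_system(ens2, bonds2, types2, system$overrides)
}

#' Apply the two ad-hoc equilibrium bond-length overrides
#'
#' Every C-O bond of a carboxylate motif (a carbon with exactly two
#' terminal oxygens, each bonded only to that carbon) is set to 1.25
#' Angstrom; every bond between the atom named CZ and a nitrogen
#' (NE/NH1/NH2) within an ARG residue is set to 1.34 Angstrom. Protonated
#' COOH groups do not match the motif and are left untouched.
#'
#' @param system a typed system.
#' @return the typed system with its `overrides` table filled in.
#' @export
apply_bond_overrides <- function(system) {
  at <- system$ensemble$atoms
  bonds <- system$bonds
  adj <- adjacency_list(bonds)
  deg <- lengths(adj)
  ov_i <- integer(); ov_j <- integer(); ov_r <- numeric()

  for (k in which(at$element == "C")) {
    os <- adj[[k]][at$element[adj[[k]]] == "O" & deg[adj[[k]]] == 1L]
    if (length(os) == 2L && sum(at$element[adj[[k]]] == "O") == 2L) {
      for (o in os) {
        ov_i <- c(ov_i, min(k, o)); ov_j <- c(ov_j, max(k, o))
        ov_r <- c(ov_r, 1.25)
      }
    }
  }
  cz <- which(at$name == "CZ" & at$resname == "ARG")
  for (k in cz) {
    ns <- adj[[k]][at$element[adj[[k]]] == "N" &
                   at$name[adj[[k]]] %in% c("NE", "NH1", "NH2")]
    for (nn in ns) {
      ov_i <- c(ov_i, min(k, nn)); ov_j <- c(ov_j, max(k, nn))
      ov_r <- c(ov_r, 1.34)
    }
  }
  ov <- data.frame(i = ov_i, j = ov_j, r0 = ov_r)
  ov <- ov[!duplicated(paste(ov$i, ov$j)), , drop = FALSE]
  system$overrides <- ov
  system
}

#' Prepare a typed system from an ensemble
#'
#' Convenience pipeline: bond perception, UFF typing, optional terminus
#' fixing, bond-length overrides.
#'
#' @param ensemble an ensemble.
#' @param fix_termini add missing terminal H1/H2/H3 and OXT (default TRUE).
#' @return a typed system.
#' @export
prepare_system <- function(ensemble, fix_termini = TRUE) {
  bonds <- perceive_bonds(ensemble)
  types <- assign_uff_types(ensemble, bonds)
  sys <- new_typed_system(ensemble, bonds, types)
  if (isTRUE(fix_termini)) sys <- fix_termini(sys)
  apply_bond_overrides(sys)
}
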