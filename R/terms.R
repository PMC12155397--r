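## Compilation of a typed system into flat force-field term arrays.
##
## Compiling once per system keeps the per-step energy/force evaluation
## fully vectorized: each term class is a set of parallel index/parameter
## vectors, and forces are scattered back to atoms with rowsum().

#' Force-field configuration
#'
#' @param bonds,angles,torsions,inversions,vdw logical switches enabling
#'   each energy term class. Inversion terms at sp2 C/N centers are on by
#'   default (OpenBabel-style UFF); electrostatics are deliberately absent.
#' @return a config list.
#' @export
ff_config <- function(bonds = TRUE, angles = TRUE, torsions = TRUE,
                      inversions = TRUE, vdw = TRUE) {
  list(bonds = bonds, angles = angles, torsions = torsions,
       inversions = inversions, vdw = vdw)
}

# cos(n*phi) expressed in cos(phi) (Chebyshev), n in {1,2,3,6}
cos_n <- function(c, n) {
  switch(as.character(n),
         "1" = c,
         "2" = 2 * c^2 - 1,
         "3" = 4 * c^3 - 3 * c,
         "6" = 32 * c^6 - 48 * c^4 + 18 * c^2 - 1,
         stop("unsupported torsion periodicity ", n))
}

dcos_n <- function(c, n) {
  switch(as.character(n),
         "1" = rep(1, length(c)),
         "2" = 4 * c,
         "3" = 12 * c^2 - 3,
         "6" = 192 * c^5 - 192 * c^3 + 36 * c,
         stop("unsupported torsion periodicity ", n))
}

# torsion parameters for a central bond j-k following the UFF case rules;
# returns NULL when the torsion is undefined (sp centers etc.)
torsion_params <- function(type_j, type_k, order_jk, j_has_sp2_nb,
                           k_has_sp2_nb) {
  p <- uff_param_table()
  hj <- uff_hybridization(type_j); hk <- uff_hybridization(type_k)
  if (hj < 2L || hk < 2L || hj == 1L || hk == 1L) return(NULL)
  g16j <- uff_is_group16(type_j); g16k <- uff_is_group16(type_k)
  if (hj == 3L && hk == 3L) {
    if (g16j && g16k) {
      vj <- if (substr(type_j, 1, 1) == "O") 2.0 else 6.8
      vk <- if (substr(type_k, 1, 1) == "O") 2.0 else 6.8
      return(list(V = sqrt(vj * vk), n = 2L, cosnphi0 = cos(2 * pi / 2)))
    }
    return(list(V = sqrt(p[type_j, "Vi"] * p[type_k, "Vi"]), n = 3L,
                cosnphi0 = cos(3 * pi / 3)))                 # phi0 = 60 deg
  }
  if (hj == 2L && hk == 2L) {
    V <- 5 * sqrt(p[type_j, "Uj"] * p[type_k, "Uj"]) *
      (1 + 4.18 * log(order_jk))
    return(list(V = V, n = 2L, cosnphi0 = cos(2 * pi)))      # phi0 = 180 deg
  }
  # mixed sp2-sp3
  sp3 <- if (hj == 3L) type_j else type_k
  sp2 <- if (hj == 3L) type_k else type_j
  sp2_extra <- if (hj == 3L) k_has_sp2_nb else j_has_sp2_nb
  if (uff_is_group16(sp3) && !uff_is_group16(sp2)) {
    V <- 5 * sqrt(p[type_j, "Uj"] * p[type_k, "Uj"]) *
      (1 + 4.18 * log(order_jk))
    return(list(V = V, n = 2L, cosnphi0 = cos(2 * pi / 2)))  # phi0 = 90 deg
  }
  if (sp2_extra) {
    # single bond sp3-sp2 where the sp2 atom is conjugated further
    return(list(V = 2.0, n = 3L, cosnphi0 = cos(3 * pi)))    # phi0 = 180 deg
  }
  list(V = 1.0, n = 6L, cosnphi0 = cos(0))                   # phi0 = 0 deg
}

# Compile all term arrays for a typed system. Exposed for inspection but
# primarily internal; energy_forces() compiles lazily and caches.
compile_terms <- function(system, config = ff_config()) {
  at <- system$ensemble$atoms
  n <- nrow(at)
  types <- system$uff_types
  p <- uff_param_table()
  bad <- !(types %in% rownames(p))
  if (any(bad)) {
    k <- which(bad)[1]
    stop("parameter error: atom ", at$name[k], " (residue ", at$resno[k],
         ") has unknown UFF type ", types[k])
  }
  g <- system$bonds
  adj <- adjacency_list(g)
  hyb <- uff_hybridization(types)

  # equilibrium lengths with overrides
  okey <- paste(system$overrides$i, system$overrides$j)
  bkey <- paste(g$i, g$j)
  r0 <- uff_natural_length(types[g$i], types[g$j], g$order)
  hit <- match(bkey, okey)
  r0[!is.na(hit)] <- system$overrides$r0[hit[!is.na(hit)]]
  kb <- uff_bond_k(types[g$i], types[g$j], r0)
  bonds <- list(i = g$i, j = g$j, r0 = r0, k = kb)

  # natural length lookup for angle force constants (overrides included)
  nat_len <- function(i, j) {
    key <- paste(pmin(i, j), pmax(i, j))
    out <- uff_natural_length(types[i], types[j],
                              g$order[match(key, bkey)])
    hit <- match(key, okey)
    out[!is.na(hit)] <- system$overrides$r0[hit[!is.na(hit)]]
    out
  }

  # angles: every i-j-k with i,k bonded neighbors of j
  ai <- integer(); aj <- integer(); ak <- integer()
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) < 2L) next
    cmb <- utils::combn(nb, 2L)
    ai <- c(ai, cmb[1L, ]); aj <- c(aj, rep(j, ncol(cmb)))
    ak <- c(ak, cmb[2L, ])
  }
  if (length(ai)) {
    th0 <- p[types[aj], "theta0"] * pi / 180
    Ka <- uff_angle_k(types[ai], types[aj], types[ak],
                      nat_len(ai, aj), nat_len(aj, ak), th0)
    lin <- th0 > 179 * pi / 180
    C2 <- 1 / (4 * sin(th0)^2)
    C1 <- -4 * C2 * cos(th0)
    C0 <- C2 * (2 * cos(th0)^2 + 1)
    angles <- list(i = ai, j = aj, k = ak, K = Ka, linear = lin,
                   C0 = C0, C1 = C1, C2 = C2)
  } else {
    angles <- list(i = integer(), j = integer(), k = integer(),
                   K = numeric(), linear = logical(), C0 = numeric(),
                   C1 = numeric(), C2 = numeric())
  }

  # proper torsions about every bond with sp2/sp3 ends
  ti <- integer(); tj <- integer(); tk <- integer(); tl <- integer()
  tV <- numeric(); tn <- integer(); tc0 <- numeric()
  has_sp2_nb <- vapply(seq_len(n), function(a)
    any(hyb[adj[[a]]] == 2L), TRUE)
  for (b in seq_along(g$i)) {
    j <- g$i[b]; k <- g$j[b]
    js <- setdiff(adj[[j]], k); ks <- setdiff(adj[[k]], j)
    if (length(js) == 0L || length(ks) == 0L) next
    tp <- torsion_params(types[j], types[k], g$order[b],
                         any(hyb[setdiff(adj[[j]], k)] == 2L),
                         any(hyb[setdiff(adj[[k]], j)] == 2L))
    if (is.null(tp) || tp$V <= 0) next
    grid <- expand.grid(a = js, d = ks)
    grid <- grid[grid$a != grid$d, , drop = FALSE]
    m <- nrow(grid)
    if (m == 0L) next
    ti <- c(ti, grid$a); tj <- c(tj, rep(j, m))
    tk <- c(tk, rep(k, m)); tl <- c(tl, grid$d)
    tV <- c(tV, rep(tp$V / m, m))      # barrier shared over the bond
    tn <- c(tn, rep(tp$n, m)); tc0 <- c(tc0, rep(tp$cosnphi0, m))
  }
  torsions <- list(i = ti, j = tj, k = tk, l = tl, V = tV, n = tn,
                   cosnphi0 = tc0)

  # inversions at trigonal sp2 C/N centers (three axis permutations each)
  ic <- integer(); ia <- integer(); ib <- integer(); id <- integer()
  iK <- numeric()
  for (cidx in seq_len(n)) {
    if (!(types[cidx] %in% c("C_2", "C_R", "N_2", "N_R"))) next
    nb <- adj[[cidx]]
    if (length(nb) != 3L) next
    K <- if (substr(types[cidx], 1, 1) == "C" &&
             any(types[nb] == "O_2")) 50 else 6
    perms <- rbind(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
    for (r in 1:3) {
      ic <- c(ic, cidx)
      ia <- c(ia, nb[perms[r, 1]]); ib <- c(ib, nb[perms[r, 2]])
      id <- c(id, nb[perms[r, 3]])
      iK <- c(iK, K / 3)
    }
  }
  inversions <- list(c = ic, a = ia, b = ib, d = id, K = iK,
                     C0 = rep(1, length(iK)), C1 = rep(-1, length(iK)),
                     C2 = rep(0, length(iK)))

  # van der Waals: all pairs except 1-2 and 1-3 (full-strength 1-4)
  D <- topo_distance_matrix(g, cap = 2L)
  pair <- which(upper.tri(D) & D > 2, arr.ind = TRUE)
  xi <- p[types, "x1"]; di <- p[types, "D1"]
  vdw <- list(i = pair[, 1L], j = pair[, 2L],
              x = sqrt(xi[pair[, 1L]] * xi[pair[, 2L]]),
              D = sqrt(di[pair[, 1L]] * di[pair[, 2L]]))

  list(natoms = n, bonds = bonds, angles = angles, torsions = torsions,
       inversions = inversions, vdw = vdw, config = config)
}
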