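## Deterministic toy-molecule generators: idealized geometries with an
## optional seeded uniform distortion, plus matching synthetic .upl text
## for the restraint cases. Everything is built in code - no data files.

peptide_internal <- list(
  b_NCA = 1.46, b_CAC = 1.52, b_CN = 1.33, b_CO = 1.23, b_NH = 1.01,
  b_CH = 1.09, b_CACB = 1.53,
  a_NCAC = 111, a_CACN = 116, a_CNCA = 121.7, a_CACO = 120.5,
  a_HNC = 119, tet = 109.47,
  # beta-strand backbone (fully extended phi = psi = 180 would create the
  # short C5 H...O contact, which is not a realistic starting geometry)
  phi = -139, psi = 135, omega = 180
)

deg <- function(x) x * pi / 180

# Build an all-trans peptide from a sequence of ALA/GLY/VAL residues.
# Returns list(atoms = data.frame without serials, xyz = matrix).
build_peptide <- function(seq_res, nterm_h = TRUE, cterm_oxt = FALSE) {
  gi <- peptide_internal
  atoms <- list(); xyz <- list()
  push <- function(name, element, resno, resname, p) {
    atoms[[length(atoms) + 1L]] <<- list(name = name, element = element,
                                         resno = resno, resname = resname)
    xyz[[length(xyz) + 1L]] <<- p
  }
  get_pos <- function(resno, name) {
    for (k in seq_along(atoms)) {
      if (atoms[[k]]$resno == resno && atoms[[k]]$name == name)
        return(xyz[[k]])
    }
    stop("internal: missing reference atom ", name, " of residue ", resno)
  }
  for (i in seq_along(seq_res)) {
    rn <- seq_res[i]
    if (i == 1L) {
      N <- c(0, 0, 0)
      CA <- c(gi$b_NCA, 0, 0)
      u <- c(-1, 0, 0)
      C <- CA + gi$b_CAC * (cos(deg(gi$a_NCAC)) * u +
                            sin(deg(gi$a_NCAC)) * c(0, 1, 0))
    } else {
      Cp <- get_pos(i - 1L, "C"); CAp <- get_pos(i - 1L, "CA")
      Np <- get_pos(i - 1L, "N")
      N <- place_internal(Cp, CAp, Np, gi$b_CN, deg(gi$a_CACN),
                          deg(gi$psi))
      CA <- place_internal(N, Cp, CAp, gi$b_NCA, deg(gi$a_CNCA),
                           deg(gi$omega))
      C <- place_internal(CA, N, Cp, gi$b_CAC, deg(gi$a_NCAC),
                          deg(gi$phi))
    }
    push("N", "N", i, rn, N)
    push("CA", "C", i, rn, CA)
    push("C", "C", i, rn, C)
    push("O", "O", i, rn, place_internal(C, CA, N, gi$b_CO,
                                         deg(gi$a_CACO),
                                         deg(gi$psi + 180)))
    if (i == 1L) {
      if (nterm_h) {
        push("H", "H", i, rn,
             place_internal(N, CA, C, gi$b_NH, deg(gi$tet), pi))
      }
    } else {
      Cp <- get_pos(i - 1L, "C")
      Op <- get_pos(i - 1L, "O")
      push("H", "H", i, rn,
           place_internal(N, Cp, Op, gi$b_NH, deg(gi$a_HNC), pi))
    }
    # side chain about CA; dihedrals X-CA-N-C chosen for L configuration
    side_at <- function(phi_deg) {
      place_internal(CA, N, C, gi$b_CACB, deg(gi$tet), deg(phi_deg))
    }
    if (rn == "GLY") {
      push("HA2", "H", i, rn,
           place_internal(CA, N, C, gi$b_CH, deg(gi$tet), deg(119)))
      push("HA3", "H", i, rn,
           place_internal(CA, N, C, gi$b_CH, deg(gi$tet), deg(-119)))
    } else {
      push("HA", "H", i, rn,
           place_internal(CA, N, C, gi$b_CH, deg(gi$tet), deg(119)))
      CB <- side_at(-119)   # L configuration: improper N-C-CA-CB ~ +120
      push("CB", "C", i, rn, CB)
      if (rn == "ALA") {
        for (k in 1:3) {
          push(paste0("HB", k), "H", i, rn,
               place_internal(CB, CA, N, gi$b_CH, deg(gi$tet),
                              deg(60 + 120 * (k - 1))))
        }
      } else if (rn == "VAL") {
        push("HB", "H", i, rn,
             place_internal(CB, CA, N, gi$b_CH, deg(gi$tet), deg(-60)))
        for (g in 1:2) {
          CG <- place_internal(CB, CA, N, 1.53, deg(gi$tet),
                               deg(if (g == 1) 180 else 60))
          push(paste0("CG", g), "C", i, rn, CG)
          for (k in 1:3) {
            push(paste0("HG", g, k), "H", i, rn,
                 place_internal(CG, CB, CA, gi$b_CH, deg(gi$tet),
                                deg(60 + 120 * (k - 1))))
          }
        }
      } else {
        stop("unsupported residue in peptide builder: ", rn)
      }
    }
    if (i == length(seq_res) && cterm_oxt) {
      push("OXT", "O", i, rn, place_internal(C, CA, N, 1.25,
                                             deg(gi$a_CACO), pi))
    }
  }
  list(atoms = do.call(rbind, lapply(atoms, function(a)
         data.frame(a, stringsAsFactors = FALSE))),
       xyz = do.call(rbind, xyz))
}

build_acetate <- function() {
  C1 <- c(0, 0, 0)
  C2 <- c(1.52, 0, 0)
  O1 <- place_internal(C2, C1, c(0, 1, 0), 1.26, deg(117), 0)
  O2 <- place_internal(C2, C1, O1, 1.26, deg(117), pi)
  H <- lapply(0:2, function(k)
    place_internal(C1, C2, O1, 1.09, deg(109.47), deg(60 + 120 * k)))
  list(atoms = data.frame(
         name = c("C1", "C2", "O1", "O2", "H11", "H12", "H13"),
         element = c("C", "C", "O", "O", "H", "H", "H"),
         resno = 1L, resname = "ACT", stringsAsFactors = FALSE),
       xyz = rbind(C1, C2, O1, O2, H[[1]], H[[2]], H[[3]]), het = TRUE)
}

# arginine side-chain fragment (methylguanidinium), residue named ARG so
# that the CZ-N* override motif applies
build_methylguanidinium <- function() {
  CD <- c(0, 0, 0)
  NE <- c(1.46, 0, 0)
  CZ <- place_internal(NE, CD, c(0, 1, 0), 1.33, deg(120), 0)
  HE <- place_internal(NE, CD, CZ, 1.01, deg(120), pi)
  NH1 <- place_internal(CZ, NE, CD, 1.33, deg(120), 0)
  NH2 <- place_internal(CZ, NE, CD, 1.33, deg(120), pi)
  HH11 <- place_internal(NH1, CZ, NE, 1.01, deg(120), 0)
  HH12 <- place_internal(NH1, CZ, NE, 1.01, deg(120), pi)
  HH21 <- place_internal(NH2, CZ, NE, 1.01, deg(120), 0)
  HH22 <- place_internal(NH2, CZ, NE, 1.01, deg(120), pi)
  HD <- lapply(0:2, function(k)
    place_internal(CD, NE, CZ, 1.09, deg(109.47), deg(60 + 120 * k)))
  list(atoms = data.frame(
         name = c("CD", "NE", "CZ", "HE", "NH1", "NH2", "HH11", "HH12",
                  "HH21", "HH22", "HD1", "HD2", "HD3"),
         element = c("C", "N", "C", "H", "N", "N", "H", "H", "H", "H",
                     "H", "H", "H"),
         resno = 1L, resname = "ARG", stringsAsFactors = FALSE),
       xyz = rbind(CD, NE, CZ, HE, NH1, NH2, HH11, HH12, HH21, HH22,
                   HD[[1]], HD[[2]], HD[[3]]), het = FALSE)
}

#' Build a deterministic toy fixture
#'
#' Generators for the small systems used throughout the test suite:
#' idealized geometry with an optional uniform seeded per-coordinate
#' distortion (bounded, so moderate amplitudes never invert chirality),
#' and for the restraint cases a matching synthetic .upl text.
#'
#' Kinds: `"acetate"` (carboxylate override motif), `"methylguanidinium"`
#' (ARG CZ-N* override motif), `"ala_tripeptide"`, `"gly_dipeptide"`,
#' `"valine_residue"` (pseudoatom naming), `"diatomic"` (two atoms of
#' chosen elements at a chosen distance), `"two_atom_restraint_case"`
#' (two neon atoms 8 A apart with a 3 A upper limit).
#'
#' @param kind fixture name (see above).
#' @param distortion uniform per-coordinate perturbation amplitude in
#'   Angstrom (default 0).
#' @param seed RNG seed for the distortion.
#' @param n_models number of (independently distorted) models.
#' @param elements,distance for `kind = "diatomic"`.
#' @return list with `ensemble` and `upl` (character lines or `NULL`).
#' @export
build_fixture <- function(kind = c("acetate", "methylguanidinium",
                                   "ala_tripeptide", "gly_dipeptide",
                                   "valine_residue", "diatomic",
                                   "two_atom_restraint_case"),
                          distortion = 0, seed = 1L, n_models = 1L,
                          elements = c("H", "H"), distance = 0.74) {
  kind <- match.arg(kind)
  upl <- NULL
  het <- FALSE
  if (kind == "acetate") {
    built <- build_acetate()
    het <- TRUE
  } else if (kind == "methylguanidinium") {
    built <- build_methylguanidinium()
  } else if (kind == "ala_tripeptide") {
    built <- build_peptide(c("ALA", "ALA", "ALA"))
    upl <- c("# synthetic upper limits for the alanine tripeptide",
             "1 ALA QB   3 ALA QB   4.00",
             "1 ALA HA   3 ALA H    3.50",
             "2 ALA QB   3 ALA HA   4.50",
             "1 ALA QB   1 ALA HA   4.00")
  } else if (kind == "gly_dipeptide") {
    built <- build_peptide(c("GLY", "GLY"))
    upl <- c("1 GLY QA   2 GLY QA   3.20")
  } else if (kind == "valine_residue") {
    built <- build_peptide("VAL")
  } else if (kind == "diatomic") {
    stopifnot(length(elements) == 2L)
    built <- list(atoms = data.frame(name = paste0(toupper(elements), 1:2),
                                     element = elements, resno = 1L,
                                     resname = "LIG",
                                     stringsAsFactors = FALSE),
                  xyz = rbind(c(0, 0, 0), c(distance, 0, 0)))
    het <- TRUE
  } else if (kind == "two_atom_restraint_case") {
    built <- list(atoms = data.frame(name = c("NE1", "NE2"),
                                     element = c("Ne", "Ne"), resno = 1L,
                                     resname = "NEO",
                                     stringsAsFactors = FALSE),
                  xyz = rbind(c(0, 0, 0), c(8, 0, 0)))
    het <- TRUE
    upl <- c("1 NEO NE1  1 NEO NE2  3.00")
  }
  if (!is.null(built$het)) het <- built$het
  at <- atom_table(serial = seq_len(nrow(built$atoms)),
                   name = built$atoms$name, element = built$atoms$element,
                   resname = built$atoms$resname,
                   resno = built$atoms$resno, chain = "A", het = het)
  base <- built$xyz
  dimnames(base) <- NULL
  coords <- vector("list", n_models)
  if (distortion > 0) set.seed(seed)
  for (m in seq_len(n_models)) {
    pert <- if (distortion > 0) {
      matrix(stats::runif(length(base), -distortion, distortion),
             ncol = 3)
    } else {
      0
    }
    coords[[m]] <- base + pert
  }
  list(ensemble = new_ensemble(at, coords), upl = upl)
}
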