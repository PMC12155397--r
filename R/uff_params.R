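## UFF parameter table access and combination rules.
##
## The table (inst/extdata/uff_params.tsv) carries, per atom type: the
## valence bond radius r1 (A), ideal angle theta0 (deg), van der Waals
## distance x1 (A) and well depth D1 (kcal/mol), the exponential scale
## zeta (unused by the 12-6 form, kept for completeness), effective charge
## Z1 (enters bond/angle force constants), the sp3 torsional barrier Vi
## (kcal/mol), the sp2 torsional constant Uj and the GMP electronegativity
## Xi (enters the bond-length electronegativity correction).

.uff_env <- new.env(parent = emptyenv())

uff_param_table <- function() {
  if (is.null(.uff_env$table)) {
    path <- system.file("extdata", "uff_params.tsv", package = "nmrefine")
    if (path == "") {  # pre-install (devtools::load_all) fallback
      path <- file.path("inst", "extdata", "uff_params.tsv")
    }
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    rownames(tab) <- tab$type
    .uff_env$table <- tab
  }
  .uff_env$table
}

#' UFF parameters for one or more atom types
#'
#' @param type character vector of UFF type labels (e.g. `"C_3"`, `"N_R"`).
#' @return a data.frame with one row per requested type.
#' @export
uff_params <- function(type) {
  tab <- uff_param_table()
  bad <- !(type %in% rownames(tab))
  if (any(bad)) {
    stop("unknown UFF atom type(s): ", paste(unique(type[bad]), collapse = ", "))
  }
  tab[type, , drop = FALSE]
}

# hybridization from the type label: 3 = sp3, 2 = sp2 (incl. resonant),
# 1 = sp, 0 = other (H, halogens, metals, noble gases)
uff_hybridization <- function(type) {
  suff <- sub("^[A-Za-z]{1,2}_?", "", type)
  out <- integer(length(type))
  out[suff %in% c("3", "3+2", "3+3", "3+4", "3+6")] <- 3L
  out[suff %in% c("2", "R")] <- 2L
  out[suff == "1"] <- 1L
  out
}

uff_is_group16 <- function(type) substr(type, 1, 1) %in% c("O", "S") &
  !(type %in% c("Os"))

# natural bond length: r_IJ = r_I + r_J + bond-order correction
# (-0.1332 (r_I + r_J) ln n) - electronegativity correction
uff_natural_length <- function(type_i, type_j, bond_order = 1) {
  p <- uff_param_table()
  ri <- p[type_i, "r1"]; rj <- p[type_j, "r1"]
  xi <- p[type_i, "Xi"]; xj <- p[type_j, "Xi"]
  rbo <- -0.1332 * (ri + rj) * log(bond_order)
  ren <- ri * rj * (sqrt(xi) - sqrt(xj))^2 / (xi * ri + xj * rj)
  ri + rj + rbo - ren
}

#' Equilibrium bond length between two UFF types
#'
#' Natural UFF bond length from the valence radii with the bond-order and
#' electronegativity corrections; when an override is supplied (carboxylate
#' 1.25 A, arginine CZ-N 1.34 A) it is returned verbatim.
#'
#' @param type_i,type_j UFF type labels.
#' @param bond_order bond order (1, 1.33, 1.41, 1.5, 2, 3).
#' @param override optional overridden length in Angstrom.
#' @return equilibrium length in Angstrom.
#' @export
equilibrium_bond_length <- function(type_i, type_j, bond_order = 1,
                                    override = NULL) {
  if (!is.null(override) && length(override) && is.finite(override)) {
    if (override <= 0) stop("bond override must be positive")
    return(as.numeric(override))
  }
  uff_params(c(type_i, type_j))  # validates types
  uff_natural_length(type_i, type_j, bond_order)
}

# harmonic stretch constant, kcal/mol/A^2: k = 664.12 Z_I Z_J / r0^3
uff_bond_k <- function(type_i, type_j, r0) {
  p <- uff_param_table()
  664.12 * p[type_i, "Z1"] * p[type_j, "Z1"] / r0^3
}

# angle bend constant for the cosine expansion, kcal/mol
uff_angle_k <- function(type_i, type_j, type_k, r_ij, r_jk, theta0) {
  p <- uff_param_table()
  ct <- cos(theta0)
  r_ik2 <- r_ij^2 + r_jk^2 - 2 * r_ij * r_jk * ct
  664.12 * p[type_i, "Z1"] * p[type_k, "Z1"] / sqrt(r_ik2)^5 *
    (3 * r_ij * r_jk * (1 - ct^2) - r_ik2 * ct)
}
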