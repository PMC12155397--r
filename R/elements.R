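## Periodic-table data used by perception and the clash metric.

# Covalent radii (Cordero 2008, single-bond), Angstrom. Used only for
# geometric bond perception of atoms not covered by residue templates.
.covalent_radius <- c(
  H = 0.31, He = 0.28, Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71,
  O = 0.66, F = 0.57, Ne = 0.58, Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11,
  P = 1.07, S = 1.05, Cl = 1.02, Ar = 1.06, K = 2.03, Ca = 1.76, Mn = 1.39,
  Fe = 1.32, Co = 1.26, Ni = 1.24, Cu = 1.32, Zn = 1.22, Br = 1.20, I = 1.39,
  Se = 1.20
)

# van der Waals radii (Bondi), Angstrom; used by the approximate clash count.
.vdw_radius <- c(
  H = 1.20, He = 1.40, C = 1.70, N = 1.55, O = 1.52, F = 1.47, Ne = 1.54,
  Na = 2.27, Mg = 1.73, P = 1.80, S = 1.80, Cl = 1.75, Ar = 1.88, K = 2.75,
  Ca = 2.31, Fe = 2.00, Zn = 1.39, Br = 1.85, I = 1.98, Se = 1.90
)

.known_elements <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Mo", "Ru", "Rh", "Pd", "Ag", "Cd", "I", "Xe", "Cs", "Ba", "W", "Pt",
  "Au", "Hg", "Pb", "U"
)

covalent_radius <- function(element) {
  r <- .covalent_radius[element]
  r[is.na(r)] <- 1.5  # generous fallback for exotic elements
  unname(r)
}

vdw_radius <- function(element) {
  r <- .vdw_radius[element]
  r[is.na(r)] <- 2.0
  unname(r)
}

normalize_element <- function(x) {
  x <- trimws(x)
  ifelse(nchar(x) >= 2,
         paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, 2))),
         toupper(x))
}

is_valid_element <- function(x) normalize_element(x) %in% .known_elements

# Infer the element from a PDB atom name. ATOM records use the first
# alphabetic character (after stripping digits/primes); HETATM names are
# first checked against two-letter elements (FE, ZN, CL, ...).
infer_element <- function(name, hetero = FALSE) {
  vapply(seq_along(name), function(k) {
    nm <- gsub("[^A-Za-z]", "", name[k])
    if (nzchar(nm) == FALSE) return("C")
    if (hetero[min(k, length(hetero))] && nchar(nm) >= 2) {
      two <- normalize_element(substr(nm, 1, 2))
      if (two %in% .known_elements && !(two %in% c("Ca", "Cd", "Co", "Ne",
                                                   "Nd", "Ho", "Os", "Hf")))
        return(two)
    }
    one <- toupper(substr(nm, 1, 1))
    if (one %in% .known_elements) one else "C"
  }, character(1))
}
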