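## Heavy-atom bond templates for the 20 standard amino acids.
##
## Templates list side-chain heavy-atom bonds only; the backbone
## (N-CA, CA-C, C=O, C-OXT) and the peptide link C(i)-N(i+1) are added
## generically, and hydrogens are attached by the naming rule implemented
## in `hydrogen_parent()`: strip the leading H and trailing digits until
## the remainder names an existing C/N/O/S atom of the residue
## (HB2 -> CB, HG11 -> CG1, HD21 -> ND2, HH -> OH, H/H1..H3 -> N).
##
## Orders: `ar` marks aromatic ring bonds (order 1.5), `res` resonant
## carboxylate/guanidinium bonds, `dbl` double bonds.

.sidechain_bonds <- list(
  ALA = character(),
  ARG = c("CB-CG", "CG-CD", "CD-NE", "NE-CZ:res", "CZ-NH1:res", "CZ-NH2:res"),
  ASN = c("CB-CG", "CG-OD1:dbl", "CG-ND2"),
  ASP = c("CB-CG", "CG-OD1:res", "CG-OD2:res"),
  CYS = c("CB-SG"),
  GLN = c("CB-CG", "CG-CD", "CD-OE1:dbl", "CD-NE2"),
  GLU = c("CB-CG", "CG-CD", "CD-OE1:res", "CD-OE2:res"),
  GLY = character(),
  HIS = c("CB-CG", "CG-ND1:ar", "CG-CD2:ar", "ND1-CE1:ar", "CD2-NE2:ar",
          "CE1-NE2:ar"),
  ILE = c("CB-CG1", "CB-CG2", "CG1-CD1"),
  LEU = c("CB-CG", "CG-CD1", "CG-CD2"),
  LYS = c("CB-CG", "CG-CD", "CD-CE", "CE-NZ"),
  MET = c("CB-CG", "CG-SD", "SD-CE"),
  PHE = c("CB-CG", "CG-CD1:ar", "CG-CD2:ar", "CD1-CE1:ar", "CD2-CE2:ar",
          "CE1-CZ:ar", "CE2-CZ:ar"),
  PRO = c("CB-CG", "CG-CD", "CD-N"),
  SER = c("CB-OG"),
  THR = c("CB-OG1", "CB-CG2"),
  TRP = c("CB-CG", "CG-CD1:ar", "CG-CD2:ar", "CD1-NE1:ar", "NE1-CE2:ar",
          "CD2-CE2:ar", "CD2-CE3:ar", "CE2-CZ2:ar", "CE3-CZ3:ar",
          "CZ2-CH2:ar", "CZ3-CH2:ar"),
  TYR = c("CB-CG", "CG-CD1:ar", "CG-CD2:ar", "CD1-CE1:ar", "CD2-CE2:ar",
          "CE1-CZ:ar", "CE2-CZ:ar", "CZ-OH"),
  VAL = c("CB-CG1", "CB-CG2")
)

standard_residues <- function() names(.sidechain_bonds)

is_standard_residue <- function(resname) resname %in% names(.sidechain_bonds)

# bond-order constants shared across the package
.BO_AROMATIC <- 1.5
.BO_RESONANT <- 1.5
.BO_GUANIDINIUM <- 1.33
.BO_AMIDE <- 1.41

# residue template as data.frame(a, b, order, aromatic) of atom-name pairs,
# including the generic backbone
residue_template <- function(resname) {
  sc <- .sidechain_bonds[[resname]]
  parse1 <- function(s) {
    parts <- strsplit(s, ":", fixed = TRUE)[[1L]]
    ab <- strsplit(parts[1L], "-", fixed = TRUE)[[1L]]
    tag <- if (length(parts) > 1L) parts[2L] else ""
    order <- switch(tag, ar = .BO_AROMATIC, res = .BO_RESONANT,
                    dbl = 2, 1)
    if (tag == "res" && resname == "ARG") order <- .BO_GUANIDINIUM
    data.frame(a = ab[1L], b = ab[2L], order = order,
               aromatic = tag == "ar", stringsAsFactors = FALSE)
  }
  bb <- data.frame(a = c("N", "CA", "CA", "C", "C"),
                   b = c("CA", "CB", "C", "O", "OXT"),
                   order = c(1, 1, 1, 2, .BO_RESONANT),
                   aromatic = FALSE, stringsAsFactors = FALSE)
  if (length(sc)) rbind(bb, do.call(rbind, lapply(sc, parse1))) else bb
}

# Find the heavy-atom parent of a hydrogen by name, among `heavy_names`
# (atom names present in the same residue). Returns the matched name or NA.
hydrogen_parent <- function(hname, heavy_names) {
  if (hname %in% c("H", "H1", "H2", "H3", "HN")) {
    return(if ("N" %in% heavy_names) "N" else NA_character_)
  }
  stem <- sub("^H", "", hname)
  repeat {
    for (el in c("C", "N", "O", "S")) {
      cand <- paste0(el, stem)
      if (cand %in% heavy_names) return(cand)
    }
    if (!grepl("[0-9]$", stem) || !nzchar(stem)) break
    stem <- sub("[0-9]$", "", stem)
  }
  NA_character_
}
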