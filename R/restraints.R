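## CYANA .upl upper-distance restraints: parsing, pseudoatom construction
## from hydrogen naming rules, the r_p * N_Q^(1/6) correction, and
## resolution of entries against the structure's atoms.

#' Build pseudoatoms from hydrogen names
#'
#' Per residue: `Q` is built from parents H1/H2/H3; for every stem `X`
#' occurring in names `HX1`/`HX2`/`HX3` (X one or more characters, e.g.
#' `B`, `G1`), `QX` is built from those; `QQX` (X a single letter) is
#' built from the up-to-six hydrogens `HXab` (a in 1..3, b in 1..3). A
#' pseudoatom is created as soon as at least one parent exists; N_Q is the
#' number of parents actually present. The pseudoatom position (used
#' later) is by contract the arithmetic mean of its parents' positions.
#'
#' @param atoms an atom table with canonical hydrogen names.
#' @return data.frame with columns `resno`, `chain`, `name`, `n` and a
#'   list-column `parents` of atom indices.
#' @export
build_pseudoatoms <- function(atoms) {
  out <- list()
  res_key <- paste(atoms$chain, atoms$resno)
  for (rk in unique(res_key)) {
    idx <- which(res_key == rk)
    hn <- atoms$name[idx]
    isH <- atoms$element[idx] == "H"
    hnames <- hn[isH]
    hidx <- idx[isH]
    addq <- function(qname, parent_names) {
      hit <- hidx[match(parent_names, hnames, nomatch = 0L)]
      hit <- hit[hit > 0L]
      if (length(hit) == 0L) return()
      out[[length(out) + 1L]] <<- list(resno = atoms$resno[idx[1L]],
                                       chain = atoms$chain[idx[1L]],
                                       name = qname, n = length(hit),
                                       parents = hit)
    }
    addq("Q", c("H1", "H2", "H3"))
    stems <- unique(sub("[0-9]$", "",
                        grep("^H.+[0-9]$", hnames, value = TRUE)))
    stems <- sub("^H", "", stems)
    stems <- stems[nzchar(stems)]
    for (s in stems) addq(paste0("Q", s), paste0("H", s, 1:3))
    letters_x <- unique(substr(sub("^H", "",
                                   grep("^H[A-Z][0-9][0-9]$", hnames,
                                        value = TRUE)), 1, 1))
    for (x in letters_x) {
      addq(paste0("QQ", x),
           paste0("H", x, rep(1:3, each = 3), rep(1:3, times = 3)))
    }
  }
  if (length(out) == 0L) {
    return(data.frame(resno = integer(), chain = character(),
                      name = character(), n = integer(),
                      parents = I(list())))
  }
  data.frame(resno = vapply(out, `[[`, 1L, "resno"),
             chain = vapply(out, `[[`, "", "chain"),
             name = vapply(out, `[[`, "", "name"),
             n = vapply(out, `[[`, 1L, "n"),
             parents = I(lapply(out, `[[`, "parents")),
             stringsAsFactors = FALSE)
}

#' Parse CYANA .upl text into raw entries
#'
#' Whitespace-separated 7+ column format: residue number, residue name and
#' atom name for each endpoint, then the upper limit in Angstrom. Trailing
#' fields (weights, `#` comments) are ignored; blank and comment lines are
#' skipped. Malformed lines are recorded, not fatal.
#'
#' @param upl .upl text: a path or character vector of lines.
#' @return list with `entries` (data.frame incl. source line numbers) and
#'   `bad` (data.frame of unparseable lines with reasons).
#' @export
parse_upl <- function(upl) {
  lines <- if (length(upl) == 1L && !grepl("\n", upl) && file.exists(upl)) {
    readLines(upl, warn = FALSE)
  } else {
    split_lines(upl)
  }
  entries <- list(); bad <- list()
  for (k in seq_along(lines)) {
    raw <- sub("#.*$", "", lines[k])
    if (!nzchar(trimws(raw))) next
    tok <- strsplit(trimws(raw), "[[:space:]]+")[[1L]]
    ok <- length(tok) >= 7L &&
      !is.na(suppressWarnings(as.integer(tok[1L]))) &&
      !is.na(suppressWarnings(as.integer(tok[4L]))) &&
      !is.na(suppressWarnings(as.numeric(tok[7L])))
    if (!ok) {
      bad[[length(bad) + 1L]] <- list(line = k, text = lines[k],
                                      reason = "parse error")
      next
    }
    lim <- as.numeric(tok[7L])
    if (lim <= 0) {
      bad[[length(bad) + 1L]] <- list(line = k, text = lines[k],
                                      reason = "nonpositive upper limit")
      next
    }
    entries[[length(entries) + 1L]] <-
      list(resno_i = as.integer(tok[1L]), resname_i = toupper(tok[2L]),
           name_i = toupper(tok[3L]), resno_j = as.integer(tok[4L]),
           resname_j = toupper(tok[5L]), name_j = toupper(tok[6L]),
           rp = lim, line = k)
  }
  to_df <- function(lst, cols) {
    if (length(lst) == 0L) {
      return(stats::setNames(
        do.call(data.frame, c(lapply(cols, function(x) x[0]),
                              stringsAsFactors = FALSE)), names(cols)))
    }
    do.call(rbind, lapply(lst, function(e)
      data.frame(e, stringsAsFactors = FALSE)))
  }
  list(entries = to_df(entries,
                       list(resno_i = integer(), resname_i = character(),
                            name_i = character(), resno_j = integer(),
                            resname_j = character(), name_j = character(),
                            rp = numeric(), line = integer())),
       bad = to_df(bad, list(line = integer(), text = character(),
                             reason = character())))
}

#' Pseudoatom upper-limit correction
#'
#' Back-converts a CYANA pseudoatom upper limit to an actual distance:
#' `r = r_p * (n_i * n_j)^(1/6)`, where `n_i`, `n_j` are the numbers of
#' protons forming each endpoint (1 for a real atom). Identity when both
#' endpoints are single atoms; monotone increasing in each n.
#'
#' @param r_p parsed upper limit, Angstrom (> 0).
#' @param n_i,n_j parent-proton counts (>= 1).
#' @return corrected upper limit in Angstrom.
#' @export
correct_pseudoatom_distance <- function(r_p, n_i = 1L, n_j = 1L) {
  if (any(r_p <= 0)) stop("upper limit must be positive")
  if (any(n_i < 1L) || any(n_j < 1L)) stop("proton counts must be >= 1")
  r_p * (as.numeric(n_i) * as.numeric(n_j))^(1 / 6)
}

#' Resolve raw .upl entries against a structure
#'
#' Each endpoint is matched by (residue number, atom name), first against
#' real atoms, then against rule-derived pseudoatoms. Matched entries get
#' the corrected limit `r_p * (N_i N_j)^(1/6)`; unmatched entries go to the
#' unresolved list with a reason. A residue-name mismatch between file and
#' structure produces a warning but the match proceeds on number + name.
#'
#' @param entries data.frame from [parse_upl()] (`$entries`), with its
#'   `$bad` rows passed via `bad`.
#' @param atoms atom table of the structure.
#' @param pseudoatoms from [build_pseudoatoms()]; built here when `NULL`.
#' @param bad parse failures to carry into the unresolved list.
#' @return an object of class `"restraint_set"`: `restraints` data.frame
#'   (with list-columns `idx_i`, `idx_j` of member-atom indices and
#'   `n_i`, `n_j`, `rp`, `r_corrected`, `line`), and `unresolved`.
#' @export
resolve_restraints <- function(entries, atoms, pseudoatoms = NULL,
                               bad = NULL) {
  if (is.null(pseudoatoms)) pseudoatoms <- build_pseudoatoms(atoms)
  res <- list(); unres <- list()
  if (!is.null(bad) && nrow(bad)) {
    for (k in seq_len(nrow(bad))) {
      unres[[length(unres) + 1L]] <- list(line = bad$line[k],
                                          reason = bad$reason[k])
    }
  }
  match_endpoint <- function(resno, name) {
    hit <- which(atoms$resno == resno & atoms$name == name)
    if (length(hit) >= 1L) {
      return(list(idx = hit[1L], n = 1L))
    }
    ph <- which(pseudoatoms$resno == resno & pseudoatoms$name == name)
    if (length(ph) >= 1L) {
      return(list(idx = pseudoatoms$parents[[ph[1L]]],
                  n = pseudoatoms$n[ph[1L]]))
    }
    NULL
  }
  for (k in seq_len(nrow(entries))) {
    e <- entries[k, ]
    for (side in c("i", "j")) {
      rn <- e[[paste0("resname_", side)]]
      resno <- e[[paste0("resno_", side)]]
      struct_rn <- unique(atoms$resname[atoms$resno == resno])
      if (length(struct_rn) && !(rn %in% struct_rn)) {
        warning("restraint line ", e$line, ": residue ", resno,
                " is ", paste(struct_rn, collapse = "/"),
                " in the structure but ", rn,
                " in the restraint file; matching on number + atom name",
                call. = FALSE)
      }
    }
    mi <- match_endpoint(e$resno_i, e$name_i)
    mj <- match_endpoint(e$resno_j, e$name_j)
    if (is.null(mi) || is.null(mj)) {
      miss <- if (is.null(mi)) c(e$name_i, e$resno_i) else c(e$name_j, e$resno_j)
      unres[[length(unres) + 1L]] <-
        list(line = e$line, reason = paste0("unknown atom ", miss[1L],
                                            " in residue ", miss[2L]))
      next
    }
    res[[length(res) + 1L]] <-
      list(resno_i = e$resno_i, name_i = e$name_i, resno_j = e$resno_j,
           name_j = e$name_j, rp = e$rp,
           r_corrected = correct_pseudoatom_distance(e$rp, mi$n, mj$n),
           n_i = mi$n, n_j = mj$n, line = e$line,
           idx_i = mi$idx, idx_j = mj$idx)
  }
  restraints <- if (length(res)) {
    data.frame(resno_i = vapply(res, `[[`, 1L, "resno_i"),
               name_i = vapply(res, `[[`, "", "name_i"),
               resno_j = vapply(res, `[[`, 1L, "resno_j"),
               name_j = vapply(res, `[[`, "", "name_j"),
               rp = vapply(res, `[[`, 1, "rp"),
               r_corrected = vapply(res, `[[`, 1, "r_corrected"),
               n_i = vapply(res, `[[`, 1L, "n_i"),
               n_j = vapply(res, `[[`, 1L, "n_j"),
               line = vapply(res, `[[`, 1L, "line"),
               idx_i = I(lapply(res, `[[`, "idx_i")),
               idx_j = I(lapply(res, `[[`, "idx_j")),
               stringsAsFactors = FALSE)
  } else {
    data.frame(resno_i = integer(), name_i = character(),
               resno_j = integer(), name_j = character(), rp = numeric(),
               r_corrected = numeric(), n_i = integer(), n_j = integer(),
               line = integer(), idx_i = I(list()), idx_j = I(list()),
               stringsAsFactors = FALSE)
  }
  unresolved <- if (length(unres)) {
    data.frame(line = vapply(unres, `[[`, 1L, "line"),
               reason = vapply(unres, `[[`, "", "reason"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(line = integer(), reason = character(),
               stringsAsFactors = FALSE)
  }
  structure(list(restraints = restraints, unresolved = unresolved),
            class = "restraint_set")
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf("restraint set: %d resolved, %d unresolved\n",
              nrow(x$restraints), nrow(x$unresolved)))
  invisible(x)
}

#' Read and resolve a .upl file in one step
#'
#' @param upl .upl path or text.
#' @param atoms atom table of the structure the restraints refer to.
#' @return a restraint set; see [resolve_restraints()].
#' @export
read_upl <- function(upl, atoms) {
  parsed <- parse_upl(upl)
  resolve_restraints(parsed$entries, atoms, bad = parsed$bad)
}

#' Write the restraints.log report of unresolved entries
#'
#' One line per unresolved restraint entry: source line number and reason.
#'
#' @param restraint_set a restraint set.
#' @param file output path (conventionally `restraints.log`).
#' @return the path, invisibly.
#' @export
write_restraint_log <- function(restraint_set, file) {
  u <- restraint_set$unresolved
  writeLines(sprintf("line %d: %s", u$line, u$reason), file)
  invisible(file)
}
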