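## Core domain types: atom table, Model/Ensemble container, bond graph.

#' Construct an atom table
#'
#' Atoms are stored as a plain data frame with one row per atom. The triple
#' (chain, residue number, atom name) must be unique: it is the key used to
#' match NOE restraints and to check ensemble consistency.
#'
#' @param serial integer atom serial numbers.
#' @param name PDB atom names (e.g. `"CA"`, `"HB2"`).
#' @param element chemical element symbols.
#' @param resname 3-letter residue (or ligand) codes.
#' @param resno integer residue numbers.
#' @param chain single-character chain identifiers.
#' @param het logical, `TRUE` for HETATM records.
#' @return a `data.frame` with class `"nmr_atoms"`.
#' @export
atom_table <- function(serial, name, element, resname, resno,
                       chain = "A", het = FALSE) {
  element <- normalize_element(element)
  bad <- !is_valid_element(element)
  if (any(bad)) {
    stop("invalid element symbol(s): ",
         paste(unique(element[bad]), collapse = ", "))
  }
  df <- data.frame(serial = as.integer(serial), name = as.character(name),
                   element = element, resname = as.character(resname),
                   resno = as.integer(resno), chain = as.character(chain),
                   het = as.logical(het), stringsAsFactors = FALSE)
  key <- paste(df$chain, df$resno, df$name)
  if (anyDuplicated(key)) {
    stop("duplicate atom identity (chain, residue, name): ",
         key[duplicated(key)][1])
  }
  class(df) <- c("nmr_atoms", "data.frame")
  df
}

#' Construct an NMR ensemble
#'
#' An ensemble is a single shared atom list plus one coordinate matrix per
#' model; only the coordinates differ between models.
#'
#' @param atoms an atom table (see [atom_table()]).
#' @param coords a list of numeric `n x 3` matrices (Angstrom), one per model.
#' @return an object of class `"nmr_ensemble"`.
#' @export
new_ensemble <- function(atoms, coords) {
  if (!is.list(coords)) coords <- list(coords)
  n <- nrow(atoms)
  for (m in seq_along(coords)) {
    x <- coords[[m]]
    if (!is.matrix(x) || ncol(x) != 3 || nrow(x) != n) {
      stop("model ", m, ": coordinates must be an n x 3 matrix matching ",
           n, " atoms")
    }
    if (!all(is.finite(x))) {
      stop("model ", m, ": non-finite coordinates")
    }
    dimnames(coords[[m]]) <- NULL
    storage.mode(coords[[m]]) <- "double"
  }
  structure(list(atoms = atoms, coords = coords), class = "nmr_ensemble")
}

#' @export
print.nmr_ensemble <- function(x, ...) {
  cat(sprintf("NMR ensemble: %d model(s), %d atoms, %d residue(s)\n",
              length(x$coords), nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno)))))
  invisible(x)
}

n_models <- function(ensemble) length(ensemble$coords)

#' Construct a covalent bond graph
#'
#' Bonds are stored once with `i < j`. Orders are real-valued (1, 1.33,
#' 1.41, 1.5, 2, 3) so that resonant and amide bonds keep their partial
#' double-bond character for the force field.
#'
#' @param i,j integer atom indices of bonded pairs.
#' @param order numeric bond orders (>= 1).
#' @param aromatic logical flags.
#' @param natoms number of atoms the indices refer to.
#' @return an object of class `"bond_graph"`.
#' @export
bond_graph <- function(i = integer(), j = integer(), order = numeric(),
                       aromatic = logical(), natoms) {
  i <- as.integer(i); j <- as.integer(j)
  if (length(order) == 0L) order <- rep(1, length(i))
  if (length(aromatic) == 0L) aromatic <- rep(FALSE, length(i))
  if (any(i == j)) stop("self-bonds are not allowed")
  if (length(i) && (min(c(i, j)) < 1L || max(c(i, j)) > natoms)) {
    stop("bond indices out of range 1..", natoms)
  }
  lo <- pmin(i, j); hi <- pmax(i, j)
  o <- base::order(lo, hi)
  lo <- lo[o]; hi <- hi[o]; order <- order[o]; aromatic <- aromatic[o]
  dup <- duplicated(paste(lo, hi))
  structure(list(i = lo[!dup], j = hi[!dup], order = as.numeric(order[!dup]),
                 aromatic = aromatic[!dup], natoms = as.integer(natoms)),
            class = "bond_graph")
}

#' @export
print.bond_graph <- function(x, ...) {
  cat(sprintf("bond graph: %d atoms, %d bonds (%d aromatic)\n",
              x$natoms, length(x$i), sum(x$aromatic)))
  invisible(x)
}

# adjacency list, cached computation
adjacency_list <- function(graph) {
  adj <- vector("list", graph$natoms)
  for (k in seq_along(graph$i)) {
    adj[[graph$i[k]]] <- c(adj[[graph$i[k]]], graph$j[k])
    adj[[graph$j[k]]] <- c(adj[[graph$j[k]]], graph$i[k])
  }
  lapply(adj, function(v) sort(unique(v)))
}

#' Bonded neighbors of an atom
#'
#' @param graph a [bond_graph()].
#' @param atom_index atom index (1-based).
#' @return sorted integer vector of bonded partners (may be empty).
#' @export
bond_neighbors <- function(graph, atom_index) {
  if (length(atom_index) != 1L || is.na(atom_index) ||
      atom_index < 1L || atom_index > graph$natoms) {
    stop("invalid atom reference: index ", atom_index,
         " not in 1..", graph$natoms)
  }
  sort(unique(c(graph$j[graph$i == atom_index],
                graph$i[graph$j == atom_index])))
}

#' Topological distance between two atoms
#'
#' Minimum number of bonds on any path between `i` and `j`, by breadth-first
#' search, capped: paths longer than `cap` (and disconnected pairs) return
#' `Inf`. Used for the 1-2/1-3 van der Waals exclusions and the clash metric.
#'
#' @param graph a [bond_graph()].
#' @param i,j atom indices.
#' @param cap maximum path length to search (>= 1).
#' @return integer distance, or `Inf` if beyond `cap`/no path.
#' @export
topological_distance <- function(graph, i, j, cap = 4L) {
  for (x in c(i, j)) {
    if (length(x) != 1L || is.na(x) || x < 1L || x > graph$natoms) {
      stop("invalid atom reference: index ", x, " not in 1..", graph$natoms)
    }
  }
  if (cap < 1L) stop("cap must be >= 1")
  if (i == j) return(0L)
  adj <- adjacency_list(graph)
  frontier <- i
  seen <- rep(FALSE, graph$natoms)
  seen[i] <- TRUE
  for (d in seq_len(cap)) {
    frontier <- unique(unlist(adj[frontier], use.names = FALSE))
    frontier <- frontier[!seen[frontier]]
    if (length(frontier) == 0L) return(Inf)
    if (j %in% frontier) return(d)
    seen[frontier] <- TRUE
  }
  Inf
}

# Dense matrix of graph distances capped at `cap` (entries > cap are Inf).
# Vectorized over the whole atom set; used to build exclusion lists.
topo_distance_matrix <- function(graph, cap = 3L) {
  n <- graph$natoms
  A <- matrix(FALSE, n, n)
  A[cbind(graph$i, graph$j)] <- TRUE
  A[cbind(graph$j, graph$i)] <- TRUE
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- diag(n) > 0
  step <- A
  for (d in seq_len(cap)) {
    newly <- step & !reach & D > d
    D[newly] <- d
    reach <- reach | step
    if (d < cap) step <- (step %*% A) > 0
  }
  D
}

# checks that every model of a multi-model input shares one atom list;
# returns invisibly or stops naming the first mismatch
check_ensemble_consistency <- function(per_model_atoms) {
  ref <- per_model_atoms[[1L]]
  refkey <- paste(ref$chain, ref$resno, ref$name)
  for (m in seq_along(per_model_atoms)[-1L]) {
    key <- paste(per_model_atoms[[m]]$chain, per_model_atoms[[m]]$resno,
                 per_model_atoms[[m]]$name)
    if (length(key) != length(refkey) || any(key != refkey)) {
      bad <- if (length(key) < length(refkey)) {
        setdiff(refkey, key)[1]
      } else if (length(key) > length(refkey)) {
        setdiff(key, refkey)[1]
      } else {
        key[which(key != refkey)[1]]
      }
      stop("ensemble inconsistency: model ", m,
           " differs from model 1 at atom [", bad, "]")
    }
  }
  invisible(TRUE)
}
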