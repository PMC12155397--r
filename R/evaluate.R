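## Post-minimization quality metrics: upper-limit target function,
## approximate steric-clash count, per-restraint violation report.

restraint_distances <- function(positions, restraint_set) {
  rs <- restraint_set$restraints
  vapply(seq_len(nrow(rs)), function(k) {
    p1 <- colMeans(positions[rs$idx_i[[k]], , drop = FALSE])
    p2 <- colMeans(positions[rs$idx_j[[k]], , drop = FALSE])
    sqrt(sum((p1 - p2)^2))
  }, 1)
}

#' Upper-limit target function of one model
#'
#' Unweighted sum of squared violations over the upper-distance
#' restraints, `TF = sum max(0, D - r_corrected)^2` (Angstrom^2), with
#' pseudoatom distances measured from mean-parent positions. This is a
#' simplified re-definition in the spirit of CYANA's target function, not
#' numerically identical to CYANA's (which weights restraint classes).
#'
#' @param positions `n x 3` model coordinates, or an ensemble (then a
#'   per-model vector is returned).
#' @param restraint_set a resolved restraint set.
#' @return TF value(s) in Angstrom^2.
#' @export
target_function <- function(positions, restraint_set) {
  if (inherits(positions, "nmr_ensemble")) {
    return(vapply(positions$coords, target_function, 1,
                  restraint_set = restraint_set))
  }
  if (nrow(restraint_set$restraints) == 0L) return(0)
  D <- restraint_distances(positions, restraint_set)
  v <- pmax(0, D - restraint_set$restraints$r_corrected)
  sum(v^2)
}

#' Approximate steric-clash count per 1000 atoms
#'
#' Counts unordered atom pairs at topological distance >= 4 (or
#' disconnected) whose separation is below
#' `r_vdw(i) + r_vdw(j) - 0.4` Angstrom (Bondi radii), normalized per
#' 1000 atoms. An approximate stand-in for a MolProbity-style clashscore,
#' not the MolProbity algorithm.
#'
#' @param system a typed system.
#' @param model_index model to score.
#' @return clashes per 1000 atoms.
#' @export
clash_count <- function(system, model_index = 1L) {
  at <- system$ensemble$atoms
  xyz <- system$ensemble$coords[[model_index]]
  n <- nrow(at)
  Dtop <- topo_distance_matrix(system$bonds, cap = 3L)
  pair <- which(upper.tri(Dtop) & Dtop > 3, arr.ind = TRUE)
  if (nrow(pair) == 0L) return(0)
  rv <- vdw_radius(at$element)
  d <- sqrt(rowSums((xyz[pair[, 1L], , drop = FALSE] -
                     xyz[pair[, 2L], , drop = FALSE])^2))
  sum(d < rv[pair[, 1L]] + rv[pair[, 2L]] - 0.4) * 1000 / n
}

#' Per-restraint violation report over an ensemble
#'
#' One row per restraint per model: the measured distance, the violation
#' against the corrected limit, and a satisfied flag; plus per-model TF
#' and ensemble summary statistics.
#'
#' @param ensemble an ensemble (or typed system).
#' @param restraint_set a resolved restraint set.
#' @return object of class `"violation_report"`: `table` (restraint x
#'   model rows, sorted worst-first within model), `tf` per model,
#'   `mean_violation`, `max_violation`.
#' @export
violation_report <- function(ensemble, restraint_set) {
  if (inherits(ensemble, "typed_system")) ensemble <- ensemble$ensemble
  rs <- restraint_set$restraints
  rows <- list()
  for (m in seq_len(n_models(ensemble))) {
    if (nrow(rs) == 0L) break
    D <- restraint_distances(ensemble$coords[[m]], restraint_set)
    v <- pmax(0, D - rs$r_corrected)
    rows[[m]] <- data.frame(model = m, line = rs$line,
                            resno_i = rs$resno_i, name_i = rs$name_i,
                            resno_j = rs$resno_j, name_j = rs$name_j,
                            upper = rs$r_corrected, distance = D,
                            violation = v, satisfied = v == 0)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(model = integer(), line = integer(), resno_i = integer(),
               name_i = character(), resno_j = integer(),
               name_j = character(), upper = numeric(),
               distance = numeric(), violation = numeric(),
               satisfied = logical())
  tab <- tab[order(tab$model, -tab$violation), , drop = FALSE]
  rownames(tab) <- NULL
  tf <- target_function(ensemble, restraint_set)
  structure(list(table = tab, tf = tf,
                 mean_violation = if (nrow(tab)) mean(tab$violation) else 0,
                 max_violation = if (nrow(tab)) max(tab$violation) else 0),
            class = "violation_report")
}

#' @export
print.violation_report <- function(x, ...) {
  cat(sprintf("violation report: %d rows; TF per model: %s A^2\n",
              nrow(x$table),
              paste(sprintf("%.3f", x$tf), collapse = ", ")))
  cat(sprintf("mean violation %.3f A, max %.3f A\n",
              x$mean_violation, x$max_violation))
  invisible(x)
}

#' Export a violation report as tab-separated values
#'
#' @param report a [violation_report()].
#' @param file output path.
#' @return the path, invisibly.
#' @export
export_violations_tsv <- function(report, file) {
  utils::write.table(report$table, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
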