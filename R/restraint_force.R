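## Flat-bottom NOE restraint potential: zero inside the upper limit,
## harmonic in the violation up to a 5 A plateau, constant force beyond.
## Pseudoatom endpoints act at the mean of their parent hydrogens; the
## pseudoatom force is distributed evenly to the parents (for a mean
## position the chain rule gives exactly the same 1/N factor, so energy
## and force stay consistent).

#' Restraint force configuration
#'
#' @param K force constant in kcal/mol/A (default 198.6).
#' @param user_scale dimensionless user multiplier of K (default 1).
#' @param plateau violation at which the force stops growing, Angstrom
#'   (default 5).
#' @return a config list.
#' @export
restraint_config <- function(K = 198.6, user_scale = 1, plateau = 5) {
  stopifnot(K > 0, plateau > 0, user_scale >= 0)
  list(K = K, user_scale = user_scale, plateau = plateau)
}

#' Flat-bottom restraint energy and forces for one atom pair
#'
#' With separation `D = |p1 - p2|` and violation `v = max(0, D - upper)`,
#' the force magnitude is `K' * min(v, plateau)` pulling the endpoints
#' together (`K' = K * user_scale`); the energy is the exact integral:
#' `K'/2 v^2` below the plateau and linear beyond. Satisfied restraints
#' contribute nothing; forces are equal and opposite.
#'
#' @param p1,p2 endpoint positions (3-vectors, Angstrom).
#' @param upper upper distance limit, Angstrom (> 0).
#' @param config a [restraint_config()].
#' @return list with `energy`, `force_p1`, `force_p2` and the scalar
#'   `violation`.
#' @export
restraint_force_energy <- function(p1, p2, upper, config = restraint_config()) {
  if (upper <= 0) stop("upper limit must be positive")
  Kp <- config$K * config$user_scale
  s <- config$plateau
  dvec <- p1 - p2
  D <- sqrt(sum(dvec * dvec))
  v <- max(0, D - upper)
  if (v == 0 || D == 0 || Kp == 0) {
    return(list(energy = 0, force_p1 = c(0, 0, 0), force_p2 = c(0, 0, 0),
                violation = v))
  }
  nvec <- dvec / D
  d_eff <- min(v, s)
  E <- if (v <= s) 0.5 * Kp * v^2 else 0.5 * Kp * s^2 + Kp * s * (v - s)
  f1 <- -Kp * d_eff * nvec               # pulls p1 toward p2
  list(energy = E, force_p1 = f1, force_p2 = -f1, violation = v)
}

#' Distribute a pseudoatom force evenly to its parent hydrogens
#'
#' @param force 3-vector force acting on the pseudoatom.
#' @param parents vector of parent atom indices (length N_Q >= 1).
#' @return an `N_Q x 3` matrix; rows sum exactly to `force`.
#' @export
distribute_to_parents <- function(force, parents) {
  if (length(parents) == 0L) stop("pseudoatom with no parents")
  matrix(rep(force / length(parents), each = length(parents)),
         nrow = length(parents))
}

#' Total restraint energy and per-atom forces for one model
#'
#' Sums the flat-bottom term over all resolved restraints, evaluating
#' pseudoatom endpoints at the mean of their parent positions and pushing
#' the endpoint forces down to the parents evenly.
#'
#' @param positions `n x 3` coordinate matrix of the model.
#' @param restraint_set a resolved restraint set.
#' @param config a [restraint_config()].
#' @return list with total `energy` and an `n x 3` `forces` matrix.
#' @export
restraint_term <- function(positions, restraint_set,
                           config = restraint_config()) {
  F <- matrix(0, nrow(positions), 3)
  E <- 0
  rs <- restraint_set$restraints
  for (k in seq_len(nrow(rs))) {
    gi <- rs$idx_i[[k]]; gj <- rs$idx_j[[k]]
    p1 <- colMeans(positions[gi, , drop = FALSE])
    p2 <- colMeans(positions[gj, , drop = FALSE])
    r <- restraint_force_energy(p1, p2, rs$r_corrected[k], config)
    if (r$energy == 0) next
    E <- E + r$energy
    F[gi, ] <- F[gi, ] + distribute_to_parents(r$force_p1, gi)
    F[gj, ] <- F[gj, ] + distribute_to_parents(r$force_p2, gj)
  }
  list(energy = E, forces = F)
}
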