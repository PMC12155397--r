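## FIRE (fast inertial relaxation engine) minimization of each model in
## the combined UFF + restraint potential. Canonical parameter values;
## unit masses (only the fixed point matters for minimization, not the
## dynamics). Deterministic: no randomness anywhere.

#' FIRE minimizer configuration
#'
#' @param dt_init,dt_max initial and maximal time step (internal units).
#' @param alpha_start initial velocity-mixing weight.
#' @param f_inc,f_dec,f_alpha adaptive factors (canonical 1.1/0.5/0.99).
#' @param n_min downhill steps before acceleration kicks in.
#' @param max_steps iteration budget.
#' @param force_tol convergence threshold on the max per-atom force,
#'   kcal/mol/A.
#' @param mass per-atom mass (unit masses by default).
#' @return a config list.
#' @export
fire_config <- function(dt_init = 1e-3, dt_max = 1e-2, alpha_start = 0.1,
                        f_inc = 1.1, f_dec = 0.5, f_alpha = 0.99,
                        n_min = 5L, max_steps = 5000L, force_tol = 0.05,
                        mass = 1) {
  stopifnot(f_dec > 0, f_dec < 1, f_inc > 1, alpha_start > 0,
            alpha_start < 1, dt_init <= dt_max, dt_init > 0)
  list(dt_init = dt_init, dt_max = dt_max, alpha_start = alpha_start,
       f_inc = f_inc, f_dec = f_dec, f_alpha = f_alpha,
       n_min = as.integer(n_min), max_steps = as.integer(max_steps),
       force_tol = force_tol, mass = mass)
}

#' Initial FIRE state
#'
#' @param positions `n x 3` starting coordinates.
#' @param config a [fire_config()].
#' @return a `fire_state` list (positions, velocities, dt, alpha,
#'   bookkeeping counters).
#' @export
fire_init <- function(positions, config = fire_config()) {
  structure(list(positions = positions,
                 velocities = matrix(0, nrow(positions), 3),
                 dt = config$dt_init, alpha = config$alpha_start,
                 n_pos = 0L, iteration = 0L),
            class = "fire_state")
}

# one FIRE update given precomputed forces at state$positions
fire_step_forces <- function(state, forces, config) {
  if (!all(is.finite(forces))) {
    worst <- which(!is.finite(rowSums(forces)))[1]
    stop("non-finite forces during minimization (atom index ", worst, ")")
  }
  P <- sum(forces * state$velocities)
  if (P > 0) {
    state$n_pos <- state$n_pos + 1L
    if (state$n_pos > config$n_min) {
      state$dt <- min(state$dt * config$f_inc, config$dt_max)
      state$alpha <- state$alpha * config$f_alpha
    }
  } else {
    state$n_pos <- 0L
    state$velocities[] <- 0
    state$dt <- state$dt * config$f_dec
    state$alpha <- config$alpha_start
  }
  v <- state$velocities + state$dt * forces / config$mass
  vnorm <- sqrt(sum(v * v))
  fnorm <- sqrt(sum(forces * forces))
  if (fnorm > 0) {
    v <- (1 - state$alpha) * v + state$alpha * vnorm * forces / fnorm
  }
  state$velocities <- v
  state$positions <- state$positions + state$dt * v
  state$iteration <- state$iteration + 1L
  state
}

#' One FIRE step
#'
#' Semi-implicit Euler integration with velocity mixing toward the force
#' direction; power `P = F . v <= 0` zeroes the velocities and shrinks the
#' time step, more than `n_min` consecutive downhill steps grow it.
#'
#' @param state a `fire_state` from [fire_init()].
#' @param force_provider function(positions) returning an `n x 3` force
#'   matrix.
#' @param config a [fire_config()].
#' @return the updated state.
#' @export
fire_step <- function(state, force_provider, config = fire_config()) {
  fire_step_forces(state, force_provider(state$positions), config)
}

#' Minimize one model of a typed system
#'
#' Iterates FIRE on the combined UFF + restraint potential until the
#' maximum per-atom force drops below `force_tol` or the step budget is
#' exhausted.
#'
#' @param system a typed system.
#' @param model_index model to minimize.
#' @param restraints optional resolved restraint set.
#' @param fire_cfg a [fire_config()].
#' @param ff_cfg an [ff_config()].
#' @param restraint_cfg a [restraint_config()].
#' @return list with `positions`, and a `report` carrying initial/final
#'   energies, the term breakdown, iteration count and `converged` flag.
#' @export
minimize_model <- function(system, model_index = 1L, restraints = NULL,
                           fire_cfg = fire_config(), ff_cfg = ff_config(),
                           restraint_cfg = restraint_config()) {
  terms <- compile_terms(system, ff_cfg)
  evalfn <- function(pos) {
    r <- eval_terms(pos, terms, ff_cfg)
    if (!is.null(restraints)) {
      rr <- restraint_term(pos, restraints, restraint_cfg)
      r$E_restraint <- rr$energy
      r$forces <- r$forces + rr$forces
    } else {
      r$E_restraint <- 0
    }
    r$E_total <- r$E_bond + r$E_angle + r$E_torsion + r$E_inversion +
      r$E_vdw + r$E_restraint
    r
  }
  state <- fire_init(system$ensemble$coords[[model_index]], fire_cfg)
  rep0 <- evalfn(state$positions)
  E0 <- rep0$E_total
  repc <- rep0
  converged <- FALSE
  while (state$iteration < fire_cfg$max_steps) {
    maxf <- max(sqrt(rowSums(repc$forces^2)))
    if (maxf < fire_cfg$force_tol) {
      converged <- TRUE
      break
    }
    state <- fire_step_forces(state, repc$forces, fire_cfg)
    repc <- evalfn(state$positions)
  }
  maxf <- max(sqrt(rowSums(repc$forces^2)))
  if (maxf < fire_cfg$force_tol) converged <- TRUE
  if (!converged && is.finite(E0) && repc$E_total > 10 * abs(E0) + 100) {
    stop("minimization diverged: E_total ", signif(repc$E_total, 6),
         " from initial ", signif(E0, 6))
  }
  report <- list(E_initial = E0, E_final = repc$E_total,
                 terms_initial = rep0[c("E_bond", "E_angle", "E_torsion",
                                        "E_inversion", "E_vdw",
                                        "E_restraint")],
                 terms_final = repc[c("E_bond", "E_angle", "E_torsion",
                                      "E_inversion", "E_vdw",
                                      "E_restraint")],
                 iterations = state$iteration, converged = converged,
                 max_force = maxf)
  list(positions = state$positions, report = report)
}

#' Minimize every model of an ensemble
#'
#' Models are minimized independently with identical settings; a failing
#' model keeps its input coordinates and is reported, the rest proceed.
#'
#' @inheritParams minimize_model
#' @return list with the minimized `ensemble` and `reports` (one per
#'   model; failed models carry an `error` message).
#' @export
minimize_ensemble <- function(system, restraints = NULL,
                              fire_cfg = fire_config(),
                              ff_cfg = ff_config(),
                              restraint_cfg = restraint_config()) {
  ens <- system$ensemble
  coords <- ens$coords
  reports <- vector("list", n_models(ens))
  for (m in seq_len(n_models(ens))) {
    out <- tryCatch(
      minimize_model(system, m, restraints, fire_cfg, ff_cfg,
                     restraint_cfg),
      error = function(e) e)
    if (inherits(out, "error")) {
      reports[[m]] <- list(converged = FALSE,
                           error = conditionMessage(out))
    } else {
      coords[[m]] <- out$positions
      reports[[m]] <- out$report
    }
  }
  list(ensemble = new_ensemble(ens$atoms, coords), reports = reports)
}
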