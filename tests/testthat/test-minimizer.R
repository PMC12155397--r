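test_that("FIRE converges to the analytic minimum of quadratic wells", {
  # independent force provider: E = 1/2 sum k (x - x0)^2
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(2:6, 1)
    x0 <- matrix(rnorm(3 * n, sd = 2), n, 3)
    kk <- runif(n, 50, 500)
    provider <- function(pos) -kk * (pos - x0)
    cfg <- fire_config(force_tol = 1e-4, max_steps = 4000)
    st <- fire_init(x0 + matrix(rnorm(3 * n), n, 3), cfg)
    for (it in seq_len(cfg$max_steps)) {
      F <- provider(st$positions)
      if (max(sqrt(rowSums(F^2))) < cfg$force_tol) break
      st <- fire_step(st, provider, cfg)
    }
    expect_lt(max(abs(st$positions - x0)), 1e-5)
  }
})

test_that("fire_step bookkeeping follows the uphill/downhill rules", {
  cfg <- fire_config()
  st <- fire_init(matrix(c(0, 0, 0), 1), cfg)
  # uphill power: velocities zeroed, dt shrinks, alpha resets
  st$velocities <- matrix(c(-1, 0, 0), 1)
  st2 <- nmrefine:::fire_step_forces(st, matrix(c(1, 0, 0), 1), cfg)
  expect_equal(st2$dt, cfg$dt_init * cfg$f_dec)
  expect_equal(st2$alpha, cfg$alpha_start)
  # velocity rebuilt purely from the current force after the reset
  expect_equal(st2$velocities, matrix(c(st2$dt, 0, 0), 1))
  # zero force: position unchanged (bookkeeping may move)
  st3 <- nmrefine:::fire_step_forces(fire_init(matrix(1, 1, 3), cfg),
                                     matrix(0, 1, 3), cfg)
  expect_equal(st3$positions, matrix(1, 1, 3))
  # dt grows only after n_min consecutive downhill steps
  st4 <- fire_init(matrix(0, 1, 3), cfg)
  st4$velocities <- matrix(c(1, 0, 0), 1)
  for (k in 1:(cfg$n_min + 2)) {
    st4 <- nmrefine:::fire_step_forces(st4, matrix(c(1, 0, 0), 1), cfg)
  }
  expect_gt(st4$dt, cfg$dt_init)
  expect_lt(st4$alpha, cfg$alpha_start)
  expect_error(
    nmrefine:::fire_step_forces(st, matrix(c(NaN, 0, 0), 1), cfg),
    "non-finite")
})

test_that("stretched diatomic relaxes to its equilibrium length", {
  r0 <- equilibrium_bond_length("H_", "H_")
  # perceive at bonding distance, then stretch to 1.5 r0 (at the
  # stretched distance the geometric cutoff would no longer bond them)
  f <- build_fixture("diatomic", elements = c("H", "H"), distance = r0)
  sys <- prepare_system(f$ensemble, fix_termini = FALSE)
  sys$ensemble$coords[[1]][2, 1] <- 1.5 * r0
  out <- minimize_model(sys, 1)
  expect_true(out$report$converged)
  expect_equal(pair_dist(out$positions, 1, 2), r0, tolerance = 1e-3)
  expect_lte(out$report$E_final, out$report$E_initial)
  # already-minimal diatomic barely moves
  f2 <- build_fixture("diatomic", elements = c("H", "H"), distance = r0)
  sys2 <- prepare_system(f2$ensemble, fix_termini = FALSE)
  out2 <- minimize_model(sys2, 1)
  expect_true(out2$report$converged)
  expect_lt(max(abs(out2$positions - sys2$ensemble$coords[[1]])), 1e-3)
})

test_that("a violated two-atom restraint pulls within its limit", {
  f <- build_fixture("two_atom_restraint_case")
  sys <- prepare_system(f$ensemble, fix_termini = FALSE)
  rset <- read_upl(f$upl, sys$ensemble$atoms)
  expect_equal(nrow(rset$restraints), 1L)
  out <- minimize_model(sys, 1, rset, ff_cfg = ff_config(vdw = FALSE))
  expect_true(out$report$converged)
  # force_tol 0.05 on K = 198.6 leaves at most ~3e-4 A of violation
  expect_lte(pair_dist(out$positions, 1, 2), 3.0 + 1e-3)
})

test_that("ensemble minimization is deterministic and isolates failures", {
  f <- build_fixture("ala_tripeptide", distortion = 0.2, seed = 12,
                     n_models = 2)
  ens <- f$ensemble
  # duplicate model 1 so two inputs are identical
  ens3 <- new_ensemble(ens$atoms, list(ens$coords[[1]], ens$coords[[1]],
                                       ens$coords[[2]]))
  sys <- prepare_system(ens3)
  rset <- read_upl(f$upl, sys$ensemble$atoms)
  cfg <- fire_config(max_steps = 800)
  out <- minimize_ensemble(sys, rset, fire_cfg = cfg)
  expect_identical(out$ensemble$coords[[1]], out$ensemble$coords[[2]])
  rerun <- minimize_ensemble(sys, rset, fire_cfg = cfg)
  expect_identical(out$ensemble$coords[[3]], rerun$ensemble$coords[[3]])
  # corrupt model (two atoms coincident -> huge forces) fails alone
  bad <- ens$coords[[1]]
  bad[2, ] <- bad[1, ]
  sys_bad <- prepare_system(
    new_ensemble(ens$atoms, list(ens$coords[[1]], bad, ens$coords[[2]])),
    fix_termini = FALSE)
  out_bad <- minimize_ensemble(sys_bad, fire_cfg = fire_config(max_steps = 200))
  ok <- vapply(out_bad$reports, function(r) is.null(r$error), TRUE)
  expect_identical(ok, c(TRUE, FALSE, TRUE))
  expect_identical(out_bad$ensemble$coords[[2]], bad)  # left untouched
})
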