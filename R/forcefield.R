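## Vectorized UFF energy and analytic forces.
##
## Forces are the exact negative gradient of the implemented energy; the
## test suite checks every term class against central finite differences.

# scatter-add per-term 3-vector contributions onto the atom force array
acc_force <- function(F, idx, contrib) {
  if (length(idx) == 0L) return(F)
  s <- rowsum(contrib, group = idx, reorder = FALSE)
  rows <- as.integer(rownames(s))
  F[rows, ] <- F[rows, ] + s
  F
}

row_norm <- function(m) sqrt(rowSums(m * m))

#' UFF energy and forces for one model
#'
#' Evaluates the harmonic bond term, the UFF cosine-expansion angle term,
#' the UFF torsion term, the inversion (out-of-plane) term at trigonal sp2
#' C/N centers and the 12-6 van der Waals term over all pairs except 1-2
#' and 1-3 (no cutoff, no electrostatics). Optionally adds the flat-bottom
#' distance-restraint term.
#'
#' @param system a typed system from [prepare_system()].
#' @param model_index which model's coordinates to evaluate.
#' @param config an [ff_config()].
#' @param restraints optional resolved restraint set; adds `E_restraint`.
#' @param restraint_config a [restraint_config()].
#' @param terms precompiled term arrays from `compile_terms()` (internal
#'   speed-up; recompiled when `NULL`).
#' @return a list of class `"energy_report"` with per-term energies
#'   (kcal/mol), `E_total` and the per-atom force matrix `forces`
#'   (kcal/mol/A).
#' @export
energy_forces <- function(system, model_index = 1L, config = ff_config(),
                          restraints = NULL,
                          restraint_config = restraint_config(),
                          terms = NULL) {
  if (is.null(terms)) terms <- compile_terms(system, config)
  pos <- system$ensemble$coords[[model_index]]
  rep_ <- eval_terms(pos, terms, config)
  if (!is.null(restraints)) {
    rr <- restraint_term(pos, restraints, restraint_config)
    rep_$E_restraint <- rr$energy
    rep_$forces <- rep_$forces + rr$forces
  } else {
    rep_$E_restraint <- 0
  }
  rep_$E_total <- rep_$E_bond + rep_$E_angle + rep_$E_torsion +
    rep_$E_inversion + rep_$E_vdw + rep_$E_restraint
  if (!all(is.finite(rep_$forces))) {
    worst <- which(!is.finite(row_norm(rep_$forces)))[1]
    stop("non-finite force on atom ", system$ensemble$atoms$name[worst],
         " (residue ", system$ensemble$atoms$resno[worst], ")")
  }
  class(rep_) <- "energy_report"
  rep_
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf(paste0("E_total %.4f kcal/mol  (bond %.4f | angle %.4f | ",
                     "torsion %.4f | inversion %.4f | vdw %.4f | ",
                     "restraint %.4f)\n"),
              x$E_total, x$E_bond, x$E_angle, x$E_torsion, x$E_inversion,
              x$E_vdw, x$E_restraint))
  invisible(x)
}

# core evaluator on a bare coordinate matrix
eval_terms <- function(pos, terms, config = terms$config) {
  n <- terms$natoms
  F <- matrix(0, n, 3)
  E_bond <- E_angle <- E_torsion <- E_inversion <- E_vdw <- 0

  if (isTRUE(config$bonds) && length(terms$bonds$i)) {
    tb <- terms$bonds
    dvec <- pos[tb$i, , drop = FALSE] - pos[tb$j, , drop = FALSE]
    d <- row_norm(dvec)
    E_bond <- sum(0.5 * tb$k * (d - tb$r0)^2)
    fmag <- -tb$k * (d - tb$r0) / pmax(d, 1e-12)
    fv <- dvec * fmag
    F <- acc_force(F, tb$i, fv)
    F <- acc_force(F, tb$j, -fv)
  }

  if (isTRUE(config$angles) && length(terms$angles$i)) {
    ta <- terms$angles
    u <- pos[ta$i, , drop = FALSE] - pos[ta$j, , drop = FALSE]
    v <- pos[ta$k, , drop = FALSE] - pos[ta$j, , drop = FALSE]
    lu <- row_norm(u); lv <- row_norm(v)
    c_ <- rowSums(u * v) / (lu * lv)
    c_ <- pmax(-1, pmin(1, c_))
    # E = K [C0 + C1 c + C2 (2c^2 - 1)]; linear centers: E = K (1 + c)
    Evec <- ifelse(ta$linear,
                   ta$K * (1 + c_),
                   ta$K * (ta$C0 + ta$C1 * c_ + ta$C2 * (2 * c_^2 - 1)))
    dEdc <- ifelse(ta$linear, ta$K, ta$K * (ta$C1 + 4 * ta$C2 * c_))
    E_angle <- sum(Evec)
    # d c / d u = v/(|u||v|) - c u/|u|^2 ; symmetric for v
    dcdu <- v / (lu * lv) - u * (c_ / lu^2)
    dcdv <- u / (lu * lv) - v * (c_ / lv^2)
    Fi <- -dEdc * dcdu
    Fk <- -dEdc * dcdv
    F <- acc_force(F, ta$i, Fi)
    F <- acc_force(F, ta$k, Fk)
    F <- acc_force(F, ta$j, -(Fi + Fk))
  }

  if (isTRUE(config$torsions) && length(terms$torsions$i)) {
    tt <- terms$torsions
    b1 <- pos[tt$j, , drop = FALSE] - pos[tt$i, , drop = FALSE]
    b2 <- pos[tt$k, , drop = FALSE] - pos[tt$j, , drop = FALSE]
    b3 <- pos[tt$l, , drop = FALSE] - pos[tt$k, , drop = FALSE]
    n1 <- rowcross(b1, b2)
    n2 <- rowcross(b2, b3)
    l2 <- row_norm(b2)
    n1sq <- rowSums(n1 * n1); n2sq <- rowSums(n2 * n2)
    ok <- n1sq > 1e-16 & n2sq > 1e-16       # collinear -> zero contribution
    cphi <- rep(0, length(l2)); sphi <- rep(0, length(l2))
    m1 <- rowcross(n1, b2 / pmax(l2, 1e-12))
    cphi[ok] <- (rowSums(n1 * n2) / sqrt(n1sq * n2sq))[ok]
    sphi[ok] <- (rowSums(m1 * n2) / sqrt(rowSums(m1 * m1) * n2sq))[ok]
    phi <- atan2(sphi, cphi)
    # E = 1/2 V (1 - cos(n phi0) cos(n phi)), dE/dphi = 1/2 V cos(n phi0) n sin(n phi)
    cn <- mapply(function(cc, nn) cos_n(cc, nn), cphi, tt$n)
    E_t <- 0.5 * tt$V * (1 - tt$cosnphi0 * cn)
    E_t[!ok] <- 0
    E_torsion <- sum(E_t)
    dEdphi <- 0.5 * tt$V * tt$cosnphi0 * tt$n * sin(tt$n * phi)
    dEdphi[!ok] <- 0
    # gradients of phi (Blondel-Karplus form, signs fixed to the atan2
    # convention above; verified against finite differences)
    g1 <- n1 * (l2 / pmax(n1sq, 1e-12))
    g4 <- -n2 * (l2 / pmax(n2sq, 1e-12))
    d12 <- rowSums(b1 * b2) / pmax(l2^2, 1e-12)
    d32 <- rowSums(b3 * b2) / pmax(l2^2, 1e-12)
    g2 <- -(1 + d12) * g1 + d32 * g4
    g3 <- d12 * g1 - (1 + d32) * g4
    F <- acc_force(F, tt$i, -dEdphi * g1)
    F <- acc_force(F, tt$j, -dEdphi * g2)
    F <- acc_force(F, tt$k, -dEdphi * g3)
    F <- acc_force(F, tt$l, -dEdphi * g4)
  }

  if (isTRUE(config$inversions) && length(terms$inversions$c)) {
    tv <- terms$inversions
    u <- pos[tv$a, , drop = FALSE] - pos[tv$c, , drop = FALSE]
    v <- pos[tv$b, , drop = FALSE] - pos[tv$c, , drop = FALSE]
    w <- pos[tv$d, , drop = FALSE] - pos[tv$c, , drop = FALSE]
    nn <- rowcross(u, v)
    N <- row_norm(nn); W <- row_norm(w)
    s <- rowSums(nn * w) / pmax(N * W, 1e-12)     # sin(omega)
    s <- pmax(-1, pmin(1, s))
    cw <- sqrt(pmax(1 - s^2, 1e-12))              # cos(omega), omega ~ 0
    # E = K (C0 + C1 cos w + C2 cos 2w), cos2w = 1 - 2 s^2
    E_inversion <- sum(tv$K * (tv$C0 + tv$C1 * cw + tv$C2 * (1 - 2 * s^2)))
    dEds <- tv$K * (-tv$C1 * s / cw - 4 * tv$C2 * s)
    # ds/dn and ds/dw, then chain through the cross product
    g_n <- w / (N * W) - nn * (rowSums(nn * w) / (N^3 * W))
    g_w <- nn / (N * W) - w * (rowSums(nn * w) / (N * W^3))
    Fa <- -dEds * rowcross(v, g_n)
    Fb <- -dEds * rowcross(g_n, u)
    Fd <- -dEds * g_w
    F <- acc_force(F, tv$a, Fa)
    F <- acc_force(F, tv$b, Fb)
    F <- acc_force(F, tv$d, Fd)
    F <- acc_force(F, tv$c, -(Fa + Fb + Fd))
  }

  if (isTRUE(config$vdw) && length(terms$vdw$i)) {
    tw <- terms$vdw
    dvec <- pos[tw$i, , drop = FALSE] - pos[tw$j, , drop = FALSE]
    d <- pmax(row_norm(dvec), 1e-8)
    q <- (tw$x / d)^6
    E_vdw <- sum(tw$D * (q^2 - 2 * q))
    # dE/dd = D(-12 q^2 + 12 q)/d ; F_i = -dE/dd * dvec/d
    fmag <- 12 * tw$D * (q^2 - q) / (d^2)
    fv <- dvec * fmag
    F <- acc_force(F, tw$i, fv)
    F <- acc_force(F, tw$j, -fv)
  }

  list(E_bond = E_bond, E_angle = E_angle, E_torsion = E_torsion,
       E_inversion = E_inversion, E_vdw = E_vdw, forces = F)
}

rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}
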