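# Conjugate-gradient minimization (Polak-Ribiere with Armijo backtracking)
# with optional harmonic torsion restraints, and the regularization
# procedure: cycling between short restrained minimizations and exact
# torsion resets until the minimized structure's torsions self-consistently
# match their targets.

# restraint set over every controllable (settable) torsion at its stored target
.restraint_set <- function(pep, k) {
  t <- pep$torsions[pep$torsions$settable, , drop = FALSE]
  list(q = as.matrix(t[, c("a", "b", "c", "d")]), target = t$target, k = k)
}

.max_torsion_dev <- function(pep) {
  t <- pep$torsions[pep$torsions$settable, , drop = FALSE]
  if (!nrow(t)) return(0)
  db <- .dihedral_batch(pep$coords, as.matrix(t[, c("a", "b", "c", "d")]))
  max(abs(wrap_angle(db$phi * .rad2deg - t$target)))
}

# diagonal preconditioner: an estimate of the per-atom curvature from the
# stiff terms (bonds, angles, torsion restraints, close contacts), so that
# the conjugate-gradient search is well scaled even under very stiff
# restraints
.precond <- function(x, model, restraints) {
  p <- model$params
  n <- nrow(x)
  m <- rep(1, n)
  add <- function(idx, val) {
    s <- rowsum(val, idx)
    ids <- as.integer(rownames(s))
    m[ids] <<- m[ids] + s[, 1L]
    invisible(NULL)
  }
  i <- model$bonds[, 1L]; j <- model$bonds[, 2L]
  add(c(i, j), rep(2 * p$k_bond, 2 * length(i)))
  ai <- model$angles[, 1L]; aj <- model$angles[, 2L]; ak <- model$angles[, 3L]
  u <- x[ai, , drop = FALSE] - x[aj, , drop = FALSE]
  v <- x[ak, , drop = FALSE] - x[aj, , drop = FALSE]
  cu <- 2 * p$k_angle / rowSums(u^2); cv <- 2 * p$k_angle / rowSums(v^2)
  add(ai, cu); add(ak, cv); add(aj, cu + cv)
  ni <- model$nb_pairs[, 1L]; nj <- model$nb_pairs[, 2L]
  r2 <- rowSums((x[ni, , drop = FALSE] - x[nj, , drop = FALSE])^2)
  crep <- 156 * model$nb_scale * p$eps_rep * (model$nb_sigma^2 / r2)^6 / r2
  add(ni, crep); add(nj, crep)
  if (!is.null(restraints) && nrow(restraints$q)) {
    db <- .dihedral_batch(x, restraints$q)
    for (col in 1:4) {
      add(restraints$q[, col], 2 * restraints$k * rowSums(db$d[[col]]^2))
    }
  }
  m
}

# core CG driver on raw coordinates (Polak-Ribiere, diagonally
# preconditioned, Armijo backtracking plus secant refinement); returns
# list(x, f, steps, converged, delta_E_last)
.cg_minimize <- function(x, model, restraints, max_steps, tol) {
  ev <- .ff_eval(x, model, restraints)
  f <- ev$total
  g <- ev$grad
  m <- .precond(x, model, restraints)
  z <- -g / m
  d <- z
  steps <- 0L
  converged <- FALSE
  delta <- NA_real_
  alpha <- NA_real_
  while (steps < max_steps) {
    gd <- sum(g * d)
    if (gd >= 0) {  # not a descent direction: restart along -z
      d <- z
      gd <- sum(g * d)
      if (gd >= -1e-300) { converged <- TRUE; delta <- 0; break }
    }
    # initial trial step: cap the largest atomic displacement at 0.2 A
    dmax <- sqrt(max(rowSums(d^2)))
    a <- if (is.na(alpha)) 0.2 / dmax else min(alpha * 2, 0.5 / dmax)
    accepted <- FALSE
    for (ls in 1:40) {
      xn <- x + a * d
      fn <- .ff_eval(xn, model, restraints, gradient = FALSE)$total
      if (fn <= f + 1e-4 * a * gd) { accepted <- TRUE; break }
      a <- a / 2
    }
    if (!accepted) {
      if (!identical(d, z)) { d <- z; alpha <- NA_real_; next }  # CG restart
      converged <- TRUE; delta <- 0; break
    }
    # secant refinement towards the exact line minimum (phi'(a) = 0);
    # exact for a quadratic profile, so conjugacy is preserved well
    evn <- .ff_eval(xn, model, restraints)
    for (it in 1:4) {
      g1d <- sum(evn$grad * d)
      if (abs(g1d) <= 0.1 * abs(gd)) break
      a2 <- a * gd / (gd - g1d)
      if (!is.finite(a2) || a2 <= 0 || a2 > 50 * a) break
      x2 <- x + a2 * d
      ev2 <- .ff_eval(x2, model, restraints)
      if (ev2$total >= fn) break
      a <- a2; xn <- x2; fn <- ev2$total; evn <- ev2
    }
    delta <- f - fn
    if (delta < tol) { converged <- TRUE; break }  # leave x at the last iterate
    zn <- -evn$grad / m
    # preconditioned Polak-Ribiere: (g_new . M^-1 (g_new - g_old)) /
    # (g_old . M^-1 g_old); both inner products carry z's minus sign
    beta <- max(0, sum(zn * (evn$grad - g)) / sum(g * z))
    x <- xn; f <- fn
    d <- zn + beta * d
    g <- evn$grad
    z <- zn
    alpha <- a
    steps <- steps + 1L
  }
  list(x = x, f = f, steps = steps, converged = converged, delta_E_last = delta)
}

#' Minimize the peptide energy by conjugate gradients
#'
#' Performs a Polak-Ribiere conjugate-gradient descent of the force-field
#' energy until the energy decrease over one accepted step falls below `tol`
#' (kcal/mol) or `max_steps` steps have been taken. With `constraint = TRUE`,
#' harmonic restraints (`k_restraint * delta^2`, delta in radians) on every
#' controllable phi, psi, omega and chi torsion at its currently stored
#' target are added to the objective; the restraint energy is excluded from
#' the reported final energy. After an unconstrained optimization the stored
#' torsion targets are refreshed from the relaxed coordinates.
#'
#' @param pep a `Peptide`.
#' @param constraint restrain all controllable torsions at their stored
#'   targets (default `FALSE`).
#' @param max_steps maximum conjugate-gradient steps (default 500).
#' @param tol convergence threshold on the per-step energy decrease,
#'   kcal/mol (default 1e-6).
#' @param k_restraint restraint stiffness in kcal mol^-1 rad^-2
#'   (default 500, which keeps restrained torsions within about a degree of
#'   their targets even on badly clashed structures).
#' @return an `OptimizationResult`: list with `peptide` (updated),
#'   `final_energy` (kcal/mol, restraints excluded), `steps`, `converged`,
#'   `delta_E_last` and `max_torsion_deviation` (degrees).
#' @export
optimize_peptide <- function(pep, constraint = FALSE, max_steps = 500,
                             tol = 1e-6, k_restraint = 500) {
  model <- .energy_model(pep)
  restraints <- if (constraint) .restraint_set(pep, k_restraint) else NULL
  run <- .cg_minimize(pep$coords, model, restraints, max_steps, tol)
  pep$coords <- run$x
  if (!constraint) {
    # stored targets follow the relaxed geometry
    pep$torsions$target <- vapply(seq_len(nrow(pep$torsions)),
                                  function(k) .measure_torsion(pep, k), 0)
  }
  structure(list(
    peptide = pep,
    final_energy = .ff_eval(run$x, model, gradient = FALSE)$energy,
    steps = run$steps, converged = run$converged,
    delta_E_last = run$delta_E_last,
    max_torsion_deviation = .max_torsion_dev(pep)), class = "OptimizationResult")
}

#' Remove steric clashes while keeping all torsions at their targets
#'
#' Cycles between a short restrained conjugate-gradient minimization
#' (`steps_per_cycle` steps) and an exact reset of every controllable
#' torsion to its stored target by rigid branch rotation, for up to `cycles`
#' iterations, stopping early once the minimized structure's maximum torsion
#' deviation (measured immediately before the reset) falls below
#' `self_consistency` degrees. The restraint stiffness is increased
#' four-fold each cycle (a standard penalty-method schedule), so the
#' constraint violation shrinks geometrically while bond lengths and angles
#' stay free to relax away from clashes. After the final reset every
#' controllable torsion equals its target exactly.
#'
#' @param pep a `Peptide`.
#' @param cycles maximum number of optimize/reset cycles (default 10).
#' @param steps_per_cycle conjugate-gradient steps per cycle (default 50).
#' @param k_restraint initial restraint stiffness, kcal mol^-1 rad^-2
#'   (default 200).
#' @param self_consistency stop once the pre-reset maximum torsion deviation
#'   is below this many degrees (default 0.002).
#' @param tol per-step energy convergence threshold passed to the inner
#'   minimizer (default 1e-6 kcal/mol).
#' @return an `OptimizationResult`; `max_torsion_deviation` is the deviation
#'   measured immediately before the final reset.
#' @export
regularize <- function(pep, cycles = 10, steps_per_cycle = 50,
                       k_restraint = 200, self_consistency = 0.002,
                       tol = 1e-6) {
  model <- .energy_model(pep)
  total_steps <- 0L
  dev <- NA_real_
  delta <- NA_real_
  k <- k_restraint
  for (cyc in seq_len(cycles)) {
    restraints <- .restraint_set(pep, k)
    run <- .cg_minimize(pep$coords, model, restraints, steps_per_cycle, tol)
    pep$coords <- run$x
    total_steps <- total_steps + run$steps
    delta <- run$delta_E_last
    dev <- .max_torsion_dev(pep)           # pre-reset deviation
    for (kk in which(pep$torsions$settable)) {  # exact reset
      pep <- .apply_torsion(pep, kk, pep$torsions$target[kk])
    }
    if (dev < self_consistency) break
    k <- min(k * 4, 1e6)
  }
  structure(list(
    peptide = pep,
    final_energy = .ff_eval(pep$coords, model, gradient = FALSE)$energy,
    steps = total_steps, converged = dev < self_consistency,
    delta_E_last = delta,
    max_torsion_deviation = dev), class = "OptimizationResult")
}

#' @export
print.OptimizationResult <- function(x, ...) {
  cat(sprintf(paste0("OptimizationResult: E = %.6f kcal/mol after %d steps ",
                     "(%sconverged)\n  last dE = %.3g kcal/mol, ",
                     "max torsion deviation = %.3g deg\n"),
              x$final_energy, x$steps, if (x$converged) "" else "not ",
              x$delta_E_last, x$max_torsion_deviation))
  invisible(x)
}
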