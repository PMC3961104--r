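# Simplified bespoke molecular-mechanics energy model with analytic
# gradients. Terms: harmonic bonds and angles referenced to the template
# geometry, a small 3-fold cosine series on proper torsions, and a purely
# repulsive r^-12 nonbonded term with Bondi-radius sigma (1-2 and 1-3 pairs
# excluded, 1-4 scaled by 0.5). Units are kcal/mol and Angstrom throughout.
# Harmonic torsion restraints (used by the constrained optimizer) are
# k * delta^2 with delta the wrapped angular deviation in radians.

.ff_params <- list(
  k_bond = 300,      # kcal mol^-1 A^-2
  k_angle = 80,      # kcal mol^-1 rad^-2
  v_torsion = 0.02,  # kcal mol^-1 (3-fold barrier amplitude)
  eps_rep = 0.1,     # kcal mol^-1
  scale_14 = 0.5,
  radii = c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80)  # Bondi, A
)

# Build the energy model for a peptide. Reference bond lengths come from the
# templates; reference angles are measured from a fresh default build of the
# same sequence and caps (torsion moves never change bond angles, so the
# default build carries the template values for every conformer, even after
# a minimization has strained the current coordinates).
.energy_model <- function(pep) {
  nb <- nrow(pep$bonds)
  nat <- nrow(pep$coords)
  ref <- build_peptide(pep$sequence, pep$nterm, pep$cterm)$coords
  stopifnot(nrow(ref) == nat)
  adj <- vector("list", nat)
  for (e in seq_len(nb)) {
    i <- pep$bonds[e, 1L]; j <- pep$bonds[e, 2L]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  # angles
  ai <- integer(0); aj <- integer(0); ak <- integer(0)
  for (j in seq_len(nat)) {
    nbrs <- adj[[j]]
    if (length(nbrs) >= 2L) {
      cmb <- utils::combn(sort(nbrs), 2L)
      ai <- c(ai, cmb[1L, ]); aj <- c(aj, rep(j, ncol(cmb))); ak <- c(ak, cmb[2L, ])
    }
  }
  v1 <- ref[ai, , drop = FALSE] - ref[aj, , drop = FALSE]
  v2 <- ref[ak, , drop = FALSE] - ref[aj, , drop = FALSE]
  cth <- rowSums(v1 * v2) / (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  theta0 <- acos(pmax(-1, pmin(1, cth)))
  # proper torsions: one 3-fold term per i-j-k-l path
  ti <- integer(0); tj <- integer(0); tk <- integer(0); tl <- integer(0)
  for (e in seq_len(nb)) {
    j <- pep$bonds[e, 1L]; k <- pep$bonds[e, 2L]
    is <- setdiff(adj[[j]], k); ls <- setdiff(adj[[k]], j)
    if (length(is) && length(ls)) {
      grid <- expand.grid(i = is, l = ls)
      grid <- grid[grid$i != grid$l, , drop = FALSE]
      ti <- c(ti, grid$i); tj <- c(tj, rep(j, nrow(grid)))
      tk <- c(tk, rep(k, nrow(grid))); tl <- c(tl, grid$l)
    }
  }
  # nonbonded pairs by topological separation
  g <- igraph::graph_from_edgelist(pep$bonds, directed = FALSE)
  topo <- igraph::distances(g)
  iu <- which(upper.tri(topo) & topo >= 3, arr.ind = TRUE)
  scale <- ifelse(topo[iu] == 3, .ff_params$scale_14, 1)
  rad <- .ff_params$radii[pep$atoms$element]
  sigma <- (rad[iu[, 1L]] + rad[iu[, 2L]]) * 2^(-1 / 6)
  list(
    bonds = pep$bonds, r0 = pep$bond_ref_length,
    angles = cbind(ai, aj, ak), theta0 = theta0,
    torsions = cbind(ti, tj, tk, tl),
    nb_pairs = iu, nb_scale = scale, nb_sigma = unname(sigma),
    params = .ff_params)
}

# dihedral angles (radians, our sign convention) and gradients for quadruple
# index matrix q (n x 4) -- shared by the cosine torsion term and restraints
.dihedral_batch <- function(x, q) {
  F <- x[q[, 1L], , drop = FALSE] - x[q[, 2L], , drop = FALSE]
  G <- x[q[, 2L], , drop = FALSE] - x[q[, 3L], , drop = FALSE]
  H <- x[q[, 4L], , drop = FALSE] - x[q[, 3L], , drop = FALSE]
  cr <- function(a, b) cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
                             a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
                             a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
  A <- cr(F, G); B <- cr(H, G)
  nG <- sqrt(rowSums(G^2))
  y <- -rowSums(cr(A, B) * G) / nG
  xx <- rowSums(A * B)
  phi <- atan2(y, xx)
  A2 <- rowSums(A^2); B2 <- rowSums(B^2)
  dphi_i <- -A * (nG / A2)
  dphi_l <- B * (nG / B2)
  p <- rowSums(F * G) / nG^2
  q2 <- rowSums(H * G) / nG^2
  dphi_j <- -dphi_i * (1 + p) - dphi_l * q2
  dphi_k <- dphi_i * p + dphi_l * (q2 - 1)
  list(phi = phi, d = list(dphi_i, dphi_j, dphi_k, dphi_l))
}

# total energy and gradient; `restraints` is NULL or
# list(q = n x 4 matrix, target = degrees, k = kcal mol^-1 rad^-2)
.ff_eval <- function(x, model, restraints = NULL, gradient = TRUE) {
  p <- model$params
  grad <- if (gradient) matrix(0, nrow(x), 3L) else NULL
  # -- bonds
  i <- model$bonds[, 1L]; j <- model$bonds[, 2L]
  dv <- x[i, , drop = FALSE] - x[j, , drop = FALSE]
  r <- sqrt(rowSums(dv^2))
  e_bond <- sum(p$k_bond * (r - model$r0)^2)
  if (gradient) {
    f <- dv * (2 * p$k_bond * (r - model$r0) / r)
    grad <- .acc3(grad, i, f); grad <- .acc3(grad, j, -f)
  }
  # -- angles
  ai <- model$angles[, 1L]; aj <- model$angles[, 2L]; ak <- model$angles[, 3L]
  u <- x[ai, , drop = FALSE] - x[aj, , drop = FALSE]
  v <- x[ak, , drop = FALSE] - x[aj, , drop = FALSE]
  ru <- sqrt(rowSums(u^2)); rv <- sqrt(rowSums(v^2))
  cth <- pmax(-1, pmin(1, rowSums(u * v) / (ru * rv)))
  th <- acos(cth)
  e_angle <- sum(p$k_angle * (th - model$theta0)^2)
  if (gradient) {
    sth <- pmax(sqrt(1 - cth^2), 1e-10)
    uh <- u / ru; vh <- v / rv
    dth_i <- (uh * cth - vh) / (ru * sth)
    dth_k <- (vh * cth - uh) / (rv * sth)
    coef <- 2 * p$k_angle * (th - model$theta0)
    grad <- .acc3(grad, ai, dth_i * coef)
    grad <- .acc3(grad, ak, dth_k * coef)
    grad <- .acc3(grad, aj, -(dth_i + dth_k) * coef)
  }
  # -- 3-fold torsions
  e_tors <- 0
  if (nrow(model$torsions)) {
    db <- .dihedral_batch(x, model$torsions)
    e_tors <- sum(p$v_torsion / 2 * (1 + cos(3 * db$phi)))
    if (gradient) {
      coef <- -1.5 * p$v_torsion * sin(3 * db$phi)
      for (col in 1:4) {
        grad <- .acc3(grad, model$torsions[, col], db$d[[col]] * coef)
      }
    }
  }
  # -- nonbonded repulsion
  ni <- model$nb_pairs[, 1L]; nj <- model$nb_pairs[, 2L]
  dv <- x[ni, , drop = FALSE] - x[nj, , drop = FALSE]
  r2 <- rowSums(dv^2)
  if (any(r2 < 1e-12)) stop("coincident atoms in nonbonded evaluation", call. = FALSE)
  sr12 <- (model$nb_sigma^2 / r2)^6
  e_rep <- sum(model$nb_scale * p$eps_rep * sr12)
  if (gradient) {
    coef <- model$nb_scale * p$eps_rep * (-12) * sr12 / r2
    f <- dv * coef
    grad <- .acc3(grad, ni, f); grad <- .acc3(grad, nj, -f)
  }
  # -- harmonic torsion restraints (not part of the reported energy terms)
  e_res <- 0
  if (!is.null(restraints) && nrow(restraints$q)) {
    db <- .dihedral_batch(x, restraints$q)
    delta <- wrap_angle(db$phi * .rad2deg - restraints$target) * .deg2rad
    e_res <- sum(restraints$k * delta^2)
    if (gradient) {
      coef <- 2 * restraints$k * delta
      for (col in 1:4) {
        grad <- .acc3(grad, restraints$q[, col], db$d[[col]] * coef)
      }
    }
  }
  list(total = e_bond + e_angle + e_tors + e_rep + e_res,
       energy = e_bond + e_angle + e_tors + e_rep,
       terms = c(bond = e_bond, angle = e_angle, torsion = e_tors,
                 repulsion = e_rep, restraint = e_res),
       grad = grad)
}

# add rows of `contrib` into grad at (possibly repeated) indices idx
.acc3 <- function(grad, idx, contrib) {
  for (d in 1:3) {
    s <- rowsum(contrib[, d], idx)
    ids <- as.integer(rownames(s))
    grad[ids, d] <- grad[ids, d] + s[, 1L]
  }
  grad
}

#' Molecular-mechanics energy of a peptide
#'
#' Evaluates the package's simplified repulsive force field (harmonic bonds
#' and angles referenced to the template geometry, 3-fold torsion terms, and
#' r^-12 steric repulsion) on the current coordinates.
#'
#' @param pep a `Peptide`.
#' @param decompose if `TRUE`, return the named per-term vector instead of
#'   the total.
#' @return energy in kcal/mol.
#' @export
get_energy <- function(pep, decompose = FALSE) {
  ev <- .ff_eval(pep$coords, .energy_model(pep), gradient = FALSE)
  if (decompose) ev$terms[c("bond", "angle", "torsion", "repulsion")] else ev$energy
}
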