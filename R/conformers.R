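# Continuous sampling of backbone and side-chain torsions from von Mises
# mixture models, with exact log-likelihoods.
#
# The sampler draws (phi, psi) pairs from a per-residue-type mixture over the
# Ramachandran basins and chi vectors from rotamer-style mixtures; side-chain
# sampling is backbone-conformation-dependent by default (component weights
# are re-weighted by the current backbone basin). Densities are per radian
# (a product of univariate von Mises densities per dimension), so a
# d-dimensional mixture integrates to 1 over the d-torus in radians.

.mixture_cache <- new.env(parent = emptyenv())

.mixture_file <- function(which) {
  f <- system.file("extdata", "mixtures", paste0(which, ".txt"),
                   package = "pepforge")
  if (!nzchar(f)) stop("mixture data file not found: ", which, call. = FALSE)
  f
}

.read_mixtures <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  toks <- lapply(strsplit(trimws(lines), "\\s+"), function(tk) {
    list(res = tk[1L], x = as.numeric(tk[-1L]))
  })
  out <- list()
  for (tk in toks) {
    k <- (length(tk$x) - 1L) / 2L
    stopifnot(k == round(k))
    cmp <- list(weight = tk$x[1L], mean = tk$x[1L + seq_len(k)],
                kappa = tk$x[1L + k + seq_len(k)])
    out[[tk$res]] <- c(out[[tk$res]], list(cmp))
  }
  lapply(out, function(cmps) {
    w <- vapply(cmps, `[[`, 0, "weight")
    m <- do.call(rbind, lapply(cmps, `[[`, "mean"))
    kp <- do.call(rbind, lapply(cmps, `[[`, "kappa"))
    if (any(kp <= 0)) stop("von Mises concentrations must be positive", call. = FALSE)
    if (abs(sum(w) - 1) > 1e-12) {
      stop("mixture weights must sum to 1 (off by ", format(sum(w) - 1), ")",
           call. = FALSE)
    }
    structure(list(weights = w, means = m, kappas = kp, dim = ncol(m)),
              class = "AngleMixture")
  })
}

.get_mixture <- function(which, code) {
  key <- which
  if (is.null(.mixture_cache[[key]])) {
    .mixture_cache[[key]] <- .read_mixtures(.mixture_file(which))
  }
  mx <- .mixture_cache[[key]][[code]]
  if (which == "backbone" && is.null(mx)) {
    stop("no backbone mixture configured for residue type ", code, call. = FALSE)
  }
  mx
}

#' Construct a von Mises angle mixture
#'
#' @param weights component weights (positive, summing to 1).
#' @param means matrix of component means in degrees (components x dimensions).
#' @param kappas matrix of von Mises concentrations, same shape as `means`.
#' @return an `AngleMixture` object.
#' @export
angle_mixture <- function(weights, means, kappas) {
  means <- rbind(means); kappas <- rbind(kappas)
  if (!all(dim(means) == dim(kappas)) || length(weights) != nrow(means)) {
    stop("weights, means and kappas have inconsistent shapes", call. = FALSE)
  }
  if (any(weights <= 0) || abs(sum(weights) - 1) > 1e-12) {
    stop("weights must be positive and sum to 1", call. = FALSE)
  }
  if (any(kappas <= 0)) stop("kappas must be positive", call. = FALSE)
  structure(list(weights = weights, means = means, kappas = kappas,
                 dim = ncol(means)), class = "AngleMixture")
}

#' Fix the random seed of the conformational sampler
#'
#' All subsequent sampling becomes a deterministic function of the seed
#' (the sampler draws from R's global random number stream). Calling with
#' `NULL` re-seeds from entropy.
#'
#' @param seed an integer seed, or `NULL` for random seeding.
#' @return invisibly, the seed.
#' @examples
#' set_seed(42)
#' @export
set_seed <- function(seed) {
  if (is.null(seed)) {
    set.seed(NULL)
  } else {
    set.seed(as.integer(seed))
  }
  invisible(seed)
}

# von Mises sampler, Best & Fisher (1979) wrapped-Cauchy rejection envelope.
# mu in degrees, kappa >= 0; vectorized over n; uses R's global RNG stream.
.rvonmises <- function(n, mu, kappa) {
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-8) return(stats::runif(n, -180, 180))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  pending <- seq_len(n)
  while (length(pending)) {
    m <- length(pending)
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3 - 0.5) * acos(pmax(-1, pmin(1, f)))
    out[pending[ok]] <- theta[ok]
    pending <- pending[!ok]
  }
  wrap_angle(mu + out * .rad2deg)
}

# log density (per radian) of a single von Mises component at x (degrees)
.lvm <- function(x, mu, kappa) {
  kappa * cos((x - mu) * .deg2rad) - log(2 * pi) -
    log(besselI(kappa, 0, expon.scaled = TRUE)) - kappa
}

#' Evaluate a von Mises mixture density
#'
#' The density is the weighted sum over components of products of univariate
#' von Mises densities, expressed per radian in every dimension, so it
#' integrates to 1 over the d-dimensional torus (in radians). Angles are
#' supplied in degrees.
#'
#' @param model an `AngleMixture`.
#' @param angles numeric vector of angles in degrees, one per model dimension.
#' @param log if `TRUE` return the log density.
#' @return the (log) probability density.
#' @export
mixture_density <- function(model, angles, log = FALSE) {
  if (!inherits(model, "AngleMixture")) stop("model must be an AngleMixture",
                                             call. = FALSE)
  if (length(angles) != model$dim) {
    stop("angle vector has dimension ", length(angles), ", model expects ",
         model$dim, call. = FALSE)
  }
  comp_ll <- vapply(seq_along(model$weights), function(j) {
    sum(.lvm(angles, model$means[j, ], model$kappas[j, ]))
  }, 0)
  m <- max(comp_ll)
  ll <- m + log(sum(model$weights * exp(comp_ll - m)))
  if (log) ll else exp(ll)
}

# draw one vector from a mixture; returns list(angles, component)
.sample_mixture <- function(model, weights = model$weights) {
  j <- sample.int(length(weights), 1L, prob = weights)
  ang <- vapply(seq_len(model$dim), function(d) {
    .rvonmises(1L, model$means[j, d], model$kappas[j, d])
  }, 0)
  list(angles = ang, component = j)
}

#' Draw many vectors from an angle mixture
#'
#' Vectorized sampling used for distributional checks and large conformer
#' ensembles; each row is one draw in degrees.
#'
#' @param model an `AngleMixture`.
#' @param n number of draws.
#' @return an `n` x `dim` matrix of angles in degrees.
#' @export
sample_angles <- function(model, n) {
  if (!inherits(model, "AngleMixture")) stop("model must be an AngleMixture",
                                             call. = FALSE)
  comp <- sample.int(length(model$weights), n, replace = TRUE,
                     prob = model$weights)
  out <- matrix(NA_real_, n, model$dim)
  for (j in seq_along(model$weights)) {
    idx <- which(comp == j)
    if (!length(idx)) next
    for (d in seq_len(model$dim)) {
      out[idx, d] <- .rvonmises(length(idx), model$means[j, d],
                                model$kappas[j, d])
    }
  }
  out
}

#' Default mixture models shipped with the package
#'
#' @param code a one-letter amino-acid code.
#' @return the backbone (phi, psi) `AngleMixture` for `code`, or the chi
#'   mixture (`NULL` for residues without controllable side chains).
#' @export
backbone_mixture <- function(code) .get_mixture("backbone", toupper(code))

#' @rdname backbone_mixture
#' @export
chi_mixture <- function(code) .get_mixture("chi", toupper(code))

# classify a (phi, psi) pair into the backbone basin with the highest
# posterior component probability; returns the component index
.bb_basin <- function(code, bb) {
  mx <- .get_mixture("backbone", code)
  post <- vapply(seq_along(mx$weights), function(j) {
    log(mx$weights[j]) + sum(.lvm(bb, mx$means[j, ], mx$kappas[j, ]))
  }, 0)
  which.max(post)
}

# backbone-dependent re-weighting of chi components: in the alpha basin the
# gauche- (chi1 = -60) rotamer is favoured, in beta/extended basins trans;
# other basins leave the weights untouched. A deliberately simple stand-in
# for a learned joint model.
.bb_boost <- 2
.reweight_chi <- function(model, code, bb) {
  basin <- .bb_basin(code, bb)
  mx <- .get_mixture("backbone", code)
  basin_phi <- mx$means[basin, 1L]; basin_psi <- mx$means[basin, 2L]
  w <- model$weights
  chi1 <- wrap_angle(model$means[, 1L])
  if (basin_psi < 45 && basin_phi < 0) {            # alpha-like basin
    w[abs(chi1 + 60) < 30] <- w[abs(chi1 + 60) < 30] * .bb_boost
  } else if (basin_phi < 0) {                       # beta/extended basin
    w[abs(abs(chi1) - 180) < 30] <- w[abs(abs(chi1) - 180) < 30] * .bb_boost
  }
  w / sum(w)
}

#' Sample and set backbone torsions of one residue
#'
#' Draws a (phi, psi) pair from the residue type's backbone mixture, applies
#' it to the peptide and returns both. For proline only psi is applied (its
#' phi is ring-locked); the returned phi is the measured ring value.
#'
#' @param pep a `Peptide`.
#' @param res 1-based residue index.
#' @return a list with `peptide` (the updated `Peptide`) and `angles`
#'   (the sampled `c(phi, psi)` in degrees).
#' @export
sample_bb_angles <- function(pep, res) {
  res <- .check_res(pep, res)
  code <- pep$residues[res]
  draw <- .sample_mixture(.get_mixture("backbone", code))
  ang <- draw$angles
  if (code == "P") {
    k <- .torsion_row(pep, res, "psi")
    pep <- .apply_torsion(pep, k, ang[2L])
    ang[1L] <- get_bb_angles(pep, res)[["phi"]]
  } else {
    pep <- set_bb_angles(pep, res, ang)
  }
  list(peptide = pep, angles = ang)
}

#' Sample and set side-chain torsions of one residue
#'
#' Draws a chi vector from the residue type's rotamer mixture and applies it.
#' In the default backbone-dependent mode the component weights are first
#' re-weighted by the residue's current backbone basin. Residues without
#' controllable side-chain torsions (glycine, alanine, proline) return an
#' empty vector.
#'
#' @param pep a `Peptide`.
#' @param res 1-based residue index.
#' @param bb_dependent re-weight rotamer components by the current backbone
#'   conformation (default `TRUE`).
#' @return a list with `peptide` and `angles` (possibly length 0).
#' @export
sample_chi_angles <- function(pep, res, bb_dependent = TRUE) {
  res <- .check_res(pep, res)
  code <- pep$residues[res]
  model <- .get_mixture("chi", code)
  if (is.null(model)) {
    return(list(peptide = pep, angles = numeric(0)))
  }
  w <- model$weights
  if (bb_dependent) {
    bb <- get_bb_angles(pep, res)[1:2]
    if (!anyNA(bb)) w <- .reweight_chi(model, code, bb)
  }
  draw <- .sample_mixture(model, weights = w)
  pep <- set_chi_angles(pep, res, draw$angles)
  list(peptide = pep, angles = draw$angles)
}

#' Draw a backbone/side-chain sample with its log-likelihood
#'
#' Samples (phi, psi) from the residue type's backbone mixture, then a chi
#' vector from the rotamer mixture conditioned on the sampled backbone basin,
#' without building a peptide. The returned `ll` is the exact log joint
#' density (per radian in every dimension) of the returned angles under the
#' sampling model: log p(phi, psi) + log p(chi | backbone basin).
#'
#' @param residue_type a one-letter amino-acid code.
#' @return a list with `chi` (numeric, possibly length 0), `bb`
#'   (`c(phi, psi)`) and `ll` (log-likelihood).
#' @examples
#' set_seed(42)
#' s <- get_sample("L")
#' @export
get_sample <- function(residue_type) {
  code <- toupper(residue_type)
  if (!code %in% names(.aa1to3)) {
    stop("unknown amino-acid code: '", residue_type, "'", call. = FALSE)
  }
  bbm <- .get_mixture("backbone", code)
  bb <- .sample_mixture(bbm)$angles
  ll <- mixture_density(bbm, bb, log = TRUE)
  chim <- .get_mixture("chi", code)
  chi <- numeric(0)
  if (!is.null(chim)) {
    w <- .reweight_chi(chim, code, bb)
    chi <- .sample_mixture(chim, weights = w)$angles
    cond <- angle_mixture(w, chim$means, chim$kappas)
    ll <- ll + mixture_density(cond, chi, log = TRUE)
  }
  list(chi = chi, bb = bb, ll = ll)
}
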