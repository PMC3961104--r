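# Vector geometry: torsion measurement, internal-coordinate atom placement
# (NeRF) and rigid rotation of a molecular branch about a bond.
#
# All user-facing angles are degrees; radians appear only inside functions.
# Torsions are kept in the canonical range [-180, 180): -180 is canonical,
# +180 wraps to -180.

.deg2rad <- pi / 180
.rad2deg <- 180 / pi

# Reference triples are rejected as collinear when the sine of their angle
# falls below this value.
.collinear_tol <- 1e-8

#' Wrap an angle into the canonical torsion range
#'
#' Reduces any angle in degrees modulo 360 into `[-180, 180)`. `-180` is the
#' canonical representation of the trans torsion; `+180` wraps to `-180`.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of the same length in `[-180, 180)`.
#' @examples
#' wrap_angle(c(280, 180, -180, 540))
#' @export
wrap_angle <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)
  # floor() rounding can land exactly on +180 for inputs like 180 - 1e-14
  w[w >= 180] <- -180
  w
}

.cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

.norm3 <- function(u) sqrt(sum(u * u))

.check_point <- function(p, what) {
  if (!is.numeric(p) || length(p) != 3L || any(!is.finite(p))) {
    stop(what, " must be a finite numeric vector of length 3", call. = FALSE)
  }
  as.numeric(p)
}

#' Measure a torsion angle from four points
#'
#' Returns the dihedral angle defined by `p1-p2-p3-p4` using the IUPAC sign
#' convention: looking from `p2` towards `p3`, a clockwise rotation carrying
#' the projection of `p1` onto the projection of `p4` is positive. The result
#' is in degrees, canonically wrapped into `[-180, 180)`.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates in Angstrom.
#' @return a single torsion value in degrees.
#' @examples
#' measure_dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0, 1)) # +90
#' @export
measure_dihedral <- function(p1, p2, p3, p4) {
  p1 <- .check_point(p1, "p1"); p2 <- .check_point(p2, "p2")
  p3 <- .check_point(p3, "p3"); p4 <- .check_point(p4, "p4")
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  l1 <- .norm3(b1); l2 <- .norm3(b2); l3 <- .norm3(b3)
  if (l1 == 0 || l2 == 0 || l3 == 0) {
    stop("degenerate torsion: two consecutive points coincide", call. = FALSE)
  }
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (.norm3(n1) / (l1 * l2) < .collinear_tol ||
      .norm3(n2) / (l2 * l3) < .collinear_tol) {
    stop("degenerate torsion: collinear reference points", call. = FALSE)
  }
  y <- sum(.cross3(n1, n2) * b2) / l2
  x <- sum(n1 * n2)
  wrap_angle(atan2(y, x) * .rad2deg)
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Natural Extension Reference Frame placement: given three previously placed
#' reference points `a`, `b`, `c`, returns the point `d` at distance `r` from
#' `c`, with bond angle `theta` = angle(b, c, d) and torsion `tau` =
#' `measure_dihedral(a, b, c, d)`.
#'
#' @param a,b,c numeric length-3 reference coordinates (Angstrom).
#' @param r bond length `c`--`d` in Angstrom, must be positive.
#' @param theta bond angle in degrees, strictly between 0 and 180.
#' @param tau torsion angle in degrees (any value; wrapped canonically).
#' @return numeric length-3 coordinates of the placed atom.
#' @export
place_atom <- function(a, b, c, r, theta, tau) {
  a <- .check_point(a, "a"); b <- .check_point(b, "b"); c <- .check_point(c, "c")
  if (!is.finite(r) || r <= 0) stop("bond length r must be positive", call. = FALSE)
  if (!is.finite(theta) || theta <= 0 || theta >= 180) {
    stop("bond angle theta must lie strictly between 0 and 180 degrees",
         call. = FALSE)
  }
  bc <- c - b
  ab <- b - a
  lbc <- .norm3(bc)
  if (lbc == 0 || .norm3(ab) == 0) {
    stop("degenerate reference frame: coincident reference points", call. = FALSE)
  }
  u <- bc / lbc
  n <- .cross3(ab, bc)
  ln <- .norm3(n)
  if (ln / (.norm3(ab) * lbc) < .collinear_tol) {
    stop("degenerate reference frame: collinear reference points", call. = FALSE)
  }
  n <- n / ln
  m <- .cross3(n, u)
  th <- theta * .deg2rad
  ta <- tau * .deg2rad
  # local displacement in the (u, m, n) frame; the sign pattern reproduces the
  # IUPAC convention of measure_dihedral (verified by round-trip tests)
  d_local <- r * c(-cos(th), sin(th) * cos(ta), sin(th) * sin(ta))
  c + d_local[1L] * u + d_local[2L] * m + d_local[3L] * n
}

#' Rigidly rotate a branch of atoms about a bond
#'
#' Rotates the atoms listed in `branch` by `delta` degrees about the axis
#' through atoms `i` and `j` (direction `i` to `j`). The sign convention is
#' chosen so that a torsion measured across the `i`--`j` bond with its distal
#' atom inside `branch` increases by exactly `delta` (mod 360). All other
#' atoms are unchanged, and all interatomic distances within the branch are
#' preserved (rigid rotation).
#'
#' @param coords numeric matrix with one row per atom and 3 columns.
#' @param i,j 1-based row indices of the pivot and axis atoms; must differ
#'   and must not be members of `branch`.
#' @param branch integer vector of 1-based row indices to rotate.
#' @param delta rotation in degrees.
#' @return the coordinate matrix with the branch rotated.
#' @export
rotate_branch <- function(coords, i, j, branch, delta) {
  if (!is.matrix(coords) || ncol(coords) != 3L) {
    stop("coords must be an n x 3 matrix", call. = FALSE)
  }
  if (i == j) stop("pivot and axis atoms must differ", call. = FALSE)
  if (any(branch == i) || any(branch == j)) {
    stop("branch must not contain the axis atoms", call. = FALSE)
  }
  axis <- coords[j, ] - coords[i, ]
  la <- .norm3(axis)
  if (la == 0) stop("zero-length rotation axis", call. = FALSE)
  if (length(branch) == 0L || delta %% 360 == 0) return(coords)
  k <- axis / la
  # Rodrigues rotation. A right-handed rotation by +delta about the i->j
  # direction increases the measured i-side -> j-side torsion by +delta under
  # the IUPAC convention used in measure_dihedral.
  ang <- delta * .deg2rad
  ca <- cos(ang); sa <- sin(ang)
  p <- sweep(coords[branch, , drop = FALSE], 2L, coords[i, ])
  cross <- cbind(k[2L] * p[, 3L] - k[3L] * p[, 2L],
                 k[3L] * p[, 1L] - k[1L] * p[, 3L],
                 k[1L] * p[, 2L] - k[2L] * p[, 1L])
  kdotp <- as.numeric(p %*% k)
  rot <- p * ca + cross * sa + outer(kdotp, k) * (1 - ca)
  coords[branch, ] <- sweep(rot, 2L, coords[i, ], "+")
  coords
}
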