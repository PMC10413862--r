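# Internal vector geometry on 3-vectors / N x 3 coordinate matrices.
# All distances Angstrom, all angles returned in degrees unless noted.

.vnorm <- function(v) sqrt(sum(v * v))

.deg <- function(rad) rad * 180 / pi
.rad <- function(deg) deg * pi / 180

#' Distance, angle and dihedral from Cartesian coordinates
#'
#' Elementary internal-coordinate measurements used throughout restraint
#' selection and fixture construction. Angles are returned in degrees;
#' dihedrals follow the IUPAC sign convention and lie in (-180, 180].
#'
#' @param a,b,c,d Numeric 3-vectors (Angstrom).
#' @return A single numeric value: distance in Angstrom or angle in degrees.
#' @examples
#' coord_distance(c(0, 0, 0), c(3, 4, 0))  # 5
#' coord_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))  # 90
#' @export
coord_distance <- function(a, b) .vnorm(b - a)

#' @rdname coord_distance
#' @export
coord_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / (.vnorm(u) * .vnorm(v))
  .deg(acos(max(-1, min(1, cosang))))
}

#' @rdname coord_distance
#' @export
coord_dihedral <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- c(
    b1[2] * b2[3] - b1[3] * b2[2],
    b1[3] * b2[1] - b1[1] * b2[3],
    b1[1] * b2[2] - b1[2] * b2[1]
  )
  n2 <- c(
    b2[2] * b3[3] - b2[3] * b3[2],
    b2[3] * b3[1] - b2[1] * b3[3],
    b2[1] * b3[2] - b2[2] * b3[1]
  )
  m1 <- c(
    n1[2] * b2[3] - n1[3] * b2[2],
    n1[3] * b2[1] - n1[1] * b2[3],
    n1[1] * b2[2] - n1[2] * b2[1]
  ) / .vnorm(b2)
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- .deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Place an atom from internal coordinates
#'
#' NeRF-style construction: returns the position of an atom at given bond
#' length from `c`, bond angle at `c` relative to `b`, and dihedral about the
#' b-c axis relative to `a`. Used by the ideal-helix and toy-ligand builders.
#'
#' @param a,b,c Numeric 3-vectors of the three preceding atoms (Angstrom).
#' @param bond Bond length c-new (Angstrom).
#' @param angle Bond angle b-c-new (degrees).
#' @param dihedral Dihedral a-b-c-new (degrees).
#' @return Numeric 3-vector.
#' @export
place_atom <- function(a, b, c, bond, angle, dihedral) {
  theta <- .rad(angle)
  phi <- .rad(dihedral)
  bc <- c - b
  bc <- bc / .vnorm(bc)
  ab <- b - a
  n <- c(
    ab[2] * bc[3] - ab[3] * bc[2],
    ab[3] * bc[1] - ab[1] * bc[3],
    ab[1] * bc[2] - ab[2] * bc[1]
  )
  n <- n / .vnorm(n)
  m <- c(
    n[2] * bc[3] - n[3] * bc[2],
    n[3] * bc[1] - n[1] * bc[3],
    n[1] * bc[2] - n[2] * bc[1]
  )
  d2 <- c(
    -bond * cos(theta),
    bond * sin(theta) * cos(phi),
    -bond * sin(theta) * sin(phi)
  )
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Circular mean of angles
#'
#' Mean direction of a sample of angles in degrees, reported in (-180, 180].
#'
#' @param deg Numeric vector of angles (degrees).
#' @return Circular mean in degrees.
#' @export
circular_mean <- function(deg) {
  stopifnot(length(deg) >= 1)
  r <- .rad(deg)
  ang <- .deg(atan2(mean(sin(r)), mean(cos(r))))
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Squared circular spread of an angle series
#'
#' Squared circular standard deviation, `(-2 ln Rbar) * (180/pi)^2` in deg^2,
#' where `Rbar` is the mean resultant length. Invariant under rotation of all
#' angles by a constant and under 360-degree wrapping. Used to reject
#' restraint candidates whose angle or dihedral fluctuates too much over an
#' equilibration trajectory.
#'
#' @param deg Numeric vector of angles (degrees), length >= 2.
#' @return Spread in squared degrees.
#' @export
circular_spread <- function(deg) {
  if (length(deg) < 1) stop("empty angle series")
  if (length(deg) < 2) stop("circular spread needs at least 2 samples")
  r <- .rad(deg)
  rbar <- sqrt(mean(cos(r))^2 + mean(sin(r))^2)
  rbar <- min(rbar, 1)
  (-2 * log(rbar)) * (180 / pi)^2
}

# Kabsch least-squares superposition: returns rotation R and translation so
# that mobile %*% R + t approximates fixed. Row-wise N x 3 matrices.
.kabsch <- function(fixed, mobile) {
  cf <- colMeans(fixed)
  cm <- colMeans(mobile)
  A <- t(sweep(mobile, 2, cm)) %*% sweep(fixed, 2, cf)
  s <- svd(A)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(R = R, center_mobile = cm, center_fixed = cf)
}

# Apply a .kabsch fit to an N x 3 coordinate matrix.
.apply_fit <- function(xyz, fit) {
  sweep(sweep(xyz, 2, fit$center_mobile) %*% fit$R, 2, fit$center_fixed, "+")
}
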