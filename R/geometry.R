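## Rigid-body geometry: Kabsch superposition, dihedrals, axis rotations.
## Coordinates are n x 3 matrices in Angstrom; angles are degrees at the
## interface and radians internally.

DEG <- pi / 180

#' Weighted least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation that minimise the weighted rmsd
#' between two paired point sets. Reflections are forbidden (the determinant
#' of the rotation is corrected to +1) so chirality is always preserved.
#'
#' @param src n x 3 matrix of source points (Angstrom).
#' @param dst n x 3 matrix of target points, row-paired with `src`.
#' @param weights optional non-negative weights, one per pair.
#' @return A `rigid_transform`: list with `R` (3 x 3 proper rotation), `t`
#'   (length-3 translation), `rmsd` (weighted, Angstrom) and
#'   `underdetermined` (TRUE when fewer than 3 pairs, or collinear input,
#'   leave the rotation non-unique). Apply with [apply_transform()]:
#'   `x %*% t(R) + t`.
#' @export
kabsch_fit <- function(src, dst, weights = NULL) {
  src <- rbind(src); dst <- rbind(dst)
  n <- nrow(src)
  if (n < 1L || nrow(dst) != n)
    stop("kabsch_fit: need at least one point pair, equal counts")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0))
    stop("kabsch_fit: bad weights")
  w <- weights / sum(weights)
  cs <- colSums(src * w); cd <- colSums(dst * w)
  s0 <- sweep(src, 2, cs); d0 <- sweep(dst, 2, cd)
  H <- t(s0 * w) %*% d0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tvec <- cd - as.vector(R %*% cs)
  fit <- sweep(src %*% t(R), 2, tvec, "+")
  rmsd <- sqrt(sum(w * rowSums((fit - dst)^2)))
  # under-determined: < 3 pairs or (near-)collinear source points
  under <- n < 3L
  if (!under) {
    s2 <- svd(s0, nu = 0, nv = 0)$d
    under <- s2[2] < 1e-8
  }
  structure(list(R = R, t = tvec, rmsd = rmsd, underdetermined = under),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param coords n x 3 matrix.
#' @param tf a `rigid_transform` from [kabsch_fit()] or [rotation_about_axis()].
#' @export
apply_transform <- function(coords, tf) {
  sweep(rbind(coords) %*% t(tf$R), 2, tf$t, "+")
}

#' Compose two rigid transforms (apply `a` first, then `b`)
#' @keywords internal
compose_transform <- function(b, a) {
  structure(list(R = b$R %*% a$R, t = as.vector(b$R %*% a$t) + b$t,
                 rmsd = NA_real_, underdetermined = FALSE),
            class = "rigid_transform")
}

identity_transform <- function() {
  structure(list(R = diag(3), t = c(0, 0, 0), rmsd = 0,
                 underdetermined = FALSE), class = "rigid_transform")
}

#' Rotation about an arbitrary axis through a point
#'
#' Rodrigues rotation by `angle_deg` about the axis from `p1` to `p2`.
#' @keywords internal
rotation_about_axis <- function(p1, p2, angle_deg) {
  u <- p2 - p1
  nu <- sqrt(sum(u^2))
  if (nu < 1e-12) stop("rotation_about_axis: degenerate axis")
  u <- u / nu
  th <- angle_deg * DEG
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  tvec <- p1 - as.vector(R %*% p1)
  structure(list(R = R, t = tvec, rmsd = NA_real_, underdetermined = FALSE),
            class = "rigid_transform")
}

## Euler rotations: intrinsic x-y-z about a centre (used by rigid-body
## chromosome terms).
euler_xyz_transform <- function(angles_deg, centre = c(0, 0, 0),
                                translation = c(0, 0, 0)) {
  a <- angles_deg * DEG
  Rx <- matrix(c(1, 0, 0, 0, cos(a[1]), sin(a[1]), 0, -sin(a[1]), cos(a[1])), 3, 3)
  Ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0, sin(a[2]), 0, cos(a[2])), 3, 3)
  Rz <- matrix(c(cos(a[3]), sin(a[3]), 0, -sin(a[3]), cos(a[3]), 0, 0, 0, 1), 3, 3)
  R <- Rz %*% Ry %*% Rx
  tvec <- centre - as.vector(R %*% centre) + translation
  structure(list(R = R, t = tvec, rmsd = NA_real_, underdetermined = FALSE),
            class = "rigid_transform")
}

#' Measure a dihedral angle
#'
#' @param coords n x 3 coordinate matrix.
#' @param quartet four 1-based atom indices a-b-c-d.
#' @return Angle in degrees in (-180, 180].
#' @export
measure_torsion <- function(coords, quartet) {
  p <- coords[quartet, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) / DEG
  if (ang <= -180) ang <- ang + 360
  ang
}

## Smallest absolute angular difference on the circle, degrees.
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}

## Circular interval membership: is angle within [min, max] walking
## counter-clockwise from min to max (degrees, interval may wrap)?
ang_in_range <- function(angle, min_deg, max_deg) {
  span <- (max_deg - min_deg) %% 360
  off <- (angle - min_deg) %% 360
  off <= span + 1e-9
}
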