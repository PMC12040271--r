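# Internal vector geometry shared by the dihedral, superposition and
# backbone-building code.  All coordinates are row-vector matrices (T x 3).

cross3 <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

dot3 <- function(a, b) rowSums(a * b)

vnorm3 <- function(a) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  sqrt(rowSums(a * a))
}

unit3 <- function(a) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  a / vnorm3(a)
}

#' Torsion angle of four points
#'
#' Signed dihedral about the b-c axis, IUPAC convention, in radians in
#' (-pi, pi].  Inputs may be single xyz vectors or T x 3 matrices (one row
#' per frame); vectorised over frames.
#'
#' @param p1,p2,p3,p4 numeric xyz vectors or T x 3 matrices.
#' @return numeric vector of length T.
#' @keywords internal
#' @noRd
torsion_angle <- function(p1, p2, p3, p4) {
  as3 <- function(p) if (is.null(dim(p))) matrix(p, nrow = 1) else p
  p1 <- as3(p1); p2 <- as3(p2); p3 <- as3(p3); p4 <- as3(p4)
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit3(b2))
  ang <- atan2(dot3(m1, n2), dot3(n1, n2))
  # canonicalize the branch point: trans is +pi, never -pi
  ang[ang <= -pi + 1e-12] <- pi
  ang
}

# Place atom D bonded to C given the frame (A, B, C), bond length r (C-D),
# bond angle theta (B-C-D, radians) and torsion chi (A-B-C-D, radians).
# Standard internal-to-Cartesian (NeRF) construction.
place_atom <- function(A, B, C, r, theta, chi) {
  bc <- unit3(C - B)
  n <- unit3(cross3(B - A, bc))
  m <- cross3(n, bc)
  d2 <- c(-r * cos(theta), r * sin(theta) * cos(chi), -r * sin(theta) * sin(chi))
  as.numeric(C) + d2[1] * as.numeric(bc) + d2[2] * as.numeric(m) + d2[3] * as.numeric(n)
}

# A unit vector perpendicular to u (robust to any orientation): cross u
# with the coordinate axis it is least aligned with.
perp_unit <- function(u) {
  u <- as.numeric(unit3(u))
  e <- diag(3)[, which.min(abs(u))]
  as.numeric(unit3(cross3(u, e)))
}

# Rodrigues rotation matrix from a rotation vector (axis * angle).
rotvec_to_matrix <- function(w) {
  th <- sqrt(sum(w * w))
  if (th < 1e-14) return(diag(3))
  k <- w / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Uniform-ish random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
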