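# Low-level 3D geometry helpers shared across the package. All coordinates
# are plain numeric vectors/matrices in Angstroms; rotations are 3x3 proper
# orthonormal matrices acting on row vectors as x %*% t(R) + t.

vecNorm <- function(v) sqrt(sum(v * v))

unitVec <- function(v) {
  n <- vecNorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

crossProd3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Angle between two vectors in degrees, in [0, 180].
vecAngle <- function(a, b) {
  ca <- sum(unitVec(a) * unitVec(b))
  acos(max(-1, min(1, ca))) * 180 / pi
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Rotation matrix about an arbitrary unit axis (Rodrigues formula).
rotationAboutAxis <- function(axis, angleDeg) {
  u <- unitVec(axis)
  th <- deg2rad(angleDeg)
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Apply a rigid motion to an n x 3 coordinate matrix.
applyRigid <- function(xyz, rotation, translation = c(0, 0, 0)) {
  sweep(xyz %*% t(rotation), 2, -translation)
}

# Kabsch least-squares superposition of P onto Q (both n x 3).
# Returns rotation R and translation t with R %*% p + t ~ q, plus the rmsd.
kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3)
  if (nrow(P) < 3) stop("superposition requires at least 3 points")
  cp <- colMeans(P)
  cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp)
  Q0 <- sweep(Q, 2, cq)
  # guard against degenerate (collinear) point sets
  sv <- svd(P0)$d
  if (sv[2] < 1e-8 * max(sv[1], 1)) stop("degenerate (collinear) point set")
  H <- t(P0) %*% Q0
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t <- cq - as.vector(R %*% cp)
  Pfit <- sweep(P %*% t(R), 2, -t)
  rmsd <- sqrt(mean(rowSums((Pfit - Q)^2)))
  list(rotation = R, translation = t, rmsd = rmsd)
}

# Axis-angle decomposition of a proper rotation. Returns the rotation axis
# (unit vector, arbitrary sign for 180 deg) and angle in [0, 180] degrees.
rotationAxisAngle <- function(R) {
  tr <- sum(diag(R))
  ca <- max(-1, min(1, (tr - 1) / 2))
  angle <- acos(ca)
  if (angle < 1e-9) {
    return(list(axis = c(0, 0, 1), angle = 0))
  }
  if (abs(angle - pi) < 1e-6) {
    # 180 degrees: axis from the symmetric part
    B <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(B), 0))
    # fix signs using off-diagonals
    i <- which.max(ax)
    if (ax[i] > 0) {
      ax <- B[, i] / ax[i]
    }
    return(list(axis = unitVec(ax), angle = 180))
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(angle))
  list(axis = unitVec(ax), angle = rad2deg(angle))
}

# Screw decomposition of a rigid transform (R, t): translation component
# along the rotation axis. For the identity rotation the full |t| is reported
# as screw translation along t itself.
screwDecompose <- function(rotation, translation) {
  aa <- rotationAxisAngle(rotation)
  if (aa$angle == 0) {
    n <- vecNorm(translation)
    return(list(axis = if (n > 1e-12) translation / n else c(0, 0, 1),
                angle = 0, screw = n))
  }
  list(axis = aa$axis, angle = aa$angle,
       screw = sum(translation * aa$axis))
}

# NeRF (natural extension reference frame) atom placement: position atom D
# given positions A, B, C, the bond length |C-D|, the bond angle B-C-D (deg)
# and the torsion A-B-C-D (deg).
nerfPlace <- function(A, B, C, bond, angleDeg, torsionDeg) {
  th <- deg2rad(angleDeg)
  ph <- deg2rad(torsionDeg)
  bc <- unitVec(C - B)
  n <- unitVec(crossProd3(B - A, bc))
  m <- crossProd3(n, bc)
  d <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# Torsion angle A-B-C-D in degrees, signed in (-180, 180].
torsionAngle <- function(A, B, C, D) {
  b1 <- B - A
  b2 <- C - B
  b3 <- D - C
  n1 <- crossProd3(b1, b2)
  n2 <- crossProd3(b2, b3)
  m1 <- crossProd3(n1, unitVec(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  rad2deg(atan2(y, x))
}

# Pairwise squared distances between two n x 3 and m x 3 matrices.
crossDist2 <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * (A %*% t(B))
  d2[d2 < 0] <- 0
  d2
}
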