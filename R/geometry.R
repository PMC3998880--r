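# Internal geometry helpers: values and Cartesian gradients of the internal
# coordinates entering the four-term potential, plus rigid-body utilities.
# Gradient formulas are the standard ones for bond/angle/torsion internal
# coordinates; all are cross-checked against finite differences in the tests.

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n == 0) stop("zero-length vector has no direction")
  v / n
}

.cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Distance between nodes i and j with gradient wrt (xi, xj).
.bond_geom <- function(xi, xj) {
  d <- xi - xj
  r <- .vnorm(d)
  if (r == 0) stop("coincident nodes in bond term")
  u <- d / r
  list(value = r, gi = u, gj = -u)
}

# Angle at j spanned by (i, j, k).  Near-collinear geometries (sin theta ~ 0)
# have an ill-defined gradient direction; they return zero gradients so that
# degenerate fixtures (straight bead chains) remain usable with the angular
# term switched off.
.angle_geom <- function(xi, xj, xk, tol = 1e-8) {
  rij <- xi - xj
  rkj <- xk - xj
  nij <- .vnorm(rij)
  nkj <- .vnorm(rkj)
  uij <- rij / nij
  ukj <- rkj / nkj
  ct <- max(-1, min(1, sum(uij * ukj)))
  th <- acos(ct)
  st <- sqrt(max(0, 1 - ct * ct))
  if (st < tol) {
    z <- c(0, 0, 0)
    return(list(value = th, gi = z, gj = z, gk = z, degenerate = TRUE))
  }
  gi <- (ct * uij - ukj) / (nij * st)
  gk <- (ct * ukj - uij) / (nkj * st)
  list(value = th, gi = gi, gj = -(gi + gk), gk = gk, degenerate = FALSE)
}

# Torsion for the quadruple (i, j, k, l) with gradients wrt all four nodes.
.dihedral_geom <- function(xi, xj, xk, xl, tol = 1e-10) {
  b1 <- xj - xi
  b2 <- xk - xj
  b3 <- xl - xk
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  nb2 <- .vnorm(b2)
  m1 <- .cross(n1, b2 / nb2)
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  phi <- atan2(y, x)
  sn1 <- sum(n1 * n1)
  sn2 <- sum(n2 * n2)
  if (sn1 < tol || sn2 < tol) {
    z <- c(0, 0, 0)
    return(list(value = phi, gi = z, gj = z, gk = z, gl = z,
                degenerate = TRUE))
  }
  # chain rule through the three bond vectors:
  # dphi/db1 = -A, dphi/db3 = -B, dphi/db2 = c1 A + c2 B
  A <- nb2 / sn1 * n1
  B <- nb2 / sn2 * n2
  c1 <- sum(b1 * b2) / (nb2 * nb2)
  c2 <- sum(b3 * b2) / (nb2 * nb2)
  gi <- A
  gj <- -(1 + c1) * A - c2 * B
  gk <- c1 * A + (1 + c2) * B
  gl <- -B
  list(value = phi, gi = gi, gj = gj, gk = gk, gl = gl, degenerate = FALSE)
}

# Least-squares rigid superposition (Kabsch).  Returns `mobile` (n x 3)
# fitted onto `fixed` (n x 3).
.kabsch_fit <- function(fixed, mobile) {
  stopifnot(nrow(fixed) == nrow(mobile), ncol(fixed) == 3L)
  cf <- colMeans(fixed)
  cm <- colMeans(mobile)
  A <- sweep(mobile, 2L, cm)
  B <- sweep(fixed, 2L, cf)
  H <- t(A) %*% B
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  fitted <- A %*% t(R)
  sweep(fitted, 2L, cf, FUN = "+")
}

# Deterministic uniformly distributed rotation matrix from a seed.
.random_rotation <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  M <- matrix(stats::rnorm(9), 3, 3)
  q <- qr(M)
  R <- qr.Q(q)
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

# The six rigid-body displacement vectors (3 translations, 3 infinitesimal
# rotations about the centroid) for CA coordinates `xyz` (N x 3), returned as
# an orthonormal 3N x 6 basis.
.rigid_basis <- function(xyz) {
  n <- nrow(xyz)
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2L, ctr)
  B <- matrix(0, 3L * n, 6L)
  for (k in 1:3) B[seq(k, 3L * n, by = 3L), k] <- 1
  ax <- diag(3)
  for (k in 1:3) {
    w <- t(apply(xc, 1L, function(p) .cross(ax[k, ], p)))
    B[, 3L + k] <- as.vector(t(w))
  }
  qr.Q(qr(B))[, 1:6, drop = FALSE]
}
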