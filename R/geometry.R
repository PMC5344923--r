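# Internal 3D geometry helpers shared by hydrogen placement, dihedral
# extraction and the backbone builder. All angles in degrees, lengths in
# Angstrom. Vectors are plain numeric length-3; point sets are n x 3 matrices.

vec_norm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("degenerate zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Signed torsion angle p1-p2-p3-p4 in degrees, in (-180, 180].
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * unit_vec(b2))
  ang <- rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

# Natural extension reference frame (NeRF): place atom D given positions of
# A-B-C, the bond length C-D, bond angle B-C-D and torsion A-B-C-D.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  d_local <- c(-bond * cos(ang),
               bond * sin(ang) * cos(tor),
               bond * sin(ang) * sin(tor))
  bc <- unit_vec(c - b)
  n <- unit_vec(cross3(b - a, bc))
  m <- cross3(n, bc)
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

# Rotate rows of `points` by `angle` degrees about the axis through `origin`
# with direction `axis` (right-hand rule), via Rodrigues' formula.
rotate_about_axis <- function(points, origin, axis, angle) {
  k <- unit_vec(axis)
  theta <- deg2rad(angle)
  p <- sweep(points, 2, origin)
  kx <- p %*% rbind(c(0, k[3], -k[2]), c(-k[3], 0, k[1]), c(k[2], -k[1], 0))
  kdp <- as.vector(p %*% k)
  rot <- p * cos(theta) + kx * sin(theta) + outer(kdp, k) * (1 - cos(theta))
  sweep(rot, 2, origin, FUN = "+")
}

# Orthonormal residue frame from backbone N, CA, C: columns are the frame
# axes, origin at CA. Used to carry side chains rigidly between backbones.
residue_frame <- function(n, ca, c) {
  x <- unit_vec(n - ca)
  z <- unit_vec(cross3(x, c - ca))
  y <- cross3(z, x)
  cbind(x, y, z)
}

# Ideal backbone geometry (Engh-Huber-like values) used by the builder and
# by rebuild_conformation.
IDEAL_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_n_h = 1.01, b_ca_cb = 1.521,
  a_c_n_ca = 121.7, a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_ca_c_o = 120.8
)
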