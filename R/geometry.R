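# Low-level 3-D geometry: internal-coordinate atom placement (NeRF),
# rotations, and the deterministic sphere point set used for SASA.

# Place atom D given positions of A-B-C, bond length |CD|, angle B-C-D
# (degrees) and dihedral A-B-C-D (degrees).  Standard NeRF construction.
.place_atom <- function(a, b, c, length, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- .cross3(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) {
    # A,B,C collinear: any perpendicular will do; dihedral is degenerate
    ref <- if (abs(bc[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n <- .cross3(ref, bc)
    nn <- sqrt(sum(n^2))
  }
  n <- n / nn
  m <- .cross3(n, bc)
  d2 <- c(-length * cos(ang),
          length * sin(ang) * cos(dih),
          length * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Rotation matrix about a unit axis by theta radians (Rodrigues).
.rotation_matrix <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Deterministic quasi-uniform points on the unit sphere
#'
#' Fibonacci-spiral (golden-angle) lattice: `n` points distributed almost
#' evenly over the sphere, fully deterministic for a given `n`.  Used as the
#' test-point set of the Shrake-Rupley SASA algorithm.
#'
#' @param n Number of points (>= 1).
#' @return An `n x 3` matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)   # golden angle
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Angle A-B-C in degrees.
.angle_deg <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosx <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, cosx))) * 180 / pi
}
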