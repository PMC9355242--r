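# Small internal 3D geometry toolkit shared by the structure and label modules.

vec_norm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180

#' Place an atom from internal coordinates
#'
#' Natural-extension reference frame (NeRF) construction: given three
#' previously placed atoms `a`, `b`, `c`, returns the position `d` such that
#' |c-d| = `bond`, the angle b-c-d equals `angle` and the dihedral
#' a-b-c-d equals `dihedral` (degrees).
#'
#' @param a,b,c numeric 3-vectors, positions in Angstrom.
#' @param bond bond length c-d in Angstrom.
#' @param angle bond angle b-c-d in degrees.
#' @param dihedral dihedral angle a-b-c-d in degrees.
#' @return numeric 3-vector, the new position.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, dihedral) {
  theta <- deg2rad(angle)
  chi <- deg2rad(dihedral)
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(theta), sin(theta) * cos(chi), sin(theta) * sin(chi))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Dihedral angle of four points (degrees, in (-180, 180])
#' @keywords internal
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# All pairwise Euclidean distances between rows of two n x 3 matrices.
cross_dist <- function(xa, xb) {
  a2 <- rowSums(xa^2)
  b2 <- rowSums(xb^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(xa, xb)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
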