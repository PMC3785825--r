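# Internal 3D geometry primitives used by the toy-complex builder and the
# loop sampler. All angles are in degrees at the interface, radians inside.

DEG <- pi / 180

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Place an atom from internal coordinates
#'
#' Natural-extension (NeRF) placement: returns the position `d` such that
#' `|c-d| = bond`, the angle b-c-d equals `angle` and the torsion a-b-c-d
#' equals `torsion`.
#'
#' @param a,b,c numeric 3-vectors, the three previously placed atoms.
#' @param bond bond length c-d in Angstrom.
#' @param angle bond angle b-c-d in degrees.
#' @param torsion dihedral a-b-c-d in degrees.
#' @return numeric 3-vector.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * DEG
  tor <- torsion * DEG
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d <- bond * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  c + d[1L] * bc + d[2L] * m + d[3L] * n
}

#' Dihedral angle of four points, in degrees in (-180, 180]
#' @keywords internal
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) / DEG
}

# Row-wise NeRF placement: A, B, C are n x 3 matrices (or single points
# recycled), `torsion` a length-n vector of degrees; returns the n placed
# points. Vectorized counterpart of place_atom() for candidate batches.
place_atom_rows <- function(A, B, C, bond, angle, torsion) {
  n <- max(nrow(A) %||% 1L, nrow(B) %||% 1L, nrow(C) %||% 1L, length(torsion))
  expand <- function(x) {
    if (is.null(nrow(x))) matrix(x, n, 3L, byrow = TRUE)
    else if (nrow(x) == n) x
    else matrix(x[1L, ], n, 3L, byrow = TRUE)
  }
  A <- expand(A); B <- expand(B); C <- expand(C)
  ang <- angle * DEG
  tor <- torsion * DEG
  bc <- C - B
  bc <- bc / sqrt(rowSums(bc^2))
  ba <- B - A
  nrm <- cbind(ba[, 2L] * bc[, 3L] - ba[, 3L] * bc[, 2L],
               ba[, 3L] * bc[, 1L] - ba[, 1L] * bc[, 3L],
               ba[, 1L] * bc[, 2L] - ba[, 2L] * bc[, 1L])
  nrm <- nrm / sqrt(rowSums(nrm^2))
  m <- cbind(nrm[, 2L] * bc[, 3L] - nrm[, 3L] * bc[, 2L],
             nrm[, 3L] * bc[, 1L] - nrm[, 1L] * bc[, 3L],
             nrm[, 1L] * bc[, 2L] - nrm[, 2L] * bc[, 1L])
  d1 <- -bond * cos(ang)
  d2 <- bond * sin(ang) * cos(tor)
  d3 <- -bond * sin(ang) * sin(tor)
  C + bc * d1 + m * d2 + nrm * d3
}

# Row-wise dihedral (degrees) for four n x 3 matrices.
dihedral_rows <- function(P1, P2, P3, P4) {
  b1 <- P2 - P1; b2 <- P3 - P2; b3 <- P4 - P3
  cr <- function(a, b) cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
                             a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
                             a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  b2u <- b2 / sqrt(rowSums(b2^2))
  m1 <- cr(n1, b2u)
  atan2(rowSums(m1 * n2), rowSums(n1 * n2)) / DEG
}

# Row-wise virtual C-beta direction (unit vectors from CA).
cbeta_direction_rows <- function(N, CA, C) {
  b <- CA - N; c_ <- C - CA
  a <- cbind(b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L],
             b[, 3L] * c_[, 1L] - b[, 1L] * c_[, 3L],
             b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])
  cb <- -0.58273431 * a + 0.56802827 * b - 0.54067466 * c_
  cb / sqrt(rowSums(cb^2))
}

# Rodrigues rotation of a point matrix (n x 3) about a unit axis through an
# origin point, by theta radians.
rotate_points <- function(pts, origin, axis, theta) {
  v <- sweep(pts, 2L, origin)
  ct <- cos(theta)
  st <- sin(theta)
  ux <- axis[1L]; uy <- axis[2L]; uz <- axis[3L]
  uxv <- cbind(uy * v[, 3L] - uz * v[, 2L],
               uz * v[, 1L] - ux * v[, 3L],
               ux * v[, 2L] - uy * v[, 1L])
  udotv <- v %*% axis
  out <- v * ct + uxv * st + (udotv %*% t(axis)) * (1 - ct)
  sweep(out, 2L, origin, "+")
}

# Rotation matrix taking unit vector `from` onto unit vector `to`.
rotation_from_to <- function(from, to) {
  f <- vunit(from)
  t_ <- vunit(to)
  v <- vcross(f, t_)
  s <- vnorm(v)
  c_ <- sum(f * t_)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # opposite vectors: rotate pi about any perpendicular axis
    perp <- if (abs(f[1L]) < 0.9) vunit(vcross(f, c(1, 0, 0))) else vunit(vcross(f, c(0, 1, 0)))
    u <- perp
    return(2 * (u %*% t(u)) - diag(3))
  }
  vx <- matrix(c(0, v[3L], -v[2L], -v[3L], 0, v[1L], v[2L], -v[1L], 0), 3L, 3L)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

# Idealized backbone geometry (Engh-Huber-like values).
BB_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.5
)

#' Build a poly-peptide backbone from phi/psi angles
#'
#' Builds N, CA, C atoms for `n` residues with idealized bond geometry and
#' omega fixed at 180 degrees. Either starts from a seed triad at the origin
#' or continues an existing chain given the previous residue's N/CA/C and the
#' psi angle linking it to the first new residue.
#'
#' @param phi,psi numeric vectors of length `n`, degrees.
#' @param prev optional list(N=, CA=, C=) of the preceding residue.
#' @param psi_prev psi of the preceding residue (degrees); required with `prev`.
#' @return list of `n` lists with elements N, CA, C (3-vectors).
#' @keywords internal
build_backbone <- function(phi, psi, prev = NULL, psi_prev = NULL, omega = 180) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 1L)
  g <- BB_GEOM
  out <- vector("list", n)
  if (is.null(prev)) {
    N1 <- c(0, 0, 0)
    CA1 <- c(g$n_ca, 0, 0)
    C1 <- place_atom(c(0, -1, 0), N1, CA1, g$ca_c, g$ang_n_ca_c, phi[1L] + 120)
    out[[1L]] <- list(N = N1, CA = CA1, C = C1)
    start <- 2L
  } else {
    stopifnot(!is.null(psi_prev))
    Np <- place_atom(prev$N, prev$CA, prev$C, g$c_n, g$ang_ca_c_n, psi_prev)
    CAp <- place_atom(prev$CA, prev$C, Np, g$n_ca, g$ang_c_n_ca, omega)
    Cp <- place_atom(prev$C, Np, CAp, g$ca_c, g$ang_n_ca_c, phi[1L])
    out[[1L]] <- list(N = Np, CA = CAp, C = Cp)
    start <- 2L
  }
  if (n >= start) {
    for (i in start:n) {
      p <- out[[i - 1L]]
      Ni <- place_atom(p$N, p$CA, p$C, g$c_n, g$ang_ca_c_n, psi[i - 1L])
      CAi <- place_atom(p$CA, p$C, Ni, g$n_ca, g$ang_c_n_ca, omega)
      Ci <- place_atom(p$C, Ni, CAi, g$ca_c, g$ang_n_ca_c, phi[i])
      out[[i]] <- list(N = Ni, CA = CAi, C = Ci)
    }
  }
  out
}

# Carbonyl oxygen from the local backbone; `psi` is the torsion
# N-CA-C-N(next) in degrees (O is placed anti to the next amide nitrogen).
place_carbonyl_o <- function(N, CA, C, psi) {
  g <- BB_GEOM
  place_atom(N, CA, C, g$c_o, g$ang_ca_c_o, psi + 180)
}

# Virtual C-beta direction from backbone N, CA, C (standard tetrahedral
# reconstruction); returns a unit vector from CA.
cbeta_direction <- function(N, CA, C) {
  b <- CA - N
  c_ <- C - CA
  a <- vcross(b, c_)
  cb <- -0.58273431 * a + 0.56802827 * b - 0.54067466 * c_
  vunit(cb)
}

# Side-chain pseudo-atom (CEN) distance from CA by residue type; NA for Gly.
CEN_DISTANCE <- c(
  GLY = NA_real_, ALA = 1.5,
  SER = 2.0, THR = 2.0, CYS = 2.0, ASP = 2.0, ASN = 2.0,
  ARG = 2.6, LYS = 2.6, GLU = 2.6, GLN = 2.6, HIS = 2.6, ILE = 2.6,
  LEU = 2.6, MET = 2.6, PHE = 2.6, PRO = 2.6, TRP = 2.6, TYR = 2.6, VAL = 2.6
)

AA_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
AA_1TO3 <- stats::setNames(names(AA_3TO1), AA_3TO1)
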