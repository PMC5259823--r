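# Geometric primitives: dihedral angles and internal-coordinate atom
# placement, used by the secondary-structure assigner and the
# synthetic-structure builder.

vnorm <- function(v) sqrt(sum(v^2))

#' Dihedral angle of four points
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors.
#' @return Torsion angle in degrees in (-180, 180].
#' @keywords internal
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / vnorm(b2)
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Natural extension reference frame: place atom D given chain A-B-C,
# the C-D bond length, the B-C-D angle (deg) and the A-B-C-D torsion
# (deg).
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  d2 <- c(bond * cos(pi - ang),
          bond * sin(pi - ang) * cos(tor),
          -bond * sin(pi - ang) * sin(tor))
  bc <- c - b
  bc <- bc / vnorm(bc)
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / vnorm(n)
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  rot <- cbind(bc, m, n)
  c + as.vector(rot %*% d2)
}

# Ideal peptide geometry (lengths A, angles deg).
PEP <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8
)

#' Build an ideal polypeptide backbone from phi/psi torsions
#'
#' Places N, CA, C, O atoms for `n` residues with ideal bond lengths
#' and angles, given per-residue phi/psi (recycled) and omega = 180.
#'
#' @param n Number of residues.
#' @param phi,psi Backbone torsions in degrees (recycled to length `n`).
#' @return Data frame with columns `resno`, `elety`, `x`, `y`, `z`.
#' @keywords internal
build_backbone <- function(n, phi = -60, psi = -45) {
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  coords <- vector("list", n)
  # seed residue frame
  N <- c(0, 0, 0)
  CA <- c(PEP$n_ca, 0, 0)
  ang <- PEP$ang_n_ca_c * pi / 180
  C <- CA + c(-PEP$ca_c * cos(ang), PEP$ca_c * sin(ang), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      prevN <- coords[[i - 1]]$N
      prevCA <- coords[[i - 1]]$CA
      prevC <- coords[[i - 1]]$C
      N <- place_atom(prevN, prevCA, prevC, PEP$c_n, PEP$ang_ca_c_n, psi[i - 1])
      CA <- place_atom(prevCA, prevC, N, PEP$n_ca, PEP$ang_c_n_ca, 180)
      C <- place_atom(prevC, N, CA, PEP$ca_c, PEP$ang_n_ca_c, phi[i])
    }
    coords[[i]] <- list(N = N, CA = CA, C = C)
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cc <- coords[[i]]
    # carbonyl O: trans to the next N (or to psi + 180 at the terminus)
    o_tor <- if (i < n) psi[i] + 180 else psi[i] + 180
    O <- place_atom(cc$N, cc$CA, cc$C, PEP$c_o, PEP$ang_ca_c_o, o_tor)
    rows[[i]] <- data.frame(
      resno = i,
      elety = c("N", "CA", "C", "O"),
      x = c(cc$N[1], cc$CA[1], cc$C[1], O[1]),
      y = c(cc$N[2], cc$CA[2], cc$C[2], O[2]),
      z = c(cc$N[3], cc$CA[3], cc$C[3], O[3])
    )
  }
  do.call(rbind, rows)
}

# Ideal CB position from backbone N, CA, C (tetrahedral branch).
place_cb <- function(N, CA, C) {
  place_atom(N, C, CA, 1.53, 110.5, 122.5)
}
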