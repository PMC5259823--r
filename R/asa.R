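# Solvent accessible surface area by Shrake-Rupley sphere sampling
# with a deterministic Fibonacci-lattice point set.

#' Deterministic Fibonacci lattice on the unit sphere
#'
#' @param n Number of points.
#' @return An `n x 3` matrix of unit vectors.
#' @keywords internal
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Compute solvent accessible surface areas
#'
#' Shrake-Rupley sphere sampling: each atom's solvent-accessible
#' sphere (van der Waals radius + probe radius) is covered with a
#' deterministic Fibonacci lattice of `n_points` points, and the
#' accessible fraction is the share of points not buried inside any
#' neighbouring atom's accessible sphere. Per-residue ASA is the sum
#' over its heavy atoms. The point set contains no randomness, so
#' repeated runs are bit-identical.
#'
#' @param struct An `spr_structure`.
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4).
#' @param n_points Sphere sample points per atom (default 960; must be
#'   at least 10).
#' @return The structure with per-atom and per-residue `asa` filled in,
#'   plus per-residue `rel_asa` (ASA divided by the residue type's
#'   JANJ780101 average accessible area).
#' @export
compute_asa <- function(struct, probe_radius = 1.4, n_points = 960L) {
  stopifnot(inherits(struct, "spr_structure"))
  if (!is.numeric(n_points) || n_points < 10) {
    stop("`n_points` must be at least 10")
  }
  if (!is.numeric(probe_radius) || probe_radius < 0) {
    stop("`probe_radius` must be non-negative")
  }
  at <- struct$atoms
  xyz <- cbind(at$x, at$y, at$z)
  rad <- at$vdw + probe_radius
  at$asa <- asa_atoms(xyz, rad, n_points)
  struct$atoms <- at
  res_asa <- rowsum(at$asa, group = at$res_id)
  struct$residues$asa <- res_asa[struct$residues$res_id, 1]
  ref <- unname(REF_ASA[struct$residues$res_type])
  struct$residues$rel_asa <- struct$residues$asa / ref
  struct
}

# Core sampler over arbitrary spheres: xyz (n x 3) centres, rad (n)
# already-expanded radii (vdw + probe). Returns per-sphere accessible
# area.
asa_atoms <- function(xyz, rad, n_points) {
  n <- nrow(xyz)
  pts <- fibonacci_sphere(as.integer(n_points))
  asa <- numeric(n)
  if (n == 1L) return(4 * pi * rad^2)
  # squared pairwise centre distances for the neighbour test
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nbr <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    if (!length(nbr)) {
      asa[i] <- 4 * pi * rad[i]^2
      next
    }
    p <- pts * rad[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    nc <- xyz[nbr, , drop = FALSE]
    pd2 <- outer(rowSums(p^2), rowSums(nc^2), "+") - 2 * (p %*% t(nc))
    buried <- rowSums(sweep(pd2, 2, rad[nbr]^2, "<")) > 0
    asa[i] <- mean(!buried) * 4 * pi * rad[i]^2
  }
  asa
}

#' Surface residues of a structure
#'
#' A residue is a surface residue when its accessible surface area
#' exceeds `asa_min` (default 1 A^2).
#'
#' @param struct An `spr_structure` with ASA computed.
#' @param asa_min Minimum ASA (A^2) strictly above which a residue
#'   counts as surface.
#' @return Character vector of residue identifiers
#'   (`chain:resno:icode`), in structure order.
#' @export
surface_residues <- function(struct, asa_min = 1.0) {
  stopifnot(inherits(struct, "spr_structure"))
  res <- struct$residues
  if (all(is.na(res$asa))) stop("ASA not computed; call compute_asa() first")
  res$res_id[!is.na(res$asa) & res$asa > asa_min]
}
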