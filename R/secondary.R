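# Three-state secondary structure: built-in dihedral-run assigner and
# optional DSSP-file override (8-state to 3-state mapping).

#' Map 8-state DSSP codes to 3 states
#'
#' H/G/I become helix (H), E/B become strand (E), everything else
#' (including blanks, S and T) becomes coil (C).
#'
#' @param ss8 Character vector of single-character DSSP codes.
#' @return Character vector over \{H, E, C\}.
#' @export
map_dssp8to3 <- function(ss8) {
  out <- rep("C", length(ss8))
  out[ss8 %in% c("H", "G", "I")] <- "H"
  out[ss8 %in% c("E", "B")] <- "E"
  out
}

# Parse a classic-format DSSP file into (chain, resno, icode, aa, ss8).
parse_dssp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr)) stop("not a DSSP file (missing residue header): ", path)
  body <- lines[(hdr[1] + 1):length(lines)]
  body <- body[nchar(body) >= 17]
  aa <- substr(body, 14, 14)
  keep <- aa != "!"
  body <- body[keep]
  data.frame(
    chain = substr(body, 12, 12),
    resno = as.integer(substr(body, 6, 10)),
    icode = trimws(substr(body, 11, 11)),
    aa = substr(body, 14, 14),
    ss8 = substr(body, 17, 17),
    stringsAsFactors = FALSE
  )
}

# phi/psi for every residue of a structure (NA where backbone atoms or
# neighbours are missing). Residues are taken consecutive within each
# chain in structure order.
backbone_dihedrals <- function(struct) {
  res <- struct$residues
  at <- struct$atoms
  bb <- at[at$elety %in% c("N", "CA", "C"), c("res_id", "elety", "x", "y", "z")]
  key <- paste(bb$res_id, bb$elety)
  get_atom <- function(id, name) {
    i <- match(paste(id, name), key)
    if (is.na(i)) return(NULL)
    c(bb$x[i], bb$y[i], bb$z[i])
  }
  n <- nrow(res)
  phi <- rep(NA_real_, n)
  psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    Ni <- get_atom(res$res_id[i], "N")
    CAi <- get_atom(res$res_id[i], "CA")
    Ci <- get_atom(res$res_id[i], "C")
    if (is.null(Ni) || is.null(CAi) || is.null(Ci)) next
    if (i > 1 && res$chain[i - 1] == res$chain[i]) {
      Cp <- get_atom(res$res_id[i - 1], "C")
      if (!is.null(Cp) && vnorm(Ni - Cp) < 2.5) {
        phi[i] <- torsion_angle(Cp, Ni, CAi, Ci)
      }
    }
    if (i < n && res$chain[i + 1] == res$chain[i]) {
      Nn <- get_atom(res$res_id[i + 1], "N")
      if (!is.null(Nn) && vnorm(Nn - Ci) < 2.5) {
        psi[i] <- torsion_angle(Ni, CAi, Ci, Nn)
      }
    }
  }
  list(phi = phi, psi = psi)
}

in_range <- function(x, lo, hi) !is.na(x) & x >= lo & x <= hi

# TRUE runs of length >= k
runs_at_least <- function(flag, k) {
  r <- rle(flag)
  keep <- r$values & r$lengths >= k
  inverse.rle(list(values = keep, lengths = r$lengths))
}

#' Assign 3-state secondary structure
#'
#' With a DSSP file, applies the standard 8-to-3 mapping (H/G/I to H,
#' E/B to E, else C). Without one, uses a built-in dihedral-run
#' assigner: helix is a run of at least 4 residues with phi in
#' \[-100, -30\] and psi in \[-80, 0\]; strand is a run of at least 3
#' residues with phi in \[-180, -40\] and psi in \[60, 180\] or
#' \[-180, -170\]; everything else (including residues with missing
#' backbone atoms) is coil.
#'
#' @param struct An `spr_structure`.
#' @param dssp_file Optional path to a classic-format DSSP file for the
#'   same structure.
#' @return The structure with the per-residue `ss` field filled with
#'   one of "H", "E", "C".
#' @export
assign_secondary_structure <- function(struct, dssp_file = NULL) {
  stopifnot(inherits(struct, "spr_structure"))
  res <- struct$residues
  if (!is.null(dssp_file)) {
    d <- parse_dssp(dssp_file)
    d_id <- res_id(d$chain, d$resno, d$icode)
    idx <- match(res$res_id, d_id)
    bad <- which(is.na(idx) |
                   (res$res_type != "X" & toupper(d$aa[idx]) != res$res_type))
    if (length(bad)) {
      stop("DSSP/structure residue mismatch at: ",
           paste(utils::head(res$res_id[bad], 10), collapse = ", "),
           if (length(bad) > 10) " ..." else "")
    }
    struct$residues$ss <- map_dssp8to3(d$ss8[idx])
    return(struct)
  }
  di <- backbone_dihedrals(struct)
  helix_ok <- in_range(di$phi, -100, -30) & in_range(di$psi, -80, 0)
  strand_ok <- in_range(di$phi, -180, -40) &
    (in_range(di$psi, 60, 180) | in_range(di$psi, -180, -170))
  ss <- rep("C", nrow(res))
  # evaluate runs within chains only
  for (ch in unique(res$chain)) {
    i <- which(res$chain == ch)
    h <- runs_at_least(helix_ok[i], 4L)
    e <- runs_at_least(strand_ok[i], 3L)
    ss[i][e] <- "E"
    ss[i][h] <- "H"
  }
  struct$residues$ss <- ss
  struct
}
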