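# Four-term empirical patch scoring: residue interface propensity,
# hydrophobicity, conservation and solvation, combined linearly into
# E_patch, plus the end-to-end single-domain predictor.

member_types <- function(patch, struct) {
  res <- struct$residues
  idx <- match(patch$members, res$res_id)
  if (anyNA(idx)) {
    stop("patch members not found in structure: ",
         paste(patch$members[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Residue interface propensity score of a patch
#'
#' `E_res = sum_i ASA_i * RIR_r / REF_r` over patch members, with
#' `ASA_i` the member's accessible surface area (A^2), `RIR_r` its
#' QIPI value and `REF_r` its JANJ780101 average accessible area.
#' Nonstandard residues contribute 0.
#'
#' @param patch An `spr_patch`.
#' @param struct The structure with ASA computed.
#' @param tables Constant tables from [spr_constants()].
#' @return The score (0 for an empty patch).
#' @export
score_eres <- function(patch, struct, tables = spr_constants()) {
  if (!length(patch$members)) return(0)
  idx <- member_types(patch, struct)
  res <- struct$residues
  if (anyNA(res$asa[idx])) stop("ASA not computed for patch members")
  types <- res$res_type[idx]
  ok <- types %in% tables$aa20
  if (!any(ok)) return(0)
  asa <- res$asa[idx][ok]
  r <- types[ok]
  sum(asa * tables$qipi[r] / tables$ref_asa[r])
}

#' Hydrophobic score of a patch
#'
#' `E_hydro = sum_i H_r`: the sum of CASG920101 hydrophobicity values
#' over patch members (nonstandard residues contribute 0).
#'
#' @inheritParams score_eres
#' @return The score (0 for an empty patch).
#' @export
score_ehydro <- function(patch, struct, tables = spr_constants()) {
  if (!length(patch$members)) return(0)
  idx <- member_types(patch, struct)
  types <- struct$residues$res_type[idx]
  ok <- types %in% tables$aa20
  if (!any(ok)) return(0)
  sum(tables$hydro[types[ok]])
}

#' Conservation score of a patch
#'
#' `E_cons = sum_i (C_ir - B_rr)`: per member, the PSSM
#' self-substitution score at its sequence position minus the BLOSUM62
#' diagonal for its residue type.
#'
#' @inheritParams score_eres
#' @param pssm An `spr_pssm` aligned to the structure's chain.
#' @return The score (0 for an empty patch).
#' @export
score_econs <- function(patch, struct, pssm, tables = spr_constants()) {
  if (!length(patch$members)) return(0)
  if (is.null(pssm)) {
    stop("configuration error: conservation term requires a PSSM ",
         "(or disable the term)")
  }
  idx <- member_types(patch, struct)
  types <- struct$residues$res_type[idx]
  ok <- types %in% tables$aa20
  if (!any(ok)) return(0)
  cir <- pssm_self_scores(pssm, struct, patch$members[ok])
  sum(cir - tables$blosum62_diag[types[ok]])
}

#' Fraction of a probe sphere outside a set of occluding spheres
#'
#' Deterministic cubic-grid estimate: grid points with spacing
#' `grid_spacing` inside the probe sphere are tested against all
#' occluding spheres; the returned value is the fraction lying outside
#' every one of them.
#'
#' @param center Numeric 3-vector, probe sphere centre.
#' @param centers Matrix (k x 3) of occluding sphere centres (may have
#'   zero rows).
#' @param radii Occluding sphere radii (length k).
#' @param sphere_radius Probe sphere radius (default 1.2 A).
#' @param grid_spacing Grid spacing (default 0.2 A).
#' @return Fraction in \[0, 1\].
#' @export
sphere_outside_fraction <- function(center, centers, radii,
                                    sphere_radius = 1.2,
                                    grid_spacing = 0.2) {
  # midpoint-rule lattice (cell centres), so boundaries aligned with a
  # lattice plane are not systematically over-counted
  half <- ceiling(sphere_radius / grid_spacing)
  g <- (seq_len(2 * half) - half - 0.5) * grid_spacing
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  pts <- pts[rowSums(pts^2) <= sphere_radius^2, , drop = FALSE]
  pts <- sweep(pts, 2, center, "+")
  if (is.null(centers) || !nrow(centers)) return(1)
  # only occluders that can reach the probe sphere matter
  dc <- sqrt(colSums((t(centers) - center)^2))
  near <- which(dc < radii + sphere_radius)
  if (!length(near)) return(1)
  centers <- centers[near, , drop = FALSE]
  radii <- radii[near]
  d2 <- outer(rowSums(pts^2), rowSums(centers^2), "+") -
    2 * (pts %*% t(centers))
  outside <- rowSums(sweep(d2, 2, radii^2, "<")) == 0
  mean(outside)
}

#' Solvation score of a patch
#'
#' For each member residue, a probe sphere of radius `sphere_radius`
#' (default 1.2 A) is centred at the centroid of the member's
#' solvent-exposed heavy atoms. `V_out` is the sphere volume outside
#' the solvent-accessible spheres (van der Waals radius + probe) of
#' all *other* residues' atoms, estimated on a deterministic cubic
#' grid, and the member contributes `V_out / (V_sphere - V_out)`. A
#' fully external sphere is capped at 1e6. Members without exposed
#' atoms contribute 0.
#'
#' @inheritParams score_eres
#' @param sphere_radius Probe sphere radius in Angstrom (default 1.2).
#' @param grid_spacing Sampling grid spacing in Angstrom (default 0.2).
#' @param probe_radius Solvent probe radius used for the accessible
#'   spheres (default 1.4).
#' @return The summed solvation score.
#' @export
score_esol <- function(patch, struct, sphere_radius = 1.2,
                       grid_spacing = 0.2, probe_radius = 1.4) {
  if (!length(patch$members)) return(0)
  at <- struct$atoms
  if (all(is.na(at$asa))) stop("ASA not computed; call compute_asa() first")
  total <- 0
  for (id in patch$members) {
    own <- at$res_id == id
    exposed <- own & at$asa > 0
    if (!any(exposed)) next
    center <- c(mean(at$x[exposed]), mean(at$y[exposed]), mean(at$z[exposed]))
    occ <- !own
    frac_out <- sphere_outside_fraction(
      center, cbind(at$x[occ], at$y[occ], at$z[occ]),
      at$vdw[occ] + probe_radius, sphere_radius, grid_spacing
    )
    term <- if (frac_out >= 1) 1e6 else frac_out / (1 - frac_out)
    total <- total + term
  }
  total
}

#' Score a patch with the four-term function
#'
#' `E_patch = E_res + w1 * E_hydro + w2 * E_cons + w3 * E_sol`. The
#' component scores are stored on the returned patch for ablation.
#' When no PSSM is given the conservation term is disabled
#' (contributes 0); if `w2` is non-zero in that case a warning is
#' issued once per call.
#'
#' @param patch An `spr_patch`.
#' @param struct The structure with ASA computed.
#' @param weights Named numeric vector `c(w1=, w2=, w3=)` (defaults to
#'   the packaged trained weights).
#' @param pssm Optional `spr_pssm` for the conservation term.
#' @param use_sol Compute the solvation term (default TRUE; skipping it
#'   sets the component to 0, useful when `w3 = 0`).
#' @param tables Constant tables.
#' @return The patch with `e_res`, `e_hydro`, `e_cons`, `e_sol` and
#'   `e_patch` filled in.
#' @export
score_patch <- function(patch, struct, weights = DEFAULT_WEIGHTS,
                        pssm = NULL, use_sol = TRUE,
                        tables = spr_constants()) {
  w <- weights_vec(weights)
  patch$e_res <- score_eres(patch, struct, tables)
  patch$e_hydro <- score_ehydro(patch, struct, tables)
  if (is.null(pssm)) {
    if (w[["w2"]] != 0) {
      warning("no PSSM given: conservation term contributes 0")
    }
    patch$e_cons <- 0
  } else {
    patch$e_cons <- score_econs(patch, struct, pssm, tables)
  }
  patch$e_sol <- if (use_sol) score_esol(patch, struct) else 0
  patch$e_patch <- patch$e_res + w[["w1"]] * patch$e_hydro +
    w[["w2"]] * patch$e_cons + w[["w3"]] * patch$e_sol
  patch
}

weights_vec <- function(weights) {
  if (is.list(weights)) weights <- unlist(weights)
  if (is.null(names(weights)) && length(weights) == 3) {
    names(weights) <- c("w1", "w2", "w3")
  }
  if (!all(c("w1", "w2", "w3") %in% names(weights)) ||
      !all(is.finite(weights[c("w1", "w2", "w3")]))) {
    stop("weights must be finite and named w1, w2, w3")
  }
  weights[c("w1", "w2", "w3")]
}

# deterministic ranking: higher score first; ties towards larger
# patches, then lexicographically smaller member sets
rank_patches <- function(patches) {
  sc <- vapply(patches, `[[`, numeric(1), "e_patch")
  sz <- vapply(patches, function(p) length(p$members), integer(1))
  keys <- vapply(patches, function(p) patch_key(p$members), character(1))
  patches[order(-sc, -sz, keys, method = "radix")]
}

#' Predict the interface of an unbound domain
#'
#' Full SPR pipeline: surface residues, side-chain distance matrix,
#' one grown patch per seed, identity-ratio merging, four-term scoring
#' and selection of the top-ranked patch (ties broken towards the
#' larger patch, then lexicographic member order). The input should be
#' a single unbound domain.
#'
#' @param struct An `spr_structure` (ASA is computed if missing).
#' @param weights Scoring weights `c(w1=, w2=, w3=)`.
#' @param pssm Optional `spr_pssm` for the conservation term.
#' @param use_sol Compute the solvation term (default TRUE).
#' @param tables Constant tables.
#' @return The top-ranked scored `spr_patch`; all ranked patches are
#'   attached as `attr(, "ranked")`.
#' @export
predict_interface <- function(struct, weights = DEFAULT_WEIGHTS, pssm = NULL,
                              use_sol = TRUE, tables = spr_constants()) {
  stopifnot(inherits(struct, "spr_structure"))
  if (all(is.na(struct$residues$asa))) struct <- compute_asa(struct)
  dm <- sidechain_distance_matrix(struct)
  patches <- generate_patches(struct, dm, tables$patch_growth)
  merged <- merge_patches(patches, total_asa(struct),
                          tables$merge_thresholds)
  scored <- lapply(merged, score_patch, struct = struct, weights = weights,
                   pssm = pssm, use_sol = use_sol, tables = tables)
  ranked <- rank_patches(scored)
  top <- ranked[[1]]
  attr(top, "ranked") <- ranked
  top
}
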