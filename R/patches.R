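# Candidate interface patches: side-chain distance matrix, seed-based
# growth with distance-binned ASA thresholds, and identity-ratio
# merging.

#' Minimum side-chain distance matrix over surface residues
#'
#' For every pair of surface residues, the minimum distance between
#' side-chain heavy atoms (the CA-CA distance for glycine or residues
#' without side-chain atoms), capped at `cap` Angstrom.
#'
#' @param struct An `spr_structure` with ASA computed.
#' @param cap Distance cap in Angstrom (default 25).
#' @param asa_min Surface-residue ASA cutoff (default 1 A^2).
#' @return Object of class `spr_distmat`: list with `ids` (surface
#'   residue identifiers in structure order) and the symmetric capped
#'   matrix `d`.
#' @export
sidechain_distance_matrix <- function(struct, cap = 25, asa_min = 1.0) {
  ids <- surface_residues(struct, asa_min)
  n <- length(ids)
  if (!n) stop("empty prediction: no surface residues")
  at <- struct$atoms
  coords <- lapply(ids, function(id) {
    a <- at[at$res_id == id, , drop = FALSE]
    if (!nrow(a)) stop("geometry error: residue without atoms: ", id)
    sc <- a[a$is_sidechain, , drop = FALSE]
    if (!nrow(sc)) sc <- a[a$elety == "CA", , drop = FALSE]
    if (!nrow(sc)) sc <- a  # last resort: any heavy atom
    cbind(sc$x, sc$y, sc$z)
  })
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      xi <- coords[[i]]
      for (j in seq(i + 1, n)) {
        xj <- coords[[j]]
        d2 <- outer(rowSums(xi^2), rowSums(xj^2), "+") - 2 * (xi %*% t(xj))
        d[i, j] <- d[j, i] <- sqrt(max(0, min(d2)))
      }
    }
  }
  d[d > cap] <- cap
  structure(list(ids = ids, d = d), class = "spr_distmat")
}

new_patch <- function(members, seed = NA_character_) {
  structure(list(seed = seed, members = members,
                 e_res = NA_real_, e_hydro = NA_real_, e_cons = NA_real_,
                 e_sol = NA_real_, e_patch = NA_real_),
            class = "spr_patch")
}

#' @export
print.spr_patch <- function(x, ...) {
  cat("spr_patch:", length(x$members), "residues",
      if (!is.na(x$seed)) paste0("(seed ", x$seed, ")") else "(merged)", "\n")
  if (!is.na(x$e_patch)) {
    cat(sprintf("  E_patch %.3f (res %.3f, hydro %.3f, cons %.3f, sol %.3f)\n",
                x$e_patch, x$e_res, x$e_hydro, x$e_cons, x$e_sol))
  }
  invisible(x)
}

#' Grow a candidate patch around a seed residue
#'
#' A surface residue joins the seed's patch when its minimum side-chain
#' distance `d` to the seed falls in a threshold bin `(lo, hi]` and its
#' ASA exceeds the bin's minimum: (2,5] -> 0, (5,7] -> 20, (7,9] -> 40,
#' (9,11] -> 60, (11,13] -> 80, (13,15] -> 100 A^2. Residues with
#' `d <= 2` join unconditionally; residues with `d > 15` never join.
#'
#' @param seed Residue identifier of a surface residue.
#' @param dm An `spr_distmat` from [sidechain_distance_matrix()].
#' @param struct The structure (for per-residue ASA).
#' @param thresholds Data frame with columns `lo`, `hi`, `min_asa`
#'   (defaults to the packaged table).
#' @return An `spr_patch` containing the seed and qualifying residues.
#' @export
grow_patch <- function(seed, dm, struct, thresholds = PATCH_GROWTH) {
  stopifnot(inherits(dm, "spr_distmat"))
  if (!seed %in% dm$ids) {
    stop("precondition error: seed is not a surface residue: ", seed)
  }
  d <- dm$d[seed, ]
  asa <- struct$residues$asa[match(dm$ids, struct$residues$res_id)]
  inc <- rep(FALSE, length(dm$ids))
  inc[d <= 2] <- TRUE  # includes the seed itself (d = 0)
  for (k in seq_len(nrow(thresholds))) {
    b <- d > thresholds$lo[k] & d <= thresholds$hi[k]
    inc[b & asa > thresholds$min_asa[k]] <- TRUE
  }
  new_patch(dm$ids[inc], seed = seed)
}

#' Generate one candidate patch per surface residue
#'
#' @param struct An `spr_structure` with ASA computed.
#' @param dm Optional precomputed `spr_distmat`.
#' @param thresholds Patch-growth thresholds (packaged default).
#' @return List of `spr_patch`, one per surface residue, in structure
#'   order (chain, then residue number).
#' @export
generate_patches <- function(struct, dm = NULL, thresholds = PATCH_GROWTH) {
  if (is.null(dm)) dm <- sidechain_distance_matrix(struct)
  lapply(dm$ids, grow_patch, dm = dm, struct = struct,
         thresholds = thresholds)
}

patch_key <- function(members) paste(sort(members), collapse = "|")

#' Merge overlapping candidate patches
#'
#' The identity ratio of two patches is the size of their intersection
#' divided by the size of the smaller patch. Two patches are merged
#' into their union when the ratio is at least the threshold selected
#' by the domain's total ASA: (0,5000] -> 0.8, (5000,7500] -> 0.7,
#' (7500,10000] -> 0.6, above 10000 -> 0.5. Merging repeatedly takes
#' the currently highest-ratio admissible pair (ties broken towards
#' the lexicographically smallest member sets) until no pair
#' qualifies, so the result is deterministic.
#'
#' @param patches List of `spr_patch`.
#' @param domain_asa Total ASA of the domain (A^2), used to select the
#'   threshold.
#' @param thresholds Data frame with columns `lo`, `hi`, `ratio`
#'   (packaged default).
#' @return List of merged `spr_patch` (seeds unset on merged patches),
#'   ordered by their lexicographically smallest member sets.
#' @export
merge_patches <- function(patches, domain_asa, thresholds = MERGE_THRESHOLDS) {
  if (!length(patches)) return(patches)
  thr_row <- which(domain_asa > thresholds$lo & domain_asa <= thresholds$hi)
  if (!length(thr_row)) stop("`domain_asa` must be positive")
  thr <- thresholds$ratio[thr_row]
  members <- lapply(patches, `[[`, "members")
  seeds <- vapply(patches, `[[`, character(1), "seed")
  repeat {
    n <- length(members)
    if (n < 2) break
    keys <- vapply(members, patch_key, character(1))
    best <- NULL
    best_ratio <- -Inf
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        ov <- length(intersect(members[[i]], members[[j]]))
        if (!ov) next
        ratio <- ov / min(length(members[[i]]), length(members[[j]]))
        if (ratio < thr) next
        cand_keys <- sort(c(keys[i], keys[j]))
        if (ratio > best_ratio ||
            (ratio == best_ratio &&
               (cand_keys[1] < best$k1 ||
                  (cand_keys[1] == best$k1 && cand_keys[2] < best$k2)))) {
          best_ratio <- ratio
          best <- list(i = i, j = j, k1 = cand_keys[1], k2 = cand_keys[2])
        }
      }
    }
    if (is.null(best)) break
    merged <- sort(union(members[[best$i]], members[[best$j]]))
    members[[best$i]] <- merged
    seeds[best$i] <- NA_character_
    members[[best$j]] <- NULL
    seeds <- seeds[-best$j]
  }
  ord <- order(vapply(members, patch_key, character(1)), method = "radix")
  lapply(ord, function(i) new_patch(sort(members[[i]]), seed = seeds[i]))
}
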