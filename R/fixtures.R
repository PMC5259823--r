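# Deterministic synthetic fixtures: two-body toy complexes with a
# planted contact interface and biased interface composition, plus toy
# PSSMs. Geometry uses ideal backbone internal coordinates and
# simplified side-chain pseudo-atoms sized by residue type; plausible,
# not physical.

# run code under a seed without disturbing the caller's RNG state
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# number of side-chain pseudo carbons per residue type (0 = glycine)
SIDECHAIN_SIZE <- c(
  G = 0, A = 1, S = 1, C = 1, T = 2, V = 2, P = 2, D = 2, N = 2,
  I = 3, L = 3, E = 3, Q = 3, M = 3, H = 3,
  K = 4, F = 4, W = 4, Y = 4, R = 5
)[AA20]
names(SIDECHAIN_SIZE) <- AA20
SIDECHAIN_NAMES <- c("CB", "CG", "CD", "CE", "CZ")

#' Specification of a synthetic two-body complex
#'
#' @param seed Integer RNG seed; identical specs give byte-identical
#'   fixtures.
#' @param n_per_side Residues per side (default 40, large enough that a
#'   domain carries several distinct candidate patches after merging).
#' @param interface_fraction Target fraction of residues in cross-side
#'   contact (default 0.3, must be in (0, 1)).
#' @param composition_bias Named enrichment factors applied to the
#'   residue-type distribution at planted interface positions; types
#'   not named have weight 1. Default: 3-fold enrichment of the
#'   high-propensity residues Arg, Phe, Met, Trp, Tyr.
#' @param geometry `"two-helix-pack"` (default), `"two-sheet-pack"` or
#'   `"blob"` (random-coil torsions).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_per_side = 40L,
                         interface_fraction = 0.3,
                         composition_bias = c(R = 3, F = 3, M = 3,
                                              W = 3, Y = 3),
                         geometry = c("two-helix-pack", "two-sheet-pack",
                                      "blob")) {
  geometry <- match.arg(geometry)
  if (!is.numeric(interface_fraction) || interface_fraction <= 0 ||
      interface_fraction >= 1) {
    stop("spec error: interface_fraction must be in (0, 1)")
  }
  if (any(composition_bias <= 0)) {
    stop("spec error: enrichment factors must be positive")
  }
  if (n_per_side < 6) stop("spec error: n_per_side must be at least 6")
  structure(list(seed = as.integer(seed), n_per_side = as.integer(n_per_side),
                 interface_fraction = interface_fraction,
                 composition_bias = composition_bias, geometry = geometry),
            class = "fixture_spec")
}

# rotation matrix taking unit vector a onto unit vector b (Rodrigues)
rotation_between <- function(a, b) {
  a <- a / vnorm(a)
  b <- b / vnorm(b)
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- vnorm(v)
  cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate pi about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- c(a[2] * p[3] - a[3] * p[2],
           a[3] * p[1] - a[1] * p[3],
           a[1] * p[2] - a[2] * p[1])
    v <- v / vnorm(v)
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
}

# build one body: backbone by geometry + side-chain pseudo atoms for
# given types; returns data.frame(resno, elety, x, y, z) aligned with
# its principal axis on x and centroid at the origin
build_body <- function(n, types, geometry) {
  tor <- switch(geometry,
    "two-helix-pack" = list(phi = -60, psi = -45),
    "two-sheet-pack" = list(phi = -120, psi = 130),
    "blob" = list(phi = stats::runif(n, -150, -50),
                  psi = stats::runif(n, -60, 160))
  )
  bb <- build_backbone(n, tor$phi, tor$psi)
  rows <- list(bb)
  for (i in seq_len(n)) {
    nsc <- SIDECHAIN_SIZE[types[i]]
    if (nsc == 0) next
    g <- bb[bb$resno == i, ]
    N <- c(g$x[g$elety == "N"], g$y[g$elety == "N"], g$z[g$elety == "N"])
    CA <- c(g$x[g$elety == "CA"], g$y[g$elety == "CA"], g$z[g$elety == "CA"])
    C <- c(g$x[g$elety == "C"], g$y[g$elety == "C"], g$z[g$elety == "C"])
    cb <- place_cb(N, CA, C)
    u <- (cb - CA) / vnorm(cb - CA)
    sc <- t(vapply(seq_len(nsc), function(k) cb + (k - 1) * 1.4 * u,
                   numeric(3)))
    rows[[length(rows) + 1]] <- data.frame(
      resno = i, elety = SIDECHAIN_NAMES[seq_len(nsc)],
      x = sc[, 1], y = sc[, 2], z = sc[, 3]
    )
  }
  body <- do.call(rbind, rows)
  # align CA principal axis with x, centroid at origin
  ca <- as.matrix(body[body$elety == "CA", c("x", "y", "z")])
  ctr <- colMeans(ca)
  xyz <- sweep(as.matrix(body[, c("x", "y", "z")]), 2, ctr)
  ax <- stats::prcomp(sweep(ca, 2, ctr), center = FALSE)$rotation[, 1]
  if (ax[1] < 0) ax <- -ax
  R <- rotation_between(ax, c(1, 0, 0))
  xyz <- xyz %*% t(R)
  body[, c("x", "y", "z")] <- xyz
  body[order(body$resno, match(body$elety, c("N", "CA", "C", "O",
                                             SIDECHAIN_NAMES))), ]
}

# per-residue cross-side contact flags at < cutoff between two atom
# tables (brute force)
contact_flags <- function(a, b, cutoff = 5) {
  xa <- as.matrix(a[, c("x", "y", "z")])
  xb <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * (xa %*% t(xb))
  hit <- d2 < cutoff^2
  list(a = sort(unique(a$resno[rowSums(hit) > 0])),
       b = sort(unique(b$resno[colSums(hit) > 0])))
}

# planted-truth contacts: only atoms that are solvent-exposed in their
# unbound side (atom ASA > min_atom_asa) count, so every planted
# residue genuinely buries surface on complexation
exposed_contact_flags <- function(a, b, cutoff = 5, probe = 1.4,
                                  min_atom_asa = 5) {
  exposure <- function(body) {
    xyz <- as.matrix(body[, c("x", "y", "z")])
    vdw <- unname(VDW_RADII[substr(body$elety, 1, 1)])
    vdw[is.na(vdw)] <- VDW_DEFAULT
    asa_atoms(xyz, vdw + probe, 960L)
  }
  ea <- exposure(a) > min_atom_asa
  eb <- exposure(b) > min_atom_asa
  contact_flags(a[ea, , drop = FALSE], b[eb, , drop = FALSE], cutoff)
}

sample_types <- function(n, weights) {
  sample(AA20, n, replace = TRUE, prob = weights / sum(weights))
}

#' Generate a deterministic toy two-body complex with a planted interface
#'
#' Builds two bodies (chains A and B) from ideal backbone internal
#' coordinates with simplified side chains, docks them face to face at
#' the inter-body separation whose cross-contact fraction best matches
#' `interface_fraction`, draws residue types at the contact face from
#' the bias-weighted composition (elsewhere uniform), and records the
#' planted interface as the exact set of residues having a
#' solvent-exposed heavy atom (unbound atom-level ASA > 5 A^2) within
#' 5 Angstrom of the other side in the final coordinates, so every
#' planted residue buries real surface on complexation.
#' Identical specs give byte-identical PDB text.
#'
#' @param spec A [fixture_spec()].
#' @return List with `pdb` (character vector of PDB lines), `truth`
#'   (list `a`, `b` of planted interface residue identifiers), the
#'   achieved `contact_fraction` and the `spec`.
#' @export
make_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_preserved_seed(spec$seed, {
    n <- spec$n_per_side
    # provisional bodies with uniform composition to choose the docking
    # separation
    types_a <- sample_types(n, rep(1, 20))
    types_b <- sample_types(n, rep(1, 20))
    prov_a <- build_body(n, types_a, spec$geometry)
    prov_b0 <- build_body(n, types_b, spec$geometry)

    flip <- diag(c(1, -1, -1))  # proper rotation: B's face turns towards A
    seps <- seq(6, 20, by = 0.5)
    frac <- vapply(seps, function(D) {
      b <- prov_b0
      xyz <- as.matrix(b[, c("x", "y", "z")]) %*% t(flip)
      xyz[, 3] <- xyz[, 3] + D
      b[, c("x", "y", "z")] <- xyz
      cf <- contact_flags(prov_a, b)
      (length(cf$a) + length(cf$b)) / (2 * n)
    }, numeric(1))
    best <- which.min(abs(frac - spec$interface_fraction))
    if (abs(frac[best] - spec$interface_fraction) >
          0.5 * spec$interface_fraction) {
      stop("spec error: interface_fraction ", spec$interface_fraction,
           " not attainable for this geometry (closest ",
           round(frac[best], 3), ")")
    }
    D <- seps[best]
    b_at_D <- function(body) {
      xyz <- as.matrix(body[, c("x", "y", "z")]) %*% t(flip)
      xyz[, 3] <- xyz[, 3] + D
      body[, c("x", "y", "z")] <- xyz
      body
    }
    prov_face <- contact_flags(prov_a, b_at_D(prov_b0))

    # final composition: biased at the planted face, uniform elsewhere
    bias_w <- rep(1, 20)
    names(bias_w) <- AA20
    bias_w[names(spec$composition_bias)] <- spec$composition_bias
    types_a <- sample_types(n, rep(1, 20))
    types_b <- sample_types(n, rep(1, 20))
    types_a[prov_face$a] <- sample_types(length(prov_face$a), bias_w)
    types_b[prov_face$b] <- sample_types(length(prov_face$b), bias_w)

    body_a <- build_body(n, types_a, spec$geometry)
    body_b <- b_at_D(build_body(n, types_b, spec$geometry))
    truth_flags <- exposed_contact_flags(body_a, body_b)

    pdb <- write_pdb_lines(body_a, body_b, types_a, types_b)
    list(
      pdb = pdb,
      truth = list(a = res_id("A", truth_flags$a, NA),
                   b = res_id("B", truth_flags$b, NA)),
      contact_fraction = (length(truth_flags$a) + length(truth_flags$b)) /
        (2 * n),
      separation = D,
      spec = spec
    )
  })
}

# render two bodies as PDB text (chains A and B)
write_pdb_lines <- function(body_a, body_b, types_a, types_b) {
  fmt <- function(body, types, chain, offset) {
    vapply(seq_len(nrow(body)), function(i) {
      rt <- types[body$resno[i]]
      sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s",
              offset + i, body$elety[i], AA1TO3[rt], chain, body$resno[i],
              body$x[i], body$y[i], body$z[i], 1, 0,
              substr(body$elety[i], 1, 1))
    }, character(1))
  }
  c(fmt(body_a, types_a, "A", 0L),
    "TER",
    fmt(body_b, types_b, "B", nrow(body_a)),
    "TER", "END")
}

#' Build an unbound prediction case from a toy complex
#'
#' Extracts one side of a [make_toy_complex()] fixture as an unbound
#' domain with its planted interface truth, ready for
#' [predict_interface()] / [train_weights()].
#'
#' @param spec A [fixture_spec()].
#' @param side `"a"` or `"b"`.
#' @param conservation_offset Per-position offset added on planted
#'   interface positions in the accompanying toy PSSM (default 2).
#' @return List with `struct` (ASA computed), `truth` (planted
#'   interface residue ids of that side) and `pssm` (a toy `spr_pssm`
#'   whose planted positions are enriched by `conservation_offset`).
#' @export
toy_unbound_case <- function(spec, side = c("a", "b"),
                             conservation_offset = 2) {
  side <- match.arg(side)
  toy <- make_toy_complex(spec)
  chain <- toupper(side)
  cx <- read_structure(toy$pdb, id = paste0("toy", spec$seed))
  dom <- compute_asa(subset_structure(cx, chain))
  res <- dom$residues
  offsets <- ifelse(res$res_id %in% toy$truth[[side]], conservation_offset, 0)
  pssm_lines <- make_toy_pssm(res$res_type, offsets)
  tf <- tempfile(fileext = ".pssm")
  writeLines(pssm_lines, tf)
  pssm <- read_pssm(tf)
  unlink(tf)
  list(struct = dom, truth = toy$truth[[side]], pssm = pssm, complex = toy)
}

#' Write a synthetic dataset to disk
#'
#' Generates `n_complexes` toy complexes (seeds `seed`, `seed + 1`,
#' ...), writing per-complex PDB files, a partition manifest
#' (`manifest.tsv`: file, side_a, side_b), a truth table (`truth.tsv`:
#' file, side, res_id) and per-chain toy PSSM files.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_complexes Number of complexes.
#' @param seed Base seed.
#' @param ... Further arguments passed to [fixture_spec()].
#' @return Invisibly, the manifest data frame.
#' @export
simulate_dataset <- function(out_dir, n_complexes = 5L, seed = 1L, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(file = character(), side_a = character(),
                         side_b = character())
  truth <- data.frame(file = character(), side = character(),
                      res_id = character())
  for (k in seq_len(n_complexes)) {
    spec <- fixture_spec(seed = seed + k - 1L, ...)
    toy <- make_toy_complex(spec)
    fn <- sprintf("complex_%03d.pdb", k)
    writeLines(toy$pdb, file.path(out_dir, fn))
    manifest <- rbind(manifest,
                      data.frame(file = fn, side_a = "A", side_b = "B"))
    truth <- rbind(truth, data.frame(
      file = fn,
      side = rep(c("a", "b"), c(length(toy$truth$a), length(toy$truth$b))),
      res_id = c(toy$truth$a, toy$truth$b)
    ))
    cx <- read_structure(toy$pdb)
    for (ch in c("A", "B")) {
      res <- cx$residues[cx$residues$chain == ch, ]
      make_toy_pssm(res$res_type, 0,
                    path = file.path(out_dir,
                                     sprintf("complex_%03d_%s.pssm", k, ch)))
    }
  }
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
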