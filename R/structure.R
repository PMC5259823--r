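# Structure model: PDB parsing into a light-weight atom/residue
# container used by all downstream analyses.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")
WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O", "SOL")

res_id <- function(chain, resno, icode) {
  icode <- ifelse(is.na(icode), "", icode)
  paste(chain, resno, icode, sep = ":")
}

new_structure <- function(atoms, id = "structure", source_path = NA_character_) {
  stopifnot(is.data.frame(atoms))
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$icode,
                       method = "radix"), , drop = FALSE]
  rownames(atoms) <- NULL
  res <- atoms[!duplicated(atoms$res_id),
               c("res_id", "chain", "resno", "icode", "resid3", "res_type")]
  res$n_atoms <- as.vector(table(atoms$res_id)[res$res_id])
  res$asa <- NA_real_
  res$rel_asa <- NA_real_
  res$ss <- NA_character_
  rownames(res) <- NULL
  structure(
    list(id = id, atoms = atoms, residues = res, source_path = source_path),
    class = "spr_structure"
  )
}

derive_element <- function(elety, elesy) {
  el <- toupper(elesy)
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    guess <- toupper(sub("^[0-9]*([A-Za-z]).*$", "\\1", elety[miss]))
    # two-letter selenium in MSE
    guess[grepl("^SE", toupper(elety[miss]))] <- "SE"
    el[miss] <- guess
  }
  el
}

#' Read a protein structure from a PDB file or text
#'
#' Parses ATOM records (plus MSE HETATM records, remapped to Met),
#' drops waters, other heteroatoms and hydrogens, resolves alternate
#' locations to the highest-occupancy conformer (ties broken towards
#' altloc "A") and orders residues by chain, then residue number and
#' insertion code.
#'
#' @param pdb_source Path to a PDB file, or PDB text (a single string
#'   with embedded newlines or a character vector of lines).
#' @param model_policy `"first"` (default) keeps MODEL 1 only;
#'   `"index"` selects the model given by `model_index`.
#' @param model_index Model number used when `model_policy = "index"`.
#' @param id Label for the structure; defaults to the file name.
#' @return An object of class `spr_structure`: a list with an `atoms`
#'   data frame (one row per heavy atom, with coordinates, element,
#'   van der Waals radius and side-chain flag), a `residues` data
#'   frame (per-residue type, ASA and secondary structure slots) and
#'   bookkeeping fields.
#' @export
read_structure <- function(pdb_source, model_policy = c("first", "index"),
                           model_index = 1L, id = NULL) {
  model_policy <- match.arg(model_policy)
  is_text <- length(pdb_source) > 1L ||
    (is.character(pdb_source) && grepl("\n", pdb_source[1], fixed = TRUE)) ||
    (is.character(pdb_source) && !file.exists(pdb_source) &&
       grepl("^(ATOM|HETATM|MODEL|HEADER|REMARK)", pdb_source[1]))
  if (is_text) {
    path <- tempfile(fileext = ".pdb")
    writeLines(unlist(strsplit(pdb_source, "\n", fixed = TRUE)), path)
    on.exit(unlink(path), add = TRUE)
    src <- NA_character_
  } else {
    if (!file.exists(pdb_source)) stop("PDB file not found: ", pdb_source)
    path <- pdb_source
    src <- normalizePath(pdb_source)
  }
  if (is.null(id)) id <- if (is.na(src)) "structure" else
    sub("\\.(pdb|ent)$", "", basename(src))

  multi <- model_policy == "index"
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = multi, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("PDB format error: ", conditionMessage(e))
  )
  at <- pdb$atom
  if (multi) {
    nmod <- nrow(pdb$xyz)
    if (model_index < 1L || model_index > nmod) {
      stop("model_index ", model_index, " out of range (", nmod, " models)")
    }
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
    n <- min(nrow(at), nrow(xyz))
    at <- at[seq_len(n), , drop = FALSE]
    at$x <- xyz[seq_len(n), 1]
    at$y <- xyz[seq_len(n), 2]
    at$z <- xyz[seq_len(n), 3]
  }

  keep <- (at$type == "ATOM" | (at$type == "HETATM" & at$resid == "MSE")) &
    !(at$resid %in% WATER_RESIDUES)
  at <- at[keep, , drop = FALSE]
  if (nrow(at)) {
    at$element <- derive_element(at$elety, at$elesy)
    at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]
  }
  if (!nrow(at)) stop("empty structure: no protein residues found")

  # altloc: keep highest occupancy per (chain, resno, icode, atom name);
  # ties resolved towards the alphabetically first altloc ("A").
  occ <- ifelse(is.na(at$o), 1, at$o)
  alt <- ifelse(is.na(at$alt), "", at$alt)
  key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
               at$elety, sep = "\r")
  ord <- order(key, -occ, alt, method = "radix")
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]

  chain <- ifelse(is.na(at$chain), " ", at$chain)
  icode <- ifelse(is.na(at$insert), "", at$insert)
  resid3 <- ifelse(at$resid == "MSE", "MET", at$resid)
  res_type <- unname(AA3TO1[resid3])
  res_type[is.na(res_type)] <- "X"

  atoms <- data.frame(
    chain = chain, resno = at$resno, icode = icode,
    resid3 = resid3, res_type = res_type,
    elety = at$elety, element = at$element,
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    stringsAsFactors = FALSE
  )
  atoms$vdw <- unname(VDW_RADII[atoms$element])
  atoms$vdw[is.na(atoms$vdw)] <- VDW_DEFAULT
  atoms$is_sidechain <- !(atoms$elety %in% BACKBONE_ATOMS)
  atoms$asa <- NA_real_
  atoms$res_id <- res_id(atoms$chain, atoms$resno, atoms$icode)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("PDB format error: non-finite coordinates")
  }
  new_structure(atoms, id = id, source_path = src)
}

#' Restrict a structure to a set of chains
#'
#' Returns a new structure containing only the given chains. ASA and
#' secondary-structure fields are reset, since they depend on the
#' molecular context.
#'
#' @param struct An `spr_structure`.
#' @param chains Character vector of chain identifiers to keep.
#' @return An `spr_structure` for the selected chains.
#' @export
subset_structure <- function(struct, chains) {
  stopifnot(inherits(struct, "spr_structure"))
  atoms <- struct$atoms[struct$atoms$chain %in% chains, , drop = FALSE]
  if (!nrow(atoms)) stop("no atoms in chains: ", paste(chains, collapse = ","))
  atoms$asa <- NA_real_
  new_structure(atoms, id = paste0(struct$id, ":", paste(chains, collapse = "")),
                source_path = struct$source_path)
}

#' Per-residue table of a structure
#'
#' @param struct An `spr_structure`.
#' @return Data frame with one row per residue: identifiers, type,
#'   atom count, ASA, relative ASA and secondary-structure state.
#' @export
residue_table <- function(struct) {
  stopifnot(inherits(struct, "spr_structure"))
  struct$residues
}

#' Total accessible surface area of a structure
#'
#' @param struct An `spr_structure` with ASA computed.
#' @return Sum of per-residue ASA values (A^2).
#' @export
total_asa <- function(struct) {
  stopifnot(inherits(struct, "spr_structure"))
  if (all(is.na(struct$residues$asa))) {
    stop("ASA not computed; call compute_asa() first")
  }
  sum(struct$residues$asa, na.rm = TRUE)
}

chains_of <- function(struct) unique(struct$atoms$chain)

#' @export
print.spr_structure <- function(x, ...) {
  cat("spr_structure", x$id, "\n")
  cat("  chains:  ", paste(chains_of(x), collapse = ", "), "\n")
  cat("  residues:", nrow(x$residues), " atoms:", nrow(x$atoms), "\n")
  if (!all(is.na(x$residues$asa))) {
    cat("  total ASA:", sprintf("%.1f", sum(x$residues$asa, na.rm = TRUE)),
        "A^2\n")
  }
  invisible(x)
}

#' Write per-residue ASA/secondary-structure table as TSV
#'
#' @param struct An `spr_structure` with ASA computed.
#' @param path Output file path.
#' @return Invisibly, the written data frame.
#' @export
write_asa_table <- function(struct, path) {
  res <- residue_table(struct)
  out <- data.frame(
    chain = res$chain, resseq = res$resno, icode = res$icode,
    res_type = res$res_type,
    asa = round(res$asa, 3), rel_asa = round(res$rel_asa, 4),
    ss_state = ifelse(is.na(res$ss), ".", res$ss)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
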