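# PSI-BLAST ASCII PSSM files: reading the 20-column integer score
# block and writing toy profiles for the synthetic fixtures.

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the first (log-odds) 20-column integer block of a PSSM
#' written with PSI-BLAST's `-out_ascii_pssm`.
#'
#' @param path Path to the ASCII PSSM file.
#' @return Object of class `spr_pssm`: list with `pos` (1-based
#'   positions), `aa` (query residue letters) and `scores` (n x 20
#'   integer matrix with columns in PSI-BLAST order
#'   A R N D C Q E G H I L K M F P S T W Y V).
#' @export
read_pssm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # data rows: position, residue letter, then at least 20 integers
  pat <- "^\\s*\\d+\\s+[A-Z](\\s+-?\\d+){20,}"
  rows <- grep(pat, lines, value = TRUE)
  if (!length(rows)) stop("PSSM format error: no score rows found in ", path)
  toks <- strsplit(trimws(rows), "\\s+")
  pos <- vapply(toks, function(t) as.integer(t[1]), integer(1))
  aa <- vapply(toks, function(t) t[2], character(1))
  scores <- t(vapply(toks, function(t) as.integer(t[3:22]), integer(20)))
  colnames(scores) <- PSSM_COLS
  structure(list(pos = pos, aa = aa, scores = scores, source = path),
            class = "spr_pssm")
}

#' Write a toy PSI-BLAST-style ASCII PSSM
#'
#' Produces a file in the `-out_ascii_pssm` dialect in which each
#' position's self-substitution score equals the BLOSUM62 diagonal of
#' its residue plus a per-position conservation offset; other columns
#' carry a filler score. Round-tripping through [read_pssm()] recovers
#' the offsets exactly.
#'
#' @param res_types Character vector of one-letter residue types (the
#'   chain sequence).
#' @param offsets Per-position conservation offsets (recycled).
#' @param path Optional output path; when `NULL` the text is returned.
#' @return Invisibly, the lines written (or returned).
#' @export
make_toy_pssm <- function(res_types, offsets = 0, path = NULL) {
  if (!all(res_types %in% AA20)) {
    stop("res_types must be standard one-letter codes")
  }
  n <- length(res_types)
  offsets <- rep_len(offsets, n)
  scores <- matrix(-1L, n, 20, dimnames = list(NULL, PSSM_COLS))
  for (i in seq_len(n)) {
    scores[i, res_types[i]] <- as.integer(BLOSUM62_DIAG[res_types[i]] +
                                            offsets[i])
  }
  header <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("           ", paste(sprintf("%3s", PSSM_COLS), collapse = ""))
  )
  body <- vapply(seq_len(n), function(i) {
    paste0(sprintf("%5d %s ", i, res_types[i]),
           paste(sprintf("%3d", scores[i, ]), collapse = ""))
  }, character(1))
  lines <- c(header, body, "", "                      K         Lambda")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

# self-substitution scores C_ir for given residue ids of a structure;
# pssm rows are aligned 1:1, in order, to the chain's residues
pssm_self_scores <- function(pssm, struct, ids) {
  stopifnot(inherits(pssm, "spr_pssm"))
  res <- struct$residues
  idx <- match(ids, res$res_id)
  if (anyNA(idx)) stop("unknown residue ids for PSSM lookup")
  # position within chain
  chain_pos <- stats::setNames(stats::ave(seq_len(nrow(res)), res$chain,
                                          FUN = seq_along), res$res_id)
  pos <- chain_pos[ids]
  if (any(pos > nrow(pssm$scores))) {
    stop("PSSM shorter than chain: alignment error")
  }
  types <- res$res_type[idx]
  mism <- which(pssm$aa[pos] != types & types != "X")
  if (length(mism)) {
    stop("PSSM/structure residue mismatch at: ",
         paste(utils::head(ids[mism], 5), collapse = ", "))
  }
  vapply(seq_along(ids), function(k) {
    if (types[k] == "X") return(NA_real_)
    as.numeric(pssm$scores[pos[k], types[k]])
  }, numeric(1))
}
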