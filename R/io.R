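# Dataset-level pipelines and table/JSON output.

#' Read a complex partition manifest
#'
#' TSV with columns `file`, `side_a`, `side_b`; chain lists within a
#' side are comma-separated.
#'
#' @param path Manifest path.
#' @return Data frame with `file` and list columns `side_a`, `side_b`.
#' @export
read_partition_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("file", "side_a", "side_b")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  m$side_a <- strsplit(m$side_a, ",", fixed = TRUE)
  m$side_b <- strsplit(m$side_b, ",", fixed = TRUE)
  m
}

#' Extract interfaces for a directory of complexes
#'
#' Reads every complex named in the manifest, assigns secondary
#' structure with the built-in assigner, and extracts its interface.
#'
#' @param dir Directory containing the PDB files.
#' @param manifest Data frame from [read_partition_manifest()] (or a
#'   path to one).
#' @param ... Passed to [extract_interface()].
#' @return List of `spr_interface` annotations.
#' @export
analyze_complexes <- function(dir, manifest, ...) {
  if (is.character(manifest)) manifest <- read_partition_manifest(manifest)
  lapply(seq_len(nrow(manifest)), function(i) {
    cx <- read_structure(file.path(dir, manifest$file[i]))
    cx <- assign_secondary_structure(cx)
    part <- complex_partition(cx, manifest$side_a[[i]], manifest$side_b[[i]])
    extract_interface(part, ...)
  })
}

#' Write a propensity table as TSV
#'
#' @param pt An `spr_propensity` table.
#' @param path Output path.
#' @return Invisibly, the written data frame (values rounded to 3
#'   decimals at report time).
#' @export
write_propensity_table <- function(pt, path) {
  out <- pt
  for (cl in c("w", "W", "rir")) out[[cl]] <- round(out[[cl]], 3)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Write contact statistics in long format
#'
#' One row per unordered type pair with count, frequency and
#' preference.
#'
#' @param cm An `spr_contacts` object.
#' @param path Output path.
#' @return Invisibly, the written data frame.
#' @export
write_contact_table <- function(cm, path) {
  types <- rownames(cm$C)
  idx <- which(upper.tri(cm$C, diag = TRUE), arr.ind = TRUE)
  out <- data.frame(
    type_i = types[idx[, 1]], type_j = types[idx[, 2]],
    count = cm$C[idx],
    freq = round(cm$freq[idx], 6),
    pref = round(cm$pref[idx], 3)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Write a prediction as JSON and TSV
#'
#' @param top Result of [predict_interface()] (top patch with the
#'   ranked list attached).
#' @param struct The predicted structure.
#' @param out_dir Output directory.
#' @param name Base name for the output files.
#' @return Invisibly, the paths written.
#' @export
write_prediction <- function(top, struct, out_dir, name = "prediction") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ranked <- attr(top, "ranked")
  js <- lapply(seq_along(ranked), function(k) {
    p <- ranked[[k]]
    list(rank = k, seed = if (is.na(p$seed)) NULL else p$seed,
         members = p$members,
         e_res = p$e_res, e_hydro = p$e_hydro, e_cons = p$e_cons,
         e_sol = p$e_sol, e_patch = p$e_patch)
  })
  json_path <- file.path(out_dir, paste0(name, ".json"))
  jsonlite::write_json(js, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  res <- struct$residues
  rows <- do.call(rbind, lapply(seq_along(ranked), function(k) {
    p <- ranked[[k]]
    i <- match(p$members, res$res_id)
    data.frame(chain = res$chain[i], resseq = res$resno[i],
               res_type = res$res_type[i], rank = k,
               e_patch = round(p$e_patch, 4))
  }))
  tsv_path <- file.path(out_dir, paste0(name, ".tsv"))
  utils::write.table(rows, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(json = json_path, tsv = tsv_path))
}

#' Read scoring weights from a JSON file
#'
#' @param path JSON file with fields `w1`, `w2`, `w3`.
#' @return Named numeric vector.
#' @export
read_weights <- function(path) {
  w <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights_vec(unlist(w))
}

# run manifest: inputs, parameters, package version, seed
write_run_manifest <- function(out_dir, subcommand, params) {
  manifest <- list(
    subcommand = subcommand,
    parameters = params,
    package = "ppiprop",
    version = as.character(utils::packageVersion("ppiprop")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
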