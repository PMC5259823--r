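# Propensity statistics: relative interface ratios (RIR) over residue
# types, secondary-structure states, 60 combined classes and per-type
# ASA classes; inter-chain contact frequencies/preferences; size
# distributions.

# stack per-residue annotation rows of one or many spr_interface
# objects
annotation_rows <- function(annotations) {
  if (inherits(annotations, "spr_interface")) annotations <- list(annotations)
  stopifnot(all(vapply(annotations, inherits, logical(1), "spr_interface")))
  do.call(rbind, lapply(annotations, `[[`, "residues"))
}

count_by <- function(keys) {
  if (!length(keys)) return(stats::setNames(integer(0), character(0)))
  tb <- table(keys)
  stats::setNames(as.integer(tb), names(tb))
}

#' Relative interface ratios from count maps
#'
#' Given interface counts `f_i` and non-interface surface counts `F_i`
#' per class, computes the class frequencies `w_i = f_i / sum(f)`,
#' `W_i = F_i / sum(F)` and the relative interface ratio
#' `RIR_i = w_i / W_i`. A class with `W_i = 0` (and no pseudocount)
#' gets an undefined RIR (`NA`) rather than an error.
#'
#' @param interface_counts Named integer vector of interface counts.
#' @param noninterface_counts Named integer vector of non-interface
#'   surface counts.
#' @param pseudocount Added to every class count (union of keys) before
#'   normalization (default 0).
#' @return A data frame of class `spr_propensity` with columns `key`,
#'   `f`, `F`, `w`, `W`, `rir`.
#' @export
compute_rir <- function(interface_counts, noninterface_counts,
                        pseudocount = 0) {
  keys <- sort(union(names(interface_counts), names(noninterface_counts)))
  if (!length(keys)) stop("no classes to compare")
  f <- stats::setNames(rep(0, length(keys)), keys)
  Fc <- f
  f[names(interface_counts)] <- interface_counts
  Fc[names(noninterface_counts)] <- noninterface_counts
  if (any(f < 0) || any(Fc < 0)) stop("counts must be non-negative")
  f <- f + pseudocount
  Fc <- Fc + pseudocount
  if (sum(f) <= 0 || sum(Fc) <= 0) {
    stop("total counts must be positive on both sides")
  }
  w <- f / sum(f)
  W <- Fc / sum(Fc)
  rir <- ifelse(W > 0, w / W, NA_real_)
  out <- data.frame(key = keys, f = unname(f), F = unname(Fc),
                    w = unname(w), W = unname(W), rir = unname(rir),
                    stringsAsFactors = FALSE)
  class(out) <- c("spr_propensity", "data.frame")
  out
}

# interface / non-interface count maps keyed by residue type, SS state
# or the 60 combined classes; nonstandard residues are excluded from
# type-keyed counts
propensity_counts <- function(annotations, key = c("type", "ss", "type_ss")) {
  key <- match.arg(key)
  rows <- annotation_rows(annotations)
  rows <- rows[rows$class %in% c("interface", "noninterface"), , drop = FALSE]
  if (key != "ss") rows <- rows[rows$res_type != "X", , drop = FALSE]
  if (key %in% c("ss", "type_ss") && anyNA(rows$ss)) {
    stop("secondary structure not assigned; run assign_secondary_structure()",
         " on the complexes before extraction")
  }
  k <- switch(key,
              type = rows$res_type,
              ss = rows$ss,
              type_ss = paste(rows$res_type, rows$ss, sep = ":"))
  list(interface = count_by(k[rows$class == "interface"]),
       noninterface = count_by(k[rows$class == "noninterface"]))
}

#' Residue-type RIR table (the QIPI of a dataset)
#'
#' @param annotations One `spr_interface` or a list of them.
#' @param pseudocount Passed to [compute_rir()].
#' @return An `spr_propensity` table keyed by the 20 residue types.
#' @export
rir_by_type <- function(annotations, pseudocount = 0) {
  cts <- propensity_counts(annotations, "type")
  compute_rir(cts$interface, cts$noninterface, pseudocount)
}

#' Secondary-structure and 60-class RIR tables
#'
#' Computes the 3-key RIR table over \{H, E, C\} and the 60-key table
#' over residue type x secondary-structure state.
#'
#' @param annotations One `spr_interface` or a list of them; secondary
#'   structure must have been assigned on the complexes.
#' @param pseudocount Passed to [compute_rir()].
#' @return List with elements `ss` (3 keys) and `class60` (type:ss
#'   keys), both `spr_propensity` tables.
#' @export
ss_and_class60_rir <- function(annotations, pseudocount = 0) {
  ss <- propensity_counts(annotations, "ss")
  c60 <- propensity_counts(annotations, "type_ss")
  list(ss = compute_rir(ss$interface, ss$noninterface, pseudocount),
       class60 = compute_rir(c60$interface, c60$noninterface, pseudocount))
}

#' ASA threshold and ASA-class RIR for one residue type
#'
#' Builds normalized ASA histograms (bin width `bin_width`, from 0) of
#' interface and non-interface surface residues of the given type. The
#' threshold `A_t` is the lower edge of the first bin where the
#' difference between the two normalized histograms changes sign (the
#' bin where the two frequencies cross). The 2x2 ASA-class RIR is then
#' `(f_IL/f_IS) / (f_SL/f_SS)` with `f_IS`/`f_IL` the interface counts
#' below / at-or-above `A_t` and `f_SS`/`f_SL` the non-interface
#' counts.
#'
#' @param annotations One `spr_interface` or a list of them.
#' @param res_type One-letter residue type.
#' @param bin_width Histogram bin width in A^2 (default 5).
#' @return List of class `spr_asa_class` with fields `res_type`, `A_t`
#'   (NA when the histograms never cross), the four counts and
#'   `asa_rir` (NA when any denominator count is zero).
#' @export
asa_threshold_and_rir <- function(annotations, res_type, bin_width = 5) {
  stopifnot(is.character(res_type), length(res_type) == 1L)
  rows <- annotation_rows(annotations)
  rows <- rows[rows$res_type == res_type, , drop = FALSE]
  asa_int <- rows$asa_unbound[rows$class == "interface"]
  asa_non <- rows$asa_unbound[rows$class == "noninterface"]
  if (!length(asa_int) || !length(asa_non)) {
    stop("no ", res_type, " residues on one of the two surfaces")
  }
  breaks <- seq(0, bin_width * ceiling(max(asa_int, asa_non) / bin_width) +
                  bin_width, by = bin_width)
  p_int <- tabulate(findInterval(asa_int, breaks, left.open = FALSE),
                    nbins = length(breaks) - 1) / length(asa_int)
  p_non <- tabulate(findInterval(asa_non, breaks, left.open = FALSE),
                    nbins = length(breaks) - 1) / length(asa_non)
  d <- p_int - p_non
  s <- sign(d)
  nz <- which(s != 0)
  a_t <- NA_real_
  if (length(nz) >= 2) {
    first_sign <- s[nz[1]]
    flip <- nz[which(s[nz] != first_sign)[1]]
    if (!is.na(flip)) a_t <- breaks[flip]
  }
  f_is <- f_il <- f_ss <- f_sl <- NA_integer_
  asa_rir <- NA_real_
  if (!is.na(a_t)) {
    f_is <- sum(asa_int < a_t)
    f_il <- sum(asa_int >= a_t)
    f_ss <- sum(asa_non < a_t)
    f_sl <- sum(asa_non >= a_t)
    if (f_is > 0 && f_sl > 0 && f_ss > 0) {
      asa_rir <- (f_il / f_is) / (f_sl / f_ss)
    }
  }
  structure(list(res_type = res_type, A_t = a_t,
                 f_IS = f_is, f_IL = f_il, f_SS = f_ss, f_SL = f_sl,
                 asa_rir = asa_rir, bin_width = bin_width),
            class = "spr_asa_class")
}

#' Inter-chain residue contact statistics
#'
#' Counts unordered residue-type pairs, one count per contacting
#' residue pair. `freq` is each pair count divided by the total number
#' of contacts (summing to 1 over unordered cells). The contact
#' preference is `log2(freq / e)` against the random-mixing
#' expectation `e = 2 w_i w_j` for distinct types and `w_i^2` on the
#' diagonal, with `w` the interface residue-type frequencies of the
#' same annotation set; cells with no observed contacts are `NA`
#' (flagged, not zero-filled). `groups4` aggregates counts over the
#' four chemical groups (basic, hydrophobic, polar, acidic) and applies
#' the same formulas with group frequencies.
#'
#' @param annotations One `spr_interface` or a list of them.
#' @return Object of class `spr_contacts` with symmetric matrices `C`,
#'   `freq`, `pref` (20 x 20), the group-level `groups4` list, the
#'   frequencies `w` and the total contact count.
#' @export
contact_statistics <- function(annotations) {
  if (inherits(annotations, "spr_interface")) annotations <- list(annotations)
  rows <- annotation_rows(annotations)
  type_of <- stats::setNames(rows$res_type, rows$res_id)
  pairs <- do.call(rbind, lapply(annotations, function(a) {
    cc <- a$cross_contacts
    if (!nrow(cc)) return(NULL)
    data.frame(ta = unname(type_of[cc$a]), tb = unname(type_of[cc$b]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(pairs) || !nrow(pairs)) {
    stop("empty contact matrix: no cross-interface contacts")
  }
  pairs <- pairs[!is.na(pairs$ta) & !is.na(pairs$tb) &
                   pairs$ta %in% AA20 & pairs$tb %in% AA20, , drop = FALSE]
  if (!nrow(pairs)) stop("empty contact matrix: no standard-residue contacts")
  w_tab <- rir_by_type(annotations)
  w <- stats::setNames(rep(0, 20), AA20)
  w[w_tab$key] <- w_tab$w

  tally <- function(ta, tb, types, wts) {
    # record each unordered pair once (alphabetical canonical order),
    # then mirror into a symmetric count matrix
    lo <- pmin(ta, tb)
    hi <- pmax(ta, tb)
    tb2 <- as.matrix(table(factor(lo, levels = types),
                           factor(hi, levels = types)))
    C <- tb2 + t(tb2)
    diag(C) <- diag(tb2)
    dimnames(C) <- list(types, types)
    total <- sum(C[upper.tri(C, diag = TRUE)])
    freq <- C / total
    e <- 2 * outer(wts, wts)
    diag(e) <- wts^2
    pref <- suppressWarnings(log2(freq / e))
    pref[C == 0] <- NA_real_
    list(C = C, freq = freq, pref = pref, total = total)
  }
  m20 <- tally(pairs$ta, pairs$tb, AA20, w)
  groups <- unique(unname(GROUP4))
  gw <- vapply(groups, function(g) sum(w[names(GROUP4)[GROUP4 == g]]),
               numeric(1))
  g4 <- tally(unname(GROUP4[pairs$ta]), unname(GROUP4[pairs$tb]), groups, gw)
  structure(list(C = m20$C, freq = m20$freq, pref = m20$pref,
                 total = m20$total, w = w, groups4 = g4),
            class = "spr_contacts")
}

#' Interface and domain size distributions
#'
#' Collects per-side interface area (sum of delta-ASA over interface
#' residues), per-side interface residue count and per-domain total
#' ASA, and summarizes each with mean, median and method-of-moments
#' gamma parameters (shape = mean^2/var, scale = var/mean).
#'
#' @param annotations One `spr_interface` or a list of them (possibly
#'   empty).
#' @return List with `samples` (one row per interface side) and
#'   `summary` (one row per metric).
#' @export
size_distributions <- function(annotations) {
  if (inherits(annotations, "spr_interface")) annotations <- list(annotations)
  if (!length(annotations)) {
    return(list(samples = data.frame(), summary = data.frame()))
  }
  samples <- do.call(rbind, lapply(annotations, function(a) {
    data.frame(
      id = a$id, side = c("a", "b"),
      interface_area = unname(a$interface_area[c("a", "b")]),
      interface_residues = c(length(a$interface_residues$a),
                             length(a$interface_residues$b)),
      domain_asa = unname(a$domain_asa[c("a", "b")]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(samples) <- NULL
  summarize <- function(x, metric) {
    m <- mean(x)
    v <- stats::var(x)
    shape <- if (isTRUE(v > 0)) m^2 / v else NA_real_
    data.frame(metric = metric, n = length(x), mean = m,
               median = stats::median(x),
               gamma_shape = shape,
               gamma_scale = if (isTRUE(v > 0)) v / m else NA_real_)
  }
  summary <- rbind(
    summarize(samples$interface_area, "interface_area"),
    summarize(samples$interface_residues, "interface_residues"),
    summarize(samples$domain_asa, "domain_asa")
  )
  list(samples = samples, summary = summary)
}
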