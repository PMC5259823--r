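# Evaluation and training: coverage / accuracy / F, macro and micro
# aggregation, grid search over scoring weights and k-fold
# cross-validation.

new_eval <- function(tp, fp, fn, cov, acc) {
  data.frame(tp = tp, fp = fp, fn = fn, cov = cov, acc = acc,
             f = cov * acc)
}

#' Evaluate a predicted interface against the truth
#'
#' `TP = |pred & truth|`, `FP = |pred \ truth|`, `FN = |truth \ pred|`;
#' coverage `COV = TP/(TP+FN)`, accuracy `ACC = TP/(TP+FP)` and
#' `F = COV * ACC`. Conventions for empty sets: empty truth with empty
#' prediction scores 1/1; empty truth with a non-empty prediction has
#' undefined coverage (`NA`) and accuracy 0; an empty prediction
#' against a non-empty truth scores 0/0.
#'
#' @param predicted Character vector of predicted interface residue
#'   identifiers (or an `spr_patch`).
#' @param truth Character vector of true interface residue identifiers.
#' @return One-row data frame with `tp`, `fp`, `fn`, `cov`, `acc`, `f`.
#' @export
evaluate_prediction <- function(predicted, truth) {
  if (inherits(predicted, "spr_patch")) predicted <- predicted$members
  predicted <- unique(as.character(predicted))
  truth <- unique(as.character(truth))
  tp <- length(intersect(predicted, truth))
  fp <- length(setdiff(predicted, truth))
  fn <- length(setdiff(truth, predicted))
  if (!length(truth)) {
    if (!length(predicted)) return(new_eval(0L, 0L, 0L, 1, 1))
    return(new_eval(0L, fp, 0L, NA_real_, 0))
  }
  if (!length(predicted)) return(new_eval(0L, 0L, fn, 0, 0))
  new_eval(tp, fp, fn, tp / (tp + fn), tp / (tp + fp))
}

#' Aggregate per-case evaluation results
#'
#' Macro aggregation averages per-case coverage and accuracy, then
#' takes `f = cov * acc`; micro aggregation pools the TP/FP/FN counts
#' and applies the formulas to the pooled counts.
#'
#' @param results Data frame of per-case results (rows from
#'   [evaluate_prediction()]).
#' @param mode `"macro"` (default) or `"micro"`.
#' @return One-row data frame with `tp`, `fp`, `fn`, `cov`, `acc`, `f`.
#' @export
aggregate_eval <- function(results, mode = c("macro", "micro")) {
  mode <- match.arg(mode)
  if (is.list(results) && !is.data.frame(results)) {
    results <- do.call(rbind, results)
  }
  if (!nrow(results)) stop("no results to aggregate")
  if (mode == "macro") {
    cov <- mean(results$cov, na.rm = TRUE)
    acc <- mean(results$acc, na.rm = TRUE)
    return(new_eval(sum(results$tp), sum(results$fp), sum(results$fn),
                    cov, acc))
  }
  tp <- sum(results$tp)
  fp <- sum(results$fp)
  fn <- sum(results$fn)
  cov <- if (tp + fn > 0) tp / (tp + fn) else 1
  acc <- if (tp + fp > 0) tp / (tp + fp) else 1
  new_eval(tp, fp, fn, cov, acc)
}

# Precompute, per case, the merged candidate patches with their four
# component scores and their cov/acc against the truth, so that a grid
# search only re-ranks. A "case" is list(struct, truth, pssm optional).
prepare_cases <- function(cases, use_cons = TRUE, use_sol = TRUE,
                          tables = spr_constants()) {
  lapply(cases, function(cs) {
    struct <- cs$struct
    if (all(is.na(struct$residues$asa))) struct <- compute_asa(struct)
    dm <- sidechain_distance_matrix(struct)
    patches <- generate_patches(struct, dm, tables$patch_growth)
    merged <- merge_patches(patches, total_asa(struct),
                            tables$merge_thresholds)
    pssm <- if (use_cons) cs$pssm else NULL
    comp <- t(vapply(merged, function(p) {
      c(e_res = score_eres(p, struct, tables),
        e_hydro = score_ehydro(p, struct, tables),
        e_cons = if (!is.null(pssm)) score_econs(p, struct, pssm, tables)
                 else 0,
        e_sol = if (use_sol) score_esol(p, struct) else 0)
    }, numeric(4)))
    ev <- do.call(rbind, lapply(merged, evaluate_prediction, truth = cs$truth))
    sz <- vapply(merged, function(p) length(p$members), integer(1))
    keys <- vapply(merged, function(p) patch_key(p$members), character(1))
    list(patches = merged, components = comp, eval = ev,
         size = sz, keys = keys)
  })
}

# index of the top patch under given weights with deterministic
# tie-breaks (larger, then lexicographically smaller member set)
top_patch_index <- function(prep, w) {
  sc <- prep$components[, "e_res"] + w[["w1"]] * prep$components[, "e_hydro"] +
    w[["w2"]] * prep$components[, "e_cons"] +
    w[["w3"]] * prep$components[, "e_sol"]
  order(-sc, -prep$size, prep$keys, method = "radix")[1]
}

#' Train scoring weights by exhaustive grid search
#'
#' For every weight triple on the grid, each training case is predicted
#' (top-ranked patch among its merged candidates) and scored against
#' its truth annotation; the objective is the mean per-case
#' `F = COV * ACC`. The argmax triple is returned, with ties broken
#' towards the lexicographically smallest `(w1, w2, w3)`.
#'
#' @param cases List of cases, each `list(struct=, truth=, pssm=)`
#'   (`pssm` optional).
#' @param grid Named list with numeric vectors `w1`, `w2`, `w3`.
#' @param use_cons,use_sol Enable the conservation / solvation
#'   components (a disabled component contributes 0 everywhere).
#' @param tables Constant tables.
#' @param prepared Optional precomputed result of the internal case
#'   preparation (reused by [cross_validate()]).
#' @return List with `weights` (named `w1`, `w2`, `w3`), `objective`
#'   (the achieved mean F) and `surface` (the full grid with its mean-F
#'   values).
#' @export
train_weights <- function(cases,
                          grid = list(w1 = c(0, 0.25, 0.5, 1, 2),
                                      w2 = c(0, 0.25, 0.5, 1, 2),
                                      w3 = c(0, 0.25, 0.5, 1, 2)),
                          use_cons = TRUE, use_sol = TRUE,
                          tables = spr_constants(), prepared = NULL) {
  if (!all(c("w1", "w2", "w3") %in% names(grid)) ||
      !all(lengths(grid[c("w1", "w2", "w3")]) > 0)) {
    stop("config error: grid must provide non-empty w1, w2, w3")
  }
  if (!length(cases)) stop("config error: no training cases")
  if (is.null(prepared)) {
    prepared <- prepare_cases(cases, use_cons, use_sol, tables)
  }
  surface <- expand.grid(w1 = sort(grid$w1), w2 = sort(grid$w2),
                         w3 = sort(grid$w3), KEEP.OUT.ATTRS = FALSE)
  # lexicographic order over (w1, w2, w3) so the first argmax is the tie-break
  surface <- surface[order(surface$w1, surface$w2, surface$w3), , drop = FALSE]
  rownames(surface) <- NULL
  surface$objective <- vapply(seq_len(nrow(surface)), function(k) {
    w <- c(w1 = surface$w1[k], w2 = surface$w2[k], w3 = surface$w3[k])
    fs <- vapply(prepared, function(pr) pr$eval$f[top_patch_index(pr, w)],
                 numeric(1))
    mean(fs)
  }, numeric(1))
  best <- which.max(surface$objective)  # first maximum = smallest triple
  list(weights = c(w1 = surface$w1[best], w2 = surface$w2[best],
                   w3 = surface$w3[best]),
       objective = surface$objective[best],
       surface = surface)
}

#' k-fold cross-validation of the weight training
#'
#' Splits the cases into `folds` folds with a seeded deterministic
#' shuffle, trains the weights on each training split and evaluates
#' the held-out fold (macro aggregation of per-case coverage and
#' accuracy), reporting per-fold results and the mean and standard
#' deviation across folds.
#'
#' @inheritParams train_weights
#' @param folds Number of folds (>= 2, at most the number of cases).
#' @param seed Integer seed for the fold shuffle.
#' @return List with `per_fold` (fold, cov, acc, f, chosen weights),
#'   `mean` and `sd` (named vectors over cov and acc) and `folds`.
#' @export
cross_validate <- function(cases, folds = 10L, seed = 1L,
                           grid = list(w1 = c(0, 0.25, 0.5, 1, 2),
                                       w2 = c(0, 0.25, 0.5, 1, 2),
                                       w3 = c(0, 0.25, 0.5, 1, 2)),
                           use_cons = TRUE, use_sol = TRUE,
                           tables = spr_constants()) {
  n <- length(cases)
  if (folds < 2L) stop("config error: folds must be >= 2")
  if (folds > n) stop("config error: more folds than cases")
  perm <- deterministic_permutation(n, seed)
  assignment <- integer(n)
  assignment[perm] <- rep_len(seq_len(folds), n)
  prepared <- prepare_cases(cases, use_cons, use_sol, tables)
  rows <- vector("list", folds)
  for (k in seq_len(folds)) {
    test_idx <- which(assignment == k)
    train_idx <- setdiff(seq_len(n), test_idx)
    tr <- train_weights(cases[train_idx], grid, use_cons, use_sol, tables,
                        prepared = prepared[train_idx])
    ev <- do.call(rbind, lapply(prepared[test_idx], function(pr) {
      pr$eval[top_patch_index(pr, tr$weights), , drop = FALSE]
    }))
    agg <- aggregate_eval(ev, "macro")
    rows[[k]] <- data.frame(fold = k, cov = agg$cov, acc = agg$acc,
                            f = agg$f, w1 = tr$weights[["w1"]],
                            w2 = tr$weights[["w2"]], w3 = tr$weights[["w3"]])
  }
  per_fold <- do.call(rbind, rows)
  list(per_fold = per_fold,
       mean = c(cov = mean(per_fold$cov), acc = mean(per_fold$acc)),
       sd = c(cov = stats::sd(per_fold$cov), acc = stats::sd(per_fold$acc)),
       folds = folds, seed = seed)
}

# seeded permutation that does not disturb the caller's RNG state
deterministic_permutation <- function(n, seed) {
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
  sample.int(n)
}
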