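# Feature-space scanning over the Firth ranking, and the brute-force
# small-combination logistic baseline.

#' Scan the ranked feature space in fixed increments
#'
#' Evaluates nested panels of the top-k ranked features for k = step,
#' 2*step, ..., n (the full set is always evaluated) using a caller-supplied
#' training closure, and returns the panel size maximizing the closure's
#' cross-validated AUC. Ties break toward the smaller panel.
#'
#' @param ranked character vector of features in rank order (best first),
#'   e.g. `rank_features(...)$feature`.
#' @param builder function(panel) returning a mean CV AUC for that panel.
#' @param step increment in number of features.
#' @return list with `best_k`, `best_auc` and `auc_by_k` (data frame).
#' @export
scan_feature_space <- function(ranked, builder, step = 10) {
  stopifnot(length(ranked) >= 1, step >= 1)
  n <- length(ranked)
  ks <- unique(c(seq(min(step, n), n, by = step), n))
  auc <- vapply(ks, function(k) builder(ranked[seq_len(k)]), numeric(1))
  best <- ks[which.max(auc)]  # which.max takes the first (smallest k) on ties
  list(best_k = best, best_auc = max(auc),
       auc_by_k = data.frame(k = ks, cv_auc = auc))
}

#' Brute-force scan of small marker combinations
#'
#' Fits a plain logistic regression for every combination of up to
#' `max_size` markers under a repeated stratified CV plan and ranks
#' combinations by mean out-of-fold AUC. Non-convergent combinations are
#' scored `NA` and ranked last.
#'
#' @param x a [cohort] (markers imputed).
#' @param markers marker names to scan (warns above 60: C(60,3) is ~34k
#'   fits).
#' @param max_size largest combination size.
#' @param n_folds,n_repeats CV plan.
#' @param seed integer seed.
#' @param oversample oversample minority inside training folds.
#' @return data frame (`combo`, `size`, `cv_auc`) sorted by decreasing AUC.
#' @export
bruteforce_combo_scan <- function(x, markers, max_size = 3, n_folds = 10,
                                  n_repeats = 1, seed = 1L,
                                  oversample = FALSE) {
  if (length(markers) > 60)
    warning("scanning ", length(markers), " markers: combination count is ",
            "large; expect a long runtime", call. = FALSE)
  xm <- cohort_matrix(x, markers)
  y <- x$status
  plan <- make_cv_plan(y, n_folds = n_folds, n_repeats = n_repeats,
                       seed = seed)
  rng <- rng_stream(seed + 1L)
  combos <- unlist(lapply(seq_len(min(max_size, length(markers))), function(k)
    utils::combn(markers, k, simplify = FALSE)), recursive = FALSE)
  auc <- vapply(combos, function(cols) {
    xi <- xm[, cols, drop = FALSE]
    fold_auc <- numeric(0)
    ok <- TRUE
    for (r in seq_len(plan$n_repeats)) {
      fold_id <- plan$folds[[r]]
      for (f in seq_len(plan$n_folds)) {
        tr <- which(fold_id != f); va <- which(fold_id == f)
        idx <- if (oversample) tr[oversample_minority(y[tr], rng$int(1))] else tr
        fit <- tryCatch(
          suppressWarnings(stats::glm.fit(cbind(1, xi[idx, , drop = FALSE]),
                                          y[idx],
                                          family = stats::binomial())),
          error = function(e) NULL)
        if (is.null(fit) || !fit$converged ||
            !all(is.finite(fit$coefficients))) {
          ok <- FALSE
          next
        }
        pred <- stats::plogis(drop(cbind(1, xi[va, , drop = FALSE]) %*%
                                     fit$coefficients))
        fold_auc <- c(fold_auc, roc_auc(pred, y[va]))
      }
    }
    if (!ok || !length(fold_auc)) NA_real_ else mean(fold_auc)
  }, numeric(1))
  out <- data.frame(combo = vapply(combos, paste, character(1), collapse = "+"),
                    size = lengths(combos), cv_auc = auc,
                    stringsAsFactors = FALSE)
  out[order(-out$cv_auc, out$size, out$combo, na.last = TRUE), ,
      drop = FALSE]
}
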