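# ROC/AUC machinery with stratified bootstrap inference and fixed-specificity
# operating points. The AUC is the normalized Mann-Whitney statistic with
# ties counted 1/2, computed from midranks.

#' ROC area under the curve
#'
#' AUC as the Mann-Whitney statistic: the mean over all case-control pairs
#' of `[score_case > score_control] + 0.5 * [equal]`, computed via midranks.
#'
#' @param scores numeric score (higher = more case-like).
#' @param y 0/1 outcomes.
#' @export
roc_auc <- function(scores, y) {
  stopifnot(length(scores) == length(y))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required", call. = FALSE)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Cases and controls are resampled separately with replacement; the
#' percentile interval of the bootstrap AUC distribution is returned. The
#' `significant` attribute flags intervals that exclude 0.5.
#'
#' @param scores,y as in [roc_auc()].
#' @param n_boot bootstrap replicates.
#' @param level confidence level.
#' @param seed integer seed.
#' @return `c(lower, upper)` with attributes `auc`, `significant`.
#' @export
auc_ci_stratified_bootstrap <- function(scores, y, n_boot = 2000,
                                        level = 0.95, seed = 1L) {
  stopifnot(n_boot >= 100)
  cases <- which(y == 1)
  ctrls <- which(y == 0)
  n1 <- length(cases); n0 <- length(ctrls)
  rng <- rng_stream(seed)
  s1 <- scores[cases]; s0 <- scores[ctrls]
  boots <- vapply(seq_len(n_boot), function(b) {
    b1 <- s1[rng$sample(n1, n1, replace = TRUE)]
    b0 <- s0[rng$sample(n0, n0, replace = TRUE)]
    fast_auc(b1, b0)
  }, numeric(1))
  ci <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  structure(c(lower = ci[1], upper = ci[2]),
            auc = roc_auc(scores, y),
            significant = !(ci[1] <= 0.5 && 0.5 <= ci[2]))
}

# AUC from case scores and control scores directly (bootstrap hot path)
fast_auc <- function(s1, s0) {
  r <- rank(c(s1, s0))
  n1 <- length(s1); n0 <- length(s0)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap comparison of two paired ROC curves
#'
#' Both score vectors are evaluated on the same samples; cases and controls
#' are resampled jointly (paired, stratified) and the AUC difference is
#' standardized by its bootstrap standard deviation, giving a two-sided
#' normal p-value. Identical scores (zero bootstrap variance) give p = 1.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param y 0/1 outcomes.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return p-value with attributes `statistic` and `auc` (the two AUCs).
#' @export
compare_roc_bootstrap <- function(scores_a, scores_b, y, n_boot = 2000,
                                  seed = 1L) {
  stopifnot(length(scores_a) == length(y), length(scores_b) == length(y))
  cases <- which(y == 1); ctrls <- which(y == 0)
  n1 <- length(cases); n0 <- length(ctrls)
  rng <- rng_stream(seed)
  d <- vapply(seq_len(n_boot), function(b) {
    i1 <- cases[rng$sample(n1, n1, replace = TRUE)]
    i0 <- ctrls[rng$sample(n0, n0, replace = TRUE)]
    fast_auc(scores_a[i1], scores_a[i0]) - fast_auc(scores_b[i1], scores_b[i0])
  }, numeric(1))
  sd_d <- stats::sd(d)
  auc_a <- roc_auc(scores_a, y); auc_b <- roc_auc(scores_b, y)
  if (!is.finite(sd_d) || sd_d < 1e-12) {
    stat <- 0
    p <- 1
  } else {
    stat <- (auc_a - auc_b) / sd_d
    p <- 2 * stats::pnorm(-abs(stat))
  }
  structure(p, statistic = stat, auc = c(a = auc_a, b = auc_b))
}

#' Operating-point metrics at fixed specificity
#'
#' Chooses the score threshold maximizing sensitivity subject to empirical
#' specificity >= `spec_target` (samples are called positive when their
#' score exceeds the threshold; controls exactly at the threshold count as
#' negative; sensitivity ties break toward the higher-specificity cutoff)
#' and reports the confusion-matrix summaries there. When no case scores
#' above the chosen threshold (e.g. all controls share the maximum score)
#' sensitivity is 0 and the operating point is flagged degenerate.
#'
#' @param scores,y as in [roc_auc()].
#' @param spec_target required specificity.
#' @return list with `threshold`, `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `mcc`, counts `tp/fp/tn/fn`, and `unreachable` flag. MCC is 0
#'   when a marginal factor is 0; PPV/NPV are `NA` when undefined.
#' @export
metrics_at_specificity <- function(scores, y, spec_target = 0.90) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required", call. = FALSE)
  s0 <- scores[y == 0]; s1 <- scores[y == 1]
  cand <- sort(unique(scores))
  spec <- vapply(cand, function(th) mean(s0 <= th), numeric(1))
  feasible <- cand[spec >= spec_target]
  if (!length(feasible)) {
    th <- max(scores) + 1
  } else {
    # maximize sensitivity; among ties prefer the higher-specificity cutoff
    sens <- vapply(feasible, function(th) mean(s1 > th), numeric(1))
    th <- max(feasible[sens == max(sens)])
  }
  tp <- sum(s1 > th); fn <- n1 - tp
  fp <- sum(s0 > th); tn <- n0 - fp
  unreachable <- tp == 0  # degenerate operating point: nothing called positive
  mcc_den <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  list(threshold = th,
       sensitivity = tp / n1,
       specificity = tn / n0,
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       mcc = mcc, tp = tp, fp = fp, tn = tn, fn = fn,
       unreachable = unreachable)
}

#' Full performance report for one score vector
#'
#' AUC with stratified-bootstrap CI plus the fixed-specificity operating
#' point, labelled with the evaluation time-group.
#'
#' @param scores,y as in [roc_auc()].
#' @param group evaluation time-group label.
#' @param spec_target operating specificity.
#' @param n_boot bootstrap replicates for the AUC CI.
#' @param seed integer seed.
#' @return a `performance_report` (one-row data frame).
#' @export
performance_report <- function(scores, y, group = NA_character_,
                               spec_target = 0.90, n_boot = 2000, seed = 1L) {
  ci <- auc_ci_stratified_bootstrap(scores, y, n_boot = n_boot, seed = seed)
  m <- metrics_at_specificity(scores, y, spec_target)
  out <- data.frame(group = group, auc = attr(ci, "auc"),
                    auc_low = ci[["lower"]], auc_high = ci[["upper"]],
                    significant = attr(ci, "significant"),
                    sensitivity = m$sensitivity, specificity = m$specificity,
                    ppv = m$ppv, npv = m$npv, mcc = m$mcc,
                    threshold = m$threshold,
                    n_cases = sum(y == 1), n_controls = sum(y == 0),
                    stringsAsFactors = FALSE)
  class(out) <- c("performance_report", "data.frame")
  out
}

#' Cross-time-group performance matrix
#'
#' Entry (g, h) evaluates the model trained on joined group `g` on the test
#' samples of joined group `h` (cases restricted to `h`; all test controls
#' included). Empty evaluation groups give `NA` with a warning.
#'
#' @param models named list of [stack_model][build_jtg2l()] objects, one per
#'   joined training group.
#' @param test test [cohort] with `single_group` assigned.
#' @param groups joined evaluation groups.
#' @param n_boot,spec_target,seed see [performance_report()].
#' @return list with `auc` (train-group x eval-group matrix) and `reports`
#'   (list-matrix of `performance_report`s).
#' @export
cross_time_group_matrix <- function(models, test, groups = JOINED_GROUPS,
                                    n_boot = 2000, spec_target = 0.90,
                                    seed = 1L) {
  train_groups <- names(models)
  auc <- matrix(NA_real_, length(train_groups), length(groups),
                dimnames = list(train = train_groups, eval = groups))
  reports <- vector("list", length(train_groups) * length(groups))
  dim(reports) <- dim(auc); dimnames(reports) <- dimnames(auc)
  for (g in train_groups) {
    scores_all <- predict(models[[g]], test)
    for (h in groups) {
      keep <- in_joined_group(test, h)
      yk <- test$status[keep]
      if (length(unique(yk)) < 2) {
        warning("evaluation group ", h, " lacks both classes; NA entry",
                call. = FALSE)
        next
      }
      rep_ <- performance_report(scores_all[keep], yk, group = h,
                                 spec_target = spec_target, n_boot = n_boot,
                                 seed = seed)
      auc[g, h] <- rep_$auc
      reports[[g, h]] <- rep_
    }
  }
  list(auc = auc, reports = reports)
}

#' Operating-point metrics across disease prevalences
#'
#' Down-samples one class to reach each target case prevalence, recomputes
#' the fixed-specificity metrics on `n_rep` replicates per prevalence, and
#' reports the analytic check
#' `PPV(p) = sens * p / (sens * p + (1 - spec) * (1 - p))` from the
#' unmodified operating point.
#'
#' @param scores,y as in [roc_auc()].
#' @param prevalences target case fractions.
#' @param n_rep replicates per prevalence.
#' @param spec_target operating specificity.
#' @param seed integer seed.
#' @return list per prevalence: data frame of replicate metrics plus the
#'   analytic `ppv`/`npv`.
#' @export
prevalence_rescan <- function(scores, y, prevalences, n_rep = 100,
                              spec_target = 0.90, seed = 1L) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  base <- metrics_at_specificity(scores, y, spec_target)
  rng <- rng_stream(seed)
  out <- lapply(prevalences, function(p) {
    stopifnot(p > 0, p < 1)
    m1 <- round(p * n0 / (1 - p))
    if (m1 <= n1) {
      m0 <- n0
    } else {
      m1 <- n1
      m0 <- round(n1 * (1 - p) / p)
      if (m0 > n0) stop("prevalence ", p, " not achievable by down-sampling",
                        call. = FALSE)
    }
    if (m1 < 1 || m0 < 1)
      stop("prevalence ", p, " not achievable by down-sampling", call. = FALSE)
    cases <- which(y == 1); ctrls <- which(y == 0)
    reps <- lapply(seq_len(n_rep), function(r) {
      i1 <- if (m1 < n1) cases[rng$sample_int(n1, m1)] else cases
      i0 <- if (m0 < n0) ctrls[rng$sample_int(n0, m0)] else ctrls
      idx <- c(i1, i0)
      m <- metrics_at_specificity(scores[idx], y[idx], spec_target)
      data.frame(auc = roc_auc(scores[idx], y[idx]),
                 sensitivity = m$sensitivity, ppv = m$ppv, npv = m$npv,
                 mcc = m$mcc)
    })
    reps <- do.call(rbind, reps)
    sens <- base$sensitivity; spec <- base$specificity
    list(prevalence = p, replicates = reps,
         analytic_ppv = sens * p / (sens * p + (1 - spec) * (1 - p)),
         analytic_npv = spec * (1 - p) / (spec * (1 - p) + (1 - sens) * p))
  })
  names(out) <- as.character(prevalences)
  out
}

#' Pairwise Cohen's kappa between dichotomized learner predictions
#'
#' Each probability column is dichotomized at its own fixed-specificity
#' threshold; Cohen's kappa is computed for every column pair. Constant
#' dichotomized columns give `NA` for their pairs.
#'
#' @param P probability matrix (samples x learners).
#' @param y 0/1 outcomes (used to set per-column thresholds).
#' @param spec_target specificity at which each column is thresholded.
#' @return symmetric kappa matrix with unit diagonal.
#' @export
pairwise_kappa <- function(P, y, spec_target = 0.90) {
  P <- as.matrix(P)
  if (ncol(P) < 2) stop("need at least two columns", call. = FALSE)
  calls <- apply(P, 2, function(s) {
    th <- metrics_at_specificity(s, y, spec_target)$threshold
    as.integer(s > th)
  })
  k <- ncol(calls)
  out <- diag(1, k)
  dimnames(out) <- list(colnames(P), colnames(P))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      out[i, j] <- out[j, i] <- cohen_kappa(calls[, i], calls[, j])
    }
  }
  out
}

cohen_kappa <- function(a, b) {
  if (length(unique(a)) < 2 || length(unique(b)) < 2) return(NA_real_)
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(1 - a) * mean(1 - b)
  if (abs(1 - pe) < 1e-12) return(NA_real_)
  (po - pe) / (1 - pe)
}
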