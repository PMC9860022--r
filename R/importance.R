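# Model-agnostic feature importance: the variability of the partial
# dependence function (a feature-importance ranking measure). For feature j,
# the partial dependence at grid value g is the model's mean predicted case
# probability with column j set to g and all other columns at their observed
# values; the raw importance is the standard deviation of the partial
# dependence over a quantile grid (half the range for two-level features).

#' FIRM importance of one feature for one model
#'
#' @param model an object with a `predict(model, matrix)` method returning
#'   case probabilities (e.g. a `trained_learner`).
#' @param x background feature matrix (typically the training matrix).
#' @param feature column name.
#' @param grid_size number of quantile grid points for continuous features.
#' @param max_background background rows used for averaging; larger tables
#'   are subsampled reproducibly.
#' @param seed seed for the background subsample.
#' @return raw importance (non-negative scalar); 0 for a constant feature.
#' @export
firm_importance <- function(model, x, feature, grid_size = 20,
                            max_background = 2000, seed = 1L) {
  x <- as.matrix(x)
  if (!feature %in% colnames(x))
    stop("feature '", feature, "' not in background matrix", call. = FALSE)
  if (nrow(x) > max_background) {
    keep <- rng_stream(seed)$sample_int(nrow(x), max_background)
    x <- x[keep, , drop = FALSE]
  }
  v <- x[, feature]
  lev <- sort(unique(v))
  if (length(lev) <= 1) return(0)
  grid <- if (length(lev) == 2) lev else
    unique(stats::quantile(v, probs = seq(0, 1, length.out = grid_size),
                           names = FALSE, type = 7))
  n <- nrow(x)
  # one batched prediction: n rows per grid point
  big <- x[rep(seq_len(n), length(grid)), , drop = FALSE]
  big[, feature] <- rep(grid, each = n)
  p <- predict(model, big)
  pd <- colMeans(matrix(p, nrow = n))
  if (length(grid) == 2) diff(range(pd)) / 2 else stats::sd(pd)
}

#' Scale and aggregate raw importances
#'
#' Within each (learner, group) cell, raw importances are divided by the
#' cell maximum (so the most important feature scores 1; all-zero cells stay
#' 0, with a warning). The summary is the per-feature median of the scaled
#' importances across all cells.
#'
#' @param raw data frame with columns `feature`, `learner`, `group`,
#'   `importance` (raw values from [firm_importance()]).
#' @return an `importance_table`: list with `long` (scaled long format) and
#'   `summary` (per-feature median, sorted decreasing).
#' @export
scale_and_aggregate <- function(raw) {
  stopifnot(all(c("feature", "learner", "group", "importance") %in% names(raw)))
  cell <- interaction(raw$learner, raw$group, drop = TRUE)
  scaled <- raw
  scaled$scaled_importance <- NA_real_
  for (s in levels(cell)) {
    rows <- which(cell == s)
    mx <- max(raw$importance[rows])
    if (mx <= 0) {
      warning("all-zero importances in cell ", s, "; left at 0", call. = FALSE)
      scaled$scaled_importance[rows] <- 0
    } else {
      scaled$scaled_importance[rows] <- raw$importance[rows] / mx
    }
  }
  med <- stats::aggregate(scaled_importance ~ feature, data = scaled,
                          FUN = stats::median)
  names(med)[2] <- "median_importance"
  med <- med[order(-med$median_importance, med$feature), , drop = FALSE]
  rownames(med) <- NULL
  structure(list(long = scaled, summary = med), class = "importance_table")
}

#' @export
print.importance_table <- function(x, n = 10, ...) {
  cat("importance_table:", nrow(x$summary), "features,",
      length(unique(interaction(x$long$learner, x$long$group))), "cells\n")
  print(utils::head(x$summary, n))
  invisible(x)
}

#' Feature importance across a stacked model's base learners
#'
#' Computes [firm_importance()] for every panel feature under every base
#' learner of a stacked model and aggregates with [scale_and_aggregate()].
#'
#' @param model a `stack_model` with architecture `"JTG2L"` (per-group
#'   architectures: pass each group's learners separately).
#' @param train training [cohort] (background distribution).
#' @param features features to score (default: the model's panel).
#' @param grid_size,max_background,seed see [firm_importance()].
#' @return an `importance_table`.
#' @export
stack_importance <- function(model, train, features = model$panel,
                             grid_size = 20, max_background = 2000,
                             seed = 1L) {
  stopifnot(inherits(model, "stack_model"))
  if (is.null(model$learners))
    stop("model carries no base learners", call. = FALSE)
  x <- cohort_matrix(train, model$panel)
  rows <- list()
  for (fam in names(model$learners)) {
    raw <- firm_importance_batch(model$learners[[fam]], x, features,
                                 grid_size = grid_size,
                                 max_background = max_background, seed = seed)
    rows[[fam]] <- data.frame(feature = features, learner = fam,
                              group = model$group %||% "all",
                              importance = raw, stringsAsFactors = FALSE)
  }
  scale_and_aggregate(do.call(rbind, rows))
}

# all-feature FIRM importances for one model with a single batched
# prediction call (the partial-dependence grids of every feature are stacked
# into one matrix); equal to looping firm_importance() feature by feature
firm_importance_batch <- function(model, x, features, grid_size = 20,
                                  max_background = 2000, seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) > max_background) {
    keep <- rng_stream(seed)$sample_int(nrow(x), max_background)
    x <- x[keep, , drop = FALSE]
  }
  n <- nrow(x)
  grids <- lapply(features, function(f) {
    v <- x[, f]
    lev <- sort(unique(v))
    if (length(lev) <= 1) return(numeric(0))
    if (length(lev) == 2) lev else
      unique(stats::quantile(v, probs = seq(0, 1, length.out = grid_size),
                             names = FALSE, type = 7))
  })
  blocks <- sum(lengths(grids))
  if (blocks == 0) return(stats::setNames(numeric(length(features)), features))
  big <- x[rep(seq_len(n), blocks), , drop = FALSE]
  at <- 0L
  for (i in seq_along(features)) {
    g <- grids[[i]]
    if (!length(g)) next
    rows <- at * n + seq_len(n * length(g))
    big[rows, features[i]] <- rep(g, each = n)
    at <- at + length(g)
  }
  p <- matrix(predict(model, big), nrow = n)
  at <- 0L
  out <- stats::setNames(numeric(length(features)), features)
  for (i in seq_along(features)) {
    g <- grids[[i]]
    if (!length(g)) { out[i] <- 0; next }
    pd <- colMeans(p[, at + seq_along(g), drop = FALSE])
    out[i] <- if (length(g) == 2) diff(range(pd)) / 2 else stats::sd(pd)
    at <- at + length(g)
  }
  out
}
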