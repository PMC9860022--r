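# Meta-learners over base-learner probability matrices, and the three
# stacking architectures:
#   JTG2L - base learners trained on a joined time-group, one stack on the
#           10-column out-of-fold matrix;
#   STG2L - base learners trained per single time-group, one stack on the
#           concatenated 10 x G column matrix (AVNNET permitted here);
#   STG3L - per-group BMA stacks, then a second-level stack on the G columns.
# The BMA stack averages logistic regressions over subsets of the columns,
# weighted by BIC-approximated posterior model probabilities with Occam's
# window pruning.

#' Bayesian-model-averaging stack
#'
#' Candidate logistic models are subsets of the probability-matrix columns:
#' enumerated exhaustively (up to `max_size` columns per model) when the
#' matrix has at most `enumerate_limit` columns, otherwise collected along
#' forward and backward stepwise BIC paths. Each candidate is scored by BIC;
#' posterior weights are `w_m` proportional to `exp(-dBIC_m / 2)`; models
#' whose odds against the best exceed `occam_odds` are discarded and the
#' weights renormalized. The stack prediction is the weight-averaged
#' logistic prediction.
#'
#' @param P probability matrix (samples x base-learner columns, values in
#'   \[0,1\]).
#' @param y 0/1 outcomes.
#' @param occam_odds Occam's-window odds cutoff.
#' @param max_size largest candidate subset (default: all columns).
#' @param enumerate_limit column count above which stepwise search replaces
#'   exhaustive enumeration.
#' @return a `stack_model` of kind `"BMA"`.
#' @export
fit_bma_stack <- function(P, y, occam_odds = 20, max_size = NULL,
                          enumerate_limit = 12) {
  P <- as.matrix(P)
  check_prob_matrix(P)
  if (length(unique(y)) < 2) stop("both classes required", call. = FALSE)
  p <- ncol(P)
  if (is.null(colnames(P))) colnames(P) <- paste0("V", seq_len(p))
  if (is.null(max_size)) max_size <- p
  max_size <- min(max_size, p)
  subsets <- if (p <= enumerate_limit) {
    unlist(lapply(seq_len(max_size), function(k)
      utils::combn(p, k, simplify = FALSE)), recursive = FALSE)
  } else {
    stepwise_bic_subsets(P, y, max_size)
  }
  n <- length(y)
  fits <- lapply(subsets, function(cols) {
    X <- cbind(1, P[, cols, drop = FALSE])
    f <- tryCatch(suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial())),
      error = function(e) NULL)
    if (is.null(f) || !all(is.finite(f$coefficients))) return(NULL)
    list(cols = cols, coef = f$coefficients,
         bic = f$deviance + (length(cols) + 1) * log(n))
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("all candidate stack fits failed", call. = FALSE)
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  dbic <- bic - min(bic)
  keep <- dbic <= 2 * log(occam_odds)
  fits <- fits[keep]
  w <- exp(-dbic[keep] / 2)
  w <- w / sum(w)
  new_stack_model(kind = "BMA", schema = colnames(P),
                  pars = list(models = fits, weights = w,
                              occam_odds = occam_odds))
}

# forward + backward stepwise BIC paths; returns the union of visited subsets
stepwise_bic_subsets <- function(P, y, max_size) {
  n <- length(y)
  p <- ncol(P)
  bic_of <- function(cols) {
    X <- cbind(1, P[, cols, drop = FALSE])
    f <- tryCatch(suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial())),
      error = function(e) NULL)
    if (is.null(f)) return(Inf)
    f$deviance + (length(cols) + 1) * log(n)
  }
  visited <- list()
  add <- function(cols) visited[[length(visited) + 1L]] <<- sort(cols)
  # forward
  current <- integer(0)
  best_bic <- Inf
  repeat {
    cand <- setdiff(seq_len(p), current)
    if (!length(cand) || length(current) >= max_size) break
    scores <- vapply(cand, function(j) bic_of(c(current, j)), numeric(1))
    j <- cand[which.min(scores)]
    current <- c(current, j)
    add(current)
    if (min(scores) >= best_bic) break
    best_bic <- min(scores)
  }
  # backward from full
  current <- seq_len(p)
  add(current)
  repeat {
    if (length(current) <= 1) break
    scores <- vapply(current, function(j) bic_of(setdiff(current, j)),
                     numeric(1))
    j <- current[which.min(scores)]
    current <- setdiff(current, j)
    add(current)
  }
  unique(visited)
}

#' Pooling stacks: arithmetic mean, geometric mean, maximum
#'
#' Parameter-free meta-learners: the stack prediction is the row-wise
#' arithmetic mean (`MEAN`), geometric mean (`GEOMEAN`) or maximum (`MAX`)
#' of the base-learner probabilities. For any row,
#' `GEOMEAN <= MEAN <= MAX`.
#'
#' @param P probability matrix.
#' @param kind `"MEAN"`, `"GEOMEAN"` or `"MAX"`.
#' @return a `stack_model`.
#' @export
fit_pooling_stack <- function(P, kind = c("MEAN", "GEOMEAN", "MAX")) {
  kind <- match.arg(kind)
  P <- as.matrix(P)
  check_prob_matrix(P)
  new_stack_model(kind = kind, schema = colnames(P), pars = list())
}

#' Averaged-neural-network stack
#'
#' A committee of small feed-forward networks with random initializations,
#' trained on the probability matrix; predictions are averaged. Permitted
#' for the single-time-group two-layer architecture.
#'
#' @param P probability matrix.
#' @param y 0/1 outcomes.
#' @param n_nets committee size.
#' @param size hidden units per network.
#' @param decay weight decay.
#' @param seed integer seed.
#' @return a `stack_model` of kind `"AVNNET"`.
#' @export
fit_avnnet_stack <- function(P, y, n_nets = 5, size = 5, decay = 0.01,
                             seed = 1L) {
  P <- as.matrix(P)
  check_prob_matrix(P)
  rng <- rng_stream(seed)
  nets <- lapply(seq_len(n_nets), function(i) {
    set.seed(rng$int(1))
    nnet::nnet(x = P, y = y, size = size, decay = decay, maxit = 200,
               trace = FALSE, entropy = TRUE, MaxNWts = 10000)
  })
  new_stack_model(kind = "AVNNET", schema = colnames(P),
                  pars = list(nets = nets))
}

new_stack_model <- function(kind, schema, pars, architecture = "RAW",
                            extra = list()) {
  structure(c(list(kind = kind, schema = schema, pars = pars,
                   architecture = architecture), extra),
            class = "stack_model")
}

check_prob_matrix <- function(P) {
  if (any(!is.finite(P)) || any(P < 0) || any(P > 1))
    stop("probability matrix entries must lie in [0, 1]", call. = FALSE)
  invisible(TRUE)
}

#' BMA posterior weights
#' @param model a BMA `stack_model`.
#' @return named vector: weight per retained candidate model, names encoding
#'   the column subset.
#' @export
bma_weights <- function(model) {
  stopifnot(model$kind == "BMA")
  w <- model$pars$weights
  names(w) <- vapply(model$pars$models, function(m)
    paste(model$schema[m$cols], collapse = "+"), character(1))
  w
}

# combine a probability matrix with a fitted meta-learner
stack_combine <- function(model, P) {
  P <- as.matrix(P)
  miss <- setdiff(model$schema, colnames(P))
  if (length(miss))
    stop("probability matrix lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  P <- clip_prob(P[, model$schema, drop = FALSE])
  switch(model$kind,
         MEAN = rowMeans(P),
         GEOMEAN = exp(rowMeans(log(P))),
         MAX = apply(P, 1, max),
         BMA = {
           pred <- numeric(nrow(P))
           for (i in seq_along(model$pars$models)) {
             m <- model$pars$models[[i]]
             eta <- drop(cbind(1, P[, m$cols, drop = FALSE]) %*% m$coef)
             pred <- pred + model$pars$weights[i] * stats::plogis(eta)
           }
           pred
         },
         AVNNET = rowMeans(vapply(model$pars$nets, function(nn)
           as.numeric(predict(nn, P)), numeric(nrow(P)))),
         stop("unknown stack kind ", model$kind, call. = FALSE))
}

fit_stack <- function(kind, P, y, seed = 1L, occam_odds = 20,
                      max_size = NULL) {
  switch(kind,
         BMA = fit_bma_stack(P, y, occam_odds = occam_odds,
                             max_size = max_size),
         MEAN = , GEOMEAN = , MAX = fit_pooling_stack(P, kind),
         AVNNET = fit_avnnet_stack(P, y, seed = seed),
         stop("unknown stack kind '", kind, "'", call. = FALSE))
}

# ---- architectures -------------------------------------------------------

# shared base-layer training on a cohort subset
train_layer_on <- function(cohort_sub, panel, cv, n_search, seed, families,
                           ranges, oversample = TRUE) {
  x <- cohort_matrix(cohort_sub, panel)
  y <- cohort_sub$status
  plan <- make_cv_plan(y, n_folds = cv$n_folds, n_repeats = cv$n_repeats,
                       seed = seed)
  train_base_layer(x, y, plan, families = families, n_search = n_search,
                   seed = seed, ranges = ranges, oversample = oversample)
}

#' Joined-time-group two-layer stacked model (JTG2L)
#'
#' Trains the ten base learners on all training samples of one joined
#' time-group (cases drawn within the group, all controls) and fits the
#' requested meta-learner on the 10-column out-of-fold probability matrix.
#'
#' @param train training [cohort] with `single_group` assigned and markers
#'   imputed.
#' @param joined_group one of `"0-1" ... "0-4+"`.
#' @param stack_kind `"BMA"`, `"MEAN"`, `"GEOMEAN"` or `"MAX"`.
#' @param panel feature panel (marker/covariate names).
#' @param cv list with `n_folds`, `n_repeats` for the base-learner CV.
#' @param n_search random hyperparameter draws per family.
#' @param seed integer seed.
#' @param families base-learner families.
#' @param ranges hyperparameter ranges ([learner_ranges()]).
#' @param occam_odds Occam's-window odds for the BMA stack.
#' @return a `stack_model` (architecture `"JTG2L"`) carrying its base
#'   learners, panel and provenance.
#' @export
build_jtg2l <- function(train, joined_group = "0-4+",
                        stack_kind = "BMA", panel,
                        cv = list(n_folds = 10, n_repeats = 5),
                        n_search = 25, seed = 1L,
                        families = learner_families(),
                        ranges = learner_ranges(), occam_odds = 20) {
  keep <- in_joined_group(train, joined_group)
  sub <- subset_cohort(train, keep)
  if (length(unique(sub$status)) < 2)
    stop("joined group ", joined_group, " lacks both classes", call. = FALSE)
  layer <- train_layer_on(sub, panel, cv, n_search, seed, families, ranges)
  meta <- fit_stack(stack_kind, layer$oof, layer$y, seed = seed + 1L,
                    occam_odds = occam_odds)
  meta$architecture <- "JTG2L"
  meta$group <- joined_group
  meta$panel <- panel
  meta$learners <- layer$learners
  meta$oof <- layer$oof
  meta$y <- layer$y
  meta
}

# per-single-group base layers shared by STG2L / STG3L.
# Columns for out-of-group samples come from plain model predictions (the
# model never saw them); in-group training samples keep their out-of-fold
# probabilities, so no sample is scored by a model that trained on it.
train_single_group_layers <- function(train, panel, cv, n_search, seed,
                                      families, ranges) {
  groups <- levels(droplevels(train$single_group))
  if (!length(groups)) stop("no case samples with single groups", call. = FALSE)
  layers <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    keep <- train$status == 0 | (!is.na(train$single_group) &
                                   train$single_group == g)
    sub <- subset_cohort(train, keep)
    if (length(unique(sub$status)) < 2)
      stop("single group ", g, " lacks both classes", call. = FALSE)
    layer <- train_layer_on(sub, panel, cv, n_search, seed + 100L * gi,
                            families, ranges)
    layer$rows <- which(keep)
    layers[[g]] <- layer
  }
  layers
}

# (families x groups) probability matrix over all training rows
stg_probability_matrix <- function(train, layers, panel, families) {
  x_all <- cohort_matrix(train, panel)
  cols <- list()
  for (g in names(layers)) {
    layer <- layers[[g]]
    for (fam in families) {
      p <- predict(layer$learners[[fam]], x_all)
      p[layer$rows] <- layer$learners[[fam]]$oof
      cols[[paste(fam, g, sep = ".")]] <- p
    }
  }
  do.call(cbind, cols)
}

#' Single-time-group two-layer stacked model (STG2L)
#'
#' Trains the ten base learners separately in each single time-group (that
#' group's cases plus all controls), concatenates the per-(family, group)
#' probability columns into a 10 x G matrix over all training samples, and
#' fits one meta-learner on it. `AVNNET` is permitted as the meta-learner in
#' this architecture.
#'
#' @inheritParams build_jtg2l
#' @param stack_kind `"BMA"`, `"MEAN"`, `"GEOMEAN"`, `"MAX"` or `"AVNNET"`.
#' @return a `stack_model` (architecture `"STG2L"`).
#' @export
build_stg2l <- function(train, stack_kind = "BMA", panel,
                        cv = list(n_folds = 10, n_repeats = 5),
                        n_search = 25, seed = 1L,
                        families = learner_families(),
                        ranges = learner_ranges(), occam_odds = 20) {
  layers <- train_single_group_layers(train, panel, cv, n_search, seed,
                                      families, ranges)
  P <- stg_probability_matrix(train, layers, panel, families)
  meta <- fit_stack(stack_kind, P, train$status, seed = seed + 1L,
                    occam_odds = occam_odds)
  meta$architecture <- "STG2L"
  meta$panel <- panel
  meta$layers <- layers
  meta$families <- families
  meta$oof <- P
  meta$y <- train$status
  meta
}

#' Single-time-group three-layer stacked model (STG3L)
#'
#' As [build_stg2l()], but stacks twice: a BMA stack per single time-group
#' over that group's ten learners produces a G-column probability matrix,
#' which a second-level stack combines.
#'
#' @inheritParams build_stg2l
#' @param top_stack_kind second-level stack kind.
#' @return a `stack_model` (architecture `"STG3L"`).
#' @export
build_stg3l <- function(train, top_stack_kind = "BMA", panel,
                        cv = list(n_folds = 10, n_repeats = 5),
                        n_search = 25, seed = 1L,
                        families = learner_families(),
                        ranges = learner_ranges(), occam_odds = 20) {
  layers <- train_single_group_layers(train, panel, cv, n_search, seed,
                                      families, ranges)
  # layer-2: per-group BMA over the group's own out-of-fold columns
  group_stacks <- list()
  for (g in names(layers)) {
    layer <- layers[[g]]
    group_stacks[[g]] <- fit_bma_stack(layer$oof, layer$y,
                                       occam_odds = occam_odds)
  }
  # layer-3 input: per-group BMA predictions over all training rows
  P_all <- stg_probability_matrix(train, layers, panel, families)
  P2 <- vapply(names(layers), function(g) {
    cols <- paste(families, g, sep = ".")
    Pg <- P_all[, cols, drop = FALSE]
    colnames(Pg) <- families
    stack_combine(group_stacks[[g]], Pg)
  }, numeric(nrow(P_all)))
  colnames(P2) <- names(layers)
  meta <- fit_stack(top_stack_kind, P2, train$status, seed = seed + 1L,
                    occam_odds = occam_odds)
  meta$architecture <- "STG3L"
  meta$panel <- panel
  meta$layers <- layers
  meta$group_stacks <- group_stacks
  meta$families <- families
  meta$oof <- P2
  meta$y <- train$status
  meta
}

#' @export
print.stack_model <- function(x, ...) {
  cat("stack_model:", x$architecture, x$kind,
      if (!is.null(x$group)) paste0("[", x$group, "]") else "",
      "| schema:", length(x$schema), "columns\n")
  if (x$kind == "BMA")
    cat("  BMA:", length(x$pars$weights), "retained models, top weight",
        round(max(x$pars$weights), 3), "\n")
  invisible(x)
}

#' Predict case probabilities from a stacked model
#'
#' Scores new samples: base learners produce their probability columns
#' (aligned to the model's schema by name), the meta-learner combines them.
#' No refitting occurs. Input columns may be in any order; missing panel
#' features raise an error naming them.
#'
#' @param object a `stack_model` from [build_jtg2l()], [build_stg2l()] or
#'   [build_stg3l()] (or a raw stack over an explicit probability matrix).
#' @param newdata a [cohort] (architectures) or probability matrix (raw
#'   stacks).
#' @param ... unused.
#' @return numeric vector of case probabilities in \[0, 1\].
#' @export
predict.stack_model <- function(object, newdata, ...) {
  if (object$architecture == "RAW")
    return(stack_combine(object, newdata))
  x <- cohort_matrix(newdata, object$panel)
  P <- switch(object$architecture,
    JTG2L = {
      cols <- vapply(object$learners, function(l) predict(l, x),
                     numeric(nrow(x)))
      if (is.null(dim(cols))) cols <- matrix(cols, nrow = nrow(x),
                                             dimnames = list(NULL, names(object$learners)))
      cols
    },
    STG2L = , STG3L = {
      cols <- list()
      for (g in names(object$layers)) {
        for (fam in object$families) {
          cols[[paste(fam, g, sep = ".")]] <-
            predict(object$layers[[g]]$learners[[fam]], x)
        }
      }
      do.call(cbind, cols)
    },
    stop("unknown architecture", call. = FALSE))
  if (object$architecture == "STG3L") {
    P2 <- vapply(names(object$layers), function(g) {
      cols <- paste(object$families, g, sep = ".")
      Pg <- P[, cols, drop = FALSE]
      colnames(Pg) <- object$families
      stack_combine(object$group_stacks[[g]], Pg)
    }, numeric(nrow(P)))
    if (is.null(dim(P2))) P2 <- matrix(P2, nrow = nrow(P),
                                       dimnames = list(NULL, names(object$layers)))
    P <- P2
  }
  stack_combine(object, P)
}

#' Meta-level cross-validated AUC of a stacking procedure
#'
#' Repeated stratified CV of the meta-learner over a fixed probability
#' matrix: per fold, the stack is refit on the training folds and scored on
#' the held-out fold.
#'
#' @param P probability matrix.
#' @param y 0/1 outcomes.
#' @param kind stack kind.
#' @param n_folds,n_repeats meta CV plan (the reference design is 10 x 10).
#' @param seed integer seed.
#' @param ... passed to [fit_bma_stack()] / [fit_avnnet_stack()].
#' @return vector of per-fold AUCs.
#' @export
meta_cv_auc <- function(P, y, kind = "BMA", n_folds = 10, n_repeats = 10,
                        seed = 1L, ...) {
  plan <- make_cv_plan(y, n_folds = n_folds, n_repeats = n_repeats,
                       seed = seed)
  aucs <- numeric(0)
  for (r in seq_len(n_repeats)) {
    fold_id <- plan$folds[[r]]
    for (f in seq_len(n_folds)) {
      tr <- fold_id != f
      m <- fit_stack(kind, P[tr, , drop = FALSE], y[tr], seed = seed, ...)
      pred <- stack_combine(m, P[!tr, , drop = FALSE])
      aucs <- c(aucs, roc_auc(pred, y[!tr]))
    }
  }
  aucs
}
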