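# The heterogeneous base-learner layer: ten classifier families, each
# producing a case probability, trained by repeated stratified CV with
# minority oversampling inside training folds and random hyperparameter
# search. Tree/kernel/boosting/net algorithms are consumed from their
# standard libraries (rpart, e1071, kernlab, ranger, glmnet, xgboost, nnet,
# MASS); the two adaptive-boosting families are a compact in-package
# AdaBoost.M1 over rpart trees since no installed library provides them.

PROB_EPS <- 1e-6

clip_prob <- function(p) pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)

#' Base-learner family names
#'
#' Ten families spanning boosted trees and rules (`boost_tree`), RBF-kernel
#' support vector machines (`svm_rbf`), random forests (`rf`), neural
#' networks on extracted principal components (`pca_nnet`), Gaussian-process
#' classifiers with RBF kernel (`gp_rbf`), elastic-net logistic regression
#' (`glmnet`), bagged adaptive boosting (`bag_boost`), gradient-boosted
#' trees (`xgb`), stepwise-AIC logistic regression (`step_glm`) and naive
#' Bayes (`nbayes`).
#' @export
learner_families <- function() {
  c("boost_tree", "svm_rbf", "rf", "pca_nnet", "gp_rbf", "glmnet",
    "bag_boost", "xgb", "step_glm", "nbayes")
}

#' Hyperparameter search ranges
#'
#' Reads the per-family random-search ranges shipped with the package
#' (`inst/extdata/learners.yaml`); pass a path to override.
#' @param path YAML file of ranges.
#' @export
learner_ranges <- function(path = system.file("extdata", "learners.yaml",
                                              package = "serostack")) {
  yaml::read_yaml(path)
}

sample_hparams <- function(family, n, ranges, rng) {
  spec <- ranges[[family]]
  if (is.null(spec) || !length(spec)) return(rep(list(list()), max(n, 1L)))
  lapply(seq_len(n), function(i) {
    hp <- lapply(spec, function(par) {
      u <- rng$runif(1, par$min, par$max)
      switch(par$type,
             int = as.integer(round(u)),
             real = u,
             log10 = 10^u,
             stop("unknown hyperparameter type ", par$type))
    })
    names(hp) <- names(spec)
    hp
  })
}

# ---- AdaBoost.M1 over rpart trees --------------------------------------

fit_adaboost <- function(x, y, n_trees, maxdepth) {
  df <- data.frame(x, check.names = FALSE)
  yf <- factor(y, levels = c(0, 1))
  n <- length(y)
  w <- rep(1 / n, n)
  trees <- vector("list", n_trees)
  alpha <- numeric(n_trees)
  used <- 0L
  ctrl <- rpart::rpart.control(maxdepth = maxdepth, cp = 0, minsplit = 5,
                               xval = 0, maxcompete = 0, maxsurrogate = 0)
  for (t in seq_len(n_trees)) {
    dft <- df
    dft$.y <- yf
    wt <- w * n
    tree <- rpart::rpart(.y ~ ., data = dft, weights = wt, method = "class",
                         control = ctrl)
    pred <- predict(tree, df, type = "class")
    wrong <- pred != yf
    err <- sum(w[wrong])
    if (err >= 0.5 && t > 1L) break
    err <- min(max(err, 1e-10), 1 - 1e-10)
    a <- 0.5 * log((1 - err) / err)
    used <- t
    trees[[t]] <- tree
    alpha[t] <- a
    w <- w * exp(a * ifelse(wrong, 1, -1))
    w <- w / sum(w)
    if (err <= 1e-8) break
  }
  structure(list(trees = trees[seq_len(used)], alpha = alpha[seq_len(used)]),
            class = "serostack_adaboost")
}

predict_adaboost <- function(object, x) {
  df <- data.frame(x, check.names = FALSE)
  f <- numeric(nrow(df))
  for (t in seq_along(object$trees)) {
    pred <- predict(object$trees[[t]], df, type = "class")
    f <- f + object$alpha[t] * ifelse(pred == "1", 1, -1)
  }
  stats::plogis(2 * f)
}

# ---- family fit/predict dispatch ---------------------------------------

fit_learner <- function(family, x, y, hp, seed = 1L) {
  x <- as.matrix(x)
  model <- switch(
    family,
    boost_tree = fit_adaboost(x, y, hp$n_trees %||% 40L, hp$maxdepth %||% 2L),
    bag_boost = {
      rng <- rng_stream(seed)
      bags <- lapply(seq_len(hp$n_bags %||% 5L), function(b) {
        idx <- rng$sample(seq_along(y), length(y), replace = TRUE)
        if (length(unique(y[idx])) < 2)
          idx <- c(idx, which(y != y[idx[1]])[1])
        fit_adaboost(x[idx, , drop = FALSE], y[idx],
                     hp$n_trees %||% 15L, hp$maxdepth %||% 2L)
      })
      structure(list(bags = bags), class = "serostack_bagboost")
    },
    svm_rbf = {
      keep <- apply(x, 2, stats::sd) > 0
      fit <- e1071::svm(x[, keep, drop = FALSE], factor(y, levels = c(0, 1)),
                        cost = hp$cost %||% 1,
                        gamma = hp$gamma %||% (1 / ncol(x)), kernel = "radial")
      # deterministic Platt calibration of the decision values (libsvm's
      # internal probability CV is not reproducible within a session)
      d <- as.numeric(attr(predict(fit, x[, keep, drop = FALSE],
                                   decision.values = TRUE),
                           "decision.values"))
      calib <- tryCatch(suppressWarnings(
        stats::glm.fit(cbind(1, d), y,
                       family = stats::binomial())$coefficients),
        error = function(e) c(0, 1))
      if (anyNA(calib)) calib <- c(0, 1)
      list(fit = fit, keep = keep, calib = calib)
    },
    rf = ranger::ranger(
      x = x, y = factor(y, levels = c(0, 1)), probability = TRUE,
      num.trees = hp$num_trees %||% 200L,
      mtry = max(1L, floor((hp$mtry_frac %||% 0.5) * ncol(x))),
      min.node.size = hp$min_node %||% 5L,
      num.threads = 1L, seed = seed, verbose = FALSE),
    pca_nnet = {
      keep <- apply(x, 2, stats::sd) > 0
      pc <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
      k <- max(1L, min(ceiling((hp$ncomp_frac %||% 0.6) * ncol(pc$x)),
                       ncol(pc$x)))
      set.seed(seed)
      nn <- nnet::nnet(x = pc$x[, seq_len(k), drop = FALSE], y = y,
                       size = hp$size %||% 3L, decay = hp$decay %||% 0.01,
                       maxit = 200, trace = FALSE, entropy = TRUE,
                       MaxNWts = 5000)
      list(pc = pc, k = k, nn = nn, keep = keep)
    },
    gp_rbf = {
      fit <- kernlab::gausspr(x = x, y = factor(y, levels = c(0, 1)),
                              kernel = "rbfdot",
                              kpar = list(sigma = hp$sigma %||% 0.1))
      fit
    },
    glmnet = {
      if (ncol(x) >= 2) {
        glmnet::glmnet(x, y, family = "binomial",
                       alpha = hp$alpha %||% 0.5,
                       lambda = hp$lambda %||% 0.01)
      } else {
        stats::glm.fit(cbind(1, x), y, family = stats::binomial())$coefficients
      }
    },
    xgb = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      eta = hp$eta %||% 0.1,
                      max_depth = hp$max_depth %||% 3L,
                      subsample = hp$subsample %||% 1,
                      nthread = 1, seed = seed),
        data = dtrain, nrounds = hp$nrounds %||% 60L, verbose = 0)
    },
    step_glm = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      full <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                          family = stats::binomial()))
      suppressWarnings(MASS::stepAIC(full, direction = "both", trace = 0))
    },
    nbayes = e1071::naiveBayes(as.data.frame(x), factor(y, levels = c(0, 1))),
    stop("unknown learner family '", family, "'", call. = FALSE)
  )
  structure(list(family = family, hp = hp, model = model,
                 features = colnames(x)),
            class = "serostack_learner_fit")
}

predict_learner_fit <- function(object, x) {
  x <- as.matrix(x)[, object$features, drop = FALSE]
  model <- object$model
  p <- switch(
    object$family,
    boost_tree = predict_adaboost(model, x),
    bag_boost = rowMeans(matrix(unlist(lapply(model$bags, predict_adaboost,
                                              x = x)), nrow = nrow(x))),
    svm_rbf = {
      d <- as.numeric(attr(predict(model$fit, x[, model$keep, drop = FALSE],
                                   decision.values = TRUE),
                           "decision.values"))
      stats::plogis(model$calib[1] + model$calib[2] * d)
    },
    rf = predict(model, data = x, num.threads = 1)$predictions[, "1"],
    pca_nnet = {
      sc <- predict(model$pc, x[, model$keep, drop = FALSE])
      as.numeric(predict(model$nn, sc[, seq_len(model$k), drop = FALSE]))
    },
    gp_rbf = kernlab::predict(model, x, type = "probabilities")[, "1"],
    glmnet = {
      if (inherits(model, "glmnet")) {
        as.numeric(predict(model, x, type = "response"))
      } else {
        stats::plogis(drop(cbind(1, x) %*% model))
      }
    },
    xgb = predict(model, xgboost::xgb.DMatrix(x, nthread = 1)),
    step_glm = {
      df <- data.frame(x, check.names = FALSE)
      as.numeric(stats::predict(model, newdata = df, type = "response"))
    },
    nbayes = predict(model, as.data.frame(x), type = "raw")[, "1"],
    stop("unknown learner family", call. = FALSE)
  )
  clip_prob(as.numeric(p))
}

# ---- design matrix from a cohort ---------------------------------------

#' Numeric design matrix for the learner layer
#'
#' Extracts the panel columns from a cohort as a numeric matrix: markers as
#' concentrations (must be imputed first), yes/no covariates as 1/0, sex as
#' male = 1.
#'
#' @param x a [cohort].
#' @param panel character vector of feature names.
#' @export
cohort_matrix <- function(x, panel) {
  df <- as.data.frame(x)
  miss <- setdiff(panel, names(df))
  if (length(miss))
    stop("missing panel feature(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cols <- lapply(panel, function(f) feature_numeric(df, f))
  out <- do.call(cbind, cols)
  colnames(out) <- panel
  if (anyNA(out)) {
    bad <- panel[colSums(is.na(out)) > 0]
    stop("missing values in feature(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out
}

# ---- tuning and training ------------------------------------------------

#' Tune and train one base learner
#'
#' Random hyperparameter search: for each of `n_search` draws from the
#' family's ranges, the learner is trained on every CV training fold (with
#' minority oversampling applied inside the fold) and scored by mean
#' out-of-fold ROC AUC; the best draw is refit on the full (oversampled)
#' training set. Out-of-fold probabilities of the winning draw, averaged
#' over CV repeats, are retained as the sample's stacking feature. A fold on
#' which the family fails to fit scores AUC 0.5 with a warning (the draw is
#' not silently dropped).
#'
#' @param family one of [learner_families()].
#' @param x numeric feature matrix (see [cohort_matrix()]).
#' @param y 0/1 outcomes.
#' @param plan a [make_cv_plan()] plan (made on `y`).
#' @param n_search number of random hyperparameter draws.
#' @param seed integer seed.
#' @param ranges see [learner_ranges()].
#' @param oversample oversample the minority class inside training folds.
#' @return a `trained_learner` with the fitted model, chosen hyperparameters,
#'   per-fold CV AUCs and the out-of-fold probability vector.
#' @export
tune_and_train <- function(family, x, y, plan, n_search = 25, seed = 1L,
                           ranges = learner_ranges(), oversample = TRUE) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y))
  rng <- rng_stream(seed)
  draws <- sample_hparams(family, n_search, ranges, rng)
  if (!length(draws)) draws <- list(list())
  best <- NULL
  for (d in seq_along(draws)) {
    hp <- draws[[d]]
    oof <- matrix(NA_real_, nrow(x), plan$n_repeats)
    aucs <- numeric(0)
    for (r in seq_len(plan$n_repeats)) {
      fold_id <- plan$folds[[r]]
      for (f in seq_len(plan$n_folds)) {
        tr <- which(fold_id != f)
        va <- which(fold_id == f)
        idx <- if (oversample) {
          tr[oversample_minority(y[tr], seed = rng$int(1))]
        } else tr
        p <- tryCatch({
          fit <- fit_learner(family, x[idx, , drop = FALSE], y[idx], hp,
                             seed = rng$int(1))
          predict_learner_fit(fit, x[va, , drop = FALSE])
        }, error = function(e) {
          warning(family, ": fold fit failed (", conditionMessage(e),
                  "); fold scored as AUC 0.5", call. = FALSE)
          rep(0.5, length(va))
        })
        oof[va, r] <- p
        aucs <- c(aucs, tryCatch(roc_auc(p, y[va]), error = function(e) 0.5))
      }
    }
    mean_auc <- mean(aucs)
    if (is.null(best) || mean_auc > best$mean_cv_auc + 1e-12) {
      best <- list(hp = hp, mean_cv_auc = mean_auc, cv_auc = aucs,
                   oof = rowMeans(oof))
    }
  }
  idx <- if (oversample) oversample_minority(y, seed = rng$int(1)) else
    seq_along(y)
  final <- fit_learner(family, x[idx, , drop = FALSE], y[idx], best$hp,
                       seed = rng$int(1))
  structure(list(family = family, hp = best$hp, fit = final,
                 features = colnames(x), oof = clip_prob(best$oof),
                 cv_auc = best$cv_auc, mean_cv_auc = best$mean_cv_auc,
                 n_search = length(draws), seed = seed),
            class = "trained_learner")
}

#' @export
print.trained_learner <- function(x, ...) {
  cat("trained_learner:", x$family, "| mean CV AUC",
      round(x$mean_cv_auc, 3), "|", length(x$features), "features |",
      x$n_search, "hyperparameter draws\n")
  invisible(x)
}

#' @export
predict.trained_learner <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "cohort")) cohort_matrix(newdata, object$features)
  else as.matrix(newdata)
  miss <- setdiff(object$features, colnames(x))
  if (length(miss))
    stop("missing panel feature(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  predict_learner_fit(object$fit, x[, object$features, drop = FALSE])
}

#' Train the full base-learner layer
#'
#' Runs [tune_and_train()] for every family on one training table and
#' assembles the out-of-fold probability matrix that feeds the meta-learner.
#'
#' @param x numeric feature matrix.
#' @param y 0/1 outcomes.
#' @param plan a [make_cv_plan()].
#' @param families learner families to include.
#' @inheritParams tune_and_train
#' @return list with `learners` (named list of `trained_learner`), `oof`
#'   (samples x families probability matrix) and `y`.
#' @export
train_base_layer <- function(x, y, plan, families = learner_families(),
                             n_search = 25, seed = 1L,
                             ranges = learner_ranges(), oversample = TRUE) {
  learners <- list()
  oof <- matrix(NA_real_, nrow(x), length(families),
                dimnames = list(NULL, families))
  for (i in seq_along(families)) {
    fam <- families[i]
    learners[[fam]] <- tune_and_train(fam, x, y, plan, n_search = n_search,
                                      seed = seed + i, ranges = ranges,
                                      oversample = oversample)
    oof[, fam] <- learners[[fam]]$oof
  }
  list(learners = learners, oof = oof, y = y)
}
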