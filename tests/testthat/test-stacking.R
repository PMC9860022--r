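test_that("pooling stacks compute row-wise mean, geometric mean and max", {
  P <- rbind(c(0.2, 0.8), c(0.5, 0.5))
  colnames(P) <- c("a", "b")
  expect_equal(predict(fit_pooling_stack(P, "MEAN"), P), c(0.5, 0.5))
  expect_equal(predict(fit_pooling_stack(P, "GEOMEAN"), P), c(0.4, 0.5),
               tolerance = 1e-6)
  expect_equal(predict(fit_pooling_stack(P, "MAX"), P), c(0.8, 0.5))

  # identical columns reproduce the column under all three pools
  Q <- cbind(a = c(0.1, 0.6, 0.9), b = c(0.1, 0.6, 0.9))
  for (k in c("MEAN", "GEOMEAN", "MAX"))
    expect_equal(predict(fit_pooling_stack(Q, k), Q), Q[, 1],
                 tolerance = 1e-6)
})

test_that("GEOMEAN <= MEAN <= MAX on random probability rows", {
  set.seed(1)
  P <- matrix(runif(5000 * 4), ncol = 4,
              dimnames = list(NULL, paste0("c", 1:4)))
  gm <- predict(fit_pooling_stack(P, "GEOMEAN"), P)
  am <- predict(fit_pooling_stack(P, "MEAN"), P)
  mx <- predict(fit_pooling_stack(P, "MAX"), P)
  expect_true(all(gm <= am + 1e-12))
  expect_true(all(am <= mx + 1e-12))
})

test_that("BMA reduces to single models and weights duplicates symmetrically", {
  set.seed(2)
  n <- 300
  y <- rbinom(n, 1, 0.5)
  p1 <- clip01(y * 0.6 + runif(n) * 0.4)
  P1 <- cbind(only = p1)
  m <- fit_bma_stack(P1, y)
  expect_equal(sum(m$pars$weights), 1)
  expect_equal(length(m$pars$weights), 1)
  expect_equal(unname(bma_weights(m)), 1)

  P2 <- cbind(a = p1, b = p1)
  m2 <- fit_bma_stack(P2, y)
  w <- bma_weights(m2)
  expect_equal(sum(w), 1)
  if (all(c("a", "b") %in% names(w)))
    expect_equal(unname(w["a"]), unname(w["b"]), tolerance = 1e-6)
})

test_that("BMA concentrates weight on the informative column", {
  set.seed(3)
  n <- 1000
  y <- rbinom(n, 1, 0.5)
  # informative column with AUC ~0.9, plus nine noise columns
  info <- plogis(qnorm(0.75) * 2 * scale(rnorm(n, 1.8 * y))[, 1])
  P <- cbind(info = clip01(info),
             matrix(runif(n * 9), n, 9,
                    dimnames = list(NULL, paste0("noise", 1:9))))
  m <- fit_bma_stack(P, y)
  w <- m$pars$weights
  has_info <- vapply(m$pars$models, function(mm) 1L %in% mm$cols, logical(1))
  expect_gte(sum(w[has_info]), 0.9)
  # prediction is the explicit weighted logistic average
  manual <- Reduce(`+`, lapply(seq_along(m$pars$models), function(i) {
    mm <- m$pars$models[[i]]
    w[i] * plogis(drop(cbind(1, clip01(P[, mm$cols, drop = FALSE])) %*% mm$coef))
  }))
  expect_equal(predict(m, P), manual, tolerance = 1e-12)
})

test_that("pooling stacks ignore column identity; BMA is schema-bound", {
  set.seed(4)
  n <- 200
  y <- rbinom(n, 1, 0.5)
  P <- cbind(a = clip01(runif(n) * 0.5 + y * 0.4), b = runif(n))
  swapped <- P[, c("b", "a")]
  colnames(swapped) <- c("a", "b")  # swap the contents, keep the names
  mean_stack <- fit_pooling_stack(P, "MEAN")
  expect_equal(predict(mean_stack, P), predict(mean_stack, swapped))
  bma <- fit_bma_stack(P, y)
  expect_false(isTRUE(all.equal(predict(bma, P), predict(bma, swapped))))
  # but reordering columns without relabelling changes nothing (name alignment)
  expect_equal(predict(bma, P[, c("b", "a")]), predict(bma, P))
})

test_that("JTG2L stack dominates its base learners on an informative cohort", {
  fx <- informative_fit()
  model <- fx$model
  expect_equal(length(model$schema), 10)
  expect_equal(sum(model$pars$weights), 1)
  meta_auc <- mean(meta_cv_auc(model$oof, model$y, kind = "BMA",
                               n_folds = 5, n_repeats = 2, seed = 1))
  best_single <- max(vapply(model$learners, function(l) l$mean_cv_auc,
                            numeric(1)))
  expect_gte(meta_auc, best_single - 0.02)

  # the 0-4+ joined group is the whole training set
  expect_equal(length(model$y), nrow(fx$train))

  # test-set predictions beat chance comfortably
  expect_gt(roc_auc(predict(model, fx$test), fx$test$status), 0.75)
})

test_that("a null cohort keeps the stacked meta CV AUC at chance", {
  cfg <- null_config(simulation_config(n_cases = 50, n_controls = 80,
                                       n_markers = 8, seed = 31))
  co <- impute_low(simulate_cohort(cfg))
  sp <- stratified_split(co, seed = 2)
  train <- split_partition(co, sp, "train")
  model <- build_jtg2l(train, "0-4+", "BMA", panel = markers(co),
                       cv = list(n_folds = 2, n_repeats = 1), n_search = 1,
                       seed = 9)
  meta_auc <- mean(meta_cv_auc(model$oof, model$y, kind = "BMA",
                               n_folds = 5, n_repeats = 2, seed = 1))
  expect_gte(meta_auc, 0.35)
  expect_lte(meta_auc, 0.65)
})

test_that("single-time-group architectures build the documented feature spaces", {
  cfg <- informative_config(seed = 77)
  co <- impute_low(simulate_cohort(cfg))
  sp <- stratified_split(co, seed = 1)
  train <- split_partition(co, sp, "train")
  expect_equal(length(levels(droplevels(train$single_group))), 5)
  panel <- markers(co)[1:6]
  fams <- c("glmnet", "nbayes")  # reduced family set keeps this fast
  s2 <- build_stg2l(train, "BMA", panel = panel,
                    cv = list(n_folds = 2, n_repeats = 1), n_search = 1,
                    seed = 2, families = fams)
  expect_equal(length(s2$schema), 2 * 5)  # families x single groups
  p <- predict(s2, train)
  expect_true(all(p >= 0 & p <= 1))

  s3 <- build_stg3l(train, "MEAN", panel = panel,
                    cv = list(n_folds = 2, n_repeats = 1), n_search = 1,
                    seed = 2, families = fams)
  expect_equal(length(s3$schema), 5)  # one BMA column per single group
  expect_true(all(predict(s3, train) >= 0 & predict(s3, train) <= 1))

  # G = 1: keep only 0-1 cases; STG2L column count collapses to the family
  # count and an STG3L with a MEAN top stack equals the single group BMA
  keep <- train$status == 0 | train$single_group == "0-1"
  tr1 <- train[keep, , drop = FALSE]
  tr1$single_group <- droplevels(tr1$single_group)
  s2g1 <- build_stg2l(tr1, "BMA", panel = panel,
                      cv = list(n_folds = 2, n_repeats = 1), n_search = 1,
                      seed = 2, families = fams)
  expect_equal(length(s2g1$schema), length(fams))
  s3g1 <- build_stg3l(tr1, "MEAN", panel = panel,
                      cv = list(n_folds = 2, n_repeats = 1), n_search = 1,
                      seed = 2, families = fams)
  x1 <- cohort_matrix(tr1, panel)
  P1 <- vapply(fams, function(f)
    predict(s3g1$layers[["0-1"]]$learners[[f]], x1), numeric(nrow(x1)))
  colnames(P1) <- fams
  # equal up to the probability clipping the pooling stack applies
  expect_equal(predict(s3g1, tr1),
               clip01(predict(s3g1$group_stacks[["0-1"]], P1)),
               tolerance = 1e-5)
})

test_that("stack predictions are invariant to input column order and row count", {
  fx <- informative_fit()
  one <- fx$test[1, , drop = FALSE]
  p1 <- predict(fx$model, one)
  expect_length(p1, 1)
  set.seed(1)
  shuffled <- fx$test[, sample(ncol(fx$test)), drop = FALSE]
  expect_equal(predict(fx$model, shuffled), predict(fx$model, fx$test))

  missing_panel <- fx$test
  missing_panel[[fx$panel[1]]] <- NULL
  expect_error(predict(fx$model, missing_panel), fx$panel[1], fixed = TRUE)
})

test_that("the averaged-network stack fits probability matrices reproducibly", {
  set.seed(12)
  n <- 250
  y <- rbinom(n, 1, 0.5)
  P <- cbind(a = clip01(0.55 * y + 0.45 * runif(n)),
             b = clip01(runif(n)), c = clip01(runif(n)))
  m1 <- fit_avnnet_stack(P, y, n_nets = 3, size = 3, seed = 4)
  m2 <- fit_avnnet_stack(P, y, n_nets = 3, size = 3, seed = 4)
  p1 <- predict(m1, P)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_equal(p1, predict(m2, P))
  expect_gt(roc_auc(p1, y), 0.6)  # it learns the informative column
})
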