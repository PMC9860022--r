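test_that("cv plans stratify folds and reproduce by seed", {
  y <- rep(c(1, 0), c(40, 60))
  plan <- make_cv_plan(y, n_folds = 10, n_repeats = 2, seed = 1)
  for (r in 1:2) {
    id <- plan$folds[[r]]
    for (f in 1:10) {
      expect_equal(sum(y[id == f] == 1), 4)
      expect_equal(sum(y[id == f] == 0), 6)
    }
  }
  y2 <- rep(c(1, 0), c(43, 60))
  plan2 <- make_cv_plan(y2, n_folds = 10, n_repeats = 1, seed = 2)
  sizes <- table(plan2$folds[[1]])
  expect_lte(diff(range(sizes)), 2)  # 43 cases and 60 controls each spread +-1
  per_fold_cases <- tapply(y2, plan2$folds[[1]], sum)
  expect_lte(diff(range(per_fold_cases)), 1)

  expect_identical(make_cv_plan(y, 10, 3, seed = 9),
                   make_cv_plan(y, 10, 3, seed = 9))
  expect_error(make_cv_plan(rep(c(1, 0), c(5, 60)), n_folds = 10),
               "fewer folds")
})

test_that("minority oversampling equalizes classes without touching majority", {
  y <- rep(c(1, 0), c(10, 30))
  idx <- oversample_minority(y, seed = 1)
  expect_equal(sum(y[idx] == 1), 30)
  expect_equal(sum(y[idx] == 0), 30)
  expect_true(all(seq_along(y) %in% idx))          # originals all kept
  expect_true(all(y[setdiff(idx, seq_along(y))] == 1))  # only minority duplicated

  balanced <- rep(c(1, 0), 15)
  expect_identical(oversample_minority(balanced, seed = 1),
                   seq_along(balanced))
  expect_error(oversample_minority(rep(1, 10)), "both classes")
})

test_that("every learner family separates a clean signal and stays at chance on noise", {
  set.seed(100)
  n <- 400
  y <- rep(c(1, 0), each = n / 2)
  x_sig <- cbind(s1 = rnorm(n, 2.5 * y), s2 = rnorm(n, -2 * y), s3 = rnorm(n))
  x_nul <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  plan <- make_cv_plan(y, n_folds = 3, n_repeats = 1, seed = 1)
  for (fam in learner_families()) {
    tl <- tune_and_train(fam, x_sig, y, plan, n_search = 1, seed = 2)
    expect_gte(tl$mean_cv_auc, 0.95)
    expect_true(all(tl$oof >= 0 & tl$oof <= 1))
    tn <- tune_and_train(fam, x_nul, y, plan, n_search = 1, seed = 2)
    expect_gte(tn$mean_cv_auc, 0.4)
    expect_lte(tn$mean_cv_auc, 0.6)
  }
})

test_that("a degenerate single-point search returns exactly that point", {
  set.seed(7)
  n <- 120
  y <- rep(c(1, 0), each = n / 2)
  x <- cbind(u = rnorm(n, y), v = rnorm(n))
  plan <- make_cv_plan(y, n_folds = 3, n_repeats = 1, seed = 1)
  ranges <- list(svm_rbf = list(cost = list(type = "real", min = 2, max = 2),
                                gamma = list(type = "real", min = 0.1,
                                             max = 0.1)))
  tl <- tune_and_train("svm_rbf", x, y, plan, n_search = 1, seed = 1,
                       ranges = ranges)
  expect_equal(tl$hp$cost, 2)
  expect_equal(tl$hp$gamma, 0.1)
})

test_that("training is deterministic given config and seed", {
  set.seed(3)
  n <- 150
  y <- rep(c(1, 0), c(60, 90))
  x <- cbind(a = rnorm(n, y), b = rnorm(n))
  plan <- make_cv_plan(y, n_folds = 3, n_repeats = 1, seed = 4)
  t1 <- tune_and_train("xgb", x, y, plan, n_search = 2, seed = 5)
  t2 <- tune_and_train("xgb", x, y, plan, n_search = 2, seed = 5)
  expect_identical(t1$hp, t2$hp)
  expect_identical(t1$oof, t2$oof)
  expect_identical(predict(t1, x), predict(t2, x))
})

test_that("out-of-fold probabilities never come from folds containing the sample", {
  # a memorizing learner exposes leakage: 1-NN achieves AUC 1 in-sample,
  # so chance-level OOF AUC on pure noise proves the folds exclude it.
  set.seed(8)
  n <- 200
  y <- rep(c(1, 0), each = n / 2)
  x <- cbind(a = rnorm(n), b = rnorm(n))
  plan <- make_cv_plan(y, n_folds = 5, n_repeats = 2, seed = 1)
  tl <- tune_and_train("rf", x, y, plan, n_search = 1, seed = 2,
                       ranges = list(rf = list(
                         num_trees = list(type = "int", min = 100, max = 100),
                         mtry_frac = list(type = "real", min = 0.9, max = 0.9),
                         min_node = list(type = "int", min = 1, max = 1))))
  # in-sample a depth-unlimited forest memorizes noise ...
  expect_gte(roc_auc(predict(tl, x), y), 0.9)
  # ... but the out-of-fold vector cannot
  expect_lte(roc_auc(tl$oof, y), 0.65)
})

test_that("feature-space scan picks the smallest best panel and clamps", {
  sc <- scan_feature_space(paste0("f", 1:25),
                           builder = function(p) c(0.7, 0.8, 0.8)[length(p) / 10],
                           step = 10)
  expect_equal(sc$best_k, 20)  # ties above 20 break to the smaller panel
  expect_equal(sc$auc_by_k$k, c(10, 20, 25))

  sc2 <- scan_feature_space(paste0("f", 1:4),
                            builder = function(p) 0.6, step = 10)
  expect_equal(sc2$best_k, 4)
  expect_equal(nrow(sc2$auc_by_k), 1)
})

test_that("the scan recovers the informative panel size on simulated data", {
  hits <- 0
  for (s in 1:20) {
    set.seed(400 + s)
    n <- 300
    y <- rep(c(1, 0), each = n / 2)
    x <- matrix(rnorm(n * 50), n, 50,
                dimnames = list(NULL, sprintf("f%02d", 1:50)))
    x[, 1:10] <- x[, 1:10] + 0.45 * y
    ranked <- sprintf("f%02d", 1:50)  # informative first
    plan <- make_cv_plan(y, n_folds = 3, n_repeats = 1, seed = s)
    builder <- function(panel) {
      cols <- x[, panel, drop = FALSE]
      aucs <- numeric(0)
      fold_id <- plan$folds[[1]]
      for (f in 1:3) {
        tr <- fold_id != f
        fit <- suppressWarnings(stats::glm.fit(cbind(1, cols[tr, ]), y[tr],
                                               family = stats::binomial()))
        pred <- stats::plogis(drop(cbind(1, cols[!tr, ]) %*% fit$coefficients))
        aucs <- c(aucs, roc_auc(pred, y[!tr]))
      }
      mean(aucs)
    }
    sc <- scan_feature_space(ranked, builder, step = 10)
    hits <- hits + (sc$best_k == 10)
  }
  expect_gte(hits, 16)
})

test_that("brute-force combination scan enumerates and ranks correctly", {
  set.seed(5)
  n <- 200
  y <- rep(c(1, 0), each = n / 2)
  df <- data.frame(subject_id = paste0("p", 1:n), sample_id = paste0("s", 1:n),
                   status = y, ytd_months = ifelse(y == 1, 12, NA),
                   A = rnorm(n, 2 * y), B = rnorm(n), C = rnorm(n))
  co <- cohort(df, c("A", "B", "C"))
  res <- bruteforce_combo_scan(co, c("A", "B", "C"), max_size = 2,
                               n_folds = 3, seed = 1)
  expect_equal(nrow(res), 6)  # C(3,1) + C(3,2)
  # every combination containing the signal marker outranks the rest
  with_a <- grepl("A", res$combo)
  expect_true(max(which(with_a)) < min(which(!with_a)))

  res1 <- bruteforce_combo_scan(co, c("A", "B", "C"), max_size = 1,
                                n_folds = 3, seed = 1)
  expect_equal(nrow(res1), 3)
  expect_equal(res1$combo[1], "A")
})
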