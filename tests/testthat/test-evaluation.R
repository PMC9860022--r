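test_that("roc_auc equals brute-force pair counting and handles ties", {
  expect_equal(roc_auc(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(1, 0), 5)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.85, 0.1), c(1, 1, 0, 0)), 0.75)
  set.seed(1)
  for (i in 1:200) {
    n1 <- sample(2:20, 1); n0 <- sample(2:20, 1)
    s <- sample(seq(0, 1, by = 0.1), n1 + n0, replace = TRUE)  # many ties
    y <- rep(c(1, 0), c(n1, n0))
    expect_equal(roc_auc(s, y), pair_count_auc(s, y), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(2)
  s <- rnorm(100)
  y <- rbinom(100, 1, 0.5)
  a <- roc_auc(s, y)
  expect_equal(roc_auc(exp(s), y), a)
  expect_equal(roc_auc(rank(s), y), a)
  expect_equal(roc_auc(plogis(3 * s - 1), y), a)
})

test_that("stratified bootstrap CIs behave at the null and at perfection", {
  set.seed(3)
  y <- rep(c(1, 0), each = 100)
  null_scores <- rnorm(200)
  ci <- auc_ci_stratified_bootstrap(null_scores, y, n_boot = 500, seed = 1)
  expect_true(ci[["lower"]] <= 0.5 && 0.5 <= ci[["upper"]])
  expect_false(attr(ci, "significant"))

  perfect <- c(rnorm(100, 10), rnorm(100, -10))
  ci2 <- auc_ci_stratified_bootstrap(perfect, y, n_boot = 200, seed = 1)
  expect_equal(unname(ci2), c(1, 1), ignore_attr = TRUE)
  expect_true(attr(ci2, "significant"))

  expect_identical(auc_ci_stratified_bootstrap(null_scores, y, 200, seed = 4),
                   auc_ci_stratified_bootstrap(null_scores, y, 200, seed = 4))
})

test_that("bootstrap ROC comparison is symmetric, null-safe and powered", {
  set.seed(4)
  y <- rep(c(1, 0), each = 50)
  s <- rnorm(100, y)
  expect_equal(as.numeric(compare_roc_bootstrap(s, s, y, n_boot = 200,
                                                seed = 1)), 1)
  s2 <- rnorm(100)
  pab <- compare_roc_bootstrap(s, s2, y, n_boot = 300, seed = 2)
  pba <- compare_roc_bootstrap(s2, s, y, n_boot = 300, seed = 2)
  expect_equal(as.numeric(pab), as.numeric(pba))

  hits <- 0
  for (r in 1:5) {
    set.seed(50 + r)
    yy <- rep(c(1, 0), each = 250)
    strong <- rnorm(500, 1.2 * yy)
    noise <- rnorm(500)
    hits <- hits + (compare_roc_bootstrap(strong, noise, yy, n_boot = 300,
                                          seed = r) < 0.01)
  }
  expect_gte(hits, 4)
})

test_that("fixed-specificity operating points match hand enumeration", {
  m <- metrics_at_specificity(c(rnorm(20, 5), rnorm(20, -5)),
                              rep(c(1, 0), each = 20), 0.9)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$ppv, 1)
  expect_equal(m$npv, 1)
  expect_equal(m$mcc, 1)

  # perfect anti-predictor: no case scores above any >=90%-spec threshold
  anti <- metrics_at_specificity(c(rep(0, 10), rep(1, 10)),
                                 rep(c(1, 0), each = 10), 0.9)
  expect_equal(anti$sensitivity, 0)

  # 30-point grid: 20 controls at 1..20, 10 cases at 15..24
  scores <- c(15:24, 1:20)
  y <- rep(c(1, 0), c(10, 20))
  m2 <- metrics_at_specificity(scores, y, 0.9)
  expect_gte(m2$threshold, 18)
  expect_equal(m2$tp, 6)
  expect_equal(m2$sensitivity, 0.6)
  expect_gte(m2$specificity, 0.9)

  # lowering the specificity target never lowers sensitivity
  set.seed(5)
  s <- rnorm(80); yy <- rbinom(80, 1, 0.4)
  sens <- vapply(c(0.95, 0.9, 0.8, 0.6),
                 function(t) metrics_at_specificity(s, yy, t)$sensitivity,
                 numeric(1))
  expect_true(all(diff(sens) >= 0))

  # unreachable target: all controls share the maximum score
  un <- metrics_at_specificity(c(0.2, 0.4, 1, 1), c(1, 1, 0, 0), 0.9)
  expect_true(un$unreachable)
  expect_equal(un$sensitivity, 0)
})

test_that("prevalence rescans track the analytic predictive values", {
  set.seed(6)
  n <- 600
  y <- rep(c(1, 0), each = n / 2)
  s <- rnorm(n, 1.8 * y)
  obs_prev <- mean(y)
  base <- metrics_at_specificity(s, y, 0.9)
  rs <- prevalence_rescan(s, y, prevalences = c(obs_prev, 0.1), n_rep = 60,
                          seed = 1)
  # at the observed prevalence the distributions centre on the unmodified metrics
  expect_equal(median(rs[[1]]$replicates$sensitivity), base$sensitivity,
               tolerance = 0.1)
  expect_equal(median(rs[[1]]$replicates$ppv), base$ppv, tolerance = 0.05)
  # at p = 0.1 the empirical PPV matches the analytic formula
  expect_equal(median(rs[[2]]$replicates$ppv, na.rm = TRUE),
               rs[[2]]$analytic_ppv, tolerance = 0.12)
  expect_lt(rs[[2]]$analytic_ppv, base$ppv)
  expect_gt(median(rs[[2]]$replicates$npv, na.rm = TRUE), 0.9)
  expect_error(prevalence_rescan(s, y, prevalences = 0.999, n_rep = 5),
               "not achievable")
})

test_that("pairwise kappa flags duplicate, independent and complementary learners", {
  set.seed(7)
  n <- 2000
  y <- rbinom(n, 1, 0.4)
  a <- clip01(runif(n))
  P <- cbind(a = a, dup = a, ind = clip01(runif(n)), comp = 1 - a)
  k <- pairwise_kappa(P, y, 0.9)
  expect_equal(unname(diag(k)), rep(1, 4))
  expect_equal(k["a", "dup"], 1)
  expect_lt(abs(k["a", "ind"]), 0.1)
  expect_lt(k["a", "comp"], 0)
  expect_equal(k, t(k))
})

test_that("cross-time-group matrices evaluate models on nested case groups", {
  fx <- informative_fit()
  lrn <- fx$model$learners[["glmnet"]]
  models <- list("0-1" = fx$model, "0-4+" = fx$model)
  cm <- cross_time_group_matrix(models, fx$test, groups = c("0-2", "0-4+"),
                                n_boot = 150, seed = 1)
  # identical models in all rows give identical rows
  expect_equal(cm$auc["0-1", ], cm$auc["0-4+", ])
  # diagonal-style entries reproduce direct per-group evaluation
  keep <- in_joined_group(fx$test, "0-2")
  direct <- roc_auc(predict(fx$model, fx$test[keep, , drop = FALSE]),
                    fx$test$status[keep])
  expect_equal(unname(cm$auc["0-1", "0-2"]), direct)
})
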