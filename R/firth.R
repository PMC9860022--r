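# Firth bias-reduced logistic regression with profile penalized-likelihood
# inference. The penalized log-likelihood is
#   l*(beta) = l(beta) + 0.5 * log det I(beta),
# i.e. the Jeffreys-prior penalty, maximized by modified-score Newton steps
# with step-halving. Estimates stay finite under complete separation; for a
# saturated one-binary-covariate (2x2) design the fit coincides with adding
# 1/2 to every cell of the contingency table.

logistic_loglik <- function(eta, y) {
  # numerically stable Bernoulli log-likelihood sum(y*eta - log(1+exp(eta)))
  sum(y * eta - ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))))
}

firth_penalized_loglik <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  w <- p * (1 - p)
  XtWX <- crossprod(X * sqrt(w))
  ld <- determinant(XtWX, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  logistic_loglik(eta, y) + 0.5 * as.numeric(ld$modulus)
}

# Core Newton engine. `fixed` names coordinates held at their starting value
# (used for penalized LRT p-values and profile CIs); the Jeffreys penalty is
# always computed on the full design.
firth_engine <- function(X, y, beta = NULL, fixed = integer(0),
                         tol = 1e-6, max_iter = 100, max_halving = 12) {
  k <- ncol(X)
  free <- setdiff(seq_len(k), fixed)
  if (is.null(beta)) beta <- numeric(k)
  pl <- firth_penalized_loglik(X, y, beta)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    Xw <- X * sqrt(w)
    info <- crossprod(Xw)
    info_inv <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(info_inv)) stop("Fisher information is singular", call. = FALSE)
    h <- rowSums((X %*% info_inv) * X) * w          # hat diagonal
    score <- drop(crossprod(X, y - p + h * (0.5 - p)))
    delta <- numeric(k)
    delta[free] <- tryCatch(
      solve(info[free, free, drop = FALSE], score[free]),
      error = function(e) stop("Fisher information is singular", call. = FALSE))
    # standardized score keeps the criterion invariant to covariate scale
    score_std <- score[free] * sqrt(diag(info_inv))[free]
    if (max(abs(score_std)) < tol && max(abs(delta)) < tol) {
      converged <- TRUE
      break
    }
    step <- 1
    for (half in seq_len(max_halving + 1L)) {
      cand <- beta + step * delta
      pl_new <- firth_penalized_loglik(X, y, cand)
      if (pl_new > pl - 1e-12) break
      step <- step / 2
    }
    beta <- beta + step * delta
    pl <- firth_penalized_loglik(X, y, beta)
  }
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  info <- crossprod(X * sqrt(p * (1 - p)))
  list(beta = beta, loglik = pl, info = info, converged = converged,
       iterations = iter)
}

firth_check_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# maximize l* with coordinate j fixed at `value` (others free); regions where
# the penalized information degenerates are treated as -Inf likelihood
firth_profile_fit <- function(X, y, j, value, init, tol, max_iter) {
  beta0 <- init
  beta0[j] <- value
  tryCatch({
    fit <- firth_engine(X, y, beta = beta0, fixed = j,
                        tol = tol, max_iter = max_iter)
    fit$loglik
  }, error = function(e) -Inf)
}

# bisection on the profile penalized likelihood, tolerant of -Inf tails
firth_profile_ci <- function(X, y, j, fit, level, tol, max_iter) {
  target <- fit$loglik - stats::qchisq(level, 1) / 2
  se <- sqrt(diag(solve(fit$info)))[j]
  bhat <- fit$beta[j]
  prof <- function(b) firth_profile_fit(X, y, j, b, fit$beta, tol, max_iter)
  root_for <- function(direction) {
    width <- 10 * se
    hi <- bhat + direction * width
    tries <- 0
    while (prof(hi) > target && tries < 6) {
      width <- width * 2
      hi <- bhat + direction * width
      tries <- tries + 1
    }
    if (prof(hi) > target) return(direction * Inf)
    lo <- bhat
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      f <- prof(mid)
      if (is.finite(f) && abs(f - target) < 1e-6) return(mid)
      if (f > target) lo <- mid else hi <- mid
      if (abs(hi - lo) < 1e-8 * (1 + abs(bhat))) break
    }
    (lo + hi) / 2
  }
  c(lower = root_for(-1), upper = root_for(+1))
}

#' Firth bias-reduced logistic regression
#'
#' Fits a binary logistic regression by maximizing the Jeffreys-prior
#' penalized log-likelihood \eqn{\ell(\beta) + \frac{1}{2}\log\det I(\beta)}
#' (Firth's bias reduction), using modified-score Newton iterations with
#' step-halving. Estimates remain finite under complete or quasi-complete
#' separation. Per-coefficient p-values come from penalized likelihood-ratio
#' tests (each coefficient profiled to zero with the remaining coefficients
#' free) and confidence intervals from the profile penalized log-likelihood;
#' Wald versions are available via `pvalue_method = "wald"`.
#'
#' @param formula model formula (binary response).
#' @param data data frame containing the variables.
#' @param level confidence level for the profile intervals.
#' @param pvalue_method `"plr"` (penalized likelihood ratio, default) or
#'   `"wald"`.
#' @param ci whether to compute profile penalized-likelihood confidence
#'   intervals (bisection on the profile likelihood; skipping them speeds up
#'   large univariate scans).
#' @param tol convergence tolerance on both the modified score and the step.
#' @param max_iter maximum Newton iterations.
#' @return An object of class `firth_glm` with components `coefficients`,
#'   `se`, `or` (odds ratios), `ci` (matrix, exponentiated profile bounds),
#'   `p`, `loglik` (penalized), `converged`, `iterations`.
#' @examples
#' d <- data.frame(y = rep(c(1, 0), c(10, 10)),
#'                 x = rep(c(1, 0, 1, 0), c(9, 1, 2, 8)))
#' f <- firth_glm(y ~ x, d)
#' coef(f)
#' @export
firth_glm <- function(formula, data, level = 0.95,
                      pvalue_method = c("plr", "wald"), ci = TRUE,
                      tol = 1e-6, max_iter = 100) {
  pvalue_method <- match.arg(pvalue_method)
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  firth_fit(X, y, level = level, pvalue_method = pvalue_method, ci = ci,
            tol = tol, max_iter = max_iter, call = match.call())
}

#' Firth logistic regression on a design matrix
#'
#' Matrix-interface engine behind [firth_glm()]. The first column of `X` is
#' expected to be the intercept.
#'
#' @param X design matrix (including intercept column).
#' @param y 0/1 outcome vector.
#' @inheritParams firth_glm
#' @param call call to record on the object.
#' @return A `firth_glm` object; see [firth_glm()].
#' @export
firth_fit <- function(X, y, level = 0.95, pvalue_method = c("plr", "wald"),
                      ci = TRUE, tol = 1e-6, max_iter = 100, call = NULL) {
  pvalue_method <- match.arg(pvalue_method)
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1L)))[seq_len(ncol(X))]
  stopifnot(length(y) == nrow(X))
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1", call. = FALSE)
  degenerate <- length(unique(y)) < 2L
  if (degenerate)
    warning("outcome has a single class; fit is degenerate", call. = FALSE)
  firth_check_rank(X)
  fit <- firth_engine(X, y, tol = tol, max_iter = max_iter)
  if (!fit$converged)
    stop(errorCondition(
      paste0("firth_fit did not converge in ", max_iter, " iterations"),
      last_beta = fit$beta, class = c("serostack_nonconvergence", "error")))
  k <- ncol(X)
  se <- sqrt(diag(solve(fit$info)))
  p <- rep(NA_real_, k)
  if (!degenerate) {
    if (pvalue_method == "plr") {
      for (j in seq_len(k)) {
        pl0 <- firth_profile_fit(X, y, j, 0, fit$beta, tol, max_iter)
        stat <- max(0, 2 * (fit$loglik - pl0))
        p[j] <- stats::pchisq(stat, 1, lower.tail = FALSE)
      }
    } else {
      p <- 2 * stats::pnorm(-abs(fit$beta / se))
    }
  }
  cimat <- matrix(NA_real_, k, 2, dimnames = list(colnames(X), c("lower", "upper")))
  if (ci && !degenerate) {
    for (j in seq_len(k))
      cimat[j, ] <- firth_profile_ci(X, y, j, fit, level, tol, max_iter)
  }
  structure(list(
    coefficients = stats::setNames(fit$beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    or = stats::setNames(exp(fit$beta), colnames(X)),
    ci = cimat, ci_or = exp(cimat), p = stats::setNames(p, colnames(X)),
    loglik = fit$loglik, converged = fit$converged,
    iterations = fit$iterations, level = level,
    pvalue_method = pvalue_method, n = length(y), call = call
  ), class = "firth_glm")
}

#' @export
coef.firth_glm <- function(object, ...) object$coefficients

#' @export
vcov.firth_glm <- function(object, ...) {
  # Wald covariance from the penalized information at the optimum
  v <- diag(object$se^2)
  dimnames(v) <- list(names(object$coefficients), names(object$coefficients))
  v
}

#' @export
confint.firth_glm <- function(object, parm, level = 0.95, ...) {
  ci <- object$ci
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
print.firth_glm <- function(x, digits = 4, ...) {
  cat("Firth bias-reduced logistic regression (n =", x$n, ")\n")
  tab <- data.frame(beta = x$coefficients, se = x$se, OR = x$or,
                    ci_low = x$ci_or[, 1], ci_high = x$ci_or[, 2], p = x$p)
  print(round(tab, digits))
  invisible(x)
}

#' @export
summary.firth_glm <- function(object, ...) {
  cat("Penalized log-likelihood:", format(object$loglik), "\n")
  cat("Iterations:", object$iterations,
      " converged:", object$converged, "\n")
  cat("P-values:", if (object$pvalue_method == "plr")
    "penalized likelihood-ratio tests" else "Wald", "\n")
  print(object)
}

#' Rank features by univariate Firth association
#'
#' Fits one univariate Firth logistic regression (feature + intercept) per
#' feature against case/control status and orders features by ascending
#' penalized likelihood-ratio p-value (ties broken by feature name). Failed
#' fits are retained with `NA` statistics and ranked last, with a warning.
#'
#' @param cohort a [cohort] object; markers must already be imputed (see
#'   [impute_low()]) and any factor covariates are coded 0/1.
#' @param features character vector of feature (marker or covariate) names.
#' @param ci compute profile CIs per feature (slower; default `TRUE`).
#' @param ... passed to [firth_fit()].
#' @return data frame with columns `feature, beta, or, ci_low, ci_high, p,
#'   converged`, ordered by p-value.
#' @export
rank_features <- function(cohort, features, ci = TRUE, ...) {
  df <- as.data.frame(cohort)
  y <- df$status
  rows <- lapply(features, function(f) {
    x <- feature_numeric(df, f)
    res <- tryCatch({
      if (any(is.na(x))) stop("feature '", f, "' contains missing values")
      fit <- firth_fit(cbind("(Intercept)" = 1, feat = x), y, ci = ci, ...)
      data.frame(feature = f, beta = fit$coefficients[["feat"]],
                 or = fit$or[["feat"]], ci_low = fit$ci_or["feat", 1],
                 ci_high = fit$ci_or["feat", 2], p = fit$p[["feat"]],
                 converged = fit$converged)
    }, error = function(e) {
      warning("rank_features: fit failed for '", f, "': ", conditionMessage(e),
              call. = FALSE)
      data.frame(feature = f, beta = NA_real_, or = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, p = NA_real_, converged = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$feature, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# coerce a cohort column to numeric 0/1 or numeric; yes/no -> 1/0
feature_numeric <- function(df, f) {
  if (!f %in% names(df)) stop("unknown feature '", f, "'", call. = FALSE)
  x <- df[[f]]
  if (is.character(x) || is.factor(x)) {
    x <- tolower(as.character(x))
    map <- c(yes = 1, no = 0, male = 1, female = 0, m = 1, f = 0)
    if (!all(x %in% names(map) | is.na(x)))
      stop("feature '", f, "' is non-numeric and not yes/no coded", call. = FALSE)
    x <- unname(map[x])
  }
  as.numeric(x)
}

#' Firth odds ratio from a 2x2 contingency table
#'
#' Convenience wrapper: expands the table of exposed/unexposed cases and
#' controls into individual rows and fits [firth_fit()] with the exposure as
#' the single covariate. For this saturated design the Firth estimate equals
#' the classical continuity-corrected odds ratio
#' \eqn{(a+\tfrac12)(d+\tfrac12) / ((b+\tfrac12)(c+\tfrac12))}.
#'
#' @param exposed_cases,exposed_controls,unexposed_cases,unexposed_controls
#'   cell counts.
#' @param ... passed to [firth_fit()].
#' @return the fitted `firth_glm` object; the exposure odds ratio is
#'   `fit$or[["exposure"]]`.
#' @export
firth_2x2 <- function(exposed_cases, exposed_controls,
                      unexposed_cases, unexposed_controls, ...) {
  y <- rep(c(1, 0, 1, 0),
           c(exposed_cases, exposed_controls, unexposed_cases, unexposed_controls))
  x <- rep(c(1, 1, 0, 0),
           c(exposed_cases, exposed_controls, unexposed_cases, unexposed_controls))
  firth_fit(cbind("(Intercept)" = 1, exposure = x), y, ...)
}
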