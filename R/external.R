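# External validation when some model covariates were never collected:
# the frozen model is scored on many copies of the external table that
# differ only in random allocations of the missing yes/no covariates
# (women Bernoulli(p_yes), men fixed "no"), marginalizing performance over
# the unobserved covariates.

#' Marginal external validation under randomly imputed covariates
#'
#' @param model a frozen `stack_model`.
#' @param external external [cohort]; the listed covariates must be entirely
#'   missing, every other panel feature present.
#' @param missing covariates to randomize (subset of `c("hrt", "ocp")`).
#' @param n_rand number of random allocations.
#' @param p_yes named per-covariate probability of "yes" for women. The
#'   defaults are the discovery-set control frequencies; `mode = "uniform"`
#'   uses 0.5 for all.
#' @param mode `"frequency"` (use `p_yes`) or `"uniform"`.
#' @param spec_target operating specificity for the per-replicate metrics.
#' @param n_boot bootstrap replicates for the mean-performance CI.
#' @param seed integer seed.
#' @return a `marginal_validation`: per-replicate metric vectors, medians,
#'   IQRs, and a bootstrap mean with CI per metric.
#' @export
marginal_validate <- function(model, external, missing = c("hrt", "ocp"),
                              n_rand = 1000,
                              p_yes = c(hrt = 48 / 249, ocp = 127 / 249),
                              mode = c("frequency", "uniform"),
                              spec_target = 0.90, n_boot = 2000, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(all(missing %in% c("hrt", "ocp")))
  df <- as.data.frame(external)
  for (v in missing) {
    if (!v %in% names(df)) df[[v]] <- NA_character_
    if (!all(is.na(df[[v]])))
      stop("covariate '", v, "' is partially observed; marginal validation ",
           "expects it entirely missing", call. = FALSE)
  }
  hard <- setdiff(model$panel, missing)
  miss <- hard[!hard %in% names(df) |
                 vapply(hard, function(f) f %in% names(df) &&
                          anyNA(df[[f]]), logical(1))]
  if (length(miss))
    stop("external table missing non-randomizable model feature(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  women <- is.na(df$sex) | tolower(as.character(df$sex)) %in% c("female", "f")
  y <- df$status
  rng <- rng_stream(seed)
  metrics <- c("auc", "sensitivity", "ppv", "npv", "mcc")
  out <- matrix(NA_real_, n_rand, length(metrics),
                dimnames = list(NULL, metrics))
  ext <- external
  for (r in seq_len(n_rand)) {
    for (v in missing) {
      p <- if (mode == "uniform") 0.5 else p_yes[[v]]
      fill <- rep("no", nrow(df))
      fill[women] <- ifelse(rng$rbinom(sum(women), 1, p) == 1, "yes", "no")
      ext[[v]] <- fill
    }
    s <- predict(model, ext)
    m <- metrics_at_specificity(s, y, spec_target)
    out[r, ] <- c(roc_auc(s, y), m$sensitivity, m$ppv, m$npv, m$mcc)
  }
  med <- apply(out, 2, stats::median, na.rm = TRUE)
  iqr <- apply(out, 2, stats::IQR, na.rm = TRUE)
  boot_mean <- t(apply(out, 2, function(v) {
    v <- v[!is.na(v)]
    bm <- vapply(seq_len(n_boot), function(b)
      mean(v[rng$sample(length(v), length(v), replace = TRUE)]), numeric(1))
    c(mean = mean(v), lower = stats::quantile(bm, 0.025, names = FALSE),
      upper = stats::quantile(bm, 0.975, names = FALSE))
  }))
  structure(list(replicates = as.data.frame(out), medians = med, iqr = iqr,
                 boot_mean = boot_mean, n_rand = n_rand, missing = missing,
                 mode = mode, p_yes = p_yes),
            class = "marginal_validation")
}

#' @export
print.marginal_validation <- function(x, ...) {
  cat("marginal_validation:", x$n_rand, "random allocations of",
      paste(x$missing, collapse = "/"), "(", x$mode, "mode )\n")
  cat("medians:\n")
  print(round(x$medians, 3))
  invisible(x)
}
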