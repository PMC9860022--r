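# Synthetic nested case-control cohort generator. Emulates the statistical
# structure the downstream analysis assumes: a discovery set of post-menopausal
# women with case samples drawn months-to-years before diagnosis (some
# subjects with 2-6 annual longitudinal draws), ~101 log-normal serum markers
# whose case/control separation grows as diagnosis approaches
# (delta_m * exp(-t / tau_m) shift on the log scale), clinical covariates with
# configurable case/control odds ratios, and marker-specific lower
# limit-of-detection censoring. It is an emulation target for testing the
# pipeline, not a fitted model of any real cohort.

#' Simulation configuration
#'
#' Defaults reproduce the discovery-study structure: 143 case subjects with
#' 218 case samples (35 subjects contributing 2-6 annual draws), 249
#' controls, 101 markers of which six are informative with effects rising
#' towards diagnosis, covariate odds ratios of the magnitudes reported for
#' the discovery set (HRT 0.41, OCP 1.47, diabetes 4.99, age +2.46 years for
#' cases), and 5% lower-LOD censoring per marker.
#'
#' @param n_cases number of case subjects.
#' @param n_controls number of control subjects (one sample each).
#' @param longitudinal_fraction fraction of case subjects with 2-6 annual
#'   draws.
#' @param samples_per_case mean case samples per case subject; fixes the
#'   total number of case samples at `round(n_cases * samples_per_case)`.
#' @param n_markers total marker count.
#' @param informative data frame with columns `name`, `delta` (log-scale
#'   case shift at diagnosis), `tau` (effect timescale, years). Set
#'   `delta = 0` (or pass a zero-row frame) for a null cohort.
#' @param marker_log_sd log-scale marker standard deviation.
#' @param equicorrelation Gaussian-copula equicorrelation between markers.
#' @param age_mean,age_sd control age-at-draw distribution (years).
#' @param age_case_shift additive case shift in mean age (years).
#' @param bmi_mean,bmi_sd,bmi_case_shift BMI model (kg/m^2).
#' @param hrt_or,ocp_or,diabetes_or case/control odds ratios of the binary
#'   covariates.
#' @param hrt_p,ocp_p,diabetes_p covariate prevalences among controls.
#' @param lod_quantile per-marker censoring quantile of the control marker
#'   distribution (0 disables censoring).
#' @param max_first_draw_months upper bound of the uniform time-to-diagnosis
#'   of each case subject's most recent draw.
#' @param seed default integer seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_cases = 143, n_controls = 249,
                              longitudinal_fraction = 35 / 143,
                              samples_per_case = 218 / 143,
                              n_markers = 101,
                              informative = default_informative_markers(),
                              marker_log_sd = 1, equicorrelation = 0.2,
                              age_mean = 62.48, age_sd = 6,
                              age_case_shift = 2.46,
                              bmi_mean = 26.64, bmi_sd = 4,
                              bmi_case_shift = 0.82,
                              hrt_or = 0.41, ocp_or = 1.47, diabetes_or = 4.99,
                              hrt_p = 48 / 249, ocp_p = 127 / 249,
                              diabetes_p = 11 / 249,
                              lod_quantile = 0.05,
                              max_first_draw_months = 70, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_cases > 0, n_controls > 0, n_markers >= 1,
            longitudinal_fraction >= 0, longitudinal_fraction <= 1,
            lod_quantile >= 0, lod_quantile < 1, marker_log_sd > 0,
            equicorrelation >= 0, equicorrelation < 1)
  if (nrow(cfg$informative) > n_markers)  # keep the top of the default panel
    cfg$informative <- cfg$informative[seq_len(n_markers), , drop = FALSE]
  if (nrow(cfg$informative)) stopifnot(all(cfg$informative$tau > 0))
  class(cfg) <- "simulation_config"
  cfg
}

#' @rdname simulation_config
#' @export
default_informative_markers <- function() {
  data.frame(
    name = c("CA19_9", "MUC16", "THBS2", "CEACAM5", "VWF", "IL6ST"),
    delta = c(2.0, 1.2, 1.0, 0.9, 0.7, 0.6),
    tau = c(2, 2, 3, 2, 4, 3),
    stringsAsFactors = FALSE)
}

#' Null-effect variant of a simulation configuration
#'
#' Zeroes every marker effect and sets all covariate odds ratios / shifts to
#' the null, so any downstream classifier should perform at chance.
#'
#' @param cfg a `simulation_config`.
#' @export
null_config <- function(cfg = simulation_config()) {
  cfg$informative <- cfg$informative[0, , drop = FALSE]
  cfg$age_case_shift <- 0
  cfg$bmi_case_shift <- 0
  cfg$hrt_or <- cfg$ocp_or <- cfg$diabetes_or <- 1
  cfg
}

# per-marker log-scale baselines; derived from cfg$seed (not the draw seed)
# so a discovery cohort and an external set from the same config share the
# same marker scales and signatures transfer
marker_baselines <- function(cfg) {
  mu <- rng_stream(cfg$seed + 99991L)$rnorm(cfg$n_markers, mean = 3, sd = 1)
  stats::setNames(mu, marker_names(cfg))
}

marker_names <- function(cfg) {
  inf <- cfg$informative$name
  if (length(inf) > cfg$n_markers)
    stop("more informative markers than n_markers", call. = FALSE)
  c(inf, sprintf("M%03d", seq_len(cfg$n_markers - length(inf))))
}

# case probability giving the requested case/control odds ratio when the
# control prevalence is p0
case_prob_from_or <- function(p0, or) {
  odds <- or * p0 / (1 - p0)
  odds / (1 + odds)
}

#' Simulate a discovery cohort
#'
#' Generates a [cohort] per the configuration: cases receive `ytd_months`
#' for each draw (the most recent draw uniform on
#' `(0, max_first_draw_months]`, longitudinal subjects adding annual earlier
#' draws); marker `m` for a case sample drawn `t` years before diagnosis is
#' log-normal with log-mean shifted by `delta_m * exp(-t / tau_m)`; binary
#' covariates are drawn so the population case/control odds ratios equal the
#' configured values in expectation; marker values below the configured
#' control-distribution quantile are flagged below-LOD. Fully reproducible
#' given the seed.
#'
#' @param cfg a [simulation_config()].
#' @param seed integer seed (defaults to `cfg$seed`).
#' @return a validated [cohort] with `single_group` assigned.
#' @export
simulate_cohort <- function(cfg = simulation_config(), seed = cfg$seed) {
  rng <- rng_stream(seed)
  rng$eval({
    mk <- marker_names(cfg)
    n_long <- round(cfg$longitudinal_fraction * cfg$n_cases)
    total_case_samples <- max(round(cfg$n_cases * cfg$samples_per_case),
                              cfg$n_cases)
    extra <- total_case_samples - cfg$n_cases
    if (n_long > extra) n_long <- extra
    draws <- rep(1L, cfg$n_cases)
    if (n_long > 0) {
      long_idx <- sample.int(cfg$n_cases, n_long)
      draws[long_idx] <- 2L
      pool <- extra - n_long  # draws beyond the guaranteed second one
      while (pool > 0) {
        open <- long_idx[draws[long_idx] < 6L]
        if (!length(open)) break
        pick <- if (length(open) == 1L) open else sample(open, 1L)
        draws[pick] <- draws[pick] + 1L
        pool <- pool - 1L
      }
    }
    case_rows <- data.frame(
      subject_id = rep(sprintf("case_%03d", seq_len(cfg$n_cases)), draws),
      status = 1)
    first_ytd <- stats::runif(cfg$n_cases, 0, cfg$max_first_draw_months)
    first_ytd <- pmax(first_ytd, 1e-3)
    ytd <- unlist(lapply(seq_len(cfg$n_cases), function(i)
      first_ytd[i] + 12 * (seq_len(draws[i]) - 1L)), use.names = FALSE)
    case_rows$ytd_months <- ytd
    ctrl_rows <- data.frame(
      subject_id = sprintf("ctrl_%03d", seq_len(cfg$n_controls)),
      status = 0, ytd_months = NA_real_)
    df <- rbind(case_rows, ctrl_rows)
    df$sample_id <- sprintf("s%04d", seq_len(nrow(df)))
    n <- nrow(df)
    case <- df$status == 1

    # covariates: subject-level, replicated across a subject's draws
    subj <- !duplicated(df$subject_id)
    subj_ids <- df$subject_id[subj]
    subj_case <- df$status[subj] == 1
    draw_bin <- function(p0, or) {
      p <- ifelse(subj_case, case_prob_from_or(p0, or), p0)
      ifelse(stats::rbinom(length(p), 1, p) == 1, "yes", "no")
    }
    cov <- data.frame(subject_id = subj_ids,
                      hrt = draw_bin(cfg$hrt_p, cfg$hrt_or),
                      ocp = draw_bin(cfg$ocp_p, cfg$ocp_or),
                      diabetes = draw_bin(cfg$diabetes_p, cfg$diabetes_or),
                      bmi = stats::rnorm(length(subj_ids),
                                         cfg$bmi_mean + cfg$bmi_case_shift * subj_case,
                                         cfg$bmi_sd),
                      age0 = stats::rnorm(length(subj_ids),
                                          cfg$age_mean + cfg$age_case_shift * subj_case,
                                          cfg$age_sd),
                      stringsAsFactors = FALSE)
    m <- match(df$subject_id, cov$subject_id)
    df$hrt <- cov$hrt[m]; df$ocp <- cov$ocp[m]; df$diabetes <- cov$diabetes[m]
    df$bmi <- pmin(pmax(cov$bmi[m], 15), 50)
    # age0 is age at the most recent draw; earlier draws are younger
    offset <- ifelse(case, (df$ytd_months - first_ytd[match(df$subject_id,
                     sprintf("case_%03d", seq_len(cfg$n_cases)))]) / 12, 0)
    df$age <- pmin(pmax(cov$age0[m] - offset, 45), 90)
    df$sex <- "female"

    # markers: equicorrelated Gaussian copula on the log scale
    rho <- cfg$equicorrelation
    g <- stats::rnorm(n)
    mu <- marker_baselines(cfg)
    t_years <- ifelse(case, df$ytd_months / 12, NA)
    delta <- stats::setNames(numeric(cfg$n_markers), mk)
    tau <- stats::setNames(rep(1, cfg$n_markers), mk)
    if (nrow(cfg$informative)) {
      delta[cfg$informative$name] <- cfg$informative$delta
      tau[cfg$informative$name] <- cfg$informative$tau
    }
    low <- matrix(FALSE, n, cfg$n_markers, dimnames = list(NULL, mk))
    for (j in seq_along(mk)) {
      z <- sqrt(rho) * g + sqrt(1 - rho) * stats::rnorm(n)
      shift <- ifelse(case, delta[j] * exp(-t_years / tau[j]), 0)
      val <- exp(mu[j] + shift + cfg$marker_log_sd * z)
      if (cfg$lod_quantile > 0) {
        thr <- stats::qlnorm(cfg$lod_quantile, mu[j], cfg$marker_log_sd)
        cens <- val < thr
        val[cens] <- NA_real_
        low[, j] <- cens
      }
      df[[mk[j]]] <- val
    }
    out <- cohort(df[c("subject_id", "sample_id", "status", "ytd_months",
                       "age", "bmi", "hrt", "ocp", "diabetes", "sex", mk)],
                  mk, low)
    validate_cohort(assign_time_groups(out))
  })
}

#' Simulate an external (post-diagnosis) validation set
#'
#' Emulates an external symptomatic cohort: cases are sampled at diagnosis
#' (marker effects at full size, no time-to-diagnosis), both sexes are
#' present, and the listed covariates were never collected (all missing).
#'
#' @param cfg a [simulation_config()] (marker panel and effect sizes are
#'   shared with the discovery generator so that signatures transfer).
#' @param drop_covariates subset of `c("hrt", "ocp", "bmi")` set to missing.
#' @param n_cases,n_controls set sizes.
#' @param p_male probability a subject is male.
#' @param seed integer seed.
#' @return a [cohort] (non-discovery design: no `ytd_months`).
#' @export
simulate_external_set <- function(cfg = simulation_config(),
                                  drop_covariates = c("hrt", "ocp"),
                                  n_cases = 17, n_controls = 17,
                                  p_male = 14 / 34, seed = cfg$seed + 1L) {
  stopifnot(all(drop_covariates %in% c("hrt", "ocp", "bmi")))
  rng <- rng_stream(seed)
  rng$eval({
    mk <- marker_names(cfg)
    n <- n_cases + n_controls
    df <- data.frame(
      subject_id = sprintf("ext_%03d", seq_len(n)),
      sample_id = sprintf("e%04d", seq_len(n)),
      status = rep(c(1, 0), c(n_cases, n_controls)))
    case <- df$status == 1
    sex <- ifelse(stats::rbinom(n, 1, p_male) == 1, "male", "female")
    draw_bin <- function(p0, or) {
      p <- ifelse(case, case_prob_from_or(p0, or), p0)
      out <- ifelse(stats::rbinom(n, 1, p) == 1, "yes", "no")
      out[sex == "male"] <- "no"
      out
    }
    df$age <- pmin(pmax(stats::rnorm(n, cfg$age_mean +
                                       cfg$age_case_shift * case, cfg$age_sd),
                        27), 90)
    df$bmi <- pmin(pmax(stats::rnorm(n, cfg$bmi_mean +
                                       cfg$bmi_case_shift * case, cfg$bmi_sd),
                        15), 50)
    df$hrt <- draw_bin(cfg$hrt_p, cfg$hrt_or)
    df$ocp <- draw_bin(cfg$ocp_p, cfg$ocp_or)
    df$diabetes <- draw_bin(cfg$diabetes_p, cfg$diabetes_or)
    df$sex <- sex
    for (v in drop_covariates) df[[v]] <- NA_character_
    mu <- marker_baselines(cfg)
    delta <- stats::setNames(numeric(cfg$n_markers), mk)
    if (nrow(cfg$informative)) delta[cfg$informative$name] <- cfg$informative$delta
    rho <- cfg$equicorrelation
    g <- stats::rnorm(n)
    low <- matrix(FALSE, n, cfg$n_markers, dimnames = list(NULL, mk))
    for (j in seq_along(mk)) {
      z <- sqrt(rho) * g + sqrt(1 - rho) * stats::rnorm(n)
      val <- exp(mu[j] + delta[j] * case + cfg$marker_log_sd * z)
      if (cfg$lod_quantile > 0) {
        thr <- stats::qlnorm(cfg$lod_quantile, mu[j], cfg$marker_log_sd)
        cens <- val < thr
        val[cens] <- NA_real_
        low[, j] <- cens
      }
      df[[mk[j]]] <- val
    }
    validate_cohort(cohort(df, mk, low), discovery = FALSE)
  })
}
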