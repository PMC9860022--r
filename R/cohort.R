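# Cohort data model: one row per serum sample, with case/control status,
# time-to-diagnosis at draw (months, cases only in the discovery design),
# marker concentrations (below-LOD cells held as flags until imputation) and
# clinical covariates. The container is a plain data.frame carrying a
# `markers` attribute (marker column names) and a logical `low` matrix
# flagging below-LOD cells (which are NA in the data until imputed).

COVARIATE_COLS <- c("age", "bmi", "hrt", "ocp", "diabetes", "sex")
SINGLE_GROUPS <- c("0-1", "1-2", "2-3", "3-4", "4+")
JOINED_GROUPS <- c("0-1", "0-2", "0-3", "0-4", "0-4+")

#' Construct a cohort table
#'
#' @param df data frame with columns `subject_id`, `sample_id`, `status`
#'   (0 = control, 1 = case), optionally `ytd_months` (months from draw to
#'   diagnosis, cases only), covariates (`age`, `bmi`, `hrt`, `ocp`,
#'   `diabetes`, `sex`) and numeric marker columns.
#' @param markers character vector naming the marker columns.
#' @param low optional logical matrix (rows x markers) flagging below
#'   limit-of-detection cells; flagged cells must be `NA` in `df`.
#' @return object of class `cohort` (a data.frame with attributes).
#' @export
cohort <- function(df, markers, low = NULL) {
  stopifnot(is.data.frame(df))
  need <- c("subject_id", "sample_id", "status")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(markers %in% names(df)))
    stop("marker column(s) not in table: ",
         paste(setdiff(markers, names(df)), collapse = ", "), call. = FALSE)
  if (is.null(low))
    low <- matrix(FALSE, nrow(df), length(markers),
                  dimnames = list(NULL, markers))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, markers = markers, low = low,
            class = c("cohort", "data.frame"))
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort:", nrow(x), "samples (", sum(x$status == 1), "case /",
      sum(x$status == 0), "control ),", length(markers(x)), "markers,",
      sum(attr(x, "low")), "below-LOD cells\n")
  invisible(x)
}

#' Marker column names of a cohort
#' @param x a cohort.
#' @export
markers <- function(x) attr(x, "markers")

# keep attributes through row subsetting
#' @export
`[.cohort` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(markers(x) %in% names(out))) {
    low <- attr(x, "low")
    if (!missing(i)) low <- low[i, , drop = FALSE]
    attr(out, "markers") <- markers(x)
    attr(out, "low") <- low
    class(out) <- c("cohort", "data.frame")
  }
  out
}

subset_cohort <- function(x, keep) x[keep, , drop = FALSE]

#' Validate a cohort table
#'
#' Checks the core invariants: status is 0/1; `ytd_months` non-negative and
#' present exactly for cases when `discovery = TRUE`; marker values
#' non-negative or flagged below-LOD; ages inside a plausibility window.
#'
#' @param x a cohort.
#' @param discovery enforce the discovery-design rule that `ytd_months` is
#'   present iff the sample is a case (external post-diagnosis sets do not
#'   carry YTD).
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_cohort <- function(x, discovery = TRUE) {
  if (!all(x$status %in% c(0, 1)))
    stop("status must be 0/1", call. = FALSE)
  if (anyDuplicated(x$sample_id))
    stop("duplicated sample_id", call. = FALSE)
  if ("ytd_months" %in% names(x)) {
    ytd <- x$ytd_months
    if (any(!is.na(ytd) & ytd < 0)) stop("negative ytd_months", call. = FALSE)
    if (discovery) {
      if (any(x$status == 1 & is.na(ytd)))
        stop("case sample without ytd_months", call. = FALSE)
      if (any(x$status == 0 & !is.na(ytd)))
        stop("control sample with ytd_months", call. = FALSE)
    }
  } else if (discovery && any(x$status == 1)) {
    stop("missing ytd_months column", call. = FALSE)
  }
  if ("age" %in% names(x) &&
      any(!is.na(x$age) & (x$age < 18 | x$age > 120)))
    stop("age outside plausibility window [18, 120]", call. = FALSE)
  low <- attr(x, "low")
  for (m in markers(x)) {
    v <- x[[m]]
    if (any(!is.na(v) & v < 0)) stop("negative value in marker ", m, call. = FALSE)
    if (any(is.na(v) & !low[, m]))
      stop("NA marker value not flagged below-LOD in ", m, call. = FALSE)
  }
  invisible(x)
}

#' Read a delimited cohort table
#'
#' Reads a delimited text file into a [cohort]. Column roles are declared in
#' a dialect list (or YAML file via [read_cohort_dialect()]): which column is
#' the status, which the time-to-diagnosis, which columns are markers
#' (explicit list or common prefix), and the token marking below
#' limit-of-detection values (default `"low"`, case-insensitive). Below-LOD
#' cells are preserved as flags, never silently converted to numbers; row
#' order is preserved.
#'
#' @param path file path.
#' @param dialect list with elements `status_col`, `ytd_col`, and either
#'   `marker_cols` (character) or `marker_prefix`; optional `low_token`
#'   (default "low"), `sep` (default ","), `covariates` (named character
#'   mapping of file column -> canonical covariate name).
#' @return a validated [cohort].
#' @export
read_cohort <- function(path, dialect = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- dialect$sep %||% ","
  low_token <- tolower(dialect$low_token %||% "low")
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  status_col <- dialect$status_col %||% "status"
  ytd_col <- dialect$ytd_col %||% "ytd_months"
  for (col in c("subject_id", "sample_id", status_col)) {
    if (!col %in% names(raw))
      stop("schema error: missing mandatory column '", col, "'", call. = FALSE)
  }
  if (!is.null(dialect$marker_cols)) {
    mk <- dialect$marker_cols
    if (!all(mk %in% names(raw)))
      stop("schema error: missing marker column(s): ",
           paste(setdiff(mk, names(raw)), collapse = ", "), call. = FALSE)
  } else if (!is.null(dialect$marker_prefix)) {
    mk <- grep(paste0("^", dialect$marker_prefix), names(raw), value = TRUE)
  } else {
    known <- c("subject_id", "sample_id", status_col, ytd_col, COVARIATE_COLS,
               names(dialect$covariates %||% character()), "single_group")
    mk <- setdiff(names(raw), known)
  }
  df <- data.frame(subject_id = raw$subject_id, sample_id = raw$sample_id,
                   status = as_numeric_col(raw[[status_col]], status_col),
                   stringsAsFactors = FALSE)
  if (ytd_col %in% names(raw))
    df$ytd_months <- as_numeric_col(raw[[ytd_col]], ytd_col)
  cov_map <- dialect$covariates %||%
    stats::setNames(intersect(COVARIATE_COLS, names(raw)),
                    intersect(COVARIATE_COLS, names(raw)))
  for (src in names(cov_map)) {
    dst <- cov_map[[src]]
    df[[dst]] <- if (dst %in% c("age", "bmi"))
      as_numeric_col(raw[[src]], src) else raw[[src]]
  }
  if ("single_group" %in% names(raw)) df$single_group <- raw$single_group
  low <- matrix(FALSE, nrow(raw), length(mk), dimnames = list(NULL, mk))
  for (m in mk) {
    v <- raw[[m]]
    is_low <- !is.na(v) & tolower(trimws(v)) == low_token
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & !is_low & is.na(num))
    if (length(bad))
      stop("parse error: non-numeric value '", v[bad[1]], "' in marker '", m,
           "' at row ", bad[1], call. = FALSE)
    num[is_low] <- NA_real_
    df[[m]] <- num
    low[, m] <- is_low
  }
  validate_cohort(cohort(df, mk, low),
                  discovery = isTRUE(dialect$discovery %||% TRUE))
}

#' Read a cohort dialect from a YAML config
#' @param path YAML file declaring column roles (see [read_cohort()]).
#' @export
read_cohort_dialect <- function(path) yaml::read_yaml(path)

#' Write a cohort table to delimited text
#'
#' Inverse of [read_cohort()]: below-LOD flags are written back as the low
#' token so that a write/read round trip is the identity.
#'
#' @param x a cohort.
#' @param path output path.
#' @param low_token token for below-LOD cells.
#' @param sep field separator.
#' @export
write_cohort <- function(x, path, low_token = "low", sep = ",") {
  out <- as.data.frame(x)
  low <- attr(x, "low")
  for (m in markers(x)) {
    v <- format(out[[m]], trim = TRUE, digits = 15)
    v[is.na(out[[m]])] <- NA
    v[low[, m]] <- low_token
    out[[m]] <- v
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Impute below-LOD marker values
#'
#' Replaces below-LOD flags with half the minimum observed numeric value of
#' the marker (`rule = "half_min"`) or with a fixed floor value
#' (`rule = "fixed_floor"`). Numeric cells are untouched.
#'
#' @param x a cohort.
#' @param rule `"half_min"` or `"fixed_floor"`.
#' @param floor floor value (scalar, or named vector per marker) when
#'   `rule = "fixed_floor"`.
#' @return the cohort with all flags resolved.
#' @export
impute_low <- function(x, rule = c("half_min", "fixed_floor"), floor = NULL) {
  rule <- match.arg(rule)
  low <- attr(x, "low")
  for (m in markers(x)) {
    flagged <- low[, m]
    if (!any(flagged)) next
    if (rule == "half_min") {
      obs <- x[[m]][!flagged]
      obs <- obs[!is.na(obs)]
      if (!length(obs))
        stop("marker '", m, "' has no observed numeric values; half_min ",
             "imputation impossible", call. = FALSE)
      x[[m]][flagged] <- min(obs) / 2
    } else {
      if (is.null(floor)) stop("fixed_floor rule requires a floor value",
                               call. = FALSE)
      f <- if (length(floor) > 1 || !is.null(names(floor))) floor[[m]] else floor
      x[[m]][flagged] <- f
    }
    low[, m] <- FALSE
  }
  attr(x, "low") <- low
  x
}

#' Assign single time-to-diagnosis groups
#'
#' Labels each case sample with its single years-to-diagnosis group using
#' half-open intervals \[0,1), \[1,2), \[2,3), \[3,4), \[4,Inf) in years
#' (a draw exactly 24 months before diagnosis falls in 2-3). Controls carry
#' no YTD and are eligible for every group (their label is `NA`).
#'
#' @param x a cohort; every case sample must have `ytd_months`.
#' @return the cohort with a `single_group` factor column.
#' @export
assign_time_groups <- function(x) {
  ytd <- x$ytd_months
  if (any(x$status == 1 & is.na(ytd)))
    stop("case sample without ytd_months", call. = FALSE)
  if (any(!is.na(ytd) & ytd < 0)) stop("negative ytd_months", call. = FALSE)
  grp <- rep(NA_character_, nrow(x))
  idx <- which(x$status == 1)
  yrs <- ytd[idx] / 12
  grp[idx] <- as.character(cut(yrs, breaks = c(0, 1, 2, 3, 4, Inf),
                               labels = SINGLE_GROUPS, right = FALSE,
                               include.lowest = TRUE))
  x$single_group <- factor(grp, levels = SINGLE_GROUPS)
  x
}

#' Membership in a joined time-group
#'
#' Joined group `0-k` is the union of the first `k` single groups; `0-4+`
#' covers everything. Controls (no YTD) are eligible for every group.
#'
#' @param x a cohort with `single_group` assigned.
#' @param group one of `"0-1", "0-2", "0-3", "0-4", "0-4+"`.
#' @return logical vector of membership.
#' @export
in_joined_group <- function(x, group) {
  group <- match.arg(group, JOINED_GROUPS)
  if (!"single_group" %in% names(x))
    stop("run assign_time_groups() first", call. = FALSE)
  k <- match(group, JOINED_GROUPS)
  ok <- x$status == 0
  ok | (as.integer(x$single_group) <= k & !is.na(x$single_group))
}

quartile_bin <- function(x) {
  # quartiles on the full table; boundary ties fall in the lower quartile
  if (all(is.na(x))) return(factor(rep("NA", length(x))))
  q <- stats::quantile(x, probs = c(0.25, 0.5, 0.75), na.rm = TRUE)
  b <- cut(x, breaks = c(-Inf, q, Inf), labels = c("Q1", "Q2", "Q3", "Q4"),
           right = TRUE)
  b <- as.character(b)
  b[is.na(b)] <- "NA"
  factor(b)
}

#' Stratified train/test split
#'
#' Splits samples into train/test with per-stratum train counts
#' `round(frac_train * stratum size)` (round-half-even), reproducibly by
#' seed. Default stratification keys follow the discovery design: age
#' quartile, BMI quartile, HRT, OCP, diabetes, case/control status and
#' sample single time-group (controls form their own time-group level).
#' Quartile boundaries are computed on the full table before splitting.
#' Strata of size one go to the training set. Longitudinal samples from one
#' subject are split independently by default; `by_subject = TRUE` keeps all
#' samples of a subject on one side instead.
#'
#' @param x a cohort with `single_group` assigned (when used as a key).
#' @param frac_train training fraction in (0, 1).
#' @param keys character vector of stratification keys (column names;
#'   `age`/`bmi` are binned into quartiles automatically).
#' @param seed integer seed.
#' @param by_subject split whole subjects rather than samples.
#' @return a `split_assignment` data frame (`sample_id`, `partition`) with
#'   the per-sample stratum label attached as attribute `strata`.
#' @export
stratified_split <- function(x, frac_train = 2 / 3,
                             keys = c("age", "bmi", "hrt", "ocp", "diabetes",
                                      "status", "single_group"),
                             seed = 1L, by_subject = FALSE) {
  if (nrow(x) == 0) stop("empty cohort", call. = FALSE)
  stopifnot(frac_train > 0, frac_train < 1)
  parts <- lapply(keys, function(k) {
    if (!k %in% names(x)) stop("stratification key '", k, "' not in cohort",
                               call. = FALSE)
    v <- x[[k]]
    if (k %in% c("age", "bmi")) return(quartile_bin(v))
    v <- as.character(v)
    v[is.na(v)] <- if (k == "single_group") "control" else "NA"
    factor(v)
  })
  lab <- as.character(interaction(parts, drop = TRUE, sep = "|"))
  # fully crossed keys leave many singleton strata on cohort-sized tables;
  # rare strata are collapsed hierarchically (outcome x time-group, then
  # outcome alone) so the split can actually stratify them
  coarse_keys <- intersect(c("status", "single_group"), keys)
  if (length(coarse_keys) && length(keys) > length(coarse_keys)) {
    coarse <- as.character(interaction(parts[match(coarse_keys, keys)],
                                       drop = TRUE, sep = "|"))
    small <- lab %in% names(which(table(lab) < 2))
    lab[small] <- paste0("~", coarse[small])
    if ("status" %in% keys) {
      small <- lab %in% names(which(table(lab) < 2))
      lab[small] <- paste0("~~", parts[[match("status", keys)]][small])
    }
  }
  strata <- factor(lab)
  partition <- rep(NA_character_, nrow(x))
  unit <- if (by_subject) x$subject_id else x$sample_id
  rng <- rng_stream(seed)
  for (s in levels(strata)) {
    rows <- which(strata == s)
    units <- unique(unit[rows])
    n <- length(units)
    n_train <- if (n == 1) 1L else round(frac_train * n)
    train_units <- units[rng$sample_int(n, n_train)]
    partition[rows] <- ifelse(unit[rows] %in% train_units, "train", "test")
  }
  out <- data.frame(sample_id = x$sample_id, partition = partition,
                    stringsAsFactors = FALSE)
  attr(out, "strata") <- as.character(strata)
  class(out) <- c("split_assignment", "data.frame")
  out
}

#' Write/read a split assignment
#' @param x a `split_assignment`.
#' @param path file path.
#' @export
write_split <- function(x, path) {
  utils::write.table(as.data.frame(x)[c("sample_id", "partition")], path,
                     sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  out <- utils::read.csv(path, colClasses = "character")
  class(out) <- c("split_assignment", "data.frame")
  out
}

#' Apply a split assignment
#' @param x a cohort.
#' @param split a `split_assignment`.
#' @param partition `"train"` or `"test"`.
#' @return the cohort subset.
#' @export
split_partition <- function(x, split, partition = c("train", "test")) {
  partition <- match.arg(partition)
  keep <- x$sample_id %in% split$sample_id[split$partition == partition]
  subset_cohort(x, keep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_numeric_col <- function(v, name) {
  num <- suppressWarnings(as.numeric(v))
  bad <- which(!is.na(v) & is.na(num))
  if (length(bad))
    stop("parse error: non-numeric value '", v[bad[1]], "' in column '", name,
         "' at row ", bad[1], call. = FALSE)
  num
}

# small seeded RNG wrapper: isolates package randomness from the caller's
# RNG state and gives each consumer an independent reproducible stream
rng_stream <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv())
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
        assign(".Random.seed", old, envir = globalenv())
    })
    expr
  }
  list(
    sample_int = function(n, k) with_state(sample.int(n, k)),
    sample = function(x, size = length(x), replace = FALSE, prob = NULL)
      with_state(sample(x, size, replace, prob)),
    runif = function(n, min = 0, max = 1) with_state(stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) with_state(stats::rnorm(n, mean, sd)),
    rbinom = function(n, size, prob) with_state(stats::rbinom(n, size, prob)),
    int = function(n = 1) with_state(sample.int(.Machine$integer.max, n)),
    eval = with_state
  )
}
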