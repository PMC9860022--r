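# Repeated stratified cross-validation plans and minority oversampling.
# Oversampling is applied only inside training folds, never to validation
# folds or the test set.

#' Repeated stratified k-fold cross-validation plan
#'
#' Per repeat, samples are partitioned into `n_folds` folds stratified on the
#' outcome: within each class samples are shuffled and dealt round-robin, so
#' the class ratio of every fold is within one sample of the global ratio.
#'
#' @param y 0/1 outcome vector.
#' @param n_folds folds per repeat.
#' @param n_repeats number of repeats.
#' @param seed integer seed.
#' @return a `cv_plan`: list with `folds` (list of integer fold-id vectors,
#'   one per repeat), `n_folds`, `n_repeats`, `seed`.
#' @export
make_cv_plan <- function(y, n_folds = 10, n_repeats = 5, seed = 1L) {
  counts <- table(y)
  if (length(counts) < 2)
    stop("both classes required", call. = FALSE)
  if (min(counts) < n_folds)
    stop("class with ", min(counts), " members cannot fill ", n_folds,
         " folds; use fewer folds", call. = FALSE)
  rng <- rng_stream(seed)
  folds <- lapply(seq_len(n_repeats), function(r) {
    id <- integer(length(y))
    for (cl in names(counts)) {
      rows <- which(y == cl)
      rows <- rows[rng$sample_int(length(rows), length(rows))]
      id[rows] <- rep_len(seq_len(n_folds), length(rows))
    }
    id
  })
  structure(list(folds = folds, n_folds = n_folds, n_repeats = n_repeats,
                 seed = seed), class = "cv_plan")
}

#' Oversample the minority class
#'
#' Duplicates minority-class rows by sampling with replacement until both
#' classes have equal counts. Intended for training folds only.
#'
#' @param y 0/1 outcome vector (index interface), or a [cohort].
#' @param seed integer seed.
#' @return for a vector, an integer index vector (originals plus duplicated
#'   minority rows); for a cohort, the row-expanded cohort.
#' @export
oversample_minority <- function(y, seed = 1L) UseMethod("oversample_minority")

#' @export
oversample_minority.default <- function(y, seed = 1L) {
  counts <- table(y)
  if (length(counts) < 2) stop("both classes required", call. = FALSE)
  if (counts[1] == counts[2]) return(seq_along(y))
  minority <- names(counts)[which.min(counts)]
  need <- abs(diff(as.integer(counts)))
  rows <- which(y == minority)
  rng <- rng_stream(seed)
  extra <- rows[rng$sample(seq_along(rows), need, replace = TRUE)]
  c(seq_along(y), extra)
}

#' @export
oversample_minority.cohort <- function(y, seed = 1L) {
  idx <- oversample_minority(y$status, seed = seed)
  y[idx, , drop = FALSE]
}
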