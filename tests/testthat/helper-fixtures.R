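# Shared fixtures, memoized so expensive objects are built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, .fixture_cache)) assign(key, builder(), .fixture_cache)
  get(key, .fixture_cache)
}

# hand-built 6-sample cohort with one below-LOD cell
tiny_cohort <- function() {
  df <- data.frame(
    subject_id = c("a", "b", "c", "d", "e", "f"),
    sample_id = paste0("s", 1:6),
    status = c(1, 1, 1, 0, 0, 0),
    ytd_months = c(11, 24, 70.09, NA, NA, NA),
    age = c(65, 60, 70, 62, 58, 66),
    bmi = c(27, 25, 30, 26, 24, 28),
    hrt = c("no", "yes", "no", "yes", "no", "no"),
    ocp = c("yes", "no", "yes", "no", "yes", "no"),
    diabetes = c("yes", "no", "no", "no", "no", "yes"),
    sex = "female",
    mk1 = c(NA, 2, 4, 1.5, 3, 2.5),
    mk2 = c(5, 6, 7, 4, 3, 2),
    stringsAsFactors = FALSE)
  low <- matrix(FALSE, 6, 2, dimnames = list(NULL, c("mk1", "mk2")))
  low[1, "mk1"] <- TRUE
  cohort(df, c("mk1", "mk2"), low)
}

# informative small cohort: 5 strong markers among 12, persisting effects
informative_config <- function(seed = 11L) {
  simulation_config(
    n_cases = 60, n_controls = 100, longitudinal_fraction = 0.2,
    samples_per_case = 1.3, n_markers = 12,
    informative = data.frame(
      name = c("CA19_9", "MUC16", "THBS2", "CEACAM5", "VWF"),
      delta = 2.0, tau = 4),
    seed = seed)
}

# trained JTG2L BMA stack on the informative cohort (expensive; memoized)
informative_fit <- function() {
  memo("informative_fit", function() {
    cfg <- informative_config()
    co <- impute_low(simulate_cohort(cfg))
    split <- stratified_split(co, seed = 5)
    train <- split_partition(co, split, "train")
    test <- split_partition(co, split, "test")
    ranking <- rank_features(train, c(markers(co), "age", "diabetes"),
                             ci = FALSE)
    panel <- ranking$feature[1:10]
    model <- build_jtg2l(train, "0-4+", "BMA", panel = panel,
                         cv = list(n_folds = 2, n_repeats = 1),
                         n_search = 1, seed = 3)
    list(cfg = cfg, cohort = co, train = train, test = test,
         ranking = ranking, panel = panel, model = model)
  })
}

clip01 <- function(p) pmin(pmax(p, 1e-6), 1 - 1e-6)

# brute-force AUC oracle: explicit O(n1*n0) pair counting
pair_count_auc <- function(scores, y) {
  s1 <- scores[y == 1]
  s0 <- scores[y == 0]
  tot <- 0
  for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}
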