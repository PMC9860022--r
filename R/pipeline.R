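# End-to-end pipeline driver: simulate (or read) -> impute -> time-groups ->
# stratified split -> Firth ranking -> feature scan -> stacked models per
# joined time-group -> evaluation -> importance -> external validation.
# One global seed fans out to per-stage seeds by a fixed counter scheme
# (stage i uses seed + 1000 * i), so stages are independently reproducible.
# File artifacts are checksummed into a run manifest; unchanged input stages
# (cohort generation, split, ranking) are skipped on rerun when their
# artifacts match the manifest.

#' Default pipeline configuration
#'
#' Desk-scale settings: a reduced cohort, 3-fold/1-repeat base CV, a small
#' random search and a reduced bootstrap, so the whole pipeline runs in
#' minutes. All fields can be overridden via `modify`.
#'
#' @param modify named list of overrides (nested lists are replaced whole).
#' @export
pipeline_config <- function(modify = list()) {
  cfg <- list(
    simulate = list(n_cases = 60, n_controls = 100, n_markers = 30),
    frac_train = 2 / 3,
    panel_step = 10,
    scan_panel = FALSE,
    panel_size = 20,
    architecture = "JTG2L",
    stack_kind = "BMA",
    joined_groups = "0-4+",
    cv = list(n_folds = 3, n_repeats = 1),
    n_search = 5,
    families = learner_families(),
    n_boot = 200,
    spec_target = 0.90,
    importance = FALSE,
    importance_grid = 10,
    external = FALSE,
    external_n_rand = 50
  )
  for (k in names(modify)) cfg[[k]] <- modify[[k]]
  cfg
}

#' Run the full analysis pipeline
#'
#' @param config a [pipeline_config()] list or path to a YAML file of
#'   overrides.
#' @param out_dir output directory for artifacts and the run manifest
#'   (`NULL` keeps everything in memory).
#' @param seed global integer seed.
#' @param cohort optionally, a pre-built [cohort] (skips simulation).
#' @param quiet suppress stage logging.
#' @return list with `cohort`, `split`, `ranking`, `panel`, `models`
#'   (per joined group), `reports`, `cross_matrix`, optionally `importance`
#'   and `external`, plus the `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         seed = 1L, cohort = NULL, quiet = FALSE) {
  if (is.character(config))
    config <- pipeline_config(yaml::read_yaml(config))
  say <- function(...) if (!quiet) message("[serostack] ", ...)
  stage_seed <- function(i) seed + 1000L * i
  manifest <- list(seed = seed, config_hash = config_hash(config),
                   package_version = as.character(utils::packageVersion("serostack")),
                   stages = list())
  artifact <- function(stage, name, writer) {
    if (is.null(out_dir)) return(invisible(NULL))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(out_dir, name)
    writer(path)
    manifest$stages[[stage]]$outputs[[name]] <<-
      unname(tools::md5sum(path))
    manifest$stages[[stage]]$time <<- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    invisible(path)
  }

  # stage 1: cohort
  say("stage 1: cohort")
  cached <- !is.null(out_dir) && reuse_artifact(out_dir, "cohort.csv",
                                                config_hash(config))
  if (is.null(cohort) && cached) {
    say("  cached cohort.csv reused")
    cohort <- assign_time_groups(read_cohort(file.path(out_dir, "cohort.csv")))
    manifest$stages[["cohort"]]$outputs[["cohort.csv"]] <-
      unname(tools::md5sum(file.path(out_dir, "cohort.csv")))
  } else {
    if (is.null(cohort)) {
      sim_cfg <- do.call(simulation_config,
                         c(config$simulate, list(seed = stage_seed(1L))))
      cohort <- simulate_cohort(sim_cfg)
    }
    cohort <- assign_time_groups(cohort)
    artifact("cohort", "cohort.csv", function(p) write_cohort(cohort, p))
  }
  cohort <- impute_low(cohort)

  # stage 2: split
  say("stage 2: stratified split")
  split <- stratified_split(cohort, frac_train = config$frac_train,
                            seed = stage_seed(2L))
  artifact("split", "split.csv", function(p) write_split(split, p))
  train <- split_partition(cohort, split, "train")
  test <- split_partition(cohort, split, "test")

  # stage 3: Firth ranking on the training set
  say("stage 3: Firth ranking")
  features <- c(markers(cohort),
                intersect(c("age", "bmi", "hrt", "ocp", "diabetes"),
                          names(as.data.frame(cohort))))
  ranking <- rank_features(train, features, ci = FALSE)
  artifact("ranking", "ranking.csv", function(p)
    utils::write.csv(ranking, p, row.names = FALSE))

  # stage 4: feature panel
  panel <- if (isTRUE(config$scan_panel)) {
    say("stage 4: feature-space scan")
    builder <- function(pn) {
      x <- cohort_matrix(train, pn)
      mean(meta_cv_auc(
        train_base_layer(x, train$status,
                         make_cv_plan(train$status, config$cv$n_folds,
                                      config$cv$n_repeats, stage_seed(4L)),
                         families = config$families,
                         n_search = config$n_search,
                         seed = stage_seed(4L))$oof,
        train$status, kind = config$stack_kind,
        n_folds = config$cv$n_folds, n_repeats = 1, seed = stage_seed(4L)))
    }
    sc <- scan_feature_space(ranking$feature, builder,
                             step = config$panel_step)
    ranking$feature[seq_len(sc$best_k)]
  } else {
    ranking$feature[seq_len(min(config$panel_size, nrow(ranking)))]
  }

  # stage 5: stacked models per joined time-group
  say("stage 5: stacked models (", config$architecture, " ",
      config$stack_kind, ")")
  models <- list()
  for (gi in seq_along(config$joined_groups)) {
    g <- config$joined_groups[gi]
    models[[g]] <- switch(
      config$architecture,
      JTG2L = build_jtg2l(train, joined_group = g,
                          stack_kind = config$stack_kind, panel = panel,
                          cv = config$cv, n_search = config$n_search,
                          seed = stage_seed(5L) + gi,
                          families = config$families),
      STG2L = build_stg2l(train, stack_kind = config$stack_kind,
                          panel = panel, cv = config$cv,
                          n_search = config$n_search,
                          seed = stage_seed(5L) + gi,
                          families = config$families),
      STG3L = build_stg3l(train, top_stack_kind = config$stack_kind,
                          panel = panel, cv = config$cv,
                          n_search = config$n_search,
                          seed = stage_seed(5L) + gi,
                          families = config$families),
      stop("unknown architecture ", config$architecture, call. = FALSE))
  }

  # stage 6: evaluation
  say("stage 6: evaluation")
  cross <- cross_time_group_matrix(models, test,
                                   groups = config$joined_groups,
                                   n_boot = config$n_boot,
                                   spec_target = config$spec_target,
                                   seed = stage_seed(6L))
  reports <- lapply(names(models), function(g) {
    keep <- in_joined_group(test, g)
    performance_report(predict(models[[g]], subset_cohort(test, keep)),
                       test$status[keep], group = g,
                       spec_target = config$spec_target,
                       n_boot = config$n_boot, seed = stage_seed(6L))
  })
  names(reports) <- names(models)
  artifact("evaluation", "reports.json", function(p)
    jsonlite::write_json(reports, p, auto_unbox = TRUE, digits = NA))

  out <- list(cohort = cohort, split = split, ranking = ranking,
              panel = panel, models = models, reports = reports,
              cross_matrix = cross)

  # stage 7: importance
  if (isTRUE(config$importance) && config$architecture == "JTG2L") {
    say("stage 7: importance")
    out$importance <- stack_importance(models[[1]], train,
                                       grid_size = config$importance_grid,
                                       seed = stage_seed(7L))
    artifact("importance", "importance.csv", function(p)
      utils::write.csv(out$importance$long, p, row.names = FALSE))
  }

  # stage 8: external validation
  if (isTRUE(config$external)) {
    say("stage 8: external validation")
    sim_cfg <- do.call(simulation_config,
                       c(config$simulate, list(seed = stage_seed(1L))))
    ext <- impute_low(simulate_external_set(sim_cfg,
                                            seed = stage_seed(8L)))
    out$external <- marginal_validate(models[[length(models)]], ext,
                                      n_rand = config$external_n_rand,
                                      n_boot = config$n_boot,
                                      seed = stage_seed(8L))
  }

  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    out$manifest <- manifest
  }
  say("done")
  out
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(utils::capture.output(utils::str(config)), collapse = "\n"),
             tmp)
  unname(tools::md5sum(tmp))
}

# TRUE when a previous manifest covers this artifact with matching config
# hash and on-disk checksum
reuse_artifact <- function(out_dir, name, hash) {
  mpath <- file.path(out_dir, "manifest.json")
  fpath <- file.path(out_dir, name)
  if (!file.exists(mpath) || !file.exists(fpath)) return(FALSE)
  man <- tryCatch(jsonlite::read_json(mpath), error = function(e) NULL)
  if (is.null(man) || !identical(man$config_hash, hash)) return(FALSE)
  for (st in man$stages) {
    if (!is.null(st$outputs[[name]]))
      return(identical(unname(tools::md5sum(fpath)), st$outputs[[name]]))
  }
  FALSE
}

#' Verify a run manifest
#'
#' Checks that every artifact referenced by a manifest exists and matches
#' its recorded checksum.
#'
#' @param out_dir pipeline output directory.
#' @return `TRUE` invisibly; errors name the first mismatching artifact.
#' @export
verify_manifest <- function(out_dir) {
  man <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
  for (stage in names(man$stages)) {
    for (name in names(man$stages[[stage]]$outputs)) {
      path <- file.path(out_dir, name)
      if (!file.exists(path))
        stop("manifest artifact missing: ", name, call. = FALSE)
      if (!identical(unname(tools::md5sum(path)),
                     man$stages[[stage]]$outputs[[name]]))
        stop("checksum mismatch for artifact: ", name, call. = FALSE)
    }
  }
  invisible(TRUE)
}
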