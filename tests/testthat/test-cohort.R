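test_that("cohort files round-trip through write/read, preserving LOD flags", {
  co <- tiny_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  rc <- read_cohort(path)
  expect_equal(nrow(rc), 6)
  expect_identical(attr(rc, "low"), attr(co, "low"))
  expect_equal(sum(attr(rc, "low")), 1)
  expect_equal(as.data.frame(rc)[markers(rc)], as.data.frame(co)[markers(co)],
               tolerance = 1e-12)
  expect_identical(rc$sample_id, co$sample_id)  # row order preserved

  # a larger synthetic cohort round-trips too
  big <- simulate_cohort(simulation_config(n_cases = 20, n_controls = 30,
                                           n_markers = 5), seed = 2)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(big, path2)
  rb <- read_cohort(path2)
  expect_identical(attr(rb, "low"), attr(big, "low"))
  expect_equal(as.data.frame(rb)$ytd_months, as.data.frame(big)$ytd_months,
               tolerance = 1e-9)
  expect_equal(as.data.frame(rb)[markers(big)],
               as.data.frame(big)[markers(big)], tolerance = 1e-9)
})

test_that("read_cohort rejects malformed tables with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,sample_id,mk1", "a,s1,1.0"), path)
  expect_error(read_cohort(path), "status")

  writeLines(c("subject_id,sample_id,status,ytd_months,mk1",
               "a,s1,1,10,oops"), path)
  expect_error(read_cohort(path), "row 1")

  writeLines(c("subject_id,sample_id,status,ytd_months,mk1",
               "a,s1,1,10,low", "b,s2,0,,2.5", "c,s3,0,,3.5"), path)
  rc <- read_cohort(path)
  expect_equal(nrow(rc), 3)
  expect_equal(sum(attr(rc, "low")), 1)
})

test_that("impute_low follows half-min and fixed-floor rules", {
  df <- data.frame(subject_id = c("a", "b", "c"), sample_id = c("1", "2", "3"),
                   status = c(1, 0, 0), ytd_months = c(5, NA, NA),
                   m = c(NA, 2, 4), stringsAsFactors = FALSE)
  low <- matrix(c(TRUE, FALSE, FALSE), 3, 1, dimnames = list(NULL, "m"))
  co <- cohort(df, "m", low)
  expect_equal(impute_low(co)$m, c(1, 2, 4))

  df2 <- df; df2$m <- c(NA, NA, 3)
  low2 <- matrix(c(TRUE, TRUE, FALSE), 3, 1, dimnames = list(NULL, "m"))
  co2 <- cohort(df2, "m", low2)
  expect_equal(impute_low(co2, "fixed_floor", floor = 0.5)$m, c(0.5, 0.5, 3))

  df3 <- df; df3$m <- c(NA, NA, NA)
  low3 <- matrix(TRUE, 3, 1, dimnames = list(NULL, "m"))
  co3 <- cohort(df3, "m", low3)
  expect_error(impute_low(co3), "no observed numeric values")
})

test_that("single time-groups use half-open year intervals and partition cases", {
  co <- assign_time_groups(tiny_cohort())
  grp <- as.character(co$single_group)
  expect_equal(grp[co$sample_id == "s1"], "0-1")   # 11 months
  expect_equal(grp[co$sample_id == "s2"], "2-3")   # exactly 24 months: boundary up
  expect_equal(grp[co$sample_id == "s3"], "4+")    # 70.09 months
  expect_true(all(is.na(grp[co$status == 0])))
  expect_equal(sum(table(co$single_group)), sum(co$status == 1))

  bad <- tiny_cohort()
  bad$ytd_months[1] <- -1
  expect_error(assign_time_groups(bad), "negative")

  # joined groups nest and controls are always eligible
  big <- simulate_cohort(simulation_config(n_cases = 40, n_controls = 40,
                                           n_markers = 3), seed = 4)
  members <- sapply(JOINED_GROUPS, function(g) sum(in_joined_group(big, g)))
  expect_true(all(diff(members) >= 0))
  expect_equal(members[["0-4+"]], nrow(big))
  expect_true(all(in_joined_group(big, "0-1")[big$status == 0]))
})

test_that("stratified split respects per-stratum rounding and reproducibility", {
  df <- data.frame(subject_id = paste0("p", 1:9), sample_id = paste0("s", 1:9),
                   status = 1, ytd_months = 5, m = 1:9,
                   stringsAsFactors = FALSE)
  co <- assign_time_groups(cohort(df, "m"))
  sp <- stratified_split(co, keys = "status", seed = 1)
  expect_equal(sum(sp$partition == "train"), 6)
  expect_equal(sum(sp$partition == "test"), 3)

  df2 <- data.frame(subject_id = paste0("p", 1:90),
                    sample_id = paste0("s", 1:90),
                    status = rep(c(1, 0), c(30, 60)),
                    ytd_months = ifelse(rep(c(1, 0), c(30, 60)) == 1, 6, NA),
                    m = rnorm(90), stringsAsFactors = FALSE)
  co2 <- assign_time_groups(cohort(df2, "m"))
  sp2 <- stratified_split(co2, keys = "status", seed = 2)
  tab <- table(co2$status, sp2$partition)
  expect_equal(unname(tab["1", "train"]), 20)
  expect_equal(unname(tab["1", "test"]), 10)
  expect_equal(unname(tab["0", "train"]), 40)
  expect_equal(unname(tab["0", "test"]), 20)

  expect_identical(stratified_split(co2, keys = "status", seed = 7),
                   stratified_split(co2, keys = "status", seed = 7))
})

test_that("split covers every sample once and balances case:control ratio", {
  co <- simulate_cohort(simulation_config(n_cases = 60, n_controls = 100,
                                          n_markers = 4), seed = 9)
  worst <- 0
  for (s in 1:100) {
    sp <- stratified_split(co, seed = s)
    expect_setequal(sp$sample_id, co$sample_id)
    expect_false(any(duplicated(sp$sample_id)))
    tr <- split_partition(co, sp, "train")
    te <- split_partition(co, sp, "test")
    expect_equal(nrow(tr) + nrow(te), nrow(co))
    worst <- max(worst, abs(mean(tr$status) - mean(te$status)))
  }
  expect_lt(worst, 0.05)

  # within-stratum train fraction deviates by at most 1/stratum size
  sp <- stratified_split(co, seed = 1)
  strata <- attr(sp, "strata")
  for (s in unique(strata)) {
    rows <- strata == s
    n <- sum(rows)
    frac <- mean(sp$partition[rows] == "train")
    expect_lte(abs(frac - 2 / 3), 1 / n + 1e-9)
  }

  expect_error(stratified_split(tiny_cohort()[0, ]), "empty")
})

test_that("split assignments serialize to two-column delimited text", {
  co <- assign_time_groups(tiny_cohort())
  sp <- stratified_split(co, keys = "status", seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_split(sp, path)
  rs <- read_split(path)
  expect_equal(rs$sample_id, sp$sample_id)
  expect_equal(rs$partition, sp$partition)
})
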