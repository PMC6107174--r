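# Structural tests run at reduced problem sizes (short series, coarse q
# sweep, small surrogate ensembles): the measures' values are noisy there,
# but the table contracts under test do not depend on them.

small_cohort <- function(n_subjects = 2, seed = 19) {
  synth_cohort(cohort_spec(n_subjects = n_subjects, series_length = 4096,
                           seed = seed))
}

test_that("analyze_series yields one ALL row plus one row per block", {
  d <- small_cohort(1)$series[[1]]
  m <- analyze_series(d, cfg = fast_cfg(), n_surrogates = 4,
                      n_iterations = 100, seed = 3)
  expect_equal(m$block, c("ALL", "1", "2", "3", "4"))
  expect_true(all(m$W >= 0, na.rm = TRUE))
  expect_true(all(is.finite(m$t)))
})

test_that("a series too short for blocks degrades to an ALL-only row", {
  d <- displacement_series(runif(2048) + 1)
  expect_warning(
    m <- analyze_series(d, cfg = fast_cfg(), n_surrogates = 4,
                        n_iterations = 100, seed = 3),
    "block measures skipped")
  expect_equal(m$block, "ALL")
})

test_that("cohort table joins whole-series measures onto block rows exactly", {
  coh <- small_cohort(2)
  tab <- build_cohort_table(coh, cfg = fast_cfg(), n_surrogates = 4,
                            n_iterations = 100, seed = 5)
  expect_equal(nrow(tab), 4 * 5)
  for (key in split(tab, paste(tab$subject_id, tab$condition))) {
    all_row <- key[key$block == "ALL", ]
    expect_equal(nrow(all_row), 1)
    expect_identical(key$W_ALL, rep(all_row$W, nrow(key)))
    expect_identical(key$t_ALL, rep(all_row$t, nrow(key)))
  }
})

test_that("cohort table construction is deterministic", {
  coh <- small_cohort(1)
  t1 <- build_cohort_table(coh, cfg = fast_cfg(), n_surrogates = 4,
                           n_iterations = 100, seed = 5)
  t2 <- build_cohort_table(coh, cfg = fast_cfg(), n_surrogates = 4,
                           n_iterations = 100, seed = 5)
  expect_identical(t1, t2)
})

test_that("block-null choice is configurable and changes the block t only", {
  d <- small_cohort(1)$series[[1]]
  a <- analyze_series(d, cfg = fast_cfg(), n_surrogates = 4,
                      n_iterations = 100, seed = 3,
                      block_surrogates = "block")
  b <- analyze_series(d, cfg = fast_cfg(), n_surrogates = 4,
                      n_iterations = 100, seed = 3,
                      block_surrogates = "series")
  expect_equal(a$W, b$W, tolerance = 1e-12)
  expect_identical(a$t[1], b$t[1])
  expect_false(identical(a$t[-1], b$t[-1]))
})

test_that("unreadable manifest entries are skipped; duplicates are fatal", {
  dir <- withr::local_tempdir()
  coh <- small_cohort(2, seed = 23)
  man_path <- write_cohort(coh, dir)
  man <- read.table(man_path, sep = "\t", header = TRUE)
  man$file[2] <- "missing.tsv"
  bad_path <- file.path(dir, "manifest_bad.tsv")
  write.table(man, bad_path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(
    tab <- build_cohort_table(bad_path, cfg = fast_cfg(), n_surrogates = 4,
                              n_iterations = 100, seed = 5),
    "skipping")
  expect_equal(nrow(tab), 3 * 5)

  dup <- read.table(man_path, sep = "\t", header = TRUE)
  dup <- rbind(dup, dup[1, ])
  dup_path <- file.path(dir, "manifest_dup.tsv")
  write.table(dup, dup_path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(build_cohort_table(dup_path, cfg = fast_cfg()), "duplicate")
})

test_that("an empty manifest yields an empty table with a warning", {
  man <- data.frame(subject_id = character(), condition = integer(),
                    file = character())
  expect_warning(tab <- build_cohort_table(man, cfg = fast_cfg()), "empty cohort")
  expect_equal(nrow(tab), 0)
  expect_true(all(c("subject_id", "condition", "block", "W", "t",
                    "W_ALL", "t_ALL") %in% names(tab)))
})

test_that("cohort summary reports the per-condition counting scheme", {
  tab <- data.frame(
    subject_id = rep(c("S1", "S2", "S3"), 2),
    condition = rep(c(0, 1), each = 3),
    block = "ALL",
    W = c(0.05, 0.07, 0.06, 0.09, 0.11, 0.10),
    t = c(2.5, -0.4, 3.1, -2.2, -5.0, 1.0),
    n_retained_q = 10, W_ALL = NA, t_ALL = NA)
  s <- cohort_summary(tab)
  expect_equal(s$n, c(3, 3))
  expect_equal(s$n_t_above, c(2, 0))
  expect_equal(s$n_t_below, c(0, 2))
  expect_equal(s$W_ALL_mean[s$condition == 0], 0.06)
  expect_equal(s$t_ALL_mean[s$condition == 1], mean(c(-2.2, -5, 1)))
})
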