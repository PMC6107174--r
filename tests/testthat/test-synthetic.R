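test_that("binomial cascade conserves unit mass and has length 2^k", {
  for (p in c(0.1, 0.25, 0.5)) {
    for (k in c(1, 5, 12)) {
      m <- binomial_cascade(p, k, seed = 11)
      expect_length(m, 2^k)
      expect_true(all(m > 0))
      expect_lt(abs(sum(m) - 1), 1e-9)
    }
  }
})

test_that("symmetric cascade weights give the uniform measure", {
  m <- binomial_cascade(0.5, 8, seed = 1)
  expect_equal(m, rep(1 / 256, 256))
})

test_that("cascade rejects invalid weight and depth", {
  expect_error(binomial_cascade(0, 4), "p must be")
  expect_error(binomial_cascade(0.6, 4), "p must be")
  expect_error(binomial_cascade(-0.2, 4), "p must be")
  expect_error(binomial_cascade(0.3, 0), "k must be")
})

test_that("cascade is bit-reproducible from its seed and leaves global RNG alone", {
  set.seed(999)
  before <- .Random.seed
  a <- binomial_cascade(0.3, 10, seed = 77)
  expect_identical(.Random.seed, before)
  b <- binomial_cascade(0.3, 10, seed = 77)
  expect_identical(a, b)
  expect_false(identical(a, binomial_cascade(0.3, 10, seed = 78)))
})

test_that("closed-form cascade spectrum matches its known extremes", {
  th <- cascade_theory(0.25, q = c(-200, 0, 200))
  expect_equal(th$width, log2(3))
  expect_equal(th$alpha[1], 2, tolerance = 1e-6)           # -log2(0.25)
  expect_equal(th$alpha[3], -log2(0.75), tolerance = 1e-6)
  expect_equal(cascade_theory(0.35)$width, log2(0.65 / 0.35))
})

test_that("flat-envelope null series is white", {
  x <- linear_null_series(1024, "flat", seed = 5)
  a <- stats::acf(x, lag.max = 30, plot = FALSE)$acf[-1]
  expect_lt(max(abs(a)), 3 / sqrt(1024))
  expect_equal(mean(x), 0, tolerance = 1e-12)
  expect_equal(sd(x), 1, tolerance = 1e-12)
})

test_that("peaked null series has its dominant frequency at the requested peak", {
  fs <- 50
  x <- linear_null_series(5000, "peaked", seed = 6, sample_rate = fs, peak_freq = 1)
  pg <- periodogram(x)
  fr <- (seq_along(pg)) * fs / 5000
  expect_equal(fr[which.max(pg)], 1, tolerance = 0.05)
})

test_that("two seeds share the periodogram envelope but not the series", {
  a <- linear_null_series(512, "powerlaw", seed = 1, exponent = 2)
  b <- linear_null_series(512, "powerlaw", seed = 2, exponent = 2)
  expect_false(identical(a, b))
  # fixed amplitude envelope: periodograms agree up to the common variance
  # normalisation, so their ratio is constant
  ratio <- periodogram(a) / periodogram(b)
  expect_lt(diff(range(ratio)), 1e-6 * mean(ratio))
})

test_that("null series rejects unknown shapes and short lengths", {
  expect_error(linear_null_series(128, "fractal"))
  expect_error(linear_null_series(32, "flat"), ">= 64")
})

test_that("default cohort is study-shaped: 42 nonnegative series of 6012 samples", {
  coh <- synth_cohort(cohort_spec(seed = 5))
  expect_length(coh$series, 42)
  expect_true(all(vapply(coh$series, function(s) length(s$u), integer(1)) == 6012L))
  expect_true(all(vapply(coh$series, function(s) all(s$u >= 0), logical(1))))
  expect_equal(sum(coh$truth$condition == 1), 21)
  expect_equal(sum(coh$truth$condition == 0), 21)
  expect_equal(anyDuplicated(coh$truth[, c("subject_id", "condition")]), 0L)
  # condition-linked mechanism assignment
  expect_true(all(coh$truth$nonlinearity[coh$truth$condition == 1] == "narrowing"))
  expect_true(all(coh$truth$nonlinearity[coh$truth$condition == 0] == "widening"))
})

test_that("cohort generation is deterministic and rejects short series", {
  sp <- cohort_spec(n_subjects = 2, series_length = 4096, seed = 31)
  a <- synth_cohort(sp)
  b <- synth_cohort(sp)
  expect_identical(lapply(a$series, `[[`, "u"), lapply(b$series, `[[`, "u"))
  expect_error(cohort_spec(series_length = 3999), ">= 4000")
})

test_that("cohort round-trips through its on-disk layout", {
  dir <- withr::local_tempdir()
  coh <- synth_cohort(cohort_spec(n_subjects = 2, series_length = 4096, seed = 8))
  man_path <- write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "cohort_spec.yaml")))
  man <- read_manifest(man_path)
  expect_equal(nrow(man), 4)
  s1 <- read_displacement_series(man$file[1])
  expect_identical(s1$u, coh$series[[1]]$u)
})
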