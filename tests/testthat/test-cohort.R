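test_that("config validation names the offending field", {
  expect_error(cohort_config(n_participants = 0), "n_participants")
  expect_error(cohort_config(timepoints = c(2, 1)), "timepoints")
  expect_error(cohort_config(missing_rate = 1), "missing_rate")
  expect_error(cohort_config(noise_sd = -1), "noise_sd")
  expect_error(cohort_config(rhythm_specs = list(1)), "rhythm_specs")
  expect_error(rhythm_spec("X", periods = 24, amplitudes = -0.1, acrophases = 0),
               "amplitudes")
  expect_error(rhythm_spec("X", periods = 0, amplitudes = 0.1, acrophases = 0),
               "periods")
})

test_that("a null protein gives a full replicate grid with no rhythm machinery", {
  cfg <- cohort_config(n_participants = 1, rhythm_specs = list(rhythm_spec("N")),
                       noise_sd = 1, seed = 3)
  x <- simulate_cohort(cfg)
  expect_equal(nrow(x), 16 * 3)
  expect_equal(sort(unique(x$dlmo_time)), seq(0, 30, by = 2))
  expect_false(anyNA(x$abundance))
  expect_equal(length(attr(x, "dlmo_clock")), 1L)
})

test_that("identical seeds give identical datasets; different seeds differ", {
  cfg <- cohort_config(n_participants = 3,
                       rhythm_specs = list(rhythm_spec("A", 24, 0.3, 5),
                                           rhythm_spec("B")),
                       missing_rate = 0.05, seed = 7)
  x1 <- simulate_cohort(cfg)
  x2 <- simulate_cohort(cfg)
  expect_identical(as.data.frame(x1), as.data.frame(x2))
  expect_identical(attr(x1, "dlmo_clock"), attr(x2, "dlmo_clock"))
  cfg2 <- cohort_config(n_participants = 3,
                        rhythm_specs = list(rhythm_spec("A", 24, 0.3, 5),
                                            rhythm_spec("B")),
                        missing_rate = 0.05, seed = 8)
  expect_false(identical(as.data.frame(simulate_cohort(cfg2)),
                         as.data.frame(x1)))
})

test_that("adding participants never perturbs earlier participants' data", {
  mk <- function(n) simulate_cohort(
    cohort_config(n_participants = n,
                  rhythm_specs = list(rhythm_spec("A", 24, 0.3, 5)),
                  seed = 11))
  records <- function(x) {
    d <- data.frame(x[c("participant_id", "protein_id", "dlmo_time",
                        "replicate", "abundance")])
    rownames(d) <- NULL
    d
  }
  small <- mk(3)
  big <- mk(5)
  keep <- big$participant_id %in% unique(small$participant_id)
  expect_identical(records(big[keep, ]), records(small))
  expect_identical(attr(big, "dlmo_clock")[1:3], attr(small, "dlmo_clock"))
})

test_that("realized MCAR missingness tracks missing_rate within 2 points", {
  cfg <- cohort_config(n_participants = 10,
                       rhythm_specs = lapply(1:10, function(i)
                         rhythm_spec(sprintf("P%d", i))),
                       missing_rate = 0.10, seed = 21)
  x <- simulate_cohort(cfg)
  cell <- paste(x$participant_id, x$protein_id, x$dlmo_time)
  cell_missing <- tapply(is.na(x$abundance), cell, all)
  expect_gte(length(cell_missing), 1000)       # 10 x 10 x 16 cells
  expect_lt(abs(mean(cell_missing) - 0.10), 0.02)
  # missingness removes all replicates of a cell, never a subset
  partial <- tapply(is.na(x$abundance), cell, function(v) any(v) && !all(v))
  expect_false(any(partial))
})

test_that("default noise gives unit total variance on the averaged series", {
  # variance sum law: signal A^2/2 plus noise 1 - A^2/2 ~ 1 per series
  cfg <- cohort_config(n_participants = 30,
                       rhythm_specs = lapply(1:5, function(i)
                         rhythm_spec(sprintf("A%d", i), 24, 0.4, 3)),
                       seed = 13)
  avg <- average_replicates(simulate_cohort(cfg))
  vars <- tapply(avg$abundance,
                 paste(avg$participant_id, avg$protein_id), stats::var)
  expect_lt(abs(mean(vars) - 1), 0.08)
})

test_that("cohort tables round-trip losslessly through delimited text", {
  cfg <- cohort_config(n_participants = 3,
                       rhythm_specs = list(rhythm_spec("A", c(24, 12),
                                                       c(0.3, 0.2), c(5, 1)),
                                           rhythm_spec("NULL1")),
                       missing_rate = 0.2, seed = 5)
  x <- simulate_cohort(cfg)
  path <- file.path(withr::local_tempdir(), "cohort.csv")
  write_cohort(x, path)
  y <- read_cohort(path)
  expect_equal(as.data.frame(y), as.data.frame(x))
  expect_equal(attr(y, "dlmo_clock"), attr(x, "dlmo_clock"))
  gt <- attr(y, "ground_truth")
  expect_length(gt, 2)
  expect_equal(gt[[1]], attr(x, "ground_truth")[[1]])
  expect_equal(gt[[2]]$protein_id, "NULL1")
  expect_length(gt[[2]]$periods, 0)
})
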