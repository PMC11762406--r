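test_that("replicate averaging takes the mean of non-missing replicates", {
  d <- rbind(toy_records("P1", "A", 0, c(1, 2, 3), replicate = 1:3),
             toy_records("P1", "A", 2, c(1, NA, 3), replicate = 1:3),
             toy_records("P1", "A", 4, c(NA, NA, NA), replicate = 1:3))
  avg <- average_replicates(d)
  expect_equal(nrow(avg), 3)
  expect_equal(avg$abundance, c(2, 2, NA_real_))
  expect_equal(avg$n_replicates, c(3L, 2L, 0L))
})

test_that("missingness filter drops strictly above the threshold", {
  t16 <- seq(0, 30, by = 2)
  mk <- function(prot, n_missing) {
    v <- rnorm(16)
    if (n_missing > 0) v[seq_len(n_missing)] <- NA
    toy_records("P1", prot, t16, v)
  }
  set.seed(1)
  d <- average_replicates(rbind(mk("TWO_MISS", 2), mk("ONE_MISS", 1),
                                mk("COMPLETE", 0)))
  fl <- filter_missing_proteins(d, max_missing = 0.10)
  rep <- fl$report[order(fl$report$protein_id), ]
  expect_equal(rep$status[rep$protein_id == "TWO_MISS"], "dropped")   # 12.5%
  expect_equal(rep$status[rep$protein_id == "ONE_MISS"], "kept")      # 6.25%
  expect_equal(rep$status[rep$protein_id == "COMPLETE"], "kept")
  expect_equal(rep$missing_fraction[rep$protein_id == "COMPLETE"], 0)
  expect_equal(rep$missing_fraction[rep$protein_id == "TWO_MISS"], 0.125)
  expect_setdiff <- setdiff(unique(fl$dataset$protein_id), c("ONE_MISS", "COMPLETE"))
  expect_length(expect_setdiff, 0)
})

test_that("z-scoring yields mean 0 / sd 1 series, is idempotent, keeps NAs", {
  d <- rbind(toy_records("P1", "A", c(0, 2, 4), c(1, 2, 3)),
             toy_records("P1", "B", seq(0, 8, 2), c(5, NA, 7, 9, 13)),
             toy_records("P2", "A", c(0, 2, 4), c(10, 40, 100)))
  z <- zscore_per_participant(d)
  expect_equal(z$z_value[z$participant_id == "P1" & z$protein_id == "A"],
               c(-1, 0, 1))
  for (k in split(z, paste(z$participant_id, z$protein_id))) {
    v <- k$z_value[!is.na(k$z_value)]
    expect_lt(abs(mean(v)), 1e-9)
    expect_lt(abs(stats::sd(v) - 1), 1e-9)
  }
  expect_true(is.na(z$z_value[z$protein_id == "B"][2]))
  prov <- attr(z, "provenance")
  expect_equal(prov$n_missing[prov$protein_id == "B"], 1L)
  # idempotence: z-scoring a z-scored series is the identity
  z2 <- zscore_per_participant(
    data.frame(participant_id = z$participant_id, protein_id = z$protein_id,
               dlmo_time = z$dlmo_time, abundance = z$z_value))
  expect_equal(z2$z_value, z$z_value, tolerance = 1e-9)
})

test_that("degenerate series are rejected with the series identified", {
  d <- toy_records("P7", "CONST", c(0, 2, 4), c(5, 5, 5))
  expect_error(zscore_per_participant(d), "P7.*CONST|CONST.*P7")
  expect_error(zscore_per_participant(toy_records("P7", "SHORT", 0, 1)),
               "fewer than 2")
})

test_that("filter then z-score commutes with participant relabeling", {
  cfg <- cohort_config(n_participants = 4,
                       rhythm_specs = list(rhythm_spec("A", 24, 0.3, 5),
                                           rhythm_spec("B")),
                       missing_rate = 0.05, seed = 9)
  avg <- average_replicates(simulate_cohort(cfg))
  relabel <- c(P01 = "Q4", P02 = "Q3", P03 = "Q2", P04 = "Q1")
  avg2 <- avg
  avg2$participant_id <- unname(relabel[avg2$participant_id])
  run <- function(d) {
    z <- zscore_per_participant(filter_missing_proteins(d)$dataset)
    z[order(z$participant_id, z$protein_id, z$dlmo_time), ]
  }
  a <- run(avg)
  b <- run(avg2)
  a$participant_id <- unname(relabel[a$participant_id])
  a <- a[order(a$participant_id, a$protein_id, a$dlmo_time), ]
  expect_equal(a$z_value, b$z_value)
})

test_that("clock/DLMO conversion matches the published anchors and inverts", {
  expect_equal(clock_to_dlmo(22.77, 22.77), 0)
  expect_equal(clock_to_dlmo(20.77, 22.77), -2)
  expect_equal(dlmo_to_clock(5, 22.77), 3.77)           # next-day clock time
  # monotone in clock time for a fixed session
  expect_true(all(diff(clock_to_dlmo(seq(18, 48, 0.5), 22.77)) > 0))
  # round trip modulo 24
  ct <- c(0, 3.77, 12.2, 20.77, 23.9)
  expect_equal(dlmo_to_clock(clock_to_dlmo(ct, 22.77), 22.77), ct %% 24)
})

test_that("decimal hours render as HH:MM with correct carry", {
  expect_equal(decimal_to_hhmm(22.77), "22:46")
  expect_equal(decimal_to_hhmm(0), "00:00")
  expect_equal(decimal_to_hhmm(23.999), "00:00")
  expect_equal(decimal_to_hhmm(c(12.5, -1.25)), c("12:30", "22:45"))
})
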