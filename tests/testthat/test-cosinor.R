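t16 <- seq(0, 30, by = 2)

test_that("noiseless cosines are recovered exactly", {
  f <- cosinor_fit(t16, cos(2 * pi * t16 / 24), period = 24)
  expect_lt(abs(coef(f)[["mesor"]]), 1e-9)
  expect_lt(abs(f$amplitude - 1), 1e-9)
  expect_lt(min(f$acrophase, 24 - f$acrophase), 1e-9)

  g <- cosinor_fit(t16, 3 + 0.3 * cos(2 * pi * (t16 - 5) / 24), period = 24)
  expect_equal(coef(g)[["mesor"]], 3, tolerance = 1e-9)
  expect_equal(g$amplitude, 0.3, tolerance = 1e-9)
  expect_equal(g$acrophase, 5, tolerance = 1e-9)
  # amplitude/acrophase form reconstructs the linear form at every fitted time
  recon <- coef(g)[["mesor"]] +
    g$amplitude * cos(2 * pi * (g$times - g$acrophase) / 24)
  expect_equal(recon, unname(fitted(g)), tolerance = 1e-9)
})

test_that("fits agree with an independent normal-equations oracle", {
  set.seed(31)
  for (period in c(24, 12)) {
    y <- 0.5 + 0.3 * cos(2 * pi * (t16 - 4) / period) + rnorm(16, 0, 0.8)
    f <- cosinor_fit(t16, y, period)
    oracle <- cosinor_oracle_coefs(t16, y, period)
    expect_equal(unname(coef(f)), unname(oracle), tolerance = 1e-9)
    expect_equal(f$residual_ss,
                 sum((y - cbind(1, cos(2 * pi * t16 / period),
                                sin(2 * pi * t16 / period)) %*% oracle)^2),
                 tolerance = 1e-9)
  }
})

test_that("degenerate designs and short series are rejected", {
  expect_error(cosinor_fit(c(0, 2, 4), c(1, 2, 1), 24), "at least 4")
  expect_error(cosinor_fit(c(0, 24, 48, 72), rnorm(4), 24), "rank-deficient")
  expect_error(cosinor_fit(t16, rep(1, 16), 0), "period")
})

test_that("acrophase is time-shift equivariant and amplitude scale equivariant", {
  set.seed(32)
  y <- 1 + 0.4 * cos(2 * pi * (t16 - 7) / 24) + rnorm(16, 0, 0.5)
  f0 <- cosinor_fit(t16, y, 24)
  for (delta in c(1.5, -3, 10)) {
    fs <- cosinor_fit(t16 + delta, y, 24)
    expect_equal((fs$acrophase - f0$acrophase) %% 24, delta %% 24,
                 tolerance = 1e-8)
    expect_equal(fs$amplitude, f0$amplitude, tolerance = 1e-9)
  }
  fc <- cosinor_fit(t16, 3 * y, 24)
  expect_equal(fc$amplitude, 3 * f0$amplitude, tolerance = 1e-9)
  expect_equal(coef(fc)[["mesor"]], 3 * coef(f0)[["mesor"]], tolerance = 1e-9)
  expect_equal(fc$acrophase, f0$acrophase, tolerance = 1e-9)
})

test_that("cross-period leakage of a pure 24-h cosine into the 12-h fit is bounded", {
  y <- cos(2 * pi * t16 / 24)
  a24 <- cosinor_fit(t16, y, 24)$amplitude
  a12 <- cosinor_fit(t16, y, 12)$amplitude
  # frozen from the design-matrix projection of this 16-point/30-h grid
  expect_equal(a12, 0.1882469, tolerance = 1e-6)
  expect_lt(a12 / a24, 0.2)
})

test_that("population summary averages coefficients and tests zero amplitude", {
  # near-identical subjects: p ~ 0, amplitude and acrophase at the truth
  set.seed(33)
  fits <- lapply(1:10, function(i) {
    y <- 0.3 * cos(2 * pi * t16 / 24) + rnorm(16, 0, 1e-6)
    cosinor_fit(t16, y, 24, participant_id = sprintf("P%02d", i), protein_id = "X")
  })
  pop <- population_cosinor(fits)
  expect_equal(pop$k_subjects, 10)
  expect_equal(pop$pop_amplitude, 0.3, tolerance = 1e-4)
  expect_lt(min(pop$pop_acrophase, 24 - pop$pop_acrophase), 1e-4)
  expect_lt(pop$p_value, 1e-10)
  expect_equal(unname(coef(pop)[c("beta", "gamma")]),
               unname(colMeans(pop$coefficient_matrix)), tolerance = 1e-12)

  # antiphase subjects cancel: population amplitude ~ 0
  anti <- lapply(1:10, function(i) {
    sgn <- if (i %% 2 == 0) 1 else -1
    y <- sgn * 0.3 * cos(2 * pi * t16 / 24) + rnorm(16, 0, 1e-6)
    cosinor_fit(t16, y, 24, protein_id = "Y")
  })
  expect_lt(population_cosinor(anti)$pop_amplitude, 1e-4)
})

test_that("population test rejects degenerate inputs", {
  mk <- function(n, noise = 0) lapply(seq_len(n), function(i)
    cosinor_fit(t16, 0.3 * cos(2 * pi * t16 / 24) + noise * rnorm(16), 24,
                protein_id = "Z"))
  expect_error(population_cosinor(mk(2, noise = 0.1)), "at least 3")
  expect_error(population_cosinor(mk(5, noise = 0)), "degenerate|singular")
  set.seed(34)
  mixed <- c(mk(3, noise = 0.5),
             list(cosinor_fit(t16, rnorm(16), 12, protein_id = "Z")))
  expect_error(population_cosinor(mixed), "period")
})

test_that("population amplitude never exceeds the mean individual amplitude", {
  set.seed(35)
  for (rep in 1:20) {
    fits <- lapply(1:6, function(i)
      cosinor_fit(t16, rnorm(16), 24, protein_id = "J"))
    pop <- population_cosinor(fits)
    expect_lte(pop$pop_amplitude, mean(pop$individual_amplitudes) + 1e-12)
  }
})

test_that("the screen is per protein x period with strict gates", {
  specs <- list(rhythm_spec("RHY24", 24, 0.6, 5),
                rhythm_spec("RHY12", 12, 0.6, 2),
                rhythm_spec("FLAT1"), rhythm_spec("FLAT2"))
  sc <- scaled_cohort(specs, seed = 41)
  s <- screen_rhythmic(sc, periods = c(24, 12))
  expect_equal(nrow(s), 8)                      # 4 proteins x 2 periods
  expect_true(all(s$passes_screen ==
                    (s$p_value < 0.05 & s$pop_amplitude > 0.1)))
  expect_true(s$passes_screen[s$protein_id == "RHY24" & s$period == 24])
  expect_true(s$passes_screen[s$protein_id == "RHY12" & s$period == 12])
  expect_true(all(diff(s$p_value[s$period == 12]) >= 0))  # sorted per period
  # strict inequalities: a threshold set exactly at an achieved value fails it
  hit <- s[s$passes_screen, ][1, ]
  s_tie_p <- screen_rhythmic(sc, periods = hit$period, p_threshold = hit$p_value)
  expect_false(s_tie_p$passes_screen[s_tie_p$protein_id == hit$protein_id])
  s_tie_a <- screen_rhythmic(sc, periods = hit$period,
                             amp_threshold = hit$pop_amplitude)
  expect_false(s_tie_a$passes_screen[s_tie_a$protein_id == hit$protein_id])
  # BH column exists but never gates
  expect_true("q_value" %in% names(s))
})

test_that("per-series fit failures are reported without aborting the screen", {
  sc <- scaled_cohort(list(rhythm_spec("OK", 24, 0.4, 5)), seed = 42,
                      n_participants = 4)
  # sabotage one participant's series down to 3 points
  broken <- sc[!(sc$participant_id == "P01" & sc$dlmo_time > 4), ]
  s <- screen_rhythmic(broken, periods = 24)
  fails <- attr(s, "failures")
  expect_false(is.null(fails))
  expect_equal(fails$participant_id, "P01")
  expect_equal(s$k_subjects, 3)                  # remaining subjects still tested
})

test_that("signed acrophase display maps peaks near cycle end to negative hours", {
  expect_equal(acrophase_signed(23.1, 24), -0.9)
  expect_equal(acrophase_signed(10.1, 12), -1.9)
  expect_equal(acrophase_signed(5, 24), 5)
  expect_equal(acrophase_signed(12, 24), 12)     # boundary stays in (-12, 12]
})
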