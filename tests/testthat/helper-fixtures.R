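# shared fixture builders; everything is generated in code at test time

# tidy replicate-level records for hand-built toy datasets
toy_records <- function(participant, protein, times, values, replicate = 1L) {
  data.frame(participant_id = participant, protein_id = protein,
             dlmo_time = times, replicate = replicate, abundance = values,
             stringsAsFactors = FALSE)
}

# simulate -> average -> z-score in one call
scaled_cohort <- function(specs, seed, n_participants = 10, ...) {
  cfg <- cohort_config(n_participants = n_participants, rhythm_specs = specs,
                       seed = seed, ...)
  zscore_per_participant(average_replicates(simulate_cohort(cfg)))
}

# independent least-squares oracle: normal equations solved by hand
cosinor_oracle_coefs <- function(times, values, period) {
  th <- 2 * pi * times / period
  X <- cbind(1, cos(th), sin(th))
  drop(solve(t(X) %*% X) %*% (t(X) %*% values))
}

# circular mean of peak times on a cycle of length `period`
circular_mean_hours <- function(hours, period) {
  ang <- 2 * pi * hours / period
  (period / (2 * pi)) * atan2(mean(sin(ang)), mean(cos(ang))) %% period
}

# published reference values for the worked power table: amplitudes and the
# integer percents they print to
reference_power_rows <- function() {
  data.frame(
    gene = c("AZGP1", "ITIH2", "FGA", "KNG1", "APOA2", "IGK", "PLG", "IGHM",
             "IGKC", "PLG", "APOC3", "FGA", "FGB", "CFH", "APOE"),
    period = c(rep(12, 9), rep(24, 6)),
    amplitude = c(0.28, 0.30, 0.30, 0.23, 0.27, 0.27, 0.22, 0.31, 0.27,
                  0.37, 0.41, 0.32, 0.31, 0.29, 0.37),
    n_increase = c(9, 10, 10, 6, 8, 8, 5, 11, 8, 16, 20, 11, 11, 9, 16),
    beta_uncontrolled = c(23, 24, 24, 22, 23, 23, 22, 24, 23,
                          26, 28, 24, 24, 24, 26))
}
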