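#' Rhythm specification for a simulated protein
#'
#' Describes the deterministic rhythmic content of one protein as a sum of
#' cosine components on the DLMO time scale. An empty specification (no
#' components) defines an arrhythmic protein.
#'
#' @param protein_id Character scalar naming the protein.
#' @param periods Numeric vector of cycle lengths in hours (each > 0);
#'   typically 24 (circadian) and/or 12 (ultradian).
#' @param amplitudes Numeric vector of cosine amplitudes, in post-z-score
#'   units (each >= 0); same length as `periods`.
#' @param acrophases Numeric vector of peak times in DLMO hours (time of the
#'   cosine maximum relative to DLMO = 0); same length as `periods`.
#' @return An object of class `rhythm_spec`.
#' @examples
#' rhythm_spec("PLG", periods = c(24, 12), amplitudes = c(0.37, 0.22),
#'             acrophases = c(-0.9, 5.8))
#' rhythm_spec("NULLPROT")   # arrhythmic
#' @export
rhythm_spec <- function(protein_id, periods = numeric(), amplitudes = numeric(),
                        acrophases = numeric()) {
  if (!is.character(protein_id) || length(protein_id) != 1L || is.na(protein_id))
    stop("invalid `protein_id`: must be a single string", call. = FALSE)
  periods <- as.numeric(periods)
  amplitudes <- as.numeric(amplitudes)
  acrophases <- as.numeric(acrophases)
  if (length(amplitudes) != length(periods) || length(acrophases) != length(periods))
    stop("invalid rhythm components: `periods`, `amplitudes`, `acrophases` must have equal length",
         call. = FALSE)
  if (any(!is.finite(periods)) || any(periods <= 0))
    stop("invalid `periods`: all periods must be finite and > 0", call. = FALSE)
  if (any(!is.finite(amplitudes)) || any(amplitudes < 0))
    stop("invalid `amplitudes`: all amplitudes must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(acrophases)))
    stop("invalid `acrophases`: all acrophases must be finite", call. = FALSE)
  structure(list(protein_id = protein_id, periods = periods,
                 amplitudes = amplitudes, acrophases = acrophases),
            class = "rhythm_spec")
}

#' @export
print.rhythm_spec <- function(x, ...) {
  if (length(x$periods) == 0L) {
    cat(sprintf("<rhythm_spec> %s: arrhythmic\n", x$protein_id))
  } else {
    cat(sprintf("<rhythm_spec> %s: %s\n", x$protein_id,
                paste(sprintf("A=%.3g @ tau=%gh, phi=%gh", x$amplitudes,
                              x$periods, x$acrophases), collapse = " + ")))
  }
  invisible(x)
}

# total rhythm variance of a spec under uniform phase sampling: sum A^2/2
rhythm_variance <- function(spec) sum(spec$amplitudes^2) / 2

#' Configuration for a synthetic constant-routine cohort
#'
#' Defines the design of a simulated multi-participant protein time-series
#' dataset: cohort size, the DLMO-aligned sampling grid, replicate structure,
#' the planted rhythms, noise, and missingness. Defaults emulate a
#' constant-routine serum proteomics study: 10 participants sampled
#' two-hourly across 30 hours (16 timepoints) with 3 technical replicates,
#' and a cohort DLMO clock time of 22.77 +/- 1.11 decimal hours.
#'
#' @param n_participants Number of participants (>= 1).
#' @param timepoints Strictly increasing numeric vector of sampling times in
#'   DLMO hours. Default `seq(0, 30, by = 2)`.
#' @param n_replicates Technical replicates per sample (>= 1). Default 3.
#' @param rhythm_specs List of [rhythm_spec()] objects, one per protein.
#' @param noise_sd Within-participant biological noise standard deviation on
#'   the abundance scale. Default `NULL` sets, per protein,
#'   `sqrt(1 - sum(A^2)/2)` so that the post-z-score series has total
#'   variance ~ 1 and the planted amplitudes are on the z-score scale.
#' @param replicate_sd Replicate-level noise standard deviation. Default
#'   `NULL` uses 20% of the protein's `noise_sd`.
#' @param missing_rate Probability, in `[0, 1)`, that a (participant,
#'   protein, timepoint) cell is missing (all its replicates). Missingness is
#'   completely at random.
#' @param baseline_mean,baseline_sd Distribution of the participant x protein
#'   baseline (MESOR) on the abundance scale.
#' @param dlmo_clock_mean,dlmo_clock_sd Cohort distribution of DLMO clock
#'   times in decimal hours. Defaults 22.77 and 1.11.
#' @param seed Integer seed; identical seeds give byte-identical datasets.
#' @return An object of class `cohort_config`.
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_participants = 10L,
                          timepoints = seq(0, 30, by = 2),
                          n_replicates = 3L,
                          rhythm_specs = list(),
                          noise_sd = NULL,
                          replicate_sd = NULL,
                          missing_rate = 0,
                          baseline_mean = 10,
                          baseline_sd = 1,
                          dlmo_clock_mean = 22.77,
                          dlmo_clock_sd = 1.11,
                          seed = 1L) {
  chk <- function(ok, field, why) if (!ok)
    stop(sprintf("invalid `%s`: %s", field, why), call. = FALSE)
  chk(is.numeric(n_participants) && length(n_participants) == 1L &&
        n_participants >= 1 && n_participants == floor(n_participants),
      "n_participants", "must be a single integer >= 1")
  chk(is.numeric(timepoints) && length(timepoints) >= 1L &&
        all(is.finite(timepoints)) && all(diff(timepoints) > 0),
      "timepoints", "must be strictly increasing finite numerics")
  chk(is.numeric(n_replicates) && length(n_replicates) == 1L &&
        n_replicates >= 1 && n_replicates == floor(n_replicates),
      "n_replicates", "must be a single integer >= 1")
  chk(is.list(rhythm_specs) &&
        all(vapply(rhythm_specs, inherits, logical(1), "rhythm_spec")),
      "rhythm_specs", "must be a list of rhythm_spec objects")
  ids <- vapply(rhythm_specs, `[[`, character(1), "protein_id")
  chk(!anyDuplicated(ids), "rhythm_specs", "protein_id values must be unique")
  if (!is.null(noise_sd))
    chk(is.numeric(noise_sd) && length(noise_sd) == 1L && is.finite(noise_sd) &&
          noise_sd > 0, "noise_sd", "must be a single number > 0 (or NULL)")
  if (!is.null(replicate_sd))
    chk(is.numeric(replicate_sd) && length(replicate_sd) == 1L &&
          is.finite(replicate_sd) && replicate_sd >= 0,
        "replicate_sd", "must be a single number >= 0 (or NULL)")
  chk(is.numeric(missing_rate) && length(missing_rate) == 1L &&
        missing_rate >= 0 && missing_rate < 1,
      "missing_rate", "must be in [0, 1)")
  chk(is.numeric(baseline_sd) && baseline_sd >= 0, "baseline_sd", "must be >= 0")
  chk(is.numeric(dlmo_clock_sd) && dlmo_clock_sd >= 0, "dlmo_clock_sd",
      "must be >= 0")
  chk(is.numeric(seed) && length(seed) == 1L && is.finite(seed) &&
        seed == floor(seed), "seed", "must be a single integer")
  if (is.null(noise_sd)) {
    for (s in rhythm_specs)
      chk(rhythm_variance(s) < 1, "rhythm_specs",
          sprintf("protein '%s': sum(A^2)/2 must be < 1 when noise_sd is derived from unit total variance",
                  s$protein_id))
  }
  structure(list(n_participants = as.integer(n_participants),
                 timepoints = as.numeric(timepoints),
                 n_replicates = as.integer(n_replicates),
                 rhythm_specs = rhythm_specs,
                 noise_sd = noise_sd, replicate_sd = replicate_sd,
                 missing_rate = missing_rate,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 dlmo_clock_mean = dlmo_clock_mean,
                 dlmo_clock_sd = dlmo_clock_sd,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# deterministic per-participant substream seed: adding participants never
# perturbs earlier participants' draws
participant_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 65521) * 32749 + i * 2957 + 7) %% 2147483629L
}

#' Simulate a multi-participant protein time-series cohort
#'
#' Generates abundance records on the grid participant x protein x timepoint
#' x replicate. Each (participant, protein) series is
#' `M + sum_c A_c * cos(2*pi*(t - phi_c)/tau_c) + eps(t) + eta(t, r)` with a
#' Gaussian participant baseline `M`, i.i.d. Gaussian cell noise `eps`
#' (sd `noise_sd`) shared by the replicates of a timepoint, and independent
#' replicate noise `eta` (sd `replicate_sd`). Missingness is applied
#' completely at random at the cell level (all replicates of a missing cell
#' are `NA`). Each participant consumes a deterministic substream of the seed,
#' so enlarging the cohort leaves earlier participants' data unchanged.
#'
#' @param config A [cohort_config()].
#' @return A `data.frame` of class `cohort_dataset` with columns
#'   `participant_id`, `protein_id`, `dlmo_time`, `replicate`, `abundance`
#'   (`NA` = missing), and attributes `dlmo_clock` (named numeric vector of
#'   per-participant DLMO clock times, decimal hours) and `ground_truth`
#'   (the list of [rhythm_spec()]s used).
#' @examples
#' cfg <- cohort_config(n_participants = 2,
#'                      rhythm_specs = list(rhythm_spec("P1", 24, 0.3, 5)),
#'                      seed = 7)
#' head(simulate_cohort(cfg))
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop("invalid `config`: must be a cohort_config object", call. = FALSE)
  tp <- config$timepoints
  nt <- length(tp)
  nr <- config$n_replicates
  specs <- config$rhythm_specs
  np <- length(specs)
  if (np == 0L)
    stop("invalid `rhythm_specs`: at least one protein is required", call. = FALSE)

  pids <- sprintf("P%02d", seq_len(config$n_participants))
  dlmo_clock <- numeric(config$n_participants)
  names(dlmo_clock) <- pids
  blocks <- vector("list", config$n_participants)

  for (i in seq_len(config$n_participants)) {
    set.seed(participant_seed(config$seed, i))
    dlmo_clock[i] <- stats::rnorm(1, config$dlmo_clock_mean, config$dlmo_clock_sd)
    per_protein <- vector("list", np)
    for (j in seq_len(np)) {
      s <- specs[[j]]
      nsd <- if (is.null(config$noise_sd)) sqrt(1 - rhythm_variance(s))
             else config$noise_sd
      rsd <- if (is.null(config$replicate_sd)) 0.2 * nsd else config$replicate_sd
      signal <- rep(0, nt)
      for (c in seq_along(s$periods))
        signal <- signal + s$amplitudes[c] *
          cos(2 * pi * (tp - s$acrophases[c]) / s$periods[c])
      m <- stats::rnorm(1, config$baseline_mean, config$baseline_sd)
      eps <- stats::rnorm(nt, 0, nsd)
      miss <- stats::runif(nt) < config$missing_rate
      eta <- matrix(stats::rnorm(nt * nr, 0, rsd), nrow = nt)
      ab <- m + signal + eps + eta        # nt x nr
      ab[miss, ] <- NA_real_
      per_protein[[j]] <- data.frame(
        participant_id = pids[i],
        protein_id = s$protein_id,
        dlmo_time = rep(tp, times = nr),
        replicate = rep(seq_len(nr), each = nt),
        abundance = as.vector(ab),
        stringsAsFactors = FALSE)
    }
    blocks[[i]] <- do.call(rbind, per_protein)
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  structure(out,
            dlmo_clock = dlmo_clock,
            ground_truth = specs,
            class = c("cohort_dataset", "data.frame"))
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d records: %d participants x %d proteins x %d timepoints\n",
              nrow(x), length(unique(x$participant_id)),
              length(unique(x$protein_id)), length(unique(x$dlmo_time))))
  cat(sprintf("  missing cells: %.1f%%\n", 100 * mean(is.na(x$abundance))))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more records\n", nrow(x) - 6L))
  invisible(x)
}

#' Write / read a cohort dataset as delimited text
#'
#' `write_cohort()` writes the records to `path` (CSV; empty field =
#' missing), the per-participant DLMO clock times to `dlmo_path`, and, when
#' ground truth is present, a rhythm sidecar to `truth_path` (one row per
#' cosine component; arrhythmic proteins get a row with empty component
#' fields). `read_cohort()` inverts it losslessly.
#'
#' @param x A `cohort_dataset` (or data.frame with the same columns).
#' @param path,dlmo_path,truth_path File paths. `dlmo_path` and `truth_path`
#'   default to `path` with `_dlmo` / `_truth` suffixes; `truth_path = NA`
#'   suppresses the sidecar.
#' @return `write_cohort()` returns the paths written, invisibly.
#'   `read_cohort()` returns a `cohort_dataset`.
#' @export
write_cohort <- function(x, path,
                         dlmo_path = sidecar_path(path, "dlmo"),
                         truth_path = sidecar_path(path, "truth")) {
  utils::write.csv(as.data.frame(x)[, c("participant_id", "protein_id",
                                        "dlmo_time", "replicate", "abundance")],
                   path, row.names = FALSE, na = "")
  paths <- path
  dl <- attr(x, "dlmo_clock")
  if (!is.null(dl) && !is.null(dlmo_path) && !is.na(dlmo_path)) {
    utils::write.csv(data.frame(participant_id = names(dl), dlmo_clock = unname(dl),
                                stringsAsFactors = FALSE),
                     dlmo_path, row.names = FALSE)
    paths <- c(paths, dlmo_path)
  }
  gt <- attr(x, "ground_truth")
  if (!is.null(gt) && !is.null(truth_path) && !is.na(truth_path)) {
    rows <- lapply(gt, function(s) {
      if (length(s$periods) == 0L)
        data.frame(protein_id = s$protein_id, period = NA_real_,
                   amplitude = NA_real_, acrophase = NA_real_,
                   stringsAsFactors = FALSE)
      else
        data.frame(protein_id = s$protein_id, period = s$periods,
                   amplitude = s$amplitudes, acrophase = s$acrophases,
                   stringsAsFactors = FALSE)
    })
    utils::write.csv(do.call(rbind, rows), truth_path, row.names = FALSE, na = "")
    paths <- c(paths, truth_path)
  }
  invisible(paths)
}

sidecar_path <- function(path, tag) {
  sub("(\\.[A-Za-z0-9]+)?$", sprintf("_%s.csv", tag), path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path,
                        dlmo_path = sidecar_path(path, "dlmo"),
                        truth_path = sidecar_path(path, "truth")) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(participant_id = "character",
                                        protein_id = "character"))
  dl <- NULL
  if (!is.null(dlmo_path) && !is.na(dlmo_path) && file.exists(dlmo_path)) {
    d <- utils::read.csv(dlmo_path, stringsAsFactors = FALSE,
                         colClasses = c(participant_id = "character"))
    dl <- stats::setNames(d$dlmo_clock, d$participant_id)
  }
  gt <- NULL
  if (!is.null(truth_path) && !is.na(truth_path) && file.exists(truth_path)) {
    tr <- utils::read.csv(truth_path, stringsAsFactors = FALSE,
                          colClasses = c(protein_id = "character"))
    gt <- lapply(split(tr, factor(tr$protein_id, levels = unique(tr$protein_id))),
                 function(d) {
                   if (all(is.na(d$period))) rhythm_spec(d$protein_id[1])
                   else rhythm_spec(d$protein_id[1], d$period, d$amplitude,
                                    d$acrophase)
                 })
    names(gt) <- NULL
  }
  structure(rec, dlmo_clock = dl, ground_truth = gt,
            class = c("cohort_dataset", "data.frame"))
}
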