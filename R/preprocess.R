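#' Average technical replicates
#'
#' Collapses replicate measurements to one record per (participant, protein,
#' timepoint): the arithmetic mean of the non-missing replicates. A cell is
#' missing only when all of its replicates are missing.
#'
#' @param dataset A `cohort_dataset` or data.frame with columns
#'   `participant_id`, `protein_id`, `dlmo_time`, `replicate`, `abundance`.
#' @return A `cohort_dataset` with one record per cell, columns
#'   `participant_id`, `protein_id`, `dlmo_time`, `abundance`,
#'   `n_replicates` (number of non-missing replicates averaged).
#' @export
average_replicates <- function(dataset) {
  need_columns(dataset, c("participant_id", "protein_id", "dlmo_time",
                          "replicate", "abundance"))
  key <- interaction(dataset$participant_id, dataset$protein_id,
                     dataset$dlmo_time, drop = TRUE, lex.order = TRUE)
  first <- !duplicated(key)
  means <- tapply(dataset$abundance, key, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else mean(v)
  })
  counts <- tapply(dataset$abundance, key, function(v) sum(!is.na(v)))
  out <- data.frame(participant_id = dataset$participant_id[first],
                    protein_id = dataset$protein_id[first],
                    dlmo_time = dataset$dlmo_time[first],
                    abundance = as.numeric(means[as.character(key[first])]),
                    n_replicates = as.integer(counts[as.character(key[first])]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$participant_id, out$protein_id, out$dlmo_time), ]
  rownames(out) <- NULL
  structure(out, dlmo_clock = attr(dataset, "dlmo_clock"),
            ground_truth = attr(dataset, "ground_truth"),
            class = c("cohort_dataset", "data.frame"))
}

#' Exclude proteins with excessive missingness
#'
#' Computes, per protein, the fraction of missing cells over the full
#' participant x timepoint grid of a replicate-averaged dataset and drops
#' proteins whose fraction is strictly greater than `max_missing`.
#'
#' @param dataset A replicate-averaged `cohort_dataset` (see
#'   [average_replicates()]).
#' @param max_missing Maximum tolerated missing fraction; default 0.10.
#' @return A list with elements `dataset` (retained records) and `report`
#'   (data.frame: `protein_id`, `missing_fraction`, `status` kept/dropped).
#' @export
filter_missing_proteins <- function(dataset, max_missing = 0.10) {
  need_columns(dataset, c("participant_id", "protein_id", "dlmo_time",
                          "abundance"))
  participants <- unique(dataset$participant_id)
  timepoints <- unique(dataset$dlmo_time)
  n_cells <- length(participants) * length(timepoints)
  proteins <- unique(dataset$protein_id)
  n_obs <- tapply(!is.na(dataset$abundance), dataset$protein_id, sum)
  frac <- 1 - as.numeric(n_obs[proteins]) / n_cells
  report <- data.frame(protein_id = proteins,
                       missing_fraction = frac,
                       status = ifelse(frac > max_missing, "dropped", "kept"),
                       stringsAsFactors = FALSE)
  keep <- dataset$protein_id %in% proteins[frac <= max_missing]
  kept <- dataset[keep, , drop = FALSE]
  rownames(kept) <- NULL
  kept <- structure(kept, dlmo_clock = attr(dataset, "dlmo_clock"),
                    ground_truth = attr(dataset, "ground_truth"),
                    class = c("cohort_dataset", "data.frame"))
  list(dataset = kept, report = report)
}

#' Per-participant z-scoring
#'
#' Standard-scales each (participant, protein) series to sample mean 0 and
#' sample (n - 1) standard deviation 1, leaving missing points missing. This
#' expresses every abundance as a participant z-score, so each retained
#' series has total variance 1 — the convention under which rhythm amplitudes
#' and the power calculations are interpreted.
#'
#' @param dataset A replicate-averaged `cohort_dataset`.
#' @return A data.frame of class `scaled_series` with columns
#'   `participant_id`, `protein_id`, `dlmo_time`, `z_value`, and attribute
#'   `provenance`: per-series counts of points used and missing points
#'   dropped.
#' @export
zscore_per_participant <- function(dataset) {
  need_columns(dataset, c("participant_id", "protein_id", "dlmo_time",
                          "abundance"))
  key <- paste(dataset$participant_id, dataset$protein_id, sep = "\r")
  groups <- split(seq_len(nrow(dataset)), key)
  z <- rep(NA_real_, nrow(dataset))
  prov <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    v <- dataset$abundance[idx]
    obs <- v[!is.na(v)]
    pid <- dataset$participant_id[idx[1]]
    prot <- dataset$protein_id[idx[1]]
    if (length(obs) < 2L)
      stop(sprintf("cannot z-score participant '%s', protein '%s': fewer than 2 non-missing values",
                   pid, prot), call. = FALSE)
    s <- stats::sd(obs)
    if (s == 0)
      stop(sprintf("cannot z-score participant '%s', protein '%s': constant series (sd = 0)",
                   pid, prot), call. = FALSE)
    z[idx] <- (v - mean(obs)) / s
    prov[[g]] <- data.frame(participant_id = pid, protein_id = prot,
                            n_points = length(obs),
                            n_missing = sum(is.na(v)),
                            stringsAsFactors = FALSE)
  }
  out <- data.frame(participant_id = dataset$participant_id,
                    protein_id = dataset$protein_id,
                    dlmo_time = dataset$dlmo_time,
                    z_value = z, stringsAsFactors = FALSE)
  structure(out, provenance = do.call(rbind, prov),
            dlmo_clock = attr(dataset, "dlmo_clock"),
            ground_truth = attr(dataset, "ground_truth"),
            class = c("scaled_series", "data.frame"))
}

#' Clock time to DLMO time and back
#'
#' `clock_to_dlmo()` converts a clock time (decimal hours; values beyond 24
#' allowed for sequential sampling into the next day) to hours elapsed since
#' the participant's dim light melatonin onset. The mapping is a plain
#' difference, so sample order is preserved and early-evening samples before
#' DLMO get negative DLMO hours. `dlmo_to_clock()` inverts it, normalised to
#' `[0, 24)` for display.
#'
#' @param clock_time Clock time(s) in decimal hours.
#' @param participant_dlmo_clock The participant's DLMO clock time (decimal
#'   hours).
#' @param dlmo_time Time(s) in DLMO hours.
#' @return Numeric vector of DLMO hours (`clock_to_dlmo`) or clock decimal
#'   hours in `[0, 24)` (`dlmo_to_clock`).
#' @examples
#' clock_to_dlmo(20.77, 22.77)   # -2: two hours before melatonin onset
#' dlmo_to_clock(5, 22.77)       # 3.77 (next-day clock time)
#' @export
clock_to_dlmo <- function(clock_time, participant_dlmo_clock) {
  stopifnot(is.numeric(clock_time), is.numeric(participant_dlmo_clock))
  clock_time - participant_dlmo_clock
}

#' @rdname clock_to_dlmo
#' @export
dlmo_to_clock <- function(dlmo_time, participant_dlmo_clock) {
  (dlmo_time + participant_dlmo_clock) %% 24
}

#' Format decimal hours as "HH:MM"
#'
#' @param decimal_hours Finite numeric vector; displayed modulo 24.
#' @return Character vector, minutes rounded with correct carry
#'   (e.g. 23.999 renders "00:00").
#' @examples
#' decimal_to_hhmm(22.77)  # "22:46"
#' @export
decimal_to_hhmm <- function(decimal_hours) {
  stopifnot(is.numeric(decimal_hours), all(is.finite(decimal_hours)))
  x <- decimal_hours %% 24
  total_min <- round(x * 60) %% (24 * 60)
  sprintf("%02d:%02d", total_min %/% 60, total_min %% 60)
}

need_columns <- function(d, cols) {
  missing <- setdiff(cols, names(d))
  if (length(missing) > 0L)
    stop(sprintf("input is missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}
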