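#' Single-component cosinor fit for one individual series
#'
#' Ordinary least squares of a time series on
#' `[1, cos(2*pi*t/period), sin(2*pi*t/period)]`, the classical
#' single-component cosinor. The fitted model is
#' `y(t) = M + beta*cos(2*pi*t/tau) + gamma*sin(2*pi*t/tau)`, equivalently
#' `M + A*cos(2*pi*(t - acrophase)/tau)` with amplitude
#' `A = sqrt(beta^2 + gamma^2)` and acrophase (time of peak)
#' `(tau/(2*pi)) * atan2(gamma, beta)` mapped into `[0, tau)`.
#'
#' @param times Sampling times (hours, typically on the DLMO scale).
#' @param values Observed values (typically participant z-scores); `NA`s are
#'   dropped pairwise with their times.
#' @param period Cycle length `tau` in hours (e.g. 24 or 12).
#' @param participant_id,protein_id Optional identifiers carried on the fit.
#' @return An object of class `cosinor_fit` with components `coefficients`
#'   (`mesor`, `beta`, `gamma`), `amplitude`, `acrophase`, `period`,
#'   `n_points`, `residual_ss`, `sigma`, and the data used.
#' @examples
#' t <- seq(0, 30, by = 2)
#' fit <- cosinor_fit(t, 3 + 0.3 * cos(2 * pi * (t - 5) / 24), period = 24)
#' coef(fit)
#' fit$amplitude   # 0.3
#' fit$acrophase   # 5
#' @export
cosinor_fit <- function(times, values, period, participant_id = NA_character_,
                        protein_id = NA_character_) {
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values))
  if (!is.numeric(period) || length(period) != 1L || !is.finite(period) ||
      period <= 0)
    stop("invalid `period`: must be a single positive number", call. = FALSE)
  ok <- !is.na(times) & !is.na(values)
  t <- times[ok]; y <- values[ok]
  if (length(y) < 4L)
    stop(sprintf("cosinor fit needs at least 4 non-missing points, got %d",
                 length(y)), call. = FALSE)
  theta <- 2 * pi * t / period
  X <- cbind(mesor = 1, beta = cos(theta), gamma = sin(theta))
  if (qr(X)$rank < 3L)
    stop("rank-deficient cosinor design: sampling times are degenerate for this period",
         call. = FALSE)
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  amp <- sqrt(cf[["beta"]]^2 + cf[["gamma"]]^2)
  acro <- (period / (2 * pi)) * atan2(cf[["gamma"]], cf[["beta"]])
  acro <- acro %% period
  rss <- sum(fit$residuals^2)
  structure(list(coefficients = cf,
                 amplitude = amp, acrophase = acro, period = period,
                 n_points = length(y), residual_ss = rss,
                 df_residual = length(y) - 3L,
                 sigma = sqrt(rss / max(length(y) - 3L, 1L)),
                 times = t, values = y, fitted_values = fit$fitted.values,
                 residuals = fit$residuals,
                 participant_id = participant_id, protein_id = protein_id),
            class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Single-component cosinor fit (period = %g h, n = %d)\n",
              x$period, x$n_points))
  if (!is.na(x$participant_id) || !is.na(x$protein_id))
    cat(sprintf("  series: participant %s, protein %s\n",
                x$participant_id, x$protein_id))
  cat(sprintf("  MESOR %s, amplitude %s, acrophase %s h\n",
              format(x$coefficients[["mesor"]], digits = digits),
              format(x$amplitude, digits = digits),
              format(x$acrophase, digits = digits)))
  invisible(x)
}

#' @export
coef.cosinor_fit <- function(object, ...) object$coefficients

#' @export
fitted.cosinor_fit <- function(object, ...) object$fitted_values

#' @export
residuals.cosinor_fit <- function(object, ...) object$residuals

#' Predict from a cosinor fit
#'
#' @param object A `cosinor_fit`.
#' @param newtimes Times at which to evaluate the fitted cosine; defaults to
#'   the fitting times.
#' @param ... Unused.
#' @return Numeric vector of fitted values.
#' @export
predict.cosinor_fit <- function(object, newtimes = object$times, ...) {
  cf <- object$coefficients
  theta <- 2 * pi * newtimes / object$period
  cf[["mesor"]] + cf[["beta"]] * cos(theta) + cf[["gamma"]] * sin(theta)
}

#' Simulate series from a fitted cosinor model
#'
#' Draws new series at the fitting times: the fitted cosine plus i.i.d.
#' Gaussian noise at the residual standard deviation.
#'
#' @param object A `cosinor_fit`.
#' @param nsim Number of series to draw.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A data.frame with one column per simulated series.
#' @export
simulate.cosinor_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0, object$sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.cosinor_fit <- function(x, ...) {
  graphics::plot(x$times, x$values, xlab = "time (DLMO h)", ylab = "value",
                 main = sprintf("Cosinor fit, period %g h", x$period), ...)
  tt <- seq(min(x$times), max(x$times), length.out = 200)
  graphics::lines(tt, predict(x, tt))
  invisible(x)
}

#' @export
summary.cosinor_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.cosinor_fit")
}

#' @export
print.summary.cosinor_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual SS %.4g on %d df (sigma %.4g)\n",
              x$fit$residual_ss, x$fit$df_residual, x$fit$sigma))
  invisible(x)
}

#' Map an acrophase to the signed display range
#'
#' Rhythm peak times are stored in `[0, period)`; reports sometimes use the
#' signed range `(-period/2, period/2]` so that peaks just before time zero
#' read as small negative hours (e.g. 23.1 h on a 24-h cycle displays as
#' -0.9 h).
#'
#' @param acrophase Acrophase(s) in hours.
#' @param period Cycle length in hours.
#' @return Acrophase(s) in `(-period/2, period/2]`.
#' @export
acrophase_signed <- function(acrophase, period) {
  x <- acrophase %% period
  ifelse(x > period / 2, x - period, x)
}

#' Population-mean cosinor with zero-amplitude test
#'
#' Summarises per-individual cosinor fits of one protein at one period by
#' the arithmetic means of their coefficients: the population rhythm is
#' `M_bar + beta_bar*cos + gamma_bar*sin`, with population amplitude
#' `sqrt(beta_bar^2 + gamma_bar^2)` and acrophase from
#' `atan2(gamma_bar, beta_bar)`. The zero-amplitude null (no population
#' rhythm) is tested with a Hotelling-type statistic on the mean
#' (beta, gamma) vector: `T2 = k * m' S^-1 m` with `S` the sample covariance
#' of the k per-subject coefficient pairs, referred to
#' `F = ((k-2) / (2*(k-1))) * T2` on (2, k-2) degrees of freedom.
#'
#' @param fits List of [cosinor_fit()] objects, one per subject, all for the
#'   same protein and period; at least 3.
#' @return An object of class `population_cosinor`.
#' @export
population_cosinor <- function(fits) {
  if (!is.list(fits) || !all(vapply(fits, inherits, logical(1), "cosinor_fit")))
    stop("`fits` must be a list of cosinor_fit objects", call. = FALSE)
  k <- length(fits)
  if (k < 3L)
    stop(sprintf("population cosinor needs at least 3 subjects, got %d", k),
         call. = FALSE)
  periods <- vapply(fits, `[[`, numeric(1), "period")
  if (length(unique(periods)) != 1L)
    stop("all fits must share the same period", call. = FALSE)
  prots <- unique(stats::na.omit(vapply(fits, `[[`, character(1), "protein_id")))
  if (length(prots) > 1L)
    stop("all fits must belong to the same protein", call. = FALSE)
  period <- periods[1]
  B <- t(vapply(fits, function(f) f$coefficients[c("beta", "gamma")], numeric(2)))
  m <- colMeans(B)
  S <- stats::cov(B)
  # singular S: e.g. identical noiseless subjects leave nothing to test against
  Sinv_m <- tryCatch(solve(S, m), error = function(e) NULL)
  if (is.null(Sinv_m) || any(!is.finite(Sinv_m)))
    stop("degenerate between-subject coefficient covariance (singular); subjects are (numerically) identical",
         call. = FALSE)
  T2 <- k * drop(m %*% Sinv_m)
  Fstat <- (k - 2) / (2 * (k - 1)) * T2
  p <- stats::pf(Fstat, 2, k - 2, lower.tail = FALSE)
  mesors <- vapply(fits, function(f) f$coefficients[["mesor"]], numeric(1))
  structure(list(protein_id = if (length(prots) == 1L) prots else NA_character_,
                 period = period, k_subjects = k,
                 pop_mesor = mean(mesors),
                 pop_beta = m[["beta"]], pop_gamma = m[["gamma"]],
                 pop_amplitude = sqrt(sum(m^2)),
                 pop_acrophase = ((period / (2 * pi)) *
                                    atan2(m[["gamma"]], m[["beta"]])) %% period,
                 T2 = T2, F_statistic = Fstat, df = c(2, k - 2), p_value = p,
                 individual_amplitudes = vapply(fits, `[[`, numeric(1), "amplitude"),
                 coefficient_matrix = B),
            class = "population_cosinor")
}

#' @export
print.population_cosinor <- function(x, digits = 4, ...) {
  cat(sprintf("Population-mean cosinor: %s, period %g h, k = %d subjects\n",
              if (is.na(x$protein_id)) "(unnamed protein)" else x$protein_id,
              x$period, x$k_subjects))
  cat(sprintf("  amplitude %s (z), acrophase %s DLMO h, MESOR %s\n",
              format(x$pop_amplitude, digits = digits),
              format(x$pop_acrophase, digits = digits),
              format(x$pop_mesor, digits = digits)))
  cat(sprintf("  zero-amplitude test: F(%d, %d) = %s, p = %s\n",
              x$df[1], x$df[2], format(x$F_statistic, digits = digits),
              format.pval(x$p_value, digits = digits)))
  invisible(x)
}

#' @export
coef.population_cosinor <- function(object, ...) {
  c(mesor = object$pop_mesor, beta = object$pop_beta, gamma = object$pop_gamma)
}

#' @export
summary.population_cosinor <- function(object, ...) {
  print(object)
  cat(sprintf("  mean of individual amplitudes %.4g (>= population amplitude)\n",
              mean(object$individual_amplitudes)))
  invisible(object)
}

#' Screen proteins for population rhythms at one or more periods
#'
#' Fits a per-individual cosinor to every (participant, protein) z-scored
#' series at each candidate period, summarises each protein by the
#' population-mean cosinor, and applies the rhythmicity screen: a protein
#' passes at a period iff the zero-amplitude p-value is strictly below
#' `p_threshold` and the population amplitude strictly above
#' `amp_threshold`. A protein may pass at several periods. No protein-level
#' multiplicity correction gates the screen; a Benjamini-Hochberg adjusted
#' column (`q_value`, per period) is emitted for reference only.
#'
#' @param data A `scaled_series` data.frame (see [zscore_per_participant()]).
#' @param periods Candidate periods in hours; default `c(24, 12)`.
#' @param p_threshold,amp_threshold Screen thresholds; defaults 0.05 and 0.1
#'   (strict inequalities).
#' @return A data.frame of class `rhythm_screen`, one row per protein x
#'   period, with population estimates, `p_value`, `q_value`, and
#'   `passes_screen`; per-series fit failures are collected in the
#'   `failures` attribute rather than aborting the screen.
#' @export
screen_rhythmic <- function(data, periods = c(24, 12), p_threshold = 0.05,
                            amp_threshold = 0.1) {
  need_columns(data, c("participant_id", "protein_id", "dlmo_time", "z_value"))
  proteins <- unique(data$protein_id)
  rows <- list()
  failures <- list()
  for (period in periods) {
    for (prot in proteins) {
      d <- data[data$protein_id == prot, , drop = FALSE]
      fits <- list()
      for (pid in unique(d$participant_id)) {
        di <- d[d$participant_id == pid, , drop = FALSE]
        f <- tryCatch(cosinor_fit(di$dlmo_time, di$z_value, period,
                                  participant_id = pid, protein_id = prot),
                      error = function(e) e)
        if (inherits(f, "error")) {
          failures[[length(failures) + 1L]] <-
            data.frame(protein_id = prot, period = period, participant_id = pid,
                       stage = "individual_fit", message = conditionMessage(f),
                       stringsAsFactors = FALSE)
        } else fits[[length(fits) + 1L]] <- f
      }
      pop <- tryCatch(population_cosinor(fits), error = function(e) e)
      if (inherits(pop, "error")) {
        failures[[length(failures) + 1L]] <-
          data.frame(protein_id = prot, period = period,
                     participant_id = NA_character_, stage = "population_test",
                     message = conditionMessage(pop), stringsAsFactors = FALSE)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = prot, period = period, k_subjects = pop$k_subjects,
        pop_mesor = pop$pop_mesor, pop_amplitude = pop$pop_amplitude,
        pop_acrophase = pop$pop_acrophase,
        pop_acrophase_signed = acrophase_signed(pop$pop_acrophase, period),
        p_value = pop$p_value, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(), period = numeric(),
               k_subjects = integer(), pop_mesor = numeric(),
               pop_amplitude = numeric(), pop_acrophase = numeric(),
               pop_acrophase_signed = numeric(), p_value = numeric(),
               stringsAsFactors = FALSE)
  out$q_value <- NA_real_
  for (period in unique(out$period)) {
    idx <- out$period == period
    out$q_value[idx] <- stats::p.adjust(out$p_value[idx], method = "BH")
  }
  out$passes_screen <- out$p_value < p_threshold & out$pop_amplitude > amp_threshold
  out <- out[order(out$period, out$p_value), ]
  rownames(out) <- NULL
  structure(out,
            failures = if (length(failures)) do.call(rbind, failures) else NULL,
            p_threshold = p_threshold, amp_threshold = amp_threshold,
            class = c("rhythm_screen", "data.frame"))
}

#' @export
print.rhythm_screen <- function(x, ...) {
  cat(sprintf("<rhythm_screen> %d protein x period tests, %d pass (p < %g, amplitude > %g)\n",
              nrow(x), sum(x$passes_screen), attr(x, "p_threshold"),
              attr(x, "amp_threshold")))
  fails <- attr(x, "failures")
  if (!is.null(fails))
    cat(sprintf("  %d series/test failure(s) recorded in attr(., \"failures\")\n",
                nrow(fails)))
  NextMethod()
}

#' Polar coordinates of screened rhythms
#'
#' Converts screen hits to polar-plot coordinates: angle is the acrophase as
#' a fraction of the cycle (radians, clockwise from the top in the usual
#' chronobiology display), radius is the population amplitude.
#'
#' @param screen A `rhythm_screen` (typically filtered to passes).
#' @param passes_only Keep only rows with `passes_screen`; default TRUE.
#' @return A data.frame: `protein_id`, `period`, `acrophase`,
#'   `angle_radians`, `amplitude`.
#' @export
polar_coordinates <- function(screen, passes_only = TRUE) {
  d <- as.data.frame(screen)
  if (passes_only) d <- d[d$passes_screen, , drop = FALSE]
  data.frame(protein_id = d$protein_id, period = d$period,
             acrophase = d$pop_acrophase,
             angle_radians = 2 * pi * d$pop_acrophase / d$period,
             amplitude = d$pop_amplitude,
             stringsAsFactors = FALSE)
}

#' @export
plot.rhythm_screen <- function(x, period = 24, ...) {
  pc <- polar_coordinates(x)
  pc <- pc[pc$period == period, , drop = FALSE]
  r <- max(pc$amplitude, 0.1)
  graphics::plot(NA, xlim = c(-r, r) * 1.3, ylim = c(-r, r) * 1.3, asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("Acrophase polar plot, %g h", period))
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(r * sin(th), r * cos(th), col = "grey")
  if (nrow(pc)) {
    xx <- pc$amplitude * sin(pc$angle_radians)
    yy <- pc$amplitude * cos(pc$angle_radians)
    graphics::points(xx, yy, pch = 19)
    graphics::text(xx, yy, pc$protein_id, pos = 3, cex = 0.7)
  }
  invisible(x)
}
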