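#' Power-analysis parameters
#'
#' Bundles the quantities entering the two-group sample-size and Type II
#' error calculations: the two-sided significance level, the baseline Type II
#' rate the study was designed for, the standardised effect size (mean
#' difference in z-units), and the variance convention used to translate a
#' rhythm amplitude into added variance (see [total_variance()]).
#'
#' @param alpha Two-sided significance level in (0, 1); default 0.05.
#' @param beta_baseline Baseline Type II error rate in (0, 1); default 0.20
#'   (80% power).
#' @param effect_size_d Mean difference between groups in z-units (> 0);
#'   default 0.5. The relative outputs ([n_increase_pct()],
#'   [beta_uncontrolled_pct()]) do not depend on it.
#' @param variance_convention `"table3_full"` (rhythm variance `A^2`) or
#'   `"eq2_half"` (rhythm variance `A^2/2`, the literal variance of a cosine
#'   of amplitude A under uniform phase sampling).
#' @return An object of class `power_params`.
#' @export
power_params <- function(alpha = 0.05, beta_baseline = 0.20,
                         effect_size_d = 0.5,
                         variance_convention = c("table3_full", "eq2_half")) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("invalid `alpha`: must be in (0, 1)", call. = FALSE)
  if (!is.numeric(beta_baseline) || length(beta_baseline) != 1L ||
      beta_baseline <= 0 || beta_baseline >= 1)
    stop("invalid `beta_baseline`: must be in (0, 1)", call. = FALSE)
  if (!is.numeric(effect_size_d) || length(effect_size_d) != 1L ||
      !is.finite(effect_size_d) || effect_size_d <= 0)
    stop("invalid `effect_size_d`: must be > 0", call. = FALSE)
  variance_convention <- match.arg(variance_convention)
  structure(list(alpha = alpha, beta_baseline = beta_baseline,
                 effect_size_d = effect_size_d,
                 variance_convention = variance_convention),
            class = "power_params")
}

#' @export
print.power_params <- function(x, ...) {
  cat(sprintf("<power_params> alpha = %g (two-sided), baseline beta = %g, d = %g, convention = %s\n",
              x$alpha, x$beta_baseline, x$effect_size_d, x$variance_convention))
  invisible(x)
}

rhythm_var <- function(amplitude, convention) {
  switch(convention,
         eq2_half = sum(amplitude^2) / 2,
         table3_full = sum(amplitude^2),
         stop("unknown variance convention: ", convention, call. = FALSE))
}

#' Variance decomposition under uncontrolled rhythmicity
#'
#' Total variance of a biomarker is the controlled ("base") variance plus the
#' variance contributed by uncontrolled rhythmic component(s) plus any
#' base-rhythm covariance. With endogenous rhythms independent of the base
#' variation the covariance is zero, and the rhythm variance is expressed in
#' the amplitude alone: `A^2/2` per cosine component under the `eq2_half`
#' convention, or `A^2` under `table3_full`. Multiple components add their
#' rhythm variances (variance sum law).
#'
#' @param sigma2_base Controlled (rhythm-free) variance, >= 0.
#' @param amplitude Amplitude(s) of the rhythmic component(s), each >= 0; a
#'   vector sums component variances.
#' @param convention `"table3_full"` or `"eq2_half"`.
#' @param sigma2_cov Base-rhythm covariance term; default 0 (independence).
#' @return An object of class `variance_decomposition` with fields
#'   `sigma2_base`, `sigma2_rhythm`, `sigma2_cov`, `sigma2_total`
#'   (their exact sum).
#' @examples
#' total_variance(1, 0.4, "eq2_half")$sigma2_total     # 1.08
#' total_variance(1, 0.4, "table3_full")$sigma2_total  # 1.16
#' @export
total_variance <- function(sigma2_base, amplitude,
                           convention = c("table3_full", "eq2_half"),
                           sigma2_cov = 0) {
  convention <- match.arg(convention)
  if (!is.numeric(sigma2_base) || length(sigma2_base) != 1L ||
      !is.finite(sigma2_base) || sigma2_base < 0)
    stop("invalid `sigma2_base`: must be a single number >= 0", call. = FALSE)
  if (!is.numeric(amplitude) || any(!is.finite(amplitude)) || any(amplitude < 0))
    stop("invalid `amplitude`: must be finite and >= 0", call. = FALSE)
  s2r <- rhythm_var(amplitude, convention)
  structure(list(sigma2_base = sigma2_base, sigma2_rhythm = s2r,
                 sigma2_cov = sigma2_cov,
                 sigma2_total = sigma2_base + s2r + sigma2_cov,
                 convention = convention),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf("<variance_decomposition> total %.4g = base %.4g + rhythm %.4g + cov %.4g (%s)\n",
              x$sigma2_total, x$sigma2_base, x$sigma2_rhythm, x$sigma2_cov,
              x$convention))
  invisible(x)
}

#' Required per-group sample size for a two-group comparison
#'
#' Normal-approximation sample size for an equal-n, equal-variance, two-sided
#' two-group mean comparison:
#' `n = (Z_{alpha/2} + Z_beta)^2 * 2 * sigma2_total / d^2`.
#'
#' @param params A [power_params()].
#' @param sigma2_total Total variance of the measurement, > 0.
#' @return List with `n_real` (the closed-form value) and `n_ceiling`
#'   (rounded up to a whole participant).
#' @examples
#' required_n(power_params(effect_size_d = 0.5), 1)$n_real  # ~62.79
#' @export
required_n <- function(params, sigma2_total) {
  stopifnot(inherits(params, "power_params"))
  if (!is.numeric(sigma2_total) || any(sigma2_total <= 0))
    stop("invalid `sigma2_total`: must be > 0", call. = FALSE)
  if (params$effect_size_d == 0)
    stop("effect size d = 0: required n undefined", call. = FALSE)
  za <- stats::qnorm(1 - params$alpha / 2)
  zb <- stats::qnorm(1 - params$beta_baseline)
  n <- (za + zb)^2 * 2 * sigma2_total / params$effect_size_d^2
  list(n_real = n, n_ceiling = ceiling(n))
}

#' Type II error at a fixed sample size
#'
#' Inverts the sample-size formula: for a given per-group `n`, effect size
#' and total variance, `Z_beta = sqrt(n * d^2 / (2 * sigma2_total)) -
#' Z_{alpha/2}`, and the Type II error rate is the upper-tail standard normal
#' probability of `Z_beta`.
#'
#' @param n Per-group sample size, > 0 (need not be an integer).
#' @param params A [power_params()].
#' @param sigma2_total Total variance, > 0.
#' @return List with `z_beta` and `beta` (probability scale).
#' @export
z_beta <- function(n, params, sigma2_total) {
  stopifnot(inherits(params, "power_params"))
  if (!is.numeric(n) || any(n <= 0))
    stop("invalid `n`: must be > 0", call. = FALSE)
  if (!is.numeric(sigma2_total) || any(sigma2_total <= 0))
    stop("invalid `sigma2_total`: must be > 0", call. = FALSE)
  za <- stats::qnorm(1 - params$alpha / 2)
  zb <- sqrt(n * params$effect_size_d^2 / (2 * sigma2_total)) - za
  list(z_beta = zb, beta = stats::pnorm(zb, lower.tail = FALSE))
}

# round-half-up at the reporting layer only
round_half_up <- function(x) floor(x + 0.5)

#' Sample-size inflation from an uncontrolled rhythm
#'
#' For z-scored data the total variance is fixed at 1; controlling the rhythm
#' would remove its variance, leaving `sigma2_base = 1 - sigma2_rhythm`.
#' Since the required n is proportional to the variance, leaving the rhythm
#' uncontrolled inflates n by `100 * (1 / sigma2_base - 1)` percent relative
#' to the controlled design.
#'
#' @param amplitude Rhythm amplitude(s) in z-units, each in `[0, 1)`
#'   (vectorised over proteins).
#' @param convention Variance convention; default `"table3_full"`.
#' @return Percent increase in required n (unrounded; see [power_table()] for
#'   the integer-rounded report).
#' @examples
#' n_increase_pct(0.41)  # ~20.2
#' @export
n_increase_pct <- function(amplitude, convention = c("table3_full", "eq2_half")) {
  convention <- match.arg(convention)
  if (!is.numeric(amplitude) || any(!is.finite(amplitude)) || any(amplitude < 0))
    stop("invalid `amplitude`: must be finite and >= 0", call. = FALSE)
  s2r <- vapply(amplitude, rhythm_var, numeric(1), convention = convention)
  if (any(s2r >= 1))
    stop("rhythm variance >= 1: amplitude incompatible with unit total variance",
         call. = FALSE)
  100 * (1 / (1 - s2r) - 1)
}

#' Type II error rate if a rhythm is left uncontrolled
#'
#' Fixes n at the value that achieves the baseline power under the controlled
#' variance `sigma2_base = 1 - sigma2_rhythm`, then evaluates the Type II
#' error of that same n at the uncontrolled (unit) variance. Closed form:
#' `Z_beta = (Z_{alpha/2} + Z_{beta0}) * sqrt(sigma2_base) - Z_{alpha/2}`,
#' independent of the effect size.
#'
#' @inheritParams n_increase_pct
#' @param params A [power_params()] supplying `alpha` and `beta_baseline`.
#' @return Type II error rate in percent (unrounded).
#' @examples
#' beta_uncontrolled_pct(0.41)  # ~27.6 -> prints as 28
#' @export
beta_uncontrolled_pct <- function(amplitude, params = power_params(),
                                  convention = c("table3_full", "eq2_half")) {
  convention <- match.arg(convention)
  stopifnot(inherits(params, "power_params"))
  if (!is.numeric(amplitude) || any(!is.finite(amplitude)) || any(amplitude < 0))
    stop("invalid `amplitude`: must be finite and >= 0", call. = FALSE)
  s2r <- vapply(amplitude, rhythm_var, numeric(1), convention = convention)
  if (any(s2r >= 1))
    stop("rhythm variance >= 1: amplitude incompatible with unit total variance",
         call. = FALSE)
  za <- stats::qnorm(1 - params$alpha / 2)
  zb0 <- stats::qnorm(1 - params$beta_baseline)
  zb <- (za + zb0) * sqrt(1 - s2r) - za
  100 * stats::pnorm(zb, lower.tail = FALSE)
}

#' Statistical-implications table for screened rhythmic proteins
#'
#' Builds the per-protein power report: for every (protein, period) that
#' passed the rhythmicity screen, the population amplitude, the percent
#' increase in n required to maintain power if the rhythm is uncontrolled,
#' and the Type II error rate at the original n. Percentages are rounded
#' half-up to integers in the `*_pct` columns; exact values are kept in the
#' `*_exact` columns.
#'
#' @param results A `rhythm_screen` data.frame (or any data.frame with
#'   columns `protein_id`, `period`, `pop_amplitude` or `amplitude`,
#'   `p_value`, and optionally `passes_screen`).
#' @param params A [power_params()].
#' @param convention Variance convention; default `"table3_full"`.
#' @return A data.frame of class `power_table`, ordered by period then
#'   ascending p-value, one row per passing (protein, period).
#' @export
power_table <- function(results, params = power_params(),
                        convention = c("table3_full", "eq2_half")) {
  convention <- match.arg(convention)
  d <- as.data.frame(results)
  if (!"amplitude" %in% names(d) && "pop_amplitude" %in% names(d))
    d$amplitude <- d$pop_amplitude
  need_columns(d, c("protein_id", "period", "amplitude"))
  if (!"p_value" %in% names(d)) d$p_value <- NA_real_
  if ("passes_screen" %in% names(d)) d <- d[d$passes_screen, , drop = FALSE]
  if (nrow(d) == 0L) {
    out <- data.frame(protein_id = character(), period = numeric(),
                      amplitude = numeric(), n_increase_exact = numeric(),
                      beta_uncontrolled_exact = numeric(),
                      n_increase_pct = numeric(),
                      beta_uncontrolled_pct = numeric(),
                      stringsAsFactors = FALSE)
    return(structure(out, class = c("power_table", "data.frame")))
  }
  d <- d[order(d$period, d$p_value), , drop = FALSE]
  inc <- n_increase_pct(d$amplitude, convention)
  bet <- beta_uncontrolled_pct(d$amplitude, params, convention)
  out <- data.frame(protein_id = d$protein_id, period = d$period,
                    amplitude = d$amplitude,
                    n_increase_exact = inc, beta_uncontrolled_exact = bet,
                    n_increase_pct = round_half_up(inc),
                    beta_uncontrolled_pct = round_half_up(bet),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, params = params, convention = convention,
            class = c("power_table", "data.frame"))
}

#' @export
print.power_table <- function(x, ...) {
  cat(sprintf("<power_table> %d rhythmic protein x period rows (%s convention)\n",
              nrow(x), attr(x, "convention") %||% "table3_full"))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Power-cost curves over an amplitude grid
#'
#' Evaluates [n_increase_pct()] and [beta_uncontrolled_pct()] over a grid of
#' amplitudes, for plotting the relationship between rhythm amplitude and
#' the cost in sample size or Type II error. Both outputs grow with the
#' square of the amplitude, so both curves are monotone non-decreasing.
#'
#' @param amplitude_grid Numeric vector of amplitudes in `[0, 1)`.
#' @inheritParams beta_uncontrolled_pct
#' @return A data.frame: `amplitude`, `n_increase_pct`, `beta_pct`
#'   (unrounded percents).
#' @export
power_curve <- function(amplitude_grid, params = power_params(),
                        convention = c("table3_full", "eq2_half")) {
  convention <- match.arg(convention)
  data.frame(amplitude = amplitude_grid,
             n_increase_pct = n_increase_pct(amplitude_grid, convention),
             beta_pct = beta_uncontrolled_pct(amplitude_grid, params, convention))
}
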