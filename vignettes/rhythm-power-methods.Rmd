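---
title: "Population-mean cosinor screening and the power cost of rhythmicity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-mean cosinor screening and the power cost of rhythmicity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmpower)
```

This vignette is the package's own account of what it computes, the
assumptions behind each stage, the defaults and why they were chosen, and
what the simulation-based tests do and do not establish.

## The problem

Protein abundance in blood can carry endogenous circadian (24-h) and
ultradian (12-h) rhythms. In a case-control study sampled at uncontrolled
times of day, a rhythm is variance that a time-controlled design would have
removed. The package answers two questions: *which proteins in a
DLMO-aligned, densely sampled cohort are rhythmic*, and *what does leaving
such a rhythm uncontrolled cost* in required sample size or Type II error.

Time is measured in DLMO hours — hours since the participant's dim light
melatonin onset, a standard circadian phase marker — so that participants
with different internal clock phases are aligned before any fitting.
`clock_to_dlmo()` is a plain difference (clock time minus the participant's
DLMO clock time), preserving sample order across midnight; late-evening
samples before DLMO take small negative DLMO hours.

## Preprocessing

Technical replicates of a (participant, protein, timepoint) cell are
averaged arithmetically over the non-missing replicates; a cell is missing
only when all its replicates are. Proteins whose missing fraction over the
full participant × timepoint grid is strictly greater than 10% are excluded
(the fraction is computed jointly across participants; the boundary is
strict, so 6.25% missing on a 16-point series is kept while 12.5% is
dropped).

Each retained (participant, protein) series is then **z-scored**: centred to
sample mean 0 and scaled to sample (n−1) standard deviation 1. The scaling
is per series, not pooled across proteins, so every series has total
variance exactly 1 — the normalisation under which rhythm amplitudes are
read and on which the power algebra below relies. Centring is included even
though only the division changes the cosinor amplitude (the MESOR absorbs
any mean shift); it makes the unit-variance convention exact and is what
"participant z-score" means. Constant series are a hard error naming the
participant and protein rather than a silent NaN. Missing points stay
missing; they are dropped pairwise at fitting time, with no imputation.

## Cosinor model and population inference

For one series and period $\tau$ the model is the classical
single-component cosinor,
$y(t) = M + \beta\cos(2\pi t/\tau) + \gamma\sin(2\pi t/\tau) + \varepsilon$,
fitted by ordinary least squares (`stats::lm.fit` on the
$[1, \cos, \sin]$ design). Amplitude and acrophase derive as
$A=\sqrt{\beta^2+\gamma^2}$ and
$\phi = (\tau/2\pi)\,\mathrm{atan2}(\gamma,\beta)$ mapped into $[0,\tau)$;
a signed display range $(-\tau/2, \tau/2]$ is available via
`acrophase_signed()` because peak times just before the phase reference are
conventionally reported as small negative hours. Fits require at least 4
non-missing points and a full-rank design (times not all congruent modulo
the period). Complex alternatives — multi-component cosinors, non-linear
period estimation, rank-based detectors — are deliberately out of scope: at
cohort sizes of ~10 the risk of overfitting outweighs their flexibility.

The population summary is the **mean of the individual models**: average
the per-subject $(\beta_i, \gamma_i)$ (and MESORs) and convert the mean
vector to amplitude and acrophase. Averaging coefficients, not amplitudes,
matters: amplitudes are norms, so their mean ignores phase disagreement,
whereas the coefficient mean lets antiphase subjects cancel. It follows
(triangle inequality) that the population amplitude never exceeds the mean
individual amplitude.

The zero-amplitude test treats the $k$ subject coefficient pairs as an
i.i.d. bivariate sample and asks whether their mean is zero:
$T^2 = k\,\bar m^\top S^{-1} \bar m$ with $S$ the sample covariance, and
$F = \frac{k-2}{2(k-1)} T^2 \sim F(2, k-2)$ under the null. This is the
classical population-mean cosinor test; it is exact under bivariate
normality of the coefficients, which in turn holds whenever the
within-subject noise is roughly Gaussian. It needs $k \ge 3$; a singular
$S$ (numerically identical subjects) is an explicit error. The screen calls
a protein rhythmic at a period iff $p < 0.05$ **and** population amplitude
$> 0.1$ z-scores, both strict. No protein-level false-discovery correction
gates the screen; a Benjamini–Hochberg column is emitted per period for
reference only, since proteins correlated within pathways would make
protein-level BH conservative.

Because the sampling window (30 h at 2-h spacing) covers only 1.25 cycles
of a 24-h rhythm, the 12-h and 24-h regressors are not orthogonal: a pure
unit 24-h cosine fitted at 12 h yields amplitude 0.188 on this grid. This
cross-period leakage is a property of the design, frozen as a regression
test; it is one reason the amplitude gate exists alongside the p-value
gate.

## The power algebra

With base (rhythm-controlled) variance $\sigma^2_{base}$, an independent
uncontrolled cosine adds its variance (covariance zero), giving
$\sigma^2_{total} = \sigma^2_{base} + \sigma^2_{rhythm}$; multiple
components add their variances (variance sum law). The two-group,
equal-n, equal-variance, two-sided normal-approximation design gives

$$n = \frac{(Z_{\alpha/2}+Z_\beta)^2 \cdot 2\sigma^2_{total}}{d^2},
\qquad
Z_\beta = \sqrt{\frac{n d^2}{2\sigma^2_{total}}} - Z_{\alpha/2},$$

mutual inverses by construction (tested to 1e-9 over random designs).
Quantiles are computed to full double precision; rounding to integer
percents (half-up) happens once, at the reporting layer.

On z-scored data $\sigma^2_{total} = 1$, so fixing
$\sigma^2_{base} = 1 - \sigma^2_{rhythm}$ makes the two reported quantities
independent of the effect size $d$:

* **n inflation**: $100\,(1/\sigma^2_{base} - 1)$ percent, since $n$ is
  proportional to variance;
* **β if uncontrolled**: fix $n$ at the value achieving the baseline power
  under $\sigma^2_{base}$, then evaluate it at variance 1:
  $Z_\beta = (Z_{\alpha/2}+Z_{\beta_0})\sqrt{\sigma^2_{base}} -
  Z_{\alpha/2}$.

Both grow with $A^2$ to leading order and are strictly increasing in $A$.

**Variance conventions.** The variance of $A\cos(2\pi t/\tau)$ under
uniform phase sampling is $A^2/2$, and that is what the decomposition
formula states; yet the published per-protein table this module reproduces
is generated, in every one of its 15 rows, by $\sigma^2_{rhythm} = A^2$
(equivalently by treating $\sigma_{cosine} = A$). Whether that is an
intentional amplitude convention or an inconsistency cannot be settled from
the text, so the package exposes both: `table3_full` ($A^2$, the default,
reproducing the published integers) and `eq2_half` ($A^2/2$, the literal
cosine variance, uniformly smaller). Neither is asserted as "correct"; the
convention audit in the test suite records that `eq2_half` reproduces none
of the published rows. Users quoting absolute rather than relative numbers
should note the published table's two columns are $d$-free only because of
the unit-total-variance formulation.

## The synthetic cohort generator

The generator emulates the structure of a constant-routine serum proteomics
study: by default 10 participants, 16 timepoints at 2-h spacing spanning
30 h of DLMO time, 3 technical replicates, and cohort DLMO clock times
drawn from Normal(22.77, 1.11²) decimal hours. Each (participant, protein)
series is

$$x(t) = M + \textstyle\sum_c A_c \cos\!\big(2\pi (t - \phi_c)/\tau_c\big)
  + \varepsilon(t) + \eta(t, r)$$

with Gaussian participant baseline $M$ (mean 10, sd 1 — placeholders, as
real abundance distributions and replicate CVs are not modelled),
i.i.d. Gaussian cell noise $\varepsilon$ shared by a timepoint's
replicates, and independent replicate noise $\eta$ at 20% of the cell noise
sd (arbitrary but configurable). Missingness is completely at random at
the cell level — all replicates of a hit cell go missing together —
matching how the downstream filter counts missing cells. By default the
cell noise sd is $\sqrt{1 - \sum_c A_c^2/2}$ so the series has total
variance ≈ 1 and planted amplitudes are on the post-z-score scale,
i.e. ground truth is directly comparable to fitted z-score amplitudes.

Randomness is organised as one seed with deterministic per-participant
substreams, so enlarging a cohort never perturbs earlier participants'
data — useful for incremental-design experiments and for regression tests.

What the generator does **not** emulate: LC-MS peak picking artefacts,
intensity-dependent (non-MCAR) missingness, heavy-tailed or
heteroscedastic noise, inter-protein correlation within pathways, and
between-participant amplitude/phase heterogeneity beyond what sampling
noise induces. Tests passing on this generator therefore establish the
statistical machinery — calibration, recovery, screen logic — not
robustness to real LC-MS pathologies.

## Numerical and design choices

* Sample (n−1) standard deviations everywhere, stated for reproducibility.
* Strict threshold inequalities: ties at exactly p = 0.05 or A = 0.1 fail
  the screen.
* Acrophase is stored in $[0, \tau)$ and displayed signed on demand;
  equivariance under time shifts is tested.
* The population test refuses $k < 3$ and singular coefficient covariance
  instead of returning fragile numbers.
* Screen failures for individual series (too few points, rank-deficient
  design) are collected in a `failures` attribute; the rest of the screen
  proceeds.
* Percent rounding is half-up (`floor(x + 0.5)`), applied once at output.
* Pipeline outputs are plain CSV plus a JSON manifest carrying a
  deterministic config fingerprint, the seed, and per-stage record counts;
  identical config and seed give byte-identical reports.

## Simulation scale in the test suite

The suite's simulation-based checks use problem sizes chosen to bound
Monte-Carlo error while keeping the default run fast: 500 null proteins at
$k=10$ for the nominal-level check of the zero-amplitude test (rejection
rate 0.05 ± 0.02), 200 replicate cohorts for recovery of a planted
$A=0.3$, $\tau=24$, $\phi=5$ rhythm, and one 73-protein cohort (13 planted
rhythmic including two dual-period proteins, 60 null) for screen logic.

One caveat worth stating: the population amplitude is the norm of a noisy
mean vector and thus biased slightly upward (a Rice-distribution effect of
order $\sigma_m^2/2A$, where $\sigma_m^2$ is the per-coordinate variance of
the coefficient mean — about +0.02 at the recovery test's conditions). The
mean recovered amplitude over replicate cohorts is therefore expected a
little above the planted value; this is a property of the estimator, not an
implementation artefact, and shrinks as $k$ or the timepoint count grows.

## Known limitations

* Single-component fits only; a protein carrying both 24-h and 12-h
  rhythms is screened per period, with the other period's component acting
  as structured residual (partially absorbed, given the non-orthogonal
  design).
* The power module addresses two-group mean comparison only; paired,
  survival or multivariable designs are out of scope, and base–rhythm
  covariance is carried only as a user-supplied constant.
* Real-data p-values from other cosinor software are not promised
  bit-exact: the screen's test statistic is the classical population-mean
  cosinor F, which matches such tools behaviourally, not byte-wise.
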