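---
title: "Modelling CD4 response to ART with cumulative viral load"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling CD4 response to ART with cumulative viral load}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Patients starting antiretroviral therapy (ART) at low CD4 counts recover
immune function at very different rates. A single viral-load (VL)
measurement says little about the damage done by intermittent viremia,
because the virus has a half-life of days: what matters biologically is the
*cumulative* exposure to detectable virus over time on treatment. This
package implements a complete Bayesian pipeline around that idea:

1. a **cumulative log viral-load metric** (cVL2, log10 copy-years/mL),
2. Bayesian **mixed-effects models** of CD4 response with cVL2 as a
   time-varying covariate,
3. **within-MCMC imputation** of missing baseline data,
4. **informative-prior elicitation** from published historical estimates,
5. **conditional-DIC** model comparison and stratified posterior-predictive
   summaries, and
6. a **synthetic cohort generator** that emulates the kind of sub-Saharan
   African treatment cohort these models target, providing ground truth for
   every stage.

## The cVL2 metric

For patient $i$ with visit times $t_{i,1} = 0 < t_{i,2} < \dots$ (years) and
viral loads $V_{i,k}$ (copies/mL),

$$\mathrm{cVL2}_{ij} \;=\; \sum_{k=2}^{j} (t_{i,k} - t_{i,k-1})\,
\frac{\log_{10}^{+}(V_{i,k}/400) + \log_{10}^{+}(V_{i,k-1}/400)}{2},$$

where $\log_{10}^{+}(x) = \max(0, \log_{10} x)$. The metric is the
trapezoidal area of log viral load *above* the 400 copies/mL threshold; the
threshold excludes transient 50–400 copies/mL blips and is a parameter
(`detection_limit`), so the 50 copies/mL assay limit or a 1000 copies/mL
variant are one argument away. Baseline cVL2 is 0 by definition; sub-limit
values are floored at 0 rather than allowed to contribute negative area, so
the per-patient series is non-decreasing.

Two choices deserve comment. First, the metric takes **raw copies/mL** and
applies the log inside the formula — the alternative (logging an already
logged value) is dimensionally incoherent. Second, visits with missing VL
contribute **no node**: the trapezoid simply bridges adjacent observed
visits with a longer inter-visit duration. Such visits still need a
covariate value for the regression; they receive the running cumulative
value at the most recent observed node at or before their time (no
interpolation into the bridging interval, since the sum only has terms at
observed nodes).

## The models

Nine model variants cross two outcomes, three time bases, and two
distributional families.

**Slope models** describe the CD4 count trajectory:
$$y_{ij} = x_{ij}^{\top}\beta + z_{ij}^{\top} b_i + \varepsilon_{ij},$$
with fixed effects for sex, baseline age, baseline CD4, baseline log10 VL,
a time basis (quadratic polynomial $t, t^2$, or cubic B-splines with inner
knots at (1.250, 2.5, 3.751) or (0.833, 1.666, 2.5, 3.334, 4.167) years and
boundary knots at 0 and 5 — the follow-up horizon; published spline analyses of
this kind fix only the inner knots, so the boundary choice is ours), and
optionally the exposure term
$\texttt{in\_care}_i \times \mathrm{cVL2}_{ij}$. The in-care indicator
zeroes the exposure coefficient for patients lost to follow-up. Random
effects are always an intercept and a slope on time, $z_{ij} = (1,
t_{ij})^{\top}$, with $2\times 2$ covariance $\Sigma_b$ — the spline options
alter only the fixed time basis.

**Asymptote models** describe the odds of reaching a normal CD4 count:
$\mathrm{logit}\,\pi_{ij} = x_{ij}^{\top}\beta + z_{ij}^{\top} b_i$ with
$y_{ij} = 1\{ \mathrm{CD4}_{ij} \ge 500\}$ at post-baseline visits
("any visit following ART initiation"); baseline rows are covariate anchors
only, and patients already at $\ge 500$ cells/uL at baseline are excluded
upstream.

**Skew-normal extensions.** CD4 counts are right-skewed, so the random
effects (and, for slope models, the errors) can be given skew-normal (SN)
distributions through the stochastic representation
$$b = \Delta\,|w| + u, \qquad w \sim N(0, I)\ \text{truncated to}\
\mathbb{R}^{+}, \quad u \sim N(0, \Sigma_b),$$
with $\Delta = \mathrm{diag}(\delta, \delta)$. At $\delta = 0$ this is
exactly the Gaussian model, which is what makes "does the skewness term
earn its keep" a well-posed question. Whether the zero in $SN(0, \Sigma,
\Delta)$ is the location or the mean is genuinely ambiguous; we adopt the
location-zero convention and expose a switch (`sn_center = "mean"`) that
applies the $\delta\sqrt{2/\pi}$ correction. Per-observation error skewness
is tied to a single shared $\delta_\varepsilon$ by default (`delta_structure
= "by_visit"` gives one per visit rank); a free per-visit-per-patient
matrix would not be identifiable from one cohort.

## Inference

Every model is fitted by MCMC through JAGS, with the model graph generated
from the specification; the posterior, not the sampling kernel, is the
contract. Three chains run from dispersed, seed-deterministic initial
values (least-squares estimates shifted by chain-specific offsets), so a
fit is bitwise reproducible given `seed`.

**Priors.** Vague Gaussian priors (mean 0, precision $10^{-6}$) on
regression coefficients, Uniform(0, `sd_upper`) on scale parameters, an
inverse-Wishart (identity scale, $q+1$ degrees of freedom) on $\Sigma_b$,
and $N(0, \text{precision } 10^{-2})$ on skewness parameters. The uniform
upper bound defaults to 1000: on the raw cells/uL scale plausible residual
and intercept sds reach well past 100, and a bound that truncates the
posterior is worse than a slightly wider vague prior. All are overridable
and should be read as assumptions.

**Informative priors** are elicited from published historical estimates.
The variance comes from inverting the upper-CI formula
$s^2 = n\,((\mathrm{uCI} - \bar x)/1.96)^2$ (1.96 is deliberately
hard-coded, matching the published arithmetic at its printed rounding); the
prior mean transfers the adjustment observed on current data: historical
estimate + (full-model estimate − simple-model estimate). Elicitation is
only offered for the Gaussian polynomial slope model — the historical
studies used that form, and asymptote studies used incompatible CD4
thresholds — so other specifications are refused with an error. Where the
published table's own chain is internally inconsistent (its "change" column
disagrees with the printed subtraction, and one precision cell rounds an
intermediate quotient), the formula is normative and the discrepancies are
left to the tests' tolerance notes.

**Missing data.** Missing CD4 outcomes are drawn from the model's
predictive distribution at every iteration. Missing baseline CD4 and log
VL follow linear imputation models on sex and age; missing sex follows a
binary model. The literal chained-equations scheme (sex given CD4 and VL,
while CD4 and VL are given sex) is cyclic and has no joint distribution, so
the sampler uses the coherent factorization sex | age, then (CD4, VL) |
sex, age: the full conditional of a missing sex then automatically involves
age, baseline CD4, baseline log VL *and* the outcome, which is the
chained scheme's intent. The literal sequential draw is still exposed as
`impute_step()` for schemes driven outside the sampler. Observed cells are
never altered — a property the tests check on the monitored draws. Missing
baseline age is not supported (no imputation model is defined for it).

**Diagnostics and model choice.** Convergence is assessed by the
Brooks–Gelman–Rubin potential scale reduction factor (flag threshold 1.1 —
the conventional cutoff; published uses of the diagnostic in this setting
name no number) and a run-length rule requiring the batch-means Monte Carlo error
to be below 5% of the posterior sd. Model comparison uses the
**conditional DIC**: $D(\theta, b) = -2\log p(y \mid b, \theta)$,
$\mathrm{cDIC} = \bar D + p_D$, $p_D = \bar D - D(\hat\theta, \hat b)$,
conditioning on the random effects and on each draw's imputed covariates
(whether to condition on or integrate over the imputations is genuinely
open; conditioning is our documented choice). Differences below 5
support no choice; only differences of roughly 10 or more are treated as a
clear choice. Equal-tail 95% intervals are the 2.5/97.5 empirical
percentiles with linear interpolation; odds-ratio summaries exponentiate
draws *before* averaging.

**Iteration schedules.** The production presets mirror the schedules the
published estimates come from: 20K burn-in/45K iterations for polynomial slope models,
80K/100K for spline and asymptote variants, 250K/250K and 500K/500K for
the skew-normal slope and asymptote models. The package's test suite and
examples use a scaled-down schedule (3 chains, 300–1000 burn-in,
500–2000 monitored draws; 5–300 patients), chosen so the whole suite runs
in minutes while leaving the Monte Carlo error comfortably inside the
tolerances being asserted.

## The synthetic cohort generator

No real cohort is shipped; the generator provides data with the structure
the analysis assumes, plus complete ground truth. Defaults emulate the
target cohort: 750 patients, 6-monthly visits over 5 years, 69.6% female,
baseline age lognormal (median 36, IQR 31–42), baseline CD4 gamma (median
≈ 89, IQR ≈ 43–143; shape 1.504, rate 0.013586), baseline log10 VL normal
(median 5.1, sd 0.62), 49% of post-baseline VLs missing, sporadic missing
baseline covariates, ~3%/visit dropout (dropouts get `in_care = 0`), and
true fixed effects set to the published adjusted polynomial-model
estimates, including the cVL2 effect of −19.6 cells/uL per log10
copy-year/mL.

Choices worth knowing about:

* **Viral-load process.** A two-state Markov chain per visit (suppression
  probability 0.85, rebound probability 0.08, rebound magnitudes
  $10^{U(3,5)}$ copies/mL) — enough to produce nonzero, heterogeneous cVL2
  (median ≈ 0.9, IQR ≈ 0.6–1.5 log10 copy-years/mL at five years, in the
  range real cohorts report), with no pretence of mechanistic viral
  dynamics.
* **The exposure covariate is the measured one.** VL missingness is part
  of the measurement process: the cVL2 that drives the simulated CD4 is
  computed from the visits that actually carry a measurement, using the
  same bridging rule the analysis applies. Computing it from the complete
  series and then deleting VLs would make the analysis covariate a noisy
  proxy of the generative one and turn every recovery test into a test of
  measurement-error attenuation instead of a test of the sampler.
* **Scale of the quadratic term.** The published time and time² estimates
  (55.7, −22.7) only yield a realistic rising-then-flattening trajectory if
  the quadratic term is z-scored (in the published analysis all continuous
  covariates except linear time are standardized). The generator therefore applies the
  time² coefficient on the z-scored $t^2$ over the visit grid; the analysis
  design keeps the raw $(t, t^2)$ basis. The two are an invertible linear
  reparameterization, so the cVL2 coefficient — the target of the recovery
  tests — is unaffected.
* **Truncation at zero.** Simulated CD4 counts below 0 are clamped at 0 and
  counted in the truth record. With the published coefficient scale and
  clinically plausible noise (σ₀ = 70, σ₁ = 25, ρ = −0.2, σ\_ε = 60 —
  within-patient CD4 variability of 50–80 cells/uL is typical) this affects
  roughly 5% of visits, concentrated at low baseline CD4. A Gaussian model
  simply puts real mass below zero there — one of the motivations for the
  skew-normal variants. The clamping is a mild misspecification of the
  Gaussian DGP that the calibration tolerances absorb.
* **Asymptote generator.** Logit-scale truths default to the logs of the
  published odds ratios; the intercept (−8.5, not published) was set once
  so that roughly a third of patients ever cross 500 cells/uL, matching the
  reported cohort, and is asserted only loosely (±15 points) as a realism
  check.
* **Missingness** is MCAR by default; a MAR option makes CD4 missingness
  depend on the previous visit's CD4. MNAR mechanisms are out of scope.

What passing tests on these cohorts shows: the sampler targets the right
posterior (conjugate closed forms, SN→Gaussian reduction), interval
calibration holds at realistic size and missingness, imputation recovers
held-out cells, and cDIC discriminates a real exposure effect. What it does
not show: robustness to the joint covariate dependence, informative
missingness, assay changes and visit irregularity of real clinic data — the
generator reproduces marginals and the model's own structure, not a clinic.

## Numerical and degenerate-input policy

Zero-variance covariates fail standardization explicitly; cohorts emptied
by exclusions raise an error; a BGR statistic over constant identical
chains is defined as 1 (separated constant chains give `Inf`); the MC-error
rule refuses chains too short to batch (< 100 draws); `variance_from_uci`
refuses a CI limit equal to the estimate; the skew-normal density is
computed on the log scale throughout. Posterior summaries use pooled
post-burn-in draws from all chains.

## Known limitations

* The logistic (asymptote) models use JAGS's generic samplers; at
  production schedules they are slow; Bayesian mixed models on cohorts of
  this size are computationally heavy by nature.
* cVL2 under sparse or missing sampling is biased toward whatever the
  bridging rule assumes between observed nodes; denser VL sampling is the
  only cure, and the sensitivity options (detection limit, missing-VL rate
  in the generator) are there to quantify it.
* The cVL1 variant (area under raw VL, logged afterwards), marginal DIC,
  second-line regimens and time-to-event models are deliberately not
  implemented.
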