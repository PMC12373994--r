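---
title: "Quantifying CB1 receptor availability and its symptom correlates: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CB1 receptor availability and its symptom correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`cb1pet` implements, end to end and at desk scale, the quantification and
inference chain used to relate cannabinoid-receptor-1 (CB1R) availability —
measured with [^11^C]OMAR PET as the regional volume of distribution
$V_T$ — to PTSD diagnosis and symptom severity. The chain starts at
region-level time–activity curves (TACs) and arterial blood-sample tables;
image reconstruction, motion correction and atlas registration are upstream
of this package and out of scope. Because individual-level study data are
not publicly available, every stage is exercised against a synthetic-data
generator whose defaults emulate the study cohort: 19 subjects with chronic
PTSD, 27 trauma-exposed controls (TC) and 16 healthy controls (HC), with
the published group-specific sex ratios, age, BMI and CAPS-5 severity
distributions.

# The blood side: metabolite-corrected input function

Tissue kinetics are driven by the arterial plasma concentration of
*unmetabolized* tracer. The package builds this input in three steps.

**Parent fraction.** HPLC measurements at 5, 15, 30, 60, 90 and 120 min
give the fraction of plasma activity still attributable to parent tracer.
These are fitted with a gamma-survival ("inverted gamma") curve

$$p(t) = p_\infty + (1 - p_\infty)\, Q(\alpha, t/\theta),$$

where $Q$ is the regularized upper incomplete gamma function. This family
guarantees $p(0) = 1$, monotone decay, and a free terminal asymptote
$p_\infty \in [0,1]$ — the qualitative behaviour every parent-fraction
curve must have. The exact parameterization used in the original analysis
is not published; the gamma-survival form is our choice, and a monotone
isotonic interpolant is kept as a logged fallback for non-convergent fits.
If per-sample extraction efficiencies are supplied, measurements are
divided by them before fitting. Fitting uses Levenberg–Marquardt
(`minpack.lm`) with box constraints ($p_\infty \in [0,1]$, $\alpha$, $\theta > 0$).

**Plasma curve.** Discrete draws at 3–120 min carry both whole-blood and
plasma activity; the early continuous segment (first 7 min) carries
whole-blood only and is converted to plasma with a constant
plasma-to-whole-blood ratio estimated as the median observed ratio. Where a
continuous and a discrete sample coincide, the discrete sample wins
(assumed better calibrated).

**Correction and integration.** The corrected input is the point-by-point
product $C_p(t_i)\,p(t_i)$ on the merged grid. The resulting
`input_function` object declares its interpolation contract explicitly:
piecewise linear between grid points, zero before the first point, and a
mono-exponential tail fitted to the last three points. Running integrals
$\int_0^t C_p$ — the quantity the kinetic estimators consume — are computed
in closed form under that contract, and integration beyond twice the last
sample time warns that the extrapolation is unvalidated.

# The tissue side: MA1 with t* = 30 min

Ground truth in the simulator is the reversible two-tissue compartment
model

$$\frac{dC_1}{dt} = K_1 C_p - (k_2 + k_3) C_1 + k_4 C_2, \qquad
  \frac{dC_2}{dt} = k_3 C_1 - k_4 C_2,$$

with analytic volume of distribution $V_T = (K_1/k_2)(1 + k_3/k_4)$. TACs
are frame averages of $(1 - v_B)(C_1 + C_2) + v_B C_{wb}$ over a 33-frame,
120-min schedule. The published description fixes only the frame count and
scan length; the default timing (6 × 30 s, 3 × 60 s, 2 × 120 s, 22 × 300 s)
is our choice of a standard early-dense schedule and is configurable.
$v_B$ defaults to 0 since no blood-volume correction is described.

$V_T$ is estimated by multilinear analysis-1 (MA1): for frames with
midpoint beyond $t^* = 30$ min,

$$C_T(t) = -\frac{V_T}{b}\int_0^t C_p(s)\,ds + \frac{1}{b}\int_0^t
  C_T(s)\,ds,$$

fitted by weighted linear least squares (weights proportional to frame
duration by default, configurable to uniform) with
$V_T = -\beta_1/\beta_2$. The tissue integral uses the trapezoid rule over
frame midpoints with activity pinned to zero at $t = 0$. Logan graphical
analysis is implemented solely as an internal concordance check. Estimates
with $V_T \le 0$ are retained with diagnostics but flagged invalid and
excluded from composites. The whole-brain score is the size-weighted mean
of the four lobes and cerebellum; the exact study weights are not
published, so the defaults are approximate AAL relative volumes
(frontal 0.32, temporal 0.23, parietal 0.16, occipital 0.12,
cerebellum 0.17), overridable wherever they enter.

On noiseless simulations across the tracer's physiological $V_T$ range
(0.8–4), MA1 recovers the analytic value to well under 1% and agrees with
Logan to under 2%; both identities are enforced by tests, as are exact
scale equivariances (scaling TAC and input together leaves $V_T$ fixed;
scaling the input alone divides it). Part of the residual error is
intrinsic to the frame-midpoint discretization (frame-average activity
treated as the midpoint value; midpoint trapezoid for the tissue
integral), which is
why very slow kinetics ($k_2 \lesssim 0.08$ with $V_T \gtrsim 5$, outside
this tracer's range) would exceed the 1% figure: the 120-min scan no
longer brackets equilibrium.

# The inference side: Bayesian robust regression

Regional $V_T$ is modelled with a Student-t likelihood to absorb outliers:

$$V_T \sim \mathrm{StudentT}(\mu,\ \nu,\ \varepsilon), \qquad
  \nu \sim \mathrm{InverseGamma}(3, 1), \qquad
  \varepsilon \sim \mathrm{Exponential}(1),$$

with $\mu = X\beta$ and independent $\mathrm{Normal}(0,1)$ priors on every
coefficient. Three design recipes are provided:

* **confounds** — intercept, sex (0 = male, 1 = female), z-scored age,
  z-scored BMI;
* **group** — adds TC and PTSD dummies (HC males the reference) and
  TC×sex, PTSD×sex interactions, eight coefficients in all;
* **symptom** — restricted to the trauma-exposed subjects with CAPS
  scores; one *raw* cluster-severity column (the published slope,
  0.014 $V_T$ per CAPS point, is on the raw scale) plus the confounds.

Z-scores are computed within each model's analysis subset; whether the
original analysis standardized over the full sample is ambiguous, and the
subset convention keeps each model self-contained.

Sampling uses JAGS with the `glm` samplers, fitting the likelihood through
its exact scale-mixture-of-normals representation
($y_i \mid \lambda_i \sim \mathrm{N}(\mu_i, \varepsilon^2/\lambda_i)$,
$\lambda_i \sim \mathrm{Gamma}(\nu/2, \nu/2)$), which block-updates the
coefficients and mixes far better than direct t-likelihood slice sampling.
Four chains are run (at least two are required for split diagnostics; the
original chain count is unpublished), each with 1000 adaptation/tuning
iterations and 1000 retained draws, no thinning, matching the published
sampler settings; the 80% target-acceptance parameter is specific to
Hamiltonian samplers and has no analogue here.

**Decision rule.** A coefficient is *robust* exactly when its 89% highest
posterior density interval — the shortest contiguous interval containing
89% of the draws — excludes zero. **Convergence gate.** A fit is
`converged` only if every regression coefficient has split-$\hat R < 1.01$
and effective sample size $> 1000$ (Geyer initial-monotone estimator over
split chains). The gate is applied to the coefficients — the quantities the
report tables and the decision rule consume; $\nu$ and $\varepsilon$
diagnostics are reported alongside but do not gate, because under the
deliberately heavy-tailed $\mathrm{InverseGamma}(3,1)$ prior (mean 0.5,
concentrated on very small degrees of freedom) $\nu$ mixes slowly in any
sampler while leaving the coefficient posteriors unaffected. That prior is
implemented exactly as published; a $\mathrm{Gamma}(2, 0.1)$ alternative is
available behind `nu_prior = "gamma"` for sensitivity analyses, off by
default.

The model suite mirrors the study's three report tables: confound models
over amygdala, hippocampus, frontal cortex and whole brain; group models
over the same regions; and 13 separate symptom models (CAPS total, four
DSM-5 clusters, eight factor-model clusters) on whole-brain $V_T$. A
failing cell is marked and the suite continues.

# The synthetic-data generator

The generator is first-class, tested code: it defines the conditions every
downstream claim is tested under.

* **Demographics** use the published group sizes, male fractions (9/16,
  25/27, 10/19) and age/BMI means and SDs; ages are floored at 18 and BMI
  at 15 (truncation effects are negligible at the published SDs).
* **CAPS-5 scores** are generated bottom-up: eight factor-model cluster
  scores from a correlated ($\rho = 0.6$) multivariate normal with means
  proportional to a fixed weight vector, rounded and floored at zero; the
  four DSM-5 clusters and the total are *sums* of these, so
  cluster/total consistency is exact. Only group totals are published;
  the weights and correlation are our choice of a realistic structure.
* **True V_T** is regional baseline (1.15–1.45, the tracer's cortical
  range) plus configured linear effects plus a shared subject-level
  Student-t (5 df) residual of scale 0.12 $V_T$ and a small independent
  regional residual (scale/3). The default effect map plants only the
  anhedonia/emotional-numbing slope of 0.014 $V_T$ per point. Gross
  outlier contamination (residual shifted by 5–10 scales) is available via
  `outlier_fraction`, default 0, and is exercised by the
  robustness-versus-OLS tests.
* **Blood and TACs**: a Feng-type arterial model (linear upslope into
  tri-exponential decay) with plausible constants for a [^11^C] bolus —
  the study's plasma-curve shape is unpublished — and TAC noise that is
  Gaussian with SD $\propto \sqrt{\mathrm{activity}/\mathrm{frame\
  duration}}$, the standard count-statistics surrogate.

What the generator does **not** emulate: spill-over and partial-volume
effects, dispersion/delay mismatch between blood detector and tissue,
residual motion, violations of the constant plasma-to-whole-blood ratio,
and any nonlinearity between symptom severity and receptor availability.
Passing tests therefore demonstrate that the chain is *internally* correct
and well calibrated under its stated assumptions, not that those
assumptions hold in real data.

# Calibration and problem sizes

The test suite checks, among others: parameter recovery of the planted
slope on a 500-subject trauma-exposed cohort at low residual noise
(posterior mean within 0.004 of 0.014, HPD excluding zero); a
near-noiseless identifiability limit (slope 0.5 on z-scored age recovered
within 0.02 — the residual is set tiny rather than exactly zero because a
literally degenerate likelihood has no finite log-density); and the false
positive rate of the robustness rule under a null cohort of the study's
size (200 replicates, n = 62), which should sit near the nominal 11% of an
89% interval. These sizes were chosen as the smallest that make the
Monte-Carlo error comfortably smaller than the tolerances.

# Known limitations

* The MA1 discretization follows the frame-midpoint convention throughout;
  finer late frames would reduce its (already sub-percent) bias.
* The constant plasma-to-whole-blood ratio is a simplification; a
  time-varying ratio would require modelling red-cell uptake.
* The HPD interval assumes a unimodal posterior; for multimodal posteriors
  the shortest *contiguous* interval is reported, matching the published
  definition but not necessarily the highest-density region.
* Group-level inference tables on the synthetic cohort are structural
  mirrors of the published tables, not reproductions: the individual-level
  data behind the published coefficients are not public.
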