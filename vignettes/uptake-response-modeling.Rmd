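---
title: "Modelling tumor kill fractions from nanoparticle uptake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tumor kill fractions from nanoparticle uptake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msnpkill)
```

## The problem

Mesoporous silica nanoparticles (MSNPs) carry chemotherapy into tumors, but
their biodistribution is heterogeneous: two animals under the same protocol
can accumulate very different particle loads in the tumor, and that load —
not the nominal dose — is what the cancer cells see. `msnpkill` implements a
small pharmacodynamic pipeline that links the measured particle load
(quantified as elemental silicon, because mammals contain almost no natural
Si) to the observed treatment response in preclinical tumor growth studies,
so that uptake measurements become quantitative predictors of efficacy.

## The response model

For a treated subject $i$ with volume series $V_i(t)$ and a control
reference $V_C(t)$, the fraction of tumor killed by treatment is

$$f_{\mathrm{kill}}(t) \;=\; 1 \;-\;
  \frac{V_i(t)\,/\,V_i(t_0)}{V_C(t)\,/\,V_C(t_0)},$$

with $t_0$ the day treatment starts. Normalizing both series to their
value at $t_0$ cancels the absolute scale: `compute_fkill()` is invariant
under rescaling all volumes by a common factor, and $f_{\mathrm{kill}}(t_0)$
is 0 by construction. Negative values — the treated tumor outgrowing the
control reference — are retained in the series (they are informative about
when the response begins) but never enter the quadratic fit below.

The control reference defaults to the per-day mean of the control group
(`control_reference()`); the underlying study designs compare groups, not
matched pairs. A specific reference animal can be passed instead.

When nanoparticles release drug at a nearly constant rate, the early-phase
response is quadratic in time:

$$f_{\mathrm{kill}} \;=\; \theta_f\,(t - t_0)^2,
  \qquad
  \theta_f \;=\; \frac{F\,\lambda_k}{2\,V_{T,0}},$$

where $F$ is the drug flux across vessel walls, $\lambda_k$ the
per-unit-drug cell death rate, and $V_{T,0}$ the tumor volume at response
onset. The data identify only the combination $\theta_f$ (units 1/day²);
`mechanistic_theta()` evaluates the decomposition in the forward direction
for consistency checks but nothing in the package attempts to separate the
three factors.

### Fitting $\theta_f$ and the onset day

`fit_kill_curve()` fits the quadratic law per subject. Design choices, all
of which were genuinely open:

* **Onset grid.** $t_0$ is searched over the *integer measurement days* of
  the series except the last two, so at least two post-onset points remain.
  Onsets between measurement days are not interpolated: with 5 measurement
  days per animal the data cannot resolve sub-day onsets, and an integer-day
  onset is the convention the coefficients in the packaged fixture use.
* **Zero-intercept regression.** The law forces $f_{\mathrm{kill}}(t_0)=0$,
  so $\theta_f$ is the no-intercept least-squares slope of
  $f_{\mathrm{kill}}$ on $(t-t_0)^2$; points with
  $f_{\mathrm{kill}} \le 0$ after the candidate onset are dropped (the
  derivation of the law presumes a positive response), and the candidate
  minimizing the residual sum of squares wins. Ties within $10^{-12}$
  relative RSS go to the earliest onset — the deterministic, biologically
  conservative choice.
* **Eligibility.** A fit supported by fewer than 3 positive post-onset
  points gets no $R^2$ or p-value and is flagged ineligible;
  `filter_eligible()` removes such subjects before the cross-subject fit.
  In the packaged seven-mouse fixture exactly two late responders (first
  response on day 7 of a 9-day experiment, hence two points) are excluded
  this way.
* **Fit statistics.** $R^2 = 1 - \mathrm{SSR}/\mathrm{SST}$ with SST taken
  about the mean of the fitted points, floored at 0 (a zero-intercept fit
  can do worse than the mean; an about-zero SST convention exists and gives
  systematically higher values, so comparisons across software must check
  the convention). The p-value is from the F-test of the zero-intercept
  quadratic against the zero model on $(1, n-1)$ degrees of freedom — the
  closest standard test, since no canonical choice exists for this design.

## The uptake–response law

Across subjects, the kill coefficient rises exponentially with tumor Si
content (absolute mass percent, so `0.00372` means 0.00372 %; the package
never silently converts to fractions):

$$\theta_f \;=\; A\,e^{B\cdot Si}.$$

`fit_uptake()` estimates $(A, B)$ by least squares **on the untransformed
$\theta_f$ scale**. This is a deliberate and consequential choice: on the
packaged five-mouse fixture the $\theta$-scale fit gives $R^2 = 0.817$
while least squares on $\log\theta$ (equivalently, the initializer below)
gives $R^2 = 0.66$ on the $\theta$ scale. The $\theta$-scale loss weights
the high-uptake, high-response animals by their absolute residuals, which
is appropriate when the quantity of scientific interest is $\theta_f$
itself.

Numerics:

* The optimizer is a Levenberg-damped Gauss–Newton iteration with the
  analytic Jacobian, initialized at the closed-form log-linear regression
  of $\ln\theta$ on Si. It never accepts a step that increases the RSS, so
  the solution is at least as good as the initializer — an invariant the
  test suite asserts on every fit.
* The raw $(A, B)$ parameterization is numerically hostile: $A$ is of
  order $10^{-5}$ while $B$ is of order $10^3$, giving a normal matrix
  with condition number near $10^{15}$. Internally the fit therefore runs
  in standardized coordinates $u = (Si - \bar{Si})/s_{Si}$, fitting
  $\theta = C e^{Du}$, and maps back ($B = D/s_{Si}$,
  $A = C e^{-D\bar{Si}/s_{Si}}$), with the covariance transformed by the
  delta method. This is invisible to the user and makes the fit
  equivariant under Si unit changes to near machine precision.
* Convergence: relative RSS change below $10^{-12}$, cap of 500
  iterations; a stall under damping is accepted as a stationary point.
  Degenerate flat data ($\theta$ constant) are handled by the same path
  and return $B \approx 0$.
* Standard errors come from the usual asymptotic NLS covariance
  $\hat\sigma^2 (J^\top J)^{-1}$. At $n = 5$–$7$ subjects these intervals
  are wide and only approximately calibrated; a simulation in the test
  suite (200 synthetic cohorts of 7) checks that 95 % t-intervals cover
  the generative truth at least 80 % of the time, documenting — not hiding
  — the small-sample fragility.

On the five eligible fixture mice the fit returns $A \approx 1.8\times
10^{-5}$, $B \approx 1664$, $R^2 = 0.817$. A one-dimensional profile check
(closed-form conditional $A$ at fixed $B$ over a $B$ grid) confirms the
optimizer sits at the global RSS minimum. Note that the slope $B$ and the
$R^2$ are the stable, reproducible summaries of this fit; the intercept
$A$ is strongly anticorrelated with $B$ and poorly determined at this
sample size, so externally quoted values of $A$ for comparable data sets
need not agree with the conditional least-squares value.

Predictions chain the two laws:
`predict_fkill_series()` evaluates
$\hat f_{\mathrm{kill}}(t) = \hat A e^{\hat B\,si}(t - t_0)^2$, capped at 1
(flagged when the cap binds), and `validate_predictions()` pools
observed/predicted pairs over strictly post-onset days across subjects and
reports the Pearson correlation with its t-based p-value, plus per-subject
correlations. Pooling across subjects is the declared convention; the
per-subject table is there so users can check it is not driven by one
animal.

## GFAA quantification and delivery efficiency

Tissue Si is measured by graphite furnace atomic absorption with the
standard-additions method: each sample is spiked with known Si increments,
the signal regressed on the addition, and the native concentration read
off the x-intercept, $\hat c = b/m$. This cancels matrix effects that
scale the signal. The reported SD uses the standard x-intercept formula

$$s_c = \frac{s_{y/x}}{m}\sqrt{\frac{1}{n} +
  \frac{\bar y^2}{m^2\sum_i (x_i-\bar x)^2}}.$$

`standard_additions()` is exact (zero residual, zero SD) on any noiseless
affine curve, refuses non-increasing curves, and carries the addition
concentration unit through unchanged — no implicit µg/mL assumption. A
single user-supplied dilution factor, not a guessed digestion protocol,
is the intended bridge from digest concentrations to tissue mass percent.

Delivery efficiency converts a background-subtracted tissue Si mass
percent to percent of injected dose:

$$\%ID = 100 \times
  \frac{(\text{net Si \%}/100)\times m_{\text{organ}}}
       {f_{Si}\times m_{\text{dose}}\times n_{\text{doses}}},$$

with $f_{Si} = 0.3936$ (the Si mass fraction of the particle) by default,
giving 1.5744 mg injected Si for the default 1 mg × 4 doses. Organ
reference masses are configuration, not data: the packaged defaults
(tumor 0.5 g, liver 1.0 g, spleen 0.1 g, kidney 0.3 g) are representative
BALB/c-scale stand-ins shipped for reproducibility and meant to be
overridden with strain tables or measured masses. Measurements below the
control baseline are kept and flagged (`below_baseline`) but contribute 0
to %ID — physical non-negativity without destroying information.

## The synthetic cohort generator

No per-animal raw volumes ship with the package, so validation rests on
`simulate_cohort()`, which generates data with exactly the structure the
analysis assumes:

* controls grow exponentially, $V_C(t) = V_0 e^{gt}$, times lognormal
  measurement noise. The kill fraction construction cancels whatever the
  true control law is, so any positive growth law would do; exponential is
  realistic for aggressive syngeneic tumors over ~9 days and admits
  closed-form checks.
* each treated subject draws a tumor Si value uniformly, maps it through
  $\theta = A e^{B\cdot Si}$ with lognormal spread, draws an integer onset
  day, and follows
  $V_i(t) = V_0 e^{gt}\,[1 - \min(\theta (t-t_0)^2, 0.99)]$ after onset
  (control kinetics before), noise applied last. The 0.99 cap keeps
  volumes positive and is a generator artifact, not a model claim.
* GFAA curves are linear in the addition with Gaussian signal noise;
  biodistribution values for liver/spleen/kidney are drawn independently
  of the tumor value, encoding the absence of inter-organ uptake
  correlation.
* one global seed drives deterministic per-subject seeds, so the same
  cohort (or any subject subset) regenerates bit-identically.

With all noise set to zero the generator and analyzer are exact inverses:
`compute_fkill()` returns $\theta_i(t-t_0)^2$ on the nose and both fitting
stages recover the latent parameters to $10^{-8}$ relative error. That
property, plus agreement with brute-force oracles on 1 000 seeded noisy
instances, is what the test suite leans on.

`table1_like_cohort()` fixes the defaults at the scale of the motivating
study: 7 mice per group, measurement days 0/3/7/8/9, ~500 mm³ tumors at
treatment start, Si in [0.001, 0.006] mass %, and an uptake law
($A = 6\times10^{-4}$, $B = 470$) chosen so the implied $\theta_f$ range
spans [0.001, 0.01] /day² — the range observed in eligible animals. The
growth rate 0.12/day (volume doubling ≈ 6 days) is typical for 4T1
xenografts; volume noise $\sigma = 0.08$ reflects caliper measurement
repeatability, and $\sigma = 0.2$ lognormal spread around the uptake law
reflects the biological scatter visible in small cohorts.

What the generator does **not** emulate — and therefore what passing
recovery tests cannot certify about real data: drug pharmacokinetics,
immune involvement, inter-animal growth-rate heterogeneity, onset days off
the measurement grid, non-lognormal outliers, and any real correlation
structure between organs. The generator tests the *pipeline*, not the
biology.

## Problem sizes and runtime choices

Validation in the test suite uses 1 000-instance oracle comparisons for
the two closed-form fits, 200 replicates of 50 subjects for slope
recovery at realistic noise (median $|\hat B - B^*|/B^*$ below 10 %), and
200 end-to-end cohorts of 7 for interval coverage. These sizes give stable
pass/fail behaviour at a few seconds each while staying far from Monte
Carlo noise on the assertions.

## Known limitations

* The per-subject $R^2$/p conventions for zero-intercept quadratic fits
  are not universal; values computed here are internally consistent but
  not automatically comparable with other software's conventions.
* $A$ and $B$ are strongly anticorrelated at small $n$; treat $B$ and
  $R^2$ as the transferable quantities.
* Onset days are restricted to measurement days; a response beginning
  between visits biases $\theta_f$ slightly upward.
* %ID depends linearly on the organ reference masses; with configured
  rather than measured masses it inherits their uncertainty wholesale.
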