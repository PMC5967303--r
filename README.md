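# msnpkill

Tumor kill-fraction modelling from nanoparticle uptake.

`msnpkill` is for preclinical researchers who measure two things on the
same animals — tumor volume time courses under nanoparticle-delivered
chemotherapy, and how much of the particle actually reached the tumor —
and want a quantitative link between them. Particle accumulation is
quantified as elemental silicon (mesoporous silica nanoparticles are
~39 % Si by mass and mammals carry almost none naturally), measured by
graphite furnace atomic absorption (GFAA) with the standard-additions
method.

## The model

For a treated subject *i* with volume series *V<sub>i</sub>(t)* and a
control reference *V<sub>C</sub>(t)* (the control-group per-day mean),
the fraction of tumor killed is

> f_kill(t) = 1 − [V_i(t)/V_i(t₀)] / [V_C(t)/V_C(t₀)]

Under sustained drug release the early response is quadratic in time,

> f_kill = θ_f · (t − t₀)²,  with  θ_f = F·λ_k / (2·V_T,0),

where t₀ is the onset day, F the drug flux across vessel walls, λ_k the
cell death rate and V_T,0 the tumor volume at onset. Per subject,
`fit_kill_curve()` estimates (θ_f, t₀) by zero-intercept least squares
with t₀ optimized over the integer measurement-day grid; subjects whose
response begins too late to leave 3 positive points are flagged
ineligible. Across subjects, `fit_uptake()` fits the exponential
uptake–response law

> θ_f = A · exp(B · Si)

by nonlinear least squares on the θ scale (Levenberg-damped
Gauss–Newton, log-linear initialization), where *Si* is the tumor's Si
content in absolute mass percent. `standard_additions()` and
`delivery_efficiency()` handle the GFAA calibration and percent-injected-
dose (%ID) arithmetic, and `simulate_cohort()` generates synthetic
cohorts with known ground truth for validating the whole pipeline.

## Worked example

The package ships the published seven-mouse summary (tumor Si content and
per-mouse quadratic coefficients) as a fixture. Fitting the uptake law to
the five eligible mice:

```r
library(msnpkill)

fx   <- load_table1_fixture()
keep <- filter_eligible(fx$fits)$retained   # MSNP 4 and 7 excluded (2-point fits)
fit  <- fit_uptake(keep$si_mass_percent, keep$theta_f)
summary(fit)
#> Exponential uptake-response law: theta_f = A * exp(B * Si)
#>
#>     Estimate Std. Error t value Pr(>|t|)
#> A 1.7622e-05 6.4932e-05  0.2714   0.8037
#> B 1.6644e+03 1.0102e+03  1.6476   0.1980
#>
#> Residual SE 0.001646 on 3 df;  R^2 (theta scale) = 0.8170;  n = 5 (gauss-newton)
```

So a mouse whose tumor Si rises by ln(2)/B ≈ 0.0004 mass % doubles its
kill coefficient; the exponential explains 82 % of the θ_f variance
across animals (the straight-line baseline explains far less). Note the
wide standard errors: at n = 5 the slope B and the R² are the stable
summaries, not the intercept A.

The same pipeline end to end on a synthetic cohort, including GFAA
quantification, %ID and observed-vs-predicted validation:

```r
d <- run_demo(out_dir = "demo-out", seed = 1)
d$validation
#> Observed vs predicted f_kill: r = 0.823 (p = 9.13e-05, 16 pooled pairs)
head(d$gfaa$percent_id[d$gfaa$percent_id$organ == "tumor", ], 3)
#>  subject_id organ net_si_mass_percent percent_id below_baseline
#>      MSNP 1 tumor         0.004458991  1.4160920          FALSE
#>      MSNP 2 tumor         0.003344402  1.0621195          FALSE
#>      MSNP 3 tumor         0.003786625  1.2025613          FALSE
```

The `percent_id` column is the share of the injected Si dose (1.5744 mg
under the default 1 mg × 4 doses configuration) recovered in each organ
after baseline subtraction. A thin command-line wrapper with
`simulate` / `fit-response` / `fit-uptake` / `gfaa` / `demo` subcommands
is installed at `system.file("cli", "msnpkill.R", package = "msnpkill")`.

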