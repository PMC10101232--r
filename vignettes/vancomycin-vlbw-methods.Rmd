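---
title: "Methods: population pharmacokinetics and dosing of vancomycin in VLBW neonates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population pharmacokinetics and dosing of vancomycin in VLBW neonates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vancneo)
```

## The model

Vancomycin disposition in very-low-birth-weight (VLBW, < 1,500 g) neonates
is described by a one-compartment model with zero-order intravenous
infusion and first-order elimination,

$$\frac{dC}{dt} = \frac{R_\mathrm{in}(t)}{V} - \frac{Cl}{V}\,C,$$

solved in closed form by superposition of infusion terms.  Typical
parameters are functions of three covariates — current body weight,
postmenstrual age (PMA) and serum creatinine (Scr, Jaffe scale):

$$V = 0.81 \left(\frac{WT}{0.93}\right), \qquad
Cl = 0.09 \left(\frac{WT}{0.93}\right)^{0.75}
\left(\frac{0.6}{Scr}\right)^{0.48}
\frac{PMA^{4.42}}{PMA^{4.42} + 26.3^{4.42}}.$$

The allometric exponents (0.75 on Cl, 1 on V) are fixed constants, never
estimated.  The sigmoidal (Hill) factor describes renal maturation:
clearance is 50% of its mature value at `tma50 = 26.3` weeks PMA and
saturates toward 1; `cl_ref = 0.09` L/h is therefore the *mature-limit*
clearance at the reference covariates (0.93 kg, Scr 0.6 mg/dl).  We note
that at PMA 26 weeks the same equation gives a typical clearance of about
0.044 L/h; the published "typical Cl" estimate
is interpreted here as the mature-limit coefficient of the printed
equation, because only that reading reproduces the printed exposure
simulations even approximately.

Interindividual variability is lognormal, $p_i = p\,e^{\eta_i}$ with
$\eta \sim N(0, \omega^2)$, $\omega_{Cl} = 0.28$, $\omega_V = 0.24$
(standard deviations of log-parameters, the usual pharmacometric reading of
"IIV 28%/24%").  Residual error is proportional,
$y = f\,(1 + b\,\varepsilon)$ with $b = 0.3$; constant and combined error
models are available as configuration options.

Creatinine measured by an enzymatic assay is converted to the Jaffe scale
once, before modelling: `jaffe = 0.122 + enzymatic / 1.05`.

### Exposure metrics

For linear elimination the steady-state 24-hour area under the curve is
the time-averaged identity $AUC_{0\text{-}24} = (24/\tau)\,D/Cl$ (dose $D$
in mg, interval $\tau$ in h).  We use this identity for every interval,
including $\tau = 18$ h where no single 24-h window tiles the dosing cycle
— the time-averaged quantity is what AUC-based dosing targets mean.  The
trough is the steady-state concentration at the end of the interval
(geometric-series accumulation, not long simulation; long simulation is
retained as a test oracle).  The "peak" follows the therapeutic drug
monitoring convention — 1 h after the end of the infusion — not the
within-interval maximum.  Infusion duration is a site practice rather than a model parameter; we
default to 1.0 h (common neonatal practice) and make
it configurable per regimen.

## The virtual cohort

`sample_cohort()` draws weight, PMA and Scr from truncated-normal
marginals (weight 1.0 ± 0.29 kg on 0.46–2.2 kg; PMA 30.0 ± 3.2 weeks on
22–42; Scr 0.64 ± 0.22 mg/dl on 0.2–1.2) joined by a Gaussian copula with
corr(weight, PMA) = 0.7, corr(weight, Scr) = 0, corr(PMA, Scr) = −0.2.
Only the marginals are reported for the real cohort; the correlations are
this package's choice (weight tracks maturation in neonates; creatinine
falls slowly with advancing age) and are configurable.  Latent parameters
are moment-matched so the *truncated* marginals hit the target mean and
sd; out-of-range draws are rejected and redrawn rather than clipped, so
the bounds carry no probability atoms.  Postnatal age is uniform on 1–30
days, gestational age is `pma − pna/7`, and birth weight is
back-calculated from current weight assuming 0.2%/day net gain — this
reproduces an extremely-low-birth-weight (< 1 kg) share near the study's
58%.

Dosing follows the tabulated reference policies (NeoFax by PMA × PNA;
Lexicomp age-directed; Lexicomp kidney-function-based by GA × Scr, with
Scr rounded to one decimal, the table's own resolution).  Where a
reference prints a dose range (10–15 mg/kg) the configured point dose
(default 15) is used.

Sampling emulates sparse steady-state therapeutic drug monitoring: one
trough 30 min before a dose once the subject is at steady state, a second
sample for 32% of subjects (reproducing ≈ 214 observations from 162
subjects), and a peak in place of a second trough for 10% of those — peak
sampling was a single-site practice with no recorded frequency, so this is
a configurable default.  **Steady state is defined as the later of five
*typical* (population-predicted) half-lives and 72 h of dosing.**  We
deliberately use the typical rather than the individual half-life: if
sampling times depended on a subject's own random effects they would
themselves carry information about $\eta$ that the standard marginal
likelihood ignores, and we verified in simulation that such informative
sampling times bias the volume estimate upward severalfold.  Clinically,
nobody knows an individual half-life before the first level is drawn, so
the typical-time rule is also the realistic one.

What the generator does *not* emulate: hospital-specific assay biases,
within-course changes of weight or creatinine (covariates are frozen at
baseline), and non-adherent or irregular dosing.  Passing tests therefore
demonstrate correctness of the machinery under the stated design, not
robustness to those real-data features.

## Estimation

`fit_population()` maximises an approximate marginal likelihood.  Per
subject the joint mode of $(\eta_{Cl}, \eta_V)$ is found by a damped
Newton iteration (analytic gradients of the superposition solution,
finite-difference curvature), vectorised across subjects; the marginal is
then the Laplace approximation or, by default, its adaptive Gauss–Hermite
refinement (5 nodes per dimension, centred and scaled at the mode), which
we verified against brute-force two-dimensional quadrature to about one
OFV point on full datasets.  The outer problem is bounded quasi-Newton
(PORT) on log-transformed positive parameters, with wide physiological
plausibility bounds (e.g. half-maturation PMA in 12–50 weeks), restarts
on "false convergence", an L-BFGS-B polish, and an explicit endpoint
gradient check.  Convergence tolerance is 1e-8 on the relative objective
change; the inner mode is solved to a gradient of 1e-9 so the outer
objective is smooth to near machine precision.

With 1–2 samples per subject some structure is simply not estimable, and
the package's defaults reflect that:

* the Hill coefficient sits on a nearly flat ridge with `cl_ref` and
  `tma50` (two maturation curves agreeing on the observed 22–42-week
  window can differ substantially in their mature limit).  The recovery
  experiments therefore fix `hill` at its published value; the API allows
  estimating it.
* the volume of distribution is informed only weakly by troughs (its
  trough elasticity is ≈ +0.5 against −1.5 for clearance, nearly
  collinear); peaks carry most of the V information.  Its uncertainty is
  honest — expect the widest intervals on `v_ref`.
* interoccasion variability and an $\eta$ covariance are not modelled
  (diagonal $\omega$), matching the reported model.

Empirical Bayes estimates are conditional modes; the reported OFV is
$-2\log$ marginal likelihood, and nested models are compared by
`lrt_step()` with a $\chi^2$ test at p < 0.05 (forward inclusion /
backward elimination order is a workflow convention, not part of the
model; the package
exposes the single step as the primitive).  Uncertainty comes from a
nonparametric subject bootstrap (default) or the observed-information
("fisher") approximation; the adequacy yardstick for a fixed effect is a
relative standard error below 30%.

## Diagnostics

The visual predictive check simulates the dataset's own design (default
1,000 replicates) and compares observed 10th/50th/90th percentiles per
bin with 90% confidence bands of the same percentiles across replicates.
Because the design is sparse and dose-interval-aligned, bins are nominal
sampling occasions (trough/peak × interval), not raw clock time; bins
with fewer than five observations are merged with a warning.  The
normalized prediction distribution errors follow the standard
decorrelated-rank construction (simulated within-subject covariance,
Cholesky decorrelation, rank → normal score, seeded uniform tie-breaking;
singular covariances are ridge-regularised with a warning) and are tested
against N(0, 1) with Shapiro–Wilk, a reasonable default at these sample
sizes.  With one observation per subject the NPDE reduces to the normal
score of the observation's rank among its simulations.

A calibration remark: with ~200 validation observations the NPDE mean has
standard error ≈ 0.07 under a perfectly calibrated model, so "mean within
±0.1" holds in only about 84% of replicates even when everything is
correct.  The calibration suite reports this check as specified, but a
miss there reflects the sample size, not necessarily the model.

## Dosing simulation

`simulate_population()` tiles the cohort (default 40×, mirroring the
replicate-the-dataset approach: 40 × 236 = 9,440), draws fresh random
effects per virtual subject, and evaluates the regimen grid (10–20 mg/kg
in 2.5 steps, every 6/8/12/18/24 h) in closed form; the same virtual
subject is pushed through every regimen.  `pta_table()` stratifies by PMA
(≤ 29 / > 29 weeks) and Scr (< 0.6, 0.6–0.9, > 0.9–1.2 mg/dl; edges
resolved as [min, 0.6), [0.6, 0.9], (0.9, max]; the conventional
“0.6–0.9” band notation is ambiguous at 0.9, so the edges are
configurable) and reports means, sds and
attainment percentages for AUC 400–600 and 400–800 µg·h/ml, AUC > 800,
trough > 15 and > 20 µg/ml, and the combined toxicity proxy
P(AUC > 800 or trough > 20).  The MIC is fixed at 1 µg/ml so AUC/MIC
≡ AUC.  `recommend_dose()` applies a target policy (narrow band in > 60%
of subjects, or wide band in > 80%, toxicity < 10%), breaking ties by
highest band attainment, then lowest P(trough > 15), then lowest daily
dose; a subgroup where nothing qualifies is reported as such with the
best achieved attainment.

A quantitative caveat worth stating plainly: with $\omega_{Cl} = 0.28$
the AUC given covariates is lognormal with log-sd ≥ 0.28, so even a
perfectly centred regimen cannot exceed ≈ 53% attainment of the 400–600
band, and within-subgroup covariate spread lowers the ceiling to
≈ 45–50%.  Under this model no regimen clears a 60% floor; published
attainment figures above that level imply less dispersion than the
model's own variance components generate.  The recommendation engine
reports what the model supports.

## Numerical choices and problem sizes

Closed-form kinetics are validated against Runge–Kutta integration
(0.1%) and trapezoidal AUC (0.5%, 0.01-h grid).  Gauss–Hermite nodes come
from the Golub–Welsch eigenvalue construction.  All randomness flows from
explicit integer seeds; no stage reads the clock.  The calibration and
recovery experiments shipped with the package use sizes chosen to make
their Monte Carlo error small relative to the tolerances they check:
240,000 virtual subjects (≥ 10,000 per subgroup) for the exposure table,
20 replicate studies of 162 subjects for parameter recovery with a
40-resample subject bootstrap for RSEs, 50 replicates for NPDE
calibration, and 200 replicates for the likelihood-ratio type-I error.

## Known limitations

* One compartment, linear elimination only; no Michaelis–Menten or
  two-compartment alternatives, no oral route, no loading-dose design.
* The model is built for Scr ≤ 1.2 mg/dl; it does not apply to neonates
  in renal failure.
* Covariate correlations in the virtual cohort are assumptions; real
  joint covariate distributions (and hence subgroup exposure summaries)
  may differ from the synthetic ones.
* `v_ref` is weakly identified by trough-dominated designs; treat its
  point estimate from such data with the bootstrap interval, not alone.
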