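---
title: "Methods: a three-compartment saturable-resorption model for PFAS dosimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a three-compartment saturable-resorption model for PFAS dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfastk)
```

## The model

Per- and polyfluoroalkyl substances (PFAS) such as PFOS, PFOA and PFHxS
are eliminated in urine, but extraordinarily slowly: serum half-lives in
humans run to years, and shorten at high doses. The mechanism behind both
observations is saturable renal resorption — filtered chemical is pumped
back from the renal filtrate into blood by a transporter that saturates.
`pfastk` implements a three-compartment model built around that
mechanism:

* a **central compartment** (volume $V_c = VCC \cdot BW$), whose total
  concentration $C_{prim} = A_{prim}/V_c$ is the serum observable;
* a **deep compartment** exchanging with the central one by first-order
  rates $k_{12}$, $k_{21}$ (tracked in amounts; its anatomical volume is
  irrelevant to serum dynamics and carries no parameter);
* a **filtrate compartment** (volume $V_{fil} = VfilC \cdot BW$) fed by
  filtration of the free fraction, $Q_{fil} \cdot Free \cdot C_{prim}$,
  and drained by urinary outflow $Q_{fil} C_{fil}$ and by
  Michaelis–Menten resorption $T_m C_{fil} / (K_t + C_{fil})$ back to the
  central compartment;
* a **gut compartment** for oral dosing, absorbed at rate $k_a$ with
  bioavailability $bioAv$ (the unabsorbed fraction is an explicit sink so
  the mass balance closes exactly).

The state equations are

$$
\begin{aligned}
\dot A_{gut} &= r_{oral}(t) - k_a A_{gut} \\
\dot A_{prim} &= bioAv\, k_a A_{gut} + k_{21} A_{deep} - k_{12} A_{prim}
  - Q_{fil}\, Free\, \frac{A_{prim}}{V_c}
  + \frac{T_m C_{fil}}{K_t + C_{fil}} \\
\dot A_{deep} &= k_{12} A_{prim} - k_{21} A_{deep} \\
V_{fil}\dot C_{fil} &= Q_{fil}\, Free\, \frac{A_{prim}}{V_c}
  - Q_{fil} C_{fil} - \frac{T_m C_{fil}}{K_t + C_{fil}}
\end{aligned}
$$

with cardiac output $QC = QCC \cdot BW^{0.74}$, filtrate flow
$Q_{fil} = QfilC \cdot QC$ and maximum resorption rate
$T_m = Tmc \cdot BW$. Bolus doses enter as impulses (oral to the gut, IV
to the central compartment); population exposure enters as a continuous
oral rate. Units are mg and mg/L (≡ µg/mL) internally; ppb (µg/L)
conversions happen only at the biomonitoring interface.

Both the unbound-fraction placement (only the filtration flux is scaled
by $Free$; serum observations are total concentration) and the
administered-dose convention in dosimetry (doses are pre-bioavailability)
are pinned down by requiring the model to reproduce the published human
PFOA reverse-dosimetry table exactly; see the acceptance checks.

## Parameters

Chemical-specific parameters (`chemical_params()`): `bioAv` (–), `VCC`
(L/kg), `Tmc` (mg/h/kg), `Kt` (mg/L), `Free` (–), `k12`, `k21`, `ka`
(1/h). Physiology (`physio_params()`): `BW` (kg), `QCC` (L/h/kg^0.74),
`QfilC` (–), `VfilC` (L/kg). Published sets for PFOS, PFOA and PFHxS in
cynomolgus monkeys (~5 kg, QCC 19.8) and scaled humans (70 kg, QCC 12.5)
ship as JSON fixtures, `tk_params("pfoa_human")` etc. The parameters that
matter most for dosimetry are `Free` and the resorption pair
$(T_m, K_t)$: in the sub-saturating regime only the ratio $T_m/K_t$
enters the clearance
$CL = Q_{fil}^2\, Free / (Q_{fil} + T_m/K_t)$, which is why `Free` and
the resorption parameters cannot be estimated jointly (their collinearity
index is in the hundreds of thousands) and `Free` is fixed from protein
binding assays.

## Numerical design

The filtrate equation is stiff: $V_{fil} \approx 4\times10^{-4}$ L/kg
gives it a sub-second relaxation time against elimination times of
months. `simulate_tk()` therefore defaults to LSODA on the full
four-state system through a compiled right-hand side (`engine = "c"`),
with `rtol = 1e-8`, `atol = 1e-10`. Three alternative engines exist and
are cross-checked in the tests:

* `"qss"` replaces $C_{fil}$ by the positive root of its algebraic
  balance (it relaxes within seconds, so the quasi-steady-state error is
  far below solver tolerance at observation time scales), removing the
  stiffness;
* `"ros"` integrates the same reduced system with a compiled L-stable
  Rosenbrock(2,3) scheme whose event handling lives inside the C loop.
  A 26-week daily-dosing simulation costs hundreds of solver restarts,
  which dominate runtime when driven from the interpreter; the
  Rosenbrock path is ~30× faster and agrees with the full system to
  ~1e-5 relative. Its error control is relative to the running maximum
  of each state, so a spent gut bolus (a dose decays through 16 orders
  of magnitude within the hour) does not throttle the step size.
  Calibration and MCMC use this path;
* `"r"` is a pure-R right-hand side kept as an independent oracle.

Other numerical choices: reverse dosimetry uses the cancellation-safe
quadratic root (the naive form loses ~7 digits at ng/kg/day doses);
optimizer finite-difference steps are set above the solver noise floor
(`epsfcn`, steps of ~1e-3 on log10 parameters); solver tolerance inside
MCMC is `1e-3` (prediction error ~4e-4 log10 units, negligible against
the residual σ = 0.1); negative round-off states are clipped at the
`atol` scale.

## Calibration and identifiability

The objective is the sum of squared log10 residuals — serum assays have
multiplicative error, and a raw-scale objective would let high-dose
groups swamp the fit. Point estimation is Levenberg–Marquardt
(`minpack.lm::nls.lm`) in log10-parameter space. Model adequacy uses
`msle()` (mean squared log10 error; the base is configurable) and
`factor_coverage()` (fraction of predictions within a factor of 2,
boundary inclusive).

Identifiability screening precedes fitting: `collinearity_index()`
builds finite-difference sensitivities of log10-predicted serum with
respect to log10 parameters at the observation design, normalizes the
columns, and reports $\gamma = 1/\sqrt{\lambda_{\min}}$ of the
cross-product; subsets with $\gamma > 20$ (the conventional threshold)
are declared not jointly estimable. For the packaged designs this
reproduces the expected structure: $\{VCC, Tmc, Kt\}$ is estimable
($\gamma \approx 4$ with a saturating dose group), while any subset
containing `Free` together with the resorption pair diverges. The
default free/fixed split is therefore free = $\{VCC, Tmc, Kt\}$
(plus `bioAv` for PFOA-like oral data), fixed = $\{Free, k_a, k_{12},
k_{21}\}$ at literature values, with `fixed_param_sensitivity()`
quantifying how much the estimates move when a fixed value is perturbed
by up to two orders of magnitude. No canonical ordering exists for the
iterative fixing of non-identifiable parameters; the package exposes the
tools (`collinearity_report()`, repeated fits) rather than hard-coding a
recipe.

Uncertainty comes from an adaptive random-walk Metropolis sampler
(`tk_mcmc()`): Gaussian likelihood on log10 residuals, flat priors on
log10 parameters within the fit-spec bounds, error variance Gibbs-sampled
under a vague inverse-gamma prior, and Haario-type proposal adaptation on
the full chain history (window-based adaptation is not diminishing and
measurably biased interval coverage when we tried it). Reported
diagnostics: acceptance rate (warned outside [0.05, 0.6]) and
split-chain R-hat. Credible intervals are the 2.5/97.5 posterior
percentiles after a 20% burn-in.

## Half-life and human scaling

Scaling an animal fit to humans takes three steps: carry over the
chemical-specific parameters, substitute human physiology (70 kg, QCC
12.5), and recalibrate `Tmc` so the human serum half-life matches a
literature value (3.4 y PFOS, 2.7 y PFOA, 5.3 y PFHxS). For PFOA the
animal bioavailability (0.32, an experiment-specific finding) is reset
to 0.9 with the matching animal refit $K_t$ = 0.008 mg/L before scaling.

`half_life()` is operationalized as the terminal slope of a washout
simulation after a sub-saturating IV bolus (default 1e-6 mg/kg),
regressing log serum on time over the final decade of a 12-half-life
horizon; the smallest-magnitude eigenvalue of the linearized system is
kept as a cross-check and the two agree to well under 1%. Because
$t_{1/2}$ is strictly increasing in `Tmc`, `calibrate_tmc()` brackets
and solves by Brent's method to 1e-4 relative.

A caveat this package documents rather than hides: no single half-life
operationalization reproduces all the published human `Tmc` values from
the published half-life targets. With the printed human parameter sets
the terminal-slope half-life computes 5.8 y (PFOS), 5.3 y (PFOA) and
9.0 y (PFHxS) — not the 3.4/2.7/5.3 y targets — while the
one-compartment form $\ln 2 \cdot V_c / CL$ reproduces PFOA's 2.7 y
almost exactly but not the other two. The packaged human fixtures
therefore keep the *printed* `Tmc` values (they are what reproduce the
published dosimetry tables), `scale_to_human()` is self-consistent under
its stated operationalization, and the discrepancy is left visible. The
same rounding shows up in the PFOS dosimetry rows (reproduced only to
~13%) and in PFHxS clearance (computed 0.071 vs reported ~0.06
mL/kg-day); the PFOA rows, by contrast, reproduce to <1%.

## Exposure reconstruction

Population intake (ng/kg BW/day) is a continuous piecewise log-linear
function of calendar time: zero before 1950, rising from a 1950 anchor
(1% of the 1990 level by default — no measured 1950 level exists; the
fitted levels are insensitive to this choice because pre-1960 intake is
negligible mass) to a 1990 peak, then log-linear to 1998 and 2017 knots
with slope discontinuities, constant after 2017. The narrative reading
of "discontinuous breaks" as slope (not level) discontinuities is the
default; multiplicative level jumps at the knots are available via
`jump_1990`/`jump_1998` for the step-break variant.

`simulate_lifecourse()` exposes a birth cohort to `intake(t) * BW` as a
continuous oral rate from max(birth year, 1950) to the survey date with
constant 70-kg adult physiology — the model has no developmental
compartment, which is why comparisons are restricted to ages 21–79 and
why serum in children would be under-predicted. Surveys are evaluated at
mid survey year. `fit_exposure()` estimates the three knot levels by
least squares on log10 serum over (survey year × age) cells; with three
survey cycles the 1998 and 2017 levels are weak directions (serum in any
one year integrates the whole history), which is visible in the
recovery studies below.

## What the synthetic generators emulate

`gen_primate_study()` emulates the repeated-dose oral and single IV
bolus cynomolgus studies used for PFAS model calibration: by default
three oral groups at 0.03/0.15/0.75 mg/kg/day — the top dose probes
resorption saturation, without which $T_m$ and $K_t$ are practically
unidentifiable — dosed daily for 26 weeks, plus a 2 mg/kg IV group, six
subjects per group, ~5 kg body weight; sampling is biweekly troughs
during dosing and a one-year recovery period (washout through the
saturation transition carries most of the $K_t$ information).
Observation noise is i.i.d. multiplicative lognormal per subject and
time point. What it does *not* emulate: between-animal kinetic
variability (all subjects in a group share one curve), assay LOQs and
censoring, or body-weight drift over the study.

`gen_biomonitoring()` emulates national-survey serum means over
(survey year × age) cells: three cycles (1999, 2003, 2017) with one
mean per single year of age 21–79, lognormal cell noise (default
σ = 0.05 log10). It does not emulate survey design weights, demographic
stratification beyond age, or age-dependent physiology.

Problem sizes in the shipped test-and-acceptance suite were chosen so
the full run completes on a laptop-class single core: 20 replicate
calibration studies at the default design, MCMC chains of 5,000
iterations, 100 random parameter sets for the steady-state equivalence
sweep, and 5 replicate biomonitoring panels for the noisy-recovery
study. At those sizes the observed results are: noise-free recovery of
$\{VCC, Tmc, Kt\}$ to <1%; at σ = 0.1, median recovery ~1/4/9% with 95%
credible-interval coverage 19/18/18 out of 20; noise-free trajectory
recovery to <0.1% with MSLE < 1e-10; at σ = 0.05, median level recovery
~4/10/7%.

## Known limitations

* No gestational/lactational or developmental physiology; adults only.
* Censored (non-positive) serum observations are dropped with a logged
  count, not modeled.
* The exposure model's pre-1990 history is anchored by assumption, and
  only three knot levels are estimable from three survey cycles.
* Published parameter tables are rounded to 2–3 significant figures;
  several published quantities are mutually inconsistent at the 10–20%
  level (see the half-life caveat above), and the package reproduces
  exactly only what is exactly reproducible.
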