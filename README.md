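# pfastk

Toxicokinetic modeling of per- and polyfluoroalkyl substances (PFAS)
with saturable renal resorption, for forward and reverse dosimetry in
risk assessment.

PFAS like PFOS, PFOA and PFHxS persist in human serum for years because
filtered chemical is actively resorbed from the renal filtrate back into
blood. `pfastk` implements the three-compartment model built around that
mechanism — a central (serum) compartment, a deep tissue compartment with
first-order exchange (k₁₂, k₂₁), and a filtrate compartment where
filtration of the free fraction (Q_fil · Free · C_prim) competes with
urinary outflow (Q_fil · C_fil) and Michaelis–Menten resorption
(T_m · C_fil / (K_t + C_fil)) — and everything needed to use it:

* **Simulation** (`simulate_tk()`): stiff-capable integration under
  arbitrary oral/IV bolus schedules and continuous intake, with a
  compiled fast path for repeated-dose calibration workloads.
* **Dosimetry** (`steady_state_serum()`, `pod_hed()`, `clearance()`,
  `half_life()`): closed-form steady state, its exact inverse (the
  human-equivalent dose, POD_HED, for a serum point of departure), and
  clearance/half-life in the linear and saturating regimes.
* **Primate-to-human scaling** (`calibrate_tmc()`, `scale_to_human()`):
  carry over an animal fit, substitute human physiology, and recalibrate
  the maximum resorption rate to a literature serum half-life.
* **Calibration** (`tk_fit()`, `tk_mcmc()`, `collinearity_index()`,
  `fixed_param_sensitivity()`): log-scale least squares, adaptive
  Metropolis credible intervals, and collinearity-based identifiability
  screening.
* **Exposure reconstruction** (`intake_trajectory()`, `fit_exposure()`):
  piecewise log-linear population intake histories (1950/1990/1998/2017
  knots) fitted to serum biomonitoring trends by birth cohort.
* **Synthetic data** (`gen_primate_study()`, `gen_biomonitoring()`):
  seeded generators shaped like the monkey PK studies and national
  biomonitoring surveys, with embedded ground truth.

Published parameter sets for PFOS/PFOA/PFHxS (monkey and human) ship as
fixtures: `tk_params("pfoa_human")` etc.

## Worked example: reverse dosimetry for hepatic endpoints

What daily oral dose would hold a 70 kg adult's serum at a given hepatic
point of departure? The steady state of the model inverts in closed form:

```r
library(pfastk)

human <- tk_params("pfoa_human")
pods <- tibble::tibble(
  endpoint = c("increased focal necrosis", "increased necrosis",
               "increased individual cell necrosis",
               "increased hepatocyte single cell death"),
  pod_mg_per_L = c(10, 26.9, 36, 100))

pod_hed_table(pods, human$physio, human$chemical)
#> # A tibble: 4 × 3
#>   endpoint                               pod_mg_per_L pod_hed_mg_kg_day
#>   <chr>                                         <dbl>             <dbl>
#> 1 increased focal necrosis                       10             0.00184
#> 2 increased necrosis                             26.9           0.00506
#> 3 increased individual cell necrosis             36             0.00686
#> 4 increased hepatocyte single cell death        100             0.0210
```

Each row is the administered dose (mg/kg/day) whose steady-state serum
concentration equals the POD; the 100 mg/L row already probes saturation
of the resorption transporter, which is why dose does not scale linearly
with the POD. The round trip
`steady_state_serum(pod_hed(x)) == x` holds to 1e-10.

A calibration run on synthetic monkey data with known truth
(VCC = 0.24 L/kg, Tmc = 2.5 mg/h/kg, Kt = 0.004 mg/L):

```r
monkey <- tk_params("pfos_monkey")
ds <- gen_primate_study(monkey$physio, monkey$chemical,
                        study_design(residual_sd = 0.1), seed = 1)
fit <- tk_fit(ds, fit_spec(monkey$chemical, free = c("VCC", "Tmc", "Kt")),
              monkey$physio)
tidy(fit)
#> # A tibble: 3 × 2
#>   term  estimate
#>   <chr>    <dbl>
#> 1 VCC    0.239
#> 2 Tmc    2.48
#> 3 Kt     0.00395
```

All three estimates land within ~2% of truth here; `tk_mcmc()` adds 95%
credible intervals, and `collinearity_report()` shows why `Free` must be
fixed rather than co-estimated with the resorption parameters.

There is also a thin command-line driver:

```sh
Rscript exec/pfastk pod-hed --chemical pfoa_human --pod 10
# 0.00184 mg/kg/day
```

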