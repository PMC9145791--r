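# neutkpd

Semi-mechanistic modelling of chemotherapy-induced neutropenia when the data
are what routine care actually produces: no drug concentrations, and absolute
neutrophil counts (ANC) measured only about twice per treatment cycle.

The package targets non-small cell lung cancer patients on paclitaxel
(175 mg/m² on day 1) and cisplatin (75 mg/m² on day 2) in up to six 28-day
cycles, with grade-4 neutropenia (ANC < 0.5×10⁹ cells/L) triggering a 25%
dose reduction and rescue G-CSF. It is useful to pharmacometricians building
or stress-testing myelosuppression models on sparse EMR-style data, and as a
reference implementation of the K-PD estimation workflow end to end.

## The model

Granulopoiesis is a transit-compartment chain with feedback
(Friberg-type): a proliferative pool, three maturation compartments and
circulating neutrophils,

    dProl/dt = Kprol · Prol · Ed · (Circ0/Circ)^γ − Ktr · Prol
    dTi/dt   = Ktr (T(i−1) − Ti),   dCirc/dt = Ktr · Tn − Kcirc · Circ

with `Kprol0 = Kcirc = Ktr0 = (n+1)/MTT`. Unobserved exposure is replaced by
kinetic-pharmacodynamic (K-PD) virtual compartments: each bolus decays as
`dA/dt = −KDE·A`, and the virtual infusion rate `VIR = KDE·A` drives an
additive response surface `Ed = 1 − U/(1+U)` with
`U = VIR_P/IR50 + VIR_C/IR50` (shared half-effect rate `IR50`, shifted by
sex and diabetes: `IR50 = θTV(1 + θsex·SEX)(1 + θDM·DM)`). While a G-CSF
indicator is on, `Ktr` is multiplied by `1 + θKtr` and `Kprol` additionally
by `1 + θprol`. Between-subject variability is log-normal on baseline,
transit time, potency and the two elimination rates; residual error is
combined proportional + additive.

Population parameters are estimated by a quadrature-refined Laplace
approximation to the marginal likelihood (a compiled ODE solver plus inner
Newton steps over the random effects), model structure by AIC, covariates by
stepwise forward/backward ΔOFV search, and uncertainty by subject-resampling
bootstrap. For a new patient, an adaptive-Metropolis sampler draws the
posterior of the individual random effects from a few observed ANC values,
and the trajectory ensemble yields the probability of grade-4 neutropenia
under any candidate regimen.

## Worked example

Simulate a sparse synthetic cohort under the protocol, then assess a new
patient from four observed ANC values:

```r
library(neutkpd)
pop <- reference_population()           # published final-model values
ds <- generate_dataset(study_design(30, seed = 42), pop)
ds
#> Synthetic cohort: 30 subjects, 309 ANC observations, 8 subjects with G-CSF rescue

patient <- read_dataset(system.file("extdata", "example_patient.csv",
                                    package = "neutkpd"))[[1]]
draws <- sample_posterior(patient, pop, n_draws = 2000, seed = 1,
                          chains = 2, burn = 500)
draws
#> Individual posterior: 2000 draws, 2 chains, acceptance 0.24
#> R-hat: eta_circ0 1.010, eta_mtt 1.032, eta_ir50 1.007, eta_kde_p 1.028, eta_kde_c 1.016
#> MAP eta: -0.060, -0.037, -0.035, 0.163, 0.120

risk_grade4(draws)
#> Grade-4 neutropenia risk over 57 days: 7.0% (threshold 0.5)
#> Nadir (1e9 cells/L): median 0.90 [5-95%: 0.49, 1.50], 500 trajectories
```

The 7% is the posterior-predictive probability that this patient's true ANC
nadir over the remaining horizon falls below 0.5×10⁹ cells/L; the nadir
summary says where the trajectory ensemble bottoms out. Reducing both drugs
by 25% for this patient drops the risk to ~0% with a median nadir of
1.30×10⁹ cells/L — the quantitative basis for a dose-adjustment decision:

```r
red <- patient$doses
cut <- red$drug %in% c("paclitaxel", "cisplatin")
red$amount[cut] <- 0.75 * red$amount[cut]
risk_grade4(draws, regimen = red)
#> Grade-4 neutropenia risk over 57 days: 0.0% (threshold 0.5)
#> Nadir (1e9 cells/L): median 1.30 [5-95%: 0.75, 1.97], 500 trajectories
```

Population estimation on a simulated cohort:

```r
fit <- fit_population(ds, init = initial_population(ds, pop$config))
summary(fit)          # estimates, OFV, AIC
plot(fit, ds)         # goodness-of-fit panels
plot(vpc(ds, fit$pop, n_sim = 200, seed = 7))   # visual predictive check
```

A YAML-driven command line mirrors the API
(`simulate | fit | compare | scm | bootstrap | vpc | map | risk`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/neutkpd", package = "neutkpd"))')" \
    risk config.yaml
```

The methods vignette (`vignettes/methods.Rmd`) documents the model, the
numerical choices (fixed-step likelihood integration, the quadrature
refinement of the Laplace approximation), what the synthetic cohorts do and
do not emulate, and a caution about a weakly identified parameter direction
under the two-samples-per-cycle design.

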