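# curox

Kinetics of oxidative curcumin consumption by AAPH-generated free radicals,
in R.

Curcumin is a radical-scavenging antioxidant whose clinical translation is
limited by rapid oxidative degradation. One way to study and design around
this is a well-mixed in-vitro system in which the thermal radical generator
AAPH (2,2'-azobis(2-amidinopropane) dihydrochloride) produces a steady flux
of alkyl/peroxyl radicals that consume curcumin — either delivered free as
a bolus, or released at a constant rate, as from degrading
poly(beta-amino ester) microparticles that also release a slower-reacting
curcumin monoacrylate by-product. `curox` implements the mass-action model
of that system, fits its consumption rate constants to measured
consumption curves, and quantifies how delivery mode (bolus versus
zero-order release) perturbs the radical environment.

## Model

With concentrations in uM and time in minutes, for AAPH `C_A`, the pooled
radical species `C_R`, curcumin `C_C` and curcumin monoacrylate `C_CM`:

    dC_A/dt  = -k_A C_A
    dC_R/dt  =  2 k_A C_A - k_el C_R - k_C C_C C_R - k_CM C_CM C_R
    dC_C/dt  =  release(t) - k_C C_C C_R
    dC_CM/dt = -k_CM C_CM C_R

Each decomposed AAPH molecule yields two radicals (`k_A = 1.26e-6` per
min at 37 C); the radical pool is eliminated first order with a ~1 ms
half-life (`k_el = 4.16e4` per min); both scavengers react bimolecularly.
Because `k_el/k_A ~ 3e10`, the system is extremely stiff and the radical
pool tracks its quasi-steady level

    C_R = 2 k_A C_A / (k_el + k_C C_C + k_CM C_CM).

The package integrates either the full stiff system (lsoda, tight
per-species tolerances) or the reduced quasi-steady system, and the two
modes are cross-checked against each other and against closed forms.

Rate constants are estimated by minimizing the pooled sum of squared
errors between the model and normalized consumption series
(Nelder-Mead/Brent over log-transformed parameters), and dosing scenarios
are summarized by the deviation of `C_R` from the antioxidant-free
baseline and its area under the curve (AUC, uM*min).

## Worked example

Fit the curcumin consumption constant from a synthetic noiseless
consumption curve (10 mM AAPH, 50 ug/ml curcumin, sampled every 2 h over
24 h), then compare a 225 uM bolus against the equivalent constant-rate
release:

```r
library(curox)

truth <- kinetic_config(rate_constants(k_C = 200),
                        species_state(C_A = aaph_mM_to_uM(10),
                                      C_C = curcumin_ugml_to_uM(50)),
                        mode = "quasi_steady_radical")
obs <- generate_observed_series(truth, seq(0, 1440, by = 120),
                                noise_model(sigma = 0))
fit <- fit_rate_constants(obs, kinetic_config(rate_constants(),
                          initial_state = truth$initial_state), free = "k_C")
coef(fit)
#> k_C
#> 200

res <- deviation_series(scenario_spec(bolus_uM = 225))
print(res)
#> Radical deviation scenario: 225 uM bolus into 10 mM AAPH over 1440 min
#>   peak deviation 3.148e-07 uM at t = 0 min
#>   AUC = 0.0004436 uM*min
#>   back within 1% of baseline at t = NA (not within window) min

run_demonstration(c(10, 25, 75, 100, 150, 225))
#> Bolus vs zero-order release: 10 mM AAPH, 1440 min window
#>  dose (uM) bolus AUC (uM*min) rate (uM/min) release AUC (uM*min)
#>         10          3.695e-05      0.006944            1.923e-05
#>         25          8.724e-05      0.017360            4.617e-05
#>         75          2.202e-04      0.052080            1.225e-04
#>        100          2.717e-04      0.069440            1.545e-04
#>        150          3.543e-04      0.104200            2.093e-04
#>        225          4.436e-04      0.156200            2.748e-04
```

The peak deviation is the instantaneous drop of the radical concentration
below its antioxidant-free baseline (~6.06e-7 uM at 10 mM AAPH); the AUC
integrates that suppression over 24 h. Every bolus suppresses more radical
exposure in total than its rate-matched controlled release (larger AUC),
but does so as a large transient rather than a small sustained offset —
the quantitative form of the toxicity-versus-efficacy trade-off in
antioxidant dosing. In the quasi-steady limit the AUC equals
(scavenger consumed)/`k_el`, a closed form the pipeline is tested against
(`analytic_auc_estimate()`).

## Command line

A thin wrapper over `run_pipeline()` ships in `inst/cli/`:

```sh
Rscript inst/cli/curox.R demo --out demo_out
Rscript inst/cli/curox.R synth --out fixtures --seed 7
Rscript inst/cli/curox.R fit --data fixtures/free_curcumin_10mM_sigma0.csv \
    --config config.yaml --free kC --out fit_out
```
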