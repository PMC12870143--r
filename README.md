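# tundratongue

Tools for studying the "tundra tongue": the adhesion of a (child's) tongue
to a sub-freezing metal lamp post through an ice bridge of frozen saliva,
and the tissue injury caused when the tongue is pulled free. The package is
aimed at researchers in injury biomechanics and bioheat transfer who want a
fully reproducible, simulation-based counterpart to the porcine
tongue-detachment experiment: a calibrated synthetic data generator, the
statistical analysis pipeline, and a transient tissue-freezing simulator.

It has three layers:

1. **Synthetic experiment generator.** Emulates the detachment study
   design: 84 tongues in slaughter batches of six, two trials per tongue
   (apex and basis), block-randomized gradual/rapid release, per-condition
   covariate distributions, and four random exclusions. Peak detachment
   force follows a mixed-effects model with tongue-in-batch random
   intercepts, a contact-time effect, and a quadratic metal-temperature
   response

   F = m(region, release) + β_c (c − c̄) − κ[(T − T_p)² − E(T − T_p)²] + u_batch + u_tongue + ε,

   with the adhesion peak at T_p = −7.5 °C. Binary avulsion injury follows
   a random-intercept logistic model on the z-scored force (slope γ₁ = 1.44
   per SD), and macroscopic cold injury a logistic model in metal
   temperature. Defaults are calibrated so the simulated study reproduces
   the experiment's marginal summaries (54 % avulsion, 92 % cold injury,
   22.6 N mean basis-rapid force).

2. **Statistical models.** `fit_force_lmm()` fits the force model by
   maximum likelihood (lme4 backend) with or without the quadratic
   temperature term; `compare_models()` / `comparison_from_chisq()` give
   likelihood-ratio tests, AIC differences and Akaike weights;
   `peak_temperature()` locates the adhesion peak; `fit_avulsion_model()` /
   `fit_cold_model()` are random-intercept logistic injury models
   (adaptive Gauss–Hermite quadrature); `predict_force_grid()` +
   `risk_surface()` implement the two-stage risk surface (fixed-effects
   force prediction over a condition grid, then avulsion risk per node);
   `required_sample_size()` reproduces the power calculation.

3. **Contact-freezing simulator.** A from-scratch 2D transient
   heat-conduction solver (ρc ∂T/∂t = ∇·(k∇T)) on a parametric layered
   geometry — steel wall, saliva film, epithelium, connective tissue,
   muscle, with sinusoidally rough interfaces and blood-vessel discs held
   at 37 °C to mimic perfusion. Finite-volume discretisation with
   harmonic-mean interface conductivities, backward-Euler stepping, a
   closed (no-flux) outer boundary, and probes for the freezing-front
   depth, interface temperature ribbons, and the histological damage
   point. A pediatric variant scales tissue thicknesses by 0.7.

## Worked example

```r
library(tundratongue)

d <- simulate_study(seed = 1)           # 164 analysed records
fit_lin  <- fit_force_lmm(d, include_quadratic = FALSE)
fit_quad <- fit_force_lmm(d, include_quadratic = TRUE)
fit_quad
#> Linear mixed model for peak detachment force (quadratic in metal temperature, ML, n = 164)
#>     intercept  contact_time  region_basis release_rapid          temp       temp_sq
#>        4.1683        1.0051        3.7411        7.6276       -0.0010       -0.0037
#> random-effect variances (N^2): batch 4.79, tongue 14.37, residual 42.75
#> logLik -565.86, 9 parameters, AIC 1149.7
```

The contact-time slope (≈1 N s⁻¹), the positive basis and rapid-release
contrasts, and the negative squared-temperature coefficient all mirror the
experiment. A single 164-record study rarely pins the quadratic term down;
refitting on a 2000-record simulation localises the adhesion peak:

```r
big <- simulate_study(n_tongues = 1000, batch_size = 4, n_excluded = 0, seed = 2)
peak_temperature(fit_force_lmm(big, include_quadratic = TRUE))
#> [1] -7.314132
```

Injury risk, with the slope per SD of detachment force:

```r
av <- fit_avulsion_model(d)
av$coefficients
#> intercept   force_z
#>   -0.1140    1.4839
100 * (exp(av$coefficients[["force_z"]]) - 1)   # percent odds increase per SD
#> [1] 340.9983
```

Tissue freezing during a 7 s contact with the wall at −12 °C:

```r
field <- simulate_contact(-12, t_end = 7, vessels_active = FALSE)
tail(damage_point_probe(field)$median, 1)   # mid-epithelial damage point, degC
#> [1] 1.83
isotherm_depth(field, 0, time = 7)$median   # freezing-front depth, mm
#> [1] 0.1375
```

At −12 °C the damage point ends just above 0 °C and freezing stays within
the superficial epithelium; at −25 °C the connective tissue starts to
freeze within 7 s, and the pediatric model at −40 °C pushes the
epithelium–connective interface below 0 °C within 2 s whether or not
vessels perfuse.

`run_pipeline()` chains all stages (generate → fit → risk surface → heat
scenarios) and writes CSV/JSON artefacts plus a summary; see
`?run_pipeline`. The methods vignette
(`vignettes/tundra-tongue-methods.Rmd`) documents the model, its
calibration, and its limitations.

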