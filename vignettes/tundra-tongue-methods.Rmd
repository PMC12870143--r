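---
title: "Models and methods: simulating cold-metal tongue adhesion and its injuries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulating cold-metal tongue adhesion and its injuries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tundratongue)
```

When a wet tongue touches metal far below freezing, the saliva film
freezes into an ice bridge within a fraction of a second. Pulling free
tears superficial tissue (avulsion injury), and the cold itself can damage
the contact patch (cold injury). This package provides a reproducible,
simulation-based counterpart to the porcine tongue-detachment experiment:
a synthetic data generator with the experiment's statistical structure,
the mixed-model analysis chain, and a transient tissue-freezing
simulator. This vignette documents the models, the reasoning behind every
tunable default, and what the package can and cannot claim.

## 1. The synthetic experiment generator

### Design

`build_design()` lays out tongues in slaughter batches (default 84 tongues
in batches of six). Each tongue contributes two trials — apex and basis —
and within every batch each region's trials are split as evenly as
possible between gradual and rapid release, independently per region
(block randomization). `apply_exclusions()` then removes a fixed number of
trials (default 4) uniformly at random. The real exclusions were
cause-specific (e.g. the force peak falling outside the sampling window),
but those causes are not simulable, so uniform exclusion is used; with 4
of 168 trials this choice is immaterial to any downstream estimate.

### Covariates

Per region-by-release cell, `sample_covariates()` draws

* **application and detachment times** from gamma distributions matching
  each cell's mean and SD. Gamma rather than truncated normal keeps
  durations strictly positive *without* shifting the cell means, which
  matters because the headline contrast "contact minus application time is
  1.8 s larger under gradual release" is a difference of detachment-time
  means (a normal truncated at zero would inflate the short rapid-release
  times by ~0.4 s and shrink that gap well below its target);
* **metal temperature** from a normal truncated to [−40, +2] °C — the
  range a dry-ice-cooled steel wall spans while warming. The experiment
  cooled the wall once per day and let it drift; that trial-order
  structure is not published, so a single truncated normal per cell is
  used. Consequently the generator reproduces marginal temperature
  distributions but not any within-day autocorrelation;
* **tongue weight** once per tongue (shared by its two trials), and
  tongue temperature per trial;
* a **poor-quality flag** for apex surfaces (Bernoulli 0.60, the pooled
  apex rate), carried as a covariate but unused by the default models —
  the experiment found results consistent across regions despite it.

Contact time is defined as application plus detachment time. The
force-trace stage decomposition also mentions a brief pre-release delay;
the published per-cell means are arithmetically consistent with the
two-term identity, so the delay is treated as part of the application
stage rather than a third term.

### Peak force

`simulate_forces()` draws

$$F = m_{\text{cell}} + \beta_c\,(c - \bar c_{\text{cell}})
  + q(T) - q(\bar T_{\text{cell}})
  + u_{\text{batch}} + u_{\text{tongue}} + \varepsilon,
  \qquad q(T) = -\kappa (T - T_{\text{peak}})^2,$$

clamped at zero. The four cell means $m_{\text{cell}}$ (10.9, 16.4, 13.0,
22.6 N) are taken directly from the experiment's condition table; a
cell-mean (interaction) truth is used so all four are matched
simultaneously, even though the analysis model fits main effects only —
the same mild misspecification the real analysis lives with.
Centring the covariate terms at their cell expectations keeps the cell
means calibrated regardless of $\beta_c$ and $\kappa$.

Calibration constants, frozen once against large-sample moment checks
(10^5-record cell draws and 200 replicate studies) before any acceptance
testing:

| parameter | default | unit | rationale |
|---|---|---|---|
| $\beta_c$ | 1.0 | N/s | contact-time slope of the fitted force model |
| $\kappa$ | 0.008 | N/°C² | quadratic curvature; gives a few-newton swing over the −40…0 °C range |
| $T_{\text{peak}}$ | −7.5 | °C | reported adhesion peak |
| $\sigma_{\text{batch}}, \sigma_{\text{tongue}}, \sigma_{\text{resid}}$ | 1.5, 3, 7 | N | put per-cell force SDs in the reported 8–13 N range |

With these values a single 164-record study shows the right effect
directions but rarely a decisive quadratic term (typical likelihood-ratio
$\chi^2 \approx 1$); the experiment's own $\chi^2(1) = 9.99$ would imply a
sharper curvature than marginal calibration supports. The package treats
the printed statistic as an input to the model-comparison arithmetic (see
below) and recovers the peak *location* from larger refits, which is the
better-posed task.

### Injury outcomes

`simulate_outcomes()` draws avulsion from a random-intercept logistic
model on the dataset's own z-scored force,
$\text{logit}\,P = \gamma_0 + \gamma_1 z(F) + u_{\text{tongue}}$, with
$\gamma_1 = 1.44$ per SD (the reported effect) and $\gamma_0 = 0.20$,
$\sigma_u = 0.7$ calibrated to the 54 % marginal rate. Cold injury is
$\text{logit}\,P = \delta_0 + \delta_1 T$ with $\delta_1 = -0.45$ per °C
(colder metal, higher risk) and $\delta_0 = -1.0$ calibrated to the 92 %
marginal rate. The cold-injury model is intentionally simple: the real
outcome was nearly saturated (92 % positive), which is also why the
experiment declined to build a formal cold-injury risk model.

### What the generator does not emulate

No force-time traces (only the peak and stage durations), no saliva
composition or ambient-humidity effects, no day structure in metal
temperature, no cause-specific exclusions. Passing tests therefore show
that the *statistical procedures* recover the *generating model*; they
cannot validate the experiment's substantive findings against new data.

## 2. Statistical models

`fit_force_lmm()` fits the force model by **maximum likelihood** (not
REML) with random intercepts for batch and tongue-within-batch, so
likelihood-ratio tests and AIC differences between nested fits are
internally consistent. Metal temperature is centred at its sample mean
before squaring (collinearity), and coefficients are reported
back-transformed to natural units; `peak_temperature()` returns the
parabola vertex $-\beta_T / (2\beta_{T^2})$, refusing when the fitted
quadratic is not concave. Fixed-effect inference uses Wald/likelihood
ratios rather than Satterthwaite degrees of freedom — at n = 164 the
difference is negligible, and ML keeps the comparison arithmetic exact.

`compare_models()` reports $\chi^2 = 2\,\Delta\ell$ (clamped at zero with
a warning if optimizer noise inverts the order), $\Delta\text{AIC}$, and
the two-model Akaike weight $1/(1 + e^{-\Delta\text{AIC}/2})$.
`comparison_from_chisq()` applies the same arithmetic to a printed
statistic: $\chi^2(1) = 9.99$ gives $\Delta\text{AIC} = 7.99$ and weight
0.982 — the reported 8.0 / 0.98.

`fit_avulsion_model()` and `fit_cold_model()` are random-intercept
logistic models fitted by adaptive Gauss–Hermite quadrature (15 nodes,
Laplace fallback on non-convergence). Tongues are uniquely coded, so the
tongue-within-batch intercept is a single tongue-level grouping factor
with the batch variance absorbed into it. Force is z-scored with the
analysis dataset's mean and SD — the reference population for the
"per SD" effect is not otherwise defined — which also makes the
downstream risk surface invariant to the force unit.

The two-stage risk surface follows the experiment's procedure:
`predict_force_grid()` evaluates the quadratic force fit, fixed effects
only, over a condition grid (default: −40…0 °C in 5 °C steps, contact
times 3/5/7/9 s, both regions, both releases — the published description
names the axes but not the nodes), and `risk_surface()` maps each
predicted force through the force-only avulsion model at the population
level (random intercept zero). Risk is then maximal where adhesion
peaks, in the moderately-cold −5…−15 °C band.

`required_sample_size()` searches the smallest N whose two-tailed
noncentral-t power for a single regression coefficient
($\text{ncp} = \sqrt{f^2 N}$, df $= N - p - 1$) reaches the target. For
the study's specification ($f^2 = 0.1$, $\alpha = 0.0125$, power 0.90,
4 predictors) it returns N = 147 and, inflated for 15 % attrition, 170
(multiplicative convention) or 173 (divisive); both are reported because
the published plan ("85 tongues, 170 experiments") does not state its
rounding path.

## 3. The contact-freezing simulator

### Model

Heat conduction only: $\rho c\,\partial T/\partial t = \nabla\cdot(k\nabla
T)$ in 2D, matching the pure-conduction ("heat transfer in solids")
formulation of the original finite-element study of ex vivo tissue. There
is deliberately **no latent heat of fusion**; freezing is diagnosed by
isotherm crossing (default 0 °C; a −0.8…−1.0 °C threshold, the freezing
range of comparable soft tissues, can be set via
`simulation_config(freezing_ref_temp=)`). Perfusion is represented by
holding all cells inside vessel discs at 37 °C — the structured-grid
analogue of a Dirichlet condition on vessel boundaries.

### Geometry

`tongue_geometry()` builds the layered cross-section: steel wall (4.6 mm —
the thickness used in the original simulations), saliva film (0.07 mm,
midpoint of the plausible 0.04–0.1 mm range), epithelium (0.45 mm mean,
porcine dorsal range), connective tissue (1.5 mm), and 8 mm of muscle/fat,
10 mm of tissue in total so the far boundary stays effectively
semi-infinite over 15 s. Deep interfaces are sinusoidally perturbed
(amplitudes 0.1 and 0.3 mm) to emulate roughness; the contact plane is
flat (the metal conforms to a plane, not the tongue). Four vessel discs
(radii 0.35–0.5 mm) sit at 2.5–5 mm depth. The pediatric variant scales
tissue thicknesses and roughness amplitudes by 0.7, keeping vessel count
and size — the assumption used for the pediatric extrapolation.

One geometric choice deserves emphasis: the metal extends 40 mm beyond
each side of the contact patch (`metal_overhang`), with air above the
overhang. A 4.6 mm slab confined to the 20 mm patch in a closed 2D domain
warms by ~9 K within 7 s, which would suppress all of the reported
freezing behaviour; the real wall is a long pipe that resupplies cold
laterally (in-plane diffusion length in steel ≈ 9 mm at 7 s). With the
overhang the model reproduces the reported phenomenology — superficial-only
freezing at −12 °C with the damage point ending barely above 0 °C at 7 s,
connective-tissue freezing at −25 °C but not −12 °C, and the pediatric
epithelium–connective interface dropping below 0 °C within 2 s at −40 °C
with or without perfusion. At −4 °C the predicted contact temperature is
only ≈ −0.4 °C, a knife-edge: the default model keeps the whole tissue
(including the mid-epithelial damage point) at or above 0 °C through 7 s,
whereas the original study reported sub-zero temperatures in the
outermost epithelium only. That hair-thin discrepancy is sensitive to the
saliva film's initial warmth and the epithelium's effusivity and is the
one qualitative result the defaults do not fully reproduce.

### Numerics

`rasterize()` builds a graded tensor-product mesh: near-surface spacing
(default 0.025 mm) through the film and epithelium, 2× in the connective
layer, 10× in the muscle and metal, 20× along the surface, 80× in the
overhang. The film must be resolved by at least two cells or
rasterization refuses. `solve_transient()` uses a conservative
finite-volume discretisation with harmonic-mean face conductivities
(correct flux continuity across the steel/saliva/tissue jumps),
backward-Euler stepping at 0.1 s (the original study's fixed step;
unconditionally stable, where an explicit scheme would need microsecond
steps at film-resolving spacings), and one sparse Cholesky factorisation
reused across all steps. Clamped (vessel/Dirichlet) cells are eliminated
from the system, so the closed-system runs conserve total enthalpy to
machine precision and satisfy the discrete maximum principle exactly.

Validation oracles, all in the test suite: the two-semi-infinite-media
contact temperature $(e_1 T_1 + e_2 T_2)/(e_1+e_2)$ within 0.5 °C at
early times; the 1D erf profile against a clamped face within 1 % (the
effective Dirichlet boundary of a volumetric clamp is the clamped cell's
*centre*, which the comparison must respect); mesh-halving changes the
damage-point temperature by < 0.2 °C; colder metal gives pointwise colder
tissue; active vessels only ever add heat.

Default problem sizes: a scenario run is a ~130 × 55 cell mesh for 70–150
time steps (well under a second); the statistical recovery studies use
2000-record refits over 10 seeds and 500 replicate studies, a few seconds
each.

### Probes

`isotherm_depth()` reports the per-column deepest tissue point at or
below a threshold, measured from the saliva–epithelium interface.
`interface_trace()` samples ≥ 50 points along a (rough) interface and
summarises median, 10th/90th percentiles and range per snapshot.
`damage_point_probe()` probes at a fraction (default 0.5) of the local
epithelium thickness — the intra-epidermal depth where avulsion injuries
sit histologically. Note the deeper interfaces cool monotonically (no
interior heat source), but the contact surface itself may rebound by a
few hundredths of a degree late in a run as the slab warms.

## 4. Material properties

Literature values shipped in `material_table()` (all overridable):
structural steel k = 44.5 W/m/K, ρ = 7850 kg/m³, c = 475 J/kg/K; saliva as
water (0.60, 1000, 4186), initially at 20 °C; epithelium (0.40, 1100,
3400), connective tissue (0.45, 1050, 3600), muscle (0.50, 1050, 3700),
blood/vessels (0.52, 1060, 3600), all initially 37 °C; air (0.026, 1.2,
1005) above the overhang. The original supplement's property table is not
public; these are standard soft-tissue values in its stated range.

## 5. Known limitations

* Generator truth is calibrated to published *marginals*; cell-level
  covariances beyond those implied by the model (e.g. operator behaviour
  linking application time to temperature) are absent.
* The curvature/χ² tension noted in §1: single 164-record studies seldom
  reproduce the decisive quadratic evidence the experiment reported.
* No phase change: once tissue crosses 0 °C the model keeps conducting as
  if unfrozen, so sub-zero *depths* are a conservative proxy, not an ice
  front.
* 2D cross-section with a flat contact plane; no mechanical model of the
  ice bridge or detachment force — the force-to-injury link is purely
  statistical, as in the original analysis.
* The adjusted positive association between avulsion risk and metal
  temperature in the four-variable model is not explicitly encoded in the
  generator and is treated as exploratory.
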