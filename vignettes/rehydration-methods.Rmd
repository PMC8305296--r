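---
title: "Models and methods behind rehydkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rehydkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rehydkin)
```

This vignette documents the models implemented in rehydkin, the assumptions
they carry, the numerical choices made where the design was genuinely open,
and what the synthetic-data generators do and do not emulate.

## Rehydration ratios and their orientation

All kinetics are expressed on the rehydration ratio
$RR(t) = (M_t - M_o)/(M_e - M_o)$, where $M_o$ and $M_e$ are the initial
and equilibrium dry-basis moistures of the dried sample, and on its
complement, the moisture ratio $MR = 1 - RR$. $RR$ runs from 0 to 1 as the
sample saturates; this orientation is the one every model below requires
(each model predicts $RR(0) = 0$). A literal variant
$(M_t - M_e)/(M_e - M_o)$, which equals $RR - 1$ and therefore starts at
$-1$, circulates in parts of the drying literature; it is available behind
`rehydration_ratio(..., as_printed = TRUE)` purely for auditing data
digitised from such sources.

Moisture is carried in % dry basis everywhere (g water per 100 g dry
solids). Temperatures are stored in kelvin internally; degrees Celsius are
accepted only at the I/O boundary (`read_rehydration_csv()`,
`pipeline_config()`), as are thicknesses in mm.

## The kinetic models

Four empirical models (`peleg_rr`, `weibull_rr`, `exponential_rr`,
`first_order_rr`) and the Fickian series solution (`fick_mr`) are
implemented; see the README for the formulas. Points worth recording:

* **Peleg.** $K_1$ (min·(%db)⁻¹) is inversely related to the initial
  uptake rate and $K_2$ ((%db)⁻¹) to the capacity; when
  $M_e = M_o + 1/K_2$ the curve saturates exactly at $RR = 1$. The unit of
  $K_1$ follows from dimensional analysis of the model equation.
* **Weibull/exponential equivalence.** The exponential model is the
  Weibull model reparameterised with $K = (1/\alpha)^\beta$, $n = \beta$;
  the package exposes both because their rate constants have different
  Arrhenius behaviour (the exponential $K$ inherits $\beta$ times the
  activation energy of the Weibull rate $1/\alpha$). The equivalence is
  tested to $10^{-12}$.
* **Diffusion model.** The series solution assumes negligible shrinkage,
  negligible external resistance, a constant boundary condition and
  constant diffusivity. The pre-series geometric constant $G$ is *not*
  fixed at its textbook value (8 for an infinite slab, 6 for a sphere) but
  estimated: a single bean is neither, and the fitted $G$ (bounded in
  (1, 10)) indicates which idealisation the bean resembles. The intercept
  of the fitted curve is $MR(0) = G/8$ (slab) or $G/6$ (sphere).
  Shrinkage-coupled or moving-boundary models and a surface mass-transfer
  (Biot) term are out of scope.
* **Series truncation.** Terms are added until one falls below
  `term_tol` (default $10^{-12}$) or `n_terms_max` (500) is reached, in
  which case an error with the smallest Fourier number is raised. At
  $t = 0$ the closed forms $G/8$ and $G/6$ are returned directly; the
  series converges only algebraically there.

## Fitting

`fit_kinetics()` minimises unweighted squared error on $RR$ ($MR$ for the
diffusion model) with `minpack.lm`'s Levenberg–Marquardt algorithm under
box constraints (all rates positive, $\beta \in (0, 2]$, $G \in (1, 10)$).
Box constraints were chosen over a log-reparameterisation because they
yield standard errors directly on the natural parameter scale. Starting
values are data-driven: Peleg from its $t/RR$ linearisation, the
Weibull/exponential/first-order family from the interpolated time to 63 %
completion, diffusivity from the slope of the $\log MR$ tail. Restarts use
a fixed, deterministic cycle of multiplicative jitters rather than random
perturbations, so a fit never touches the RNG. Standard errors come from
the Jacobian-based asymptotic covariance at the optimum, matching the
"estimate ± standard error" convention of kinetic tables.

Two defaults matter scientifically:

* $M_e$ defaults to the last observed moisture (the gravimetric saturation
  criterion used when the curves are recorded: saturation is declared when
  consecutive weighings differ by at most 0.05 g, see
  `estimate_rehydration_time()`); it can be overridden when the true
  equilibrium is known.
* $M_o$ defaults to the first observed moisture. For the diffusion model
  this forces the observed intercept to 1 and makes $G$ unidentifiable;
  supplying the independently measured dried-sample moisture (oven method)
  restores identifiability. The package therefore accepts an `M_o`
  override in both fitting functions.

`goodness_of_fit()` reports $R^2 = 1 - SSE/SST$, $RMSE = \sqrt{SSE/N}$ and
$\chi^2 = SSE/(N - p)$. The reduced form $SSE/(N-p)$ is the convention
common in the drying literature; a weighted variant was considered and
rejected since no replicate-level variance model is available.
`compare_models()` ranks by ($R^2$ desc, RMSE asc, $\chi^2$ asc) —
deterministic tie-breaking in that order — and adds a Wald–Wolfowitz runs
test on residual signs as a summary of error randomness.

## Single-step Arrhenius estimation

`fit_arrhenius()` substitutes
$k(T) = k_\mathrm{ref}\exp\!\big((E_a/R)(1/T_\mathrm{ref} - 1/T)\big)$ for
the temperature-dependent constant and solves one joint least-squares
problem over all observations at all temperatures, all weighted equally
("concatenate and fit"). Centring on a reference temperature inside the
studied range — 353.15 K, the middle of a 70–100 °C experiment —
decorrelates $k_\mathrm{ref}$ and $E_a$. Any remaining model parameter
($K_2$, $\beta$, $n$, $G$) is shared across temperatures. $E_a$ is carried
in kJ/mol and converted to J/mol only inside `arrhenius_k()`.

For the time-like constants (Peleg's $K_1$, Weibull's $\alpha$) the
Arrhenius law is applied to their reciprocals — the rates $1/K_1$ and
$1/\alpha$ — so a positive $E_a$ means faster rehydration at higher
temperature; the reported reference value is nevertheless the constant
itself at $T_\mathrm{ref}$, matching how kinetic tables print it.

The classical two-step route (fit each temperature, then regress
$\log k$ on $1/T$) is available via `method = "two_step"`; on noiseless
data the two coincide (tested to $10^{-6}$ relative on $E_a$), and the
two-step result initialises the joint optimisation. The acceptance studies
use four temperatures, 31 time points per curve and 50 noise replicates —
sizes chosen so each study is a desk-scale computation.

## Quality metrics and group comparison

$\Delta E^*$ is the Euclidean CIELAB distance; because a published table
may average per-replicate $\Delta E^*$ or take the $\Delta E^*$ of group
means (the two differ by Jensen's inequality at replicate noise), the
pipeline computes and reports both. $DR\%$ is the enthalpy ratio of
retrograded to native starch; DSC curve integration is out of scope — the
enthalpies are inputs.

`group_compare()` runs one-way ANOVA plus pairwise t-tests (Welch by
default, since equal variances across drying methods is not a safe
assumption; a pooled option exists) with **no** multiple-testing
correction by default, mirroring common reporting practice in quality
tables; Holm and friends are one argument away. The compact letter display
uses a greedy insert-and-absorb algorithm: start with one letter covering
all groups, split any letter set containing a significantly different
pair, then absorb sets contained in others; letters are assigned in order
of the first group each set covers, making the display deterministic given
the p-value matrix.

## PLS-DA, VID and their calibration

`plsda()` one-hot encodes the class factor, autoscales the columns of X
(centring and unit variance — the standard preprocessing for GC-MS
fingerprint tables, and the scaling that makes correlation bi-plots
meaningful) and runs NIPALS PLS2 with deflation of both blocks; the
algorithm is deterministic and refits are bit-identical. Constant columns
are dropped with a warning. Model size follows the rule implemented in
`plsda_ncomp()`: the smallest number of latent variables whose
leave-one-out class accuracy reaches 100 %, falling back to the most
accurate size; 3 LVs is the conventional choice for four classes and is
the pipeline default.

The VID coefficient of a volatile for a class is defined here as the
Pearson correlation between the autoscaled volatile and the
model-reconstructed class-membership column ($\hat Y = T Q^\top$). The
measure is a reconstruction of a correlation-type variable-identification
coefficient used with PLS-DA in volatile fingerprinting; it lies in
$[-1, 1]$, its sign matches the direction of the class mean difference,
and a variable equal to the class indicator scores $\approx 1$. Volatiles
with $|VID| > 0.8$ are reported per class, in decreasing order of VID with
negative discriminants last. Whether VIDs should be computed one-vs-rest
or pairwise is open in the literature; one-vs-rest is used.

One quantitative limit is worth stating. For a single variable and a
one-vs-rest contrast with class prevalence $p$, the correlation with the
ideal indicator is bounded by the point-biserial form
$r = d\sqrt{pq}/\sqrt{1 + d^2 pq}$, where $d$ is the standardised class
separation. With four balanced classes ($pq = 3/16$) a $d = 3$ shift caps
at $r = 0.79$ — *below* the 0.8 threshold — and the threshold is first
crossed at $d \approx 3.1$. Calibration studies of the selection rule
therefore plant effects well above that boundary (5 log-scale standard
deviations in the shipped studies); at the boundary itself, all-variable
recovery is mathematically unattainable regardless of implementation. On
null tables (no planted effect) the false-selection rate reflects the mild
overfitting of the rank-3 reconstruction at 24 samples; the shipped
calibration measures the family-wise rate over 100 simulated tables, and
the per-variable rate is far smaller. Both calibrations are recomputed by
`scripts/acceptance.R` at run time.

## The synthetic generators

`sim_rehydration_curves()` emulates: saturating monotone uptake curves
whose time constant follows the Arrhenius law across 70–100 °C water
baths; about 10 g of dried sample starting near 11 %db and saturating
near 150 %db; additive Gaussian moisture noise truncated so weights never
fall below the dry mass. The default noise (0.5 %db) is the moisture
equivalent of a 0.05 g balance resolution on a 10 g dry mass — the
measurement-noise magnitude is otherwise a free parameter of the study
design and is documented here rather than hidden. It does **not** emulate
solid leaching during rehydration, shrinkage, moisture-dependent
diffusivity, or within-batch bean-to-bean variability; passing tests on
generated data therefore validate the estimation machinery, not those
physical effects.

`sim_peak_table()` draws log-normal areas (peak areas are positive and
right-skewed, so noise is multiplicative) with a 30 % coefficient of
variation, four classes of six replicates and 30 aligned variables by
default, and plants class-specific upward log-mean shifts expressed in
units of the log-noise standard deviation. It does not simulate
chromatographic peak shapes, retention-time drift, censoring at the
detection limit, or correlated compound families.

`sim_replicates()` draws Gaussian replicates around nominal group means —
the generative counterpart of a "mean ± sd" quality-table row. The nominal
values used by the demonstration pipeline (`bean_quality_nominals`,
`bean_kinetic_nominals`) are reference group means for cooked-then-dried
red kidney beans.

All generators take a single integer seed, derive any sub-streams from it
deterministically, and restore the caller's RNG state, so identical seeds
give byte-identical output and the full pipeline is reproducible end to
end (`run_pipeline()` writes no timestamps for the same reason).

## Known limitations

* The diffusion model's $D_{eff}$ is an apparent, lumped coefficient; for
  highly porous (freeze-dried) material capillarity dominates and the
  "diffusivity" should be read as an effective rate, not a transport
  property.
* Asymptotic standard errors can be optimistic near parameter bounds
  (e.g. $G$ close to its box limit).
* The VID measure is computed in-sample; it quantifies association, not
  validated predictive importance. Cross-validated selection was examined
  and found to attenuate true discriminants at these sample sizes.
* `group_compare()` without correction inflates family-wise error across
  many metrics; use `p_adjust = "holm"` when that matters.
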