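---
title: "Methods: microscale habitat modelling with microsdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microscale habitat modelling with microsdm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(microsdm)
```

## The problem

On degraded gullied hillslopes, plant performance and habitat suitability
vary over metres: valleys collect water, nutrients and milder temperatures,
ridges shed them. Evaluating a restoration measure such as an
arbor--bush--herb mixed plantation (ABHMP) — operationally, contour-aligned
level trenches whose soil and microclimate are ameliorated — therefore needs
analysis at the *microscale*: a decimetre-resolution terrain model, landform
classes at the scale of individual plants, environmental factor surfaces
interpolated from a handful of field samples, and a species distribution
model (SDM) that turns those surfaces into a habitat-probability map that a
counterfactual scenario can be pushed through.

`microsdm` implements that pipeline end to end for presence--absence data:

1. **terrain** — scattered (x, y, z) survey points are triangulated (a TIN)
   and linearly interpolated to a 0.1 m DEM; slope and aspect come from the
   Horn 3x3 stencil; the topographic position index (TPI) with a 1 m
   circular neighbourhood plus the slope classify each cell into six
   landforms (valley, lower/flat/middle/upper slope, ridge);
2. **geostat** — each point-sampled soil or microclimate factor is
   interpolated to the DEM grid by ordinary kriging under a fitted
   semivariogram, validated by leave-one-out statistics;
3. **sdm** — per-cell presence/absence labels and the factor stack feed a
   logistic generalized linear model scored by AUC, with permutation-based
   factor importance;
4. **scenario** — trench footprints overwrite the treated factors with
   reference values, the model predicts the counterfactual probability
   surface, and a three-class suitability map with area accounting follows;
5. **fieldstats** — grouped field measurements get the classic treatment:
   normality (Lilliefors KS) and homogeneity (Levene) checks, optional
   natural-log transform, one-way ANOVA with LSD letters;
6. **synthetic_data** — a generator for terrain, factor fields, presence,
   sampling designs and trench geometry with known ground truth, so every
   stage is testable without any field data.

## Terrain model

The DEM is linear interpolation on the Delaunay triangulation of the survey
points, evaluated at cell centres; cells outside the convex hull are
nodata. The grid is a local planar system in metres, origin at the min-x /
max-y corner of the point cloud, rows north to south, values at cell
centres. No geodetic transforms are applied (sites of interest span tens of
metres).

For a cell with elevation $z_0$ and neighbourhood $N$ (all valid cells
whose centres lie within radius $r$ of it, the focal cell excluded),

$$\mathrm{TPI} = z_0 - \bar z_N, \qquad
  \mathrm{TPI}_{sd} = \frac{z_0 - \bar z_N}{s_N},$$

where $s_N$ is the standard deviation of the neighbourhood elevations. The
six classes partition the $(\mathrm{TPI}_{sd}, \text{slope})$ plane:

| class        | criterion                                   |
|--------------|---------------------------------------------|
| valley       | $\mathrm{TPI}_{sd} \le -0.3$                |
| lower slope  | $-0.3 < \mathrm{TPI}_{sd} \le -0.05$        |
| flat slope   | $-0.05 < \mathrm{TPI}_{sd} \le 0.15$, slope $\le 7^\circ$ |
| middle slope | $-0.05 < \mathrm{TPI}_{sd} \le 0.15$, slope $> 7^\circ$  |
| upper slope  | $0.15 < \mathrm{TPI}_{sd} \le 0.4$          |
| ridge        | $\mathrm{TPI}_{sd} > 0.4$                   |

Every upper bound is closed ("$\le$"), so the bands are exhaustive and
mutually exclusive for any finite input — a property the test suite checks
over a threshold-straddling grid. Aspect is reclassified into four
insolation codes (sunny 135--225° = 4, half-sunny 45--135° = 3, half-shady
225--315° = 2, shady otherwise = 1), boundaries going to the
higher-numbered band.

Numerical choices worth knowing:

* the focal cell is excluded from the neighbourhood mean and SD (the
  neighbourhood is "around" the cell); `exclude_focal = FALSE` restores the
  inclusive convention;
* standardization divides by the *neighbourhood* SD by default; whether to
  use the global DEM SD instead is genuinely open in common TPI practice,
  so `standardize = "global"` is provided — on the synthetic terrain the
  two give visibly similar class maps, but the neighbourhood form adapts
  the thresholds to local relief and is the default;
* cells whose neighbourhood SD is zero get $\mathrm{TPI}_{sd} = 0$ (a flat
  patch is "at grade"), and cells with fewer than 3 valid neighbours are
  nodata;
* flat (zero-gradient) cells carry the aspect flag `-1` and map to the
  shady code 1, the lowest-insolation class — a convention, since flatness
  gives no azimuth;
* rasterization of polygons uses the centre-point rule (a cell belongs to a
  patch iff its centre does), matching the point-conversion of a fine
  raster rather than area-weighted coverage.

## Ordinary kriging

The empirical semivariogram bins half squared differences by pair distance
(default 12 lags to half the maximum pairwise distance); a spherical model
(nugget $c_0$, partial sill $c$, range $a$) is fitted by weighted least
squares with pair counts as weights. Spherical is the default family — the
common default of desktop geostatistics tools — with exponential and
Gaussian available; for the latter two the `range` parameter is the
practical range (95% of the sill). Predictions solve, per target $s_0$,

$$\begin{pmatrix} \Gamma & \mathbf 1 \\ \mathbf 1^\top & 0 \end{pmatrix}
  \begin{pmatrix} \mathbf w \\ \mu \end{pmatrix} =
  \begin{pmatrix} \boldsymbol\gamma_0 \\ 1 \end{pmatrix},$$

with $\Gamma_{ij} = \gamma(\|s_i - s_j\|)$ and
$\gamma_{0,i} = \gamma(\|s_i - s_0\|)$; $\hat z(s_0) = \mathbf w^\top
\mathbf z$ and $\sigma^2(s_0) = \mathbf w^\top \boldsymbol\gamma_0 + \mu$.
The constraint $\sum_i w_i = 1$ makes the predictor unbiased, and with a
zero nugget it interpolates the samples exactly — both are tested
invariants. Duplicate sample locations are averaged; if the system is still
singular a $10^{-10}$ diagonal ridge is added (and logged), a stabilizer
that matters with a few dozen spatially clustered samples. Negative weights
can legitimately occur; cells with any are counted and reported rather than
clamped.

Validation is leave-one-out: the mean prediction error
$\mathrm{MPE} = \overline{\hat z_{-i} - z_i}$ (ideally 0) and the
root-mean-square standardized error
$\mathrm{RMSSE} = \sqrt{\overline{((\hat z_{-i} - z_i)/\sigma_{-i})^2}}$
(ideally 1). No numeric acceptance gate is imposed on these — with ~54
clustered points the sampling design itself limits what kriging can do —
they are reported for judgement.

## The species distribution model

The reference model is a binomial GLM with logit link on z-score
standardized factors,

$$\Pr(Y = 1 \mid \mathbf x) = \operatorname{logit}^{-1}\!\big(\beta_0 +
  \textstyle\sum_j \beta_j \tilde x_j\big), \qquad
  \tilde x_j = (x_j - m_j)/s_j,$$

fitted by iteratively reweighted least squares (`stats::glm`); an optional
ridge penalty (`l2 > 0`, own penalized IRLS, intercept unpenalized) handles
quasi-perfect separation, which the fitter diagnoses and reports rather
than silently returning divergent coefficients. Coefficients are reported
on both the standardized and the original factor scale. The aspect codes
1--4 enter as a single ordinal numeric factor. Class imbalance is left
unweighted. Training AUC uses the rank-sum (Mann--Whitney) formulation with
midrank ties; the conventional accuracy bands (excellent > 0.9, good
0.8--0.9, fair, poor, fail) label it, and model selection takes the
highest-AUC candidate above the 0.9 gate, ties resolving to input order
(logged). AUC is computed on the calibration cells and labelled as such —
no spatial hold-out is attempted, which overstates transferable accuracy;
see Limitations.

Factor importance is the mean AUC drop over `k` seeded permutations of each
factor column. The metric choice is a design decision: it is
model-agnostic, uses the same score the model is selected by, and needs no
refitting.

Alternative model families (maximum entropy, neural networks, support
vector machines) are deliberately out of scope; anything exposing the same
fit/predict contract can be added as a candidate to `select_model()`.

## Scenario and area accounting

`apply_scenario()` rasterizes the trench footprints and overwrites each
treated factor inside them with its replacement value — in practice the
mean of that factor measured in established trenches of a reference stand
(the pipeline's synthetic path uses the valley-class means of the sampled
table, valleys being the presence-favoured stratum). Topographic layers
are *not* modified: a trench is a soil/microclimate amelioration, not a
landform change; the `factors_replaced` argument makes this overridable.
Outside the footprints every cell is bit-identical, and an empty scenario
is the identity — both tested invariants.

The probability surface is reclassified with two thresholds,
$t_{low} = 0.5$ and $t_{high} = 0.75$ by default: below $t_{low}$
unsuitable, from $t_{low}$ (inclusive) sub-suitable, from $t_{high}$
(inclusive) suitable. The thresholds are design parameters, not measured
quantities — 0.5 is the model's decision boundary and 0.75 halves the
presence-favoured range — and they are echoed in every output so reported
areas stay interpretable. Class areas are cell counts times cell area;
percentages sum to 100 whenever any valid cell exists, and class areas sum
to the valid total for *any* threshold choice (tested). The stratified
report cross-tabulates suitability against in-trench, valley-outside-trench
and other cells.

## Field statistics

Normality uses the Lilliefors variant of the Kolmogorov--Smirnov test
(parameters estimated from the data; p-value from the Lilliefors
approximation via `nortest`), labelled as such in output since the plain KS
null would be anticonservative. Homogeneity uses Levene's test on absolute
deviations from group *means* (the mean-centred variant, via `car`).
`anova_lsd()` runs one-way ANOVA, unadjusted pairwise LSD t-tests on the
pooled within-group mean square, and assigns compact letters by the
insert-and-absorb algorithm, ordering groups by descending mean so 'a'
always marks the largest mean — the convention of field tables. The letter
display satisfies, by construction: groups sharing a letter do not differ
at $\alpha$; groups sharing none do (property-tested over random data). No
multiplicity correction beyond LSD is applied, matching the analysis style
this reproduces. The natural-log transform is available for
positive-valued, variance-heterogeneous measurements and acts on the
analysis scale (means, SEs and letters are reported on the log scale when
used).

## What the synthetic generator emulates — and what it does not

The generator produces a planar hillslope (default gradient 0.25) with
sinusoidal cross-slope ridges and valleys (default 3 gullies over 24 m,
amplitude 1.2 m), surveyed by ~3,358 quasi-uniform points with 0.05 m
Gaussian elevation noise and a 0.05 m minimum spacing — the simplest
surface that produces all six landform classes with realistic band widths
at the default thresholds. Factor fields are affine in the z-scored
standardized TPI,

$$f_k = \mu_k + d_k\, a_k\, \tilde T + \varepsilon_k, \qquad
  \varepsilon_k \sim N(0, (0.8\, a_k)^2),$$

with means $\mu_k$, half-ranges $a_k$ and directions $d_k \in \{\pm 1\}$
taken from magnitudes and valley-to-ridge trends typical of gullied
red-soil sites (cooler, moister, more fertile valleys; see
`default_factor_config()`). The noise fraction 0.8 keeps factors that share
the topographic gradient statistically distinguishable, so coefficient
signs remain identifiable. Presence is Bernoulli under a known logistic
response; the default prefers valley conditions with standardized
coefficients of magnitude 1--2.5 and intercept $-5$, giving a site
prevalence near 0.2 — a realistic patch fraction for a recovering fern
stand. The sampling design stratifies 9 points per merged class (valley /
slope / ridge) per gully type (2), i.e. 54 points; trenches are 4.0 m x
0.5 m rectangles, contour-oriented, non-overlapping, at the customary 600
per hectare.

Deliberate non-goals: the generator does not reproduce any real site's
hypsometry, factor covariances beyond the shared topographic gradient,
temporal microclimate structure (it emits period summaries directly), or
spatially autocorrelated presence noise. Consequently, passing tests show
that the *methods* are implemented correctly and recover known structure;
they do not show that a real site's AUC or suitability areas would be
reproduced. On this synthetic world the GLM's calibration AUC (~0.98)
exceeds what noisy field data yield, and sign recovery at |coef| >= 1
holds at a few thousand training cells.

One pipeline design point follows from this: in the synthetic path the SDM
is calibrated on the generated factor fields, while kriging of the 54-point
sample table is still run and validated. Kriged layers from 54 points lose
the cell-level noise that separates collinear TPI-driven factors, so
coefficient recovery is only meaningful against the true fields; in the
file-input path (real surveys) the kriged layers are, as in the field
workflow, the only available predictors and are used for fitting.

## Degenerate inputs, tie-breaks, tolerances

* collinear survey points fail triangulation with a clear error; duplicate
  points are averaged;
* a constant factor gives an all-zero semivariogram, flagged, and the
  degenerate flat variogram (nugget = sill = 0) rather than an error;
* constant-in-training factors are dropped with a warning and recorded on
  the model object;
* AUC with a single class, empty polygon sets, empty masks, and zero
  trenches all follow explicit documented contracts (error, all-zero grid,
  zero-area table with `NA` percentages flagged, empty set respectively);
* all grid comparisons use a 1e-9 m alignment tolerance; variogram fitting
  uses multiple starting values with box constraints; IRLS converges at
  1e-9 on the coefficient step.

## Problem sizes

The bundled test suite exercises the pipeline at 8--12 m extents
(~650--1,300 survey points, ~10^4 cells), sizes chosen so the whole suite
runs in under a minute while every stage still produces all six landform
classes and both label classes. The acceptance script
(`scripts/acceptance.R`) runs the full default configuration — 24 m x
24 m, 3,358 points, 57,600 cells, 54 sampling points, 26 kriged factors —
in about a minute.

## Known limitations

* Training-data AUC overstates transferable accuracy; no spatial
  cross-validation is implemented.
* Isotropic variograms only; with strongly anisotropic gully terrain the
  microclimate surfaces would benefit from directional models.
* The suitability thresholds are conventions; reported areas move with
  them, which is why they are echoed everywhere.
* The compact letter display is exact for the LSD decisions it encodes but,
  like all CLDs, can obscure near-threshold p-values; the pairwise p matrix
  is always returned alongside.
* ~54 clustered samples limit kriging accuracy in sparsely sampled areas;
  the LOO report quantifies but cannot repair this.
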