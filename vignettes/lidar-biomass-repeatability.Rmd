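---
title: "LiDAR biomass indices, growth rate and repeatability: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LiDAR biomass indices, growth rate and repeatability: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenolidar)
```

This vignette is the package's account of what it computes and why the
open design choices were made the way they were. The companion README
shows the user-facing workflow; here we document the models, the
parameters that matter, the synthetic generator's assumptions, and the
limits of what the tests demonstrate.

## 1. The measurement problem

Destructive above-ground biomass (AGB) sampling cuts a fixed quadrat from
each plot, dries and weighs it. The sampled area is small relative to the
plot (0.25–1.1 m² in typical wheat trials), so the measurement carries
large sampling noise, and the repeatability

$$\rho \;=\; \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_\varepsilon /
n_{rep}}$$

— the fraction of genotype-mean variance that is genetic, given
$n_{rep}$ replicates — can be low, which caps the usefulness of AGB as a
selection trait. A ground-based LiDAR scan of the same plot section
measures thousands of returns nondestructively; a good scalar summary of
the cloud can be both well correlated with AGB and much more repeatable,
because beam-sampling noise is tiny compared with quadrat noise.

## 2. Point-cloud traits

**Ground elevation.** Soil returns concentrate in a narrow height band,
so the mode of the height histogram (bin width 0.01 m, matching the 3DPI
layer scale) identifies the soil; the ground elevation is the mean z of
the returns in the modal bin. Pooling all plots of one field column
before taking the mode makes soil dominance robust even near canopy
closure — this presumes the field is graded level along a column, which
is how the generator builds its terrain. Ties between equally occupied
bins break toward the lower bin (soil is below canopy by construction).
`estimate_ground()` also accepts a single plot's cloud for standalone
use.

**Crop height.** The mean of the returns at or above the 95th percentile
of the plot's height distribution, minus the ground elevation. The
percentile estimator is linear interpolation of order statistics
(`stats::quantile` type 7); the defining sentence of the method does not
pin down an estimator, so the most common one is used. Returns within one
histogram bin of the ground are excluded first (configurable,
`exclude_ground`): whether soil returns belong in the height distribution
is genuinely ambiguous, and excluding them makes early-season heights
mean "canopy top above soil" rather than a soil–canopy mixture. Small
negative heights (within twice the per-return noise scale) clamp to
zero; larger negatives indicate a broken ground model and raise a
data-quality warning.

**3DVI.** The bounding volume is the plot rectangle's footprint from the
ground elevation to the highest canopy return, divided into cubic voxels
(default 0.05 m). The index is occupied voxels over total voxels. Three
conventions had to be fixed because the verbal definition leaves them
open: the grid anchors at the rectangle corner and the ground elevation;
cells are half-open, so a point exactly on a boundary belongs to the
higher-index cell; and the top, partial voxel layer is counted. None of
these choices moves the index by more than one voxel layer's worth.

**3DPI.** "The sum of the fractional number of points intercepted by the
canopy in 0.01 m segments from the ground to the maximum crop height" is
ambiguous, and the package implements both readings:

* `interception` (default): process layers top-down; a layer's fraction
  is its returns divided by the beams not yet intercepted above it. This
  is a discrete gap-fraction profile: for a homogeneous canopy its sum
  approximates the optical depth, so it grows (without bound) with
  leaf area — the behaviour a biomass surrogate needs.
* `fraction_of_total`: a layer's fraction is its returns over all
  returns. Summed over canopy layers this telescopes to the canopy
  return fraction — it discards the vertical profile entirely and
  saturates at 1. It is retained so users can see the degeneracy, not
  because we recommend it.

Returns within one ground bin of the ground elevation count as soil
(uninterception) for both indices.

## 3. Growth rate

CGR between stem elongation (GS31) and anthesis (GS65) is the trait
difference over the window length in days. Genotypes reach GS65 on
different dates while scans happen on common dates, so index series are
linearly interpolated to each genotype's GS65 date before differencing;
when a sampling event coincides with the target date its value is used
exactly. There is no extrapolation: a plot whose sampled window does not
bracket its genotype's phenology is excluded, with the reason recorded on
the result (`attr(, "excluded")`). When a common stem-elongation sampling
exists it anchors the window start; dates are calendar days (no
thermal-time scaling).

## 4. The random-effects analysis

Each trait × event is fit by REML (`lme4::lmer`) with random intercepts
for genotype, field row and field column, and optionally a fixed
second-order polynomial in the (row, column) coordinates. The published
analyses of this design family fit a P-spline spatial surface (SpATS);
the row/column-plus-quadratic-trend model is this package's declared
substitution for it — the random row/column effects catch the striped
component of field variation and the polynomial catches the smooth bowl.
The pipeline default enables the trend; `fit_random_effects()` alone
defaults to row/column only.

REML's bounded optimizer truncates negative variance components at zero,
so a signal-free trait reports $\sigma^2_g = 0$ and $\rho = 0$ exactly.
`nrep` is the arithmetic mean genotype replication (2.45 and 1.6 in the
partial-replicate layouts the generator reproduces); a harmonic-mean
option exists for strongly unbalanced designs. BLUPs come from the fitted
model; BLUP correlations use the pairwise intersection of genotypes, a
t-distributed two-sided p-value on $n-2$ df, and the conventional star
thresholds. Between-event intraclass correlations are BLUP correlations
of the same trait at two events. p-values are reported unadjusted — the
workflow this mirrors applies no multiplicity correction, and adding one
silently would change the stars users compare against.

Degenerate inputs (one genotype, constant observations, failed fits)
yield a zero decomposition flagged in `$convergence` rather than an
error, so a pipeline over many trait × event cells never aborts on one
flat cell. Residual normality (Shapiro–Wilk W) and a residual
variance-ratio are logged per fit as advisory diagnostics; they gate
nothing, because the source workflow states the check but no action.

## 5. The synthetic trial generator

No public dataset carries plot-segmented clouds plus destructive AGB plus
phenology for this design family, so the generator is a first-class
module: every acceptance-level claim about the pipeline is made against
its known truth. What it emulates, per module:

**Designs.** RCBD (every genotype once per block; blocks fill contiguous
bands of the field grid) and partial-replicate layouts (a plot budget
spread over genotypes within a replication range — e.g. 98 genotypes in
240 plots averaging 2.45, or 41 in 64 averaging 1.6). Plot sections use
the row geometry of real trials (6 rows × 0.18 m × 1.0 m = 1.08 m² by
default).

**Genotypes.** Maximum height ~ N(0.95, 0.10²) m (near-isogenic wheat
panels vary strongly for height), canopy density lognormal (12% CV),
logistic growth rate ~ N(0.062, 0.006²) d⁻¹, GS31 at 75 ± 2 days after
sowing and GS65 at 108 ± 2 (ordering enforced). Height and the green-area
index follow logistic curves; the GAI curve lags the height curve by 5
days and saturates at 6 × the genotype's density factor. The
`water_limited` scenario multiplies growth rates by 0.6 and observation
noise by 2.

**Field structure.** A smooth second-order polynomial trend over the plot
grid plus independent row and column effects, all log-scale with standard
deviations 0.04/0.03/0.03 — deliberately *not* identical to the analysis
model's structure, so the stats module is stressed with partially
misspecified spatial signal. Terrain slopes gently across columns only
(graded-field assumption; see section 2).

**Scanner.** Beams on a 0.02 m grid (the instrument class this emulates
delivers several thousand points per m²) traverse 0.01 m layers top-down;
a layer intercepts with probability $1 - e^{-k \, d \, \Delta z}$
(baseline extinction k = 0.55 per unit GAI). Horizontal canopy cover is
$1 - e^{-0.8\,\mathrm{GAI}}$ — young row crops leave inter-row soil
exposed — and the green area concentrates in the covered fraction, with
a two-zone vertical profile (60% of green area in the top 35% of the
canopy, the sparse stem zone below). A beam's first interception yields
its single return; misses (plus a 10% standing gap fraction) return soil
points. Vertical noise is N(0, 0.003²) m, truncated at ±3σ so no return
falls below terrain − 3σ. Every beam returns exactly one point.

**Destructive sampling.** Expected plot AGB is proportional to height ×
GAI × the spatial multiplier, calibrated to ≈ 5–6 t/ha at anthesis under
good conditions. Observed AGB adds noise with standard deviation
$0.27\sqrt{\mathrm{AGB}}/\sqrt{\mathrm{quadrat\ m^2}}$ — the exact
1/√area scaling that makes a 0.3 m² quadrat √3.6 times noisier than a
1.08 m² one, with a square-root biomass dependence so that both the
stem-elongation and anthesis repeatabilities land in the empirically
reported range for small quadrats (≈ 0.2–0.4 and ≈ 0.5–0.6 at two
replicates). NDVI is a saturating function of GAI
($0.9 - 0.75 e^{-0.65\,\mathrm{GAI}}$) with additive noise — enough to
reproduce its saturation on closed canopies, with no radiometric model.

All randomness flows through explicit per-call seeds; the same seed
reproduces any simulated object bit for bit, and the pipeline derives
per-stage streams from one master seed.

**What the generator does not emulate** — and therefore what passing
tests do *not* show about real data: occlusion from oblique beam angles
and multi-pass registration; organ-level structure (ears versus leaves);
lodging; weeds and gaps from establishment failure; scanner intensity;
GPS/encoder geocoding error. One visible consequence: simulated 3DVI
*declines* slightly from stem elongation to anthesis (the bounding volume
grows with height faster than occupancy fills it), so within-event 3DVI–
AGB correlations in the simulation are weak-to-negative, whereas field
studies report moderate-to-strong positive ones. Repeatability
conclusions are unaffected (they compare variance ratios within a trait),
but correlation *signs* involving 3DVI should not be read as predictions
about real canopies. 3DPI, which tracks optical depth, correlates
positively with AGB in the simulation as it does in the field.

## 6. Numerical choices and problem sizes

* Ground histogram and 3DPI layers: 0.01 m; voxels 0.05 m (the method's
  published scales).
* Half-open intervals everywhere a point meets a boundary (segmentation
  rectangles, voxels, layers, histogram bins); ties in the ground mode go
  to the lower bin.
* REML fits use `lme4` defaults with singular fits tolerated; variance
  components are already bounded at zero by the optimizer.
* The test suite's simulation sizes were chosen to give stable
  Monte-Carlo checks at interactive runtimes: 500 random clouds for the
  brute-force oracle comparisons, 500 simulated trials (50 genotypes × 3
  replicates) for variance-component recovery, and 200 paired replicates
  of a 25-genotype × 2-replicate trial (three scan events, 0.3 m²
  quadrat) for the index-versus-AGB repeatability contrast.
* `run_all()` reports are serialized with fixed-precision JSON and a
  config fingerprint (FNV-1a over the canonical config JSON) in every
  table header, so identical configs are verifiable byte for byte.

## 7. Known limitations

* The spatial substitution (row/column + quadratic trend) is coarser
  than a P-spline surface; under sharply localised fertility patches it
  will under-correct, deflating repeatability for all traits equally.
* The interception 3DPI depends on `beams_total`; when a cloud is not
  one-return-per-beam (e.g. merged passes), the caller must supply the
  emitted beam count or the gap-fraction interpretation drifts.
* LAS support covers LAS 1.2 point format 0 only — enough for xyz
  interchange, not a general LAS reader.
* CGR uses calendar days; thermal time would be the natural refinement
  where sowing dates differ between trials.
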