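---
title: "Quantifying facial sexual dimorphism in shape and color"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying facial sexual dimorphism in shape and color}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facedim)
library(dplyr)
```

## The problem

Human faces differ between the sexes in two largely independent channels:
geometry (jaw width, brow position, face outline) and surface color (overall
skin lightness, redness and yellowness, and the local contrast between
features such as eyes, brows and lips and the skin around them). `facedim`
measures both on a common footing:

* **SShD** (sexual shape dimorphism): each face's landmark configuration is
  scored by its position along the axis joining the female-mean and
  male-mean shapes in Procrustes shape space.
* **SCoD** (sexual color dimorphism): the same construction applied to a
  matrix of CIELAB skin measurements and facial contrasts.

The magnitude of dimorphism in either space is the Euclidean distance
between the two sex means; its significance is assessed by a permutation
test that reassigns individuals to sex groups, and its effect size by
Cohen's *d*.

## Shape: symmetrization and Procrustes alignment

Landmarks come in as 72 two-dimensional points per face (36 anatomical
landmarks and 36 outline semilandmarks, here treated as fixed points — no
sliding). Because frontal faces have *object symmetry*, each configuration
is first symmetrized: it is centered, reflected about the vertical midline
(x negated), the members of each bilateral pair are swapped, the reflected
copy is rotated back onto the original (rotation only), and the two are
averaged. This removes fluctuating asymmetry and is idempotent. The
left/right pairing is a required user input because digitizing schemes
differ; `face_template()` carries a complete worked example.

Generalized Procrustes Analysis then aligns all faces of both sexes jointly:
translate centroids to the origin, scale to unit centroid size, rotate each
configuration onto the consensus (rotations only, reflections never), and
iterate until the consensus root-mean-square change falls below `tol`
(default `1e-8`, `max_iter = 100`). Two numerical choices matter:

* the consensus is initialized with the renormalized mean of the centered,
  scaled configurations, which makes the converged consensus an exact fixed
  point — re-running `gpa()` on aligned output stops after one iteration —
  and makes the result independent of input order;
* after convergence the whole set is rotated so the principal axis of the
  consensus is vertical, with a deterministic sign rule, so output
  orientation is reproducible.

The aligned coordinates, flattened to 144 columns (`x1, y1, ..., x72, y72`),
form the shape feature matrix.

## Color: CIELAB measurements and facial contrast

Color arrives either as a measured table or as sRGB images plus region
masks. Conversion uses the standard sRGB transfer function and D65 2° white
point; region means are computed *after* conversion (convert each pixel,
then average in CIELAB). Eight regions are used: the three features (eye,
brow, lips), their surrounding skin areas, plus cheek and forehead. Overall
skin color is the unweighted mean of the five skin areas (the three
surrounds, cheek, forehead) per channel.

Facial contrast uses the adapted Michelson formula
$$C_f = \frac{L_s - L_f}{L_f + L_s},$$
with $L_f$ the feature mean and $L_s$ its own surrounding-skin mean:
0 means no contrast, positive values a feature darker than its surround.
The same formula is applied to a\* ("red") and b\* ("yellow"), where the
bound $|C_f| \le 1$ is not guaranteed and values are kept unclipped; a zero
denominator yields a missing value rather than an error.

The default SCoD matrix has 15 columns: cheek and forehead L\*, a\*, b\*
(6) plus the nine feature × channel contrasts. Columns are left in raw
mixed units by default — L\* spans 0–100 while contrasts span roughly
−1 to 1, so L\* dominates the distance; `standardize = TRUE` z-scores the
columns when a unit-free comparison is wanted. Faces with any missing
column are dropped listwise and every exclusion is reported by name.

## Scores, distances, and inference

For either space, the axis is $\mathbf{d} = \mathrm{MM} - \mathrm{FM}$, the
difference of the per-variable male and female means. An individual's score
is the plain dot product $\langle \mathbf{x}_i, \mathbf{d} \rangle$ — the
direction is *not* normalized by default, so the male−female difference in
mean scores equals $\lVert \mathbf{d} \rVert^2$ exactly (a convenient
algebraic check, tested); `normalize_axis = TRUE` rescales scores to
feature-space units. Scores are also reported mean-centered per population;
centering affects no downstream statistic.

Inference on $\lVert \mathbf{d} \rVert$ uses a permutation test: sex labels
are shuffled without replacement (10,000 replications by default), the
distance recomputed each time, and the add-one estimate
$p = (\#\{d_{perm} \ge d_{obs}\} + 1)/(B + 1)$ reported, so $p$ is never
exactly zero and the test is exact under exchangeability. Every result
records its seed.

The effect size accompanying this multivariate comparison is Cohen's *d* of
the projection scores along the observed axis — the natural univariate
reduction of the same contrast. Two caveats are deliberate and documented:
the pooled SD uses $n_1 + n_2 - 2$ degrees of freedom; and because the axis
is estimated from the same individuals it scores, the projection *d* is
optimistically biased when the number of variables is large relative to the
sample (noticeable for the 144-column shape space at ~100 faces). It is a
descriptive companion to the permutation *p*, not an unbiased population
parameter.

Univariate comparisons (overall skin L\*, a\*, b\*, and each contrast) use
classical one-way ANOVA with $R^2 = SS_{between}/SS_{total}$ and, for two
groups, `df2 = n − 2` (the classical choice; published tables sometimes
print `n − 1`-style denominators). Attractiveness correlations use Pearson's
*r* with a two-sided *t*-based *p*. Rater agreement uses ICC(3,k) — two-way
mixed, consistency, average-measures: $(BMS - EMS)/BMS$ from the additive
stimulus + rater model. The design must be complete; incomplete rating
designs (raters who saw random subsets) should be subset upstream, never
silently imputed.

## The synthetic population generator

`population_spec()` fixes the study conditions the generators emulate;
`simulate_study()` produces landmarks, color tables and rating matrices
that exercise every downstream contract. Choices and defaults:

* **Sample size** 50 faces per sex — the order of the per-population samples
  typical of this kind of study.
* **Shape**: females are a bilaterally symmetric 72-point template (unit
  centroid size) plus isotropic Gaussian landmark noise
  (`landmark_noise_sd = 0.01`); males are additionally displaced by
  `m_shape = 0.03` along a unit-norm field (wider jaw and lower outline,
  lowered brows, longer chin — chosen for anatomical plausibility; all
  tests depend only on its magnitude). Each raw configuration is then
  rotated (±15°), scaled (0.8–1.2) and translated — nuisance that GPA must
  remove. The resulting between-sex Procrustes distances (~0.03) match the
  range reported for real populations.
* **Color**: per-region female means of a light-skinned population with
  darker features; male offsets default to −2.5 L\* and +1 b\* on the skin
  regions (males darker and slightly yellower). Individual variation is a
  per-channel *complexion deviation shared across all regions of a face*
  (`color_noise_sd`, L\* SD 3), plus small independent per-region
  measurement noise (`region_noise_sd`). The shared structure is what makes
  a person who is lighter lighter everywhere; it also makes the analytic
  expectation $d \approx \Delta L^*/\sigma_L$ hold for the five-area mean,
  which the recovery tests rely on.
* **Ratings**: stimulus effect + rater leniency + residual noise, rounded
  and clamped to the 7-point scale. The continuous-model expectation is
  $ICC(3,k) = \sigma_s^2 / (\sigma_s^2 + \sigma_e^2/k)$; defaults give
  ≈ 0.97 with 30 raters. Rounding and clamping attenuate agreement
  slightly, which the test tolerance bands absorb.

What the generator does **not** emulate: correlated (anatomically
structured) shape covariance, any coupling between a face's shape and its
color, asymmetric faces, or photometric artifacts of real photography.
Passing tests therefore demonstrate that the estimators recover known
parameters under clean conditions — not that real-image segmentation or
digitization error is handled.

## Numerical and degenerate-input policy

Configurations with zero centroid size abort by specimen name; identical
sex means abort as a degenerate axis; zero pooled SD makes `cohens_d()`
error, while the permutation test downgrades that to `d = NA` with a
warning so a perfectly separated comparison still yields its *p* value.
Zero-denominator contrasts become missing values and propagate through
listwise deletion, with every excluded specimen logged in the run report.

## Validation suite and problem sizes

`run_validation_suite()` re-derives the calibration claims by simulation:
type-I error of the permutation test at α = 0.05 over 200 datasets of 20
exchangeable rows (tolerance: twice the binomial SE); recovery of
$d = \Delta L^*/\sigma = 2$ at 200 faces per sex within ±0.35; recovery of
the true shape displacement magnitude — measured by a noiseless two-face
run through the same pipeline — within 5% at 1000 faces per sex (the plain
between-mean distance is biased upward by noise, and the bias only falls
safely inside 5% at this size); and ICC recovery within ±0.03 for a design
tuned to 0.95. The `targets` override exists to let the suite's own failure
detection be tested by injecting a wrong expectation.

## A worked run

```{r, message = FALSE}
study <- simulate_study(population_spec(n_female = 30, n_male = 30, seed = 1))
report <- run_population_analysis(list(
  name = "demo",
  landmarks = study$landmarks, colors = study$colors,
  ratings = study$ratings, pairing = study$pairing,
  n_perm = 999, seed = 1
))
report$summary
report$anova_skin
```

```{r, fig.width = 6, fig.height = 4}
plot_dimorphism_scores(report$scores)
```

## Known limitations

* Semilandmarks are fixed; no sliding criterion is implemented.
* Shapes are two-dimensional; no 3-D support.
* The projection *d* for high-dimensional spaces is optimistic (see above);
  compare spaces by their permutation *p* and mean distance, not by *d*.
* No multiple-testing correction is applied across the per-channel and
  per-feature ANOVAs.
* Automatic facial-region segmentation and photographic color calibration
  are out of scope: masks and calibrated images are inputs.
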