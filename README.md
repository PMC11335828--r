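# facedim

Quantifies **sexual dimorphism of human faces** in two channels at once:

* **shape** — SShD scores from 2-D landmark configurations: faces are
  symmetrized (object symmetry), jointly aligned by Generalized Procrustes
  Analysis, and projected onto the axis joining the female-mean and
  male-mean shapes;
* **color** — SCoD scores from CIELAB skin measurements (cheek, forehead)
  and adapted Michelson contrasts of the eye, brow, and lips regions
  against their surrounding skin,
  `C_f = (L_s − L_f)/(L_f + L_s)`.

In either feature space the axis is `d = MM − FM` (difference of sex-mean
vectors), an individual's score is the dot product `⟨x, d⟩` (higher = more
male-typical), and the magnitude of dimorphism is `‖d‖`, the Euclidean
distance between sex means. Inference uses a label-permutation test with
add-one p values, Cohen's *d* effect sizes, per-channel one-way ANOVA with
R², Pearson correlations against perceived attractiveness, and ICC(3,k)
inter-rater reliability. A synthetic two-sex population generator with
known dimorphism parameters supports validation end to end.

The package is tidyverse-native: functions take data frames and return
tibbles, fitted objects have `tidy()`/`glance()`/`autoplot()` methods.

## Worked example

Simulate a population of 30 faces per sex (males: wider jaw and lower
brows at Procrustes magnitude 0.03; skin 2.5 L\* units darker and slightly
yellower), then run the full analysis:

```r
library(facedim)

study <- simulate_study(population_spec(n_female = 30, n_male = 30, seed = 1))
report <- run_population_analysis(list(
  name = "demo",
  landmarks = study$landmarks, colors = study$colors,
  ratings = study$ratings, pairing = study$pairing,
  n_perm = 999, seed = 1
))

report$summary
#> # A tibble: 2 × 9
#>   space mean_distance p_value cohens_d n_perm n_female n_male  seed population
#>   <chr>         <dbl>   <dbl>    <dbl>  <int>    <int>  <int> <int> <chr>
#> 1 shape        0.0352   0.001     3.38    999       30     30     1 demo
#> 2 color        4.93     0.002     1.01    999       30     30     1 demo
```

Both spaces show significant dimorphism: the sexes sit 0.035 Procrustes
units apart in shape and 4.9 (mixed CIELAB/contrast) units apart in color,
and no more than a handful of the 999 label permutations reach those
distances. `cohens_d` is computed on the projection scores along the
observed axis; for the 144-column shape space at n = 60 it is
optimistically biased (see the methods vignette) — compare spaces by
`p_value` and `mean_distance`.

```r
report$anova_skin
#> # A tibble: 3 × 8
#>   measure statistic   df1   df2  p_value r_squared cohens_d     n
#>   <chr>       <dbl> <int> <int>    <dbl>     <dbl>    <dbl> <int>
#> 1 skin_L      14.5      1    58 0.000340    0.200    -0.983    60
#> 2 skin_a       2.36     1    58 0.130       0.0391    0.397    60
#> 3 skin_b       5.13     1    58 0.0272      0.0813    0.585    60
```

Overall skin lightness (the mean of the five skin areas) differs strongly
between the sexes — males darker, d ≈ −1 — redness does not, and
yellowness differs mildly, matching the offsets the generator planted.
`report$icc` shows the raters agree at ICC(3,k) ≈ 0.94, and
`plot_dimorphism_scores(report$scores)` draws the violin plot of SShD and
SCoD score distributions by sex.

The same analysis runs from files (TPS landmarks, CSV color table and
pairing, CSV rating matrices) via a YAML config:
`run_population_analysis("run.yaml")`.

## Package tour

| area | functions |
|---|---|
| Landmarks | `read_tps()`, `write_tps()`, `face_pairing()`, `symmetrize()`, `gpa()`, `centroid_size()` |
| Color | `srgb_to_lab()`, `region_mean()`, `measure_regions()`, `mean_skin_color()`, `michelson_contrast()`, `contrast_profile()` |
| Dimorphism | `assemble_sshd_matrix()`, `assemble_scod_matrix()`, `build_axis()`, `project_scores()`, `mean_distance()` |
| Inference | `permutation_distance_test()`, `cohens_d()`, `anova_oneway()`, `pearson_r()`, `icc_3k()` |
| Synthetic data | `population_spec()`, `face_template()`, `generate_landmarks()`, `generate_colors()`, `generate_ratings()`, `simulate_study()` |
| Orchestration | `run_population_analysis()`, `run_validation_suite()`, `read_run_config()` |

The methods vignette (`vignettes/facedim-methods.Rmd`) documents the model,
its assumptions, all tunable parameters with defaults and rationale, and
what the synthetic validation does and does not demonstrate.
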