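# linecross

Movement and habitat-selection analysis of radio-tracked animals around
**linear anthropogenic features** — roads, paved foot trails, roadside
buffer habitat, and powerline clear cuts.  The package was built for
telemetry studies of small-bodied, sit-and-wait terrestrial predators
(its motivating system is a suburban population of copperhead snakes
confined to a ~45 ha forest park), where long stationary runs make
correlated-random-walk null models inappropriate and zero-inflated
displacement data call for hurdle models.

It provides three complementary inferential tools plus the plumbing to
run them end to end:

1. **Trajectory-randomization null models.**  Each animal-year path is
   rigidly rotated about its true start (`random_angle`), or translated
   to a uniform random start inside the study area and rotated
   (`random_start_random_angle`), 1000 times.  Feature interactions
   (road/trail crossings; relocations inside the powerline or roadside
   polygons) are tallied for the observed and each randomized path,
   pooled by sex with *paired* summation, and summarized by the
   percentile statistic

   *P*ᵢ = (#{null < observed} + ½·#{null = observed}) / n,

   read like a randomization p-value: *P*ᵢ < 0.05 ⇒ avoidance,
   *P*ᵢ > 0.95 ⇒ preference.  Leave-one-individual-out cross-validation
   (`loiocv()`) gauges how much any single animal drives a result.

2. **Step selection functions (SSF).**  Every realized movement step is
   matched with 10 random available steps sharing its start (gamma step
   lengths fitted per sex, uniform turn angles) and scored with four
   binary covariates: crossed a road, crossed a trail, ended in the
   powerline cut, ended within 5 m of a road.  The conditional logistic
   likelihood Π exp(xᵤβ)/Σⱼ exp(xⱼβ) is maximized exactly (Newton), or
   through the equivalent Poisson stratum-intercept reformulation, with
   optional individual-level Gaussian random slopes (Laplace
   approximation).  Coefficients are reported as **relative selection
   strength**, RSS = exp(β): the multiplicative odds of choosing a step
   with the feature over an otherwise identical step without it.

3. **Movement-state models.**  A sex-specific mixed gamma **hurdle
   model** (binomial move/stay + gamma step length, log link, animal
   random intercepts) and a **context-dependent movement** model:
   mixed logistic regression of moving on whether the *previous*
   relocation sat inside a habitat polygon, reported as odds changes
   ((e^β − 1)·100 %) and shifted probabilities
   (logit⁻¹(logit(p) + β)).

A synthetic-data module (`sim_config()`, `simulate_population()`)
generates landscapes and telemetry with known ground truth — the same
exp(β·x) choice kernel the SSF fitter maximizes — so every stage is
testable without field data.

## Worked example

```r
library(linecross)

sim    <- simulate_population(sim_config(seed = 11))   # 23 animal-years, ~85 fixes each
relocs <- build_trajectories(sim$fixes)                # field averaging protocol

nulls <- pooled_null_analysis(relocs, sim$landscape,
                              null_scheme("random_angle", n_paths = 1000, seed = 11))
print(nulls)
#>  sex             feature observed    p_i null_mean ...
#>    F    buffer_occupancy      128 1.0000    24.366
#>    M         trail_cross       57 0.9985    26.016
#>    ...
```

Both sexes occupy the roadside buffer far more than any of 1000 rotated
paths (*P*ᵢ = 1.000: preference), and males cross trails more than 99.8%
of them — the generator's truth (β_buffer = +0.9, β_trail = +0.6) showing
through at the whole-path scale.

```r
ssf <- build_ssf_data(relocs, sim$landscape, n_random = 10, seed = 11)
fit_conditional_logistic(ssf$F$sets)
#> Step-selection fit (fixed effects, 471 strata)
#>              term estimate    se    lwr    upr   rss
#>        road_cross   -1.680 0.381 -2.426 -0.934 0.186
#>       trail_cross    0.790 0.503 -0.196  1.775 2.203
#>  end_in_powerline    0.786 0.178  0.438  1.134 2.195
#>     end_in_buffer    1.166 0.222  0.731  1.601 3.210
```

The female SSF recovers the simulated road-crossing avoidance
(truth −1.7, estimate −1.68): a step crossing a road has 0.19 times the
odds of being chosen (RSS), i.e. the animal is ~5.4× more likely to
avoid the crossing, given the choice.

```r
ctx <- fit_context_movement(context_records(relocs, sim$landscape, "buffer"))
print(ctx)
#> Context-dependent movement: beta = -0.472 (95% CI -0.740, -0.204)
#>   P(move | outside) = 0.51 (0.49-0.54)
#>   P(move | inside)  = 0.40 (0.34-0.46)
describe_odds_change(ctx$beta)
#> [1] "38% lower"
```

Snakes simulated with a lower move probability in the buffer (0.37 vs
0.50 outside) are correctly found less likely to move when occupying
roadside habitat.

The whole analysis (preprocess → null paths → SSF → movement models →
figures + manifest) runs as one call:

```r
run_pipeline(run_config(simulate = TRUE, seed = 1, out_dir = "run1"))
```

or from a shell via the bundled CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/linecross.R", package="linecross"))')" \
    all --simulate --seed 1 --out run1
```

## Input formats

* Relocations: CSV with `animal_id,sex,timestamp,x,y[,reading_index]`,
  ISO-8601 timestamps, coordinates in projected planar meters.
* Landscape: GeoJSON FeatureCollection in the same projected CRS; each
  feature tagged with a `layer` property — `roads`, `trails`,
  `powerline`, `road_polygon`, `boundary` (the 5 m `road_buffer` is
  derived on read, or supplied explicitly).
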