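---
title: "Methods: null paths, step selection, and context-dependent movement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: null paths, step selection, and context-dependent movement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(linecross)
```

# The problem

Telemetry studies of small terrestrial predators in fragmented habitat
ask whether linear human features — roads, paved trails, powerline clear
cuts, mowed roadside verges — act as barriers, corridors, or habitat.
Two properties of the data shape everything in this package:

* **Sit-and-wait movement.**  Animals often stay put for days, so
  displacement series are zero-inflated and successive fixes are highly
  dependent.  Correlated-random-walk nulls, which resample step lengths
  and turns, destroy exactly the path structure (stationary runs,
  hibernaculum-anchored season shape) we need to hold fixed.
* **Small samples of individuals.**  A handful of animals tracked over
  a few seasons means individual idiosyncrasy can masquerade as a
  population pattern; every analysis carries an individual-level check
  (LOIOCV, random effects).

# Preprocessing: the relocation protocol

GPS error can fabricate movement in a species that moves meters per day,
so raw readings pass through a field-calibrated protocol
(`average_relocation()`, `build_trajectories()`):

* movements of **≤ 1 m** are not unique locations — the fix inherits the
  previous coordinates exactly;
* a movement **> 1 m** needs two readings (different days, different
  satellite geometry) within **3 m** of each other; the first qualifying
  pair, in reading order, is averaged.  Readings that never pair are
  unresolved and excluded with a warning.

The protocol is stated for *raw* multi-reading tables.  Tables in which
no relocation event carries repeated readings are treated as already
field-averaged: single readings are then authoritative and only the 1 m
collapse rule applies.  (Without this, every pre-averaged dataset would
be rejected wholesale.)  "Year" is the calendar year of the fix; active
seasons here run April–November, so no season spans New Year.  An
animal-year with fewer than two unique locations supports no movement
inference and is dropped with a warning.

# Null paths and the percentile statistic

For each animal-year trajectory we build `n_paths` (default 1000)
randomized copies (`pooled_null_analysis()`):

* **random angle** — rigid rotation about the first relocation by
  U[0, 2π) angles.  Tests feature interaction *given* the true anchor
  (hibernaculum fidelity fixes the start);
* **random start + random angle** — the start is drawn uniformly from
  the study area (MCP of all locations merged with the property
  boundary, `minimum_convex_polygon()` + `union_polygons()`), then the
  path is rotated.  Only the start is constrained to the study area;
  the body of the path may leave it, since only the starting location
  is part of the stated randomization.

Both schemes preserve the step-length multiset and the stationary runs
exactly — the whole point of recycling the observed path.  Tallies
(`tally_features()`) count transversal line crossings for roads/trails
and *vertex* occupancy (all relocations, repeats included) for the
polygon habitats: site fidelity is part of the occupancy signal, so
stationary repeats are deliberately not collapsed.  The randomized
copies therefore carry the repeats too; rotating the full relocation
polyline is identical to rotating the unique-location polyline and
re-inserting the repeated vertices, and crossing counts are unaffected
because zero-length segments cannot cross anything.

Pooling is **paired**: the *j*-th pooled null value is the sum of the
*j*-th random path's tally over a sex's trajectories, giving exactly
`n_paths` pooled values — the histogram one draws has 1000 entries, not
1000^k combinations.  The percentile statistic uses the **mid-rank tie
rule**, P = (#below + ½·#equal)/n, which makes P of the observed count
and P of the reflected comparison sum to one, and keeps count ties from
biasing either tail.  Interpretation: < 0.05 avoidance, > 0.95
preference.

Randomness is **per-trajectory substreams** derived from the master
seed, so LOIOCV can drop an individual without perturbing anyone else's
paths, and the whole analysis is bit-reproducible given the seed.  A
consequence worth knowing: two *identical* individuals draw different
rotation angles, so their leave-one-out P values agree only up to null
Monte-Carlo error (exactly equal values would require sharing one
stream, which would correlate every trajectory's nulls).

# Step selection

Strata are built from movement steps only (unique locations > 1 m
apart); staying put is modeled by the hurdle and context models instead,
because a gamma has no mass at zero and conflating the two states blurs
both.  The first movement step of a trajectory has no turn angle and is
skipped.  Each stratum = 1 used + `n_random` (default 10) available
steps from the same start; available lengths come from the sex-pooled
gamma MLE of observed movement steps, available turns are uniform on
(−π, π] — the observed turn distribution is deliberately *not* reused;
fully random turns are the availability model.

The conditional logistic likelihood is maximized by Newton iteration on
the softmax form (`fit_conditional_logistic()`).  The classical Poisson
reformulation — a Poisson GLM of the used indicator with one intercept
per stratum, the limit of a stratum random intercept whose variance is
fixed very large (10⁶ in the usual presentation) — yields identical
covariate estimates; `fit_clogit_poisson()` implements it and the test
suite asserts agreement to 1e−3 (and to `survival::clogit` at 1e−4).
With `random_effects = TRUE`, individual-level Gaussian random slopes
(diagonal covariance — the covariance structure is not identified at
these sample sizes) are integrated by a Laplace approximation over each
animal's slope deviation; the stratum intercepts drop out *exactly*
through the conditioning, so no large-variance tuning constant is
needed at all, and sensitivity to its value (10⁴ vs 10⁶) is moot by
construction.  Random effects are at the animal level: multi-year
individuals share one deviation, a deliberate choice favoring
identifiability over a year-level structure the data cannot support.

Separation (a covariate that perfectly predicts the used step) caps the
estimate at |β| = 15 with a warning; a covariate with no within-stratum
variation anywhere raises a non-identifiability error naming it.
Intervals are Wald on the link scale, exponentiated for RSS; RSS(−β) =
1/RSS(β) by construction.

# Movement-state models

The **hurdle** factorizes into a binomial move/stay part and a gamma
(log link) step-length part with disjoint parameters, so the two are
fit independently (`fit_hurdle()`, via `lme4::glmer` with animal random
intercepts; `glm` when random effects are off or only one animal
exists).  Sex-specific mean step lengths are reported at the random
effect's center with a 95% parametric-bootstrap interval (1000 draws
from the asymptotic normal of the fixed effects); as interval-width
conventions vary between implementations, interval widths are not an
acceptance surface here.

The **context model** (`fit_context_movement()`) regresses moving on
whether the *previous* relocation lay in the habitat polygon, pooling
sexes (the hurdle shows no sex effect on move probability), one model
per habitat (roadside buffer; powerline) rather than one model with two
indicators — matching how the two contexts are reported and plotted.
Reporting transforms: (e^β − 1)·100% odds change and
logit⁻¹(logit(p)+β) probability shifts, mutually consistent to 1e−9.

# The synthetic world

`simulate_population()` emulates the motivating system, and its defaults
*are* the stated world — chosen once from the motivating field system's
scale and estimated quantities, not tuned to tests:

| quantity | default | why |
|---|---|---|
| animals | 7 F + 7 M, 23 animal-years | field tracking effort |
| relocations / animal-year | 85 (~daily) | field mean |
| step length | gamma, mean 21.8 m (F) / 35.1 m (M), shape 1.5 | field sex means; shape is plumbing (right-skewed, CV ≈ 0.8, typical of snake steps) |
| P(move) by habitat | buffer 0.37, powerline 0.67, other 0.5 | field context probabilities; 0.5 is the neutral baseline |
| selection β | road −1.7, trail +0.6, powerline +0.6, buffer +0.9 | field selection estimates |
| candidates per move | 50 | richer than the 10 analysis steps so the discrete choice approximates the continuous kernel being fitted |
| study area | 670 × 670 m (~45 ha) | park area |

Movement: start uniform in the study area; each subsequent relocation
draws move/stay from the *current* habitat's probability; a move draws
50 candidate steps (gamma length, uniform turn about the previous
heading) and picks one with probability ∝ exp(β·x) — exactly the SSF
kernel, so the SSF estimator is consistent for the configured truth and
recovery tests are meaningful.  Candidates ending outside the study
area are re-weighted to zero (the real animals are hemmed in by
highways; this mimics confinement without modeling it).  Stationarity
comes from the move/stay Bernoulli, never from zero gamma draws.
Optionally each moved relocation is emitted as two GPS readings
jittered ≤ 1 m to exercise the averaging protocol; the jitter RNG phase
is separated from the movement phase so toggling it never changes the
realized paths for a given seed.

What the generator does **not** emulate: hibernaculum-anchored seasonal
migration and inter-annual site fidelity, GPS outliers beyond 1 m,
irregular fix cadence, temporal autocorrelation in behavior, and
between-individual heterogeneity in β (animals share one truth).  A
green recovery test therefore establishes estimator correctness under
the assumed data-generating process — not robustness to everything real
data do.

# Numerical and geometric choices

* Coordinates are planar meters; no geodesy.  All geometry is
  hand-rolled and vectorized (no spatial stack is assumed at runtime),
  and every primitive is cross-checked in the test suite against an
  independent brute-force oracle (all-pairs segment enumeration,
  winding-number containment, gift-wrapping hulls).
* Crossings are **transversal only**: endpoint tangency and collinear
  overlap do not count (a path running along a road edge has not
  crossed it), and a segment crossing k feature segments at k distinct
  points counts k.  Whether a step *ending* exactly on a road counts as
  a crossing is undefined in the field description; transversal-only
  resolves it as "no".
* Polygon containment is **boundary-inclusive** (snap ~1e−6 m): an
  animal located on a habitat edge at GPS precision is in that habitat.
* Polygons are unions of even-odd parts.  Dilation
  (`buffer_polygon()`) of convex parts is an exact offset ring with
  ≥ 16 chords per quarter arc (area error < 0.2%, tested against the
  closed form wh + 2(w+h)d + πd² at 1%); non-convex parts dilate to
  the exact union of the part and per-edge capsules — containment is
  exact, area falls back to a documented grid estimate.
* Union area uses inclusion–exclusion with Sutherland–Hodgman clipping
  when a convex part is involved (always true for the MCP ∪ boundary
  study area); disjoint parts sum exactly.
* Gamma MLE: Newton on the profile likelihood in the shape with the
  standard closed-form start; degenerate (zero-variance) input errors.
* Optimizers are deterministic given the data; all simulation entry
  points take explicit seeds, and seeds derived from a master stay
  below 2³¹.

# Calibration of the percentile statistic

Under a feature-indifferent world (all β = 0, one move probability
everywhere) rotation nulls are exchangeable with the observed path, so
P should be approximately uniform.  With count data P is discrete, and
at very small scale tie mass concentrates in the interior, deflating
tail frequencies well below nominal; the calibration experiment
therefore uses a world large enough for count-rich tallies (6
single-year females, 60 relocations, 200 rotations, 200 replicate
datasets) — chosen for that reason, once, before freezing the test.
Boundary confinement mildly breaks exchangeability near the study-area
edge; empirically the outside-[0.05, 0.95] frequency stays within the
0.10 ± 0.05 acceptance band for all four features.

# Known limitations

* The random-slope Laplace fit is practical for a handful of binary
  covariates and tens of animals; it is not a general GLMM engine.
* Grid-estimated areas of non-convex dilations are approximate (the
  pipeline never relies on them; the roadside buffer derives from a
  convex footprint).
* The null-path schemes assume the landscape is meaningfully sampled by
  rigid motions of the observed path; in a study area much larger than
  a home range the random-start scheme dilutes feature exposure.
* LOIOCV equality for literally identical individuals holds only in
  distribution (see the substream note above).
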