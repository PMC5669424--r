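---
title: "Modelling perceived visual complexity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling perceived visual complexity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symcomp)
```

## The model

Perceived visual complexity of abstract black-and-white patterns is
treated as a two-factor quantity: a *quantitative* factor — how much
content the image carries — raises it, and a *structural* factor — how
strongly the content is organized, chiefly by mirror symmetry — lowers
it. `symcomp` operationalizes the quantitative factor with
compression-based measures (the best-behaved being `RMSGIF`, the GIF
compressibility of the local RMS-contrast map) and the structural factor
with a weighted four-axis mirror-symmetry score, and provides the full
fitting machinery to confront linear and random-forest combinations of
24 such predictors with human (or simulated) 5-point complexity
ratings, including per-participant models and random-slope mixed
models for individual differences.

## The mirror-symmetry measure

For a binary image with `m` rows and `w` columns, symmetry about the
vertical axis compares each pixel with its mirror across the axis.
With `n = w/2` pair columns (`(w-1)/2` when `w` is odd; the centre
column is ignored), and `X_ij = 1` when the pair starting at border
column `j` of row `i` matches,

```
s = 2/(3·m·n) · Σ_i Σ_j X_ij · (1 + (j−1)/(n−1)) .
```

The weight grows linearly from 1 at the border to 2 beside the axis, so
pixels close to the axis — where human observers are most sensitive to
violations — count double. The constant `2/(3mn)` is exactly the
reciprocal of the total weight, so `s ∈ [0, 1]` with `s = 1` iff the
image is mirror-symmetric. For `n = 1` the weight ratio is undefined;
the weight is then taken as 1 and the normalizer as `1/m`, preserving
continuity. The aggregate score over the four axes is
`MS = 100·(s₁+s₂+s₃+s₄)/4`; per-axis scores are exported as `MSA`
(horizontal), `MSB` (vertical), `MSC` (main diagonal), `MSD`
(secondary diagonal) — the aggregate does not depend on this order.

**Diagonal axes.** The vertical-axis formula transfers to the
horizontal axis by transposition. For the diagonals no transposition
maps the axis onto a column axis, so the implementation enumerates the
reflected pairs across the diagonal directly — the pair at offset `d`
from a `w×w` image's diagonal gets weight `1 + (n_d − d)/(n_d − 1)`
with `n_d = w − 1`, again 2 beside the axis and 1 in the far corner,
normalized by the total weight. This reproduces the orthogonal-axis
formula exactly in its own setting and is verified against a
brute-force pair-enumeration oracle to 1e-12 in the tests. The
secondary diagonal is scored as the main diagonal of the 90°-rotated
image.

**Transforms.** Raw `MS` barely distinguishes a perfectly symmetric
pattern (100) from one whose symmetry was locally broken (≈ 90–97),
yet observers judge the latter far more complex. The per-axis
transforms `s → s^a` (power, default `a = 20`), the matched
exponential, and threshold-stretch (`s → max(0, (s−t)/(1−t))`,
`t = 0.95`) give small deviations from perfection large influence
before averaging: `MSA20 = 100·mean(s_axis^20)`.
`transform_search()` sweeps a grid of transforms and ranks them by the
R² of the two-predictor model with a companion (quantitative)
predictor.

## The pattern simulator

Stimuli are 8×8 grids holding 36–44 black *elements*: each cell is
empty, one of the four half-square triangles, or full (counting two
elements). Rendering maps each cell to a `px_per_cell` square block
(default 75, giving the 600×600 stimulus format); triangle masks
include their diagonal pixels, which makes every grid reflection
correspond exactly to an image reflection at any rendering resolution
(the parity of `px_per_cell` is therefore immaterial — a property the
tests pin by checking that rendering and reflection commute).

`generate_pattern()` uses simulated annealing, but symmetry is exact
*by construction*, never approximate: moves resample whole orbits of
cells under the reflection group generated by the target axes, with the
orbit's admissible states restricted by stabilizer constraints (a cell
on a target diagonal cannot hold a triangle its own reflection
contradicts). The energy is the element-count distance to `[36, 44]`
plus a penalty for every non-target axis scoring at or above the
asymmetry threshold (0.98, configurable), evaluated on a small
rendering (4 px/cell); acceptance requires zero energy, and the
geometric schedule (T₀ = 1, factor 0.95, 200 steps per level,
T_min = 1e-3) terminates early once it is reached. Failure to reach
zero energy raises an error naming the residual energy. Declared axes
are always re-verified post hoc by the independent oracle in the test
suite rather than assumed.

`break_symmetry()` produces the just-not-symmetric variants: it
re-randomizes a 3×3 cell window, rejecting candidates until the image
changes, the element count stays in range, and *every* previously
perfect axis drops strictly below 1. The window move permutes the
window's states and re-orients its triangles (with an occasional
single-cell jitter) — a count-preserving proposal; re-drawing all nine
cells uniformly has an expected nine elements in the window and almost
never respects the count range when the window is sparse or dense, so
it stalls near the range boundaries. The window origin is an explicit
argument; corpus generation draws it from the pattern's derived seed.

## The predictor battery

- **Compression ratios** (`GIF`, `PNG`, `TIF`, `JPG`): encoded bytes
  per pixel, averaged over the image and its 90° rotation (compression
  is not rotation-invariant). Encoders are pinned: the package's own
  GIF87a/LZW encoder (verified bit-exactly against the Pillow decoder
  in the tests), `png`, `tiff` with LZW, and `jpeg` at quality 90 on
  8-bit grayscale. Absolute byte counts are encoder-specific;
  cross-encoder agreement should be expected at the rank level only.
- **Edge operators**: phase congruency (log-Gabor formulation, 4
  scales, 6 orientations, noise-thresholded energy over summed
  amplitude — parameters recorded in `run_config()`); Canny (Gaussian
  σ = 1, Sobel gradients, non-maximum suppression, Otsu-derived high
  threshold, low = 0.4·high, hysteresis by connected components);
  perimeter (black pixels with a 4-neighbour background, image border
  counting as background); and local RMS contrast (population SD in a
  5×5 reflective window over mean image intensity). Each map yields
  `MN`, `SD`, `MNSD = MN·SD`, and the GIF ratio of the (8-bit
  quantized) map.
- **Structural measures**: `APB` (mean absolute black-mass imbalance
  over eight axes through the centre, scaled so perfect balance scores
  100), `DCM` (black-centroid distance from the image centre over the
  half-diagonal), `MS`, and `HG` (entropy of the black-mass
  distribution over an 8×8 block grid, relative to log 64). The APB
  and HG constructions follow their usual descriptions but were not
  reprinted in full in the literature this package draws on; their
  absolute values should be treated as package-specific, and no
  validation here depends on them beyond their invariants.

## The rating simulator

`simulate_ratings()` draws, for participant *p* and stimulus *s*,

```
latent = β₀ + (β_q + b_q,p)·quant_s + (β_s + b_s,p)·sym_s + u_p + v_s + ε
```

and discretizes by rounding and clipping to 1..5. Defaults: β₀ = 3,
β_q = 0.5 on standardized `RMSGIF`, β_s = −0.4 on the standardized
*transformed* symmetry (`MSA20`) — using the transformed score as the
structural factor encodes the empirical finding that perception reacts
sharply to small deviations from symmetry, and it is what makes broken
patterns properly complex in simulation. Random effects are Gaussian
and independent, slope SDs 0.1, intercept SDs 0.2 (participants and
stimuli), residual SD 0.5 — values a rating study of this kind would
find unremarkable; they are deliberately fixed once and not revisited.
Round-and-clip discretization is simple and transparent, but it is not
innocuous: group-mean slopes of heavy-tailed predictors are attenuated
by floor/ceiling effects (a few percent in Set-1-like corpora), and
nonzero slope SDs make the realized group slope vary by
`slope_sd/√n_participants` across replicates — more than the OLS
standard error captures. Parameter-recovery checks therefore isolate
the fixed effects (variance components at zero); both effects are real
features of 5-point scales, not estimator defects.

## Modelling choices

- Predictors are z-standardized with the sample SD (n−1) before
  fitting, so slopes are comparable.
- Best-subset selection enumerates all subsets up to size 3
  (C(24,3) = 2024 fits) through cross-product algebra — one moment
  computation, then a tiny solve per subset — with lexicographic
  tie-breaking for determinism; the top model per size is refitted for
  full inference.
- Linear-model R² is the full-data coefficient of determination;
  forest R² is the squared Pearson correlation of pooled out-of-fold
  predictions (10 folds, seeded permutation; each stimulus predicted
  exactly once out of fold). Forests use the regression defaults of
  the classical implementation: 500 trees, `max(1, ⌊p/3⌋)` split
  candidates.
- Mixed models are fitted by maximum likelihood (not REML) so that
  AIC/BIC comparisons across random-effects structures are valid; the
  four structures are random intercepts for participants and stimuli
  (M1), plus an uncorrelated participant slope on the first predictor
  (M2), on the second (M3), or both (M4). Each slope is tested by a
  likelihood-ratio test against its nested model; because the null
  puts a variance on the boundary, the χ²₁ p-value is halved.
  Non-convergence is reported per model without aborting the
  comparison.
- Per-participant selection always uses exactly the stimuli each
  participant rated; participants with constant ratings are flagged
  and excluded from the frequency counts.

## Problem sizes

The test suite builds a 504-pattern corpus (84 per symmetry class,
48×48 rendering) for selection and ordering checks, uses 500-row
simulated predictor tables with 50 participants for recovery, and runs
the mixed-model power/size simulations at 150 stimuli × 25
participants with 12 replicates per condition. The acceptance script
uses a 440-pattern corpus (40 per class plus broken variants) with 50
simulated raters. These sizes were chosen to estimate every quantity
stably; all are parameters, not constants.

## Known limitations

- The symmetry measure requires predefined axes; arbitrary-angle
  symmetry detection is out of scope, as are grayscale extensions of
  the measure (binary equality only).
- Absolute compression ratios are encoder-pinned; comparing against
  numbers produced with other encoders is meaningful only at the rank
  level.
- The rating simulator emulates the two-factor structure, crossed
  random effects and scale discretization of real rating studies, but
  not presentation-order, familiarity or session effects; passing
  recovery tests demonstrates the estimators, not the psychology.
- The published stimulus sets themselves are not redistributed; the
  reproduction path (`reproduce_published_models()`) activates only
  when their supplementary tables are supplied locally.
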