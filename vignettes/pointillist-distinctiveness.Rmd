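---
title: "Models and methods for pointillist transition distinctiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for pointillist transition distinctiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macchia)
```

This vignette is the package's own account of its science: the stimulus
model, the colour measures, the synthetic-observer design, and the numerical
and design choices that were genuinely open. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The question

Pointillist textures build transitions between regions out of separately
visible dots, and those transitions can be almost purely chromatic. The
package quantifies the *distinctiveness* of a bipartite colour transition —
the achromatic Michelson contrast that looks "mutually equally distinct" —
and asks which of three per-pair predictors organises such settings best:
CIE luminance contrast, CIEDE2000, or raw Euclidean distance in the encoded
RGB cube.

## Stimulus model

A stimulus is two abutting squares (default 128 px each). Dot layout:

1. Uniform random seed points over the union rectangle (default 600 per
   square).
2. A Voronoi tessellation of the seeds, each cell clipped to the rectangle.
3. One circular dot per cell, centred at the cell's barycentre (the area
   centroid of the clipped polygon), with radius equal to the shortest
   barycentre-to-vertex distance times a common factor.
4. The common factor is calibrated by bisection so that the rasterised
   uncovered background fraction is within 0.02 of its target (default
   0.25); overlapping dots count once. Uncovered area is monotone
   non-increasing in the factor, so bisection cannot miss.

Hard edges classify each dot left/right by the abscissa of its centre; soft
edges ramp the probability of a *right* designation linearly across a strip
(default 0.2 of the square side) centred on the midline. The ramp affects
designation only — each dot's colour is drawn from the gamut of the side it
was designated to, never blended. Three gamuts:

* **achromatic** — grey levels, normal dither of SD 0.20 of the full
  black–white scale around the side mean, clipped to `[0, 1]`;
* **monochromatic** — tints and shades of the side's cardinal colour with
  Ostwald-style coefficients (c, w, k), c + w + k = 1 exactly, drawn by
  skewing the first of three uniforms by a factor 4 before normalising
  (favouring saturated colour);
* **polychromatic** — hue drawn from a symmetric triangular density one
  colour-circle step to each side of the side's cardinal, then the same
  (c, w, k) dither on the dithered full colour.

Mixing `c F + w W + k K` is additive in linear light (decode the gamma,
mix, re-encode); an encoded-domain option exists for ablation. The paper's
own layout table (dot counts, fill, strip width) is not in the available
text, so the layout defaults above are explicit reconstructions, all exposed
in `stimulus_spec()`.

## Colour measures

The display model is a `display_calibration()`: primary luminances
(default 69, 197, 53 cd/m² — the measured R:G:B ratio), primary
chromaticities (the display's own chromaticities are not published, so the
default is sRGB/BT.709 with D65 white, the generic-display convention), and
a pure power-law gamma 2.2 (the piecewise sRGB curve is available behind
`transfer = "srgb"`). Photometric luminance is the dot product of decoded
linear components with the primary luminances, which makes the yellow/white
fraction 83% and the blue/white fraction 17%, a luminance range of a factor
five, and a maximal cardinal Michelson contrast just under 70%.

Note that the luminance vector and the Lab conversion are deliberately
independent: `rgb_to_lab()` builds its RGB→XYZ matrix from the
chromaticities, scaled so encoded white maps exactly to the white point,
because CIEDE2000 is defined against a reference white, while `luminance()`
uses the measured (non-sRGB) luminances. CIEDE2000 is implemented in full
(lightness, chroma, hue and rotation terms, `kL = kC = kH = 1` by default)
and is verified in the test suite against the published verification pairs
to four decimals.

The RGB-cube distance is the Euclidean norm of the *encoded* coordinates —
no gamma decoding by design: that is the whole point of the "poor man's"
model. For cardinal pairs it takes the values 1, √2, √3 for 1, 2, 3
differing channels, strictly increasing with distance along the six-step
colour circle (Y = 0, G = 1, C = 2, B = 3, M = 4, R = 5), which the package
also exposes directly as `colour_circle_distance()`.

## Transition structure

`decompose_transition()` compares a cardinal pair channel by channel. A
channel switching between 0 and 1 is a *transition* (polarity = sign of
right − left); a channel fully on at both sides is a *veil*. A channel off
at both sides is counted as *absent*, not as a veil: veils are discussed as
coloured (red, green or blue) overlays, and a dark channel overlays nothing.
The 15 pairs split into 6 analogous (N_t = 1), 6 incongruent (N_t = 2) and
3 complementary (N_t = 3) pairs, and N_t equals the colour-circle distance.

The linear distinctiveness model `D = a0 + a_t N_t + a_v N_v` is fitted by
ordinary least squares with one row per (observer-normalised) response. The
aggregation level is configurable because the original fit's level is not
stated; per-row fitting is the default. The per-channel/per-veil refinement
(indicators for RK/GK/BK transitions and R/G/B veils — a dozen parameters)
is implemented behind `extended = TRUE` but off by default: with only 15
distinct stimuli it is too detailed to be the primary description.

## Synthetic observers

Observer `i` responds `clip(offset_i + gain_i · latent + noise)`, with the
latent distinctiveness produced by a ground-truth model (`rgb_cube`,
`luminance_contrast`, `ciede2000`, or `linear_nt_nv`) and an affine map to
contrast units. For the three colour models the map is auto-calibrated so
the 15 pair latents span `[0.30, 0.55]`, the global band of pooled
settings; `linear_nt_nv` is already in contrast units and uses the identity.
Defaults: 5 observers, offset SD 0.05, log-normal gain with log-SD 0.15,
response noise SD 0.05, and 4 conditions × 15 pairs × 4 replicates = 240
rows per observer (the replicate structure is a reconstruction; the
bookkeeping, not the repetition scheme, is documented). Response-step
quantisation (the live experiment moved in 10% steps) is available but off
by default, since pooled settings are finer-grained. Response times are
emitted as log-normal values with a median near 9 s purely for interface
completeness and are never analysed.

Two identifiability choices deserve emphasis:

* **Panel centring.** Only offsets and gains *relative to the panel
  consensus* are identifiable — the consensus defines the response scale.
  Panels are therefore centred (median gain 1, median offset 0) so that the
  consensus observer is the identity map and recovered coefficients live on
  the latent scale.
* **Gain pivot.** A gain is applied about a pivot contrast of 0.42 (the
  middle of the response band) rather than about zero: an observer who
  "spreads out" their settings does so around their operating range. Without
  the pivot, gain idiosyncrasies masquerade as large offset idiosyncrasies
  at the band location and the intercept of any downstream fit inherits
  that wobble.

## Analysis chain

* `normalize_observers()` fits, per observer, the least-squares line of
  that observer's responses against the cross-observer median of the same
  (condition, pair) cell, and inverts it. It is a single pass: the reference
  medians are not recomputed, which makes the procedure idempotent (exactly
  so on noise-free affine observers, and to numerical tolerance in
  general). An observer with constant responses has no defined slope and is
  reported as an error rather than silently dropped.
* `concordance()` computes tie-corrected Kendall τ-b between observers'
  matched cell medians, pooled and per condition, with two-sided 5%
  significance from the normal approximation; non-significant entries are
  masked in a dedicated column rather than removed.
* `summarize_pairs()` / `summarize_classes()` report (Q1, median, Q3).
* `pair_matrix()` arranges pair values into the symmetric 6 × 6 cardinal
  array (zero diagonal, doubly periodic bands by cyclic distance) and maps
  the off-diagonal range affinely onto the full grey scale per matrix.
* `compare_models()` reports Kendall τ-b and Pearson r of each model's
  predictions against observed cell medians, per condition and pooled.
  Model predictions use the nominal full-intensity cardinals of each side
  (all three models work from patch averages); zero-variance predictions
  leave Pearson r as a flagged `NA`. τ-b is the right rank statistic here
  because quantised settings guarantee ties.
* `hexagon_summary()` produces the per-fiducial spoke weights, normalised
  to unit mean so panels are comparable.

### The triangle-inequality Monte Carlo

CIEDE2000 is not a metric. `triangle_inequality_mc()` samples ordered
triples (P, Q, R) uniformly in the encoded RGB cube, converts to L\*a\*b\*
under the calibration, and by default counts a violation when the direct
route P–R exceeds the detour P–Q–R through the middle colour — the sense in
which the green–cyan–magenta detour beats the direct green–magenta route.
The alternative reading, "any one of the three distances exceeds the sum of
the other two", is available as `rule = "any"` and is by symmetry about
three times as frequent; the ordered rule is the default because it is the
reading consistent with the ~3% violation rate the package's acceptance
check reproduces. Sampling is uniform in the *encoded* cube (the natural
measure on display colours). The estimate at n = 100,000 carries a binomial
standard error of about 0.06 percentage points.

## Numerical choices

* Voronoi cells are built by half-plane (perpendicular-bisector) clipping
  of the bounding rectangle, visiting neighbours in distance order and
  stopping once half the distance to the next neighbour exceeds the
  farthest current vertex — an exact early-stop bound, not a heuristic.
  Duplicate seeds are rejected as degenerate; collinear seeds are fine
  (they produce strip cells).
* Cell barycentres use the shoelace centroid; a zero-area polygon falls
  back to the vertex mean (it can only arise transiently during clipping).
* Fill calibration: bisection on the common factor in (0, 2], tolerance
  0.02 in uncovered fraction, at most 40 iterations; unreachable targets
  are errors, not clamps.
* Rasterisation paints hard (unantialiased) disks in layout order without
  overlap resolution; pixels are unit squares sampled at centres, 0-based,
  top-left origin, half-open intervals.
* Achromatic dither clips out-of-range samples rather than redrawing:
  clipping preserves the stated SD in the interior of the scale and is
  the simplest to document.
* 8-bit image quantisation rounds half to even; PNG and PPM round-trip
  bit-exactly at 8 bits.
* Gamma decode/encode compose to the identity to better than 1e−12; CWK
  membership of monochromatic dots is checked by solving for (c, w) in
  linear light with residuals below 1e−9.
* The hue-diameter grey mapping projects each pixel's hexagon-plane
  position (primaries at unit vectors 120° apart, so secondaries land on
  their own unit vectors and greys at the origin) orthogonally onto the
  chosen diameter; only on-diameter colours are treated in the source
  material, orthogonal projection is the package's extension. The
  channel-mixer mapping operates on encoded values (as image editors do);
  it coincides with the luminance mapping when the transfer is linear and
  the weights are the normalised primary luminances.

## What the generator does and does not emulate

The synthetic observers reproduce the *statistical structure* the analysis
assumes: a latent per-pair distinctiveness, affine observer idiosyncrasies,
independent response noise, optional quantisation, and the full
4 × 15 × 4 bookkeeping. They do not emulate sequential effects, learning,
asymmetric or heteroscedastic noise, condition-dependent latents (the same
latent serves all four conditions), or the display dynamics of the live
matching task. Passing tests therefore show that the pipeline recovers
known structure from data *of the assumed form*; they cannot show that
human settings have that form. Reported human-dependent numbers (pooled
median τ, response IQRs) are consequently used only as calibration anchors
for the generator's scales, never as test targets.

## Problem sizes

The test suite simulates sessions at the study's own size (5 × 240 rows),
uses 200 replicates for the coefficient-recovery property, 100 replicates
for model identifiability, 20,000-triple Monte Carlo runs for reproducibility
properties, and renders stimuli at 32–80 px squares with 30–90 dots per
square; the acceptance script uses the full 100,000-triple Monte Carlo.
These sizes were chosen so each property is measured well inside its
tolerance.

## Known limitations

* Transition structure is defined for full-intensity cardinal endpoints
  only; fractional-hue or desaturated endpoint pairs, and white/black as
  patch colours, are out of scope.
* All model predictions work from nominal side colours; models based on
  patch averages are blind to dither statistics, so textures with equal
  means but different spreads are predicted indistinguishable regardless
  of how visible their transition is.
* The Lab pipeline assumes chromaticity-accurate sRGB primaries; a display
  whose primaries deviate chromatically will shift CIEDE2000 values (the
  calibration object accepts measured chromaticities where available).
* The Voronoi construction is O(n · k) with small neighbour counts k in
  practice, adequate for the layout sizes used here, but it is not a
  general-purpose computational-geometry library.
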