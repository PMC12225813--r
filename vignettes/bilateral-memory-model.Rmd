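---
title: "The bilateral Mushroom-Body memory model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The bilateral Mushroom-Body memory model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbnav)
```

This vignette is the package's own account of the model it implements: the
assumptions behind each stage, the tunable parameters and their defaults,
the numerical choices made where the design was genuinely open, and what
the simulations do and do not establish. The scientific setting is the use
of the *fractional position of mass* (FPM) — the proportion of a large wall
shape lying left of the visual centre — by ants navigating to a feeder in a
cylindrical arena, and the hypothesis that FPM retrieval emerges from
bilaterally organised memory circuits rather than from an explicit feature
extractor.

## 1. Arena geometry and rendering

The arena is a cylinder of radius R = 1.5 m; the feeder sits r = 0.6 m from
the centre (`arena_config()`). Shapes are filled polygons given in stimulus
angles measured from the arena centre, and world azimuth 0 is placed at the
training shape's left edge, so every plotted direction reads as "degrees
right of the left edge". Azimuths increase rightward (clockwise from
above).

For a wall point P with stimulus angles (θ, ϕ) and an agent at L, the
transformed azimuth is the angle between LZ and LP (Z marks azimuth 0 at
the wall base) and the transformed elevation is
ϕ′ = tan⁻¹(R tan ϕ / |LP|). The arccos form of the azimuth is unsigned, so
the side is resolved with the planar cross product of LZ and LP; this makes
θ′ continuous and reduces it to θ at the centre (checked exhaustively on
the 90×360 grid in the test suite).

Three choices here were open and are deliberate:

* **Vertical anchoring.** Shape heights are quoted as single stimulus
  angles, so all shapes are anchored with their base on the arena floor
  (elevation 0). The physical 1.8 m wall height is *not* used for
  clipping; the wall is treated as unbounded in elevation. Shapes up to
  ~65° of elevation would otherwise be impossible on a 1.8 m wall seen
  from 1.5 m, so the stimulus-angle reading is the only self-consistent
  one.
* **Rasterisation.** Polygon outlines are sampled every 0.1° along each
  edge before transformation, then filled by the even-odd rule at the 1°
  pixel centres (half-degree positions). The fill is an own scanline
  rasteriser (crossing elevations per image column); the test suite
  verifies it pixel-for-pixel against an independent point-in-polygon
  oracle on off-centre poses. A 160°×38° rectangle viewed from the centre
  covers exactly 6080 pixels.
* **Azimuth wrap.** Transformed outlines are unwrapped to a continuous
  azimuth coordinate and pixels are queried modulo 360°, so shapes may
  cross the rear seam without special cases.

The training path runs straight from the centre to the feeder with the
agent facing ahead; `n_train = 30` views are taken at equal distances
including both endpoints (`training_path_poses()`). Testing uses a single
view from the centre, since no movement direction can be presumed for the
test scans.

## 2. View processing

A panorama is split into left and right 180° visual fields. A frontal
`overlap` of width o means the left field covers relative azimuths
[−180°+o/2, o/2) and the right [−o/2, 180°−o/2): both image the frontal o
degrees and neither the rear o degrees. The fields are stacked left-then-
right, the top 10 pixel rows are cropped, and the 80×360 remainder is
4×4 mean-pooled into the 20×90 network input (4°/pixel). Overlap values on
the study grid {0, 8, …, 40}° align field boundaries with the pooling
blocks; other even values are accepted with nearest-degree cropping.

Rotation of the agent is a circular column shift of the raw panorama
*before* splitting — exactly equivalent to re-rendering at the rotated
heading (an identity the tests assert bit-for-bit). Rotating first matches
the semantics of "the view associated with each facing direction".

## 3. The memory network

Defaults (`mb_params()`): N_KC = 25,000 Kenyon cells per hemisphere,
mean in-degree K = 8, APL firing fraction p = 0.05, crossover 0.2,
overlap 0°, depreciation α = 0.95, constant weight initialisation.

* **Connectivity.** Each of the 1800 vPNs emits
  round(2·K·N_KC / N_vPN) = 222 connections, each ipsilateral with
  probability 1−crossover, with the KC index uniform in the chosen
  hemisphere. N_vPN in the out-degree formula is the *total* vPN count:
  only then is the mean KC in-degree K across the 2·N_KC cells
  (399,600 / 50,000 ≈ 8). Sampling is with replacement and coincident
  (vPN, KC) picks merge additively — at ~222 picks into 25,000 cells the
  collision probability is negligible and the merged weight keeps the
  summed drive.
* **Weights.** Constant init sets vPN→KC weights to 1/K and KC→MBON
  weights to 1/(p·N_KC), which normalises the maximal expected novelty to
  exactly 1. Random modes draw uniformly on [0, 2/K] and
  [0, 2/(p·N_KC)], preserving the means.
* **APL.** The APL is modelled as an exact top-round(p·N_KC) selection per
  hemisphere. Ties at the threshold are broken by ascending KC index —
  deterministic and effectively unbiased because KC indices are random
  with respect to connectivity — and cells with zero input never fire, so
  a blank scene silences the MBON rather than firing an arbitrary subset.
* **Learning.** Anti-Hebbian depreciation of KC→MBON weights only:
  w_trained = w_init · α^n_tot, with n_tot the number of training views
  on which the KC fired. Dopaminergic gating and MBON feedback are
  intentionally not modelled. With α = 1 training is a no-op; training
  can only ever lower the novelty of any fixed view.
* **RNG contract.** One seed per model instance; construction consumes it
  in a fixed order (crossover draws, KC targets, vPN weights, output
  weights), so connectomes are bit-reproducible and identical across α/p
  scans at a fixed seed. Ensembles use consecutive seeds from a base
  seed.

The forward pass (sparse input summation plus APL readout) is implemented
in compiled code (RcppArmadillo) with semantics identical to the reference
R implementation `apl_select()`; the tests compare the two paths directly.
A full 360-direction scan of a default-size model takes on the order of
two seconds on one CPU.

## 4. Rotational signals and the IDF baseline

`rotational_signals()` scans all 360 integer facing directions and returns
left novelty, right novelty, their sum S and difference Δ.
`ensemble_signals()` averages over seeded model instances (the reporting
convention is the mean of 50 initialisations ± one standard deviation;
smaller ensembles are used in unit tests where only the machinery is under
test).

The image difference function baseline (`rotational_idf()`) is the RMS
pixel difference between the processed test view at each direction and the
best-matching stored training view — computed on processed views so the
baseline sees exactly the network's input space. The minimal set collects
directions within a tolerance ε of the minimum, default 1% of the IDF's
dynamic range. One caveat found during development: the 4° mean-pooling
blocks impose a deterministic ripple of roughly 1.3% of the range on an
otherwise flat IDF floor, so at 1% the genuinely flat region fragments
into short runs; analyses of flat-region *width* should use a tolerance
just above that ripple (the flatness test uses 2%). For the nested pair
train 160°×38° / test 80°×38° the flat region spans ≈ 29°, which is what
leaves the goal direction under-determined for sum-like signals and
motivates the bilateral difference signal.

## 5. Heading distributions

Tentative directions are drawn continuously uniformly on [−180°, 180°);
signals are looked up at the nearest integer degree (the lookup rule is
not dictated by the sampling story, and nearest-degree is the least
structured choice); acceptance follows
P(S, Δ) = e^(−β|S−S_min|/(S_max−S_min)) · e^(−β|Δ|/|Δ|_max) with β = 4,
chosen to reproduce the qualitative spread of the behavioural
distributions. Acceptance is bounded below by e^(−2β) > 0 so the sampler
always terminates. If a factor is degenerate (flat sum, identically zero
difference) it defaults to 1, which makes the flat-signal limit exactly
uniform — a property the tests verify distributionally. Accepted angles
are reported in the 360° window centred on the histogram range
[−70°, 200°] so that binning never splits the distribution across a seam.

Pooling (`pool_distributions()`) runs the 5-crossover × 6-overlap grid
with 50 models per crossover and 100 saccades per run → 150,000 samples;
per-run provenance is retained for per-pair heatmaps. The full grid is an
hours-scale computation; the test suite verifies the bookkeeping
arithmetically and runs a reduced grid (one pair, five models) end to end,
which exercises every code path at the default network size.

Modes are extracted from a Gaussian KDE with bandwidth h = 5° (matching
the 5° histogram bins and angular acuity of the data), evaluated at 1°
steps on [−70°, 200°]; a grid point is a mode only if the density rises
strictly for 5 consecutive degrees before it and falls for 5 after, which
suppresses duplicate optima from sample ripple. The KDE is linear, not
circular: distributions are confined well inside the evaluation window.
Performance against user-supplied reference modes uses
DBM = min_i |m_i − m_true| averaged over n_iter = 10 fresh Monte-Carlo
realisations (resampling saccades on fixed signals — the repetition is
about sampler variance, not connectome variance), and MAE is the mean DBM
over experiments. Reference modes for the original behavioural data are
*inputs*: they are not distributed with this package, so the package's own
checks score against the geometric FPM-match directions instead, clearly a
proxy.

## 6. The theory oracle

For a test shape nested in the training shape, split by the visual midline
into train-left/right areas X, W and test-left/right areas Y, Z:
FPM alignment means X/W = Y/Z, which rearranges into equal covering
fractions γ_L = Y/X = Z/W = γ_R (`fpm_balance_identity()`). After a single
training exposure with constant initialisation the forward pass obeys
novelty = 1 − I·(1−α)/(p·N_KC) *exactly*, with I the train/test firing-set
intersection (`closed_form_novelty()`; verified to machine precision both
on random patterns and on rendered shape pairs at full network size). The
final probabilistic link — each train-time connection of a conditioning KC
is "captured" by the nested test set with probability γ, so equal γs
balance the conditional firing probabilities and hence the novelties — is
verified by Monte Carlo over seeded connectomes
(`conditional_probability_mc()`), with balance operationalised as
agreement within 3 combined standard errors (no tolerance is dictated by
the argument itself).

The oracle follows the theory's own simplifications: crossover 0,
overlap 0, and bar patterns built directly in vPN space
(`nested_bar_patterns()`) so the covering fractions are exact rather than
rasterised. Random vPN→KC weights are used in the oracle because binary
bar patterns with constant weights produce massive input ties, which the
deterministic tie-break would otherwise resolve identically in both
hemispheres — a harmless bias for the balance claim but a needless one.

## 7. Fixtures and study conditions

`shape_library()` provides every training and test shape used across the
reference experiment sets, and `fpm_experiments()` bundles them with their
feeder placements: the rectangle set (feeder 30° right of the left edge of
the 160°×38° rectangle, FPM 0.1875), the nested-rectangle scan
(tests 120/80/40° wide, width-FPM-match directions 22.5/15/7.5°), the
scalene-triangle set, and the composite (two abutting triangles) sets with
feeders at 25/35/55°. The feeder azimuth of the triangle set is not
independently documented and is taken equal to the rectangle set's 30°
inset — the one fixture value that is an assumption rather than a
specification.

## 8. What passing tests show — and what they do not

The synthetic world is exactly the modelled arena: binary shapes on a
featureless white cylinder, noise-free rendering, a deterministic training
path, and a single test view from the centre. Passing tests therefore
establish the *model's* internal claims — the geometry, the learning rule,
the emergence of an FPM-aligned zero crossing of the ensemble-mean novelty
difference (within 8° for the nested rectangles at the default operating
point), its collapse at crossover 0.5, and the sampler's analytic form.
They do not bear on real visual scenes (clutter, lighting, skyline
statistics), on photoreceptor front-ends, on KC–KC recurrence or
dopaminergic modulation, nor on closed-loop behaviour: the signals here
are open-loop rotational scans, and how a real insect turns those into
steering is outside the package's scope. Quantitative agreement with the
behavioural mode locations additionally requires the experimental
reference modes, which must be supplied by the user.
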