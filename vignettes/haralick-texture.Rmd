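---
title: "Quantifying biofilm surface texture with directional GLCM statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying biofilm surface texture with directional GLCM statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haratex)
```

## The measurement

Bacterial biofilms secrete an extracellular polymeric substance (EPS) that
can form a smooth overlayer above the cells. Microscopies differ in how much
of that overlayer they see: a scanning helium microscope images only the
outermost surface, while optical and electron microscopy are comparatively
insensitive to the thin matrix and show the cells beneath. The visual
difference — a veiled, uniform surface versus exposed, heterogeneous cells —
is a difference in image *texture*, and this package quantifies it with the
classical grey-level co-occurrence matrix (GLCM) statistics.

The pipeline is: quantize the image to `L` grey levels; count ordered level
pairs at a fixed pixel displacement into an `L x L` co-occurrence matrix;
normalize to probabilities `p(i, j)`; reduce to five scalars — contrast
$\sum_{ij}(i-j)^2 p_{ij}$, correlation
$\sum_{ij}(i-\mu_i)(j-\mu_j)p_{ij}/(\sigma_i\sigma_j)$ (marginal moments
$\mu$, $\sigma$), energy $\sum_{ij} p_{ij}^2$, homogeneity
$\sum_{ij} p_{ij}/(1+|i-j|)$ and entropy $-\sum_{ij} p_{ij}\ln p_{ij}$ with
$0\ln 0 \equiv 0$. Because texture is directional, the matrix is built at
the four canonical offsets (0°, 45°, 90°, 135°; displacement mapping
0°→(0,+d), 45°→(−d,+d), 90°→(−d,0), 135°→(−d,−d) in (row, col) with rows
increasing downward) and each feature is reported as mean ± standard
deviation over the four directions. `haralick()` performs the whole chain;
`quantize()`, `glcm()`, `normalize_glcm()` and `haralick_features()` expose
the individual steps.

```{r}
h <- haralick(simulate_micrograph("native", "shem", seed = 1),
              range = c(0, 1))
h
```

## Parameters and conventions

* **Grey levels `L = 8`** (default). The classical GLCM toolchain's default;
  configurable. More levels resolve finer intensity differences but thin the
  per-cell counts.
* **Offset distance `d = 1` pixel** (default): nearest-neighbour texture.
* **Accumulation**: asymmetric by default (ordered pairs); `symmetric = TRUE`
  also accumulates each pair reversed, making the matrix equal its
  transpose.
* **Quantization range**: by default each image is binned between its own
  minimum and maximum, with linear bin edges (values at or below the lower
  bound map to level 0, at or above the upper bound to `L − 1`; a constant
  image maps entirely to level 0). For *any comparison across images* — the
  native/treated tables, the modality ordering — a fixed common range should
  be passed instead (`range = c(0, 1)` for normalized micrographs): with
  per-image min–max binning, a change in a single extreme pixel rescales
  every bin and the comparison measures the histogram tails rather than the
  texture. All cross-image results in this package's tests and acceptance
  script use `range = c(0, 1)`.
* **Entropy** is reported in nats by default (`entropy_base` configurable).
* **Degenerate inputs**: a zero-variance (constant) window has undefined
  correlation; it is reported as `NA` and propagated as missing in maps and
  summaries, never silently zero. Empty co-occurrence sets (an image smaller
  than the displacement) are an error naming the offending offset.
* **Directional spread**: the standard deviation over the four offsets uses
  the population convention (divide by 4).

## Sliding-window texture maps

`texture_map()` computes one feature in a square window centred on every
pixel (window side 21 px by default — about 5 µm at the default
0.25 µm/pixel, a few cell widths; stride 1). Within each window the feature
is computed per offset and averaged over the four offsets, exactly as for
whole images. The image is quantized **once**, against a single range
(default: the whole image's min–max), so that all windows share one grey
scale; the map value at a centre therefore equals
`haralick(window, range = attr(map, "range"))$mean[feature]` for the window
extracted as a standalone image — bitwise, since both paths run the same
compiled kernels. Boundary handling is `"valid"` by default (a missing
border of half the window width, no padding artefacts); `"reflect"` pads by
reflection to cover every pixel. With `stride > 1` skipped centres are
filled from the nearest computed centre.

`render_feature_overlay()` draws the base micrograph in grey and tints it
red (low) to green (high) by the map, the conventional presentation for
energy maps; colour bounds default to the 2nd–98th percentile of the defined
values and are recorded in the overlay's provenance. `channel_overlay()`
builds the two-colour cross-modality composite (each image min–max
normalized independently, since modality intensity scales are
incommensurate; only integer manual translation is supported — automatic
registration is out of scope).

## The synthetic scene generator

No micrographs ship with the package, so the generator provides seeded,
bit-reproducible stand-ins for the three modalities and two conditions. It
is *phenomenological*: it reproduces the texture statistics that the
analysis measures, not the physics of any instrument.

A scene (default 400 × 400 px at 0.25 µm/px) is a smooth large-scale
background relief plus rod-shaped cells — capsules 4.0 × 0.6 µm with a
Lambertian-like cylindrical shading profile — placed in clusters. The
background field is standardized by its own standard deviation
(0.45 ± 0.15 intensity): a deliberate choice, because a field compressed
into a narrow intensity band falls inside a single quantization bin and its
texture statistics degenerate into *bin-placement noise* (whether the band
happens to straddle a bin edge). Realistic micrographs span several grey
levels; so do these scenes.

The **native** condition applies an EPS veil over the whole field
(coverage 1.0, strength 0.85): inside the veiled region the image is blended
toward a heavily blurred, intensity-flattened version of itself that retains
0.7 of the large-scale relief — a semi-transparent smooth overlayer, not a
blank sheet. The **treated** condition (emulating enzymatic disruption of
the matrix) keeps only the thickest 20% of the veil at strength 0.25 and
scatters short, dim capsule fragments (8 per 1000 µm²). Both conditions at
one master seed share the same underlying scene — the same field imaged
before and after treatment, as in a within-specimen experiment — so their
texture difference is the effect of the veil and debris, not of resampling
the field.

`modality_transform()` re-images a scene under three profiles chosen so that
contrast orders optical < SEM < SHeM (and energy the reverse) on a common
scene:

| profile | blur (px) | edge emphasis | noise sd |
|---------|-----------|---------------|----------|
| optical | 2.5       | –             | 0.002    |
| sem     | 0.8       | –             | 0.005    |
| shem    | –         | unsharp ×1.5 (σ 1.5) | 0.06 |

The chain is deliberately monotone — strictly less blur and more noise from
optical to SHeM — so the ordering is paired and robust on any scene. A gamma
step was tried for the SEM profile and dropped: a gamma relocates the
image's intensity band relative to the fixed bin grid, which on flat-ish
scenes can cancel the noise ordering; with the monotone chain it cannot.

What the generator does **not** emulate: real EPS microstructure and
hydration, three-dimensional relief and shadowing, detector-specific noise
statistics (all noise is additive Gaussian), charging or topographic SHeM
contrast mechanisms, or instrument drift. Tests passing on these scenes
demonstrate that the *pipeline* recovers the qualitative structure built
into them — veiled surfaces score more uniform than exposed ones, and the
profile ordering is recovered — not that real biofilms behave this way.

## The robustness test

`noise_injection_test()` adds zero-mean Gaussian noise of a given amplitude
(expressed as a fraction of the image's dynamic range, clipped back to the
original range) and tracks two numbers: the global RMS intensity change and
the mean of the defined windowed-energy map. The point of the test is the
asymmetry between them: at an amplitude of a few percent the image is
visually indistinguishable (RMS change of the same few percent) while the
windowed energy collapses — so a *difference* in windowed energy between two
micrographs of similar signal-to-noise reflects surface texture, not noise.
"Loss of textural uniformity" is operationalized here as the drop in mean
windowed energy; amplitude 0 reproduces the input exactly, and as the
amplitude grows the energy approaches that of pure-noise images at the same
window and level count.

## Problem sizes and numerical checks

The test suite verifies the kernels against independent brute-force oracles
(exhaustive pair enumeration for counts, direct double-loop summation for
features) on a hundred random images up to 32 × 32 at up to 16 levels, plus
over a thousand fuzzed invariant cases (probability normalization, feature
ranges, grey-level-reversal invariance, closed-form pair-count
conservation). End-to-end properties use the generator's default 400 × 400
scenes: 20 seeded native/treated pairs per modality for the trend direction,
20 noise seeds on one fixed reference scene for the modality ordering, and
the amplitude set {0, 0.01, 0.05, 0.10} for the noise test. These sizes are
the package's chosen test conditions; all are recomputed from scratch by
`scripts/acceptance.R`.

## Known limitations

* Only the five classical statistics are computed; no sum-average,
  information-measure-of-correlation or other extended Haralick features,
  and no multi-distance anisotropy analysis.
* Windows are rectangular; no segmentation- or superpixel-based regions.
* The comparison table performs no hypothesis testing; it reports means,
  directional spreads and signed deltas only.
* Cross-modality overlays assume pre-aligned inputs up to an integer
  translation.
* Quantitative texture values depend on `L`, `d` and the quantization range;
  only comparisons made under identical settings are meaningful, which is
  why those settings are recorded on every result object.
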