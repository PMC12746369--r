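# haratex

Grey-level co-occurrence matrix (GLCM) texture analysis for greyscale
micrographs of bacterial biofilm surfaces, in R.

Biofilms encase their cells in an extracellular polymeric substance (EPS) —
a smooth secreted overlayer that surface-sensitive microscopies (such as the
scanning helium microscope, SHeM) image directly, while optical and electron
microscopy largely see the cells beneath it. Whether a micrograph shows a
veiled, uniform surface or exposed, heterogeneous cells is a question of
*image texture*, and this package quantifies it the standard way: Haralick
statistics of the grey-level co-occurrence matrix.

For a quantized image with `L` grey levels, the GLCM at displacement
`(dr, dc)` counts ordered level pairs `(i, j)` of pixel and neighbour;
normalized to probabilities `p(i,j)` it yields the five statistics

- contrast `sum (i-j)^2 p(i,j)`
- correlation `sum (i-mu_i)(j-mu_j) p(i,j) / (sigma_i sigma_j)`
- energy (angular second moment) `sum p(i,j)^2`
- homogeneity `sum p(i,j) / (1 + |i-j|)`
- entropy `-sum p(i,j) log p(i,j)`

computed at the four canonical offsets (0°, 45°, 90°, 135°) and summarized
as mean ± standard deviation over the directions. A uniform EPS-veiled
surface scores high energy and low contrast; disrupting the matrix (e.g. by
DNase I digestion of its structural eDNA) exposes cells and debris, raising
contrast and lowering energy.

The package provides:

- `haralick()` — the directional texture summary of an image, a classed
  object with `print`/`summary`/`coef` methods;
- `quantize()`, `glcm()`, `normalize_glcm()`, `haralick_features()` — the
  individual pipeline steps;
- `texture_map()` and `render_feature_overlay()` — sliding-window,
  spatially resolved texture maps and grey + red–green feature overlays;
- `channel_overlay()` — two-channel cross-modality composites (e.g. SHeM
  red vs optical blue);
- `compare_conditions()` and `noise_injection_test()` — native-vs-treated
  comparison tables with trend flags, and a robustness check showing that
  noise too small to see still collapses windowed energy;
- a fully seeded synthetic micrograph generator (`scene_params()`,
  `render_scene()`, `apply_eps_veil()`, `modality_transform()`,
  `simulate_micrograph()`, `generate_study()`) emulating rod-shaped cell
  fields with an optional EPS veil under optical / SEM / SHeM imaging
  profiles, with ground-truth masks — so every analysis stage is testable
  without any image download.

## Worked example

```r
library(haratex)

native  <- list(); treated <- list()
for (mod in c("optical", "sem", "shem")) {
  native[[mod]]  <- haralick(simulate_micrograph("native",  mod, seed = 1),
                             range = c(0, 1))
  treated[[mod]] <- haralick(simulate_micrograph("treated", mod, seed = 1),
                             range = c(0, 1))
}
compare_conditions(native, treated)
```

```
Haralick comparison (native vs treated), mean ± SD over offsets:
 modality     feature        native       treated  delta
  optical    contrast 0.043 ± 0.006 0.076 ± 0.012 +0.034
  optical      energy 0.368 ± 0.003 0.233 ± 0.005 -0.135
      sem    contrast 0.063 ± 0.005 0.115 ± 0.018 +0.052
      sem      energy 0.348 ± 0.002 0.213 ± 0.005 -0.135
     shem    contrast 0.634 ± 0.003 0.847 ± 0.049 +0.213
     shem      energy 0.126 ± 0.000 0.080 ± 0.000 -0.046
  ...
Trends (treated relative to native):
  optical  contrast up, energy down
  sem      contrast up, energy down
  shem     contrast up, energy down
```

(abridged; `correlation`, `homogeneity` and `entropy` rows omitted here).
Reading the table: contrast rises and energy falls in every modality after
the simulated matrix disruption — the texture signature of a degraded
biofilm surface — and on a common scene the modalities order
optical < SEM < SHeM in contrast and the reverse in energy, the surface
sensitivity ordering. A spatially resolved view:

```r
img <- simulate_micrograph("native", "shem", seed = 1)
emap <- texture_map(img, "energy", window = 21)
plot(render_feature_overlay(img, emap))      # grey base, red-green energy
```

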