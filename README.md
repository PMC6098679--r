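# berrymorph

Image-based fruit morphometrics, Euler-characteristic shape descriptors,
and QTL mapping for four-way crosses — as one tested, simulation-backed R
pipeline.

## The problem

Fruit size and shape drive the processing value of crops like the American
cranberry, but they are slow to score by hand, and simple measures cannot
tell an elongated fruit from a bell-shaped one of the same aspect ratio.
This package is for quantitative geneticists and breeders who want to go
from fruit photographs to mapped quantitative trait loci (QTL) — and for
methodologists who want every stage of that pipeline testable against
known ground truth. A synthetic-data generator (parametric fruit
silhouettes, a simulated four-way cross with planted QTL, repeated-year
phenotypes) stands in for field data, so the whole workflow runs and
validates itself without any download.

## What it computes

- **Basic morphometrics** per fruit from segmented, scale-calibrated
  images: length and width as extreme chords through the centroid, their
  ratio (LW), projected area, and moment-ellipse eccentricity
  (0 = circle, 1 = segment).
- **Topological shape descriptors**: a pixel-density filtration (Gaussian
  kernel, bandwidth 0.2 r_max, normalized to [0,1]) over four concentric
  annuli; per annulus the Euler characteristic chi = components − holes of
  the density superlevel set at 30 thresholds; the concatenated 120-value
  descriptor is reduced by PCA to PC1/PC2.
- **Kinship-BLUP and genomic heritability** per trait-year: marker
  indicators (maternal a, paternal c) with VanRaden-style scaling, then
  y = 1*mu + u + e with u ~ N(0, A sigma_u^2), fitted by spectral REML on
  log lambda; h^2 = sigma_u^2 / (sigma_u^2 + sigma_e^2).
- **QTL mapping**: four-way genotype probabilities by a Haldane HMM,
  Haley–Knott regression (LOD = (n/2) log10(RSS0/RSS1)), genome-wide
  permutation thresholds (type-7 quantile), additive stepwise selection
  penalized by T_m, 1.5-LOD support intervals, covariate diallel scans,
  and cross-year collocation under an 8 cM window.

## Worked example

From pixels to a measured fruit:

```r
library(berrymorph)
set.seed(42)
scene <- compose_scene(scene_spec(random_fruits(25), ref_diameter_mm = 30,
                                  px_per_mm = 4), seed = 42)
seg <- segment_scene(scene$image, ref_expected_area_px = pi * (15 * 4)^2)
length(seg$fruit); length(seg$refs)
#> 25 fruit masks and 12 reference circles
cal <- calibrate_scale(seg$refs, 30)
#> <scale_calibration: 0.25023 mm/px from 12 references (cv 0.0000)>
fruit <- apply_scale(seg$fruit, cal)
measure_basic(fruit[[1]])
#> length 19.17 mm, width 14.79 mm, L/W 1.296, area 209.20 mm^2, ecc 0.589
length(ph_descriptor(fruit[[1]]))
#> [1] 120
```

The calibration recovers the rasterization scale (4 px/mm) from the
reference circles; the first fruit is a moderately elongated berry, and
its 120-value descriptor feeds the PCA that yields PC1/PC2.

From a simulated cross to a mapped QTL (a 20%-variance locus planted at
40 cM on linkage group 2, n = 351):

```r
map <- sim_linkage_map(n_lg = 2, length_cm = 80, spacing_cm = 5)
cross <- simulate_cross(map, n = 351, seed = 1)
sim <- simulate_phenotypes(cross, qtl_spec(lg = 2, pos = 40, frac = 0.2),
                           n_years = 1, seed = 2)
gp <- calc_genoprob(cross, step = 2.5)
y <- sim$per_genotype$value
pen <- perm_threshold(gp, y, n_perm = 200, seed = 3)
#> <perm_threshold: T_m = 3.314 at alpha = 0.05 (200 permutations)>
stepwise_additive(gp, y, penalty = pen)
#> <qtl_model: 1 QTL, LOD 15.65, pLOD 12.34 (T_m 3.31), 18.6% variance>
#>    lg pos lod_drop1 pct_var_drop1 ci_lo ci_hi  eff_ac  eff_ad eff_bc eff_bd
#> x2  2  40     15.65         18.56    35  42.5 -0.4487 -0.4019 0.3179 0.5327
reml_fit(y, kinship(cross))
#> <kinblup: n = 351, sigma2_u = 0.2472, sigma2_e = 0.8469, h2 = 0.226>
```

The scan recovers the planted locus at its true position with an 18.6%
drop-one explained variance (truth: 20%), a 7.5 cM support interval, and a
genome-wide threshold calibrated by permutation. The single-marker
heritability estimate (0.23) reflects that only the one QTL is genetic
here.

The whole pipeline — scenes, segmentation, descriptors, BLUPs, scans,
collocation, report — runs from one configuration:

```r
man <- run_pipeline(default_config(out_dir = "demo_run", seed = 1))
```

writing `cross.csv`, `traits.csv`, `descriptors.csv`, `blups.csv`,
`h2.csv`, `qtl.csv`, `collocation.csv`, per-LG scan plots, and a JSON
manifest with per-stage seeds, timings, and artifact checksums. A thin
command-line front end over the same functions ships in
`inst/cli/berrymorph` (`berrymorph run --config config.yaml`, plus
`phenotype`, `ph`, `blup`, `scan`, `collocate` subcommands).

See `vignettes/berrymorph-methods.Rmd` for the model details, parameter
defaults, and the design decisions behind them.

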