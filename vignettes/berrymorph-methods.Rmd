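---
title: "Methods: fruit morphometrics, Euler-characteristic shape descriptors, and QTL mapping in a four-way cross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fruit morphometrics, ECC shape descriptors, and QTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(berrymorph)
```

## Overview

`berrymorph` implements an image-based fruit phenotyping and
quantitative-genetics workflow for a full-sib four-way mapping population,
driven entirely by a synthetic-data generator, so that every stage — from
pixels to QTL — is testable without any external data. The stages are:

1. **Scene simulation**: fruit silhouettes with known ground truth placed on
   a light background with size-reference circles.
2. **Image phenotyping**: segmentation, scale calibration, and the five
   basic descriptors (length, width, length-to-width ratio, projected area,
   eccentricity).
3. **Topological shape descriptors**: Euler-characteristic curves (ECCs) of
   a pixel-density filtration over four concentric annuli, 30 thresholds
   each — 120 values per fruit — reduced by PCA to PC1/PC2.
4. **Quantitative genetics**: genotype means, a marker-based additive
   relationship matrix, spectral-REML BLUPs and genomic heritability per
   trait and year.
5. **QTL mapping**: four-way genotype probabilities by HMM, Haley–Knott
   regression scans, permutation-derived genome-wide thresholds, additive
   stepwise model selection, 1.5-LOD support intervals, and cross-year
   collocation under an 8 cM window.

## The silhouette model

Fruit outlines come from a two-family parameterization chosen as the
smallest one that spans the three shape classes seen in cranberry — round,
elongated, and bell-shaped — while letting bell and elongated fruit share
the same length-to-width (LW) distribution:

- round/elongated: the superellipse $|x/a|^n + |y/b|^n = 1$ with semi-axes
  $a \ge b$ (mm) and exponent $n \ge 1$;
- bell (piriform): half-width $w(t) = b\,(1 - k t)\,(1 - t^2)^{1/n}$ at
  axial coordinate $t \in [-1, 1]$, with asymmetry $k \in (0, 1)$ producing
  one blunt and one tapered end.

This matters because the LW ratio cannot distinguish a bell from an
elongated fruit of the same aspect; only the topological descriptors can
(see *Discrimination* below). Fruit-to-fruit variation enters through the
shape parameters — not through pixel noise — so segmentation stays exact
and tests isolate descriptor behavior; optional Gaussian pixel noise is
available via `scene_spec(pixel_noise_sd = )`.

Scenes emulate the photographing protocol: by default 25 fruit per
genotype, six reference circles of known diameter on each side (two
horizontal bands), non-touching placements, dark objects on a light
background. Composition is bit-reproducible under a fixed seed.

## Basic descriptors

Length and width are the extreme chords *through the centroid*, measured
over 360 directions (a literal reading of "longest diameter / shortest
axis determined by the centroid"); Feret extents are available as
`measure_basic(method = "feret")` and differ for bell shapes. Area is the
foreground pixel count times the squared scale. Eccentricity is that of
the second-central-moment (best-fit) ellipse, $\sqrt{1 -
\lambda_{\min}/\lambda_{\max}}$, 0 for a circle and approaching 1 for a
segment. The scale (mm/px) comes from the reference circles: equivalent
area diameter per reference, averaged, with a coefficient-of-variation
guard (default 5%) against inconsistent references.

Numerical choices: chords are sampled at 0.35 px along each ray, and a
non-convex mask whose centroid falls outside the foreground falls back to
the longest intersection run (documented fallback). Connectivity is
8-connected foreground everywhere; labeling is EBImage's with a
diagonal-merge pass to upgrade its 4-connectivity.

## The topological descriptor

Each foreground pixel receives a density: the Gaussian-kernel sum over
foreground pixels with bandwidth $\sigma = 0.2\, r_{max}$ ($r_{max}$ =
centroid-to-rim distance), min–max normalized to $[0,1]$. The mask is cut
into 4 concentric annuli of equal normalized radial width (the last bin
closed). For each annulus the Euler characteristic
$\chi$ (8-connected components minus enclosed 4-connected holes, computed
by the 2×2 quad-count formula) of the density superlevel set is evaluated
at 30 thresholds evenly spaced on $[0,1]$; the four 30-point curves are
concatenated, innermost annulus first, giving the 120-value descriptor.
PCA (column-centered, covariance eigendecomposition) reduces descriptors
to scores; the sign of each component is fixed by making the largest-|loading|
entry positive, because PC orientation is otherwise arbitrary and was
observed to flip between years in practice.

Design choices that the underlying method leaves open, and how we fixed
them:

- **Density source.** Contour-only and all-foreground kernel sums are both
  implemented (`density_map(mode = )`). The default is **all foreground
  pixels**: on simulated continua where size and shape vary independently,
  all-pixel density gives stable loadings with $|cor(\mathrm{PC1},
  \mathrm{LW})| \approx 0.9$ and $|cor(\mathrm{PC1}, \mathrm{area})|
  \approx 0$, while contour-only density was noticeably less stable across
  simulation seeds at the package's working resolutions.
- **Filtration direction.** Superlevel sets by default; sublevel behind
  `direction = "sublevel"`.
- **Threshold grid.** Global per annulus on the normalized $[0,1]$ scale,
  so curves are comparable across fruit without any dataset-level pass.
- **Annuli.** Equal radial width (not equal area), reading "increasing
  annuli emanating from the center" as concentric rings of equal step.
- **PCA scope.** Fitted per year (each year's export stands alone); a
  pooled fit is a one-liner on the stacked descriptor matrix.

## Mixed model, BLUPs, and heritability

Per-fruit measurements are averaged to genotype-year means. The additive
relationship matrix encodes each marker as two biallelic indicators —
maternal allele $a$ (codes 1,2) and paternal allele $c$ (codes 1,3) —
centered at observed frequencies, with VanRaden-style scaling
$A = WW^\top / \sum_k p_k(1-p_k)$ over the indicator columns, which puts
the mean diagonal near 1. Because the indicators are centered within this
single full-sib family, $A\mathbf{1} = 0$: relationships are expressed
relative to the family mean (off-diagonals average $-1/(n-1)$), which is
the correct reference for BLUP within a mapping population. Missing
genotypes are mean-imputed for $A$; REML uses casewise deletion.

For one trait-year, $y = \mathbf{1}\mu + u + \varepsilon$ with $u \sim
N(0, A\sigma_u^2)$: the restricted likelihood is profiled over $\lambda =
\sigma_u^2/\sigma_e^2$ via the spectral decomposition of $A$ and maximized
by 1-D search on $\log\lambda \in [-10, 10]$ (tolerance $10^{-6}$);
genomic heritability is $h^2 = \sigma_u^2/(\sigma_u^2 + \sigma_e^2)$ on
the genotype-mean scale. Tests pin the optimizer against a 10,000-point
grid search of the same profiled likelihood, and parameter-recovery
simulations at $n = 351$ with 976 markers recover $h^2 \in \{0.2, 0.5,
0.8\}$ within ±0.1 on average.

## QTL mapping

Genotype probabilities over the four offspring classes (ac, ad, bc, bd)
come from a forward–backward HMM per linkage group: transitions are the
Kronecker product of two 2×2 Haldane transitions (maternal and paternal
meioses independent, no interference), emissions give $1-e$ to the
observed class ($e$ = genotyping error, default $10^{-4}$), and
pseudomarkers (default step 1 cM) receive uniform emissions. The scan
regresses the phenotype on an intercept, optional covariates, and three
class-probability contrasts; $LOD = (n/2)\log_{10}(RSS_0/RSS_1)$.

Genome-wide thresholds are the type-7 empirical $1-\alpha$ quantile of the
max-LOD over permutations of the phenotype against the genotypes
(covariates travel with the phenotype, preserving trait–covariate
correlation under the null). The full permutation matrix is drawn from a
single seeded stream before any work happens, so results are invariant to
how the permutations are distributed over workers. When no covariates are
present, all permuted scans are computed by blocked QR projections — one
matrix product per position — which makes 200-permutation thresholds
essentially free at desk scale.

Model selection is additive-only stepwise: forward addition of the
position maximizing the model LOD while the penalized LOD $pLOD = LOD -
T_m \cdot \#QTL$ increases, backward deletion, and one round of ±10 cM
per-QTL position refinement. Two-dimensional two-QTL scans and the
interaction penalties are deliberately out of scope; the additive search
with the main-effect penalty reproduces single-QTL positions on synthetic
data. Reported per QTL: drop-one LOD, drop-one explained variance
($100(RSS_{-q} - RSS_{full})/TSS$), genotype-class effects, and the
1.5-LOD support interval from the conditional scan (the run of grid points
within 1.5 LOD of the peak, expanded one grid point outward; degenerate at
the peak when the drop is 0; one-sided at linkage-group ends).

Collocation groups same-trait QTL on a linkage group whose peaks are
pairwise within 8 cM (complete-linkage clustering cut at the window; the
published criterion is ambiguous between peak distance and interval
overlap, so an interval-overlap mode is provided behind
`collocate(mode = "interval")`). Covariate scans run every ordered
(trait, covariate) pair — a complete diallel — flagging all-year
collocated QTL absent from the univariate results as novel. No
multiple-testing adjustment is applied across traits or years beyond the
per-scan permutation threshold, matching the original protocol.

## Simulation design and what the tests do (and do not) show

The phenotype generator works on a normalized genotype-mean scale with
total variance 1: each planted QTL has a variance *fraction* (class-effect
pattern centered and rescaled; default a maternal contrast), the polygenic
background is drawn from $N(0, \sigma_p^2 A)$ with its own fraction, and
the per-fruit residual SD defaults to $\sigma_e = \sqrt{(1 - \sum
\mathrm{frac})\, n_{fruit}}$ so genotype-year means of $n_{fruit}$ fruit
carry exactly the residual fraction. Requesting fractions $\ge 1$ is a
configuration error. Year effects are additive genotype-independent
shifts (default $N(0, 0.25^2)$); genotype-by-year interaction beyond
independent residuals is not modeled.

Within-genotype fruit-to-fruit variation is an assumption, not an
estimate: silhouette parameters vary around the genotype-year latent with
SD 0.08 on the LW ratio and 0.9 mm on length. The QTL planted in the
image route acts on the shape latent only, and fruit size is simulated
independently, so a correct pipeline must show the shape signal in
LW/PC1 and no size signal at the same locus — the end-to-end test asserts
exactly this.

Simulation scales in the shipped tests — 2-linkage-group maps, 200
permutations, 50-replicate power runs, 200-replicate calibration runs,
scenes of 5–25 fruit — are the package's chosen desk-scale defaults; the
generator accepts the full study scale (12 linkage groups, 976 markers via
`study_map()`, $n = 351$, 3 years, 25 fruit) and the heritability-recovery
checks run at that scale. What passing tests show is that the machinery is
correct and calibrated under the generator's assumptions: clean
segmentation, parametric silhouettes, Haldane meiosis, Gaussian residuals.
They do not show robustness to photographic artifacts (shadows, touching
fruit, color variation), segregation distortion, or crossover
interference, none of which the generator emulates.

One practical caution surfaced during calibration: seeding a set of
Mersenne–Twister streams from a constant-offset family (e.g. `base + i`)
for *different roles* (phenotype draws vs. permutations) produced
measurably correlated streams and an inflated null exceedance rate. All
randomness within a simulation loop should flow from a single stream, with
sub-seeds drawn from that stream; the package's own permutation and
pipeline seeding follow this rule.

## Known limitations

- Touching fruit are not split; they trigger a segmentation warning.
- The descriptor's integer ECC values retain some rasterization noise at
  low resolution; working above ~3 px/mm keeps it immaterial.
- Additive-only QTL search: epistatic pairs are invisible by design.
- The mixed model is strictly per trait-year; no multi-trait or
  multi-year covariance is estimated.
- A single full-sib family supports no base-population relatedness scale;
  heritabilities and BLUPs are family-referenced.
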