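---
title: "Quantifying cerebrovascular complexity with fractal dimensions"
author: "fractalvasc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cerebrovascular complexity with fractal dimensions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fractalvasc)
```

## The problem

Cerebral arteriovenous malformations (AVMs) shunt arterial blood directly
into draining veins through a nidus of coiled vessels. The surplus of
feeding arteries makes the vascular network of the affected hemisphere
visibly more complex than its contralateral counterpart, and that
complexity carries physiological information: it tracks the speed of
contrast-media transit and the size of the nidus. `fractalvasc`
quantifies this complexity on skeletonized 2-D projections of
angiographic volumes by estimating fractal dimensions — single numbers
that summarize how the vessel pattern fills the plane across scales.

A fractal dimension (FD) is the exponent of the power law relating
measurement scale to measured size. A smooth curve has FD 1 and a filled
region FD 2; branching vasculature sits in between, and a hemisphere with
more, finer, more tortuous vessels sits higher.

## Estimators

Three estimators are implemented, all operating on a `BinaryImage`
(foreground = vessel skeleton) and all reducing to an ordinary
least-squares slope in log-log coordinates.

**Box-counting dimension** (`boxCounts()` + `fitDimension()`, or
`boxDimension()`). The image is covered with grids of square boxes of
side $\varepsilon = 2^n$, $n = 0, 1, 2, \dots$, anchored at the top-left
pixel; $N(\varepsilon)$ counts boxes containing at least one foreground
pixel, partial boxes at the right/bottom edges included. Then
$D_b = -\,\mathrm{slope}\,[\log N(\varepsilon) \sim \log \varepsilon]$.
The dyadic series is generated bottom-up ($\varepsilon = 1, 2, 4, \dots
\le \max(W, H)$), which is the same set a top-down halving description
produces but is unambiguous for non-square images. For image sides that
are not powers of two the counts depend on where the grid originates, so
the anchor is configurable (`anchor=`) — this grid-origin sensitivity is
itself one of the phenomena the package studies.

**Minkowski (dilation) dimension** (`minkowskiAreas()`,
`minkowskiDimension()`). The foreground is dilated with square
structuring elements of side $2n + 1$, $n = 0 \dots n_{\max}$ (default
protocol $n_{\max} = 20$), giving the covered area $A(r_n)$ at radius
$r_n = (2n+1)/2$; then $D_m = 2 - \mathrm{slope}\,[\log A(r) \sim \log
r]$. This is the "sausage" reading of the dilation construction: the
defining relation counts covering elements, and a covering count is the
dilated area divided by the element area, which changes only the
intercept of the log-log fit — we therefore work with areas directly.
For the same reason any proportional redefinition of $r_n$ leaves $D_m$
unchanged (log-shift invariance), so the choice $r_n = (2n+1)/2$ affects
only which radii the range selector sees. The $n = 0$ point (area =
foreground count) is an ordinary curve point; no special-casing. On
small rasters the default $n_{\max}$ is capped so the structuring
element stays below roughly one sixth of the image extent: radii beyond
the self-similar range of a small object measure its convex bulk, not
its fractal structure, and demonstrably bias the fit.

**Generalized (Rényi) dimensions** (`partitionMoments()`,
`generalizedSpectrum()`). Each foreground pixel carries uniform mass
$1/M_0$; for box size $l$ the moments are
$M(q, l) = \sum_i \mu_i^q$ over occupied boxes, $\mu_i = M_i / M_0$.
For $q \ne 1$, $D_q = \mathrm{slope}[\log M(q, l) \sim \log(l/L)]/(q-1)$
with $L = \max(W, H)$; at $q = 1$ the information-dimension limit
$D_1 = \mathrm{slope}[\sum_i \mu_i \log \mu_i \sim \log(l/L)]$ is used.
$D_0$ is the capacity (box-counting) dimension, $D_1$ the information
and $D_2$ the correlation dimension; the spectrum is non-increasing in
$q$, and strict decrease is the signature of multifractality. The q grid
defaults to $0 \dots 5$ in steps of 0.25; negative $q$ is excluded
because moments of near-empty boxes are dominated by rasterization noise
and their interpretation is contested. One box-size range (selected on
the $q = 0$ curve) is reused for every $q$, keeping the spectrum
comparable across $q$ and making $D_0$ agree exactly with the
box-counting estimate over the same boxes. `generalizedSpectrum()` also
accepts a 1-D mass vector of length $2^k$ (e.g. a binomial cascade),
aggregating cells dyadically — on exact cascade measures the estimate
matches the closed form $D_q = \log_2(p^q + (1-p)^q)/(1-q)$ to
floating-point precision.

## Selecting the scaling range

Digital rasters of natural structures scale linearly only over part of
the accessible range; fitting all points biases the dimension.
`selectLinearRange()` returns the longest contiguous window of curve
points whose log-log Pearson $|R|$ reaches a threshold (default 0.995),
breaking ties toward the smaller starting scale; when no window of at
least three points qualifies, the best three-point window is returned
flagged. The maximal-window rule is deterministic and order-independent,
which we prefer over grow-and-test procedures whose result depends on
the order in which endpoints are moved.

Within a cohort analysis (`runStudy()`) a *shared* window is used for
all subjects — the constant-number-of-points convention — so that
between-subject differences reflect the images, not window jumps:

* box counting and the Rényi spectrum use the dyadic series with the
  single-pixel scale dropped ($\varepsilon = 2 \dots 2^{k_{\max}}$). At
  $\varepsilon = 1$ every occupied box holds exactly one pixel, so the
  partition is exactly uniform for *any* image and the point carries no
  mass information;
* the Minkowski range is selected once, at the usual threshold, on the
  pooled cohort curve (elementwise mean of log areas).

A consequence worth knowing: for a uniform-mass binary raster the Rényi
entropies at $\varepsilon = 1$ coincide for all $q$, so any *two-point*
estimate anchored there is forced into the inverted order
$D_0 \le D_1 \le D_2$ regardless of the image. Real multifractality can
only be detected from windows over which the box-mass heterogeneity
*decreases* with scale; dropping the single-pixel scale and regressing
over the remaining window is what makes the estimator sensitive to it.

## Image operations

`mip()` collapses a 3-D volume by per-pixel maxima along a chosen axis
(default the first, "axial"). `kmeansBinarize()` separates vessel from
background with the exact two-class 1-D k-means solution — an
exhaustive threshold search minimizing within-cluster sum of squares —
so segmentation is deterministic and invariant to positive affine
intensity rescaling; the brighter cluster becomes foreground.
`skeletonize()` is two-subiteration Zhang–Suen thinning with
8-connectivity, plus a component guard: when a parallel subiteration
would delete the last pixels of an 8-connected component (the classic
case is an isolated 2×2 block, which textbook Zhang–Suen erases
entirely), one pixel is retained, so the component count of the input is
preserved even on degenerate inputs. Thinning residue at free line ends
can cost one or two pixels per end, which is the usual behaviour of
parallel thinning schemes. `splitHemispheres()` cuts at the vertical
midline (the 364×436 study geometry yields two 182×436 halves); mapping
raster left/right to anatomical sides is the caller's responsibility.

## Synthetic data

Nothing is downloaded: every input the pipeline needs is generated.

**DLA clusters** (`generateDLA()`, Rcpp). On-lattice
diffusion-limited aggregation: walkers start on a launch circle (cluster
radius + 5), take nearest-neighbour steps, stick on 4-neighbour contact,
and are discarded beyond the kill radius (3× launch) or off the grid.
Growth stops when the cluster radius reaches 0.45 of the smaller
half-extent, or when the particle budget (default 50 000, counting the
seed; large enough that the radius rule binds) is exhausted. The
364×436 raster is grown on 436×436 and centre-cropped so the same
morphology populates both matrix geometries. All parameters are
configurable; the defaults are fixed once and drive the matrix-size
experiment (`dlaMatrixSizeExperiment()`).

**Analytic prefractals and cascades** (`generatePrefractal()`,
`generateCascade()`): Sierpiński carpet ($D = \log 8/\log 3$), triangle
($\log 3/\log 2$), Koch curve ($\log 4/\log 3$), and the binomial
multiplicative cascade with its closed-form spectrum
(`cascadeSpectrumExact()`) — the oracles the test suite validates the
estimators against.

**The synthetic AVM cohort** (`generateCohort()`). Each hemisphere is a
bifurcating backbone tree (6 levels, trunk 50 px, length decay 0.76,
branching half-angle 0.55 rad, angle jitter SD 0.2) overlaid with a
stratified field of small "lobule" knots — clusters of 4 short crossing
strokes, one per occupied 14-px grid cell, 55 % of cells occupied, with
the occupied count fixed exactly so the branch total is deterministic.
The knots emulate the fine-scale vessel crossings a maximum intensity
projection produces, spread evenly the way cortex is vascularized. This
structure is deliberate: a single central tree concentrates mass at
coarse scales, and box-mass heterogeneity that *grows* with scale
inverts finite-window Rényi spectra; fine-scale clumps on a
coarse-homogeneous field give the decreasing heterogeneity — hence
$D_0 > D_1 > D_2$ — seen in real skeletons. Patients receive a nidus on
a random side: $d$ extra curved vessels (uniform $d \in [30, 150]$ by
default) packed in a disk of radius $5\sqrt{d}$ px, so local density is
constant while the malformed territory grows with $d$. The intensity-
time curve is a gamma-variate bolus ($t_0 = 8$ s, shape 3, scale 1.8 s,
sampled at 2 Hz for 60 s) scaled so its analytic peak upslope equals
$1 + 0.02 \times (\text{total branches})$ plus Gaussian noise (SD 0.1
a.u./s by default); the four nidus diameters average to
$0.5 + 0.015\,d$ cm plus noise (SD 0.05 cm). At zero noise both
covariates are exactly monotone in the ground-truth complexity.

What the generator does *not* emulate: gray-level contrast, vessel
superposition and width variation, anatomical asymmetries, partial
voluming, registration error, or hemodynamics — the bolus is a
stand-in encoding the monotone complexity–flow relationship, not a
perfusion model. Passing tests therefore certify the estimators and the
pipeline logic under a controlled statistical structure that mimics the
study design; they are not evidence about any particular scanner or
patient population.

## The study pipeline

`runStudy()` generates (or is pointed at) a cohort, computes all five
dimensions ($D_b$, $D_m$, $D_0$, $D_1$, $D_2$) for every hemisphere and
for the recombined whole image under the shared-window protocol above,
summarizes group means ± SEM and paired hemisphere contrasts
(`compareHemispheres()`), correlates the AVM-side dimensions with the
peak contrast-transit slope (`maxSlope()`: maximum of the
central-difference derivative) and with the mean nidus diameter
(`nidusMeanDiameter()`: mean of the four view diameters — the wording
"average of the minimum and maximum diameter from both views" could
mean two or four numbers; four is implemented), and converts the
correlations into required sample sizes with the Fisher-z formula
$n = \lceil ((z_{1-\alpha/2} + z_{\text{power}})/\operatorname{atanh}
r)^2 + 3 \rceil$ (defaults $\alpha = 0.05$ two-sided, power 0.80).
Omnibus machinery (mixed-design ANOVA, normality tests, multiplicity
corrections) is deliberately left to general statistics software: the
report exposes the descriptive means/SEM, paired statistics and
per-correlation p-values it is built from.

```{r study, eval = FALSE}
report <- runStudy(list(nPatients = 10, nControls = 10, seed = 11,
                        noise = list(slopeSD = 0, diamSD = 0)))
report@correlations
```

Everything is a pure function of the configuration: rerunning with the
same list writes byte-identical CSVs.

## Numerical choices and degenerate inputs

* Perfectly flat log-measure curves (a saturated or single-box image)
  are exactly log-linear with slope 0; their window $|R|$ is defined as
  1, so a filled image cleanly yields $D_b = 2$, $D_m = 2$ and a single
  pixel $D_b = D_m = 0$.
* $M(1, l) = 1$ holds to floating point by construction; moments use the
  normalized masses $\mu_i$, never raw counts.
* Empty images are errors for all estimators ("no foreground");
  `skeletonize()` passes them through.
* Dilation is clipped at the canvas; $A(r) \le WH$ always.
* Ties in the exact k-means threshold search resolve to the lowest
  threshold; ties in range selection to the smaller starting scale —
  both deterministic.
* DLA uses R's RNG (via Rcpp), so `set.seed()`/the `seed` arguments
  reproduce clusters bit-for-bit.

## Problem sizes used by the test suite

The validation suite grows 10 DLA clusters per geometry for the
matrix-size experiment, runs one 10-patient/10-control cohort for the
inequality and correlation checks, and validates the estimators on
depth-5 carpet, depth-4/5 Koch, depth-8 triangle and depth-10 cascade
oracles, with exhaustive brute-force oracles on 64×64 random images.
These sizes give stable means (SEMs of order 0.01 on DLA dimensions)
while keeping a full run in a few minutes.

## Known limitations

* Absolute dimension values depend on the segmentation, the skeleton
  algorithm, the grid anchor and the regression window; they are
  comparable within a protocol, not across tools. This mirrors the
  matrix-size sensitivity the DLA experiment demonstrates for $D_b$.
* The estimators are 2-D; projecting a 3-D vascular tree loses
  superimposed vessels, and 3-D (voxel) box counting is out of scope.
* Only binary (uniform-mass) multifractal analysis is provided;
  gray-mass variants and negative $q$ are excluded.
* Lattice DLA with 4-neighbour sticking has a slightly anisotropic,
  sparser morphology than off-lattice variants; its dilation dimension
  sits near 1.53 under our protocol, somewhat below commonly quoted
  values for denser growth protocols, while its box dimension (~1.37)
  and the direction of every matrix-size effect match the literature.
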