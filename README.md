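# fractalvasc

Fractal-complexity analysis of cerebral vasculature images in R.

Cerebral arteriovenous malformations (AVMs) shunt arterial blood through a
nidus of coiled vessels, and the surplus of feeding arteries makes the
affected hemisphere's vascular network measurably more complex. This
package quantifies that complexity on skeletonized 2-D vessel projections
with three fractal-dimension estimators, and reproduces, end to end, a
study design that relates those dimensions to physiology:

* **Box-counting dimension** `D_b`: cover the binary image with grids of
  boxes of side `eps = 2^n` and regress `log N(eps)` on `log eps`;
  `D_b = -slope`.
* **Minkowski (dilation) dimension** `D_m`: dilate the foreground with
  squares of side `2n + 1` (n = 0..20) and regress the covered area,
  `D_m = 2 - slope` of `log A(r)` vs `log r`.
* **Generalized (Rényi) dimensions** `D_q`, `q ∈ [0, 5]`: from partition
  moments `M(q, l) = Σ_i (M_i/M_0)^q` over occupied boxes,
  `D_q = slope[log M(q, l) ~ log(l/L)]/(q - 1)` (entropy limit at
  `q = 1`); `D_0 ≥ D_1 ≥ D_2`, with strict decrease indicating
  multifractality.

Every log-log fit is restricted to an automatically selected scaling
range: the longest contiguous window whose Pearson `|R| ≥ 0.995`.

Around the estimators sit the image operations to get from an
angiographic volume to estimator input (maximum intensity projection,
exact two-class k-means binarization, Zhang–Suen skeletonization,
hemisphere splitting at the midline), a lattice diffusion-limited
aggregation (DLA) simulator for the matrix-size sensitivity experiment,
analytic prefractal and cascade oracles, a synthetic AVM cohort
generator, and `runStudy()`, which produces the full per-hemisphere
dimension table, hemisphere contrasts, dimension-versus-physiology
correlations and Fisher-z sample sizes.

The package is aimed at researchers in quantitative neurovascular
imaging and at anyone needing validated, deterministic fractal
estimators for binary rasters.

## Worked example

Validate the estimators on an analytic oracle, then measure a DLA
cluster:

```r
library(fractalvasc)

carpet <- generatePrefractal("sierpinski_carpet", 5)   # D = log 8 / log 3 = 1.893
boxDimension(carpet)
#> FDEstimate (box): D = 1.8619  [fit R = -0.9997, points 1..8]
minkowskiDimension(carpet)
#> FDEstimate (minkowski): D = 1.9072  [fit R = 0.9950, points 3..18]

cl <- generateDLA(512, 512, seed = 7)
cl
#> BinaryImage: 512 x 512 (W x H), 3229 foreground pixels (1.23%)
boxDimension(cl)
#> FDEstimate (box): D = 1.3086  [fit R = -0.9955, points 1..10]
```

Both carpet estimates sit within 0.04 of the exact self-similarity
dimension 1.893, and the DLA cluster lands near the 1.3–1.4 range that
box counting yields for lattice DLA under threshold-selected scaling
ranges. A full synthetic study:

```r
rep <- runStudy(list(nPatients = 10, nControls = 10, seed = 11,
                     noise = list(slopeSD = 0, diamSD = 0)))
subset(rep@correlations, method %in% c("Db", "Dm"))
#>  method     covariate     r        p  n slope intercept
#>      Db      maxSlope 0.995 2.45e-09 10 34.65    -11.37
#>      Db nidusDiameter 0.995 2.45e-09 10 26.75    -37.56
#>      Dm      maxSlope 0.981 5.66e-07 10 19.96     18.21
#>      Dm nidusDiameter 0.981 5.66e-07 10 15.42    -14.72
subset(rep@pairedTests, method == "Db")
#>              contrast method meanDiff semDiff     t        p  n
#>   patient AVM - noAVM     Db   0.0685  0.0068 10.05 3.43e-06 10
#>  control left - right     Db   0.0018  0.0011  1.68 1.26e-01 10
```

The AVM-side box dimension exceeds the contralateral side in every
patient (mean difference 0.069, paired p ≈ 3e-6) while control
hemispheres are symmetric (p ≈ 0.13), and the AVM-side `D_b` tracks both
the peak contrast-transit slope and the nidus diameter with r ≈ 0.99 on
this noise-free cohort — the qualitative structure of the clinical
findings, recovered from fully synthetic data.

## Layout

```
R/                 estimators, image ops, multifractal spectrum,
                   synthetic generators, study pipeline (S4 classes)
src/               Rcpp DLA walker
tests/testthat/    unit, property and reproduction tests with
                   brute-force oracles
vignettes/         methods vignette: models, assumptions, parameter
                   choices, limitations
scripts/           acceptance.R (see above)
```
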