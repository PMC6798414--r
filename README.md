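# camrad

Intratumoural heterogeneity analysis for dynamic contrast-enhanced MRI
(DCE-MRI), for imaging scientists and computational oncologists who want
to go from a 4-D enhancement series to prognostic, biologically annotated
imaging biomarkers.

Tumour voxels are partial-volume mixtures: each voxel's enhancement curve
blends the kinetics of the tissue compartments it straddles.  `camrad`
models the curve of pixel *i* as a convex combination of *J* compartment
curves,

    x(i) = Σⱼ Kⱼ(i)·aⱼ,   Kⱼ(i) ≥ 0,  Σⱼ Kⱼ(i) = 1,

so pixel curves live in a simplex whose corners are the compartment
kinetics.  Convex analysis of mixtures (CAM) recovers the corners and the
per-pixel proportions: affinity propagation clusters the pixel curves into
exemplars; the corner subset minimizing the total convex-hull projection
margin `Σₘ δₘ` is found by exhaustive subset search (compiled, exact
simplex-constrained least squares); each corner is polished over candidate
pixels; the compartment count can be chosen by minimum description length.
With the conventional J = 3, compartments are labelled **plasma input**
(earliest peak, deepest wash-out), **fast flow** and **slow flow**, and
every pixel with a nontrivial proportion (≥ 1e-2) of a compartment joins
that subregion.

Around the decomposition the package provides: fuzzy C-means tumour
segmentation from a seed point; 14 radiomic features (histogram skewness,
kurtosis and median; GLCM energy, maximum probability and correlation;
volume and compactness) on the precontrast (S-0) and early-subtraction
(S-1) series over the whole tumour and each subregion; Cox /
Kaplan-Meier survival analysis with optimal log-rank cutoffs, correlation
pruning, Harrell's c-index and Benjamini-Hochberg correction; and a
radiogenomic layer (co-expression modules with eigengenes, module-feature
correlation, elastic-net multigene signatures, signature transfer,
hypergeometric enrichment).  A synthetic-data module generates images,
survival tables and expression matrices with known ground truth.  See
`vignettes/camrad-methods.Rmd` for the model, parameter choices and known
limitations.

## Worked example

```r
library(camrad)

# simulate a three-compartment tumour: 10x10x4 voxels, 8 time points, 2% noise
curves <- generateKineticCurves(J = 3, timepoints = 0:7, seed = 1)
tumour <- generateMixtureImage(curves, shape = c(10, 10, 4),
                               noiseSigma = 0.02 * max(kineticCurves(curves)),
                               seed = 2)
model <- camDecompose(tumour, J = 3, seed = 3)
model
#> CompartmentModel: J = 3 compartments, 400 pixels, 8 timepoints
#>   roles: slow_flow, fast_flow, plasma_input | corner margin = 0.6016
```

The recovered proportion maps correlate with the planted ground truth at
0.99+ per compartment (off-diagonals negative, as proportions compete):

```r
round(cor(proportions(model)[, match(curveRoles(curves), curveRoles(model))],
          trueProportions(tumour)), 3)
#>        [,1]   [,2]   [,3]
#> [1,]  0.998 -0.568 -0.362
#> [2,] -0.563  0.995 -0.545
#> [3,] -0.368 -0.565  0.994
```

Subregion membership at the nontrivial-proportion threshold (pixels may
belong to several subregions — those are mixture pixels):

```r
colSums(assignSubregions(proportions(model), curveRoles(model)))
#>    slow_flow    fast_flow plasma_input
#>          372          372          383
```

Radiomic features for the whole tumour versus the fast-flow subregion
(S-0 texture, volume in voxel units, face-counted compactness):

```r
#>                           whole  fast_flow
#> S0_maximum_probability   0.013      0.012
#> S0_energy                0.004      0.004
#> S0_volume              400.000    372.000
#> S0_compactness           0.388      0.224
```

Benjamini-Hochberg adjustment reproduces the published corrected
p-values of the bundled 14-feature worked example exactly at printed
precision:

```r
tab <- workedExamplePValues("training_rfs")
data.frame(feature = paste(tab$series, tab$feature), raw = tab$rawP,
           adjusted = signif(bhAdjust(tab$rawP), 2))[c(1, 6, 14), ]
#>        feature   raw adjusted
#> 1    S0 volume 0.004    0.024
#> 6    S0 energy 0.023    0.054
#> 14 S1 skewness 0.940    0.940
```

`runFull()` chains the stages (synthesis → segmentation → decomposition →
features → survival → optional radiogenomics) under one master seed and
writes TSV/JSON outputs with a provenance record.

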