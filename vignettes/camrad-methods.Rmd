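---
title: "Methods: convex analysis of mixtures, subregion radiomics and radiogenomic survival mapping"
author: "camrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: convex analysis of mixtures, subregion radiomics and radiogenomic survival mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camrad)
```

## The problem

Dynamic contrast-enhanced MRI (DCE-MRI) records a T1-weighted volume before
contrast injection and again at several time points afterwards, so every
tumour voxel carries a kinetic enhancement curve.  Because imaging
resolution is coarse relative to tissue microstructure, a voxel's curve is
a partial-volume mixture of the kinetics of the tissue compartments it
straddles.  `camrad` implements a full analysis chain built around this
observation:

1. **Unmixing** (convex analysis of mixtures, CAM): model each in-tumour
   pixel curve as a convex combination of a small number of compartment
   curves and recover both the curves and the per-pixel proportions.
2. **Subregion radiomics**: derive per-compartment subregions from the
   proportions and extract 14 histogram, texture and morphology features
   from the whole tumour and each subregion.
3. **Survival analysis**: univariate and multivariate Cox models,
   optimal log-rank cutoff stratification, Kaplan-Meier curves, Harrell's
   c-index and Benjamini-Hochberg correction.
4. **Radiogenomics**: co-expression modules and eigengenes from a paired
   expression matrix, module-feature correlation, elastic-net multigene
   signatures for prognostic features, signature transfer to an
   independent cohort, and hypergeometric gene-set enrichment.

A first-class synthetic-data module generates images, survival tables and
expression matrices with known ground truth, so every stage is testable
without clinical data.

## The mixture model

For pixel $i$ with time-series $x(i) \in \mathbb{R}^T$,

$$x(i) = \sum_{j=1}^{J} K_j(i)\, a_j, \qquad K_j(i) \ge 0,\ \sum_j K_j(i) = 1,$$

where $a_j \in \mathbb{R}^T_{\ge 0}$ are the compartment curves.  Pixel
curves therefore live in the convex hull (a simplex) spanned by the
$a_j$, and the $a_j$ are identifiable as its corners whenever near-pure
pixels exist.  The decomposition proceeds as:

* **Affinity propagation** clusters the pixel curves into $M$ exemplars
  (actual pixels), using similarity $-\lVert x_i - x_k \rVert_2^2$, the
  median off-diagonal similarity as preference, damping 0.9, and a
  seed-controlled $10^{-12}$ relative jitter so tie-breaking is
  deterministic.  Message passing follows the standard
  responsibility/availability updates; convergence requires a stable
  exemplar set for 50 sweeps.
* **Corner identification** minimizes the total error margin
  $\sum_m \delta_m$, where $\delta_m$ is the Euclidean residual of
  projecting exemplar $m$ onto the convex hull of a candidate corner
  subset, over all $\binom{M}{J}$ exemplar subsets (capped at $10^5$;
  the cap asks for a lower preference when exceeded).  Each projection is
  a tiny simplex-constrained quadratic program solved exactly by support
  enumeration of its KKT system with a dual-feasibility certificate; the
  enumeration is compiled (RcppArmadillo) with cached KKT inverses and
  running-sum pruning.
* **Corner polish.** Exemplars are cluster medoids and thus slightly
  interior to the true simplex.  Each selected corner is therefore
  refined by coordinate descent over the highest-proportion candidate
  pixels, minimizing the total projection margin of *all* pixels.
  Corners remain actual measured pixels; on noise-free mixtures with
  occupied corners the zero-margin optimum is exactly the set of true
  vertices, which is what makes the package's exact-recovery tests
  meaningful.  An optional Gaussian-noise EM pass (`emRefine`,
  alternating least squares, off by default) can further re-estimate the
  curves off the data; it minimizes reconstruction error but, like any
  unconstrained simplex fit, may return a slightly inflated enclosing
  simplex, so it is not used for corner placement.
* **Proportions** are the per-pixel simplex projections onto the corner
  hull, with the same exact QP.
* **Compartment roles** for $J = 3$: the curve with the earliest
  time-to-peak is the plasma input (ties by deeper wash-out, then row
  index); of the rest, the steeper initial wash-in slope is fast flow and
  the other slow flow.
* **Subregions**: pixel $i$ belongs to subregion $j$ iff
  $K_j(i) \ge 10^{-2}$ (the nontrivial-proportion threshold); pixels with
  several nontrivial proportions are mixture pixels and belong to several
  subregions.

The pipeline default is $J = 3$ (plasma input, fast flow, slow flow), the
standard convention for breast DCE-MRI subregion analysis.

### Model-order selection

`mdlSelect()` scores each candidate $J$ by a two-part description length
after refining the candidate fit by alternating least squares (MDL
compares maximized likelihoods; the raw corner-exemplar fit at $J = 1$ is
inflated by exemplar noise):

$$\mathrm{MDL}(J) = \frac{NT}{2}\,\log\frac{\mathrm{RSS}}{NT}
  + \frac{JT}{2}\,\log(NT) + \frac{N(J-1)}{2}\,\log T .$$

The curve parameters ($JT$ values) are priced by the full sample size,
while each pixel's $J - 1$ proportion parameters are priced by the $T$
observations that support them.  The alternative of pricing every
parameter by $\log(NT)$ is available as `penalty = "global"`, but it
over-penalizes the proportions so strongly that it selects $J = 1$ even
on clearly three-compartment data, which is why it is not the default.
Ties go to the smaller $J$; an RSS of zero is floored at $10^{-12}$.

## Radiomic features

From the precontrast volume (S-0) and the early-postcontrast minus
precontrast subtraction (S-1; the late subtraction S-2 is constructed but
contributes no features), each region yields 14 features:

| group | features | notes |
|---|---|---|
| histogram | skewness, kurtosis, median (S-0 and S-1) | $m_3/m_2^{3/2}$ and Pearson $m_4/m_2^2$ (not excess); zero-variance regions return 0 with a degeneracy flag |
| Haralick (GLCM) | energy, maximum probability, correlation (S-0 and S-1) | 32 grey levels, min-max quantized inside the region; 13 unique 3-D unit offsets accumulated into one symmetrized, normalized matrix |
| morphology | volume, compactness (S-0 geometry) | volume = voxel count x voxel volume; compactness $36\pi V^2/A^3$ with face-counted surface area |

Quantization level, offset set, symmetrization and min-max normalization
are conventional radiomics choices and are recorded in the feature
configuration.  Texture is computed volumetrically (3-D); passing 2-D
offsets restricts it to slices.

Two warts of these conventions are documented rather than hidden.
Min-max quantization makes the GLCM exactly invariant to intensity shift
*and scale*, so "texture flattens as noise grows" does not hold in
general — for a pure-noise region the quantized distribution is
scale-invariant, and tightly bimodal regions actually *concentrate* the
quantized GLCM.  And face-counted surface area overestimates smooth
surfaces by the staircase factor (3/2 for a ball), so a digitized ball's
compactness tends to $64/216 \approx 0.296$ rather than 1; the feature
is comparable across regions of one analysis, not absolutely
sphere-normalized.

## Survival analysis

Cox models use the Breslow tie approximation throughout.  Features are
z-scored before fitting, so hazard ratios are per standard deviation (the
scaling of published per-feature HRs in this literature is typically
unstated; per-SD makes them comparable across features).  Multivariate
models first prune correlated features greedily: while any pair has
$|r| > 0.7$, the most correlated pair's member with the larger univariate
p-value is dropped.  Optimal-cutoff stratification evaluates the two-group
log-rank p-value at every distinct feature value inside the 10th-90th
percentile window (degenerate arms are impossible by construction) and
returns the minimizing threshold, ties toward the lower value; the number
of candidates searched is reported as a multiple-testing optimism
indicator, and no minP correction is applied.  In transfer mode a fixed
training threshold is applied unchanged to a new cohort.
Benjamini-Hochberg adjustment is the standard step-up rule.

## Radiogenomics

Genes expressed in fewer than 20% of samples are dropped and the top
5000 by variance retained.  The co-expression network uses the printed
recipe: adjacency $|r|^5$, dissimilarity $1 - |r|^5$, average-linkage
hierarchical clustering, a static cut at fixed height 0.99 (the
conventional static-cut height: co-expressed blocks join far below it,
unrelated genes only above it), minimum module size 60, and iterative
merging of modules whose eigengenes are closer than 0.25 in correlation
dissimilarity.  A cut height chosen to maximize module count was
evaluated and rejected: near the tree root, unrelated genes agglomerate
into spurious size-passing clusters that absorb real modules.  The
eigengene is the first right singular vector of the gene-standardized
module submatrix, sign-fixed to correlate positively with its member
genes and scaled to unit variance.

Multigene signatures preselect the 100 genes with the largest absolute
Pearson correlation to the target feature and fit an elastic net over
$\alpha \in \{0.05, \dots, 0.95\}$ (step 0.05) and 50 log-spaced
$\lambda \in [10^{-4}, 1]$, choosing the pair with the smallest tenfold
cross-validated error under a shared fold assignment.  The signature is
the set of nonzero-coefficient genes.  Known limitation: the
prediction-optimal $\lambda$ retains correlated false-positive genes, so
the *support* of the signature is noisy (F1 around 0.5 against a planted
10-gene model at $n = 87$) even when predictive $R^2$ is high (0.8-0.95);
support-exact selection would require stability selection or
post-thresholding, which the package deliberately does not bolt on.
Signature transfer is a linear score ($\beta_0 + \sum \beta_g x_g$) plus
log-rank stratification at the fixed training threshold.  Enrichment is
the upper-tail hypergeometric test against a user-supplied GMT
collection, BH-corrected; the default universe is the post-filter gene
set.

## The synthetic-data generators

The generators define the package's study conditions:

* **Kinetic curves** are gamma-variate wash-in/wash-out curves
  $A\,(t/t_p)^a e^{a(1 - t/t_p)}$, parameterized per role (plasma: peak
  at ~10-16% of the acquisition window, sharp decay; fast flow:
  peak ~35-45%; slow flow: broad plateau peaking near the end).  The
  functional form is a modelling choice — smooth, nonnegative, and
  qualitatively matching observed compartment kinetics.
* **Proportion fields** are spatially correlated Dirichlet maps built
  through a Gaussian copula: per compartment, white noise is smoothed by
  a 3-voxel moving average inside the mask, standardized, mapped through
  the gamma quantile function, and the fields normalized to row sums of
  one.  This keeps the full Dirichlet($\alpha$) marginal spread (a
  well-grounded simplex whose corners are approached by real pixels)
  while making subregions spatially contiguous.  Smoothing the
  proportions themselves would shrink their variance roughly 27-fold and
  empty the simplex interior, which both breaks corner identification
  and makes compartments statistically invisible.  5% of voxels (split
  evenly across compartments, chosen as the highest-proportion voxels)
  are forced to exactly pure proportions, making the corner-occupancy
  assumption explicit.  Gaussian additive noise is an assumption of
  convenience; scanner physics, motion and protocol variation are not
  emulated, so passing tests certify algorithmic correctness on the
  model's own terms, not robustness to real-world artefacts.
* **Survival** is exponential proportional hazards,
  $\lambda_i = e^{\beta f_i}/s$ with baseline scale $s$ (years), under
  independent uniform censoring on $(0, c)$ with $c$ solved numerically
  for the requested censoring fraction.
* **Expression** is block-modular: module genes are
  $\mathrm{loading} \times \mathrm{latent} + \mathcal{N}(0, \sigma)$
  with loadings on $U(0.8, 1.2)$ and $\sigma = 0.3$ by default; one
  designated module's latent is $r\,z_f + \sqrt{1 - r^2}\,z_\perp$ with
  $z_\perp$ orthogonalized against the standardized feature $z_f$, so
  the planted module-feature correlation equals the target (default
  0.59, a representative reported module-feature link strength) exactly
  in-sample before estimation noise.

All generators are pure functions of their seed; `runFull()` derives all
stage seeds deterministically from one master seed and records every
parameter in a provenance report.

## Numerical choices and degenerate inputs

* Simplex projections: support enumeration is exact for $J \le 6$;
  duplicated corners make the weights non-unique but the residual is
  still unique and returned correctly (singular KKT systems fall back to
  a pseudo-inverse).
* FCM: a data point coinciding with a centroid receives full membership
  there; the objective trace is non-increasing and convergence is a
  $10^{-6}$ objective change or 300 iterations.
* Affinity propagation on all-identical points returns a single exemplar
  directly; non-convergence returns the current exemplars with a
  warning.
* Proportions are clipped at zero and renormalized after projection, so
  rows sum to one within $10^{-6}$.
* Cox fits refuse constant features and tables with fewer than two
  events; optimal cutoffs refuse constant features and degenerate arms.
* Zero-variance regions return degenerate-flagged histogram/Haralick
  values rather than NaN.

## Problem sizes used in the tests

The test-suite and acceptance experiments run at deliberately compact
sizes chosen to exercise every code path with stable statistics: tumours
of $10 \times 10 \times 4$ voxels ($N = 400$ pixels, $T = 8$ time
points) over 10 seeds for unmixing and model-order selection, survival
cohorts of $n = 200$-$500$, expression matrices of 300-500 genes (module
sizes 60-158) at $n = 87$ samples, and a transfer cohort of $n = 500$.

## Known limitations

* Compartments are purely data-driven; no pharmacokinetic (Tofts-type)
  parameters or arterial input functions are estimated.
* Segmentation is single-lesion, intensity-driven FCM on the
  early-enhancement volume with 26-connectivity; there is no bias-field
  correction or registration.  Whether to segment per series and fuse
  masks is an open choice; the package segments once on early
  enhancement.
* Pixel curves enter clustering raw (no baseline subtraction or
  area normalization); both are available as explicit preprocessing by
  the caller.
* The elastic-net signature's gene membership should be read as a
  predictive set, not as the true support (see above).
* Enrichment runs on user-supplied GMT collections only; no pathway
  database is bundled.
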