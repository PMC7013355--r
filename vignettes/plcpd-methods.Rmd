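---
title: "Probabilistic-learning coherent point drift: model, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic-learning coherent point drift: model, pipeline and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Fetal 3D ultrasound of the head suffers from speckle, operator-dependent
intensity variation, and — after cranial calcification sets in — acoustic
shadows that wipe out whole sectors of the cranium. Two acquisitions of the
same head taken from different probe positions (axial and coronal
projections, say) therefore carry *complementary* information, and aligning
them is a prerequisite for growth monitoring, atlas-based structure
segmentation, or multi-view compounding. Intensity-based registration
(mutual information, correlation, mean-squared error) struggles here,
because the two volumes genuinely do not contain the same intensities.

`plcpd` implements a geometry-based alternative: the cranium is segmented
automatically, turned into a point cloud, and registered with a weighted
variant of coherent point drift in which each point's Gaussian-mixture
membership prior is the probability — produced by a random-forest voxel
classifier — that the point really belongs to the cranium. Dubious points
(misclassifications, shadow remnants, outliers) then barely participate in
the alignment.

## The registration model

Let $X = \{x_n\}_{n=1}^N$ be the fixed cloud and $Y = \{y_m\}_{m=1}^M$ the
moving cloud, viewed as the centroids of a Gaussian mixture with isotropic
variance $\sigma^2$ that drifts coherently under a similarity transform
$\mathcal{T}(y) = sRy + t$. A uniform component with mixing mass
$w \in [0,1)$ absorbs points explained by no centroid. Standard coherent
point drift gives every centroid the same prior $1/M$; here the priors are

$$P(m)^* = \frac{P(c{=}+1 \mid y_m)}{\sum_k P(c{=}+1 \mid y_k)},$$

the classifier posteriors normalized to sum to one. EM alternates:

* **E-step** — correspondence posteriors
  $P(m \mid x_n) \propto P(m)^* e^{-\|x_n - \mathcal{T}(y_m)\|^2 / 2\sigma^2}$,
  with the outlier constant $(2\pi\sigma^2)^{D/2}\, w / ((1-w) N)$ added to
  each column's denominator. With uniform priors this reduces *exactly*
  (multiply numerator and denominator by $M$) to the classic equiprobable
  E-step, which is how the uniform-prior baseline in this package is the
  standard method, not an approximation. Columns are evaluated with a
  max-subtraction log-sum-exp scheme so small $\sigma^2$ cannot overflow.
* **M-step** — closed-form weighted Procrustes update: posterior-weighted
  centroids, SVD of the weighted cross-covariance, determinant-corrected
  rotation $R = U\,\mathrm{diag}(1,1,\det(UV^\top))\,V^\top$, optional
  isotropic scale (clamped to $[0.5, 2]$ against collapse; a rigid mode
  fixes $s=1$), translation, and the posterior-weighted residual variance.

The tracked objective is
$Q = \frac{1}{2\sigma^2}\sum_{m,n} P(m,n)\,\|x_n - \mathcal{T}(y_m)\|^2 +
\frac{D N_\mathbf{P}}{2}\log\sigma^2$, plus a prior term for the weighted
variant ($Q^* = Q + \sum_{m,n} P(m,n) \log P(m)^*$). EM guarantees descent of
the observed negative log-likelihood, not of $Q$ itself across iterations
(the posteriors change too); in practice $Q$ decreases monotonically, and the
implementation enforces this by construction: a step that would raise $Q$ by
more than $10^{-8}$ is rejected and the run is declared converged at the
previous iterate. Convergence otherwise means
$|\Delta Q| / \max(1, |Q|) < 10^{-6}$ or the variance reaching its floor
($10^{-8}$ in normalized units); the iteration cap is 150. On exactly
overlapping clouds the variance anneals geometrically, so convergence takes
a few dozen iterations, not a handful — the transform is at the identity to
machine precision long before the trajectory flattens.

Both clouds are centered and scaled to unit RMS radius before EM (the
recovered transform is mapped back to millimetres afterwards), and the
initial $\sigma^2$ is the mean squared distance between all cross-pairs
divided by $D$. The fixed cloud's weights are ignored: the model weights
only the mixture centroids. The default outlier mass is $w = 0.1$; harnesses
with deliberate contamination use $w = 0.3$.

## The upstream pipeline

**Confidence maps.** Ultrasound reliability decays with depth and collapses
behind strong reflectors. The package uses a per-beam-line recurrence:
$c(0) = 1$ at the transducer-side face and
$c(k) = c(k-1)\,e^{-\Delta(\mu + \gamma \hat g_k)}$, with $\Delta$ the voxel
spacing along the beam (mm), $\mu$ the baseline attenuation (default
0.02/mm), $\gamma$ the shadow gain (default 0.5), and $\hat g_k$ the
beam-axis gradient magnitude normalized to $[0,1]$ over the volume. This is
a deliberate closed-form model — it reproduces the two properties the
pipeline relies on (depth attenuation; darkening distal to strong
reflectors), is invariant to global affine intensity rescaling, and can be
swapped for a full random-walk formulation behind the same contract.
Confidence weighting multiplies intensities voxelwise (the natural reading
of a "weighted image").

**Features and the forest.** Eight per-voxel features feed the classifier:
raw intensity, local variance, normalized local rank, local histogram
entropy (32 gray levels, bits), local median, a Wiener-style local adaptive
filter (noise variance estimated as the mean local variance), slice-wise 2D
Canny edges (hysteresis at 0.1/0.2 of each slice's gradient maximum,
recorded as 0/1), and the 6-neighbor Laplacian. Window statistics use a
9×9×9 analysis window with edge replication. The forest grows
entropy-split trees: at each node a fresh random candidate set —
$\lceil\sqrt{d}\rceil$ feature indices × 10 quantile thresholds of the
node's values — is scored by information gain in bits, with a minimum leaf
of 5 samples, maximum depth 12, and 50 trees by default; leaves store
empirical class histograms and the ensemble posterior is their plain
average. Training subsamples at most 50 000 voxels per volume,
class-balanced. These hyperparameters are conventional random-forest
practice; none is critical, and all are exposed. Features are computed on
the confidence-weighted volume, with the raw intensity also in the stack.

**Cloud construction.** The posterior is thresholded at 0.5 (ties to
cranium), cleaned to its largest 26-connected component (the cranium is one
shell), and the mask's boundary voxels — the mask minus its 6-neighbor
erosion, i.e. both the inner and outer shell surfaces — become vertices at
their world-frame centers. Each vertex's weight is the posterior sampled
trilinearly at it. Farthest-point subsampling (seeded start) reduces the
cloud to about 2000 points while preserving coverage of both surfaces; a
tetrahedral meshing backend could replace this behind the same contract,
but boundary voxels are deterministic, dependency-free and testable.

## The phantom generator

Real paired fetal acquisitions are not redistributable, so validation runs
on a synthetic phantom: an ellipsoidal cranium shell (semi-axes 28/24/20 mm,
2.5 mm thick — second-trimester scale) over soft-tissue interior and dim
background (mean intensities 220/120/40), multiplied by a correlated
speckle field (Rayleigh with mode 1, Gaussian-smoothed at 0.8 voxels — the
simplest standard model of multiplicative ultrasound speckle). Occlusion
sectors are azimuthal wedges through the ellipsoid center whose shell
intensities are multiplied by an attenuation factor; the wedge geometry
makes sector width directly interpretable (a 90° fully occluding wedge
removes ≈25% of the shell) and mirrors how calcification shadows cut
through the skull. Occluded shell voxels lose both signal and label. The
second acquisition evaluates the same anatomy analytically at coordinates
mapped through a known ground-truth similarity transform (so its grid
carries no interpolation error), applies *different* occlusion sectors —
complementary missing data, as real projections provide — and an
independent speckle realization. The default grid is 160³ at 0.4 mm
(clinical 3D fetal ultrasound is 0.2–0.5 mm); test harnesses use 64³ at
1.0 mm so that suites finish quickly, a resolution at which segmentation
and registration behave the same way, just with proportionally coarser
quantization.

Cloud pairs for registration-only studies are sampled directly on the inner
and outer shell surfaces. The moving cloud's inliers are the *same*
generating surface points mapped through the inverse ground-truth transform
— the round-trip contract is exact correspondence, which is what makes
noiseless recovery testable at sub-degree tolerances — optionally jittered
with isotropic Gaussian noise, with a deterministic count of box-uniform
outliers substituted in at low nominal weight (defaults: inliers 0.95,
outliers 0.01) and optional beta-perturbation of the weights.

What the phantom does *not* emulate: beam-convolution speckle texture,
internal brain anatomy (ventricles, peduncles), probe-dependent intensity
falloff profiles, or fetal motion between acquisitions. Passing phantom
tests therefore demonstrates the correctness and robustness of the
*method* — segmentation features that separate a bright shell from textured
tissue, and registration under occlusion, noise and outliers — not clinical
performance on real scanners.

## Validation harnesses and the choices behind them

* **Oracle equivalence.** The E-step and objective are checked against
  naive double-loop Bayes implementations on dozens of random small
  configurations, and the M-step against transforms it must recover exactly
  under identity pairing.
* **Descent.** Every seeded phantom registration must have a non-increasing
  $Q$ trajectory (tolerance $10^{-8}$), which the stagnation guard makes
  structural rather than statistical.
* **Noiseless recovery.** Ten seeded corresponding cloud pairs (N = 500,
  rotations up to 40°, translations up to 20 mm, scale 0.9–1.1) must be
  recovered to 0.5°, 0.5 mm and 1 mm TRE.
* **The weighting advantage.** Twenty seeded pairs with 30% box-uniform
  outliers (weights 0.01 vs 0.95, $w = 0.3$) compare classifier-weighted
  priors against the uniform baseline on the same clouds. The inliers carry
  1.5 mm Gaussian jitter: with *exact* correspondences both variants drive
  $\sigma^2$ to the floor and recover the transform to machine precision,
  so the comparison degenerates to numerical noise — outliers only ever
  matter when the converged $\sigma^2$ is large enough to keep them
  competitive with genuine correspondences. 1.5 mm is well inside the
  surface error the package's own segmentation pipeline produces on
  phantoms, so the jittered condition is the realistic one, chosen once
  and kept.
* **Segmentation.** Five-fold cross-validation over five phantom
  realizations (leave-one-volume-out), reporting held-out Dice, AUC and
  Hausdorff surface distance. A phantom-specific caveat: labels exclude
  occluded shell voxels (the signal is gone) while the classifier may still
  recover the attenuated shell there, so held-out Hausdorff distances are
  dominated by the occlusion wedges and run far above what the Dice/AUC
  values would suggest — a property of the label convention, not of the
  segmenter.
* **End-to-end.** A phantom pair with complementary 90° occlusion sectors
  runs the full pipeline — confidence weighting, forest segmentation
  (forest trained on an independent labeled phantom), weighted clouds,
  registration — and the TRE must be under 10% of the head's mean diameter.

## Numerical and degenerate-input policy

Intensities are double precision throughout; no 8-bit quantization.
$\sigma^2$ is floored at $10^{-8}$ (normalized units) and the scale clamp
prevents mixture collapse; SVD sign ambiguity is resolved by the
determinant-correction diagonal. All-zero classifier weights abort
registration (there is nothing to align); a moving cloud without weights
falls back to uniform priors with a notice; non-convergence at the
iteration cap is a flagged warning state, not an error. Empty masks refuse
cloud construction and surface distances; two empty masks have Dice 1 by
convention; AUC requires both classes; ROC direction and class levels are
pinned so that reversed scores score 0 rather than being auto-flipped.
TRE is the *mean* of Euclidean distances (an RMS variant is a flag);
Euler angles use intrinsic Z-Y-X extraction in degrees — any fixed
convention is valid since truth and estimate share it; the Hausdorff
surface distance uses the maximum by default with a percentile flag.

## Known limitations

The confidence map is a stand-in with the right qualitative behavior, not
a reimplementation of the random-walk literature. Canny is applied
slice-wise (it is a 2D operator); a genuinely 3D edge detector would
handle oblique interfaces better. The forest has no bagging — randomness
enters only through per-node candidate sets, which the tree-growth
description implies — so very small forests are more correlated than a
bootstrap ensemble would be. Registration is similarity/rigid only: no
coherent velocity-field deformation, no fast Gauss transform acceleration,
so cost is $O(MN)$ per iteration. The phantom's azimuthal-wedge occlusion
is a geometric idealization of acoustic shadowing.
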