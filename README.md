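# plcpd

Automatic rigid/similarity registration of 3D ultrasound fetal-head
acquisitions with **probabilistic-learning coherent point drift (PL-CPD)**:
a Gaussian-mixture point-set registration whose per-centroid membership
priors are the posterior probabilities of a random-forest cranium
classifier, so that dubious points — acoustic-shadow remnants,
misclassified tissue, outliers — barely participate in the alignment.

The package is aimed at researchers in fetal/obstetric image analysis and
point-set registration who need:

* the full pipeline from a raw volume to an aligned pair — confidence-map
  preprocessing, texture/edge features, random-forest segmentation,
  posterior-weighted shell point clouds, EM registration;
* a standard coherent point drift baseline (uniform priors are the exact
  special case of the weighted E-step);
* the evaluation metrics of the field — target registration error (TRE),
  translation/rotation RMS, Dice, Hausdorff surface distance, ROC AUC;
* a synthetic ultrasound phantom generator with known ground-truth
  transforms, so everything is testable without clinical data.

## The model

Moving points $Y=\{y_m\}$ are centroids of a GMM with isotropic variance
$\sigma^2$ drifting coherently under $\mathcal T(y)=sRy+t$ onto the fixed
cloud $X=\{x_n\}$, with a uniform outlier component of mass $w$. PL-CPD
replaces the equiprobable prior $1/M$ with

$$P(m)^* = P(c{=}{+}1\mid y_m)\Big/\sum\nolimits_k P(c{=}{+}1\mid y_k),$$

the normalized classifier posteriors. EM alternates a log-sum-exp-stable
E-step

$$P(m\mid x_n)=\frac{P(m)^*\,e^{-\|x_n-\mathcal T(y_m)\|^2/2\sigma^2}}
{\sum_k P(k)^*\,e^{-\|x_n-\mathcal T(y_k)\|^2/2\sigma^2}
+(2\pi\sigma^2)^{D/2}\frac{w}{(1-w)N}}$$

with a closed-form weighted-Procrustes M-step (SVD with determinant
correction, optional isotropic scale, posterior-weighted variance update),
tracking the objective
$Q=\frac{1}{2\sigma^2}\sum P(m,n)\|x_n-\mathcal T(y_m)\|^2
+\frac{DN_P}{2}\log\sigma^2$.

## Worked example

```r
library(plcpd)

# a synthetic acquisition pair: ellipsoidal cranium shell, speckle,
# complementary 90-degree occlusion sectors, known ground-truth transform
occ <- function(d) list(list(direction = d, width_deg = 90, factor = 0.1))
spec <- phantom_spec(grid_dim = c(64, 64, 64), spacing = 1,
                     occlusion_a = occ(c(1, 0, 0)),
                     occlusion_b = occ(c(-1, 0, 0)), seed = 42)
ph <- make_phantom_pair(spec)

# train the cranium forest on an independent labeled phantom
tr <- make_phantom_pair(phantom_spec(grid_dim = c(64, 64, 64), spacing = 1,
                                     seed = 43))
cm <- compute_confidence_map(tr$vol_a)
fs <- extract_features(weight_by_confidence(tr$vol_a, cm))
forest <- train_forest(fs, tr$label_a, sample_cap = 20000, seed = 13)

# full pipeline: segment both volumes, build weighted clouds, register
fit <- register_volumes(ph$vol_a, ph$vol_b, forest, seed = 5)
fit$transform
#> <similarity_transform> scale 0.980708, translation (2.81245, 5.63793, -2.2119) mm,
#>   rotation ZYX (8.19618, 3.19315, 2.30921) deg

evaluate_registration(ph$transform, fit$transform,
                      mask_bbox(ph$label_a), seed = 7)
#> # A tibble: 1 x 6
#>     tre rms_translation rms_rotation rotation_error scale_error n_targets
#>   <dbl>           <dbl>        <dbl>          <dbl>       <dbl>     <int>
#> 1  2.34            2.12         3.54           5.98      0.0193      1000
```

`tre` is the mean distance (mm) between 1000 uniformly sampled head-box
target points mapped through the true vs the estimated transform — here
2.3 mm, about 5% of the phantom head's 48 mm mean diameter, under
complementary occlusions, speckle and segmentation error. `tidy(fit)`,
`glance(fit)` and `autoplot(fit)` expose the transform parameters, the run
summary and the EM objective trajectory.

On cloud-only studies with 30% injected outliers, the classifier-weighted
priors beat the uniform-prior baseline run on the same clouds in the large
majority of seeds (see the acceptance script below for the exact numbers
your machine reproduces).

A thin command-line front end covering each stage
(`phantom`, `confidence`, `train`, `segment`, `cloud`, `register`,
`evaluate`) ships at `inst/cli/plcpd`.

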