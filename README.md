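# stainclust

Unsupervised clustering of **multi-stain histopathology patches** by
regularized information maximization.

A tissue section digitized under five staining protocols (HE, MT, CD31,
CK19, Ki67) yields five co-registered colour renditions of the same
anatomy.  `stainclust` embeds all five stains of a patch jointly — a
`(side, side, 15)` array — with a convolutional autoencoder, and trains a
softmax classifier head on the latent features without any labels by
maximizing the mutual information between patches and their soft cluster
assignments.  The training objective is

```
L = R_L − (λ_ME·H(Y) − λ_CE·H(Y|X)) + λ_AF·L_AF
```

where `R_L` is the reconstruction mean-squared error, `H(Y)` the marginal
entropy of the batch-average assignment (rewards balanced cluster usage),
`H(Y|X)` the mean per-patch assignment entropy (rewards confident
assignments), `H(Y) − H(Y|X)` the plug-in mutual information `I(X;Y)`, and
`L_AF` a KL-divergence consistency penalty between the assignments of each
patch and a randomly rotated/translated/scaled copy.  Defaults:
`λ_ME = 0.1`, `λ_CE = 0.03`, `λ_AF = 0.03`, Adadelta, batch 100.

The number of clusters is chosen by training one model per candidate count
and voting across six internal validity indices (Xie–Beni,
Calinski–Harabasz, C index, Hartigan, Dunn, McLain–Rao).  A whole slide is
then rendered as a per-tile cluster colormap for patch-level anomaly
localization.  A synthetic multi-stain generator with known class structure
makes the entire pipeline testable offline, and a tiled synthetic slide
exercises the map stage end to end.

Who this is for: computational-pathology researchers who want an
annotation-free baseline for tissue-type discovery on co-registered
multi-stain panels, and anyone needing a self-contained, tested reference
implementation of information-maximization clustering with internal
validity-index model selection.

## Worked example

```r
library(stainclust)

# 600 synthetic 32-px patches, 4 latent tissue classes, 5 pseudo-stains
spec    <- synth_spec(n_classes = 4, n_patches = 600, patch_size = 32, seed = 1)
patches <- generate_patch_dataset(spec)
patches
#> <stain_patchset> 600 patches, 32x32 px, 15 channels (5 stains), 4 labelled classes

fit <- train_imclust(patches, train_config(n_clusters = 4, epochs = 300,
                                           learning_rate = 1, seed = 1))
glance(fit)
#> # A tibble: 1 × 5
#>   n_clusters epochs final_total final_mutual_info mi_gain
#>        <int>  <int>       <dbl>             <dbl>   <dbl>
#> 1          4    300      -0.130              1.36    1.36

assignment <- assign_clusters(fit, patches)
agreement(assignment$labels, patches$labels)
#> # A tibble: 1 × 2
#>     ari   nmi
#>   <dbl> <dbl>
#> 1     1     1
```

The mutual information climbs from ≈ 0 to 1.36 nats — essentially
`ln 4 ≈ 1.386`, a confident, balanced 4-way partition — and the hard
assignments match the generator's hidden labels exactly (adjusted Rand
index 1).

Slide-level utilities reproduce the published patch arithmetic, and the
shipped reference grid of validity indices reproduces the published
14-cluster selection:

```r
tile_grid(15000, 20000, 128)
#> <tile_grid> 15000x20000 px at tile 128: 117 x 156 = 18252 tiles
vote_optimal(select_optimal(reference_validity_grid()))
#> <validity_vote> optimal K = 14 with 6 of 12 votes
```

`run_pipeline(pipeline_config("desk"), "out/")` chains every stage —
generate, train per candidate cluster count, assign, validate, select,
embed in 2-D, render the cluster map — and writes all artifacts plus a
manifest under `out/`.  A thin command-line wrapper with the same stages
lives in `inst/scripts/stainclust.R`.

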