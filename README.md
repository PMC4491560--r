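# taxvis

Feature extraction and evaluation for **hierarchical visual object
categorization**. Object concepts are commonly organized over three
tiers of inclusiveness — superordinate (artificial vs natural), basic
(animal vs plant) and subordinate (a specific kind of animal or plant)
— and each tier is best served by a different kind of visual
information. `taxvis` is for researchers in computational vision and
visual cognition who want a small, fully reproducible implementation of
one feature family per tier, together with synthetic image sets that
carry the corresponding category structure and an evaluation harness.

## What it computes

**Superordinate — global frequency features.** For the unnormalized 2-D
DFT *F(u,v)* of a grayscale image:

- *f₁* = Σ |F(u,v)| (total spectral magnitude),
- *f₂* = Σ ln(1 + |F(u,v)|),
- *f₃* = Σ arg F(u,v) (phase sum, range (−π, π]).

Artificial scenes concentrate spectral energy in few harmonics; natural
textures spread power as ~1/f^β, so the families separate in this
3-dimensional space. Separation is scored unsupervised with fuzzy
c-means plus precision / recall / f-measure / accuracy.

**Basic — a 32-dimensional shape descriptor.** Silhouettes (global Otsu
binarization with automatic polarity) are described by 16 standardized
moments (per-axis mean, variance and standardized central moments of
orders 3–8, odd orders in absolute value) concatenated with 16 Zernike
moment magnitudes |A\_nm| for all n ≤ 6, n − m even, on the
centroid-centered unit disk. A 128-dimensional basic HOG descriptor
(4×4 blocks, 8 orientation bins) is included as a baseline.
Classification uses a linear SVM over repeated stratified splits.

**Subordinate — flat vs conceptual eigenspaces.** 100×100 training
images are stacked into S (10⁴ × n) and principal axes are obtained via
the small-covariance trick (eigendecompose SᵀS, map back u = S v). A
*flat* model fits one basis over all classes; a *conceptual* model fits
one basis per basic class and concatenates the projections. Conceptual
features improve subordinate-class recognition because each per-class
basis spends its leading directions on within-class structure.

## Worked example

```r
library(taxvis)

# basic level: animal vs plant silhouettes
cfg  <- synthetic_config(n_per_class = 25, seed = 42)
df   <- shape_descriptor_table(gen_basic_silhouette_set(cfg))
rep  <- classification_harness(as.matrix(df[, grep("^(mu|z)_", names(df))]),
                               df$basic, train_fraction = 0.5,
                               n_runs = 10, seed = 42)
print(rep)
#> Linear-SVM report: 10 runs, train fraction 0.50
#> Total accuracy: 100.00% (sd 0.00)
#>   animal       100.00% (sd 0.00)
#>   plant        100.00% (sd 0.00)

# superordinate level: artificial vs natural, unsupervised
ft <- frequency_feature_table(gen_superordinate_set(synthetic_config(50, seed = 42)))
fc <- fuzzy_cmeans(as.matrix(ft[, c("f1", "f2", "f3")]), seed = 42)
cluster_metrics(max.col(fc$memberships), ft$superordinate)
#> f-measure 0.971  precision 0.943  recall 1.000  accuracy 0.970
```

The SVM report says the 32-dimensional shape descriptor separates the
two silhouette families perfectly on held-out images in all ten random
splits; the clustering metrics say fuzzy 2-means on the three frequency
features recovers the artificial/natural split for 97 of 100 images
without seeing any labels (the natural cluster is the positive class).

A command-line front end over the same functions lives at
`inst/cli/taxvis.R` (`synth`, `features`, `evaluate` subcommands driven
by a YAML config).

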