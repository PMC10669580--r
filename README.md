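# lesionlab

Classical image analysis for **benign vs. malignant dermoscopic skin lesion
classification**: persistent-homology preprocessing, iso-contour
segmentation, ABCD-rule feature extraction, and boosted-tree classification
under a balanced resampling protocol with a disjoint test source. A
synthetic lesion generator with ground-truth masks makes the entire
pipeline testable without external image corpora.

## Who this is for

Researchers building or auditing classical (feature-based) skin-lesion
classifiers, and anyone who needs a self-contained, oracle-tested
implementation of the individual stages: H0 persistence of an intensity
image, persistence-guided contrast enhancement, lesion mask extraction,
pose normalization and eight-sector partition, the seven ABCD features, the
65%-benign balancing protocol, and mean ± SD confusion-matrix evaluation.

## The method in brief

1. **Segmentation.** The grayscale image is filtered by sublevel sets on
   the 4-connected pixel grid; connected components are tracked with the
   elder rule, giving bars `[birth, death)`. Noise components have short
   lifespans; a largest-gap rule picks the lifespan threshold; short-lived
   components are erased to their merge level, surviving components are
   flattened to their birth level, and the background goes to its modal
   intensity. The mask is the iso-contour interior at the enhanced image's
   Otsu level (largest component, holes filled).
2. **Features.** After rotating the major axis horizontal and centering,
   the lesion is divided into eight 45° sectors and described by: NEF shape
   asymmetry (contact-perimeter compactness complement), border
   irregularity `4πA/P²`, compactness `P²/(4πA)`, box-counting fractal
   dimension of the boundary, six palette color densities (K-means, k = 3,
   snapped to the dermoscopy palette), opposite-sector color asymmetry
   (L1 histogram distance), and the SD of the color densities. Features are
   min–max normalized to their nominal ranges, fitted on training data
   only.
3. **Protocol.** Ten balanced datasets are drawn by sampling 65% of the
   dominant benign pool each time; each splits 70/30 (stratified) into
   train/validation; a disjoint source is held out for testing; metrics
   (accuracy, specificity, sensitivity, precision; malignant positive) are
   reported as mean ± SD over the ten runs by a gradient-boosted tree
   ensemble (100 depth-3 trees, shrinkage 0.1), with KNN/SVM/decision-tree
   comparators.

## Worked example

```r
library(lesionlab)

spec <- lesion_spec(base_radius = 32, harmonic_amplitudes = c(0.15, 0, 0.08),
                    asymmetry_shift = 0.2,
                    palette_weights = c(dark_brown = 0.5, light_brown = 0.3,
                                        blue_gray = 0.2),
                    noise_sd = 8, seed = 42)
les  <- make_lesion(spec, label = "malignant")
mask <- segment(les$image)                  # persistence-guided chain
2 * sum(mask & les$mask) / (sum(mask) + sum(les$mask))
#> [1] 0.972                                # Dice vs. ground truth

extract_features(les$image, mask)
#> shape_asymmetry border_irregularity fractal_dimension compactness
#>           0.034               0.367             1.133       2.728
#> color_asymmetry  color_sd
#>           1.855    17.711
#> density_light_brown density_dark_brown density_blue_gray  (others 0)
#>                42.1               36.0              21.9
```

Reading the numbers: the three radial harmonics push circularity
(`border_irregularity`) well below the circle optimum of 1; the displaced
three-color paint shows up as a high opposite-sector color asymmetry
(1.86 of a maximum 2) and three nonzero palette densities; NEF stays low
because the lesion is still one compact blob.

The full study — simulate three sources, segment, extract features, balance
ten subsets, train and evaluate — is one call:

```r
res <- run_all(lesionlab_config(seed = 11), out_dir = "study")
print(res$result)
#> Balanced-resampling experiment (boosted_tree, 10 subsets)
#>       split      metric  mean    sd
#>  validation    accuracy 0.971 0.016
#>        test    accuracy 0.980 0.006
#>        ...
```

A thin CLI wraps the same functions:

```sh
exec/lesionlab simulate --n-benign 20 --n-malignant 20 --seed 1 --out data/
exec/lesionlab segment data/DB1_benign_0001.png --out mask.png
exec/lesionlab run --seed 11 --out study/
```

## Layout

- `R/`, `src/` — implementation (union-find persistence core in Rcpp)
- `tests/testthat/` — unit, property and acceptance suites with
  brute-force oracles in `helper-oracles.R`
- `vignettes/lesionlab-methods.Rmd` — the methods vignette: model,
  parameter choices, numerical decisions, limitations
- `exec/lesionlab` — command-line interface
- `scripts/acceptance.R` — end-to-end reproduction script
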