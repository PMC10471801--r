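# fieldlines

Two-stage extraction of farmland boundary lines from aerial RGB orthoimage
tiles, for researchers and engineers working on autonomous agricultural
machinery: first a lightweight semantic segmentation network labels each
pixel as Crop, Soil or Background; then a boundary-tracing and line-fitting
stage turns the class mask into straight boundary-line equations with
quality scores.

## The method

**Segmentation.** An encoder–decoder network of the DeeplabV3+ family:
MobileNetV2 inverted-residual backbone at output stride 16, a convolutional
block attention module (CBAM) on its final feature map

    F'  = Mc(F) ⊗ F        Mc ∈ (0,1)^{C×1×1}   (channel gate)
    F'' = Ms(F') ⊗ F'      Ms ∈ (0,1)^{1×H×W}   (spatial gate)

and an atrous-spatial-pyramid-pooling (ASPP) head augmented with a
strip-pooling branch (H×1 and 1×W mean pools → 1-D convolutions → expand,
sum, 1×1 convolution + sigmoid gate) that captures long thin structures
such as field edges. Training minimizes the multi-class Dice loss

    Dice = 1 − 2 Σ pᵢgᵢ / (Σ pᵢ² + Σ gᵢ²)

with Adam (β₁ = 0.9), batch size 8, and a cosine-annealed learning rate
from 5e-4 to 5e-6. The network, its backward passes and the training loop
are implemented in R with compiled kernels — no external deep-learning
framework. Segmentation is scored by pixel accuracy, mPA and mIoU from the
confusion matrix.

**Line extraction.** The class mask is binarized per field class, cleaned
by a morphological opening, labelled into 8-connected regions (small
regions excluded), and each region's boundary is traced with
Moore-neighbour contour following. Boundary points are split into
horizontal and vertical line sets by their local walk direction, and each
set is fitted by least squares (y = θ₀ + θ₁x, axis-swapped for vertical
lines) with standardized-residual screening: points with

    Z = |e| / S_e > 3,   S_e = sqrt(S / (m − n − 1))

are removed and the line refit. Fits are scored by the angular error
|atan θ₁,true − atan θ₁,fit| (degrees) and the vertical error
|Δ intercept| / image height.

A seeded synthetic-scene generator (`generate_scene`) produces textured
images, exact masks and ground-truth boundary lines, so every stage is
testable end to end without field data.

## Worked example

```r
library(fieldlines)

# a synthetic scene: two plots (one Crop, one Soil) with known edges
sc <- generate_scene(scene_config(size = c(512, 512), n_plots = 2,
                                  plot_classes = c("Crop", "Soil"), seed = 31))

# mask -> boundary lines
fl <- extract_field_lines(sc$mask)
fl
#> Extracted 8 boundary line(s) from a 512x512 mask
#>  region 1 (class 1): horizontal boundary line: y = 102.915 + 0.177766 t^1 (support 152)
#>  region 1 (class 1): horizontal boundary line: y = 452.219 + -0.124128 t^1 (support 165)
#>  region 1 (class 1): vertical boundary line: x = 33.8673 + 0.0686299 t^1 (support 330)
#>  region 1 (class 1): vertical boundary line: x = 179.842 + 0.126775 t^1 (support 281)
#>  region 1 (class 2): horizontal boundary line: y = 89.0952 + 0.123486 t^1 (support 163)
#>  region 1 (class 2): horizontal boundary line: y = 391.63 + -0.0421815 t^1 (support 122)
#>  region 1 (class 2): vertical boundary line: x = 284.044 + 0.0849265 t^1 (support 249)
#>  region 1 (class 2): vertical boundary line: x = 474.887 + -0.0908445 t^1 (support 224)

# score against the generator's ground truth
cls <- vapply(sc$lines, function(l) sc$classes[l$region_id], "")
ev <- evaluate_lines(fl, sc$lines, c(512, 512), truth_classes = cls)
attr(ev, "summary")$overall
#>      angular     vertical
#> 0.0074339771 0.0009334349
```

Horizontal lines are reported as `y = θ0 + θ1·x`, vertical lines in the
axis-swapped frame `x = θ0 + θ1·y`; `support` is the number of boundary
pixels behind each fit. The summary gives the mean angular error in degrees
and the mean vertical error as a fraction of the image height; here the
fitted lines deviate from the true plot edges by under a hundredth of a
degree and about half a pixel.

The four architecture variants and their sizes:

```r
for (v in c("baseline", "attention_only", "aspp_only", "full"))
  cat(sprintf("%-15s %.3f M parameters\n", v,
              count_parameters(network_config(variant = v))))
#> baseline        5.814 M parameters
#> attention_only  5.839 M parameters
#> aspp_only       6.044 M parameters
#> full            6.070 M parameters
```

A command-line surface over the same functions lives in
`inst/cli/fieldlines.R` (subcommands `synth`, `train`, `predict`,
`extract`, `eval-seg`, `eval-lines`, `params`).

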