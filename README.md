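# strokegraph

Automatic segmentation of ischemic stroke lesions in CT perfusion (CTP)
slices with a superpixel-graph Chebyshev convolutional network.

Ischemic lesions occupy a small, irregular fraction of a 256×256 axial
slice, which makes pixel-level classifiers both expensive and fragile.
`strokegraph` instead partitions each slice into ~100 SLIC superpixels,
connects spatially adjacent regions into a weighted graph, and classifies
*regions* with a five-block spectral graph convolutional network. The
package is aimed at medical-image-analysis researchers who want a complete,
reproducible, CPU-scale implementation of this pipeline: preprocessing,
graph construction, the network and its optimizer, patient-level
cross-validation, segmentation metrics, and an SNR-controlled
noise-robustness protocol — plus a seeded synthetic phantom generator so
that everything runs and is testable without clinical data.

## The model

Each preprocessed slice (Hounsfield window `[0, 150]` with out-of-window
pixels replaced by zero, intensities normalized to `[0, 1]`) is partitioned
into superpixels R_i. Region i becomes node i with feature x_i = mean
intensity of R_i, and adjacent regions are joined with Gaussian weights

    A_ij = exp( -d_ij² / (2σ²) ),   d_ij = ‖centroid_i − centroid_j‖₂.

With degree matrix `D_ii = Σ_j A_ij` and Laplacian `L = D − A`, spectral
filters act through the graph Fourier transform `L = U Λ Uᵀ`. The network
avoids the eigendecomposition with the Chebyshev expansion on the rescaled
Laplacian `L̃` (spectrum in `[−1, 1]`):

    g(L̃) X = Σ_{k=0}^{K−1} T_k(L̃) X Θ_k,
    T_0 = I,  T_1 = L̃,  T_k = 2 L̃ T_{k−1} − T_{k−2}.

Five such blocks (order `K = 3`, widths 16 → 16 → 16 → 16 → 16 → 2, each
with batch normalization, Leaky ReLU and a second batch normalization),
then dropout (0.3) and a per-node softmax, produce lesion probabilities.
Training minimizes per-node cross-entropy with Adadelta (weight decay
6×10⁻⁴ on the convolution coefficients, 150 epochs, one step per graph).
Evaluation is strictly patient-level: all slices of a patient stay in one
cross-validation fold. Predicted node labels are projected back to pixels
for Dice (DSC), Jaccard, sensitivity, precision and accuracy.

The training loop is compiled (RcppArmadillo) with a pure-R reference
engine kept alongside; the test suite asserts their equality to ~1e−12 and
checks the spectral filtering against a dense eigendecomposition oracle.

## Worked example

```r
library(strokegraph)

# a small synthetic cohort: 4 patients, 128x128 slices, hypoattenuating lesions
cohort <- generate_cohort(phantom_spec(seed = 7, n_patients = 4,
                                       image_size = c(128L, 128L),
                                       slices_per_patient = c(3L, 5L),
                                       lesion_radius = c(6, 14)))
print(cohort)
#> slice_cohort: 15 slices, 4 patients
#>   image size: 128 x 128  lesion fraction range: 0 - 0.0696

# leave-one-patient-out style cross-validation of the full pipeline
cv <- cross_validate(cohort, k = 4,
                     train_cfg = train_config(epochs = 60, seed = 7),
                     pre_cfg = preprocess_config(target_size = c(128L, 128L)),
                     graph_cfg = graph_config(n_zones = 60))
print(cv)
#> strokegraph_cv: 4 patient-level folds
#>   mean fold metrics: DSC 0.716  Jaccard 0.605  Sens 0.627  Prec 0.949  Acc 0.989

print(cv$models[[1]])
#> Chebyshev spectral GCN (5 blocks, dims 16-16-16-16-16-2, orders 3,3,3,3,3)
#>   3498 parameters; trained on 24 graphs / 1502 nodes; final loss 0.08806
```

The fold metrics are pixel-level and pooled over each held-out patient's
slices: a mean DSC of 0.716 means that, averaged over folds, the predicted
lesion masks overlap the reference masks at Dice 0.72 on patients the model
never saw — with precision 0.95 (few false-positive pixels) and the high
accuracy that the strong class imbalance makes easy. At the full operating
point (256×256 slices, 100 zones, 150 epochs, 10 patients, 10 folds) the
same procedure reaches a mean global DSC of about 0.97 on the phantom; the
noise protocol (`robustness_sweep()`) then re-runs the whole pipeline on
noise-degraded copies and reports one metrics row per SNR.

A single slice can be inspected at every stage:

```r
g <- graphify_sample(cohort[[2]], preprocess_config(target_size = c(128L, 128L)),
                     graph_config(n_zones = 60))
print(g)
#> region_graph: 61 nodes, 150 edges, sigma = 18.54
#>   lesion nodes: 2 / 61
mask <- predict(cv$models[[1]], g, type = "mask")   # binary pixel mask
```

A thin command-line interface (`inst/cli/strokegraph`) wraps the same
functions: `strokegraph phantom --out d/`, `strokegraph run --config
cfg.yaml`, `strokegraph sweep-snr --config cfg.yaml`, with YAML
configurations from `write_pipeline_config()`.

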