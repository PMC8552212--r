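# MSIbackfit

Unsupervised segmentation of extremely low-count hyperspectral ToF-SIMS
images by a bin--train--backfit strategy.

## The problem

Large-area (macroraster) time-of-flight secondary ion mass spectrometry
images are acquired under the static limit: each pixel sees so few primary
ions that a single-pixel mass spectrum is a "barcode" of isolated
single-count signals. A 10^3--10^4 pixel-per-side raster integrated over a
few hundred mass peaks gives a pixels-by-peaks count matrix where per-pixel
per-peak counts are 0 or 1 and the per-pixel total ion count (TIC) rarely
exceeds a few tens. Classical pixel binning (summing B x B neighboring
pixels) recovers usable counting statistics but throws away the lateral
resolution that applications such as latent-fingermark analysis need.

The strategy implemented here keeps both: a parametric low-dimensional
embedding -- a fuzzy k-nearest-neighbor graph whose layout is produced by a
neural-network encoder trained under a cross-entropy objective -- is
**trained on the binned cube**, where statistics are sound, and then
**backfitted** (applied row-wise, no re-optimization) to every pixel of the
original unbinned cube. Cluster structure is likewise learned from the
binned embedding and transferred to full resolution by nearest-centroid
assignment. Downstream tools reconstruct per-cluster mass spectra, decide
the deposition order of two overlapping fingermarks from the surface
coverage of their overlap zone, and sweep the binning level to show that
both too little and too much compression hurt.

Because no public raw data exist for this kind of experiment, the package
ships a synthetic overlapping-fingermark phantom with analytic ground truth
(four spatial classes: substrate, print A, print B, chemically shared
overlap; sinusoidal ridges inside elliptical footprints; Bernoulli
single-ion counting; a deposition-order occlusion effect). Every
quantitative claim in the test suite is made against this phantom.

## Core model

For the binned matrix rows x_i, directed neighbor weights are

    w(i -> j) = exp(-max(0, d_ij - rho_i) / sigma_i),   j in kNN(i)

with rho_i the nearest-neighbor distance and sigma_i calibrated by
bisection so that sum_j w(i -> j) = log2(k). Symmetrized weights
w_ij = w(i->j) + w(j->i) - w(i->j) w(j->i) define edge probabilities. An
MLP encoder f: R^K -> R^d (two hidden layers of 128 ReLU units) minimizes
the fuzzy cross-entropy between w_ij and the embedding similarity

    q_ij = 1 / (1 + a ||f(x_i) - f(x_j)||^(2b)),

with (a, b) least-squares-fitted from `min_dist`, optimized by Adam over
weighted edge minibatches with uniform negative sampling. Two additions
make the backfit to unbinned pixels statistically sound: the encoder is
pretrained to a rescaled PCA layout, and during optimization its inputs are
resampled from the counting distribution implied by the binned rates
(Poisson noise augmentation), so the network is trained on the very
distribution of sparse single-pixel spectra it will later embed.

## Worked example

The reference phantom is 504 x 504 pixels with K = 64 peaks; the full
pipeline below takes about two minutes on one CPU.

```r
library(MSIbackfit)

config <- phantomConfig(seed = 1)      # the reference low-count scene
truth  <- composeScene(config)
cube   <- sampleCube(truth, config)
cube
#> SparseCube: 504 x 504 pixels, 64 peaks, 958551 events, 958551 total counts
max(totalIonMap(cube))
#> [1] 20

res <- binTrainBackfit(cube, factor = 14, seed = 1)
res$labels
#> LabelImage (pixel domain): 504 x 504 pixels, 4 clusters

truthLabels <- as.integer(t(classMap(truth)))
mclust::adjustedRandIndex(as.integer(t(clusterLabels(res$labels))), truthLabels)
#> [1] 0.8339928

# clusters are numbered by decreasing size; here print A's region carries
# cluster 2 and print B's cluster 1 (e.g. by majority over known regions,
# or by their reconstructed spectra on real data)
sequenceVerdict(res$labels, printACluster = 2, printBCluster = 1,
                overlapRegion = classMap(truth) == 3)
#> SequenceVerdict: A on top (coverage A 0.083 vs B 0.012 over 6642 overlap
#> pixels, margin threshold 0.10)
```

Reading the output: the phantom's true scene has four classes and the
pipeline, trained on a 36 x 36 binned cube and backfitted to all 254,016
pixels, recovers four clusters at full lateral resolution with an adjusted
Rand index of 0.83 against ground truth. In the true overlap zone the
pixels not captured by the shared-composition cluster are claimed almost
entirely by print A's cluster (8.3% vs 1.2%) -- the surface-sensitive
signature of the print deposited last, matching the phantom's configured
deposition order (A on top, occlusion weight 0.8).

`rgbMap(res$coords, 504, 504)` renders the 3-D embedding as an RGB
similarity map; `clusterSpectra(densify(cube), labels = res$labels)`
reconstructs the per-cluster mass spectra; `binningSweep()` scores the
pipeline over a grid of binning factors. A command-line front end over the
same functions is installed at `inst/scripts/msibackfit`.

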