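---
title: "Reconstruction-based anomalous-region detection for breast ultrasound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstruction-based anomalous-region detection for breast ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the approach

Breast ultrasonography is a first-line diagnostic modality, but lesion
conspicuity depends heavily on the operator, and labeled lesion data are
scarce relative to normal scans. Reconstruction-based anomaly detection
sidesteps the label shortage: a generative model is trained on **normal
images only**, so it learns to reproduce healthy tissue through a
low-dimensional bottleneck. Presented with an image containing a mass or
tumor, the model reconstructs the anatomy it knows and fails on the
anomalous structure. The per-pixel absolute difference between input $x$
and reconstruction $\hat{x}$ — the *anomaly map* — therefore localizes
the lesion, and binarizing the map at a threshold yields a predicted
region of interest (ROI) that can be scored against a ground-truth mask.

`aedetect` implements this pipeline end to end with three autoencoder
variants sharing one convolutional backbone:

* **AE** — plain autoencoder, trained with the L1 distance
  $L(x,\hat{x}) = \sum_i |x_i - \hat{x}_i|$;
* **VAE** — variational autoencoder; the encoder outputs a diagonal
  Gaussian posterior $(\mu, \sigma)$, sampled via the reparameterization
  trick $z = \mu + \epsilon\sigma$, $\epsilon \sim N(0, I)$, and trained
  with L1 reconstruction plus the closed-form Kullback–Leibler divergence
  $-\tfrac12\sum_j (1 + \log\sigma_j^2 - \mu_j^2 - \sigma_j^2)$ against
  the standard-normal prior;
* **SWAE** — sliced-Wasserstein autoencoder; per-pixel MSE reconstruction
  plus $\lambda$ times the sliced-Wasserstein distance between the
  encoded batch and an equal-size standard-normal draw. The
  sliced-Wasserstein distance averages, over random unit directions
  $\theta$, the exact one-dimensional squared 2-Wasserstein distance
  between the projected samples; in one dimension optimal transport is
  solved exactly by sorting, which is why the estimator needs no
  adversarial critic and no transport-plan optimization.

All three are trained with Adam (learning rate annealed from
$2\times 10^{-4}$ by a single-cycle cosine schedule, batch size 16) on
normal images, optionally augmented with gamma-corrected copies
($\gamma = 0.5$ and $1.5$), mirroring a clinical training protocol.

## Why a synthetic phantom

The clinical dataset this class of study uses (hundreds of curated breast
ultrasound frames with radiologist ROIs) is not publicly distributable, so
the package ships a parametric phantom generator that emulates its
*statistical shape*, not its anatomy:

* a smooth low-frequency echogenicity field in $[0.2, 0.8]$ (white noise
  blurred at scale `smoothness`) stands in for large-scale tissue
  variation;
* multiplicative unit-mean Rayleigh speckle reproduces the granular noise
  texture of B-mode imaging to first order; the factor
  $(1-s) + sR$, $E[R] = 1$, leaves mean echogenicity unchanged before
  clipping;
* lesions are hypoechoic (darkened) ellipses — pixel
  $\leftarrow$ pixel$\,\times (1 - \text{drop})$ inside an optionally
  edge-softened ellipse — because masses typically appear darker than
  surrounding tissue; the ground-truth mask is the hard ellipse interior.

The generator's defaults define the benchmark conditions used throughout
the tests: splits of 853/94 normal and 200 lesioned images mirror the
clinical study design (tests scale these down), lesion intensity drop is
uniform in $[0.4, 0.7]$, lesion area uniform in $[50, 400]$ px on a
$64 \times 64$ grid, speckle mixing weight $0.3$, background smoothness
$8$ px. Everything is a deterministic function of one integer seed.

What the phantom does **not** emulate: beamforming and attenuation
artifacts (shadowing, enhancement), anisotropic speckle, anatomical
context, operator variability, and the benign/malignant distinction.
Passing tests on the phantom therefore demonstrate that the pipeline is
implemented correctly and that the qualitative mechanisms (normal-only
training, threshold behavior, lesion-size effects) operate as described —
not that clinical-grade detection accuracy would be reached on real scans.

## Threshold selection

Given validation anomaly maps from normal images, the ReLU-max rule
computes the pixel-wise average map, rectifies each map's excess over the
average, and returns the maximum rectified excess over all maps and
pixels (`find_threshold()`). The rule is conservative: any flagged test
pixel deviates more than any normal validation pixel ever did. Because it
tends to come out large (roughly 0.5–0.75 on the phantom benchmark,
large enough that many lesion pixels pass as normal), fixed thresholds
$\{0.1, 0.2, 0.3\}$ are swept alongside it.
Binarization uses a strict comparison (`map > threshold`), so the pixel
achieving the maximum is itself not flagged at its own value — the sweep
and the monotonicity tests rely on this edge convention. The phrase
"average of the anomaly maps" admits two readings; the pixel-wise mean
map is the default baseline and a grand-scalar-mean variant is available
via `find_threshold(average = "scalar")`.

## Evaluation protocol

Per image, predicted and true masks are cross-tabulated into pixel
confusion counts, from which
$\mathrm{Dice} = 2TP/(2TP+FN+FP)$, $\mathrm{TPR} = TP/(TP+FN)$ and
$\mathrm{FPR} = FP/(FP+TN)$ are computed. Reconstruction quality is
tracked by $\mathrm{RMSE} = \sqrt{\tfrac1n\sum_i(\hat{x}_i - x_i)^2}$ on
normal validation versus lesioned test images: a model that reconstructs
normal tissue well but lesioned images poorly is exactly the model whose
anomaly maps are informative.

Aggregation conventions (the source protocols rarely state them):

* **macro vs micro** — the headline numbers are macro averages (mean of
  per-image metrics over images where they are defined); pooled-count
  micro variants are reported alongside in every table.
* **degenerate denominators** — if truth and prediction are both empty
  the masks agree, so Dice is 1 and FPR 0; TPR is undefined (`NA`)
  whenever the truth is empty and such records are excluded from means.
  These cases cannot arise on the lesioned test split but can in custom
  configurations.
* **size stratification** — lesion areas are binned by quantiles
  (default 5 bins) so every bin stays populated at any scale; fixed-width
  bins would empty out under the uniform-area default.

Raising the threshold can only shrink predicted masks, so TP and FP are
non-increasing in the threshold, hence mean TPR and FPR are non-increasing
across a sweep — an exact, not statistical, property that the test suite
asserts. Dice is *not* monotone in general and is deliberately not
asserted to be.

## Architecture and numerical choices

The shared backbone is four stride-2 $3\times3$ convolution blocks
(BatchNorm, LeakyReLU slope 0.2) mirrored by transposed convolutions,
with a sigmoid output so every reconstructed pixel lies strictly in
$(0,1)$; the variants differ only in latent heads and loss, and the test
suite asserts their conv stacks have identical parameter counts. Default
channel widths are $8\!-\!16\!-\!32\!-\!64$ with a dense bottleneck of
dimension 32. These widths are deliberately modest: the package's
networks are trained by its own single-threaded conv kernels
(C++/Armadillo `im2col` + BLAS), and the defaults keep a full
three-model experiment in the minutes range on one CPU core while
preserving the architecture's structure. Wider stacks (e.g.
$32\!-\!64\!-\!128\!-\!256$, latent 128, the scale a GPU study would use)
are a constructor argument away (`channels`, `latent_dim`). A
`latent_dim = NULL` mode keeps the spatial conv features as the latent
representation (1×1-conv posterior heads for the VAE), supporting
experiments on whether dimension reduction matters.

Further choices a reimplementer would need to know:

* **Transposed convolutions** are implemented as the exact adjoint of the
  strided convolution (the same `im2col` kernels run backwards), so
  encoder and decoder are algebraically mirrored.
* **BatchNorm** uses biased batch variance, momentum 0.1 running
  statistics, $\epsilon = 10^{-5}$; inference always uses running
  statistics.
* **VAE stability** — the log-variance head is clamped to $[-10, 10]$
  with vanishing gradients outside; inference uses the posterior mean
  (no sampling) so anomaly maps are deterministic, with an opt-in
  sampling mode.
* **Loss scaling** — reconstruction terms are optimized as per-image
  sums (L1) or per-pixel means (MSE) exactly as written above; histories
  log per-image means so curves are comparable across batch sizes. The
  VAE's reconstruction term follows the L1 prose convention of its
  source; a Bernoulli cross-entropy alternative appears in some
  derivations but L1 is the default here.
* **SWD estimator** — equal-size sample sets only (a training batch is
  matched against an equal-size prior draw, where sorting is exact);
  default 50 projections per evaluation, drawn fresh each step from the
  seeded stream. $\lambda$ defaults to 10 and $\beta$ to 1; the source
  protocols state neither, and both are exposed.
* **Cosine schedule** — per-epoch, single cycle, no restarts:
  $\eta(t) = \eta_{\min} + (\eta_{\max}-\eta_{\min})(1+\cos(\pi t/T))/2$
  with $\eta(0) = 2\times10^{-4}$. A per-step or warm-restart schedule is
  a plausible alternative reading; the simplest one is implemented and
  logged so conformance is checkable exactly.
* **Last batch** is kept rather than dropped (desk-scale datasets are
  small); the SWAE prior draw matches the realized batch size.
* **Gaussian denoising** is a separable kernel truncated at radius
  $\lceil 3\sigma \rceil$ with mirror padding — reflective boundaries
  avoid the dark frame that zero padding would inject into border pixels
  of anomaly maps.
* **Determinism** — one global seed drives everything through
  `derive_seed(seed, tag)` (a 31-bit multiplicative hash), so stages are
  independently reproducible; two runs with equal seeds produce
  bit-identical reports.

## Desk-scale benchmark sizes

The package's own evaluation (test suite and `scripts/acceptance.R`) runs
the pipeline at 200/40/40 images of $64\times64$, 20 training epochs —
sizes chosen so the full benchmark trains all models in minutes on one
core while leaving the protocol's structure (batch 16, cosine annealing
from $2\times10^{-4}$, gamma augmentation) intact. At these sizes the
benchmark reproduces the qualitative orderings reported for the clinical
setting: the SWAE reconstructs *worse* overall than the AE (higher RMSE
on both splits), and precisely because its regularized latent cannot
absorb anomalous structure, its anomaly maps separate lesion from
background more strongly — higher mean map values inside the ROI than
outside, and higher TPR than the AE at the 0.2 threshold. The smoke
configuration in the examples (tens of images, 2–3 epochs) only
exercises plumbing; its metric values are not meaningful.

## Known limitations

* The phantom's realism bounds what the benchmark can show (see above);
  no claim transfers quantitatively to clinical data.
* Pixel-level evaluation only; no image-level anomaly score or ROC
  analysis is provided.
* Single lesion per abnormal image; confluent or multiple masses are out
  of scope, which keeps size stratification unambiguous.
* Hand-rolled training runs on one core; the implementation favors
  determinism and transparency over speed, and very large
  configurations (224×224×3, 150 epochs, wide channels) are possible
  but slow.
* Reported FPR is sensitive to the speckle scale: heavier speckle raises
  background reconstruction error and with it the false-positive floor,
  as the threshold sweep makes visible.
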