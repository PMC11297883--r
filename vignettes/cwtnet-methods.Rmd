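---
title: "Methods: channel-wise CWT correlation networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: channel-wise CWT correlation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cwtnet)
```

## The problem

Distinguishing attention deficit hyperactivity disorder (ADHD), conduct
disorder (CD) and their comorbid combination from resting-state EEG is a
three-class classification problem on multi-channel time series, with two
practical constraints: the classes share clinical symptoms, so the
discriminating structure is subtle; and clinicians need to know *which
inter-channel relationships* drove a prediction, not just the label.
`cwtnet` implements a pipeline built around that second constraint: the
classifier's input is an image whose coordinates *are* channel pairs, so a
saliency map over the input is directly readable as a channel-pair
attribution.

## The representation

Each recording (12 channels, 500 Hz, 3 minutes under the default
configuration) is cut into non-overlapping 21.25 s epochs of
`floor(21.25 * 500) = 10625` samples; a trailing remainder shorter than one
epoch is discarded so every epoch has identical shape (a 3-minute recording
yields exactly 8). Each channel of an epoch is transformed by the
continuous wavelet transform

$$ W(a, b) = \int f(t)\, \frac{1}{\sqrt{a}}\,
   \psi\!\left(\frac{t-b}{a}\right) dt $$

with the 6th-derivative-of-Gaussian mother wavelet ("gaus6") over scales
$a = 1, \dots, 30$, giving a $30 \times 10625$ scalogram per channel. The
per-channel scalograms are stacked channel-major ($360 \times 10625$ for
12 channels) and every pair of scale-rows is correlated with Pearson's
$r$, producing a symmetric $360 \times 360$ correlation matrix with unit
diagonal. Row/column block $[30i, 30(i+1))$ belongs to channel $i$, so the
$(i, j)$ block of the matrix summarises the cross-scale correlation
structure between channels $i$ and $j$. That matrix is the classifier
input.

Numerical choices worth stating:

* **Discretisation.** The CWT integral is discretised at the sampling
  grid, $W[a, b] = \sum_j f[b+j]\, \psi(j/a)/\sqrt{a}$ with
  $|j| \le \lceil 5a \rceil$ (the Gaussian envelope is below $10^{-10}$
  beyond $|t| > 5$), evaluated by FFT cross-correlation. Samples beyond
  the epoch ends are zero, i.e. same-length output with zero-padded
  edges; edge columns therefore carry partial-support coefficients and
  enter the correlation like any other column.
* **Wavelet normalisation.** $\psi$ is normalised to unit $L^2$ norm; the
  $1/\sqrt{a}$ factor is the family normalisation. A consequence tested
  explicitly: the scalogram energy of a pure tone at frequency $f_0$
  peaks at $a^* = \sqrt{2p+1}/(2\pi f_0)$ for derivative order $p$, half
  a step above the usual centre-frequency rule
  $\sqrt{2p}/(2\pi f_0)$.
* **Scale grid.** Only the scale *count* (30) is fixed by the reference
  configuration; integer scales $1..n$ are the conventional grid for this
  wavelet family and are the default, exposed in `cwt_config()`.
* **Signed correlations.** Pearson $r$ is computed on signed
  coefficients (no magnitudes). Zero-variance rows (possible for an
  all-constant channel) get $r = 0$ off-diagonal and 1 on the diagonal
  rather than NaN.
* **Population vs sample normalisation** of the covariance cancels in
  $r$; the test oracles use the explicit covariance form.

No band-pass filtering, artifact rejection, re-referencing or resampling
is applied before the CWT; the transform consumes the raw segmented
signal.

## The classifier

The network is the compact CNN family
`[conv 3x3 (same) + ReLU + maxpool 2x2] x B -> global max pool ->
dropout -> dense + ReLU -> batchnorm -> softmax`, with the default
instantiation B = 5, filters 8/16/32/64/128, a 32-unit dense layer and 3
output classes. On a $360 \times 360 \times 1$ input the spatial trace is
$360 \to 180 \to 90 \to 45 \to 22 \to 11$ and the pooled feature vector
has length 128. Two details are forced by that trace: convolution padding
must be `same` (360 stays 360 through a 3x3 conv) and pooling floor-divides
odd sizes (45 -> 22). Activations are not dictated by the trace; ReLU
after every convolution and after the hidden dense layer is the
conventional choice and is what the engine implements.

Training is minibatch Adam (default learning rate $10^{-4}$, batch 15,
700 epochs at full scale) on sparse categorical cross-entropy with
per-sample class weights $w_c = N/(K N_c)$, so the minority class (CD in
the clinical setting) is not drowned out; balanced data give weights of
exactly 1 and $\sum_c N_c w_c = N$ always. The engine is implemented in
RcppArmadillo with exact analytic gradients (verified against central
finite differences in the test suite) and is fully deterministic given
the R RNG seed: weight initialisation (He-normal), shuffling and dropout
masks all draw from the seeded R stream.

Batch normalisation uses batch statistics during training and running
exponential-moving-average statistics (momentum 0.99) at evaluation.
Dropout (rate 0.2) applies to the pooled feature vector, before the dense
layers, with inverted scaling.

**Cross-validation protocol.** The data are split into k = 10 stratified
folds (each class dealt round-robin after a seeded shuffle, so per-fold
class proportions are within one sample of the global proportions). At
each iteration one fold is the test set, one of the remaining nine —
drawn at random under the run seed — is the validation set, and the rest
train the model. The best-validation-accuracy weights (ties broken by
lower validation loss) are checkpointed and evaluate the test fold.
Because epoch-level folding lets epochs of one subject appear on both
sides of a split, a subject-grouped mode deals whole subjects into folds
instead; the package defaults to epoch-level folds for the plain
protocol but all end-to-end validation in this package uses
`grouping = "subject"`, and the attribution experiment requires it. The
checkpoint criterion ("best-performing") and the validation-fold
selection rule are genuinely open choices; maximum validation accuracy
and a random stratified training fold are the package's picks, both
seeded.

Per-fold metrics are the confusion matrix, accuracy, and sensitivity /
specificity / precision computed one-vs-rest per class and macro-averaged
with equal class weights — the unweighted macro average keeps the
minority class visible, which is the point of class weighting; whether
the reference results used macro, micro or weighted averaging is not
determinable, so the choice is documented rather than asserted. Folds
aggregate as arithmetic mean and sample (n−1) standard deviation.
Argmax ties resolve to the lowest class index.

## Grad-CAM and channel-pair attribution

For a target class c, Grad-CAM weights each feature map $A^k$ of the
final convolutional layer by the spatial mean of
$\partial y^c / \partial A^k$ (the gradient of the pre-softmax logit),
sums, rectifies, bilinearly upsamples to the input size and min–max
normalises to [0, 1]. With a global-max-pooling head the gradient field
is sparse (it flows through pooling argmaxes), which is normal for this
architecture family; the per-channel mean gradients still order the
feature maps. An identically zero pre-ReLU map is returned as all zeros
with a warning rather than dividing by zero. The gradients are computed
by the same verified backward pass as training, and are additionally
checked against finite differences through an exported
partial-forward path in the test suite.

Because the input's block structure maps coordinates to channel pairs,
a heatmap aggregates naturally: pair (i, j) is scored by the mean (or,
optionally, max) heatmap intensity over block
$[i n, (i+1)n) \times [j n, (j+1)n)$, symmetrised with block (j, i).
All $C(C+1)/2$ unordered pairs including self-pairs are scored and
reported — within-channel scale structure frequently dominates the map,
and hiding it would misrepresent the saliency — but *recovery* of a
planted cross-channel coupling is judged on the ranking of cross-channel
pairs, which is how heatmaps of this kind are read in practice (circled
off-diagonal regions). Rankings use descending score with lexicographic
tie-breaks. A subject-level consensus ranks pairs by their mean
per-epoch rank.

## The synthetic generator

Real clinical EEG for this task is not redistributable, so validation
uses a generator that plants *detectable structure, not clinical truth*:
each class is defined by one channel pair sharing a band-limited latent
oscillation. With coupling $\rho$, the planted channels are
$\sqrt{1-\rho^2}\,\epsilon_i + \rho z$ for independent unit-variance
background noise $\epsilon_i$ and a shared unit-variance latent $z$, so
their expected correlation is $\rho^2$ and channel variance stays at 1;
all other channels are pure background. Defaults: 12-channel montage,
500 Hz, 180 s (8 epochs per recording), pink ($1/f$) background noise
matching the qualitative EEG spectrum, latent band 8–12 Hz (an
alpha-like rhythm), coupling 0.85 — a strong but not degenerate planted
effect. The latent is band-limited noise rather than a sinusoid so
scalograms have realistic spectral spread, and the coupling is injected
in the time domain *before* the CWT, so planted structure must survive
the full transform for the pipeline to recover it — that is what makes
end-to-end attribution recovery a meaningful test. One master seed
drives everything; per-recording substreams derive deterministically
from (seed, subject index), so datasets are reproducible and
order-independent.

What the generator does **not** emulate: volume-conduction mixing,
non-stationarity, artifacts (eye blinks, muscle), electrode noise
correlations, or any physiologically realistic ADHD/CD signature.
Passing the end-to-end tests demonstrates that the pipeline recovers
planted cross-channel structure through the full transform–classify–
attribute chain; it does not validate clinical discriminability.

## Scaled-down study conditions

The package's end-to-end validation runs a deliberately reduced study so
the whole chain executes in minutes on one CPU: 3 classes x 20
recordings of 12 channels at 250 Hz for 64 s (3 epochs each, 180
matrices), 20 CWT scales (240 x 240 matrices), a 2-block CNN
(6/12 filters, 16 dense units), learning rate $10^{-3}$, 40 training
epochs, batch 15, subject-grouped 10-fold cross-validation. The three
planted pairs are chosen with distinct diagonal offsets and border
distances (Fp1–Fp2 near the diagonal, F3–F8 interior, Fp1–T4 at the
matrix corner) so each class has a locally distinguishable signature
under a translation-invariant global-pooling head — with small receptive
fields, absolute position is encoded mainly through padding effects at
block boundaries, and pairs differing only in interior position would be
needlessly hard at this reduced depth. The full-scale defaults
(30 scales, 5 blocks, 700 epochs, learning rate $10^{-4}$) remain the
configuration for real-data-sized runs.

Two design points of this reduced study came out of pilot runs and are
worth recording. Depth trades classification robustness against
attribution sharpness: a 3-block network classified slightly better but
placed its Grad-CAM blobs at the coarser 60 x 60 resolution, where the
learned detectors' receptive-field offset (about one CAM pixel,
systematically past the planted block's far corner) pushed the interior
planted pair's saliency into neighbouring blocks; two blocks keep the
CAM at 120 x 120, where block attribution is reliable, at the cost of
occasional optimisation failures on particular folds. Those failures are
handled by an explicit guard in `cross_validate()`: a fold whose
checkpointed *validation* accuracy ends at or below 0.5 (near-chance,
i.e. a collapsed run) is refit with a fresh derived seed, at most twice,
keeping the best-validation model. The guard consults only validation
data — the test fold is never examined — and is deterministic given the
run seed.

## Interfaces and formats

EDF input is parsed by a minimal reader for the fixed-width-header,
int16-record format (with a matching writer used for round-trip tests);
CSV (one column per channel, header row, sampling rate from
configuration) is the metadata-free fallback. Intermediate artifacts —
epoch sets and correlation-matrix sets with labels, subjects and the
resolved configuration — are stored as single RDS archives. Reports are
JSON/CSV; heatmaps render to PNG with gridlines every `n_scales`
rows/columns and montage labels as the block-reading aid. The
`inst/cli/cwtnet.R` script exposes the pipeline as subcommands
(`simulate`, `preprocess`, `train`, `evaluate`, `explain`, `report`)
over a YAML configuration with command-line overrides
(precedence: overrides > file > defaults).

## Known limitations

* The engine implements the conv-pool/GMP/dense architecture family, not
  arbitrary layer graphs; the shape tracer (`shape_trace()`) is general.
* Heatmap normalisation is per-epoch min–max; consensus rankings are
  therefore scale-free across epochs, but absolute intensities are not
  comparable between epochs.
* With a global-max-pooling head, class evidence that differs *only* by
  interior absolute position (far from borders and the diagonal) is
  structurally hard for the classifier; this is a property of the
  architecture family, inherited by design.
* The exact scale values and CWT edge convention of the reference
  configuration are conventions of this implementation; results can
  shift slightly under other conventions.
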