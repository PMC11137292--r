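---
title: "Gershgorin circle features from visibility graphs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gershgorin circle features from visibility graphs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcfe)
```

## The model

`gcfe` summarises a fixed-length window of a biomedical recording by the
Gershgorin disks of a graph Laplacian built from its visibility
structure. The chain is deterministic:

normalized epoch → weighted visibility graph → modified weighted
Laplacian → disk radii and centers → 2N feature vector.

**Visibility.** Two samples are connected when the straight line between
their (index, value) points passes *strictly* above every intermediate
sample. The strictness matters: a collinear intermediate point blocks the
edge. This is the standard natural-visibility convention and is the
tie-break that reproduces the worked five-sample example shipped in the
tests. Edge weights are absolute slopes, `|q_i − q_j| / |i − j| + 1e-8`,
with **time in sample-index units**. Using seconds instead would scale
all radii by the sampling rate and break the correspondence between the
printed example radii and the unit-interval normalization; sample-index
units also make features comparable across recordings digitised at
different rates. The `1e-8` floor keeps flat segments (equal adjacent
samples) connected with a positive weight, so every graph on an N ≥ 2
epoch is connected.

**Reflection.** The dual-perspective graph (WDPVG) unions the visibility
graph of the epoch with that of its reflection. We reflect about the
amplitude midline, `q' = max(q) + min(q) − q`, because it is an
involution and keeps the reflected signal inside the original range;
plain negation is available (`reflection = "negate"`). Both are affine
maps, and visibility is invariant under positive affine transforms, so
the two choices produce identical graphs — the option exists for
transparency, not effect. Edges present in both orientations are kept
once: `|q_i − q_j|` is reflection-invariant, so both copies carry the
same weight, and double-counting would corrupt the adjacency into a
multigraph and spoil diagonal dominance.

**The modified weighted Laplacian.** `L = D − A` mixes the *weighted*
adjacency `A` with the *unweighted* degree diagonal `D`. This is
deliberately not the standard weighted Laplacian (the test suite asserts
the difference on a generic epoch): for epochs normalized to [0, 1],
every weight is at most `1 + 1e-8`, so each integer degree on the
diagonal dominates its row's absolute off-diagonal sum up to the epsilon
inflation. Dominance can be exactly marginal when an epoch contains both
the recording minimum and maximum in adjacent samples, which is why the
package (and its tests) state the property as
`L_ii + N·1e-8 ≥ Σ_{j≠i} |L_ij|` rather than strictly.

**Gershgorin features.** Radii are absolute off-diagonal row sums, centers
are the diagonal (the integer node degrees). Every eigenvalue of the
symmetric `L` lies in the union of disks — the property suite verifies
this against a dense eigensolver on hundreds of random epochs for both
graph kinds. The feature vector is `[r_1..r_N, c_1..c_N]`: the block
order (radii first) is fixed, the intra-block order is natural node
order, and features are emitted at full floating precision; 3-decimal
values in displays are rounding only.

## Normalization and epoching

Normalization is min–max against the *full recording* extrema, so
between-epoch amplitude relationships survive — they are exactly what
the radii and centers discriminate on. Per-epoch renormalization is
available (`per_epoch_normalize = TRUE`) for users who only have
isolated windows, but it is off by default and not used anywhere in the
package's own studies. A constant recording normalizes to all zeros
(rather than erroring), which downstream produces a visibility chain
with epsilon weights — a defined, testable degenerate case. Trailing
samples that do not fill an epoch are discarded, never padded: padded
samples would fabricate visibility edges.

## The spike simulator

The simulator emulates a synthetic extracellular recording: three
action-potential classes plus a noise class, 20 kHz sampling, mean
firing rate 3.3 Hz per unit, 200 s recordings, 56-sample epochs.

The template is `V(t) = A·cos(2π(t − τ_ph)/τ₁)·exp(−(2.3548·t/τ₂)²)` — a
cosine under a Gaussian envelope whose FWHM is τ₂ (2.3548 = 2√(2 ln 2)).
Default parameters (τ₁ = 1.2/1.6/2.0 ms, τ₂ = 0.6/0.9/1.2 ms, amplitude
ratios 1 : 1.1 : 1.5) give three visually distinct biphasic spikes with
class 3 the largest. They are package defaults chosen for qualitative
structure — distinct widths, a dominant class — and are not claimed to
match any particular published electrode dataset.

Design choices that merit explanation:

* **One recording, one normalization.** All three units fire into a
  single recording which is normalized once. Simulating each class in
  its own recording and normalizing separately would rescale each
  class's noise-plus-spike range to [0, 1] independently, erasing the
  between-class amplitude differences that make class 3 separable — we
  verified this variant destroys both the amplitude ordering of the
  radii and classification accuracy.
* **Noise parameterization.** The `snr` argument of
  `simulate_dataset1()` is a noise *level*: noise sd = `snr` ×
  RMS(clean recording), with no free constant. Larger values are
  noisier, so the conventional 0.5 / 1.25 / 2.0 series is monotonically
  harder — matching how difficulty orders in the synthetic spike
  corpora this emulates. The general-purpose `add_noise_at_snr()`
  utility also offers the two conventional ratio definitions
  (peak/sd and rms/sd) for users who think in true SNR terms.
* **Spike-centered epochs.** A 56-sample epoch at 20 kHz spans 2.8 ms —
  exactly one spike — so windows are centered on spike times (classes
  1–3) or drawn from stretches at least two epochs away from any spike
  (class 4). Free-running segmentation at this epoch length would mix
  partial spikes into both classes. Firing is homogeneous Poisson with
  a one-epoch refractory veto so spike windows never overlap.

What the simulator does *not* model: electrode drift, overlapping
spikes, bursting statistics, correlated (non-Gaussian) background
activity, or the epoch-count bookkeeping of any specific released
dataset. Passing tests on simulated data therefore demonstrate that the
pipeline recovers class structure from amplitude/shape differences under
additive Gaussian noise — not that any particular accuracy transfers to
a real electrode or EEG recording.

The EEG surrogate is similar in spirit: five condition-like classes
generated as AR(1)/AR(2) processes differing in amplitude scale,
autocorrelation, and stationarity (class 4 adds sharp interictal-like
transients; class 5 is ictal-like, with high-amplitude waxing 4 Hz
bursts), 4096 samples per channel at 173.61 Hz, segmented 4 : 1 into
1024-sample epochs. It is a statistical stand-in for pipeline testing,
not a physiological model.

## The classifier harness

The reference classifier is a 1-D CNN: `n` blocks of conv(32 filters,
kernel 3, same padding, ReLU) + max-pool(2, stride 2), then flatten →
dense(100, ReLU) → dropout(0.1) → dense(100, ReLU) → softmax, trained
with Adam (learning rate 1e-3) on integer-class cross-entropy, batch
size 32, 30 epochs. Two blocks are used for 112-feature inputs and six
for 2048-feature inputs (2048/2⁶ = 32 before flattening). Pool size 2 is
the conventional default for an unsized max-pool layer. The network is
implemented in base R matrix operations (im2col-style convolutions as
three shifted matrix products); a finite-difference gradient check in
the test suite pins the backpropagation. Training is deterministic given
the seed: initialization, shuffling, and dropout all draw from the
seeded RNG stream.

Features are standardized (train-split mean/sd) before training — radii
live near zero while centers are integer degrees up to N, and a common
scale stabilises both the CNN and the SVM. Multi-class sensitivity and
specificity are macro-averaged one-vs-rest from the confusion matrix;
the "30 iterations" of the training recipe are read as 30 passes over
the training data. The harness is pluggable: `arch = "svm"` substitutes
a radial-basis SVM (`e1071`) behind the same split/standardize/report
machinery, and serves as an independent cross-check on the CNN in the
package's own experiments.

Splits are stratified 70/15/15 train/validation/test by default; the
validation split is monitored (per-epoch loss/accuracy in the history)
but not used for early stopping — training runs the configured number
of epochs, flat.

## Numerical choices and degenerate inputs

* Strict visibility inequality; collinear points block (tie-break).
* Equal-valued pairs get weight exactly `1e-8`.
* Diagonal dominance asserted with the `N·1e-8` epsilon allowance.
* Constant epochs: defined chain graph, degree centers `[1, 2, …, 2, 1]`,
  epsilon radii.
* Non-finite samples are rejected with the offending index named;
  sampling rates are never inferred from files.
* Matrices serialise at 17 significant digits and round-trip bit-exactly.

## Problem sizes in the shipped studies

The package's own test studies use sizes chosen to exercise the claims
at desk scale: the eigenvalue-inclusion suite covers 200 random
epoch/graph-kind combinations at N ∈ {8..64}; the graph-builder
equivalence suite checks 250 random epochs at N ≤ 32 against an O(N³)
direct enumeration (plus the same check inside several property tests);
the classification study uses 400 epochs per class at noise level 2.0
with a shuffled-label chance control; the amplitude-ordering study uses
200 epochs per class. These sizes make the stochastic checks stable
under their fixed seeds while keeping a full run in the low minutes.

## Known limitations

* Gershgorin disks only *bound* the spectrum; epochs with very different
  eigenvalues can in principle share disks. The features are a lossy,
  cheap spectral summary — that is the point, but it is a trade.
* Features scale as 2N with epoch length; radii depend on the
  normalization reference, so recordings must be normalized consistently
  before comparison.
* The graph builder is O(N²) per epoch (dense matrices); epochs beyond a
  few thousand samples would warrant a sparse path, which this package
  does not provide.
* Refined inclusion regions (Brauer ovals, etc.) are out of scope.
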