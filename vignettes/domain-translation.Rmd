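---
title: "Modelling intra-muscular contraction dynamics with in-silico to in-vivo domain translation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling intra-muscular contraction dynamics with in-silico to in-vivo domain translation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ultrafast ultrasound can image the mechanical twitches of individual motor
units (MUs) inside a contracting muscle as tissue-velocity image (TVI)
sequences: 3D grids of axial velocity over a cross-sectional plane, here
128×128 pixels covering 40×40 mm² at 512 frames/s for 2 s. Simulation models
of these contractions capture the twitch dynamics of active MUs but none of
the surrounding anatomy — connective tissue, fat, vasculature, the quiet
subcutaneous layer — so simulated sequences look conspicuously clean compared
with in vivo recordings. `tvigan` implements the full in-silico-to-in-vivo
translation system around that gap:

* a **simulator** of TVI sequences as superpositions of MU twitch trains
  (domain A),
* the **preprocessing chain** applied to experimental recordings
  (domain B),
* a **surrogate generator** that emulates the in vivo statistics when no
  recordings are available,
* a modified **3D cycleGAN** that learns the unpaired mapping between the
  two domains,
* an **evaluation battery** of spatio-temporal features, and **similarity
  maps** that visualize what the generator adds.

## The simulator (domain A)

Each sequence draws a population of 4–10 active MUs (uniform), with circular
territories of 2.5–10 mm diameter (uniform) placed uniformly over the
cross-section, and firing rates of 8–13 Hz (uniform). Inter-pulse intervals
follow N(1/FR, (0.2/FR)²), truncated at a 10 ms floor because the normal
model has tail mass below zero; 10% of each unit's firings (Bernoulli
selection) are re-aligned to the nearest firing of one uniformly drawn
partner unit with 2 ms Gaussian jitter and flagged synchronized. These
parameter values are the study conditions; the package treats them as
defaults of `sim_config()` and the acceptance script recomputes the CV and
synchronization statistics from fresh draws.

Two quantities were genuinely open:

* **Twitch waveform.** Only "superposition of mechanical twitches" is
  specified. We use the displacement transient d(t) = A·(t/T)²·exp(2(1−t/T))
  with contraction time T = 25 ms and differentiate it to velocity. Compared
  with the classic A·(t/T)·exp(1−t/T) twitch this variant has a smooth
  (zero) velocity onset and its velocity integrates to exactly zero —
  displacement returns to baseline, as it must in an isometric steady state.
  The choice of twitch family is not critical for the downstream behaviour
  (a point-source variant with Dirac firing trains is provided as
  `simplified_render()` for exactly this robustness check).
* **Territory profile.** A raised-cosine taper (1 at the center, 0 at the
  territory edge) avoids the ringing spatial spectra of hard discs; a
  uniform profile is available via `territory_profile = "uniform"`.

`render_sequence()` is exactly linear in the firing pattern, pixels outside
all territories are exactly zero, and a fixed seed reproduces sequences
bit-for-bit.

## Preprocessing (domain B conditioning)

Raw TVI sequences pass, in order: a 4th-order Butterworth bandpass at
5–50 Hz (MATLAB order convention, 8 poles) applied zero-phase
(forward–backward) so per-pixel signals stay lag-free for the content-lag
metric; a per-frame 2D median filter with a 1×1 mm kernel, converted to the
nearest odd pixel count with a floor of 3 (3×3 at the default 0.3125 mm
pitch); and bicubic-spline downsampling to 128×128×1024 at 512 Hz, with a
zero-phase windowed-sinc anti-alias filter ahead of temporal decimation.
Standardization to zero mean and unit variance happens per sequence (it is
applied independently at inference, so a per-dataset variant would leak
statistics across sequences). The forward–backward pass doubles the
effective filter order; the −3 dB points of the designed single-pass filter
sit at 5 and 50 Hz by construction, which the tests verify from the
transfer function.

## The surrogate (stand-in for in vivo data)

The in vivo recordings behind the original study are not public. The
surrogate module generates raw sequences that reproduce exactly the
descriptive statistics the evaluation battery measures: twitch-train sources
at 8–20 Hz (the physiological discharge band), an amplitude texture field
with 1–2 mm granularity built by thresholding a band-limited Gaussian random
field, a quiet superficial layer (attenuated top 5 mm), and spatially
correlated background noise. It makes **no claim of physiological
fidelity** — its only purpose is to let every downstream stage be trained
and tested end-to-end. Anyone with real TVI data bypasses it entirely
through `preprocess_experimental()`. Consequently, everything the tests show
about translation *to this domain* is a property of the pipeline, not
evidence about real tissue.

## The translator

The translator is a cycleGAN extended to 3D: generators G_B (A→B) and G_A
(B→A) with PatchGAN discriminators D_B, D_A. All convolution, padding and
instance-normalization layers are 3D. The generators use a ResNet-6 layout:
7×7×7 entry convolution, two downsampling convolutions (spatial stride 2),
six residual blocks, a mirrored decoder, and a single-channel output.
Four deliberate modifications:

1. **Stochastic noise injection** (G_B only): per-location Gaussian noise
   with a learned per-channel scale (initialized at zero) is added after
   each convolution inside the residual blocks, with the same noise value
   broadcast across the temporal axis so the fabricated spatial texture
   stays coherent over frames. A deterministic generator would have to
   *compute* pseudo-random texture from its input; injected noise supplies
   it for free and leaves content intact.
2. **Temporal stride 1** in the downsampling layers of both generators and
   discriminators (configurable to 2), preserving the temporal receptive
   field over the twitch time-scale.
3. **Precision contract**: `precision_mode = "mixed"` rounds convolution
   activations to float32 while normalization statistics stay in double;
   only forward-pass closeness to the double-precision path is asserted, not
   training equivalence.
4. **Identity regularization**: L1 identity terms keep the generators from
   inverting contraction phases that the cycle loss cannot see. The
   domain-B identity term is L1 by default with an L2 option
   (`idt_b_norm = "l2"`).

The adversarial objective is least-squares (LSGAN); cycle losses are L1 with
λ_A = λ_B = 10 and the identity weight 0.5·λ. Training uses Adam
(β₁ = 0.5) at a constant 2e-4 for 80 epochs, batch 2, sequences split into
non-overlapping 32-frame crops with vertical-flip augmentation, and a
50-element image buffer for discriminator updates.

Design choices where the reference recipe was not directly transplantable:

* **Decoder upsampling** uses nearest-neighbour interpolation followed by a
  3×3×3 convolution rather than transposed convolution, avoiding
  checkerboard artifacts that are particularly visible in variance maps.
* **Linear output layer** (no tanh): the data are standardized to N(0, 1)
  and unbounded, so a saturating output cannot represent the target domain.
* **Engine**: the network layers, backpropagation and Adam are implemented
  in the package itself (C++ gather/scatter kernels feeding BLAS matrix
  products, direct convolution for the wide 7×7×7 kernels), which keeps
  training bit-reproducible under a fixed seed in single precision.
* **Inference** runs the whole sequence in one fully convolutional pass;
  convolutions gather their inputs in bounded-memory chunks, so sequence
  length is limited only by one feature map's footprint. Overlap-tiled
  inference is available for hard memory caps, but because instance
  normalization uses per-pass statistics, tiles are normalized slightly
  differently: tiling is an approximation that tightens with tile length,
  and the exact single pass is the default.
* Training is implemented for the LSGAN objective; the logistic (log-loss)
  form of the adversarial objective is available in `adversarial_loss()`
  for evaluation.

## Evaluation battery

Comparisons between sequence *sets* follow a cross-comparison protocol: all
|X|·|Y| ordered pairs contribute, and each metric is reported as mean ± sd.

* **Spatial features** operate on log-transformed per-pixel temporal
  variance maps (ε = 1e-12 floor): histogram correlation and the
  Hellinger-form Bhattacharyya distance √(1 − Σ√(pᵢqᵢ)) on 64 shared bins
  over the pooled range, and SSIM between the log-compressed magnitudes of
  the strictly-positive-frequency K-space quadrants (DC and Nyquist
  excluded, 11×11 Gaussian window, standard constants).
* **Temporal features**: Pearson correlation of the log average Welch Psds
  (256-sample Hann segments, 50% overlap), averaged over all pixels.
* **Content consistency** (paired input/translation only): per-pixel
  normalized cross-correlation, reporting the maximum and its lag in ms.
  Pixels below 1% of the median temporal variance are excluded, and the lag
  search is bounded to ±250 ms — an unbounded search inflates lag spread
  under the null.

Each metric has an independent brute-force oracle in the test suite
(explicit pair loops, direct per-lag correlation, literal windowed-statistics
SSIM).

## Similarity maps

`similarity_map()` aggregates frame-wise |input − output| over a sequence
(mean by default; the sum differs by the constant frame count), and
`depth_profile()` reduces it to a per-depth-row mean against physical depth.
On a translator trained against the surrogate domain, the profile dips in
the attenuated superficial band — the generator learns to silence
superficial tissue — which is the package's testable analogue of the
subcutaneous-layer observation that motivates these maps.

## Problem sizes used by the tests

The full study-scale configuration (128×128×1024 sequences, 128+64 simulated
and 64 experimental examples, width-32 generators, 80 epochs) is the
package default. The test suite and acceptance script exercise the identical
code paths at reduced scale, chosen so the whole suite runs on a single CPU:
simulator calibration uses hundreds of populations and >10⁴ intervals;
metric oracles use ≤16×16×64 grids; the training smoke test uses two toy
32×32×64 domains (domain B = domain A times a fixed 1.5 mm texture field
plus 12 Hz oscillatory sources), width-4 ResNet-2 generators, 200 iterations
at batch 2 and lr 2e-4; and the domain-ordering check uses 64×64×256
sequences at the default pixel pitch. Scaling the architecture width and
iteration count back up changes cost, not code.

One subtlety in the smoke test is worth making explicit: a fully
convolutional generator is translation-equivariant, so it can learn to
fabricate granular texture (that is what the injected noise is for) but it
cannot reproduce a texture field pinned to absolute image coordinates. The
learned mapping is therefore judged by correlating the similarity map of a
held-out translated sequence against that sequence's ground-truth
modification map — the texture magnitude as experienced by that input —
rather than against the absolute texture field itself.

## Numerical notes and degenerate inputs

* Constant sequences cannot be standardized (an error, not silent zeros);
  single-frame sequences have no variance map; empty histograms and
  single-bin histograms are errors; a perfectly flat histogram yields an NA
  histogram correlation (Pearson is undefined there) while the
  Bhattacharyya distance is still reported.
* Negative inter-pulse draws are truncated at 10 ms; firing times are
  clipped to the sequence window and re-sorted to strict monotonicity after
  synchronization re-alignment.
* The simplified point-source renderer interprets the white-noise level
  N(0, 0.1) as a *variance* (sd = √0.1), and exposes the sd as a parameter.
  Its smoothing uses circular FFT convolution, so a normalized kernel
  conserves impulse mass exactly.
* All randomness flows through explicit seeds; a run seed deterministically
  derives per-sequence and per-stage seeds, and identical seeds give
  bit-identical sequences, training histories and pipeline outputs in
  single precision.

## Known limitations

* The surrogate domain is a statistical stand-in; conclusions about real in
  vivo translation quality require real recordings through
  `preprocess_experimental()`.
* Training at the full study scale (two GPUs, ~24 h in the original
  setting) is out of reach of a single-CPU R process; the package trains
  the same model class at reduced width and scale.
* Tiled inference approximates the exact pass in the presence of instance
  normalization (see above).
* The logistic adversarial objective is evaluation-only; training uses
  LSGAN.
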