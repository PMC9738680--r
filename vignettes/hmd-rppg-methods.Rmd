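---
title: "Remote heart-rate estimation from HMD facial regions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Remote heart-rate estimation from HMD facial regions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A virtual-reality head-mounted display (HMD) occludes most of the face, but
devices increasingly carry small cameras aimed at the eye regions and the
lower face. Remote photoplethysmography (rPPG) estimates the blood-volume
pulse — and from it the heart rate in beats per minute (BPM) — from the
minute skin-colour oscillations that cardiac activity produces in video.
`hmdrppg` implements a complete rPPG pipeline restricted to the three facial
regions an HMD can see (left eye, right eye, lower face), together with a
synthetic-scene generator that stands in for real HMD footage, so that every
stage is testable end to end on one CPU with no external data.

## Synthetic scenes: what they emulate, and what they do not

`generate_clip()` renders an ellipsoidal skin region whose mean colour is
modulated by a pulse waveform

\[ w(\theta) = \sin\theta + 0.3\,\sin 2\theta, \qquad \theta = 2\pi \frac{\mathrm{HR}}{60} t + \phi_0, \]

with the green channel weighted most strongly, mimicking the channel
asymmetry of haemoglobin absorption. The second harmonic makes each beat a
single well-defined peak, so peak-based BPM conversion behaves as it does on
real PPG. The face performs a seeded Gaussian random walk (translation
only), ground-truth landmarks ride rigidly on it, and per-pixel Gaussian
noise is added. Defaults: 640×480 at 30 FPS, heart rate 72 BPM, pulse
amplitude 0.02 colour units (≈2% of full scale — stronger than real rPPG
signals, which keeps desk-scale parameter-recovery experiments feasible),
noise SD 0.005, jitter step 0.5 px/frame.

What the generator does **not** model: skin-tone diversity, specular
lighting, rotation/expression deformation, sensor rolling shutter, and
occlusion. A green recovery test therefore establishes that the pipeline's
plumbing, filters and estimators are correct — not that the estimators
would reach the same accuracy on real faces.

The returned PPG trace is the exact noise-free modulation applied to the
skin (so `pulse_amplitude = 0` yields a constant trace), sampled at the
frame rate.

## ROI extraction with threshold stabilization

Landmark detections jitter even on a still face. Each ROI keeps a square
track whose centre is the arithmetic mean of its landmark group; a new
detection moves the track only when the Euclidean displacement exceeds a
threshold of **5% of the ROI side** (a displacement exactly equal to the
threshold keeps the old centre — the strict reading is deterministic).
Above threshold, `update_mode = "smooth"` moves to the midpoint of old and
new centres and `"replace"` adopts the new centre. Because the threshold
scales with the ROI side, and ROI sides scale with apparent face size, the
stabilizer is invariant to camera distance.

Crop sides are not printed constants, so they are derived from the scene:
eyes use 2.2× the landmark bounding-box diagonal and the lower face spans
from the mouth centre up to just below the eye line (90% of that distance,
doubled). Crops touching the frame border are clamped with edge
replication. Outputs are resized to 100×100 (eyes) and 400×400 (lower
face). A radial "approximation" distortion (default strength 0.3, radius =
mouth-to-nose distance) magnifies the mouth area so the face appears closer
to the camera; strength 0 is the exact identity.

On a landmark-detection failure the previous coordinates are reused; after
`max_consecutive_failures` (default 2) consecutive failures the run aborts
with a diagnostic naming the frame. RGB frames export as PNG, grayscale as
PGM, with the source-frame index in the file name.

## Causal Eulerian magnification

The optional motion-magnification stage decomposes each frame into a
Gaussian pyramid, filters every level with a causal recursive band-pass —
the difference of two one-pole low-pass filters with cutoffs at the band
edges, so no future frame is ever used — and adds α times the filtered
component back before collapsing. Defaults α = 10, band 0.5–4 Hz, 4 levels;
the stage is **off by default** because magnification amplifies
non-cardiac motion as readily as cardiac motion and measurably hurt
accuracy in the upstream experiments. With α = 0 the stream passes through
bit-identically, and truncating the input reproduces a prefix of the output
exactly (causality).

## Feature images and the depthwise-separable regression network

One second of an ROI stream becomes a 25×25×3 **feature image**:

1. each frame is reduced to the lowest band of its Gaussian pyramid
   (blur-and-halve until ≤ 8 px, then resize to 5×5 per channel),
2. the 25 values are flattened row-major into one column per frame,
3. the time axis is linearly resampled to 25 columns (one second at 30 FPS
   gives 30 frames; the fixed 25-column geometry wins), and
4. every pixel row is FFT-masked to 0.75–4 Hz (45–240 BPM), DC included in
   the stop band, edge bins inclusive; the mask is idempotent.

A constant video therefore maps to an identically zero feature image.

The regression network is a MobileNet-style stack (full 5×5 convolution to
96 channels, then alternating depthwise 3×3 / pointwise 1×1 stages at
96→96→96→128→128 with batch norm + ReLU after every convolution, 2×2
average pooling, FC 128→192, dropout 0.6, FC 192→1) trained with a
Euclidean (L2) loss on labels normalized so 45 BPM → 0 and 240 BPM → 1, and
the Adam optimizer. The first fully connected layer gets a ReLU (two
stacked linear layers would collapse to one). The PPG-target variant widens
the head to 25 outputs — one per time column — so each window predicts a
waveform segment that is later converted to BPM by peak detection.

## The meta-learning estimator

The three crops are composed into one 64×64 face-like frame (right-eye crop
on the image-left, eyes side by side on top, lower face below). Sequences
of 60 frames feed a five-block convolutional encoder (3×3 convolutions,
batch norm, 2×2 average pooling, ReLU; widths 32–48–64–80–120) with
1×1-projected additive shortcuts between blocks, giving one 120-vector per
frame. A bidirectional LSTM (hidden size 60 per direction), a linear layer
to 80 and an ordinal layer to 40 cumulative thresholds complete the
estimator. The ordinal loss is mean per-threshold binary cross-entropy —
the standard construction for a cumulative 40-threshold output; decoding
counts thresholds with probability above 0.5 and divides by 40, so the
encode/decode round trip is accurate to 1/40.

A synthetic-gradient generator — four 1-D convolutional blocks over time
(60→40→20→40→60 at 120 channels, an encoder–decoder over the temporal
axis; the last block omits the ReLU so gradient estimates keep their sign)
— is trained to mimic the true gradient of the ordinal loss with respect to
the encoder features (mean squared matching loss, with the target scaled by
10³ for conditioning; the scale is divided out when the gradient is used).
This enables transductive adaptation: at test time the encoder can take `k`
small steps (default 3, step size 10⁻⁴) along generated gradients computed
on the *unlabeled* test sequences before prediction.

Data routing follows the published protocol: an 88%/12% train/test split;
22% of the training portion goes to episodic pre-training, divided 55%/45%
into query and support sets. Videos contribute ⌊frames/60⌋ sequences
(dynamic lengths — nothing but the tail remainder is discarded). Per
sequence, ground-truth PPG is min–max normalized to [0, 1] before ordinal
encoding (the waveform's shape, not its scale, carries the rate).

## PPG → BPM conversion

Re-specified explicitly rather than delegated to an external analysis
library: per analysis window (default 8 s, stride 1 s) the trace is
band-passed to 0.75–4 Hz, beats are local maxima above an adaptive
threshold (rolling mean + 0.5 × rolling SD over 2 s) separated by at least
60/240 s, and the window BPM is 60 / median inter-beat interval. The median
makes one missed or spurious peak inconsequential; windows with fewer than
3 peaks or a BPM outside [30, 250] are marked invalid. The conversion is
invariant to positive rescaling of the trace.

Frame-rate rescaling to the models' 30 FPS uses nearest-frame selection
(no blending): output frame *i* is input frame ⌊*i*·src/dst⌋.

## Evaluation metrics

With error \(E_i = P_i - GT_i\): ME = mean error; SD = population standard
deviation of the error (1/n form, exactly as printed — this gives the
identity RMSE² = ME² + SD², which the tests assert to 10⁻⁹); RMSE;
MAPE = 100·mean(|E|/GT) (reported in percent); ρ = Pearson correlation.
MAE is available but not part of the core report.

## Numerical choices

* **Neural-network core.** No deep-learning framework is assumed:
  convolutions (im2col + BLAS), batch norm, pooling, LSTM/BPTT and Adam are
  implemented in the package, with the hot kernels in C++
  (RcppArmadillo). Every backward pass is validated against
  finite-difference oracles in the test suite; this is the correctness
  anchor for all training results.
* **Coordinates** are 0-based pixels, x right / y down; crops use half-open
  ranges; resizing uses half-pixel-centre bilinear interpolation, so
  identity resizes are exact and constant images stay constant.
* **Determinism.** One run seed fans out to per-module seeds through a
  fixed hash (`derive_seed`), so clips, initializations, shuffles and
  dropout masks are all reproducible; identical seeds give bit-identical
  pipelines.
* **Ties and edges.** Stabilizer ties keep the previous centre; FFT band
  edges are inclusive; Gaussian pyramid halving uses ceiling sizes
  (25 → 13 → 7); stride-2 convolution output sizes use floor, padding 1,
  matching the printed layer geometry.

## Scaled-down testing and limitations

The acceptance suite trains both estimators on synthetic data sized to fit
a 25-minute single-CPU budget: the feature-image CNN sees 24 clips cut into
360 overlapping one-second windows (overlap supplies phase diversity) and
the meta estimator sees 12 sequences (scaled down from the nominal ≈40)
for two epochs plus one episodic pre-training pass. The MAE ≤ 5 BPM
recovery criterion is unchanged and is asserted on the median over training
seeds {0, 1, 2} — individual seeds at this training scale can land on a
harmonic of the true rate, which the median absorbs. Training curves at this scale are short, so the meta model's
pre-training phase is one episodic pass. The published headline results on
UBFC-rPPG and MR-NIRP require those external datasets and GPU-scale
training and are explicitly out of scope; nothing in this package claims to
reproduce them. The landmark detectors themselves (dense mesh, 68-point
SVM) are not re-implemented — the tested path uses the generator's
ground-truth landmarks, and real detectors can be plugged in as adapters.
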