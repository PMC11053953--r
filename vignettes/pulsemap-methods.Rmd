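---
title: "Pulsatile feature maps from facial video: models and methods"
author: "pulsemap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulsatile feature maps from facial video: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Camera-based photoplethysmography (rPPG) measures the blood volume pulse
(BVP) without contact: each heartbeat changes the arterial blood volume in
facial skin, which modulates the light the skin reflects by a fraction of
a gray level.  `pulsemap` implements a complete pipeline from short
(about 4 s, 30 fps) facial video clips to *pulsatile feature maps* — the
per-pixel amplitude of that modulation, sampled at heartbeat peaks and
troughs — plus a subject-grouped cross-validation harness that tests
whether the spatial pattern of those maps carries information (for
example, about the emotional state of the subject).

## Optical model

Reflected light at wavelength $\lambda$ is modelled as incident light
times the sum of a diffuse Beer–Lambert term and a specular term:

$$ I_\lambda = I_{0,\lambda}\left(e^{-(A_{DC,\lambda} +
   A_{pulse,\lambda}\, s(t))} + R_{S,\lambda}\right), $$

where $A_{DC}$ is the static absorbance of tissue and average blood
volume, $A_{pulse}$ the pulsatile absorbance amplitude (per pixel),
$s(t)$ a unit periodic waveform at the heart-rate frequency $f_0$, and
$R_S$ the specular fraction, which carries no pulse.  Two feature maps
follow from frames $I_{max}$ (taken at signal peaks, minimal absorbance)
and $I_{min}$ (taken at troughs):

$$ I_{AC} = I_{max} - I_{min}, \qquad
   I_R = \ln\!\frac{I_{max}}{I_{min}}. $$

$I_{AC}$ is the pulsatile amplitude in gray levels; $I_R$ cancels the
static factors ($I_0$ and the DC reflectance divide out) and, for
$R_S = 0$, equals the peak-to-trough absorbance swing
$2\,A_{pulse}$ — the property the test suite checks to 10%.

The synthetic generator (`generate_synthetic_clip()`) implements exactly
this model on an elliptical skin region, with a dark hair crescent, an
optional bright chin-stand rectangle (gray level 230), Gaussian camera
noise, and 8-bit quantization applied after the noise.  The pulse
waveform is a pure sinusoid by default; a `"ppg"` option provides an
asymmetric wave with a fast systolic rise and dicrotic shoulder, since
the waveform shape is not part of the model being tested.

## Pipeline stages and their parameters

1. **Facial ROI** (`detect_face_roi_reflective()`,
   `detect_face_roi_thermal()`).  Reflective clips use a pluggable
   per-frame detector whose boxes are averaged over every 10th frame;
   thermal clips average 3 uniformly sampled frames, blur with a 5×5
   kernel and Otsu-threshold the warm face.  The built-in detector and
   person segmenter are simple Otsu-brightness procedures adequate for
   synthetic scenes; real deployments should inject trained backends
   (any function `frame -> boxes` or `frame -> mask`).
2. **Skin segmentation** (`combine_skin_mask()`).  Per sampled frame
   (stride 10, so 12 frames of a 120-frame clip): person segmentation,
   then k-means (k = 2) binarization of the blue channel within the
   person mask.  The masks are ANDed across frames, multiplied by the
   chin-stand keep-mask (static threshold 185, a pixel exactly at 185
   counts as stand), and smoothed by a 10×10 morphological opening.
3. **Head-movement rejection** (`motion_filter()`).  The AND of the
   per-frame skin masks must cover at least 35% of the frame
   (`sum(mask)/(H·W) ≥ 0.35`), otherwise the clip is rejected.
4. **Heart rate** (`estimate_clip_heart_rate()`).  Green channel only
   (strongest pulsatile SNR of the Bayer channels): 10×10 block-average
   downsampling, 6th-order Butterworth band-pass 0.75–3.5 Hz
   (45–210 bpm), per-pixel FFT, argmax of the in-band magnitude, 3×3
   spatial median filter, median of the non-zero map.
5. **Dual resolution** (`reshape_low_res()`, `reshape_high_res()`).
   56×56 for temporal analysis (10×10 blocks for RGB, 5×5 for NIR, then
   bicubic), 224×224 for the classifier input (2×2 blocks for RGB, then
   bicubic).
6. **Peaks and troughs** (`detect_peaks_troughs()`).  Per 56×56 pixel,
   band-pass as in stage 4, local maxima under a minimum separation of
   $d = \lfloor \tfrac34 T_{HR}/T_S \rfloor$ samples (¾ of a heartbeat
   period); troughs by the same procedure on the negated series.  At
   most 5 extrema of each kind are stored, padded otherwise; a 4×4
   nearest-neighbour index upsampling carries the times to the 224 grid
   where `extract_stacks()` gathers $I_{max}$ and $I_{min}$.  The
   thermal channel carries no pulse and is reduced to 5 uniformly
   sampled frames instead.
7. **Classification harness** (`train_and_evaluate()`).
   Leave-5-subjects-out cross-validation, inverse-frequency class
   weights $w_c = N/(5 N_c)$, augmentation by quarter-turn rotations
   and per-pixel temporal zeroing (probability 1/124), training
   hyperparameters defaulting to 25 epochs, learning rate 0.001, batch
   size 64, dropout 0.5, Adam.

## Numerical choices

* **Filter order.** A Butterworth *band-pass* of total order 6 has three
  pole pairs per edge; the design therefore passes order/2 to the
  low-level designer.  `bandpass_spec(order = 6)` is the total order.
* **Zero-phase filtering.** Forward–backward application with
  odd-reflection edge padding, so extremum timing is not shifted —
  the peak indices of stage 6 depend on it.  Filtering is vectorized
  across all pixels of a clip (one state-update loop over time).
* **FFT length** is the clip length (no padding, no window); the bin
  width is $f_s/T$ = 0.25 Hz for 4 s at 30 fps, which is the resolution
  limit used by the recovery experiment.  Argmax ties break toward the
  lowest frequency (deterministic and conservative).
* **Medians.** Even-count medians use the lower-median convention, so
  estimates are always observed bin frequencies.  The 3×3 median filter
  excludes zero (non-skin) neighbours by default (flag-switchable):
  including them would drag boundary pixels toward zero, which is not a
  frequency.
* **Morphological opening** is the anchor-free set formulation (union of
  fully contained 10×10 blocks), which is well defined for the even
  block size and exactly matches a brute-force oracle.
* **Peak bookkeeping.** The pad sentinel is −1 internally because frame
  index 0 is a legal extremum time; exported stacks use zero padding
  with validity masks.  When more than 5 extrema exist (possible above
  ~2 Hz), the first 5 in time are kept (`keep = "highest"` is
  available).  The n-th peak pairs with the n-th trough; a position
  where only one of the two exists is treated as padded, since the
  starting phase of a 4 s clip legitimately produces 4 extrema of one
  kind and 5 of the other.
* **$I_R$ guard.** `epsilon = 1` gray level bounds the denominator;
  guard activations are counted on the returned block.  $I_{AC}$ may be
  negative on noisy data (stacks sample raw frames at filtered-signal
  extrema) and is passed through unclipped.

## Decisions where the procedure was open

* The AND across sampled frames is applied to the per-frame *skin*
  masks (post chin-stand removal); the overlap ratio of the movement
  rule uses those same pre-opening masks.
* The chin-stand threshold is evaluated on the blue channel, the same
  frame used for k-means.
* The k-means skin cluster is the one with the larger pixel count
  (facial skin dominates the person area in a chin-mounted setup); an
  exact tie goes to the brighter cluster.  1-D two-means on separated
  modes has a unique optimum, so the seed only guards degenerate cases.
* The global clip-level heart rate (not the local per-pixel rate) sets
  the minimum peak separation for all pixels.
* Every cross-validation fold retrains from a fresh initialization.
* No feature normalization is applied before training by default; the
  tiny CNN standardizes its pooled inputs internally (a property of the
  classifier, not of the features).

## The classifier backbone

No deep-learning framework is assumed: the built-in `"tiny"` backbone is
a small CNN written with base matrix algebra — 8×8 input pooling to a
28×28 grid, one 3×3 convolution (8 filters, ReLU), 2×2 average pooling,
dropout, dense softmax — trained with Adam on the class-weighted
cross-entropy.  It accepts any input depth, so concatenated
multi-feature inputs work unchanged.  Compound-scaled pretrained
backbones are out of scope for the built-ins and are supplied as plug-in
learners to `train_and_evaluate()`; for such a backbone a sensible
first-layer adaptation from 3-channel weights to depth-5 input is to
tile the channel weights cyclically and rescale by 3/5.

## What the experiments show (and what they cannot)

The generator emulates the *optical* situation — per-pixel Beer–Lambert
pulse, channel-dependent amplitude, quantization, background, chin
stand, rigid translation — but not photorealistic faces, facial
expressions, breathing or heart-rate variability, illumination drift,
or non-rigid motion.  Recovery results on synthetic cohorts therefore
validate the machinery (segmentation, timing, feature algebra,
grouped CV without subject leakage), not field performance on real
recordings.

Problem sizes were chosen so the whole suite runs on one CPU: synthetic
clips are generated at 112×112 native resolution (60×60 for the
heart-rate recovery experiment), 120 frames at 30 fps; the recovery
experiment uses 50 clips with $f_0 \sim U(0.9, 3.0)$ Hz at roughly
0 dB pixel-level SNR; the classifier experiments use 20 subjects × 5
clips with leave-5-subjects-out CV.  Class patterns in the separable
cohort are disjoint concentric rings of boosted pulsatile amplitude
(boost ×4 over a baseline absorbance amplitude of 0.008, noise SD 0.5
gray): rings are invariant under the quarter-turn rotation
augmentation on the circular default face, so the augmentation does not
destroy the class signal it is meant to regularize.  The null cohort
maps all classes to the same template and must sit at the 20% chance
level.

## Known limitations

* The built-in detector/segmenter backends assume a bright face on a
  dark background; they are stand-ins for trained models, not
  general-purpose segmenters.
* Peak timing is frame-quantized (no sub-frame interpolation).
* A single heart rate per 4 s clip; no HR tracking or HRV.
* Bicubic interpolation uses edge replication; values near the mask
  boundary mix in zeros from masked-out pixels, which is why closed-form
  checks evaluate interior pixels.
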