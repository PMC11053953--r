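# pulsemap

Pulsatile feature maps from short facial videos, in R.

Camera-based photoplethysmography (rPPG) reads the blood volume pulse
from video of skin: every heartbeat modulates the diffusely reflected
light by a fraction of a gray level.  `pulsemap` implements the full
chain from a short (~4 s, 30 fps) facial clip — visible (B, G, R),
near-infrared or thermal — to the physiological feature maps used for
downstream classification:

1. facial ROI cropping (detector averaging for reflective clips, Otsu
   thresholding for thermal ones);
2. skin segmentation: person mask (pluggable backend), k-means (k = 2)
   binarization of the blue channel, AND across every 10th frame,
   chin-stand removal at a static threshold of 185, 10×10 morphological
   opening;
3. head-movement rejection when the stable skin overlap covers < 35% of
   the frame;
4. heart-rate estimation from the green channel: 10×10 block averaging,
   6th-order Butterworth band-pass 0.75–3.5 Hz (45–210 bpm), per-pixel
   FFT dominant frequency, 3×3 median filter, median of the non-zero
   map;
5. per-pixel heartbeat peak/trough detection at 56×56 resolution with
   minimum separation `d = floor(3/4 · T_HR / T_S)` samples, and
   pulsatile image stacks `I_max`, `I_min` (224×224×5) gathered at those
   times;
6. the feature maps

   `I_AC = I_max − I_min`  (pulsatile amplitude, gray levels)

   `I_R = ln(I_max / I_min)` (absorbance swing; static absorbers cancel,
   and for zero specular reflection `I_R ≈ 2·A_pulse`);
7. a leave-5-subjects-out cross-validation harness (110 subjects in
   groups of 5 → 22 folds) with inverse-frequency class weights,
   rotation / pixel-dropout augmentation and a small CPU-friendly CNN.

Because the kind of multi-subject recording campaign this pipeline
targets is rarely shareable, the package ships a synthetic facial-video
generator with exact ground truth (Beer–Lambert skin model, known pulse
frequency and phase, known skin geometry, camera noise and 8-bit
quantization).  Every stage is tested against brute-force oracles on
generator output; see `vignettes/pulsemap-methods.Rmd` for the model
and all numerical conventions.

## Worked example

```r
library(pulsemap)

# a synthetic 4 s clip: 72 bpm pulse, realistic noise, known truth
g <- generate_synthetic_clip(skin_model(f0 = 1.2, noise_sd = 0.5),
                             face_geometry(112, 112),
                             duration_frames = 120, fps = 30, seed = 2)

res <- clip_feature_block(g$clip, channel = "R", feature = "AC")
res$ehr
#> <ehr_result> 1.250 Hz = 75.0 bpm (T_HR = 0.800 s)
res$feature
#> <feature_block> I_AC(R), 224 x 224 x 5, 233792 valid positions
```

The estimated 1.25 Hz is the FFT bin (bin width 0.25 Hz for 4 s at
30 fps) nearest the true 1.2 Hz pulse.  The feature block holds the
peak-minus-trough amplitude at the five detected heartbeats for every
224×224 position; positions without a detected extremum are zero-padded
and flagged in `res$feature$validity`.

A classification experiment on a 20-subject synthetic cohort whose
classes differ by disjoint ring-shaped amplitude patterns:

```r
rep <- run_cohort_experiment(n_subjects = 20, clips_per_subject = 5,
                             seed = 101)
rep$accuracy          # ~1.0  (0.2 = chance for 5 classes)
rep$row_normalized    # summed row-normalized confusion matrix
```

A command-line front end over the same functions is installed at
`inst/cli/pulsemap.R` (`detect`, `skinmask`, `ehr`, `feature`
subcommands operating on TIFF clip stacks).

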