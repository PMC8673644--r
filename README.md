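# clickchain

Passive acoustic monitoring of toothed whales rests on detecting their
echolocation clicks — impulsive signals of tens to hundreds of
microseconds — in months-long hydrophone recordings, sorting the millions
of resulting detections into signal classes, and classifying new data
against those classes. clickchain implements this workflow end to end for
scientists and monitoring programs working with single-channel PCM
recordings:

1. **Generic impulse detection.** Calibrated audio is band-passed with a
   five-pole Butterworth filter (5–100 kHz by default) and every transient
   whose peak-to-peak received level reaches a static threshold
   (`RL_pp = 20 log10(max p − min p)` ≥ 120 dB re 1 µPa) with an
   envelope-crossing duration of 30–1200 µs is kept; events within 100 µs
   merge. Each detection carries a 1-ms waveform snippet, its Hilbert
   envelope, and a 500-Hz-resolution spectrum. A diagnostic checks that
   detection counts grow toward the threshold, as they must when sources
   are uniformly distributed in area (`N(≥RL) ∝ 10^((SL−RL)/10)`).
2. **Unsupervised class discovery.** Detections in each 5-minute bin form
   a similarity network (Pearson correlation of spectra, clipped to
   [0, 1]), pruned to its strongest edges and partitioned by Chinese
   Whispers label propagation; each bin-level cluster is summarized by its
   mean spectrum, mean envelope and inter-detection-interval histogram. A
   second clustering pass over all bin summaries — repeated five times,
   keeping the consensus partition by normalized mutual information —
   yields dataset-wide signal-class templates that an analyst names; the
   labels propagate to every member detection.
3. **Deep classification.** A fixed four-layer 512-unit MLP (leaky ReLU,
   50% dropout, softmax; RMSprop at 3e-4, early stopping on validation
   loss) is trained either on standardized individual detections or on
   bin-level average vectors, with train/validation/test split 60/10/30 by
   *encounter* (bouts separated by ≥ 15 min of class silence) and balanced
   per-class sampling.
4. **Evaluation.** Confusion matrices, per-class precision/recall,
   probability-threshold sweeps, and bin-level accounting in which a truly
   present class that received no label is booked as "none".

A synthetic-scene simulator (Gabor click kernels, uniform-area received
levels, encounter structure, interferers, Gaussian noise floor, 16-bit WAV
with calibration sidecar, byte-reproducible under a seed) provides ground
truth so the whole pipeline is testable without field recordings.

## Worked example

Simulate five minutes of a delphinid click train overlapping a sonar-like
interferer, detect, and cluster the bin:

```r
library(clickchain)

cls <- list(
  click_class_spec("delphinid", 20000, 5000, 300e-6, modal_idi = 0.15,
                   idi_jitter = 0.02, source_level = 160),
  click_class_spec("sonar", 6500, 1500, 1000e-6, modal_idi = 0.8,
                   source_level = 150, class_kind = "sonar_like"))
cfg <- scene_config(fs = 64000, total_duration = 300, noise_floor = 50,
  classes = cls,
  encounters = data.frame(class = c("delphinid", "sonar"),
                          start = c(10, 60), end = c(290, 240)),
  min_rl = 125, seed = 1)
scene <- synth_scene(cfg, "scene_dir")

det <- detect_file(scene$wav, detector_params_for_fs(64000))
print(det)
#> <detection_set> 2095 detections, fs 64000 Hz
#>   time span 10.04-289.91 s, RL 124.0-160.0 dB pp re 1 uPa
#>   snippet 64 samples, spectrum 51 bins (5000-30000 Hz)

summaries <- cluster_phase1(det, phase1_params(max_nodes = 2000), seed = 1)
#>   bin 0: 1783 members, IDI mode 0.15 s, majority delphinid (purity 1.000)
#>   bin 0:  209 members, IDI mode 0.80 s, majority sonar  (purity 1.000)

rl_distribution_diagnostic(det$meta$rl_pp_db, threshold = 125)$flag
#> [1] "pass"
```

The two clusters recover the two injected classes exactly: member counts
match the injected click trains, the IDI histogram modes sit at the
classes' modal inter-click intervals (0.15 s and 0.8 s), and the
received-level histogram rises toward the threshold as the uniform-area
model predicts. On the packaged two-hour five-class reference scene
(`scene_class_discovery()`), phase-2 clustering returns one template per
planted class at > 0.999 member purity, and the classifiers trained on the
propagated labels reach ≥ 99% held-out accuracy at both the detection and
bin level (`classification_study()`).

A thin command-line front end is installed with the package
(`inst/scripts/clickchain`) for the file-level stages:
`clickchain simulate --config scene.yaml --out dir/`,
`clickchain detect --wav scene.wav --out detections`,
`clickchain evaluate --truth truth.csv --detections detections`.

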