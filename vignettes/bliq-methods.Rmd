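---
title: "Stimulus-locked analysis of bioluminescence imaging video: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stimulus-locked analysis of bioluminescence imaging video: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bliq)
```

## The problem

Bioluminescence imaging (BLI) of the awake mouse brain records the light
produced by a luciferase oxidizing an injected substrate. Unlike
fluorescence, there is no excitation light, so the background is essentially
dark — but the signal rides on the substrate's pharmacokinetics: global
brightness rises for a few minutes after injection and then decays. Two
kinds of stimulus-evoked modulation sit on top of that envelope:

* a **hemodynamic response**: neuronal activity increases local blood flow,
  which delivers more substrate and oxygen and so raises light output a few
  seconds after a stimulus (the bioluminescent analogue of the fMRI BOLD
  response), present for any luciferase reporter; and
* a **calcium response**: with a calcium-modulated indicator (Antares with a
  calcium-sensing module; eightfold brightness response, 110 nM dissociation
  constant), light output also follows neuronal calcium, peaking about 1 s
  after the stimulus.

The analysis problem is to turn a raw EM-CCD video at 5 Hz into a
trial-averaged fractional-response movie (ΔL/L₀) in which these two
components can be separated by their latency, and to quantify them per
animal so that groups can be compared. `bliq` implements that chain, the
supporting enzymological fits, and a synthetic video generator with exact
ground truth so the whole pipeline is testable without animal data.

## The analysis chain

Given a stack `L(x, y, t)` and a stimulus schedule (the standard design is
57 cycles of a 1 s foot vibration followed by 19 s rest, beginning 60 s
after acquisition onset):

1. **Dark subtraction** (`subtract_dark`): the camera bias is removed and
   results are clipped at zero.
2. **Head mask** (`compute_head_mask`): one static binary mask per
   recording, from Otsu's threshold on the temporal-mean image followed by
   retention of the largest connected component. Pixels outside the mask
   are treated as missing everywhere downstream — they are never zeros.
3. **Decay correction** (`masked_mean_trace`, `lowpass_smooth`,
   `decay_correct`): the mean intensity inside the mask is computed per
   frame, smoothed with a zero-phase order-4 Butterworth lowpass at
   0.02 Hz, and each frame is divided by the smoothed value. The cutoff
   sits well below the 0.05 Hz stimulus-cycle frequency, so the
   pharmacokinetic envelope is tracked while stimulus-locked responses pass
   through; zero-phase (forward–backward) application avoids the lag that a
   causal filter would introduce, which would leak decay into ΔL/L₀.
4. **Epoching** (`epoch_trials`): trials of 20 s (the cycle length) are cut
   starting 2 s before each onset, mapping times to frames by
   nearest-frame rounding; at 5 Hz each trial has 100 frames with the onset
   at trial frame 11 (1-based). Trials that would overrun the recording are
   dropped and counted.
5. **Baseline normalization** (`normalize_trials`): each pixel of each
   trial is divided by its own mean over the first 1 s of the trial, so the
   stored values are L/L₀ ratios; ΔL/L₀ = ratio − 1 is applied only at the
   statistics and rendering boundaries.
6. **Averaging** (`average_trials`): pointwise mean of the first 20 trials
   (the standard protocol), missing values ignored.
7. **Rendering** (`render_pseudocolor`): a diverging lookup table clamped
   at ΔL/L₀ = ±0.3, brightness-modulated by normalized luminance.

`bli_trial_average()` runs stages 1–6 and returns all intermediates. For
speed it performs the frame-level arithmetic on the masked pixels only;
this is exactly equivalent because background pixels are missing by
construction (the tests assert agreement with the stage-by-stage chain and
that poisoning background pixels changes nothing).

Two exact invariances follow from the two divisions: multiplying the
dark-subtracted stack by any constant leaves the final movie unchanged
(both divisions cancel the constant), and on noiseless input the chain
returns `1 + hemo(t) + calcium(t)` up to the filter's interaction with
stimulus-locked content (measured below 1e-3, dominated by the lowpass
transient at the start of the stimulation block).

## Response statistics

`roi_response_trace` reduces the averaged movie to a cortical ΔL/L₀
waveform; `split_auc` integrates it by trapezoid over an early window
(default 0–2 s post-onset, the calcium component) and a late window
(default 2–6 s, the hemodynamic component), split at the 2 s time point.
The late window's right edge is configurable because the source protocol
states only the 2 s split; 6 s is the default since the late response has
ended by then. `compare_groups` applies the two-tailed Student's t-test —
pooled-variance unpaired by default, matching the design used for
between-cohort AUC comparisons — with the degenerate zero-variance,
equal-means case returning p = 1 by convention. `summarize_timecourse`
reports peak, time-to-peak and total integral of whole-recording traces.

## The synthetic generator

`simulate_bli_video()` composes, per pixel and frame,

```
expectation = profile(x, y) * substrate(t) * (1 + hemo(t) + calcium(t)) * exposure
counts      = dark_offset + em_gain * F^2 * Poisson(expectation / F^2) + N(0, read_sd^2)
```

* **Head profile**: an elliptical plateau with a ~1 px Gaussian rim
  falloff on a dark field; the true mask (profile ≥ 0.5) is returned as
  ground truth. Responses are applied uniformly inside the head,
  emulating the bilateral arousal-type response.
* **Substrate kinetics** (`substrate_kinetics`): a Bateman (one-compartment
  absorption/elimination) curve, the simplest form with a single interior
  peak. Defaults `k_abs = 0.5`, `k_elim = 0.1` per minute put the peak
  4 min after injection, with acquisition starting 60 s post-injection —
  matching the few-minute rise-and-decay of brain BLI time courses. The
  equal-rate limit `t e^{-kt}` is handled analytically. The default
  amplitude (1000 photons/s at the profile peak, ~200 photoelectrons per
  200 ms frame) gives single-trial ΔL/L₀ noise of a few percent inside the
  mask, a realistic regime for EM-CCD BLI video. Seconds-timescale
  substrate dynamics are assumed smooth and slow; that is an assumption of
  the generator, not an observed property.
* **Response kernels** (`response_kernel`): the hemodynamic kernel is a
  gamma-variate with a 2 s onset delay, peak at 3 s and truncation at 6 s
  (the late response occupies 2–6 s post-stimulus); the calcium kernel is
  a difference of exponentials (rise 0.55 s, decay 2 s) peaking at ~1 s,
  truncated at 4 s. Both are peak-normalized to a default amplitude of
  0.10 ΔL/L₀, the ~10% modulation seen in vivo. The explicit onset delay
  keeps the hemodynamic kernel out of the early window, which is what makes
  the early/late split identifiable in the first place.
* **Indicator model** (`calcium_indicator`): brightness multiplier
  `1 + (R − 1) ca^n / (ca^n + Kd^n)` with defaults Kd = 110 nM, R = 8 and
  n = 1 (one-site binding is the minimal model consistent with a reported
  Kd and fold-response).
* **Camera** (`camera_model`): 200 ms exposure, 5 Hz, 4×4 binning, EM gain
  50, read noise 10 counts, excess noise factor √2 (the standard value for
  an EM register; no camera noise statistics are published for the source
  recordings). The scaled-Poisson construction gives mean
  `gain * expectation` exactly and variance `gain² F² expectation`, which
  the tests verify by regression over a brightness ladder.

Everything is a pure function of parameters and seed; identical seeds give
bit-identical stacks. What the generator does *not* model: optical
scattering through skull and skin, motion (the head-fixed assumption),
spatially structured responses, or multi-luciferase spectral mixing — so
passing tests demonstrate the correctness of the analysis arithmetic and
its statistical calibration, not robustness to those real-world effects.

## Enzymology

`fit_michaelis_menten` fits `v = Vmax S / (Km + S)` by unweighted nonlinear
least squares (weights can be supplied), pooling replicate points rather
than fitting means. The optimizer is seeded from the Lineweaver–Burk
linearization and restarted from 5 perturbed seeds, keeping the lowest-RSS
solution, so the fit is deterministic for a given data set. Readings are
treated as initial velocities. `relative_kcat` compares substrates at
matched enzyme concentration as the Vmax ratio with a first-order
(delta-method) standard error, validated against a parametric bootstrap.
`fit_one_site_binding` fits `y = y0 + (ymax − y0) c / (c + Kd)` for
indicator titrations, and `normalize_emission_spectrum` peak-normalizes
spectra (idempotently). Absolute kcat is out of scope: it would require
absolute photon calibration and enzyme quantitation.

## Numerical choices and known limitations

* **Filter edges.** The zero-phase filter starts each pass in steady state
  for the first sample and extends the trace by odd reflection, so
  constants pass exactly and trends are absorbed. Residual edge transients
  decay over a few filter time constants (~50 s at 0.02 Hz); the
  decay-corrected trace of a noiseless null recording is flat to 1e-6 in
  the interior but only to ~1e-4 within ~160 s of the record ends. With
  the standard 60 s lead-in the first trials sit clear of the start
  transient.
* **Baseline ratio bias.** Dividing each pixel by its own 5-frame baseline
  mean makes post-baseline expectations slightly positive (Jensen's
  inequality): measured ~0.2% ΔL/L₀ at the default flux and scaling
  inversely with photon count. It is invisible next to the ~10% responses
  and identical across conditions, so group contrasts cancel it — the
  type-I calibration test confirms the early-AUC group test keeps its
  nominal 5% false-positive rate at default flux. Frame-wise
  "no-signal" assertions, however, are only meaningful at high flux, and
  per-cohort significance is therefore always assessed against a control
  cohort rather than against literal zero.
* **Trial bookkeeping.** Windows are half-open `[start, start + span)`,
  frames 1-based in R with frame `f` at time `t0 + (f − 1)/rate`;
  onset-to-frame mapping uses nearest-frame rounding.
* **Masking.** One static mask per recording (the protocol generates "a
  binary mask", singular); per-frame masking is deliberately not
  implemented. A fixed-fraction threshold is available as an alternative
  to Otsu.
* **Dark level.** The sidecar metadata value is used when present;
  otherwise supply a measured level or background-ROI median. No implicit
  estimation is performed.
* **Problem sizes in the tests.** The type-I calibration property runs 200
  null cohorts at 24×24 px / 600 frames; the acceptance-level calibration
  runs 50 cohorts at 64×64 px / 1200 frames; cohort comparisons use 3
  subjects per group. These sizes were chosen to make the Monte-Carlo
  checks sharp while keeping the default test run in minutes.

## Worked example

```{r example, eval = FALSE}
sched <- stimulus_schedule(9, 1, 19, 60)
sim <- simulate_bli_video(schedule = sched, duration = 240, seed = 7)
an <- bli_trial_average(sim$video, sched,
                        dark = camera_model()$dark_offset, n_first = "all")
tr <- roi_response_trace(an$movie, an$mask)
split_auc(tr)
compare_groups(c(0.21, 0.18, 0.24), c(0.02, -0.01, 0.03))
```
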