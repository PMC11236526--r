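---
title: "Modeling CO2-driven cerebrovascular dynamics and CSF inflow"
author: "csfdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling CO2-driven cerebrovascular dynamics and CSF inflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfdyn)
```

## The physiological model

Arterial CO2 is a potent vasodilator.  During a controlled hypercapnic
challenge, the blood oxygen level-dependent (BOLD) signal of gray matter
rises with cerebral blood volume (CBV) and flow; when the end-tidal CO2
(PetCO2) returns to baseline, vasoconstriction shrinks CBV.  Under the
Monro-Kellie doctrine the intracranial volume is constant, so a falling CBV
draws cerebrospinal fluid (CSF) into the cranium.  An imaging slab placed
with its bottom slices below the fourth ventricle sees this as a
time-of-flight inflow signal: fresh, unsaturated spins enter the slab and
appear bright.  Because the effect requires *inflow* of unsaturated spins,
the signal is rectified — outflow produces nothing.

`csfdyn` implements this chain as a forward model plus the estimators that
invert it:

1. **Vascular response.**  The regional BOLD response is modeled as
   \[ s(t) = s_0 + A\,(\Delta\mathrm{CO2} \otimes h_\tau)(t), \qquad
      h_\tau(t) = \tfrac{1}{\tau} e^{-t/\tau}, \]
   with $A$ the cerebrovascular reactivity (CVR) amplitude in signal units
   per mmHg and $\tau$ the response time constant in seconds.  `fit_tau()`
   estimates $\tau$ by exhaustive grid search: for each candidate $\tau$ the
   PetCO2 trace is convolved with the unit-sum exponential kernel and the
   BOLD trace is regressed on it by ordinary least squares; the $\tau$
   minimizing the residual sum of squares wins, with ties broken toward the
   smaller value.  A one-parameter problem does not need a fancier
   optimizer, and the grid makes the estimate exactly reproducible.  An
   optional parabolic refinement of the RSS profile (`refine = TRUE`) can
   interpolate between grid points.

2. **CSF inflow peak.**  The inflow trace shows a peak after the end of the
   hypercapnic block.  `fit_inflow_peak()` fits an Azzalini skew-normal
   density scaled by an amplitude plus a linear baseline,
   \[ f(t) = A_p \tfrac{2}{\omega}\,
      \phi\!\big(\tfrac{t-\xi}{\omega}\big)
      \Phi\!\big(\alpha\tfrac{t-\xi}{\omega}\big) + a + bt , \]
   by bounded Levenberg-Marquardt least squares.  `hwhm_right()` then
   reports the right-sided half width at half maximum of the baseline-free
   component — a proxy for how long the displaced CSF keeps flowing back.
   The skew-normal mode has no closed form, so the mode is located
   numerically and the half-height point found by bisection to
   $10^{-6}\omega$.

3. **Coupling.**  `shifted_crosscorr()` measures the lag between the inflow
   trace and the (negated) temporal derivatives of the gray-matter BOLD
   signal — the CBV-change surrogate — and of the PetCO2 trace, as the
   integer-volume shift maximizing the Pearson correlation over the
   overlapping samples.  `regress()` and `paired_change_test()` provide the
   cohort-level statistics relating $\tau$ to inflow width and edema load.

Imaging volumes are numbered from 0 throughout, so volume $k$ is acquired
at $k \cdot TR$ seconds; with $TR = 1.05$ s, volume 250 is 262.5 s.

## The gas-challenge protocol and its analysis windows

The default protocol (`default_protocol()`) is a 90-s hypercapnic block
(+10 mmHg), a 120-s ramp rising to +12 mmHg, and a 180-s hyperoxic block
targeting 680 mmHg, interleaved with 120-s baselines; TR = 1.05 s, 1000
volumes; baseline PetCO2 and PetO2 default to 40 and 110 mmHg
(physiologically typical values — real sessions use individually measured
baselines).  The leading baseline is a parameter, defaulting to 172.5 s so
that the hypercapnic block ends exactly at volume 250; the published
analysis anchors (block end at volume 250, tau window 250-450, inflow
window ending at volume 525, and a figure annotated 200-450) are not all
mutually consistent with the nominal epoch durations, so all windows are
configurable and 250-450 / 250-525 are the defaults.

Because the 250-525 window contains the ramp-associated inflow peak under
the nominal timings, `inflow_window_from_protocol()` derives the window
the analysis actually wants from the protocol itself: from the block end
to the midpoint between block end and ramp peak, which captures the full
tail of the block-associated peak while excluding the ramp event.  The
pipeline examples and the acceptance script use this derived window.

```{r}
p <- default_protocol()
protocol_epochs(p)
inflow_window_from_protocol(p)
```

## What the generator emulates — and what it does not

`simulate_dataset()` produces a complete experiment: rendered end-tidal
traces, a small 4-D BOLD volume, tissue/edema masks, and the generating
truth.

* **End-tidal targeting** is idealized as piecewise-linear plateaus.  The
  transition into a plateau rises inside the epoch; the return to baseline
  *starts at the epoch end* and takes `transition_time` seconds (default
  10 s, the two-three breaths a prospective targeting system needs).  The
  inflow-generating CO2 drop therefore begins exactly at the block end,
  which is also where the inflow fit window starts.  Breath-to-breath
  variability can be added as Gaussian noise but is off by default — the
  analysis consumes the trace, not the controller.
* **CSF inflow** is generated as the rectified negative BOLD derivative of
  the *vasoactive* signal component, scaled by `inflow_gain`.  The
  hyperoxic saturation effect (optional, `o2_amplitude`) raises BOLD
  without moving CBV and deliberately produces no inflow.  A right skew is
  imposed by stretching the falling flank of the block-associated peak by
  $1+\texttt{inflow\_skew}$ (the slow return of displaced CSF); the mapping
  returns to the identity at the next zero of the rectified derivative so
  later events keep their timing, and the stretched ground-truth HWHM is
  computable on a dense grid (`true_inflow_hwhm()`).
* **Anatomy** is schematic: an ellipsoidal brain, radius-banded CSF/WM/GM
  partition, and a face-connected edema blob grown to the requested voxel
  fraction.  Noise is additive Gaussian (high-SNR magnitude data); Rician
  noise, motion, distortion and k-space physics are out of scope.  Passing
  tests therefore demonstrate correctness of the estimators under the
  assumed signal model, not robustness to acquisition artifacts.

## Numerical and design choices

* **Wavelet de-noising** uses the sym4 (least-asymmetric, 8-tap) filter at
  level 2 with the Donoho-Johnstone universal threshold
  $\lambda = \hat\sigma\sqrt{2\ln N}$, $\hat\sigma$ the MAD of the
  finest-level details over 0.6745, applied hard and level-independently.
  Boundaries use half-sample symmetric extension; reconstruction is exact
  to machine precision when nothing is thresholded.  The transform is
  implemented in the package and validated against reference coefficients
  from an independent implementation.
* **Temporal derivative**: central differences (one-sided at the ends),
  divided by TR.  Central differences add no phase shift, which matters
  when the derivative feeds lag estimates.
* **Convolution** with $h_\tau$ is causal, truncated to the input length,
  unit-sum normalized (so the CVR amplitude keeps its units for every
  $\tau$), and steady-state initialized: the trace is assumed to have sat
  at its first value before the scan, so no warm-up transient leaks into
  the fit window.
* **Bulk CO2-BOLD alignment** maximizes Pearson correlation over integer
  shifts (ties toward zero, edge-hold padding).  It exists to remove the
  clock offset and gas-transit delay of a real acquisition.  On synthetic
  data whose clocks are already synchronized the max-correlation shift
  would instead absorb part of the exponential response delay — the very
  quantity $\tau$ measures — so `pipeline_config(align_co2 = FALSE)` is
  used for generator data and `TRUE` (the acquisition default) for real
  recordings.
* **Inflow-voxel selection** ranks de-noised voxel time courses within the
  two bottom slices by max-minus-min contrast over the analysis window and
  keeps the top 5 per slice (the published analyses selected voxels by
  hand; 5 is a reasonable emulation and is configurable); per-slice means
  are averaged.  Ties break by voxel index.
* **Inflow presence screening** compares the de-noised peak excursion in
  the post-block window against 3 times the *raw* baseline noise SD.  The
  raw-noise reference is deliberate: the maximum of a couple of hundred
  de-noised samples exceeds 3 de-noised SDs with appreciable probability
  at any noise level, so a de-noised reference would make the screen a
  coin flip rather than a detector.  A manual override flag mirrors visual
  screening.
* **Skew-normal fitting** starts from $\xi_0$ at the windowed maximum,
  $\omega_0 = \text{span}/6$, $\alpha_0 = 0$, amplitude from the peak
  height, baseline from the endpoints, restarting from $\alpha_0 = \pm 2$
  on failure; bounds are $\omega \in (TR, \text{span})$,
  $|\alpha| \le 20$, amplitude $\ge 0$, and $\xi$ may sit one window-span
  outside the window because the analyzed peak can begin at its edge.
  Note that at fixed $\omega$ skewing *narrows* both half-widths of the
  Azzalini density; what distinguishes a right-skewed peak is
  $\mathrm{HWHM}_{right} > \mathrm{HWHM}_{left}$.

## Problem sizes and verification

The test-suite fixtures use a compact protocol (60-s epochs, 400 volumes)
so that grid-search fits stay fast, and the full 1000-volume protocol for
the acceptance-level properties.  Parameter-recovery checks run the
forward model at the conditions of a regional gray-matter average: a
2-signal-unit response to the +10 mmHg block with trace noise SD 0.1
(contrast-to-noise 20 — a mean over a few hundred voxels sits well above
this, and recovery degrades gracefully below it).  Synthetic 4-D volumes
are 12 x 12 x 6 voxels: large enough to exercise masking, exclusion and
slice-wise selection, while keeping a full pipeline run in seconds.

Every estimator is tested against an independent oracle where one exists:
the wavelet transform against frozen reference coefficients, the tau grid
search against per-tau `lm()` fits on the public convolution, the HWHM
bisection against a dense-grid evaluation of the density, and the lag
search against brute-force correlation at every shift.

## Known limitations

* The skew-normal is an approximation to the shape of the simulated
  (stretched-exponential) inflow peak, so pipeline-level HWHM estimates
  carry a small systematic error even without noise (a few percent in the
  default configuration).
* Lags are estimated at integer-volume resolution (1.05 s); sub-TR delays
  such as a ~1-s inflow-to-CBV offset are below the quantization step.
* `paired_change_test()` returns $t = 0$, $p = 1$ for identical inputs and
  raises an error for constant non-zero differences.
* The generator shares one $\tau$ between gray matter and the whole brain;
  consequences of regionally heterogeneous dynamics (e.g. for the bulk
  alignment) are not modeled.
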