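# csfdyn

Gas-challenge BOLD fMRI analysis of cerebrovascular response dynamics and
CO2-driven cerebrospinal fluid (CSF) inflow.

## What problem this addresses

Controlled hypercapnia dilates cerebral vessels; the return to baseline
CO2 constricts them again.  Because total intracranial volume is fixed
(Monro-Kellie), the shrinking cerebral blood volume (CBV) draws CSF into
the cranium, visible as a time-of-flight inflow signal in the bottom
slices of a BOLD acquisition.  Two quantities summarize the physiology:

* **tau** — the time constant of the vascular response, estimated by
  least-squares fitting of the gray-matter BOLD signal against the
  end-tidal CO2 trace convolved with an exponential hemodynamic response
  function `h_tau(t) = (1/tau) exp(-t/tau)`:

      s(t) = s0 + A * (dCO2 ⊗ h_tau)(t)

  where `A` is the cerebrovascular reactivity amplitude (signal/mmHg).

* **right-sided HWHM** of the CSF inflow peak — the peak after the end of
  the hypercapnic block is fit with an Azzalini skew-normal density plus a
  linear baseline, and the half width at half maximum of its falling side
  measures how long the displaced CSF keeps flowing back.

The package is aimed at researchers analyzing gas-challenge BOLD
experiments (or prototyping such analyses): it provides the estimators,
the coupling statistics (shifted cross-correlation lags between inflow and
the CBV-change surrogate, cohort regressions of tau against inflow width
and edema load), a complete synthetic-data generator with known ground
truth, and a per-subject/cohort pipeline over NIfTI + CSV inputs.

## Worked example

Simulate a full experiment with known truth (tau = 20 s, 5% edema load,
skewed inflow peak) and run the subject pipeline on it:

```r
library(csfdyn)
proto <- default_protocol()    # 90-s +10 mmHg block, ramp, hyperoxia
pars  <- forward_model_params(tau_true = 20, noise_sd = 0.2,
                              inflow_skew = 0.5, seed = 1)
ds  <- simulate_dataset(proto, pars, shape = c(12, 12, 6),
                        edema_fraction_target = 0.05)
cfg <- pipeline_config(dataset = ds, id = "demo",
                       inflow_window = inflow_window_from_protocol(proto),
                       align_co2 = FALSE)
report <- run_subject(cfg)
#> [demo/pre] tau = 21.00 s, inflow present, edema 0.050 (1.5 s)
```

The report holds every result block:

```
tau: 21.0 s, CVR: 0.199 su/mmHg
inflow HWHM: 22.09 s (truth 21.90 s)
lag vs CBV: 0.00 s (r=0.98); lag vs dCO2: 10.50 s (r=0.74)
edema fraction: 0.050, inflow peak 54 x noise SD
```

Reading: the fitted time constant (21 s) recovers the generating 20 s to
within the noise; the skew-normal fit reproduces the generator's inflow
peak width to 1%; the inflow peak coincides with the CBV-change peak
(lag 0, r = 0.98) and follows the CO2 drop by ~10 s; and the hyperoxic
block — included in every simulation — produces no inflow peak, because
oxygen raises BOLD through blood saturation without moving blood volume.

`fit_tau()` and `fit_inflow_peak()` also work directly on numeric traces
and return classed objects with `print`, `summary`, `coef`, `predict`,
`plot`, `fitted` and `residuals` methods.  `run_cohort()` aggregates
subject reports into the edema/tau and HWHM/tau regressions and the
paired pre/post comparison.  A thin command-line wrapper with
`simulate` / `subject` / `cohort` subcommands lives in
`inst/cli/csfdyn.R`.

## Volume indexing

Imaging volumes are numbered from 0: volume `k` is acquired at `k * TR`
seconds, so with TR = 1.05 s the default tau-fit window 250-450
corresponds to 262.5-472.5 s.  See the vignette
(`vignettes/csf-inflow-dynamics.Rmd`) for the model details, window
conventions, and the design rationale of the generator.
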