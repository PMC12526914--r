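# kinasm

Single-molecule kinetochore assembly kinetics from two-channel TIRFM
colocalization time courses.

## What this package is for

Kinetochores — the protein machines that couple chromosomes to spindle
microtubules — assemble de novo on centromeric DNA every cell cycle. A
powerful way to watch this happen is colocalization single-molecule
spectroscopy (CoSMoS): fluorescent centromeric (CEN) DNA molecules are
tethered sparsely on a coverslip, incubated with yeast lysate carrying
a GFP-tagged kinetochore protein for increasing times, washed, and
imaged by two-channel TIRF microscopy. The fraction of DNA spots with a
colocalized GFP spot, followed over incubation time, reveals when and
how completely each kinetochore component assembles.

`kinasm` is a tidyverse-style R package for analysts of such
experiments. It provides:

* **Synthetic data with ground truth** — two-channel field images
  (Gaussian-PSF spots, configurable SNR), count-level colocalization
  time series, and photobleaching traces, all reproducible from a seed
  (`sim_config()`, `simulate_field_pair()`, `simulate_series()`,
  `simulate_traces()`).
* **Spot detection and colocalization scoring** — difference-of-Gaussians
  band-pass, robust thresholding, subpixel centroids, greedy one-to-one
  matching within a radius, chance-colocalization estimation, and
  pooled per-replicate time series (`detect_spots()`, `match_spots()`,
  `colocalization_fraction()`, `score_field_series()`).
* **Photobleaching step counting** — penalized binary-segmentation
  changepoint search used to verify that DNA foci are single molecules
  (`count_bleach_steps()`, `single_molecule_fraction()`).
* **Kinetic fitting and model selection** — the four sequential
  irreversible-step models, chi-squared fitting, minimum-chi-squared
  model selection, bootstrap uncertainties, censored threshold-crossing
  times, and assembly-order comparison (`assembly_curve()`,
  `fit_fixed_steps()`, `select_model()`, `time_to_threshold()`,
  `estimate_uncertainties()`, `compare_curves()`).
* **A reproducible pipeline** — `run_pipeline()` chains the stages,
  writes CSV/JSON artifacts plus a checksummed manifest, and a thin CLI
  (`inst/cli/kinasm.R`) exposes the verbs from a shell.

## The model

Colocalization-versus-time data are fit with curves for a pathway of
*n* sequential irreversible transitions (n = 1..4), all sharing one
rate constant *k*:

    f(t) = Cmax * P(n, k t)

where P is the regularized lower incomplete gamma function (the Erlang
CDF; for n = 1 this is `Cmax * (1 - exp(-k t))`). Each dataset is fit
with all four forms and the minimum-chi-squared fit is selected. Curves
are summarized by **Cmax**, the plateau colocalization, and **T30**,
the time at which the curve crosses 30% colocalization; a curve that
never reaches 30% within the observation window is reported censored,
e.g. `> 180 min`.

## A worked example

```r
library(kinasm)

# an Ndc10-like experiment: fast, efficient assembly
cfg <- sim_config(
  n_dna_per_field = 200, n_fields_per_timepoint = 15,   # 3000 DNAs/timepoint
  kinetic_truth = list(n_steps = 1, k = 0.1057, c_max = 0.87),
  seed = 11
)
series <- simulate_series(cfg, protein = "Ndc10")$series
fit <- select_model(series)
fit <- estimate_uncertainties(series, fit, n_boot = 200, seed = 12)
fit
```

```
Kinetic fit: 1 irreversible step(s)
  k     = 0.1054 /min
  c_max = 0.8685 (se 0.0018)
  chi2  = 2.813
  T30   = 4.02 min (se 0.05)
```

The fitted plateau (86.9 ± 0.2%) and 30%-crossing time (4.02 ± 0.05
min) recover the generating truth (Cmax = 0.87, T30 = 4.0 min); the
chi-squared is against 9 timepoints with 2 free parameters.
`autoplot(fit)` draws the data with replicate-SD error bars and the
fitted curve; `tidy(fit)` and `glance(fit)` return broom-style tibbles.
To rank proteins by assembly order, pass several fits to
`compare_curves()`, which sorts by T30 with censored fits last.

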