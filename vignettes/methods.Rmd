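---
title: "Methods: models, generators and numerical choices in cellfate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, generators and numerical choices in cellfate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cellfate implements four measurement pipelines for longitudinal single-cell
imaging of aggregation-prone proteins, together with seeded generators that
produce data from the same model families with known truth. This vignette
records the models, the tunable parameters and their defaults, what the
generators do and do not emulate, and the numerical and design decisions.

## FRAP granule fluidity

**Normalization.** A raw trace carries pre-bleach and post-bleach frames of
the bleached region's intensity, optionally alongside a whole-granule channel.
When the whole-granule channel is present, the bleached signal is first
divided by it to correct acquisition photobleaching. The trace is then mapped
affinely so the pre-bleach mean equals 1 and the first post-bleach frame
equals 0. A trace whose first post-bleach value equals its pre-bleach mean has
zero bleach depth and is rejected — the map is undefined. The affine map does
not require non-negative intensities: additive camera noise can push values at
the bleach floor slightly below zero, and such traces are valid inputs.

**Model.** Post-bleach recovery is fit as

\[ y(t) = A\,(1 - e^{-\tau t}), \]

where \(A\) is the mobile fraction and \(\tau\) the recovery rate. The fit
uses Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) rather than
`stats::nls` because `nlsLM` converges cleanly on zero-residual (noiseless)
series, which `nls` rejects; bounds \(A \in [0, 1.5]\), \(\tau \in (0, 10]\)
keep the optimizer in the physically meaningful region. Starting values are
taken from the data (plateau from the last three points, rate from the time
to half-rise). A constant post-bleach series leaves \(\tau\) unidentifiable
and is an error, not a silent fit.

**Derived physics.** Half-time \(t_{1/2} = \ln 2 / \tau\); diffusion
coefficient \(D = 0.88\,r^2/(4\,t_{1/2})\) for a circular bleach region of
radius \(r\) (default 3.7 µm, a typical granule-scale ROI); apparent
viscosity by Einstein–Stokes, \(\eta = k_B T / (6 \pi D R)\). The probe
Stokes radius defaults to \(R = 4.5\) nm — the empirical minimal radius
\((0.66\,M)^{1/3}\) Å for a globular protein of \(M \approx 140\) kDa,
exposed as `stokes_radius()` — and temperature to 310 K (cell culture at
37 °C). Both are plain arguments, since the appropriate probe radius depends
on the construct being imaged.

**Generator.** `simulate_frap_trace` draws the model curve on an imaging
schedule (default 5-s steps to 60 s, then 10-s steps to 300 s — denser early
sampling where the curve bends) plus i.i.d. Gaussian noise, with pre-bleach
frames at the pre-bleach level. It does not emulate diffusion geometry,
acquisition bleaching of the bleached channel itself, or focal drift; it
exists to validate the estimator, not to replace microscope data.

## Puncta classification

The per-cell statistic is the coefficient of variation of reporter intensity
over the cell's pixels, CV = SD/mean, with the **population** SD
(denominator \(n\)) by default since the pixels are the complete population
of the cell, not a sample; the sample convention is available via
`sd_convention = "sample"`. A cell is punctate when CV strictly exceeds the
fixed threshold 0.62; a cell at exactly 0.62 is diffuse. CV is invariant to
multiplying all pixels by a constant, so the classifier is insensitive to
exposure and gain.

`simulate_cell_image` renders a disk-shaped cell on a background, adds
Gaussian puncta and Gaussian read noise, and returns the reporter image, a
morphology channel, the ground-truth mask, and the realized CV. When a
`target_cv` is requested, the punctate regime calibrates the puncta amplitude
by root-finding (`uniroot`) on the noiseless image so the design CV is exact,
and the diffuse regime sets the read-noise SD to `target_cv * cell_level`.
The generator does not emulate cell-shape variability, uneven illumination,
or out-of-focus light. Image I/O uses 16-bit TIFF via the `tiff` package
(`as.is = TRUE` on read, so pixel values round-trip exactly); segmentation
without a provided mask uses Otsu thresholding from `EBImage` (a suggested,
not required, dependency).

## Neurotoxicity survival analysis

Event tables are derived from long-format tracks: one row per cell and
imaging day, with death detected at the first imaging day at or past the
latent death time and puncta treated as an **absorbing** state (once
punctate, always punctate — transient dissolution is not modelled). Cells
alive at the censoring day are right-censored.

Hazard ratios come from `survival::coxph` with the **Efron** ties
approximation — discrete imaging days produce heavy ties, where Efron is
markedly less biased than Breslow — stratified by experiment so each
experiment contributes its own baseline hazard. Delegating to `coxph` rather
than hand-rolling Newton iterations buys decades of numerical hardening; the
package's test suite independently verifies the fits against a brute-force
grid maximization of the Efron partial likelihood written from the
definition. Monotone-likelihood fits (complete separation: the coefficient
runs away) are flagged via `coxph`'s warnings plus magnitude checks
(\(|\beta| > 15\) or SE > 100), not silently returned.

Dose analyses bin cells into quintiles of day-1 expression or day-1 CV by
rank, `ceiling(5 * rank(ties = "first") / n)`, which gives equal-sized, stable
bins under ties. The diffuse/punctate analysis contrasts day-1 punctate
versus diffuse cells against a control line and within each genotype; empty
subgroups produce warnings and are dropped rather than fabricating estimates.

`simulate_cohort` draws, per cell, a genotype, a log-normal expression level,
an exponential latent puncta time from day 0 (so some cells are already
punctate at the first imaging day) and an exponential latent death time from
day 1 (no cell can be observed dead on its first imaging day), with
log-linear genotype, expression and day-1-puncta effects on the hazards. The
default cohort — 2000 cells, seven groups, baseline death rate 0.11/day,
censoring at day 10 — yields roughly 30% censoring, a realistic regime chosen
before any estimator was run. Constant hazards are a simplification: real
neuronal death hazards are typically time-varying, and the Cox model does not
require constancy, but constant-hazard truth makes the ground-truth hazard
ratios exact.

## Autophagic flux

Hourly reporter intensities are normalized to the photoconversion depth
\(T_1 - T_0\) (pre- and post-conversion frames). Two conventions are
provided: `"as-printed"` divides the raw values (the series then starts above
1 when background \(T_0 > 0\)) and `"background-subtracted"` subtracts
\(T_0\) first so the series starts at 1 — the form consistent with the
fixed-scale model \(y = e^{-kt}\), and the default in `fit_flux_wells`. The
half-life is \(\ln 2 / k\). A series that does not decay (non-negative
trend, or constant) is flagged up front with an `NA` half-life; the
non-decay check uses a relative slope tolerance because an exactly constant
series can produce a slope of \(-10^{-18}\) in floating point.

Aggregation follows the superplot convention for nested replicates: wells are
averaged within each experiment, then per-experiment means are summarized per
condition with **n = number of experiments**, so the SEM reflects biological
rather than technical replication. `simulate_decay_trace` (default: 3
experiments × 6 wells, 14 hourly reads, 2% multiplicative noise, 10 h
half-life) emulates this design; it does not model plate-position effects or
photoconversion variability between wells beyond the noise term.

## Reproducibility machinery

Every generator takes an integer `seed` and runs inside `with_seed()`, which
saves and restores the global RNG state, so simulation never perturbs a
user's session. Independent substreams are derived as
`substream_seed(seed, offset) = (seed * 48271 + offset) mod (2^31 - 1)`,
keeping derived seeds in integer range while decorrelating stages.
`run_pipeline` seeds each stage from the configuration seed, writes a
resolved configuration (JSON) and a deterministic run log without timestamps,
and is byte-identical across reruns of the same configuration. Configuration
merging rejects unknown keys with their dotted paths, so typos fail loudly.

## Repository shape and problem sizes

The package uses the classic R modelling idiom where a fitted object is the
natural unit — `fit_recovery` and `fit_halflife` return classed objects with
`print`, `summary`, `coef`, `predict`, `residuals`, `plot` and `simulate`
methods — and plain functions returning data frames where the natural unit
is a table (classification, risk tables, quintile analyses, aggregation).
Internals are base R plus the imported modelling packages; there is no
tidyverse dependency.

Default problem sizes (2000-cell cohorts, 64×64 images, 200-trace FRAP
calibrations) were chosen so the full test suite and the
`scripts/acceptance.R` rerun complete in minutes on one CPU while keeping
Monte Carlo error well below the tolerances being asserted. Known
limitations: no time-varying hazards or frailty terms, no puncta dissolution,
no spatial image artefacts, and mono-exponential-only kinetics for FRAP and
flux — each a deliberate trade of realism for exactly checkable truth.
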