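# cellfate

Quantitative single-cell analysis of protein aggregation and neuronal fate, for
longitudinal imaging experiments on aggregation-prone proteins such as UBQLN2
in ALS/FTD models. The package covers four measurement pipelines that are
usually scattered across ad-hoc scripts, plus seeded synthetic-data generators
so every analysis can be validated against known ground truth:

- **FRAP granule fluidity** — normalize fluorescence-recovery-after-
  photobleaching traces, fit mono-exponential recovery, and derive the
  biophysics (half-time, diffusion coefficient, apparent viscosity).
- **Puncta classification** — per-cell coefficient of variation (CV) of
  reporter intensity, with a fixed threshold separating diffuse from punctate
  cells, computed from pixel vectors or directly from 16-bit TIFF images.
- **Neurotoxicity survival analysis** — Cox proportional-hazards contrasts of
  death and puncta-formation risk across genotypes, stratified by experiment,
  with expression- and CV-quintile dose analyses and diffuse-vs-punctate
  subgroup contrasts.
- **Autophagic flux** — mono-exponential half-life of a photoconverted
  reporter (optical pulse labeling), with superplot-style nested aggregation
  where n is the number of biological replicates, not wells.

## Models

FRAP recovery is fit as `y(t) = A (1 − exp(−τ t))` on traces normalized so the
pre-bleach mean is 1 and the first post-bleach frame is 0; the half-time is
`t½ = ln 2 / τ`, the diffusion coefficient `D = 0.88 r² / (4 t½)` for a bleach
ROI of radius `r`, and the apparent viscosity follows Einstein–Stokes,
`η = k_B T / (6 π D R)` with a probe Stokes radius `R`.

A cell is called punctate when the population CV (SD/mean over its pixels)
strictly exceeds 0.62. Survival models use `survival::coxph` with the Efron
ties approximation and per-experiment strata; monotone-likelihood
(separation) fits are flagged rather than silently returned. Flux decays are
fit as `y = exp(−k t)` after normalizing hourly intensities to the
photoconversion depth `T1 − T0`, giving half-life `ln 2 / k`.

The generators (`simulate_frap_trace`, `simulate_cell_image`,
`simulate_cohort`, `simulate_decay_trace`) produce data from these same model
families with known parameters, are fully determined by their `seed`
argument, and attach the ground truth so estimators can be checked end to end.

## Worked example

```r
library(cellfate)

# FRAP: simulate a noisy trace with known truth, normalize, fit
trace <- simulate_frap_trace(frap_sim_params(
  mobile_fraction = 0.7, rate = log(2) / 30, noise_sd = 0.02, seed = 101))
fit <- fit_recovery(normalize_frap_trace(trace), granule_id = "g1", genotype = "WT")
fit
#> Mono-exponential FRAP recovery fit
#>   granule: g1 (WT)
#>   mobile fraction A : 0.6994
#>   rate tau          : 0.02278 s^-1
#>   t_half            : 30.43 s
#>   RSS 0.0123 on 37 post-bleach points

phys <- frap_physics(fit, roi_radius_um = 3.7)
c(D = phys$diffusion_um2_s, eta = phys$viscosity_pa_s)
#>          D        eta
#> 0.09897544 0.50980479

# Puncta classification from a simulated image
img <- simulate_cell_image(image_sim_params(
  target_cv = 1.0, puncta_count = 5, read_noise_sd = 10, seed = 7))
cv <- cell_cv(img$reporter[img$mask])
classify_punctate(cv)   # cv = 0.999972
#> [1] "punctate"

# Survival: null cohort, genotype contrasts vs the iRFP control
sim <- simulate_cohort(cohort_sim_params(n_cells = 1500, seed = 9))
rec <- event_records(extract_events(sim$tracks), "death")
fit_cox(rec, reference = "iRFP")
#> Cox proportional hazards contrasts (reference: iRFP)
#>   stratified by stratum
#>   term   n hazard_ratio    ci_low  ci_high         p ...
#>  A282V 232    1.0401402 0.8306817 1.302414 0.7315752
#>  M446R 197    1.0615330 0.8396278 1.342085 0.6177295
#>  P497H 219    1.0914719 0.8692445 1.370513 0.4511237
#>  P497S 209    0.9379646 0.7408985 1.187447 0.5945773
#>  P506T 190    0.9855732 0.7771755 1.249852 0.9045665
#>     WT 217    0.9853183 0.7824732 1.240748 0.8999195

# Flux: half-life with nested (superplot) aggregation, n = experiments
d <- simulate_decay_trace(decay_sim_params(half_life = 10, seed = 3))
aggregate_flux(fit_flux_wells(d, mode = "background-subtracted"))$condition_summary
#>   condition n     mean         sd         sem
#> 1      DMSO 3 10.02052 0.01024641 0.005915766
```

`run_pipeline(pipeline_config(seed = ..., out_dir = ...))` chains these
stages over a simulated cohort and writes all tables (tracks, classification,
risk tables, quintile analyses, flux summaries) plus a resolved configuration
and deterministic run log to disk; reruns with the same configuration are
byte-identical.

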