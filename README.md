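# bgotof

Monte Carlo simulation and timing analysis of Compton-scatter effects on
Cherenkov-based coincidence timing in pixelated BGO TOF-PET detector
modules.

## The problem

BGO has re-emerged as a TOF-PET detector material because its prompt
Cherenkov emission (~17 photons per 511 keV photoelectron) permits fast
time pickoff despite the slow ~300 ns scintillation.  In pixelated arrays,
however, a 511 keV annihilation photon frequently Compton-scatters: energy
may be shared across neighbouring pixels (inter-crystal scatter, *InterCS*)
or deposited at several points inside one pixel (intra-crystal scatter,
*IntraCS*) while the summed energy still falls in the photopeak window.
Because the Cherenkov yield is energy dependent — and the low threshold
(~63 keV at n = 2.2) means even the ~170 keV photon that survives a 180°
backscatter still yields Cherenkov light where it is absorbed — both
crystals of an InterCS event emit prompt light, while the split lowers the
yield at each site.

`bgotof` is for detector physicists who want a transparent, desk-scale
model of this chain: a dual-pixel 2.5 × 2.8 × 15 mm BGO module with two
SiPM channels per crystal, a collimated 511 keV beam on crystal 1, and a
reference detector with 83 ps FWHM jitter.

## The model in brief

* **Gamma transport**: exponential free paths through a tabulated BGO
  attenuation model (analytic Klein–Nishina incoherent part plus an
  E⁻³ photoelectric law anchored to a 0.42 photofraction at 511 keV);
  Klein–Nishina angular sampling; exact energy bookkeeping per history.
* **Optics**: Cherenkov counts Poisson with mean
  N(T) = Y ∫₀ᵀ max(0, 1 − 1/(β²n²)) dT′, calibrated to N(511 keV) = 17
  (N is convex, so splitting a deposit lowers the total yield);
  scintillation 8.2 photons/keV with 300 ns decay; isotropic emission,
  closed-form specular transport to the SiPM face at the group velocity;
  PDE, SPTR and energy-resolution smearing on readout.
* **Event pipeline**: energy-weighted position P = (E₂ − E₁)/(E₂ + E₁)
  classifies photopeak events into FED (P ≤ −0.8), Pene (P ≥ 0.8) and
  InterCS; timestamp strategies
  T_min = min(T₁, T₂),
  T_adap = T₁ if T₁ < T₂ + k else T₂,
  T_EnergyAdap = T₁ if E₁ > E₂ (BWD) else T₂ (FWD);
  prompt photons counted in the first 1 ns per channel with a 300 ps
  inter-channel tolerance.
* **Timing statistics**: FWHM/FWTM by histogram interpolation, margin
  sweeps, asymmetry-binned timing, travel-time order statistics,
  quadrant (energy dominance × timestamp order) fractions, aspect-ratio
  studies of IntraCS prevalence.

See `vignettes/bgo-compton-timing.Rmd` for the full model account,
assumptions and limitations.

## Worked example

```r
library(bgotof)
cfg <- sim_config()                                   # the dual-pixel module
cal <- calibrate_detection_scale(cfg, target = 5.76,  # FED prompt-count anchor
                                 n_events = 2e4, seed = 1)
sim <- simulate_detector(3e5, cal, seed = 1)
cl  <- classify_events(sim)
table(cl$assigned_class)
#>      FED  InterCS     Pene rejected
#>   137278     5415      514   156793

fed <- cl[cl$assigned_class == "FED", ]
ics <- cl[cl$assigned_class == "InterCS", ]
fwhm_fwtm(coincidence_deltas(fed, "min"))
#> FWHM 163.5 / FWTM 326.7 (peak 115.0, n = 137278, bin 10)
fwhm_fwtm(coincidence_deltas(ics, "min"))
#> FWHM 164.6 / FWTM 354.7 (peak 115.0, n = 5415, bin 10)
fwhm_fwtm(coincidence_deltas(ics, "energy"))
#> FWHM 185.8 / FWTM 450.3 (peak 115.0, n = 5415, bin 10)

round(mean(fed$n_prompt), 2); round(mean(ics$n_prompt, na.rm = TRUE), 2)
#> [1] 5.77
#> [1] 3.33
round(fwd_bwd_fractions(ics), 3)
#>   FWD   BWD
#> 0.601 0.399
quadrant_fractions(ics)$discordant
#> [1] 0.291
sweep_k(ics, seq(-300, 300, 50))   # FWHM minimised within one step of k = 0
```

Reading: after anchoring the detection efficiency so full-energy (FED)
events average 5.76 prompt photons, InterCS events — which split the
511 keV between pixels — retain only ~3.3 prompt photons from the crystal
that forms the timestamp.  Their coincidence distribution is visibly
heavier-tailed than FED (FWTM 355 vs 327 ps), the energy-based strategy is
clearly worse than taking the earlier timestamp (186 vs 165 ps FWHM), a
margin sweep confirms k ≈ 0 is optimal, forward scattering slightly
dominates, and ~29% of events are "discordant" (the higher-energy crystal
is not the earlier one) — energy dominance and arrival order decouple in
the photon-starved regime.

Truth-level analyses use the same chain: `truth_label()` exposes
PE/IntraCS/InterCS ground truth, `travel_time_stats()` the photon
order-statistic travel times, `aspect_ratio_study()` the IntraCS fraction
versus crystal pitch, and `intracs_contamination()` the IntraCS share
hiding inside FED-classified events.

A thin CLI over the same functions is installed at
`inst/scripts/bgotof-cli.R`
(`simulate`, `classify`, `ctr`, `sweep-k`, `asymmetry`, `travel-time`,
`aspect-ratio`, `calibrate`).

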