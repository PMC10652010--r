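---
title: "Methods: an isotope-constrained mercury budget for an open peatland"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an isotope-constrained mercury budget for an open peatland}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peatHg)
```

## The problem

Open boreal peatlands receive atmospheric mercury by two pathways: living
vegetation (chiefly *Sphagnum* mosses) assimilates gaseous elemental Hg0,
and rainfall delivers oxidised HgII. Part of the deposited pool is
photochemically reduced at the living surface and re-emitted as Hg0, so
the Hg archived in dated peat is the *net* of gross deposition minus
re-emission (and, optionally, runoff export). peatHg reconstructs that
budget from Hg stable-isotope systematics measured on peat cores, soil
gas, groundwater and the atmosphere.

Two properties of the Hg isotope system make this possible:

* **Even-mass MIF is conservative.** The Δ²⁰⁰Hg anomaly is set in the
  upper atmosphere and is not measurably altered by surface redox
  processing, so a peat sample's Δ²⁰⁰Hg is a faithful mixture of its two
  deposition end-members.
* **Odd-mass MIF records photoreduction.** Photoreduction of HgII bound
  to thiol ligands enriches the product Hg0 in Δ¹⁹⁹Hg, so the residual
  (archived) pool drifts to more negative Δ¹⁹⁹Hg as the loss proceeds.

## Notation

Delta values are standard-sample-bracketing per-mil deviations,
δᴮHg = 1000·(Rₛ/R_std − 1) with R the B/198 ratio. Anomalies subtract the
kinetic mass-dependent prediction, ΔᴮHg = δᴮHg − β·δ²⁰²Hg, with
β = 0.2520, 0.5024, 0.7520, 1.493 for masses 199, 200, 201, 204
(`beta_table()`). Enrichment factors between compartments (ε²⁰², E¹⁹⁹)
are arithmetic differences of compartment means; at per-mil magnitudes
this agrees with the logarithmic definition 1000·(α − 1) to second order,
which is far below analytical precision. Uncertainty on such a difference
is the quadrature of the supplied standard errors — a documented choice,
since reporting conventions for this propagation vary.

## Deposition partitioning (Δ²⁰⁰Hg mass balance)

With end-members Δ²⁰⁰Hg(Hg0) = −0.06 ± 0.02 ‰ (n = 71) and
Δ²⁰⁰Hg(HgII) = 0.16 ± 0.07 ‰ (n = 55) — compiled Northern-Hemisphere
remote-site signatures shipped as presets (`em_preset()`) — the fraction
of peat Hg derived from plant Hg0 uptake solves the linear two-source
balance

α·Δ_Hg0 + θ·Δ_HgII = Δ_sample,  α + θ = 1,

so α = (Δ_HgII − Δ_sample)/(Δ_HgII − Δ_Hg0) (`endmember_fraction()`).
Samples outside the end-member interval return fractions outside [0, 1]
and are flagged rather than silently clamped, so data problems stay
visible. `mixing_monte_carlo()` propagates analytical noise and
end-member dispersion: each draw perturbs the sample and both end-member
means with independent Gaussian noise, and the per-draw α distribution is
summarised by its median and quartiles. Out-of-range draws are clipped to
[0, 1] by default — clipping preserves the draw count and keeps fractions
physical — with `reject` and `keep` policies available because the
handling is a genuine modelling choice. The default draw count is 10⁵ and
a seed is mandatory. When several samples are supplied the simulation
resamples one sample per draw, so the spread reflects between-sample
variability as well as noise; a mean-based mode (`resample = FALSE`)
covers the alternative reading.

The same machinery apportions dissolved gaseous Hg (DGM) in peat
groundwater between peat/groundwater HgII (default Δ²⁰⁰Hg −0.01 ± 0.05 ‰,
the peat grand mean) and rainfall HgII (`run_dgm_mix()`).

## Photoreductive loss (Rayleigh model)

The conservative mixing baseline in (Δ²⁰⁰, Δ¹⁹⁹) space is the straight
line through the two end-member means (`mixing_line_prediction()`): a
deterministic stand-in for a refit of the literature compilation, which
is out of scope here and whose fitted line passes through those means to
within its stated uncertainty. A peat sample's shift below that baseline,
s = Δ¹⁹⁹(observed) − Δ¹⁹⁹(baseline), is interpreted as Rayleigh
distillation of the HgII pool with enrichment magnitude E¹⁹⁹ = 0.49 ‰
(foliar photoreduction of thiol-bound HgII): the fraction remaining is
f = exp(s/E) and the loss is L = 1 − f (`rayleigh_loss_fraction()`). The
sign convention is fixed so that the product Hg0 is Δ¹⁹⁹-enriched and the
residual shift is negative; this is the only sense in which negative peat
anomalies imply a positive loss. Positive shifts are inconsistent with
loss: they are returned as zero loss with a flag (never an exception),
and profile aggregation counts them as zero by default (`"exclude"` is
available). This clipping induces a small upward bias at small true
losses; the recovery tests bound it by numerically integrating the
clipped estimator against the injected noise rather than pretending it
away.

Per-core, `profile_loss()` averages slice losses over a period and
converts to fluxes against the period's net accumulation:
gross = net/(1 − L̄) and loss flux = net·L̄/(1 − L̄). Expressing the loss
relative to *gross* deposition is inferred from the budget arithmetic of
the study system (a 4.4 flux out of 17.1 gross at net 12.7) rather than
stated anywhere as a formula, and is therefore documented here as the
package's reading. `deposition_budget()` then splits gross deposition by
α/θ and closes by construction:
uptake + rainfall − loss − runoff − net = 0. Runoff export (a catchment
constant, default `degero_runoff_flux` = 1.6 µg m⁻² yr⁻¹) defaults to 0
in the budget so that gross = net/(1 − L̄) holds against the measured
archive; enabling it moves the residual net line, not the gross estimate.

## Accumulation chronology

`hg_accumulation_rate()` is concentration × density × thickness / age
interval (ng cm⁻² yr⁻¹, ×10 to µg m⁻² yr⁻¹). Depths are cm below the
living surface, positive downward; ages are calendar years CE. External
age-depth output is consumed as control points
(`age_depth_model()`/`interpolate_ages()`, piecewise linear, no
extrapolation); radiocarbon calibration and Bayesian age modelling are
out of scope. Period means are time-weighted — each slice weighted by the
years it overlaps the period, boundary slices split pro-rata — because
slice-count weighting would let slice thickness leak into the flux
estimate; the unweighted mean and sd are reported alongside. The sd is
measurement scatter only; an age-ensemble component would require the
age model's posterior, which the control-point interface does not carry.

## Gas–water exchange diagnostics

`fick_flux()` computes the diffusive Hg0 flux across the
atmosphere/unsaturated-peat interface, positive downward:
F = D_eff·(c_atm − c_soil)/ℓ, converted to ng m⁻² d⁻¹. The effective
diffusivity applies a pluggable tortuosity correction, by default a
Millington–Quirk power law D_eff = D_air·φₐ^(10/3)/φ_t²; the defaults
(D_air = 1.2×10⁻⁵ m² s⁻¹, φ = 0.9, ℓ = 0.2 m) are documented,
order-of-magnitude values for a drained *Sphagnum* acrotelm, and every
generated report echoes the parameter set used so no default is silent.
The flux is a potential-gradient diagnostic, not a measured evasion rate;
convective flow and plant-mediated transport are explicitly outside it.

`henry_saturation()` expresses a water sample's DGM against the
equilibrium concentration implied by a gas phase:
saturation % = 100·c_water·H_cc/c_gas, with H_cc the dimensionless
gas/water partition ratio. The default H_cc = 0.25 is the
two-significant-figure value appropriate for Hg0 near boreal summer water
temperatures, and it is the unique such value jointly consistent with
both observed saturation levels of the study system (77 ng m⁻³ aqueous
against 1.31 and 0.45 ng m⁻³ gives 1500 % and 4300 %); it is a plain
argument wherever it appears, so temperature-specific values drop in.
`gradient_summary()` provides per-compartment means, sds and Welch
two-sample comparisons.

## York regression

Fractionation trajectories and mixing lines are fitted with the York
errors-in-both-variables model (`york_fit()`): iteratively reweighted
with W = wₓw_y/(wₓ + b²w_y − 2br√(wₓw_y)), converged when successive
slopes agree to 10⁻¹⁰, standard errors from the adjusted-point analytic
expressions, goodness of fit as MSWD = S/(n − 2). Per-point x–y error
correlation defaults to 0 (nothing in the application suggests
otherwise). Zero uncertainties are floored at 10⁻⁸ of the coordinate
scale and flagged, since exact zeros break the weight algebra. The
confidence band (`confidence_band()`) uses the asymptotic
slope–intercept covariance with normal quantiles; it is narrowest at the
weighted centroid and the construction is a documented package choice, as
band conventions differ across implementations. Robust variants and
Bayesian line fitting are non-goals.

## The forward simulator

`generate_core()` builds a core downward from the surface: slice
duration = density × thickness / peat-mass accumulation rate; gross
deposition follows a piecewise history; the archived concentration is
back-computed so the slice's accumulation rate equals gross×(1 − L);
true Δ²⁰⁰Hg is the α-mixture of the end-members, true Δ¹⁹⁹Hg the mixing
baseline plus the Rayleigh shift E·ln(1 − L); observations add
independent Gaussian noise with σ = (2σ)/2 at the procedural-standard
precisions (δ²⁰² 0.17 ‰, Δ¹⁹⁹ 0.13 ‰, Δ²⁰⁰ 0.08 ‰, all 2σ).
Cross-isotope error correlations are not modelled (none are reported),
the loss is constant within a period, and peat decomposition, compaction
and water-table dynamics are not simulated — so recovery tests
demonstrate correctness of the estimators under the model's own
assumptions, not robustness to real-core violations of them. Default
scenario: a hummock with gross deposition 4 → 12 → 30 → 20 µg m⁻² yr⁻¹
over pre-1800 / 1800–1950 / 1950–2000 / 2000–2020, α = 0.73, L = 0.28,
density 0.05 ± 0.01 g cm⁻³, mass accumulation 0.036 g cm⁻² yr⁻¹ — the
observed magnitudes for such systems. The end-member Δ¹⁹⁹ means
(−0.21 ‰ for Hg0, +0.33 ‰ for rainfall HgII) are representative remote
Northern-Hemisphere values chosen once for the baseline; only their
difference-to-Δ²⁰⁰ ratio enters the loss estimate.
`generate_gas_water()` draws gas compartments at the observed means
(atmosphere 1.31 ± 0.17, soil gas ≈ 0.45 ± 0.12 ng m⁻³) and a DGM
profile peaking just below the water table and declining exponentially.
`simulate_scenario()` writes observation CSVs and a separate
`truth.json`; latent values never enter the observation schema.

## Reproducibility and test scale

Every stochastic stage takes an explicit seed, and pipeline reports embed
the full analytic configuration plus its MD5 fingerprint, so identical
configs give byte-identical reports. The test suite exercises parameter
recovery on 100 simulated cores (~80 isotope-bearing slices each over
1800–2020), 500-replicate York coverage checks at n = 5, and Monte Carlo
mixing at 2×10⁴–5×10⁴ draws — sizes chosen to give stable statistics in
seconds on a single CPU. Recovery bounds are derived from the injected
noise (per-slice σ propagated through the estimator, plus the
numerically integrated clipping bias), not tuned constants.

## Known limitations

* The Δ¹⁹⁹ baseline uses the line through the end-member means, not a
  refit of the underlying literature compilation; the difference is
  within the compilation's stated scatter but cannot be verified without
  it.
* Loss-flux uncertainty propagates the slice-loss sd only; age-model and
  density uncertainties are not folded in.
* The Fick flux depends linearly on poorly constrained transport
  parameters (tortuosity, path length); treat its magnitude as an order
  estimate and rely on its sign and the isotope trajectories for process
  inference.
* Three-or-more end-member unmixing, Bayesian mixing models, Δ²⁰¹-based
  process discrimination and mechanistic photochemical kinetics are out
  of scope.
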