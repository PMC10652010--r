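# peatHg

Isotope-constrained mercury budgets for peatlands.

Open boreal peatlands take up atmospheric mercury by two routes — living
*Sphagnum* assimilates gaseous elemental Hg⁰, and rainfall delivers
oxidised Hgᴵᴵ — and lose part of it again when photoreduction at the
living surface re-emits Hg⁰. What the dated peat archive records is only
the net of that exchange. peatHg reconstructs the full budget from Hg
stable-isotope systematics, for biogeochemists working with peat-core,
soil-gas and groundwater Hg data.

The package implements:

* **δ/Δ arithmetic** — bracketing-standard δ values, mass-independent
  anomalies Δᴮ = δᴮ − β·δ²⁰² (β = 0.2520/0.5024/0.7520/1.493 for masses
  199/200/201/204), enrichment factors between compartments.
* **Deposition partitioning** — the conservative even-mass anomaly Δ²⁰⁰Hg
  solves the two-source balance α·Δ_Hg⁰ + θ·Δ_HgII = Δ_sample, α + θ = 1,
  between the compiled end-members (−0.06 ± 0.02 ‰ for atmospheric Hg⁰,
  0.16 ± 0.07 ‰ for rainfall HgII), with Monte Carlo uncertainty
  propagation and quartile reporting.
* **Photoreductive loss** — the shift of peat Δ¹⁹⁹Hg below the
  conservative mixing baseline, read as Rayleigh distillation with
  E¹⁹⁹ = 0.49 ‰: fraction remaining f = exp(shift/E), loss L = 1 − f;
  gross deposition = net accumulation / (1 − L̄), and a closed budget
  table (uptake + rainfall − loss − runoff − net = 0).
* **Peat chronology** — accumulation rates
  (concentration × density × thickness / age interval, µg m⁻² yr⁻¹) and
  time-weighted period means from dated slices.
* **Gas–water exchange** — Fick diffusive Hg⁰ fluxes with pluggable
  tortuosity models, Henry-law saturation of dissolved gaseous Hg
  (saturation % = 100·c_water·H_cc/c_gas, default H_cc = 0.25), Welch
  compartment comparisons.
* **York regression** — errors-in-both-variables line fits with analytic
  standard errors, MSWD and confidence bands, for fractionation
  trajectories and mixing lines.
* **A forward simulator** — synthetic cores and gas/water samples with
  known truth (deposition history, mixing fraction, loss fraction,
  analytical noise at the procedural-standard 2σ precisions), so every
  estimator is covered by parameter-recovery tests.

## Worked example

Simulate a hummock scenario (gross deposition rising from 4 to a
late-20th-century peak of 30 µg m⁻² yr⁻¹, α = 0.73, 28 % photoreductive
loss, realistic analytical noise), then run the budget pipeline blind on
the emitted observations:

```r
library(peatHg)

dir <- tempfile()
paths <- simulate_scenario(scenario_config(seed = 42), dir)
rep <- run_budget(list(core_csv = paths[["core"]], period = c(1800, 2020)))
rep$budget
#>             component      flux
#> 1    gross_deposition 16.416117
#> 2          hg0_uptake 12.107153
#> 3       rainfall_hgII  4.308964
#> 4 photoreduction_loss  4.327258
#> 5       runoff_export  0.000000
#> 6    net_accumulation 12.088859
```

The recovered mixing fraction is α = 0.738 (truth 0.73) and the mean
photoreductive loss 26.4 % ± 14.4 % (truth 28 %): the archive kept
12.1 of the 16.4 µg m⁻² yr⁻¹ gross deposition, the rest returned to the
atmosphere as Hg⁰.

Saturation of groundwater dissolved gaseous Hg (77 ng m⁻³ aqueous)
against the atmosphere (1.31 ng m⁻³) and the soil gas (0.45 ng m⁻³):

```r
signif(henry_saturation(77, 1.31), 2)  # 1500 (%)
signif(henry_saturation(77, 0.45), 2)  # 4300 (%)
```

Monte Carlo apportionment of that DGM between peat-groundwater HgII
(Δ²⁰⁰Hg −0.01 ± 0.05 ‰) and rainfall HgII:

```r
mixing_monte_carlo(0.078, 0.04,
                   end_member("peat groundwater HgII", -0.01, 0.05),
                   em_preset("nh_rainfall_hgII"),
                   n_draws = 1e5, seed = 42)
#> <mixing_result> monte_carlo
#>   median alpha: 0.493  (n_draws = 100000, seed = 42)
#>   percentiles: p25 = 0.229  p50 = 0.493  p75 = 0.721
```

i.e. about half of the dissolved gaseous Hg derives from the
peat-groundwater pool, with wide quartiles reflecting the overlapping
end-member signatures.

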