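Package: peatHg
Title: Isotope-Constrained Mercury Budgets for Peatlands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build an isotope-constrained atmospheric mercury budget
    for an open peatland. Partitions total Hg deposition between plant uptake
    of gaseous elemental Hg(0) and rainfall Hg(II) using a two-end-member
    Delta-200-Hg mass balance with Monte Carlo uncertainty, quantifies
    photoreductive Hg(0) re-emission from the Delta-199-Hg shift of peat
    relative to the atmospheric mixing baseline with a Rayleigh fractionation
    model, derives peat Hg accumulation rates from dated core slices, and
    characterises atmosphere-soil-gas-groundwater Hg(0) exchange with Fick
    diffusion fluxes, Henry-law saturation levels and York errors-in-variables
    regression. A forward simulator generates synthetic cores and gas/water
    samples with known truth so that every stage supports parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
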