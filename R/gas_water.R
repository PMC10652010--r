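#' Transport parameters for diffusive Hg0 exchange
#'
#' Parameters of the Fick's-law flux across the atmosphere/unsaturated-peat
#' interface and the Henry-law gas/water partition.
#'
#' @param D_air Free-air diffusivity of Hg0, m2 s-1 (default 1.2e-5, a
#'   typical ambient-temperature value).
#' @param porosity Air-filled porosity of the peat, dimensionless in (0, 1].
#' @param tortuosity_model Effective-diffusivity correction:
#'   `"millington_quirk"` (default) uses `D_eff = D_air * porosity^(10/3) /
#'   total_porosity^2`; `"power"` uses `D_air * porosity^power`; `"none"`
#'   applies no correction.
#' @param total_porosity Total porosity for the Millington-Quirk form
#'   (default equal to `porosity`, i.e. fully drained pores).
#' @param power Exponent for the `"power"` model (default 4/3).
#' @param path_length Diffusion path length, m.
#' @param H_cc Dimensionless Henry partition expressed as the gas/water
#'   concentration ratio at equilibrium (default 0.25, appropriate for Hg0
#'   near boreal summer water temperatures).
#' @return Object of class `transport_params`.
#' @export
transport_params <- function(D_air = 1.2e-5, porosity = 0.9,
                             tortuosity_model = c("millington_quirk",
                                                  "power", "none"),
                             total_porosity = porosity, power = 4 / 3,
                             path_length = 0.2, H_cc = 0.25) {
  tortuosity_model <- match.arg(tortuosity_model)
  if (D_air <= 0 || path_length <= 0 || H_cc <= 0) {
    stop("D_air, path_length and H_cc must be positive", call. = FALSE)
  }
  if (porosity <= 0 || porosity > 1 || total_porosity <= 0 ||
      total_porosity > 1 || porosity > total_porosity + 1e-12) {
    stop("porosities must lie in (0, 1] with air-filled <= total",
         call. = FALSE)
  }
  structure(list(D_air = D_air, porosity = porosity,
                 tortuosity_model = tortuosity_model,
                 total_porosity = total_porosity, power = power,
                 path_length = path_length, H_cc = H_cc),
            class = "transport_params")
}

#' Effective diffusivity under the configured tortuosity model
#'
#' @param params [transport_params()].
#' @return Effective diffusivity, m2 s-1.
#' @export
effective_diffusivity <- function(params) {
  stopifnot(inherits(params, "transport_params"))
  switch(params$tortuosity_model,
    millington_quirk = params$D_air * params$porosity^(10 / 3) /
      params$total_porosity^2,
    power = params$D_air * params$porosity^params$power,
    none = params$D_air)
}

#' Fick's-law diffusive Hg0 flux across the soil-atmosphere interface
#'
#' `flux = D_eff * (c_atm - c_soil) / path_length`, converted from per
#' second to per day. Positive flux is downward (atmosphere into soil gas),
#' the sense observed when dark oxidation depletes soil-gas Hg0 below the
#' overlying atmosphere.
#'
#' @param c_atm Atmospheric Hg0 concentration, ng m-3.
#' @param c_soil Soil-gas Hg0 concentration, ng m-3.
#' @param params [transport_params()].
#' @return Flux in ng m-2 d-1, positive downward.
#' @export
#' @examples
#' fick_flux(1.31, 0.45, transport_params())
fick_flux <- function(c_atm, c_soil, params = transport_params()) {
  stopifnot(inherits(params, "transport_params"))
  if (any(c_atm < 0) || any(c_soil < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  D_eff <- effective_diffusivity(params)
  86400 * D_eff * (c_atm - c_soil) / params$path_length
}

#' Henry-law saturation of dissolved gaseous Hg0
#'
#' The equilibrium aqueous Hg0 concentration against a gas phase at
#' `c_gas` is `c_gas / H_cc` (with `H_cc` the dimensionless gas/water
#' partition ratio), so the saturation level of a water sample is
#' `100 * c_water * H_cc / c_gas` percent; 100% is equilibrium and values
#' above it indicate supersaturation sustained by in-situ Hg0 production.
#'
#' @param c_water Dissolved gaseous Hg concentration, ng m-3 of the aqueous
#'   phase (1 pg L-1 = 1 ng m-3).
#' @param c_gas Gas-phase Hg0 concentration, ng m-3.
#' @param H_cc Dimensionless gas/water partition ratio (default 0.25).
#' @return Saturation in percent (vectorised).
#' @export
#' @examples
#' henry_saturation(77, 1.31)  # ~1500 %
#' henry_saturation(77, 0.45)  # ~4300 %
henry_saturation <- function(c_water, c_gas, H_cc = 0.25) {
  if (any(c_gas <= 0)) stop("gas-phase concentration must be positive",
                            call. = FALSE)
  if (H_cc <= 0) stop("H_cc must be positive", call. = FALSE)
  if (any(c_water < 0)) stop("c_water must be non-negative", call. = FALSE)
  100 * c_water * H_cc / c_gas
}

#' Construct gas-phase Hg0 sample records
#'
#' @param compartment One of `"atmosphere"`, `"soil_gas_hummock"`,
#'   `"soil_gas_lawn"` per sample.
#' @param conc Hg0 concentration, ng m-3 (>= 0).
#' @param date Optional sampling date.
#' @return data.frame of class `gas_samples`.
#' @export
gas_samples <- function(compartment, conc, date = NA) {
  valid <- c("atmosphere", "soil_gas_hummock", "soil_gas_lawn")
  if (!all(compartment %in% valid)) {
    stop("compartment must be one of: ", paste(valid, collapse = ", "),
         call. = FALSE)
  }
  if (any(conc < 0)) stop("concentrations must be non-negative", call. = FALSE)
  structure(data.frame(compartment = compartment, conc = conc, date = date),
            class = c("gas_samples", "data.frame"))
}

#' Per-compartment concentration summary with pairwise comparisons
#'
#' Descriptive statistics (mean, sd, n) for each gas compartment plus
#' Welch two-sample t comparisons between every compartment pair.
#'
#' @param samples [gas_samples()] data.frame (columns `compartment`,
#'   `conc`).
#' @param compartments Compartments required to be present (default: those
#'   observed).
#' @return List with `stats` (data.frame compartment/mean/sd/n) and
#'   `comparisons` (data.frame pair/difference/p_value).
#' @export
gradient_summary <- function(samples, compartments = NULL) {
  stopifnot(is.data.frame(samples),
            all(c("compartment", "conc") %in% names(samples)))
  if (is.null(compartments)) compartments <- unique(samples$compartment)
  groups <- lapply(compartments, function(k) {
    samples$conc[samples$compartment == k]
  })
  names(groups) <- compartments
  empty <- vapply(groups, length, integer(1)) == 0L
  if (any(empty)) {
    stop("empty compartment(s): ",
         paste(compartments[empty], collapse = ", "), call. = FALSE)
  }
  stats_df <- data.frame(
    compartment = compartments,
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, function(g) if (length(g) > 1L) stats::sd(g) else 0,
                numeric(1)),
    n = vapply(groups, length, integer(1)),
    row.names = NULL)
  comps <- NULL
  if (length(compartments) > 1L) {
    pairs <- utils::combn(compartments, 2L, simplify = FALSE)
    comps <- do.call(rbind, lapply(pairs, function(p) {
      a <- groups[[p[1L]]]; b <- groups[[p[2L]]]
      pval <- if (length(a) > 1L && length(b) > 1L &&
                  (stats::sd(a) > 0 || stats::sd(b) > 0)) {
        stats::t.test(a, b)$p.value
      } else NA_real_
      data.frame(pair = paste(p, collapse = " vs "),
                 difference = mean(a) - mean(b), p_value = pval)
    }))
  }
  list(stats = stats_df, comparisons = comps)
}

#' Read gas / water sample CSVs
#'
#' Gas schema: `compartment`, `conc_ng_m3`, optional `date` and isotope
#' columns. Water schema: `depth_below_wt_cm`, `dgm_pg_L`, optional isotope
#' columns (1 pg L-1 is numerically 1 ng m-3 of the aqueous phase).
#'
#' @param path CSV path.
#' @return For gas, a [gas_samples()] data.frame; for water, a data.frame
#'   with `depth_below_wt` (cm) and `dgm` (pg L-1).
#' @export
read_gas_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("compartment", "conc_ng_m3"), names(df))
  if (length(missing)) {
    stop("gas CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- gas_samples(df$compartment, df$conc_ng_m3,
                     date = if ("date" %in% names(df)) df$date else NA)
  extra <- setdiff(names(df), c("compartment", "conc_ng_m3", "date"))
  for (col in extra) out[[col]] <- df[[col]]
  out
}

#' @rdname read_gas_csv
#' @export
read_water_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("depth_below_wt_cm", "dgm_pg_L"), names(df))
  if (length(missing)) {
    stop("water CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$dgm_pg_L < 0)) stop("DGM concentrations must be non-negative",
                                 call. = FALSE)
  names(df)[names(df) == "depth_below_wt_cm"] <- "depth_below_wt"
  names(df)[names(df) == "dgm_pg_L"] <- "dgm"
  df
}
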