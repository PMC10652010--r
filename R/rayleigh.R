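#' Rayleigh fractionation parameters for foliar photoreduction
#'
#' Photochemical reduction of thiol-bound HgII at the vegetation surface
#' preferentially exports odd-mass isotopes in the product Hg0, leaving the
#' residual HgII pool depleted in Delta-199-Hg. The magnitude of the
#' odd-MIF enrichment factor for this pathway is E199 = 0.49 per mil; the
#' sign convention is fixed so that the residual (peat) pool shifts
#' negative as the loss proceeds.
#'
#' @param E199 Enrichment magnitude, per mil (> 0). Default 0.49.
#' @return Object of class `rayleigh_params`.
#' @export
rayleigh_params <- function(E199 = 0.49) {
  if (!is.finite(E199) || E199 <= 0) {
    stop("E199 must be a positive enrichment magnitude (per mil)",
         call. = FALSE)
  }
  structure(list(E199 = E199, sense = "product_enriched"),
            class = "rayleigh_params")
}

#' Photoreductive loss fraction from a Delta-199-Hg shift
#'
#' Under Rayleigh distillation of a shrinking HgII pool the residual
#' anomaly obeys `shift = E199 * ln(f)` with `f` the fraction of Hg
#' remaining, so `f = exp(shift / E199)` and the loss is `1 - f`. Shifts
#' are observed-minus-baseline and must be non-positive for a loss to be
#' inferred; positive shifts are returned as zero loss with a flag rather
#' than raising, so profile-level aggregation can apply its own policy.
#'
#' @param shift_D199 Observed minus baseline Delta-199-Hg, per mil
#'   (vectorised).
#' @param params [rayleigh_params()].
#' @return List with `loss` (fraction of gross deposition lost),
#'   `f_remaining`, and `flagged` (logical, TRUE where the shift was
#'   positive and therefore inconsistent with loss).
#' @export
#' @examples
#' rayleigh_loss_fraction(-0.16)$loss  # 0.2786
rayleigh_loss_fraction <- function(shift_D199, params = rayleigh_params()) {
  stopifnot(inherits(params, "rayleigh_params"))
  flagged <- shift_D199 > 0
  shift <- pmin(shift_D199, 0)
  f <- exp(shift / params$E199)
  list(loss = 1 - f, f_remaining = f, flagged = flagged)
}

#' Profile-wide photoreductive loss and flux
#'
#' For every dated slice in a period that carries Delta-199 and Delta-200
#' values, the conservative deposition baseline Delta-199-Hg is predicted
#' from the slice's Delta-200-Hg via [mixing_line_prediction()]; the shift
#' of the observed value below that baseline is converted to a per-slice
#' loss fraction by [rayleigh_loss_fraction()]. Losses are averaged over
#' slices and the mean loss is converted to a flux against the period's net
#' accumulation: `loss_flux = net * L / (1 - L)`, i.e. losses are expressed
#' relative to gross deposition `gross = net / (1 - L)`.
#'
#' @param profile [core_profile()] whose slices carry isotopes.
#' @param em_hg0,em_hgII Deposition [end_member()] objects.
#' @param params [rayleigh_params()].
#' @param period `c(start_CE, end_CE)`.
#' @param positive_shift `"zero"` (default) counts flagged slices as zero
#'   loss; `"exclude"` drops them from the aggregate.
#' @return Object of class `rayleigh_result`: `per_sample_loss`,
#'   `mean_loss`, `sd_loss`, `n`, `n_flagged`, `net_flux`, `loss_flux`,
#'   `sd_loss_flux`, `gross_deposition` (fluxes ug m-2 yr-1), `period`.
#' @export
profile_loss <- function(profile, em_hg0, em_hgII,
                         params = rayleigh_params(), period,
                         positive_shift = c("zero", "exclude")) {
  positive_shift <- match.arg(positive_shift)
  stopifnot(inherits(profile, "core_profile"))
  lo <- vapply(profile$slices, `[[`, numeric(1), "age_bottom")
  hi <- vapply(profile$slices, `[[`, numeric(1), "age_top")
  has_iso <- vapply(profile$slices, function(s) {
    !is.null(s$isotopes) && !is.na(s$isotopes$D199) && !is.na(s$isotopes$D200)
  }, logical(1))
  keep <- has_iso & pmin(hi, period[2L]) > pmax(lo, period[1L])
  if (!any(keep)) {
    stop("no slice with isotope data overlaps the requested period",
         call. = FALSE)
  }
  D199 <- vapply(profile$slices[keep], function(s) s$isotopes$D199, numeric(1))
  D200 <- vapply(profile$slices[keep], function(s) s$isotopes$D200, numeric(1))
  baseline <- mixing_line_prediction(D200, em_hg0, em_hgII)
  shift <- D199 - baseline
  rl <- rayleigh_loss_fraction(shift, params)
  loss <- rl$loss
  if (positive_shift == "exclude" && any(rl$flagged)) {
    loss <- loss[!rl$flagged]
  }
  if (!length(loss)) {
    stop("all slices flagged (positive shifts) and excluded", call. = FALSE)
  }
  mean_loss <- mean(loss)
  sd_loss <- if (length(loss) > 1L) stats::sd(loss) else 0
  flux <- period_mean_flux(profile, period)
  net <- flux$mean
  loss_flux <- net * mean_loss / (1 - mean_loss)
  # first-order error propagation of the loss-fraction sd through L/(1-L)
  sd_loss_flux <- net * sd_loss / (1 - mean_loss)^2
  structure(list(per_sample_loss = loss,
                 shifts = shift, flagged = rl$flagged,
                 mean_loss = mean_loss, sd_loss = sd_loss,
                 n = length(loss), n_flagged = sum(rl$flagged),
                 net_flux = net,
                 loss_flux = loss_flux, sd_loss_flux = sd_loss_flux,
                 gross_deposition = net / (1 - mean_loss),
                 period = period),
            class = "rayleigh_result")
}

#' @export
print.rayleigh_result <- function(x, ...) {
  cat(sprintf("<rayleigh_result> %d slices, %s-%s CE\n",
              x$n, format(x$period[1L]), format(x$period[2L])))
  cat(sprintf("  mean loss: %.1f%% ± %.1f%%  (%d positive-shift slices flagged)\n",
              100 * x$mean_loss, 100 * x$sd_loss, x$n_flagged))
  cat(sprintf("  net %.1f, loss %.1f ± %.1f, gross %.1f ug m-2 yr-1\n",
              x$net_flux, x$loss_flux, x$sd_loss_flux, x$gross_deposition))
  invisible(x)
}

#' Deposition budget table
#'
#' Splits gross atmospheric deposition into plant Hg0 uptake and rainfall
#' HgII input by the mixing fraction alpha, and lists photoreductive
#' re-emission, optional runoff export, and the net accumulation residual.
#' The budget closes by construction:
#' `uptake + rainfall - loss - runoff - net = 0`.
#'
#' @param rayleigh [profile_loss()] result (supplies gross deposition and
#'   loss flux).
#' @param mixing [endmember_fraction()] or [mixing_monte_carlo()] result
#'   (supplies alpha); a plain numeric alpha is also accepted.
#' @param runoff Runoff export flux, ug m-2 yr-1 (default 0; see
#'   [degero_runoff_flux]).
#' @param period Optional period consistency check against
#'   `rayleigh$period`.
#' @return Object of class `hg_budget`: data.frame with columns `component`
#'   and `flux` (ug m-2 yr-1) plus attributes `alpha` and `period`.
#' @export
deposition_budget <- function(rayleigh, mixing, runoff = 0, period = NULL) {
  stopifnot(inherits(rayleigh, "rayleigh_result"))
  alpha <- if (is.numeric(mixing)) mixing else {
    stopifnot(inherits(mixing, "mixing_result"))
    mean(mixing$alpha)
  }
  if (!is.null(period) && !isTRUE(all.equal(period, rayleigh$period))) {
    stop("budget period does not match the Rayleigh result's period",
         call. = FALSE)
  }
  gross <- rayleigh$gross_deposition
  loss <- rayleigh$loss_flux
  uptake <- alpha * gross
  rainfall <- (1 - alpha) * gross
  net <- gross - loss - runoff
  tab <- data.frame(
    component = c("gross_deposition", "hg0_uptake", "rainfall_hgII",
                  "photoreduction_loss", "runoff_export", "net_accumulation"),
    flux = c(gross, uptake, rainfall, loss, runoff, net))
  structure(tab, class = c("hg_budget", "data.frame"),
            alpha = alpha, period = rayleigh$period)
}

#' @export
print.hg_budget <- function(x, ...) {
  cat(sprintf("<hg_budget> alpha = %.2f, %s-%s CE (ug m-2 yr-1)\n",
              attr(x, "alpha"), format(attr(x, "period")[1L]),
              format(attr(x, "period")[2L])))
  print.data.frame(data.frame(component = x$component,
                              flux = round(x$flux, 2)), row.names = FALSE)
  invisible(x)
}

#' Default runoff export flux for the study peatland
#'
#' Catchment mass-balance estimate of dissolved Hg export with runoff,
#' 1.6 +/- 0.2 ug m-2 yr-1, supplied as an optional budget line.
#'
#' @format Numeric scalar, ug m-2 yr-1.
#' @export
degero_runoff_flux <- 1.6
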