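#' Define a deposition end-member
#'
#' An end-member is a source pool with a conserved isotope signature.
#' Even-mass Delta-200-Hg is used to separate atmospheric Hg0 (taken up by
#' plants) from rainfall HgII because it is not altered by surface redox
#' processing; Delta-199-Hg and d202 means may be attached for mixing-line
#' prediction in the odd-MIF dimension.
#'
#' @param name Source name.
#' @param D200_mean,D200_sd Delta-200-Hg mean and 1-sigma, per mil.
#' @param D199_mean,D199_sd Optional Delta-199-Hg mean and 1-sigma, per mil.
#' @param d202_mean,d202_sd Optional d202 mean and 1-sigma, per mil.
#' @param n Number of compiled observations behind the mean.
#' @return Object of class `end_member`.
#' @export
end_member <- function(name, D200_mean, D200_sd,
                       D199_mean = NA_real_, D199_sd = NA_real_,
                       d202_mean = NA_real_, d202_sd = NA_real_,
                       n = 1L) {
  sds <- c(D200_sd, D199_sd, d202_sd)
  if (any(sds < 0, na.rm = TRUE)) {
    stop("end-member standard deviations must be non-negative", call. = FALSE)
  }
  if (n < 1L) stop("end-member n must be >= 1", call. = FALSE)
  structure(list(name = name,
                 D200_mean = D200_mean, D200_sd = D200_sd,
                 D199_mean = D199_mean, D199_sd = D199_sd,
                 d202_mean = d202_mean, d202_sd = d202_sd,
                 n = as.integer(n)),
            class = "end_member")
}

#' @export
print.end_member <- function(x, ...) {
  cat(sprintf("<end_member> %s: D200 = %.2f ± %.2f‰ (n = %d)\n",
              x$name, x$D200_mean, x$D200_sd, x$n))
  invisible(x)
}

#' Built-in Northern-Hemisphere deposition end-members
#'
#' Compiled remote-site signatures used as deposition end-members:
#' atmospheric Hg0 with Delta-200-Hg = -0.06 +/- 0.02 per mil (1-sigma,
#' n = 71) and rainfall HgII with 0.16 +/- 0.07 per mil (n = 55). The
#' Delta-199-Hg means attached here (-0.21 +/- 0.06 and +0.33 +/- 0.12 per
#' mil) are representative remote Northern-Hemisphere values used to place
#' the mixing baseline in the odd-MIF dimension.
#'
#' @param name `"nh_atmospheric_hg0"` or `"nh_rainfall_hgII"`.
#' @return [end_member()].
#' @export
#' @examples
#' em_preset("nh_atmospheric_hg0")
em_preset <- function(name = c("nh_atmospheric_hg0", "nh_rainfall_hgII")) {
  name <- match.arg(name)
  switch(name,
    nh_atmospheric_hg0 = end_member(
      "NH atmospheric Hg0", D200_mean = -0.06, D200_sd = 0.02,
      D199_mean = -0.21, D199_sd = 0.06,
      d202_mean = 0.5, d202_sd = 0.3, n = 71L),
    nh_rainfall_hgII = end_member(
      "NH rainfall HgII", D200_mean = 0.16, D200_sd = 0.07,
      D199_mean = 0.33, D199_sd = 0.12,
      d202_mean = -0.4, d202_sd = 0.4, n = 55L))
}

#' Load an end-member from a YAML/JSON config block
#'
#' Config fields: `name`, `D200_mean`, `D200_sd`, optional `D199_mean`,
#' `D199_sd`, `d202_mean`, `d202_sd`, `n`. A character scalar naming a
#' preset (see [em_preset()]) is accepted as shorthand.
#'
#' @param x Named list (parsed config) or preset name.
#' @return [end_member()].
#' @export
end_member_from_config <- function(x) {
  if (is.character(x) && length(x) == 1L) return(em_preset(x))
  if (inherits(x, "end_member")) return(x)
  stopifnot(is.list(x))
  end_member(name = x[["name"]] %||% "end-member",
             D200_mean = x[["D200_mean"]], D200_sd = x[["D200_sd"]] %||% 0,
             D199_mean = x[["D199_mean"]] %||% NA_real_,
             D199_sd = x[["D199_sd"]] %||% NA_real_,
             d202_mean = x[["d202_mean"]] %||% NA_real_,
             d202_sd = x[["d202_sd"]] %||% NA_real_,
             n = x[["n"]] %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-end-member deposition fraction from Delta-200-Hg
#'
#' Solves the two-source mass balance
#' `alpha * D200_Hg0 + theta * D200_HgII = D200_sample` with
#' `alpha + theta = 1` for the fraction alpha of Hg derived from plant
#' uptake of atmospheric Hg0 (theta is the rainfall-HgII fraction). Samples
#' outside the end-member interval yield fractions outside `[0, 1]`; these
#' are returned as-is and flagged.
#'
#' @param sample_D200 Sample Delta-200-Hg, per mil (vectorised).
#' @param em_hg0,em_hgII [end_member()] objects for atmospheric Hg0 and
#'   rainfall HgII.
#' @param tol End-members closer than this are considered coincident.
#' @return Object of class `mixing_result`: list with `alpha`, `theta`,
#'   `out_of_range` (logical), and `method = "point"`.
#' @export
#' @examples
#' endmember_fraction(-0.01, em_preset("nh_atmospheric_hg0"),
#'                    em_preset("nh_rainfall_hgII"))$alpha  # 0.773
endmember_fraction <- function(sample_D200, em_hg0, em_hgII, tol = 1e-9) {
  stopifnot(inherits(em_hg0, "end_member"), inherits(em_hgII, "end_member"))
  denom <- em_hgII$D200_mean - em_hg0$D200_mean
  if (abs(denom) <= tol) {
    stop("end-member D200 means coincide: mixture is unidentifiable",
         call. = FALSE)
  }
  alpha <- (em_hgII$D200_mean - sample_D200) / denom
  structure(list(alpha = alpha, theta = 1 - alpha,
                 out_of_range = alpha < 0 | alpha > 1,
                 method = "point"),
            class = "mixing_result")
}

#' @export
print.mixing_result <- function(x, ...) {
  cat("<mixing_result>", x$method, "\n")
  if (identical(x$method, "point")) {
    cat(sprintf("  alpha (Hg0 fraction): %s\n",
                paste(sprintf("%.3f", x$alpha), collapse = ", ")))
  } else {
    cat(sprintf("  median alpha: %.3f  (n_draws = %d, seed = %d)\n",
                x$alpha, x$n_draws, x$seed))
    cat("  percentiles:",
        paste(sprintf("p%s = %.3f", names(x$percentiles), x$percentiles),
              collapse = "  "), "\n")
  }
  invisible(x)
}

#' Monte Carlo two-source apportionment
#'
#' Propagates analytical and end-member dispersion through the
#' Delta-200-Hg mass balance. Each draw perturbs the sample value(s) and
#' both end-member means with independent normal noise, solves for alpha,
#' and the draws are summarised by their median and requested percentiles.
#' When several samples are given, each draw first picks one sample at
#' random (resampling mode) so the draw distribution reflects both
#' analytical noise and between-sample spread; `resample = FALSE` instead
#' uses the mean of the sample values each draw.
#'
#' @param samples Numeric vector of sample Delta-200-Hg values, per mil.
#' @param sds Per-sample 1-sigma uncertainties (recycled).
#' @param em_hg0,em_hgII [end_member()] objects.
#' @param n_draws Number of Monte Carlo draws (>= 1000).
#' @param seed Integer seed (mandatory for reproducibility).
#' @param probs Percentiles to report, default quartiles.
#' @param policy Handling of draws with alpha outside `[0, 1]`:
#'   `"clip"` (default) clips to the boundary, `"reject"` discards them,
#'   `"keep"` retains them untouched.
#' @param resample Resample individual samples per draw (default TRUE).
#' @return `mixing_result` with `alpha` (median), `theta`, `percentiles`,
#'   `theta_percentiles`, `n_draws`, `seed`, `n_rejected`.
#' @export
mixing_monte_carlo <- function(samples, sds, em_hg0, em_hgII,
                               n_draws = 1e5, seed,
                               probs = c(0.25, 0.5, 0.75),
                               policy = c("clip", "reject", "keep"),
                               resample = TRUE) {
  policy <- match.arg(policy)
  stopifnot(inherits(em_hg0, "end_member"), inherits(em_hgII, "end_member"))
  if (missing(seed)) stop("seed is required for Monte Carlo runs", call. = FALSE)
  if (n_draws < 1000) stop("n_draws must be >= 1000", call. = FALSE)
  if (any(sds < 0)) stop("sample sds must be non-negative", call. = FALSE)
  sds <- rep_len(sds, length(samples))
  denom0 <- em_hgII$D200_mean - em_hg0$D200_mean
  if (abs(denom0) <= 1e-9) {
    stop("end-member D200 means coincide: mixture is unidentifiable",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  if (resample && length(samples) > 1L) {
    idx <- sample.int(length(samples), n_draws, replace = TRUE)
    s_draw <- stats::rnorm(n_draws, samples[idx], sds[idx])
  } else {
    s_draw <- stats::rnorm(n_draws, mean(samples), mean(sds))
  }
  e0 <- stats::rnorm(n_draws, em_hg0$D200_mean, em_hg0$D200_sd)
  e2 <- stats::rnorm(n_draws, em_hgII$D200_mean, em_hgII$D200_sd)
  denom <- e2 - e0
  ok <- abs(denom) > 1e-12
  alpha <- (e2[ok] - s_draw[ok]) / denom[ok]
  n_rejected <- 0L
  if (policy == "clip") {
    alpha <- pmin(1, pmax(0, alpha))
  } else if (policy == "reject") {
    keep <- alpha >= 0 & alpha <= 1
    n_rejected <- sum(!keep)
    alpha <- alpha[keep]
    if (!length(alpha)) {
      stop("degenerate simulation: all draws rejected by truncation policy",
           call. = FALSE)
    }
  }
  pct <- stats::quantile(alpha, probs = probs, names = FALSE)
  names(pct) <- formatC(100 * probs, format = "fg")
  structure(list(alpha = stats::median(alpha), theta = 1 - stats::median(alpha),
                 percentiles = pct,
                 theta_percentiles = stats::setNames(
                   1 - stats::quantile(alpha, probs = 1 - probs, names = FALSE),
                   names(pct)),
                 n_draws = as.integer(n_draws), seed = as.integer(seed),
                 n_rejected = n_rejected, policy = policy,
                 method = "monte_carlo"),
            class = "mixing_result")
}

#' Delta-199-Hg mixing baseline at a sample's Delta-200-Hg
#'
#' The deposition baseline in (Delta-200, Delta-199) space is the straight
#' line through the two end-member means. For a sample's Delta-200-Hg the
#' alpha-weighted Delta-199-Hg on that line is the value the peat would
#' carry if only conservative mixing of the two deposition pathways had
#' occurred; any deficit below it records post-depositional odd-MIF
#' fractionation.
#'
#' @inheritParams endmember_fraction
#' @return Predicted baseline Delta-199-Hg, per mil (vectorised).
#' @export
mixing_line_prediction <- function(sample_D200, em_hg0, em_hgII) {
  stopifnot(inherits(em_hg0, "end_member"), inherits(em_hgII, "end_member"))
  if (is.na(em_hg0$D199_mean) || is.na(em_hgII$D199_mean)) {
    stop("both end-members need a D199 mean for mixing-line prediction",
         call. = FALSE)
  }
  fr <- endmember_fraction(sample_D200, em_hg0, em_hgII)
  fr$alpha * em_hg0$D199_mean + fr$theta * em_hgII$D199_mean
}
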