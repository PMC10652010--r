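#' Mass-dependent scaling coefficients for Hg isotope anomalies
#'
#' The kinetic mass-dependent fractionation law predicts, for each Hg isotope
#' ratio XXX/198, a fixed proportionality to the 202/198 ratio. The capital
#' delta anomaly is the deviation of the measured delta value from that
#' prediction, \eqn{\Delta^{XXX}Hg = \delta^{XXX}Hg - \beta \cdot
#' \delta^{202}Hg}, with beta = 0.2520, 0.5024, 0.7520 and 1.493 for masses
#' 199, 200, 201 and 204.
#'
#' @return Named numeric vector of the four beta coefficients, names
#'   "199", "200", "201", "204".
#' @export
#' @examples
#' beta_table()[["200"]]
beta_table <- function() {
  c("199" = 0.2520, "200" = 0.5024, "201" = 0.7520, "204" = 1.493)
}

#' Delta value from measured and bracketing-standard isotope ratios
#'
#' Standard-sample bracketing delta notation relative to NIST 3133:
#' \eqn{\delta = 1000 \cdot (R_{sample}/R_{standard} - 1)} per mil.
#'
#' @param sample_ratio Measured XXX/198 isotope ratio of the sample.
#' @param bracket_ratio Same ratio in the bracketing standard.
#' @return Delta value in per mil. Vectorised over both arguments.
#' @export
#' @examples
#' delta_from_ratios(0.998, 1.000)  # -2 per mil
delta_from_ratios <- function(sample_ratio, bracket_ratio) {
  if (any(!is.finite(sample_ratio)) || any(!is.finite(bracket_ratio)) ||
      any(sample_ratio <= 0) || any(bracket_ratio <= 0)) {
    stop("isotope ratios must be finite and strictly positive", call. = FALSE)
  }
  1000 * (sample_ratio / bracket_ratio - 1)
}

#' Mass-independent anomaly from delta values
#'
#' @param dXXX Delta value (per mil) of the odd or even isotope of interest.
#' @param d202 Delta-202 value (per mil) of the same sample.
#' @param mass Isotope mass: one of 199, 200, 201, 204.
#' @return Capital-delta anomaly in per mil.
#' @export
#' @examples
#' mif_from_deltas(-0.50, -1.65, 199)
mif_from_deltas <- function(dXXX, d202, mass) {
  b <- beta_table()
  key <- as.character(mass)
  if (length(key) != 1L || !key %in% names(b)) {
    stop("mass must be one of 199, 200, 201, 204", call. = FALSE)
  }
  dXXX - b[[key]] * d202
}

#' Invert the anomaly definition to recover the raw delta value
#'
#' @inheritParams mif_from_deltas
#' @param DXXX Capital-delta anomaly (per mil).
#' @return The raw delta value dXXX = DXXX + beta * d202.
#' @export
delta_from_mif <- function(DXXX, d202, mass) {
  b <- beta_table()
  key <- as.character(mass)
  if (length(key) != 1L || !key %in% names(b)) {
    stop("mass must be one of 199, 200, 201, 204", call. = FALSE)
  }
  DXXX + b[[key]] * d202
}

#' Construct an isotope composition record
#'
#' Bundles a sample's mass-dependent (d202) and mass-independent (D199, D200,
#' D201, D204) signatures in per mil with optional per-isotope 2-sigma
#' analytical uncertainties and optional raw delta values. When raw delta
#' values are supplied they are checked for consistency with the anomaly
#' definition.
#'
#' @param d202 Delta-202 value, per mil.
#' @param D199,D200,D201,D204 Capital-delta anomalies, per mil (NA allowed).
#' @param sigma2 Named numeric vector of 2-sigma uncertainties (per mil), e.g.
#'   `c(d202 = 0.17, D199 = 0.13, D200 = 0.08)`. All must be >= 0.
#' @param d199,d200,d201,d204 Optional raw delta values, per mil.
#' @return Object of class `isotope_composition` (a named list).
#' @export
#' @examples
#' isotope_composition(d202 = -1.65, D199 = -0.25, D200 = -0.01,
#'                     sigma2 = c(d202 = 0.17, D199 = 0.13, D200 = 0.08))
isotope_composition <- function(d202, D199 = NA_real_, D200 = NA_real_,
                                D201 = NA_real_, D204 = NA_real_,
                                sigma2 = numeric(0),
                                d199 = NULL, d200 = NULL, d201 = NULL,
                                d204 = NULL) {
  if (length(sigma2) && any(sigma2 < 0, na.rm = TRUE)) {
    stop("analytical uncertainties must be non-negative", call. = FALSE)
  }
  raw <- list("199" = d199, "200" = d200, "201" = d201, "204" = d204)
  big <- list("199" = D199, "200" = D200, "201" = D201, "204" = D204)
  for (m in names(raw)) {
    if (!is.null(raw[[m]]) && !is.na(big[[m]])) {
      implied <- mif_from_deltas(raw[[m]], d202, as.numeric(m))
      if (abs(implied - big[[m]]) > 1e-12) {
        stop(sprintf(
          "inconsistent delta/anomaly pair for mass %s: D = %.15g but d - beta*d202 = %.15g",
          m, big[[m]], implied), call. = FALSE)
      }
    }
  }
  structure(
    list(d202 = d202, D199 = D199, D200 = D200, D201 = D201, D204 = D204,
         sigma2 = sigma2,
         d199 = d199, d200 = d200, d201 = d201, d204 = d204),
    class = "isotope_composition"
  )
}

#' @export
print.isotope_composition <- function(x, ...) {
  cat("<isotope_composition>\n")
  vals <- c(d202 = x$d202, D199 = x$D199, D200 = x$D200,
            D201 = x$D201, D204 = x$D204)
  for (nm in names(vals)) {
    if (!is.na(vals[[nm]])) {
      s <- if (nm %in% names(x$sigma2)) sprintf(" ± %.2f (2s)", x$sigma2[[nm]]) else ""
      cat(sprintf("  %s: %.2f‰%s\n", nm, vals[[nm]], s))
    }
  }
  invisible(x)
}

#' Enrichment factor between two compartment means
#'
#' Computes the signed per-mil differences (A minus B) in d202 and D199
#' between two isotope compositions, e.g. soil gas minus atmosphere or DGM
#' minus soil gas. At per-mil magnitudes the difference of means and the
#' logarithmic enrichment factor 1000*(alpha - 1) agree to second order, so
#' the arithmetic difference is used. Uncertainty, when per-field standard
#' errors are supplied via `se_A`/`se_B`, is propagated in quadrature.
#'
#' @param mean_A,mean_B `isotope_composition` objects holding compartment
#'   means (A and B respectively).
#' @param label Text label, conventionally "A - B".
#' @param se_A,se_B Optional named numeric vectors of standard errors on the
#'   means, names among `d202`, `D199`.
#' @return Object of class `enrichment_factor`: list with `label`,
#'   `epsilon202`, `E199` and `uncertainty` (named vector, NA when no
#'   standard errors were given).
#' @export
#' @examples
#' a <- isotope_composition(d202 = -0.09, D199 = -0.15)
#' b <- isotope_composition(d202 = 0.71, D199 = -0.24)
#' enrichment_between(a, b, label = "soil gas - atmosphere")
enrichment_between <- function(mean_A, mean_B, label = "A - B",
                               se_A = NULL, se_B = NULL) {
  stopifnot(inherits(mean_A, "isotope_composition"),
            inherits(mean_B, "isotope_composition"))
  need <- function(x, f) {
    v <- x[[f]]
    if (is.null(v) || is.na(v)) {
      stop(sprintf("isotope field '%s' missing from a compartment mean", f),
           call. = FALSE)
    }
    v
  }
  eps202 <- need(mean_A, "d202") - need(mean_B, "d202")
  E199 <- need(mean_A, "D199") - need(mean_B, "D199")
  unc <- c(epsilon202 = NA_real_, E199 = NA_real_)
  quad <- function(f) {
    a <- if (!is.null(se_A) && f %in% names(se_A)) se_A[[f]] else NA_real_
    b <- if (!is.null(se_B) && f %in% names(se_B)) se_B[[f]] else NA_real_
    if (is.na(a) || is.na(b)) NA_real_ else sqrt(a^2 + b^2)
  }
  unc[["epsilon202"]] <- quad("d202")
  unc[["E199"]] <- quad("D199")
  structure(list(label = label, epsilon202 = eps202, E199 = E199,
                 uncertainty = unc),
            class = "enrichment_factor")
}

#' @export
print.enrichment_factor <- function(x, ...) {
  cat(sprintf("<enrichment_factor> %s\n", x$label))
  cat(sprintf("  epsilon202: %.2f‰   E199: %.2f‰\n",
              x$epsilon202, x$E199))
  invisible(x)
}

# --- tabular IO ------------------------------------------------------------

iso_csv_columns <- c("sample_id", "compartment", "d202",
                     "D199", "D200", "D201", "D204",
                     "sigma2_d202", "sigma2_D199", "sigma2_D200",
                     "sigma2_D201", "sigma2_D204")

#' Read a sample isotope table from CSV
#'
#' Expects columns `sample_id`, `compartment`, `d202`, `D199`, `D200`,
#' `D201`, `D204` and optional `sigma2_*` uncertainty columns; extra columns
#' are preserved.
#'
#' @param path Path to a CSV file.
#' @return data.frame of samples.
#' @export
read_isotope_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "d202")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("isotope CSV missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write a sample isotope table to CSV
#'
#' @param df data.frame as returned by [read_isotope_csv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_isotope_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialise a package object to JSON and back
#'
#' Round-trips the plain-list domain objects (isotope compositions,
#' end-members, fit reports) through JSON for reporting and archival.
#'
#' @param x Object (named list / S3 object built on a list).
#' @return JSON string.
#' @export
to_json <- function(x) {
  cls <- class(x)
  out <- unclass(x)
  # named numeric vectors must serialise as objects, not bare arrays
  out <- lapply(out, function(v) {
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v
  })
  out <- c(out, list(.class = cls[[1L]]))
  jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, null = "null")
}

#' @rdname to_json
#' @param json JSON string produced by [to_json()].
#' @export
from_json <- function(json) {
  out <- jsonlite::fromJSON(json)
  cls <- out$.class
  out$.class <- NULL
  if (!is.null(out$sigma2)) out$sigma2 <- unlist(out$sigma2)
  if (!is.null(cls)) class(out) <- cls
  out
}
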