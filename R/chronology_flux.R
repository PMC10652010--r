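#' Construct a dated peat core slice
#'
#' A slice is a contiguous depth increment of a peat core with its dry bulk
#' density, total Hg concentration and the calendar-year interval it spans.
#' Depths are positive downward from the living surface (cm); ages are
#' calendar years CE, so the top of a slice is at least as young as its
#' bottom.
#'
#' @param depth_top,depth_bottom Depth below surface, cm (`bottom > top`).
#' @param density Dry bulk density, g cm-3 (> 0).
#' @param hg_conc Total Hg concentration, ng g-1 (>= 0).
#' @param age_top,age_bottom Calendar years CE of slice top / bottom;
#'   `age_top >= age_bottom`.
#' @param isotopes Optional [isotope_composition()].
#' @return Object of class `peat_slice`.
#' @export
peat_slice <- function(depth_top, depth_bottom, density, hg_conc,
                       age_top, age_bottom, isotopes = NULL) {
  if (depth_bottom <= depth_top) {
    stop("depth_bottom must exceed depth_top", call. = FALSE)
  }
  if (density <= 0) stop("density must be positive", call. = FALSE)
  if (hg_conc < 0) stop("hg_conc must be non-negative", call. = FALSE)
  if (age_top < age_bottom) {
    stop("age_top (younger, CE) must be >= age_bottom (older, CE)",
         call. = FALSE)
  }
  if (!is.null(isotopes) && !inherits(isotopes, "isotope_composition")) {
    stop("isotopes must be an isotope_composition", call. = FALSE)
  }
  structure(
    list(depth_top = depth_top, depth_bottom = depth_bottom,
         thickness = depth_bottom - depth_top,
         density = density, hg_conc = hg_conc,
         age_top = age_top, age_bottom = age_bottom,
         isotopes = isotopes),
    class = "peat_slice"
  )
}

#' Assemble slices into a core profile
#'
#' @param slices List of [peat_slice()] objects ordered surface-first.
#' @param microform `"hummock"` or `"lawn"`.
#' @param water_table_depth Mean unsaturated-zone depth, cm.
#' @param water_table_sd Its standard deviation, cm.
#' @param allow_gaps Permit non-contiguous depth intervals (default FALSE).
#' @return Object of class `core_profile`.
#' @export
core_profile <- function(slices, microform = c("hummock", "lawn"),
                         water_table_depth = NA_real_,
                         water_table_sd = NA_real_,
                         allow_gaps = FALSE) {
  microform <- match.arg(microform)
  if (!length(slices)) stop("a core needs at least one slice", call. = FALSE)
  ok <- vapply(slices, inherits, logical(1), what = "peat_slice")
  if (!all(ok)) stop("all elements must be peat_slice objects", call. = FALSE)
  tops <- vapply(slices, `[[`, numeric(1), "depth_top")
  bots <- vapply(slices, `[[`, numeric(1), "depth_bottom")
  if (is.unsorted(tops, strictly = TRUE)) {
    stop("slices must be ordered by strictly increasing depth", call. = FALSE)
  }
  if (!allow_gaps && length(slices) > 1L) {
    gaps <- abs(tops[-1L] - bots[-length(bots)])
    if (any(gaps > 1e-9)) {
      stop("slices are not contiguous in depth; set allow_gaps = TRUE to permit",
           call. = FALSE)
    }
  }
  structure(
    list(microform = microform, slices = slices,
         water_table_depth = water_table_depth,
         water_table_sd = water_table_sd),
    class = "core_profile"
  )
}

#' @export
print.core_profile <- function(x, ...) {
  n <- length(x$slices)
  cat(sprintf("<core_profile> %s, %d slices, %.0f-%.0f cm, %s-%s CE\n",
              x$microform, n,
              x$slices[[1L]]$depth_top, x$slices[[n]]$depth_bottom,
              format(round(x$slices[[n]]$age_bottom)),
              format(round(x$slices[[1L]]$age_top))))
  invisible(x)
}

#' Age-depth model from external control points
#'
#' Wraps control points produced by an external age-depth run (e.g. a
#' Bayesian accumulation model) for piecewise-linear interpolation. Depths
#' must increase strictly and calendar ages must not increase with depth.
#'
#' @param depth_cm Numeric vector of control-point depths, cm.
#' @param age_CE Numeric vector of calendar ages, years CE.
#' @return Object of class `age_depth_model`.
#' @export
age_depth_model <- function(depth_cm, age_CE) {
  if (length(depth_cm) != length(age_CE) || length(depth_cm) < 2L) {
    stop("need >= 2 paired (depth, age) control points", call. = FALSE)
  }
  ord <- order(depth_cm)
  depth_cm <- depth_cm[ord]
  age_CE <- age_CE[ord]
  if (any(diff(depth_cm) <= 0)) {
    stop("control-point depths must be strictly increasing", call. = FALSE)
  }
  if (any(diff(age_CE) > 0)) {
    stop("ages must be non-increasing (CE) with depth", call. = FALSE)
  }
  structure(list(depth_cm = depth_cm, age_CE = age_CE),
            class = "age_depth_model")
}

#' Interpolate calendar ages at arbitrary depths
#'
#' Monotone piecewise-linear interpolation of the age-depth control points.
#' Extrapolation beyond the control-point span is refused.
#'
#' @param model [age_depth_model()].
#' @param boundaries Numeric vector of depths (cm) to date.
#' @return Numeric vector of calendar ages (CE), non-increasing with depth.
#' @export
interpolate_ages <- function(model, boundaries) {
  stopifnot(inherits(model, "age_depth_model"))
  rng <- range(model$depth_cm)
  if (any(boundaries < rng[1L] - 1e-9) || any(boundaries > rng[2L] + 1e-9)) {
    stop(sprintf("depth outside the dated span [%g, %g] cm; refusing to extrapolate",
                 rng[1L], rng[2L]), call. = FALSE)
  }
  stats::approx(model$depth_cm, model$age_CE, xout = boundaries,
                method = "linear", ties = "ordered")$y
}

#' Hg accumulation rate of one slice
#'
#' `HgAR = concentration x density x thickness / age interval`, computed in
#' ng cm-2 yr-1 and converted (x10) to ug m-2 yr-1.
#'
#' @param slice [peat_slice()].
#' @return Flux in ug m-2 yr-1.
#' @export
#' @examples
#' s <- peat_slice(0, 1, density = 0.05, hg_conc = 100,
#'                 age_top = 2020, age_bottom = 2015)
#' hg_accumulation_rate(s)  # 10 ug m-2 yr-1
hg_accumulation_rate <- function(slice) {
  stopifnot(inherits(slice, "peat_slice"))
  dt <- slice$age_top - slice$age_bottom
  if (dt <= 0) {
    stop("degenerate slice: age interval must be positive", call. = FALSE)
  }
  10 * slice$hg_conc * slice$density * slice$thickness / dt
}

#' Mean Hg accumulation flux over a calendar period
#'
#' Averages per-slice accumulation rates over a period of interest. The
#' primary statistic weights each slice by the number of years it overlaps
#' the period (slices straddling a boundary are split pro-rata by time); the
#' unweighted mean and sd over the overlapping slices are returned for
#' comparison.
#'
#' @param profile [core_profile()].
#' @param period Numeric length-2, `c(start_CE, end_CE)` with start < end.
#' @return List with `mean` (time-weighted), `sd` (time-weighted), `mean_unweighted`,
#'   `sd_unweighted`, `n` (slices contributing) and `years` (total slice-years
#'   inside the period). Fluxes in ug m-2 yr-1.
#' @export
period_mean_flux <- function(profile, period) {
  stopifnot(inherits(profile, "core_profile"))
  if (length(period) != 2L || period[2L] <= period[1L]) {
    stop("period must be c(start_CE, end_CE) with start < end", call. = FALSE)
  }
  flux <- vapply(profile$slices, hg_accumulation_rate, numeric(1))
  lo <- vapply(profile$slices, `[[`, numeric(1), "age_bottom")
  hi <- vapply(profile$slices, `[[`, numeric(1), "age_top")
  overlap <- pmax(0, pmin(hi, period[2L]) - pmax(lo, period[1L]))
  keep <- overlap > 0
  if (!any(keep)) {
    stop("no slice overlaps the requested period", call. = FALSE)
  }
  w <- overlap[keep]
  f <- flux[keep]
  wm <- sum(w * f) / sum(w)
  wv <- sum(w * (f - wm)^2) / sum(w)
  list(mean = wm,
       sd = sqrt(wv),
       mean_unweighted = mean(f),
       sd_unweighted = stats::sd(f),
       n = sum(keep),
       years = sum(w))
}

#' Read a peat-core CSV into a core profile
#'
#' Column schema: `depth_top_cm`, `depth_bottom_cm`, `density_g_cm3`,
#' `hg_ng_g`, `age_top_CE`, `age_bottom_CE`, with optional isotope columns
#' `d202`, `D199`, `D200`, `D201`, `D204` (and `sigma2_*`). A `thickness_cm`
#' column, if present, is checked against the depth interval.
#'
#' @param path CSV path.
#' @param microform `"hummock"` or `"lawn"`.
#' @param ... Passed to [core_profile()] (e.g. `water_table_depth`).
#' @return [core_profile()].
#' @export
read_core_csv <- function(path, microform = "hummock", ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("depth_top_cm", "depth_bottom_cm", "density_g_cm3",
                "hg_ng_g", "age_top_CE", "age_bottom_CE")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("core CSV missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!nrow(df)) stop("core CSV has no data rows", call. = FALSE)
  slices <- lapply(seq_len(nrow(df)), function(i) {
    iso <- NULL
    if ("D200" %in% names(df) && !is.na(df$D200[i])) {
      sig <- numeric(0)
      for (f in c("d202", "D199", "D200")) {
        col <- paste0("sigma2_", f)
        if (col %in% names(df) && !is.na(df[[col]][i])) {
          sig[f] <- df[[col]][i]
        }
      }
      iso <- isotope_composition(
        d202 = if ("d202" %in% names(df)) df$d202[i] else NA_real_,
        D199 = if ("D199" %in% names(df)) df$D199[i] else NA_real_,
        D200 = df$D200[i],
        sigma2 = sig)
    }
    peat_slice(df$depth_top_cm[i], df$depth_bottom_cm[i],
               density = df$density_g_cm3[i], hg_conc = df$hg_ng_g[i],
               age_top = df$age_top_CE[i], age_bottom = df$age_bottom_CE[i],
               isotopes = iso)
  })
  core_profile(slices, microform = microform, ...)
}

#' Flatten a core profile to a data.frame
#'
#' Inverse of [read_core_csv()]: one row per slice with the CSV column
#' schema, suitable for writing with [utils::write.csv()].
#'
#' @param profile [core_profile()].
#' @return data.frame.
#' @export
core_as_data_frame <- function(profile) {
  stopifnot(inherits(profile, "core_profile"))
  rows <- lapply(profile$slices, function(s) {
    iso <- s$isotopes
    data.frame(
      depth_top_cm = s$depth_top, depth_bottom_cm = s$depth_bottom,
      thickness_cm = s$thickness, density_g_cm3 = s$density,
      hg_ng_g = s$hg_conc, age_top_CE = s$age_top, age_bottom_CE = s$age_bottom,
      d202 = if (is.null(iso)) NA_real_ else iso$d202,
      D199 = if (is.null(iso)) NA_real_ else iso$D199,
      D200 = if (is.null(iso)) NA_real_ else iso$D200)
  })
  do.call(rbind, rows)
}

#' Read an age-model CSV (`depth_cm`, `age_CE`) as control points
#'
#' @param path CSV path.
#' @return [age_depth_model()].
#' @export
read_age_model_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("depth_cm", "age_CE"), names(df))
  if (length(missing)) {
    stop("age-model CSV missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  age_depth_model(df$depth_cm, df$age_CE)
}
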