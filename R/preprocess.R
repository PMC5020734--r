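#' Standardize survey counts to a common sampling effort
#'
#' Years were surveyed with different numbers of 50 x 1 m transects; counts
#' are rescaled by `reference_transects / transects` so all years express
#' colonies per the same reference effort. A 2010 survey of 3 transects
#' against a reference of 6 therefore has its counts doubled.
#'
#' @param series A [survey_series()] with unit `"raw"`.
#' @param reference_transects Reference effort (default 6).
#' @return A [survey_series()] with unit `"standardized_count"`.
#' @export
standardize_effort <- function(series, reference_transects = 6L) {
  stopifnot(inherits(series, "survey_series"))
  if (reference_transects < 1) stop("reference_transects must be >= 1")
  df <- as.data.frame(series)
  if (any(df$transects < 1, na.rm = TRUE)) {
    stop("cannot standardize rows with zero transects")
  }
  sc <- survey_scheme(series)
  f <- reference_transects / df$transects
  df[sc$class_labels] <- df[sc$class_labels] * f
  survey_series(df, unit = "standardized_count", scheme = sc)
}

#' Rescale a count vector to percent contributions
#'
#' Divides by the total and multiplies by 100, so the vector's direction
#' (size structure) is kept while its magnitude (sampling effort, density)
#' is discarded. This is what makes surveys of unequal effort comparable to
#' the inverse solver.
#'
#' @param x Nonnegative numeric vector with at least one positive entry.
#' @return Numeric vector summing to 100.
#' @export
to_proportional <- function(x) {
  if (any(x < 0)) stop("negative entries are not allowed")
  s <- sum(x)
  if (s <= 0) stop("all-zero vector: empty sample cannot be made proportional")
  100 * x / s
}

#' Rescale every row of a survey series to percent contributions
#'
#' @param series A [survey_series()].
#' @return A [survey_series()] with unit `"proportional"`.
#' @export
proportionalize <- function(series) {
  stopifnot(inherits(series, "survey_series"))
  df <- as.data.frame(series)
  sc <- survey_scheme(series)
  cnt <- as.matrix(df[sc$class_labels])
  df[sc$class_labels] <- t(apply(cnt, 1, to_proportional))
  survey_series(df, unit = "proportional", scheme = sc)
}

#' Fill unsurveyed years by per-class linear regression on year
#'
#' For each stratum and each size class independently, an ordinary
#' least-squares line `value ~ year` is fitted on the window years and its
#' fitted value fills each target year. Negative fits are clipped to zero
#' (no negative abundance) when `clip_negative` is on. Imputed rows carry
#' `imputed = TRUE` and `transects = NA`.
#'
#' @param series A [survey_series()]; all window years must be present in
#'   every stratum.
#' @param target_years Years to fill.
#' @param window_years Years whose data feed the regression (>= 2 distinct,
#'   disjoint from the targets).
#' @param clip_negative Clip negative fitted values to 0 (default `TRUE`).
#' @return The input series with imputed rows appended (ordered by stratum
#'   then year).
#' @export
impute_missing_years <- function(series, target_years, window_years,
                                 clip_negative = TRUE) {
  stopifnot(inherits(series, "survey_series"))
  target_years <- as.integer(target_years)
  window_years <- as.integer(window_years)
  if (length(unique(window_years)) < 2) {
    stop("need at least 2 distinct window years for regression imputation")
  }
  if (length(intersect(target_years, window_years)) > 0) {
    stop("target years must not be window years")
  }
  df <- as.data.frame(series)
  sc <- survey_scheme(series)
  out <- df
  for (st in unique(df$stratum)) {
    sub <- df[df$stratum == st, , drop = FALSE]
    if (!all(window_years %in% sub$year)) {
      stop("stratum ", st, " lacks window year(s): ",
           paste(setdiff(window_years, sub$year), collapse = ", "))
    }
    w <- sub[sub$year %in% window_years, , drop = FALSE]
    todo <- setdiff(target_years, sub$year)
    for (y in todo) {
      vals <- vapply(sc$class_labels, function(lab) {
        fit <- stats::lm(w[[lab]] ~ w$year)
        v <- unname(stats::coef(fit)[1] + stats::coef(fit)[2] * y)
        if (clip_negative) max(v, 0) else v
      }, numeric(1))
      row <- data.frame(year = y, stratum = st, transects = NA_real_)
      row[sc$class_labels] <- as.list(vals)
      row$imputed <- TRUE
      out <- rbind(out, row)
    }
  }
  out <- out[order(out$stratum, out$year), , drop = FALSE]
  survey_series(out, unit = survey_unit(series), scheme = sc)
}
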