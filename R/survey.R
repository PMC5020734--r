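#' Survey series container
#'
#' A long-format table of size-frequency survey counts: one row per
#' (year, stratum), with the transect effort and one count column per size
#' class, plus an `imputed` flag. A unit tag records what the counts mean:
#' \describe{
#'   \item{raw}{colonies as counted, at whatever effort was surveyed}
#'   \item{standardized_count}{counts rescaled to a common reference effort}
#'   \item{proportional}{percent contributions per class (rows sum to 100)}
#' }
#'
#' @param df A data.frame with columns `year`, `stratum`, `transects`, one
#'   numeric column per size class, and optionally `imputed`.
#' @param unit One of `"raw"`, `"standardized_count"`, `"proportional"`.
#' @param scheme A [size_class_scheme()] naming the count columns.
#' @return A data.frame of class `survey_series` with attributes `unit` and
#'   `scheme`.
#' @export
survey_series <- function(df, unit = c("raw", "standardized_count", "proportional"),
                          scheme = size_class_scheme()) {
  unit <- match.arg(unit)
  need <- c("year", "stratum", "transects", scheme$class_labels)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!"imputed" %in% names(df)) df$imputed <- rep(FALSE, nrow(df))
  cnt <- as.matrix(df[scheme$class_labels])
  if (nrow(df) > 0) {
    # imputed rows may go negative when clipping is disabled (diagnostics)
    bad <- which(apply(cnt < 0, 1, any) & !df$imputed)
    if (length(bad) > 0) {
      stop("negative count(s) in row(s): ", paste(bad, collapse = ", "))
    }
    dup <- which(duplicated(df[c("year", "stratum")]))
    if (length(dup) > 0) {
      stop("duplicate (year, stratum) in row(s): ", paste(dup, collapse = ", "))
    }
    if (unit == "proportional") {
      # imputed rows are regression fits; clipping can pull them off 100
      rs <- rowSums(cnt)
      off <- which(abs(rs - 100) > 1e-9 & !is.na(rs) & !df$imputed)
      if (length(off) > 0) {
        stop("proportional rows must sum to 100; row(s): ",
             paste(off, collapse = ", "))
      }
    }
  }
  df <- df[c("year", "stratum", "transects", scheme$class_labels, "imputed")]
  rownames(df) <- NULL
  structure(df, unit = unit, scheme = scheme,
            class = c("survey_series", "data.frame"))
}

#' @export
print.survey_series <- function(x, ...) {
  cat("Survey series (unit:", attr(x, "unit"), ")\n")
  print(as.data.frame(x))
  invisible(x)
}

survey_unit <- function(x) attr(x, "unit")
survey_scheme <- function(x) attr(x, "scheme")

# keep attributes through subsetting
#' @export
`[.survey_series` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("year", "stratum") %in% names(out))) {
    attr(out, "unit") <- attr(x, "unit")
    attr(out, "scheme") <- attr(x, "scheme")
    class(out) <- class(x)
  }
  out
}

#' Counts of one stratum as a classes x years matrix
#'
#' @param x A [survey_series()].
#' @param stratum Stratum label to extract; `NULL` takes all rows.
#' @return k x T numeric matrix, columns named by year, ascending.
#' @export
series_matrix <- function(x, stratum = NULL) {
  sc <- survey_scheme(x)
  df <- as.data.frame(x)
  if (!is.null(stratum)) df <- df[df$stratum == stratum, , drop = FALSE]
  df <- df[order(df$year), , drop = FALSE]
  m <- t(as.matrix(df[sc$class_labels]))
  colnames(m) <- df$year
  m
}
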