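#' Size-class scheme for colony diameters
#'
#' Defines the ordered diameter bins used to classify coral colonies and the
#' representative diameter per class used when converting abundance to
#' percent cover. The default is the five-bin scheme common in coral
#' size-frequency work: 0-5, 5-10, 10-20, 20-40 and >40 cm, with
#' representative diameters at the bin midpoints (50 cm for the open top
#' bin). Cover values depend directly on the representative diameters, so
#' they are an explicit field rather than a hidden convention.
#'
#' @param class_labels Character vector of ordered class names.
#' @param lower_cm,upper_cm Numeric diameter bounds (cm) per class; the last
#'   upper bound may be `Inf` (open top class).
#' @param representative_cm One diameter (cm) per class used for planar-area
#'   conversion; must lie within the class bounds (strictly above the lower
#'   edge for the open top class).
#' @return An object of class `size_class_scheme`.
#' @examples
#' sc <- size_class_scheme()
#' sc$representative_cm
#' @export
size_class_scheme <- function(class_labels = paste0("SC", 1:5),
                              lower_cm = c(0, 5, 10, 20, 40),
                              upper_cm = c(5, 10, 20, 40, Inf),
                              representative_cm = c(2.5, 7.5, 15, 30, 50)) {
  k <- length(class_labels)
  if (k < 2L) stop("a size-class scheme needs at least 2 classes")
  if (length(lower_cm) != k || length(upper_cm) != k ||
      length(representative_cm) != k) {
    stop("class_labels, lower_cm, upper_cm and representative_cm must have equal length")
  }
  if (any(upper_cm <= lower_cm)) stop("each upper edge must exceed its lower edge")
  if (k > 1 && any(lower_cm[-1] != upper_cm[-k])) {
    stop("classes must be contiguous: lower edges must equal the previous upper edge")
  }
  if (any(diff(lower_cm) <= 0)) stop("edges must be strictly increasing")
  bad <- representative_cm <= lower_cm |
    (is.finite(upper_cm) & representative_cm > upper_cm)
  if (any(bad)) {
    stop("representative diameter outside class bounds for: ",
         paste(class_labels[bad], collapse = ", "))
  }
  structure(
    list(class_labels = as.character(class_labels),
         lower_cm = as.numeric(lower_cm),
         upper_cm = as.numeric(upper_cm),
         representative_cm = as.numeric(representative_cm)),
    class = "size_class_scheme"
  )
}

#' @export
print.size_class_scheme <- function(x, ...) {
  cat("Size-class scheme (", length(x$class_labels), " classes)\n", sep = "")
  up <- ifelse(is.finite(x$upper_cm), paste0("-", x$upper_cm), "+")
  for (i in seq_along(x$class_labels)) {
    cat(sprintf("  %-4s %s%s cm  (representative %.1f cm)\n",
                x$class_labels[i], x$lower_cm[i], up[i], x$representative_cm[i]))
  }
  invisible(x)
}

n_classes <- function(scheme) length(scheme$class_labels)
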