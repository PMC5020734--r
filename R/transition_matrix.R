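#' Stage-transition (Leslie) matrix constrained by a life-cycle graph
#'
#' Wraps a k x k nonnegative matrix together with the life-cycle structure
#' it must respect. Entry (i, j) moves abundance from class j to class i in
#' one annual step; fertility entries sit in the first row. Validation
#' enforces: zeros off the allowed arcs, nonnegative entries, and per-column
#' survival sums (stasis + growth + shrinkage) at most 1. Fertility entries
#' are exempt from the column-sum cap: in a Leslie matrix fertilities and
#' growth transitions need not add to unity.
#'
#' @param values Numeric k x k matrix.
#' @param structure A [life_cycle_structure()].
#' @param scheme Optional [size_class_scheme()] used for labelling.
#' @param tol Numerical slack for the zero-pattern and column-sum checks.
#' @return An object of class `transition_matrix` (a matrix with attributes
#'   `structure` and `scheme`).
#' @export
transition_matrix <- function(values, structure, scheme = NULL, tol = 1e-9) {
  values <- as.matrix(values)
  k <- structure$n_classes
  if (!all(dim(values) == k)) stop("matrix must be ", k, " x ", k)
  if (any(values < -tol)) stop("negative entries are not allowed")
  values[values < 0] <- 0
  P <- structure_pattern(structure)
  off <- abs(values) > tol & P == 0
  if (any(off)) {
    ij <- which(off, arr.ind = TRUE)
    stop("nonzero entries off the allowed arcs at (",
         paste(apply(ij, 1, paste, collapse = ","), collapse = "), ("), ")")
  }
  values[P == 0] <- 0
  cs <- survival_column_sums(values, structure)
  if (any(cs > 1 + 1e-9 + tol)) {
    stop("survival column sum exceeds 1 in column(s): ",
         paste(which(cs > 1 + 1e-9 + tol), collapse = ", "))
  }
  labs <- if (!is.null(scheme)) scheme$class_labels else paste0("SC", seq_len(k))
  dimnames(values) <- list(labs, labs)
  structure(values, structure = structure, scheme = scheme,
            class = c("transition_matrix", "matrix", "array"))
}

# survival-only (stasis+growth+shrinkage) sums per source column
survival_column_sums <- function(values, structure) {
  k <- structure$n_classes
  surv <- structure$arcs[is_survival_role(structure$arcs$role), , drop = FALSE]
  cs <- numeric(k)
  for (j in seq_len(k)) {
    rows <- surv$target[surv$source == j]
    cs[j] <- sum(values[cbind(rows, rep(j, length(rows)))])
  }
  cs
}

#' @export
print.transition_matrix <- function(x, digits = 4, ...) {
  cat("Stage-transition matrix (", nrow(x), " classes, ",
      n_arcs(attr(x, "structure")), " arcs)\n", sep = "")
  print(round(unclass(x), digits))
  cat("survival column sums:",
      paste(round(survival_column_sums(unclass(x), attr(x, "structure")), 4),
            collapse = " "), "\n")
  invisible(x)
}

#' Split a transition matrix into survival and fecundity parts
#'
#' The survival matrix S holds the stasis diagonal, growth subdiagonal and
#' shrinkage superdiagonal; the fecundity matrix R holds the first-row
#' fertility entries. The supports are disjoint and S + R reproduces M
#' exactly. The split is what lets density dependence act on recruitment
#' and growth separately in the forward model.
#'
#' @param M A [transition_matrix()] or plain matrix.
#' @param structure The [life_cycle_structure()]; defaults to the one
#'   attached to `M`.
#' @return A list of class `matrix_decomposition` with elements `S`, `R`
#'   and `structure`.
#' @export
decompose <- function(M, structure = attr(M, "structure")) {
  if (is.null(structure)) stop("no structure supplied or attached to M")
  V <- unclass(as.matrix(M))
  k <- structure$n_classes
  P <- structure_pattern(structure)
  off <- abs(V) > 1e-12 & P == 0
  if (any(off)) stop("matrix has entries on arcs absent from the structure")
  S <- R <- matrix(0, k, k, dimnames = dimnames(V))
  a <- structure$arcs
  sv <- a[is_survival_role(a$role), , drop = FALSE]
  fe <- a[a$role == "fertility", , drop = FALSE]
  S[cbind(sv$target, sv$source)] <- V[cbind(sv$target, sv$source)]
  R[cbind(fe$target, fe$source)] <- V[cbind(fe$target, fe$source)]
  structure(list(S = S, R = R, structure = structure),
            class = "matrix_decomposition")
}

#' @export
print.matrix_decomposition <- function(x, digits = 4, ...) {
  cat("S (survival):\n"); print(round(x$S, digits))
  cat("R (fecundity):\n"); print(round(x$R, digits))
  invisible(x)
}
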