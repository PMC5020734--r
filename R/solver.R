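#' Count equations against free parameters for an inverse solve
#'
#' Each observed transition contributes k equations (one per size class);
#' the unknowns are the arcs of the life-cycle graph. The system is
#' (over)determined, and the constrained least-squares estimate unique in
#' general position, when equations >= unknowns.
#'
#' @param series_length Number of abundance vectors available (>= 2).
#' @param structure A [life_cycle_structure()].
#' @return A list with `equations`, `unknowns` and logical `identifiable`.
#' @export
check_identifiability <- function(series_length, structure) {
  if (series_length < 2) stop("need at least 2 vectors")
  k <- structure$n_classes
  eq <- k * (series_length - 1L)
  un <- n_arcs(structure)
  list(equations = as.integer(eq), unknowns = as.integer(un),
       identifiable = eq >= un)
}

# Stack the per-transition linear systems into design matrix A and response
# y so that || A theta - y ||^2 = sum_t || n(t+1) - M(theta) n(t) ||^2,
# with theta the vector of arc values in structure$arcs order.
build_design <- function(series, structure) {
  k <- structure$n_classes
  a <- structure$arcs
  p <- nrow(a)
  nt <- ncol(series) - 1L
  A <- matrix(0, k * nt, p)
  y <- numeric(k * nt)
  for (t in seq_len(nt)) {
    rows <- (t - 1L) * k + seq_len(k)
    y[rows] <- series[, t + 1L]
    for (g in seq_len(p)) {
      A[rows[a$target[g]], g] <- series[a$source[g], t]
    }
  }
  list(A = A, y = y)
}

# per-column survival-sum constraint rows: C theta <= 1
build_survival_constraints <- function(structure) {
  a <- structure$arcs
  k <- structure$n_classes
  C <- matrix(0, k, nrow(a))
  for (j in seq_len(k)) {
    C[j, is_survival_role(a$role) & a$source == j] <- 1
  }
  keep <- rowSums(C) > 0
  C[keep, , drop = FALSE]
}

#' Inversely solve a stage-transition matrix from an abundance series
#'
#' Wood's method: find the matrix M, constrained to the arcs of a
#' life-cycle graph, that minimizes the summed squared one-step prediction
#' error `sum_t || n(t+1) - M n(t) ||^2` subject to nonnegative entries and
#' per-column survival sums at most 1. The problem is a small convex
#' quadratic program, solved to its global optimum with an active-set
#' method; the objective value is reported so any backend can be validated
#' against an independent minimizer.
#'
#' @param series k x T matrix of abundance vectors (columns ordered in
#'   time), T >= 2. Any positive rescaling of the whole series (e.g. to
#'   percent contributions) leaves the estimate unchanged.
#' @param structure A [life_cycle_structure()].
#' @param ridge Ridge penalty `lambda * ||theta||^2` added to the objective;
#'   0 (default) requires an identifiable system, > 0 permits solving
#'   underdetermined systems at the minimum-norm solution.
#' @param scheme Optional [size_class_scheme()] for labelling.
#' @return An object of class `wood_fit`: list with `matrix`
#'   (a [transition_matrix()]), `rss`, `residuals` (k x (T-1) matrix),
#'   `equations`, `unknowns`, `identifiable`, `ridge`.
#' @export
solve_wood <- function(series, structure, ridge = 0, scheme = NULL) {
  series <- as.matrix(series)
  if (ncol(series) < 2) stop("need at least 2 vectors")
  if (nrow(series) != structure$n_classes) {
    stop("series has ", nrow(series), " classes but structure expects ",
         structure$n_classes)
  }
  if (any(series < 0)) stop("abundance vectors must be nonnegative")
  if (all(series == 0)) stop("degenerate input: all-zero series")
  idf <- check_identifiability(ncol(series), structure)
  if (!idf$identifiable && ridge <= 0) {
    stop("system not identifiable (", idf$equations, " equations < ",
         idf$unknowns, " unknowns); supply ridge > 0 to regularize")
  }
  d <- build_design(series, structure)
  A <- d$A; y <- d$y
  if (ridge > 0) {
    A <- rbind(A, sqrt(ridge) * diag(ncol(A)))
    y <- c(y, numeric(ncol(A)))
  }
  C <- build_survival_constraints(structure)
  theta <- pracma::lsqlincon(A, y, A = C, b = rep(1, nrow(C)),
                             lb = rep(0, ncol(A)))
  theta <- pmax(theta, 0)
  k <- structure$n_classes
  V <- matrix(0, k, k)
  V[cbind(structure$arcs$target, structure$arcs$source)] <- theta
  M <- transition_matrix(V, structure, scheme = scheme)
  resid <- series[, -1L, drop = FALSE] - unclass(M) %*% series[, -ncol(series), drop = FALSE]
  structure(list(matrix = M, rss = sum(resid^2), residuals = resid,
                 equations = idf$equations, unknowns = idf$unknowns,
                 identifiable = idf$identifiable, ridge = ridge),
            class = "wood_fit")
}

#' @export
print.wood_fit <- function(x, digits = 4, ...) {
  cat("Wood's-method inverse fit:", x$equations, "equations,",
      x$unknowns, "free parameters",
      if (x$identifiable) "(identifiable)" else "(ridge-regularized)", "\n")
  cat("RSS:", format(x$rss, digits = 6), "\n")
  print(x$matrix, digits = digits)
  invisible(x)
}

#' Serialize a solve report to JSON
#'
#' @param fit A `wood_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_solve_report <- function(fit, path) {
  rep <- list(matrix = unclass(fit$matrix), rss = fit$rss,
              residuals = fit$residuals, equations = fit$equations,
              unknowns = fit$unknowns, identifiable = fit$identifiable,
              ridge = fit$ridge)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
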