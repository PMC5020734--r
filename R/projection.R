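#' Recruitment specification for an open population
#'
#' Recruitment into the smallest size class combines a deterministic
#' sequence (recruits added at steps t = 0, 1, 2, ..., zero once the
#' sequence is exhausted — the hindcast uses [5, 0, 0, 3, 0]) and a
#' stochastic imported component drawn each step from a Gaussian truncated
#' at zero (no negative recruitment). The defaults, mean 25 and variance 25
#' (sd 5), are the imported-recruitment level that lets a largely open
#' massive-coral population regain cover after a mass mortality.
#'
#' @param deterministic Numeric vector of recruits per step (may be empty).
#' @param mean Mean of the Gaussian imported recruitment.
#' @param variance Variance of the Gaussian (sd = sqrt(variance)); 0 makes
#'   the stochastic component deterministic at `max(0, mean)`.
#' @return An object of class `recruitment_spec`.
#' @export
recruitment_spec <- function(deterministic = c(5, 0, 0, 3, 0),
                             mean = 25, variance = 25) {
  if (any(deterministic < 0)) stop("deterministic recruit counts must be >= 0")
  if (variance < 0) stop("variance must be >= 0")
  structure(list(deterministic = as.numeric(deterministic),
                 mean = as.numeric(mean), variance = as.numeric(variance)),
            class = "recruitment_spec")
}

#' Zero recruitment (closed population), a convenience for tests and limits
#' @return A [recruitment_spec()] adding nothing at any step.
#' @export
no_recruitment <- function() {
  recruitment_spec(deterministic = numeric(0), mean = 0, variance = 0)
}

# deterministic recruit count applied at step t (t = 0, 1, ...)
recruit_at <- function(spec, t) {
  if (t + 1L <= length(spec$deterministic)) spec$deterministic[t + 1L] else 0
}

# one stochastic draw; consumes RNG only when variance > 0 so that purely
# deterministic configurations match project_linear bitwise
draw_stochastic_recruits <- function(spec) {
  if (spec$variance > 0) {
    max(0, stats::rnorm(1, spec$mean, sqrt(spec$variance)))
  } else {
    max(0, spec$mean)
  }
}

#' Ricker density-dependence configuration
#'
#' Per-class inhibition coefficients `b` and the placement mode deciding
#' where the factors `exp(-b_j n_j)` act:
#' \describe{
#'   \item{inflow}{(default) rows of S + R are scaled, inhibiting additions
#'     *into* each class — this caps the large classes and yields the
#'     bounded equilibrium a space-limited reef shows}
#'   \item{outflow}{columns are scaled, inhibiting contributions *from*
#'     each class}
#'   \item{fertility_only}{only the first-row fecundity entries are scaled}
#' }
#' The default coefficients put b = 0.001 on the three largest of five
#' classes and none on the small classes.
#'
#' @param b Nonnegative per-class coefficients.
#' @param mode One of `"inflow"`, `"outflow"`, `"fertility_only"`.
#' @return An object of class `density_dependence`.
#' @export
density_dependence <- function(b = c(0, 0, 0.001, 0.001, 0.001),
                               mode = c("inflow", "outflow", "fertility_only")) {
  mode <- match.arg(mode)
  if (any(b < 0)) stop("b must be nonnegative")
  structure(list(b = as.numeric(b), mode = mode), class = "density_dependence")
}

#' Ricker inhibition factors
#'
#' `factor_j = exp(-b_j * n_j)`, each in (0, 1]: no inhibition at zero
#' abundance, exponentially stronger inhibition as a class fills space.
#'
#' @param n Nonnegative abundance vector.
#' @param dd A [density_dependence()].
#' @return Numeric vector of factors in (0, 1].
#' @export
ricker_factors <- function(n, dd) {
  if (any(n < 0)) stop("abundances must be nonnegative")
  if (length(dd$b) != length(n)) stop("b and n must have equal length")
  exp(-dd$b * n)
}

#' Linear (density-independent) projection with deterministic recruits
#'
#' `n(t+1) = M n(t) + v(t) e1`, the model used for hindcast verification of
#' an inversely solved matrix: start from the held-out initial vector and
#' compare the projected vectors with the observed ones.
#'
#' @param M A [transition_matrix()] or plain k x k matrix.
#' @param n0 Nonnegative initial vector.
#' @param steps Number of annual steps (>= 1).
#' @param recruitment A [recruitment_spec()]; only its deterministic
#'   sequence is used.
#' @return k x (steps + 1) matrix, column t + 1 = vector at time t.
#' @export
project_linear <- function(M, n0, steps, recruitment = no_recruitment()) {
  M <- unclass(as.matrix(M))
  k <- nrow(M)
  if (length(n0) != k) stop("n0 has length ", length(n0), ", expected ", k)
  if (any(n0 < 0)) stop("n0 must be nonnegative")
  if (steps < 1) stop("steps must be >= 1")
  out <- matrix(0, k, steps + 1)
  out[, 1] <- n0
  for (t in seq_len(steps)) {
    nn <- as.numeric(M %*% out[, t])
    nn[1] <- nn[1] + recruit_at(recruitment, t - 1L)
    out[, t + 1] <- pmax(nn, 0)
  }
  colnames(out) <- paste0("t", 0:steps)
  rownames(out) <- rownames(M)
  out
}

#' Pooled R-squared of a hindcast against observations
#'
#' One coefficient of determination pooled over all class-by-year cells:
#' `R^2 = 1 - SSE / SST` with SST taken about the grand mean of the
#' observed cells (a single printed number per depth stratum, not a
#' per-class average).
#'
#' @param predicted,observed Equal-shaped matrices (classes x years).
#' @return An object of class `hindcast_fit`: list with `r_squared`,
#'   `sse`, `sst`, `residuals`, `predicted`, `observed`.
#' @export
hindcast_fit <- function(predicted, observed) {
  predicted <- as.matrix(predicted); observed <- as.matrix(observed)
  if (!all(dim(predicted) == dim(observed))) stop("shape mismatch")
  if (length(observed) < 2) stop("need at least 2 observed cells")
  sse <- sum((observed - predicted)^2)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("undefined R-squared: observed cells are all equal")
  structure(list(r_squared = 1 - sse / sst, sse = sse, sst = sst,
                 residuals = observed - predicted,
                 predicted = predicted, observed = observed),
            class = "hindcast_fit")
}

#' @export
print.hindcast_fit <- function(x, ...) {
  cat(sprintf("Hindcast fit: pooled R^2 = %.4f over %d cells\n",
              x$r_squared, length(x$observed)))
  invisible(x)
}

# the shared step engine: density-dependent projection with optional pulse
# disturbances. schedule/kills are pre-drawn so disturbance randomness and
# recruitment randomness live on separate streams.
project_engine <- function(S, R, dd, n0, steps, recruitment,
                           schedule = integer(0), kills = numeric(0),
                           seed = NULL) {
  k <- nrow(S)
  out <- matrix(0, k, steps + 1)
  out[, 1] <- n0
  with_seed(seed, {
    for (t in seq_len(steps)) {
      n <- out[, t]
      ev <- match(t, schedule)
      if (!is.na(ev)) n <- n * (1 - kills[ev])
      g <- exp(-dd$b * n)
      M_eff <- switch(dd$mode,
        inflow = g * (S + R),            # row-wise scaling
        outflow = t(t(S + R) * g),       # column-wise scaling
        fertility_only = {
          Rg <- R
          Rg[1, ] <- R[1, ] * g
          S + Rg
        })
      nn <- as.numeric(M_eff %*% n)
      nn[1] <- nn[1] + recruit_at(recruitment, t - 1L) +
        draw_stochastic_recruits(recruitment)
      out[, t + 1] <- pmax(nn, 0)
    }
  })
  colnames(out) <- paste0("t", 0:steps)
  rownames(out) <- rownames(S)
  out
}

#' Density-dependent stochastic projection
#'
#' One annual step applies Ricker inhibition to the decomposed matrix
#' (placement set by the density-dependence mode), then adds deterministic
#' and zero-truncated Gaussian recruits to class 1:
#' `n(t+1) = apply_mode(S, R, G(n(t))) n(t) + e1 max(0, N(mu, sigma^2)) + v(t) e1`.
#' With `b = 0` and a purely deterministic recruitment spec this reduces
#' exactly to [project_linear()] on `S + R`.
#'
#' @param decomp A [decompose()] result (or a list with `S` and `R`).
#' @param dd A [density_dependence()].
#' @param n0 Nonnegative initial vector.
#' @param steps Number of annual steps.
#' @param recruitment A [recruitment_spec()].
#' @param seed RNG seed; fixed seed gives bitwise-identical trajectories.
#' @return k x (steps + 1) matrix of abundance vectors.
#' @export
project_density_dependent <- function(decomp, dd, n0, steps,
                                      recruitment = recruitment_spec(),
                                      seed = NULL) {
  if (is.null(decomp$S) || is.null(decomp$R)) stop("decomp must carry S and R")
  k <- nrow(decomp$S)
  if (length(dd$b) != k) stop("b has length ", length(dd$b), ", expected ", k)
  if (length(n0) != k) stop("n0 has length ", length(n0), ", expected ", k)
  if (any(n0 < 0)) stop("n0 must be nonnegative")
  project_engine(decomp$S, decomp$R, dd, n0, steps, recruitment, seed = seed)
}

#' Convert an abundance vector to percent cover
#'
#' Each class contributes its colony count times the planar area of a
#' circle at the class's representative diameter; cover is that area as a
#' percentage of the reference substrate area (default 300 m^2, six
#' 50 x 1 m transects).
#'
#' @param n Nonnegative abundance vector.
#' @param scheme A [size_class_scheme()] (supplies representative diameters
#'   in cm).
#' @param reference_area_m2 Reference substrate area (> 0).
#' @return An object of class `cover_result`: list with `per_class_pct`,
#'   `total_pct`, `reference_area_m2`.
#' @export
cover_from_vector <- function(n, scheme = size_class_scheme(),
                              reference_area_m2 = 300) {
  if (any(n < 0)) stop("abundances must be nonnegative")
  if (reference_area_m2 <= 0) stop("reference area must be > 0")
  if (length(n) != n_classes(scheme)) stop("length mismatch with scheme")
  area_m2 <- pi * (scheme$representative_cm / 200)^2   # cm diameter -> m radius
  per <- 100 * n * area_m2 / reference_area_m2
  names(per) <- scheme$class_labels
  structure(list(per_class_pct = per, total_pct = sum(per),
                 reference_area_m2 = reference_area_m2),
            class = "cover_result")
}

#' Total percent cover along a trajectory
#'
#' @param series k x (T+1) abundance matrix.
#' @inheritParams cover_from_vector
#' @return Numeric vector of total cover per column.
#' @export
cover_series <- function(series, scheme = size_class_scheme(),
                         reference_area_m2 = 300) {
  apply(series, 2, function(n) {
    cover_from_vector(n, scheme, reference_area_m2)$total_pct
  })
}

#' First time a cover trajectory settles into a stable regime
#'
#' Scans for the first index t (0-based, matching the trajectory's time
#' axis) such that over the window `[t, t + window]` cover stays within
#' `rel_tol` (relative) of the window mean.
#'
#' @param cover Numeric cover series (element 1 = time 0).
#' @param window Window length in steps.
#' @param rel_tol Relative tolerance around the window mean.
#' @return 0-based time index, or `NA` if the series never settles.
#' @export
time_to_stability <- function(cover, window = 20L, rel_tol = 0.05) {
  if (length(cover) <= window) stop("series must be longer than the window")
  for (t in seq_len(length(cover) - window)) {
    seg <- cover[t:(t + window)]
    m <- mean(seg)
    if (all(abs(seg - m) <= rel_tol * abs(m))) return(t - 1L)
  }
  NA_integer_
}
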