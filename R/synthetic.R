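#' Draw a random ground-truth transition matrix on a given life-cycle graph
#'
#' Generates a structured, feasible stage-transition matrix for recovery
#' experiments: survival entries (stasis, growth, shrinkage) are drawn per
#' source column and rescaled so the column survival sum lands uniformly in
#' `[0.5, survival_cap]`; fertility entries are drawn uniformly in
#' `[0, fertility_max]`. The low default fertility ceiling mirrors the weak
#' local recruitment typical of largely open coral populations.
#'
#' @param structure A [life_cycle_structure()].
#' @param survival_cap Upper bound for per-column survival sums, in (0, 1].
#' @param fertility_max Upper bound for fertility entries.
#' @param seed RNG seed (draws are made under a local RNG scope).
#' @return A [transition_matrix()].
#' @export
generate_true_matrix <- function(structure, survival_cap = 0.95,
                                 fertility_max = 0.1, seed = NULL) {
  if (!inherits(structure, "life_cycle_structure")) stop("invalid structure")
  if (survival_cap <= 0 || survival_cap > 1) stop("survival_cap must be in (0, 1]")
  k <- structure$n_classes
  with_seed(seed, {
    V <- matrix(0, k, k)
    a <- structure$arcs
    for (j in seq_len(k)) {
      sv <- a[is_survival_role(a$role) & a$source == j, , drop = FALSE]
      if (nrow(sv) > 0) {
        w <- stats::runif(nrow(sv), 0.05, 1)
        total <- stats::runif(1, 0.5 * survival_cap, survival_cap)
        V[cbind(sv$target, sv$source)] <- w / sum(w) * total
      }
    }
    fe <- a[a$role == "fertility", , drop = FALSE]
    if (nrow(fe) > 0) {
      V[cbind(fe$target, fe$source)] <- stats::runif(nrow(fe), 0, fertility_max)
    }
    transition_matrix(V, structure)
  })
}

#' Bundle the unobservable true dynamics behind a synthetic survey
#'
#' @param matrix A [transition_matrix()].
#' @param initial_vector Nonnegative abundance per class at t = 0.
#' @param recruitment A [recruitment_spec()]; default: no recruitment.
#' @param seed Seed used for any stochastic recruitment during simulation.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(matrix, initial_vector,
                         recruitment = recruitment_spec(deterministic = numeric(0),
                                                        mean = 0, variance = 0),
                         seed = NULL) {
  stopifnot(inherits(matrix, "transition_matrix"))
  k <- nrow(matrix)
  if (length(initial_vector) != k) stop("initial vector must have length ", k)
  if (any(initial_vector < 0)) stop("initial vector must be nonnegative")
  structure(list(matrix = matrix, initial_vector = as.numeric(initial_vector),
                 recruitment = recruitment, seed = seed),
            class = "ground_truth")
}

#' Simulate a true abundance series from ground truth
#'
#' Applies `n(t+1) = M n(t) + v(t) e1` stepwise, where `v(t)` combines the
#' deterministic recruit sequence and (if the recruitment spec has positive
#' variance) a zero-truncated Gaussian draw. Abundances are real-valued;
#' rounding to whole colonies happens only in [emulate_survey()].
#'
#' @param truth A [ground_truth()].
#' @param steps Number of annual transitions (>= 1).
#' @return A k x (steps + 1) matrix; column t + 1 is the abundance vector at
#'   time t (column 1 is the initial vector).
#' @export
simulate_series <- function(truth, steps) {
  stopifnot(inherits(truth, "ground_truth"), steps >= 1)
  M <- unclass(truth$matrix)
  k <- nrow(M)
  out <- matrix(0, k, steps + 1)
  out[, 1] <- truth$initial_vector
  with_seed(truth$seed, {
    for (t in seq_len(steps)) {
      n_next <- as.numeric(M %*% out[, t])
      n_next[1] <- n_next[1] + recruit_at(truth$recruitment, t - 1L) +
        draw_stochastic_recruits(truth$recruitment)
      out[, t + 1] <- pmax(n_next, 0)
    }
  })
  colnames(out) <- paste0("t", 0:steps)
  rownames(out) <- rownames(M)
  out
}

#' Observation model for transect surveys
#'
#' Describes how a survey sees the true population: sampling effort varies
#' by year (counts scale with the share of transects surveyed relative to a
#' reference effort), about half of the smallest colonies are overlooked on
#' video transects (binomial thinning of class 1 by `sc1_detection_prob`),
#' counts are optionally Poisson-resampled, and some years are simply not
#' surveyed.
#'
#' @param transects_per_year Named integer vector: year -> transects surveyed.
#' @param reference_transects Effort that defines "full" counts (default 6).
#' @param transect_area_m2 Area per transect in m^2 (default 50).
#' @param sc1_detection_prob Detection probability for class 1, in (0, 1].
#' @param count_noise `"none"` or `"poisson"`.
#' @param missing_years Integer years with no survey at all.
#' @param deterministic_detection If `TRUE`, class-1 thinning multiplies by
#'   the detection probability instead of drawing binomially (for tests).
#' @return An object of class `observation_model`.
#' @export
observation_model <- function(transects_per_year,
                              reference_transects = 6L,
                              transect_area_m2 = 50,
                              sc1_detection_prob = 0.5,
                              count_noise = c("none", "poisson"),
                              missing_years = integer(0),
                              deterministic_detection = FALSE) {
  count_noise <- match.arg(count_noise)
  if (is.null(names(transects_per_year))) {
    stop("transects_per_year must be a named (by year) vector")
  }
  if (any(transects_per_year < 0)) stop("transect counts must be >= 0")
  if (sc1_detection_prob <= 0 || sc1_detection_prob > 1) {
    stop("sc1_detection_prob must be in (0, 1]")
  }
  if (transect_area_m2 <= 0) stop("transect_area_m2 must be > 0")
  structure(list(transects_per_year = transects_per_year,
                 reference_transects = as.integer(reference_transects),
                 transect_area_m2 = transect_area_m2,
                 sc1_detection_prob = sc1_detection_prob,
                 count_noise = count_noise,
                 missing_years = as.integer(missing_years),
                 deterministic_detection = isTRUE(deterministic_detection)),
            class = "observation_model")
}

#' Turn a true abundance series into survey-like counts
#'
#' @param series k x (T+1) matrix from [simulate_series()]; column t + 1 is
#'   year `start_year + t`.
#' @param obs An [observation_model()].
#' @param scheme A [size_class_scheme()] supplying column labels.
#' @param start_year Calendar year of the first series column.
#' @param stratum Stratum label written into the output rows.
#' @param seed RNG seed for thinning/noise.
#' @return A [survey_series()] with unit `"raw"`, one row per surveyed year.
#' @export
emulate_survey <- function(series, obs, scheme = size_class_scheme(),
                           start_year = 2010L, stratum = "synthetic",
                           seed = NULL) {
  if (any(series < 0)) stop("series must be nonnegative")
  k <- nrow(series)
  years <- as.integer(names(obs$transects_per_year))
  years <- setdiff(years, obs$missing_years)
  years <- years[years >= start_year & years <= start_year + ncol(series) - 1L]
  rows <- with_seed(seed, {
    lapply(years, function(y) {
      tr <- obs$transects_per_year[[as.character(y)]]
      n_true <- series[, y - start_year + 1L]
      x <- n_true * tr / obs$reference_transects
      if (obs$deterministic_detection) {
        x[1] <- x[1] * obs$sc1_detection_prob
      } else {
        x[1] <- stats::rbinom(1, round(x[1]), obs$sc1_detection_prob)
      }
      if (obs$count_noise == "poisson") x <- stats::rpois(k, x)
      counts <- round(x)
      data.frame(year = y, stratum = stratum, transects = tr,
                 rbind(stats::setNames(counts, scheme$class_labels)))
    })
  })
  df <- if (length(rows) > 0) do.call(rbind, rows) else {
    empty <- data.frame(year = integer(0), stratum = character(0),
                        transects = integer(0))
    for (lab in scheme$class_labels) empty[[lab]] <- numeric(0)
    empty
  }
  survey_series(df, unit = "raw", scheme = scheme)
}

#' A fixed, plausible ground-truth matrix for demonstrations
#'
#' A synthetic five-class transition matrix with the qualitative anatomy of
#' a massive-coral population: strong growth transitions in the small
#' classes, increasing retention (stasis) toward the large classes, weak
#' shrinkage of the largest class, and very low local recruitment. It is
#' the default dynamics behind the package's synthetic surveys and worked
#' examples; it is constructed, not estimated from any field data.
#'
#' @return A [transition_matrix()] on [porites_structure()].
#' @export
example_porites_matrix <- function() {
  st <- porites_structure()
  V <- matrix(0, 5, 5)
  diag(V) <- c(0.15, 0.25, 0.45, 0.70, 0.85)       # stasis
  V[cbind(2:5, 1:4)] <- c(0.55, 0.55, 0.35, 0.15)  # growth
  V[4, 5] <- 0.05                                  # shrinkage SC5 -> SC4
  V[1, 4] <- 0.01                                  # weak local recruitment
  V[1, 5] <- 0.02
  transition_matrix(V, st, scheme = size_class_scheme())
}
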