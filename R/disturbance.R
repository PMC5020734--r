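#' Random pulse-disturbance regime
#'
#' Disturbances recur at uniform-random intervals (default 10 to 20 years)
#' and each kills a uniform-random fraction (default 0 to 100 percent) of
#' the colonies in every size class.
#'
#' @param interval_min_yr,interval_max_yr Waiting-time bounds in years.
#' @param kill_min,kill_max Support of the uniform kill fraction, within
#'   `[0, 1]`.
#' @return An object of class `disturbance_regime`.
#' @export
disturbance_regime <- function(interval_min_yr = 10, interval_max_yr = 20,
                               kill_min = 0, kill_max = 1) {
  if (interval_min_yr <= 0 || interval_min_yr > interval_max_yr) {
    stop("need 0 < interval_min_yr <= interval_max_yr")
  }
  if (kill_min < 0 || kill_max > 1 || kill_min > kill_max) {
    stop("kill fraction support must lie within [0, 1]")
  }
  structure(list(interval_min_yr = interval_min_yr,
                 interval_max_yr = interval_max_yr,
                 kill_min = kill_min, kill_max = kill_max),
            class = "disturbance_regime")
}

#' Draw the disturbance years of one realization
#'
#' Event times are cumulative sums of i.i.d. uniform waiting times, rounded
#' to whole years with a minimum spacing of one year, truncated at the
#' horizon.
#'
#' @param regime A [disturbance_regime()].
#' @param horizon_yr Projection horizon in years (>= 1).
#' @param seed RNG seed.
#' @return Strictly increasing integer vector of event years (possibly
#'   empty).
#' @export
sample_disturbance_schedule <- function(regime, horizon_yr, seed = NULL) {
  if (horizon_yr < 1) stop("horizon must be >= 1")
  with_seed(seed, {
    n_max <- ceiling(horizon_yr / regime$interval_min_yr) + 2L
    waits <- stats::runif(n_max, regime$interval_min_yr, regime$interval_max_yr)
    times <- round(cumsum(waits))
    times <- times[times <= horizon_yr]
    if (length(times) > 1) {
      for (i in 2:length(times)) {
        if (times[i] <= times[i - 1]) times[i] <- times[i - 1] + 1
      }
      times <- times[times <= horizon_yr]
    }
    as.integer(times)
  })
}

#' Apply a pulse disturbance to an abundance vector
#'
#' Every size class is reduced by the same fraction (no size selectivity).
#'
#' @param n Nonnegative abundance vector.
#' @param kill_fraction Fraction killed, in `[0, 1]`.
#' @return The thinned vector.
#' @export
apply_disturbance <- function(n, kill_fraction) {
  if (kill_fraction < 0 || kill_fraction > 1) {
    stop("kill fraction must be in [0, 1]")
  }
  if (any(n < 0)) stop("abundances must be nonnegative")
  n * (1 - kill_fraction)
}

#' Ensemble of stochastic trajectories under pulse disturbances
#'
#' Runs many seeded realizations of the density-dependent projection, each
#' with its own disturbance schedule and kill fractions (drawn on a stream
#' separate from the recruitment draws, so a null regime reproduces the
#' undisturbed trajectory under the same master seed). Disturbance acts at
#' the start of a step, before that year's growth and recruitment.
#'
#' @param decomp A [decompose()] result.
#' @param dd A [density_dependence()].
#' @param n0 Initial abundance vector.
#' @param recruitment A [recruitment_spec()].
#' @param regime A [disturbance_regime()], or `NULL` for no disturbances.
#' @param realizations Number of realizations (>= 1).
#' @param horizon Projection horizon in years.
#' @param master_seed Master seed; realization i runs on child seeds
#'   derived from `child_seed(master_seed, i)`.
#' @param scheme,reference_area_m2 Passed to the cover conversion.
#' @return An object of class `trajectory_ensemble`: list with `cover`
#'   (realizations x horizon + 1 matrix), `mean_cover`, `quantiles`
#'   (3 x horizon + 1: q05, q50, q95), `final_abundance`, `seeds`,
#'   `persistent` (mean cover at horizon > 0) and the configuration echo.
#' @export
run_ensemble <- function(decomp, dd, n0, recruitment = recruitment_spec(),
                         regime = disturbance_regime(), realizations = 500L,
                         horizon = 100L, master_seed = 1L,
                         scheme = size_class_scheme(),
                         reference_area_m2 = 300) {
  if (realizations < 1) stop("realizations must be >= 1")
  k <- nrow(decomp$S)
  cover <- matrix(0, realizations, horizon + 1)
  final_ab <- matrix(0, realizations, k)
  seeds <- integer(realizations)
  for (i in seq_len(realizations)) {
    base <- child_seed(master_seed, i)
    seeds[i] <- base
    seed_proj <- child_seed(base, 1L)
    seed_dist <- child_seed(base, 2L)
    if (is.null(regime)) {
      schedule <- integer(0); kills <- numeric(0)
    } else {
      sk <- with_seed(seed_dist, {
        sch <- sample_disturbance_schedule(regime, horizon)
        list(schedule = sch,
             kills = stats::runif(length(sch), regime$kill_min, regime$kill_max))
      })
      schedule <- sk$schedule; kills <- sk$kills
    }
    traj <- project_engine(decomp$S, decomp$R, dd, n0, horizon, recruitment,
                           schedule = schedule, kills = kills,
                           seed = seed_proj)
    cover[i, ] <- cover_series(traj, scheme, reference_area_m2)
    final_ab[i, ] <- traj[, horizon + 1]
  }
  mean_cover <- colMeans(cover)
  qs <- apply(cover, 2, stats::quantile, probs = c(0.05, 0.5, 0.95))
  structure(list(cover = cover, mean_cover = mean_cover, quantiles = qs,
                 final_abundance = final_ab, seeds = seeds,
                 persistent = mean_cover[horizon + 1] > 0,
                 config = list(dd = dd, recruitment = recruitment,
                               regime = regime, realizations = realizations,
                               horizon = horizon, master_seed = master_seed,
                               reference_area_m2 = reference_area_m2,
                               disturbance_order = "start_of_step")),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  h <- length(x$mean_cover) - 1L
  cat("Trajectory ensemble:", nrow(x$cover), "realizations over", h, "years\n")
  cat(sprintf("mean cover at horizon: %.3f%% (q05 %.3f, q95 %.3f); persistent: %s\n",
              x$mean_cover[h + 1], x$quantiles[1, h + 1], x$quantiles[3, h + 1],
              x$persistent))
  invisible(x)
}

#' Sensitivity of long-run cover to the imported-recruitment level
#'
#' For each candidate mean recruitment, runs undisturbed stochastic
#' projections and records the long-run mean total cover (average over the
#' last `tail_steps` years, averaged over replicates), then fits an
#' ordinary least-squares line of cover against recruitment mean.
#'
#' @param decomp,dd,n0 As in [run_ensemble()].
#' @param recruit_means Numeric vector of candidate Gaussian means (>= 2
#'   distinct values for the line fit).
#' @param variance Gaussian recruitment variance used at every level.
#' @param horizon,reps Projection length and replicates per level.
#' @param tail_steps Years averaged at the end of each trajectory.
#' @param master_seed Master seed; level/replicate seeds derive from it.
#' @param scheme,reference_area_m2 Cover conversion settings.
#' @return An object of class `recruitment_sweep`: list with `table`
#'   (data.frame: recruit_mean, mean_cover, sd_cover), `fit` (list with
#'   slope, intercept, r_squared).
#' @export
recruitment_sweep <- function(decomp, dd, n0, recruit_means = c(0, 10, 25, 50),
                              variance = 25, horizon = 100L, reps = 100L,
                              tail_steps = 20L, master_seed = 1L,
                              scheme = size_class_scheme(),
                              reference_area_m2 = 300) {
  if (length(unique(recruit_means)) < 2) stop("need >= 2 distinct means")
  if (reps < 1) stop("reps must be >= 1")
  rows <- lapply(seq_along(recruit_means), function(mi) {
    mu <- recruit_means[mi]
    spec <- recruitment_spec(deterministic = numeric(0), mean = mu,
                             variance = variance)
    covers <- vapply(seq_len(reps), function(r) {
      sd_seed <- child_seed(child_seed(master_seed, mi), r)
      traj <- project_density_dependent(decomp, dd, n0, horizon, spec,
                                        seed = sd_seed)
      cv <- cover_series(traj, scheme, reference_area_m2)
      mean(cv[(horizon + 1 - tail_steps + 1):(horizon + 1)])
    }, numeric(1))
    data.frame(recruit_mean = mu, mean_cover = mean(covers),
               sd_cover = stats::sd(covers))
  })
  tab <- do.call(rbind, rows)
  fit <- stats::lm(mean_cover ~ recruit_mean, data = tab)
  r2 <- summary(fit)$r.squared
  structure(list(table = tab,
                 fit = list(slope = unname(stats::coef(fit)[2]),
                            intercept = unname(stats::coef(fit)[1]),
                            r_squared = r2)),
            class = "recruitment_sweep")
}

#' @export
print.recruitment_sweep <- function(x, ...) {
  cat("Recruitment sweep:\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("line: cover = %.4f + %.4f * recruits, R^2 = %.4f\n",
              x$fit$intercept, x$fit$slope, x$fit$r_squared))
  invisible(x)
}
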