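#' Read a long-format survey CSV
#'
#' Expected columns: `year`, `stratum`, `transects`, one numeric column per
#' size class (named after the scheme's labels), optionally `imputed`.
#' Malformed rows are rejected with their row numbers.
#'
#' @param path CSV path.
#' @param scheme A [size_class_scheme()].
#' @param unit Unit tag of the file's counts.
#' @return A [survey_series()].
#' @export
read_survey_csv <- function(path, scheme = size_class_scheme(), unit = "raw") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "stratum", "transects", scheme$class_labels)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  }
  survey_series(df, unit = unit, scheme = scheme)
}

#' Write a survey series as CSV (with its unit recorded in a column)
#'
#' @param series A [survey_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survey_csv <- function(series, path) {
  df <- as.data.frame(series)
  df$unit <- survey_unit(series)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a transition matrix as labelled CSV
#'
#' Row-major k x k matrix with class labels as header and first column.
#'
#' @param M A [transition_matrix()] or plain matrix.
#' @param path File path.
#' @param structure A [life_cycle_structure()] to validate against on read.
#' @return `write_matrix_csv` returns `path` invisibly; `read_matrix_csv`
#'   returns a [transition_matrix()] (or plain matrix if `structure` is
#'   `NULL`).
#' @export
write_matrix_csv <- function(M, path) {
  utils::write.csv(as.data.frame(unclass(as.matrix(M))), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path, structure = NULL) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  V <- as.matrix(df)
  if (is.null(structure)) return(V)
  transition_matrix(V, structure)
}

#' Pipeline configuration with the study's default parameters
#'
#' Central bag of options for [run_pipeline()]. Every default is explicit:
#' reference effort 6 transects, imputation targets 2011-2012 on window
#' 2010/2013/2014, solve on the four vectors after the held-out start year,
#' Ricker b = 0.001 on the three largest classes (inflow mode), Gaussian
#' imported recruitment mean 25 variance 25, hindcast recruit sequence
#' [5, 0, 0, 3, 0], 100-year horizon, disturbance intervals U(10, 20) with
#' kill U(0, 1).
#'
#' @param reference_transects Reference sampling effort.
#' @param impute_targets,impute_window Years to fill / regression window.
#' @param hindcast_start_year Held-out year that seeds the hindcast (and is
#'   excluded from the solve window).
#' @param use_years Years entering the inverse solve; `NULL` = all
#'   post-start years present.
#' @param ridge Ridge penalty for [solve_wood()].
#' @param b,dd_mode Density-dependence coefficients and placement.
#' @param recruit_deterministic,recruit_mean,recruit_variance Recruitment.
#' @param steps Forecast horizon (years).
#' @param regime A [disturbance_regime()] or `NULL` to skip the ensemble.
#' @param realizations Ensemble size.
#' @param sweep_means Recruitment-sweep means, or `NULL` to skip the sweep.
#' @param sweep_reps Replicates per sweep level.
#' @param scheme Size-class scheme.
#' @param reference_area_m2 Cover reference area.
#' @param master_seed Master seed; each stage runs on a child seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(reference_transects = 6L,
                            impute_targets = c(2011L, 2012L),
                            impute_window = c(2010L, 2013L, 2014L),
                            hindcast_start_year = 2010L,
                            use_years = NULL,
                            ridge = 0,
                            b = c(0, 0, 0.001, 0.001, 0.001),
                            dd_mode = "inflow",
                            recruit_deterministic = c(5, 0, 0, 3, 0),
                            recruit_mean = 25, recruit_variance = 25,
                            steps = 100L,
                            regime = disturbance_regime(),
                            realizations = 500L,
                            sweep_means = NULL, sweep_reps = 100L,
                            scheme = size_class_scheme(),
                            reference_area_m2 = 300,
                            master_seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline on a survey table
#'
#' Chains, per depth stratum independently: effort standardization ->
#' proportional scaling -> regression imputation -> inverse matrix solve
#' (Wood's method) -> hindcast verification from the held-out start year ->
#' density-dependent 100-year forecast with cover conversion -> optional
#' disturbance ensemble and recruitment sweep. Every intermediate artifact
#' is written under `out_dir` together with a manifest (file checksums,
#' configuration echo, seed), and a rerun with the same configuration and
#' seed reproduces all stochastic outputs bitwise.
#'
#' @param survey A [survey_series()] (unit `"raw"`) or path to a survey CSV.
#' @param structure A [life_cycle_structure()].
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the per-stratum fits, hindcasts,
#'   forecasts, ensembles and the manifest.
#' @export
run_pipeline <- function(survey, structure = porites_structure(),
                         config = pipeline_config(), out_dir = tempfile("run")) {
  if (is.character(survey)) survey <- read_survey_csv(survey, config$scheme)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- character(0)
  put <- function(name) { art <<- c(art, file.path(out_dir, name)); art[length(art)] }

  std <- standardize_effort(survey, config$reference_transects)
  write_survey_csv(std, put("standardized.csv"))
  prop <- proportionalize(std)
  write_survey_csv(prop, put("proportional.csv"))
  imp <- impute_missing_years(prop, config$impute_targets, config$impute_window)
  write_survey_csv(imp, put("imputed.csv"))

  dd <- density_dependence(config$b, config$dd_mode)
  rec_hind <- recruitment_spec(config$recruit_deterministic, 0, 0)
  rec_fore <- recruitment_spec(config$recruit_deterministic,
                               config$recruit_mean, config$recruit_variance)
  strata <- unique(as.data.frame(imp)$stratum)
  res <- list()
  for (si in seq_along(strata)) {
    st <- strata[si]
    mat <- series_matrix(imp, st)
    years <- as.integer(colnames(mat))
    fit_years <- if (is.null(config$use_years)) {
      years[years > config$hindcast_start_year]
    } else config$use_years
    if (length(fit_years) < 2) stop("solver stage: fewer than 2 fit years for stratum ", st)
    idf <- check_identifiability(length(fit_years), structure)
    if (!idf$identifiable && config$ridge <= 0) {
      stop("solver stage: system not identifiable for stratum ", st, " (",
           idf$equations, " equations < ", idf$unknowns, " unknowns)")
    }
    fit <- solve_wood(mat[, as.character(fit_years), drop = FALSE], structure,
                      ridge = config$ridge, scheme = config$scheme)
    write_matrix_csv(fit$matrix, put(paste0("matrix_", st, ".csv")))
    write_solve_report(fit, put(paste0("solve_report_", st, ".json")))

    n0 <- mat[, as.character(config$hindcast_start_year)]
    obs_years <- years[years > config$hindcast_start_year]
    pred <- project_linear(fit$matrix, n0, length(obs_years), rec_hind)
    hc <- hindcast_fit(pred[, -1, drop = FALSE],
                       mat[, as.character(obs_years), drop = FALSE])
    jsonlite::write_json(list(stratum = st, r_squared = hc$r_squared,
                              sse = hc$sse, sst = hc$sst),
                         put(paste0("hindcast_", st, ".json")),
                         auto_unbox = TRUE, digits = NA)

    dec <- decompose(fit$matrix)
    seed_f <- child_seed(config$master_seed, 100L + si)
    traj <- project_density_dependent(dec, dd, n0, config$steps, rec_fore,
                                      seed = seed_f)
    cv <- cover_series(traj, config$scheme, config$reference_area_m2)
    tidy <- data.frame(step = rep(0:config$steps, each = nrow(traj)),
                       class = rep(config$scheme$class_labels, config$steps + 1),
                       abundance = as.numeric(traj),
                       cover_pct = as.numeric(vapply(0:config$steps, function(t) {
                         cover_from_vector(traj[, t + 1], config$scheme,
                                           config$reference_area_m2)$per_class_pct
                       }, numeric(nrow(traj)))))
    utils::write.csv(tidy, put(paste0("forecast_", st, ".csv")), row.names = FALSE)

    ens <- NULL
    if (!is.null(config$regime)) {
      ens <- run_ensemble(dec, dd, n0, rec_fore, config$regime,
                          config$realizations, config$steps,
                          master_seed = child_seed(config$master_seed, 200L + si),
                          scheme = config$scheme,
                          reference_area_m2 = config$reference_area_m2)
      summ <- data.frame(step = 0:config$steps, mean = ens$mean_cover,
                         q05 = ens$quantiles[1, ], q50 = ens$quantiles[2, ],
                         q95 = ens$quantiles[3, ])
      utils::write.csv(summ, put(paste0("ensemble_", st, "_summary.csv")),
                       row.names = FALSE)
    }
    sweep <- NULL
    if (!is.null(config$sweep_means)) {
      sweep <- recruitment_sweep(dec, dd, n0, config$sweep_means,
                                 config$recruit_variance, config$steps,
                                 config$sweep_reps,
                                 master_seed = child_seed(config$master_seed, 300L + si),
                                 scheme = config$scheme,
                                 reference_area_m2 = config$reference_area_m2)
      utils::write.csv(sweep$table, put(paste0("sweep_", st, ".csv")),
                       row.names = FALSE)
      jsonlite::write_json(sweep$fit, put(paste0("sweep_", st, "_fit.json")),
                           auto_unbox = TRUE, digits = NA)
    }
    res[[st]] <- list(fit = fit, hindcast = hc, forecast = traj, cover = cv,
                      ensemble = ens, sweep = sweep)
  }

  manifest <- list(
    package = "coralmpm",
    version = as.character(utils::packageVersion("coralmpm")),
    master_seed = config$master_seed,
    config_hash = unname(digest_config(config)),
    artifacts = lapply(art, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  res$out_dir <- out_dir
  invisible(res)
}

# stable hash of the configuration (serialize deterministically, md5)
digest_config <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  plain <- rapply(unclass(config), function(x) x, how = "replace")
  writeLines(jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA,
                              force = TRUE, null = "null"), tmp)
  tools::md5sum(tmp)
}
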