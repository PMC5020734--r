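#!/usr/bin/env Rscript
# Stage 5: 100-year density-dependent forecast.
#
# The solved matrix is split into survival (S) and fecundity (R), Ricker
# inhibition exp(-b n) with b = 0.001 caps the three largest classes
# (inflow mode), and zero-truncated Gaussian recruitment of mean and
# variance 25 feeds class 1 each year. Abundance is converted to percent
# cover on the 300 m^2 reference area and the year the trajectory settles
# into a stable regime is reported.

source("analysis/00_common.R")

imp <- read_survey_csv(file.path(res_dir, "imputed.csv"), scheme,
                       unit = "proportional")
M <- read_matrix_csv(file.path(res_dir, "solved_matrix.csv"), struct)
n0 <- series_matrix(imp, "2m")[, "2010"]

dec <- decompose(M)
dd <- density_dependence()              # b = (0, 0, 0.001, 0.001, 0.001)
rec <- recruitment_spec()               # [5,0,0,3,0] then N(25, 25), >= 0

traj <- project_density_dependent(dec, dd, n0, 100, rec,
                                  seed = child_seed(seed, 51L))
cover <- cover_series(traj, scheme, 300)
tts <- time_to_stability(cover, window = 20, rel_tol = 0.05)

tidy <- data.frame(step = rep(0:100, each = 5),
                   class = rep(scheme$class_labels, 101),
                   abundance = as.numeric(traj))
tidy$cover_pct <- 100 * tidy$abundance *
  pi * (scheme$representative_cm[match(tidy$class, scheme$class_labels)] / 200)^2 / 300
utils::write.csv(tidy, file.path(res_dir, "forecast.csv"), row.names = FALSE)
jsonlite::write_json(list(seed = seed, b = dd$b, mode = dd$mode,
                          recruit_mean = 25, recruit_variance = 25,
                          representative_cm = scheme$representative_cm,
                          reference_area_m2 = 300,
                          total_cover_y100_pct = cover[101],
                          time_to_stability_yr = tts),
                     file.path(res_dir, "forecast_meta.json"),
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("Total cover: %.2f%% (year 0) -> %.2f%% (year 50) -> %.2f%% (year 100)\n",
            cover[1], cover[51], cover[101]))
cat(sprintf("Trajectory settles into a stable regime at about year %s\n",
            ifelse(is.na(tts), "never (within horizon)", tts)))
cat("Dominant class at year 100:",
    scheme$class_labels[which.max(traj[, 101])], "\n")
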