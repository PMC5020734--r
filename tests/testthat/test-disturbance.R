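test_that("disturbance schedules follow the interval distribution", {
  # degenerate uniform: events at exact multiples of 10
  reg10 <- disturbance_regime(10, 10)
  expect_identical(sample_disturbance_schedule(reg10, 100, seed = 1),
                   as.integer(seq(10, 100, by = 10)))

  # U(10, 20) waiting times bound the event count in [5, 10] over 100 years
  reg <- disturbance_regime(10, 20)
  counts <- vapply(1:200, function(s) {
    length(sample_disturbance_schedule(reg, 100, seed = s))
  }, integer(1))
  expect_true(all(counts >= 5 & counts <= 10))

  # strictly increasing, within horizon, reproducible
  sch <- sample_disturbance_schedule(reg, 100, seed = 77)
  expect_true(all(diff(sch) > 0))
  expect_true(all(sch >= 1 & sch <= 100))
  expect_identical(sch, sample_disturbance_schedule(reg, 100, seed = 77))
})

test_that("a pulse kills the same fraction in every class", {
  n <- c(8, 4, 4, 0, 0)
  expect_equal(apply_disturbance(n, 0), n)
  expect_equal(apply_disturbance(n, 1), rep(0, 5))
  expect_equal(apply_disturbance(n, 0.25), c(6, 3, 3, 0, 0))
  expect_error(apply_disturbance(n, 1.2), "\\[0, 1\\]")
})

test_that("a null regime reproduces the undisturbed ensemble under matched seeds", {
  d <- decompose(example_porites_matrix())
  dd <- density_dependence()
  n0 <- c(40, 20, 10, 4, 2)
  null_reg <- disturbance_regime(10, 20, kill_min = 0, kill_max = 0)
  e_null <- run_ensemble(d, dd, n0, recruitment_spec(), null_reg,
                         realizations = 8, horizon = 40, master_seed = 3)
  e_none <- run_ensemble(d, dd, n0, recruitment_spec(), regime = NULL,
                         realizations = 8, horizon = 40, master_seed = 3)
  expect_identical(e_null$cover, e_none$cover)

  # and a single no-regime realization equals one plain projection
  e1 <- run_ensemble(d, dd, n0, recruitment_spec(), regime = NULL,
                     realizations = 1, horizon = 40, master_seed = 9)
  seed_proj <- child_seed(child_seed(9, 1L), 1L)
  traj <- project_density_dependent(d, dd, n0, 40, recruitment_spec(),
                                    seed = seed_proj)
  expect_identical(e1$cover[1, ], unname(cover_series(traj)))
})

test_that("total kill with no recruitment extinguishes every realization", {
  d <- decompose(example_porites_matrix())
  dd <- density_dependence()
  reg <- disturbance_regime(10, 20, kill_min = 1, kill_max = 1)
  e <- run_ensemble(d, dd, c(40, 20, 10, 4, 2), no_recruitment(), reg,
                    realizations = 20, horizon = 60, master_seed = 5)
  expect_true(all(e$cover[, 61] == 0))
  expect_false(e$persistent)
})

test_that("the ensemble mean lies within the realized envelope and reruns bitwise", {
  d <- decompose(example_porites_matrix())
  dd <- density_dependence()
  e <- run_ensemble(d, dd, c(40, 20, 10, 4, 2), recruitment_spec(),
                    disturbance_regime(), realizations = 30, horizon = 50,
                    master_seed = 21)
  lo <- apply(e$cover, 2, min); hi <- apply(e$cover, 2, max)
  expect_true(all(e$mean_cover >= lo - 1e-12 & e$mean_cover <= hi + 1e-12))
  expect_true(all(e$quantiles >= matrix(lo, 3, 51, byrow = TRUE) - 1e-12))
  expect_true(all(e$quantiles <= matrix(hi, 3, 51, byrow = TRUE) + 1e-12))
  e2 <- run_ensemble(d, dd, c(40, 20, 10, 4, 2), recruitment_spec(),
                     disturbance_regime(), realizations = 30, horizon = 50,
                     master_seed = 21)
  expect_identical(e$cover, e2$cover)
})

test_that("stochastically harsher kill regimes lower mean cover at the horizon", {
  d <- decompose(example_porites_matrix())
  dd <- density_dependence()
  n0 <- c(40, 20, 10, 4, 2)
  harsh <- run_ensemble(d, dd, n0, recruitment_spec(),
                        disturbance_regime(kill_min = 0.5, kill_max = 1),
                        realizations = 500, horizon = 100, master_seed = 31)
  mild <- run_ensemble(d, dd, n0, recruitment_spec(),
                       disturbance_regime(kill_min = 0, kill_max = 0.5),
                       realizations = 500, horizon = 100, master_seed = 31)
  expect_lt(harsh$mean_cover[101], mild$mean_cover[101])
})

test_that("the recruitment sweep rises with the imported-recruitment level", {
  d <- decompose(example_porites_matrix())
  dd <- density_dependence()
  sw <- recruitment_sweep(d, dd, c(5, 0, 0, 3, 0),
                          recruit_means = c(0, 10, 25, 50), horizon = 60,
                          reps = 20, master_seed = 13)
  expect_gt(sw$fit$slope, 0)
  expect_true(all(diff(sw$table$mean_cover) > 0))

  # duplicate means agree up to Monte-Carlo error
  sw2 <- recruitment_sweep(d, dd, c(5, 0, 0, 3, 0),
                           recruit_means = c(0, 25, 25), horizon = 60,
                           reps = 40, master_seed = 13)
  delta <- abs(diff(sw2$table$mean_cover[2:3]))
  scale_mc <- max(sw2$table$sd_cover[2:3]) / sqrt(40)
  expect_lt(delta, 4 * scale_mc)
})

test_that("sweeping a closed subcritical population to zero recruits empties it", {
  S <- diag(rep(0.5, 5))
  d <- list(S = S, R = matrix(0, 5, 5))
  dd <- density_dependence()
  sw <- recruitment_sweep(d, dd, rep(10, 5), recruit_means = c(0, 25),
                          variance = 0, horizon = 80, reps = 2,
                          master_seed = 1)
  expect_lt(sw$table$mean_cover[sw$table$recruit_mean == 0], 1e-8)
})
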