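test_that("identifiability counts equations against free parameters", {
  st <- porites_structure()
  r <- check_identifiability(4, st)
  expect_identical(r$equations, 15L)
  expect_identical(r$unknowns, 12L)
  expect_true(r$identifiable)

  r2 <- check_identifiability(2, st)
  expect_identical(r2$equations, 5L)
  expect_false(r2$identifiable)

  r3 <- check_identifiability(2, stasis_structure(5))
  expect_identical(r3$equations, 5L)
  expect_identical(r3$unknowns, 5L)
  expect_true(r3$identifiable)
})

test_that("a constant positive series under stasis-only structure gives unit loops", {
  ser <- matrix(c(40, 30, 20, 10, 5), 5, 3)
  fit <- solve_wood(ser, stasis_structure(5))
  expect_equal(diag(unclass(fit$matrix)), rep(1, 5), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_lt(fit$rss, 1e-18)
})

test_that("a noise-free structured series is recovered to machine-level accuracy", {
  st <- porites_structure()
  for (seed in c(4, 17, 23)) {
    M <- generate_true_matrix(st, seed = seed)
    ser <- fix_series(M, c(120, 80, 60, 30, 10), 5)
    fit <- solve_wood(ser, st)
    expect_lt(max(abs(unclass(fit$matrix) - unclass(M))), 1e-6)
    expect_lt(fit$rss, 1e-12)
  }
})

test_that("the QP solution matches the projected-gradient oracle objective", {
  st3 <- fix_structure3()
  set.seed(31)
  for (rep in 1:6) {
    M <- generate_true_matrix(st3, seed = 300 + rep)
    n0 <- runif(3, 5, 50)
    ser <- fix_series(M, n0, 3)
    # perturb so the minimum is interior to neither constraint trivially
    ser_obs <- ser * matrix(exp(rnorm(length(ser), 0, 0.1)), nrow(ser))
    fit <- solve_wood(ser_obs, st3)
    oracle <- pg_oracle(ser_obs, st3, iters = 20000)
    expect_lt(abs(fit$rss - oracle$objective), 1e-6)
    expect_lte(fit$rss, oracle$objective + 1e-6)
  }
})

test_that("the estimate is invariant to uniform rescaling of the series", {
  st <- porites_structure()
  M <- generate_true_matrix(st, seed = 5)
  ser <- fix_series(M, c(90, 55, 35, 18, 6), 5)
  noisy <- ser * matrix(exp(rnorm(length(ser), 0, 0.05)), nrow(ser))
  f1 <- solve_wood(noisy, st)
  f2 <- solve_wood(noisy * 37.5, st)
  expect_equal(unclass(f1$matrix), unclass(f2$matrix), tolerance = 1e-7)
})

test_that("constraints hold exactly on returned matrices", {
  st <- porites_structure()
  set.seed(8)
  for (rep in 1:10) {
    M <- generate_true_matrix(st, seed = 800 + rep)
    ser <- fix_series(M, runif(5, 5, 120), 5)
    noisy <- ser * matrix(exp(rnorm(length(ser), 0, 0.2)), 5)
    V <- unclass(solve_wood(noisy, st)$matrix)
    expect_true(all(V >= 0))
    P <- matrix(0, 5, 5); P[cbind(st$arcs$target, st$arcs$source)] <- 1
    expect_true(all(V[P == 0] == 0))
    surv <- V; surv[1, 4] <- 0; surv[1, 5] <- 0
    expect_true(all(colSums(surv) <= 1 + 1e-8))
  }
})

test_that("recovery degrades gracefully under observation noise", {
  # tracked statistic: CV-5% noise, 10 transitions, errors pooled over the
  # nonzero entries of 100 replicates (the sample size the bound refers to;
  # smaller samples leave the median dominated by Monte-Carlo noise)
  st <- porites_structure()
  rel_errs <- lapply(1:100, function(s) {
    M <- generate_true_matrix(st, seed = 4000 + s)
    ser <- fix_series(M, c(150, 90, 60, 30, 12), 10)
    set.seed(9000 + s)
    noisy <- ser * matrix(exp(rnorm(length(ser), 0, 0.05)), 5)
    V <- unclass(solve_wood(noisy, st)$matrix)
    tru <- unclass(M)
    nz <- tru > 0
    abs(V[nz] - tru[nz]) / tru[nz]
  })
  expect_lt(stats::median(unlist(rel_errs)), 0.15)
})

test_that("degenerate and unidentifiable inputs are rejected or regularized", {
  st <- porites_structure()
  ser2 <- matrix(c(10, 5, 3, 2, 1, 9, 6, 3, 2, 1), 5, 2)
  expect_error(solve_wood(ser2, st), "not identifiable")
  ridge_fit <- solve_wood(ser2, st, ridge = 1e-6)
  expect_s3_class(ridge_fit$matrix, "transition_matrix")
  expect_false(ridge_fit$identifiable)
  expect_error(solve_wood(matrix(0, 5, 3), st), "all-zero")
})

test_that("decomposition partitions the matrix with disjoint supports", {
  st <- porites_structure()
  M <- generate_true_matrix(st, seed = 12)
  d <- decompose(M)
  expect_equal(d$S + d$R, unclass(M), ignore_attr = TRUE)
  expect_true(all(d$S * d$R == 0))
  expect_true(all(d$R[-1, ] == 0))

  # diagonal matrix: all survival, no fecundity
  D <- transition_matrix(diag(0.5, 5), stasis_structure(5))
  dd <- decompose(D)
  expect_equal(dd$S, unclass(D), ignore_attr = TRUE)
  expect_true(all(dd$R == 0))

  # fertility-only matrix
  Vf <- matrix(0, 5, 5); Vf[1, 4] <- 0.3; Vf[1, 5] <- 0.6
  Mf <- transition_matrix(Vf, porites_structure())
  df_ <- decompose(Mf)
  expect_true(all(df_$S == 0))
  expect_equal(df_$R, Vf, ignore_attr = TRUE)

  # entries off the structure are a structural error
  expect_error(decompose(matrix(1, 5, 5), st), "absent from the structure")
})

test_that("solve reports serialize to JSON with residuals and counts", {
  st <- porites_structure()
  M <- generate_true_matrix(st, seed = 2)
  ser <- fix_series(M, c(80, 40, 20, 10, 5), 5)
  fit <- solve_wood(ser, st)
  path <- withr::local_tempfile(fileext = ".json")
  write_solve_report(fit, path)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(rep$equations, 25L)
  expect_identical(rep$unknowns, 12L)
  expect_equal(dim(rep$residuals), c(5L, 5L))
})
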