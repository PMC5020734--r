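test_that("linear projection applies the matrix and recruit vector", {
  # identity matrix, no recruits: constant
  out <- project_linear(diag(5), c(9, 7, 5, 3, 1), 4)
  expect_true(all(out == c(9, 7, 5, 3, 1)))

  # zero matrix isolates the recruit sequence
  outz <- project_linear(matrix(0, 5, 5), rep(2, 5), 5,
                         recruitment_spec(c(5, 0, 0, 3, 0), 0, 0))
  expect_equal(outz[, 2], c(5, 0, 0, 0, 0), ignore_attr = TRUE)
  expect_true(all(outz[, 3] == 0) && all(outz[, 4] == 0))
  expect_equal(outz[, 5], c(3, 0, 0, 0, 0), ignore_attr = TRUE)

  # one step equals the brute-force product
  M <- unclass(example_porites_matrix())
  n0 <- c(31, 17, 8, 4, 2)
  expect_equal(project_linear(M, n0, 1)[, 2], slow_matvec(M, n0),
               ignore_attr = TRUE)

  expect_error(project_linear(M, c(1, 2), 3), "length")
})

test_that("pooled hindcast R-squared matches its definition", {
  obs <- matrix(c(4, 7, 2, 9), 2, 2)
  expect_equal(hindcast_fit(obs, obs)$r_squared, 1)

  # predicting the grand mean everywhere gives exactly zero
  gm <- matrix(mean(obs), 2, 2)
  expect_equal(hindcast_fit(gm, obs)$r_squared, 0)

  # toy case against hand arithmetic
  pred <- matrix(c(5, 6, 3, 8), 2, 2)
  sse <- sum((obs - pred)^2)            # 1+1+1+1 = 4
  sst <- sum((obs - mean(obs))^2)       # mean 5.5 -> 2.25+2.25+12.25+12.25
  expect_equal(hindcast_fit(pred, obs)$r_squared, 1 - sse / sst)
  expect_equal(hindcast_fit(pred, obs)$r_squared, 1 - 4 / 29)

  expect_error(hindcast_fit(matrix(1, 2, 2), matrix(3, 2, 2)), "undefined")
})

test_that("Ricker factors follow exp(-b n)", {
  dd <- density_dependence(b = rep(0, 5))
  expect_equal(ricker_factors(c(10, 20, 30, 40, 50), dd), rep(1, 5))

  dd2 <- density_dependence()
  f <- ricker_factors(c(0, 0, 1000, 0, 0), dd2)
  expect_equal(f[3], exp(-1))
  expect_equal(f[c(1, 2, 4, 5)], rep(1, 4))

  # monotone nonincreasing in each abundance
  ns <- seq(0, 5000, by = 250)
  fs <- vapply(ns, function(n) ricker_factors(c(0, 0, n, 0, 0), dd2)[3],
               numeric(1))
  expect_true(all(diff(fs) <= 0))
  expect_true(all(fs > 0 & fs <= 1))
})

test_that("density-free deterministic projection reduces to the linear model bitwise", {
  M <- example_porites_matrix()
  d <- decompose(M)
  dd0 <- density_dependence(b = rep(0, 5))
  rec <- recruitment_spec(c(5, 0, 0, 3, 0), mean = 0, variance = 0)
  n0 <- c(60, 35, 20, 8, 3)
  a <- project_density_dependent(d, dd0, n0, 50, rec, seed = 1)
  b <- project_linear(d$S + d$R, n0, 50, rec)
  expect_identical(unname(a), unname(b))
})

test_that("subcritical survival without recruitment decays to extinction", {
  S <- diag(c(0.4, 0.4, 0.4, 0.4, 0.4))
  d <- list(S = S, R = matrix(0, 5, 5))
  dd <- density_dependence()
  out <- project_density_dependent(d, dd, rep(100, 5), 60, no_recruitment())
  expect_lt(sum(out[, 61]), 1e-10)
})

test_that("the default forecast stays bounded and nonnegative for 100 years", {
  d <- decompose(example_porites_matrix())
  dd <- density_dependence()    # b = 0.001 on the three largest classes
  out <- project_density_dependent(d, dd, c(5, 0, 0, 3, 0), 100,
                                   recruitment_spec(), seed = 42)
  expect_true(all(out >= 0))
  expect_true(all(is.finite(out)))
  expect_lt(max(out), 1e5)
  # same seed, same trajectory, bitwise
  out2 <- project_density_dependent(d, dd, c(5, 0, 0, 3, 0), 100,
                                    recruitment_spec(), seed = 42)
  expect_identical(out, out2)
})

test_that("the undriven growth factor converges to the dominant eigenvalue of S + R", {
  d <- decompose(example_porites_matrix())
  dd0 <- density_dependence(b = rep(0, 5))
  out <- project_density_dependent(d, dd0, c(100, 40, 20, 10, 5), 200,
                                   no_recruitment())
  lam_hat <- sum(out[, 201]) / sum(out[, 200])
  ev <- eigen(d$S + d$R)$values
  lam <- max(Re(ev[abs(Im(ev)) < 1e-12]))
  expect_lt(abs(lam_hat - lam), 1e-6)
})

test_that("cover conversion sums per-class circle areas over the reference area", {
  sc <- size_class_scheme()
  expect_equal(cover_from_vector(rep(0, 5), sc)$total_pct, 0)

  # one SC5 colony at its 50 cm representative diameter on 300 m^2
  cv <- cover_from_vector(c(0, 0, 0, 0, 1), sc, 300)
  expect_equal(cv$total_pct, 100 * pi * 0.25^2 / 300, tolerance = 1e-12)
  expect_equal(cv$total_pct, 0.06544985, tolerance = 1e-6)

  # linear in abundance
  n <- c(12, 8, 5, 3, 1)
  expect_equal(cover_from_vector(2 * n, sc)$total_pct,
               2 * cover_from_vector(n, sc)$total_pct)
  expect_equal(cover_from_vector(n, sc)$total_pct,
               sum(cover_from_vector(n, sc)$per_class_pct))
  expect_error(cover_from_vector(n, sc, 0), "> 0")
})

test_that("stability detection finds the plateau onset", {
  expect_identical(time_to_stability(rep(4.2, 40), window = 10), 0L)
  expect_true(is.na(time_to_stability(2^(seq(0, 8, length.out = 50)),
                                      window = 10, rel_tol = 0.01)))
  # saturating ramp with an exact plateau from t = 40
  s <- c(seq(0, 30, length.out = 41), rep(30, 59))
  det <- time_to_stability(s, window = 20, rel_tol = 0.05)
  expect_lte(abs(det - 40L), 2L)
})
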