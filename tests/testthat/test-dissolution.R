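test_that("weibull_fraction matches its defining identities", {
  # half-dissolution at td50 for the fitted fast-release parameters
  p <- weibull_params(td50 = 9.7, shape = 1.37)
  expect_equal(weibull_fraction(9.7, p), 0.5)
  # hand-evaluated closed form at t = 30
  expect_equal(weibull_fraction(30, p), 0.9614346, tolerance = 1e-6)
  # nothing released at or before the lag
  pl <- weibull_params(td50 = 10, shape = 1.5, tlag = 12)
  expect_equal(weibull_fraction(12, pl), 0)
  expect_equal(weibull_fraction(5, pl), 0)
  expect_equal(weibull_fraction(12 + 10, pl), 0.5)
})

test_that("weibull_fraction is a CDF for random valid parameters", {
  set.seed(101)
  for (i in 1:50) {
    p <- weibull_params(td50 = runif(1, 0.5, 300),
                        shape = runif(1, 0.2, 5),
                        tlag = runif(1, 0, 30))
    t <- sort(runif(200, 0, 1000))
    f <- weibull_fraction(t, p)
    expect_true(all(f >= 0 & f <= 1))
    expect_true(all(diff(f) >= 0))
    expect_equal(weibull_fraction(p$tlag + p$td50, p), 0.5)
    # far tail: t with ln2 (t/td50)^shape = ln2 * 20 gives F = 1 - 2^-20
    expect_gt(weibull_fraction(p$tlag + p$td50 * 20^(1 / p$shape), p),
              0.999)
  }
})

test_that("parameter validation rejects invalid Weibull parameters", {
  expect_error(weibull_params(td50 = 0, shape = 1), "td50")
  expect_error(weibull_params(td50 = -3, shape = 1), "td50")
  expect_error(weibull_params(td50 = 10, shape = 0), "shape")
  expect_error(weibull_params(td50 = 10, shape = 1, tlag = -1), "tlag")
})

test_that("weibull_hazard special cases and consistency with the CDF", {
  # exponential special case: constant hazard ln2/td50
  p1 <- weibull_params(td50 = 10, shape = 1)
  expect_equal(weibull_hazard(5, p1), log(2) / 10)
  expect_equal(weibull_hazard(500, p1), log(2) / 10)
  # zero before the lag
  pl <- weibull_params(td50 = 10, shape = 1.4, tlag = 8)
  expect_equal(weibull_hazard(8, pl), 0)
  expect_equal(weibull_hazard(3, pl), 0)

  # integrating dS/dt = -h(t) S reproduces 1 - F(t) to 1e-6
  for (pars in list(weibull_params(9.7, 1.37), weibull_params(77.22, 1.06),
                    weibull_params(30, 2, tlag = 10))) {
    rhs <- function(t, y, parms) list(-weibull_hazard(t, pars) * y)
    tt <- seq(0, 400, by = 0.5)
    sol <- deSolve::lsoda(c(S = 1), tt, rhs, NULL,
                          rtol = 1e-10, atol = 1e-12)
    expect_equal(unname(sol[, "S"]), 1 - weibull_fraction(tt, pars),
                 tolerance = 1e-6)
  }
})

test_that("dissolution_profile validates its contract", {
  expect_error(dissolution_profile(c(5, 10), c(10, 20)), "3 sampling")
  expect_error(dissolution_profile(c(5, 10, 10), c(1, 2, 3)), "increasing")
  expect_error(dissolution_profile(c(5, 10, 15), c(1, 2)), "equal length")
  expect_error(dissolution_profile(c(5, 10, 15), c(1, 2, 150)), "105")
  p <- dissolution_profile(c(5, 10, 15), c(10, 30, 50), medium_ph = 6.8)
  expect_s3_class(p, "dissolution_profile")
})

test_that("fit_weibull recovers generating parameters from noiseless data", {
  # slow-release truth at the long in vitro schedule
  truth <- weibull_params(td50 = 77.22, shape = 1.06)
  tt <- dissolution_schedule("glyburide")
  prof <- dissolution_profile(tt, 100 * weibull_fraction(tt, truth))
  fit <- fit_weibull(prof)
  expect_equal(fit$params$td50, 77.22, tolerance = 1e-3)
  expect_equal(fit$params$shape, 1.06, tolerance = 1e-3)
  expect_lt(fit$rss, 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-8)

  # round-trip to 1e-4 relative across several parameter sets
  set.seed(7)
  for (i in 1:8) {
    truth <- weibull_params(runif(1, 5, 100), runif(1, 0.7, 2.5))
    tt <- sort(c(truth$td50 * c(0.2, 0.5, 1, 1.5, 2.5, 4), 5))
    prof <- dissolution_profile(tt, 100 * weibull_fraction(tt, truth))
    fit <- fit_weibull(prof)
    expect_equal(fit$params$td50, truth$td50, tolerance = 1e-4)
    expect_equal(fit$params$shape, truth$shape, tolerance = 1e-4)
  }
})

test_that("fit_weibull tolerates measurement noise (5% td50 recovery)", {
  truth <- weibull_params(td50 = 10, shape = 1.2)
  tt <- dissolution_schedule("metformin")
  set.seed(42)
  rel_err <- replicate(100, {
    pct <- pmin(pmax(100 * weibull_fraction(tt, truth) + rnorm(6, 0, 2),
                     0), 105)
    fit <- fit_weibull(dissolution_profile(tt, pct))
    abs(fit$params$td50 - 10) / 10
  })
  # typical-case tolerance: the bulk of seeds recover td50 within 5%
  expect_lt(median(rel_err), 0.05)
  expect_lt(mean(rel_err), 0.08)
})

test_that("fit_weibull rejects degenerate profiles", {
  expect_error(fit_weibull(dissolution_profile(c(5, 10, 15), c(0, 0, 0))),
               "nonzero|all-zero")
})

test_that("f2 similarity matches the regulatory formula", {
  tt <- c(5, 10, 15, 30, 45, 60)
  r <- c(20, 40, 55, 70, 78, 84)
  ref <- dissolution_profile(tt, r)
  # identical profiles -> 100
  expect_equal(f2_similarity(ref, ref)$f2, 100)
  # constant offsets: direct formula oracles
  expect_equal(f2_similarity(ref, dissolution_profile(tt, r + 10))$f2,
               49.89197, tolerance = 1e-5)
  expect_equal(f2_similarity(ref, dissolution_profile(tt, r + 2))$f2,
               82.52575, tolerance = 1e-5)
  # symmetry
  tst <- dissolution_profile(tt, r + 7)
  expect_equal(f2_similarity(ref, tst)$f2, f2_similarity(tst, ref)$f2)
  # decreasing in a growing uniform offset
  f2s <- sapply(c(1, 3, 5, 8, 12), function(d)
    f2_similarity(ref, dissolution_profile(tt, r + d))$f2)
  expect_true(all(diff(f2s) < 0))
})

test_that("f2 applies the 85% rule and validates grids", {
  tt <- c(5, 10, 15, 30, 45, 60)
  ref <- dissolution_profile(tt, c(30, 60, 80, 90, 96, 99))
  tst <- dissolution_profile(tt, c(28, 57, 78, 88, 95, 99))
  res <- f2_similarity(ref, tst)
  # both exceed 85% from t=30 on: keep 30, drop 45 and 60
  expect_equal(res$dropped, c(45, 60))
  expect_equal(res$n_points, 4)
  expect_error(
    f2_similarity(ref, dissolution_profile(c(5, 10, 20, 30, 45, 60),
                                           c(28, 57, 78, 88, 95, 99))),
    "identical time grid")
})
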