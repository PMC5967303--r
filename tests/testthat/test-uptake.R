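test_that("noiseless exponential data are recovered to high precision", {
  si <- seq(0.001, 0.006, length.out = 8)
  theta <- 0.001 * exp(500 * si)
  fit <- fit_uptake(si, theta)
  expect_lt(abs(fit$A - 0.001) / 0.001, 1e-8)
  expect_lt(abs(fit$B - 500) / 500, 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_true(fit$converged)
})

test_that("a flat uptake law degenerates to A = const, B = 0", {
  si <- seq(0.001, 0.006, length.out = 6)
  theta <- rep(0.004, 6)
  fit <- fit_uptake(si, theta)
  expect_equal(fit$A, 0.004, tolerance = 1e-6)
  expect_lt(abs(fit$B) * diff(range(si)), 1e-4)
})

test_that("the NLS solution is never worse than its log-linear start", {
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(5:40, 1)
    si <- runif(n, 0.001, 0.006)
    theta <- 5e-4 * exp(1200 * si) * exp(rnorm(n, 0, 0.3))
    fit <- fit_uptake(si, theta)
    expect_lte(fit$rss, fit$init$rss * (1 + 1e-12))
  }
})

test_that("the fit agrees with an independent Levenberg-Marquardt oracle", {
  skip_if_not_installed("minpack.lm")
  set.seed(37)
  for (rep in 1:10) {
    n <- 20
    si <- runif(n, 0.001, 0.006)
    theta <- 5e-4 * exp(1200 * si) * exp(rnorm(n, 0, 0.2))
    fit <- fit_uptake(si, theta)
    orc <- minpack.lm::nlsLM(
      theta ~ A * exp(B * si),
      start = list(A = fit$init$A, B = fit$init$B),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    expect_equal(fit$rss, sum(residuals(orc)^2), tolerance = 1e-6)
    expect_equal(fit$B, coef(orc)[["B"]], tolerance = 1e-3)
  }
})

test_that("the fit is equivariant under Si unit rescaling", {
  set.seed(41)
  si <- runif(12, 0.001, 0.006)
  theta <- 5e-4 * exp(1200 * si) * exp(rnorm(12, 0, 0.2))
  fit1 <- fit_uptake(si, theta)
  for (cc in c(100, 1e4)) {
    fit2 <- fit_uptake(si * cc, theta)
    expect_equal(fit2$B * cc, fit1$B, tolerance = 1e-6)
    expect_equal(fit2$r_squared, fit1$r_squared, tolerance = 1e-9)
    expect_equal(predict(fit2, si * cc), predict(fit1, si),
                 tolerance = 1e-8)
  }
})

test_that("prediction follows A*exp(B*si) with its doubling property", {
  si <- seq(0.001, 0.006, length.out = 5)
  fit <- fit_uptake(si, 0.001 * exp(500 * si))
  expect_equal(predict(fit, 0), fit$A, tolerance = 1e-10)
  s0 <- 0.002
  expect_equal(predict(fit, s0 + log(2) / fit$B), 2 * predict(fit, s0),
               tolerance = 1e-8)

  flat <- fit_uptake(si, rep(0.004, 5))
  expect_equal(predict(flat, c(0, 0.01, 0.5)),
               rep(flat$A, 3), tolerance = 1e-4)
})

test_that("formula interface matches the vector interface", {
  fx <- load_table1_fixture()
  keep <- filter_eligible(fx$fits)$retained
  f1 <- fit_uptake(keep$si_mass_percent, keep$theta_f)
  f2 <- fit_uptake(theta_f ~ si_mass_percent, data = keep)
  expect_equal(coef(f1), coef(f2))
  expect_equal(f1$r_squared, f2$r_squared)
})

test_that("predicted kill series obey the quadratic law and the cap", {
  si <- seq(0.001, 0.006, length.out = 5)
  fit <- fit_uptake(si, 0.001 * exp(500 * si))
  ps <- predict_fkill_series(fit, log(10) / fit$B, 0, c(0, 1, 2, 3))
  expect_equal(ps$fkill, 0.01 * c(0, 1, 4, 9), tolerance = 1e-8)
  expect_false(attr(ps, "capped"))
  expect_identical(ps$fkill[1], 0)

  big <- predict_fkill_series(fit, log(1000) / fit$B, 0, c(0, 1, 2, 3))
  expect_true(attr(big, "capped"))
  expect_true(all(big$fkill <= 1 & big$fkill >= 0))
  expect_true(all(diff(big$fkill) >= 0))
})

test_that("validation correlation matches the definitional Pearson formula", {
  mk <- function(id, v) fkill_series(id, 0, c(1, 2, 3), v)
  obs <- list(mk("a", c(0.1, 0.2, 0.3)), mk("b", c(0.05, 0.15, 0.4)))
  same <- validate_predictions(obs, obs)
  expect_equal(same$pearson_r, 1)

  anti <- lapply(obs, function(o)
    fkill_series(o$subject_id, 0, o$times, mean(o$fkill) * 2 - o$fkill))
  expect_equal(validate_predictions(obs, anti)$pearson_r, -1)

  # Pearson r is affine-invariant, so the scaled-down pairs carry the
  # same correlation as the raw (0, 0.1), (1, 0.9), (2, 2.1) triplet
  o <- list(fkill_series("x", 0, c(1, 2, 3), c(0, 1, 2) / 10))
  p <- list(fkill_series("x", 0, c(1, 2, 3), c(0.1, 0.9, 2.1) / 10))
  got <- validate_predictions(o, p)
  expect_equal(got$pearson_r, oracle_pearson(c(0, 1, 2), c(0.1, 0.9, 2.1)))
  expect_equal(got$n_pairs, 3L)

  short <- list(fkill_series("a", 0, c(1, 2), c(0.1, 0.2)))
  expect_error(validate_predictions(short, short), "3")
})

test_that("uptake fit refuses unusable input", {
  expect_error(fit_uptake(c(1, 2), c(1, 2)), "3")
  expect_error(fit_uptake(c(0.001, 0.002, 0.003), c(0.1, -0.1, 0.2)),
               "positive")
})
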