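test_that("a noiseless affine spike curve is quantified exactly", {
  cv <- addition_curve("s1", "tumor", c(0, 1, 2), c(2, 3, 4))
  est <- standard_additions(cv)
  expect_equal(est$concentration, 2)
  expect_equal(est$slope, 1)
  expect_equal(est$intercept, 2)
  expect_equal(est$sd, 0)

  # any noiseless line: zero residual, zero sd
  set.seed(5)
  for (rep in 1:20) {
    m <- runif(1, 0.1, 50); c0 <- runif(1, 0.1, 10)
    x <- c(0, sort(runif(4, 0.5, 10)))
    cv <- addition_curve("s", "liver", x, m * (x + c0))
    est <- standard_additions(cv)
    expect_equal(est$concentration, c0, tolerance = 1e-10)
    expect_equal(est$sd, 0, tolerance = 1e-8)
  }
})

test_that("quantification is signal-scale invariant and addition-unit equivariant", {
  x <- c(0, 1, 2, 4)
  y <- 3 * (x + 1.5) + c(0.01, -0.02, 0.015, -0.005)
  base <- standard_additions(addition_curve("s", "tumor", x, y))
  scaled <- standard_additions(addition_curve("s", "tumor", x, y * 10))
  expect_equal(scaled$concentration, base$concentration, tolerance = 1e-12)
  units <- standard_additions(addition_curve("s", "tumor", x * 100, y))
  expect_equal(units$concentration, base$concentration * 100,
               tolerance = 1e-10)
})

test_that("noisy curves match the lm-based OLS oracle exactly", {
  set.seed(13)
  for (rep in 1:50) {
    x <- c(0, 2, 4, 8, 12)
    y <- 0.05 * (x + 5) + rnorm(5, 0, 0.01)
    cv <- addition_curve("s", "kidney", x, y)
    est <- standard_additions(cv)
    orc <- oracle_standard_additions(x, y)
    expect_equal(est$concentration, orc$concentration, tolerance = 1e-12)
    expect_equal(est$sd, orc$sd, tolerance = 1e-12)
    expect_equal(est$slope, orc$slope, tolerance = 1e-12)
  }
})

test_that("unusable curves are rejected with informative errors", {
  expect_error(standard_additions(
    addition_curve("s", "tumor", c(0, 1, 2), c(4, 3, 2))), "slope")
  expect_error(addition_curve("s", "tumor", c(0, 1), c(1, 2)), "3 points")
  expect_error(addition_curve("s", "tumor", c(1, 2, 3), c(1, 2, 3)),
               "zero-addition")
  expect_error(addition_curve("s", "tumor", c(0, -1, 2), c(1, 2, 3)),
               "non-negative")
})

test_that("baseline subtraction keeps below-background values but flags them", {
  cfg <- study_config(control_baseline = c(tumor = 0.001, liver = 0))
  net <- subtract_baseline(0.005, "tumor", cfg)
  expect_equal(net$net_si_mass_percent, 0.004)
  expect_false(net$below_baseline)

  low <- subtract_baseline(0.0005, "tumor", cfg)
  expect_equal(low$net_si_mass_percent, -0.0005)
  expect_true(low$below_baseline)
  expect_equal(delivery_efficiency(low$net_si_mass_percent, "tumor",
                                   study_config()), 0)

  zero <- subtract_baseline(0.003, "liver", cfg)
  expect_equal(zero$net_si_mass_percent, 0.003)

  expect_error(subtract_baseline(0.001, "brain", cfg), "brain")
})

test_that("delivery efficiency follows the mass-balance arithmetic", {
  # 1 mg particles/dose x 4 doses x 0.3936 -> 1.5744 mg injected Si
  cfg <- study_config()
  expect_equal(injected_si_mass(cfg), 1.5744)

  # net 0.01% of a 1 g organ = 0.1 mg Si; against 1 mg injected -> 10 %ID
  cfg1 <- study_config(particle_mass_per_dose_mg = 1 / 0.3936, n_doses = 1,
                       organ_reference_masses = c(tumor = 1))
  expect_equal(delivery_efficiency(0.01, "tumor", cfg1), 10)
  expect_equal(delivery_efficiency(0, "tumor", cfg1), 0)

  # linear in net Si and in organ mass; organ %IDs add like pooled mass
  expect_equal(delivery_efficiency(0.02, "tumor", cfg1),
               2 * delivery_efficiency(0.01, "tumor", cfg1))
  cfg2 <- study_config(particle_mass_per_dose_mg = 1 / 0.3936, n_doses = 1,
                       organ_reference_masses = c(tumor = 2))
  expect_equal(delivery_efficiency(0.01, "tumor", cfg2),
               2 * delivery_efficiency(0.01, "tumor", cfg1))

  cfg3 <- study_config(organ_reference_masses = c(tumor = 0.5, liver = 1.0),
                       control_baseline = c(tumor = 0, liver = 0))
  sep <- delivery_efficiency(0.01, "tumor", cfg3) +
    delivery_efficiency(0.01, "liver", cfg3)
  pooled <- study_config(organ_reference_masses = c(tumor = 1.5),
                         control_baseline = c(tumor = 0))
  expect_equal(sep, delivery_efficiency(0.01, "tumor", pooled))
})

test_that("percent-ID tables zero out below-baseline rows and flag them", {
  cfg <- study_config(control_baseline = c(tumor = 0.001, liver = 0.001))
  biod <- data.frame(
    subject_id = c("m1", "m1"), organ = c("tumor", "liver"),
    si_mass_percent = c(0.004, 0.0002))
  tab <- percent_id_table(biod, cfg)
  expect_equal(tab$net_si_mass_percent, c(0.003, -0.0008))
  expect_identical(tab$below_baseline, c(FALSE, TRUE))
  expect_equal(tab$percent_id[2], 0)
  expect_gt(tab$percent_id[1], 0)
})
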