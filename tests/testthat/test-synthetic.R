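test_that("the study-design spec carries the published design constants", {
  spec <- table1_like_cohort(seed = 3)
  expect_equal(spec$measurement_days, c(0, 3, 7, 8, 9))
  expect_equal(spec$n_per_group, 7L)
  expect_equal(spec$si_range, c(0.001, 0.006))
  a <- table1_like_cohort(seed = 1)
  b <- table1_like_cohort(seed = 2)
  a$seed <- b$seed <- NULL
  expect_identical(a, b)  # only the seed varies between calls
})

test_that("simulation is deterministic given the seed", {
  s1 <- simulate_cohort(table1_like_cohort(seed = 99))
  s2 <- simulate_cohort(table1_like_cohort(seed = 99))
  expect_identical(s1$tumors, s2$tumors)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$gfaa, s2$gfaa)
  s3 <- simulate_cohort(table1_like_cohort(seed = 100))
  expect_false(identical(s1$truth, s3$truth))
})

test_that("generated cohorts satisfy the physical invariants", {
  for (seed in 1:5) {
    sim <- simulate_cohort(table1_like_cohort(seed = seed))
    vols <- unlist(lapply(sim$tumors, `[[`, "volumes"))
    expect_true(all(vols > 0))
    ref <- control_reference(
      sim$tumors[vapply(sim$tumors, `[[`, "", "group") == "control"])
    for (id in sim$truth$subject_id) {
      fk <- compute_fkill(sim$tumors[[id]], ref, 0)
      expect_true(all(fk$fkill < 1))
    }
  }
})

test_that("generator and analyzer are an inverse pair without noise", {
  sim <- simulate_cohort(noiseless_spec(seed = 8))
  groups <- vapply(sim$tumors, `[[`, "", "group")
  ref <- control_reference(sim$tumors[groups == "control"])
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    fk <- compute_fkill(sim$tumors[[tr$subject_id]], ref, 0)
    expected <- ifelse(fk$times >= tr$t0_true,
                       pmin(tr$theta_true * (fk$times - tr$t0_true)^2, 0.99),
                       0)
    expect_equal(fk$fkill, expected, tolerance = 1e-12)

    fit <- fit_kill_curve(fk)
    if (max(expected) < 0.99 && fit$n_points >= 2) {  # away from the cap
      expect_identical(fit$t0, tr$t0_true)
      expect_lt(abs(fit$theta_f - tr$theta_true) / tr$theta_true, 1e-8)
    }
  }
})

test_that("a flat generative law is recovered as B ~ 0", {
  spec <- cohort_spec(n_per_group = 30, theta_law = c(A = 4e-3, B = 0),
                      t0_weights = c(`0` = 1), noise_sd_volume = 0,
                      noise_sd_theta = 0.1, seed = 17)
  sim <- simulate_cohort(spec)
  res <- run_fit_response(sim$tumors)
  up <- run_fit_uptake(res$table, sim$biodistribution)
  se_b <- summary(up$model)$coefficients["B", "Std. Error"]
  expect_lt(abs(up$model$B), 2 * se_b)
})

test_that("uptake-law intervals cover the generative truth at study scale", {
  # 200 cohorts of 7 mice at the default noise; 95% t-based intervals
  # (the standard small-sample choice for a 2-parameter regression) from
  # the fit's SEs should cover the generative A* and B* in at least 80%
  # of cohorts (small-n fragility is the point of the check)
  spec0 <- table1_like_cohort()
  a_star <- spec0$theta_law[["A"]]
  b_star <- spec0$theta_law[["B"]]
  cover_a <- cover_b <- 0L
  fitted <- 0L
  for (seed in 1:200) {
    sim <- simulate_cohort(table1_like_cohort(seed = 3000 + seed))
    res <- try(run_fit_response(sim$tumors), silent = TRUE)
    if (inherits(res, "try-error")) next
    up <- tryCatch(run_fit_uptake(res$table, sim$biodistribution),
                   msnpkill_config_error = function(cnd) NULL,
                   error = function(cnd) NULL)
    if (is.null(up) || !all(is.finite(up$model$se))) next
    fitted <- fitted + 1L
    z <- stats::qt(0.975, up$model$n_subjects - 2L)
    if (abs(up$model$A - a_star) <= z * up$model$se[["A"]])
      cover_a <- cover_a + 1L
    if (abs(up$model$B - b_star) <= z * up$model$se[["B"]])
      cover_b <- cover_b + 1L
  }
  expect_gt(fitted, 150L)
  expect_gte(cover_a / fitted, 0.80)
  expect_gte(cover_b / fitted, 0.80)
})

test_that("cohorts round-trip through the on-disk table formats", {
  sim <- simulate_cohort(table1_like_cohort(seed = 12))
  dir <- withr::local_tempdir()
  paths <- write_cohort(sim, dir)
  back <- read_tumor_table(paths[["tumors"]])
  expect_identical(names(back), names(sim$tumors))
  expect_equal(back[["MSNP 3"]]$volumes, sim$tumors[["MSNP 3"]]$volumes,
               tolerance = 1e-12)
  biod <- read_biodistribution_table(paths[["biodistribution"]])
  expect_equal(nrow(biod), nrow(sim$biodistribution))
  curves <- read_gfaa_table(paths[["gfaa"]])
  expect_equal(curves[["MSNP 1"]]$signals, sim$gfaa[["MSNP 1"]]$signals,
               tolerance = 1e-12)
})

test_that("impossible generator settings are rejected", {
  expect_error(cohort_spec(si_range = c(0, 0.5)), "si_range")
  expect_error(cohort_spec(measurement_days = c(3, 1)), "increasing")
  expect_error(cohort_spec(growth_rate = -0.1))
})
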