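# Independent oracles used to cross-check the implementation.
# These deliberately take a different route (stats::lm, direct formulas)
# from the package internals.

# exhaustive onset-grid search with lm()-based zero-intercept slope
oracle_kill_fit <- function(times, fkill, t0_grid) {
  best <- NULL
  for (t0 in t0_grid) {
    keep <- times > t0 & fkill > 0
    if (sum(keep) < 2L) next
    x <- (times[keep] - t0)^2
    y <- fkill[keep]
    f <- stats::lm(y ~ 0 + x)
    rss <- sum(stats::residuals(f)^2)
    if (is.null(best) || rss < best$rss * (1 - 1e-12)) {
      best <- list(t0 = t0, slope = unname(stats::coef(f)), rss = rss,
                   n = sum(keep))
    }
  }
  best
}

# standard-additions concentration via lm()
oracle_standard_additions <- function(additions, signals) {
  f <- stats::lm(signals ~ additions)
  b <- unname(stats::coef(f)[1L])
  m <- unname(stats::coef(f)[2L])
  n <- length(additions)
  s_yx <- if (n > 2L) summary(f)$sigma else 0
  sxx <- sum((additions - mean(additions))^2)
  list(concentration = b / m,
       sd = (s_yx / m) * sqrt(1 / n + mean(signals)^2 / (m^2 * sxx)),
       slope = m, intercept = b)
}

# Pearson r from the definitional formula
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# conditional closed-form A at fixed B, for profiling RSS(B)
oracle_conditional_A <- function(B, si, theta) {
  e <- exp(B * si)
  sum(theta * e) / sum(e^2)
}

oracle_exp_rss <- function(B, si, theta) {
  A <- oracle_conditional_A(B, si, theta)
  sum((theta - A * exp(B * si))^2)
}

# noiseless study-scale cohort, handy across tests
noiseless_spec <- function(seed = 1L, ...) {
  cohort_spec(noise_sd_volume = 0, noise_sd_theta = 0, gfaa_noise_sd = 0,
              seed = seed, ...)
}
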