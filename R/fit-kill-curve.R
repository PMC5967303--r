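#' Fit the quadratic kill law with onset-day optimization
#'
#' Fits \eqn{f_{kill} = \theta_f (t - t_0)^2} to one subject's
#' kill-fraction series. The onset day \eqn{t_0} — the first day the tumor
#' shows a positive response — is optimized over a grid of candidate
#' integer measurement days: for each candidate, \eqn{\theta_f} is the
#' zero-intercept least-squares slope of `fkill` against \eqn{(t - t_0)^2}
#' over the points with `t > t0` and `fkill > 0`, and the candidate with
#' the smallest residual sum of squares wins (ties, to within 1e-12
#' relative, go to the earliest onset day).
#'
#' The regression has no intercept because the law forces
#' \eqn{f_{kill}(t_0) = 0}. Non-positive kill fractions after the
#' candidate onset are excluded from the fit: the mechanistic derivation
#' of the law presumes onset of a positive response. A subject is
#' `eligible` for the cross-subject uptake fit only when at least 3
#' positive post-onset points support the fit; with 2 points a slope can
#' be computed but no p-value, mirroring how late responders are excluded
#' in practice.
#'
#' `r_squared` is \eqn{1 - SSR/SST} over the fitted points with SST taken
#' about their mean (a declared convention; zero-intercept fits admit an
#' about-zero convention too). `p_value` is from the F-test of the
#' zero-intercept quadratic model against the zero model on
#' (1, n_points - 1) degrees of freedom. Both are `NA` when fewer than 3
#' points support the fit.
#'
#' @param fk An [fkill_series()].
#' @param t0_grid Candidate onset days. Default: the integer measurement
#'   days of the series except the last two (at least two points must
#'   remain after the onset).
#' @return An object of class `"kill_fit"` with fields `subject_id`,
#'   `theta_f`, `t0`, `r_squared`, `p_value`, `n_points`, `eligible`,
#'   `rss`, and `grid` (the per-candidate search table). If no candidate
#'   leaves at least 2 positive points, `theta_f` and `t0` are `NA` and
#'   `eligible` is `FALSE`; this is a result, not an error.
#' @examples
#' fk <- fkill_series("m1", 0, c(0, 1, 2, 3), c(0, 0.01, 0.04, 0.09))
#' fit_kill_curve(fk)
#' @export
fit_kill_curve <- function(fk, t0_grid = NULL) {
  stopifnot(inherits(fk, "fkill_series"))
  if (is.null(t0_grid)) {
    cand <- fk$times[fk$times == round(fk$times)]
    n <- length(cand)
    t0_grid <- if (n > 2L) cand[seq_len(n - 2L)] else numeric(0)
  }
  grid <- lapply(t0_grid, function(t0) {
    keep <- fk$times > t0 & fk$fkill > 0
    n <- sum(keep)
    if (n < 2L)
      return(list(t0 = t0, slope = NA_real_, rss = NA_real_, n = n))
    x <- (fk$times[keep] - t0)^2
    y <- fk$fkill[keep]
    slope <- sum(x * y) / sum(x * x)
    list(t0 = t0, slope = slope, rss = sum((y - slope * x)^2), n = n)
  })
  grid <- do.call(rbind, lapply(grid, as.data.frame))
  fit <- list(subject_id = fk$subject_id, theta_f = NA_real_, t0 = NA_real_,
              r_squared = NA_real_, p_value = NA_real_, n_points = 0L,
              eligible = FALSE, rss = NA_real_, grid = grid, series = fk)
  ok <- !is.na(grid$rss)
  if (!any(ok)) {
    fit$n_points <- if (nrow(grid)) max(grid$n) else 0L
    class(fit) <- "kill_fit"
    return(fit)
  }
  best_rss <- min(grid$rss[ok])
  tol <- 1e-12 * max(best_rss, 1e-300)
  # ties go to the earliest onset day
  i <- which(ok & grid$rss <= best_rss + tol)[1L]
  slope <- grid$slope[i]
  n <- grid$n[i]
  fit$t0 <- grid$t0[i]
  fit$theta_f <- max(slope, 0)
  fit$n_points <- as.integer(n)
  fit$rss <- grid$rss[i]
  fit$eligible <- n >= 3L && slope > 0
  if (n >= 3L && slope > 0) {
    keep <- fk$times > fit$t0 & fk$fkill > 0
    y <- fk$fkill[keep]
    sst <- sum((y - mean(y))^2)
    # floored at 0: a zero-intercept fit can have RSS above the
    # about-mean SST when the quadratic explains less than the mean does
    fit$r_squared <- if (sst > 0) max(0, 1 - fit$rss / sst) else 1
    rss0 <- sum(y^2)  # zero model
    if (fit$rss > 0) {
      F <- (rss0 - fit$rss) / (fit$rss / (n - 1))
      fit$p_value <- stats::pf(F, 1, n - 1, lower.tail = FALSE)
    } else fit$p_value <- 0
  }
  class(fit) <- "kill_fit"
  fit
}

#' @export
print.kill_fit <- function(x, ...) {
  cat(sprintf("Quadratic kill fit '%s':\n", x$subject_id))
  if (is.na(x$theta_f)) {
    cat("  no onset day leaves >= 2 positive response points; not fitted\n")
  } else {
    cat(sprintf("  theta_f = %.6g /day^2, t0 = %g d, n = %d points%s\n",
                x$theta_f, x$t0, x$n_points,
                if (x$eligible) "" else " (ineligible)"))
    if (!is.na(x$r_squared))
      cat(sprintf("  R^2 = %.4f, p = %.4g\n", x$r_squared, x$p_value))
  }
  invisible(x)
}

#' @export
coef.kill_fit <- function(object, ...) {
  c(theta_f = object$theta_f, t0 = object$t0)
}

#' @export
predict.kill_fit <- function(object, times = object$series$times, ...) {
  if (is.na(object$theta_f)) return(rep(NA_real_, length(times)))
  pmax(times - object$t0, 0)^2 * object$theta_f
}

#' @export
summary.kill_fit <- function(object, ...) {
  out <- as.data.frame(object[c("subject_id", "theta_f", "t0", "n_points",
                                "r_squared", "p_value", "eligible")])
  class(out) <- c("summary.kill_fit", "data.frame")
  out
}

#' @export
plot.kill_fit <- function(x, ...) {
  s <- x$series
  graphics::plot(s$times, s$fkill, xlab = "day", ylab = "f_kill",
                 main = x$subject_id, ...)
  if (!is.na(x$theta_f)) {
    tt <- seq(min(s$times), max(s$times), length.out = 100)
    graphics::lines(tt, predict(x, tt))
    graphics::abline(v = x$t0, lty = 2)
  }
  invisible(x)
}

#' Tabulate a list of kill fits
#'
#' One row per subject: `subject_id`, `theta_f`, `t0`, `n_points`,
#' `r_squared`, `p_value`, `eligible`.
#'
#' @param fits List of [fit_kill_curve()] results.
#' @return A data frame.
#' @export
kill_fit_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f)
    data.frame(subject_id = f$subject_id, theta_f = f$theta_f, t0 = f$t0,
               n_points = f$n_points, r_squared = f$r_squared,
               p_value = f$p_value, eligible = f$eligible,
               stringsAsFactors = FALSE)))
}

#' Split fits into eligible and excluded subjects
#'
#' A subject enters the cross-subject uptake fit only if its quadratic fit
#' is supported by at least 3 positive post-onset points (with 2 points no
#' p-value can be assigned). Accepts either a list of `kill_fit` objects
#' or a data frame with an `n_points` column (e.g. the published fixture
#' from [load_table1_fixture()]); ordering is preserved.
#'
#' @param fits List of `kill_fit` objects or a data frame with `n_points`.
#' @return A list with components `retained` and `excluded`, of the same
#'   type as the input.
#' @examples
#' fx <- load_table1_fixture()
#' filter_eligible(fx$fits)$excluded$subject_id  # "MSNP 4" "MSNP 7"
#' @export
filter_eligible <- function(fits) {
  if (is.data.frame(fits)) {
    keep <- fits$n_points >= 3L
    return(list(retained = fits[keep, , drop = FALSE],
                excluded = fits[!keep, , drop = FALSE]))
  }
  keep <- vapply(fits, function(f) f$n_points >= 3L, logical(1L))
  list(retained = fits[keep], excluded = fits[!keep])
}
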