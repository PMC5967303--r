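#' Kill-fraction time course
#'
#' Container for one subject's derived kill-fraction series. By
#' construction `fkill` is exactly 0 at the reference day `t0` and never
#' exceeds 1; negative values (treated tumor growing faster than the
#' control reference) are legal and retained — they matter for onset
#' detection — but are excluded from quadratic fitting.
#'
#' @param subject_id Character scalar.
#' @param t0 Reference day at which volumes were normalized.
#' @param times Numeric vector of days `>= t0`, strictly increasing.
#' @param fkill Numeric vector of kill fractions, all `<= 1`, with
#'   `fkill == 0` where `times == t0`.
#' @return An object of class `"fkill_series"`.
#' @export
fkill_series <- function(subject_id, t0, times, fkill) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L,
            length(times) == length(fkill), length(times) >= 1L)
  times <- as.numeric(times); fkill <- as.numeric(fkill)
  if (any(times < t0)) stop("'times' must all be >= t0", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (any(fkill > 1 + 1e-12))
    stop("kill fractions cannot exceed 1", call. = FALSE)
  at0 <- which(times == t0)
  if (length(at0) && any(abs(fkill[at0]) > 1e-12))
    stop("fkill at t0 must be 0", call. = FALSE)
  structure(
    list(subject_id = subject_id, t0 = as.numeric(t0),
         times = times, fkill = fkill),
    class = "fkill_series"
  )
}

#' @export
print.fkill_series <- function(x, ...) {
  cat(sprintf("Kill-fraction series '%s' (t0 = %g):\n", x$subject_id, x$t0))
  print(data.frame(day = x$times, fkill = signif(x$fkill, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Compute a kill-fraction time course
#'
#' Derives the fraction of tumor killed by treatment from a treated and a
#' control volume series:
#' \deqn{f_{kill}(t) = 1 - \frac{V_i(t)/V_i(t_0)}{V_C(t)/V_C(t_0)}}
#' where \eqn{V_i} is the treated subject's volume, \eqn{V_C} the control
#' reference (typically the per-day control-group mean from
#' [control_reference()]), and \eqn{t_0} the day treatment started.
#' Normalizing both series to their value at \eqn{t_0} makes the quantity
#' scale-free: rescaling all volumes by a common factor leaves it
#' unchanged.
#'
#' `t0` must be an actual measurement day present in both series (no
#' interpolation); only days `>= t0` shared by both series enter the
#' result.
#'
#' @param treated A [tumor_series()] for the treated subject.
#' @param control_reference A [tumor_series()] for the control reference.
#' @param t0 Reference day, present in both series. Default 0.
#' @return An [fkill_series()].
#' @examples
#' ctrl <- tumor_series("C", "control", c(0, 3, 7), c(500, 1000, 2000))
#' trt  <- tumor_series("m1", "nanoparticle", c(0, 3, 7), c(500, 750, 1000))
#' compute_fkill(trt, ctrl)
#' @export
compute_fkill <- function(treated, control_reference, t0 = 0) {
  stopifnot(inherits(treated, "tumor_series"),
            inherits(control_reference, "tumor_series"))
  shared <- intersect(treated$days, control_reference$days)
  if (!(t0 %in% shared))
    stop("t0 = ", t0, " is not a measurement day shared by both series",
         call. = FALSE)
  tt <- sort(shared[shared >= t0])
  vi <- treated$volumes[match(tt, treated$days)]
  vc <- control_reference$volumes[match(tt, control_reference$days)]
  vi0 <- treated$volumes[match(t0, treated$days)]
  vc0 <- control_reference$volumes[match(t0, control_reference$days)]
  fk <- 1 - (vi / vi0) / (vc / vc0)
  fk[tt == t0] <- 0  # exact, not merely up to rounding
  fkill_series(treated$subject_id, t0, tt, fk)
}

#' Per-day group mean and SD of tumor volumes
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of a
#' group's volumes at each measurement day. All series must share the same
#' day grid; the SD is `NA` for a single-subject group.
#'
#' @param series List of [tumor_series()] on a common day grid.
#' @return Data frame with columns `day`, `mean_volume`, `sd_volume`, `n`.
#' @export
group_mean_series <- function(series) {
  if (!length(series)) stop("empty group", call. = FALSE)
  days <- series[[1L]]$days
  bad <- vapply(series, function(s) !identical(s$days, days), logical(1L))
  if (any(bad))
    stop("mismatched measurement days for subject(s): ",
         paste(vapply(series[bad], `[[`, "", "subject_id"),
               collapse = ", "), call. = FALSE)
  vols <- do.call(rbind, lapply(series, `[[`, "volumes"))
  data.frame(
    day = days,
    mean_volume = colMeans(vols),
    sd_volume = if (nrow(vols) > 1L) apply(vols, 2L, stats::sd) else NA_real_,
    n = nrow(vols)
  )
}

#' Average-control reference series
#'
#' Builds the control reference \eqn{V_C} used in [compute_fkill()] as the
#' per-day mean of the control group. The study design compares groups,
#' not matched pairs, so the group mean is the declared convention; pass a
#' single subject's series directly to [compute_fkill()] to use a specific
#' reference animal instead.
#'
#' @param controls Non-empty list of control [tumor_series()] on a common
#'   day grid.
#' @return A [tumor_series()] with `subject_id` `"control_mean"`.
#' @export
control_reference <- function(controls) {
  if (!length(controls)) stop("empty control group", call. = FALSE)
  gm <- group_mean_series(controls)
  tumor_series("control_mean", "control", gm$day, gm$mean_volume)
}

#' Mechanistic quadratic response coefficient
#'
#' Forward evaluation of the mechanistic decomposition of the quadratic
#' response coefficient,
#' \deqn{\theta_f = \frac{F \lambda_k}{2 V_{T,0}},}
#' where \eqn{F} is the (approximately constant) drug flux across blood
#' vessel walls, \eqn{\lambda_k} the per-unit-drug tumor cell death rate,
#' and \eqn{V_{T,0}} the tumor volume at response onset. The package never
#' estimates these three parameters from data (the data identify only
#' their combination \eqn{\theta_f}); this function exists for forward
#' consistency checks.
#'
#' @param flux Drug flux `F` (> 0).
#' @param death_rate Kill rate `lambda_k` (> 0).
#' @param v_t0 Tumor volume at response onset, mm^3 (> 0).
#' @return The coefficient `theta_f` in 1/day^2.
#' @examples
#' mechanistic_theta(2, 3, 3)  # 1
#' @export
mechanistic_theta <- function(flux, death_rate, v_t0) {
  stopifnot(flux > 0, death_rate > 0, v_t0 > 0)
  flux * death_rate / (2 * v_t0)
}
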