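#' GFAA standard-additions curve
#'
#' One tissue sample's signal-vs-addition curve from graphite furnace
#' atomic absorption. The sample is spiked with known Si additions (at
#' least 3 points including a zero addition, in a single concentration
#' unit that is carried through unchanged) and the instrument signal
#' recorded at each.
#'
#' @param sample_id Character scalar.
#' @param tissue Organ label.
#' @param additions Numeric vector of added Si concentrations; must
#'   contain 0, be non-negative, and not all equal.
#' @param signals Numeric vector of instrument signals (absorbance,
#'   arbitrary units), same length.
#' @return An object of class `"addition_curve"`.
#' @export
addition_curve <- function(sample_id, tissue, additions, signals) {
  additions <- as.numeric(additions); signals <- as.numeric(signals)
  stopifnot(is.character(sample_id), length(sample_id) == 1L,
            length(additions) == length(signals))
  if (length(additions) < 3L)
    stop("standard additions needs at least 3 points", call. = FALSE)
  if (!any(additions == 0))
    stop("additions must include a zero-addition point", call. = FALSE)
  if (any(additions < 0))
    stop("additions must be non-negative", call. = FALSE)
  if (length(unique(additions)) < 2L)
    stop("additions must not all be equal", call. = FALSE)
  structure(
    list(sample_id = sample_id, tissue = tissue,
         additions = additions, signals = signals),
    class = "addition_curve"
  )
}

#' Standard-additions quantification of Si
#'
#' Fits the ordinary least-squares line `signal = m * addition + b` to a
#' sample's spike curve and reads the native analyte concentration off the
#' x-intercept: `concentration = b / m` (the magnitude of the
#' extrapolation of the line to zero signal). Matrix effects scale the
#' signal but not this ratio, which is the point of the method. The
#' standard deviation of the x-intercept estimate is
#' \deqn{s_c = \frac{s_{y/x}}{m}\sqrt{\frac{1}{n} +
#'   \frac{\bar{y}^2}{m^2 \sum_i (x_i - \bar{x})^2}}}
#' with \eqn{s_{y/x}} the residual SD of the regression.
#'
#' @param curve An [addition_curve()].
#' @return An object of class `"si_estimate"`: list with `sample_id`,
#'   `tissue`, `concentration` (same unit as the additions), `sd`,
#'   `slope`, `intercept`, `n`.
#' @examples
#' cv <- addition_curve("s1", "tumor", c(0, 1, 2), c(2, 3, 4))
#' standard_additions(cv)$concentration  # 2
#' @export
standard_additions <- function(curve) {
  stopifnot(inherits(curve, "addition_curve"))
  x <- curve$additions; y <- curve$signals
  n <- length(x)
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  m <- sum((x - xbar) * (y - ybar)) / sxx
  b <- ybar - m * xbar
  if (m <= 0)
    stop("signal must increase with addition (fitted slope <= 0) for sample ",
         curve$sample_id, call. = FALSE)
  resid <- y - (b + m * x)
  s_yx <- if (n > 2L) sqrt(sum(resid^2) / (n - 2L)) else 0
  sd_c <- (s_yx / m) * sqrt(1 / n + ybar^2 / (m^2 * sxx))
  structure(
    list(sample_id = curve$sample_id, tissue = curve$tissue,
         concentration = b / m, sd = sd_c, slope = m, intercept = b, n = n),
    class = "si_estimate"
  )
}

#' @export
print.si_estimate <- function(x, ...) {
  cat(sprintf("Si in '%s' (%s): %.5g +/- %.2g (slope %.4g, intercept %.4g)\n",
              x$sample_id, x$tissue, x$concentration, x$sd, x$slope,
              x$intercept))
  invisible(x)
}

#' Subtract the natural Si background of a tissue
#'
#' Tissues contain trace Si naturally; the background measured in
#' untreated control animals (`control_baseline` in the study
#' configuration) is subtracted before computing delivery efficiency.
#' A measurement below baseline yields a negative net value, which is
#' reported as-is with `below_baseline = TRUE` but contributes 0 to \%ID.
#'
#' @param si_mass_percent Measured Si absolute mass percent.
#' @param organ Organ label present in `config$control_baseline`.
#' @param config A [study_config()].
#' @return List with `net_si_mass_percent` and `below_baseline`.
#' @export
subtract_baseline <- function(si_mass_percent, organ, config) {
  stopifnot(inherits(config, "study_config"), si_mass_percent >= 0)
  if (!organ %in% names(config$control_baseline))
    stop("no control baseline for organ '", organ, "'", call. = FALSE)
  net <- si_mass_percent - config$control_baseline[[organ]]
  list(net_si_mass_percent = net, below_baseline = net < 0)
}

#' Delivery efficiency (%ID) of an organ
#'
#' Converts a baseline-subtracted tissue Si mass percent to percent of the
#' injected Si dose recovered in the organ:
#' organ Si mass = `net/100 * organ reference mass`;
#' injected Si mass = `si_fraction * particle_mass_per_dose * n_doses`;
#' \%ID = 100 * organ Si / injected Si. The result is linear in the net Si
#' mass percent and in the organ mass, so organ-level \%ID values add up
#' to the \%ID of the pooled Si mass. Negative net values (below
#' background) contribute 0.
#'
#' @param net_si_mass_percent Baseline-subtracted Si mass percent.
#' @param organ Organ label present in `config$organ_reference_masses`.
#' @param config A [study_config()].
#' @return \%ID, a non-negative number.
#' @examples
#' cfg <- study_config(particle_mass_per_dose_mg = 2.540650,
#'                     n_doses = 1, si_fraction = 0.3936,
#'                     organ_reference_masses = c(tumor = 1))
#' delivery_efficiency(0.01, "tumor", cfg)  # 10
#' @export
delivery_efficiency <- function(net_si_mass_percent, organ, config) {
  stopifnot(inherits(config, "study_config"))
  if (!organ %in% names(config$organ_reference_masses))
    stop("no reference mass for organ '", organ, "'", call. = FALSE)
  injected_mg <- injected_si_mass(config)
  if (injected_mg <= 0) stop("injected Si mass must be positive", call. = FALSE)
  net <- max(net_si_mass_percent, 0)
  organ_si_mg <- net / 100 * config$organ_reference_masses[[organ]] * 1000
  100 * organ_si_mg / injected_mg
}

#' Per-subject %ID table from a biodistribution table
#'
#' Applies [subtract_baseline()] and [delivery_efficiency()] to every row
#' of a biodistribution table.
#'
#' @param biodistribution Data frame with `subject_id`, `organ`,
#'   `si_mass_percent` (see [read_biodistribution_table()]).
#' @param config A [study_config()].
#' @return Data frame with columns `subject_id`, `organ`,
#'   `net_si_mass_percent`, `percent_id`, `below_baseline`.
#' @export
percent_id_table <- function(biodistribution, config) {
  rows <- lapply(seq_len(nrow(biodistribution)), function(i) {
    r <- biodistribution[i, ]
    net <- subtract_baseline(r$si_mass_percent, r$organ, config)
    data.frame(
      subject_id = r$subject_id, organ = r$organ,
      net_si_mass_percent = net$net_si_mass_percent,
      percent_id = delivery_efficiency(net$net_si_mass_percent, r$organ,
                                       config),
      below_baseline = net$below_baseline,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
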