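#' Tumor volume time series
#'
#' Container for one subject's tumor volume time course. Days are relative
#' to treatment start (day 0 = first dose) and may be non-integer; volumes
#' are caliper-derived tumor volumes in mm^3 and must be strictly positive.
#'
#' @param subject_id Character scalar identifying the animal.
#' @param group Treatment group, one of `"control"`, `"free_drug"`,
#'   `"nanoparticle"`.
#' @param days Numeric vector of non-negative measurement days, strictly
#'   increasing.
#' @param volumes Numeric vector of positive volumes (mm^3), same length as
#'   `days`.
#' @return An object of class `"tumor_series"`: a list with fields
#'   `subject_id`, `group`, `days`, `volumes`.
#' @examples
#' tumor_series("m1", "control", c(0, 3, 7), c(500, 650, 900))
#' @export
tumor_series <- function(subject_id, group, days, volumes) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  group <- match.arg(group, c("control", "free_drug", "nanoparticle"))
  days <- as.numeric(days)
  volumes <- as.numeric(volumes)
  if (length(days) != length(volumes) || length(days) < 1L)
    stop("'days' and 'volumes' must have equal length >= 1", call. = FALSE)
  if (any(days < 0) || any(!is.finite(days)))
    stop("'days' must be finite and non-negative", call. = FALSE)
  if (is.unsorted(days, strictly = TRUE))
    stop("'days' must be strictly increasing", call. = FALSE)
  if (any(volumes <= 0) || any(!is.finite(volumes)))
    stop("'volumes' must be finite and strictly positive", call. = FALSE)
  structure(
    list(subject_id = subject_id, group = group,
         days = days, volumes = volumes),
    class = "tumor_series"
  )
}

#' @export
print.tumor_series <- function(x, ...) {
  cat(sprintf("Tumor series '%s' (%s): %d measurements, days %s\n",
              x$subject_id, x$group, length(x$days),
              paste(x$days, collapse = ", ")))
  invisible(x)
}

#' Read a tumor volume table
#'
#' Reads a CSV with columns `subject_id`, `group`, `day`, `volume_mm3`
#' (header row, decimal point, UTF-8) and returns one [tumor_series()] per
#' subject, day-sorted. Group labels other than `control`, `free_drug`,
#' `nanoparticle` are rejected.
#'
#' @param path Path to the CSV file.
#' @return Named list of `tumor_series`, one per subject, in first-appearance
#'   order.
#' @seealso [write_tumor_table()]
#' @export
read_tumor_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "day", "volume_mm3")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("tumor table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(tab$volume_mm3) | tab$volume_mm3 <= 0)
  if (length(bad))
    stop("non-positive or missing volume_mm3 at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  unknown <- setdiff(unique(tab$group),
                     c("control", "free_drug", "nanoparticle"))
  if (length(unknown))
    stop("unknown group label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  ids <- unique(tab$subject_id)
  out <- lapply(ids, function(id) {
    sub <- tab[tab$subject_id == id, , drop = FALSE]
    grp <- unique(sub$group)
    if (length(grp) != 1L)
      stop("subject '", id, "' appears in more than one group", call. = FALSE)
    ord <- order(sub$day)
    tumor_series(as.character(id), grp, sub$day[ord], sub$volume_mm3[ord])
  })
  names(out) <- ids
  out
}

#' Write a tumor volume table
#'
#' Inverse of [read_tumor_table()]: serializes a list of [tumor_series()] to
#' CSV in canonical (subject, day-sorted) order.
#'
#' @param series List of `tumor_series`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tumor_table <- function(series, path) {
  rows <- do.call(rbind, lapply(series, function(s)
    data.frame(subject_id = s$subject_id, group = s$group,
               day = s$days, volume_mm3 = s$volumes,
               stringsAsFactors = FALSE)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a biodistribution table
#'
#' Reads a CSV with columns `subject_id`, `organ`, `si_mass_percent`.
#' Si values are absolute mass percent of elemental silicon in the tissue
#' (0.00372 means 0.00372\%); this scale is used throughout the package,
#' never a fraction.
#'
#' @param path Path to the CSV file.
#' @return A data frame with the three columns, organs validated against
#'   `tumor`, `liver`, `spleen`, `kidney`.
#' @export
read_biodistribution_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "organ", "si_mass_percent")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("biodistribution table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  bad_organ <- setdiff(unique(tab$organ),
                       c("tumor", "liver", "spleen", "kidney"))
  if (length(bad_organ))
    stop("unknown organ label(s): ", paste(bad_organ, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(tab$si_mass_percent) | tab$si_mass_percent < 0))
    stop("si_mass_percent must be finite and non-negative", call. = FALSE)
  tab[need]
}

#' Read a GFAA standard-additions table
#'
#' Reads a CSV with columns `sample_id`, `tissue`, `addition_si`, `signal`.
#' One signal-vs-addition curve per sample; the concentration unit of
#' `addition_si` is whatever the experimenter used and is carried through
#' unchanged by [standard_additions()].
#'
#' @param path Path to the CSV file.
#' @return Named list of [addition_curve()] objects, one per sample.
#' @export
read_gfaa_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "addition_si", "signal")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("GFAA table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  ids <- unique(tab$sample_id)
  out <- lapply(ids, function(id) {
    sub <- tab[tab$sample_id == id, , drop = FALSE]
    addition_curve(as.character(id), unique(sub$tissue)[1L],
                   sub$addition_si, sub$signal)
  })
  names(out) <- ids
  out
}

#' Study configuration
#'
#' Holds the dosing and reference constants needed for delivery-efficiency
#' (percent injected dose, \%ID) calculations: the particle mass injected
#' per dose, the number of doses, the Si mass fraction of the particle
#' (default 0.3936, i.e. 39.36\% of nanoparticle mass is elemental Si),
#' strain-standard reference organ masses, and per-organ background Si
#' levels measured in untreated control animals.
#'
#' @param particle_mass_per_dose_mg Particle mass per dose in mg.
#' @param n_doses Number of doses over the treatment course.
#' @param si_fraction Si mass fraction of the particle, in (0, 1].
#' @param organ_reference_masses Named numeric vector, organ -> mass in g.
#' @param control_baseline Named numeric vector, organ -> mean background Si
#'   mass percent in untreated tissue.
#' @return An object of class `"study_config"`.
#' @examples
#' cfg <- study_config()
#' cfg$si_fraction
#' @export
study_config <- function(particle_mass_per_dose_mg = 1,
                         n_doses = 4,
                         si_fraction = 0.3936,
                         organ_reference_masses = c(tumor = 0.5, liver = 1.0,
                                                    spleen = 0.1, kidney = 0.3),
                         control_baseline = c(tumor = 5e-4, liver = 5e-4,
                                              spleen = 5e-4, kidney = 5e-4)) {
  stopifnot(particle_mass_per_dose_mg > 0,
            n_doses >= 1, n_doses == round(n_doses),
            si_fraction > 0, si_fraction <= 1,
            all(organ_reference_masses > 0),
            all(control_baseline >= 0))
  structure(
    list(particle_mass_per_dose_mg = particle_mass_per_dose_mg,
         n_doses = as.integer(n_doses),
         si_fraction = si_fraction,
         organ_reference_masses = organ_reference_masses,
         control_baseline = control_baseline),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf(
    "Study config: %g mg particles/dose x %d doses, Si fraction %.4f\n",
    x$particle_mass_per_dose_mg, x$n_doses, x$si_fraction))
  cat("  injected Si:", format(injected_si_mass(x)), "mg\n")
  invisible(x)
}

#' Total injected Si mass
#'
#' `si_fraction * particle_mass_per_dose_mg * n_doses`, in mg. With the
#' default configuration (1 mg particles/dose, 4 doses, 39.36\% Si) this is
#' 1.5744 mg.
#'
#' @param config A [study_config()].
#' @return Injected Si mass in mg.
#' @export
injected_si_mass <- function(config) {
  stopifnot(inherits(config, "study_config"))
  config$si_fraction * config$particle_mass_per_dose_mg * config$n_doses
}

#' Read / write a study configuration
#'
#' YAML serialization of [study_config()] with keys
#' `particle_mass_per_dose_mg`, `n_doses`, `si_fraction`,
#' `organ_reference_masses`, `control_baseline`. A packaged default lives at
#' `system.file("extdata", "study_config.yml", package = "msnpkill")`.
#'
#' @param path Path to a YAML file.
#' @return `read_study_config()` returns a `study_config`;
#'   `write_study_config()` returns `path` invisibly.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  study_config(
    particle_mass_per_dose_mg = y$particle_mass_per_dose_mg,
    n_doses = y$n_doses,
    si_fraction = y$si_fraction,
    organ_reference_masses = unlist(y$organ_reference_masses),
    control_baseline = unlist(y$control_baseline)
  )
}

#' @rdname read_study_config
#' @param config A [study_config()] to serialize.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  yaml::write_yaml(list(
    particle_mass_per_dose_mg = config$particle_mass_per_dose_mg,
    n_doses = config$n_doses,
    si_fraction = config$si_fraction,
    organ_reference_masses = as.list(config$organ_reference_masses),
    control_baseline = as.list(config$control_baseline)
  ), path)
  invisible(path)
}

#' Published per-mouse coefficients and tumor Si content
#'
#' Returns the published seven-mouse summary of the nanoparticle group:
#' tumor Si content (absolute mass percent) together with the per-mouse
#' quadratic response coefficient theta_f, onset day t0, p-value and R^2.
#' Two mice (MSNP 4 and MSNP 7) responded only on the last two measurement
#' days, leaving two post-onset points; their onset day, p-value and R^2
#' are therefore absent and they are ineligible for the cross-subject
#' uptake fit. `n_points` counts post-onset measurement days implied by the
#' reported onset day and the day 0/3/7/8/9 measurement schedule.
#'
#' @return A list with components:
#'   \item{biodistribution}{data frame `subject_id`, `organ` (all
#'     `"tumor"`), `si_mass_percent`.}
#'   \item{fits}{data frame `subject_id`, `si_mass_percent`, `t0`,
#'     `theta_f`, `p_value`, `r_squared`, `n_points`, `eligible`.}
#' @examples
#' fx <- load_table1_fixture()
#' subset(fx$fits, eligible)
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_fits.csv", package = "msnpkill")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$eligible <- tab$n_points >= 3L
  list(
    biodistribution = data.frame(
      subject_id = tab$subject_id, organ = "tumor",
      si_mass_percent = tab$si_mass_percent, stringsAsFactors = FALSE),
    fits = tab
  )
}
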