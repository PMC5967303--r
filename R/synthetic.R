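#' Generative specification for a synthetic cohort
#'
#' Parameters of the synthetic-data generator. The generator emulates the
#' statistical structure the analysis assumes: exponentially growing
#' control tumors with multiplicative lognormal measurement noise, treated
#' tumors following control kinetics until an integer onset day
#' \eqn{t_0} and thereafter depressed by the quadratic kill law
#' \eqn{1 - \theta (t - t_0)^2} (capped at 0.99 so volumes stay
#' positive — a generator artifact, not a model claim), a per-subject
#' tumor Si content drawn uniformly and mapped to \eqn{\theta} through the
#' exponential uptake law with lognormal spread, and linear GFAA
#' standard-additions signal curves with Gaussian noise.
#'
#' @param n_per_group Animals per group (control and nanoparticle).
#' @param measurement_days Strictly increasing measurement days.
#' @param control_v0 Mean tumor volume at day 0, mm^3.
#' @param growth_rate Exponential control growth rate, 1/day.
#' @param theta_law Named vector `c(A = , B = )` of the generative uptake
#'   law \eqn{\theta = A e^{B \cdot Si}}.
#' @param si_range Length-2 vector, uniform range of tumor Si mass percent
#'   (within `[0, 0.02]`).
#' @param t0_weights Named numeric vector of sampling weights over integer
#'   onset days (names are days).
#' @param noise_sd_volume Lognormal sigma of volume measurement noise.
#' @param noise_sd_theta Lognormal sigma of the per-subject spread around
#'   the uptake law.
#' @param gfaa_additions Spike levels for the synthetic GFAA curves, same
#'   unit as Si mass percent.
#' @param gfaa_slope GFAA signal per unit concentration.
#' @param gfaa_noise_sd Gaussian SD of the GFAA signal noise.
#' @param seed Integer seed; drives a per-subject seed tree so that
#'   subject subsets are reproducible independently.
#' @return An object of class `"cohort_spec"`.
#' @seealso [table1_like_cohort()] for defaults mimicking the published
#'   study design, [simulate_cohort()] to realize a spec.
#' @export
cohort_spec <- function(n_per_group = 7,
                        measurement_days = c(0, 3, 7, 8, 9),
                        control_v0 = 500,
                        growth_rate = 0.12,
                        theta_law = c(A = 6e-4, B = 470),
                        si_range = c(0.001, 0.006),
                        t0_weights = c(`0` = 0.6, `3` = 0.3, `7` = 0.1),
                        noise_sd_volume = 0.08,
                        noise_sd_theta = 0.2,
                        gfaa_additions = c(0, 0.002, 0.004, 0.008),
                        gfaa_slope = 50,
                        gfaa_noise_sd = 0.002,
                        seed = 1L) {
  stopifnot(n_per_group >= 1, control_v0 > 0, growth_rate > 0,
            all(theta_law[["A"]] > 0),
            length(si_range) == 2L, si_range[1L] <= si_range[2L],
            si_range[1L] >= 0, si_range[2L] <= 0.02,
            all(t0_weights >= 0), sum(t0_weights) > 0,
            noise_sd_volume >= 0, noise_sd_theta >= 0,
            gfaa_slope > 0, gfaa_noise_sd >= 0)
  if (is.unsorted(measurement_days, strictly = TRUE))
    stop("'measurement_days' must be strictly increasing", call. = FALSE)
  structure(
    list(n_per_group = as.integer(n_per_group),
         measurement_days = as.numeric(measurement_days),
         control_v0 = control_v0, growth_rate = growth_rate,
         theta_law = theta_law, si_range = si_range,
         t0_weights = t0_weights,
         noise_sd_volume = noise_sd_volume, noise_sd_theta = noise_sd_theta,
         gfaa_additions = gfaa_additions, gfaa_slope = gfaa_slope,
         gfaa_noise_sd = gfaa_noise_sd, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Cohort specification mimicking the published study design
#'
#' Ready-made [cohort_spec()] matching the study scale: 7 mice per group,
#' measurements on days 0, 3, 7, 8 and 9, tumors of roughly 500 mm^3 at
#' treatment start, tumor Si in [0.001, 0.006] mass percent and kill
#' coefficients in about [0.001, 0.01] per day^2. Only the seed varies
#' between calls; the design itself is fixed.
#'
#' @param seed Integer seed.
#' @return A [cohort_spec()].
#' @export
table1_like_cohort <- function(seed = 1L) {
  cohort_spec(seed = seed)
}

# deterministic per-subject seed derived from the cohort seed, so that
# any subject subset regenerates identically
.subject_seed <- function(seed, index) {
  (as.numeric(seed %% 1048576L) * 7919 + index * 104729) %% 2147483647
}

#' Simulate a synthetic cohort with ground truth
#'
#' Realizes a [cohort_spec()]: control and nanoparticle-treated tumor
#' volume series, a per-subject biodistribution table (tumor Si plus
#' uncorrelated liver/spleen/kidney values — the study design assumes no
#' inter-organ uptake correlation), one GFAA standard-additions curve per
#' treated tumor, and the latent ground truth for every subject.
#'
#' The treated volume model is, for measurement day `t` and onset `t0`,
#' \deqn{V_i(t) = V_0 e^{g t} \times
#'   \left[1 - \min(\theta_i (t - t_0)^2, 0.99)\right]_{t \ge t_0}}
#' times lognormal measurement noise applied last, so that with all noise
#' SDs at zero, [compute_fkill()] against the control reference returns
#' exactly \eqn{\theta_i (t - t_0)^2}: the generator and the analyzer are
#' an inverse pair.
#'
#' @param spec A [cohort_spec()].
#' @return A list with components `tumors` (named list of
#'   [tumor_series()], controls then treated), `biodistribution` (data
#'   frame), `gfaa` (named list of [addition_curve()]), `truth` (data
#'   frame `subject_id`, `si_true`, `theta_true`, `t0_true`,
#'   `growth_rate`), and `spec`.
#' @examples
#' sim <- simulate_cohort(table1_like_cohort(seed = 42))
#' names(sim$tumors)
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  days <- spec$measurement_days
  latent_control <- spec$control_v0 * exp(spec$growth_rate * days)
  t0_days <- as.numeric(names(spec$t0_weights))

  controls <- lapply(seq_len(spec$n_per_group), function(i) {
    set.seed(.subject_seed(spec$seed, i))
    noise <- exp(stats::rnorm(length(days), 0, spec$noise_sd_volume))
    tumor_series(sprintf("CTRL %d", i), "control", days,
                 latent_control * noise)
  })

  truth <- vector("list", spec$n_per_group)
  treated <- vector("list", spec$n_per_group)
  gfaa <- vector("list", spec$n_per_group)
  organs <- c("liver", "spleen", "kidney")
  biod <- vector("list", spec$n_per_group)
  for (i in seq_len(spec$n_per_group)) {
    set.seed(.subject_seed(spec$seed, spec$n_per_group + i))
    id <- sprintf("MSNP %d", i)
    si <- stats::runif(1, spec$si_range[1L], spec$si_range[2L])
    theta <- spec$theta_law[["A"]] * exp(spec$theta_law[["B"]] * si) *
      exp(stats::rnorm(1, 0, spec$noise_sd_theta))
    t0 <- if (length(t0_days) == 1L) t0_days else
      sample(t0_days, 1L, prob = spec$t0_weights)
    kill <- ifelse(days >= t0, pmin(theta * (days - t0)^2, 0.99), 0)
    latent <- latent_control * (1 - kill)
    noise <- exp(stats::rnorm(length(days), 0, spec$noise_sd_volume))
    vols <- latent * noise
    if (any(vols <= 0))
      stop("generated non-positive volume for ", id, " at day ",
           days[which(vols <= 0)[1L]], call. = FALSE)
    treated[[i]] <- tumor_series(id, "nanoparticle", days, vols)
    other <- stats::runif(length(organs), spec$si_range[1L],
                          spec$si_range[2L])
    biod[[i]] <- data.frame(
      subject_id = id, organ = c("tumor", organs),
      si_mass_percent = c(si, other), stringsAsFactors = FALSE)
    sig <- spec$gfaa_slope * (si + spec$gfaa_additions) +
      stats::rnorm(length(spec$gfaa_additions), 0, spec$gfaa_noise_sd)
    gfaa[[i]] <- addition_curve(id, "tumor", spec$gfaa_additions, sig)
    truth[[i]] <- data.frame(subject_id = id, si_true = si,
                             theta_true = theta, t0_true = t0,
                             growth_rate = spec$growth_rate,
                             stringsAsFactors = FALSE)
  }

  tumors <- c(controls, treated)
  names(tumors) <- vapply(tumors, `[[`, "", "subject_id")
  names(gfaa) <- vapply(gfaa, `[[`, "", "sample_id")
  list(tumors = tumors,
       biodistribution = do.call(rbind, biod),
       gfaa = gfaa,
       truth = do.call(rbind, truth),
       spec = spec)
}

#' Write a simulated cohort to disk
#'
#' Writes the three input tables read by the package (tumor volumes,
#' biodistribution, GFAA curves) plus the ground-truth table, as CSV under
#' `dir`.
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(tumors = file.path(dir, "tumors.csv"),
             biodistribution = file.path(dir, "biodistribution.csv"),
             gfaa = file.path(dir, "gfaa.csv"),
             truth = file.path(dir, "truth.csv"))
  write_tumor_table(sim$tumors, paths[["tumors"]])
  utils::write.csv(sim$biodistribution, paths[["biodistribution"]],
                   row.names = FALSE, quote = FALSE)
  gf <- do.call(rbind, lapply(sim$gfaa, function(cv)
    data.frame(sample_id = cv$sample_id, tissue = cv$tissue,
               addition_si = cv$additions, signal = cv$signals,
               stringsAsFactors = FALSE)))
  utils::write.csv(gf, paths[["gfaa"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$truth, paths[["truth"]], row.names = FALSE,
                   quote = FALSE)
  invisible(paths)
}
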