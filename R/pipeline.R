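# condition helpers: configuration problems (bad inputs, missing groups)
# are distinguished from computation errors so the CLI can exit 2 vs 1
config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("msnpkill_config_error",
                                             "error", "condition")))
}

.as_tumor_list <- function(tumors) {
  if (is.character(tumors)) read_tumor_table(tumors) else tumors
}

#' Fit the quadratic kill law across a cohort
#'
#' End-to-end response fitting: builds the average-control reference,
#' derives each nanoparticle-treated subject's kill-fraction series
#' (normalized at `t0_reference`, the treatment start day), and fits the
#' quadratic law with onset optimization per subject.
#'
#' @param tumors Path to a tumor volume CSV (see [read_tumor_table()]) or
#'   a list of [tumor_series()]. Must contain both a `control` and a
#'   `nanoparticle` group.
#' @param t0_reference Normalization day for the kill fraction (default
#'   0, the first treatment day).
#' @param reference_subject Optional subject id to use as the control
#'   reference instead of the control-group mean.
#' @return A list with `fits` (list of `kill_fit`), `table` (data frame,
#'   one row per subject), `fkill` (list of [fkill_series()]), and
#'   `reference` (the control reference series).
#' @export
run_fit_response <- function(tumors, t0_reference = 0,
                             reference_subject = NULL) {
  tumors <- .as_tumor_list(tumors)
  groups <- vapply(tumors, `[[`, "", "group")
  if (!any(groups == "control"))
    config_error("no control group in tumor table")
  if (!any(groups == "nanoparticle"))
    config_error("no nanoparticle group in tumor table")
  reference <- if (is.null(reference_subject)) {
    control_reference(tumors[groups == "control"])
  } else {
    if (!reference_subject %in% names(tumors))
      config_error("reference subject '", reference_subject, "' not found")
    tumors[[reference_subject]]
  }
  treated <- tumors[groups == "nanoparticle"]
  fkill <- lapply(treated, compute_fkill, control_reference = reference,
                  t0 = t0_reference)
  fits <- lapply(fkill, fit_kill_curve)
  list(fits = fits, table = kill_fit_table(fits), fkill = fkill,
       reference = reference)
}

#' Fit the uptake-response law across a cohort
#'
#' Joins per-subject quadratic-fit coefficients with tumor Si content and
#' fits \eqn{\theta_f = A e^{B \cdot Si}}. By default only subjects
#' passing the eligibility filter ([filter_eligible()]) enter the fit;
#' `include_excluded = TRUE` keeps every subject.
#'
#' @param fits Data frame with `subject_id`, `theta_f`, `n_points` (from
#'   [kill_fit_table()] or [load_table1_fixture()]`$fits`), or a path to
#'   such a CSV.
#' @param biodistribution Data frame with `subject_id`, `organ`,
#'   `si_mass_percent`, or a path to such a CSV; tumor rows are used.
#' @param include_excluded Keep subjects with fewer than 3 response
#'   points.
#' @return A list with `model` (an [fit_uptake()] object), `summary`
#'   (one-row data frame: A, B, r_squared, n_subjects, fit_method), and
#'   `linear_baseline` (R^2 of the straight-line comparison fit).
#' @export
run_fit_uptake <- function(fits, biodistribution, include_excluded = FALSE) {
  if (is.character(fits)) fits <- utils::read.csv(fits,
                                                  stringsAsFactors = FALSE)
  if (is.character(biodistribution))
    biodistribution <- read_biodistribution_table(biodistribution)
  tumor <- biodistribution[biodistribution$organ == "tumor",
                           c("subject_id", "si_mass_percent")]
  if (!include_excluded) fits <- filter_eligible(fits)$retained
  # Si always comes from the biodistribution table, even if the fits
  # table happens to carry a column of the same name
  fits <- fits[, setdiff(names(fits), "si_mass_percent"), drop = FALSE]
  merged <- merge(fits, tumor, by = "subject_id")
  if (nrow(merged) < 3L)
    config_error("fewer than 3 matched eligible subjects (",
                 nrow(merged), ")")
  model <- fit_uptake(merged$si_mass_percent, merged$theta_f,
                      subject_id = merged$subject_id)
  list(
    model = model,
    summary = data.frame(A = model$A, B = model$B,
                         r_squared = model$r_squared,
                         n_subjects = model$n_subjects,
                         fit_method = model$fit_method,
                         stringsAsFactors = FALSE),
    linear_baseline = linear_uptake_baseline(merged$si_mass_percent,
                                             merged$theta_f)
  )
}

#' Quantify Si and delivery efficiency across samples
#'
#' Runs [standard_additions()] on every GFAA curve; a sample whose curve
#' cannot be quantified (e.g. non-increasing signal) yields an error row
#' and the run continues. When a biodistribution table is supplied,
#' baseline-subtracted \%ID values are computed as well.
#'
#' @param curves Path to a GFAA CSV (see [read_gfaa_table()]) or a named
#'   list of [addition_curve()].
#' @param config A [study_config()] or path to its YAML form.
#' @param biodistribution Optional data frame or CSV path for \%ID
#'   computation.
#' @return A list with `estimates` (data frame `sample_id`, `tissue`,
#'   `si_concentration`, `sd`, `slope`, `intercept`, `error`) and
#'   `percent_id` (data frame or `NULL`).
#' @export
run_gfaa <- function(curves, config = study_config(),
                     biodistribution = NULL) {
  if (is.character(curves)) curves <- read_gfaa_table(curves)
  if (is.character(config)) config <- read_study_config(config)
  rows <- lapply(curves, function(cv) {
    est <- tryCatch(standard_additions(cv), error = function(cnd) cnd)
    if (inherits(est, "error"))
      data.frame(sample_id = cv$sample_id, tissue = cv$tissue,
                 si_concentration = NA_real_, sd = NA_real_,
                 slope = NA_real_, intercept = NA_real_,
                 error = conditionMessage(est), stringsAsFactors = FALSE)
    else
      data.frame(sample_id = est$sample_id, tissue = est$tissue,
                 si_concentration = est$concentration, sd = est$sd,
                 slope = est$slope, intercept = est$intercept,
                 error = NA_character_, stringsAsFactors = FALSE)
  })
  pid <- NULL
  if (!is.null(biodistribution)) {
    if (is.character(biodistribution))
      biodistribution <- read_biodistribution_table(biodistribution)
    pid <- percent_id_table(biodistribution, config)
  }
  list(estimates = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       percent_id = pid)
}

#' Assemble and serialize a fit report
#'
#' Bundles the per-subject quadratic fits, the uptake model, the
#' observed-vs-predicted validation and run provenance into one
#' serializable report. `write_fit_report()` writes both a human-readable
#' text summary (`<stem>.txt`) and a machine-readable JSON document
#' (`<stem>.json`); `read_fit_report()` reads the JSON back with all
#' numeric fields reproduced exactly.
#'
#' @param response Result of [run_fit_response()].
#' @param uptake Result of [run_fit_uptake()].
#' @param validation Optional [validate_predictions()] result.
#' @param seed Seed recorded in provenance.
#' @param inputs Character vector of input file names for provenance.
#' @return An object of class `"fit_report"`.
#' @export
fit_report <- function(response, uptake, validation = NULL, seed = NA,
                       inputs = character()) {
  structure(
    list(subject_fits = response$table,
         uptake_model = uptake$summary,
         linear_baseline_r_squared = uptake$linear_baseline$r_squared,
         validation = if (is.null(validation)) NULL else
           list(pearson_r = validation$pearson_r,
                p_value = validation$p_value,
                n_pairs = validation$n_pairs),
         provenance = list(inputs = inputs, seed = seed,
                           timestamp = format(Sys.time(), tz = "UTC"),
                           package_version =
                             as.character(utils::packageVersion("msnpkill")))),
    class = "fit_report"
  )
}

#' @rdname fit_report
#' @param report A `fit_report`.
#' @param stem Output path without extension.
#' @export
write_fit_report <- function(report, stem) {
  stopifnot(inherits(report, "fit_report"))
  json_path <- paste0(stem, ".json")
  # 17 significant digits: doubles survive the write/read round trip bit
  # for bit
  jsonlite::write_json(unclass(report), json_path, digits = I(17),
                       auto_unbox = TRUE, null = "null", na = "null")
  txt <- c(
    "Kill-fraction response and uptake model report",
    "==============================================",
    "",
    "Per-subject quadratic fits (f_kill = theta_f * (t - t0)^2):",
    utils::capture.output(print(report$subject_fits, row.names = FALSE)),
    "",
    "Uptake law (theta_f = A * exp(B * Si)):",
    utils::capture.output(print(report$uptake_model, row.names = FALSE)),
    sprintf("Linear baseline R^2: %.4f", report$linear_baseline_r_squared),
    if (!is.null(report$validation))
      sprintf("Validation: pearson r = %.4f (p = %.3g, %d pairs)",
              report$validation$pearson_r, report$validation$p_value,
              report$validation$n_pairs),
    "",
    sprintf("Seed: %s | Generated: %s | msnpkill %s",
            report$provenance$seed, report$provenance$timestamp,
            report$provenance$package_version))
  writeLines(txt, paste0(stem, ".txt"))
  invisible(c(json = json_path, txt = paste0(stem, ".txt")))
}

#' @rdname fit_report
#' @param path Path to a report JSON file.
#' @export
read_fit_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat("Fit report:", nrow(x$subject_fits), "subjects;")
  cat(sprintf(" uptake R^2 = %.3f (n = %d)\n",
              x$uptake_model$r_squared, x$uptake_model$n_subjects))
  invisible(x)
}

#' One-command end-to-end demonstration
#'
#' Runs the whole pipeline twice: once on the packaged published fixture
#' (eligibility filter + uptake fit) and once on a synthetic cohort
#' generated from [table1_like_cohort()] (response fits, uptake fit,
#' GFAA quantification, observed-vs-predicted validation), writing all
#' tables and a [fit_report()] under `out_dir`.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed for the synthetic cohort.
#' @return Invisibly, a list with `fixture_uptake`, `response`, `uptake`,
#'   `gfaa`, `validation`, `report`.
#' @export
run_demo <- function(out_dir = tempfile("msnpkill-demo"), seed = 1L) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fx <- load_table1_fixture()
  fixture_uptake <- run_fit_uptake(fx$fits, fx$biodistribution)

  sim <- simulate_cohort(table1_like_cohort(seed = seed))
  paths <- write_cohort(sim, file.path(out_dir, "synthetic"))
  response <- run_fit_response(sim$tumors)
  uptake <- run_fit_uptake(response$table, sim$biodistribution)
  gfaa <- run_gfaa(sim$gfaa, study_config(), sim$biodistribution)

  tumor_si <- sim$biodistribution[sim$biodistribution$organ == "tumor", ]
  eligible <- names(response$fits)[vapply(response$fits, `[[`, TRUE,
                                          "eligible")]
  # compare on strictly post-onset days: the law pins f_kill(t0) to 0 on
  # both sides, so the onset day itself carries no information
  observed <- lapply(eligible, function(id) {
    o <- response$fkill[[id]]
    t0 <- response$fits[[id]]$t0
    keep <- o$times > t0
    fkill_series(id, t0, o$times[keep], o$fkill[keep])
  })
  predicted <- lapply(eligible, function(id) {
    si <- tumor_si$si_mass_percent[tumor_si$subject_id == id]
    f <- response$fits[[id]]
    o <- response$fkill[[id]]
    predict_fkill_series(uptake$model, si, f$t0, o$times[o$times > f$t0],
                         subject_id = id)
  })
  validation <- validate_predictions(observed, predicted)

  report <- fit_report(response, uptake, validation, seed = seed,
                       inputs = basename(paths))
  write_fit_report(report, file.path(out_dir, "report"))
  utils::write.csv(response$table, file.path(out_dir, "subject_fits.csv"),
                   row.names = FALSE)
  utils::write.csv(gfaa$estimates, file.path(out_dir, "gfaa_estimates.csv"),
                   row.names = FALSE)
  utils::write.csv(gfaa$percent_id, file.path(out_dir, "percent_id.csv"),
                   row.names = FALSE)
  invisible(list(fixture_uptake = fixture_uptake, response = response,
                 uptake = uptake, gfaa = gfaa, validation = validation,
                 report = report))
}
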