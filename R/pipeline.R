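#' Pipeline configuration
#'
#' Resolves the configuration the pipeline verbs share, merging (highest
#' precedence first) explicit `overrides`, a JSON config file, and package
#' defaults. The configuration has three blocks: `geometry` (arguments of
#' [voxel_geometry()]), `simulation` (arguments of [simulation_config()])
#' and `analysis` (`comparisons`, `loa_multiplier`, `bias_digits`,
#' `loa_digits`).
#'
#' @param path Optional path to a JSON configuration file.
#' @param overrides Optional named list of blocks overriding the file.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    geometry = list(),
    simulation = list(),
    analysis = list(comparisons = c("A", "S"), loa_multiplier = 1.96,
                    bias_digits = 2, loa_digits = 1)
  )
  from_file <- if (!is.null(path)) {
    if (!file.exists(path)) abort_validation(sprintf("Config file not found: %s", path))
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else list()
  merge_block <- function(name) {
    utils::modifyList(utils::modifyList(defaults[[name]],
                                        from_file[[name]] %||% list()),
                      overrides[[name]] %||% list())
  }
  cfg <- list(geometry = merge_block("geometry"),
              simulation = merge_block("simulation"),
              analysis = merge_block("analysis"))
  cfg$geometry_obj <- do.call(voxel_geometry, cfg$geometry)
  cfg$simulation_obj <- do.call(simulation_config, cfg$simulation)
  bad <- setdiff(cfg$analysis$comparisons, c("A", "S"))
  if (length(bad)) {
    abort_validation(sprintf("Unknown comparison(s): %s", paste(bad, collapse = ", ")))
  }
  structure(cfg, class = "pipeline_config")
}

resolve_config <- function(config) {
  if (is.null(config)) return(pipeline_config())
  if (inherits(config, "pipeline_config")) return(config)
  if (is.character(config)) return(pipeline_config(path = config))
  if (is.list(config)) return(pipeline_config(overrides = config))
  abort_validation("`config` must be NULL, a path, a list, or a pipeline_config.")
}

provenance <- function(config, out_dir = NULL) {
  # Prefer the provenance of the dataset actually sitting in out_dir (its
  # seed may have been overridden at simulate time).
  if (!is.null(out_dir) && file.exists(file.path(out_dir, "config.json"))) {
    cfg <- jsonlite::read_json(file.path(out_dir, "config.json"),
                               simplifyVector = TRUE)
    return(list(seed = cfg$seed, config_hash = cfg$config_hash))
  }
  list(seed = config$simulation_obj$seed,
       config_hash = rlang::hash(unclass(config$simulation_obj)))
}

#' Pipeline verbs: simulate, measure, agree, report
#'
#' Thin orchestration over the computational modules, reading and writing
#' the documented CSV/JSON interchange files in `out_dir` so the full
#' validation workflow (`simulate` then `measure` then `agree` then
#' `report`) is reproducible end to end from one seed. Every output embeds
#' the seed and a configuration hash.
#'
#' @param config A [pipeline_config()], a path to a JSON config file, a
#'   list of overrides, or `NULL` for the defaults.
#' @param out_dir Working directory for the pipeline files.
#' @param seed Optional seed overriding the configured one (`simulate`).
#' @return Each verb invisibly returns its main product (`simulate`: the
#'   dataset; `measure`: the measurements tibble; `agree`: the report list;
#'   `report`: the path of the markdown summary).
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
pipeline_simulate <- function(config = NULL, out_dir, seed = NULL) {
  config <- resolve_config(config)
  if (!is.null(seed)) {
    sim_args <- utils::modifyList(config$simulation, list(seed = as.integer(seed)))
    config$simulation_obj <- do.call(simulation_config, sim_args)
  }
  ds <- generate_dataset(config$simulation_obj, config$geometry_obj)
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
    iad_log(sprintf("Created output directory %s", out_dir))
  }
  write_dataset(ds, out_dir)
  iad_log(sprintf("Simulated %d participants x %d timepoints (seed %d) into %s",
                  ds$config$n_participants,
                  nrow(ds$truth) / ds$config$n_participants,
                  ds$config$seed, out_dir))
  invisible(ds)
}

#' @rdname pipeline
#' @export
pipeline_measure <- function(config = NULL, out_dir) {
  config <- resolve_config(config)
  boxes <- read_boxes(file.path(out_dir, "boxes.csv"))
  fiducials <- read_fiducials(file.path(out_dir, "fiducials.csv"))
  measurements <- pair_timepoints(boxes, fiducials, config$geometry_obj)
  dropped <- attr(measurements, "dropped")
  write_measurements(measurements, file.path(out_dir, "measurements.csv"))
  iad_log(sprintf(
    "Measured %d paired timepoints (%d IAD_S exclusions; dropped: %s).",
    nrow(measurements), sum(measurements$s_excluded),
    paste(sprintf("%s=%d", names(dropped), dropped), collapse = ", ")))
  invisible(measurements)
}

#' @rdname pipeline
#' @param comparison `"A"`, `"S"`, or `"both"`.
#' @export
pipeline_agree <- function(config = NULL, out_dir, comparison = "both") {
  config <- resolve_config(config)
  comparisons <- if (identical(comparison, "both")) {
    config$analysis$comparisons
  } else {
    match.arg(comparison, c("A", "S"))
  }
  measurements <- read_measurements(file.path(out_dir, "measurements.csv"))
  prov <- provenance(config, out_dir)
  mult <- config$analysis$loa_multiplier

  reports <- list()
  fits <- list()
  ba <- list()
  for (cmp in comparisons) {
    rep_cmp <- agreement_report(measurements, cmp, multiplier = mult)
    fit_cmp <- mixed_regression(measurements, cmp)
    reports[[cmp]] <- list(
      comparison = cmp,
      n_pairs = rep_cmp$vc$n_pairs,
      n_participants = rep_cmp$vc$n_participants,
      bias_mm = rep_cmp$vc$bias,
      within_participant_sd_mm = rep_cmp$vc$sigma_within,
      between_participant_sd_mm = rep_cmp$vc$sigma_between,
      total_sd_mm = rep_cmp$vc$total_sd,
      loa_lower_mm = rep_cmp$loa_lower,
      loa_upper_mm = rep_cmp$loa_upper,
      loa_multiplier = mult,
      n_excluded = rep_cmp$n_dropped
    )
    fits[[cmp]] <- list(comparison = cmp, slope = fit_cmp$slope,
                        intercept = fit_cmp$intercept, model = fit_cmp$model,
                        fallback = fit_cmp$fallback,
                        converged = fit_cmp$converged,
                        singular = fit_cmp$singular)
    ba[[cmp]] <- dplyr::mutate(bland_altman_points(measurements, cmp),
                               comparison = cmp)
  }
  jsonlite::write_json(c(list(provenance = prov), list(comparisons = reports)),
                       file.path(out_dir, "agreement_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(c(list(provenance = prov), list(fits = fits)),
                       file.path(out_dir, "regression_fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(dplyr::bind_rows(ba), file.path(out_dir, "ba_points.csv"))
  iad_log(sprintf("Agreement analysis written for comparison(s): %s.",
                  paste(comparisons, collapse = ", ")))
  invisible(reports)
}

#' @rdname pipeline
#' @param plots Emit Bland-Altman / scatter plot files (requires ggplot2)?
#' @export
pipeline_report <- function(config = NULL, out_dir, plots = FALSE) {
  config <- resolve_config(config)
  path <- file.path(out_dir, "agreement_report.json")
  if (!file.exists(path)) {
    abort_validation("No agreement_report.json found; run pipeline_agree() first.")
  }
  rep <- jsonlite::read_json(path, simplifyVector = FALSE)
  bd <- config$analysis$bias_digits
  ld <- config$analysis$loa_digits
  lines <- c("# IAD agreement summary", "",
             sprintf("Seed: %s; config hash: %s",
                     rep$provenance$seed, rep$provenance$config_hash), "")
  for (r in rep$comparisons) {
    lab <- if (r$comparison == "A") "IAD_A vs IAD_M" else "IAD_S vs IAD_M"
    lines <- c(lines,
      sprintf("## %s", lab), "",
      "| Quantity | Value |", "|---|---|",
      sprintf("| Number of paired measurements | %d |", r$n_pairs),
      sprintf("| Mean bias (mm) | %.*f |", bd, r$bias_mm),
      sprintf("| 95%% limits of agreement (mm) | %.*f to %.*f |",
              ld, r$loa_lower_mm, ld, r$loa_upper_mm),
      sprintf("| Within participant SD (mm) | %.*f |", bd, r$within_participant_sd_mm),
      sprintf("| Between participant SD (mm) | %.*f |", bd, r$between_participant_sd_mm),
      sprintf("| Total SD (mm) | %.*f |", ld, r$total_sd_mm),
      "")
  }
  out_path <- file.path(out_dir, "report.md")
  writeLines(lines, out_path)
  if (isTRUE(plots)) {
    if (!requireNamespace("ggplot2", quietly = TRUE)) {
      abort_validation("Plot output requires the ggplot2 package.")
    }
    measurements <- read_measurements(file.path(out_dir, "measurements.csv"))
    for (r in rep$comparisons) {
      cmp <- r$comparison
      rep_obj <- agreement_report(measurements, cmp,
                                  multiplier = config$analysis$loa_multiplier)
      ggplot2::ggsave(file.path(out_dir, sprintf("ba_%s.png", cmp)),
                      plot_bland_altman(measurements, cmp, rep_obj),
                      width = 6, height = 4, dpi = 150)
      ggplot2::ggsave(file.path(out_dir, sprintf("scatter_%s.png", cmp)),
                      plot_paired_scatter(measurements, cmp),
                      width = 6, height = 4, dpi = 150)
    }
  }
  iad_log(sprintf("Report written to %s", out_path))
  invisible(out_path)
}
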