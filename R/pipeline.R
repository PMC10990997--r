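## Pipeline layer: configuration, fixed file dialects (comma-separated,
## UTF-8, header row, '.' decimal, lowercase canonical region names),
## quantification of a whole study and the group analysis report.

#' Default pipeline configuration
#'
#' Nested list of every tunable parameter with the package defaults:
#' kinetics (lambda 0.80, m 1, decapitation 60 s), calibration
#' (interpolating, hard range errors, 8-reading floor), quench handling,
#' statistics (alpha 0.05, per-region 2x2 layout) and the synthetic design
#' block mirroring the modeled study.
#'
#' @return A named list.
#' @examples
#' str(default_config(), max.level = 1)
#' @export
default_config <- function() {
  list(
    kinetics = list(lambda = 0.80, m = 1.0, decap_time_s = 60),
    calibration = list(mode = "interpolating", extrapolation = "error",
                       min_readings = 8, od_per_nci = 0.001),
    quench = list(efficiency = 1.0),
    blood = list(volume_ml = 0.010),
    stats = list(alpha = 0.05, layout = "per_region"),
    synthetic = list(
      n_per_group = 8, between_animal_cv = 0.10, od_noise_sd = 0.005,
      arterial_noise_cv = 0.05, peak_conc = 800, rise_time_s = 60,
      n_readings = 8,
      base_flow = list(cortex = 1.10, hippocampus = 1.00,
                       cerebellum = 1.05, pons = 0.85),
      mutant_vehicle_ratio = list(cortex = 1.32, hippocampus = 1.15,
                                  cerebellum = 1.00, pons = 1.00),
      inhibitor_ratio = 0.95),
    seed = 1
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else
      base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a pipeline configuration file
#'
#' Reads a YAML config and merges it over [default_config()]; every
#' top-level section left at its default is logged. The merged config
#' round-trips through YAML serialization unchanged.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param quiet Suppress the defaulted-section log lines.
#' @return The merged configuration list.
#' @export
read_config <- function(path = NULL, quiet = FALSE) {
  cfg <- default_config()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (!is.null(path) && !is.list(user))
    iap_validation_error(sprintf("config file %s does not contain a YAML mapping", path))
  if (!quiet) {
    for (nm in names(cfg))
      if (!nm %in% names(user))
        message(sprintf("[iapflow] config: section '%s' left at package defaults", nm))
  }
  merge_config(cfg, user)
}

config_checksum <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Build a study design from a pipeline config
#'
#' @param config A configuration list (see [default_config()]).
#' @param seed Optional seed overriding `config$seed`.
#' @return A [study_design()].
#' @export
design_from_config <- function(config, seed = NULL) {
  syn <- config$synthetic
  study_design(
    n_per_group = syn$n_per_group,
    group_mean_flow = mirror_group_means(
      base_flow = unlist(syn$base_flow),
      mutant_vehicle_ratio = unlist(syn$mutant_vehicle_ratio),
      inhibitor_ratio = syn$inhibitor_ratio),
    between_animal_cv = syn$between_animal_cv,
    od_noise_sd = syn$od_noise_sd,
    arterial_noise_cv = syn$arterial_noise_cv,
    peak_conc = syn$peak_conc,
    rise_time_s = syn$rise_time_s,
    n_readings = syn$n_readings,
    seed = seed %||% config$seed,
    regions = names(syn$base_flow))
}

kinetic_params_from_config <- function(config) {
  kinetic_params(lambda = config$kinetics$lambda, m = config$kinetics$m,
                 decap_time_s = config$kinetics$decap_time_s)
}

#' Write a simulated study to pipeline input files
#'
#' Emits the pipeline's input dialects — `arterial.csv`
#' (`animal_id,time_s,conc_nci_ml`), `standards.csv`
#' (`standard_id,activity_nci_g,od`), `roi.csv` (`animal_id,region,od`, long
#' format), `animals.csv` (`animal_id,strain,treatment`), a ground-truth
#' `truth.csv` for recovery tests, `design.yaml`, and `manifest.json` with
#' the seed, config checksum and per-file MD5 checksums. No timestamps are
#' written, so identical seeds give byte-identical outputs.
#'
#' @param study An `iap_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @param config Optional config list stored by checksum in the manifest.
#' @return Invisibly, a named vector of file paths.
#' @export
write_study_files <- function(study, dir, config = NULL) {
  if (!inherits(study, "iap_study"))
    iap_validation_error("study must be an iap_study")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir))
    iap_stop(sprintf("cannot create output directory %s", dir), "iap_io_error")
  paths <- c(arterial = file.path(dir, "arterial.csv"),
             standards = file.path(dir, "standards.csv"),
             roi = file.path(dir, "roi.csv"),
             animals = file.path(dir, "animals.csv"),
             truth = file.path(dir, "truth.csv"),
             design = file.path(dir, "design.yaml"),
             manifest = file.path(dir, "manifest.json"))
  utils::write.csv(study$arterial, paths["arterial"], row.names = FALSE)
  utils::write.csv(study$standards, paths["standards"], row.names = FALSE)
  utils::write.csv(study$roi, paths["roi"], row.names = FALSE)
  utils::write.csv(study$animals, paths["animals"], row.names = FALSE)
  utils::write.csv(study$truth, paths["truth"], row.names = FALSE)
  design_list <- unclass(study$design)
  design_list$group_mean_flow <- as.list(as.data.frame(study$design$group_mean_flow))
  yaml::write_yaml(design_list, paths["design"])
  data_files <- paths[setdiff(names(paths), "manifest")]
  manifest <- list(
    seed = study$design$seed,
    config_checksum = if (is.null(config)) NA else config_checksum(config),
    n_animals = nrow(study$animals),
    files = as.list(stats::setNames(unname(tools::md5sum(data_files)),
                                    basename(data_files))))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}

#' Simulate stage of the pipeline
#'
#' Generates the synthetic study described by the config's `synthetic` block
#' and writes all pipeline input files plus a manifest.
#'
#' @param config Configuration list (see [read_config()]).
#' @param out_dir Output directory.
#' @param seed Optional seed overriding `config$seed`.
#' @return Invisibly, a list with the `study` object and the file `paths`.
#' @export
run_simulate <- function(config = default_config(), out_dir, seed = NULL) {
  design <- design_from_config(config, seed = seed)
  message(sprintf("[iapflow] simulate: seed %d, %d animals per group",
                  design$seed, design$n_per_group))
  study <- simulate_study(design,
                          params = kinetic_params_from_config(config),
                          od_per_nci = config$calibration$od_per_nci)
  paths <- write_study_files(study, out_dir, config = config)
  message(sprintf("[iapflow] simulate: wrote %d files to %s", length(paths), out_dir))
  invisible(list(study = study, paths = paths))
}

read_arterial_table <- function(arterial, config) {
  if ("conc_nci_ml" %in% names(arterial)) return(arterial)
  if (!"cpm" %in% names(arterial))
    iap_validation_error("arterial table needs a conc_nci_ml or cpm column")
  eff <- if ("efficiency" %in% names(arterial)) arterial$efficiency
         else config$quench$efficiency
  arterial$conc_nci_ml <- counts_to_concentration(
    arterial$cpm, efficiency = eff, volume_ml = config$blood$volume_ml)
  arterial
}

#' Quantify regional blood flow for a whole study
#'
#' Core of the quantification stage, operating on in-memory tables in the
#' pipeline's dialects: fits the calibration curve from the standards,
#' converts each animal-region's density readings to a tissue concentration,
#' and inverts the kinetic model against the animal's own arterial curve.
#' Saturated (non-identifiable) regions are flagged and skipped rather than
#' aborting the run.
#'
#' @param arterial Data frame `animal_id,time_s,conc_nci_ml` (or
#'   `cpm` + optional `efficiency`, converted via the config's quench
#'   settings).
#' @param standards Data frame `standard_id,activity_nci_g,od`.
#' @param roi Data frame `animal_id,region,od`, >= `min_readings` rows per
#'   animal-region.
#' @param animals Optional data frame `animal_id,strain,treatment` joined
#'   onto the output.
#' @param config Configuration list.
#' @return Data frame with one row per animal x region:
#'   `animal_id`, (`strain`, `treatment`,) `region`, `flow_ml_g_min`,
#'   `ci_nci_g`, `od_mean`, `od_sd`, QC columns `calibration_mode`,
#'   `iterations`, `residual` and `flag` (`"ok"` or `"saturated"`).
#' @export
quantify_tables <- function(arterial, standards, roi, animals = NULL,
                            config = default_config()) {
  if (!is.data.frame(roi) || nrow(roi) == 0)
    iap_validation_error("ROI table is empty")
  if (!all(c("animal_id", "region", "od") %in% names(roi)))
    iap_validation_error("ROI table needs columns animal_id, region, od")
  arterial <- read_arterial_table(arterial, config)
  missing_curves <- setdiff(unique(roi$animal_id), unique(arterial$animal_id))
  if (length(missing_curves))
    iap_validation_error(sprintf("no arterial curve for animal(s): %s",
                                 paste(missing_curves, collapse = ", ")))
  cal <- fit_calibration(standards, mode = config$calibration$mode,
                         extrapolation = config$calibration$extrapolation)
  params <- kinetic_params_from_config(config)

  rows <- list()
  for (id in unique(roi$animal_id)) {
    adf <- arterial[arterial$animal_id == id, ]
    curve <- arterial_curve(adf$time_s, adf$conc_nci_ml)
    rdf <- roi[roi$animal_id == id, ]
    for (region in unique(rdf$region)) {
      readings <- rdf$od[rdf$region == region]
      ra <- region_activity(readings, cal,
                            min_readings = config$calibration$min_readings)
      inv <- tryCatch(
        invert_flow(ra$activity, curve, params, details = TRUE),
        iap_saturation_error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = id, region = region,
        flow_ml_g_min = if (is.null(inv)) NA_real_ else inv$flow,
        ci_nci_g = ra$activity,
        od_mean = mean(readings), od_sd = stats::sd(readings),
        calibration_mode = cal$mode,
        iterations = if (is.null(inv)) NA_integer_ else inv$iterations,
        residual = if (is.null(inv)) NA_real_ else inv$residual,
        flag = if (is.null(inv)) "saturated" else "ok")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(animals)) {
    out <- merge(out, animals[, c("animal_id", "strain", "treatment")],
                 by = "animal_id", sort = FALSE)
    out <- out[, c("animal_id", "strain", "treatment",
                   setdiff(names(out), c("animal_id", "strain", "treatment")))]
  }
  out
}

#' Quantify stage of the pipeline (file interface)
#'
#' @param config Configuration list.
#' @param arterial_file,standards_file,roi_file,animals_file CSV inputs in
#'   the pipeline dialects (`animals_file` optional).
#' @param out_file Optional path for the flow table CSV.
#' @return The flow table data frame (see [quantify_tables()]).
#' @export
run_quantify <- function(config = default_config(), arterial_file,
                         standards_file, roi_file, animals_file = NULL,
                         out_file = NULL) {
  read <- function(p) utils::read.csv(p, stringsAsFactors = FALSE)
  message(sprintf("[iapflow] quantify: arterial=%s standards=%s roi=%s",
                  arterial_file, standards_file, roi_file))
  flows <- quantify_tables(read(arterial_file), read(standards_file),
                           read(roi_file),
                           animals = if (is.null(animals_file)) NULL else read(animals_file),
                           config = config)
  n_flagged <- sum(flows$flag != "ok")
  if (n_flagged > 0)
    message(sprintf("[iapflow] quantify: %d region(s) flagged non-identifiable", n_flagged))
  if (!is.null(out_file)) utils::write.csv(flows, out_file, row.names = FALSE)
  flows
}

#' Group analysis of a flow table
#'
#' Per region: mean +/- SEM per strain x treatment group, the 2x2 two-way
#' ANOVA with Tukey HSD, and the percent differences the study reports
#' (mutant-vehicle vs control-vehicle, and inhibitor vs vehicle within each
#' strain). Rows flagged non-identifiable are dropped with a message. If
#' only one group is present the ANOVA is skipped with a warning and
#' summaries alone are returned.
#'
#' @param flows Tidy flow table with columns `animal_id`, `strain`,
#'   `treatment`, `region`, `flow_ml_g_min` (QC columns ignored).
#' @param config Configuration list (supplies `alpha`).
#' @return A list of class `iap_report`: `alpha`, and `per_region`, a named
#'   list with `summaries`, `anova` (a `group_comparison` or `NULL`) and
#'   `percent_diff`.
#' @export
analyze_flows <- function(flows, config = default_config()) {
  needed <- c("animal_id", "strain", "treatment", "region", "flow_ml_g_min")
  if (!is.data.frame(flows) || !all(needed %in% names(flows)))
    iap_validation_error(sprintf("flow table needs columns %s",
                                 paste(needed, collapse = ", ")))
  bad_region <- setdiff(unique(flows$region), IAP_REGIONS)
  if (length(bad_region))
    iap_validation_error(sprintf("unknown region label(s): %s",
                                 paste(bad_region, collapse = ", ")))
  bad_strain <- setdiff(unique(flows$strain), IAP_STRAINS)
  if (length(bad_strain))
    iap_validation_error(sprintf("unknown strain label(s): %s",
                                 paste(bad_strain, collapse = ", ")))
  bad_treat <- setdiff(unique(flows$treatment), IAP_TREATMENTS)
  if (length(bad_treat))
    iap_validation_error(sprintf("unknown treatment label(s): %s",
                                 paste(bad_treat, collapse = ", ")))
  if ("flag" %in% names(flows) && any(flows$flag != "ok")) {
    message(sprintf("[iapflow] analyze: dropping %d non-identifiable row(s)",
                    sum(flows$flag != "ok")))
    flows <- flows[flows$flag == "ok", ]
  }
  flows <- flows[!is.na(flows$flow_ml_g_min), ]
  alpha <- config$stats$alpha

  per_region <- list()
  skipped <- character(0)
  for (region in unique(flows$region)) {
    d <- flows[flows$region == region, ]
    grp <- interaction(d$strain, d$treatment, sep = ":", lex.order = TRUE)
    summaries <- summarize_groups(d$flow_ml_g_min, droplevels(grp),
                                  units = "ml/g/min")
    full_layout <- length(unique(d$strain)) == 2 &&
      length(unique(d$treatment)) == 2 &&
      all(table(d$strain, d$treatment) >= 2)
    if (!full_layout) {
      skipped <- c(skipped, region)
      per_region[[region]] <- list(summaries = summaries, anova = NULL,
                                   percent_diff = NULL)
      next
    }
    comparison <- two_way_anova_tukey(d$flow_ml_g_min, d$strain, d$treatment,
                                      alpha = alpha)
    gmean <- function(s, t) mean(d$flow_ml_g_min[d$strain == s & d$treatment == t])
    pd <- list(
      mutant_vehicle_vs_control_vehicle =
        percent_difference(gmean("control", "vehicle"), gmean("mutant", "vehicle")),
      mutant_inhibitor_vs_mutant_vehicle =
        percent_difference(gmean("mutant", "vehicle"), gmean("mutant", "inhibitor")),
      control_inhibitor_vs_control_vehicle =
        percent_difference(gmean("control", "vehicle"), gmean("control", "inhibitor")))
    per_region[[region]] <- list(summaries = summaries, anova = comparison,
                                 percent_diff = pd)
  }
  if (length(skipped))
    warning(sprintf("incomplete group layout; ANOVA skipped for region(s): %s",
                    paste(skipped, collapse = ", ")))
  structure(list(alpha = alpha, per_region = per_region), class = "iap_report")
}

#' @export
print.iap_report <- function(x, ...) {
  for (region in names(x$per_region)) {
    cat(sprintf("== %s ==\n", region))
    r <- x$per_region[[region]]
    print(r$summaries, row.names = FALSE)
    if (!is.null(r$percent_diff))
      cat(sprintf("  mutant-vehicle vs control-vehicle: %+.1f%%\n",
                  r$percent_diff$mutant_vehicle_vs_control_vehicle))
    if (!is.null(r$anova)) {
      sig <- r$anova$tukey[r$anova$tukey$significant, "pair"]
      cat(sprintf("  significant Tukey pairs (alpha %g): %s\n", x$alpha,
                  if (length(sig)) paste(sig, collapse = "; ") else "none"))
    }
  }
  invisible(x)
}

report_to_list <- function(report) {
  per_region <- lapply(report$per_region, function(r) {
    out <- list(summaries = r$summaries)
    if (!is.null(r$anova))
      out$anova <- list(effects = r$anova$effects, tukey = r$anova$tukey,
                        note = r$anova$note)
    if (!is.null(r$percent_diff)) out$percent_diff <- r$percent_diff
    out
  })
  list(alpha = report$alpha, per_region = per_region)
}

#' Analyze stage of the pipeline
#'
#' Runs [analyze_flows()] (plus [blot_normalize_and_test()] when a blot
#' table is given) and writes `report.json` and `summary.tsv` to `out_dir`.
#' Outputs contain no timestamps, so regenerating from the same inputs is
#' byte-identical.
#'
#' @param config Configuration list.
#' @param flows Flow table data frame or CSV path.
#' @param blots Optional blot table data frame or CSV path
#'   (`animal_id,strain,treatment,marker,phospho,total`).
#' @param out_dir Optional output directory for the report files.
#' @return The report list (invisibly when `out_dir` is given).
#' @export
run_analyze <- function(config = default_config(), flows, blots = NULL,
                        out_dir = NULL) {
  if (is.character(flows)) flows <- utils::read.csv(flows, stringsAsFactors = FALSE)
  if (is.character(blots)) blots <- utils::read.csv(blots, stringsAsFactors = FALSE)
  report <- analyze_flows(flows, config)
  blot_res <- if (!is.null(blots)) blot_normalize_and_test(blots, alpha = config$stats$alpha)
  if (is.null(out_dir)) {
    return(list(flows = report, blots = blot_res))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- report_to_list(report)
  if (!is.null(blot_res))
    out$blots <- lapply(blot_res$tests, function(tst)
      list(effects = tst$effects, tukey = tst$tukey))
  out$config_checksum <- config_checksum(config)
  jsonlite::write_json(out, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  summary_rows <- do.call(rbind, lapply(names(report$per_region), function(region) {
    s <- report$per_region[[region]]$summaries
    s$region <- region
    s[, c("region", "group", "n", "mean", "sem")]
  }))
  utils::write.table(summary_rows, file.path(out_dir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  message(sprintf("[iapflow] analyze: wrote report.json and summary.tsv to %s", out_dir))
  invisible(list(flows = report, blots = blot_res))
}
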