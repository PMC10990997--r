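## Seeded synthetic-study generator. Emulates the complete experiment --
## gamma-variate arterial curves sampled every 3 s for 60 s, terminal tissue
## concentrations produced by the forward kinetic model from ground-truth
## regional flows with strain x treatment effects, eight calibration
## standards log-spaced over 40-1069 nCi/g, and replicate optical-density
## readings per region -- so the full quantification pipeline can be
## validated by parameter recovery without any external data.

IAP_REGIONS <- c("cortex", "hippocampus", "cerebellum", "pons")
IAP_STRAINS <- c("control", "mutant")
IAP_TREATMENTS <- c("vehicle", "inhibitor")

#' Group mean flows mirroring the study's effect structure
#'
#' Builds the (strain, treatment, region) -> mean flow table used as the
#' generator's ground truth. Baseline (control-vehicle) flows are free
#' parameters; the mutant-vehicle group is elevated by the configured ratios
#' (default +32% cortex, +15% hippocampus, no change elsewhere), and both
#' inhibitor-treated groups sit at `inhibitor_ratio` times the control
#' baseline in every region: a small, non-significant reduction in controls,
#' and a restoration toward control levels in the previously elevated mutant
#' regions.
#'
#' @param base_flow Named vector of control-vehicle mean flows per region,
#'   ml g^-1 min^-1.
#' @param mutant_vehicle_ratio Named vector of mutant-vehicle / control-vehicle
#'   flow ratios per region.
#' @param inhibitor_ratio Scalar ratio applied to the control baseline for
#'   both inhibitor-treated groups.
#' @return A data frame with columns `strain`, `treatment`, `region`,
#'   `mean_flow`.
#' @examples
#' head(mirror_group_means())
#' @export
mirror_group_means <- function(base_flow = c(cortex = 1.10, hippocampus = 1.00,
                                             cerebellum = 1.05, pons = 0.85),
                               mutant_vehicle_ratio = c(cortex = 1.32,
                                                        hippocampus = 1.15,
                                                        cerebellum = 1.00,
                                                        pons = 1.00),
                               inhibitor_ratio = 0.95) {
  regions <- names(base_flow)
  if (is.null(regions) || !setequal(names(mutant_vehicle_ratio), regions))
    iap_validation_error("base_flow and mutant_vehicle_ratio must be named by the same regions")
  mutant_vehicle_ratio <- mutant_vehicle_ratio[regions]
  rows <- rbind(
    data.frame(strain = "control", treatment = "vehicle", region = regions,
               mean_flow = unname(base_flow)),
    data.frame(strain = "mutant", treatment = "vehicle", region = regions,
               mean_flow = unname(base_flow * mutant_vehicle_ratio)),
    data.frame(strain = "control", treatment = "inhibitor", region = regions,
               mean_flow = unname(base_flow * inhibitor_ratio)),
    data.frame(strain = "mutant", treatment = "inhibitor", region = regions,
               mean_flow = unname(base_flow * inhibitor_ratio))
  )
  rownames(rows) <- NULL
  rows
}

#' Define a synthetic study design
#'
#' Encapsulates the strain x treatment x region layout, the per-group mean
#' flows, all noise levels and the master seed of one synthetic experiment.
#' Defaults mirror the modeled study: 2 strains x 2 treatments with n = 8
#' animals per group, four brain regions, 10% between-animal coefficient of
#' variation on true flows.
#'
#' @param n_per_group Animals per strain x treatment cell (>= 2).
#' @param group_mean_flow Data frame from [mirror_group_means()] (or of the
#'   same shape) giving the true mean flow of every group x region.
#' @param between_animal_cv Coefficient of variation of true flows across
#'   animals within a group (fraction, >= 0).
#' @param od_noise_sd Additive Gaussian SD of individual optical-density
#'   readings (OD units).
#' @param arterial_noise_cv Multiplicative log-normal CV of individual
#'   arterial samples (fraction).
#' @param peak_conc Peak of the arterial gamma-variate input, nCi/ml.
#' @param rise_time_s Time to peak of the arterial input, s.
#' @param n_readings Optical-density readings per region (>= 8 by study
#'   convention).
#' @param seed Master seed; per-animal streams are derived from it by fixed
#'   offsets so enlarging the study never perturbs earlier animals.
#' @param strains,treatments,regions Factor level sets.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_per_group = 8,
                         group_mean_flow = mirror_group_means(),
                         between_animal_cv = 0.10,
                         od_noise_sd = 0.005,
                         arterial_noise_cv = 0.05,
                         peak_conc = 800,
                         rise_time_s = 60,
                         n_readings = 8,
                         seed = 1,
                         strains = IAP_STRAINS,
                         treatments = IAP_TREATMENTS,
                         regions = IAP_REGIONS) {
  if (n_per_group < 2) iap_validation_error("n_per_group must be at least 2")
  if (between_animal_cv < 0) iap_validation_error("between_animal_cv must be non-negative")
  if (od_noise_sd < 0 || arterial_noise_cv < 0)
    iap_validation_error("noise levels must be non-negative")
  needed <- expand.grid(strain = strains, treatment = treatments,
                        region = regions, stringsAsFactors = FALSE)
  key <- function(d) paste(d$strain, d$treatment, d$region)
  if (!all(key(needed) %in% key(group_mean_flow)))
    iap_validation_error("group_mean_flow must cover every strain x treatment x region combination")
  if (any(group_mean_flow$mean_flow <= 0))
    iap_validation_error("all group mean flows must be positive")
  structure(list(n_per_group = as.integer(n_per_group),
                 group_mean_flow = group_mean_flow,
                 between_animal_cv = between_animal_cv,
                 od_noise_sd = od_noise_sd,
                 arterial_noise_cv = arterial_noise_cv,
                 peak_conc = peak_conc,
                 rise_time_s = rise_time_s,
                 n_readings = as.integer(n_readings),
                 seed = as.integer(seed),
                 strains = strains, treatments = treatments, regions = regions),
            class = "study_design")
}

## Normal draws truncated at zero by redraw (cv <= ~0.3 in practice, so the
## truncated mass is negligible and the mean shift immaterial).
rnorm_pos <- function(n, mean, sd) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- which(x <= 0)
  }
  x
}

#' Simulate an arterial input curve
#'
#' Gamma-variate-shaped rise from zero,
#' `C_A(t) = peak * (t / rise) * exp(1 - t / rise)`, sampled every 3 s for
#' 60 s (21 samples) as in the modeled experiment, with optional per-sample
#' multiplicative log-normal noise (unit mean).
#'
#' @param peak_conc Peak concentration, nCi/ml, > 0.
#' @param rise_time_s Time to peak, s, in (0, 60].
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (0 for a noiseless curve).
#' @param times Sample times, s (default `seq(0, 60, by = 3)`).
#' @param seed Optional seed for reproducibility; when `NULL` the current
#'   RNG stream is used.
#' @return An [arterial_curve()].
#' @examples
#' simulate_arterial_curve(800, 20, seed = 1)
#' @export
simulate_arterial_curve <- function(peak_conc, rise_time_s = 60, noise_cv = 0,
                                    times = seq(0, 60, by = 3), seed = NULL) {
  if (peak_conc <= 0) iap_validation_error("peak_conc must be positive")
  if (rise_time_s <= 0 || rise_time_s > max(times))
    iap_validation_error("rise_time_s must lie in (0, max(times)]")
  if (!is.null(seed)) set.seed(seed)
  conc <- peak_conc * (times / rise_time_s) * exp(1 - times / rise_time_s)
  if (noise_cv > 0) {
    sdlog <- sqrt(log1p(noise_cv^2))
    conc <- conc * stats::rlnorm(length(times), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  arterial_curve(times, conc)
}

#' Simulate a complete synthetic study
#'
#' For every animal: true regional flows are drawn from
#' Normal(group mean, cv * mean) truncated at zero; an arterial input curve
#' is simulated; each region's terminal tissue concentration is computed with
#' the forward kinetic model from the animal's own (noisy) curve; the
#' concentration is mapped to optical density through the generator's true
#' linear film response (`od = activity * od_per_nci`); and `n_readings`
#' noisy density readings are emitted per region. The eight calibration
#' standards (log-spaced over `standards_range`) follow the same film
#' response, so with all noise set to zero the calibrate-and-invert pipeline
#' recovers the true flows to numerical precision.
#'
#' Per-animal RNG streams are derived from the design seed by fixed offsets,
#' so increasing `n_per_group` never changes previously generated animals.
#'
#' @param design A [study_design()].
#' @param params [kinetic_params()] used by the forward model (decapitation
#'   defaults to the last arterial sample, 60 s).
#' @param od_per_nci Slope of the generator's true film response, OD per
#'   nCi/g.
#' @param standards_range Activity span of the calibration standards, nCi/g.
#' @param n_standards Number of standards (log-spaced).
#' @return An object of class `iap_study`: a list with the `design`,
#'   `params`, and data frames `animals` (id, strain, treatment), `truth`
#'   (true flows), `arterial`, `roi`, `standards` and `tissue` (noiseless
#'   concentrations).
#' @examples
#' study <- simulate_study(study_design(n_per_group = 2, seed = 7))
#' head(study$truth)
#' @export
simulate_study <- function(design, params = kinetic_params(),
                           od_per_nci = 0.001,
                           standards_range = c(40, 1069), n_standards = 8) {
  if (!inherits(design, "study_design"))
    iap_validation_error("design must be a study_design")
  acts <- exp(seq(log(standards_range[1]), log(standards_range[2]),
                  length.out = n_standards))
  standards <- data.frame(standard_id = sprintf("std%02d", seq_len(n_standards)),
                          activity_nci_g = acts,
                          od = acts * od_per_nci)
  od_lo <- min(standards$od); od_hi <- max(standards$od)

  groups <- expand.grid(treatment = design$treatments, strain = design$strains,
                        stringsAsFactors = FALSE)[, c("strain", "treatment")]
  gm <- design$group_mean_flow
  animals <- truth <- arterial <- roi <- tissue <- list()
  for (gi in seq_len(nrow(groups))) {
    strain <- groups$strain[gi]
    treatment <- groups$treatment[gi]
    means <- vapply(design$regions, function(r)
      gm$mean_flow[gm$strain == strain & gm$treatment == treatment & gm$region == r],
      numeric(1))
    for (j in seq_len(design$n_per_group)) {
      id <- sprintf("%s_%s_%02d", strain, treatment, j)
      set.seed(design$seed + gi * 100000L + j * 100L)
      flows <- rnorm_pos(length(means), means, design$between_animal_cv * means)
      curve <- simulate_arterial_curve(design$peak_conc, design$rise_time_s,
                                       noise_cv = design$arterial_noise_cv)
      ci <- vapply(flows, forward_tissue_concentration, numeric(1),
                   curve = curve, params = params)
      od_true <- ci * od_per_nci
      if (any(od_true < od_lo | od_true > od_hi))
        iap_stop(sprintf(
          "animal %s: simulated tissue concentration %.4g nCi/g falls outside the calibration standards' span [%.4g, %.4g] nCi/g; widen the standards or adjust the group mean flows",
          id, ci[which(od_true < od_lo | od_true > od_hi)[1]],
          min(acts), max(acts)), "iap_range_error")
      readings <- lapply(od_true, function(m)
        m + stats::rnorm(design$n_readings, 0, design$od_noise_sd))

      animals[[id]] <- data.frame(animal_id = id, strain = strain,
                                  treatment = treatment)
      truth[[id]] <- data.frame(animal_id = id, strain = strain,
                                treatment = treatment, region = design$regions,
                                true_flow_ml_g_min = flows)
      arterial[[id]] <- data.frame(animal_id = id, time_s = curve$times,
                                   conc_nci_ml = curve$conc)
      roi[[id]] <- data.frame(animal_id = id,
                              region = rep(design$regions,
                                           each = design$n_readings),
                              od = unlist(readings))
      tissue[[id]] <- data.frame(animal_id = id, region = design$regions,
                                 ci_nci_g = ci)
    }
  }
  bind <- function(x) { d <- do.call(rbind, x); rownames(d) <- NULL; d }
  structure(list(design = design, params = params, od_per_nci = od_per_nci,
                 standards = standards,
                 animals = bind(animals), truth = bind(truth),
                 arterial = bind(arterial), roi = bind(roi),
                 tissue = bind(tissue)),
            class = "iap_study")
}

#' @export
print.iap_study <- function(x, ...) {
  cat(sprintf("Synthetic study: %d animals (%d per group), %d regions, seed %d\n",
              nrow(x$animals), x$design$n_per_group,
              length(x$design$regions), x$design$seed))
  invisible(x)
}

#' Simulate Western-blot densitometry signals
#'
#' Log-normal phospho and total signals for two phosphorylation markers,
#' three animals per strain x treatment group (as in the immunoblot arm of
#' the modeled study), with configurable group multipliers on the
#' phospho/total ratio and a loading-control signal per lane.
#'
#' @param seed Seed for the fixture.
#' @param group_effects Optional data frame with columns `strain`,
#'   `treatment`, optionally `marker`, and `multiplier`, applied to the
#'   phospho/total ratio of matching groups (default 1 everywhere).
#' @param n_per_group Animals per group (default 3).
#' @param noise_cv Log-normal coefficient of variation of each signal
#'   (0 for a noiseless fixture).
#' @param markers Marker labels.
#' @param base_total Median total-protein signal (arbitrary units).
#' @param base_ratio Baseline phospho/total ratio.
#' @return A data frame with columns `animal_id`, `strain`, `treatment`,
#'   `marker`, `phospho`, `total`, `loading_control`.
#' @examples
#' blots <- simulate_blots(seed = 1)
#' head(blots)
#' @export
simulate_blots <- function(seed, group_effects = NULL, n_per_group = 3,
                           noise_cv = 0.1,
                           markers = c("pS6_S240_244", "pAkt_S473"),
                           base_total = 1000, base_ratio = 1) {
  if (!is.null(group_effects)) {
    if (!all(c("strain", "treatment", "multiplier") %in% names(group_effects)))
      iap_validation_error("group_effects needs columns strain, treatment, multiplier")
    if (any(group_effects$multiplier <= 0))
      iap_validation_error("effect multipliers must be positive")
  }
  set.seed(seed)
  sdlog <- if (noise_cv > 0) sqrt(log1p(noise_cv^2)) else 0
  rnoise <- function(n) if (sdlog > 0)
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog) else rep(1, n)
  lookup_mult <- function(strain, treatment, marker) {
    if (is.null(group_effects)) return(1)
    ge <- group_effects
    hit <- ge$strain == strain & ge$treatment == treatment &
      (if ("marker" %in% names(ge)) ge$marker == marker else TRUE)
    if (any(hit)) ge$multiplier[which(hit)[1]] else 1
  }
  groups <- expand.grid(treatment = IAP_TREATMENTS, strain = IAP_STRAINS,
                        stringsAsFactors = FALSE)
  rows <- list()
  for (gi in seq_len(nrow(groups))) {
    for (j in seq_len(n_per_group)) {
      id <- sprintf("blot_%s_%s_%d", groups$strain[gi], groups$treatment[gi], j)
      for (mk in markers) {
        total <- base_total * rnoise(1)
        ratio <- base_ratio *
          lookup_mult(groups$strain[gi], groups$treatment[gi], mk) * rnoise(1)
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = id, strain = groups$strain[gi],
          treatment = groups$treatment[gi], marker = mk,
          phospho = total * ratio, total = total,
          loading_control = base_total * rnoise(1))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
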