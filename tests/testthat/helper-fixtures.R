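# Fixture builders and independent oracles shared across tests.

# Truly constant arterial input (user-supplied time-0 concentration).
constant_curve <- function(value = 100, t_end = 60) {
  arterial_curve(c(0, t_end), c(value, value))
}

# Linear ramp C_A(t) = slope * t sampled every 3 s.
ramp_curve <- function(slope = 2, times = seq(0, 60, by = 3)) {
  arterial_curve(times, slope * times)
}

# Random non-negative piecewise-linear curve on the 3-s sampling grid.
random_curve <- function(times = seq(0, 60, by = 3)) {
  arterial_curve(times, c(0, runif(length(times) - 1, 0, 300)))
}

# Identity calibration: optical density equals activity over the standard
# span, so calibrated values can be read off directly.
identity_standards <- function(n = 8, lo = 40, hi = 1069) {
  acts <- exp(seq(log(lo), log(hi), length.out = n))
  data.frame(activity_nci_g = acts, od = acts)
}

# Independent brute-force quadrature oracle for the forward model:
# fine-grid trapezoid over the linear interpolant of C_A.
trapz_forward <- function(f, curve, params = kinetic_params(), dt = 1e-3) {
  t_end <- max(curve$times)
  tt <- seq(0, t_end, by = dt)
  ca <- stats::approx(curve$times, curve$conc, xout = tt)$y
  K <- params$m * f / params$lambda / 60
  if (K == 0) return(0)
  params$lambda * K * pracma::trapz(tt, ca * exp(-K * (t_end - tt)))
}

# Balanced 2x2 layout with n per cell; returns a data frame of labels.
cell_layout <- function(n) {
  expand.grid(strain = c("control", "mutant"),
              treatment = c("vehicle", "inhibitor"),
              rep = seq_len(n), stringsAsFactors = FALSE)
}

# Noise-free study configuration at a small size.
noiseless_config <- function(n_per_group = 2) {
  cfg <- default_config()
  cfg$synthetic$n_per_group <- n_per_group
  cfg$synthetic$between_animal_cv <- 0
  cfg$synthetic$od_noise_sd <- 0
  cfg$synthetic$arterial_noise_cv <- 0
  cfg
}

run_pipeline_in_memory <- function(cfg, seed) {
  study <- simulate_study(design_from_config(cfg, seed = seed))
  flows <- quantify_tables(study$arterial, study$standards, study$roi,
                           study$animals, cfg)
  list(study = study, flows = flows, report = analyze_flows(flows, cfg))
}
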