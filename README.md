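# iapflow

Quantitative regional cerebral blood flow (rCBF) analysis for
¹⁴C-iodoantipyrine (IAP) autoradiography, built around the
indicator-fractionation (tissue-equilibration) tracer-kinetic model. The
package is aimed at physiologists quantifying terminal autoradiographic
blood-flow experiments — arterial sample tables, calibration standards and
regional optical densities in, flows and group statistics out — and at
anyone validating such a pipeline by simulation.

## The model

During a one-minute tracer infusion the tissue concentration at
decapitation time *T* follows

```
Ci(T) = λ K ∫₀ᵀ C_A(t) e^(−K(T−t)) dt,   K = m f / λ
```

where `C_A(t)` is the arterial input function (nCi/ml), `λ` the
tissue:blood partition coefficient (0.80 for IAP in brain), `m` a
proportionality constant (1 by convention) and `f` the blood flow per unit
tissue mass (ml·g⁻¹·min⁻¹). `iapflow` provides:

* **Kinetics** — exact evaluation of the forward integral for a
  piecewise-linear arterial curve, and its inversion for `f` by bracketed
  root-finding with explicit saturation (non-identifiability) diagnostics.
* **Calibration** — monotone interpolation (or linear fit) through
  precalibrated isotope standards to convert optical densities to nCi/g,
  plus quench correction of scintillation counts (cpm → dpm → nCi/ml).
* **Statistics** — mean ± SEM summaries, one-way and 2×2 strain × treatment
  ANOVA with Tukey HSD over cell means, percent differences, and
  Western-blot phospho/total normalization tests.
* **Simulation** — a seeded generator of complete synthetic studies
  (arterial curves, standards, densitometry readings, ground-truth flows,
  blot fixtures) for end-to-end parameter-recovery validation.
* **Pipeline** — `run_simulate()`, `run_quantify()`, `run_analyze()` over
  fixed CSV/YAML dialects, with manifests and byte-reproducible outputs,
  plus a thin CLI at `inst/cli/iapflow.R`.

## Worked example

```r
library(iapflow)

# A constant 100 nCi/ml arterial input for 60 s; at f = 0.8 ml/g/min the
# closed form gives lambda * C * (1 - e^-1):
curve <- arterial_curve(c(0, 60), c(100, 100))
forward_tissue_concentration(0.8, curve)
#> [1] 50.56964
invert_flow(50.5696, curve)
#> [1] 0.7999988

# A full synthetic study at the mirrored design (4 groups x 8 animals,
# cortex elevated 1.32x in the mutant-vehicle group, cv = 0.10):
cfg    <- default_config()
study  <- simulate_study(design_from_config(cfg, seed = 1))
flows  <- quantify_tables(study$arterial, study$standards, study$roi,
                          study$animals, cfg)
report <- analyze_flows(flows, cfg)

report$per_region$cortex$summaries
#>               group n     mean        sem
#> 1 control:inhibitor 8 1.030177 0.03861342
#> 2   control:vehicle 8 1.094313 0.03449228
#> 3  mutant:inhibitor 8 0.999595 0.04493506
#> 4    mutant:vehicle 8 1.459259 0.05544630

report$per_region$cortex$percent_diff$mutant_vehicle_vs_control_vehicle
#> [1] 33.34932

report$per_region$cortex$anova$tukey[, c("pair", "diff", "p_adj", "significant")]
#>                                   pair        diff        p_adj significant
#> 1  control:vehicle - control:inhibitor  0.06413542 7.342635e-01       FALSE
#> 2 mutant:inhibitor - control:inhibitor -0.03058226 9.605647e-01       FALSE
#> 3   mutant:vehicle - control:inhibitor  0.42908127 1.023203e-06        TRUE
#> 4   mutant:inhibitor - control:vehicle -0.09471768 4.399105e-01       FALSE
#> 5     mutant:vehicle - control:vehicle  0.36494586 1.551981e-05        TRUE
#> 6    mutant:vehicle - mutant:inhibitor  0.45966354 2.902398e-07        TRUE
```

Flows recovered by calibration + inversion reproduce the configured group
structure: the mutant-vehicle cortex sits ~33% above the control-vehicle
cortex for this seed (configured: +32%), that elevation and its reversal by
the inhibitor are the significant Tukey pairs, and the small vehicle-vs-
inhibitor difference within controls is not significant. With all noise
parameters set to zero the pipeline recovers every true flow to within
1e−6 relative — the identifiability check run in the test suite.

See `vignettes/iapflow-methods.Rmd` for the model's assumptions, the
numerical choices (exact segment integration, smallest-root inversion,
saturation ceiling) and what the generator does and does not emulate.

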