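---
title: "Quantifying regional cerebral blood flow from iodoantipyrine autoradiograms"
author: "iapflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying regional cerebral blood flow from iodoantipyrine autoradiograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iapflow)
```

## The measurement and its model

The indicator-fractionation (tissue-equilibration) method measures regional
cerebral blood flow (rCBF) from the brain uptake of a freely diffusible
radiotracer, here carbon-14 iodoantipyrine, during a one-minute intravenous
infusion terminated by decapitation. Arterial blood is sampled from a femoral
catheter roughly every 3 s for 60 s, giving the arterial input function
$C_A(t)$ (nCi per ml blood); the brain is frozen, sectioned, and exposed to
X-ray film, and each region's tracer concentration at the moment of
decapitation, $C_i(T)$ (nCi per g tissue), is read off the autoradiogram by
densitometry against co-exposed isotope standards.

Uptake follows the one-compartment tissue-equilibration model

$$C_i(T) = \lambda\,K \int_0^T C_A(t)\,e^{-K(T-t)}\,dt,
  \qquad K = \frac{m f}{\lambda},$$

where $\lambda$ is the tissue:blood partition coefficient of the tracer
(0.80 for iodoantipyrine in brain, the package default), $m$ is a
dimensionless proportionality constant, and $f$ is the blood flow per unit
tissue mass in ml·g⁻¹·min⁻¹ — the quantity of interest. Within the package,
time is in seconds and $K$ in s⁻¹; flows cross the interface in
ml·g⁻¹·min⁻¹ (a factor 60 at the boundary). Blood (nCi/ml) and tissue
(nCi/g) concentrations are treated as numerically commensurate, tissue
density being close to 1 g/ml. $m$ has no published value for this assay;
the package follows the classical indicator-fractionation convention
$m = 1$ and exposes it in `kinetic_params()` so other conventions can be
expressed.

## Numerical choices

**Input interpolation and integration.** The arterial curve is modeled as
piecewise linear between samples, with an implicit $(0, 0)$ sample prepended
when the series does not start at zero (no tracer precedes the infusion).
Because the integrand is then a linear function times an exponential on each
segment, the convolution integral has a closed form per segment; the forward
model evaluates that form exactly rather than by quadrature. Written with
$s = t - T \le 0$ the segment antiderivative involves only $e^{Ks} \le 1$,
so the evaluation is stable for arbitrarily large $K$. Constant-input checks
against $\lambda C_A (1 - e^{-KT})$ agree to machine precision, and
brute-force fine-grid trapezoid integration is kept in the test suite as an
independent oracle.

**Inversion.** Uptake rises strictly with $f$ throughout the physiological
range, but for arterial inputs that decline toward the end of the experiment
the forward value eventually peaks in $K$ and relaxes to
$\lambda C_A(T)$ as $K \to \infty$. The physical solution is therefore the
*smallest* root: `invert_flow()` scans a logarithmic grid in $K$ (80 points,
initial upper end 10 s⁻¹, widened tenfold up to twice) for the first upward
crossing and polishes it with Brent's method to an absolute tolerance of
$10^{-10}$ s⁻¹. A tissue concentration above the supremum of the forward
value over all $K$ cannot be produced by the model; it raises a saturation
error naming that ceiling, and the pipeline flags such regions row by row
instead of aborting.

**Decapitation time.** $T$ defaults to the last arterial sample time
(decapitation immediately follows the final sample); a configured $T$ may
exceed the last sample by at most one sampling interval, over which the
curve is held at its last value.

## Calibration

Optical density is mapped to activity by monotone piecewise-linear
interpolation through the standards (eight, spanning 40–1069 nCi/g in the
modeled assay), which reproduces every standard exactly and assumes no
film-response physics; an ordinary least-squares linear mode is available
and reports its $R^2$. Queries outside the standards' span are refused by
default — the standards define the trusted range — with clamping available
behind an explicit flag. Each region's concentration is the calibrated value
of the mean of its replicate density readings (at least eight, the assay's
convention), with per-reading calibrated values and their SD reported as a
dispersion check.

Arterial counts are quench-corrected by dividing counts per minute by the
counting efficiency (supplied directly, or through a linear quench curve
$a + b \cdot \text{index}$ clipped at 1; with neither supplied, efficiency 1
is assumed and a warning logged), converted at 2220 dpm/nCi and divided by
the 10 µl sample volume.

## The synthetic study generator

No deposited data accompany the modeled experiment, so the package ships a
seeded generator that emulates its full structure: 2 strains (control,
mutant) × 2 treatments (vehicle, inhibitor) × n = 8 animals, four regions
(cortex, hippocampus, cerebellum, pons).

* **Arterial input.** A gamma-variate rise
  $C_A(t) = \text{peak}\,(t/t_r)\,e^{1 - t/t_r}$ sampled every 3 s for
  60 s, with multiplicative log-normal per-sample noise (unit mean,
  CV 0.05 by default). The default peak is 800 nCi/ml and the default rise
  time is 60 s, i.e. the concentration climbs throughout the sampling
  window — the behavior of a continuous one-minute infusion — which also
  keeps the forward model strictly monotone (hence invertible) across the
  whole physiological flow range. Each animal's tissue concentrations are
  computed from its *own* noisy curve, as in the real assay.
* **Flows.** True regional flows are drawn per animal from
  Normal(group mean, cv·mean), truncated at zero, with cv = 0.10. The
  modeled study prints no absolute flows (its figure is graphical), so
  baselines are free parameters chosen once as realistic values for
  isoflurane-anesthetized young rats: cortex 1.10, hippocampus 1.00,
  cerebellum 1.05, pons 0.85 ml·g⁻¹·min⁻¹. Only the *ratios* are pinned to
  the reported effects: mutant-vehicle flows are 1.32× (cortex) and 1.15×
  (hippocampus) the control baseline, other regions unchanged; both
  inhibitor-treated groups sit at 0.95× the control baseline everywhere — a
  small, non-significant reduction in controls and a restoration toward
  control levels in the mutant's elevated regions, mirroring the reported
  significance pattern. The between-animal cv is a guess (only SEM bars are
  published); results that depend on it should be read accordingly.
* **Densitometry.** Tissue concentrations are mapped to optical density
  through a linear film response (0.001 OD per nCi/g), and eight readings
  per region are emitted with additive Gaussian noise (SD 0.005 OD ≈ 1–2%
  of a typical tissue signal). The standards are log-spaced over 40–1069
  nCi/g on the same response, so with all noise at zero the
  calibrate-and-invert pipeline reproduces the true flows to numerical
  precision — the core identifiability check.
* **Seeding.** Per-animal RNG streams are derived from the design seed by
  fixed offsets, so enlarging a study never perturbs existing animals, and
  identical seeds give byte-identical output files (no timestamps are
  written).

What the generator does *not* emulate: film-exposure physics and its
nonlinear response, anatomical structure within regions, correlated
between-region physiology within an animal, catheter dead-time or sampling
jitter, and any pharmacokinetics of the inhibitor (treatment is purely a
group label). Passing recovery tests therefore demonstrate the correctness
of the estimation pipeline under the stated noise model, not robustness to
those unmodeled features of real data.

## Statistics

Following the modeled study's analysis plan: group summaries as mean ± SEM
(sample SD over √n); one-way ANOVA across groups for scalar physiology;
and, as the primary flow analysis, a per-region 2×2 strain × treatment
ANOVA followed by Tukey HSD over the four cell means using the
studentized-range distribution (Tukey–Kramer standard errors). The study's
wording leaves the two-way factors ambiguous ("between the groups and among
multiple brain regions"); the per-region 2×2 layout is fixed here as the
primary analysis because it matches the figure's pairwise asterisk/dagger
comparisons, and no additional correction is applied across the four
regions (none is applied in the source analysis). Unbalanced layouts fall
back to type-II sums of squares with a logged note. Exact fits (zero
residual variance, routine with noiseless synthetic data) are
post-processed explicitly: effects with non-zero sums of squares report
unbounded F with p = 0 and a warning, and all-constant data report NaN/NA.
Western-blot signals are normalized per animal as phospho/total before the
same 2×2 analysis, marker by marker (n = 3 per group in the mirrored
fixture).

The suite verifies calibration of the machinery itself: one-way type-I
error within [0.04, 0.06] and familywise error of the 2×2 + Tukey analysis
within [0.03, 0.07] at α = 0.05 over 2000 null simulations, and agreement
of the in-package Tukey table with `stats::TukeyHSD` to 10⁻⁶.

## Problem sizes and reproducibility

The recovery analyses run the full simulate → calibrate → invert → analyze
pipeline at the study's own scale (32 animals, 128 region inversions per
replicate). Ensemble checks use 200 seeded replicates, which puts the
Monte-Carlo standard error of the recovered percent elevations near 0.5
points — comfortably inside the ±2-point band they are held to — while a
single replicate is held only to ±6 points, about one between-animal
standard deviation at cv = 0.10 and n = 8. The same 200-replicate ensemble
drives `scripts/acceptance.R`, which derives its replicate seeds from a
single command-line seed.

## Known limitations

* A single $\lambda$ is applied to all regions; regional variation in the
  partition coefficient is not modeled (a single 0.80 is all the assay
  specifies).
* The one-compartment model ignores diffusion limitation, partial-volume
  effects and isotope decay (negligible over 60 s for ¹⁴C).
* The film response is treated as monotone and static; real OD–activity
  response over multi-day exposures is nonlinear and unmodeled.
* With arterial inputs that decline steeply before decapitation the model's
  identifiable flow range narrows (the forward map loses monotonicity at
  high flow); the generator's default ramped input avoids this, but real
  bolus-shaped inputs may not.
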