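#' Arterial input function
#'
#' Container for a timed arterial tracer-concentration series, the input
#' function \eqn{C_A(t)} of the tissue-equilibration model. Samples are taken
#' from a cannulated femoral artery roughly every 3 s during the one-minute
#' tracer infusion; between samples the curve is treated as piecewise linear.
#' If the series does not start at time zero, a (0, 0) sample is prepended:
#' no tracer is in the arterial blood before the infusion starts.
#'
#' @param times Sample times in seconds since infusion start; non-negative,
#'   strictly increasing.
#' @param concentrations Arterial tracer concentration at each time, in
#'   nCi per ml whole blood; non-negative.
#' @return An object of class `arterial_curve` with elements `times` and
#'   `conc`.
#' @examples
#' curve <- arterial_curve(seq(3, 60, by = 3), seq(10, 200, by = 10))
#' curve$times[1]   # 0, prepended
#' @export
arterial_curve <- function(times, concentrations) {
  if (!is.numeric(times) || !is.numeric(concentrations))
    iap_validation_error("times and concentrations must be numeric")
  if (length(times) != length(concentrations))
    iap_validation_error("times and concentrations must have the same length")
  if (anyNA(times) || anyNA(concentrations))
    iap_validation_error("arterial curve contains missing values")
  if (any(times < 0))
    iap_validation_error("arterial sample times must be non-negative")
  if (length(times) > 1 && is.unsorted(times, strictly = TRUE))
    iap_validation_error("arterial sample times must be strictly increasing")
  if (any(concentrations < 0))
    iap_validation_error("arterial concentrations must be non-negative")
  if (length(times) == 0 || times[1] > 0) {
    times <- c(0, times)
    concentrations <- c(0, concentrations)
  }
  if (length(times) < 2)
    iap_validation_error("an arterial curve needs at least 2 samples")
  structure(list(times = as.numeric(times), conc = as.numeric(concentrations)),
            class = "arterial_curve")
}

#' @export
print.arterial_curve <- function(x, ...) {
  cat(sprintf("Arterial input function: %d samples over [%g, %g] s, peak %.4g nCi/ml\n",
              length(x$times), min(x$times), max(x$times), max(x$conc)))
  invisible(x)
}

#' Kinetic model parameters
#'
#' Constants of the indicator-fractionation model: the tissue:blood partition
#' coefficient \eqn{\lambda} (0.80 for iodoantipyrine in brain), the
#' proportionality constant \eqn{m} (dimensionless, 1 by convention) and the
#' decapitation time \eqn{T}. The rate constant \eqn{K = m f / \lambda} is
#' always derived from the flow, never stored.
#'
#' @param lambda Tissue:blood partition coefficient, dimensionless, > 0.
#' @param m Proportionality constant, dimensionless, > 0.
#' @param decap_time_s Decapitation time in seconds since infusion start, or
#'   `NULL` to use the last arterial sample time (decapitation immediately
#'   follows the final blood sample).
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params()                 # lambda 0.80, m 1, T from the curve
#' kinetic_params(decap_time_s = 60)
#' @export
kinetic_params <- function(lambda = 0.80, m = 1.0, decap_time_s = NULL) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) || lambda <= 0)
    iap_validation_error("lambda must be a single positive number")
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m <= 0)
    iap_validation_error("m must be a single positive number")
  if (!is.null(decap_time_s)) {
    if (!is.numeric(decap_time_s) || length(decap_time_s) != 1L ||
        is.na(decap_time_s) || decap_time_s <= 0)
      iap_validation_error("decap_time_s must be a single positive number or NULL")
    decap_time_s <- as.numeric(decap_time_s)
  }
  structure(list(lambda = as.numeric(lambda), m = as.numeric(m),
                 decap_time_s = decap_time_s),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("Kinetic parameters: lambda = %g, m = %g, T = %s\n",
              x$lambda, x$m,
              if (is.null(x$decap_time_s)) "last arterial sample"
              else paste0(x$decap_time_s, " s")))
  invisible(x)
}

## Decapitation time resolved against the curve. T may exceed the last
## arterial sample by at most one sampling interval (the final sample is
## drawn immediately before decapitation); beyond that the curve does not
## cover the experiment.
resolve_decap_time <- function(params, curve) {
  tmax <- max(curve$times)
  t_end <- params$decap_time_s %||% tmax
  n <- length(curve$times)
  last_interval <- if (n >= 2) curve$times[n] - curve$times[n - 1L] else tmax
  if (t_end > tmax + last_interval)
    iap_validation_error(sprintf(
      "decapitation time %g s is more than one sampling interval beyond the last arterial sample (%g s): the arterial curve does not cover the experiment",
      t_end, tmax))
  t_end
}

## Nodes of the piecewise-linear input restricted to [0, t_end]; the curve is
## held at its last value if t_end slightly exceeds the last sample.
curve_nodes <- function(curve, t_end) {
  tt <- curve$times
  cc <- curve$conc
  if (t_end > tt[length(tt)]) {
    tt <- c(tt, t_end)
    cc <- c(cc, cc[length(cc)])
  } else if (t_end < tt[length(tt)]) {
    keep <- tt < t_end
    c_end <- stats::approx(tt, cc, xout = t_end)$y
    tt <- c(tt[keep], t_end)
    cc <- c(cc[keep], c_end)
  }
  list(times = tt, conc = cc)
}

## Exact integral lambda * K * int_0^T C_A(t) exp(-K(T-t)) dt for the
## piecewise-linear interpolant of C_A. With s = t - T <= 0 the segment
## antiderivative is exp(K s) ((c1 + b (s - s1))/K - b/K^2), numerically
## stable for large K because exp(K s) <= 1 on s <= 0.
forward_on_nodes <- function(K, nodes, lambda) {
  if (K <= 0) return(0)
  t_end <- nodes$times[length(nodes$times)]
  s <- nodes$times - t_end
  cc <- nodes$conc
  n <- length(s)
  s1 <- s[-n]; s2 <- s[-1L]
  c1 <- cc[-n]; c2 <- cc[-1L]
  b <- (c2 - c1) / (s2 - s1)
  antideriv <- function(sv, cref, sref) exp(K * sv) * ((cref + b * (sv - sref)) / K - b / K^2)
  integral <- sum(antideriv(s2, c1, s1) - antideriv(s1, c1, s1))
  max(0, lambda * K * integral)
}

## Vectorized over a set of K values (segments x K outer products); used by
## the inversion's bracket scan.
forward_on_nodes_vec <- function(Ks, nodes, lambda) {
  t_end <- nodes$times[length(nodes$times)]
  s <- nodes$times - t_end
  cc <- nodes$conc
  n <- length(s)
  s1 <- s[-n]; s2 <- s[-1L]
  c1 <- cc[-n]; c2 <- cc[-1L]
  b <- (c2 - c1) / (s2 - s1)
  vals <- vapply(Ks, function(K) {
    antideriv <- function(sv) exp(K * sv) * ((c1 + b * (sv - s1)) / K - b / K^2)
    max(0, lambda * K * sum(antideriv(s2) - antideriv(s1)))
  }, numeric(1))
  vals
}

#' Forward tissue uptake model
#'
#' Tissue tracer concentration at decapitation predicted by the
#' tissue-equilibration model,
#' \deqn{C_i(T) = \lambda K \int_0^T C_A(t)\, e^{-K(T-t)}\, dt,\qquad
#'       K = m f / \lambda,}
#' with `f` the blood flow per unit tissue mass in ml g^-1 min^-1 (`K` is
#' converted to s^-1 internally; times are in seconds). The arterial curve is
#' integrated exactly as a piecewise-linear function. Blood (nCi/ml) and
#' tissue (nCi/g) concentrations are treated as numerically commensurate
#' (tissue density about 1 g/ml).
#'
#' @param f Blood flow per unit tissue mass, ml g^-1 min^-1, >= 0.
#' @param curve An [arterial_curve()].
#' @param params A [kinetic_params()] object.
#' @return Tissue concentration at time `T`, nCi per g. Bounded by
#'   `lambda * max(C_A)`.
#' @examples
#' curve <- arterial_curve(c(0, 60), c(100, 100))  # constant input
#' forward_tissue_concentration(0.8, curve, kinetic_params())
#' # 0.8 * 100 * (1 - exp(-1)) = 50.57 nCi/g
#' @seealso [invert_flow()] for the inverse problem.
#' @export
forward_tissue_concentration <- function(f, curve, params = kinetic_params()) {
  if (!inherits(curve, "arterial_curve"))
    iap_validation_error("curve must be an arterial_curve")
  if (!inherits(params, "kinetic_params"))
    iap_validation_error("params must be a kinetic_params object")
  if (!is.numeric(f) || length(f) != 1L || is.na(f))
    iap_validation_error("f must be a single number")
  if (f < 0)
    iap_validation_error("flow must be non-negative")
  t_end <- resolve_decap_time(params, curve)
  nodes <- curve_nodes(curve, t_end)
  K <- params$m * f / params$lambda / 60  # s^-1
  forward_on_nodes(K, nodes, params$lambda)
}

#' Invert the uptake model for blood flow
#'
#' Recovers the flow per unit tissue mass `f` whose forward prediction equals
#' the measured tissue concentration. Uptake rises strictly with `f`
#' throughout the physiological range; for arterial inputs that decline
#' toward the end of the experiment the forward value eventually passes a
#' maximum in `K` and relaxes to `lambda * C_A(T)` (instantaneous
#' equilibration), so the physical solution is the smallest root. It is
#' located by scanning a logarithmic grid in the rate constant `K` (s^-1)
#' for the first sign change, refined by Brent root-finding, and converted
#' via `f = K lambda / m * 60`.
#'
#' A tissue concentration above the supremum of the forward value over all
#' `K` cannot be produced by the model; it raises an error of class
#' `iap_saturation_error` naming that ceiling.
#'
#' @param Ci Measured tissue concentration at decapitation, nCi per g, >= 0.
#' @param curve An [arterial_curve()].
#' @param params A [kinetic_params()] object.
#' @param K_max Initial upper bracket for `K`, s^-1. Widened tenfold up to
#'   twice before saturation is declared.
#' @param tol Absolute root tolerance on `K`, s^-1.
#' @param details If `TRUE`, return a list with the flow plus solver
#'   diagnostics (`K_per_s`, `iterations`, `residual`).
#' @return Flow in ml g^-1 min^-1 (or a diagnostics list).
#' @examples
#' curve <- arterial_curve(c(0, 60), c(100, 100))
#' invert_flow(50.57, curve, kinetic_params())  # about 0.8 ml/g/min
#' @export
invert_flow <- function(Ci, curve, params = kinetic_params(),
                        K_max = 10, tol = 1e-10, details = FALSE) {
  if (!is.numeric(Ci) || length(Ci) != 1L || is.na(Ci))
    iap_validation_error("Ci must be a single number")
  if (Ci < 0)
    iap_validation_error("tissue concentration must be non-negative")
  if (!inherits(curve, "arterial_curve"))
    iap_validation_error("curve must be an arterial_curve")
  t_end <- resolve_decap_time(params, curve)
  nodes <- curve_nodes(curve, t_end)

  if (Ci == 0) {
    out <- list(flow = 0, K_per_s = 0, iterations = 0L, residual = 0)
    return(if (details) out else out$flow)
  }
  if (all(nodes$conc == 0))
    iap_stop("non-identifiable: the arterial curve is identically zero but the tissue concentration is positive",
             "iap_saturation_error")

  objective <- function(K) forward_on_nodes(K, nodes, params$lambda) - Ci

  ## Scan a log grid for the first upward crossing (smallest root), widening
  ## the upper end tenfold up to twice before declaring saturation.
  bracket <- NULL
  hi <- K_max
  for (widening in 0:2) {
    grid <- exp(seq(log(1e-8), log(hi * 10^widening), length.out = 80L))
    vals <- forward_on_nodes_vec(grid, nodes, params$lambda) - Ci
    cross <- which(vals >= 0)[1]
    if (!is.na(cross)) {
      bracket <- c(if (cross == 1L) 0 else grid[cross - 1L], grid[cross])
      break
    }
  }
  if (is.null(bracket)) {
    opt <- stats::optimize(function(K) forward_on_nodes(K, nodes, params$lambda),
                           interval = c(1e-8, hi * 100), maximum = TRUE)
    iap_stop(sprintf(
      "non-identifiable: tissue concentration %.6g nCi/g exceeds the model's ceiling (supremum over K of the forward value) %.6g nCi/g (saturation)",
      Ci, opt$objective), "iap_saturation_error")
  }
  root <- stats::uniroot(objective, lower = bracket[1], upper = bracket[2],
                         tol = tol)
  flow <- root$root * params$lambda / params$m * 60
  out <- list(flow = flow, K_per_s = root$root,
              iterations = root$iter, residual = objective(root$root))
  if (details) out else out$flow
}

#' Equilibrium tissue:blood concentration ratio
#'
#' For a constant arterial input the tissue:blood ratio
#' \eqn{C_i(T)/C_A = \lambda (1 - e^{-KT})} approaches the partition
#' coefficient \eqn{\lambda} as \eqn{K T \to \infty}. This limiting ratio is
#' \eqn{\lambda} itself, independent of `m` and `T`.
#'
#' @param params A [kinetic_params()] object.
#' @return The partition coefficient, dimensionless.
#' @examples
#' equilibrium_tissue_blood_ratio(kinetic_params())  # 0.80
#' @export
equilibrium_tissue_blood_ratio <- function(params = kinetic_params()) {
  if (!inherits(params, "kinetic_params"))
    iap_validation_error("params must be a kinetic_params object")
  params$lambda
}
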