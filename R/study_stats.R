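## Group statistics as reported in the modeled study: mean +/- SEM
## summaries, one-way and 2x2 two-way ANOVA, Tukey HSD post hoc over cell
## means (studentized-range distribution), percent differences, and
## phospho/total Western-blot normalization.

#' Per-group mean and standard error
#'
#' @param x Numeric values.
#' @param g Group labels (coerced to factor). Every level must be observed.
#' @param units Optional unit string attached as an attribute.
#' @return Data frame with columns `group`, `n`, `mean`, `sem`
#'   (SEM = sample SD / sqrt(n); `NA` with a warning for n = 1).
#' @examples
#' summarize_groups(c(1, 2, 3, 4, 2, 4, 6, 8), rep(c("a", "b"), each = 4))
#' @export
summarize_groups <- function(x, g, units = NULL) {
  if (!is.numeric(x) || anyNA(x))
    iap_validation_error("x must be numeric without missing values")
  g <- as.factor(g)
  if (length(g) != length(x))
    iap_validation_error("x and g must have the same length")
  counts <- table(g)
  if (any(counts == 0))
    iap_validation_error(sprintf("empty group: %s",
                                 paste(names(counts)[counts == 0], collapse = ", ")))
  if (any(counts == 1))
    warning("groups with a single observation have undefined SEM")
  means <- tapply(x, g, mean)
  sems <- tapply(x, g, function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)
  out <- data.frame(group = names(counts), n = as.integer(counts),
                    mean = as.numeric(means), sem = as.numeric(sems),
                    row.names = NULL)
  if (!is.null(units)) attr(out, "units") <- units
  out
}

## Synthetic noiseless fixtures routinely produce exact fits; the inference
## is post-processed explicitly for that case, so R's generic warning about
## perfect fits is muffled.
muffle_perfect_fit <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

## Tukey HSD over k cell means sharing one error term. Tukey-Kramer standard
## error sqrt(MSE/2 (1/ni + 1/nj)); adjusted p from the studentized-range
## distribution. Unadjusted p (pooled-variance t test) is kept so the
## adjustment's coherence can be audited.
tukey_cell_means <- function(means, ns, mse, df_error, alpha = 0.05) {
  k <- length(means)
  labs <- names(means)
  cmb <- utils::combn(k, 2)
  a <- cmb[1, ]; b <- cmb[2, ]
  diff <- means[b] - means[a]
  se_tukey <- sqrt(mse / 2 * (1 / ns[a] + 1 / ns[b]))
  se_t <- sqrt(mse * (1 / ns[a] + 1 / ns[b]))
  q <- ifelse(se_tukey > 0, abs(diff) / se_tukey, ifelse(diff == 0, 0, Inf))
  p_adj <- stats::ptukey(q, nmeans = k, df = df_error, lower.tail = FALSE)
  p_unadj <- ifelse(se_t > 0,
                    2 * stats::pt(abs(diff) / se_t, df = df_error, lower.tail = FALSE),
                    ifelse(diff == 0, 1, 0))
  data.frame(pair = paste(labs[b], labs[a], sep = " - "),
             diff = as.numeric(diff),
             se = as.numeric(se_tukey),
             q = as.numeric(q),
             p_adj = pmin(pmax(as.numeric(p_adj), 0), 1),
             p_unadj = pmin(pmax(as.numeric(p_unadj), 0), 1),
             significant = as.numeric(p_adj) < alpha,
             row.names = NULL)
}

group_comparison <- function(effects, tukey, summaries, alpha,
                             cell_means = NULL, note = NULL) {
  structure(list(effects = effects, tukey = tukey, summaries = summaries,
                 alpha = alpha, cell_means = cell_means, note = note),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("ANOVA effects:\n")
  print(x$effects, row.names = FALSE)
  if (!is.null(x$tukey)) {
    cat(sprintf("\nTukey HSD (alpha = %g):\n", x$alpha))
    print(x$tukey, row.names = FALSE)
  }
  if (!is.null(x$note)) cat("\nNote:", x$note, "\n")
  invisible(x)
}

#' One-way analysis of variance with Tukey post hoc
#'
#' Classical between/within decomposition across k groups (used in the
#' modeled study for hemodynamic and blood-gas parameters), followed by
#' Tukey HSD over the group means.
#'
#' @param x Numeric values.
#' @param g Group labels; at least two groups with n >= 2 each.
#' @param alpha Significance level (default 0.05).
#' @return A `group_comparison` object: `effects` (term, df, F, p),
#'   `tukey` pairwise table, `summaries` (mean +/- SEM), `alpha`.
#' @examples
#' one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))$effects
#' @export
one_way_anova <- function(x, g, alpha = 0.05) {
  g <- as.factor(g)
  counts <- table(g)
  if (length(counts) < 2)
    iap_validation_error("at least two groups are required")
  if (any(counts < 2))
    iap_validation_error("every group needs at least 2 observations")
  fit <- stats::lm(x ~ g)
  av <- muffle_perfect_fit(stats::anova(fit))
  ms_within <- av$`Mean Sq`[2]
  ms_between <- av$`Mean Sq`[1]
  degenerate <- ms_within <= .Machine$double.eps * max(ms_between, 1)
  if (degenerate && ms_between > 0) {
    warning("zero within-group variance with unequal means; F is unbounded and p is reported as 0")
    Fv <- Inf; pv <- 0
  } else {
    Fv <- av$`F value`[1]; pv <- av$`Pr(>F)`[1]
  }
  effects <- data.frame(term = "group", df1 = av$Df[1], df2 = av$Df[2],
                        F = Fv, p = pv, row.names = NULL)
  means <- tapply(x, g, mean)
  tk <- tukey_cell_means(means, as.integer(counts),
                         mse = if (degenerate) 0 else ms_within,
                         df_error = av$Df[2], alpha = alpha)
  group_comparison(effects, tk, summarize_groups(x, g), alpha,
                   cell_means = means)
}

#' 2x2 two-way ANOVA with Tukey HSD over cell means
#'
#' The study's primary flow analysis: per region, a strain x treatment ANOVA
#' (main effects and interaction) followed by Tukey HSD over the four cell
#' means using the studentized-range distribution, which provides the two
#' comparisons of interest (mutant-vehicle vs control-vehicle and
#' mutant-inhibitor vs mutant-vehicle). Balanced layouts use the classical
#' sequential decomposition (identical to type II/III under balance);
#' unbalanced layouts fall back to type-II sums of squares with a message.
#'
#' @param x Numeric response values.
#' @param strain,treatment Factor labels, two levels each, all four cells
#'   present with n >= 2.
#' @param alpha Significance level.
#' @return A `group_comparison` object. Cell labels in the Tukey table are
#'   `strain:treatment`.
#' @examples
#' set.seed(1)
#' d <- expand.grid(strain = c("control", "mutant"),
#'                  treatment = c("vehicle", "inhibitor"))[rep(1:4, each = 4), ]
#' x <- rnorm(16, mean = ifelse(d$strain == "mutant" & d$treatment == "vehicle", 1.3, 1))
#' two_way_anova_tukey(x, d$strain, d$treatment)
#' @export
two_way_anova_tukey <- function(x, strain, treatment, alpha = 0.05) {
  strain <- droplevels(as.factor(strain))
  treatment <- droplevels(as.factor(treatment))
  if (nlevels(strain) != 2 || nlevels(treatment) != 2)
    iap_validation_error("strain and treatment must each have exactly two levels")
  cells <- table(strain, treatment)
  if (any(cells == 0))
    iap_validation_error("missing strain x treatment cell: the 2x2 layout must be complete")
  if (any(cells < 2))
    iap_validation_error("every strain x treatment cell needs at least 2 observations")

  balanced <- length(unique(as.vector(cells))) == 1
  fit <- stats::lm(x ~ strain * treatment)
  note <- NULL
  if (balanced) {
    av <- muffle_perfect_fit(stats::anova(fit))
    effects <- data.frame(term = c("strain", "treatment", "strain:treatment"),
                          df1 = av$Df[1:3], df2 = av$Df[4],
                          ss = av$`Sum Sq`[1:3],
                          F = av$`F value`[1:3], p = av$`Pr(>F)`[1:3],
                          row.names = NULL)
  } else {
    note <- "unbalanced design: type-II sums of squares"
    message(note)
    av <- muffle_perfect_fit(car::Anova(fit, type = 2))
    idx <- match(c("strain", "treatment", "strain:treatment"), rownames(av))
    effects <- data.frame(term = c("strain", "treatment", "strain:treatment"),
                          df1 = av$Df[idx], df2 = av$Df[rownames(av) == "Residuals"],
                          ss = av$`Sum Sq`[idx],
                          F = av$`F value`[idx], p = av$`Pr(>F)`[idx],
                          row.names = NULL)
  }
  cell <- interaction(strain, treatment, sep = ":", lex.order = TRUE)
  means <- tapply(x, cell, mean)
  ns <- as.integer(table(cell))
  df_err <- fit$df.residual
  sse <- sum(stats::residuals(fit)^2)
  mse <- sse / df_err
  if (sse == 0) {
    # exact fit: F is unbounded for any effect with non-zero sum of squares
    # and undefined (no evidence either way) when the effect is zero too
    if (any(effects$ss > 0))
      warning("zero residual variance with unequal cell means; affected F statistics are unbounded and p is reported as 0")
    effects$F <- ifelse(effects$ss > 0, Inf, NaN)
    effects$p <- ifelse(effects$ss > 0, 0, NA_real_)
  }
  effects$ss <- NULL
  tk <- tukey_cell_means(means, ns, mse, df_err, alpha = alpha)
  group_comparison(effects, tk, summarize_groups(x, cell), alpha,
                   cell_means = means, note = note)
}

#' Percent difference relative to a reference mean
#'
#' `100 * (comparison - reference) / reference`, the scale on which the
#' study reports group contrasts (e.g. a 32% cortical elevation).
#'
#' @param reference Reference group mean, > 0.
#' @param comparison Comparison group mean.
#' @return Percent difference (vectorized).
#' @examples
#' percent_difference(100, 132)  # 32
#' @export
percent_difference <- function(reference, comparison) {
  if (!is.numeric(reference) || !is.numeric(comparison))
    iap_validation_error("reference and comparison must be numeric")
  if (any(reference <= 0))
    iap_validation_error("reference mean must be positive")
  100 * (comparison - reference) / reference
}

#' Normalize Western-blot phosphorylation signals and test group effects
#'
#' Computes the per-animal phospho/total ratio for every marker and runs the
#' 2x2 strain x treatment ANOVA with Tukey HSD on the ratios, marker by
#' marker (the normalization and test reported for the immunoblot data).
#'
#' @param blots Data frame with columns `animal_id`, `strain`, `treatment`,
#'   `marker`, `phospho`, `total` (as produced by [simulate_blots()]).
#' @param alpha Significance level.
#' @return A list with `ratios` (the input plus a `ratio` column) and
#'   `tests`, a named list of `group_comparison` objects (one per marker).
#' @examples
#' blots <- simulate_blots(seed = 1)
#' res <- blot_normalize_and_test(blots)
#' res$tests[[1]]$effects
#' @export
blot_normalize_and_test <- function(blots, alpha = 0.05) {
  needed <- c("strain", "treatment", "marker", "phospho", "total")
  if (!is.data.frame(blots) || !all(needed %in% names(blots)))
    iap_validation_error(sprintf("blots must be a data frame with columns %s",
                                 paste(needed, collapse = ", ")))
  if (any(blots$total <= 0))
    iap_validation_error("total-protein signals must be positive")
  if (any(blots$phospho < 0))
    iap_validation_error("phospho signals must be non-negative")
  blots$ratio <- blots$phospho / blots$total
  tests <- lapply(split(blots, blots$marker), function(d)
    two_way_anova_tukey(d$ratio, d$strain, d$treatment, alpha = alpha))
  list(ratios = blots, tests = tests)
}
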