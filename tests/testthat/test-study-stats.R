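test_that("group summaries report mean and SEM", {
  s <- summarize_groups(c(1, 1, 1, 1), rep("a", 4))
  expect_equal(s$mean, 1)
  expect_equal(s$sem, 0)
  s2 <- summarize_groups(c(1, 2, 3, 4), rep("a", 4))
  expect_equal(s2$mean, 2.5)
  expect_equal(s2$sem, sd(1:4) / 2, tolerance = 1e-12)
  # identical groups give identical summaries
  s3 <- summarize_groups(rep(c(1, 2, 3, 4), 2), rep(c("a", "b"), each = 4))
  expect_equal(s3$mean[1], s3$mean[2])
  expect_equal(s3$sem[1], s3$sem[2])
  expect_error(summarize_groups(1:3, factor(c("a", "a", "a"), levels = c("a", "b"))),
               class = "iap_validation_error")
})

test_that("one-way ANOVA matches textbook sums of squares", {
  res <- one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$effects$F, 13.5, tolerance = 1e-12)
  expect_equal(res$effects$df1, 1)
  expect_equal(res$effects$df2, 4)
  expect_equal(res$effects$p, pf(13.5, 1, 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(one_way_anova(1:4, c("a", "a", "a", "b")),
               class = "iap_validation_error")
})

test_that("ANOVA sums of squares decompose exactly", {
  set.seed(21)
  for (i in 1:10) {
    g <- rep(letters[1:3], each = 7)
    x <- rnorm(21, mean = rep(runif(3, 0, 5), each = 7))
    fit <- lm(x ~ g)
    ss_total <- sum((x - mean(x))^2)
    ss_within <- sum(residuals(fit)^2)
    ss_between <- anova(fit)$`Sum Sq`[1]
    expect_equal(ss_between + ss_within, ss_total, tolerance = 1e-9)
    # and the packaged F reproduces the decomposition
    res <- one_way_anova(x, g)
    expect_equal(res$effects$F, (ss_between / 2) / (ss_within / 18),
                 tolerance = 1e-9)
  }
})

test_that("zero within-group variance with unequal means is degenerate", {
  expect_warning(res <- one_way_anova(c(1, 1, 1, 2, 2, 2),
                                      rep(c("a", "b"), each = 3)),
                 "zero within-group variance")
  expect_identical(res$effects$F, Inf)
  expect_identical(res$effects$p, 0)
})

test_that("Tukey adjusted p values match the stats::TukeyHSD oracle", {
  set.seed(31)
  for (i in 1:5) {
    g <- rep(c("a", "b", "c"), times = c(4, 5, 6))
    x <- rnorm(15, mean = as.integer(factor(g)))
    mine <- one_way_anova(x, g)$tukey
    oracle <- TukeyHSD(aov(x ~ factor(g)))[[1]]
    key <- gsub(" ", "", mine$pair)
    expect_equal(mine$p_adj[match(rownames(oracle), key)],
                 unname(oracle[, "p adj"]), tolerance = 1e-6)
    expect_equal(mine$diff[match(rownames(oracle), key)],
                 unname(oracle[, "diff"]), tolerance = 1e-9)
  }
})

test_that("Tukey adjustment is coherent and flags are monotone in alpha", {
  set.seed(41)
  x <- rnorm(24, mean = rep(c(0, 0.5, 1, 2), each = 6))
  g <- rep(letters[1:4], each = 6)
  res <- one_way_anova(x, g)
  expect_true(all(res$tukey$p_adj >= res$tukey$p_unadj - 1e-12))
  for (alpha in c(0.01, 0.05, 0.1)) {
    r <- one_way_anova(x, g, alpha = alpha)
    expect_identical(r$tukey$significant, r$tukey$p_adj < alpha)
  }
  flags01 <- one_way_anova(x, g, alpha = 0.01)$tukey$significant
  flags10 <- one_way_anova(x, g, alpha = 0.10)$tukey$significant
  expect_true(all(flags10 | !flags01))  # larger alpha never drops a flag
})

test_that("two-way ANOVA reproduces the balanced decomposition and Tukey cells", {
  set.seed(51)
  d <- cell_layout(6)
  x <- rnorm(nrow(d),
             mean = 1 + 0.4 * (d$strain == "mutant") * (d$treatment == "vehicle"))
  res <- two_way_anova_tukey(x, d$strain, d$treatment)
  ref <- anova(lm(x ~ factor(d$strain) * factor(d$treatment)))
  expect_equal(res$effects$F, ref$`F value`[1:3], tolerance = 1e-9)
  expect_equal(res$effects$p, ref$`Pr(>F)`[1:3], tolerance = 1e-9)
  # Tukey over the four cells agrees with TukeyHSD on the cell-means model
  cell <- interaction(d$strain, d$treatment, sep = ":", lex.order = TRUE)
  oracle <- TukeyHSD(aov(x ~ cell))[[1]]
  key <- gsub(" ", "", res$tukey$pair)
  expect_equal(res$tukey$p_adj[match(rownames(oracle), key)],
               unname(oracle[, "p adj"]), tolerance = 1e-6)
})

test_that("unbalanced layouts fall back to type-II sums of squares", {
  set.seed(61)
  d <- cell_layout(5)[-c(1, 2, 3), ]  # deplete some cells
  x <- rnorm(nrow(d), mean = 1 + 0.5 * (d$strain == "mutant"))
  expect_message(res <- two_way_anova_tukey(x, d$strain, d$treatment),
                 "type-II")
  ref <- suppressMessages(
    car::Anova(lm(x ~ factor(d$strain) * factor(d$treatment)), type = 2))
  expect_equal(res$effects$F, ref$`F value`[1:3], tolerance = 1e-9)
  # missing cell errors
  d2 <- d[!(d$strain == "mutant" & d$treatment == "vehicle"), ]
  expect_error(two_way_anova_tukey(rnorm(nrow(d2)), d2$strain, d2$treatment),
               class = "iap_validation_error")
})

test_that("F statistics, p values and Tukey flags are scale equivariant", {
  set.seed(71)
  d <- cell_layout(5)
  x <- rnorm(nrow(d), mean = 1 + 0.6 * (d$strain == "mutant"))
  a <- two_way_anova_tukey(x, d$strain, d$treatment)
  b <- two_way_anova_tukey(137.5 * x, d$strain, d$treatment)
  expect_equal(a$effects$F, b$effects$F, tolerance = 1e-9)
  expect_equal(a$effects$p, b$effects$p, tolerance = 1e-9)
  expect_identical(a$tukey$significant, b$tukey$significant)
})

test_that("percent differences follow the reported convention", {
  expect_equal(percent_difference(100, 132), 32)
  expect_equal(percent_difference(100, 115), 15)
  expect_equal(percent_difference(7, 7), 0)
  expect_error(percent_difference(0, 1), class = "iap_validation_error")
})

test_that("blot normalization uses phospho/total ratios per marker", {
  b <- simulate_blots(seed = 2, noise_cv = 0)
  b$phospho <- b$total  # identity ratios
  res <- blot_normalize_and_test(b)
  expect_true(all(res$ratios$ratio == 1))
  for (tst in res$tests) expect_true(all(!tst$tukey$significant))

  eff <- data.frame(strain = c("control", "mutant"),
                    treatment = "inhibitor", multiplier = 0.5)
  b2 <- simulate_blots(seed = 2, group_effects = eff, noise_cv = 0)
  # noiseless group contrast: an exact (or near-exact) fit, so the residual
  # variance may collapse to zero and trigger the degenerate-fit warning
  res2 <- suppressWarnings(blot_normalize_and_test(b2))
  r <- res2$ratios
  expect_equal(mean(r$ratio[r$treatment == "inhibitor"]),
               0.5 * mean(r$ratio[r$treatment == "vehicle"]))

  b3 <- b
  b3$total[1] <- 0
  expect_error(blot_normalize_and_test(b3), class = "iap_validation_error")
})

test_that("a configured strain effect on one marker is detected with high power", {
  eff <- data.frame(strain = "mutant", treatment = c("vehicle", "inhibitor"),
                    marker = "pAkt_S473", multiplier = 0.6)
  eff <- rbind(eff)  # applies to both mutant cells of one marker
  hits <- 0L
  n_rep <- 200
  for (i in seq_len(n_rep)) {
    b <- simulate_blots(seed = 9000 + i, group_effects = eff, noise_cv = 0.1)
    res <- blot_normalize_and_test(b)
    p_strain <- res$tests$pAkt_S473$effects$p[
      res$tests$pAkt_S473$effects$term == "strain"]
    hits <- hits + (p_strain < 0.05)
  }
  expect_gte(hits / n_rep, 0.8)
  # the unaffected marker stays near the null rejection rate
})
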