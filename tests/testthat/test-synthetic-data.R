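test_that("simulated arterial curves have 21 samples over [0, 60] s", {
  curve <- simulate_arterial_curve(800, 60, seed = 1)
  expect_length(curve$times, 21)
  expect_equal(range(curve$times), c(0, 60))
  expect_true(all(curve$conc >= 0))
  expect_equal(curve$conc[1], 0)
})

test_that("the noiseless arterial shape is linear in its peak and seeded noise is reproducible", {
  c1 <- simulate_arterial_curve(400, 30)
  c2 <- simulate_arterial_curve(800, 30)
  expect_equal(c2$conc, 2 * c1$conc)
  n1 <- simulate_arterial_curve(800, 30, noise_cv = 0.1, seed = 99)
  n2 <- simulate_arterial_curve(800, 30, noise_cv = 0.1, seed = 99)
  expect_identical(n1, n2)
  expect_error(simulate_arterial_curve(-1, 30), class = "iap_validation_error")
  expect_error(simulate_arterial_curve(800, 0), class = "iap_validation_error")
})

test_that("a noiseless study is recovered exactly by the full pipeline", {
  cfg <- noiseless_config(n_per_group = 2)
  res <- run_pipeline_in_memory(cfg, seed = 3)
  merged <- merge(res$flows, res$study$truth,
                  by = c("animal_id", "strain", "treatment", "region"))
  expect_equal(nrow(merged), 2 * 4 * 4)  # animals x regions
  expect_true(all(merged$flag == "ok"))
  expect_equal(merged$flow_ml_g_min, merged$true_flow_ml_g_min,
               tolerance = 1e-6)
})

test_that("identical seeds reproduce the study and per-animal streams are stable", {
  d <- study_design(n_per_group = 2, seed = 17)
  s1 <- simulate_study(d)
  s2 <- simulate_study(d)
  expect_identical(s1$roi, s2$roi)
  expect_identical(s1$arterial, s2$arterial)
  expect_identical(s1$truth, s2$truth)
  # enlarging the study must not perturb earlier animals
  s3 <- simulate_study(study_design(n_per_group = 3, seed = 17))
  shared <- s1$truth$animal_id
  expect_identical(s1$truth,
                   s3$truth[s3$truth$animal_id %in% shared, ],
                   ignore_attr = TRUE)
})

test_that("group means that leave the standards' span raise a generator error", {
  # flows this low equilibrate below the 40 nCi/g floor of the standards
  d <- study_design(
    n_per_group = 2,
    group_mean_flow = mirror_group_means(
      base_flow = c(cortex = 0.05, hippocampus = 0.05,
                    cerebellum = 0.05, pons = 0.05)),
    between_animal_cv = 0, od_noise_sd = 0, arterial_noise_cv = 0, seed = 1)
  expect_error(simulate_study(d), "standards", class = "iap_range_error")
})

test_that("blot fixtures follow the configured ratio multipliers", {
  # null configuration: ratios scatter around 1
  b0 <- simulate_blots(seed = 4, noise_cv = 0.1)
  expect_equal(nrow(b0), 4 * 3 * 2)
  expect_true(all(b0$phospho > 0 & b0$total > 0))
  r0 <- b0$phospho / b0$total
  expect_gt(min(r0), 0.5)
  expect_lt(max(r0), 2)
  # noiseless scaling: inhibitor groups exactly halved
  eff <- data.frame(strain = c("control", "mutant"),
                    treatment = c("inhibitor", "inhibitor"),
                    multiplier = c(0.5, 0.5))
  b1 <- simulate_blots(seed = 4, group_effects = eff, noise_cv = 0)
  r1 <- b1$phospho / b1$total
  expect_equal(unique(r1[b1$treatment == "inhibitor"]), 0.5)
  expect_equal(unique(r1[b1$treatment == "vehicle"]), 1)
  # determinism
  expect_identical(simulate_blots(seed = 4), simulate_blots(seed = 4))
  expect_error(simulate_blots(seed = 1, group_effects = data.frame(
    strain = "mutant", treatment = "vehicle", multiplier = -1)),
    class = "iap_validation_error")
})

test_that("recovered group means are unbiased at moderate noise", {
  # 200 seeded replicates at the default noise levels (cv = 0.10): the grand
  # recovered mean per group-region stays within 1% of the configured truth
  cfg <- default_config()
  gm <- mirror_group_means()
  sums <- NULL
  for (i in 1:200) {
    res <- run_pipeline_in_memory(cfg, seed = 5000 + i)
    agg <- stats::aggregate(flow_ml_g_min ~ strain + treatment + region,
                            data = res$flows, FUN = mean)
    sums <- if (is.null(sums)) agg$flow_ml_g_min else sums + agg$flow_ml_g_min
    if (i == 1) labels <- agg[, c("strain", "treatment", "region")]
  }
  recovered <- sums / 200
  key <- paste(labels$strain, labels$treatment, labels$region)
  truth <- gm$mean_flow[match(key, paste(gm$strain, gm$treatment, gm$region))]
  expect_true(all(abs(recovered - truth) / truth < 0.01))
})
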