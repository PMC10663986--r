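test_that("null cohorts have chance-level oracle concordance", {
  # with every pathway effect zero and no risk noise the hazard is flat, so
  # the recorded risk carries no information about the event times
  pm <- toy_pm()
  co <- simulate_cohort(simulation_config(
    n = 2000, pm = pm, active_pathways = 1:2, pathway_effects = c(0, 0),
    noise_sd = 0, seed = 17))
  expect_lt(abs(oracle_cindex(co) - 0.5), 0.03)
  # scoring the same cohort with unrelated random risks is also at chance
  set.seed(1)
  expect_lt(abs(harrell_cindex(rnorm(2000), co$data$events,
                               co$data$durations) - 0.5), 0.03)
})

test_that("a single strong effect orders samples by its pathway score", {
  pm <- toy_pm()
  co <- simulate_cohort(simulation_config(
    n = 100, pm = pm, active_pathways = 2L, pathway_effects = 3,
    noise_sd = 0, seed = 8))
  expect_equal(order(co$true_risk), order(co$pathway_scores[, 2]))
})

test_that("cohorts are bit-identical given the seed and calibrated otherwise", {
  pm <- example_pathway_matrix()
  cfg <- simulation_config(n = 120, pm = pm, seed = 33)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$data$features, c2$data$features)
  expect_identical(c1$data$durations, c2$data$durations)
  # censoring fraction lands within 5 points of target over several seeds
  for (s in 1:5) {
    co <- simulate_cohort(simulation_config(n = 150, pm = pm, seed = 40 + s))
    expect_lt(abs(co$censoring_fraction - 0.3), 0.05)
  }
  # no censoring when the target is zero
  co0 <- simulate_cohort(simulation_config(n = 50, pm = pm,
                                           censoring_rate_target = 0,
                                           seed = 1))
  expect_true(all(co0$data$events == 1))
})

test_that("class imbalance defaults to the 78/22 aggressive/benign split", {
  pm <- example_pathway_matrix()
  co <- simulate_cohort(simulation_config(n = 384, pm = pm, seed = 12))
  expect_lt(abs(mean(co$data$malignancy) - 0.78), 0.03)
})

test_that("mean event time decreases as the baseline rate increases", {
  pm <- toy_pm()
  means <- vapply(c(1 / 2000, 1 / 730, 1 / 100), function(rate) {
    co <- simulate_cohort(simulation_config(
      n = 500, pm = pm, active_pathways = 1:2, pathway_effects = c(1, -1),
      baseline_rate = rate, censoring_rate_target = 0, seed = 77))
    mean(co$event_times)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("a simulated cohort round-trips through the text readers", {
  pm <- toy_pm()
  co <- simulate_cohort(simulation_config(n = 30, pm = pm,
                                          active_pathways = 1:2,
                                          pathway_effects = c(1, -1),
                                          seed = 5))
  dir <- tempfile()
  write_cohort(co, dir)
  back <- read_dataset(file.path(dir, "features.csv"),
                       file.path(dir, "labels.csv"))
  expect_identical(back$features, co$data$features)
  expect_identical(back$events, co$data$events)
  expect_identical(back$durations, co$data$durations)
  pm_back <- read_pathway_mapping(file.path(dir, "mapping.tsv"),
                                  co$data$metabolite_names)
  expect_equal(pm_back$matrix[, sort(pm$pathway_names)],
               pm$matrix[, sort(pm$pathway_names)])
})
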