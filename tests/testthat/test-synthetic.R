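test_that("designs validate their schedule and require a seed", {
  expect_error(experiment_design(n_generations = 5, light_schedule = c(12, 12), seed = 1),
               "one entry per generation transition")
  expect_error(experiment_design(light_schedule = 30, seed = 1), "hours in")
  expect_error(experiment_design(n_lines = 2), "seed")
})

test_that("datasets are reproducible from the design seed", {
  d <- experiment_design(n_lines = 2, n_generations = 6, seed = 31,
                         params = calibrated_params())
  a <- generate_experiment(d)
  b <- generate_experiment(d)
  for (tbl in c("offspring", "adults", "matings", "availability", "truth"))
    expect_identical(a[[tbl]], b[[tbl]])
  d2 <- experiment_design(n_lines = 2, n_generations = 6, seed = 32,
                          params = calibrated_params())
  expect_false(identical(a$offspring, generate_experiment(d2)$offspring))
})

test_that("scored offspring sum to the sample size and censuses to the census", {
  d <- experiment_design(n_lines = 3, n_generations = 8, seed = 77,
                         params = calibrated_params())
  ds <- generate_experiment(d)
  pheno <- c("males_red", "males_white", "females_red", "females_orange",
             "females_white")
  expect_true(all(rowSums(ds$offspring[, pheno]) == 300))
  males <- rowSums(ds$adults[, male_genotypes])
  females <- rowSums(ds$adults[, female_genotypes])
  # founding P1 census has 90 males; every rebuilt census holds exactly 100
  expect_true(all(males[ds$adults$generation > 1] == 100))
  expect_true(all(females[ds$adults$generation > 1] == 100))
})

test_that("drift-only designs keep the founding frequency in expectation", {
  d <- experiment_design(n_lines = 60, n_generations = 6,
                         founding = "P6", obs_per_generation = 0,
                         params = neutral_params(), seed = 12)
  ds <- generate_experiment(d)
  fin <- ds$truth$saa_x_freq[ds$truth$generation == 6]
  q0 <- ds$truth$saa_x_freq[ds$truth$generation == 1][1]
  se <- sd(fin) / sqrt(length(fin))
  expect_lt(abs(mean(fin) - q0), 3 * se)
})

test_that("dark schedules never emit photophase mating observations", {
  d <- experiment_design(n_lines = 2, n_generations = 5, light_schedule = 0,
                         obs_per_generation = 6, seed = 4,
                         params = calibrated_params())
  expect_equal(nrow(generate_experiment(d)$matings), 0L)
})

test_that("spot-check aggregation recovers the true photophase weight", {
  # ~1050 observations per dataset; median estimate within 10% of truth
  w_true <- 3
  p <- model_params(mating = mating_params(w_photo = w_true))
  est <- sapply(1:25, function(i) {
    d <- experiment_design(n_lines = 5, n_generations = 16, founding = "P6",
                           obs_per_generation = 14, params = p, seed = 600 + i)
    ds <- generate_experiment(d)
    mating_opportunity_summary(ds$matings, ds$availability)$weight_estimate
  })
  expect_lt(abs(median(est) - w_true) / w_true, 0.10)
})

test_that("phenotype scoring inverts exactly and flags impossible males", {
  expect_equal(genotype_counts_from_phenotypes(
    c(males_red = 10, males_white = 90)),
    c(M_SAA = 10L, M_CTRL = 90L, F_SAA_SAA = 0L, F_SAA_CTRL = 0L,
      F_CTRL_CTRL = 0L))
  expect_equal(genotype_counts_from_phenotypes(
    c(females_red = 5, females_orange = 20, females_white = 75)),
    c(M_SAA = 0L, M_CTRL = 0L, F_SAA_SAA = 5L, F_SAA_CTRL = 20L,
      F_CTRL_CTRL = 75L))
  expect_error(genotype_counts_from_phenotypes(c(males_orange = 1)),
               "orange males")
  expect_error(genotype_counts_from_phenotypes(c(males_blue = 1)),
               "unknown phenotype")
})
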