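test_that("neutral parameters conserve the allele frequency exactly", {
  p <- neutral_params()
  st <- hw_state(0.3)
  q0 <- x_allele_frequency(st)
  for (i in 1:1000) st <- deterministic_step(st, p)
  expect_equal(x_allele_frequency(st), q0, tolerance = 1e-14)
  expect_equal(st$generation, 1001L)

  traj <- run_deterministic(p, hw_state(0.1), 100)
  expect_equal(nrow(traj), 100L)
  expect_true(all(abs(traj$saa_x_freq - traj$saa_x_freq[1]) < 1e-12))
  expect_true(attr(traj, "converged"))
})

test_that("fixation and loss are absorbing", {
  p <- calibrated_params()
  fixed <- population_state(c(1, 0), c(1, 0, 0))
  expect_equal(x_allele_frequency(deterministic_step(fixed, p)), 1)
  lost <- population_state(c(0, 1), c(0, 0, 1))
  expect_equal(x_allele_frequency(deterministic_step(lost, p)), 0)
})

test_that("without a male advantage the female costs drive the allele down", {
  p <- model_params(mating = mating_params(w_photo = 1))
  traj <- run_deterministic(p, hw_state(0.03), 50)
  expect_true(all(diff(traj$saa_x_freq) < 0))
})

test_that("a fully recessive cost with male advantage protects the polymorphism", {
  # increases when rare AND decreases when common: single-step sign checks
  p <- model_params(mating = mating_params(w_photo = 1.5, light_hours = 24),
                    female_fecundity = c(0.388, 1, 1))
  q_lo <- x_allele_frequency(hw_state(0.01))
  expect_gt(x_allele_frequency(deterministic_step(hw_state(0.01), p)), q_lo)
  q_hi <- x_allele_frequency(hw_state(0.9))
  expect_lt(x_allele_frequency(deterministic_step(hw_state(0.9), p)), q_hi)
})

test_that("the equilibrium frequency is non-decreasing in the photophase weight", {
  eq <- sapply(c(1.5, 2, 3, 5), function(w) {
    p <- model_params(mating = mating_params(w_photo = w))
    find_equilibrium(p, hw_state(0.03))$equilibrium
  })
  expect_true(all(diff(eq) >= 0))
})

test_that("permanent dark drives the allele extinct from any start", {
  p <- calibrated_params()
  p$mating$light_hours <- 0
  for (q0 in c(0.03, 0.48)) {
    traj <- run_deterministic(p, hw_state(q0), 500)
    expect_lt(traj$saa_x_freq[nrow(traj)], 1e-4)
    expect_true(attr(traj, "extinct"))
  }
})

test_that("the same interior equilibrium is reached from both boundaries", {
  p <- calibrated_params()
  eq_rare <- find_equilibrium(p, hw_state(0.03))$equilibrium
  eq_common <- find_equilibrium(p, founding_composition("P8"))$equilibrium
  expect_lt(abs(eq_rare - eq_common), 1e-3)
  expect_gt(eq_rare, 0.05)
  expect_lt(eq_rare, 0.20)
})

test_that("stochastic sampling is unbiased for the deterministic pool", {
  p <- calibrated_params()
  st <- state_from_counts(founding_composition("P6"))
  det <- deterministic_step(st, p)
  # class proportions over repeated draws match the expectation within 3 SE
  set.seed(7)
  draws <- replicate(2000, attr(stochastic_step(st, p), "sampled_counts"))
  prop <- rowMeans(draws) / p$sample_size
  expected <- c(det$male, det$female) / 2  # each sex is half the pool
  se <- sqrt(expected * (1 - expected) / (2000 * p$sample_size))
  expect_true(all(abs(prop - expected) <= 3 * se + 1e-12))
})

test_that("huge sample sizes collapse the stochastic step onto the deterministic one", {
  p <- calibrated_params(sample_size = 1e6)
  st <- state_from_counts(founding_composition("P6"))
  det <- deterministic_step(st, p)
  set.seed(11)
  sto <- stochastic_step(st, p)
  expect_equal(sto$male, det$male, tolerance = 1e-2)
  expect_equal(sto$female, det$female, tolerance = 1e-2)
})

test_that("a fixed seed reproduces stochastic trajectories exactly", {
  p <- calibrated_params()
  st <- hw_state(0.1)
  set.seed(99); a <- replicate(5, x_allele_frequency(stochastic_step(st, p)))
  set.seed(99); b <- replicate(5, x_allele_frequency(stochastic_step(st, p)))
  expect_identical(a, b)

  e1 <- run_ensemble(p, st, 10, seed = 5, n_runs = 10)
  e2 <- run_ensemble(p, st, 10, seed = 5, n_runs = 10)
  expect_identical(e1$freqs, e2$freqs)
  e3 <- run_ensemble(p, st, 10, seed = 6, n_runs = 10)
  expect_false(identical(e1$freqs, e3$freqs))
})

test_that("ensemble summaries bracket their own runs", {
  p <- calibrated_params()
  ens <- run_ensemble(p, hw_state(0.1), 15, seed = 3, n_runs = 20)
  s <- ens$summary
  expect_true(all(s$lo95 <= s$mean + 1e-12 & s$mean <= s$hi95 + 1e-12))
  expect_equal(nrow(s), 15L)
  expect_equal(s$sd[1], 0)  # generation 1 is the shared initial state
})

test_that("expected pool sizes match the per-female bookkeeping", {
  p <- model_params()
  st <- state_from_counts(c(M_CTRL = 100, F_CTRL_CTRL = 100))
  expect_equal(expected_pool_size(st, p), 100 * 30)
  # the default fecundities keep a 3%-SAA cage inside the reported 2500-5400
  pool <- expected_pool_size(state_from_counts(founding_composition("P1")), p)
  expect_gt(pool, 2500); expect_lt(pool, 5400)
  empty_f <- population_state(c(0.1, 0.9), c(0, 0, 1), n_male = 100, n_female = 0)
  expect_equal(expected_pool_size(empty_f, p), 0)
})
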