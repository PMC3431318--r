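test_that("effective weight interpolates the photophase advantage over the cycle", {
  # no photophase advantage means no overall advantage, any photoperiod
  for (L in c(0, 6, 12, 24))
    expect_equal(effective_male_weight(mating_params(w_photo = 1, light_hours = L)), 1)
  # permanent dark abolishes any advantage
  for (w in c(2, 13, 100))
    expect_equal(effective_male_weight(mating_params(w_photo = w, light_hours = 0)), 1)
  # permanent light realizes the full photophase weight
  expect_equal(effective_male_weight(mating_params(w_photo = 13, light_hours = 24)), 13)
  # 12:12 anchors the published light:dark mating split
  expect_equal(effective_male_weight(mating_params(w_photo = 13, light_hours = 12)),
               0.402 * 13 + 0.598)
  expect_error(mating_params(w_photo = 2, light_hours = 25), "\\[0, 24\\]")
})

test_that("effective weight is increasing in w_photo when there is any light", {
  ws <- c(1, 1.5, 2, 5, 13)
  for (L in c(3, 12, 24)) {
    eff <- sapply(ws, function(w)
      effective_male_weight(mating_params(w_photo = w, light_hours = L)))
    expect_true(all(diff(eff) > 0))
  }
  eff0 <- sapply(ws, function(w)
    effective_male_weight(mating_params(w_photo = w, light_hours = 0)))
  expect_equal(eff0, rep(1, length(ws)))
})

test_that("cross frequencies tilt males by advantage and let every female mate once", {
  st <- hw_state(0.3)
  # random mating: outer product of the frequency vectors
  expect_equal(cross_frequencies(st, 1), outer(st$male, st$female))
  # an advantaged male class takes w/(w+1) of matings at 50:50 frequencies
  st2 <- population_state(c(0.5, 0.5), c(0.2, 0.3, 0.5))
  cf <- cross_frequencies(st2, 13)
  expect_equal(unname(cf[1, ] / colSums(cf)), rep(13 / 14, 3))
  # absent SAA males sire nothing
  st3 <- population_state(c(0, 1), c(0.2, 0.3, 0.5))
  expect_equal(unname(cross_frequencies(st3, 13)[1, ]), c(0, 0, 0))
  # marginals: females exactly recovered, males advantage-tilted
  cf <- cross_frequencies(st, 5)
  expect_equal(colSums(cf), st$female)
  tilted <- c(5, 1) * st$male; tilted <- tilted / sum(tilted)
  expect_equal(rowSums(cf), tilted)
  expect_equal(sum(cf), 1)
})

test_that("paired-trial odds estimate the photophase weight", {
  expect_equal(estimate_weight_paired(26, 28), 13)
  expect_equal(estimate_weight_paired(14, 28), 1)
  expect_equal(estimate_weight_paired(1, 2), 1)
  expect_warning(w0 <- estimate_weight_paired(0, 10), "degenerate")
  expect_equal(w0, 0)
  expect_warning(wi <- estimate_weight_paired(10, 10), "degenerate")
  expect_equal(wi, Inf)
})

test_that("the paired estimator is consistent for the true weight", {
  set.seed(101)
  w_true <- 13
  n <- 10000
  est <- replicate(31, {
    k <- rbinom(1, n, w_true / (w_true + 1))
    k / (n - k)
  })
  expect_lt(abs(median(est) - w_true) / w_true, 0.05)
})

test_that("binomial upper tail matches exact enumeration", {
  # independent oracle: direct summation of the binomial pmf
  tail_oracle <- function(k, n, p) sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
  expect_equal(binomial_tail(14, 28, 0.5), tail_oracle(14, 28, 0.5))
  expect_equal(round(binomial_tail(14, 28, 0.5), 4), 0.5747)
  expect_equal(binomial_tail(26, 28, 0.5), tail_oracle(26, 28, 0.5))
  expect_lt(binomial_tail(26, 28, 0.5), 1e-4)
  expect_equal(binomial_tail(0, 17, 0.5), 1)
  expect_error(binomial_tail(29, 28, 0.5), "integer in")
})

test_that("mating opportunity summaries compare observed with proportional expectation", {
  # balanced case: observed equals expected, chi-square 0
  obs <- data.frame(generation = rep(1:3, each = 10),
                    winner = rep(rep(c("M_SAA", "M_CTRL"), each = 5), 3))
  avail <- data.frame(generation = 1:3, saa_male_freq = 0.5)
  s <- mating_opportunity_summary(obs, avail)
  expect_equal(unname(s$observed), unname(s$expected))
  expect_equal(s$chisq, 0)
  expect_equal(s$weight_estimate, 1)

  # strong excess: 50 SAA wins in 100 observations at 10% availability
  obs2 <- data.frame(generation = 1,
                     winner = rep(c("M_SAA", "M_CTRL"), each = 50))
  avail2 <- data.frame(generation = 1, saa_male_freq = 0.1)
  s2 <- mating_opportunity_summary(obs2, avail2)
  expect_equal(s2$observed[["M_SAA"]], 50)
  expect_equal(s2$expected[["M_SAA"]], 10)
  expect_equal(s2$weight_estimate, (50 / 50) / (10 / 90))

  expect_error(
    mating_opportunity_summary(data.frame(generation = 5, winner = "M_SAA"), avail),
    "no availability")
  expect_error(
    mating_opportunity_summary(data.frame(generation = 1, winner = "M_BLUE"), avail),
    "unknown winner")
})
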