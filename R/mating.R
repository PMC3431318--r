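# Male mating-advantage machinery: photoperiod weighting, cross frequencies,
# and estimation of the advantage from paired-trial and cage-observation data.

#' Mating parameters
#'
#' The SAA male mating advantage exists only in photophase (the light part of
#' the cycle): `w_photo` is the relative mating weight of an SAA male during
#' light, with control males fixed at weight 1. Drosophila mate slightly more
#' often in the dark; under a 12:12 cycle the expected split of matings is
#' 0.402 light : 0.598 dark, the default propensities.
#'
#' @param w_photo Positive photophase mating weight of SAA males.
#' @param light_hours Hours of light per 24 h cycle, in `[0, 24]`.
#' @param light_dark_propensity Length-2 positive proportions summing to 1:
#'   share of matings in light vs dark under a 12:12 cycle.
#' @return List of class `mating_params`.
#' @export
mating_params <- function(w_photo = 1, light_hours = 12,
                          light_dark_propensity = c(0.402, 0.598)) {
  stopifnot(is.numeric(w_photo), length(w_photo) == 1L, w_photo > 0)
  if (!is.numeric(light_hours) || length(light_hours) != 1L ||
      light_hours < 0 || light_hours > 24)
    stop("'light_hours' must be in [0, 24]")
  stopifnot(length(light_dark_propensity) == 2L, all(light_dark_propensity > 0),
            abs(sum(light_dark_propensity) - 1) < 1e-9)
  structure(list(w_photo = w_photo, light_hours = light_hours,
                 light_dark_propensity = as.numeric(light_dark_propensity)),
            class = "mating_params")
}

#' Cycle-averaged SAA male mating weight
#'
#' Averages the photophase-only advantage over the full light cycle. The
#' fraction of matings occurring in light is obtained by scaling the 12:12
#' propensities (0.402 light : 0.598 dark) linearly by the actual light and
#' dark hours: `p_L = 0.402 (L/12) / (0.402 (L/12) + 0.598 ((24-L)/12))`.
#' The effective weight is then `p_L * w_photo + (1 - p_L)`, since SAA and
#' control males mate equally well in the dark. Under permanent dark (L = 0)
#' the advantage vanishes (weight 1); under permanent light it equals
#' `w_photo`.
#'
#' @param p A [mating_params] object.
#' @return Positive cycle-averaged weight.
#' @examples
#' effective_male_weight(mating_params(w_photo = 13, light_hours = 12)) # 5.824
#' @export
effective_male_weight <- function(p) {
  stopifnot(inherits(p, "mating_params"))
  L <- p$light_hours
  prop <- p$light_dark_propensity
  light_mass <- prop[1] * (L / 12)
  dark_mass <- prop[2] * ((24 - L) / 12)
  p_light <- if (light_mass + dark_mass == 0) 0 else light_mass / (light_mass + dark_mass)
  p_light * p$w_photo + (1 - p_light)
}

#' Mating proportions between genotype classes
#'
#' The share of all matings occurring between each male genotype and each
#' female genotype, given the current population state and the cycle-averaged
#' SAA male weight. Every female mates exactly once (sperm competition is
#' neutral between the genotypes), and within each female class males are
#' allocated proportionally to their advantage-tilted frequencies:
#' `entry(i, j) = w_i m_i / sum_k(w_k m_k) * f_j`.
#'
#' @param state A [population_state].
#' @param w_eff Positive effective male weight (see [effective_male_weight]).
#' @return 2 x 3 matrix (father genotype x mother genotype) of non-negative
#'   proportions summing to 1.
#' @export
cross_frequencies <- function(state, w_eff) {
  stopifnot(inherits(state, "population_state"), w_eff > 0)
  if ((!is.null(state$n_male) && state$n_male == 0) ||
      (!is.null(state$n_female) && state$n_female == 0))
    stop("no matings possible: one sex is absent")
  tilted <- c(w_eff, 1) * state$male
  tilted <- tilted / sum(tilted)
  outer(tilted, state$female)
}

#' Mating-advantage estimate from paired trials
#'
#' In a one-on-one contest between an SAA and a control male for a single
#' virgin female, the SAA male wins with probability `w / (w + 1)` where `w`
#' is his relative weight; inverting, the odds `k / (n - k)` of the observed
#' wins estimate `w`.
#'
#' @param k_wins Trials won by the SAA male.
#' @param n_trials Total paired trials.
#' @return Estimated weight. A clean sweep (`k_wins` of 0 or `n_trials`)
#'   returns 0 or `Inf` with a warning; callers must handle the degenerate
#'   estimate.
#' @examples
#' estimate_weight_paired(26, 28)  # 13: the photophase advantage
#' estimate_weight_paired(14, 28)  # 1: no advantage in the dark
#' @export
estimate_weight_paired <- function(k_wins, n_trials) {
  stopifnot(k_wins >= 0, n_trials >= 1, k_wins <= n_trials,
            k_wins == round(k_wins), n_trials == round(n_trials))
  if (k_wins == 0 || k_wins == n_trials) {
    warning("all trials won by one genotype: estimate is degenerate (0 or Inf)")
    return(if (k_wins == 0) 0 else Inf)
  }
  k_wins / (n_trials - k_wins)
}

#' Exact binomial upper tail
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`; the one-sided exact test of whether
#' wins exceed the null rate.
#'
#' @param k Observed successes, `0 <= k <= n`.
#' @param n Number of trials.
#' @param p0 Null success probability in `(0, 1)`.
#' @return Upper-tail probability.
#' @examples
#' binomial_tail(14, 28, 0.5)  # 0.5747
#' @export
binomial_tail <- function(k, n, p0) {
  if (!(k >= 0 && k <= n && k == round(k) && n == round(n)))
    stop("'k' must be an integer in [0, n]")
  stopifnot(p0 > 0, p0 < 1)
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Observed vs expected matings from cage spot checks
#'
#' Aggregates spot-check mating observations against the per-generation
#' availability of SAA males. Under proportional (advantage-free) mating the
#' expected SAA matings in a generation are the SAA male frequency times the
#' observations made that generation; totals over generations feed a
#' chi-square comparison of observed against expected mating opportunities
#' taken.
#'
#' @param observations Data frame with columns `generation` and `winner`
#'   ("M_SAA" or "M_CTRL"), one row per observed mating.
#' @param availability Data frame with columns `generation` and
#'   `saa_male_freq`, one row per generation observed.
#' @return List of class `mating_summary`: `per_generation` table, observed
#'   and expected totals per male class, the chi-square statistic (1 df) and
#'   its p-value, and `weight_estimate` — the ratio of observed to expected
#'   mating odds, a moment estimate of the photophase advantage underlying
#'   the observations.
#' @export
mating_opportunity_summary <- function(observations, availability) {
  stopifnot(is.data.frame(observations),
            all(c("generation", "winner") %in% names(observations)),
            is.data.frame(availability),
            all(c("generation", "saa_male_freq") %in% names(availability)))
  if (!all(observations$winner %in% male_genotypes))
    stop("unknown winner labels: ",
         paste(setdiff(observations$winner, male_genotypes), collapse = ", "))
  gens <- sort(unique(observations$generation))
  missing <- setdiff(gens, availability$generation)
  if (length(missing))
    stop("no availability for generation(s): ", paste(missing, collapse = ", "))
  freq <- availability$saa_male_freq[match(gens, availability$generation)]
  n_obs <- as.integer(table(factor(observations$generation, levels = gens)))
  saa_obs <- as.integer(table(factor(
    observations$generation[observations$winner == "M_SAA"], levels = gens)))
  per_gen <- data.frame(generation = gens, n_obs = n_obs,
                        saa_male_freq = freq,
                        saa_observed = saa_obs,
                        saa_expected = freq * n_obs)
  observed <- c(M_SAA = sum(per_gen$saa_observed),
                M_CTRL = sum(per_gen$n_obs - per_gen$saa_observed))
  expected <- c(M_SAA = sum(per_gen$saa_expected),
                M_CTRL = sum(per_gen$n_obs - per_gen$saa_expected))
  chisq <- sum((observed - expected)^2 / expected)
  w_hat <- (observed[["M_SAA"]] / observed[["M_CTRL"]]) /
    (expected[["M_SAA"]] / expected[["M_CTRL"]])
  structure(list(per_generation = per_gen, observed = observed,
                 expected = expected, chisq = chisq,
                 p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
                 weight_estimate = w_hat),
            class = "mating_summary")
}

#' @export
print.mating_summary <- function(x, ...) {
  cat("<mating_summary> over", nrow(x$per_generation), "generations,",
      sum(x$per_generation$n_obs), "observations\n")
  cat(sprintf("  observed SAA/control: %d / %d\n", x$observed[["M_SAA"]], x$observed[["M_CTRL"]]))
  cat(sprintf("  expected SAA/control: %.2f / %.2f\n", x$expected[["M_SAA"]], x$expected[["M_CTRL"]]))
  cat(sprintf("  chi-square (1 df) = %.3f, p = %.4g\n", x$chisq, x$p_value))
  invisible(x)
}
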