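# Genotype-frequency recursion for the sexually antagonistic allele:
# deterministic map, 300-offspring stochastic variant, ensembles, equilibria.

#' Model parameters for the cage recursion
#'
#' Bundles everything one generation of the model needs: the mating
#' parameters, a 2 x 3 cross-fecundity table giving the mean number of
#' surviving offspring per mating for each father x mother genotype
#' combination, and the simulation sizes. The default fecundities are a
#' baseline brood of `brood_size` offspring scaled by the relative female
#' fecundities (SAA homozygote 0.388, heterozygote 0.9, control 1),
#' identical for both father genotypes because sperm competition between the
#' genotypes is neutral. A measured cross table (e.g. per-cross offspring
#' means) can be supplied to override the default.
#'
#' @param mating A [mating_params] object.
#' @param brood_size Baseline offspring per mating for a control female
#'   (default 30, which keeps the per-generation offspring pool of a
#'   100-female cage near 3000, inside the 2500-5400 range the experiment
#'   reported).
#' @param female_fecundity Length-3 relative fecundities of
#'   `F_SAA_SAA`, `F_SAA_CTRL`, `F_CTRL_CTRL` females.
#' @param cross_fecundity Optional 2 x 3 matrix (father x mother genotype) of
#'   mean surviving offspring per mating; overrides
#'   `brood_size`/`female_fecundity`.
#' @param sample_size Offspring drawn per generation in the stochastic model
#'   (default 300, matching the 300 larvae scored per cage generation).
#' @param n_runs Ensemble size (default 100).
#' @param max_generations Horizon for equilibrium determination (default
#'   1000).
#' @param adult_census Adults per sex maintained each generation (default
#'   100).
#' @return List of class `model_params`.
#' @export
model_params <- function(mating = mating_params(), brood_size = 30,
                         female_fecundity = c(0.388, 0.9, 1),
                         cross_fecundity = NULL, sample_size = 300,
                         n_runs = 100, max_generations = 1000,
                         adult_census = 100) {
  stopifnot(inherits(mating, "mating_params"), brood_size > 0,
            length(female_fecundity) == 3L, all(female_fecundity >= 0),
            sample_size >= 1, n_runs >= 1, max_generations >= 1,
            adult_census >= 1)
  if (is.null(cross_fecundity)) {
    cross_fecundity <- rbind(brood_size * female_fecundity,
                             brood_size * female_fecundity)
  }
  cross_fecundity <- as.matrix(cross_fecundity)
  if (!all(dim(cross_fecundity) == c(2L, 3L)) || any(cross_fecundity < 0))
    stop("'cross_fecundity' must be a non-negative 2 x 3 (father x mother) matrix")
  dimnames(cross_fecundity) <- list(male_genotypes, female_genotypes)
  structure(list(mating = mating, cross_fecundity = cross_fecundity,
                 sample_size = as.integer(sample_size),
                 n_runs = as.integer(n_runs),
                 max_generations = as.integer(max_generations),
                 adult_census = as.integer(adult_census)),
            class = "model_params")
}

# Expected offspring pool (unnormalized class weights over the five states).
# Cross weights = mating proportions x fecundity; pool = weights %*% kernel.
.offspring_pool <- function(male, female, w_eff, fec) {
  tilted <- c(w_eff, 1) * male
  tilted <- tilted / sum(tilted)
  w <- as.vector(t(outer(tilted, female) * fec))  # father-major order
  as.vector(w %*% .cross_kernel)
}

#' One deterministic generation
#'
#' Advances the genotype frequencies by one generation: matings form at
#' advantage-tilted proportions, each cross contributes offspring at its mean
#' fecundity with Mendelian X-linked segregation, and the resulting offspring
#' pool is renormalized within each sex to give the next generation's
#' frequencies.
#'
#' @param state A [population_state].
#' @param params A [model_params] object.
#' @return The next-generation [population_state] (adult census carried
#'   over from `params$adult_census`).
#' @export
deterministic_step <- function(state, params) {
  stopifnot(inherits(state, "population_state"), inherits(params, "model_params"))
  pool <- .offspring_pool(state$male, state$female,
                          effective_male_weight(params$mating),
                          params$cross_fecundity)
  if (sum(pool) <= 0) stop("population collapse: zero total offspring")
  population_state(pool[1:2] / sum(pool[1:2]), pool[3:5] / sum(pool[3:5]),
                   generation = state$generation + 1L,
                   n_male = params$adult_census, n_female = params$adult_census)
}

#' One stochastic generation (multinomial offspring sampling)
#'
#' Computes the expected offspring pool exactly as [deterministic_step], then
#' draws `params$sample_size` offspring (default 300) in one multinomial draw
#' over the five (sex, genotype) classes — the model analogue of picking 300
#' larvae from the thousands generated. Next-generation frequencies
#' renormalize the drawn counts within each sex. Sampling without
#' replacement from the finite pool (typically 2500-5400) would shrink
#' variances by at most a few percent; the multinomial approximation ignores
#' this.
#'
#' @inheritParams deterministic_step
#' @return Next [population_state], with attributes `sampled_counts` (the
#'   drawn offspring, named integer vector) and `failed` (TRUE if a sex drew
#'   zero individuals, a terminal state for the line).
#' @export
stochastic_step <- function(state, params) {
  stopifnot(inherits(state, "population_state"), inherits(params, "model_params"))
  pool <- .offspring_pool(state$male, state$female,
                          effective_male_weight(params$mating),
                          params$cross_fecundity)
  if (sum(pool) <= 0) stop("population collapse: zero total offspring")
  draw <- as.vector(stats::rmultinom(1, params$sample_size, pool))
  names(draw) <- saa_genotypes
  nm <- sum(draw[1:2]); nf <- sum(draw[3:5])
  if (nm == 0 || nf == 0) {
    out <- state
    attr(out, "sampled_counts") <- draw
    attr(out, "failed") <- TRUE
    return(out)
  }
  out <- population_state(draw[1:2] / nm, draw[3:5] / nf,
                          generation = state$generation + 1L,
                          n_male = params$adult_census,
                          n_female = params$adult_census)
  attr(out, "sampled_counts") <- draw
  attr(out, "failed") <- FALSE
  out
}

#' Deterministic trajectory
#'
#' Iterates [deterministic_step] from the initial state (generation 1 by
#' convention) up to generation `n_gen`, recording all five class frequencies
#' and the SAA X-chromosome frequency at every generation. The trajectory is
#' flagged `converged` once the per-generation frequency change stays below
#' 1e-10 for 10 consecutive generations, `extinct`/`fixed` when the final
#' frequency is at the respective boundary.
#'
#' @param params A [model_params] object.
#' @param initial Initial [population_state] (or a `saa_composition`, which
#'   is converted).
#' @param n_gen Final generation index (the trajectory has
#'   `n_gen - initial$generation + 1` rows).
#' @return Object of class `saa_trajectory`: a data frame with columns
#'   `generation`, the five class frequencies, `saa_x_freq`; attributes
#'   `converged`, `extinct`, `fixed`.
#' @export
run_deterministic <- function(params, initial, n_gen) {
  initial <- .as_state(initial)
  stopifnot(n_gen >= initial$generation)
  n_rows <- n_gen - initial$generation + 1L
  rows <- matrix(NA_real_, n_rows, 6)
  state <- initial
  streak <- 0L; converged <- FALSE
  q_prev <- x_allele_frequency(state)
  rows[1, ] <- c(state$male, state$female, q_prev)
  for (i in seq_len(n_rows - 1L)) {
    state <- deterministic_step(state, params)
    q <- x_allele_frequency(state)
    rows[i + 1L, ] <- c(state$male, state$female, q)
    streak <- if (abs(q - q_prev) < 1e-10) streak + 1L else 0L
    if (streak >= 10L) converged <- TRUE
    q_prev <- q
  }
  df <- data.frame(generation = seq(initial$generation, n_gen), rows)
  names(df) <- c("generation", saa_genotypes, "saa_x_freq")
  structure(df, class = c("saa_trajectory", "data.frame"),
            converged = converged,
            extinct = q_prev < 1e-12, fixed = q_prev > 1 - 1e-12)
}

.as_state <- function(x, generation = 1) {
  if (inherits(x, "population_state")) return(x)
  if (inherits(x, "saa_composition") || (is.numeric(x) && !is.null(names(x))))
    return(state_from_counts(x, generation = generation))
  stop("'initial' must be a population_state or a named composition")
}

#' Equilibrium SAA frequency
#'
#' Runs the deterministic recursion to `params$max_generations` (default
#' 1000) and reports the terminal frequency as the equilibrium, together with
#' the frequency at generation 700 (the horizon at which the experimental
#' model's equilibrium was quoted) and the convergence flag.
#'
#' @inheritParams run_deterministic
#' @return List: `equilibrium`, `freq_700` (NA if the horizon is shorter),
#'   `generation`, `converged`, `trajectory`.
#' @export
find_equilibrium <- function(params, initial) {
  traj <- run_deterministic(params, .as_state(initial), params$max_generations)
  q <- traj$saa_x_freq
  list(equilibrium = q[length(q)],
       freq_700 = if (max(traj$generation) >= 700)
         q[match(700, traj$generation)] else NA_real_,
       generation = max(traj$generation),
       converged = attr(traj, "converged"),
       trajectory = traj)
}

#' Stochastic ensemble with per-generation confidence band
#'
#' Runs `n_runs` independent stochastic trajectories (multinomial sampling of
#' `sample_size` offspring each generation) from per-run seeds derived
#' deterministically from the master seed, and summarizes the SAA frequency
#' at each generation by its mean, standard deviation and percentile 95%
#' band (2.5 and 97.5 percentiles across runs). Runs that lose or fix the
#' allele continue at the absorbed frequency and stay in the summary; a run
#' whose multinomial draw loses a whole sex is held at its last state and
#' counted as failed.
#'
#' @inheritParams run_deterministic
#' @param seed Master seed (integer); every source of randomness derives
#'   from it, so a repeated call reproduces the ensemble exactly.
#' @param n_runs Number of runs (default `params$n_runs`).
#' @return Object of class `saa_ensemble`: list with `summary` (data frame:
#'   generation, mean, sd, lo95, hi95), `freqs` (runs x generations matrix),
#'   `n_failed`, `seed`.
#' @export
run_ensemble <- function(params, initial, n_gen, seed, n_runs = params$n_runs) {
  initial <- .as_state(initial)
  stopifnot(n_runs >= 2, n_gen >= initial$generation)
  set.seed(as.integer(seed))
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  n_rows <- n_gen - initial$generation + 1L
  freqs <- matrix(NA_real_, n_runs, n_rows)
  n_failed <- 0L
  for (r in seq_len(n_runs)) {
    set.seed(run_seeds[r])
    state <- initial
    freqs[r, 1] <- x_allele_frequency(state)
    failed <- FALSE
    for (i in seq_len(n_rows - 1L)) {
      if (!failed) {
        state <- stochastic_step(state, params)
        failed <- isTRUE(attr(state, "failed"))
        if (failed) n_failed <- n_failed + 1L
      }
      freqs[r, i + 1L] <- x_allele_frequency(state)
    }
  }
  gens <- seq(initial$generation, n_gen)
  summ <- data.frame(
    generation = gens,
    mean = colMeans(freqs),
    sd = apply(freqs, 2, stats::sd),
    lo95 = apply(freqs, 2, stats::quantile, probs = 0.025),
    hi95 = apply(freqs, 2, stats::quantile, probs = 0.975)
  )
  structure(list(summary = summ, freqs = freqs, n_failed = n_failed,
                 seed = as.integer(seed)),
            class = "saa_ensemble")
}

#' @export
print.saa_ensemble <- function(x, ...) {
  s <- x$summary
  last <- s[nrow(s), ]
  cat("<saa_ensemble>", nrow(x$freqs), "runs x", nrow(s), "generations (seed",
      paste0(x$seed, ")"), "\n")
  cat(sprintf("  final SAA frequency: mean %.4f, sd %.4f, 95%% band [%.4f, %.4f]\n",
              last$mean, last$sd, last$lo95, last$hi95))
  if (x$n_failed > 0) cat("  failed lines:", x$n_failed, "\n")
  invisible(x)
}

#' Expected per-generation offspring pool size
#'
#' Total offspring expected from one generation of matings, with matings
#' scaled to the number of adult females (each mates once): the quantity the
#' experiment reported as "typically 2500-5400" per cage generation. Useful
#' for sanity-checking a fecundity configuration.
#'
#' @inheritParams deterministic_step
#' @return Expected offspring count.
#' @examples
#' st <- state_from_counts(c(M_CTRL = 100, F_CTRL_CTRL = 100))
#' expected_pool_size(st, model_params())  # 100 females x brood 30 = 3000
#' @export
expected_pool_size <- function(state, params) {
  stopifnot(inherits(state, "population_state"), inherits(params, "model_params"))
  nf <- if (is.null(state$n_female)) params$adult_census else state$n_female
  if (nf == 0) return(0)
  cf <- cross_frequencies(state, effective_male_weight(params$mating))
  nf * sum(cf * params$cross_fecundity)
}

#' Calibrated photophase mating weight
#'
#' The package's reference calibration of the one free parameter the source
#' experiment did not print: the SAA male photophase mating weight observed
#' in cages. Under the default fecundities (brood 30; female relative
#' fecundities 0.388/0.9/1) and a 12:12 light cycle, `w_photo = 1.9331164`
#' makes the deterministic 1000-generation equilibrium equal 0.126 — the
#' 12.6% equilibrium the parameterized model predicted. Note this cage-level
#' advantage is far below the 13:1 odds from one-on-one paired trials:
#' in a cage an advantaged male must still find and court females among 200
#' flies, so the realized advantage is diluted.
#'
#' @format A single numeric value.
#' @seealso [calibrate_male_advantage] to recompute it for other
#'   parameterizations.
#' @export
calibrated_w_photo <- 1.9331164086

#' Calibrate the photophase weight to a target equilibrium
#'
#' Solves for the `w_photo` whose deterministic equilibrium (frequency at
#' `params$max_generations`) equals `target`, by root bisection. The
#' equilibrium is monotone non-decreasing in `w_photo`, so the root is
#' unique within the bracket when it exists.
#'
#' @param target Target equilibrium SAA X-frequency (default 0.126).
#' @param params A [model_params]; its `w_photo` entry is the free variable.
#' @param initial Initial state (default: the 3% founding composition).
#' @param interval Search bracket for `w_photo`.
#' @param tol Root tolerance.
#' @return The calibrated `w_photo` value.
#' @export
calibrate_male_advantage <- function(target = 0.126, params = model_params(),
                                     initial = founding_composition("P1"),
                                     interval = c(1.01, 40), tol = 1e-8) {
  initial <- .as_state(initial)
  eq_of <- function(w) {
    p <- params
    p$mating$w_photo <- w
    find_equilibrium(p, initial)$equilibrium - target
  }
  stats::uniroot(eq_of, interval, tol = tol)$root
}
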