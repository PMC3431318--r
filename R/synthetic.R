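# Synthetic cage-experiment generator: produces datasets with the observation
# structure of the real experiment (300 scored offspring per line per
# generation, 100+100 adult census, photophase spot-check matings) from known
# ground-truth parameters.

#' Cage-experiment design
#'
#' Everything needed to simulate a replicated cage experiment: number of
#' replicate lines, generations per line, the founding composition, the
#' light-regime schedule, the spot-check observation density, the true model
#' parameters, and a master seed. Defaults mirror the source experiment's
#' P1-P4 arm: 4 lines founded at 3% SAA, 16 generations, 12:12 light.
#'
#' @param n_lines Replicate lines (default 4).
#' @param n_generations Generations tracked per line, founding included
#'   (default 16).
#' @param founding A preset name ("P1".."P8"), a `saa_composition`, or a
#'   named count vector (default "P1": 9 SAA males, 81 control males, 100
#'   control females).
#' @param light_schedule Hours of light per 24 h for each transition; a
#'   scalar is recycled to `n_generations - 1` entries (entry g governs the
#'   matings of generation g adults).
#' @param obs_per_generation Photophase spot-check mating observations per
#'   generation per line (default 6, about the density of the experiment's
#'   62 observations over 10 generations; 0 disables). No observations are
#'   made under a dark regime.
#' @param params True [model_params] driving the simulation.
#' @param seed Master seed; required, so datasets are reproducible.
#' @return List of class `experiment_design`.
#' @export
experiment_design <- function(n_lines = 4, n_generations = 16,
                              founding = "P1", light_schedule = 12,
                              obs_per_generation = 6,
                              params = model_params(), seed) {
  stopifnot(n_lines >= 1, n_generations >= 2, obs_per_generation >= 0,
            inherits(params, "model_params"))
  if (missing(seed)) stop("an explicit 'seed' is required")
  if (is.character(founding)) founding <- founding_composition(founding)
  founding <- .as_state(founding)
  n_trans <- n_generations - 1L
  if (length(light_schedule) == 1L) light_schedule <- rep(light_schedule, n_trans)
  if (length(light_schedule) != n_trans)
    stop("'light_schedule' must have one entry per generation transition (",
         n_trans, ")")
  if (any(light_schedule < 0 | light_schedule > 24))
    stop("'light_schedule' entries must be hours in [0, 24]")
  structure(list(n_lines = as.integer(n_lines),
                 n_generations = as.integer(n_generations),
                 founding = founding,
                 light_schedule = as.numeric(light_schedule),
                 obs_per_generation = as.integer(obs_per_generation),
                 params = params, seed = as.integer(seed)),
            class = "experiment_design")
}

# round per class within a sex, then fix the total to the census by
# largest-remainder adjustment (the adult census really holds 100 flies of
# each sex; the residue a pure per-class rounding can leave is reconciled)
.census_counts <- function(freqs, census) {
  target <- freqs * census
  counts <- round_half_up(target)
  resid <- census - sum(counts)
  if (resid != 0) {
    frac <- target - floor(target)
    ord <- order(if (resid > 0) -frac else frac)
    for (i in seq_len(abs(resid))) {
      j <- ord[((i - 1L) %% length(counts)) + 1L]
      counts[j] <- counts[j] + sign(resid)
    }
  }
  pmax(counts, 0)
}

#' Generate a synthetic cage experiment
#'
#' Simulates each line forward with [stochastic_step] under the design's
#' light schedule. Each generation the 300-offspring multinomial draw is
#' recorded as the scored offspring — reported as eye-colour counts per sex,
#' exactly what a scorer sees — and the next adult census of 100 males and
#' 100 females is formed from the drawn proportions by rounding. During
#' light regimes, spot-check mating observations are emitted as independent
#' Bernoulli draws with SAA-win probability
#' `w_photo m_SAA / (w_photo m_SAA + m_CTRL)` (the photophase-tilted male
#' shares). The true per-generation frequencies are embedded for
#' parameter-recovery tests.
#'
#' @param design An [experiment_design].
#' @return Object of class `cage_dataset`: list of data frames `offspring`
#'   (line, generation, males_red, males_white, females_red, females_orange,
#'   females_white), `adults` (line, generation, five genotype counts),
#'   `matings` (line, generation, obs, winner), `availability` (line,
#'   generation, saa_male_freq), `truth` (line, generation, saa_x_freq),
#'   plus the `design`.
#' @export
generate_experiment <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  set.seed(design$seed)
  line_seeds <- sample.int(.Machine$integer.max - 1L, design$n_lines)
  params <- design$params
  offspring <- adults <- matings <- avail <- truth <- list()
  for (ln in seq_len(design$n_lines)) {
    set.seed(line_seeds[ln])
    state <- design$founding
    fc <- round(c(state$male * state$n_male, state$female * state$n_female))
    adults[[length(adults) + 1L]] <- data.frame(
      line = ln, generation = 1L, t(fc))
    truth[[length(truth) + 1L]] <- data.frame(
      line = ln, generation = 1L, saa_x_freq = x_allele_frequency(state))
    for (g in seq_len(design$n_generations - 1L)) {
      L <- design$light_schedule[g]
      avail[[length(avail) + 1L]] <- data.frame(
        line = ln, generation = state$generation,
        saa_male_freq = state$male[["M_SAA"]])
      if (design$obs_per_generation > 0 && L > 0) {
        w <- params$mating$w_photo
        m <- state$male
        p_win <- w * m[["M_SAA"]] / (w * m[["M_SAA"]] + m[["M_CTRL"]])
        wins <- stats::rbinom(design$obs_per_generation, 1, p_win)
        matings[[length(matings) + 1L]] <- data.frame(
          line = ln, generation = state$generation,
          obs = seq_along(wins),
          winner = ifelse(wins == 1, "M_SAA", "M_CTRL"))
      }
      params$mating$light_hours <- L
      state <- stochastic_step(state, params)
      drawn <- attr(state, "sampled_counts")
      offspring[[length(offspring) + 1L]] <- data.frame(
        line = ln, generation = state$generation,
        males_red = drawn[["M_SAA"]], males_white = drawn[["M_CTRL"]],
        females_red = drawn[["F_SAA_SAA"]],
        females_orange = drawn[["F_SAA_CTRL"]],
        females_white = drawn[["F_CTRL_CTRL"]])
      census_m <- .census_counts(state$male, params$adult_census)
      census_f <- .census_counts(state$female, params$adult_census)
      adults[[length(adults) + 1L]] <- data.frame(
        line = ln, generation = state$generation,
        t(c(census_m, census_f)))
      truth[[length(truth) + 1L]] <- data.frame(
        line = ln, generation = state$generation,
        saa_x_freq = x_allele_frequency(state_from_counts(drawn)))
      if (isTRUE(attr(state, "failed"))) break
    }
  }
  bind <- function(l) {
    out <- do.call(rbind, l)
    rownames(out) <- NULL
    out
  }
  structure(list(offspring = bind(offspring), adults = bind(adults),
                 matings = if (length(matings)) bind(matings) else
                   data.frame(line = integer(), generation = integer(),
                              obs = integer(), winner = character()),
                 availability = bind(avail), truth = bind(truth),
                 design = design),
            class = "cage_dataset")
}

#' @export
print.cage_dataset <- function(x, ...) {
  d <- x$design
  cat("<cage_dataset>", d$n_lines, "lines x", d$n_generations,
      "generations (seed", paste0(d$seed, ")"), "\n")
  cat("  scored offspring rows:", nrow(x$offspring),
      " mating observations:", nrow(x$matings), "\n")
  fin <- x$truth[x$truth$generation == max(x$truth$generation), ]
  cat(sprintf("  mean final SAA frequency: %.4f\n", mean(fin$saa_x_freq)))
  invisible(x)
}

#' Genotype counts from scored eye colours
#'
#' Inverts the eye-colour map per sex: red males are SAA hemizygotes, white
#' males controls; red / orange / white females are SAA homozygotes,
#' heterozygotes and controls. Orange males are impossible under X-linked
#' hemizygosity and indicate a scoring or data-integrity error.
#'
#' @param scored Named counts with entries among `males_red`, `males_white`,
#'   `males_orange`, `females_red`, `females_orange`, `females_white`
#'   (missing entries count as 0).
#' @return Named integer counts over the five genotype classes.
#' @examples
#' genotype_counts_from_phenotypes(c(males_red = 10, males_white = 90))
#' @export
genotype_counts_from_phenotypes <- function(scored) {
  allowed <- c("males_red", "males_white", "males_orange",
               "females_red", "females_orange", "females_white")
  if (is.null(names(scored)) || !all(names(scored) %in% allowed))
    stop("unknown phenotype classes: ",
         paste(setdiff(names(scored), allowed), collapse = ", "))
  get0 <- function(k) if (k %in% names(scored)) as.integer(scored[[k]]) else 0L
  if (get0("males_orange") > 0)
    stop("data-integrity error: orange males are impossible (hemizygous X)")
  c(M_SAA = get0("males_red"), M_CTRL = get0("males_white"),
    F_SAA_SAA = get0("females_red"), F_SAA_CTRL = get0("females_orange"),
    F_CTRL_CTRL = get0("females_white"))
}
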