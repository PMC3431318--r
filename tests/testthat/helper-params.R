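# Shared fixtures: parameterizations used across test files.

# reference parameterization: calibrated photophase advantage, default
# fecundities, 12:12 light -- supports a stable interior equilibrium
calibrated_params <- function(...) {
  model_params(mating = mating_params(w_photo = calibrated_w_photo), ...)
}

# neutral parameterization: no male advantage, equal fecundities everywhere
neutral_params <- function(...) {
  model_params(mating = mating_params(w_photo = 1),
               female_fecundity = c(1, 1, 1), ...)
}

# a Hardy-Weinberg population state at allele frequency q (no selection)
hw_state <- function(q, n = 100) {
  population_state(c(q, 1 - q), c(q^2, 2 * q * (1 - q), (1 - q)^2),
                   n_male = n, n_female = n)
}

# published founding compositions, as printed
printed_compositions <- list(
  P5 = c(44, 56, 4, 42, 54),
  P6 = c(65, 35, 12, 56, 31),
  P7 = c(81, 19, 29, 57, 14),
  P8 = c(94, 6, 64, 33, 2)
)
preset_q <- c(P5 = 0.3, P6 = 0.5, P7 = 0.7, P8 = 0.9)
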