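# Founding cage compositions at Hardy-Weinberg-with-selection proportions.

# nearest integer, halves away from zero (base round() rounds halves to even,
# which does not reproduce the published compositions)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Rudimentary per-genotype fitness estimates
#'
#' Relative fitness weights used to tilt Hardy-Weinberg proportions when
#' composing starting populations: SAA males 1 vs control males 0.55
#' (photophase mating advantage), SAA homozygote females 0.388, heterozygote
#' females 0.9, control females 1 (fecundity costs of the allele).
#'
#' @param male Length-2 positive weights `(SAA, control)`.
#' @param female Length-3 positive weights `(SAA homozygote, heterozygote,
#'   control)`.
#' @return List with elements `male`, `female` (named numeric vectors).
#' @export
fitness_estimates <- function(male = c(1, 0.55), female = c(0.388, 0.9, 1)) {
  stopifnot(length(male) == 2L, length(female) == 3L,
            all(male > 0), all(female > 0))
  list(male = stats::setNames(as.numeric(male), male_genotypes),
       female = stats::setNames(as.numeric(female), female_genotypes))
}

#' Starting composition under Hardy-Weinberg with selection
#'
#' Composes a founding cage of `n_per_sex` males and `n_per_sex` females at
#' a pre-selection allele frequency `q`: genotype classes take
#' Hardy-Weinberg proportions (males `(q, 1-q)`, females
#' `(q^2, 2q(1-q), (1-q)^2)`), are weighted by the relative fitness
#' estimates, renormalized within each sex, scaled to `n_per_sex`, and
#' rounded per class to the nearest integer (halves away from zero). No
#' reconciliation is applied, so a sex's total may differ from `n_per_sex`
#' by one — exactly as in the published compositions, where two female
#' totals come to 99.
#'
#' @param q Pre-selection SAA allele frequency in `[0, 1]`.
#' @param n_per_sex Target adults per sex (default 100).
#' @param fitness A [fitness_estimates] list.
#' @return Named integer vector of counts over the five genotype classes,
#'   class `saa_composition`, with attributes `q` and `n_per_sex`.
#' @examples
#' hw_selection_composition(0.30)  # males 44/56, females 4/42/54
#' @export
hw_selection_composition <- function(q, n_per_sex = 100,
                                     fitness = fitness_estimates()) {
  if (!is.numeric(q) || length(q) != 1L || q < 0 || q > 1)
    stop("'q' must be a single value in [0, 1]")
  stopifnot(n_per_sex >= 1)
  m <- c(q, 1 - q) * fitness$male
  f <- c(q^2, 2 * q * (1 - q), (1 - q)^2) * fitness$female
  counts <- c(round_half_up(m / sum(m) * n_per_sex),
              round_half_up(f / sum(f) * n_per_sex))
  structure(stats::setNames(as.integer(counts), saa_genotypes),
            class = "saa_composition", q = q, n_per_sex = n_per_sex)
}

# Published founding compositions. P1-P4 were constructed directly from
# crosses (9 SAA males, 81 control males, 100 control females: 3% SAA X
# chromosomes); P5-P8 as printed in the source experiment. Note P8's SAA
# homozygote female count is the printed 64, although the stated
# Hardy-Weinberg-with-selection procedure at q = 0.9 yields 64.63 -> 65;
# the printed rows are preserved verbatim here while
# hw_selection_composition() follows the procedure.
.founding_presets <- list(
  P1 = c(9, 81, 0, 0, 100), P2 = c(9, 81, 0, 0, 100),
  P3 = c(9, 81, 0, 0, 100), P4 = c(9, 81, 0, 0, 100),
  P5 = c(44, 56, 4, 42, 54),
  P6 = c(65, 35, 12, 56, 31),
  P7 = c(81, 19, 29, 57, 14),
  P8 = c(94, 6, 64, 33, 2)
)
.preset_q <- c(P5 = 0.3, P6 = 0.5, P7 = 0.7, P8 = 0.9)

#' Published founding compositions P1-P8
#'
#' The experimental founding censuses: P1-P4 start at 3% SAA X chromosomes
#' (9 SAA males, 81 control males, 100 control females); P5-P8 start at
#' 31/48/65/85% via Hardy-Weinberg-with-selection compositions at
#' pre-selection frequencies 0.3/0.5/0.7/0.9.
#'
#' @param preset One of "P1".."P8".
#' @return A `saa_composition` (named integer counts).
#' @export
founding_composition <- function(preset) {
  if (!(is.character(preset) && length(preset) == 1L &&
        preset %in% names(.founding_presets)))
    stop("'preset' must be one of ", paste(names(.founding_presets), collapse = ", "))
  structure(stats::setNames(as.integer(.founding_presets[[preset]]), saa_genotypes),
            class = "saa_composition",
            q = if (preset %in% names(.preset_q)) .preset_q[[preset]] else NA_real_,
            n_per_sex = 100)
}

#' @export
print.saa_composition <- function(x, ...) {
  cat("<saa_composition>", if (!is.na(attr(x, "q"))) sprintf("q = %.2f,", attr(x, "q")),
      sprintf("%d per sex\n", attr(x, "n_per_sex")))
  print(stats::setNames(as.integer(x), names(x)))
  cat("SAA X-chromosome percentage:", composition_percent(x), "\n")
  invisible(x)
}

#' SAA X-chromosome percentage of a composition
#'
#' The SAA allele frequency of a founding composition, in percent rounded to
#' the nearest integer. Each sex contributes its nominal census of X
#' chromosomes (`n_per_sex` males and `2 * n_per_sex` female copies): the
#' published percentages treat each sex at its intended census, ignoring the
#' one-fly residue that per-class rounding can leave.
#'
#' @param counts A `saa_composition` or named count vector over
#'   [saa_genotypes].
#' @param n_per_sex Nominal census per sex; defaults to the composition's own
#'   target, else to the realized per-sex maximum.
#' @return Integer percentage.
#' @examples
#' composition_percent(founding_composition("P8"))  # 85
#' @export
composition_percent <- function(counts, n_per_sex = NULL) {
  if (is.null(names(counts)) || !all(saa_genotypes %in% names(counts)))
    stop("'counts' must be named over all five genotype classes")
  if (is.null(n_per_sex)) n_per_sex <- attr(counts, "n_per_sex")
  if (is.null(n_per_sex))
    n_per_sex <- max(sum(counts[male_genotypes]), sum(counts[female_genotypes]))
  if (n_per_sex <= 0 || sum(counts) <= 0) stop("undefined frequency: empty composition")
  saa_x <- counts[["M_SAA"]] + 2 * counts[["F_SAA_SAA"]] + counts[["F_SAA_CTRL"]]
  as.integer(round_half_up(100 * saa_x / (3 * n_per_sex)))
}
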