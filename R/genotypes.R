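# X-linked biallelic genotype space and Mendelian transmission.

#' Genotype labels
#'
#' The five legal (sex, genotype) states at an X-linked biallelic locus
#' carrying a sexually antagonistic allele (SAA). Males are hemizygous, so
#' only two male states exist; females carry two X copies, giving three.
#' These fixed strings are the serialization labels used in every CSV/JSON
#' artifact the package reads or writes.
#'
#' @format Character vectors of genotype labels.
#' @export
saa_genotypes <- c("M_SAA", "M_CTRL", "F_SAA_SAA", "F_SAA_CTRL", "F_CTRL_CTRL")

#' @rdname saa_genotypes
#' @export
male_genotypes <- c("M_SAA", "M_CTRL")

#' @rdname saa_genotypes
#' @export
female_genotypes <- c("F_SAA_SAA", "F_SAA_CTRL", "F_CTRL_CTRL")

# P(maternal gamete carries SAA) by mother genotype
.maternal_saa_prob <- c(F_SAA_SAA = 1, F_SAA_CTRL = 0.5, F_CTRL_CTRL = 0)

#' Eye-colour phenotype of a genotype
#'
#' The SAA construct carries a white+ rescue in a white-mutant background:
#' SAA hemizygote males and SAA homozygote females have red eyes, heterozygote
#' females orange eyes, and all control (non-carrier) flies white eyes. The
#' mapping is a bijection between female genotypes and colours, so scored eye
#' colours identify female genotypes unambiguously; male red/white likewise.
#'
#' @param genotype Character vector of genotype labels (see [saa_genotypes]).
#' @return Character vector in `{"red", "orange", "white"}`.
#' @examples
#' phenotype_of("F_SAA_CTRL")  # "orange"
#' @export
phenotype_of <- function(genotype) {
  stopifnot(all(genotype %in% saa_genotypes))
  map <- c(M_SAA = "red", M_CTRL = "white", F_SAA_SAA = "red",
           F_SAA_CTRL = "orange", F_CTRL_CTRL = "white")
  unname(map[genotype])
}

#' Offspring genotype distribution of a cross
#'
#' Mendelian X-linked transmission for a father x mother cross: sons inherit
#' one maternal X (and the Y), daughters inherit the paternal X plus one
#' maternal X drawn at random. Sexes are equally likely at birth and
#' recombination between the deficiency and its eye-colour marker is taken
#' as zero, so the allele is transmitted as a unit.
#'
#' @param father Male genotype label ("M_SAA" or "M_CTRL").
#' @param mother Female genotype label.
#' @return Named numeric vector of probabilities over the five genotype
#'   states, summing to 1.
#' @examples
#' offspring_distribution("M_SAA", "F_SAA_CTRL")
#' @export
offspring_distribution <- function(father, mother) {
  if (!(is.character(father) && length(father) == 1L && father %in% male_genotypes))
    stop("invalid cross: 'father' must be one of ", paste(male_genotypes, collapse = ", "))
  if (!(is.character(mother) && length(mother) == 1L && mother %in% female_genotypes))
    stop("invalid cross: 'mother' must be one of ", paste(female_genotypes, collapse = ", "))
  p <- .maternal_saa_prob[[mother]]
  out <- c(M_SAA = 0.5 * p, M_CTRL = 0.5 * (1 - p),
           F_SAA_SAA = 0, F_SAA_CTRL = 0, F_CTRL_CTRL = 0)
  if (father == "M_SAA") {
    out["F_SAA_SAA"] <- 0.5 * p
    out["F_SAA_CTRL"] <- 0.5 * (1 - p)
  } else {
    out["F_SAA_CTRL"] <- 0.5 * p
    out["F_CTRL_CTRL"] <- 0.5 * (1 - p)
  }
  out
}

# 6 x 5 transmission kernel: row (father i, mother j) in father-major order,
# columns the five genotype classes. Fixed by Mendelian segregation; computed
# once at load time and reused by every recursion step.
.cross_kernel <- local({
  K <- matrix(0, 6, 5, dimnames = list(NULL, saa_genotypes))
  r <- 0
  for (fa in male_genotypes) for (mo in female_genotypes) {
    r <- r + 1
    K[r, ] <- offspring_distribution(fa, mo)
  }
  K
})

#' Population state at one generation
#'
#' Per-sex genotype frequencies at one discrete generation, optionally backed
#' by integer adult counts per sex. Frequencies must sum to 1 within each sex
#' (tolerance 1e-12).
#'
#' @param male_freqs Numeric length-2, frequencies of `M_SAA`, `M_CTRL`.
#' @param female_freqs Numeric length-3, frequencies of `F_SAA_SAA`,
#'   `F_SAA_CTRL`, `F_CTRL_CTRL`.
#' @param generation Non-negative integer generation index (experiments and
#'   model runs start at generation 1).
#' @param n_male,n_female Optional adult counts per sex, used to weight the
#'   sexes when computing the X-chromosome allele frequency.
#' @return An object of class `population_state`.
#' @export
population_state <- function(male_freqs, female_freqs, generation = 1,
                             n_male = NULL, n_female = NULL) {
  stopifnot(length(male_freqs) == 2L, length(female_freqs) == 3L,
            all(male_freqs >= 0), all(female_freqs >= 0),
            generation >= 0)
  if (abs(sum(male_freqs) - 1) > 1e-12)
    stop("male frequencies must sum to 1 (got ", sum(male_freqs), ")")
  if (abs(sum(female_freqs) - 1) > 1e-12)
    stop("female frequencies must sum to 1 (got ", sum(female_freqs), ")")
  structure(list(
    generation = as.integer(generation),
    male = stats::setNames(as.numeric(male_freqs), male_genotypes),
    female = stats::setNames(as.numeric(female_freqs), female_genotypes),
    n_male = if (is.null(n_male)) NULL else as.integer(n_male),
    n_female = if (is.null(n_female)) NULL else as.integer(n_female)
  ), class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat("<population_state> generation", x$generation, "\n")
  cat("  males  :", paste(sprintf("%s=%.4f", names(x$male), x$male), collapse = " "),
      if (!is.null(x$n_male)) sprintf("(n=%d)", x$n_male), "\n")
  cat("  females:", paste(sprintf("%s=%.4f", names(x$female), x$female), collapse = " "),
      if (!is.null(x$n_female)) sprintf("(n=%d)", x$n_female), "\n")
  cat("  SAA X-frequency:", format(x_allele_frequency(x), digits = 6), "\n")
  invisible(x)
}

#' Build a population state from genotype counts
#'
#' @param counts Named integer vector over (a subset of) [saa_genotypes];
#'   omitted classes count as zero.
#' @param generation Generation index.
#' @return A [population_state] with per-sex totals taken from the counts.
#' @examples
#' state_from_counts(c(M_SAA = 9, M_CTRL = 81, F_CTRL_CTRL = 100))
#' @export
state_from_counts <- function(counts, generation = 1) {
  stopifnot(!is.null(names(counts)))
  if (!all(names(counts) %in% saa_genotypes))
    stop("unknown genotype labels: ",
         paste(setdiff(names(counts), saa_genotypes), collapse = ", "))
  full <- stats::setNames(numeric(5), saa_genotypes)
  full[names(counts)] <- counts
  nm <- sum(full[male_genotypes]); nf <- sum(full[female_genotypes])
  if (nm <= 0 || nf <= 0) stop("both sexes must be present to form a population state")
  population_state(full[male_genotypes] / nm, full[female_genotypes] / nf,
                   generation = generation, n_male = nm, n_female = nf)
}

#' SAA frequency among X chromosomes
#'
#' Allele frequency denominated in X chromosomes: each male contributes one X,
#' each female two. Sexes are weighted by their actual adult counts when the
#' state carries them (so a 90 male / 100 female founding census is handled
#' correctly); with no counts the sexes are weighted equally.
#'
#' @param state A [population_state].
#' @return SAA frequency in `[0, 1]`.
#' @examples
#' x_allele_frequency(state_from_counts(
#'   c(M_SAA = 9, M_CTRL = 81, F_CTRL_CTRL = 100)))  # 9/290
#' @export
x_allele_frequency <- function(state) {
  stopifnot(inherits(state, "population_state"))
  nm <- if (is.null(state$n_male)) 1 else state$n_male
  nf <- if (is.null(state$n_female)) 1 else state$n_female
  if (nm + nf <= 0) stop("undefined frequency: no adults in either sex")
  (state$male[["M_SAA"]] * nm +
     (2 * state$female[["F_SAA_SAA"]] + state$female[["F_SAA_CTRL"]]) * nf) /
    (nm + 2 * nf)
}
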