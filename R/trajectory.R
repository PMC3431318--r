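# Turning observed cage data into SAA frequency trajectories and
# descriptive summaries.

#' SAA frequency trajectories from cage data
#'
#' Converts a cage dataset's scored eye-colour counts into per-line,
#' per-generation SAA X-chromosome frequencies: phenotypes are inverted to
#' genotype counts ([genotype_counts_from_phenotypes]) and the X-allele
#' frequency computed with the sexes weighted by their realized counts in
#' the sample. Generation 1 (the founding census, which has no scored
#' offspring) is taken from the adult table. By default frequencies come
#' from the 300 scored offspring — the observable the experiment records;
#' `source = "adults"` instead uses the reconstituted 100+100 adult census,
#' which differs only by rounding.
#'
#' @param dataset A `cage_dataset` (from [generate_experiment] or
#'   [read_cage_dataset]).
#' @param source "offspring" (default) or "adults".
#' @return Data frame `line`, `generation`, `saa_x_freq`.
#' @export
frequency_trajectory <- function(dataset, source = c("offspring", "adults")) {
  stopifnot(inherits(dataset, "cage_dataset"))
  source <- match.arg(source)
  if (source == "adults") {
    ad <- dataset$adults
    freq <- vapply(seq_len(nrow(ad)), function(i) {
      x_allele_frequency(state_from_counts(
        unlist(ad[i, saa_genotypes]), generation = ad$generation[i]))
    }, numeric(1))
    out <- data.frame(line = ad$line, generation = ad$generation,
                      saa_x_freq = freq)
  } else {
    off <- dataset$offspring
    pheno_cols <- c("males_red", "males_white", "females_red",
                    "females_orange", "females_white")
    freq <- vapply(seq_len(nrow(off)), function(i) {
      cts <- genotype_counts_from_phenotypes(unlist(off[i, pheno_cols]))
      x_allele_frequency(state_from_counts(cts, generation = off$generation[i]))
    }, numeric(1))
    founding <- dataset$adults[dataset$adults$generation == 1L, ]
    f0 <- vapply(seq_len(nrow(founding)), function(i) {
      x_allele_frequency(state_from_counts(unlist(founding[i, saa_genotypes])))
    }, numeric(1))
    out <- rbind(data.frame(line = founding$line, generation = 1L,
                            saa_x_freq = f0),
                 data.frame(line = off$line, generation = off$generation,
                            saa_x_freq = freq))
  }
  out <- out[order(out$line, out$generation), ]
  rownames(out) <- NULL
  out
}

#' Equilibrium estimate from the tail of a series
#'
#' Arithmetic mean of the last `window` frequencies of a series — the
#' descriptive analogue of "stabilized around 8%": once a trajectory has
#' plateaued, the tail mean estimates the equilibrium.
#'
#' @param series Numeric frequency vector, or a data frame with a
#'   `saa_x_freq` column ordered by generation (a single line).
#' @param window Number of trailing generations to average (default 5).
#' @return List: `mean`, `min`, `max` over the window, and `window`.
#' @export
equilibrium_estimate <- function(series, window = 5) {
  f <- if (is.data.frame(series)) series$saa_x_freq else as.numeric(series)
  if (window < 1) stop("'window' must be at least 1")
  if (window > length(f)) stop("'window' exceeds the series length")
  tail_f <- f[(length(f) - window + 1L):length(f)]
  list(mean = mean(tail_f), min = min(tail_f), max = max(tail_f),
       window = as.integer(window))
}

#' Frequency change per phase segment
#'
#' Splits a frequency series at the given generation breakpoints and reports
#' the end-minus-start frequency change of each segment with its sign — a
#' descriptive summary of rise / decline / plateau phases (the inferential
#' segmented-regression fits on the original data are out of scope here).
#'
#' @param series Data frame with `generation` and `saa_x_freq` (one line),
#'   or a numeric vector indexed by generation starting at 1.
#' @param breakpoints Increasing generation indices strictly inside the
#'   series range.
#' @return Data frame: `from`, `to`, `delta`, `sign` (+1/0/-1 with a 1e-3
#'   flatness tolerance) per segment.
#' @export
phase_deltas <- function(series, breakpoints) {
  if (is.data.frame(series)) {
    gen <- series$generation; f <- series$saa_x_freq
  } else {
    f <- as.numeric(series); gen <- seq_along(f)
  }
  if (length(breakpoints)) {
    if (is.unsorted(breakpoints, strictly = TRUE))
      stop("'breakpoints' must be strictly increasing")
    if (min(breakpoints) <= min(gen) || max(breakpoints) >= max(gen))
      stop("'breakpoints' must lie strictly inside the generation range")
    if (!all(breakpoints %in% gen)) stop("'breakpoints' must be observed generations")
  }
  bounds <- c(min(gen), breakpoints, max(gen))
  out <- data.frame(from = bounds[-length(bounds)], to = bounds[-1])
  out$delta <- f[match(out$to, gen)] - f[match(out$from, gen)]
  out$sign <- ifelse(abs(out$delta) < 1e-3, 0, sign(out$delta))
  out
}
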