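---
title: "Modeling the fate of an X-linked sexually antagonistic allele"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the fate of an X-linked sexually antagonistic allele}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saadyn)
```

## The biological setting

A sexually antagonistic allele (SAA) helps one sex and hurts the other.
`saadyn` models a specific engineered case in *Drosophila melanogaster*: an
X-linked variant that gives carrier males a mating advantage — but only in
the light, because the advantage works through vision — while sharply
reducing the fecundity of homozygous females. Because males are hemizygous,
the male benefit is always expressed; because the female cost is largely
recessive, it is almost never expressed while the allele is rare. Theory
predicts such an allele invades when rare, declines when common, and settles
at a protected interior equilibrium — and that the equilibrium collapses to
extinction if the male advantage is removed (for instance by keeping the
flies in permanent dark).

The allele is tracked through eye colour: SAA hemizygote males and
homozygous females have red eyes, heterozygous females orange, and
non-carriers white. Eye colour therefore identifies every female genotype
and both male genotypes, which is what makes cage experiments on this
system scoreable.

## The model

The population has five (sex, genotype) classes: males `M_SAA`, `M_CTRL`
and females `F_SAA_SAA`, `F_SAA_CTRL`, `F_CTRL_CTRL`. Generations are
discrete and non-overlapping; one recursion step is:

1. **Mating.** Every female mates exactly once. Within each female class,
   males are allocated in proportion to their frequencies tilted by the
   cycle-averaged advantage $w_\mathrm{eff}$: the share of matings between
   male class $i$ and female class $j$ is
   $\frac{w_i m_i}{\sum_k w_k m_k} f_j$ with $w_{SAA} = w_\mathrm{eff}$,
   $w_{CTRL} = 1$. Sperm competition between the genotypes is neutral, so
   single mating per female loses no generality for sired-offspring shares.
2. **Reproduction.** Each cross contributes offspring in proportion to its
   mean fecundity (a 2 × 3 father × mother table) with Mendelian X-linked
   segregation: sons receive a maternal X, daughters the paternal X plus a
   maternal X, sexes equally likely, no recombination between the allele
   and its eye-colour marker.
3. **Renormalization (deterministic model)** of the offspring pool within
   each sex — or, in the **stochastic model**, one multinomial draw of 300
   offspring from the pool's class proportions, mirroring the 300 larvae
   scored per cage generation.

The photophase advantage $w_\mathrm{photo}$ (an SAA male's mating weight
relative to a control male, in the light) is converted to
$w_\mathrm{eff}$ by averaging over the cycle. Matings split 0.402 : 0.598
between light and dark under 12 h : 12 h; for $L$ hours of light we scale
those propensities linearly by the light and dark durations,

$$p_L = \frac{0.402\,(L/12)}{0.402\,(L/12) + 0.598\,((24-L)/12)}, \qquad
w_\mathrm{eff} = p_L\, w_\mathrm{photo} + (1 - p_L),$$

which reproduces the three anchor cases exactly (12:12 gives weight 0.402 to
the photophase advantage; permanent dark gives none; permanent light gives
all of it) and interpolates linearly in between. This linear form is the
simplest rule consistent with those anchors; no claim is made about the
true diurnal mating schedule at other photoperiods.

Allele frequency is counted in X chromosomes — one per male, two per
female — with the sexes weighted by their actual adult counts when known.
A 90-male, 100-female founding census with 9 SAA males is therefore
9/290 ≈ 3.1%, the "3%" founding condition.

## Parameters and defaults

| parameter | meaning | default |
|---|---|---|
| `w_photo` | SAA male mating weight in light (control = 1) | 1 (no advantage); calibrated value `calibrated_w_photo` ≈ 1.9331 |
| `light_hours` | hours of light per 24 h | 12 |
| `light_dark_propensity` | mating share light : dark at 12:12 | 0.402, 0.598 |
| `female_fecundity` | relative offspring of SS / het / control females | 0.388, 0.9, 1 |
| `brood_size` | offspring per control-female mating | 30 |
| `sample_size` | offspring drawn per generation (stochastic) | 300 |
| `n_runs` | ensemble size | 100 |
| `max_generations` | equilibrium horizon | 1000 |
| `adult_census` | adults per sex per generation | 100 |

The female fecundities and the paired-trial male weights (1 vs 0.55 used in
founding compositions) are the published rudimentary estimates. `brood_size`
is chosen so that a 100-female cage produces an expected offspring pool near
3000, inside the 2500–5400 range the experiment reported
(`expected_pool_size()` checks any configuration against this).

## Calibration of the male advantage

The one load-bearing parameter that was never published numerically is the
cage-level photophase mating advantage (it was measured in cages and shown
only graphically). The package therefore documents a calibration: under the
default fecundities and a 12:12 cycle,

```{r}
calibrated_w_photo
p <- model_params(mating = mating_params(w_photo = calibrated_w_photo))
find_equilibrium(p, founding_composition("P1"))$equilibrium
```

the deterministic 1000-generation equilibrium is 0.126 — the 12.6%
equilibrium the original parameterized model predicted. The calibration can
be recomputed from scratch with `calibrate_male_advantage()` (the
equilibrium is monotone in `w_photo`, so the root is unique). Two things are
worth noting. First, this cage advantage (~1.9 : 1) is far below the 13 : 1
odds implied by one-on-one paired trials (26 wins in 28): in a cage of 200
flies an advantaged male still has to find females, so the realized
advantage is diluted. The two scales are deliberately kept apart in the API
— `w_photo` is the cage photophase weight; `w_eff` is derived, never set.
Second, because the fecundity table here is the default two-row table
rather than the unpublished measured cross means, the calibration makes the
equilibrium quantitatively right by construction, and everything *else*
(invasion when rare, decline when common, dark-regime extinction, the width
of stochastic bands) is then a genuine prediction of the parameterization.

With 300-offspring sampling the allele drifts; over 700 generations many
runs lose it entirely, so the ensemble's 95% percentile band at that horizon
is wide and its lower edge sits at zero while still containing the
deterministic equilibrium:

```{r, eval = FALSE}
ens <- run_ensemble(p, founding_composition("P1"), 700, seed = 1)
ens$summary[700, ]
```

Whether lost runs should be censored from the band is not specified by the
original description; `saadyn` keeps absorbed runs in the summary, which is
the conservative choice and the reason the band is wider than the published
0.05–0.20 interval.

## Numerical and design choices

* **Rounding of founding compositions** is nearest-integer, halves away from
  zero, per class independently — the only scheme consistent with the
  published female totals of 99 for the q = 0.5 and q = 0.9 compositions.
  One published cell (the q = 0.9 SAA-homozygote female count) is
  inconsistent with this or any half-rounding of the stated procedure
  (64.63 prints as 64); `hw_selection_composition()` follows the procedure
  (returning 65), while `founding_composition("P8")` preserves the published
  row verbatim.
* **Composition percentages** treat each sex at its nominal census (100
  males, 100 females → 300 X copies), ignoring the one-fly residue that
  per-class rounding can leave; this reproduces every published percentage.
  `x_allele_frequency()` by contrast always uses the realized counts.
* **Adult census reconciliation.** In the synthetic generator the rebuilt
  census must actually hold 100 flies per sex, so per-class rounding is
  followed by a largest-remainder adjustment. Published founding
  compositions are *not* reconciled (their totals of 99 are preserved);
  the two behaviors live in different functions on purpose.
* **Multinomial vs without-replacement sampling.** Drawing 300 offspring
  multinomially from pool proportions ignores the finiteness of the
  2500–5400 pool; the hypergeometric correction to variances is at most a
  few percent and is not applied.
* **Confidence bands** are percentile bands (2.5/97.5 across runs), not
  normal approximations; with absorbing boundaries the run distribution is
  far from Gaussian at long horizons.
* **Convergence** is declared when the per-generation frequency change
  stays below 1e-10 for 10 consecutive generations; equilibria are always
  reported at the full horizon regardless.
* **Generation indexing** starts at 1 at the founding census, matching the
  experimental convention.
* **Degenerate inputs**: a paired-trial estimate with a clean sweep returns
  0 or `Inf` with a warning rather than an error; a stochastic draw that
  loses an entire sex marks the line failed and holds its state rather than
  aborting an ensemble.

## What the synthetic generator does and does not emulate

`generate_experiment()` reproduces the observation *structure* of the cage
experiment: replicate lines, a founding composition, 300 genotype-scored
offspring per line per generation (reported as eye-colour counts per sex),
a reconstituted 100 + 100 adult census, per-generation light regimes, and
photophase spot-check mating observations drawn with SAA-win probability
$w_\mathrm{photo} m_{SAA} / (w_\mathrm{photo} m_{SAA} + m_{CTRL})$. The
default density of six observations per generation approximates the
experiment's 62 observations over ten generations.

It does not emulate: viability or development-time differences beyond the
fecundity scalars, ejaculate depletion or remating dynamics, scoring error
(an optional misclassification knob was considered and deliberately left
out of the default surface), overlapping generations, or density
dependence. Passing round-trip and recovery tests on synthetic data
therefore demonstrates the *bookkeeping* is exact and the estimators are
consistent under the model's own assumptions — not that the model captures
every force acting in a real cage. The original experiment's early
frequency overshoot relative to its model is exactly the kind of
discrepancy this generator cannot manufacture.

## Problem sizes used by the test suite

The suite runs ensembles of 100 runs at 23 and 700 generations, equilibrium
sweeps of a handful of 1000-generation deterministic runs, 2000-draw
sampling checks, 60-line drift designs, and a 25-replicate recovery study
of the spot-check weight estimator (about a thousand observations per
replicate). These sizes were chosen as the smallest at which the checked
statistics are stable; the full-scale study conditions (100-run ensembles,
1000-generation horizons, 300-offspring samples) are used wherever the
checked claim depends on them.

## Limitations

* The measured per-cross offspring means and the cage photophase advantage
  were never published numerically, so quantitative agreement with the
  published equilibrium rests on the documented calibration; only the
  qualitative dynamics are parameter-free predictions.
* The photoperiod interpolation is exact only at its three anchors.
* Frequencies estimated from 300 scored offspring carry binomial noise of
  roughly ±0.02 at the equilibrium; the package exposes both
  offspring-based and census-based trajectories, which differ by census
  rounding only.
* All machinery is single-locus and X-linked by construction; autosomal or
  multi-locus extensions are out of scope.
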