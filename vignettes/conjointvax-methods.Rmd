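---
title: "Methods: design, weighting, and estimation for vaccine-acceptance conjoints"
author: "conjointvax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: design, weighting, and estimation for vaccine-acceptance conjoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conjointvax)
```

## What the package models

A conjoint experiment on vaccine-hesitant respondents: each person
evaluates five hypothetical mass-vaccination scenarios whose five
attributes (vaccine producer, efficacy disclosure, endorser, distributor,
community uptake) are randomized independently within each scenario. The
outcomes after each scenario are a binary willingness-to-vaccinate item, a
months-to-wait item (reverse-coded so positive effects always mean greater
willingness), and four mechanism agreement items (spread would end
quickly; the respondent would not contract COVID-19; side effects
unlikely; the government acts in the public interest).

Three attributes carry a pure-control "unspecified" level that is
assignable **only in the first round**: once a respondent has seen a named
producer, a disclosed efficacy rate, or an uptake figure, showing them "no
information" on that dimension later would not be credible. Efficacy
disclosure is modeled as its own two-level dimension whose displayed value
is a deterministic function of the drawn producer (95% Pfizer, 70%
AstraZeneca-Oxford, 91% Gamaleya, 50% Sinovac); when the producer is
unspecified there is no rate to disclose, so disclosure is forced to its
control level. This coupling is the one deviation from a pure product
randomization and is carried through the probability model.

## Randomization

Assignment is blocked by country x prior-willingness stratum
(disagree-side / neutral / agree-side of the 5-point item) x age group
(18-29, 30-44, 45-59, 60+); the exact strata of the original fielded
design are not published, so both cuts are configurable arguments of
`make_blocks()`. Within every block, round, and dimension the engine draws
a balanced random permutation over the levels available in that round
(uniform probabilities by default; configurable per level in the catalog),
independently across dimensions. Balanced permutation gives near-exact
within-block balance while preserving the design probabilities and
independence across dimensions.

The religious-leader endorser is displayed as the respondent's
co-religious organization -- the Catholic archbishop for Catholics and
non-Evangelical others, the national Evangelical organization for
Evangelicals -- purely at display time; the underlying level and its
assignment probability are unchanged, and estimation always uses the
underlying level.

Randomness derives from one integer seed through per-(round, dimension)
substreams with a canonical respondent ordering, so regeneration under the
same seed is bit-identical and independent of input row order. (A
per-respondent substream rule would offer finer partial regeneration but
costs one RNG reseed per respondent-round-dimension, which is prohibitive
in R at realistic sizes; stability under a fixed seed is what the
guarantee requires.)

## Design-based weights

The joint assignment probability of a realized profile given its round is
the product of per-dimension factors over the levels available in that
round, with the efficacy factor conditional on the producer. Under the
default catalog a fully specified round-1 profile has probability
1/5 x 1/2 x 1/6 x 1/3 x 1/5 = 1/900, a round-1 pure-control profile 1/450,
and any later-round profile 1/288. `compute_ipw()` attaches weights
proportional to the inverse probability, normalized to mean one (so
weighting does not rescale variance bookkeeping; sum-to-n would be
equivalent). Probabilities are always computed analytically from the
catalog; `empirical_assignment_freq()` provides the observed-frequency
comparison as a diagnostic only.

What the weights do and do not do: within round 1 they equalize the mass
of the nine valid producer-by-disclosure cells (unweighted, the forced
pure-control cell carries twice the mass of each specified cell), and
pooled across rounds they keep the composition of always-available levels
exactly uniform. No row weighting can equalize a round-1-only level with
levels that occur in all five rounds -- a level absent from rounds 2-5
cannot be conjured there -- so pooled frequencies of the unspecified
levels remain below 1/L by construction. The weights' purpose is to
correct the round-composition of the comparisons entering the regression,
not to equalize marginal level counts.

## Estimation

`fit_amce()` estimates, by weighted least squares,

Y_irc = a_brc + b_r Ypre_ic + g_i + sum tau' X_irc + e_irc,

where a_brc are block x round x country fixed effects, g_i respondent
fixed effects, and the treatment block contains 19 dummies under the
default catalog: 4 producers vs unspecified, 4 producer-by-efficacy
interactions, 5 endorsers vs the medical association, 2 distributors vs
the public healthcare system, 4 uptake rates vs unspecified. Because the
pre-treatment willingness item Ypre is respondent-constant, its main
effect is absorbed by g_i; only its round-varying part is identified, so
b_r enters as interactions of Ypre with round indicators (first round
omitted). Without respondent fixed effects (`fe = "cell"`/`"none"`) the
main effect is included as well.

Both fixed-effect groups are absorbed by alternating weighted group
demeaning (`within_transform()`), iterated to a 1e-10 fixed point; no
installed package provides high-dimensional fixed-effect absorption, and
the algorithm is a dozen lines of `rowsum()` arithmetic. On fixtures the
absorbed estimator is tested to agree with explicit-dummy `lm()` to 1e-8
relative error.

Collinearity is detected by an in-order Gram-matrix sweep (tolerance 1e-9
relative): columns are ordered treatment, interaction, control, so the
sweep drops the later member of a collinear pair. A dropped control is a
logged warning; a dropped treatment dummy is an error, because silently
losing a requested estimate would corrupt downstream tables.

### Inference

Standard errors are cluster-robust at the respondent level with the CR1
multiplier G/(G-1) x (N-1)/(N-K). K counts the estimated columns plus the
rank of the absorbed fixed-effect space, computed exactly via a union-find
over the bipartite respondent/cell graph -- with one convention choice:
fixed effects nested within clusters (respondent effects under respondent
clustering) are excluded from K by default (`df_fe = "nested"`). Counting
them makes the correction grow with the number of respondents and inflates
standard errors by ~16% at five rounds per respondent, which a 2000-replicate
null simulation showed as 95-99% coverage; excluding them restores
0.94-0.96 coverage for every treatment term. `df_fe = "all"` reproduces
the explicit-dummy software convention and is used in the oracle
equivalence tests. Confidence intervals use normal critical values
(two-tailed, 95% by default); Student-t with G-1 degrees of freedom is
available by flag and is indistinguishable at realistic cluster counts.

### Heterogeneous effects and marginal means

`fit_heterogeneous()` adds interactions of treatment dummies with a
moderator. For trust moderation, each producer, endorser, and distributor
dummy is interacted with the respondent's 1-4 trust score in *that* actor
(trust in the producer's country, the endorsing actor, the distributing
institution); producer-by-efficacy and uptake terms are not interacted.
Raw (uncentered) trust values are used, so interaction coefficients read
as the change in an effect per one-unit trust increase; centering would
change only the main effects, which respondent fixed effects absorb
anyway. For a respondent-trait moderator every treatment dummy is
interacted, and the trait's main effect is included whenever respondent
fixed effects do not absorb it. A constant moderator makes the
interactions collinear; they are flagged and dropped with a warning.

`marginal_means()` reports the IPW-weighted mean outcome per attribute
level with a cluster-linearized ratio-estimator standard error; empty
cells are flagged missing rather than imputed as zero.

### First-round robustness

`first_round_robustness()` refits on round-1 rows only: one row per
respondent, so respondent fixed effects are dropped (block cells remain)
and Ypre enters as a main effect. Design weights are kept, renormalized
within the subset, because round-1 probabilities still differ across
profiles through the producer/disclosure coupling; the round-composition
correction the pooled weights perform is moot with a single round.
Metadata flags the restriction. Divergence between pooled and first-round
estimates signals carryover (a stability/SUTVA violation); with
history-dependent effects the pooled within-respondent estimator is
contaminated in ways that need not even match the sign of the planted
carryover, which is exactly why the first-round comparison is the right
screen.

## Diagnostics

`balance_test()` regresses each pre-treatment covariate on all 19
treatment dummies (weighted, respondent-clustered) and reports per-term
z-tests plus a joint Wald chi-square per covariate; the fielded study's
exact supplementary specification is unavailable, so both granularities
are reported. `attrition_test()` regresses an indicator of dropping out
after round r on the round-r attributes -- attrition orthogonal to the
just-shown scenario supports ignorability -- and reports a vacuous-test
note when there is no attrition. Diagnostics never mutate their input.

## The synthetic-data generator

The generator exists so every estimator and diagnostic has a known truth
to recover; it is a first-class module, not a test fixture.

* **Population.** Six countries, configurable n per country; age uniform
  18-80 (with a 0.1% sliver of minors for screening emulation); religion
  with a configurable Evangelical share (default 25% in Brazil, 15%
  elsewhere, Catholic 60%); presidential co-partisanship 36% Brazil, 31%
  Mexico, 11% elsewhere; independent 1-4 trust scores per actor (default
  mass 0.25/0.35/0.25/0.15, reflecting a low-trust hesitant-leaning
  panel); a 5-point prior willingness item (10/15/16/28/31%) with intended
  wait drawn Poisson with willingness-dependent mean (9, 8, 5.5, 2.5, 1.5
  months, capped at 24). These defaults reproduce the recruited panel's
  stated funnel: ~40% acceptant (agree/strongly agree and wait <= 2
  months), ~59% hesitant retained, mean intended wait ~4.2 months.
  Survey metadata (log-normal duration with median 26 min, 0.1% attention
  failures) feed `apply_screening()`, whose rules run in the study's
  order: acceptant, under-18, attention, under-10-minutes.
* **Responses.** Linear-probability model: willingness probability = p0 +
  sum of level effects + actor-matched trust moderation + respondent
  random effect (SD 0.15), clipped to [0.01, 0.99] with the clipped share
  counted (warning above 2% of rows, error above 10%). A linear rather
  than logistic index makes the preset constants exactly the AMCEs, giving
  a clean recovery target. Trust slopes multiply (trust - population mean
  trust): pinning the effect to any particular trust value is a centering
  convention, and centering at the mean keeps the preset level effects
  equal to the population-average AMCEs the estimator targets
  (interaction slopes are centering-invariant). Months-to-wait is Poisson
  with mean = 5 - 6 x (the same linear index), floored at 0.1 and capped
  at 12 -- the cap reflects the survey instrument's bounded response; the
  shared index makes months and willingness negatively associated, as a
  coherent respondent requires. Mechanism items are the index scaled by
  1.5 plus N(0, 0.8) noise, rounded onto a 1-5 agreement scale.
* **Presets.** `"paper"` sets the level effects to the published point
  estimates (Sinovac -0.11, Gamaleya -0.054, Pfizer +0.025, AstraZeneca
  +0.021; disclosure interactions +0.059 Pfizer and +0.076 Gamaleya;
  endorsers -0.037 to -0.068; distributors -0.017/-0.021; uptake -0.027
  to +0.053; baseline willingness 0.52). Four quantities the study
  describes only qualitatively are fixed once at plausible magnitudes:
  uptake-25% +0.005 (monotone between its neighbors), AstraZeneca x
  efficacy -0.010 ("slightly reduced", not significant), Sinovac x
  efficacy -0.040 ("further reduced"), and trust slopes 0.06/0.03/0.02
  per unit for producers/endorsers/distributors (a high-trust respondent
  gains roughly a third of baseline willingness toward that producer's
  vaccine). `"null"` zeroes everything at p0 = 0.5 for size and coverage
  studies. `"carryover"` shifts the Sinovac effect by +0.15 after first
  exposure; `"attrition"` adds 5% per-round dropout plus 10% after Sinovac
  scenarios.

### What the generator does not emulate

Real panel behavior beyond the duration screen (speeders, straight-lining,
item nonresponse), country-specific attribute labels beyond a display map,
correlation between trust scores and religion or education, non-linear or
interactive preference structures beyond the trust moderation, and any
survey-weighting to census margins. Passing recovery tests therefore shows
the estimator is correct *under the stated potential-outcomes model*, not
that the substantive published estimates are right; the replication data
for that exercise are deposited publicly, and the estimator accepts any
long-format CSV with the documented schema.

## Numerical choices and problem sizes

Within-transform tolerance 1e-10 (max absolute update), at most 1000
sweeps; collinearity tolerance 1e-9 relative; probability clipping bounds
[0.01, 0.99]; CR1 with nested-FE exclusion as above. Monte Carlo studies
in the test suite use consecutive integer seeds from 1: AMCE recovery runs
200 replicates at ~1000 respondents x 5 rounds (every mean estimate within
0.01 probability points of truth), interval coverage runs 2000 null-DGP
replicates at the same size (a 500-replicate check of a +/-0.02 band on 19
terms simultaneously would be dominated by its own binomial noise),
balance size runs 500 replicates, balance power 25 replicates at 4000
respondents, and the round-constraint/weighting checks use a single
~50,000-row study. The acceptance script simulates 10,000 hesitant
respondents per country so that single-draw recovery error is small
relative to the published magnitudes.

## Known limitations

* The months outcome's original top-coding and "never" coding are not
  published; the generator caps at 12 and the reader accepts any
  nonnegative numeric.
* CR1 with normal critical values is mildly anti-conservative for the
  producer contrasts, whose pure-control comparisons draw on the ~20% of
  respondents with a round-1 unspecified producer (observed coverage
  ~0.94 at 1000 respondents); cluster-bootstrap or CR2/CR3 corrections
  are out of scope.
* With history-dependent effects (carryover), pooled two-way fixed-effects
  AMCEs are not a weighted average of the planted per-round effects; the
  package's answer is the first-round estimate, not a dynamic model.
* Balance and attrition regressions use the same linear machinery as the
  main fit; survival-style attrition models are out of scope.
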