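---
title: "Methods and design notes for the msrs validation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for the msrs validation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msrs)
```

This vignette records the statistical model behind each pipeline stage, the
parameters that matter and why their defaults are what they are, what the
synthetic generator does and does not emulate, and the numerical choices
made where the design was genuinely open. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The measurement model

A survey is one rater's 36 ordinal answers (1–4) about one monkey. Items
are worded in both directions to control response bias; reverse-keyed items
are flipped at scoring (`4 − r` instead of `r − 1`) so that high scores
always mean greater social impairment. A complete survey totals 0–108.

Which items are reverse-keyed is *data*, not code: the packaged
questionnaire (`default_questionnaire()`) carries a `reverse_keyed` flag
per item and every analysis parameterizes on the questionnaire it is
given. The packaged file is a synthetic stand-in (the instrument's own
supplementary item list is not redistributed here), which is why its
filename says so.

**Missing answers.** Raters may skip items they cannot judge. Skips are
kept as explicit `NA` from file to analysis; nothing is imputed at load
time. Totals follow one of two policies: `strict` (any skip makes the
total undefined) or `prorate` (`round(n_items * mean(answered))`,
half-up). `strict` is the default for scoring because the source
instrument is silent on skipped-item totals; reliability stages use
`prorate` so that a single skip does not discard a whole survey.

## 2. Score distribution

Per-monkey scores are the mean of that monkey's survey totals (the
collapse rule is configurable — `mean`, `median`, `first` — because
surveys-per-monkey varies and no canonical rule exists). The summary
reports:

* mean and SD (n−1 denominator);
* skewness, default `g1 = m3 / m2^(3/2)` — the biased moment estimator,
  which is what the common statistics toolboxes print — with the
  bias-corrected `G1` behind a flag;
* a Lilliefors normality test;
* upper outliers: scores strictly greater than `mean + k·SD`, default
  `k = 2`. The rule is one-sided and strict by design ("greater than two
  standard deviations above the mean" reads as an upper-tail rule).

**Lilliefors test.** The statistic is the sup-distance between the ECDF
and the normal CDF with mean and SD estimated from the sample, evaluated
on both sides of every jump. Because parameters are estimated, standard KS
tables are wrong; p-values come from a Monte-Carlo null — `n_mc` standard
normal samples of the same size, the statistic recomputed with per-sample
estimates, and `p = (1 + #{D* ≥ D}) / (n_mc + 1)`. Defaults: `n_mc =
10000`, seeded. The null table depends only on `n`, so callers running
many tests at one sample size can precompute it (`lilliefors_null()`) and
pass it in; the acceptance suite uses this to verify the 5% type-I error
over 2,000 null datasets within ±1 point.

## 3. Reliability

**Inter-rater ICC.** Two-way mixed, *average-measures* intraclass
correlation from the subjects × raters ANOVA mean squares. Both
average-measures flavors are implemented, and every report records which
was used: `consistency` (C-k, `(MSR − MSE)/MSR`) is the default because
rater mean offsets are irrelevant when raters are a fixed panel;
`absolute` (A-k) adds the rater variance term.

In the sparse main design most rater pairs share no monkeys, so ICCs are
computed per qualifying pair (≥ `min_shared` shared monkeys, default 3 —
below that the ANOVA is numerically meaningless). Two rating units are
supported:

* `scores = "totals"` — the two raters' survey totals over shared monkeys.
  This is the stricter reading but is *explosive* on tiny shared sets: C-k
  is unbounded below, and when 3 shared monkeys happen to have similar
  true scores, `MSR ≈ 0` and the estimate can be −100 or worse. The
  package reports such values as they are.
* `scores = "items"` — concatenated (monkey, item) score pairs. With 36
  items per shared monkey the pair matrix has ≥ 108 rows, the estimate is
  stable, and in the generator's world the per-pair values land in the
  0.5–0.9 range typical of published rater-reliability tables. This is the
  reading most consistent with "reliability of raters on the 36-item
  survey", and the acceptance report uses it as the headline pairwise
  figure while also reporting the totals-based mean.

**Item-level reliability.** For a complete block of raters who all rated
the same monkeys, Cronbach's alpha is computed per item with raters as the
parallel measurements and monkeys as cases (complete cases per item).
Alpha is negative when raters are anti-correlated. The filter feeding the
factor analysis retains items with positive alpha *and* nonzero variance;
zero-variance items (alpha undefined) and negative-alpha items are
excluded and listed separately.

## 4. Factor analysis

EFA runs on the survey-level item-score matrix of retained items
(complete-case rows).

**Retention.** Eigenvalues of the Pearson correlation matrix; rows are
resampled with replacement (`n_boot`, default 10,000; < 100 refused),
ordered eigenvalues recorded per replicate, percentile 95% CIs taken per
order statistic, and factors retained while the lower bound exceeds 1 — a
bootstrap-hardened Kaiser rule.

*Known anti-conservatism.* The rule's CIs are centered on the *sample*
ordered eigenvalues, and the largest sample eigenvalue of pure-noise data
exceeds 1 at any n (the Marchenko–Pastur edge is `(1 + sqrt(p/n))^2`), so
on data containing items with near-unit uniqueness the rule will retain
one or two spurious factors regardless of sample size — on exactly
identity-correlated data it can never return zero. The implementation is
faithful to the stated rule; tests assert the real behavior, and users
should read `n_retained` as an upper bound when low-communality items are
present. Parallel analysis would fix this but is a different rule and is
out of scope.

**Extraction and rotation.** Maximum likelihood on the correlation matrix
(`factanal`-style, single deterministic start; uniquenesses bounded to
[0.005, 1], a bound hit is a clamped Heywood case and warns). Varimax
rotation uses the classical Kaiser cyclic pairwise algorithm with the
closed-form angle `4θ = atan2(D − 2AB/p, C − (A² − B²)/p)`; the
gradient-projection fixed point used by some implementations stalls short
of the optimum on symmetric two-cluster loading patterns, which is why the
pairwise form is used here. Kaiser row normalization is on by default.
Factors are ordered by explained variance with column sums made positive;
percent variance per factor is `100 · Σ loadings² / p`.

**Bootstrap loadings.** Each resample is refit and rotated, then aligned
to the full-sample solution: greedy one-to-one matching by maximal
absolute Tucker congruence, sign-flipping a column when its congruence is
negative. Greedy matching (rather than Procrustes) keeps the replicate's
rotated axes intact and only resolves the label/sign indeterminacy, which
is the stated intent of reporting *median bootstrapped loadings*.
Replicates that fail to converge or resample a constant column are redrawn
and counted; more than 20% failures aborts. Per cell the report gives the
median and percentile 2.5/97.5 bounds; significance is strict CI exclusion
of zero (an interval touching zero is not significant). Identical seeds
give bit-identical summaries.

## 5. Demographic associations

Spearman's rho is the Pearson correlation of midranks; p-values use the t
approximation, or the exact AS 89 distribution for n ≤ 10 without ties.
Group summaries give mean, SEM and n by rank thirds (low/middle/high,
"unknown" kept separate) or sex. The source study's General Linear Model
is deliberately not reproduced: its printed degrees of freedom imply a
factor coding that cannot be reconstructed from the text, so the module
stops at the rank-based statistics.

## 6. The synthetic generator

`simulate_survey()` draws a world with known truth:

* Monkey `m` has factor scores `η_m ~ MVN(0, Σ)`; item `i`'s latent is
  `y*_{m,i} = λ_i·η_m + ε_{m,i}` with uniqueness `1 − ‖λ_i‖²` (floored at
  0.05). Demographic structure (a per-year age effect and rank-level
  shifts) and a small contaminant subpopulation (elevated scores, the
  source of the positive tail and the `> 2 SD` outliers) act on factor 1.
* Rater `r` observes `y* + u`, `u ~ N(0, sd_r²)`, discretized by fixed
  thresholds (default `{−1, 0.5, 1.5}`, a right-skewed response mix
  matching a low-pathology population) to 1–4. Reverse-keyed items are
  emitted flipped so that scoring un-flips them; zero-variance items emit
  a constant; responses are blanked at `missing_rate`.
* Three item classes: *loaded* (nonzero `λ` row), *zero-variance*, and
  *unreliable*. Unreliable items carry no factor signal. In the sparse
  sample they are rater-specific independent noise; in the complete block
  the per-monkey value's sign alternates with rater parity, making the
  block's item columns anti-correlated and the item's alpha strictly
  negative. Purely independent noise would put alpha near 0 with a random
  sign on a 16-monkey block, so the anti-correlated mechanism is what
  makes "the retained set equals the 17 reliable items by construction"
  actually hold; the parity trick is confined to the block because at the
  survey-total level it would anti-correlate whole rater pairs, which the
  sparse sample should not exhibit.

`paperlike_preset()` fixes the canonical world: 105 monkeys / 15 raters /
175 surveys (each monkey rated once or twice, second raters drawn from
ring-neighbors so a realistic subset of pairs share ≥ 3 monkeys), plus a
separate complete 4 × 16 all-female block; 36 items split 17 reliable
(12 on factor 1 — items 2 and 5 negatively — 3 on factor 2, 2 on factor 3
with mild cross-loadings), 14 unreliable, 5 zero-variance (7, 19, 24, 25,
30); ~1% skips; 6 contaminants (+2.2 SD on factor 1); rank ordering
low > middle > high (0.8/0.4/0); age effect 0.06 per year, calibrated so
the age–score Spearman correlation is of the order the instrument's
validation reported (~0.2). The anti-correlation scale 1.3 gives per-item
alpha a comfortable negative margin across seeds at block size 16.

What the generator does **not** emulate: pedigree/matriline structure,
rater drift over time, differential item difficulty beyond the shared
thresholds, and any dependence of skipping on the true score (missingness
is completely at random). A green pipeline run on this world therefore
establishes internal correctness of the statistics and the recovery of a
known structure — not that real mSRS data satisfies the model.

## 7. Numerical choices and degenerate inputs

* Totals round half-up in proration; scores are integers 0–3.
* `distribution_summary` requires n ≥ 4; constant vectors report SD 0,
  undefined skewness, no outliers, and an undefined normality test.
* ICC requires a 2 × 2 matrix minimum; zero total variance errors.
* Alpha returns a flagged `NA` on zero total-score variance.
* `correlation_eigenvalues` refuses constant columns, naming the item.
* Bootstrap resamples that produce a constant column are redrawn (eigen
  stage) or counted as failures (loading stage).
* All stochastic stages take explicit seeds; the pipeline derives per-stage
  substreams from one master seed so stages can be re-run in isolation.
* JSON output is written with full precision (`digits = NA`).

## 8. Known limitations

* The retention rule's anti-conservatism on low-communality data (above).
* ML extraction becomes ill-conditioned as uniquenesses approach zero;
  the degenerate-bootstrap identity (medians ≈ point estimates) is
  therefore checked at small-but-nonzero noise.
* Totals-based pairwise ICCs on minimal shared sets are unstable by
  nature; prefer `scores = "items"` when shared sets are small.
* XLSX files are read (via readxl) but not written; round-trip guarantees
  cover CSV/TSV.
* The packaged questionnaire's reverse-key set is a synthetic stand-in;
  analyses of real data must supply the true instrument definition.
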