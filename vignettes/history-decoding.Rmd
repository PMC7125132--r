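---
title: "Decoding prospective metacognitive decisions from trial history"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding prospective metacognitive decisions from trial history}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metalag)
```

## The scientific question

In near-threshold psychophysics, observers can be asked — *before* each
trial — for a prospective metacognitive judgment: a belief that they will
succeed on the upcoming discrimination, or a decision about how much
attention to engage. `metalag` implements a complete analysis pipeline for
asking what information from *recent trials* shapes that prospective
decision: the correctness of the previous response, the reported awareness
of the previous stimulus, and the retrospective confidence in the previous
response, considered at lags 1–4 (each lag in isolation).

The pipeline has five stages:

1. **Synthetic data** — a generative model of a full multi-subject session
   with known ground-truth history weights, so every downstream estimator
   can be validated by parameter recovery.
2. **Trial I/O** — a validated CSV exchange format and the participant
   exclusion rules used with this paradigm.
3. **History decoding** — per-subject shuffle-split cross-validated
   logistic classification of the prospective decision from the lag-k
   feature triplet, scored by ROC AUC against a permutation-based
   empirical chance level, with sign-flip group inference, odds-ratio
   attribution, and univariate conditional-probability summaries.
4. **Signal detection** — type-1 d′/criterion and maximum-likelihood
   meta-d′ (with M-ratio) inside each cell of the awareness ×
   prospective-decision 2×2.
5. **Transfer decoding** — train the decoder on one prospective-decision
   type and test it on the other, quantifying shared structure.

## The generative model

Each simulated trial draws, independently of history:

* a stimulus $s \in \{\text{left}, \text{right}\}$ with equal probability
  (left is coded $+1$ and serves as S1 throughout);
* an awareness state $a \sim \mathrm{Bernoulli}(p_\text{aware})$,
  exogenous by design: the experimental staircase holds the awareness rate
  near 0.5, and an exogenous coin reproduces exactly that while leaving
  the awareness–correctness association tunable through the sensitivity
  gap below;
* an evidence sample $e \sim \mathcal{N}(s\,d/2,\,1)$ where
  $d = d'_\text{aware}$ on aware trials and $d'_\text{unaware}$ otherwise;
  the orientation response is $\mathrm{sign}(e - c)$ with type-1 criterion
  $c$;
* a high-confidence rating when
  $|e - c| + \varepsilon > \theta - a\,\delta$, with
  $\varepsilon \sim \mathcal{N}(0, \sigma_c)$. Absolute evidence couples
  confidence to correctness; the awareness-dependent threshold shift
  $\delta$ couples confidence to awareness. This is the simplest mechanism
  that produces all three pairwise feature associations simultaneously.

The prospective decision before trial $t$ is then Bernoulli with log-odds

$$
\beta_0 + \sum_{k=1}^{4} \sum_{f} \beta_{k,f}\,(x_{f,t-k} - 0.5),
$$

over the lagged binary features $f \in$ {correctness, awareness,
confidence} (plus an autoregressive term on past prospective decisions,
available in the configuration but zero by default, since the phenomenon
under study is feature-mediated history dependence). Predictors are
centered at 0.5 so that absent history contributes zero log-odds and
$\beta_0 = 0$ yields a 0.5 base rate; warm-up trials equal to the longest
active lag are simulated and discarded so every retained trial has a full
history.

### Default calibration

The defaults describe a belief-of-success experiment of 15 subjects × 12
blocks × 50 trials:

| parameter | default | role |
|---|---|---|
| `p_aware` | 0.5 | staircase-stabilised awareness rate |
| `dprime_aware` / `dprime_unaware` | 1.2 / 0.3 | type-1 sensitivity by awareness state |
| `conf_threshold` $\theta$ | 0.95 | confidence cut on absolute evidence |
| `conf_noise_sd` $\sigma_c$ | 0.3 | confidence noise |
| `conf_aware_shift` $\delta$ | 0.3 | threshold reduction when aware |
| `beta` lag 1 | $\log 3$ (awareness, confidence), $\log 1.2$ (correctness) | dominant lag-1 history weights |
| decay | 0.5 per lag | geometric fall-off over lags 2–4 |

The three confidence parameters were fixed once, by matching the
across-subject mean phi correlations of the three feature pairs to the
values reported for this paradigm (awareness–confidence ≈ 0.22,
correctness–awareness ≈ 0.23, correctness–confidence ≈ 0.17); with the
default sensitivities the model yields ≈ 0.23 / 0.17 / 0.17. The lag-1
odds ratio of 3 for awareness and confidence mirrors the reported effect
size ("over 3 times more likely"), and the geometric decay reproduces
decodability that falls off smoothly with lag.

```{r calibration}
tab <- simulate_experiment(generator_config(n_subjects = 15, seed = 1))
summarize_calibration(tab)
```

### What the generator does and does not emulate

It emulates: binary feature coding, the ≈0.5 prospective base rate and
awareness rate, the magnitude and decay of lagged history dependence, the
awareness-dependent sensitivity gap, and the pairwise feature
associations. It does **not** emulate: between-subject heterogeneity in
any parameter (every simulated subject shares one configuration, so
across-subject SDs are much smaller than in real data), reaction times,
staircase dynamics, graded confidence/awareness scales, slow drifts in
criterion or vigilance, or subject-idiosyncratic long-lag structure.
Passing tests therefore certify the *estimators* — not that real data
behave this way. The last omission matters for transfer decoding (below).

## The decoding pipeline

For one subject and lag $k$, the design pairs the feature triplet of trial
$t-k$ with the prospective decision of trial $t$ over the concatenated
session (block boundaries are not breaks by default; a `within_block`
switch restricts pairs for sensitivity analysis). Decoding uses an
**unpenalised** logistic regression — the maximum-likelihood limit of a
classifier whose regularisation is made negligible so its coefficients
remain interpretable as log-odds — under 100-fold shuffle-split
cross-validation: each fold holds out a random 20%, and probabilistic
predictions are scored by rank-based ROC AUC (ties count one half). Splits
that lack a target class on either side are re-drawn (at most 1000
attempts). Because the features are three binary variables, each fit is
aggregated over the at most 8 distinct feature patterns as a weighted
binomial GLM — algebraically identical to the row-wise fit (a unit test
asserts equality) and fast enough to sit inside the permutation loops.

Chance is estimated *empirically*: feature rows and target entries are
permuted independently and the full cross-validation is re-run, 100 times;
the mean of the resulting AUCs is the chance level, which sits at 0.5 for
calibrated data. Group-level significance per lag uses a sign-flip
permutation test on subject-level (AUC − chance) differences with the
add-one correction $p = (1 + \#\{|\bar{x}^*| \ge |\bar{x}|\})/(1 + B)$,
Bonferroni-corrected over lags. Note the resolution floor: with $n$
subjects a one-sample sign-flip test cannot go below $\approx 2/2^n$.

Attribution exponentiates the fold-averaged coefficients into odds ratios
(a full-data refit is exported alongside; the two agree closely), with
percentile bootstrap CIs across subjects (1000 resamples). Univariate
summaries report $P(\text{prospective}=\text{high} \mid
\text{correct}_{t-1}, \text{aware}_{t-1}, \text{conf}_{t-1})$ per subject
and cell, in long format ready for repeated-measures machinery elsewhere.

```{r decode}
dec <- decode_table(tab, lags = 1:2, n_splits = 20, n_permutations = 20,
                    seed = 2)
dec
group_significance(dec, seed = 3)
```

## Signal-detection estimation

Within each awareness × prospective cell, type-1 sensitivity uses the
left-stimulus-as-signal convention: $d' = z(\mathrm{HR}) -
z(\mathrm{FAR})$, $c = -\tfrac12(z(\mathrm{HR}) + z(\mathrm{FAR}))$.
Metacognitive sensitivity is **meta-d′**: the type-1 sensitivity an
SDT-ideal observer would need to produce the observed type-2 (confidence)
data. It is estimated by maximum likelihood of the confidence outcomes
*conditional on each stimulus × response cell* under an equal-variance
Gaussian model in which the type-1 criterion is rescaled proportionally
($c' = c \cdot \text{meta-}d'/d'$) and one type-2 criterion per response
side is fitted jointly (L-BFGS-B, meta-d′ bounded to $[-5, 5]$, two
starting points). Conditioning on the response cell is essential — it is
what prevents type-1 performance from leaking into the metacognitive
estimate. A profile grid search (`meta_d_grid()`, 0.001 steps) provides an
optimizer-independent oracle and agrees with the ML fit to < 0.01 on all
fixtures.

Numerical choices: every one of the 8 counts cells is padded by
$1/(2 \times 4)$ before estimation (4 response categories per stimulus),
preventing degenerate rates; cell probabilities are floored at $10^{-12}$;
the M-ratio meta-d′/d′ is flagged undefined when $|d'| < 0.1$, because the
ratio explodes as task sensitivity vanishes — a regime in which this
efficiency index is best treated with caution anyway. Empty cells in the
2×2 grid propagate as missing rows, never imputed.

```{r sdt}
head(condition_sdt_grid(tab), 4)
```

## Transfer decoding

To ask whether two prospective-decision types share representational
structure, all subjects of each experiment are pooled (pooling precedes
splitting by design; a subject-blocked variant is available through the
same machinery), and each of 100 iterations trains on a random 80% of the
source pool and tests on a random 20% of the target pool. Significance
re-uses the independently-shuffled permutation null applied to the target
design.

A caution from the generator's design: when both simulated experiments
share the default decaying weights, transfer is above chance at *every*
lag with nonzero weight, because pooled designs of ~9000 rows detect even
an odds ratio of 1.3. Real datasets show transfer only from the
immediately preceding trial; reproducing that specific pattern would
require long-lag structure that is subject-idiosyncratic (so it survives
within-subject decoding but not pooled transfer), which this generator
deliberately does not model. The package's tests assert the shared-weight
predictions — above-chance transfer at lag 1, monotone degradation toward
chance with lag — and this discrepancy is documented rather than patched.

## Orchestration and reproducibility

`run_full_analysis()` chains every stage from two generator
configurations, writing all tables as CSV plus a JSON manifest (package
version, seeds, configuration, exclusions, collected warnings). A single
mandatory master seed deterministically derives every substream (subject
simulation, splits, permutations, bootstraps), so a config + seed pair
reproduces byte-identical outputs; there is no silent nondeterminism
anywhere in the pipeline. A `fast` mode (20 splits / 20 permutations / 20
transfer iterations) exists for quick runs; published-scale analyses use
100 of each. The vignette and test suite run reduced problem sizes
(e.g. 5–15 subjects, 20-fold loops) chosen so each property remains
testable at comfortable Monte-Carlo error.

## Known limitations

* Homogeneous subjects: across-subject variances are unrealistically
  small; group-level CIs on synthetic data are tighter than real ones.
* Binary ratings only; no graded confidence, hence a single type-2
  criterion per side.
* meta-d′ here is the classical single-subject ML variant — no
  hierarchical pooling, unequal-variance, or response-specific versions.
* The permutation-based transfer p-value is one convention among several;
  parametric alternatives will differ in small samples.
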