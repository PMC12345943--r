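---
title: "Transcription-based intelligibility scoring and listener–ASR agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcription-based intelligibility scoring and listener–ASR agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asragree)
```

## The measurement problem

Transcription by naïve listeners is the reference standard for measuring
speech intelligibility in motor speech disorders: a panel of listeners who do
not know the speaker types what they hear, and the proportion of target words
recovered is the intelligibility score. Automatic speech recognition (ASR)
promises to replace part of this labor, but an ASR transcript is only useful
clinically if it *scores* speech the way listeners do — including agreeing
with them when they get a word wrong. `asragree` implements the full chain
for word and sentence stimuli in Hebrew and English:

1. normalize free-typed transcripts into comparable token sequences;
2. score each transcript against its target under a strict
   phonemic-identity rule;
3. aggregate per speaker: listener scores (three listeners per stimulus),
   ASR scores, and listener–ASR agreement;
4. analyze group/language/stimulus effects with the factorial and
   split-plot ANOVA machinery conventional in this literature;
5. simulate complete synthetic studies with the same structure, so the
   whole chain is testable without confidential recordings.

## Scoring rules

**Word identity.** A transcribed word is correct only when it is
phonemically identical to the target; omission or substitution of any part
of the word, including bound morphology (e.g. a plural suffix), is an error.
We operationalize phonemic identity as *exact match after orthographic
normalization*, plus an explicit, user-supplied equivalence lexicon of word
pairs (spelling variants, plene/defective matres lectionis). No
grapheme-to-phoneme conversion is attempted: a lexicon keeps the rule
auditable, and the lexicon defaults to empty because typed spelling variants
cannot be adjudicated generically. Normalization is language-aware:

* both languages: lowercase, strip all Unicode punctuation (`\p{P}`, so
  Hebrew gershayim and quote marks are covered), collapse whitespace;
* Hebrew: remove combining marks (`\p{M}` — niqqud and cantillation) and
  fold the five final letter forms onto their base forms, since typing
  conventions vary across listeners.

Normalization is idempotent, and a single-word item is correct only if the
transcript normalizes to exactly one token that matches the target
(`score_word()`); a transcript with extra words is an error.

**Word-level aggregation.** Each listener's score for a speaker is the
proportion of word items correct; the speaker's listener intelligibility
score is the mean of the three listener proportions. The ASR score is the
proportion of items the single ASR transcript got correct.

**Listener–ASR agreement (words).** For each item the three listener
statuses are reduced by majority vote (three binary statuses always have a
majority). In the default `"status"` mode, the ASR agrees on an item when
its correct/incorrect status equals the majority status — agreement in how
the item is *scored*, whether correctly or incorrectly. Because "transcribed
it as such" can also be read as agreement on the specific word string, a
`"string"` mode is provided: agreement requires at least two listeners to
have typed the same normalized transcript and the ASR to have typed it too.
Neither reading is asserted to be the original study's; status mode is the
default because agreement is defined relative to scoring correctly *or
incorrectly* with respect to the target.

**Sentences.** Sentence transcripts are scored as the percentage of target
words correctly transcribed, using a minimum edit-distance alignment
(`align_tokens()`) with unit costs in which a zero-cost hit requires the
word-identity rule — so the equivalence lexicon participates in the
alignment. The denominator is always the target length and insertions
cannot push a score below zero, keeping all scores in [0, 1]. Among
minimum-cost alignments, ties prefer hits, then substitutions, then
deletions; the dynamic program optimizes this lexicographic objective
exactly (verified against exhaustive enumeration). The speaker's listener
sentence score averages percent-correct across the three listeners within
each sentence and then across sentences; the ASR sentence score averages
its percent-correct across sentences. Sentence-level agreement is the
proportion of *ASR successes*: sentences for which the ASR percent-correct
is equal to or greater than the three-listener average for that sentence.
Speakers with fewer elicited sentences are scored over their available
sentences.

## Statistical layer

All analyses run on per-speaker summary scores.

* **Correlations** between listener and ASR scores per cell are Pearson
  product-moment coefficients with two-sided p-values on n − 2 df.
* **Word-level factorial ANOVA** of agreement on group × language uses Type
  III sums of squares with sum-to-zero coding. The design of interest is
  markedly unbalanced (24/24/8/6), and Type III is the decomposition
  consistent with estimated-marginal-means contrasts; partial eta squared is
  SS_effect / (SS_effect + SS_error), and the error df is N − (number of
  cells). A design with zero error SS is returned flagged `degenerate`
  rather than as an error, so simulation sweeps keep running.
* **EMM pairwise contrasts.** Under the full-interaction model the EMM of a
  cell is its raw mean, a contrast is a difference of cell means, its SE is
  `sqrt(MSE (1/n_i + 1/n_j))`, and the Tukey–Kramer adjusted p comes from
  the studentized-range distribution with k = number of cells. Because only
  cell means, SDs and sizes enter, `emm_from_summary()` reconstructs the
  full contrast table from published summary statistics alone — pooling
  `sum((n_i − 1) s_i²) / (N − k)` as the error variance. All k(k−1)/2
  contrasts are always computed.
* **Split-plot ANOVA** for the word-vs-sentence comparison uses the
  classical two-stratum decomposition: the between-subject factor is tested
  against subjects-within-groups, the within-subject factor and the
  interaction against the within × subject residual. Subjects missing a
  within level are dropped listwise with a warning (so a 48-speaker design
  with 6 incomplete speakers reports F(1, 40)). Contrasts between the four
  group × stimulus cells use the error stratum they live in: paired
  within-group contrasts use the within-subject error; between-group
  contrasts use the average of the two stratum mean squares (the cell-mean
  variance) with Satterthwaite df. Published split-plot tables that report
  different SEs for between-group contrasts at the two within levels cannot
  arise from this (or any equal-variance univariate) model, so only
  contrast *estimates* — which depend on cell means alone — should be
  compared against such tables.
* **Subgroup regressions** of agreement on listener score are ordinary least
  squares; slope p-values are Holm–Bonferroni corrected within the family
  passed in one call. Word-level subgroups (4) and sentence-level subgroups
  (2) are corrected as separate families, mirroring how such results are
  reported by stimulus type.
* **Normality screen**: bias-corrected sample skewness and excess kurtosis
  (the SPSS/SAS G1/G2 estimators), with the conventional screening
  thresholds |skewness| ≤ 2 and |excess kurtosis| ≤ 7.

## The synthetic study generator

`simulate_study()` emulates the design the scoring assumes: 2 languages × 2
groups with unbalanced cells (24 Hebrew DS, 24 Hebrew TD, 8 English DS, 6
English TD), a fixed word list per language (46 Hebrew, 78 English items),
five sentences of 3–4 words (mean 3.6) for Hebrew cells only, exactly three
listeners plus one ASR transcript per stimulus, and group-dependent
correctness probabilities.

Correctness is modeled on the logit scale:

* each speaker draws a latent intelligibility probability θ from a per-cell
  Beta distribution;
* each *production* (speaker × item) draws a difficulty deviate
  d ~ N(0, σ_d) shared by all four transcribers — the sole source of
  listener–ASR coupling beyond θ;
* a listener is correct with probability `plogis(qlogis(s·θ) − d)` with
  listener slope s (default 1);
* the ASR is correct with probability `plogis(λ·qlogis(θ) + δ − d)` with
  slope λ (default 1) and offset δ;
* a wrong word is drawn uniformly from a held-out confusion vocabulary, so
  string-mode agreement between wrong answers is possible but rare;
  sentence errors are generated word-wise with the same model (no grammar
  model — the analysis consumes only per-word correctness).

Default parameters were fixed once, by moment-matching the per-cell Beta
distributions to the listener word-score means and SDs that characterize
this population contrast (Hebrew DS 0.80 ± 0.10, Hebrew TD 0.98 ± 0.02,
English DS 0.56 ± 0.24, English TD 0.91 ± 0.06), and by giving the ASR a
per-cell offset (−0.8 for Hebrew, +0.25 for English): ASR quality differs by
language in the target setting, and a single global offset cannot express
that. σ_d defaults to 0.8, a realistic spread of item difficulty on the
logit scale. These values are illustrative study conditions, not estimates
fitted to any dataset: the real dependence structure between listener and
ASR errors is unknown.

`expected_statistics()` computes the implied per-cell expectations of the
listener score, ASR score and status-mode agreement by Rao-Blackwellized
Monte Carlo: conditional on (θ, d) the three listeners are independent
Bernoulli(p_L), so the majority is correct with probability
`p_L³ + 3 p_L² (1 − p_L)` and the expected agreement is
`P(maj) p_A + (1 − P(maj)) (1 − p_A)`; these closed-form conditionals are
averaged over draws of (θ, d), with reported Monte-Carlo standard errors.
The test suite demonstrates parameter recovery: on a simulated study of 200
speakers × 100 words, the pipeline's cell-mean listener score, ASR score and
agreement all fall within three Monte-Carlo standard errors of these
expectations, and the empirical majority rate matches the binomial closed
form at p = 0.5 and p = 0.8.

What the generator does *not* emulate: acoustic confusability (wrong words
are unrelated to targets, so near-miss morphological errors are rarer than
in real data), listener fatigue or learning, per-listener ability
differences, and any grammar in sentences. Passing tests therefore show that
the scoring and inference machinery is correct under the declared model, not
that the model captures every property of real transcription data.

## Numerical and design choices

* Alignment tie-breaks are encoded as an additive lexicographic key inside
  the dynamic program (cost bands dominate hit bands, etc.), which is exact
  for sequences far longer than any stimulus used here.
* Degenerate inputs: zero-variance correlation cells report `NA` in the
  pipeline; an all-identical factorial response is flagged `degenerate`; a
  flat regression response reports slope 0, R² = 0, p = 1, and an exactly
  collinear fit reports p = 0; a within-subject factor with zero effect SS
  reports F = 0 even when the error stratum is also zero.
* Determinism: `simulate_study()` and `expected_statistics()` restore the
  caller's RNG state; the pipeline is a pure function of (input files,
  config, seed); written reports embed the schema version, a configuration
  hash, and the seed, and contain no timestamps, so identical runs are
  byte-identical.
* Problem sizes in the test suite (e.g. 10⁴ random alignment pairs, 200 ×
  100 parameter-recovery studies, 1,000 random p-vectors for monotonicity)
  were chosen to give comfortable statistical resolution while keeping the
  default test run fast.

## A worked example

```{r example, eval = FALSE}
library(asragree)

cfg <- run_config(sim = sim_config(seed = 20260930L), seed = 20260930L)
bundle <- run_pipeline(cfg)

# per-cell descriptives (means, SDs, ranges) by stimulus type and measure
bundle$cell_summary

# word-level group x language ANOVA and Tukey-Kramer contrasts
bundle$analyses$word_anova
bundle$analyses$word_contrasts

# word-vs-sentence split-plot for the sentence-bearing language
bundle$analyses$split_plot
```

## Limitations

* "Phonemic identity" is orthographic-plus-lexicon; homophones spelled
  differently are errors unless listed.
* The sentence measure depends on the alignment's unit-cost assumption;
  weighting substitutions differently would change percent-correct for
  heavily garbled productions.
* The split-plot model assumes compound symmetry; with only two within
  levels this is innocuous for the F tests, but contrast SEs inherit the
  equal-variance-per-stratum assumption.
* The generator's independence assumptions (listeners conditionally
  independent given θ and d) are a modeling convenience; real listener
  panels share biases that would inflate majority agreement.
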