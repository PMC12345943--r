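# asragree

Transcription-based speech intelligibility scoring and listener–ASR
agreement analysis for word and sentence stimuli in Hebrew and English.

## The problem

For speakers with motor speech disorders (e.g. adults with Down syndrome),
intelligibility is conventionally measured by having three naïve listeners
transcribe each recorded word or sentence and scoring the transcripts
against the targets. Automatic speech recognition (ASR) could automate
this, but only if the ASR *scores* speech the way listeners do — agreeing
with them both when they recover the target and when they fail to.
`asragree` is for researchers and clinicians who work with such
transcription panels: it implements the scoring rules, the agreement
statistics, and the inferential layer used in this literature, plus a
synthetic-study generator so the entire pipeline can be exercised and
validated without access to confidential recordings.

## What it computes

**Scoring.** Transcripts are normalized per language (lowercasing, Unicode
punctuation stripping; for Hebrew also niqqud/cantillation removal and
final-letter folding) and scored under a strict phonemic-identity rule: a
word is correct only if it matches the target exactly after normalization
or via an explicit equivalence lexicon — any partial or morphological
mismatch is an error. Per speaker:

* listener word score = mean over the 3 listeners of their proportion of
  items correct; ASR word score = proportion correct of the single ASR
  transcript;
* word-level **agreement** = proportion of items where the ASR's
  correct/incorrect status matches the status given by ≥ 2 of the 3
  listeners (a string-identity mode is also provided);
* sentence percent-correct = aligned hits / target length, using a minimum
  edit-distance token alignment (unit costs; hits require the word-identity
  rule); sentence-level agreement = proportion of **ASR successes**,
  sentences where the ASR percent-correct ≥ the 3-listener average.

**Statistics.** Pearson correlations per cell; Type III group × language
ANOVA with partial η²; estimated-marginal-mean pairwise contrasts with
Tukey–Kramer adjustment — computable both from raw data (`emm_pairwise()`)
and from published cell means/SDs/sizes alone (`emm_from_summary()`), since
under a full-interaction model the EMM of a cell is its raw mean and the
pooled error variance is `Σ(nᵢ−1)sᵢ²/(N−k)`; classical split-plot (mixed)
ANOVA with stratum-aware contrasts for the word-vs-sentence comparison;
per-subgroup OLS regressions with Holm–Bonferroni correction; and a
skewness/kurtosis normality screen (|G1| ≤ 2, |G2| ≤ 7).

**Simulation.** `simulate_study()` generates complete synthetic studies
(unbalanced 24/24/8/6 cells, 46 Hebrew / 78 English word items, Hebrew
sentence sets, 3 listeners + 1 ASR per stimulus) from a logit-scale model:
speaker ability θ ~ Beta per cell, shared production difficulty
d ~ N(0, σ_d), listener correct w.p. `plogis(qlogis(θ) − d)`, ASR correct
w.p. `plogis(λ·qlogis(θ) + δ − d)`. `expected_statistics()` returns the
implied cell expectations for parameter-recovery checks.

## Worked example

```r
library(asragree)
bundle <- run_pipeline(run_config(sim = sim_config(seed = 20260930L),
                                  seed = 20260930L))
subset(as.data.frame(bundle$cell_summary),
       measure %in% c("agreement", "asr_success"))
```

```
  stimulus language group     measure  n  mean     sd   min   max
1     word  english    DS   agreement  8 0.663 0.1169 0.538 0.872
2     word  english    TD   agreement  6 0.929 0.0554 0.859 0.974
3     word   hebrew    DS   agreement 24 0.648 0.1413 0.370 0.957
4     word   hebrew    TD   agreement 24 0.935 0.0801 0.696 1.000
5 sentence   hebrew    DS asr_success 24 0.392 0.2394 0.000 0.800
6 sentence   hebrew    TD asr_success 24 0.750 0.1978 0.200 1.000
```

Each row is one design cell: for word stimuli, `agreement` is the mean
proportion of a speaker's words on which the ASR and the listener majority
assigned the same correctness status (TD speakers ≈ 0.93, DS speakers ≈
0.65 under this simulation's conditions); for sentences it is the ASR
success rate. The factorial analysis of the same run:

```r
as.data.frame(bundle$analyses$word_anova)
```

```
          effect        ss df        f         p partial_eta_sq
1          group 0.8159724  1 65.93879 3.852e-11      0.5320271
2       language 0.0002952  1  0.02385 8.778e-01      0.0004111
3 group:language 0.0011886  1  0.09605 7.577e-01      0.0016533
4          error 0.7177323 58       NA        NA             NA
```

The speaker-group effect dominates (η_p² = 0.53 with error df = 58 = 62
speakers − 4 cells), and `bundle$analyses$word_contrasts` lists all six
Tukey-adjusted pairwise cell contrasts. A command-line wrapper with
`simulate` / `score` / `analyze` / `report` subcommands is in
`inst/cli/asragree.R`.

Contrast tables can also be rebuilt from published summary statistics
alone:

```r
emm_from_summary(c("DS Hebrew", "TD Hebrew", "DS English", "TD English"),
                 means = c(0.74, 0.94, 0.91, 0.98),
                 ns    = c(24, 24, 8, 6),
                 sds   = c(0.08, 0.06, 0.04, 0.02))
```

which reports, e.g., the DS Hebrew − TD Hebrew contrast as −0.20 with
pooled SE 0.0187 on 58 df.

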