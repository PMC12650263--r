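# createlab

Scoring and statistical validation for multi-modal cognitive–affective
session data, with a synthetic-cohort generator that makes the whole
pipeline testable end to end.

The package is aimed at researchers building or evaluating digital
mental-health platforms that combine, in one sitting:

- an **adaptive sequence-recall (Corsi-style) working-memory game**
  producing per-trial logs;
- **PSQI** (sleep quality, 19 items → 7 components → global 0–21) and
  **ERQ** (emotion regulation, 10 Likert items → Cognitive Reappraisal +
  Expressive Suppression) questionnaires;
- short **emotional narratives** about art stimuli, scored with a
  transparent packaged lexicon (Polarity, Subjectivity, Average Word
  Length, Token Count, Unique Tokens, Type–Token Ratio);
- **spontaneous eye-blink rate (sEBR)** — a non-invasive proxy of striatal
  dopaminergic tone — detected from eye-opening-ratio time series;
- **valence–arousal ratings** of the stimuli, reduced to quadrant labels
  and a per-participant HVHA arousal-deviation predictor.

## The statistics at the core

Pilot cohorts in this field are small (n ≈ 27) and non-normal, so the
validation pipeline is non-parametric and permutation-based:

1. **Outlier filter.** Per variable, bounds are x̄ ± k·s (sample SD,
   default k = 2); participants strictly outside any bound are excluded
   listwise.
2. **Permutation Spearman matrix.** For every variable pair, Spearman's ρ
   (Pearson on mid-ranks) is compared with an empirical null built by
   permuting one variable B = 2000 times:
   p = #{|ρ_perm| ≥ |ρ_obs|} / B, masked at α = 0.05.
3. **Group comparisons.** Good vs Poor sleepers (PSQI global > 5 → Poor)
   via the Mann–Whitney U test — exact by full enumeration for small
   untied samples, tie/continuity-corrected normal approximation
   otherwise.
4. **Regression.** OLS of the WM mean score on the HVHA arousal
   deviation, with the full report: R², adjusted R², F, AIC/BIC,
   Durbin–Watson, D'Agostino–Pearson omnibus, Jarque–Bera, residual
   skewness/kurtosis, design-matrix condition number.

The synthetic cohort plants a Gaussian copula over four latent traits
(WM capacity, ER level, sleep-problem tendency, dopaminergic tone) and
maps them monotonically onto the observables, emitting the planted truth
alongside the data so every stage can be checked against it.

## Worked example

```r
library(createlab)

cohort <- generate_cohort(cohort_config(seed = 42))
report <- run_pipeline(cohort, analysis_config(seed = 42))
print(report)
#> analysis report: 18 analyzed (9 excluded of 27); 9 good / 9 poor sleepers
#> significant correlations at alpha 0.05: 93 of 231 tested pairs
#> regression mean_score ~ hvha_deviation: R2 = 0.089, slope = -0.046 (p = 0.2295)

subset(report$group_tests, variable == "sebr_pre")
#>  variable n_good n_poor U p_two_sided               method
#>  sebr_pre      9      9 0    0.000407 normal-approximation
```

The report mirrors the planted world: the ER trait is correlated with the
sleep trait in the default copula, so `er_total` shows significant
positive ρ with every PSQI component (0.61–0.72 here); poor sleepers were
planted with ~3× the baseline blink count of good sleepers, and the
Mann–Whitney test flags `sebr_pre` accordingly (U = 0 means complete
group separation). The negative regression slope reflects the planted
negative coupling between arousal-rating bias and WM capacity; at n = 18
after filtering it is not individually significant, as expected for an
effect of this size.

Each stage is also usable on its own:

```r
score_session(data.frame(correct = c(1, 0, 1, 1, 0)))
#>   num_correct_responses num_total_responses max_score median_score mean_score
#> 1                     3                   5         1    0.6666667  0.7033333
#>   count_above_0_25 count_above_0_5 successive_correct_count
#> 1                5               4                        2

d <- detect_blinks(generate_eye_signal(20, duration_s = 60, fps = 30, seed = 4)$signal)
d$blink_count
#> [1] 20
```

## Command line

```sh
create-lab simulate --out data/ --seed 3 [--config cohort.json]
create-lab score-wm --in data/wm_trials.csv --out wm_scores.csv
create-lab analyze  --in data/ --out results/ --seed 7
create-lab report   --in results/
```

(The script installs to `<library>/createlab/exec/create-lab`.) Exit codes:
0 ok, 1 validation error, 2 runtime error.

## Documentation

The methods vignette (`vignettes/createlab-methods.Rmd`) describes the
models, the generator's stated world, numerical choices and known
limitations.
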