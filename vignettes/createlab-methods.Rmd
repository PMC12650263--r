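---
title: "Methods: models, synthetic world, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, synthetic world, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(createlab)
```

This vignette is the package's own account of its science: what each
module computes, what the synthetic-data generator does and does not
emulate, and where the design was genuinely open — with the choice we
made and why. No empirical claim is made here that the test suite or the
acceptance script does not itself compute.

## 1. The working-memory game and its scores

The game engine models a computerized forward-span recall task. A
sequence is displayed for a limited time; the player reproduces it; the
outcome is binary (full sequence correct or not). Difficulty is
re-evaluated after every `eval_window` trials (default 10): accuracy
above `up_threshold` raises the level and shortens the display duration
by one step; accuracy below `down_threshold` lengthens it. The level
never decreases — only display time eases. Defaults
(`up_threshold = 0.7`, `down_threshold = 0.3`, initial 1000 ms, step
100 ms, clamped to [200, 2000] ms) were chosen once so that a
mid-ability synthetic player sits near the adaptive boundary; only the
window of 10 trials is fixed by the task description itself.

**Per-trial score.** The task description anchors the score to the
*cumulative* accuracy (cumulative correct / cumulative attempts), and
the maximum-score metric is explicitly "(correct/total)". We therefore
take the per-trial score sequence to be the running cumulative accuracy,
and compute max/median/mean and the two threshold counts (strict `>`,
0.25 and 0.5) over that sequence, with the streak metric counting the
longest run of consecutive correct trials. A `score_mode = "per_trial"`
switch treats the binary outcomes themselves as scores instead; it
exists because the threshold counts would read differently under that
interpretation, and the ambiguity cannot be resolved from the metric
table alone.

**Sequence length.** Difficulty is attributed to display time, so the
default keeps a fixed 9-position sequence and lets the level modulate
duration only; a `sequence_length_rule` makes length adaptive for users
who want the classical span progression.

**Synthetic player.** Recall is Bernoulli with a logistic psychometric
function of sequence length: capacity is the span at 50% recall, `slope`
the span-unit width, `lapse` a floor/ceiling mixture. Because the
default length is fixed, the per-trial probability is constant per
player — which is exactly what makes the Monte-Carlo oracle for the mean
score analytic (the expectation of a mean of running means of i.i.d.
Bernoulli draws is the success probability itself).

## 2. Questionnaire scoring

PSQI components follow the instrument's published banding rules
(latency minutes + the "cannot sleep within 30 min" item; duration
bands at 7/6/5 h; efficiency = sleep hours / time in bed with bands at
85/75/65%; disturbances as the 0–27 sum banded 0/1–9/10–18/19–27;
daytime dysfunction as a two-item sum). The global score is the
component sum, 0–21, higher = worse sleep.

**Good/Poor split.** The source material contains an internal
contradiction: one sentence assigns *low* global scores to Poor
Sleepers, while the instrument definition (and the reported group sizes
and means) imply the opposite. We follow the instrument convention:
`global > 5` → Poor, `≤ 5` → Good, strict-greater at the boundary.

**ERQ.** The item→subscale map is not restated in the source, so the
original instrument's standard assignment is used (reappraisal items
1, 3, 5, 7, 8, 10; suppression 2, 4, 6, 9) and is overridable via
`item_map` so a different administration order can be accommodated.

## 3. Narrative features and the packaged lexicon

The six text features are Polarity ([−1, 1]), Subjectivity ([0, 1]),
Average Word Length (characters per token), Token Count, Unique Tokens
and Type–Token Ratio. The tokenizer lowercases, splits on any
non-alphanumeric run and drops empties — so hyphens split words and AWL
counts letters/digits only.

The sentiment engine behind the original scores is not identified, so
the package ships a transparent ~250-word affect lexicon (plain TSV:
word, polarity weight, subjectivity weight) rather than pinning an
external model: results stay reproducible, auditable, and testable in a
closed loop with the narrative generator. Polarity is the mean polarity
weight over lexicon-matched tokens; a match immediately preceded by a
negator is multiplied by `negation_factor` (default −0.5). The negation
window is exactly one token and there are no intensifiers — the smallest
rule that makes generator → extractor round trips exact. Zero matches
give (0, 0); an empty token list propagates missing (not zero), since
TTR and AWL are undefined there.

## 4. Blink detection

The module boundary is the eye-opening-ratio time series — the quantity
a face-landmark tracker plots — so no camera dependency enters the test
path; users with landmark streams can adapt by computing their ratio per
frame and calling `detect_blinks()`. The detector is a two-threshold
state machine: an event opens below `threshold`, closes above
`threshold + hysteresis`, must stay below threshold for
`min_closed_frames`, and onsets inside `refractory_ms` of the previous
onset merge. Defaults (2 frames ≈ 66 ms at 30 fps; 100 ms refractory;
hysteresis 0.02) reflect typical blink physiology and are all
overridable. Counts per session (not per minute) feed the analysis,
matching the magnitudes reported for sessions of unstated duration;
`sebr_diff = post − pre` by definition.

## 5. Affect space

Stimulus quadrants are classified from group-mean valence/arousal with
midpoint 5.5 on the 1–10 sliders; the midpoint is not stated anywhere in
the source, and boundary values are assigned "low" so the labeling is
deterministic. The HVHA deviation is, per participant, the mean signed
difference between their arousal ratings and the stimulus group means,
over HVHA stimuli only; mean is the default reduction (sum and median
are offered), and participants missing some HVHA ratings average over
what they rated. Presentation order is carried as metadata and never
affects results.

## 6. Statistical pipeline

- **Outlier filter:** listwise exclusion outside x̄ ± 2s per variable,
  sample SD, strict inequality, so constant columns exclude nobody.
  Listwise matching the source's participant-level exclusions; a
  per-cell masking mode is deliberately *not* the default.
- **Permutation test:** one variable of each pair is permuted (the null
  law is the same whichever is permuted); p is the plain proportion of
  permuted |ρ| at least the observed |ρ|, which can be exactly 0 at
  extreme effects — an add-one smoothed option exists behind a flag,
  off by default for fidelity. No multiple-testing correction by
  default (a BH option exists). Cells with fewer than 3 complete pairs
  or zero rank variance are reported missing, never significant.
  Floating-point ties in |ρ| are compared with a 1e-12 guard so
  enumeration equivalence is exact.
- **Mann–Whitney:** exact two-sided p by full enumeration of group
  assignments when `n1·n2 ≤ 400` with no ties (p = share of assignments
  with |U − n1n2/2| at least the observed); otherwise normal
  approximation with tie and continuity corrections. U is reported for
  the first group (rank-sum convention).
- **OLS report:** coefficients via QR; AIC/BIC from the Gaussian
  log-likelihood with k = 2 (coefficient count); the omnibus normality
  test is D'Agostino–Pearson K² (the conventional "Omnibus" of
  regression reports), reported NA with a warning below n = 8 where the
  skewness transform is undefined; kurtosis is reported non-excess;
  condition number = singular-value ratio of the raw design matrix
  including the intercept column. The minimum fit size is 3 pairs
  (the documented hand cases demand it), though diagnostics only become
  meaningful from n ≈ 8.

## 7. The synthetic world

The generator's defaults are a stated world, fixed once:

- **Cohort:** 27 participants, one third good sleepers (matching the
  reported 9/18 split), 15 stimuli, 70-trial sessions (the reported
  correct-count/mean-score ratio implies roughly 70 trials), 300-second
  blink recordings at 30 fps.
- **Copula:** latent traits (wm, er, sleep, dopamine) with default
  correlations ρ(wm, er) = 0.4, ρ(er, sleep) = 0.5,
  ρ(sleep, dopamine) = 0.4 — the sign pattern of the reported findings
  (WM–ER association; ER–sleep-score association; higher baseline blink
  counts with worse sleep).
- **Maps:** WM trait → agent capacity 6.8 + 1.5z (logistic recall, slope
  2, lapse 0.02 — capacity centered so a fixed 9-span task yields mean
  scores near the reported ≈ 0.25); ER trait → ordinal ERQ items
  (loading 0.8, thresholds at normal quantiles); sleep trait →
  percentile-mapped PSQI global target realized through
  instrument-consistent item responses (so scored global equals the
  target exactly and the good fraction is binomial by construction);
  dopaminergic tone → blink counts, linear with SD 15 around group means
  good = (33, 42), poor = (94, 95) pre/post (the reported group means);
  ER trait → narrative subjectivity targets centered at 0.49 ± 0.14 with
  polarity 0.07 ± 0.09 and ~10 tokens (the reported descriptives);
  arousal-rating bias −0.6z_wm (planting the negative HVHA→WM slope).
- **Eye signal:** baseline 0.32, noise SD 0.015 (8σ from the 0.2
  threshold, so noise alone never triggers), rectangular dips to 0.05
  for 4 frames, ≥ 0.5 s onset separation — infeasible rates error rather
  than silently overlapping.

What the generator does **not** emulate: real blink waveform shapes
(ramps, partial closures), response-time structure in the game, item-level
PSQI heterogeneity beyond the component targets, semantic coherence of
narratives, or missingness. A green test therefore establishes that the
pipeline recovers what was planted under clean monotone maps — not that
it would survive sensor artifacts or non-monotone confounding.

One visible consequence of the stated world: a 2-SD *listwise* filter
over ~22 variables at n = 27 excludes more participants (typically 8–11)
than the 5-of-32 reported for the original cohort; with 22 chances per
participant to stray outside ±2s this is the expected behavior of the
rule itself, and we kept the rule faithful rather than tuning the world
to reduce exclusions.

Determinism: every random draw flows from one master seed through a
string-hashed stream-derivation (`seed × stream label → 32-bit child
seed`), so regeneration is byte-identical across platforms and no
unordered iteration is relied upon.

## 8. Oracles used by the tests

- Spearman permutation p: full enumeration of all n! permutations for
  n ≤ 6, with the sampled estimate required to fall within 3 Monte-Carlo
  standard errors.
- Mann–Whitney: brute-force enumeration by direct pair counting.
- The copula attenuation target (latent ρ(wm, er) = 0.6 → Spearman 0.495
  between WM mean score and ERQ total) was computed once by a vectorized
  n = 100 000 simulation of the documented maps, independent of the
  generator code, and frozen.
- The regression diagnostic suite is checked against frozen values from
  an independent reference implementation on fixed fixtures, and against
  closed-form hand computations (3-point fits, alternating-sign
  Durbin–Watson).

## 9. Known limitations

- The lexicon couples high |polarity| with high subjectivity (as real
  affect lexicons do), so extreme joint targets such as (0.8, 0.2) are
  unreachable; `generate_narrative()` names the feasible range in its
  error instead of silently missing.
- Exact Mann–Whitney enumeration is capped at `n1·n2 ≤ 400`; beyond
  that, and whenever ties occur (blink counts often tie), the corrected
  normal approximation is used and the method is reported alongside p.
- Empirical permutation p-values have resolution 1/B; with the default
  B = 2000 the smallest nonzero p is 0.0005.
- The omnibus normality test is undefined below n = 8 and reported NA.
- Session duration for blink counts is a config value; per-minute
  normalization is left to the caller, as counts per session are what
  the analysis consumes.
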