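---
title: "Measuring serial dependence in sequential diagnostic judgments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring serial dependence in sequential diagnostic judgments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serialdep)
```

## The problem

An observer classifying a long stream of skin-lesion images as benign or
malignant does not judge each image in isolation: the current judgment can be
attracted toward recently seen stimuli. Two signatures separate genuine
serial dependence from mundane artifacts such as lapsing or pressing the same
button repeatedly:

* **feature tuning** — the bias is strongest when successive stimuli are
  *moderately* similar and vanishes for identical or very different ones;
* **temporal tuning** — the bias decays with the number of intervening
  trials.

`serialdep` implements the full analysis that measures both signatures on
trial-record tables, and a generative observer model that injects a known
bias so the analysis can be validated end to end by parameter recovery.
This vignette documents the model, the estimator choices, the numerical
details, and what the synthetic validation does and does not establish.

## The generative observer model

`generate_stimuli()` draws a pool of stimuli: a true label (malignant with
probability 0.427, the benign-heavy mix typical of curated dermatology
stimulus sets), a latent malignancy *evidence* value from class-conditional
normals (means −1 / +1, SD 1, an arbitrary but convenient evidence scale),
and a consensus malignancy score `M`. `M` is built from a popularity vote:
each of `k_raters = 25` simulated voters reports "malignant" when the
stimulus evidence plus independent normal noise (SD 0.8) exceeds the voter
criterion (−0.05); `M = 100 (n_mal − n_ben)/k`. A voter model, rather than a
deterministic transform of evidence, is used deliberately: it gives `M` a
realistic spread with mass throughout the mid-range while still pinning the
endpoints (±100 exactly when the vote is unanimous). The vote count is drawn
in one step as a binomial with per-voter probability
`pnorm((evidence − c0)/sigma_rater)`, which is distributionally identical to
looping over voters. The voter noise and criterion default to the observer's
values but are separate configuration fields, since raters and the observer
under study need not share parameters.

`simulate_trials()` gives every user an independent random stimulus sequence
(sampled with replacement by default — the sampling scheme of deployed
diagnostic apps is rarely documented, so it is exposed as configuration).
The internal signal on trial *t* is

```
x_t = evidence_t + N(0, sigma_obs) + sum_{n=1..max_lag} A1 * rho^(n-1) * DoG(M_{t-n} - M_t)
```

with `DoG(d) = (d/sigma_w) exp(−d²/(2 sigma_w²))`, a derivative-of-Gaussian
attraction toward the previous stimulus: zero for identical stimuli, maximal
at a malignancy difference of `sigma_w`, vanishing for very different ones.
The response is "malignant" iff `x_t` exceeds the criterion, replaced by a
fair coin with probability `lapse`. The bias enters additively on the
evidence axis — a trial-wise criterion shift, the simplest mechanism that
moves d′, criterion and error rate simultaneously. Lag decay is geometric
(`rho^(n−1)`), a one-parameter monotone decay.

Defaults (`sigma_obs = 0.8`, `c0 = −0.05`, `A1 = 0.5`, `rho = 0.55`,
`sigma_w = 60`, `lapse = 0.02`, `max_lag = 4`) were chosen once so that the
*unbiased* parts of the model land near the overall performance a competent
reader population shows on this task — pooled d′ around 1.4–1.5 with a
slightly liberal criterion — while the bias produces error-rate tuning
curves with peak heights of a few percent at intermediate similarity.

What the simulator does **not** emulate: real lesion-image statistics (there
are no images, only latent evidence), learning or fatigue across a session,
reaction times, feedback effects, heterogeneous users (all users share one
parameter set), and any dependence of the stimulus sequence on behavior.
Passing recovery tests therefore shows that the *estimator* is correct and
well calibrated under its own assumptions, not that real reader data will
satisfy those assumptions.

## Records, preprocessing, sessions

Trial CSVs carry `user_id, seq_index, timestamp, stimulus_id, true_label,
response`; `read_trials()` type-checks every row and drops invalid ones with
row-numbered diagnostics rather than failing the file. `preprocess_trials()`
applies an ordered, configurable exclusion pipeline (duplicate
user/seq-index rows, missing fields, users below `min_trials_per_user = 20`)
and always emits a balanced exclusion report; published preprocessing of
comparable datasets typically removes a fraction of a percent of records
without disclosing exact criteria, so the rules here are conservative
defaults meant to be adjusted against a known target count. The pipeline is
idempotent. `sessionize()` starts a new session whenever the within-user gap
exceeds 30 minutes (configurable); n-back lookups never cross session
boundaries, because conditioning on a stimulus seen before a long break is
not meaningful. The first *n* trials of a session serve only as history for
lag *n*, never as the conditioned trial.

## The estimator

For lag *n*, each trial's outcome (cell of the confusion table) is
accumulated in the bin of its n-back similarity `|M_{t−n} − M_t|`; bins are
half-open `[low, low+width)` with the last bin closed, width 10 over
[0, 200], giving exactly 20 groups (so the domain maximum has a bin and
every in-range value has exactly one). Semantic similarity uses 19 bins of
width 0.02 over [0.3, 0.68], with bins under 100 trials excluded by default;
the malignancy bins default to no minimum beyond non-emptiness because the
20-group grid is dense at realistic sample sizes. Per-bin metrics use the
pooled confusion counts (a per-user-mean mode exists in `sdt_summary()` for
comparison; pooled rates are the internally consistent choice for deriving
d′ and criterion). Hit and false-alarm rates of exactly 0 or 1 — possible in
small per-bin subsets even though an overall dataset never hits them — are
clamped to `1/(2N)` and flagged.

**The future baseline.** The same conditioning is repeated against the
*next* trial's similarity `|M_{t+1} − M_t|`. Since the future stimulus is
unpredictable, any apparent "effect" of it estimates chance-level sequential
structure and absorbs stereotyped-response artifacts (a user who always
presses the same button shows identical past- and future-conditioned
curves). The net change is the bin-wise difference, past minus future;
bin-wise subtraction (rather than one global future baseline) is the default
because it cancels structure that varies *with* similarity, and a global
mode is available behind `baseline = "global"`.

**Cost direction.** A positive net change in error rate is a cost; for
sensitivity, specificity and d′ a negative one is. For the criterion the
analysis treats the *magnitude* of the shift as the statistic, since a
history bias can push the criterion in either direction depending on the
stimulus mix.

**Permutation null.** Trial order is shuffled within user × session with
(stimulus, response) pairs intact, preserving marginal accuracy, response
bias and stimulus mix while destroying only sequential structure. For each
bin the upper 95% quantile of the permuted cost-direction net changes is
reported, plus a one-sided add-one p-value `(1 + #{perm ≥ obs})/(B + 1)`
(minimum attainable `1/(B+1)`, never 0). `B` defaults to 1000; the seed is
mandatory and two runs with the same seed are identical. Per-bin p-values
are deliberately *not* multiplicity-corrected — the per-bin star convention
of this literature — but Benjamini–Hochberg adjusted values are printed
alongside for transparency.

## Tuning fits and amplitude

A scaled Gaussian `a/√(2πσ²) · exp(−(x−μ)²/(2σ²))` is fitted to each
cost-signed net-change curve by bounded Levenberg–Marquardt least squares,
weighted by per-bin trial counts (weighting is the default because bin
populations differ by an order of magnitude; an unweighted mode exists).
The reported **amplitude** is the fitted peak `a/√(2πσ²)`, not raw `a`;
both are kept. There is no baseline-offset parameter — the net change is
already baseline-subtracted. Initialization: `μ` at the extreme-cost bin,
`σ` at a quarter of the domain span, `a` matched to the extreme value;
bounds keep `μ` inside the domain and `σ` between one bin width and the
span; three jittered restarts from a fixed internal stream guard against
local minima (best weighted RSS wins, ties by first). Non-convergence is
reported honestly in the `converged` flag with the best iterate returned;
an exactly flat curve yields a zero-amplitude fit flagged accordingly.
Excluded bins are dropped, never interpolated; at least four usable bins
are required.

The null bound for an amplitude is obtained by fitting the same model to
permuted-data curves and taking the 95th percentile of those peaks (capped
at 200 fits by default). With small true amplitudes the fitted peak is
biased upward — the optimizer can chase a narrow noise bump — which is
exactly why observed peaks are compared against permuted-fit peaks, which
carry the same bias.

## Semantic similarity and super-groups

The pipeline consumes precomputed pairwise perceptual-distance scores
(long-format or square-matrix CSV; 0 = identical) such as deep
perceptual-similarity metrics produce; computing such scores with a neural
network is out of scope. For image matrices a classical multi-scale
filter-bank distance (`filter_bank_distance()`: three octaves, local
mean/gradient features, contrast normalization, mean squared feature
difference) is provided as a deterministic, documented metric in its own
right — it makes no claim of equivalence to any learned metric. Sequential
pairs are split at the mean score (strictly below = similar; ties go to
dissimilar); the threshold defaults to the mean over *sequential* pairs,
with an all-pairs option, since either reading of "mean similarity of all
image pairs" is defensible. The similar-minus-dissimilar cost contrast is
tested with the same order-permutation scheme, holding the observed
threshold fixed across permutations.

## Validation by parameter recovery, and problem sizes

The test suite validates the estimator against the generator:

* **Exactness** — per-bin confusion counts agree integer-for-integer with an
  independent brute-force loop on 100 randomized small tables.
* **Calibration** — with the bias switched off (`A1 = 0`; 50 users × 300
  trials, B = 500) the fraction of bins whose net change exceeds the 95%
  permutation bound stays near the nominal 5% for every metric.
* **Feature tuning** — under the default biased observer (100 users × 500
  trials) the fitted lag-1 error-rate Gaussian has its mean strictly inside
  (0, 200) — the "moderately similar" worst case — and its peak exceeds the
  permuted-peak bound.
* **Temporal tuning** — with geometric decay 0.55, fitted peaks strictly
  decrease over lags 1→4 in a majority of 10 replicates. The replicate size
  (2400 users × 500 trials) was fixed by a pre-run power analysis: the
  standard error of a fitted peak must sit well below the injected lag-3 vs
  lag-4 amplitude gap (≈ 0.2 percentage points), which requires roughly a
  million trials per replicate. With `rho = 0` (lag-1-only bias), lag-2–4
  peaks stay below their permuted-peak bounds.
* **Artifact control** — an always-same-response population shows net
  changes within the permutation bounds in ≥ 90% of bins: the future
  baseline absorbs pure stereotypy.

These checks are one-shot stochastic tests at fixed seeds; each 95%-bound
comparison carries its nominal false-alarm probability, which is inherent to
the design rather than a defect.

## Known limitations

* The analysis pools trials across users within each bin; user-level
  heterogeneity is averaged over, and no mixed-effects inference is offered.
* The criterion's cost direction is a magnitude, so its per-bin test has no
  sign information.
* Amplitude estimates at small effect sizes are upward-biased (see above);
  only the comparison against permuted-fit peaks, not the raw value, is
  calibrated.
* The exclusion pipeline's defaults cannot reproduce an undisclosed
  published preprocessing exactly; they are designed to be tuned against a
  known record count.
* Spatial tuning of serial dependence (position on screen) is not modeled
  or analyzed.
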