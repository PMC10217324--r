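# serialdep

Serial dependence in sequential binary diagnostic judgments.

When observers classify a stream of medical images one after another —
for example store-and-forward teledermatology readers deciding *benign*
vs. *malignant* for each skin-lesion image — their judgment on the current
image can be attracted toward recently seen images. This history bias is
*feature tuned* (strongest when successive stimuli are moderately similar,
absent for identical or very different ones) and *temporally tuned* (it
decays with lag). `serialdep` provides a tested pipeline to detect and
quantify this bias in trial-record tables, together with a synthetic
observer simulator that generates data with exactly the statistical
structure the analysis assumes, so the whole method can be validated by
parameter recovery.

## The method

Each stimulus carries a consensus malignancy score from a popularity vote
over independent raters,

    M = 100 * (n_malignant - n_benign) / n_voters  in [-100, 100],

so −100 means unanimously benign and 100 unanimously malignant. Performance
is measured with signal-detection metrics on the benign/malignant confusion
table (malignant = positive): sensitivity (hit rate) `HR = TP/(TP+FN)`,
specificity `TN/(TN+FP)`, error rate `(FN+FP)/total`, and

    d' = z(HR) - z(FAR),        c = -0.5 * (z(HR) + z(FAR)),

with `z` the inverse standard-normal CDF and `FAR = FP/(FP+TN)`. Rates of
exactly 0 or 1 are clamped to `1/(2N)` before the z-transform.

The serial-dependence analysis conditions each trial's outcome on its
n-back similarity `|M[t-n] - M[t]|`, grouped into 20 bins of width 10 over
[0, 200]. As a chance baseline the same metric is conditioned on the
*future* (N+1) trial's similarity — the future stimulus cannot influence
the present, so any structure it shows is artifact (response stereotypy,
marginal biases). The per-bin **net change** (past minus future) is tested
against a permutation null that shuffles trial order within user × session
while keeping stimulus–response pairs intact. Finally a scaled Gaussian

    f(x | a, mu, sigma) = a / sqrt(2 pi sigma^2) * exp(-(x - mu)^2 / (2 sigma^2))

is fitted to each net-change curve; its peak `a / sqrt(2 pi sigma^2)` is the
serial-dependence **amplitude**, assembled across lags 1–4 into the
temporal-decay summary. A parallel analysis splits sequential image pairs
into similar/dissimilar super-groups by a semantic (perceptual) similarity
score.

## Worked example

Simulate 100 observers × 500 trials from the default biased observer
(attractive bias of 0.5 evidence units at lag 1, tuning width 60 malignancy
units, geometric lag decay 0.55), then run the lag-1 analysis:

```r
library(serialdep)

cfg    <- sim_config(n_users = 100, trials_per_user = 500, seed = 42)
pool   <- generate_stimuli(cfg)
trials <- simulate_trials(pool, observer_params(), cfg)

sdt_summary(trials)[, c("sensitivity", "specificity", "d_prime", "criterion", "error_rate")]
#>   sensitivity specificity d_prime criterion error_rate
#> 1       0.770       0.757    1.44   -0.0212      0.237

res <- serial_dependence(trials, pool, lag = 1, n_permutations = 500, seed = 42)
fit_tuning(res, metric = "error_rate", null_peaks = TRUE)
#> Gaussian tuning fit [error_rate] lag 1
#>   a = 0.7024, mu = 87.88, sigma = 10, peak = 0.02802
#>   rss = 5.032, converged = TRUE, null peak 95% = 0.02259
```

The overall metrics show a competent observer (d′ ≈ 1.44, slightly liberal
criterion). The tuning fit says the error rate rises about 2.8 percentage
points above the future-trial baseline when the previous image is moderately
similar (Gaussian mean ≈ 88 on the 0–200 similarity axis), and that peak
exceeds the 95% bound of peaks fitted to permuted data — recovered serial
dependence, maximal at intermediate similarity, exactly as injected.
`autoplot(res)` draws the per-bin curves with their permutation bounds;
`amplitude_by_lag()` repeats the analysis across lags 1–4.

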